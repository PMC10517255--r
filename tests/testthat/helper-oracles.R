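# Independent oracles used across the test suite. These are deliberately
# brute-force / textbook implementations, kept separate from the package's
# own algorithms.

# Exhaustive-minimum parsimony: enumerate every labeling of the internal
# nodes and count state changes over edges. Masked leaves (NA) may take
# either state. Also returns the per-node set of states attained by at
# least one minimal labeling.
bruteParsimony <- function(tree, states) {
  nTip <- ape::Ntip(tree)
  nInt <- tree$Nnode
  n <- nTip + nInt
  e <- tree$edge
  leafStates <- states[tree$tip.label]
  maskedTips <- which(is.na(leafStates))
  freeNodes <- c(maskedTips, nTip + seq_len(nInt))
  best <- Inf
  sets <- matrix(FALSE, n, 2L)
  grid <- expand.grid(rep(list(0:1), length(freeNodes)))
  for (r in seq_len(nrow(grid))) {
    lab <- integer(n)
    lab[seq_len(nTip)] <- ifelse(is.na(leafStates), 0L, leafStates)
    lab[freeNodes] <- as.integer(grid[r, ])
    cost <- sum(lab[e[, 1]] != lab[e[, 2]])
    if (cost < best) {
      best <- cost
      sets[] <- FALSE
    }
    if (cost == best)
      sets[cbind(seq_len(n), lab + 1L)] <- TRUE
  }
  list(score = best, sets = sets)
}

# Exhaustive marginal posterior of state 1 at each node: sum the joint
# likelihood over every assignment of states to internal nodes (and masked
# leaves).
brutePosterior <- function(tree, states, model) {
  nTip <- ape::Ntip(tree)
  n <- nTip + tree$Nnode
  e <- tree$edge
  root <- nTip + 1L
  leafStates <- states[tree$tip.label]
  freeNodes <- c(which(is.na(leafStates)), nTip + seq_len(tree$Nnode))
  Pt <- lapply(seq_len(nrow(e)), function(i)
    uoxkit::transitionMatrix(model, tree$edge.length[i]))
  grid <- expand.grid(rep(list(0:1), length(freeNodes)))
  num <- numeric(n)
  den <- 0
  for (r in seq_len(nrow(grid))) {
    lab <- integer(n)
    lab[seq_len(nTip)] <- ifelse(is.na(leafStates), 0L, leafStates)
    lab[freeNodes] <- as.integer(grid[r, ])
    lik <- model$rootPrior[lab[root] + 1L]
    for (i in seq_len(nrow(e)))
      lik <- lik * Pt[[i]][lab[e[i, 1]] + 1L, lab[e[i, 2]] + 1L]
    den <- den + lik
    num[lab == 1L] <- num[lab == 1L] + lik
  }
  num / den
}

# Bateman cascade: closed-form concentrations for the irreversible chain
# A -> B -> C -> D with distinct rates and A(0) = a0.
batemanCascade <- function(k1, k2, k3, a0, times) {
  lam <- c(k1, k2, k3)
  stopifnot(length(unique(lam)) == 3L)
  A <- a0 * exp(-k1 * times)
  B <- a0 * k1 * (exp(-k1 * times) / (k2 - k1) +
                  exp(-k2 * times) / (k1 - k2))
  C <- a0 * k1 * k2 *
    (exp(-k1 * times) / ((k2 - k1) * (k3 - k1)) +
     exp(-k2 * times) / ((k1 - k2) * (k3 - k2)) +
     exp(-k3 * times) / ((k1 - k3) * (k2 - k3)))
  D <- a0 - A - B - C
  cbind(UA = A, UA2 = B, PIU = C, HIU = D)
}

# Step-doubling RK4 integrator for dc/dt = A c, independent of deSolve.
rk4Chain <- function(Amat, c0, times, dtMax = 1e-4) {
  f <- function(y) as.vector(Amat %*% y)
  out <- matrix(NA_real_, length(times), length(c0))
  y <- c0
  tcur <- 0
  for (i in seq_along(times)) {
    while (tcur < times[i] - 1e-15) {
      h <- min(dtMax, times[i] - tcur)
      k1 <- f(y); k2 <- f(y + h / 2 * k1)
      k3 <- f(y + h / 2 * k2); k4 <- f(y + h * k3)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      tcur <- tcur + h
    }
    out[i, ] <- y
  }
  colnames(out) <- names(c0)
  out
}

# Dense grid-search oracle for the Michaelis-Menten least-squares optimum.
gridMM <- function(S, v, KmGrid, VmaxGrid) {
  best <- c(Vmax = NA, Km = NA, rss = Inf)
  for (Km in KmGrid) for (Vmax in VmaxGrid) {
    rss <- sum((Vmax * S / (Km + S) - v)^2)
    if (rss < best["rss"]) best <- c(Vmax = Vmax, Km = Km, rss = rss)
  }
  best
}

# Write a toy orthogroup fixture (FASTA + membership + clade TSVs) into dir.
writeToyOrthoFiles <- function(dir,
                               seqs = c(s1 = "CCCC", s2 = "ACDE",
                                        s3 = "MMMM", s4 = "CCCA",
                                        s5 = "AAAA", s6 = "CDEF"),
                               members = data.frame(
                                 orthogroup_id = c("og1", "og1", "og1",
                                                   "og2", "og2", "og2"),
                                 species_id = c("spA", "spB", "spC",
                                                "spA", "spB", "spC"),
                                 sequence_id = c("s1", "s2", "s3",
                                                 "s4", "s5", "s6")),
                               clades = data.frame(
                                 species_id = c("spA", "spB", "spC"),
                                 clade = c("X", "X", "Y"))) {
  fa <- file.path(dir, "seqs.fasta")
  writeLines(paste0(">", names(seqs), "\n", seqs), fa)
  mem <- file.path(dir, "members.tsv")
  write.table(members, mem, sep = "\t", quote = FALSE, row.names = FALSE)
  cl <- file.path(dir, "clades.tsv")
  write.table(clades, cl, sep = "\t", quote = FALSE, row.names = FALSE)
  list(fasta = fa, membership = mem, clades = cl)
}

# Minimal composition SummarizedExperiment from a fraction matrix whose
# columns are sequences and rows the 20 amino acids.
makeCompSE <- function(fractions, orthogroup, species) {
  SummarizedExperiment::SummarizedExperiment(
    assays = list(fraction = fractions),
    colData = S4Vectors::DataFrame(orthogroup_id = orthogroup,
                                   species_id = species))
}

AA20_TEST <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
               "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Fraction matrix holding a chosen Cys fraction per sequence; remaining mass
# spread evenly over the other 19 residues.
cysFractionMatrix <- function(cys) {
  m <- matrix(rep((1 - cys) / 19, each = 20), nrow = 20,
              dimnames = list(AA20_TEST, NULL))
  m["C", ] <- cys
  m
}
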