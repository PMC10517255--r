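# Baseline amino-acid frequencies for synthetic vertebrate-like proteins:
# average vertebrate proteome composition, with cysteine pinned at 1% (the
# typical Uox-ortholog background against which a 5-fold enrichment is
# planted). Normalized to sum to 1.
baselineAAFreqs <- function() {
  f <- c(A = 7.4, C = 1.0, D = 5.9, E = 6.3, F = 4.0, G = 7.4, H = 2.9,
         I = 3.8, K = 7.2, L = 7.6, M = 1.8, N = 4.4, P = 5.0, Q = 3.7,
         R = 4.2, S = 8.1, T = 6.2, V = 6.8, W = 1.3, Y = 3.3)
  f[AA20] / sum(f)
}

#' Generate a clade-structured orthogroup dataset with planted shifts
#'
#' Draws per-sequence residues from clade/orthogroup-specific multinomials
#' over the 20 standard amino acids. Compositional shifts are planted as
#' (orthogroup, amino acid, clade, fold-change) tuples: the target residue's
#' baseline frequency is multiplied by the fold change and the vector
#' renormalized. Presence dropout and gene duplication can be injected; the
#' returned truth table records every planted shift, every orthogroup whose
#' realized presence falls below the 90% filter threshold, and every
#' multi-copy orthogroup. Sequences are i.i.d.-residue draws: there is no
#' phylogenetic autocorrelation within clades.
#'
#' @param nOrthogroups Number of orthogroups; default 30.
#' @param cladeSizes Named integer vector of species counts per clade;
#'   default 50 each of Sauropsida, Mammalia, Actinopterygii.
#' @param seqLength Sequence length (residues); default 2500, long enough
#'   that the sampling coefficient of variation of a 1% residue stays below
#'   20% per sequence.
#' @param baseFreqs Baseline amino-acid frequency vector (named, 20 long,
#'   sums to 1).
#' @param shifts `NULL` or a `data.frame` with columns `orthogroup_id`,
#'   `amino_acid`, `clade`, `fold` (fold > 0).
#' @param dropout Probability that an (orthogroup, species) entry is absent;
#'   default 0.
#' @param duplication Probability that a present entry carries a second gene
#'   copy; default 0.
#' @param seed RNG seed; the same seed and configuration give byte-identical
#'   output.
#' @param dir Optional directory: writes `sequences.fasta`,
#'   `membership.tsv`, `clades.tsv` in the formats [loadOrthogroups()]
#'   reads.
#' @return A list with `table` (an [OrthogroupSet-class]) and `truth` (list:
#'   `shifts`, `lowPresence`, `multiCopy`, plus the configuration).
#' @export
genOrthogroupDataset <- function(nOrthogroups = 30L,
                                 cladeSizes = c(Sauropsida = 50L,
                                                Mammalia = 50L,
                                                Actinopterygii = 50L),
                                 seqLength = 2500L,
                                 baseFreqs = baselineAAFreqs(),
                                 shifts = NULL,
                                 dropout = 0, duplication = 0,
                                 seed = 1L, dir = NULL) {
  stopifnot(nOrthogroups >= 1L, all(cladeSizes >= 1L), seqLength >= 1L,
            dropout >= 0, dropout < 1, duplication >= 0, duplication < 1)
  baseFreqs <- baseFreqs[AA20] / sum(baseFreqs[AA20])
  if (!is.null(shifts)) {
    need <- c("orthogroup_id", "amino_acid", "clade", "fold")
    stopifnot(is.data.frame(shifts), all(need %in% colnames(shifts)))
    if (any(shifts$fold <= 0)) stop("fold-change must be > 0")
    if (!all(shifts$clade %in% names(cladeSizes)))
      stop("shift clade(s) not in cladeSizes")
  }
  set.seed(seed)

  ogIds <- sprintf("OG%04d", seq_len(nOrthogroups))
  clades <- names(cladeSizes)
  species <- unlist(lapply(clades, function(cl)
    sprintf("%s_sp%02d", tolower(substr(cl, 1, 4)),
            seq_len(cladeSizes[[cl]]))), use.names = FALSE)
  speciesClade <- setNames(rep(clades, cladeSizes), species)

  freqFor <- function(og, clade) {
    f <- baseFreqs
    if (!is.null(shifts)) {
      hit <- shifts$orthogroup_id == og & shifts$clade == clade
      for (i in which(hit))
        f[shifts$amino_acid[i]] <- f[shifts$amino_acid[i]] * shifts$fold[i]
    }
    f / sum(f)
  }

  rows <- list()
  seqTexts <- character(0)
  seqNames <- character(0)
  for (og in ogIds) {
    for (sp in species) {
      if (dropout > 0 && runif(1) < dropout) next
      copies <- 1L + (duplication > 0 && runif(1) < duplication)
      f <- freqFor(og, speciesClade[[sp]])
      for (cp in seq_len(copies)) {
        res <- sample(AA20, seqLength, replace = TRUE, prob = f)
        sid <- sprintf("%s|%s%s", og, sp,
                       if (copies > 1L) paste0(".", cp) else "")
        seqNames <- c(seqNames, sid)
        seqTexts <- c(seqTexts, paste(res, collapse = ""))
        rows[[length(rows) + 1L]] <- c(og, sp, sid)
      }
    }
  }
  members <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  colnames(members) <- c("orthogroup_id", "species_id", "sequence_id")
  seqs <- AAStringSet(setNames(seqTexts, seqNames))
  tab <- new("OrthogroupSet", sequences = seqs, members = members,
             cladeMap = speciesClade, speciesUniverse = species)

  perOgSpecies <- table(members$orthogroup_id, members$species_id)
  nSpecies <- apply(perOgSpecies, 1L, function(r) sum(r > 0))
  multi <- rownames(perOgSpecies)[apply(perOgSpecies, 1L,
                                        function(r) any(r > 1))]
  truth <- list(
    shifts = shifts,
    lowPresence = names(nSpecies)[nSpecies < 0.9 * length(species)],
    multiCopy = multi,
    seed = seed, seqLength = seqLength, cladeSizes = cladeSizes,
    baseFreqs = baseFreqs)

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    Biostrings::writeXStringSet(seqs, file.path(dir, "sequences.fasta"))
    utils::write.table(members, file.path(dir, "membership.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(species_id = species,
                 clade = unname(speciesClade[species])),
      file.path(dir, "clades.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(table = tab, truth = truth)
}

#' Evolve a binary character history on a tree
#'
#' Simulates presence/absence of a residue along a rooted tree with branch
#' lengths under the two-state gain/loss chain: the root state is drawn from
#' the stationary distribution and each branch applies the exact two-state
#' transition probabilities for its length. Per-branch events are recorded
#' from the endpoint pair (a single-change-per-branch reading; with
#' `rate x length > 0.5` on some branch, multiple hits become likely and a
#' warning is emitted).
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param alpha,beta Gain and loss rates (>= 0, `alpha + beta > 0`).
#' @param nColumns Number of independent columns.
#' @param seed RNG seed.
#' @param residue Residue tag for the resulting [ColumnStates-class];
#'   default "C".
#' @return A list: `columns` (tip [ColumnStates-class]), `nodeStates` (full
#'   node x column matrix), `events` (per-branch `data.frame` with `parent`,
#'   `child`, `gains`, `losses`, `net`), `model` (the [twoStateModel()]).
#' @export
genCharacterHistory <- function(tree, alpha, beta, nColumns,
                                seed = 1L, residue = "C") {
  tree <- checkTree(tree, needLengths = TRUE)
  model <- twoStateModel(alpha, beta)
  if (max(c(alpha, beta)) * max(tree$edge.length) > 0.5)
    warning("rate x branch length > 0.5: endpoint event counts may ",
            "undercount multiple hits")
  set.seed(seed)
  n <- Ntip(tree) + tree$Nnode
  root <- Ntip(tree) + 1L
  st <- matrix(NA_integer_, n, nColumns,
               dimnames = list(nodeLabels(tree), NULL))
  st[root, ] <- stats::rbinom(nColumns, 1L, model$rootPrior[2])
  elen <- numeric(n)
  elen[tree$edge[, 2]] <- tree$edge.length
  parent <- integer(n)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  for (v in rev(postorderNodes(tree))) {
    if (v == root) next
    P <- transitionMatrix(model, elen[v])
    sp <- st[parent[v], ]
    p1 <- ifelse(sp == 1L, P[2, 2], P[1, 2])
    st[v, ] <- stats::rbinom(nColumns, 1L, p1)
  }
  e <- tree$edge
  gains <- integer(nrow(e))
  losses <- integer(nrow(e))
  for (i in seq_len(nrow(e))) {
    gains[i] <- sum(st[e[i, 1], ] == 0L & st[e[i, 2], ] == 1L)
    losses[i] <- sum(st[e[i, 1], ] == 1L & st[e[i, 2], ] == 0L)
  }
  tipStates <- st[seq_len(Ntip(tree)), , drop = FALSE]
  list(columns = new("ColumnStates", states = tipStates,
                     residue = residue),
       nodeStates = st,
       events = data.frame(parent = nodeLabels(tree)[e[, 1]],
                           child = nodeLabels(tree)[e[, 2]],
                           gains = gains, losses = losses,
                           net = gains - losses,
                           stringsAsFactors = FALSE),
       model = model)
}

#' Reference kinetic models for the two uricases
#'
#' Study conditions for the synthetic stopped-flow experiments, at 25 uM
#' initial urate (single-turnover). `drUoxLikeModel()` is the irreversible
#' chain with fast early steps and the rate-limiting final conversion at
#' 4.11 1/s, the regime where the HIU yield is complete.
#' `ggUoxLikeModel()` is the reversible chain with a final step biased
#' backwards (km3 > k3), which plateaus at roughly 20% HIU of the initial
#' urate; its early steps are fast enough to complete within a typical
#' stopped-flow dead time, so acquired spectra report on the PIU = HIU
#' conversion (only the final step is a quantitative anchor).
#'
#' @param ua0 Initial urate concentration (uM); default 25.
#' @return A [KineticModel-class].
#' @export
drUoxLikeModel <- function(ua0 = 25) {
  kineticModel(50, 20, 4.11,
               conc0 = c(UA = ua0, UA2 = 0, PIU = 0, HIU = 0))
}

#' @rdname drUoxLikeModel
#' @export
ggUoxLikeModel <- function(ua0 = 25) {
  kineticModel(3000, 1500, 1.5, km1 = 100, km2 = 50, km3 = 6,
               conc0 = c(UA = ua0, UA2 = 0, PIU = 0, HIU = 0))
}

#' Generate a noisy stopped-flow dataset with known truth
#'
#' Runs [simulateChain()] and [synthesizeSpectra()] and attaches the ground
#' truth (model and concentration profiles). Default design mirrors a
#' single-turnover stopped-flow run: 25 uM initial urate, log-spaced
#' acquisition times from 2 ms (just past a 1.5 ms instrument dead time),
#' additive Gaussian noise of 0.002 AU.
#'
#' @param model A [KineticModel-class]; default [ggUoxLikeModel()].
#' @param spectra A [speciesSpectra()] bundle;
#'   default [defaultSpeciesSpectra()].
#' @param times Acquisition times (s); default `logTimes(2e-3, 20, 150)`.
#' @param sigma Noise s.d. (AU); default 0.002.
#' @param seed RNG seed.
#' @return A list: `spectra` (a [SpectraMatrix-class]), `truth` (list with
#'   `model`, `profiles`, `times`, `sigma`).
#' @export
genStoppedFlowDataset <- function(model = ggUoxLikeModel(),
                                  spectra = defaultSpeciesSpectra(),
                                  times = logTimes(2e-3, 20, 150),
                                  sigma = 0.002, seed = 1L) {
  if (sigma < 0) stop("noise sigma must be >= 0")
  prof <- simulateChain(model, times)
  sm <- synthesizeSpectra(prof, times, spectra, sigma = sigma, seed = seed)
  list(spectra = sm,
       truth = list(model = model, profiles = prof, times = times,
                    sigma = sigma))
}

#' Generate a Michaelis-Menten initial-rate table
#'
#' Rates `v = kcat * E * S / (Km + S)` with multiplicative Gaussian noise
#' per replicate. The default substrate grid spans 2-140 uM, the range used
#' for uricase kinetic characterization.
#'
#' @param Km Michaelis constant (uM), > 0.
#' @param kcat Turnover number (1/s), > 0.
#' @param enzymeConc Enzyme concentration (uM).
#' @param S Substrate grid (uM); default `c(2, 5, 10, 20, 40, 80, 140)`.
#' @param cv Multiplicative noise coefficient of variation; default 0.02.
#' @param replicates Replicates per substrate level; default 3.
#' @param seed RNG seed.
#' @return A list: `data` (`data.frame` with `S`, `replicate`, `v`), `truth`
#'   (list with the parameters).
#' @export
genMMDataset <- function(Km, kcat, enzymeConc,
                         S = c(2, 5, 10, 20, 40, 80, 140),
                         cv = 0.02, replicates = 3L, seed = 1L) {
  stopifnot(Km > 0, kcat > 0, enzymeConc > 0, replicates >= 1L, cv >= 0)
  if (length(S) == 0L) stop("empty substrate grid")
  set.seed(seed)
  Sall <- rep(S, each = replicates)
  vTrue <- kcat * enzymeConc * Sall / (Km + Sall)
  v <- vTrue * (1 + rnorm(length(Sall), 0, cv))
  v <- pmax(v, 0)
  list(data = data.frame(S = Sall,
                         replicate = rep(seq_len(replicates), length(S)),
                         v = v),
       truth = list(Km = Km, kcat = kcat, enzymeConc = enzymeConc,
                    cv = cv, seed = seed))
}

#' Generate FOX-assay hydrogen peroxide standards
#'
#' A595 readings for H2O2 standards on a known line, with optional Gaussian
#' noise. Default concentrations are the four assay standards
#' 10, 25, 50, 100 uM.
#'
#' @param slope Line slope (AU/uM), > 0.
#' @param intercept Line intercept (AU).
#' @param sigma Additive noise s.d. (AU); default 0.
#' @param conc Standard concentrations (uM).
#' @param seed RNG seed.
#' @return A `data.frame` with columns `conc` and `a595`.
#' @export
genFoxStandards <- function(slope = 0.005, intercept = 0.04, sigma = 0,
                            conc = c(10, 25, 50, 100), seed = 1L) {
  if (slope <= 0) stop("slope must be > 0")
  if (sigma < 0) stop("noise sigma must be >= 0")
  set.seed(seed)
  data.frame(conc = conc,
             a595 = intercept + slope * conc +
               rnorm(length(conc), 0, sigma))
}
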