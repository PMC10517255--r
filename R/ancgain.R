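#' Binarize a protein alignment for one target residue
#'
#' Recodes every cell of a protein multiple alignment as 1 (target residue
#' present), 0 (any other residue) or masked (gap or ambiguity letter). Only
#' presence/absence of a single residue -- cysteine by default -- is tracked,
#' which is what per-branch gain/loss counting consumes.
#'
#' @param alignment An [Biostrings::AAStringSet] of aligned (equal-width)
#'   sequences, or a path to an aligned FASTA file.
#' @param residue Target residue letter; one of the 20 standard amino acids.
#' @return A [ColumnStates-class] object (taxa x columns).
#' @export
binarizeAlignment <- function(alignment, residue = "C") {
  if (is.character(alignment) && length(alignment) == 1L)
    alignment <- readAAStringSet(alignment)
  stopifnot(is(alignment, "AAStringSet"))
  if (length(unique(width(alignment))) != 1L)
    stop("ragged alignment: sequences have unequal lengths")
  if (length(residue) != 1L || !residue %in% AA20)
    stop("residue must be a single standard amino-acid letter")
  chars <- as.matrix(alignment)
  states <- matrix(NA_integer_, nrow(chars), ncol(chars),
                   dimnames = list(rownames(chars), NULL))
  std <- chars %in% AA20
  states[std] <- 0L
  states[chars == residue] <- 1L
  new("ColumnStates", states = states, residue = residue)
}

# ---- tree plumbing -------------------------------------------------------

# Validate a rooted ape tree and return it in postorder-friendly form with
# node labels filled in. Internal labels default to "node<N>".
checkTree <- function(tree, needLengths = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.rooted(tree)) stop("tree must be rooted")
  if (anyDuplicated(tree$tip.label)) stop("tip labels must be unique")
  if (needLengths) {
    if (is.null(tree$edge.length)) stop("tree has no branch lengths")
    if (any(tree$edge.length < 0)) stop("negative branch lengths")
  }
  if (is.null(tree$node.label) || !length(tree$node.label))
    tree$node.label <- paste0("node", seq_len(tree$Nnode) + Ntip(tree))
  empty <- !nzchar(tree$node.label)
  tree$node.label[empty] <-
    paste0("node", which(empty) + Ntip(tree))
  tree
}

nodeLabels <- function(tree) c(tree$tip.label, tree$node.label)

# Children list indexed by node number.
childrenList <- function(tree) {
  n <- Ntip(tree) + tree$Nnode
  kids <- vector("list", n)
  for (i in seq_len(nrow(tree$edge)))
    kids[[tree$edge[i, 1]]] <- c(kids[[tree$edge[i, 1]]], tree$edge[i, 2])
  kids
}

# Nodes in postorder (children before parents), derived from edge postorder.
postorderNodes <- function(tree) {
  e <- reorder.phylo(tree, "postorder")$edge
  unique(c(e[, 2], e[nrow(e), 1]))
}

# ---- parsimony -----------------------------------------------------------

# Unit-cost Sankoff down-pass: minimal changes in the subtree of each node
# conditional on its state. Masked tips cost 0 in either state. Returns an
# (Ntip + Nnode) x 2 matrix of costs for states 0 and 1.
sankoffDown <- function(tree, states) {
  n <- Ntip(tree) + tree$Nnode
  cost <- matrix(Inf, n, 2L)
  kids <- childrenList(tree)
  for (v in postorderNodes(tree)) {
    if (v <= Ntip(tree)) {
      s <- states[tree$tip.label[v]]
      cost[v, ] <- if (is.na(s)) c(0, 0) else
        if (s == 0L) c(0, Inf) else c(Inf, 0)
    } else {
      acc <- c(0, 0)
      for (ch in kids[[v]]) {
        trans0 <- min(cost[ch, 1L], cost[ch, 2L] + 1)
        trans1 <- min(cost[ch, 1L] + 1, cost[ch, 2L])
        acc <- acc + c(trans0, trans1)
      }
      cost[v, ] <- acc
    }
  }
  cost
}

#' Fitch/MPR parsimony for a binary alignment column
#'
#' Computes the parsimony score of a binary presence/absence column on a
#' rooted tree and, per node, the exact set of states attainable in at least
#' one most-parsimonious labeling (the MPR sets). Implemented as a unit-cost
#' dynamic program over the rooted tree: a postorder pass of conditional
#' subtree costs and a preorder pass of rest-of-tree costs; a state belongs
#' to a node's MPR set iff its combined cost attains the minimum. Masked
#' leaves (NA) are uninformative (state set \{0, 1\}).
#'
#' @param tree A rooted `phylo` tree (multifurcations allowed).
#' @param states Named integer vector of leaf states (0/1/NA), names matching
#'   `tree$tip.label`.
#' @return A list with `score` (integer), `stateSets` (an
#'   (Ntip + Nnode) x 2 logical matrix, `TRUE` where the state is in the MPR
#'   set; rows named by node label), and internal fields consumed by
#'   [acctranResolve()].
#' @export
fitchMPR <- function(tree, states) {
  tree <- checkTree(tree)
  states <- states[tree$tip.label]
  if (sum(!is.na(states)) < 2L)
    stop("fewer than 2 unmasked leaves")
  down <- sankoffDown(tree, states)
  n <- Ntip(tree) + tree$Nnode
  root <- Ntip(tree) + 1L
  kids <- childrenList(tree)
  parent <- integer(n)
  parent[tree$edge[, 2]] <- tree$edge[, 1]

  # preorder rest-of-tree costs
  up <- matrix(0, n, 2L)
  for (v in rev(postorderNodes(tree))) {
    if (v == root) next
    u <- parent[v]
    sib <- setdiff(kids[[u]], v)
    base <- up[u, ]
    for (w in sib) {
      base <- base + c(min(down[w, 1L], down[w, 2L] + 1),
                       min(down[w, 1L] + 1, down[w, 2L]))
    }
    up[v, ] <- c(min(base[1L], base[2L] + 1),
                 min(base[1L] + 1, base[2L]))
  }
  total <- down + up
  score <- min(total[root, ])
  sets <- total <= score + 1e-9
  rownames(sets) <- nodeLabels(tree)
  colnames(sets) <- c("0", "1")
  structure(list(score = as.integer(round(score)), stateSets = sets,
                 down = down, tree = tree, states = states),
            class = "fitchMPR")
}

#' ACCTRAN resolution of an MPR reconstruction
#'
#' Resolves ambiguous most-parsimonious state sets to a single optimal
#' labeling under accelerated transformation: nodes are visited in preorder
#' and, wherever both states remain optimal given the parent's resolved
#' state, the state differing from the parent is chosen, pushing changes as
#' close to the root as possible. At the root, ties resolve to state 0
#' (absence). The returned labeling always realizes exactly the parsimony
#' score.
#'
#' @param tree A rooted `phylo` tree (must match the one used for the MPR).
#' @param mpr A `fitchMPR` result from [fitchMPR()].
#' @return Named integer vector of states (0/1) over all nodes (tips
#'   included; masked tips receive their resolved state).
#' @export
acctranResolve <- function(tree, mpr) {
  stopifnot(inherits(mpr, "fitchMPR"))
  tree <- checkTree(tree)
  if (!identical(tree$edge, mpr$tree$edge))
    stop("tree does not match the one used in fitchMPR()")
  down <- mpr$down
  if (any(rowSums(mpr$stateSets) == 0L))
    stop("internal error: empty MPR state set")
  n <- Ntip(tree) + tree$Nnode
  root <- Ntip(tree) + 1L
  parent <- integer(n)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  res <- integer(n)

  pick <- function(costs, prefer) {
    best <- min(costs)
    cand <- which(costs <= best + 1e-9) - 1L   # states 0/1
    if (length(cand) == 1L) cand else prefer
  }
  for (v in rev(postorderNodes(tree))) {
    if (v == root) {
      # root tie resolves to absence (state 0)
      res[v] <- pick(down[v, ], prefer = 0L)
    } else {
      sp <- res[parent[v]]
      costs <- down[v, ] + c(0L + (sp != 0L), 0L + (sp != 1L))
      res[v] <- pick(costs, prefer = 1L - sp)   # prefer a change (ACCTRAN)
    }
  }
  setNames(res, nodeLabels(tree))
}

# ---- two-state likelihood ------------------------------------------------

#' Two-state gain/loss model
#'
#' Continuous-time two-state Markov model for residue presence: gain rate
#' `alpha` (0 -> 1) and loss rate `beta` (1 -> 0), both per unit branch
#' length. The root prior defaults to the stationary distribution
#' (beta, alpha) / (alpha + beta).
#'
#' @param alpha,beta Non-negative rates with `alpha + beta > 0`.
#' @param rootPrior Optional length-2 probability vector over states (0, 1);
#'   `NULL` means stationary.
#' @return A list of class `TwoStateModel`.
#' @export
twoStateModel <- function(alpha, beta, rootPrior = NULL) {
  if (alpha < 0 || beta < 0) stop("rates must be >= 0")
  if (alpha + beta <= 0) stop("zero total rate")
  if (is.null(rootPrior))
    rootPrior <- c(beta, alpha) / (alpha + beta)
  stopifnot(length(rootPrior) == 2L, all(rootPrior >= 0),
            abs(sum(rootPrior) - 1) < 1e-9)
  structure(list(alpha = alpha, beta = beta, rootPrior = rootPrior),
            class = "TwoStateModel")
}

#' Two-state transition probability matrix
#'
#' Closed-form transition probabilities of the gain/loss chain over branch
#' length `t`: `P[i+1, j+1] = P(state j at the end | state i at the start)`.
#'
#' @param model A [twoStateModel()].
#' @param t Non-negative branch length.
#' @return A 2 x 2 stochastic matrix.
#' @export
transitionMatrix <- function(model, t) {
  r <- model$alpha + model$beta
  e <- exp(-r * t)
  p0 <- model$beta / r    # stationary P(0)
  p1 <- model$alpha / r
  matrix(c(p0 + p1 * e, p1 * (1 - e),
           p0 * (1 - e), p1 + p0 * e),
         2L, 2L, byrow = TRUE)
}

# Partial (conditional) likelihoods by the pruning algorithm, postorder.
pruneDown <- function(tree, states, model) {
  n <- Ntip(tree) + tree$Nnode
  L <- matrix(1, n, 2L)
  kids <- childrenList(tree)
  elen <- numeric(n)
  elen[tree$edge[, 2]] <- tree$edge.length
  for (v in postorderNodes(tree)) {
    if (v <= Ntip(tree)) {
      s <- states[tree$tip.label[v]]
      if (!is.na(s)) L[v, ] <- if (s == 0L) c(1, 0) else c(0, 1)
    } else {
      acc <- c(1, 1)
      for (ch in kids[[v]]) {
        P <- transitionMatrix(model, elen[ch])
        acc <- acc * as.vector(P %*% L[ch, ])
      }
      L[v, ] <- acc
    }
  }
  list(L = L, elen = elen, kids = kids)
}

#' Marginal ancestral posteriors for a binary column
#'
#' Marginal posterior probability of residue presence at every node of a
#' rooted tree with branch lengths, under the two-state gain/loss model.
#' Computed by the pruning algorithm: one postorder pass of conditional
#' (below) likelihoods and one preorder pass combining the likelihood of the
#' rest of the tree, so each node's posterior integrates over all other
#' nodes. Masked leaves carry partials (1, 1).
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param states Named leaf states (0/1/NA).
#' @param model A [twoStateModel()].
#' @return Named numeric vector: posterior probability of state 1 per node
#'   (tips included; an unmasked tip has posterior equal to its state).
#' @export
mlMarginal <- function(tree, states, model) {
  tree <- checkTree(tree, needLengths = TRUE)
  states <- states[tree$tip.label]
  if (all(is.na(states))) stop("all leaves masked")
  pd <- pruneDown(tree, states, model)
  n <- Ntip(tree) + tree$Nnode
  root <- Ntip(tree) + 1L
  parent <- integer(n)
  parent[tree$edge[, 2]] <- tree$edge[, 1]

  above <- matrix(1, n, 2L)
  above[root, ] <- model$rootPrior
  for (v in rev(postorderNodes(tree))) {
    if (v == root) next
    u <- parent[v]
    sib <- setdiff(pd$kids[[u]], v)
    ctx <- above[u, ]
    for (w in sib) {
      P <- transitionMatrix(model, pd$elen[w])
      ctx <- ctx * as.vector(P %*% pd$L[w, ])
    }
    P <- transitionMatrix(model, pd$elen[v])
    above[v, ] <- as.vector(ctx %*% P)
  }
  post <- above * pd$L
  post1 <- post[, 2L] / rowSums(post)
  setNames(post1, nodeLabels(tree))
}

#' Joint maximum-likelihood ancestral states for a binary column
#'
#' The single most probable joint assignment of states to all internal nodes
#' (max-product pruning with backtracking), as opposed to the per-node
#' marginal of [mlMarginal()].
#'
#' @inheritParams mlMarginal
#' @return Named integer vector of states (0/1) over all nodes.
#' @export
mlJoint <- function(tree, states, model) {
  tree <- checkTree(tree, needLengths = TRUE)
  states <- states[tree$tip.label]
  if (all(is.na(states))) stop("all leaves masked")
  n <- Ntip(tree) + tree$Nnode
  root <- Ntip(tree) + 1L
  kids <- childrenList(tree)
  elen <- numeric(n)
  elen[tree$edge[, 2]] <- tree$edge.length

  M <- matrix(0, n, 2L)       # max log-likelihood of subtree given state
  back <- array(0L, c(n, 2L)) # best child-state pointer is per child; store
  bptr <- vector("list", n)   # list: per node, 2 x nchildren best states
  for (v in postorderNodes(tree)) {
    if (v <= Ntip(tree)) {
      s <- states[tree$tip.label[v]]
      M[v, ] <- if (is.na(s)) c(0, 0) else
        if (s == 0L) c(0, -Inf) else c(-Inf, 0)
    } else {
      ch <- kids[[v]]
      ptr <- matrix(0L, 2L, length(ch))
      acc <- c(0, 0)
      for (j in seq_along(ch)) {
        P <- log(transitionMatrix(model, elen[ch[j]]))
        for (s in 1:2) {
          vals <- P[s, ] + M[ch[j], ]
          ptr[s, j] <- which.max(vals)
          acc[s] <- acc[s] + max(vals)
        }
      }
      M[v, ] <- acc
      bptr[[v]] <- ptr
    }
  }
  res <- integer(n)
  res[root] <- which.max(log(model$rootPrior) + M[root, ]) - 1L
  for (v in rev(postorderNodes(tree))) {
    if (v <= Ntip(tree) || is.null(bptr[[v]])) next
    ch <- kids[[v]]
    for (j in seq_along(ch))
      res[ch[j]] <- bptr[[v]][res[v] + 1L, j] - 1L
  }
  # observed tips keep their state
  obs <- !is.na(states)
  res[seq_len(Ntip(tree))][obs] <- states[obs]
  setNames(res, nodeLabels(tree))
}

#' Ancestral states over all alignment columns
#'
#' Runs one reconstruction method over every column of a
#' [ColumnStates-class] object and returns a full node x column state matrix
#' (plus posteriors for the probabilistic methods). Methods: `"mpr"`
#' (Fitch/MPR with ACCTRAN applied so a single labeling is returned),
#' `"mpr_acctran"` (identical resolution, kept as a distinct tag),
#' `"ml"` (joint max-product reconstruction) and `"bayes"` (marginal
#' highest-posterior state per node). Columns with fewer than two unmasked
#' leaves are skipped with a warning and contribute all-NA states (hence no
#' events downstream).
#'
#' @param tree Rooted `phylo`; branch lengths required for `"ml"`/`"bayes"`.
#' @param columns A [ColumnStates-class].
#' @param method One of `"mpr"`, `"mpr_acctran"`, `"ml"`, `"bayes"`.
#' @param model A [twoStateModel()] (probabilistic methods only).
#' @param threshold Posterior threshold for calling state 1 under `"bayes"`;
#'   default 0.5. Exact ties at the threshold resolve to the parent's state
#'   when events are counted.
#' @return A list with `states` (node x column integer matrix, rows named by
#'   node label), `posterior` (same shape, `"ml"`/`"bayes"` only), `method`,
#'   and `skipped` (indices of skipped columns).
#' @export
ancestralStates <- function(tree, columns,
                            method = c("mpr", "mpr_acctran", "ml", "bayes"),
                            model = NULL, threshold = 0.5) {
  method <- match.arg(method)
  probabilistic <- method %in% c("ml", "bayes")
  tree <- checkTree(tree, needLengths = probabilistic)
  stopifnot(is(columns, "ColumnStates"))
  if (probabilistic && is.null(model))
    stop("method '", method, "' needs a twoStateModel()")
  sm <- stateMatrix(columns)
  missingTips <- setdiff(tree$tip.label, rownames(sm))
  if (length(missingTips))
    stop("alignment rows missing for tips: ",
         paste(head(missingTips, 5), collapse = ", "))
  nNode <- Ntip(tree) + tree$Nnode
  nCol <- ncol(sm)
  res <- matrix(NA_integer_, nNode, nCol,
                dimnames = list(nodeLabels(tree), NULL))
  post <- if (probabilistic)
    matrix(NA_real_, nNode, nCol, dimnames = dimnames(res)) else NULL
  skipped <- integer()
  for (j in seq_len(nCol)) {
    st <- setNames(sm[tree$tip.label, j], tree$tip.label)
    if (sum(!is.na(st)) < 2L) {
      skipped <- c(skipped, j)
      next
    }
    if (method %in% c("mpr", "mpr_acctran")) {
      res[, j] <- acctranResolve(tree, fitchMPR(tree, st))
    } else if (method == "ml") {
      res[, j] <- mlJoint(tree, st, model)
      post[, j] <- mlMarginal(tree, st, model)
    } else {
      p <- mlMarginal(tree, st, model)
      post[, j] <- p
      res[, j] <- as.integer(p > threshold)
      res[abs(p - threshold) < 1e-12, j] <- NA_integer_  # tie: defer to parent
    }
    # observed tip states always override
    obs <- !is.na(st)
    res[seq_len(Ntip(tree)), j][obs] <- st[obs]
  }
  if (length(skipped))
    warning(length(skipped), " column(s) with < 2 unmasked leaves skipped")
  list(states = res, posterior = post, method = method, tree = tree,
       threshold = threshold, skipped = skipped)
}

#' Per-branch gain/loss event counts
#'
#' Counts, for every branch (parent -> child) of the tree, the number of
#' alignment columns with a 0 -> 1 transition (gain) and a 1 -> 0 transition
#' (loss), and their difference (net enrichment). Nodes left without a state
#' in a column (skipped columns, masked tips, posterior ties) inherit the
#' parent's state, hence contribute no event on that branch.
#'
#' @param tree Rooted `phylo` (must match the reconstruction).
#' @param assignment Result of [ancestralStates()].
#' @param perColumn Also return the per-column event list (for residue-level
#'   gain/loss tracking along branches).
#' @return A `data.frame` with columns `parent`, `child`, `gains`, `losses`,
#'   `net`, `method`; one row per branch, ordered as `tree$edge`. With
#'   `perColumn = TRUE`, an attribute `"events"` holds a `data.frame` of
#'   (branch, column, type).
#' @export
branchEvents <- function(tree, assignment, perColumn = FALSE) {
  tree <- checkTree(tree)
  st <- assignment$states
  if (is.null(st)) stop("assignment has no state matrix")
  if (!identical(rownames(st), nodeLabels(tree)))
    stop("assignment does not match tree node labels")
  if (any(is.na(st))) {
    # inherit parent's state downwards so unresolved cells make no events
    for (v in rev(postorderNodes(tree))) {
      if (v == Ntip(tree) + 1L) next
      p <- tree$edge[match(v, tree$edge[, 2]), 1]
      miss <- is.na(st[v, ])
      st[v, miss] <- st[p, miss]
    }
  }
  e <- tree$edge
  gains <- integer(nrow(e))
  losses <- integer(nrow(e))
  evList <- list()
  for (i in seq_len(nrow(e))) {
    sp <- st[e[i, 1], ]
    sc <- st[e[i, 2], ]
    g <- which(!is.na(sp) & !is.na(sc) & sp == 0L & sc == 1L)
    l <- which(!is.na(sp) & !is.na(sc) & sp == 1L & sc == 0L)
    gains[i] <- length(g)
    losses[i] <- length(l)
    if (perColumn && (length(g) || length(l)))
      evList[[length(evList) + 1L]] <- data.frame(
        parent = nodeLabels(tree)[e[i, 1]],
        child = nodeLabels(tree)[e[i, 2]],
        column = c(g, l),
        type = rep(c("gain", "loss"), c(length(g), length(l))),
        stringsAsFactors = FALSE)
  }
  out <- data.frame(
    parent = nodeLabels(tree)[e[, 1]],
    child = nodeLabels(tree)[e[, 2]],
    gains = gains, losses = losses, net = gains - losses,
    method = assignment$method,
    stringsAsFactors = FALSE)
  if (perColumn)
    attr(out, "events") <- if (length(evList))
      do.call(rbind, evList) else
      data.frame(parent = character(), child = character(),
                 column = integer(), type = character())
  out
}
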