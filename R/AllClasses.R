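#' OrthogroupSet: orthologous protein sequences with clade labels
#'
#' Container for a set of orthogroups. Each orthogroup maps species to one or
#' more protein sequences; every species carries a clade label (e.g. Mammalia,
#' Sauropsida, Actinopterygii). The species universe against which presence is
#' judged is the full set of species in the clade map, not merely the species
#' observed in the data, so a "present in 90% of species" filter is
#' deterministic.
#'
#' @slot sequences An [Biostrings::AAStringSet] holding all protein sequences,
#'   named by sequence id.
#' @slot members A `data.frame` with columns `orthogroup_id`, `species_id`,
#'   `sequence_id`; one row per sequence membership. Duplicate
#'   (orthogroup, species) pairs denote multi-copy genes.
#' @slot cladeMap Named character vector: species id -> clade label.
#' @slot speciesUniverse Character vector of all species ids considered.
#'
#' @seealso [loadOrthogroups()], [filterOrthogroups()], [computeComposition()]
#' @export
setClass("OrthogroupSet",
  representation(
    sequences = "AAStringSet",
    members = "data.frame",
    cladeMap = "character",
    speciesUniverse = "character"
  )
)

setValidity("OrthogroupSet", function(object) {
  msg <- character()
  need <- c("orthogroup_id", "species_id", "sequence_id")
  if (!all(need %in% colnames(object@members)))
    msg <- c(msg, paste("members must have columns",
                        paste(need, collapse = ", ")))
  else {
    bad <- setdiff(object@members$species_id, names(object@cladeMap))
    if (length(bad))
      msg <- c(msg, paste("species without clade label:",
                          paste(head(bad, 5), collapse = ", ")))
    bad <- setdiff(object@members$sequence_id, names(object@sequences))
    if (length(bad))
      msg <- c(msg, paste("sequence ids missing from sequences:",
                          paste(head(bad, 5), collapse = ", ")))
  }
  if (length(object@sequences)) {
    if (any(width(object@sequences) == 0L))
      msg <- c(msg, "empty sequences are not allowed")
    alpha <- Biostrings::uniqueLetters(object@sequences)
    bad <- setdiff(alpha, c(AA20, AA_AMBIGUOUS))
    if (length(bad))
      msg <- c(msg, paste("disallowed residue letters:",
                          paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(object@speciesUniverse))
    msg <- c(msg, "speciesUniverse must be unique")
  if (length(msg)) msg else TRUE
})

#' @describeIn OrthogroupSet-class Number of orthogroups.
#' @param x,object An `OrthogroupSet`.
#' @export
nOrthogroups <- function(x) length(unique(x@members$orthogroup_id))

#' Accessors for OrthogroupSet
#'
#' `cladeMap()` returns the named species -> clade vector,
#' `speciesUniverse()` the full species id set, `orthogroupMembers()` the
#' membership table, and `orthogroupSequences()` the underlying
#' `AAStringSet`.
#'
#' @param x An `OrthogroupSet`.
#' @return See description.
#' @export
cladeMap <- function(x) {
  stopifnot(is(x, "OrthogroupSet"))
  x@cladeMap
}

#' @rdname cladeMap
#' @export
speciesUniverse <- function(x) {
  stopifnot(is(x, "OrthogroupSet"))
  x@speciesUniverse
}

#' @rdname cladeMap
#' @export
orthogroupMembers <- function(x) {
  stopifnot(is(x, "OrthogroupSet"))
  x@members
}

#' @rdname cladeMap
#' @export
orthogroupSequences <- function(x) {
  stopifnot(is(x, "OrthogroupSet"))
  x@sequences
}

setMethod("show", "OrthogroupSet", function(object) {
  cat("OrthogroupSet with", nOrthogroups(object), "orthogroups,",
      length(object@sequences), "sequences,",
      length(object@speciesUniverse), "species universe,",
      length(unique(object@cladeMap)), "clades\n")
})

#' ColumnStates: binarized alignment columns for one target residue
#'
#' Presence/absence matrix of a target residue across the columns of a protein
#' multiple alignment. Cells are 1 where the taxon holds the target residue in
#' that column, 0 where it holds any other residue, and NA where the cell is a
#' gap or ambiguity letter (masked).
#'
#' @slot states Integer matrix, taxa x columns, values in {0, 1, NA}.
#' @slot residue Single target residue letter (default "C").
#'
#' @seealso [binarizeAlignment()], [ancestralStates()], [branchEvents()]
#' @export
setClass("ColumnStates",
  representation(states = "matrix", residue = "character")
)

setValidity("ColumnStates", function(object) {
  msg <- character()
  v <- object@states
  if (!all(v %in% c(0L, 1L, NA)))
    msg <- c(msg, "states must be 0, 1 or NA")
  if (is.null(rownames(v)))
    msg <- c(msg, "states must have taxon rownames")
  if (length(object@residue) != 1L || !object@residue %in% AA20)
    msg <- c(msg, "residue must be a single standard amino-acid letter")
  if (length(msg)) msg else TRUE
})

#' @describeIn ColumnStates-class The taxa x columns state matrix
#'   (NA = masked).
#' @param x A `ColumnStates` object.
#' @export
stateMatrix <- function(x) {
  stopifnot(is(x, "ColumnStates"))
  x@states
}

setMethod("show", "ColumnStates", function(object) {
  cat("ColumnStates for residue", object@residue, ":",
      nrow(object@states), "taxa x", ncol(object@states), "columns;",
      sum(is.na(object@states)), "masked cells\n")
})

#' KineticModel: the four-species uricase reaction chain
#'
#' First-order sequential chain UA = UA2- = PIU = HIU describing uricase
#' catalysis under single-turnover, enzyme-excess conditions (the enzyme is
#' not modelled explicitly; all steps are pseudo-first-order). Forward rate
#' constants k1, k2, k3 and reverse rate constants km1, km2, km3 in 1/s;
#' in the irreversible variant all reverse constants are zero.
#'
#' @slot kf Numeric length-3 forward rate constants (1/s).
#' @slot kr Numeric length-3 reverse rate constants (1/s).
#' @slot conc0 Named numeric length-4 initial concentrations (uM), in the
#'   order UA, UA2, PIU, HIU.
#' @slot reversible Logical flag.
#'
#' @seealso [kineticModel()], [simulateChain()], [fitChainModel()]
#' @export
setClass("KineticModel",
  representation(kf = "numeric", kr = "numeric", conc0 = "numeric",
                 reversible = "logical")
)

setValidity("KineticModel", function(object) {
  msg <- character()
  if (length(object@kf) != 3L || length(object@kr) != 3L)
    msg <- c(msg, "kf and kr must each have length 3")
  if (any(object@kf < 0) || any(object@kr < 0))
    msg <- c(msg, "rate constants must be >= 0")
  if (length(object@conc0) != 4L || any(object@conc0 < 0))
    msg <- c(msg, "conc0 must be 4 non-negative concentrations")
  if (!identical(names(object@conc0), SPECIES_NAMES))
    msg <- c(msg, "conc0 must be named UA, UA2, PIU, HIU")
  if (!object@reversible && any(object@kr > 0))
    msg <- c(msg, "irreversible model must have all reverse rates zero")
  if (length(msg)) msg else TRUE
})

SPECIES_NAMES <- c("UA", "UA2", "PIU", "HIU")

#' Construct a KineticModel
#'
#' @param k1,k2,k3 Forward rate constants (1/s) for UA -> UA2-,
#'   UA2- -> PIU and PIU -> HIU.
#' @param km1,km2,km3 Reverse rate constants (1/s); default 0 (irreversible).
#' @param conc0 Initial concentrations (uM) as a length-4 vector in the order
#'   UA, UA2-, PIU, HIU; default 25 uM urate, matching single-turnover
#'   stopped-flow conditions.
#' @param reversible Logical; defaults to `TRUE` whenever a reverse rate is
#'   nonzero.
#' @return A [KineticModel-class] object.
#' @examples
#' m <- kineticModel(50, 20, 4.11)
#' simulateChain(m, c(0, 0.1, 1))
#' @export
kineticModel <- function(k1, k2, k3, km1 = 0, km2 = 0, km3 = 0,
                         conc0 = c(UA = 25, UA2 = 0, PIU = 0, HIU = 0),
                         reversible = any(c(km1, km2, km3) > 0)) {
  conc0 <- setNames(as.numeric(conc0), SPECIES_NAMES)
  new("KineticModel", kf = c(k1, k2, k3), kr = c(km1, km2, km3),
      conc0 = conc0, reversible = reversible)
}

setMethod("show", "KineticModel", function(object) {
  cat(if (object@reversible) "Reversible" else "Irreversible",
      "3-step chain UA = UA2- = PIU = HIU\n")
  cat("  forward (1/s):", paste(signif(object@kf, 4), collapse = ", "), "\n")
  cat("  reverse (1/s):", paste(signif(object@kr, 4), collapse = ", "), "\n")
  cat("  conc0 (uM):",
      paste(names(object@conc0), signif(object@conc0, 4),
            sep = "=", collapse = ", "), "\n")
})

#' SpectraMatrix: time-resolved absorbance spectra
#'
#' A times x wavelengths absorbance matrix (AU) as acquired in stopped-flow
#' photodiode-array experiments. Times must be strictly increasing and are
#' typically log-spaced.
#'
#' @slot times Numeric vector of acquisition times (s), strictly increasing.
#' @slot wavelengths Numeric vector of wavelengths (nm).
#' @slot absorbance Numeric matrix, length(times) x length(wavelengths).
#' @slot sigma Numeric; additive Gaussian noise s.d. used to generate the
#'   matrix (NA for real data).
#'
#' @seealso [synthesizeSpectra()], [svdComponents()], [readSpectraCSV()]
#' @export
setClass("SpectraMatrix",
  representation(times = "numeric", wavelengths = "numeric",
                 absorbance = "matrix", sigma = "numeric")
)

setValidity("SpectraMatrix", function(object) {
  msg <- character()
  if (any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (!identical(dim(object@absorbance),
                 c(length(object@times), length(object@wavelengths))))
    msg <- c(msg, "absorbance must be length(times) x length(wavelengths)")
  if (length(msg)) msg else TRUE
})

#' @describeIn SpectraMatrix-class Extract the absorbance matrix with times as
#'   rownames and wavelengths as colnames.
#' @param x A `SpectraMatrix`.
#' @export
absorbanceMatrix <- function(x) {
  stopifnot(is(x, "SpectraMatrix"))
  m <- x@absorbance
  dimnames(m) <- list(format(x@times, trim = TRUE), x@wavelengths)
  m
}

#' @rdname absorbanceMatrix
#' @export
spectraTimes <- function(x) {
  stopifnot(is(x, "SpectraMatrix"))
  x@times
}

#' @rdname absorbanceMatrix
#' @export
spectraWavelengths <- function(x) {
  stopifnot(is(x, "SpectraMatrix"))
  x@wavelengths
}

setMethod("show", "SpectraMatrix", function(object) {
  cat("SpectraMatrix:", length(object@times), "times x",
      length(object@wavelengths), "wavelengths;",
      "t =", signif(min(object@times), 3), "-",
      signif(max(object@times), 3), "s;",
      "lambda =", min(object@wavelengths), "-",
      max(object@wavelengths), "nm\n")
})
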