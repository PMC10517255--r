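#' Load orthogroups from FASTA + membership + clade tables
#'
#' Reads protein sequences (FASTA), an orthogroup membership table (TSV with
#' header columns `orthogroup_id`, `species_id`, `sequence_id`) and a clade
#' map (TSV with header columns `species_id`, `clade`) into an
#' [OrthogroupSet-class]. Duplicate (orthogroup, species) rows are retained as
#' multi-copy entries; filtering is a separate step
#' ([filterOrthogroups()]).
#'
#' @param sequencesPath Path to a protein FASTA file. Header ids must be
#'   unique.
#' @param membershipPath Path to the membership TSV.
#' @param cladesPath Path to the clade map TSV.
#' @return An [OrthogroupSet-class]. The species universe is the full set of
#'   species in the clade map.
#' @export
loadOrthogroups <- function(sequencesPath, membershipPath, cladesPath) {
  seqs <- readAAStringSet(sequencesPath)
  if (length(seqs) == 0L)
    stop("no sequences in FASTA file '", sequencesPath, "'")
  # keep only the first whitespace-delimited token of each header
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  dup <- names(seqs)[duplicated(names(seqs))]
  if (length(dup))
    stop("duplicated FASTA header id(s): ",
         paste(unique(head(dup, 5)), collapse = ", "))

  members <- read.delim(membershipPath, header = TRUE,
                        colClasses = "character")
  if (nrow(members) == 0L)
    stop("empty membership table '", membershipPath, "'")
  need <- c("orthogroup_id", "species_id", "sequence_id")
  if (!all(need %in% colnames(members)))
    stop("membership table must have columns ", paste(need, collapse = ", "))
  members <- members[, need]
  missing <- setdiff(members$sequence_id, names(seqs))
  if (length(missing))
    stop("sequence id(s) absent from FASTA: ",
         paste(head(missing, 5), collapse = ", "))

  clades <- read.delim(cladesPath, header = TRUE, colClasses = "character")
  if (nrow(clades) == 0L)
    stop("empty clade map '", cladesPath, "'")
  if (!all(c("species_id", "clade") %in% colnames(clades)))
    stop("clade map must have columns species_id, clade")
  cmap <- setNames(clades$clade, clades$species_id)
  orphan <- setdiff(members$species_id, names(cmap))
  if (length(orphan))
    stop("species without clade label: ",
         paste(head(orphan, 5), collapse = ", "))

  new("OrthogroupSet",
      sequences = seqs[unique(members$sequence_id)],
      members = members,
      cladeMap = cmap,
      speciesUniverse = unique(names(cmap)))
}

#' Filter orthogroups on single-copy status and species presence
#'
#' Retains orthogroups in which (a) every represented species has exactly one
#' sequence (when `requireSingleCopy`) and (b) the number of represented
#' species is at least `minPresence` of the species universe. This reproduces
#' the standard "single copy, present in 90% of species" orthogroup selection.
#'
#' @param x An [OrthogroupSet-class].
#' @param minPresence Minimum fraction of the species universe that must be
#'   represented; in (0, 1]. Default 0.9.
#' @param requireSingleCopy Drop orthogroups with any multi-copy species.
#'   Default `TRUE`.
#' @return A new, filtered `OrthogroupSet`; the input is unmodified.
#' @export
filterOrthogroups <- function(x, minPresence = 0.9,
                              requireSingleCopy = TRUE) {
  stopifnot(is(x, "OrthogroupSet"))
  if (!is.numeric(minPresence) || length(minPresence) != 1L ||
      minPresence <= 0 || minPresence > 1)
    stop("minPresence must be in (0, 1]")
  if (length(x@speciesUniverse) == 0L)
    stop("empty species universe")
  m <- x@members
  if (nrow(m) == 0L) return(x)

  counts <- table(m$orthogroup_id, m$species_id)
  singleCopy <- apply(counts, 1L, function(r) all(r <= 1L))
  nSpecies <- apply(counts, 1L, function(r) sum(r > 0L))
  keepOg <- rownames(counts)[
    (!requireSingleCopy | singleCopy) &
      nSpecies >= minPresence * length(x@speciesUniverse)]
  m2 <- m[m$orthogroup_id %in% keepOg, , drop = FALSE]
  rownames(m2) <- NULL
  new("OrthogroupSet",
      sequences = x@sequences[unique(m2$sequence_id)],
      members = m2, cladeMap = x@cladeMap,
      speciesUniverse = x@speciesUniverse)
}

#' Per-sequence amino-acid composition
#'
#' Computes, for every membership row of an [OrthogroupSet-class], the count
#' and length-normalized fraction of each of the 20 standard amino acids.
#' Ambiguity letters (X, B, Z, U, J, O) and the stop symbol are excluded from
#' both numerator and denominator; their tally is kept per row. Fractions per
#' row therefore sum to 1 over the 20 standard residues.
#'
#' @param x An [OrthogroupSet-class] with at least one membership row.
#' @return A [SummarizedExperiment::SummarizedExperiment] with 20 rows (amino
#'   acids, alphabetical one-letter order) and one column per sequence
#'   membership; assays `count` and `fraction`; column data `orthogroup_id`,
#'   `species_id`, `sequence_id`, `counted_length`, `excluded`.
#' @export
computeComposition <- function(x) {
  stopifnot(is(x, "OrthogroupSet"))
  m <- x@members
  if (nrow(m) == 0L) stop("empty OrthogroupSet")
  seqs <- x@sequences[m$sequence_id]
  counts <- t(letterFrequency(seqs, letters = AA20))
  countedLength <- colSums(counts)
  if (any(countedLength == 0L))
    stop("sequence(s) with zero standard residues: ",
         paste(head(m$sequence_id[countedLength == 0L], 5), collapse = ", "))
  frac <- sweep(counts, 2L, countedLength, "/")
  cd <- DataFrame(
    orthogroup_id = m$orthogroup_id,
    species_id = m$species_id,
    sequence_id = m$sequence_id,
    counted_length = as.integer(countedLength),
    excluded = as.integer(width(seqs) - countedLength)
  )
  colnames(counts) <- colnames(frac) <-
    make.unique(paste(m$orthogroup_id, m$sequence_id, sep = "|"))
  SummarizedExperiment(
    assays = list(count = counts, fraction = frac),
    colData = cd)
}

#' Per-sequence counts of a single residue
#'
#' Raw counts of one residue (cysteine by default) per sequence, the quantity
#' shown in per-taxon cysteine-abundance boxplots.
#'
#' @param x An [OrthogroupSet-class] or [Biostrings::AAStringSet].
#' @param residue Single residue letter; default "C".
#' @return Named integer vector of counts.
#' @export
residueCounts <- function(x, residue = "C") {
  if (is(x, "OrthogroupSet")) x <- x@sequences
  stopifnot(is(x, "AAStringSet"), residue %in% AA20)
  setNames(as.integer(letterFrequency(x, letters = residue)), names(x))
}

#' Translate a coding sequence FASTA to protein
#'
#' Thin wrapper over [Biostrings::translate()] for counting residues in a
#' protein derived from a downloaded coding sequence (e.g. the GgUox CDS,
#' NCBI accession XM_015290876.2). Trailing stop symbols are trimmed.
#'
#' @param path Path to a DNA FASTA file holding coding sequence(s).
#' @return An [Biostrings::AAStringSet] of translated proteins.
#' @export
translateCDS <- function(path) {
  dna <- readDNAStringSet(path)
  if (length(dna) == 0L) stop("no sequences in '", path, "'")
  aa <- translate(dna, if.fuzzy.codon = "solve")
  AAStringSet(sub("\\*$", "", as.character(aa)))
}

# Vectorized Welch (or pooled) two-sample t-test on matched mean/var/n
# vectors. Returns two-sided p-values; NA where undefined (n < 2 in either
# group, or zero variance in both groups).
welchP <- function(ma, va, na, mb, vb, nb, pooled = FALSE) {
  p <- rep(NA_real_, length(ma))
  ok <- !is.na(ma) & !is.na(mb) & na >= 2L & nb >= 2L
  if (pooled) {
    sp2 <- (pmax(na - 1, 0) * va + pmax(nb - 1, 0) * vb) / (na + nb - 2)
    se2 <- sp2 * (1 / na + 1 / nb)
    df <- na + nb - 2
  } else {
    se2 <- va / na + vb / nb
    df <- se2^2 / (va^2 / (na^2 * (na - 1)) + vb^2 / (nb^2 * (nb - 1)))
  }
  ok <- ok & se2 > 0
  tstat <- (ma - mb) / sqrt(se2)
  p[ok] <- 2 * pt(-abs(tstat[ok]), df[ok])
  p
}

#' Pairwise clade differential-composition test
#'
#' For every orthogroup and every one of the 20 amino acids, contrasts the
#' mean per-sequence content between two clades: arithmetic group means, log2
#' fold change of means (first clade over second), and a two-sided
#' unequal-variance (Welch) t-test p-value. Rows where a statistic is
#' undefined (fewer than two sequences in a clade, zero variance in both
#' groups, or a zero group mean for the fold change) are emitted with `NA`,
#' never dropped.
#'
#' @param comp Composition `SummarizedExperiment` from
#'   [computeComposition()].
#' @param cladeMap Named character vector species id -> clade (or an
#'   [OrthogroupSet-class], from which the map is taken).
#' @param pair Length-2 character vector of clade labels; the fold change is
#'   `log2(mean(pair[1]) / mean(pair[2]))`.
#' @param pooled Use the pooled-variance t-test instead of Welch. Default
#'   `FALSE`.
#' @param pseudocount Optional: add half the smallest nonzero fraction to all
#'   group means before the fold change, avoiding undefined log2 ratios for
#'   absent residues. Off (`FALSE`) by default, since pseudocounts distort
#'   rare residues such as Cys and Trp.
#' @return A `data.frame` with columns `orthogroup_id`, `amino_acid`,
#'   `clade_a`, `clade_b`, `mean_a`, `mean_b`, `log2fc`, `p_value`, `n_a`,
#'   `n_b`; one row per orthogroup x amino acid.
#' @export
differentialComposition <- function(comp, cladeMap, pair, pooled = FALSE,
                                    pseudocount = FALSE) {
  if (is(cladeMap, "OrthogroupSet")) cladeMap <- cladeMap@cladeMap
  stopifnot(is(comp, "SummarizedExperiment"), length(pair) == 2L)
  if (!all(pair %in% cladeMap))
    stop("unknown clade label(s): ",
         paste(setdiff(pair, cladeMap), collapse = ", "))
  cd <- colData(comp)
  clade <- unname(cladeMap[cd$species_id])
  frac <- t(assay(comp, "fraction"))    # sequences x 20
  ogs <- sort(unique(cd$orthogroup_id))
  ogf <- factor(cd$orthogroup_id, levels = ogs)

  groupStats <- function(which) {
    sel <- clade == which & !is.na(clade)
    f <- frac[sel, , drop = FALSE]
    g <- ogf[sel]
    n <- as.vector(table(g))
    if (!any(sel)) {
      z <- matrix(NA_real_, length(ogs), ncol(frac))
      return(list(mean = z, var = z, n = rep(0L, length(ogs))))
    }
    sums <- rowsum(f, g)                       # includes all levels? no:
    # rowsum drops absent levels; rebuild on full level set
    full <- matrix(0, length(ogs), ncol(frac), dimnames = list(ogs, NULL))
    full[rownames(sums), ] <- sums
    sq <- matrix(0, length(ogs), ncol(frac), dimnames = list(ogs, NULL))
    sq[rownames(sums), ] <- rowsum(f * f, g)
    mean <- sweep(full, 1L, n, "/")
    mean[n == 0L, ] <- NA_real_
    var <- (sq - sweep(mean^2, 1L, n, "*")) / pmax(n - 1L, 1L)
    var[n < 2L, ] <- NA_real_
    var <- pmax(var, 0)   # guard tiny negative from round-off
    list(mean = mean, var = var, n = n)
  }
  a <- groupStats(pair[1])
  b <- groupStats(pair[2])

  out <- data.frame(
    orthogroup_id = rep(ogs, times = 20L),
    amino_acid = rep(AA20, each = length(ogs)),
    clade_a = pair[1], clade_b = pair[2],
    mean_a = as.vector(a$mean), mean_b = as.vector(b$mean),
    log2fc = NA_real_,
    p_value = welchP(as.vector(a$mean), as.vector(a$var), rep(a$n, 20L),
                     as.vector(b$mean), as.vector(b$var), rep(b$n, 20L),
                     pooled = pooled),
    n_a = rep(a$n, 20L), n_b = rep(b$n, 20L),
    stringsAsFactors = FALSE
  )
  ma <- out$mean_a
  mb <- out$mean_b
  if (isTRUE(pseudocount)) {
    eps <- min(frac[frac > 0]) / 2
    ma <- ma + eps
    mb <- mb + eps
  }
  defined <- !is.na(ma) & !is.na(mb) & ma > 0 & mb > 0
  out$log2fc[defined] <- log2(ma[defined] / mb[defined])
  rownames(out) <- NULL
  out
}

#' Volcano classification of differential-composition rows
#'
#' Assigns each row of a differential table to `increased` (p below cutoff
#' and log2 fold change above `lfcCut`), `decreased` (p below cutoff and
#' log2fc below `-lfcCut`) or `ns`. Rows with undefined statistics are `ns`.
#' Default cutoffs are a raw p-value of 1e-16 and |log2fc| of 1; no multiple
#' testing correction is applied to the classification, but a
#' Bonferroni-adjusted p column is appended for reference.
#'
#' @param diff Output of [differentialComposition()].
#' @param pCut P-value cutoff in (0, 1); default 1e-16.
#' @param lfcCut Positive log2 fold-change cutoff; default 1.
#' @return `diff` with added columns `volcano_class` and `p_bonferroni`.
#' @export
classifyVolcano <- function(diff, pCut = 1e-16, lfcCut = 1) {
  stopifnot(is.data.frame(diff),
            all(c("p_value", "log2fc") %in% colnames(diff)))
  if (!is.numeric(pCut) || pCut <= 0 || pCut >= 1)
    stop("pCut must be in (0, 1)")
  if (!is.numeric(lfcCut) || lfcCut <= 0)
    stop("lfcCut must be > 0")
  cls <- rep("ns", nrow(diff))
  ok <- !is.na(diff$p_value) & !is.na(diff$log2fc)
  cls[ok & diff$p_value < pCut & diff$log2fc > lfcCut] <- "increased"
  cls[ok & diff$p_value < pCut & diff$log2fc < -lfcCut] <- "decreased"
  diff$volcano_class <- factor(cls, levels = c("increased", "decreased",
                                               "ns"))
  diff$p_bonferroni <- pmin(diff$p_value * sum(ok), 1)
  diff
}

#' Per-amino-acid counts of differentiated orthogroups
#'
#' Counts, per amino acid and clade pair, how many orthogroups are classified
#' `increased` and `decreased` (the quantities shown in per-amino-acid bar
#' plots of compositional divergence).
#'
#' @param diff Output of [classifyVolcano()].
#' @return A `data.frame` with columns `amino_acid`, `clade_a`, `clade_b`,
#'   `increased`, `decreased`, `ns`, `tested`.
#' @export
summarizeByAminoAcid <- function(diff) {
  if (!"volcano_class" %in% colnames(diff))
    stop("input has no volcano_class; run classifyVolcano() first")
  pairs <- unique(diff[, c("clade_a", "clade_b"), drop = FALSE])
  out <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    sub <- diff[diff$clade_a == pairs$clade_a[i] &
                  diff$clade_b == pairs$clade_b[i], , drop = FALSE]
    tab <- table(factor(sub$amino_acid, levels = AA20),
                 sub$volcano_class)
    data.frame(amino_acid = rownames(tab),
               clade_a = pairs$clade_a[i], clade_b = pairs$clade_b[i],
               increased = as.integer(tab[, "increased"]),
               decreased = as.integer(tab[, "decreased"]),
               ns = as.integer(tab[, "ns"]),
               stringsAsFactors = FALSE)
  }))
  out$tested <- out$increased + out$decreased + out$ns
  rownames(out) <- NULL
  out
}

#' Parse OrthoDB-style flat orthogroup files
#'
#' Minimal reader for the OrthoDB v10 flat TSV dialect mapping orthogroups to
#' genes (two tab-separated columns: orthogroup id and gene id of the form
#' `taxid_version:xxxx`, no header). Returns the long membership table from
#' which an [OrthogroupSet-class] can be assembled once sequences and clade
#' labels are attached. Network retrieval of OrthoDB releases is out of
#' scope; files must be local.
#'
#' @param path Path to an `OG2genes`-style TSV file.
#' @param level Optional orthogroup-level suffix filter, e.g. `"at7742"` to
#'   keep Vertebrata-level orthogroups only.
#' @return A `data.frame` with columns `orthogroup_id`, `gene_id`, `tax_id`.
#' @export
readOrthoDBFlat <- function(path, level = NULL) {
  x <- read.delim(path, header = FALSE, colClasses = "character",
                  col.names = c("orthogroup_id", "gene_id"),
                  comment.char = "#")
  if (nrow(x) == 0L) stop("empty OrthoDB flat file '", path, "'")
  if (!is.null(level))
    x <- x[endsWith(x$orthogroup_id, level), , drop = FALSE]
  x$tax_id <- sub("[:_].*$", "", x$gene_id)
  rownames(x) <- NULL
  x
}

#' Write a differential or summary table to CSV
#'
#' @param x A `data.frame` (differential table or per-amino-acid summary).
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
writeDifferentialTable <- function(x, path) {
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}
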