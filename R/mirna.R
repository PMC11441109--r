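# Quantification of mature miRNAs by approximate matching in clean reads.
# A read contributes its multiplicity when the mature sequence occurs
# within it at edit distance <= maxErrors (approximate-grep semantics,
# indels allowed; a Hamming-only mode restricts to substitutions). Counting
# is strand-specific: mature catalogs are oriented, so no reverse-complement
# search. A read matching two catalog entries (isomiR families) is counted
# for both, matching independent per-miRNA runs of the matcher.

#' Per-sample approximate-match counts for one mature sequence
#'
#' @param mature Mature miRNA sequence (RNA or DNA alphabet).
#' @param pool A [SmallRNAPool-class] of clean (filtered, collapsed) reads.
#' @param maxErrors Edit tolerance (default 1, the classic "one mismatch"
#'   rule).
#' @param mode `"edit"` (substitutions, insertions, deletions; default) or
#'   `"hamming"` (substitutions only).
#' @return Named numeric vector of multiplicity-weighted counts, one entry
#'   per sample present in the pool.
#' @examples
#' p <- smallRNAPool(c("UGUAGAUACUCCCUAAGGCUU", "UGUAGAUACUCUCUAAGGCUU"))
#' approximateCount("UGUAGAUACUCCCUAAGGCUU", p)  # both reads count
#' @export
approximateCount <- function(mature, pool, maxErrors = 1L,
                             mode = c("edit", "hamming")) {
  mode <- match.arg(mode)
  mature <- normalizeRna(mature)
  samples <- unique(pool@sample)
  out <- stats::setNames(numeric(length(samples)), samples)
  if (length(pool) == 0) return(out)
  if (nchar(mature) > max(nchar(pool@sequence)) + maxErrors) {
    warning("mature sequence is longer than every read: zero counts")
    return(out)
  }
  uniq <- unique(pool@sequence)
  hit <- uniq[approxMatch(mature, uniq, maxErrors, mode)]
  sel <- pool@sequence %in% hit
  if (any(sel)) {
    agg <- tapply(pool@multiplicity[sel], pool@sample[sel], sum)
    out[names(agg)] <- agg
  }
  out
}

#' Quantify a mature miRNA catalog against a read pool
#'
#' Runs [approximateCount()] independently for every catalog entry.
#'
#' @param catalog Named character vector of mature sequences (names are
#'   miRNA ids; the `name_x{count}` id dialect is accepted as-is).
#' @param pool A [SmallRNAPool-class].
#' @param maxErrors,mode Passed to [approximateCount()].
#' @return Numeric matrix, miRNAs x samples.
#' @export
quantifyMirnas <- function(catalog, pool, maxErrors = 1L,
                           mode = c("edit", "hamming")) {
  mode <- match.arg(mode)
  samples <- unique(pool@sample)
  m <- matrix(0, length(catalog), max(length(samples), 1L),
              dimnames = list(names(catalog),
                              if (length(samples)) samples else "S1"))
  for (i in seq_along(catalog)) {
    cnt <- approximateCount(catalog[[i]], pool, maxErrors, mode)
    m[i, names(cnt)] <- cnt
  }
  m
}

#' Detection flags from summed counts
#'
#' A miRNA is detected iff its counts summed across samples reach
#' `minCopies` (boundary inclusive: "at least `minCopies` copies").
#'
#' @param counts Numeric matrix (miRNAs x samples) or vector of totals.
#' @param minCopies Detection threshold (default 50).
#' @return Named logical vector of detected flags.
#' @export
detectExpressed <- function(counts, minCopies = 50) {
  totals <- if (is.matrix(counts)) rowSums(counts) else counts
  totals >= minCopies
}

#' Differential expression of miRNA counts
#'
#' Delegates to [differentialExpression()] on the miRNA count matrix with
#' the same thresholds used for transcripts of the silencing pipeline
#' (|log2FC| >= 1.5, FDR < 0.05 by default).
#'
#' @param counts miRNA x sample count matrix.
#' @param condition Per-sample condition labels.
#' @param conditionA,conditionB Reference and test condition labels.
#' @param fcThreshold,alpha Call thresholds.
#' @return data.frame as from [differentialExpression()].
#' @export
mirnaDifferentialExpression <- function(counts, condition, conditionA,
                                        conditionB, fcThreshold = 1.5,
                                        alpha = 0.05) {
  differentialExpression(counts, condition, conditionA, conditionB,
                         fcThreshold = fcThreshold, alpha = alpha)
}
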