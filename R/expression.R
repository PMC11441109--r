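# Count normalization, two-group negative-binomial differential expression,
# and hypergeometric term enrichment. The DE test is a plain NB Wald test
# with method-of-moments dispersion: group means on size-factor-normalized
# counts, MoM dispersion pooled over the within-group residuals of all
# replicated conditions (floored at 1e-8), and the Wald statistic referred
# to a t distribution on the pooled residual degrees of freedom. The t
# reference (rather than a standard normal) absorbs the uncertainty of a
# dispersion estimated from a handful of replicates; with three replicates
# per group it is what keeps the nominal 5% level honest.

#' Median-of-ratios size factors
#'
#' For each sample, the factor is the median over features (restricted to
#' features with strictly positive counts in every sample) of the ratio
#' between the sample's count and the feature's geometric mean across
#' samples.
#'
#' @param counts Non-negative integer matrix, features x samples.
#' @return Positive numeric vector of per-sample size factors.
#' @examples
#' m <- rbind(a = c(10, 20), b = c(100, 200))
#' computeSizeFactors(m)  # (1/sqrt(2), sqrt(2)): sample 2 is twice sample 1
#' @export
computeSizeFactors <- function(counts) {
  counts <- as.matrix(counts)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stop("no feature has positive counts in every sample; ",
         "a pseudo-reference fallback (e.g. adding a pseudocount) is ",
         "required before normalization")
  logGeo <- rowMeans(log(counts[pos, , drop = FALSE]))
  sf <- apply(counts[pos, , drop = FALSE], 2, function(cnt)
    exp(stats::median(log(cnt) - logGeo)))
  if (any(sf <= 0)) stop("non-positive size factor computed")
  sf
}

#' Up/down/ns call from a fold change and a significance flag
#'
#' @param log2fc Numeric log2 fold changes.
#' @param significant Logical significance flags (e.g. `fdr < alpha`).
#' @param fcThreshold Minimum |log2FC| for a call (default 1.5). Use 0 to
#'   call on significance alone.
#' @return Factor with levels `up`, `down`, `ns`.
#' @export
applyCallRule <- function(log2fc, significant, fcThreshold = 1.5) {
  call <- rep("ns", length(log2fc))
  sel <- significant & !is.na(log2fc) & abs(log2fc) >= fcThreshold
  call[sel & log2fc > 0] <- "up"
  call[sel & log2fc < 0] <- "down"
  factor(call, levels = c("up", "down", "ns"))
}

#' Two-group negative-binomial differential expression
#'
#' Features with zero counts in all samples are dropped. Counts are
#' normalized by median-of-ratios size factors (computed over all
#' replicated conditions unless supplied); group means use a pseudocount of
#' 0.5 so the log2 fold change (`conditionB` versus `conditionA`) is always
#' finite. Dispersion is a per-feature method-of-moments estimate pooled
#' over the within-group residuals of every condition with at least two
#' replicates (the full design informs the dispersion) and floored at 1e-8;
#' the Wald statistic is referred to a t distribution with the pooled
#' residual degrees of freedom, and p-values are Benjamini-Hochberg
#' adjusted across all tested features. Calls require
#' `|log2FC| >= fcThreshold` and `fdr < alpha`.
#'
#' @param counts Integer matrix (features x samples) or a
#'   `SummarizedExperiment` with a `counts` assay and a `condition` column
#'   in `colData`.
#' @param condition Character/factor of per-sample condition labels
#'   (ignored for a SummarizedExperiment input).
#' @param conditionA,conditionB Reference and test condition labels.
#' @param fcThreshold,alpha Call thresholds (defaults 1.5 and 0.05).
#' @param sizeFactors Optional per-sample size factors.
#' @return data.frame: feature, baseMeanA, baseMeanB, log2FC, pvalue, fdr,
#'   call.
#' @export
differentialExpression <- function(counts, condition = NULL,
                                   conditionA, conditionB,
                                   fcThreshold = 1.5, alpha = 0.05,
                                   sizeFactors = NULL) {
  if (is(counts, "SummarizedExperiment")) {
    condition <- as.character(SummarizedExperiment::colData(counts)$condition)
    counts <- SummarizedExperiment::assay(counts, "counts")
  }
  counts <- as.matrix(counts)
  if (is.null(condition) || length(condition) != ncol(counts))
    stop("'condition' must label every sample")
  selA <- condition == conditionA
  selB <- condition == conditionB
  if (sum(selA) < 2 || sum(selB) < 2)
    stop("each compared condition needs >= 2 replicates ",
         "(no dispersion estimate otherwise)")
  # dispersion is estimated from within-group residuals of every condition
  # with >= 2 replicates (the whole design informs the dispersion, as is
  # standard for NB differential expression), while means and the fold
  # change use only the two contrasted conditions
  replicated <- names(which(table(condition) >= 2))
  selD <- condition %in% replicated
  if (is.null(sizeFactors))
    sizeFactors <- computeSizeFactors(counts[, selD, drop = FALSE])
  norm <- sweep(counts[, selD, drop = FALSE], 2, sizeFactors, `/`)
  condD <- condition[selD]
  keep <- rowSums(counts) > 0
  norm <- norm[keep, , drop = FALSE]

  groups <- lapply(replicated, function(g)
    norm[, condD == g, drop = FALSE])
  ng <- vapply(groups, ncol, integer(1))
  dfRes <- sum(ng - 1)
  vPool <- Reduce(`+`, lapply(seq_along(groups), function(i)
    (ng[i] - 1) * apply(groups[[i]], 1, stats::var))) / dfRes
  muPool <- Reduce(`+`, lapply(groups, rowSums)) / sum(ng)
  disp <- pmax((vPool - muPool) / pmax(muPool, 1e-8)^2, 1e-8)

  A <- norm[, condD == conditionA, drop = FALSE]
  B <- norm[, condD == conditionB, drop = FALSE]
  nA <- ncol(A); nB <- ncol(B)
  muA <- rowMeans(A); muB <- rowMeans(B)
  log2FC <- log2((muB + 0.5) / (muA + 0.5))
  se2 <- ((muA + disp * muA^2) / (nA * pmax(muA, 0.5)^2) +
            (muB + disp * muB^2) / (nB * pmax(muB, 0.5)^2)) / log(2)^2
  z <- log2FC / sqrt(se2)
  pvalue <- 2 * stats::pt(-abs(z), df = dfRes)
  fdr <- stats::p.adjust(pvalue, method = "BH")
  data.frame(feature = rownames(norm),
             baseMeanA = muA, baseMeanB = muB,
             log2FC = log2FC, pvalue = pvalue, fdr = fdr,
             call = applyCallRule(log2FC, fdr < alpha, fcThreshold),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Hypergeometric term over-representation
#'
#' One-sided upper-tail hypergeometric test per term for over-representation
#' of term carriers in `selected` relative to `universe`, BH-adjusted across
#' terms. Terms are flat labels (no ontology propagation). Features in the
#' term map that are absent from the universe are skipped with a warning.
#'
#' @param selected Character vector of selected features (must be a subset
#'   of `universe`).
#' @param universe Character vector of all tested features.
#' @param termMap data.frame with columns `feature`, `term`.
#' @param alpha FDR threshold for the `enriched` flag (default 0.05).
#' @return data.frame: term, nSelected, nTerm, pvalue, fdr, enriched.
#' @export
termEnrichment <- function(selected, universe, termMap, alpha = 0.05) {
  if (!all(selected %in% universe))
    stop("'selected' must be a subset of 'universe'")
  unknown <- !(termMap$feature %in% universe)
  if (any(unknown)) {
    warning(sum(unknown), " term-map feature(s) absent from the universe; ",
            "skipped")
    termMap <- termMap[!unknown, , drop = FALSE]
  }
  N <- length(unique(universe))
  n <- length(unique(selected))
  terms <- unique(termMap$term)
  res <- lapply(terms, function(tm) {
    carriers <- unique(termMap$feature[termMap$term == tm])
    K <- length(carriers)
    k <- sum(selected %in% carriers)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, nSelected = k, nTerm = K, pvalue = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    return(data.frame(term = character(), nSelected = integer(),
                      nTerm = integer(), pvalue = numeric(), fdr = numeric(),
                      enriched = logical(), stringsAsFactors = FALSE))
  out$fdr <- stats::p.adjust(out$pvalue, method = "BH")
  out$enriched <- out$fdr < alpha
  out
}
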