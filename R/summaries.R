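# Descriptive small-RNA analytics: read length and 5' nucleotide profiles,
# percentile-rank analysis of antisense sRNA load versus transcript
# expression (ANOVA + Tukey HSD with a compact letter display), and qPCR
# quantities (2^-ddCt relative expression, fungal/plant colonization ratio
# with ANOVA + Fisher LSD group comparison).

#' Read length and 5' nucleotide distributions
#'
#' Multiplicity-weighted fractions of reads per length and per 5' terminal
#' nucleotide. Collapsed and uncollapsed pools give identical fractions.
#'
#' @param pool A non-empty [SmallRNAPool-class] (typically one species'
#'   partition of the clean reads).
#' @return List with numeric vectors `length` (named by nt length) and
#'   `fivePrime` (named A, C, G, U); each sums to 1.
#' @export
lengthFivePrimeProfile <- function(pool) {
  if (length(pool) == 0) stop("empty read pool")
  w <- pool@multiplicity
  total <- sum(w)
  lens <- nchar(pool@sequence)
  lengthFrac <- vapply(split(w, lens), sum, numeric(1)) / total
  fp <- substr(pool@sequence, 1, 1)
  fpFrac <- vapply(split(w, factor(fp, levels = c("A", "C", "G", "U"))),
                   sum, numeric(1)) / total
  list(length = lengthFrac, fivePrime = fpFrac)
}

# Compact letter display from a symmetric matrix of pairwise p-values over
# groups ordered by decreasing mean: maximal runs of mutually
# non-significant groups each get one letter; runs contained in another are
# absorbed.
compactLetters <- function(pmat, means, alpha = 0.05) {
  ord <- order(-means)
  g <- names(means)[ord]
  k <- length(g)
  runs <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && all(pmat[g[i:(j + 1)], g[i:(j + 1)]][
      upper.tri(matrix(0, j + 2 - i, j + 2 - i))] > alpha))
      j <- j + 1
    runs[[length(runs) + 1L]] <- i:j
  }
  keep <- !vapply(seq_along(runs), function(a)
    any(vapply(seq_along(runs), function(b)
      a != b && all(runs[[a]] %in% runs[[b]]), logical(1))), logical(1))
  runs <- runs[keep]
  letters_ <- stats::setNames(rep("", k), g)
  for (r in seq_along(runs))
    letters_[g[runs[[r]]]] <- paste0(letters_[g[runs[[r]]]], letters[r])
  letters_[names(means)]
}

#' Percentile-rank analysis of antisense sRNA load
#'
#' Genes with zero antisense counts are removed; remaining genes receive a
#' percentile rank of their antisense count (mean rank for ties, scaled to
#' (0, 100\]) and are binned into quintiles with right-closed edges
#' ((0,20\], (20,40\], ...). Per-bin mean expression is compared with a
#' one-way ANOVA followed by Tukey HSD at `alpha`; bins sharing a letter in
#' the compact letter display are not significantly different.
#'
#' @param antisense Named numeric vector of per-gene antisense sRNA counts.
#' @param expression Named numeric vector of per-gene (normalized)
#'   expression, same genes.
#' @param nBins Number of percentile bins (default 5).
#' @param alpha Significance level for the Tukey grouping.
#' @return List: `table` (data.frame bin, n, meanExpression, letter) and
#'   `assignment` (per-gene bin labels).
#' @export
percentileRankAnalysis <- function(antisense, expression, nBins = 5L,
                                   alpha = 0.05) {
  genes <- intersect(names(antisense), names(expression))
  antisense <- antisense[genes]
  expression <- expression[genes]
  nz <- antisense > 0
  antisense <- antisense[nz]; expression <- expression[nz]
  if (!length(antisense)) stop("no gene with antisense count > 0")
  pct <- rank(antisense, ties.method = "average") / length(antisense) * 100
  edges <- seq(0, 100, length.out = nBins + 1)
  lab <- paste0(edges[-length(edges)] + 1, "-", edges[-1])
  bin <- cut(pct, breaks = edges, labels = lab, right = TRUE)
  occupied <- levels(bin)[tabulate(bin, nBins) > 0]
  if (length(occupied) < 2) stop("fewer than 2 non-empty bins")
  df <- data.frame(expr = expression, bin = factor(bin, levels = occupied))
  # internal dash-free codes so Tukey comparison labels parse unambiguously
  code <- paste0("B", seq_along(occupied))
  df$bincode <- factor(code[as.integer(df$bin)], levels = code)
  fit <- stats::aov(expr ~ bincode, data = df)
  means <- vapply(split(df$expr, df$bin), mean, numeric(1))
  pmat <- matrix(1, length(occupied), length(occupied),
                 dimnames = list(occupied, occupied))
  if (stats::var(df$expr) > 0 && length(occupied) > 1) {
    tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$bincode
    for (rn in rownames(tk)) {
      gg <- occupied[match(strsplit(rn, "-", fixed = TRUE)[[1]], code)]
      pmat[gg[1], gg[2]] <- pmat[gg[2], gg[1]] <- tk[rn, "p adj"]
    }
  }
  letter <- compactLetters(pmat, means, alpha)
  list(table = data.frame(bin = occupied,
                          n = as.integer(table(df$bin)),
                          meanExpression = means,
                          letter = letter, row.names = NULL,
                          stringsAsFactors = FALSE),
       assignment = stats::setNames(as.character(bin), names(antisense)))
}

#' Relative expression by the 2^-ddCt method
#'
#' `2^-((Ct_target - Ct_ref)_treatment - (Ct_target - Ct_ref)_calibrator)`.
#'
#' @param ctTarget,ctRef Target and reference gene Ct values in the
#'   treatment condition.
#' @param ctTargetCal,ctRefCal The same in the calibrator condition.
#' @return Relative expression (1 when treatment equals calibrator).
#' @examples
#' ddct(25, 20, 24, 20)  # dCt 5 vs 4 -> 0.5
#' @export
ddct <- function(ctTarget, ctRef, ctTargetCal, ctRefCal) {
  if (any(missing(ctTargetCal), missing(ctRefCal)))
    stop("calibrator Ct values are required")
  stopifnot(all(c(ctTarget, ctRef, ctTargetCal, ctRefCal) > 0))
  2^-((ctTarget - ctRef) - (ctTargetCal - ctRefCal))
}

#' Relative expression from a Ct table
#'
#' Convenience wrapper around [ddct()] for a measurement table. Calibrator
#' dCt is the mean over calibrator rows.
#'
#' @param measurements data.frame: sample, ctTarget, ctRef, condition
#'   (`treatment` / `calibrator`).
#' @return data.frame of treatment rows with a `relativeExpression` column.
#' @export
relativeExpression <- function(measurements) {
  stopifnot(all(c("sample", "ctTarget", "ctRef", "condition") %in%
                  names(measurements)))
  cal <- measurements[measurements$condition == "calibrator", , drop = FALSE]
  if (!nrow(cal)) stop("calibrator Ct values are required")
  dctCal <- mean(cal$ctTarget - cal$ctRef)
  tr <- measurements[measurements$condition == "treatment", , drop = FALSE]
  tr$relativeExpression <- 2^-((tr$ctTarget - tr$ctRef) - dctCal)
  tr
}

#' Fungal / plant colonization ratio
#'
#' Ratio of the fungal marker quantity to the plant marker quantity. Inputs
#' must be positive and on a common relative scale (e.g. `2^-Ct` against a
#' shared baseline, or standard-curve quantities).
#'
#' @param fungal,plant Positive marker quantities.
#' @return `fungal / plant` (vectorized).
#' @export
colonizationRatio <- function(fungal, plant) {
  if (any(fungal <= 0) || any(plant <= 0))
    stop("marker quantities must be positive")
  fungal / plant
}

#' Compare colonization ratios between groups
#'
#' One-way ANOVA followed by pairwise Fisher LSD comparisons (t tests on
#' the pooled ANOVA mean square, unadjusted) and a compact letter display.
#'
#' @param values Numeric response (e.g. colonization ratios).
#' @param group Group labels.
#' @param alpha Significance level (default 0.05).
#' @return List: `anovaP`, `pairwise` (matrix of LSD p-values), `letters`.
#' @export
colonizationTest <- function(values, group, alpha = 0.05) {
  group <- factor(group)
  fit <- stats::aov(values ~ group)
  anovaP <- summary(fit)[[1]][["Pr(>F)"]][1]
  mse <- summary(fit)[[1]][["Mean Sq"]][2]
  dfres <- fit$df.residual
  g <- levels(group)
  n <- table(group)
  means <- vapply(split(values, group), mean, numeric(1))
  pmat <- matrix(1, length(g), length(g), dimnames = list(g, g))
  for (i in seq_along(g)) for (j in seq_along(g)) if (i < j) {
    se <- sqrt(mse * (1 / n[[g[i]]] + 1 / n[[g[j]]]))
    tstat <- (means[[g[i]]] - means[[g[j]]]) / se
    pmat[g[i], g[j]] <- pmat[g[j], g[i]] <- 2 * stats::pt(-abs(tstat), dfres)
  }
  list(anovaP = anovaP, pairwise = pmat,
       letters = compactLetters(pmat, means, alpha))
}
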