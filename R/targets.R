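# Target inference: consensus across prediction tools, opposite-expression
# filtering, anticorrelation against a per-miRNA background, and
# endogenous / cross-kingdom classification. Verdicts are assigned at the
# first failing stage in fixed order (consensus -> expression -> correlation
# threshold -> background test); identical inputs give identical tables.

#' Gapless complementarity expectation score
#'
#' Slides the mature miRNA along the transcript (no gaps, antiparallel
#' pairing) and scores each candidate site position-by-position from the
#' miRNA 5' end: Watson-Crick pair 0, G:U wobble 0.5, mismatch 1.0, with
#' penalties doubled over the seed-extended region (miRNA positions 2-13).
#' The site score is the penalty sum; lower means a better site. The
#' minimal-score site is reported (leftmost on ties) if its score does not
#' exceed `cutoff`.
#'
#' @param mirna Mature miRNA sequence, 5' to 3'.
#' @param transcript Transcript sequence, 5' to 3'.
#' @param cutoff Maximum reportable score (default 5.0).
#' @return `list(score=, start=, end=)` with a 1-based inclusive site
#'   interval on the transcript, or `NULL` if no site scores within the
#'   cutoff (or the transcript is shorter than the miRNA).
#' @examples
#' m <- "UGUAGAUACUCCCUAAGGCUU"
#' tx <- paste0("AAAA", revCompRna(m), "AAAA")
#' surrogateExpectation(m, tx)  # perfect site, score 0
#' @export
surrogateExpectation <- function(mirna, transcript, cutoff = 5.0) {
  m <- strsplit(normalizeRna(mirna), "", fixed = TRUE)[[1]]
  tx <- strsplit(normalizeRna(transcript), "", fixed = TRUE)[[1]]
  L <- length(m); Tn <- length(tx)
  if (Tn < L) return(NULL)
  P <- matrix(1, 4, 4, dimnames = list(c("A", "C", "G", "U"),
                                       c("A", "C", "G", "U")))
  P["A", "U"] <- P["U", "A"] <- P["G", "C"] <- P["C", "G"] <- 0
  P["G", "U"] <- P["U", "G"] <- 0.5
  w <- ifelse(seq_len(L) >= 2 & seq_len(L) <= 13, 2, 1)
  nW <- Tn - L + 1L
  scores <- numeric(nW)
  for (i in seq_len(L)) {
    # miRNA position i (from its 5' end) pairs with transcript position
    # s + L - i for a site starting at s (antiparallel duplex)
    idx <- seq(L - i + 1L, Tn - i + 1L)
    scores <- scores + w[i] * P[m[i], tx[idx]]
  }
  best <- unname(which.min(scores))
  if (scores[best] > cutoff) return(NULL)
  list(score = unname(scores[best]), start = best, end = best + L - 1L)
}

#' Run the surrogate scorer over a catalog and a transcript set
#'
#' @param catalog Named character vector of mature sequences.
#' @param transcripts Named character vector of transcript sequences.
#' @param cutoff Maximum reportable site score.
#' @return Prediction table (mirna_id, transcript_id, tool = "surrogate",
#'   style = "plant", score) of all sites within the cutoff.
#' @export
surrogatePredict <- function(catalog, transcripts, cutoff = 5.0) {
  rows <- list()
  for (mi in names(catalog))
    for (ti in names(transcripts)) {
      hit <- surrogateExpectation(catalog[[mi]], transcripts[[ti]], cutoff)
      if (!is.null(hit))
        rows[[length(rows) + 1L]] <-
          data.frame(mirna_id = mi, transcript_id = ti, tool = "surrogate",
                     style = "plant", score = hit$score,
                     stringsAsFactors = FALSE)
    }
  if (!length(rows))
    return(data.frame(mirna_id = character(), transcript_id = character(),
                      tool = character(), style = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Consensus filter over prediction tables
#'
#' Collapses duplicate (tool, pair) rows to one vote and retains a pair iff
#' it has at least `minPlantTools` plant-style votes or at least
#' `minAnimalTools` animal-style votes.
#'
#' @param predictions data.frame with columns mirna_id, transcript_id, tool,
#'   style (`plant`/`animal`) and optionally score. Concatenate tables from
#'   several tools with `rbind` (the surrogate scorer counts as one
#'   plant-style tool when its table is included).
#' @param thresholds A [FilterThresholds-class].
#' @return data.frame: mirna_id, transcript_id, tool_votes (comma-joined),
#'   plant_votes, animal_votes, expectation (surrogate score or NA),
#'   consensus (logical).
#' @export
consensusFilter <- function(predictions, thresholds = filterThresholds()) {
  stopifnot(all(c("mirna_id", "transcript_id", "tool", "style") %in%
                  names(predictions)))
  key <- paste(predictions$mirna_id, predictions$transcript_id,
               predictions$tool)
  predictions <- predictions[!duplicated(key), , drop = FALSE]
  pk <- paste(predictions$mirna_id, predictions$transcript_id, sep = "\r")
  split_ <- split(seq_len(nrow(predictions)), pk)
  rows <- lapply(split_, function(idx) {
    p <- predictions[idx, , drop = FALSE]
    data.frame(mirna_id = p$mirna_id[1], transcript_id = p$transcript_id[1],
               tool_votes = paste(sort(p$tool), collapse = ","),
               plant_votes = sum(p$style == "plant"),
               animal_votes = sum(p$style == "animal"),
               expectation = if ("score" %in% names(p) &&
                                 any(p$tool == "surrogate"))
                 p$score[p$tool == "surrogate"][1] else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$consensus <- out$plant_votes >= thresholds@minPlantTools |
    out$animal_votes >= thresholds@minAnimalTools
  out[order(out$mirna_id, out$transcript_id), , drop = FALSE]
}

#' Opposite-expression filter
#'
#' A pair passes iff its miRNA is significantly differentially expressed
#' with |log2FC| at or above the miRNA threshold, its transcript is
#' significant at the FDR threshold (no fold-change requirement), and the
#' two log2 fold changes have opposite signs. Pairs whose miRNA or
#' transcript is missing from the tables fail with reason `untested`.
#'
#' @param pairs data.frame with mirna_id, transcript_id.
#' @param mirnaDE,mrnaDE DE tables as from [differentialExpression()]
#'   (column `feature` keyed by miRNA / transcript id).
#' @param thresholds A [FilterThresholds-class].
#' @return `pairs` with added columns mirna_log2fc, mirna_fdr,
#'   transcript_log2fc, transcript_fdr, opposite_expression,
#'   expression_reason.
#' @export
oppositeExpressionFilter <- function(pairs, mirnaDE, mrnaDE,
                                     thresholds = filterThresholds()) {
  im <- match(pairs$mirna_id, mirnaDE$feature)
  it <- match(pairs$transcript_id, mrnaDE$feature)
  pairs$mirna_log2fc <- mirnaDE$log2FC[im]
  pairs$mirna_fdr <- mirnaDE$fdr[im]
  pairs$transcript_log2fc <- mrnaDE$log2FC[it]
  pairs$transcript_fdr <- mrnaDE$fdr[it]
  untested <- is.na(im) | is.na(it)
  mirnaOk <- !untested & pairs$mirna_fdr < thresholds@targetFdrAlpha &
    abs(pairs$mirna_log2fc) >= thresholds@mirnaFcThreshold
  txOk <- !untested & pairs$transcript_fdr < thresholds@targetFdrAlpha
  opposite <- !untested & sign(pairs$mirna_log2fc) *
    sign(pairs$transcript_log2fc) < 0
  pairs$opposite_expression <- mirnaOk & txOk & opposite
  pairs$expression_reason <- ifelse(untested, "untested",
    ifelse(!mirnaOk, "mirna_not_de",
      ifelse(!txOk, "transcript_not_de",
        ifelse(!opposite, "same_sign", "ok"))))
  pairs
}

#' Spearman and Pearson correlation of a matched pair
#'
#' Computed on size-factor-normalized counts over matched samples. Spearman
#' uses average ranks for ties. Returns `NA` for both when either vector is
#' constant (such pairs are excluded downstream as degenerate).
#'
#' @param x,y Named numeric vectors (normalized counts) over identical
#'   sample sets.
#' @return `c(spearman=, pearson=)`.
#' @export
pairCorrelation <- function(x, y) {
  if (is.null(names(x)) || is.null(names(y)))
    stop("'x' and 'y' must be named by sample")
  if (!setequal(names(x), names(y))) {
    onlyX <- setdiff(names(x), names(y))
    onlyY <- setdiff(names(y), names(x))
    stop("mismatched sample sets; only in x: {",
         paste(onlyX, collapse = ", "), "}; only in y: {",
         paste(onlyY, collapse = ", "), "}")
  }
  y <- y[names(x)]
  if (length(x) < 4)
    stop("at least 4 matched samples are required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(c(spearman = NA_real_, pearson = NA_real_))
  c(spearman = stats::cor(x, y, method = "spearman"),
    pearson = stats::cor(x, y, method = "pearson"))
}

#' Anticorrelation-versus-background test
#'
#' Tests whether the correlation between a miRNA and its putative target is
#' smaller (more negative) than the correlations between the same miRNA and
#' the other transcripts of the target's organism. With several target-side
#' values this is a one-sided Wilcoxon rank-sum test; with the usual single
#' target correlation it degenerates to the empirical percentile
#' `p = (1 + #\{background <= r\}) / (1 + |background|)`.
#'
#' @param rTarget Correlation value(s) for the target pair.
#' @param background Correlations of the same miRNA with every other
#'   transcript of the same organism (undefined/NA values excluded).
#' @return The p-value, with attribute `lowPower = TRUE` when fewer than 10
#'   background correlations were available.
#' @export
backgroundTest <- function(rTarget, background) {
  background <- background[!is.na(background)]
  rTarget <- rTarget[!is.na(rTarget)]
  if (!length(rTarget) || !length(background))
    return(structure(NA_real_, lowPower = TRUE))
  p <- if (length(rTarget) > 1)
    stats::wilcox.test(rTarget, background, alternative = "less",
                       exact = FALSE)$p.value
  else (1 + sum(background <= rTarget)) / (1 + length(background))
  structure(p, lowPower = length(background) < 10)
}

#' Classify candidate pairs through the full filter cascade
#'
#' Applies, in order: tool consensus, opposite expression, the Spearman
#' retention threshold, and the anticorrelation-versus-background test.
#' Each pair's verdict is the first failing stage (`rejected_consensus`,
#' `rejected_expression`, `rejected_correlation`, `rejected_background`) or
#' `retained`. Relationship is `cross_kingdom` iff the miRNA's species
#' differs from the transcript's. Retained pairs are sorted by Spearman
#' ascending; rejected pairs follow in a fixed deterministic order.
#'
#' @param predictions Prediction table(s) rbind-ed together (columns
#'   mirna_id, transcript_id, tool, style, score); include the surrogate
#'   table from [surrogatePredict()] to let it vote.
#' @param mirnaSpecies Named character vector: species label per miRNA id.
#' @param mirnaDE DE table for the miRNAs (all species combined).
#' @param mrnaDE DE table for the transcripts (all species combined).
#' @param mirnaCounts Named list of per-species raw miRNA count matrices.
#' @param mrnaCounts Named list of per-species raw transcript count
#'   matrices.
#' @param thresholds A [FilterThresholds-class].
#' @return data.frame of target calls with all intermediate columns and the
#'   final `verdict`.
#' @export
classifyTargets <- function(predictions, mirnaSpecies, mirnaDE, mrnaDE,
                            mirnaCounts, mrnaCounts,
                            thresholds = filterThresholds()) {
  cons <- consensusFilter(predictions, thresholds)
  txSpecies <- unlist(lapply(names(mrnaCounts), function(sp)
    stats::setNames(rep(sp, nrow(mrnaCounts[[sp]])),
                    rownames(mrnaCounts[[sp]]))))
  cons$species_of_transcript <- txSpecies[cons$transcript_id]
  cons$relationship <- ifelse(
    mirnaSpecies[cons$mirna_id] == cons$species_of_transcript,
    "endogenous", "cross_kingdom")

  cons <- oppositeExpressionFilter(cons, mirnaDE, mrnaDE, thresholds)

  normalize <- function(m) sweep(m, 2, computeSizeFactors(m), `/`)
  mirnaNorm <- lapply(mirnaCounts, normalize)
  mrnaNorm <- lapply(mrnaCounts, normalize)

  bgCache <- new.env(parent = emptyenv())
  bgCorrelations <- function(mirnaId, sp) {
    key <- paste(mirnaId, sp)
    if (!is.null(bgCache[[key]])) return(bgCache[[key]])
    msp <- mirnaSpecies[[mirnaId]]
    mi <- mirnaNorm[[msp]][mirnaId, ]
    tx <- mrnaNorm[[sp]]
    shared <- intersect(names(mi), colnames(tx))
    r <- suppressWarnings(
      stats::cor(t(tx[, shared, drop = FALSE]), mi[shared],
                 method = "spearman"))[, 1]
    bgCache[[key]] <- r
    r
  }

  n <- nrow(cons)
  cons$spearman <- NA_real_
  cons$pearson <- NA_real_
  cons$background_p <- NA_real_
  cons$verdict <- "retained"
  for (i in seq_len(n)) {
    if (!cons$consensus[i]) { cons$verdict[i] <- "rejected_consensus"; next }
    if (!cons$opposite_expression[i]) {
      cons$verdict[i] <- "rejected_expression"; next
    }
    msp <- mirnaSpecies[[cons$mirna_id[i]]]
    sp <- cons$species_of_transcript[i]
    mi <- mirnaNorm[[msp]][cons$mirna_id[i], ]
    tx <- mrnaNorm[[sp]][cons$transcript_id[i], ]
    shared <- intersect(names(mi), names(tx))
    r <- pairCorrelation(mi[shared], tx[shared])
    cons$spearman[i] <- r[["spearman"]]
    cons$pearson[i] <- r[["pearson"]]
    if (is.na(r[["spearman"]]) ||
        r[["spearman"]] > thresholds@spearmanMax) {
      cons$verdict[i] <- "rejected_correlation"; next
    }
    bg <- bgCorrelations(cons$mirna_id[i], sp)
    bg <- bg[setdiff(names(bg), cons$transcript_id[i])]
    p <- backgroundTest(r[["spearman"]], bg)
    cons$background_p[i] <- as.numeric(p)
    if (!is.na(p) && p >= thresholds@wilcoxonAlpha)
      cons$verdict[i] <- "rejected_background"
  }
  retained <- cons[cons$verdict == "retained", , drop = FALSE]
  retained <- retained[order(retained$spearman), , drop = FALSE]
  rejected <- cons[cons$verdict != "retained", , drop = FALSE]
  rejected <- rejected[order(rejected$verdict, rejected$mirna_id,
                             rejected$transcript_id), , drop = FALSE]
  out <- rbind(retained, rejected)
  rownames(out) <- NULL
  out
}

#' Run the full target-inference pipeline on a synthetic experiment
#'
#' Convenience wrapper: per-species transcript and miRNA differential
#' expression (interaction versus the species' own control), surrogate
#' target prediction for the candidate pairs, and the filter cascade of
#' [classifyTargets()] against the manifest's emulated tool tables.
#'
#' @param sim An [SrnaSimulation-class].
#' @param thresholds A [FilterThresholds-class].
#' @param interaction Condition label used as the test condition
#'   (default `"interaction_wt"`).
#' @param useSurrogate Add the surrogate scorer's vote (default TRUE).
#' @return List: `calls` (the TargetCall table), `mirnaDE`, `mrnaDE`.
#' @export
analyzeSimulation <- function(sim, thresholds = filterThresholds(),
                              interaction = "interaction_wt",
                              useSurrogate = TRUE) {
  lay <- sampleLayout(sim@config)
  ctrl <- c(plant = "control_plant", fungus = "control_fungus")
  deTx <- list(); deMi <- list()
  for (sp in c("plant", "fungus")) {
    deTx[[sp]] <- differentialExpression(sim@mrna[[sp]],
                                         conditionA = ctrl[[sp]],
                                         conditionB = interaction)
    cnt <- sim@mirnaCounts[[sp]]
    cond <- lay$condition[match(colnames(cnt), lay$sample)]
    deMi[[sp]] <- mirnaDifferentialExpression(cnt, cond, ctrl[[sp]],
                                              interaction)
  }
  mrnaDE <- rbind(deTx$plant, deTx$fungus)
  mirnaDE <- rbind(deMi$plant, deMi$fungus)

  predictions <- sim@manifest@predictions
  if (useSurrogate) {
    cand <- unique(predictions[, c("mirna_id", "transcript_id")])
    catalog <- stats::setNames(sim@manifest@mirnas$sequence,
                               sim@manifest@mirnas$id)
    txAll <- c(sim@references$plant, sim@references$fungus)
    rows <- lapply(seq_len(nrow(cand)), function(i) {
      hit <- surrogateExpectation(catalog[[cand$mirna_id[i]]],
                                  txAll[[cand$transcript_id[i]]])
      if (is.null(hit)) return(NULL)
      data.frame(mirna_id = cand$mirna_id[i],
                 transcript_id = cand$transcript_id[i],
                 tool = "surrogate", style = "plant", score = hit$score,
                 stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows))
      predictions <- rbind(predictions[, c("mirna_id", "transcript_id",
                                           "tool", "style", "score")],
                           do.call(rbind, rows))
  }
  mirnaSpecies <- stats::setNames(sim@manifest@mirnas$species,
                                  sim@manifest@mirnas$id)
  mrnaCounts <- lapply(sim@mrna, function(se)
    SummarizedExperiment::assay(se, "counts"))
  calls <- classifyTargets(predictions, mirnaSpecies, mirnaDE, mrnaDE,
                           sim@mirnaCounts, mrnaCounts, thresholds)
  list(calls = calls, mirnaDE = mirnaDE, mrnaDE = mrnaDE)
}
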