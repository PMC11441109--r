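test_that("surrogate expectation scores follow the penalty rules", {
  m <- "UGUAGAUACUCCCUAAGGCUU"
  perfect <- paste0("GGGG", revCompRna(m), "CCCC")
  hit <- surrogateExpectation(m, perfect)
  expect_equal(hit$score, 0)
  expect_equal(hit$start, 5)

  # single mismatch at miRNA position 5 (seed region): 1.0 x 2
  site <- revCompRna(m)
  L <- nchar(m)
  tpos <- L - 5 + 1  # transcript site position pairing miRNA position 5
  mm <- site
  cur <- substr(mm, tpos, tpos)
  # replace with a base that neither pairs nor wobbles with miRNA pos 5 (A)
  substr(mm, tpos, tpos) <- if (cur != "C") "C" else "G"
  expect_equal(surrogateExpectation(m, paste0("AA", mm, "AA"))$score, 2.0)

  # single G:U wobble at position 15 (non-seed): miRNA G pairs target U
  m2 <- "UGUAGAUACUCCCUGAGGCUU"  # position 15 is G
  site2 <- revCompRna(m2)
  wpos <- nchar(m2) - 15 + 1
  expect_equal(substr(site2, wpos, wpos), "C")
  substr(site2, wpos, wpos) <- "U"
  expect_equal(surrogateExpectation(m2, site2)$score, 0.5)

  # transcript shorter than the miRNA: no site
  expect_null(surrogateExpectation(m, "ACGUACGU"))
  # cutoff excludes poor sites
  expect_null(surrogateExpectation(m, strrep("A", 100), cutoff = 5))
})

test_that("consensus voting applies plant and animal minima", {
  th <- filterThresholds()
  mk <- function(tools, styles)
    data.frame(mirna_id = "m1", transcript_id = "t1", tool = tools,
               style = styles, score = 1, stringsAsFactors = FALSE)
  expect_true(consensusFilter(mk(c("psRNATarget", "TAPIR"),
                                 c("plant", "plant")), th)$consensus)
  expect_false(consensusFilter(mk(c("Miranda", "PITA"),
                                  c("animal", "animal")), th)$consensus)
  expect_true(consensusFilter(mk(c("Miranda", "PITA", "TargetSpy"),
                                 rep("animal", 3)), th)$consensus)
  expect_false(consensusFilter(mk("surrogate", "plant"), th)$consensus)
  # duplicate (tool, pair) rows collapse to one vote
  dup <- mk(c("TAPIR", "TAPIR"), c("plant", "plant"))
  expect_equal(consensusFilter(dup, th)$plant_votes, 1)
})

test_that("opposite-expression filter enforces sign and thresholds", {
  th <- filterThresholds()
  mirnaDE <- data.frame(feature = c("mA", "mB", "mC"),
                        log2FC = c(-2.2, -2.0, -1.0),
                        fdr = c(0.01, 0.01, 0.01))
  mrnaDE <- data.frame(feature = c("t1", "t2", "t3"),
                       log2FC = c(5.63, -3.0, 0.3),
                       fdr = c(0.001, 0.001, 0.01))
  pairs <- data.frame(mirna_id = c("mA", "mB", "mA", "mC", "mA"),
                      transcript_id = c("t1", "t2", "t3", "t1", "missing"))
  out <- oppositeExpressionFilter(pairs, mirnaDE, mrnaDE, th)
  expect_true(out$opposite_expression[1])    # down miRNA, up transcript
  expect_false(out$opposite_expression[2])   # both down: same sign
  expect_equal(out$expression_reason[2], "same_sign")
  # transcript log2FC +0.3 passes: no fold-change threshold on transcripts
  expect_true(out$opposite_expression[3])
  expect_equal(out$expression_reason[4], "mirna_not_de")  # |FC| < 1.5
  expect_equal(out$expression_reason[5], "untested")
})

test_that("pair correlations match brute-force ranking", {
  x <- c(a = 10, b = 8, c = 6, d = 4)
  y <- c(a = 1, b = 2, c = 3, d = 4)
  r <- pairCorrelation(x, y)
  expect_equal(r[["spearman"]], -1)

  const <- c(a = 2, b = 2, c = 2, d = 2)
  expect_true(all(is.na(pairCorrelation(x, const))))

  set.seed(31)
  for (i in 1:10) {
    v1 <- stats::setNames(sample(20, 6, replace = TRUE), letters[1:6])
    v2 <- stats::setNames(sample(20, 6, replace = TRUE), letters[1:6])
    if (sd(v1) == 0 || sd(v2) == 0) next
    expect_equal(pairCorrelation(v1, v2)[["spearman"]],
                 bfSpearman(v1, v2), tolerance = 1e-12)
  }

  expect_error(pairCorrelation(x, c(a = 1, b = 2, c = 3, e = 4)),
               "mismatched")
})

test_that("background percentile test behaves at the boundaries", {
  bg <- seq(0, 0.98, length.out = 99)
  p <- backgroundTest(-1, bg)
  expect_equal(as.numeric(p), 0.01)
  expect_false(attr(p, "lowPower"))

  pMid <- backgroundTest(stats::median(bg), bg)
  expect_gt(as.numeric(pMid), 0.4)

  # |background| = 9 and a target below all of it: p = 0.1 exactly,
  # failing a strict p < 0.1 rule
  p9 <- backgroundTest(-0.9, seq(-0.5, 0.5, length.out = 9))
  expect_equal(as.numeric(p9), 0.1)
  expect_true(attr(p9, "lowPower"))
  expect_false(as.numeric(p9) < filterThresholds()@wilcoxonAlpha)
})

test_that("verdicts are ordered, deterministic and threshold-sensitive", {
  sim <- simulateExperiment(smallSimConfig(seed = 33,
                                           nTranscriptsPlant = 60,
                                           nTranscriptsFungus = 60,
                                           nEndogenousPairs = 3,
                                           nCrosskingdomPairs = 3),
                            reads = FALSE)
  res1 <- analyzeSimulation(sim)
  res2 <- analyzeSimulation(sim)
  expect_identical(res1$calls, res2$calls)

  ret <- res1$calls[res1$calls$verdict == "retained", ]
  expect_false(is.unsorted(ret$spearman))
  expect_true(all(ret$opposite_expression))
  expect_true(all(ret$spearman <= filterThresholds()@spearmanMax))
  # relationship follows the species labels
  expect_true(all(ret$relationship[startsWith(ret$mirna_id, "pla") &
                                     ret$species_of_transcript == "fungus"]
                  == "cross_kingdom"))

  # a stricter Spearman threshold can only shrink the retained set
  strict <- analyzeSimulation(sim, filterThresholds("strict"))
  keyOf <- function(d) paste(d$mirna_id, d$transcript_id)
  expect_true(all(keyOf(strict$calls[strict$calls$verdict == "retained", ])
                  %in% keyOf(ret)))
})

test_that("relaxing thresholds never shrinks the retained set", {
  sim <- simulateExperiment(smallSimConfig(seed = 34,
                                           nTranscriptsPlant = 60,
                                           nTranscriptsFungus = 60),
                            reads = FALSE)
  keyOf <- function(d) paste(d$mirna_id, d$transcript_id)
  base <- analyzeSimulation(sim, filterThresholds())$calls
  relaxed <- analyzeSimulation(sim, filterThresholds(
    spearmanMax = -0.2, wilcoxonAlpha = 0.3, targetFdrAlpha = 0.2,
    mirnaFcThreshold = 1))$calls
  expect_true(all(keyOf(base[base$verdict == "retained", ]) %in%
                    keyOf(relaxed[relaxed$verdict == "retained", ])))
})
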