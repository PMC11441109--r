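test_that("approximate counting implements the one-mismatch rule", {
  mature <- "UGUAGAUACUCCCUAAGGCUU"
  oneSub <- "UGUAGAUACUCUCUAAGGCUU"   # Hamming distance 1 at position 12
  twoSub <- "UGUAGAUACUCUCUAAGGAUU"   # distance 2
  pool <- smallRNAPool(c(mature, oneSub, twoSub))
  expect_equal(unname(approximateCount(mature, pool, maxErrors = 0)), 1)
  expect_equal(unname(approximateCount(mature, pool, maxErrors = 1)), 2)
  expect_equal(unname(approximateCount(mature, pool, maxErrors = 2)), 3)
  # agrees with the brute-force edit-distance oracle
  for (k in 0:2)
    expect_equal(unname(approximateCount(mature, pool, maxErrors = k)),
                 length(bfMatchesAnywhere(mature, pool@sequence, k)))
})

test_that("edit and Hamming modes differ exactly on indels", {
  mature <- "UGUAGAUACUCCCUAAGGCUU"
  delRead <- paste0("AAA", sub("CCC", "CC", mature), "AAA")  # one deletion
  pool <- smallRNAPool(delRead)
  expect_equal(unname(approximateCount(mature, pool, 1, mode = "edit")), 1)
  expect_equal(unname(approximateCount(mature, pool, 1, mode = "hamming")),
               0)
})

test_that("counts are monotone in the error budget and exact at zero", {
  set.seed(21)
  pool <- randomPool(300, seed = 21)
  for (m in c("UGUAGAUACUCCCUAAGGCUU", pool@sequence[5])) {
    counts <- vapply(0:3, function(k)
      sum(approximateCount(m, pool, k)), numeric(1))
    expect_true(all(diff(counts) >= 0))
    exact <- sum(vapply(pool@sequence, function(r)
      grepl(m, r, fixed = TRUE), logical(1)) * pool@multiplicity)
    expect_equal(counts[1], exact)
  }
})

test_that("distant catalog entries never absorb each other's reads", {
  m1 <- "UGUAGAUACUCCCUAAGGCUU"
  m2 <- "ACCGGAUUCGAAGGGCAUCAU"  # edit distance >= 4 from m1
  expect_gte(utils::adist(m1, m2), 4)
  pool <- smallRNAPool(rep(c(m1, m2), c(7, 9)))
  q <- quantifyMirnas(c(a = m1, b = m2), collapseReads(pool))
  expect_equal(q["a", "S1"], 7)
  expect_equal(q["b", "S1"], 9)
})

test_that("detection threshold is boundary inclusive", {
  counts <- matrix(c(20, 29, 20, 30), nrow = 2, byrow = TRUE,
                   dimnames = list(c("m49", "m50"), c("s1", "s2")))
  det <- detectExpressed(counts, minCopies = 50)
  expect_false(det[["m49"]])
  expect_true(det[["m50"]])
  expect_true(all(detectExpressed(counts, minCopies = 0)))
})

test_that("planted error-free copies are counted exactly", {
  cfg <- smallSimConfig(seed = 22, readsPerSample = 500L, fracMirna = 1,
                        fracStructural = 0, fracOutOfRange = 0,
                        seqErrorRate = 0)
  sim <- simulateExperiment(cfg)
  pool <- collapseReads(sim@reads)
  mir <- plantedMirnas(sim@manifest)
  catalog <- stats::setNames(mir$sequence, mir$id)
  q1 <- quantifyMirnas(catalog, pool, maxErrors = 1)
  q0 <- quantifyMirnas(catalog, pool, maxErrors = 0)
  # error-free reads: the <=1-error count equals the exact count, which
  # equals the number of planted copies
  expect_equal(q1, q0)
  expect_equal(sum(q1), sum(pool@multiplicity))

  # self-match: a pool holding the mature sequence n times yields >= n
  selfPool <- smallRNAPool(rep(catalog[[1]], 11))
  expect_gte(approximateCount(catalog[[1]], selfPool)[["S1"]], 11)
})

test_that("an over-long mature sequence warns and returns zero", {
  pool <- randomPool(10, lens = 18:20, seed = 23)
  expect_warning(cnt <- approximateCount(strrep("ACGU", 10), pool), "longer")
  expect_equal(sum(cnt), 0)
})

test_that("miRNA differential expression recovers planted repression", {
  set.seed(24)
  # four replicated groups, as in the emulated design (control, wildtype
  # interaction, two mutant interactions); the planted 8-fold repression
  # acts in the wildtype interaction only
  hits <- vapply(1:200, function(i) {
    mu <- exp(runif(30, log(100), log(1000)))
    eff <- rep(c(0.125, 1), c(5, 25))
    cnt <- cbind(matrix(rnbinom(30 * 3, mu = mu, size = 20), ncol = 3),
                 matrix(rnbinom(30 * 3, mu = mu * eff, size = 20), ncol = 3),
                 matrix(rnbinom(30 * 6, mu = mu, size = 20), ncol = 6))
    rownames(cnt) <- paste0("m", 1:30)
    cond <- rep(c("ctl", "int", "mut1", "mut2"), each = 3)
    de <- mirnaDifferentialExpression(cnt, cond, "ctl", "int")
    as.character(de$call[de$feature == "m1"]) == "down"
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  flat <- matrix(rep(c(50L, 60L, 55L), 4), nrow = 2, byrow = TRUE)
  rownames(flat) <- c("x", "y")
  deF <- mirnaDifferentialExpression(flat, rep(c("ctl", "int"), each = 3),
                                     "ctl", "int")
  expect_true(all(deF$call == "ns"))
})
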