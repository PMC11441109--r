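test_that("length filter keeps the inclusive 18-32 window", {
  p <- smallRNAPool(c(strrep("A", 17), strrep("C", 18), strrep("G", 32),
                      strrep("U", 33)))
  kept <- lengthFilter(p)
  expect_setequal(nchar(kept@sequence), c(18, 32))

  expect_length(lengthFilter(smallRNAPool(character())), 0)

  p21 <- randomPool(20, lens = 21, seed = 1)
  expect_identical(lengthFilter(p21), p21)

  expect_error(lengthFilter(p21, minLen = 30, maxLen = 20),
               "configuration error")
})

test_that("structural removal matches the substring contract", {
  set.seed(42)
  rrna <- paste(sample(c("A", "C", "G", "U"), 120, TRUE), collapse = "")
  window <- substr(rrna, 31, 50)
  twoSub <- window
  substr(twoSub, 3, 3) <- if (substr(twoSub, 3, 3) == "A") "C" else "A"
  substr(twoSub, 15, 15) <- if (substr(twoSub, 15, 15) == "G") "U" else "G"
  p <- smallRNAPool(c(window, twoSub))
  out <- removeStructural(p, rrna, maxErrors = 0)
  expect_identical(out@sequence, twoSub)

  expect_warning(same <- removeStructural(p, character()), "empty")
  expect_identical(same, p)
})

test_that("structural removal recovers the planted contaminant fraction", {
  cfg <- smallSimConfig(seed = 9, readsPerSample = 600L, seqErrorRate = 0,
                        fracStructural = 0.15)
  sim <- simulateExperiment(cfg)
  pool <- lengthFilter(sim@reads)
  clean <- removeStructural(pool, sim@manifest@structural)
  nStruct <- sum(vapply(unique(pool@sequence), function(r)
    any(grepl(r, sim@manifest@structural, fixed = TRUE)), logical(1)) [
      match(pool@sequence, unique(pool@sequence))])
  expect_equal(sum(pool@multiplicity) - sum(clean@multiplicity), nStruct)
})

test_that("collapsing merges duplicates and conserves multiplicity", {
  p <- smallRNAPool(c("ACGUACGUACGUACGUAC", "ACGUACGUACGUACGUAC",
                      "UGCAUGCAUGCAUGCAUG"),
                    multiplicity = c(1L, 2L, 5L))
  cp <- collapseReads(p)
  expect_length(cp, 2)
  expect_equal(sum(cp@multiplicity), 8)
  expect_equal(cp@multiplicity[cp@sequence == "ACGUACGUACGUACGUAC"], 3L)

  distinct <- randomPool(25, seed = 3)
  expect_length(collapseReads(distinct), 25)

  rp <- randomPool(50, seed = 4)
  rp@multiplicity <- sample(1:5, 50, replace = TRUE)
  expect_equal(sum(collapseReads(rp)@multiplicity), sum(rp@multiplicity))
})

test_that("species partitioning handles constructed reads correctly", {
  cfg <- smallSimConfig(seed = 10, fracHomologous = 0.1)
  refs <- plantMirnasAndTargets(generateReferences(cfg), cfg)$references
  hom <- generateReferences(cfg)$homologous

  fOnly <- setdiff(names(refs$fungus), hom$fungus_id)[1]
  senseRead <- substr(refs$fungus[[fOnly]], 41, 62)
  homRead <- substr(refs$fungus[[hom$fungus_id[1]]], 11, 32)
  set.seed(99)
  repeat {  # a random 25-mer absent from both references
    rnd <- paste(sample(c("A", "C", "G", "U"), 25, TRUE), collapse = "")
    if (bfClassify(rnd, refs$plant, refs$fungus) == "unmapped") break
  }
  pool <- smallRNAPool(c(senseRead, homRead, rnd))
  part <- partitionBySpecies(pool, refs$plant, refs$fungus)
  expect_equal(as.character(partitionClass(part)),
               c("unique_B", "ambiguous", "unmapped"))
  h <- partitionHits(part)
  expect_true(all(h$strand[h$read == 1] == "sense"))

  # exact matching records the 0-based half-open window coordinates
  part0 <- partitionBySpecies(smallRNAPool(senseRead), refs$plant,
                              refs$fungus, maxErrors = 0)
  h0 <- partitionHits(part0)
  h0 <- h0[h0$transcript == fOnly & h0$strand == "sense", ]
  expect_equal(h0$start, 40)
  expect_equal(h0$end, 62)

  # antisense orientation: the reverse complement of a fungal window
  anti <- smallRNAPool(revCompRna(senseRead))
  pa <- partitionBySpecies(anti, refs$plant, refs$fungus)
  expect_equal(as.character(partitionClass(pa)), "unique_B")
  expect_true("antisense" %in% partitionHits(pa)$strand)
})

test_that("partition classes are complete and symmetric", {
  cfg <- smallSimConfig(seed = 12, readsPerSample = 150L)
  sim <- simulateExperiment(cfg)
  pool <- collapseReads(lengthFilter(
    xksilence:::subsetPool(sim@reads,
                           sim@reads@sample == "interaction_wt_1")))
  part <- partitionBySpecies(pool, sim@references$plant,
                             sim@references$fungus)
  expect_equal(sum(partitionTallies(part)), sum(pool@multiplicity))

  swapped <- partitionBySpecies(pool, sim@references$fungus,
                                sim@references$plant)
  tA <- partitionTallies(part); tB <- partitionTallies(swapped)
  expect_equal(tA[["unique_A"]], tB[["unique_B"]])
  expect_equal(tA[["unique_B"]], tB[["unique_A"]])
  expect_equal(tA[["ambiguous"]], tB[["ambiguous"]])
  expect_equal(tA[["unmapped"]], tB[["unmapped"]])
})

test_that("partitioning agrees with the brute-force sliding scan", {
  cfg <- smallSimConfig(seed = 13, nTranscriptsPlant = 15,
                        nTranscriptsFungus = 15, readsPerSample = 120L)
  sim <- simulateExperiment(cfg)
  pool <- collapseReads(lengthFilter(
    xksilence:::subsetPool(sim@reads,
                           sim@reads@sample == "interaction_dcl1_2")))
  part <- partitionBySpecies(pool, sim@references$plant,
                             sim@references$fungus)
  oracle <- vapply(pool@sequence, bfClassify, character(1),
                   refA = sim@references$plant,
                   refB = sim@references$fungus)
  expect_equal(as.character(partitionClass(part)), unname(oracle))
})

test_that("antisense counting conserves weighted multiplicities", {
  cfg <- smallSimConfig(seed = 14, readsPerSample = 200L)
  sim <- simulateExperiment(cfg)
  pool <- collapseReads(lengthFilter(
    xksilence:::subsetPool(sim@reads,
                           sim@reads@sample == "interaction_wt_2")))
  part <- partitionBySpecies(pool, sim@references$plant,
                             sim@references$fungus)
  for (sp in c("A", "B")) {
    anti <- antisenseCounts(part, pool, sp, "antisense")
    sens <- antisenseCounts(part, pool, sp, "sense")
    expect_equal(sum(anti) + sum(sens),
                 partitionTallies(part)[[paste0("unique_", sp)]])
  }
})
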