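test_that("reference generation is deterministic and controls homology", {
  cfg <- simulationConfig(seed = 1, nTranscriptsPlant = 10,
                          nTranscriptsFungus = 5, fracHomologous = 0.2)
  refs <- generateReferences(cfg)
  expect_length(refs$plant, 10)
  expect_length(refs$fungus, 5)
  expect_equal(nrow(refs$homologous), 1)  # 0.2 x 5
  expect_true(refs$plant[[refs$homologous$plant_id]] ==
                refs$fungus[[refs$homologous$fungus_id]])

  refs2 <- generateReferences(cfg)
  expect_identical(refs, refs2)

  refs0 <- generateReferences(simulationConfig(seed = 1,
                                               nTranscriptsPlant = 10,
                                               nTranscriptsFungus = 5,
                                               fracHomologous = 0))
  expect_length(intersect(refs0$plant, refs0$fungus), 0)

  expect_error(simulationConfig(transcriptLenRange = c(500L, 300L)),
               "inverted")
})

test_that("planted miRNAs embed complementary sites in their targets", {
  cfg <- smallSimConfig(seed = 4, mirnaLenRange = c(21L, 21L))
  refs <- generateReferences(cfg)
  pl <- plantMirnasAndTargets(refs, cfg)
  expect_true(all(nchar(pl$mirnas$sequence) == 21))
  for (i in seq_len(nrow(pl$pairs))) {
    m <- pl$mirnas$sequence[pl$mirnas$id == pl$pairs$mirna_id[i]]
    sp <- if (startsWith(pl$pairs$transcript_id[i], "PT")) "plant"
    else "fungus"
    tx <- pl$references[[sp]][[pl$pairs$transcript_id[i]]]
    expect_true(grepl(revCompRna(m), tx, fixed = TRUE))
  }
  # cross-kingdom pairs link a plant miRNA to a fungal transcript
  ck <- pl$pairs[pl$pairs$relationship == "cross_kingdom", ]
  expect_true(all(startsWith(ck$mirna_id, "pla")))
  expect_true(all(startsWith(ck$transcript_id, "FT")))
})

test_that("degenerate pair requests are handled", {
  cfg0 <- smallSimConfig(seed = 2, nEndogenousPairs = 0,
                         nCrosskingdomPairs = 0)
  pl <- plantMirnasAndTargets(generateReferences(cfg0), cfg0)
  expect_equal(nrow(pl$pairs), 0)

  cfgBig <- smallSimConfig(seed = 2, nTranscriptsFungus = 3,
                           nCrosskingdomPairs = 10, fracHomologous = 0)
  expect_error(plantMirnasAndTargets(generateReferences(cfgBig), cfgBig),
               "more pairs requested")
})

test_that("count draws approach the Poisson limit as dispersion vanishes", {
  cfg <- simulationConfig(seed = 8, nTranscriptsPlant = 4,
                          nTranscriptsFungus = 4,
                          transcriptLenRange = c(300L, 400L),
                          conditions = c("control_plant", "control_fungus"),
                          nSamplesPerCondition = 5000L,
                          nbDispersion = 1e-8, nMirnasPlant = 2,
                          nMirnasFungus = 2, nEndogenousPairs = 0,
                          nCrosskingdomPairs = 0, nDePerSpecies = 0)
  sim <- simulateExperiment(cfg, reads = FALSE)
  cnt <- SummarizedExperiment::assay(sim@mrna$plant, "counts")
  depth <- sim@samples$depth[match(colnames(cnt), sim@samples$sample)]
  scaled <- sweep(cnt, 2, depth, `/`)  # removes the depth variation
  ratio <- apply(scaled, 1, stats::var) / rowMeans(scaled)
  # E[1/depth] with lognormal(0, 0.15) depth shifts the ratio slightly
  # above 1; the Poisson limit keeps it within the Monte-Carlo band
  expect_true(all(abs(ratio - 1) < 0.06))
})

test_that("planted pairs anticorrelate across interaction samples", {
  hits <- vapply(1:100, function(s) {
    # one released target planted into the default-scale design
    cfg <- simulationConfig(seed = s, nEndogenousPairs = 0,
                            nCrosskingdomPairs = 1, readsPerSample = 0)
    sim <- simulateExperiment(cfg, reads = FALSE)
    pair <- plantedPairs(sim@manifest)
    # size-factor-normalized counts, as the inference pipeline uses them
    miM <- sim@mirnaCounts$plant
    txM <- SummarizedExperiment::assay(sim@mrna$fungus, "counts")
    mi <- (sweep(miM, 2, computeSizeFactors(miM), `/`))[pair$mirna_id, ]
    tx <- (sweep(txM, 2, computeSizeFactors(txM), `/`))[pair$transcript_id, ]
    int <- intersect(names(mi), names(tx))
    cor(mi[int], tx[int], method = "spearman") <= -0.7
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("zero repression leaves planted targets at background behaviour", {
  cfg <- smallSimConfig(seed = 11, repressionLog2fc = 0,
                        nSamplesPerCondition = 40L, nDePerSpecies = 0)
  sim <- simulateExperiment(cfg, reads = FALSE)
  pair <- plantedPairs(sim@manifest)
  expect_true(all(pair$repression == 0))
  cnt <- SummarizedExperiment::assay(sim@mrna$fungus, "counts")
  lay <- sim@samples
  ctlSmp <- lay$sample[lay$condition == "control_fungus"]
  intSmp <- lay$sample[lay$interaction]
  for (tid in pair$transcript_id[startsWith(pair$transcript_id, "FT")])
    expect_lt(abs(log2(mean(cnt[tid, intSmp]) / mean(cnt[tid, ctlSmp]))),
              0.5)
})

test_that("read pools respect composition, error model and determinism", {
  cfg <- smallSimConfig(seed = 5, readsPerSample = 1000L,
                        fracStructural = 0.1, seqErrorRate = 0)
  sim <- simulateExperiment(cfg)
  pool <- sim@reads
  # conservation: per-sample totals equal readsPerSample
  tot <- tapply(pool@multiplicity, pool@sample, sum)
  expect_true(all(tot == 1000))
  # structural contaminants within the binomial 99% interval, one sample
  s1 <- pool@sequence[pool@sample == "interaction_wt_1"]
  nStruct <- sum(vapply(s1, function(r)
    any(grepl(r, sim@manifest@structural, fixed = TRUE)), logical(1)))
  expect_gte(nStruct, qbinom(0.005, 1000, 0.1))
  expect_lte(nStruct, qbinom(0.995, 1000, 0.1))
  # determinism: a rerun is byte-identical
  sim2 <- simulateExperiment(cfg)
  expect_identical(sim@reads, sim2@reads)
  d1 <- tempfile(); d2 <- tempfile()
  writeSrnaFastq(sim@reads, d1); writeSrnaFastq(sim2@reads, d2)
  f <- list.files(d1)
  expect_identical(lapply(file.path(d1, f), readLines),
                   lapply(file.path(d2, f), readLines))
})

test_that("a miRNA-only error-free pool contains only exact mature copies", {
  cfg <- smallSimConfig(seed = 6, readsPerSample = 500L, fracMirna = 1,
                        fracStructural = 0, fracOutOfRange = 0,
                        seqErrorRate = 0)
  sim <- simulateExperiment(cfg)
  mature <- plantedMirnas(sim@manifest)$sequence
  expect_true(all(sim@reads@sequence %in% mature))
  # length histogram supported exactly on planted mature lengths
  expect_true(all(nchar(sim@reads@sequence) %in% unique(nchar(mature))))
})

test_that("an empty read budget yields an empty pool with a warning", {
  cfg <- smallSimConfig(seed = 7, readsPerSample = 0L)
  refs <- generateReferences(cfg)
  pl <- plantMirnasAndTargets(refs, cfg)
  cm <- simulateCountMatrices(pl$references, pl, cfg)
  expect_warning(pool <- simulateSrnaReads(pl$references, pl,
                                           cm$mirnaTruth, cfg),
                 "empty")
  expect_length(pool, 0)
})
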