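#' @import methods
#' @importFrom S4Vectors DataFrame metadata
NULL

#' Configuration for the two-species synthetic experiment
#'
#' A `SimulationConfig` fully determines a synthetic dual-species small-RNA /
#' mRNA experiment: transcriptome sizes, sample layout, planted mature miRNAs,
#' planted differential expression, planted endogenous and cross-kingdom
#' target pairs, and the composition of the simulated small-RNA read pools.
#' Identical configurations (including the seed) always yield byte-identical
#' simulations.
#'
#' @slot seed Integer master seed; every stage of the generator derives its
#'   own substream from it, so upstream outputs never change when later
#'   stages are added or skipped.
#' @slot nTranscriptsPlant,nTranscriptsFungus Number of transcripts per
#'   species reference.
#' @slot transcriptLenRange Inclusive transcript length interval (nt).
#' @slot nSamplesPerCondition Biological replicates per condition (default 3,
#'   matching the three-replicate design the generator emulates).
#' @slot conditions Ordered condition labels. Conditions named
#'   `control_plant` / `control_fungus` contain a single species; all other
#'   conditions are interaction conditions containing both.
#' @slot nbDispersion Negative-binomial dispersion used for every simulated
#'   count (variance = mu + dispersion * mu^2). Must be > 0.
#' @slot nMirnasPlant,nMirnasFungus Planted mature miRNAs per species.
#' @slot mirnaLenRange Mature miRNA length interval, must lie within
#'   \[18, 32\].
#' @slot nEndogenousPairs,nCrosskingdomPairs Planted target pairs.
#'   Endogenous pairs alternate between the two species; cross-kingdom pairs
#'   link a plant miRNA to a fungal transcript.
#' @slot repressionLog2fc Planted induction of target transcripts during
#'   interaction and the strength of their per-sample anticorrelation
#'   coupling with the targeting miRNA (default 3.0). Zero makes planted
#'   targets indistinguishable from background.
#' @slot mirnaLog2fc Magnitude of the planted down-regulation of pair-owning
#'   miRNAs during interaction (default 3.0).
#' @slot nDePerSpecies Planted (non-target) differentially expressed
#'   transcripts per species.
#' @slot deLog2fcRange Magnitude interval for planted |log2FC| (default 2-6,
#'   random sign).
#' @slot seqErrorRate Per-read probability of a single substitution error in
#'   miRNA-derived reads (at most one substitution per read, no indels).
#' @slot fracStructural,fracMirna,fracOutOfRange Expected fractions of the
#'   read pool that are structural-RNA contaminants, mature miRNA copies, and
#'   out-of-length-range reads; the remainder are transcript degradation
#'   fragments drawn from both strands.
#' @slot fracHomologous Fraction of fungal transcripts that also occur
#'   identically in the plant reference, producing reads that map to both
#'   species.
#' @slot readsPerSample Reads simulated per sample.
#'
#' @seealso [simulationConfig()], [simulateExperiment()]
#' @export
setClass("SimulationConfig", representation(
  seed = "integer",
  nTranscriptsPlant = "integer",
  nTranscriptsFungus = "integer",
  transcriptLenRange = "integer",
  nSamplesPerCondition = "integer",
  conditions = "character",
  nbDispersion = "numeric",
  nMirnasPlant = "integer",
  nMirnasFungus = "integer",
  mirnaLenRange = "integer",
  nEndogenousPairs = "integer",
  nCrosskingdomPairs = "integer",
  repressionLog2fc = "numeric",
  mirnaLog2fc = "numeric",
  nDePerSpecies = "integer",
  deLog2fcRange = "numeric",
  seqErrorRate = "numeric",
  fracStructural = "numeric",
  fracMirna = "numeric",
  fracOutOfRange = "numeric",
  fracHomologous = "numeric",
  readsPerSample = "integer"
))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  chkpos <- function(x, nm) if (length(x) != 1L || is.na(x) || x < 1L)
    sprintf("'%s' must be a single count >= 1", nm) else character()
  msg <- c(msg,
    chkpos(object@seed, "seed"),
    chkpos(object@nTranscriptsPlant, "nTranscriptsPlant"),
    chkpos(object@nTranscriptsFungus, "nTranscriptsFungus"),
    chkpos(object@nSamplesPerCondition, "nSamplesPerCondition"))
  if (length(object@transcriptLenRange) != 2L ||
      object@transcriptLenRange[1] > object@transcriptLenRange[2])
    msg <- c(msg, "'transcriptLenRange' must be an ordered length-2 interval")
  if (length(object@mirnaLenRange) != 2L ||
      object@mirnaLenRange[1] > object@mirnaLenRange[2])
    msg <- c(msg, "'mirnaLenRange' must be an ordered length-2 interval")
  else if (object@mirnaLenRange[1] < 18L || object@mirnaLenRange[2] > 32L)
    msg <- c(msg, "'mirnaLenRange' must lie within [18, 32]")
  if (object@nbDispersion <= 0)
    msg <- c(msg, "'nbDispersion' must be > 0")
  for (nm in c("seqErrorRate", "fracStructural", "fracMirna",
               "fracOutOfRange", "fracHomologous")) {
    v <- slot(object, nm)
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
      msg <- c(msg, sprintf("'%s' must be a probability in [0, 1]", nm))
  }
  if (object@fracStructural + object@fracMirna + object@fracOutOfRange > 1)
    msg <- c(msg, "read composition fractions must sum to <= 1")
  if (object@repressionLog2fc < 0)
    msg <- c(msg, "'repressionLog2fc' must be >= 0")
  if (length(object@conditions) < 2L)
    msg <- c(msg, "at least two conditions are required")
  if (object@readsPerSample < 0L)
    msg <- c(msg, "'readsPerSample' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Ground truth manifest of a synthetic experiment
#'
#' Records everything the generator planted, so downstream inference can be
#' scored against a known truth: mature miRNA sequences with their true
#' per-sample abundances and condition effects, planted differentially
#' expressed transcripts, planted target pairs (with relationship class and
#' repression strength), transcripts duplicated across the two references,
#' structural contaminant sequences, and the emulated external
#' target-prediction tables.
#'
#' @slot mirnas data.frame: id, species, sequence, length, baseAbundance,
#'   log2fc (planted interaction effect), isDe.
#' @slot pairs data.frame: pair_id, mirna_id, transcript_id, relationship
#'   (`endogenous` or `cross_kingdom`), repression, polarity (-1: miRNA
#'   down during wildtype interaction, target released; +1: miRNA up,
#'   target repressed), site_start (1-based position of the embedded
#'   complementary site).
#' @slot deFeatures data.frame: feature, species, log2fc of planted
#'   (non-target) differential expression.
#' @slot homologous data.frame: plant_id, fungus_id of identical transcript
#'   copies.
#' @slot structural Named character vector of structural-RNA reference
#'   sequences (contaminant source).
#' @slot predictions data.frame emulating external target-prediction tool
#'   output: mirna_id, transcript_id, tool, style, score. Planted pairs are
#'   predicted by two plant-style pseudo-tools; decoy pairs exercise the
#'   rejection paths.
#' @export
setClass("GroundTruthManifest", representation(
  mirnas = "data.frame",
  pairs = "data.frame",
  deFeatures = "data.frame",
  homologous = "data.frame",
  structural = "character",
  predictions = "data.frame"
))

setValidity("GroundTruthManifest", function(object) {
  msg <- character()
  if (nrow(object@pairs)) {
    if (!all(object@pairs$mirna_id %in% object@mirnas$id))
      msg <- c(msg, "every planted pair must reference an existing miRNA")
    if (!all(object@pairs$relationship %in% c("endogenous", "cross_kingdom")))
      msg <- c(msg, "pair relationship must be endogenous or cross_kingdom")
  }
  if (length(msg)) msg else TRUE
})

#' A pool of (collapsed) small-RNA reads
#'
#' Sequences are normalized to the RNA alphabet (uppercase, T -> U) on
#' construction. Each record carries a multiplicity (copies observed) and the
#' sample it came from; a pool may span several samples.
#'
#' @slot sequence Character vector of RNA sequences.
#' @slot multiplicity Integer vector of copy numbers (>= 1).
#' @slot sample Character vector of sample ids.
#' @seealso [smallRNAPool()], [collapseReads()], [lengthFilter()]
#' @export
setClass("SmallRNAPool", representation(
  sequence = "character",
  multiplicity = "integer",
  sample = "character"
))

setValidity("SmallRNAPool", function(object) {
  msg <- character()
  n <- length(object@sequence)
  if (length(object@multiplicity) != n || length(object@sample) != n)
    msg <- c(msg, "slots must have equal length")
  if (n > 0) {
    if (any(!nzchar(object@sequence)))
      msg <- c(msg, "sequences must be non-empty")
    if (any(object@multiplicity < 1L))
      msg <- c(msg, "multiplicities must be >= 1")
    if (any(grepl("[^ACGU]", object@sequence)))
      msg <- c(msg, "sequences must be over the RNA alphabet {A,C,G,U}")
  }
  if (length(msg)) msg else TRUE
})

#' Result of partitioning reads between two species
#'
#' Every read is assigned to exactly one of four classes: matching only
#' species A, only species B, both (ambiguous, excluded from species-specific
#' counting downstream), or neither (unmapped). Individual transcript hits
#' with orientation and position are retained for antisense counting.
#'
#' @slot classification Factor per read with levels `unique_A`, `unique_B`,
#'   `ambiguous`, `unmapped`.
#' @slot hits data.frame of placements: read (index into the pool), species
#'   (`A`/`B`), transcript, strand (`sense`/`antisense`), start, end (0-based
#'   half-open on the transcript), weight (1/number of placements within the
#'   species, placements capped at `maxPlacements`).
#' @slot tallies Multiplicity-weighted read totals per class.
#' @slot nReads Number of read records partitioned.
#' @seealso [partitionBySpecies()], [antisenseCounts()]
#' @export
setClass("SpeciesPartition", representation(
  classification = "factor",
  hits = "data.frame",
  tallies = "numeric",
  nReads = "integer"
))

#' Thresholds for the target-inference filter cascade
#'
#' @slot minPlantTools Minimum plant-style tool votes for consensus
#'   (default 2).
#' @slot minAnimalTools Minimum animal-style tool votes for consensus
#'   (default 3).
#' @slot targetFdrAlpha FDR threshold applied to both the miRNA and the
#'   transcript differential-expression calls (default 0.05).
#' @slot mirnaFcThreshold |log2FC| threshold for the miRNA call (default
#'   1.5); transcripts need significance only, with no fold-change threshold.
#' @slot spearmanMax Retention threshold on the pair Spearman correlation
#'   (must be negative; default -0.4 for the lenient profile, -0.7 for the
#'   strict profile).
#' @slot wilcoxonAlpha Threshold on the anticorrelation-versus-background
#'   test p-value (default 0.1).
#' @seealso [filterThresholds()], [classifyTargets()]
#' @export
setClass("FilterThresholds", representation(
  minPlantTools = "integer",
  minAnimalTools = "integer",
  targetFdrAlpha = "numeric",
  mirnaFcThreshold = "numeric",
  spearmanMax = "numeric",
  wilcoxonAlpha = "numeric"
))

setValidity("FilterThresholds", function(object) {
  msg <- character()
  if (object@spearmanMax >= 0)
    msg <- c(msg, "'spearmanMax' must be negative")
  for (nm in c("targetFdrAlpha", "wilcoxonAlpha")) {
    v <- slot(object, nm)
    if (v <= 0 || v >= 1)
      msg <- c(msg, sprintf("'%s' must be in (0, 1)", nm))
  }
  if (object@minPlantTools < 1L || object@minAnimalTools < 1L)
    msg <- c(msg, "tool vote minima must be >= 1")
  if (length(msg)) msg else TRUE
})

#' A complete synthetic dual-species experiment
#'
#' Container returned by [simulateExperiment()]: the two transcript
#' references, the ground-truth manifest, per-species mRNA count matrices
#' (as [SummarizedExperiment::SummarizedExperiment] objects), per-species
#' miRNA count matrices, the true per-sample miRNA abundances, and
#' (optionally) the simulated small-RNA read pool.
#'
#' @slot config The [SimulationConfig-class] that produced the experiment.
#' @slot references Named list with elements `plant`, `fungus` (named
#'   character vectors of transcript sequences) and `structural`.
#' @slot manifest The [GroundTruthManifest-class].
#' @slot mrna Named list of two SummarizedExperiments (`plant`, `fungus`)
#'   with a `counts` assay and a `condition` column in `colData`.
#' @slot mirnaCounts Named list of two integer matrices (miRNA x sample).
#' @slot mirnaTruth Named list of two numeric matrices of true per-sample
#'   miRNA abundances (the means the counts were drawn around).
#' @slot reads A [SmallRNAPool-class] (zero-length when read simulation was
#'   skipped).
#' @slot samples data.frame of the sample layout: sample, condition,
#'   species-presence flags, and the per-sample depth factor every count
#'   mean was multiplied by.
#' @export
setClass("SrnaSimulation", representation(
  config = "SimulationConfig",
  references = "list",
  manifest = "GroundTruthManifest",
  mrna = "list",
  mirnaCounts = "list",
  mirnaTruth = "list",
  reads = "SmallRNAPool",
  samples = "data.frame"
))

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig\n")
  cat(sprintf("  seed: %d\n", object@seed))
  cat(sprintf("  transcripts: %d plant / %d fungus (len %d-%d nt, %.0f%% homologous)\n",
              object@nTranscriptsPlant, object@nTranscriptsFungus,
              object@transcriptLenRange[1], object@transcriptLenRange[2],
              100 * object@fracHomologous))
  cat(sprintf("  miRNAs: %d plant / %d fungus (len %d-%d nt)\n",
              object@nMirnasPlant, object@nMirnasFungus,
              object@mirnaLenRange[1], object@mirnaLenRange[2]))
  cat(sprintf("  pairs: %d endogenous, %d cross-kingdom (repression log2FC %.1f)\n",
              object@nEndogenousPairs, object@nCrosskingdomPairs,
              object@repressionLog2fc))
  cat(sprintf("  samples: %d x {%s}\n", object@nSamplesPerCondition,
              paste(object@conditions, collapse = ", ")))
  cat(sprintf("  counts: NB dispersion %.3g; reads/sample %d\n",
              object@nbDispersion, object@readsPerSample))
})

setMethod("show", "SmallRNAPool", function(object) {
  n <- length(object@sequence)
  cat(sprintf("SmallRNAPool with %d record(s), %d read(s), %d sample(s)\n",
              n, sum(object@multiplicity), length(unique(object@sample))))
  if (n > 0) {
    k <- min(n, 5L)
    for (i in seq_len(k))
      cat(sprintf("  %s x%d [%s]\n", object@sequence[i],
                  object@multiplicity[i], object@sample[i]))
    if (n > k) cat(sprintf("  ... and %d more\n", n - k))
  }
})

setMethod("show", "SpeciesPartition", function(object) {
  cat(sprintf("SpeciesPartition of %d read record(s)\n", object@nReads))
  t <- object@tallies
  for (nm in names(t))
    cat(sprintf("  %-10s %g\n", nm, t[[nm]]))
})

setMethod("show", "FilterThresholds", function(object) {
  cat("FilterThresholds\n")
  cat(sprintf("  consensus: >= %d plant-style or >= %d animal-style votes\n",
              object@minPlantTools, object@minAnimalTools))
  cat(sprintf("  expression: miRNA |log2FC| >= %.2g & FDR < %.2g; transcript FDR < %.2g\n",
              object@mirnaFcThreshold, object@targetFdrAlpha,
              object@targetFdrAlpha))
  cat(sprintf("  correlation: Spearman <= %.2g; background test p < %.2g\n",
              object@spearmanMax, object@wilcoxonAlpha))
})

setMethod("show", "SrnaSimulation", function(object) {
  cat("SrnaSimulation\n")
  cat(sprintf("  plant mRNA: %d x %d; fungus mRNA: %d x %d\n",
              nrow(object@mrna$plant), ncol(object@mrna$plant),
              nrow(object@mrna$fungus), ncol(object@mrna$fungus)))
  cat(sprintf("  miRNAs: %d plant, %d fungus; planted pairs: %d\n",
              nrow(object@mirnaCounts$plant), nrow(object@mirnaCounts$fungus),
              nrow(object@manifest@pairs)))
  cat(sprintf("  reads: %d record(s)\n", length(object@reads@sequence)))
})

setMethod("show", "GroundTruthManifest", function(object) {
  cat("GroundTruthManifest\n")
  cat(sprintf("  miRNAs: %d; pairs: %d (%d cross-kingdom); DE features: %d\n",
              nrow(object@mirnas), nrow(object@pairs),
              sum(object@pairs$relationship == "cross_kingdom"),
              nrow(object@deFeatures)))
  cat(sprintf("  homologous transcripts: %d; structural refs: %d; predictions: %d rows\n",
              nrow(object@homologous), length(object@structural),
              nrow(object@predictions)))
})

#' @describeIn SmallRNAPool-class Number of read records in the pool.
#' @param x A `SmallRNAPool`.
#' @export
setMethod("length", "SmallRNAPool", function(x) length(x@sequence))
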