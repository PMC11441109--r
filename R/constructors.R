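#' Create a simulation configuration
#'
#' Builds a validated [SimulationConfig-class]. Defaults describe the study
#' design the generator emulates: three biological replicates per condition,
#' two single-species control conditions plus three interaction conditions
#' (a wildtype and two silencing-mutant strains, in which planted miRNA
#' responses are absent),
#' 100 transcripts and 30 mature miRNAs per species (so differentially
#' expressed miRNAs stay a minority and median-of-ratios normalization is
#' unbiased), five endogenous and five cross-kingdom planted target pairs
#' with repression strength 3 log2 units, and negative-binomial counts with
#' dispersion 0.05.
#'
#' @param seed Integer master seed.
#' @param nTranscriptsPlant,nTranscriptsFungus Transcripts per species.
#' @param transcriptLenRange Length-2 integer interval of transcript lengths.
#' @param nSamplesPerCondition Replicates per condition.
#' @param conditions Ordered condition labels; `control_plant` and
#'   `control_fungus` are single-species, the rest are interactions.
#' @param nbDispersion Negative-binomial dispersion (> 0).
#' @param nMirnasPlant,nMirnasFungus Planted miRNAs per species.
#' @param mirnaLenRange Mature length interval within \[18, 32\].
#' @param nEndogenousPairs,nCrosskingdomPairs Planted pair counts.
#' @param repressionLog2fc Planted target induction / coupling strength.
#' @param mirnaLog2fc Planted miRNA down-regulation magnitude.
#' @param nDePerSpecies Planted non-target DE transcripts per species.
#' @param deLog2fcRange |log2FC| interval for planted DE.
#' @param seqErrorRate Per-read substitution probability for miRNA reads.
#' @param fracStructural,fracMirna,fracOutOfRange Read pool composition.
#' @param fracHomologous Fraction of fungal transcripts copied identically
#'   into the plant reference.
#' @param readsPerSample Simulated reads per sample.
#' @return A [SimulationConfig-class] object.
#' @examples
#' cfg <- simulationConfig(seed = 1, nTranscriptsPlant = 20,
#'                         nTranscriptsFungus = 20)
#' cfg
#' @export
simulationConfig <- function(seed = 1L,
                             nTranscriptsPlant = 100L,
                             nTranscriptsFungus = 100L,
                             transcriptLenRange = c(300L, 1500L),
                             nSamplesPerCondition = 3L,
                             conditions = c("control_plant", "control_fungus",
                                            "interaction_wt",
                                            "interaction_dcl1",
                                            "interaction_dcl2"),
                             nbDispersion = 0.05,
                             nMirnasPlant = 30L,
                             nMirnasFungus = 30L,
                             mirnaLenRange = c(19L, 24L),
                             nEndogenousPairs = 5L,
                             nCrosskingdomPairs = 5L,
                             repressionLog2fc = 3.0,
                             mirnaLog2fc = 3.5,
                             nDePerSpecies = 10L,
                             deLog2fcRange = c(2, 6),
                             seqErrorRate = 0.005,
                             fracStructural = 0.1,
                             fracMirna = 0.15,
                             fracOutOfRange = 0.05,
                             fracHomologous = 0.05,
                             readsPerSample = 2000L) {
  if (transcriptLenRange[1] > transcriptLenRange[2])
    stop("configuration error: 'transcriptLenRange' is inverted")
  new("SimulationConfig",
      seed = as.integer(seed),
      nTranscriptsPlant = as.integer(nTranscriptsPlant),
      nTranscriptsFungus = as.integer(nTranscriptsFungus),
      transcriptLenRange = as.integer(transcriptLenRange),
      nSamplesPerCondition = as.integer(nSamplesPerCondition),
      conditions = conditions,
      nbDispersion = nbDispersion,
      nMirnasPlant = as.integer(nMirnasPlant),
      nMirnasFungus = as.integer(nMirnasFungus),
      mirnaLenRange = as.integer(mirnaLenRange),
      nEndogenousPairs = as.integer(nEndogenousPairs),
      nCrosskingdomPairs = as.integer(nCrosskingdomPairs),
      repressionLog2fc = repressionLog2fc,
      mirnaLog2fc = mirnaLog2fc,
      nDePerSpecies = as.integer(nDePerSpecies),
      deLog2fcRange = as.numeric(deLog2fcRange),
      seqErrorRate = seqErrorRate,
      fracStructural = fracStructural,
      fracMirna = fracMirna,
      fracOutOfRange = fracOutOfRange,
      fracHomologous = fracHomologous,
      readsPerSample = as.integer(readsPerSample))
}

#' Create a small-RNA read pool
#'
#' @param sequence Character vector of read sequences (DNA or RNA alphabet;
#'   normalized to uppercase RNA).
#' @param multiplicity Integer copy numbers, recycled to the sequence length.
#' @param sample Sample ids, recycled likewise.
#' @return A [SmallRNAPool-class].
#' @examples
#' smallRNAPool(c("UGUAGAUACUCCCUAAGGCUU", "acguacguacguacguacgu"))
#' @export
smallRNAPool <- function(sequence = character(), multiplicity = 1L,
                         sample = "S1") {
  n <- length(sequence)
  new("SmallRNAPool",
      sequence = normalizeRna(sequence),
      multiplicity = rep_len(as.integer(multiplicity), n),
      sample = rep_len(as.character(sample), n))
}

#' Filter-cascade thresholds with profile presets
#'
#' The `lenient` profile uses the Spearman retention threshold -0.4; the
#' `strict` profile uses -0.7. All other defaults are shared: consensus
#' requires two plant-style or three animal-style tool votes, expression
#' calls use FDR < 0.05 (with |log2FC| >= 1.5 for the miRNA only), and the
#' anticorrelation background test uses p < 0.1.
#'
#' @param profile `"lenient"` (default) or `"strict"`.
#' @param minPlantTools,minAnimalTools,targetFdrAlpha,mirnaFcThreshold,spearmanMax,wilcoxonAlpha
#'   Individual overrides; see [FilterThresholds-class].
#' @return A [FilterThresholds-class].
#' @examples
#' filterThresholds()
#' filterThresholds("strict")
#' @export
filterThresholds <- function(profile = c("lenient", "strict"),
                             minPlantTools = 2L,
                             minAnimalTools = 3L,
                             targetFdrAlpha = 0.05,
                             mirnaFcThreshold = 1.5,
                             spearmanMax = NULL,
                             wilcoxonAlpha = 0.1) {
  profile <- match.arg(profile)
  if (is.null(spearmanMax))
    spearmanMax <- if (profile == "strict") -0.7 else -0.4
  new("FilterThresholds",
      minPlantTools = as.integer(minPlantTools),
      minAnimalTools = as.integer(minAnimalTools),
      targetFdrAlpha = targetFdrAlpha,
      mirnaFcThreshold = mirnaFcThreshold,
      spearmanMax = spearmanMax,
      wilcoxonAlpha = wilcoxonAlpha)
}

#' Coerce a read pool to a data.frame
#'
#' @param x A [SmallRNAPool-class].
#' @param ... Ignored.
#' @return data.frame with columns sequence, multiplicity, sample.
#' @export
as.data.frame.SmallRNAPool <- function(x, ...) {
  data.frame(sequence = x@sequence, multiplicity = x@multiplicity,
             sample = x@sample, stringsAsFactors = FALSE)
}

#' @rdname SpeciesPartition-class
#' @param x A `SpeciesPartition`.
#' @export
partitionClass <- function(x) x@classification

#' @rdname SpeciesPartition-class
#' @export
partitionHits <- function(x) x@hits

#' @rdname SpeciesPartition-class
#' @export
partitionTallies <- function(x) x@tallies

#' @rdname GroundTruthManifest-class
#' @param x A `GroundTruthManifest`.
#' @export
plantedPairs <- function(x) x@pairs

#' @rdname GroundTruthManifest-class
#' @export
plantedMirnas <- function(x) x@mirnas

#' @rdname GroundTruthManifest-class
#' @export
predictionTables <- function(x) x@predictions
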