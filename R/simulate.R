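# Synthetic two-species experiment generator. Stages run on independent RNG
# substreams derived once from the master seed, in a fixed documented order
# (references -> miRNA/target planting -> count matrices -> reads), so that
# running a stage standalone reproduces exactly what a composed run produces
# and adding stages never reshuffles earlier outputs.

stageSeeds <- function(config) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config@seed)
  s <- sample.int(2^30, 4L)
  names(s) <- c("references", "planting", "counts", "reads")
  s
}

sampleLayout <- function(config) {
  cond <- rep(config@conditions, each = config@nSamplesPerCondition)
  id <- paste(cond, sequence(rep(config@nSamplesPerCondition,
                                 length(config@conditions))), sep = "_")
  data.frame(sample = id, condition = cond,
             plant = cond != "control_fungus",
             fungus = cond != "control_plant",
             interaction = !startsWith(cond, "control"),
             stringsAsFactors = FALSE)
}

#' Generate the two species transcript references
#'
#' Draws random transcript sequences for both species plus a small set of
#' structural-RNA reference sequences (the contaminant source). A fraction
#' `fracHomologous` of the fungal transcripts is copied identically into the
#' plant reference, creating the ambiguous (both-species) mapping class
#' downstream. Deterministic under the configuration seed.
#'
#' @param config A [SimulationConfig-class].
#' @return List with named character vectors `plant`, `fungus`,
#'   `structural`, and a data.frame `homologous` (plant_id, fungus_id).
#' @examples
#' refs <- generateReferences(simulationConfig(seed = 1,
#'   nTranscriptsPlant = 10, nTranscriptsFungus = 5, fracHomologous = 0.2))
#' lengths(refs[c("plant", "fungus")])
#' @export
generateReferences <- function(config) {
  validObject(config)
  set.seed(stageSeeds(config)[["references"]])
  lens <- function(n) {
    v <- seq(config@transcriptLenRange[1], config@transcriptLenRange[2])
    v[sample.int(length(v), n, replace = TRUE)]
  }
  plant <- randomRna(lens(config@nTranscriptsPlant))
  names(plant) <- sprintf("PT%05d", seq_along(plant))
  fungus <- randomRna(lens(config@nTranscriptsFungus))
  names(fungus) <- sprintf("FT%05d", seq_along(fungus))

  nHom <- round(config@fracHomologous * config@nTranscriptsFungus)
  nHom <- min(nHom, config@nTranscriptsPlant)
  homologous <- data.frame(plant_id = character(), fungus_id = character(),
                           stringsAsFactors = FALSE)
  if (nHom > 0) {
    fi <- sample(length(fungus), nHom)
    pi <- sample(length(plant), nHom)
    plant[pi] <- fungus[fi]
    homologous <- data.frame(plant_id = names(plant)[pi],
                             fungus_id = names(fungus)[fi],
                             stringsAsFactors = FALSE)
  }
  structural <- randomRna(sample(150:300, 4, replace = TRUE))
  names(structural) <- c("rRNA_1", "tRNA_1", "snRNA_1", "snoRNA_1")
  list(plant = plant, fungus = fungus, structural = structural,
       homologous = homologous)
}

#' Plant mature miRNAs and target pairs into the references
#'
#' Draws the mature miRNA sequences for both species, assigns endogenous
#' (within-species, alternating) and cross-kingdom (plant miRNA to fungal
#' transcript) target pairs, and embeds the exact reverse complement of each
#' pair's mature sequence into its target transcript at a random position.
#' Also fixes the planted expression program (which miRNAs and transcripts
#' are differentially expressed and how strongly) and emulates two external
#' plant-style target-prediction tools: both predict every planted pair and
#' a set of decoy pairs that exercise the rejection paths downstream.
#'
#' @param references Output of [generateReferences()].
#' @param config A [SimulationConfig-class].
#' @return List: `mirnas` (data.frame id, species, sequence, length,
#'   baseAbundance, log2fc, isDe), `pairs` (data.frame pair_id, mirna_id,
#'   transcript_id, relationship, repression, polarity, site_start),
#'   `references`
#'   (updated, with sites embedded), `predictions` (emulated tool tables),
#'   `deFeatures` (planted non-target DE).
#' @export
plantMirnasAndTargets <- function(references, config) {
  validObject(config)
  set.seed(stageSeeds(config)[["planting"]])
  lenDraw <- function(n) {
    v <- seq(config@mirnaLenRange[1], config@mirnaLenRange[2])
    v[sample.int(length(v), n, replace = TRUE)]
  }
  mirnas <- data.frame(
    id = c(sprintf("pla-mir-%d", seq_len(config@nMirnasPlant)),
           sprintf("fun-mir-%d", seq_len(config@nMirnasFungus))),
    species = rep(c("plant", "fungus"),
                  c(config@nMirnasPlant, config@nMirnasFungus)),
    sequence = randomRna(lenDraw(config@nMirnasPlant + config@nMirnasFungus)),
    stringsAsFactors = FALSE)
  mirnas$length <- nchar(mirnas$sequence)
  mirnas$baseAbundance <- exp(stats::runif(nrow(mirnas), log(200), log(1000)))
  mirnas$log2fc <- 0

  nEnd <- config@nEndogenousPairs
  nCk <- config@nCrosskingdomPairs
  endSpecies <- rep(c("plant", "fungus"), length.out = nEnd)
  pairSpecies <- data.frame(
    mirna_species = c(endSpecies, rep("plant", nCk)),
    target_species = c(endSpecies, rep("fungus", nCk)),
    relationship = rep(c("endogenous", "cross_kingdom"), c(nEnd, nCk)),
    stringsAsFactors = FALSE)

  # distinct target transcripts per species, homologous copies excluded
  hom <- unlist(references$homologous, use.names = FALSE)
  avail <- lapply(c(plant = "plant", fungus = "fungus"), function(sp)
    setdiff(names(references[[sp]]), hom))
  pairs <- NULL
  if (nrow(pairSpecies)) {
    need <- table(factor(pairSpecies$target_species,
                         levels = c("plant", "fungus")))
    for (sp in names(need))
      if (need[[sp]] > length(avail[[sp]]))
        stop("configuration error: more pairs requested than ", sp,
             " transcripts available")
    picked <- lapply(names(avail), function(sp)
      sample(avail[[sp]], need[[sp]]))
    names(picked) <- names(avail)
    used <- c(plant = 0L, fungus = 0L)
    rows <- lapply(seq_len(nrow(pairSpecies)), function(i) {
      sm <- pairSpecies$mirna_species[i]
      st <- pairSpecies$target_species[i]
      cand <- mirnas$id[mirnas$species == sm]
      mid <- cand[((i - 1L) %% length(cand)) + 1L]
      used[st] <<- used[st] + 1L
      data.frame(pair_id = sprintf("pair_%d", i), mirna_id = mid,
                 transcript_id = picked[[st]][used[st]],
                 relationship = pairSpecies$relationship[i],
                 repression = config@repressionLog2fc,
                 polarity = if (i %% 2L == 1L) -1L else 1L,
                 site_start = NA_integer_, stringsAsFactors = FALSE)
    })
    pairs <- do.call(rbind, rows)
  } else {
    pairs <- data.frame(pair_id = character(), mirna_id = character(),
                        transcript_id = character(),
                        relationship = character(), repression = numeric(),
                        polarity = integer(), site_start = integer(),
                        stringsAsFactors = FALSE)
  }

  # embed exact reverse-complement sites
  for (i in seq_len(nrow(pairs))) {
    mseq <- mirnas$sequence[mirnas$id == pairs$mirna_id[i]]
    site <- revCompRna(mseq)
    sp <- if (startsWith(pairs$transcript_id[i], "PT")) "plant" else "fungus"
    tx <- references[[sp]][[pairs$transcript_id[i]]]
    pos <- sample(nchar(tx) - nchar(site) + 1L, 1L)
    substr(tx, pos, pos + nchar(site) - 1L) <- site
    references[[sp]][[pairs$transcript_id[i]]] <- tx
    pairs$site_start[i] <- pos
  }

  # planted expression program: pair-owning miRNAs respond during the
  # wildtype interaction with alternating polarity (a down-regulated miRNA
  # releases its target, an up-regulated one represses it), so planted
  # pairs do not all share one condition profile; a further ~15% of each
  # species' unpaired miRNAs respond too (alternating up/down), mirroring
  # the broad miRNA response the interaction elicits beyond the
  # target-coupled ones
  for (i in seq_len(nrow(pairs))) {
    j <- which(mirnas$id == pairs$mirna_id[i])
    if (mirnas$log2fc[j] == 0)
      mirnas$log2fc[j] <- pairs$polarity[i] * config@mirnaLog2fc
    else  # a miRNA reused across pairs keeps its first polarity
      pairs$polarity[i] <- sign(mirnas$log2fc[j])
  }
  for (sp in c("plant", "fungus")) {
    free <- which(mirnas$species == sp & mirnas$log2fc == 0)
    nExtra <- min(length(free),
                  max(1L, round(0.15 * sum(mirnas$species == sp))))
    if (nExtra > 0)
      mirnas$log2fc[free[seq_len(nExtra)]] <-
        config@mirnaLog2fc * rep_len(c(1, -1), nExtra)
  }
  mirnas$isDe <- mirnas$log2fc != 0

  # planted non-target DE transcripts
  deRows <- lapply(c("plant", "fungus"), function(sp) {
    cand <- setdiff(avail[[sp]], pairs$transcript_id)
    n <- min(config@nDePerSpecies, length(cand))
    if (n == 0) return(NULL)
    data.frame(feature = sample(cand, n), species = sp,
               log2fc = stats::runif(n, config@deLog2fcRange[1],
                                     config@deLog2fcRange[2]) *
                 sample(c(-1, 1), n, replace = TRUE),
               stringsAsFactors = FALSE)
  })
  deFeatures <- do.call(rbind, deRows)
  if (is.null(deFeatures))
    deFeatures <- data.frame(feature = character(), species = character(),
                             log2fc = numeric(), stringsAsFactors = FALSE)

  predictions <- simulatePredictionTables(mirnas, references, pairs)
  list(mirnas = mirnas, pairs = pairs, references = references,
       predictions = predictions, deFeatures = deFeatures)
}

# Emulated external prediction tables: two plant-style pseudo-tools that
# both predict every planted pair, plus shared and tool-unique random decoy
# pairs (non-planted), so consensus, expression and correlation rejections
# are all exercised.
simulatePredictionTables <- function(mirnas, references, pairs,
                                     nSharedDecoys = 10L,
                                     nUniqueDecoys = 5L) {
  allTx <- c(names(references$plant), names(references$fungus))
  planted <- paste(pairs$mirna_id, pairs$transcript_id)
  drawDecoys <- function(n) {
    out <- data.frame(mirna_id = character(), transcript_id = character(),
                      stringsAsFactors = FALSE)
    guard <- 0L
    while (nrow(out) < n && guard < 50L) {
      guard <- guard + 1L
      cand <- data.frame(mirna_id = sample(mirnas$id, n, replace = TRUE),
                         transcript_id = sample(allTx, n, replace = TRUE),
                         stringsAsFactors = FALSE)
      cand <- cand[!(paste(cand$mirna_id, cand$transcript_id) %in%
                       c(planted, paste(out$mirna_id, out$transcript_id))), ]
      out <- rbind(out, cand)
    }
    utils::head(out, n)
  }
  shared <- drawDecoys(nSharedDecoys)
  uniqA <- drawDecoys(nUniqueDecoys)
  uniqB <- drawDecoys(nUniqueDecoys)
  mk <- function(df, tool) {
    if (!nrow(df))
      return(data.frame(mirna_id = character(), transcript_id = character(),
                        tool = character(), style = character(),
                        score = numeric(), stringsAsFactors = FALSE))
    data.frame(mirna_id = df$mirna_id, transcript_id = df$transcript_id,
               tool = tool, style = "plant",
               score = round(stats::runif(nrow(df), 0, 5), 2),
               stringsAsFactors = FALSE)
  }
  plantedDf <- pairs[, c("mirna_id", "transcript_id")]
  rbind(mk(rbind(plantedDf, shared, uniqA), "simtool_A"),
        mk(rbind(plantedDf, shared, uniqB), "simtool_B"))
}

#' Simulate mRNA and miRNA count matrices
#'
#' Counts are negative binomial with the configured dispersion around
#' per-sample means. Planted DE transcripts shift their mean by
#' `2^log2fc` in interaction samples. Responsive miRNAs carry their
#' planted effect in the wildtype interaction only (not in mutant
#' interaction conditions), plus lognormal per-sample variation; planted
#' targets couple to the targeting miRNA's relative abundance
#' `rel = a / max(a)` as `2^(repression * (1 - rel))` (released target of
#' a down-regulated miRNA) or `2^(-repression * rel)` (repressed target of
#' an up-regulated one), so miRNA and target counts anticorrelate across
#' samples. With `repressionLog2fc = 0` planted targets follow exactly the
#' background model.
#'
#' @param references References with embedded sites
#'   (from [plantMirnasAndTargets()]).
#' @param planting Output of [plantMirnasAndTargets()].
#' @param config A [SimulationConfig-class].
#' @return List: `mrna` (two [SummarizedExperiment::SummarizedExperiment]s),
#'   `mirnaCounts` and `mirnaTruth` (per-species matrices), `samples`
#'   (layout data.frame).
#' @importFrom SummarizedExperiment SummarizedExperiment
#' @importFrom S4Vectors DataFrame
#' @export
simulateCountMatrices <- function(references, planting, config) {
  validObject(config)
  if (config@nbDispersion <= 0)
    stop("configuration error: 'nbDispersion' must be > 0")
  set.seed(stageSeeds(config)[["counts"]])
  lay <- sampleLayout(config)
  size <- 1 / config@nbDispersion
  depth <- exp(stats::rnorm(nrow(lay), 0, 0.15))
  names(depth) <- lay$sample
  mirnas <- planting$mirnas
  pairs <- planting$pairs

  # true per-sample miRNA abundances (means), per species. Planted
  # condition effects act in interaction conditions except those named
  # *_mut / *_dcl* (emulating silencing-deficient mutant strains in which
  # the miRNA response is absent); the wildtype/mutant contrast is what
  # spreads miRNA levels across interaction samples and drives the planted
  # anticorrelation.
  responsive <- lay$interaction & !grepl("mut|dcl", lay$condition)
  mirnaTruth <- list()
  for (sp in c("plant", "fungus")) {
    rows <- mirnas[mirnas$species == sp, ]
    cols <- lay$sample[lay[[sp]]]
    resp <- responsive[lay[[sp]]]
    a <- matrix(0, nrow(rows), length(cols),
                dimnames = list(rows$id, cols))
    for (i in seq_len(nrow(rows))) {
      jit <- exp(stats::rnorm(length(cols), 0, 0.35))
      a[i, ] <- rows$baseAbundance[i] * 2^(rows$log2fc[i] * resp) * jit
    }
    mirnaTruth[[sp]] <- a
  }

  # mRNA mean model
  meanModel <- list()
  for (sp in c("plant", "fungus")) {
    feat <- names(references[[sp]])
    cols <- lay$sample[lay[[sp]]]
    isInt <- lay$interaction[lay[[sp]]]
    base <- pmax(exp(stats::rnorm(length(feat), log(300), 1)), 5)
    names(base) <- feat
    if (config@repressionLog2fc > 0) {
      tg <- pairs$transcript_id[pairs$transcript_id %in% feat]
      base[tg] <- exp(stats::runif(length(tg), log(300), log(1000)))
    }
    lfc <- stats::setNames(numeric(length(feat)), feat)
    de <- planting$deFeatures[planting$deFeatures$species == sp, ]
    lfc[de$feature] <- de$log2fc
    mu <- outer(base, rep(1, length(cols)))
    colnames(mu) <- cols
    mu <- mu * 2^(outer(lfc, as.numeric(isInt)))
    meanModel[[sp]] <- mu
  }

  # couple planted targets to their miRNA's relative abundance: for a
  # down-regulated miRNA the target is released (induced by up to
  # 2^repression where the miRNA is lowest); for an up-regulated miRNA it
  # is repressed below baseline where the miRNA is highest
  for (i in seq_len(nrow(pairs))) {
    rep_fc <- pairs$repression[i]
    if (rep_fc == 0) next
    mid <- pairs$mirna_id[i]
    sm <- mirnas$species[mirnas$id == mid]
    st <- if (startsWith(pairs$transcript_id[i], "PT")) "plant" else "fungus"
    mu <- meanModel[[st]]
    tcols <- colnames(mu)
    cols <- if (pairs$relationship[i] == "endogenous")
      intersect(tcols, colnames(mirnaTruth[[sm]]))
    else tcols[lay$interaction[match(tcols, lay$sample)]]
    a <- mirnaTruth[[sm]][mid, cols]
    rel <- a / max(a)
    mult <- if (pairs$polarity[i] < 0) 2^(rep_fc * (1 - rel))
    else 2^(-rep_fc * rel)
    mu[pairs$transcript_id[i], cols] <-
      mu[pairs$transcript_id[i], cols] * mult
    meanModel[[st]] <- mu
  }

  drawCounts <- function(mu, cols) {
    m <- matrix(stats::rnbinom(length(mu),
                               mu = sweep(mu, 2, depth[cols], `*`),
                               size = size),
                nrow(mu), ncol(mu), dimnames = dimnames(mu))
    storage.mode(m) <- "integer"
    m
  }
  mrna <- list()
  for (sp in c("plant", "fungus")) {
    cols <- colnames(meanModel[[sp]])
    cnt <- drawCounts(meanModel[[sp]], cols)
    se <- SummarizedExperiment(
      assays = list(counts = cnt),
      colData = DataFrame(condition = lay$condition[match(cols, lay$sample)],
                          row.names = cols))
    S4Vectors::metadata(se)$species <- sp
    S4Vectors::metadata(se)$orientation <- "sense"
    mrna[[sp]] <- se
  }
  mirnaCounts <- lapply(c(plant = "plant", fungus = "fungus"), function(sp)
    drawCounts(mirnaTruth[[sp]], colnames(mirnaTruth[[sp]])))

  lay$depth <- depth
  list(mrna = mrna, mirnaCounts = mirnaCounts, mirnaTruth = mirnaTruth,
       samples = lay)
}

#' Simulate per-sample small-RNA read pools
#'
#' Each sample's pool is a multinomial mixture of mature miRNA copies
#' (sampled proportionally to the sample's true abundances, with at most one
#' substitution error per read at `seqErrorRate`), transcript degradation
#' fragments of 18-32 nt drawn uniformly from both strands of the species
#' present in the sample, exact windows of the structural references, and
#' out-of-length-range fragments. Per-sample totals always equal
#' `readsPerSample`.
#'
#' @param references References with embedded sites.
#' @param planting Output of [plantMirnasAndTargets()].
#' @param mirnaTruth True per-sample miRNA abundances
#'   (from [simulateCountMatrices()]).
#' @param config A [SimulationConfig-class].
#' @return A [SmallRNAPool-class] covering all samples (multiplicity 1;
#'   collapse with [collapseReads()]).
#' @export
simulateSrnaReads <- function(references, planting, mirnaTruth, config) {
  validObject(config)
  set.seed(stageSeeds(config)[["reads"]])
  lay <- sampleLayout(config)
  if (config@readsPerSample == 0L) {
    warning("readsPerSample is 0: returning an empty pool")
    return(smallRNAPool(character(), integer(), character()))
  }
  mirnas <- planting$mirnas
  structural <- references$structural
  bases <- c("A", "C", "G", "U")
  probs <- c(structural = config@fracStructural,
             mirna = config@fracMirna,
             out = config@fracOutOfRange)
  probs <- c(probs, degradation = max(0, 1 - sum(probs)))

  fragment <- function(seqs, lens) {
    src <- sample(length(seqs), length(lens), replace = TRUE)
    vapply(seq_along(lens), function(j) {
      s <- seqs[[src[j]]]
      L <- min(lens[j], nchar(s))
      st <- sample(nchar(s) - L + 1L, 1L)
      substr(s, st, st + L - 1L)
    }, character(1))
  }

  out <- vector("list", nrow(lay))
  for (si in seq_len(nrow(lay))) {
    smp <- lay$sample[si]
    comp <- as.vector(stats::rmultinom(1, config@readsPerSample, probs))
    names(comp) <- names(probs)
    present <- c("plant", "fungus")[c(lay$plant[si], lay$fungus[si])]
    txSeqs <- unlist(lapply(present, function(sp) references[[sp]]),
                     use.names = FALSE)

    reads <- character(0)
    if (comp[["mirna"]] > 0) {
      rows <- mirnas[mirnas$species %in% present, ]
      ab <- vapply(seq_len(nrow(rows)), function(i) {
        tr <- mirnaTruth[[rows$species[i]]]
        if (smp %in% colnames(tr)) tr[rows$id[i], smp] else 0
      }, numeric(1))
      idx <- sample(nrow(rows), comp[["mirna"]], replace = TRUE, prob = ab)
      mr <- rows$sequence[idx]
      err <- stats::runif(length(mr)) < config@seqErrorRate
      for (j in which(err)) {
        p <- sample(nchar(mr[j]), 1L)
        cur <- substr(mr[j], p, p)
        substr(mr[j], p, p) <- sample(setdiff(bases, cur), 1L)
      }
      reads <- c(reads, mr)
    }
    if (comp[["structural"]] > 0)
      reads <- c(reads, fragment(structural,
                                 sample(18:32, comp[["structural"]],
                                        replace = TRUE)))
    if (comp[["degradation"]] > 0) {
      fr <- fragment(txSeqs, sample(18:32, comp[["degradation"]],
                                    replace = TRUE))
      anti <- stats::runif(length(fr)) < 0.5
      fr[anti] <- revCompRna(fr[anti])
      reads <- c(reads, fr)
    }
    if (comp[["out"]] > 0)
      reads <- c(reads, fragment(txSeqs,
                                 sample(c(15:17, 33:36), comp[["out"]],
                                        replace = TRUE)))
    out[[si]] <- smallRNAPool(reads, 1L, smp)
  }
  do.call(combinePools, out)
}

#' Concatenate read pools
#'
#' @param ... [SmallRNAPool-class] objects.
#' @return A single combined [SmallRNAPool-class].
#' @export
combinePools <- function(...) {
  ps <- list(...)
  new("SmallRNAPool",
      sequence = unlist(lapply(ps, slot, "sequence"), use.names = FALSE),
      multiplicity = unlist(lapply(ps, slot, "multiplicity"),
                            use.names = FALSE),
      sample = unlist(lapply(ps, slot, "sample"), use.names = FALSE))
}

#' Simulate a complete two-species experiment
#'
#' Runs all generator stages in their documented order and assembles the
#' result with its ground-truth manifest.
#'
#' @param config A [SimulationConfig-class].
#' @param reads Simulate the small-RNA read pool as well? Count-level
#'   analyses do not need it; skipping it makes multi-seed studies cheap.
#' @return An [SrnaSimulation-class].
#' @examples
#' sim <- simulateExperiment(simulationConfig(seed = 7,
#'   nTranscriptsPlant = 20, nTranscriptsFungus = 20,
#'   nEndogenousPairs = 1, nCrosskingdomPairs = 1, readsPerSample = 200))
#' sim
#' @export
simulateExperiment <- function(config, reads = TRUE) {
  refs <- generateReferences(config)
  planting <- plantMirnasAndTargets(refs, config)
  cm <- simulateCountMatrices(planting$references, planting, config)
  pool <- if (reads)
    simulateSrnaReads(planting$references, planting, cm$mirnaTruth, config)
  else smallRNAPool(character(), integer(), character())
  manifest <- new("GroundTruthManifest",
                  mirnas = planting$mirnas,
                  pairs = planting$pairs,
                  deFeatures = planting$deFeatures,
                  homologous = refs$homologous,
                  structural = refs$structural,
                  predictions = planting$predictions)
  new("SrnaSimulation", config = config,
      references = planting$references, manifest = manifest,
      mrna = cm$mrna, mirnaCounts = cm$mirnaCounts,
      mirnaTruth = cm$mirnaTruth, reads = pool, samples = cm$samples)
}
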