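# File interfaces: FASTA/FASTQ through Biostrings, TSV count and
# prediction tables, the JSON ground-truth manifest, and the shipped
# published miRNA differential-expression catalog.

#' Write a collapsed read pool as FASTA
#'
#' Headers follow the collapsed-read dialect `seq{i}_x{multiplicity}` used
#' by small-RNA toolchains (and mirrored by catalog ids such as
#' `mir_12061_x13`). One file per call; multi-sample pools should be split
#' first.
#'
#' @param pool A [SmallRNAPool-class].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @importFrom Biostrings RNAStringSet writeXStringSet
#' @export
writeCollapsedFasta <- function(pool, path) {
  s <- RNAStringSet(pool@sequence)
  names(s) <- sprintf("seq%d_x%d", seq_along(pool@sequence),
                      pool@multiplicity)
  writeXStringSet(s, path)
  invisible(path)
}

#' Read a collapsed-read FASTA
#'
#' Multiplicities are recovered from the trailing `_x{count}` of each
#' header (1 when absent).
#'
#' @param path FASTA path.
#' @param sample Sample id to assign (default "S1").
#' @return A [SmallRNAPool-class].
#' @importFrom Biostrings readBStringSet
#' @export
readCollapsedFasta <- function(path, sample = "S1") {
  s <- readBStringSet(path)
  mult <- suppressWarnings(as.integer(sub(".*_x(\\d+)$", "\\1", names(s))))
  mult[is.na(mult)] <- 1L
  smallRNAPool(as.character(s), mult, sample)
}

#' Write per-sample FASTQ files
#'
#' Sequences are written in the DNA alphabet (U back to T) with constant
#' quality "I"; multiplicities are expanded to repeated records so the
#' files represent raw (uncollapsed) reads.
#'
#' @param pool A [SmallRNAPool-class].
#' @param dir Output directory; one `<sample>.fastq` per sample.
#' @return Named character vector of written paths, invisibly.
#' @importFrom Biostrings DNAStringSet
#' @export
writeSrnaFastq <- function(pool, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  for (smp in unique(pool@sample)) {
    sel <- pool@sample == smp
    seqs <- rep(pool@sequence[sel], pool@multiplicity[sel])
    s <- DNAStringSet(chartr("U", "T", seqs))
    names(s) <- sprintf("%s_read%d", smp, seq_along(s))
    p <- file.path(dir, paste0(smp, ".fastq"))
    writeXStringSet(s, p, format = "fastq",
                    qualities = Biostrings::BStringSet(
                      strrep("I", nchar(seqs))))
    paths[smp] <- p
  }
  invisible(paths)
}

#' Read a FASTQ file into a read pool
#'
#' @param path FASTQ path.
#' @param sample Sample id to assign (default: file name without
#'   extension).
#' @return An uncollapsed [SmallRNAPool-class] (multiplicity 1 per record).
#' @importFrom Biostrings readDNAStringSet
#' @export
readSrnaFastq <- function(path, sample = NULL) {
  if (is.null(sample))
    sample <- sub("\\.(fastq|fq)(\\.gz)?$", "", basename(path))
  s <- readDNAStringSet(path, format = "fastq")
  smallRNAPool(as.character(s), 1L, sample)
}

#' Write a count matrix as TSV
#'
#' Header row holds sample ids; the first column (`feature`) holds feature
#' ids.
#'
#' @param counts Matrix or `SummarizedExperiment` (its `counts` assay).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeCountMatrix <- function(counts, path) {
  if (is(counts, "SummarizedExperiment"))
    counts <- SummarizedExperiment::assay(counts, "counts")
  df <- data.frame(feature = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV count matrix
#'
#' @param path TSV path (first column feature ids, header sample ids).
#' @return Integer matrix.
#' @export
readCountMatrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Read an external target-prediction table
#'
#' @param path TSV with columns mirna_id, transcript_id and optionally
#'   tool, style, score.
#' @param tool,style Defaults for tables lacking those columns.
#' @return Prediction data.frame suitable for [consensusFilter()].
#' @export
readPredictionTable <- function(path, tool = NULL, style = "plant") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"tool" %in% names(df)) {
    if (is.null(tool)) stop("table has no 'tool' column and no default")
    df$tool <- tool
  }
  if (!"style" %in% names(df)) df$style <- style
  if (!"score" %in% names(df)) df$score <- NA_real_
  df[, c("mirna_id", "transcript_id", "tool", "style", "score")]
}

#' Write a ground-truth manifest as JSON
#'
#' @param manifest A [GroundTruthManifest-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeManifestJson <- function(manifest, path) {
  jsonlite::write_json(
    list(mirnas = manifest@mirnas, pairs = manifest@pairs,
         de_features = manifest@deFeatures,
         homologous = manifest@homologous,
         structural = as.list(manifest@structural),
         predictions = manifest@predictions),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a complete simulation to disk
#'
#' FASTA references and miRNA catalog, per-sample FASTQ read files, TSV
#' count matrices, and the JSON manifest.
#'
#' @param sim An [SrnaSimulation-class].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (sp in c("plant", "fungus")) {
    s <- RNAStringSet(sim@references[[sp]])
    writeXStringSet(s, file.path(dir, paste0(sp, "_transcripts.fasta")))
    writeCountMatrix(sim@mrna[[sp]],
                     file.path(dir, paste0(sp, "_mrna_counts.tsv")))
    writeCountMatrix(sim@mirnaCounts[[sp]],
                     file.path(dir, paste0(sp, "_mirna_counts.tsv")))
  }
  cat_ <- RNAStringSet(stats::setNames(sim@manifest@mirnas$sequence,
                                       sim@manifest@mirnas$id))
  writeXStringSet(cat_, file.path(dir, "mirna_catalog.fasta"))
  writeXStringSet(RNAStringSet(sim@manifest@structural),
                  file.path(dir, "structural.fasta"))
  if (length(sim@reads) > 0)
    writeSrnaFastq(sim@reads, file.path(dir, "reads"))
  writeManifestJson(sim@manifest, file.path(dir, "manifest.json"))
  invisible(dir)
}

#' Read a mature miRNA catalog FASTA
#'
#' @param path FASTA of mature sequences (DNA or RNA alphabet).
#' @return Named character vector of RNA-normalized mature sequences.
#' @export
readMirnaCatalog <- function(path) {
  s <- readBStringSet(path)
  stats::setNames(normalizeRna(as.character(s)), names(s))
}

#' Write a species-partition report as TSV
#'
#' One row per read record: classification, sequence, multiplicity, sample.
#'
#' @param partition A [SpeciesPartition-class].
#' @param pool The partitioned [SmallRNAPool-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writePartitionTsv <- function(partition, pool, path) {
  df <- data.frame(sequence = pool@sequence,
                   multiplicity = pool@multiplicity,
                   sample = pool@sample,
                   class = as.character(partition@classification),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a differential-expression table as TSV
#'
#' @param de data.frame from [differentialExpression()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeDeTable <- function(de, path) {
  utils::write.table(de, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Published miRNA / milRNA differential-expression catalog
#'
#' The catalog of differentially expressed wheat miRNAs and fungal
#' (Clonostachys rosea) milRNAs from a published wheat-root interaction
#' experiment, shipped with the package: mature sequence, length, total
#' read count, and log2 fold changes with significance flags for the
#' interaction-versus-control contrast and the two Dicer-deletion
#' (dcl1/dcl2 versus wildtype interaction) contrasts.
#'
#' @return data.frame with columns id, group, total_count, sequence,
#'   length, log2fc_interaction, sig_interaction, log2fc_dcl1, sig_dcl1,
#'   log2fc_dcl2, sig_dcl2.
#' @examples
#' cat3 <- publishedMirnaDe()
#' table(applyCallRule(cat3$log2fc_interaction, cat3$sig_interaction),
#'       cat3$group)
#' @export
publishedMirnaDe <- function() {
  utils::read.delim(system.file("extdata", "published_mirna_de.tsv",
                                package = "xksilence"),
                    stringsAsFactors = FALSE)
}
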