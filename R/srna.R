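# Small-RNA read triage: length filtering, structural-RNA removal, read
# collapsing and two-species partitioning. Partitioning matches reads (and
# their reverse complements) against transcriptome references by approximate
# substring search; reads matching both species are classed ambiguous and
# excluded from species-specific counting, mirroring dual RNA-seq practice.

#' Filter reads by length
#'
#' Retains reads whose length lies in `[minLen, maxLen]`, boundaries
#' inclusive (the conventional small-RNA window is 18-32 nt).
#'
#' @param pool A [SmallRNAPool-class].
#' @param minLen,maxLen Inclusive length bounds.
#' @return The filtered pool.
#' @examples
#' p <- smallRNAPool(c("ACGUACGUACGUACGUA", "ACGUACGUACGUACGUAC"))
#' length(lengthFilter(p))  # the 17-mer is dropped
#' @export
lengthFilter <- function(pool, minLen = 18L, maxLen = 32L) {
  if (minLen > maxLen)
    stop("configuration error: minLen > maxLen")
  keep <- nchar(pool@sequence) >= minLen & nchar(pool@sequence) <= maxLen
  subsetPool(pool, keep)
}

subsetPool <- function(pool, keep) {
  new("SmallRNAPool", sequence = pool@sequence[keep],
      multiplicity = pool@multiplicity[keep], sample = pool@sample[keep])
}

#' Remove structural-RNA contaminant reads
#'
#' A read is removed iff it occurs as a substring of any structural
#' reference sequence (rRNA/tRNA/snRNA/snoRNA) within `maxErrors` edits
#' (default 0: exact substring). Multiplicities of surviving reads are
#' untouched.
#'
#' @param pool A [SmallRNAPool-class].
#' @param structuralRef Character vector (or RNA-coercible) of structural
#'   reference sequences.
#' @param maxErrors Edit tolerance for the substring match.
#' @return The filtered pool. An empty reference set passes everything
#'   through with a warning.
#' @export
removeStructural <- function(pool, structuralRef, maxErrors = 0L) {
  if (length(structuralRef) == 0) {
    warning("empty structural reference: no reads removed")
    return(pool)
  }
  refs <- normalizeRna(structuralRef)
  uniq <- unique(pool@sequence)
  hit <- vapply(uniq, function(s)
    length(approxMatch(s, refs, maxErrors)) > 0, logical(1))
  remove <- pool@sequence %in% uniq[hit]
  subsetPool(pool, !remove)
}

#' Collapse identical reads within samples
#'
#' Merges records with identical sequence and sample id, summing
#' multiplicities; total multiplicity is conserved.
#'
#' @param pool A [SmallRNAPool-class].
#' @return The collapsed pool, ordered by sample then sequence.
#' @export
collapseReads <- function(pool) {
  if (length(pool) == 0) return(pool)
  key <- paste(pool@sample, pool@sequence, sep = "\r")
  mult <- tapply(pool@multiplicity, key, sum)
  parts <- strsplit(names(mult), "\r", fixed = TRUE)
  new("SmallRNAPool",
      sequence = vapply(parts, `[`, character(1), 2L),
      multiplicity = as.integer(mult),
      sample = vapply(parts, `[`, character(1), 1L))
}

#' Partition reads between two species
#'
#' A read "maps" to a species iff the read or its reverse complement occurs
#' as a substring of any transcript of that species within `maxErrors` edits.
#' Reads matching only one species are unique to it; reads matching both are
#' ambiguous (excluded from species-specific counting downstream); reads
#' matching neither are unmapped. For reads matching several transcripts of
#' one species, each transcript hit is recorded once, capped at
#' `maxPlacements` placements, and weighted `1/n` placements so total counts
#' are conserved. The leftmost match position per transcript is recorded in
#' 0-based half-open coordinates; `sense` means the read itself matches the
#' transcript, `antisense` means its reverse complement does.
#'
#' @param pool A [SmallRNAPool-class].
#' @param refA,refB Named character vectors of transcript sequences for
#'   species A and B.
#' @param maxErrors Edit tolerance (default 1).
#' @param maxPlacements Cap on recorded placements per read and species.
#' @return A [SpeciesPartition-class].
#' @export
partitionBySpecies <- function(pool, refA, refB, maxErrors = 1L,
                               maxPlacements = 200L) {
  if (length(refA) == 0 || length(refB) == 0)
    stop("both references must be non-empty")
  refA <- vapply(refA, normalizeRna, character(1))
  refB <- vapply(refB, normalizeRna, character(1))
  n <- length(pool)
  uniq <- unique(pool@sequence)
  rc <- revCompRna(uniq)

  hitTable <- function(seqs, ref, species, strand) {
    res <- vector("list", length(seqs))
    for (i in seq_along(seqs)) {
      idx <- approxMatch(seqs[[i]], ref, maxErrors)
      if (length(idx))
        res[[i]] <- data.frame(useq = i, species = species,
                               transcript = names(ref)[idx],
                               strand = strand, stringsAsFactors = FALSE)
    }
    do.call(rbind, res[!vapply(res, is.null, logical(1))])
  }
  hits <- rbind(hitTable(uniq, refA, "A", "sense"),
                hitTable(rc, refA, "A", "antisense"),
                hitTable(uniq, refB, "B", "sense"),
                hitTable(rc, refB, "B", "antisense"))

  inA <- logical(length(uniq)); inB <- logical(length(uniq))
  if (!is.null(hits)) {
    inA[unique(hits$useq[hits$species == "A"])] <- TRUE
    inB[unique(hits$useq[hits$species == "B"])] <- TRUE
  }
  classUniq <- ifelse(inA & inB, "ambiguous",
                      ifelse(inA, "unique_A",
                             ifelse(inB, "unique_B", "unmapped")))
  um <- match(pool@sequence, uniq)
  classification <- factor(classUniq[um],
                           levels = c("unique_A", "unique_B", "ambiguous",
                                      "unmapped"))

  hitsOut <- data.frame(read = integer(), species = character(),
                        transcript = character(), strand = character(),
                        start = integer(), end = integer(),
                        weight = numeric(), stringsAsFactors = FALSE)
  if (!is.null(hits)) {
    # cap placements per unique read within each species, weight 1/n
    keyUS <- paste(hits$useq, hits$species)
    hits <- hits[stats::ave(seq_len(nrow(hits)), keyUS,
                            FUN = seq_along) <= maxPlacements, ]
    keyUS <- paste(hits$useq, hits$species)
    nPlace <- stats::ave(rep(1L, nrow(hits)), keyUS, FUN = sum)
    hits$weight <- 1 / nPlace
    # positions (leftmost) on demand
    pos <- t(vapply(seq_len(nrow(hits)), function(i) {
      ref <- if (hits$species[i] == "A") refA else refB
      q <- if (hits$strand[i] == "sense") uniq[hits$useq[i]] else
        rc[hits$useq[i]]
      loc <- approxLocate(q, ref[[hits$transcript[i]]], maxErrors)
      if (is.null(loc)) c(NA_integer_, NA_integer_) else as.integer(loc)
    }, integer(2)))
    # expand unique-sequence hits to read records
    expand <- lapply(seq_along(pool@sequence), function(ri) {
      sel <- which(hits$useq == um[ri])
      if (!length(sel)) return(NULL)
      data.frame(read = ri, species = hits$species[sel],
                 transcript = hits$transcript[sel],
                 strand = hits$strand[sel],
                 start = pos[sel, 1], end = pos[sel, 2],
                 weight = hits$weight[sel], stringsAsFactors = FALSE)
    })
    expand <- expand[!vapply(expand, is.null, logical(1))]
    if (length(expand)) hitsOut <- do.call(rbind, expand)
  }

  tallies <- vapply(split(pool@multiplicity, classification), sum,
                    numeric(1))
  tallies[is.na(tallies)] <- 0
  new("SpeciesPartition", classification = classification,
      hits = hitsOut, tallies = tallies, nReads = n)
}

#' Antisense (or sense) read counts per transcript
#'
#' Sums multiplicity-weighted placement weights over reads uniquely assigned
#' to the requested species, for one strand orientation. Ambiguous and
#' unmapped reads contribute nothing.
#'
#' @param partition A [SpeciesPartition-class].
#' @param pool The pool that was partitioned.
#' @param species `"A"` or `"B"`.
#' @param strand `"antisense"` (default; the orientation used for
#'   silencing-target counting) or `"sense"`.
#' @return Named numeric vector of per-transcript counts.
#' @export
antisenseCounts <- function(partition, pool, species = c("A", "B"),
                            strand = c("antisense", "sense")) {
  species <- match.arg(species)
  strand <- match.arg(strand)
  wanted <- paste0("unique_", species)
  h <- partition@hits
  h <- h[h$species == species & h$strand == strand &
           partition@classification[h$read] == wanted, , drop = FALSE]
  if (!nrow(h)) return(stats::setNames(numeric(0), character(0)))
  contrib <- h$weight * pool@multiplicity[h$read]
  vapply(split(contrib, h$transcript), sum, numeric(1))
}
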