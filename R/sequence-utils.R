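# Shared sequence primitives: RNA normalization, reverse complement, and the
# approximate substring matcher used for species partitioning, structural
# removal and miRNA quantification. Matching is delegated to base R's TRE
# engine (agrep/aregexec), which implements the classic approximate-grep
# error model: a pattern matches inside a text if some substring of the text
# is within the given edit distance of the pattern.

#' Normalize sequences to the RNA alphabet
#'
#' Uppercases and converts T to U. Errors on characters outside
#' \{A, C, G, U, T\}.
#'
#' @param x Character vector of sequences.
#' @return Character vector over \{A, C, G, U\}.
#' @examples
#' normalizeRna("acgtACGT")
#' @export
normalizeRna <- function(x) {
  x <- chartr("t", "T", toupper(x))
  x <- chartr("T", "U", x)
  bad <- grepl("[^ACGU]", x)
  if (any(bad))
    stop("non-nucleotide characters in sequence(s): ",
         paste(utils::head(x[bad], 3), collapse = ", "))
  x
}

#' Reverse complement of RNA sequences
#'
#' Complementation is U<->A, G<->C after normalization, so the reverse
#' complement of a read is the sequence that would base-pair with it in
#' antiparallel orientation.
#'
#' @param x Character vector of RNA (or DNA) sequences.
#' @return Character vector of reverse complements (RNA alphabet).
#' @examples
#' revCompRna("AUGC")  # "GCAU"
#' @export
revCompRna <- function(x) {
  x <- normalizeRna(x)
  comp <- chartr("ACGU", "UGCA", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

# Indices of `texts` containing `pattern` within `maxErrors` edits.
# mode "edit": substitutions, insertions and deletions each cost 1 (the
# approximate-grep default). mode "hamming": substitutions only.
approxMatch <- function(pattern, texts, maxErrors = 1L,
                        mode = c("edit", "hamming")) {
  mode <- match.arg(mode)
  if (maxErrors == 0L)
    return(grep(pattern, texts, fixed = TRUE))
  dist <- if (mode == "edit") maxErrors else
    list(insertions = 0, deletions = 0, substitutions = maxErrors,
         all = maxErrors)
  agrep(pattern, texts, max.distance = dist, fixed = TRUE)
}

# Leftmost approximate occurrence of `pattern` in a single `text`.
# Returns c(start, end) in 0-based half-open coordinates, or NULL.
approxLocate <- function(pattern, text, maxErrors = 1L,
                         mode = c("edit", "hamming")) {
  mode <- match.arg(mode)
  if (maxErrors == 0L) {
    s <- regexpr(pattern, text, fixed = TRUE)
    if (s < 0) return(NULL)
    return(c(start = s - 1L, end = s - 1L + attr(s, "match.length")))
  }
  dist <- if (mode == "edit") maxErrors else
    list(insertions = 0, deletions = 0, substitutions = maxErrors,
         all = maxErrors)
  m <- aregexec(pattern, text, max.distance = dist, fixed = TRUE)[[1]]
  if (m[1] < 0) return(NULL)
  c(start = m[1] - 1L, end = m[1] - 1L + attr(m, "match.length")[1])
}

# Deterministic random RNA sequences of the given lengths.
randomRna <- function(lengths) {
  vapply(lengths, function(L)
    paste(sample(c("A", "C", "G", "U"), L, replace = TRUE), collapse = ""),
    character(1))
}
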