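# Independent brute-force oracles used across the suite. These deliberately
# avoid the code paths they check: approximate substring matching via the
# adist dynamic-programming matrix, Spearman via explicit mean ranks,
# Benjamini-Hochberg via the literal step-up recipe, and hypergeometric
# tails via combinatorial enumeration.

# minimal edit distance between `pattern` and any substring of `text`
bfSubstringDist <- function(pattern, text) {
  as.integer(utils::adist(pattern, text, partial = TRUE))
}

bfMatchesAnywhere <- function(pattern, texts, maxErrors) {
  which(vapply(texts, function(tx)
    bfSubstringDist(pattern, tx) <= maxErrors, logical(1)))
}

# brute-force two-species classification of one read
bfClassify <- function(read, refA, refB, maxErrors = 1L) {
  rc <- revCompRna(read)
  inA <- length(bfMatchesAnywhere(read, refA, maxErrors)) > 0 ||
    length(bfMatchesAnywhere(rc, refA, maxErrors)) > 0
  inB <- length(bfMatchesAnywhere(read, refB, maxErrors)) > 0 ||
    length(bfMatchesAnywhere(rc, refB, maxErrors)) > 0
  if (inA && inB) "ambiguous" else if (inA) "unique_A"
  else if (inB) "unique_B" else "unmapped"
}

bfMeanRanks <- function(x) {
  r <- numeric(length(x))
  for (i in seq_along(x))
    r[i] <- sum(x < x[i]) + (1 + sum(x == x[i])) / 2
  r
}

bfSpearman <- function(x, y) {
  rx <- bfMeanRanks(x); ry <- bfMeanRanks(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

bfBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# upper-tail hypergeometric P(X >= k) by enumeration
bfHyperUpper <- function(k, K, N, n) {
  ks <- k:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

randomPool <- function(n, lens = 18:32, sample = "S1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  drawn <- lens[sample.int(length(lens), n, replace = TRUE)]
  smallRNAPool(vapply(drawn, function(L)
    paste(sample(c("A", "C", "G", "U"), L, replace = TRUE), collapse = ""),
    character(1)), 1L, sample)
}

smallSimConfig <- function(seed = 1, ...) {
  args <- list(seed = seed, nTranscriptsPlant = 30L, nTranscriptsFungus = 30L,
               transcriptLenRange = c(300L, 600L), nMirnasPlant = 10L,
               nMirnasFungus = 10L, nEndogenousPairs = 2L,
               nCrosskingdomPairs = 2L, readsPerSample = 400L)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(simulationConfig, args)
}
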