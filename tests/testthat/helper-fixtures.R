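# Shared fixtures and independent oracles used across test files.

# Quick expression-matrix builder with automatic dimnames.
make_em <- function(values, scale = "raw", features = NULL, samples = NULL) {
  values <- as.matrix(values)
  if (is.null(features)) features <- sprintf("f%02d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(values)))
  dimnames(values) <- list(features, samples)
  expr_mat(values, scale = scale)
}

# Kolmogorov distance of a sample against Uniform(0, 1).
ks_unif <- function(p) {
  n <- length(p)
  p <- sort(p)
  max(pmax(abs(p - seq_len(n) / n), abs(p - (seq_len(n) - 1) / n)))
}

# Independent O(N) re-scan of the GSEA running sum: walks every position,
# accumulates the weighted hit increments and miss decrements, and returns
# the maximum-magnitude deviation (positive preferred on exact ties).
es_bruteforce <- function(scores, hit_positions, weight) {
  n <- length(scores)
  is_hit <- seq_len(n) %in% hit_positions
  w <- abs(scores)^weight
  nr <- sum(w[is_hit])
  inc <- ifelse(is_hit,
    if (nr > 0) w / nr else 1 / sum(is_hit),
    -1 / (n - sum(is_hit))
  )
  running <- cumsum(inc)
  hi <- max(running)
  lo <- min(running, 0)
  if (hi >= -lo) hi else lo
}

# Exhaustive hypergeometric oracle: enumerate every possible hit
# configuration of size n_hits from the universe and count those whose
# overlap with the set reaches at least the observed overlap.
ora_enumeration <- function(universe, set, hits) {
  obs <- length(intersect(set, hits))
  combos <- utils::combn(universe, length(hits))
  at_least <- sum(apply(combos, 2, function(h) length(intersect(set, h)) >= obs))
  at_least / ncol(combos)
}
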