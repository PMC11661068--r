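#' Log2 transform an expression matrix
#'
#' @param mat A raw-scale [expr_mat()]; observed values must be >= 0.
#' @param pseudocount Added before the log (0 for intensities already
#'   strictly positive, 1 for counts).
#' @return An [expr_mat()] on log2 scale; missing entries stay missing.
#'   Applying the transform to an already-log2 matrix is an error, so the
#'   transform can never be applied twice.
#' @export
log2_transform <- function(mat, pseudocount = 0) {
  stopifnot(inherits(mat, "expr_mat"))
  if (mat$scale == "log2") {
    stop("matrix is already on log2 scale; refusing to transform twice",
      call. = FALSE
    )
  }
  v <- mat$values
  if (any(v < 0, na.rm = TRUE)) {
    stop("negative values cannot be log2 transformed", call. = FALSE)
  }
  expr_mat(log2(v + pseudocount), scale = "log2")
}

first_term <- function(labels) {
  trimws(vapply(strsplit(labels, ",", fixed = TRUE), `[`, character(1), 1L))
}

#' Deduplicate gene-group rows
#'
#' Protein-group ("gene group") labels are comma-joined symbol lists, and
#' groups from different runs can share a first term (e.g. `TRPV1` vs
#' `TRPV1,TRPV2,TRPA1`). This collapses to one row per distinct first term
#' under one of two policies:
#' * `first_term_highest_abundance`: the retained row is the one with the
#'   highest mean observed abundance among rows sharing the first term;
#' * `exact_single_term_preferred`: a single-symbol row wins over composite
#'   rows sharing its first term, falling back to highest abundance when no
#'   single-symbol row exists.
#'
#' Either way the retained row is relabelled to the bare first term.
#'
#' @param mat An [expr_mat()].
#' @param policy Deduplication policy (see above).
#' @return An [expr_mat()] with unique single-symbol row labels.
#' @export
dedup_gene_groups <- function(mat,
                              policy = c(
                                "first_term_highest_abundance",
                                "exact_single_term_preferred"
                              )) {
  policy <- match.arg(policy)
  v <- mat$values
  ft <- first_term(rownames(v))
  keep <- vapply(split(seq_len(nrow(v)), ft), function(idx) {
    if (length(idx) == 1L) return(idx)
    if (policy == "exact_single_term_preferred") {
      single <- idx[rownames(v)[idx] == ft[idx]]
      if (length(single) == 1L) return(single)
    }
    means <- rowMeans(v[idx, , drop = FALSE], na.rm = TRUE)
    idx[which.max(means)]
  }, integer(1))
  out <- v[keep, , drop = FALSE]
  rownames(out) <- names(keep)
  out <- out[order(match(keep, seq_len(nrow(v)))), , drop = FALSE]
  expr_mat(out, scale = mat$scale)
}

#' Filter features by completeness
#'
#' Keeps rows observed in at least `min_fraction` of samples. The boundary
#' is inclusive: with 8 samples and the default 0.8, a feature observed in
#' 7 samples (87.5%) is kept and one observed in 6 (75%) is removed —
#' "present in less than 80%" is what gets dropped.
#'
#' @param mat An [expr_mat()].
#' @param min_fraction Minimum observed fraction, in (0, 1].
#' @return Filtered [expr_mat()]; an empty result is allowed with a warning.
#' @export
completeness_filter <- function(mat, min_fraction = 0.8) {
  stopifnot(min_fraction > 0, min_fraction <= 1)
  v <- mat$values
  frac <- rowMeans(!is.na(v))
  keep <- frac >= min_fraction
  if (!any(keep)) warning("completeness filter removed every feature", call. = FALSE)
  expr_mat(v[keep, , drop = FALSE], scale = mat$scale)
}

#' Merge technical replicates by mean
#'
#' Collapses replicate columns of the same biological sample (same donor
#' and tissue) to their mean, ignoring missing entries; a value missing in
#' all replicates stays missing. The merged sample id is `donor_tissue`.
#'
#' @param mat An [expr_mat()].
#' @param meta Metadata tibble covering the matrix columns.
#' @return A list with merged `matrix` and per-biological-sample `metadata`
#'   (replicate set to 1).
#' @export
merge_replicates <- function(mat, meta) {
  al <- align_samples(mat, meta)
  mat <- al$matrix
  meta <- al$metadata
  key <- paste(meta$donor_id, meta$tissue, sep = "_")
  groups <- split(seq_len(ncol(mat$values)), key)
  if (any(lengths(groups) == 0L)) {
    stop("biological sample with zero replicate columns", call. = FALSE)
  }
  # preserve first-appearance order of biological samples
  groups <- groups[unique(key)]
  merged <- vapply(groups, function(idx) {
    rowMeans(mat$values[, idx, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(mat$values)))
  merged[is.nan(merged)] <- NA_real_
  dimnames(merged) <- list(rownames(mat$values), names(groups))
  first_idx <- vapply(groups, `[`, integer(1), 1L)
  new_meta <- meta[first_idx, , drop = FALSE]
  new_meta$sample_id <- names(groups)
  new_meta$replicate <- 1L
  list(matrix = expr_mat(merged, scale = mat$scale), metadata = new_meta)
}

#' Rank features by mean observed abundance
#'
#' @param mat An [expr_mat()] (deduplicated and filtered).
#' @return A tibble (`feature`, `score`) sorted by decreasing mean of
#'   observed values, ties broken by label order for determinism.
#' @export
rank_by_mean <- function(mat) {
  v <- mat$values
  means <- rowMeans(v, na.rm = TRUE)
  ord <- order(-means, rownames(v))
  tibble::tibble(feature = rownames(v)[ord], score = unname(means[ord]))
}

#' Quantile normalize a complete matrix
#'
#' Replaces each column's sorted values with the mean of row-wise sorted
#' values, so all columns share one empirical distribution (identical as
#' multisets) while preserving within-column order. Ties are assigned in
#' first-occurrence order for determinism.
#'
#' @param mat A complete [expr_mat()] (no missing entries — filter or
#'   merge first).
#' @return A quantile-normalized [expr_mat()].
#' @export
quantile_normalize <- function(mat) {
  v <- mat$values
  if (anyNA(v)) {
    stop("quantile_normalize requires a complete matrix; ",
      "apply completeness_filter or merge replicates first",
      call. = FALSE
    )
  }
  ref <- rowMeans(apply(v, 2L, sort))
  out <- apply(v, 2L, function(x) ref[rank(x, ties.method = "first")])
  dimnames(out) <- dimnames(v)
  expr_mat(out, scale = mat$scale)
}

#' Transcripts-per-million from counts
#'
#' @param counts A raw [expr_mat()] of non-negative counts.
#' @param lengths_kb Per-feature effective length in kilobases (named or in
#'   row order).
#' @return An [expr_mat()] whose columns each sum to 1e6.
#' @export
tpm_from_counts <- function(counts, lengths_kb) {
  v <- counts$values
  stopifnot(all(v >= 0, na.rm = TRUE), all(lengths_kb > 0))
  if (!is.null(names(lengths_kb))) lengths_kb <- lengths_kb[rownames(v)]
  stopifnot(length(lengths_kb) == nrow(v))
  rate <- v / lengths_kb
  denom <- colSums(rate, na.rm = TRUE)
  if (any(denom == 0)) {
    stop("column(s) with zero total rate: ",
      paste(colnames(v)[denom == 0], collapse = ", "),
      call. = FALSE
    )
  }
  expr_mat(sweep(rate, 2L, denom, "/") * 1e6, scale = "raw")
}

#' Median-of-ratios log2 fold changes
#'
#' Size-factor-normalized group difference of mean log2 values, a simple
#' stand-in for shrunken model-based fold changes: the per-sample size
#' factor is the median across reference features of value over geometric
#' row mean (features containing any zero or missing value are excluded
#' from the reference), and the fold change is the difference of group
#' mean log2 normalized values.
#'
#' @param mat A raw [expr_mat()] of positive intensities or counts.
#' @param groups Two-level factor (or character) over columns; the reported
#'   `lfc` is the first level minus the second.
#' @return A tibble (`feature`, `score`) with `score` the log2 fold change,
#'   sorted descending (ties by label), ready for enrichment.
#' @export
median_ratio_lfc <- function(mat, groups) {
  v <- mat$values
  groups <- droplevels(as.factor(groups))
  stopifnot(length(groups) == ncol(v), nlevels(groups) == 2)
  usable <- rowSums(is.na(v) | v <= 0) == 0
  if (!any(usable)) {
    stop("no feature is positive in every sample; cannot compute size factors",
      call. = FALSE
    )
  }
  log_geo <- rowMeans(log(v[usable, , drop = FALSE]))
  sf <- apply(v[usable, , drop = FALSE], 2L, function(col) {
    exp(stats::median(log(col) - log_geo))
  })
  norm <- sweep(v, 2L, sf, "/")
  logn <- log2(norm)
  logn[!is.finite(logn)] <- NA_real_
  a <- groups == levels(groups)[1]
  lfc <- rowMeans(logn[, a, drop = FALSE], na.rm = TRUE) -
    rowMeans(logn[, !a, drop = FALSE], na.rm = TRUE)
  ord <- order(-lfc, rownames(v))
  tibble::tibble(feature = rownames(v)[ord], score = unname(lfc[ord]))
}
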