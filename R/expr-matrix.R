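#' Expression matrix container
#'
#' A light wrapper around a numeric features-by-samples matrix that keeps
#' track of the measurement scale so that log transforms are never applied
#' twice. Row names hold feature labels (gene symbols or comma-joined
#' "gene group" labels from protein-group ambiguity); column names hold
#' sample ids. Missing intensities are `NA`.
#'
#' @param values Numeric matrix with rownames (features) and colnames
#'   (samples). May contain `NA`.
#' @param scale Either `"raw"` (intensities, counts, TPM) or `"log2"`.
#' @return An object of class `expr_mat`.
#' @examples
#' m <- matrix(1:6, nrow = 3, dimnames = list(c("A", "B", "C"), c("s1", "s2")))
#' expr_mat(m)
#' @export
expr_mat <- function(values, scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if ((nrow(values) > 0 && is.null(rownames(values))) ||
    (ncol(values) > 0 && is.null(colnames(values)))) {
    stop("`values` must carry feature rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    dup <- unique(colnames(values)[duplicated(colnames(values))])
    stop("duplicate sample id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  structure(list(values = values, scale = scale), class = "expr_mat")
}

#' @export
print.expr_mat <- function(x, ...) {
  cat(sprintf(
    "<expr_mat> %d features x %d samples [%s scale], %.1f%% missing\n",
    nrow(x$values), ncol(x$values), x$scale,
    100 * mean(is.na(x$values))
  ))
  invisible(x)
}

#' @export
dim.expr_mat <- function(x) dim(x$values)

#' @export
dimnames.expr_mat <- function(x) dimnames(x$values)

#' @export
as.matrix.expr_mat <- function(x, ...) x$values

#' Convert an expression matrix to a long tibble
#'
#' @param x An `expr_mat`.
#' @param ... Unused.
#' @return A tibble with columns `feature`, `sample`, `value` (observed
#'   entries only carry numbers; missing entries are kept as `NA`).
#' @export
tidy.expr_mat <- function(x, ...) {
  v <- x$values
  tibble::tibble(
    feature = rep(rownames(v), times = ncol(v)),
    sample = rep(colnames(v), each = nrow(v)),
    value = as.vector(v)
  )
}

#' Sample metadata constructor
#'
#' Validates and normalizes a per-sample annotation table. `sex` must be
#' "F"/"M" and `tissue` one of "ganglia", "nerve_root", "other"; both are
#' closed vocabularies because downstream contrasts depend on them.
#'
#' @param df Data frame with columns `sample_id`, `donor_id`, `sex`,
#'   `tissue`, `replicate`; extra columns (age, ethnicity, ...) pass through.
#' @return A tibble.
#' @export
sample_metadata <- function(df) {
  required <- c("sample_id", "donor_id", "sex", "tissue", "replicate")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("metadata missing column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  df <- tibble::as_tibble(df)
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id in metadata", call. = FALSE)
  }
  if (!all(df$sex %in% c("F", "M"))) {
    stop("sex must be 'F' or 'M'", call. = FALSE)
  }
  if (!all(df$tissue %in% c("ganglia", "nerve_root", "other"))) {
    stop("tissue must be one of 'ganglia', 'nerve_root', 'other'", call. = FALSE)
  }
  df$replicate <- as.integer(df$replicate)
  df
}

#' Align an expression matrix with sample metadata
#'
#' Reorders matrix columns to the metadata row order and drops samples
#' present on only one side (a message reports how many were dropped).
#'
#' @param mat An `expr_mat`.
#' @param meta A metadata tibble (see [sample_metadata()]).
#' @return A list with elements `matrix` and `metadata`, restricted to the
#'   shared samples in metadata order.
#' @export
align_samples <- function(mat, meta) {
  shared <- intersect(meta$sample_id, colnames(mat$values))
  if (length(shared) == 0L) {
    stop("no overlapping samples between matrix and metadata", call. = FALSE)
  }
  n_drop <- (ncol(mat$values) - length(shared)) +
    (nrow(meta) - length(shared))
  if (n_drop > 0) {
    message(sprintf("align_samples: dropped %d unmatched sample(s)", n_drop))
  }
  list(
    matrix = expr_mat(mat$values[, shared, drop = FALSE], scale = mat$scale),
    metadata = meta[match(shared, meta$sample_id), , drop = FALSE]
  )
}

#' Analysis configuration defaults
#'
#' Central bundle of thresholds used across the pipeline. Defaults follow
#' the study settings: 80% completeness, |LFC| > 1 with FDR < 0.05 for
#' differential calls, q < 0.1 for factor-level sex tests, KMO >= 0.5
#' adequacy, 10000 GSEA permutations with minimum set size 25 (5 for
#' factor-loading runs), and an ECM iteration cap of 10000 at tolerance 1e-6.
#'
#' @param completeness Minimum observed fraction per feature, in (0, 1].
#' @param lfc_cut Absolute log2 fold-change cutoff for differential calls.
#' @param fdr_cut FDR threshold for differential and enrichment calls.
#' @param q_cut Adjusted-p threshold for factor-level sex contrasts.
#' @param kmo_min Minimum acceptable Kaiser-Meyer-Olkin adequacy.
#' @param gsea_nperm Number of gene-label permutations for GSEA.
#' @param gsea_min_size,gsea_max_size Set-size filter for expression/LFC GSEA.
#' @param gsea_loading_min_size Set-size minimum for factor-loading GSEA.
#' @param gsea_weight Running-sum weight exponent.
#' @param msfa_max_iter,msfa_tol ECM iteration cap and relative log-likelihood
#'   tolerance.
#' @param dedup_policy Gene-group deduplication policy; see
#'   [dedup_gene_groups()].
#' @param seed Integer seed fanned out to stochastic stages.
#' @return A list of class `dimorph_config`.
#' @export
analysis_config <- function(completeness = 0.8,
                            lfc_cut = 1.0,
                            fdr_cut = 0.05,
                            q_cut = 0.1,
                            kmo_min = 0.5,
                            gsea_nperm = 10000L,
                            gsea_min_size = 25L,
                            gsea_max_size = Inf,
                            gsea_loading_min_size = 5L,
                            gsea_weight = 1,
                            msfa_max_iter = 10000L,
                            msfa_tol = 1e-6,
                            dedup_policy = "first_term_highest_abundance",
                            seed = 1L) {
  stopifnot(
    completeness > 0, completeness <= 1,
    fdr_cut > 0, fdr_cut <= 1,
    q_cut > 0, q_cut <= 1,
    kmo_min >= 0, kmo_min <= 1,
    gsea_nperm >= 1, gsea_min_size >= 1,
    msfa_max_iter >= 1, msfa_tol > 0
  )
  dedup_policy <- match.arg(
    dedup_policy,
    c("first_term_highest_abundance", "exact_single_term_preferred")
  )
  structure(
    list(
      completeness = completeness, lfc_cut = lfc_cut, fdr_cut = fdr_cut,
      q_cut = q_cut, kmo_min = kmo_min, gsea_nperm = as.integer(gsea_nperm),
      gsea_min_size = as.integer(gsea_min_size), gsea_max_size = gsea_max_size,
      gsea_loading_min_size = as.integer(gsea_loading_min_size),
      gsea_weight = gsea_weight, msfa_max_iter = as.integer(msfa_max_iter),
      msfa_tol = msfa_tol, dedup_policy = dedup_policy, seed = as.integer(seed)
    ),
    class = "dimorph_config"
  )
}

# Derive a reproducible per-stage seed from the global seed, so adding a
# stage never perturbs another stage's random stream.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  # double arithmetic: intermediate products exceed 32-bit integer range
  as.integer((as.numeric(seed) * 1009 + h %% 99991) %% 2147483647)
}
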