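#' Build a ranked feature list
#'
#' Orders features by decreasing score with deterministic tie-breaking by
#' label, and checks uniqueness — the input contract for [gsea()].
#'
#' @param features Character vector of unique feature labels.
#' @param scores Numeric scores (mean expression, log2 fold change, or
#'   factor loading).
#' @return A tibble (`feature`, `score`) sorted for enrichment.
#' @export
ranked_list <- function(features, scores) {
  stopifnot(length(features) == length(scores), !anyNA(scores))
  if (anyDuplicated(features)) {
    stop("ranked features must be unique", call. = FALSE)
  }
  ord <- order(-scores, features)
  tibble::tibble(feature = features[ord], score = scores[ord])
}

# Running-sum enrichment score for hit positions `hit` (1-based, any order)
# in a ranked score vector. Hits increment by |score|^weight normalized by
# the within-set total; misses decrement by 1/(N - Nh). Returns the
# maximum-magnitude deviation (positive wins exact-magnitude ties) and the
# peak position for leading-edge extraction.
gsea_es <- function(scores, hit, weight) {
  n <- length(scores)
  nh <- length(hit)
  hit <- sort(hit)
  w <- abs(scores[hit])^weight
  nr <- sum(w)
  w <- if (nr > 0) w / nr else rep(1 / nh, nh)
  miss_step <- 1 / (n - nh)
  cw <- cumsum(w)
  before <- -(hit - seq_len(nh)) * miss_step + c(0, cw[-nh])
  after <- before + w
  i_max <- which.max(after)
  i_min <- which.min(before)
  es_pos <- after[i_max]
  es_neg <- min(before[i_min], 0)
  if (es_pos >= -es_neg) {
    list(es = es_pos, peak = hit[i_max], sign = 1L)
  } else {
    list(es = es_neg, peak = hit[i_min], sign = -1L)
  }
}

#' Gene set enrichment analysis by weighted running sum
#'
#' For each set, walks the ranked list accumulating `|score|^weight`
#' (normalized over set members) at hits and subtracting `1/(N - set size)`
#' at misses; the enrichment score (ES) is the maximum-magnitude deviation
#' of this running sum. The null distribution comes from `nperm`
#' seed-controlled gene-label permutations (appropriate for pre-ranked
#' statistics); the normalized score (NES) divides ES by the mean |null ES|
#' of matching sign, and the nominal p-value is the fraction of same-sign
#' null scores at least as extreme, with a +1 pseudo-count so permutation
#' p-values are never zero. BH adjustment is applied across sets.
#'
#' @param ranked A tibble from [ranked_list()] (or any `feature`/`score`
#'   frame; it is re-sorted defensively).
#' @param sets Named list of gene-symbol vectors (see [read_gmt()]).
#' @param nperm Number of permutations (default 10000; < 100 warns).
#' @param weight Running-sum weight exponent (default 1, the classic
#'   weighted statistic; 0 gives the rank-only Kolmogorov-Smirnov form).
#' @param min_size,max_size Set-size filter after intersection with the
#'   ranked features (defaults 25 and unbounded; use `min_size = 5` for
#'   factor-loading runs on small panels).
#' @param seed Integer seed for the permutation stream.
#' @return A tibble (`set`, `size`, `es`, `nes`, `p_value`, `adj_p`,
#'   `leading_edge` list-column), one row per retained set.
#' @export
gsea <- function(ranked, sets, nperm = 10000L, weight = 1,
                 min_size = 25L, max_size = Inf, seed = 1L) {
  stopifnot(all(c("feature", "score") %in% names(ranked)))
  ranked <- ranked_list(ranked$feature, ranked$score)
  if (nperm < 100L) warning("nperm < 100: permutation p-values will be coarse", call. = FALSE)
  scores <- ranked$score
  feats <- ranked$feature
  n <- length(feats)

  idx_list <- lapply(sets, function(s) which(feats %in% s))
  sizes <- lengths(idx_list)
  keep <- sizes >= min_size & sizes <= max_size & sizes < n
  idx_list <- idx_list[keep]
  sizes <- sizes[keep]
  if (length(idx_list) == 0L) {
    return(tibble::tibble(
      set = character(0), size = integer(0), es = numeric(0),
      nes = numeric(0), p_value = numeric(0), adj_p = numeric(0),
      leading_edge = list()
    ))
  }

  set.seed(seed)
  null_by_size <- list()
  for (sz in sort(unique(sizes))) {
    null_by_size[[as.character(sz)]] <- vapply(seq_len(nperm), function(b) {
      gsea_es(scores, sample.int(n, sz), weight)$es
    }, numeric(1))
  }

  res <- purrr::map2(idx_list, sizes, function(idx, sz) {
    obs <- gsea_es(scores, idx, weight)
    null_es <- null_by_size[[as.character(sz)]]
    same <- null_es * obs$sign > 0
    nes <- if (any(same)) obs$es / mean(abs(null_es[same])) else NA_real_
    p <- (sum(same & abs(null_es) >= abs(obs$es)) + 1) / (sum(same) + 1)
    le <- if (obs$sign > 0) {
      feats[intersect(idx, seq_len(obs$peak))]
    } else {
      feats[intersect(idx, seq(obs$peak, n))]
    }
    tibble::tibble(
      size = sz, es = obs$es, nes = nes, p_value = p,
      leading_edge = list(le)
    )
  })
  out <- dplyr::bind_rows(res, .id = "set")
  out$adj_p <- bh_adjust(out$p_value)
  out[, c("set", "size", "es", "nes", "p_value", "adj_p", "leading_edge")]
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test of each set's overlap with a hit list
#' against an explicit background universe (here, the gene groups entering
#' the differential comparison).
#'
#' @param hits Character vector of significant genes (must be contained in
#'   `universe`).
#' @param universe Character vector, the background.
#' @param sets Named list of gene-symbol vectors; intersected with the
#'   universe before testing.
#' @return A tibble (`set`, `set_size`, `overlap`, `expected`, `p_value`,
#'   `adj_p`).
#' @export
ora_hypergeometric <- function(hits, universe, sets) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  hits <- unique(hits)
  if (!all(hits %in% universe)) {
    stop("hits must be a subset of the universe", call. = FALSE)
  }
  n_u <- length(universe)
  n_h <- length(hits)
  rows <- purrr::imap(sets, function(members, nm) {
    m <- length(intersect(members, universe))
    ov <- length(intersect(members, hits))
    p <- if (m == 0L) 1 else {
      stats::phyper(ov - 1L, m, n_u - m, n_h, lower.tail = FALSE)
    }
    tibble::tibble(
      set = nm, set_size = m, overlap = ov,
      expected = n_h * m / n_u, p_value = p
    )
  })
  out <- dplyr::bind_rows(rows)
  out$adj_p <- bh_adjust(out$p_value)
  out
}

#' Build marker gene sets from per-group expression quantiles
#'
#' For each subpopulation, genes whose mean within-group value exceeds the
#' `quantile_cut` quantile of that group's mean vector form the marker set.
#' Intended for variance-stabilized log-scale input; here log2 of
#' size-factor-normalized counts plus a pseudocount is the supported
#' stabilization, so membership near the quantile boundary can differ from
#' transformations with stronger low-count damping.
#'
#' @param mat A log-scale [expr_mat()].
#' @param group_labels Per-sample subpopulation labels over columns.
#' @param quantile_cut Quantile threshold in [0, 1) (default 0.95); 0 keeps
#'   every gene.
#' @param min_size Sets smaller than this are dropped with a warning.
#' @return A `gene_sets` collection (named list of symbol vectors).
#' @export
build_marker_genesets <- function(mat, group_labels, quantile_cut = 0.95,
                                  min_size = 1L) {
  stopifnot(quantile_cut >= 0, quantile_cut < 1)
  v <- mat$values
  group_labels <- as.factor(group_labels)
  stopifnot(length(group_labels) == ncol(v))
  if (any(table(group_labels) < 1L)) stop("group with no samples", call. = FALSE)
  sets <- lapply(levels(group_labels), function(g) {
    means <- rowMeans(v[, group_labels == g, drop = FALSE], na.rm = TRUE)
    cut <- if (quantile_cut == 0) -Inf else stats::quantile(means, quantile_cut, names = FALSE)
    rownames(v)[means > cut]
  })
  names(sets) <- levels(group_labels)
  small <- lengths(sets) < min_size
  if (any(small)) {
    warning("dropping marker set(s) below min_size: ",
      paste(names(sets)[small], collapse = ", "),
      call. = FALSE
    )
    sets <- sets[!small]
  }
  structure(sets,
    descriptions = stats::setNames(
      rep(sprintf("markers above %g quantile", quantile_cut), length(sets)),
      names(sets)
    ),
    class = "gene_sets"
  )
}
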