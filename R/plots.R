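#' Scree plot of correlation eigenvalues
#'
#' @param object A `scree` from [scree_factor_count()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.scree <- function(object, ...) {
  df <- tibble::tibble(
    component = seq_along(object$eigenvalues),
    eigenvalue = object$eigenvalues
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$eigenvalue)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_vline(
      xintercept = object$n_factors + 0.5,
      linetype = "dotted", colour = "firebrick"
    ) +
    ggplot2::labs(
      title = sprintf("Scree (%s rule: %d factors)", object$rule, object$n_factors),
      x = "component", y = "eigenvalue"
    ) +
    ggplot2::theme_minimal()
}

#' Eigengene (PC1) scores by class
#'
#' @param object An `spca_result` from [spca()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spca_result <- function(object, ...) {
  ggplot2::ggplot(object$scores, ggplot2::aes(x = .data$class, y = .data$score)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.7) +
    ggplot2::labs(
      title = sprintf(
        "Supervised PCA: PC1 (%.0f%% variance), Welch p = %.3g",
        100 * object$var_explained[1], object$welch$p_value
      ),
      x = NULL, y = "PC1 score (eigengene)"
    ) +
    ggplot2::theme_minimal()
}

#' Volcano plot of a moderated fit
#'
#' @param object A `moderated_fit` from [moderated_two_group()].
#' @param lfc_cut,fdr_cut Thresholds drawn as guides and used to colour
#'   significant features.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.moderated_fit <- function(object, lfc_cut = 1, fdr_cut = 0.05, ...) {
  df <- object$table
  df$significant <- abs(df$lfc) > lfc_cut & df$adj_p < fdr_cut
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$lfc, y = -log10(.data$p_value),
    colour = .data$significant
  )) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::geom_vline(xintercept = c(-lfc_cut, lfc_cut), linetype = "dashed") +
    ggplot2::labs(
      x = expression(log[2] ~ "fold change"), y = expression(-log[10] ~ p),
      colour = "significant"
    ) +
    ggplot2::theme_minimal()
}

#' Shared-loading heatmap of a multi-study factor model
#'
#' @param object An `msfa_model` from [msfa_fit()].
#' @param top_n Show the `top_n` features by maximum absolute loading.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.msfa_model <- function(object, top_n = 40L, ...) {
  df <- tidy(object, what = "shared")
  keep <- df |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(m = max(abs(.data$loading)), .groups = "drop") |>
    dplyr::slice_max(.data$m, n = top_n) |>
    dplyr::pull(.data$feature)
  ggplot2::ggplot(
    dplyr::filter(df, .data$feature %in% keep),
    ggplot2::aes(
      x = factor(.data$factor), y = .data$feature,
      fill = .data$loading
    )
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white", high = "firebrick") +
    ggplot2::labs(x = "shared factor", y = NULL, fill = "loading") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 6))
}

#' Factor scores stratified by sex
#'
#' Boxplots of Bartlett factor scores per shared factor, split by sex and
#' pooled over studies — the standard readout for sex-separating factors.
#'
#' @param scores A `factor_scores` tibble from [pooled_factor_scores()].
#' @return A ggplot.
#' @export
plot_factor_scores <- function(scores) {
  ggplot2::ggplot(scores, ggplot2::aes(
    x = .data$sex, y = .data$score,
    fill = .data$sex
  )) +
    ggplot2::geom_boxplot(coef = 1.5, outlier.size = 0.8) +
    ggplot2::facet_wrap(~ factor, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_manual(values = c(F = "#E69F00", M = "#56B4E9")) +
    ggplot2::labs(x = NULL, y = "factor score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' GSEA running-sum profile for one set
#'
#' Recomputes and draws the full running sum of a set along the ranked
#' list, with hit positions marked.
#'
#' @param ranked A [ranked_list()] tibble.
#' @param set Character vector of set members.
#' @param weight Running-sum weight exponent (default 1).
#' @return A ggplot.
#' @export
plot_gsea_running_sum <- function(ranked, set, weight = 1) {
  ranked <- ranked_list(ranked$feature, ranked$score)
  hit <- ranked$feature %in% set
  n <- nrow(ranked)
  nh <- sum(hit)
  stopifnot(nh >= 1, nh < n)
  w <- abs(ranked$score)^weight
  inc <- ifelse(hit, w / sum(w[hit]), -1 / (n - nh))
  df <- tibble::tibble(position = seq_len(n), running = cumsum(inc), hit = hit)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$running)) +
    ggplot2::geom_line(colour = "forestgreen") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_rug(
      data = dplyr::filter(df, .data$hit), sides = "b",
      colour = "black", length = ggplot2::unit(0.03, "npc")
    ) +
    ggplot2::labs(x = "rank", y = "running enrichment") +
    ggplot2::theme_minimal()
}
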