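#' Quantify a phospho-array membrane
#'
#' Chemiluminescent film semantics: darker spots mean more signal, so the
#' per-site signal is `mean(PBS background) - mean(ROI pixel intensity)`,
#' using the PBS negative control printed on the same membrane. Duplicate
#' spots of a site are averaged before subtraction. Signals are not
#' clamped at zero — faint spots may exceed the PBS background.
#'
#' @param spot_table Data frame for one membrane with columns `site` and
#'   `roi_mean` (mean pixel intensity per spot).
#' @param pbs_mean PBS background mean; if `NULL`, taken from rows with
#'   `site == "PBS"` (error when absent).
#' @return A tibble (`site`, `roi_mean`, `signal`), one row per site.
#' @export
quantify_membrane <- function(spot_table, pbs_mean = NULL) {
  stopifnot(all(c("site", "roi_mean") %in% names(spot_table)))
  if (any(spot_table$roi_mean < 0, na.rm = TRUE)) {
    stop("pixel intensities must be >= 0", call. = FALSE)
  }
  if (is.null(pbs_mean)) {
    pbs_rows <- spot_table$site == "PBS"
    if (!any(pbs_rows)) {
      stop("no PBS background: provide pbs_mean or a site == 'PBS' row",
        call. = FALSE
      )
    }
    pbs_mean <- mean(spot_table$roi_mean[pbs_rows])
    spot_table <- spot_table[!pbs_rows, , drop = FALSE]
  }
  stopifnot(pbs_mean >= 0)
  spot_table |>
    dplyr::group_by(.data$site) |>
    dplyr::summarise(roi_mean = mean(.data$roi_mean), .groups = "drop") |>
    dplyr::mutate(signal = pbs_mean - .data$roi_mean)
}

#' Quantify all membranes of a spot-intensity table
#'
#' @param spot_table Data frame with columns `membrane`, `sex`, `site`,
#'   `roi_mean`, including a `site == "PBS"` row (or rows) per membrane —
#'   the format written by [simulate_phospho_membranes()].
#' @return A long tibble (`membrane`, `sex`, `site`, `signal`).
#' @export
quantify_membranes <- function(spot_table) {
  stopifnot(all(c("membrane", "sex", "site", "roi_mean") %in% names(spot_table)))
  spot_table |>
    dplyr::group_by(.data$membrane, .data$sex) |>
    dplyr::group_modify(~ quantify_membrane(.x)) |>
    dplyr::ungroup() |>
    dplyr::select("membrane", "sex", "site", "signal")
}

#' Sex-by-site analysis of phospho-array signals
#'
#' Two-way ANOVA (Type II) of background-subtracted signals on sex, site
#' and their interaction, followed by Tukey HSD over the sex-by-site cell
#' means, from which the per-site male-vs-female contrasts are extracted.
#'
#' @param quants Long tibble from [quantify_membranes()] (`membrane`,
#'   `sex`, `site`, `signal`).
#' @return A list: `anova` (tibble), `site_contrasts` (per-site sex
#'   comparisons with Tukey-adjusted p), `pairwise` (all cell pairs).
#' @export
phospho_sex_anova <- function(quants) {
  stopifnot(all(c("membrane", "sex", "site", "signal") %in% names(quants)))
  n_mem <- quants |>
    dplyr::distinct(.data$membrane, .data$sex) |>
    dplyr::count(.data$sex)
  if (nrow(n_mem) < 2 || min(n_mem$n) < 2) {
    stop("need >= 2 membranes per sex", call. = FALSE)
  }
  n_membranes <- sum(n_mem$n)
  shared <- quants |>
    dplyr::distinct(.data$membrane, .data$site) |>
    dplyr::count(.data$site) |>
    dplyr::filter(.data$n == n_membranes) |>
    dplyr::pull(.data$site)
  dropped <- setdiff(unique(quants$site), shared)
  if (length(dropped)) {
    warning("dropping site(s) not shared across membranes: ",
      paste(dropped, collapse = ", "),
      call. = FALSE
    )
    quants <- dplyr::filter(quants, .data$site %in% shared)
  }
  if (length(shared) == 0L) stop("no shared sites", call. = FALSE)

  single_site <- length(shared) == 1L
  anova_tab <- if (single_site) {
    warning("single shared site: reduces to a two-group sex comparison",
      call. = FALSE
    )
    fit <- stats::lm(signal ~ sex, data = quants)
    a <- stats::anova(fit)
    tibble::tibble(
      term = "sex", sumsq = a[["Sum Sq"]][1], df = a[["Df"]][1],
      statistic = a[["F value"]][1], p_value = a[["Pr(>F)"]][1]
    )
  } else {
    two_way_anova(quants,
      response = "signal", factor_a = "sex", factor_b = "site"
    )
  }

  cells <- quants |>
    dplyr::mutate(cell = paste(.data$sex, .data$site, sep = "|"))
  pairwise <- tukey_hsd(cells, response = "signal", group = "cell")
  parts <- strsplit(pairwise$contrast, "-", fixed = TRUE)
  lhs <- do.call(rbind, strsplit(vapply(parts, `[`, character(1), 1L), "|", fixed = TRUE))
  rhs <- do.call(rbind, strsplit(vapply(parts, `[`, character(1), 2L), "|", fixed = TRUE))
  same_site <- lhs[, 2] == rhs[, 2] & lhs[, 1] != rhs[, 1]
  site_contrasts <- pairwise[same_site, , drop = FALSE]
  site_contrasts$site <- lhs[same_site, 2]
  # orient every contrast as M - F
  flip <- lhs[same_site, 1] == "F"
  site_contrasts$estimate[flip] <- -site_contrasts$estimate[flip]
  tmp <- site_contrasts$conf_low[flip]
  site_contrasts$conf_low[flip] <- -site_contrasts$conf_high[flip]
  site_contrasts$conf_high[flip] <- -tmp
  site_contrasts$contrast <- paste0("M|", site_contrasts$site, " - F|", site_contrasts$site)
  list(
    anova = anova_tab,
    site_contrasts = tibble::as_tibble(site_contrasts[, c("site", "contrast", "estimate", "conf_low", "conf_high", "adj_p")]),
    pairwise = pairwise
  )
}
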