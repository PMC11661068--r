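#' Benjamini-Hochberg adjustment
#'
#' Validates inputs then applies the step-up false discovery rate
#' procedure, preserving input order.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1] with no missing values", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

# Inverse of trigamma by Newton iteration on log scale (monotone decreasing
# function), to tolerance 1e-8. Used for the empirical-Bayes prior df.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:60) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

# Moment-match a scaled-F distribution to observed sample variances s2 with
# residual df: returns prior df d0 and prior variance s02 (Smyth-style fit
# on log s2 using digamma/trigamma identities).
fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & df > 0 & s2 > 0
  s2 <- s2[ok]
  df <- df[ok]
  if (length(s2) < 2L) {
    return(list(d0 = 0, s02 = if (length(s2)) s2 else NA_real_))
  }
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - mean(trigamma(df / 2))
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- exp(emean)
  }
  list(d0 = d0, s02 = s02)
}

#' Moderated two-group test with empirical-Bayes variance shrinkage
#'
#' Per feature, an ordinary two-group comparison on log2 data gives the
#' fold change, pooled residual variance \eqn{s^2} and residual df. Across
#' features, a scaled-F model for \eqn{s^2} is moment-matched on
#' \eqn{\log s^2} (digamma/trigamma equations, solved numerically) to give
#' a prior df \eqn{d_0} and prior variance \eqn{s_0^2}; each feature's
#' posterior variance \eqn{(d_0 s_0^2 + d s^2)/(d_0 + d)} then replaces
#' \eqn{s^2} in the t statistic, which gains \eqn{d_0} df. This stabilizes
#' variance estimates at small n (here, 4 donors per sex).
#'
#' @param mat A log2-scale [expr_mat()], deduplicated/filtered/merged.
#' @param groups Two-level factor (or character) over columns; `lfc` is
#'   the first level minus the second.
#' @param prior_df Optional override of the estimated prior df: `0` turns
#'   shrinkage off (ordinary t), `Inf` shrinks fully to the prior variance.
#' @return An object of class `moderated_fit`; use [tidy.moderated_fit()]
#'   for the per-feature table and [glance.moderated_fit()] for the prior.
#' @export
moderated_two_group <- function(mat, groups, prior_df = NULL) {
  stopifnot(inherits(mat, "expr_mat"))
  if (mat$scale != "log2") {
    stop("moderated_two_group expects a log2-scale matrix", call. = FALSE)
  }
  v <- mat$values
  groups <- droplevels(as.factor(groups))
  stopifnot(length(groups) == ncol(v), nlevels(groups) == 2)
  a <- groups == levels(groups)[1]

  n_a <- rowSums(!is.na(v[, a, drop = FALSE]))
  n_b <- rowSums(!is.na(v[, !a, drop = FALSE]))
  testable <- n_a >= 1 & n_b >= 1 & (n_a + n_b) >= 3
  if (!all(testable)) {
    warning(sum(!testable), " feature(s) with insufficient observations dropped",
      call. = FALSE
    )
    v <- v[testable, , drop = FALSE]
    n_a <- n_a[testable]
    n_b <- n_b[testable]
  }
  m_a <- rowMeans(v[, a, drop = FALSE], na.rm = TRUE)
  m_b <- rowMeans(v[, !a, drop = FALSE], na.rm = TRUE)
  rss <- rowSums((v[, a, drop = FALSE] - m_a)^2, na.rm = TRUE) +
    rowSums((v[, !a, drop = FALSE] - m_b)^2, na.rm = TRUE)
  df <- n_a + n_b - 2
  s2 <- ifelse(df > 0, rss / pmax(df, 1), NA_real_)
  lfc <- m_a - m_b

  if (is.null(prior_df)) {
    if (nrow(v) < 2L) {
      warning("fewer than 2 features: no prior estimated, using ordinary t",
        call. = FALSE
      )
      prior <- list(d0 = 0, s02 = NA_real_)
    } else {
      prior <- fit_variance_prior(s2, df)
    }
  } else {
    est <- if (nrow(v) >= 2L) fit_variance_prior(s2, df) else list(s02 = mean(s2, na.rm = TRUE))
    prior <- list(d0 = prior_df, s02 = est$s02)
  }
  d0 <- prior$d0
  s02 <- prior$s02

  post_var <- if (is.infinite(d0)) {
    rep(s02, length(s2))
  } else if (d0 == 0) {
    s2
  } else {
    (d0 * s02 + df * ifelse(df > 0, s2, 0)) / (d0 + df)
  }
  se <- sqrt(post_var * (1 / n_a + 1 / n_b))
  t_stat <- lfc / se
  df_total <- df + d0
  p <- 2 * stats::pt(-abs(t_stat), df = df_total)
  structure(
    list(
      table = tibble::tibble(
        feature = rownames(v), lfc = unname(lfc), s2 = unname(s2),
        df = unname(df), post_var = unname(post_var),
        statistic = unname(t_stat), p_value = unname(p),
        adj_p = bh_adjust(ifelse(is.na(p), 1, p))
      ),
      d0 = d0, s02 = s02,
      contrast = paste(levels(groups)[1], "-", levels(groups)[2])
    ),
    class = "moderated_fit"
  )
}

#' @rdname moderated_two_group
#' @param x A `moderated_fit`.
#' @param ... Unused.
#' @export
tidy.moderated_fit <- function(x, ...) x$table

#' @rdname moderated_two_group
#' @export
glance.moderated_fit <- function(x, ...) {
  tibble::tibble(
    prior_df = x$d0, prior_var = x$s02,
    n_features = nrow(x$table), contrast = x$contrast
  )
}

#' Call differential features at joint thresholds
#'
#' Post-hoc joint filter: |lfc| above `lfc_cut` and BH-adjusted p below
#' `fdr_cut`.
#'
#' @param fit A `moderated_fit`.
#' @param lfc_cut,fdr_cut Thresholds (defaults: 1 log2 unit, 0.05).
#' @return Tibble of significant features.
#' @export
differential_features <- function(fit, lfc_cut = 1, fdr_cut = 0.05) {
  dplyr::filter(fit$table, abs(.data$lfc) > lfc_cut, .data$adj_p < fdr_cut)
}

#' Welch's two-sample t-test
#'
#' @param a,b Numeric sample vectors (>= 2 observations each).
#' @param sides `"two.sided"` (default), `"less"` or `"greater"`.
#' @return A tibble (`statistic`, `df`, `p_value`).
#' @export
welch_test <- function(a, b, sides = c("two.sided", "less", "greater")) {
  sides <- match.arg(sides)
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(tibble::tibble(statistic = 0, df = length(a) + length(b) - 2, p_value = 1))
    }
    stop("both groups have zero variance with unequal means", call. = FALSE)
  }
  fit <- stats::t.test(a, b, alternative = sides, var.equal = FALSE)
  tibble::tibble(
    statistic = unname(fit$statistic), df = unname(fit$parameter),
    p_value = fit$p.value
  )
}

#' Two-way ANOVA with interaction
#'
#' Type-II sums of squares by default (appropriate for the unbalanced
#' membrane designs here); Type I available by flag.
#'
#' @param data Long data frame.
#' @param response,factor_a,factor_b Column names (strings) of the value
#'   and the two factors.
#' @param type `"II"` (default) or `"I"`.
#' @return A tibble (`term`, `sumsq`, `df`, `statistic`, `p_value`).
#' @export
two_way_anova <- function(data, response = "value", factor_a = "factorA",
                          factor_b = "factorB", type = c("II", "I")) {
  type <- match.arg(type)
  fa <- droplevels(as.factor(data[[factor_a]]))
  fb <- droplevels(as.factor(data[[factor_b]]))
  stopifnot(nlevels(fa) >= 2, nlevels(fb) >= 2)
  cell <- table(fa, fb)
  if (any(cell == 0)) {
    bad <- which(cell == 0, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "empty cell under the interaction model: %s = %s, %s = %s",
      factor_a, rownames(cell)[bad[1]], factor_b, colnames(cell)[bad[2]]
    ), call. = FALSE)
  }
  df <- data.frame(y = data[[response]], A = fa, B = fb)
  fit <- stats::lm(y ~ A * B, data = df)
  if (type == "II") {
    tab <- car::Anova(fit, type = 2)
    terms_ <- rownames(tab)
    out <- tibble::tibble(
      term = terms_, sumsq = tab[["Sum Sq"]], df = tab[["Df"]],
      statistic = tab[["F value"]], p_value = tab[["Pr(>F)"]]
    )
  } else {
    tab <- stats::anova(fit)
    out <- tibble::tibble(
      term = rownames(tab), sumsq = tab[["Sum Sq"]], df = tab[["Df"]],
      statistic = tab[["F value"]], p_value = tab[["Pr(>F)"]]
    )
  }
  out$term <- sub("^A$", factor_a, out$term)
  out$term <- sub("^B$", factor_b, out$term)
  out$term <- sub("^A:B$", paste0(factor_a, ":", factor_b), out$term)
  out
}

#' Tukey honestly-significant-difference comparisons
#'
#' @param data Long data frame.
#' @param response,group Column names (strings) of the value and grouping
#'   factor.
#' @return A tibble (`contrast`, `estimate`, `conf_low`, `conf_high`,
#'   `adj_p`) with studentized-range adjusted p-values.
#' @export
tukey_hsd <- function(data, response = "value", group = "group") {
  g <- droplevels(as.factor(data[[group]]))
  stopifnot(nlevels(g) >= 2)
  counts <- table(g)
  if (any(counts < 2)) {
    stop("singleton group(s): ", paste(names(counts)[counts < 2], collapse = ", "),
      call. = FALSE
    )
  }
  df <- data.frame(y = data[[response]], g = g)
  hsd <- stats::TukeyHSD(stats::aov(y ~ g, data = df))$g
  tibble::tibble(
    contrast = rownames(hsd), estimate = unname(hsd[, "diff"]),
    conf_low = unname(hsd[, "lwr"]), conf_high = unname(hsd[, "upr"]),
    adj_p = unname(hsd[, "p adj"])
  )
}

#' Exact power of the two-sample t-test
#'
#' Equal-n two-sample design: the rejection region comes from the central
#' t distribution at level `alpha`, and power is the corresponding tail
#' mass of the noncentral t with noncentrality \eqn{d\sqrt{n/2}}.
#'
#' @param n Samples per group (>= 2).
#' @param d Standardized mean difference (Cohen's d).
#' @param alpha Type-I error rate in (0, 1).
#' @param sides `"two.sided"` (default) or `"one.sided"`.
#' @return Power in [0, 1]; equals `alpha` exactly at `d = 0` (two-sided).
#' @export
t_test_power <- function(n, d, alpha = 0.05, sides = c("two.sided", "one.sided")) {
  sides <- match.arg(sides)
  stopifnot(n >= 2, alpha > 0, alpha < 1)
  df <- 2 * n - 2
  ncp <- d * sqrt(n / 2)
  if (ncp == 0) return(alpha) # central case, exact at any df
  if (sides == "two.sided") {
    crit <- stats::qt(1 - alpha / 2, df)
    stats::pt(-crit, df, ncp = ncp) + stats::pt(crit, df, ncp = ncp, lower.tail = FALSE)
  } else {
    crit <- stats::qt(1 - alpha, df)
    stats::pt(crit, df, ncp = ncp, lower.tail = FALSE)
  }
}
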