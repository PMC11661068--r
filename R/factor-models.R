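#' Z-score features within a study
#'
#' Centres and scales each feature (row) across samples — the form in
#' which data enter the factor models and Bartlett scoring.
#'
#' @param mat An [expr_mat()].
#' @return An [expr_mat()] with per-row mean 0 and sd 1.
#' @export
scale_features <- function(mat) {
  v <- mat$values
  if (anyNA(v)) stop("scale_features requires a complete matrix", call. = FALSE)
  sds <- apply(v, 1L, stats::sd)
  if (any(sds == 0)) {
    stop("constant feature(s): ",
      paste(utils::head(rownames(v)[sds == 0], 5), collapse = ", "),
      call. = FALSE
    )
  }
  expr_mat((v - rowMeans(v)) / sds, scale = mat$scale)
}

#' Supervised PCA with eigengene extraction
#'
#' Restricts the matrix to an externally defined feature list (e.g. genes
#' near sex-dimorphic accessible chromatin regions, or differentially
#' expressed genes), runs PCA over samples, and extracts per-sample scores
#' ("eigengenes") and per-feature loadings ("eigenvectors") from the first
#' principal component, whose sign is fixed so the largest-magnitude
#' loading is positive. A Welch test compares PC1 scores between the two
#' classes.
#'
#' @param mat An [expr_mat()].
#' @param feature_list Character vector of feature labels to keep.
#' @param class_labels Two-level factor (or character) over samples.
#' @param scale. Scale features to unit variance before the decomposition.
#' @return An object of class `spca_result` with elements `scores`
#'   (tibble: sample, class, score), `loadings` (tibble: feature, loading),
#'   `var_explained` (per component), `welch` (tibble), `features_used`.
#' @export
spca <- function(mat, feature_list, class_labels, scale. = FALSE) {
  v <- mat$values
  present <- intersect(feature_list, rownames(v))
  if (length(present) < 2L) {
    stop("fewer than 2 listed features present in the matrix; missing: ",
      paste(utils::head(setdiff(feature_list, rownames(v)), 10), collapse = ", "),
      call. = FALSE
    )
  }
  sub <- v[present, , drop = FALSE]
  complete <- rowSums(is.na(sub)) == 0L
  if (!all(complete)) {
    warning(sum(!complete), " feature(s) with missing values dropped", call. = FALSE)
    sub <- sub[complete, , drop = FALSE]
  }
  if (nrow(sub) < 2L) stop("fewer than 2 complete features remain", call. = FALSE)
  class_labels <- droplevels(as.factor(class_labels))
  stopifnot(length(class_labels) == ncol(sub), nlevels(class_labels) == 2)

  pc <- stats::prcomp(t(sub), center = TRUE, scale. = scale.)
  flip <- sign(pc$rotation[which.max(abs(pc$rotation[, 1])), 1])
  scores1 <- pc$x[, 1] * flip
  load1 <- pc$rotation[, 1] * flip
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  lv <- levels(class_labels)
  w <- welch_test(scores1[class_labels == lv[1]], scores1[class_labels == lv[2]])
  structure(
    list(
      scores = tibble::tibble(
        sample = colnames(sub), class = as.character(class_labels),
        score = unname(scores1)
      ),
      loadings = tibble::tibble(feature = rownames(sub), loading = unname(load1)),
      var_explained = ve,
      welch = w,
      features_used = rownames(sub)
    ),
    class = "spca_result"
  )
}

#' @rdname spca
#' @param x An `spca_result`.
#' @param ... Unused.
#' @export
tidy.spca_result <- function(x, ...) x$scores

#' @rdname spca
#' @export
glance.spca_result <- function(x, ...) {
  tibble::tibble(
    n_features = length(x$features_used),
    pc1_var_explained = x$var_explained[1],
    welch_statistic = x$welch$statistic,
    welch_p = x$welch$p_value
  )
}

#' Kaiser-Meyer-Olkin sampling adequacy
#'
#' KMO compares squared correlations to squared partial correlations
#' (computed from the inverse correlation matrix): values near 1 indicate
#' data compressible by common factors, values below 0.5 inadequate
#' sampling. Variables are the matrix rows (features), observed across
#' samples.
#'
#' @param mat An [expr_mat()] with at least 3 samples.
#' @param ridge Ridge added to the correlation diagonal when it is not
#'   invertible (warned; unavoidable when features outnumber samples).
#' @return A list with `kmo` (overall, in [0, 1]) and `msa` (per-variable
#'   tibble).
#' @export
kmo <- function(mat, ridge = 1e-6) {
  v <- mat$values
  stopifnot(ncol(v) >= 3)
  sds <- apply(v, 1L, stats::sd)
  if (any(sds == 0)) {
    stop("constant variable(s): ",
      paste(utils::head(rownames(v)[sds == 0], 5), collapse = ", "),
      call. = FALSE
    )
  }
  r <- stats::cor(t(v))
  inv <- tryCatch(solve(r), error = function(e) {
    warning("correlation matrix singular; using ridge-regularized inverse",
      call. = FALSE
    )
    solve(r + diag(ridge, nrow(r)))
  })
  d <- 1 / sqrt(diag(inv))
  partial <- -inv * tcrossprod(d)
  diag(r) <- 0
  diag(partial) <- 0
  r2 <- r^2
  p2 <- partial^2
  overall <- sum(r2) / (sum(r2) + sum(p2))
  msa <- rowSums(r2) / (rowSums(r2) + rowSums(p2))
  list(
    kmo = overall,
    msa = tibble::tibble(feature = rownames(v), msa = unname(msa))
  )
}

#' Choose a factor count from the eigenvalue scree
#'
#' @param mat An [expr_mat()] (variables in rows).
#' @param rule `"kaiser"` (count of correlation eigenvalues above 1) or
#'   `"elbow"` (position of the largest drop between consecutive
#'   eigenvalues).
#' @return A list of class `scree` with `n_factors` and `eigenvalues`.
#' @export
scree_factor_count <- function(mat, rule = c("kaiser", "elbow")) {
  rule <- match.arg(rule)
  v <- mat$values
  stopifnot(nrow(v) >= 3)
  ev <- eigen(stats::cor(t(v)), symmetric = TRUE, only.values = TRUE)$values
  n <- switch(rule,
    kaiser = sum(ev > 1),
    elbow = which.max(-diff(ev))
  )
  structure(list(n_factors = as.integer(n), eigenvalues = ev, rule = rule),
    class = "scree"
  )
}

#' @export
print.scree <- function(x, ...) {
  cat(sprintf(
    "<scree> %d factor(s) by %s rule; leading eigenvalues: %s\n",
    x$n_factors, x$rule,
    paste(signif(utils::head(x$eigenvalues, 5), 3), collapse = ", ")
  ))
  invisible(x)
}

#' Bartlett (weighted-least-squares) factor scores
#'
#' Estimates shared-factor scores per sample as
#' \deqn{\hat f = (\Phi^\top \Psi^{-1} \Phi)^{-1} \Phi^\top \Psi^{-1} \tilde x,}
#' using the shared loadings and the scored study's specific variances;
#' study-specific factors are treated as noise at scoring time. The input
#' must be the centred/scaled data the model was fitted to.
#'
#' @param model An `msfa_model` from [msfa_fit()].
#' @param data Centred/scaled study data: an [expr_mat()], a
#'   features-by-samples matrix, or a single-sample numeric vector.
#' @param study Study name or index selecting which \eqn{\Psi_s} to use
#'   (defaults to the first study).
#' @return An n-by-K matrix of factor scores (rownames = sample ids).
#' @export
bartlett_scores <- function(model, data, study = 1L) {
  phi <- model$phi
  psi <- model$psi[[study]]
  x <- if (inherits(data, "expr_mat")) data$values else data
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  stopifnot(nrow(x) == nrow(phi), length(psi) == nrow(phi))
  wphi <- phi / psi
  gram <- crossprod(phi, wphi)
  if (kappa(gram) > 1e12) {
    stop("t(Phi) Psi^-1 Phi is singular: collinear loadings", call. = FALSE)
  }
  scores <- t(solve(gram, crossprod(wphi, x)))
  dimnames(scores) <- list(colnames(x), paste0("factor", seq_len(ncol(phi))))
  scores
}

#' Pool Bartlett scores across studies into a long tibble
#'
#' @param model An `msfa_model`.
#' @param data_list Named list of centred/scaled study matrices
#'   ([expr_mat()] or matrix), names matching the model's studies.
#' @param sex_list Named list of per-sample sex labels aligned to each
#'   study's columns.
#' @return A tibble (`study`, `sample`, `sex`, `factor`, `score`) of class
#'   `factor_scores`.
#' @export
pooled_factor_scores <- function(model, data_list, sex_list) {
  stopifnot(identical(sort(names(data_list)), sort(names(model$psi))))
  rows <- purrr::imap(data_list, function(d, nm) {
    sc <- bartlett_scores(model, d, study = nm)
    tibble::tibble(
      study = nm,
      sample = rep(rownames(sc), times = ncol(sc)),
      sex = rep(sex_list[[nm]], times = ncol(sc)),
      factor = rep(seq_len(ncol(sc)), each = nrow(sc)),
      score = as.vector(sc)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("factor_scores", class(out))
  out
}

#' Align factor signs to a reference class
#'
#' Factor loading signs are arbitrary; for interpretation they are
#' constrained to correlate positively with a chosen class (here, male
#' samples) whenever the factor looks class-relevant. Per factor, the
#' point-biserial correlation between pooled scores and the class
#' indicator is computed; if it is negative and at least `relevance_r` in
#' magnitude, that factor's loadings and scores are sign-flipped.
#'
#' @param model An `msfa_model`.
#' @param scores A `factor_scores` tibble from [pooled_factor_scores()].
#' @param positive_class Class label to correlate positively (default "M").
#' @param relevance_r Minimum |correlation| for a flip (gates flips to
#'   factors where class actually looks relevant; default 0.3).
#' @return A list `model`, `scores`, `flipped` (integer factor indices),
#'   `correlations` (post-alignment per-factor correlations).
#' @export
align_sign_to_class <- function(model, scores, positive_class = "M",
                                relevance_r = 0.3) {
  ind <- as.numeric(scores$sex == positive_class)
  cors <- vapply(seq_len(ncol(model$phi)), function(k) {
    s <- scores$score[scores$factor == k]
    stats::cor(s, ind[scores$factor == k])
  }, numeric(1))
  flip <- which(cors < 0 & abs(cors) >= relevance_r)
  if (length(flip)) {
    model$phi[, flip] <- -model$phi[, flip]
    scores$score[scores$factor %in% flip] <- -scores$score[scores$factor %in% flip]
    message(
      "align_sign_to_class: flipped factor(s) ",
      paste(flip, collapse = ", ")
    )
  }
  cors[flip] <- -cors[flip]
  list(model = model, scores = scores, flipped = flip, correlations = cors)
}

#' Test factors for sex differences
#'
#' Fits a sex-by-factor ANOVA on the long score table, then per-factor
#' male-minus-female contrasts from the cell-means model (pooled residual
#' variance), familywise-adjusted across the K factors (Holm by default;
#' single-step multivariate-t via multcomp behind a flag). Factors with
#' adjusted p below `q_cut` are flagged.
#'
#' @param scores A `factor_scores` tibble (columns `sex`, `factor`,
#'   `score`).
#' @param q_cut Adjusted-p threshold for flagging (default 0.1).
#' @param adjust `"holm"` (default) or `"single-step"` (requires multcomp).
#' @return A list with `anova` (tibble) and `contrasts` (tibble: factor,
#'   estimate, statistic, p_value, adj_p, significant).
#' @export
factor_sex_test <- function(scores, q_cut = 0.1,
                            adjust = c("holm", "single-step")) {
  adjust <- match.arg(adjust)
  stopifnot(all(c("sex", "factor", "score") %in% names(scores)))
  k_levels <- sort(unique(scores$factor))
  if (min(table(scores$sex)) < 2 * length(k_levels)) {
    stop("need >= 2 samples per sex", call. = FALSE)
  }
  single <- length(k_levels) == 1L
  if (single) {
    warning("single factor: reduces to a two-group comparison", call. = FALSE)
  }

  df <- data.frame(
    score = scores$score,
    sex = factor(scores$sex),
    fac = factor(paste0("F", scores$factor))
  )
  anova_tab <- if (single) {
    two_group <- stats::lm(score ~ sex, data = df)
    a <- stats::anova(two_group)
    tibble::tibble(
      term = "sex", sumsq = a[["Sum Sq"]][1], df = a[["Df"]][1],
      statistic = a[["F value"]][1], p_value = a[["Pr(>F)"]][1]
    )
  } else {
    two_way_anova(df, response = "score", factor_a = "sex", factor_b = "fac")
  }

  # cell-means model: one mean per sex x factor cell, shared error variance
  df$cell <- interaction(df$sex, df$fac)
  fit <- stats::lm(score ~ 0 + cell, data = df)
  cells <- levels(df$cell)
  beta <- stats::coef(fit)
  sigma2 <- sum(stats::residuals(fit)^2) / fit$df.residual
  n_cell <- table(df$cell)

  contr <- purrr::map(k_levels, function(k) {
    m_cell <- paste0("M.F", k)
    f_cell <- paste0("F.F", k)
    est <- beta[paste0("cell", m_cell)] - beta[paste0("cell", f_cell)]
    se <- sqrt(sigma2 * (1 / n_cell[m_cell] + 1 / n_cell[f_cell]))
    t_stat <- est / se
    tibble::tibble(
      factor = k,
      contrast = paste0("Male.Factor", k, " - Female.Factor", k),
      estimate = unname(est), statistic = unname(t_stat),
      p_value = unname(2 * stats::pt(-abs(t_stat), fit$df.residual))
    )
  })
  contr <- dplyr::bind_rows(contr)
  if (adjust == "holm" || !requireNamespace("multcomp", quietly = TRUE)) {
    contr$adj_p <- stats::p.adjust(contr$p_value, method = "holm")
  } else {
    cm <- matrix(0, nrow = length(k_levels), ncol = length(cells))
    colnames(cm) <- paste0("cell", cells)
    for (i in seq_along(k_levels)) {
      cm[i, paste0("cell", "M.F", k_levels[i])] <- 1
      cm[i, paste0("cell", "F.F", k_levels[i])] <- -1
    }
    gl <- multcomp::glht(fit, linfct = cm)
    contr$adj_p <- summary(gl)$test$pvalues
  }
  contr$significant <- contr$adj_p < q_cut
  list(anova = anova_tab, contrasts = contr)
}

#' Rank features by a shared-factor loading column
#'
#' @param model An `msfa_model`.
#' @param factor_index Shared factor index in `1..K`.
#' @return A [ranked_list()] tibble of features by descending loading,
#'   ready for [gsea()] (use a small `min_size`, e.g. 5, on small panels).
#' @export
loadings_to_ranked <- function(model, factor_index) {
  k <- ncol(model$phi)
  if (!(factor_index %in% seq_len(k))) {
    stop("factor_index must be in 1..", k, call. = FALSE)
  }
  ranked_list(rownames(model$phi), model$phi[, factor_index])
}
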