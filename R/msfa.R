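#' Multi-study factor analysis by expectation/conditional maximization
#'
#' Fits the Gaussian latent factor model in which study \eqn{s} has
#' covariance
#' \deqn{\Sigma_s = \Phi\Phi^\top + \Lambda_s\Lambda_s^\top + \Psi_s,}
#' with loadings \eqn{\Phi} (p x K) shared across studies, study-specific
#' loadings \eqn{\Lambda_s} (p x J_s) and diagonal specific variances
#' \eqn{\Psi_s}. Data are centred and scaled per feature within each study
#' before fitting. Identifiability uses the block-lower-triangular family:
#' entries above the diagonal of the leading K x K block of \eqn{\Phi} and
#' of each \eqn{\Lambda_s}'s leading J_s x J_s block are fixed at zero.
#' Because the likelihood identifies \eqn{\Phi} only up to rotation within
#' its column space, the reported shared loadings are the principal-axis
#' representative of \eqn{\Phi\Phi^\top} (eigenvectors scaled by square-root
#' eigenvalues, ordered by decreasing shared variance) — a deterministic,
#' label-free basis that leaves every implied covariance unchanged; the raw
#' block-lower representative is retained as `phi_constrained`. No further
#' rotation (varimax etc.) is applied; signs are aligned separately (see
#' [align_sign_to_class()]).
#'
#' Starting values take the shared block from the leading singular vectors
#' of the concatenated standardized data and the specific blocks from
#' per-study residual factor extraction. Each ECM iteration computes the
#' joint posterior moments of shared plus specific factors per study
#' (E-step) and then conditionally maximizes over \eqn{\Phi} (pooled
#' across studies, feature-wise weighted by \eqn{n_s/\psi_{sj}}), each
#' \eqn{\Lambda_s}, and each \eqn{\Psi_s}. The observed-data
#' log-likelihood is recorded every iteration and is non-decreasing by
#' construction; iteration stops when its relative change drops below
#' `tol` or at `max_iter`.
#'
#' @param studies Named list of [expr_mat()] (or matrices),
#'   features-by-samples, sharing one feature panel in the same order.
#' @param k Number of shared factors (>= 1).
#' @param j Integer vector of study-specific factor counts (recycled).
#' @param max_iter Iteration cap (default 10000).
#' @param tol Relative log-likelihood convergence tolerance (default 1e-6).
#' @param psi_floor Lower bound on specific variances, preventing Heywood
#'   collapse (default 1e-6; floor hits are counted in the result).
#' @param scale Centre/scale features within each study first (default
#'   TRUE; set FALSE only if the input is already standardized).
#' @return An object of class `msfa_model`: `phi` (principal-axis shared
#'   loadings), `phi_constrained` (block-lower ECM representative),
#'   `lambda` (named list), `psi` (named list of variance vectors),
#'   `loglik` (per-iteration trace), `converged`, `n_iter`,
#'   `n_floor_hits`, `data` (the centred/scaled matrices used, for
#'   scoring), `n` (per-study sample sizes).
#' @export
msfa_fit <- function(studies, k, j = 1L, max_iter = 10000L, tol = 1e-6,
                     psi_floor = 1e-6, scale = TRUE) {
  stopifnot(length(studies) >= 1, k >= 1)
  if (is.null(names(studies))) {
    names(studies) <- paste0("study", seq_along(studies))
  }
  j <- rep_len(as.integer(j), length(studies))
  mats <- lapply(studies, function(s) if (inherits(s, "expr_mat")) s$values else s)
  p <- nrow(mats[[1]])
  feats <- rownames(mats[[1]])
  for (m in mats) {
    if (!identical(rownames(m), feats)) {
      stop("all studies must share one feature panel in the same order",
        call. = FALSE
      )
    }
  }
  if (k + max(j) >= p) stop("k + max(j) must be < p", call. = FALSE)
  if (scale) {
    mats <- lapply(mats, function(m) scale_features(expr_mat(m))$values)
  }
  n_s <- vapply(mats, ncol, integer(1))
  # sample covariance with MLE denominator, per study
  s_list <- lapply(mats, function(m) tcrossprod(m - rowMeans(m)) / ncol(m))

  # ---- starting values ----------------------------------------------------
  z_all <- t(do.call(cbind, mats)) # samples x features
  sv <- svd(z_all, nu = 0, nv = k)
  d_scale <- sv$d[seq_len(k)] / sqrt(nrow(z_all))
  phi <- sv$v %*% diag(d_scale, k)
  lambda <- vector("list", length(mats))
  for (s in seq_along(mats)) {
    if (j[s] > 0) {
      zr <- t(mats[[s]]) - t(mats[[s]]) %*% sv$v %*% t(sv$v)
      svr <- svd(zr, nu = 0, nv = j[s])
      lambda[[s]] <- svr$v %*% diag(svr$d[seq_len(j[s])] / sqrt(n_s[s]), j[s])
    } else {
      lambda[[s]] <- matrix(0, p, 0)
    }
  }
  psi <- lapply(seq_along(mats), function(s) {
    pmax(diag(s_list[[s]]) - rowSums(phi^2) - rowSums(lambda[[s]]^2), psi_floor)
  })
  phi <- rotate_to_block_lower(phi)
  lambda <- lapply(lambda, rotate_to_block_lower)

  # ---- ECM iterations -----------------------------------------------------
  loglik <- numeric(0)
  converged <- FALSE
  n_floor <- 0L
  const <- -0.5 * p * log(2 * pi)
  for (iter in seq_len(max_iter)) {
    e <- vector("list", length(mats))
    ll <- 0
    for (s in seq_along(mats)) {
      l_s <- cbind(phi, lambda[[s]])
      m_s <- ncol(l_s)
      sigma <- tcrossprod(phi) + tcrossprod(lambda[[s]]) + diag(psi[[s]], p)
      ch <- chol(sigma)
      logdet <- 2 * sum(log(diag(ch)))
      sig_inv <- chol2inv(ch)
      b <- crossprod(l_s, sig_inv) # m x p
      cmat <- s_list[[s]] %*% t(b) # p x m
      mmat <- diag(m_s) - b %*% l_s + b %*% cmat # E[zz'] (m x m)
      mmat <- (mmat + t(mmat)) / 2
      e[[s]] <- list(c = cmat, m = mmat, b = b)
      ll <- ll + n_s[s] * (const - 0.5 * (logdet + sum(sig_inv * s_list[[s]])))
    }
    loglik <- c(loglik, ll)
    if (iter > 1 && abs(ll - loglik[iter - 1]) <
      tol * (abs(loglik[iter - 1]) + 1e-10)) {
      converged <- TRUE
      break
    }

    # CM step 1: shared loadings, feature-wise weighted across studies
    kf <- seq_len(k)
    rhs_mats <- lapply(seq_along(mats), function(s) {
      cf <- e[[s]]$c[, kf, drop = FALSE]
      if (j[s] > 0) {
        mlf <- e[[s]]$m[-kf, kf, drop = FALSE]
        cf - lambda[[s]] %*% mlf
      } else {
        cf
      }
    })
    mff <- lapply(e, function(es) es$m[kf, kf, drop = FALSE])
    w <- vapply(seq_along(mats), function(s) n_s[s] / psi[[s]], numeric(p))
    phi_new <- matrix(0, p, k)
    for (r in seq_len(p)) {
      free <- seq_len(min(r, k))
      a_r <- matrix(0, k, k)
      b_r <- numeric(k)
      for (s in seq_along(mats)) {
        a_r <- a_r + w[r, s] * mff[[s]]
        b_r <- b_r + w[r, s] * rhs_mats[[s]][r, ]
      }
      phi_new[r, free] <- solve(
        a_r[free, free, drop = FALSE],
        b_r[free]
      )
    }
    phi <- phi_new

    # CM step 2: study-specific loadings (given the new Phi)
    for (s in seq_along(mats)) {
      if (j[s] == 0) next
      cl <- e[[s]]$c[, -kf, drop = FALSE]
      mfl <- e[[s]]$m[kf, -kf, drop = FALSE]
      mll <- e[[s]]$m[-kf, -kf, drop = FALSE]
      resid <- cl - phi %*% mfl
      lam <- matrix(0, p, j[s])
      for (r in seq_len(p)) {
        free <- seq_len(min(r, j[s]))
        lam[r, free] <- solve(
          mll[free, free, drop = FALSE],
          resid[r, free]
        )
      }
      lambda[[s]] <- lam
    }

    # CM step 3: specific variances (given the new loadings)
    for (s in seq_along(mats)) {
      l_s <- cbind(phi, lambda[[s]])
      quad <- rowSums((l_s %*% e[[s]]$m) * l_s)
      cross <- rowSums(l_s * e[[s]]$c)
      psi_new <- diag(s_list[[s]]) - 2 * cross + quad
      n_floor <- n_floor + sum(psi_new < psi_floor)
      psi[[s]] <- pmax(psi_new, psi_floor)
    }
  }
  if (!converged) {
    warning(sprintf(
      "ECM did not converge in %d iterations (rel. change %.3g)",
      max_iter,
      if (length(loglik) > 1) {
        abs(diff(utils::tail(loglik, 2))) / (abs(loglik[length(loglik) - 1]) + 1e-10)
      } else {
        NA_real_
      }
    ), call. = FALSE)
  }
  rownames(phi) <- feats
  names(lambda) <- names(mats)
  names(psi) <- names(mats)
  lambda <- lapply(lambda, function(l) {
    rownames(l) <- feats
    l
  })
  # The likelihood identifies Phi only up to rotation; the block-lower ECM
  # representative is arbitrary with respect to any interpretable axis. For
  # reporting and scoring, re-express the shared loadings in the principal
  # axes of Phi Phi^T (eigenvectors scaled by sqrt eigenvalues, ordered by
  # decreasing shared variance, largest-|loading| sign positive). This is
  # deterministic, label-free, and leaves every Sigma_s unchanged; the raw
  # constrained representative is kept as `phi_constrained`.
  ed <- eigen(tcrossprod(phi), symmetric = TRUE)
  phi_pa <- ed$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(ed$values[seq_len(k)], 0)), k)
  for (kk in seq_len(k)) {
    if (phi_pa[which.max(abs(phi_pa[, kk])), kk] < 0) phi_pa[, kk] <- -phi_pa[, kk]
  }
  rownames(phi_pa) <- feats
  structure(
    list(
      phi = phi_pa, phi_constrained = phi, lambda = lambda, psi = psi,
      loglik = loglik,
      converged = converged, n_iter = length(loglik),
      n_floor_hits = n_floor,
      data = lapply(mats, function(m) expr_mat(m)),
      n = n_s
    ),
    class = "msfa_model"
  )
}

# Rotate a loading matrix within its column space so the leading square
# block is lower-triangular (the block-lower identifiability pattern),
# leaving the implied covariance untouched; the constrained entries are
# then set to exact zeros.
rotate_to_block_lower <- function(m) {
  q <- ncol(m)
  if (q < 2) return(m)
  b <- m[seq_len(q), , drop = FALSE]
  rot <- qr.Q(qr(t(b)))
  out <- m %*% rot
  for (r in seq_len(q - 1)) out[r, (r + 1):q] <- 0
  out
}

#' @export
print.msfa_model <- function(x, ...) {
  cat(sprintf(
    "<msfa_model> p = %d features, K = %d shared factor(s), %d study/ies (n = %s)\n",
    nrow(x$phi), ncol(x$phi), length(x$psi),
    paste(x$n, collapse = ", ")
  ))
  cat(sprintf(
    "  %s after %d iteration(s); log-likelihood %.4f\n",
    if (x$converged) "converged" else "NOT converged", x$n_iter,
    utils::tail(x$loglik, 1)
  ))
  invisible(x)
}

#' Tidy a fitted multi-study factor model
#'
#' @param x An `msfa_model`.
#' @param what `"shared"` (default) for shared loadings, `"specific"` for
#'   study-specific loadings, `"psi"` for specific variances.
#' @param ... Unused.
#' @return A long tibble.
#' @export
tidy.msfa_model <- function(x, what = c("shared", "specific", "psi"), ...) {
  what <- match.arg(what)
  if (what == "shared") {
    tibble::tibble(
      feature = rep(rownames(x$phi), times = ncol(x$phi)),
      factor = rep(seq_len(ncol(x$phi)), each = nrow(x$phi)),
      loading = as.vector(x$phi)
    )
  } else if (what == "specific") {
    dplyr::bind_rows(purrr::imap(x$lambda, function(l, nm) {
      if (ncol(l) == 0) return(NULL)
      tibble::tibble(
        study = nm,
        feature = rep(rownames(l), times = ncol(l)),
        factor = rep(seq_len(ncol(l)), each = nrow(l)),
        loading = as.vector(l)
      )
    }))
  } else {
    dplyr::bind_rows(purrr::imap(x$psi, function(ps, nm) {
      tibble::tibble(study = nm, feature = rownames(x$phi), psi = unname(ps))
    }))
  }
}

#' @rdname tidy.msfa_model
#' @export
glance.msfa_model <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x$phi), k_shared = ncol(x$phi),
    n_studies = length(x$psi),
    loglik = utils::tail(x$loglik, 1), n_iter = x$n_iter,
    converged = x$converged, n_floor_hits = x$n_floor_hits
  )
}

#' Implied per-study covariance of a fitted model
#'
#' @param model An `msfa_model`.
#' @param study Study name or index.
#' @return The p x p matrix \eqn{\Phi\Phi^\top + \Lambda_s\Lambda_s^\top +
#'   \Psi_s}.
#' @export
msfa_implied_cov <- function(model, study = 1L) {
  tcrossprod(model$phi) + tcrossprod(model$lambda[[study]]) +
    diag(model$psi[[study]], nrow(model$phi))
}

#' Tucker congruence between two loading matrices
#'
#' Matches columns greedily by absolute congruence (sign- and
#' permutation-invariant) and returns the per-column coefficients — the
#' standard factor-recovery score.
#'
#' @param a,b Loading matrices with the same number of rows.
#' @return Numeric vector, one coefficient per column of `a`, in [0, 1].
#' @export
tucker_congruence <- function(a, b) {
  stopifnot(nrow(a) == nrow(b))
  cong <- function(x, y) abs(sum(x * y)) / sqrt(sum(x^2) * sum(y^2))
  avail <- seq_len(ncol(b))
  out <- numeric(ncol(a))
  for (i in seq_len(ncol(a))) {
    cc <- vapply(avail, function(jj) cong(a[, i], b[, jj]), numeric(1))
    best <- which.max(cc)
    out[i] <- cc[best]
    avail <- avail[-best]
  }
  out
}
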