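#' Simulation parameters for multi-study omic data
#'
#' Defines the generative model used as ground truth throughout the
#' package: each sample in study \eqn{s} is drawn as
#' \deqn{x = \Phi f + \Lambda_s l + e,}
#' with shared loadings \eqn{\Phi} (p x K), study-specific loadings
#' \eqn{\Lambda_s} (p x J_s), factor scores \eqn{f \sim N(0, I_K)} (plus a
#' mean shift on sex-associated factors for male samples),
#' \eqn{l \sim N(0, I_{J_s})} and diagonal noise \eqn{e \sim N(0, \Psi_s)}.
#'
#' Defaults emulate the motivating study design: a shared panel of 402
#' genes, a proteomic study of 16 samples (8 donors, 4 F + 4 M, ganglia and
#' nerve-root tissue per donor) and a transcriptomic study of 50 samples,
#' three shared factors of which the second and third carry a sex shift,
#' and planted pathway gene sets loading on the last sex factor.
#'
#' @param p Number of genes on the shared panel.
#' @param studies Named list; each element a list with `n` (samples), `j`
#'   (number of study-specific factors) and logical `missing` — whether
#'   entries of that study drop out at `missing_rate` (true for DIA
#'   proteomics, false for an RNA abundance matrix, which is complete).
#' @param k Number of shared factors.
#' @param sex_factors Integer indices (in `1:k`) of shared factors whose
#'   scores are mean-shifted in males.
#' @param sex_shift Shift size in factor-score standard deviations.
#' @param loading_sparsity Fraction of exactly-zero loadings.
#' @param loading_sd Standard deviation of non-zero shared loadings.
#' @param psi_range Interval for uniform specific variances.
#' @param missing_rate Missing-completely-at-random fraction in [0, 1).
#' @param n_replicates Technical replicates per proteomic sample.
#' @param replicate_sd Technical noise standard deviation added per replicate.
#' @param gene_group_rate Fraction of features rewritten into composite
#'   comma-joined gene-group labels that share a first term with another row.
#' @param planted_sets Named list; each element `list(factor =, n_genes =)`
#'   describing a gene set concentrated on one shared factor.
#' @param n_decoy_sets Number of random same-sized decoy sets generated
#'   alongside the planted ones (gives multiplicity context for enrichment).
#' @param seed Integer seed; every generator is deterministic given it.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(p = 402L,
                       studies = list(
                         proteomics = list(n = 16L, j = 1L, missing = TRUE),
                         rna = list(n = 50L, j = 1L, missing = FALSE)
                       ),
                       k = 3L,
                       sex_factors = c(2L, 3L),
                       sex_shift = 2,
                       loading_sparsity = 0.3,
                       loading_sd = 0.7,
                       psi_range = c(0.2, 0.8),
                       missing_rate = 0.05,
                       n_replicates = 2L,
                       replicate_sd = 0.2,
                       gene_group_rate = 0.1,
                       planted_sets = list(sex_pathway = list(factor = 3L, n_genes = 30L)),
                       n_decoy_sets = 20L,
                       seed = 1L) {
  stopifnot(
    p >= 2, k >= 1, length(studies) >= 1,
    all(sex_factors %in% seq_len(k)) || length(sex_factors) == 0,
    loading_sparsity >= 0, loading_sparsity < 1,
    missing_rate >= 0, missing_rate < 1,
    gene_group_rate >= 0, gene_group_rate < 1,
    n_replicates >= 1, length(psi_range) == 2, psi_range[1] <= psi_range[2],
    psi_range[1] >= 0
  )
  for (ps in planted_sets) {
    stopifnot(ps$factor %in% seq_len(k), ps$n_genes >= 1, ps$n_genes <= p)
  }
  structure(
    list(
      p = as.integer(p), studies = studies, k = as.integer(k),
      sex_factors = as.integer(sex_factors), sex_shift = sex_shift,
      loading_sparsity = loading_sparsity, loading_sd = loading_sd,
      psi_range = psi_range, missing_rate = missing_rate,
      n_replicates = as.integer(n_replicates), replicate_sd = replicate_sd,
      gene_group_rate = gene_group_rate, planted_sets = planted_sets,
      n_decoy_sets = as.integer(n_decoy_sets), seed = as.integer(seed)
    ),
    class = "sim_params"
  )
}

gene_panel <- function(p) sprintf("G%04d", seq_len(p))

draw_loadings <- function(p, k, sparsity, sd) {
  m <- matrix(stats::rnorm(p * k, sd = sd), p, k)
  m[matrix(stats::runif(p * k) < sparsity, p, k)] <- 0
  m
}

# Balanced deterministic sex assignment: F then M, interleaved.
balanced_sex <- function(n) rep(c("F", "M"), length.out = n)

#' Simulate multi-study omic data with shared latent factors
#'
#' Draws every study from the latent model described in [sim_params()] and
#' returns the data alongside the full generative truth, so parameter
#' recovery by the fitting stages can be scored exactly.
#'
#' @param params A [sim_params()] object.
#' @return A list with:
#'   * `studies`: named list of `list(matrix, metadata)` — a genes-by-samples
#'     [expr_mat()] (raw scale, Gaussian signal) and a metadata tibble;
#'   * `truth`: `phi` (p x K), `lambda`/`psi` per study, `scores` per study,
#'     sex labels, the planted set -> factor map;
#'   * `gene_sets`: planted sets plus random decoys, as a GMT-style list.
#' @export
simulate_msfa_studies <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  max_j <- max(vapply(params$studies, function(s) as.integer(s$j), integer(1)))
  if (params$k + max_j >= params$p) {
    stop("k + max(j) must be < p (model unidentifiable)", call. = FALSE)
  }
  set.seed(params$seed)
  p <- params$p
  k <- params$k
  genes <- gene_panel(p)

  phi <- draw_loadings(p, k, params$loading_sparsity, params$loading_sd)
  planted_map <- list()
  used <- integer(0)
  for (nm in names(params$planted_sets)) {
    ps <- params$planted_sets[[nm]]
    idx <- sample(setdiff(seq_len(p), used), ps$n_genes)
    used <- c(used, idx)
    # concentrate strong positive loadings on the target factor and mute the
    # rest so the set sits at the top of that factor's ranked loadings
    phi[idx, ] <- phi[idx, ] * 0.2
    phi[idx, ps$factor] <- abs(stats::rnorm(ps$n_genes, mean = 1.1, sd = 0.15))
    planted_map[[nm]] <- list(factor = ps$factor, genes = genes[idx])
  }
  rownames(phi) <- genes

  studies <- list()
  truth <- list(
    phi = phi, lambda = list(), psi = list(), scores = list(),
    sex = list(), planted = planted_map
  )
  for (nm in names(params$studies)) {
    cfg <- params$studies[[nm]]
    n <- as.integer(cfg$n)
    j <- as.integer(cfg$j)
    lambda <- if (j > 0) {
      draw_loadings(p, j, params$loading_sparsity, 0.5)
    } else {
      matrix(0, p, 0)
    }
    psi <- stats::runif(p, params$psi_range[1], params$psi_range[2])
    sex <- balanced_sex(n)
    f <- matrix(stats::rnorm(n * k), n, k)
    if (length(params$sex_factors)) {
      f[sex == "M", params$sex_factors] <-
        f[sex == "M", params$sex_factors] + params$sex_shift
    }
    l <- matrix(stats::rnorm(n * j), n, j)
    e <- matrix(stats::rnorm(p * n, sd = sqrt(psi)), p, n)
    x <- phi %*% t(f) + lambda %*% t(l) + e
    use_missing <- isTRUE(cfg$missing)
    if (use_missing && params$missing_rate > 0) {
      x[matrix(stats::runif(p * n) < params$missing_rate, p, n)] <- NA_real_
    }
    ids <- sprintf("%s_s%03d", nm, seq_len(n))
    dimnames(x) <- list(genes, ids)
    meta <- sample_metadata(tibble::tibble(
      sample_id = ids, donor_id = ids, sex = sex,
      tissue = "other", replicate = 1L
    ))
    studies[[nm]] <- list(matrix = expr_mat(x), metadata = meta)
    truth$lambda[[nm]] <- lambda
    truth$psi[[nm]] <- psi
    truth$scores[[nm]] <- f
    truth$sex[[nm]] <- sex
  }

  sets <- lapply(planted_map, `[[`, "genes")
  if (params$n_decoy_sets > 0) {
    sizes <- if (length(sets)) lengths(sets) else 30L
    for (i in seq_len(params$n_decoy_sets)) {
      sets[[sprintf("decoy_%02d", i)]] <-
        sample(genes, sizes[1 + (i - 1) %% length(sizes)])
    }
  }
  gene_sets <- structure(sets,
    descriptions = stats::setNames(rep("synthetic", length(sets)), names(sets)),
    class = "gene_sets"
  )
  list(studies = studies, truth = truth, gene_sets = gene_sets)
}

#' Simulate a replicated proteomics experiment
#'
#' Builds a paper-style proteomic design — donors balanced by sex, two
#' tissues per donor, technical replicates per biological sample — on top
#' of the latent factor model, then degrades it the way acquisition does:
#' technical noise per replicate, missing values completely at random, and
#' a fraction of row labels rewritten into composite "gene group" labels
#' (comma-joined symbol lists whose first term collides with another row),
#' which the deduplication stage must later resolve.
#'
#' @param params A [sim_params()] object; `studies` is ignored — the design
#'   here is `n_donors` donors x 2 tissues x `n_replicates` replicates.
#' @param n_donors Number of donors (half F, half M).
#' @param baseline_log2 Mean log2 intensity added before exponentiation, so
#'   the returned matrix holds positive raw intensities on the scale DIA
#'   software reports (default 20; the latent signal is log2-additive).
#' @return A list with `matrix` (raw-scale [expr_mat()] with one column per
#'   replicate), `metadata`, and `truth` (loadings, scores, sex per donor).
#' @export
simulate_proteomics_experiment <- function(params, n_donors = 8L,
                                           baseline_log2 = 20) {
  stopifnot(inherits(params, "sim_params"), n_donors >= 2, n_donors %% 2 == 0)
  set.seed(stage_seed(params$seed, "proteomics_experiment"))
  p <- params$p
  k <- params$k
  genes <- gene_panel(p)
  tissues <- c("ganglia", "nerve_root")
  donors <- sprintf("d%02d", seq_len(n_donors))
  sex_by_donor <- stats::setNames(balanced_sex(n_donors), donors)

  phi <- draw_loadings(p, k, params$loading_sparsity, params$loading_sd)
  psi <- stats::runif(p, params$psi_range[1], params$psi_range[2])
  n_bio <- n_donors * length(tissues)
  f <- matrix(stats::rnorm(n_bio * k), n_bio, k)
  bio_sex <- rep(sex_by_donor, each = length(tissues))
  if (length(params$sex_factors)) {
    f[bio_sex == "M", params$sex_factors] <-
      f[bio_sex == "M", params$sex_factors] + params$sex_shift
  }
  x_bio <- phi %*% t(f) + matrix(stats::rnorm(p * n_bio, sd = sqrt(psi)), p, n_bio)

  bio_ids <- paste(rep(donors, each = length(tissues)), tissues, sep = "_")
  reps <- params$n_replicates
  x <- x_bio[, rep(seq_len(n_bio), each = reps), drop = FALSE] +
    matrix(stats::rnorm(p * n_bio * reps, sd = params$replicate_sd), p, n_bio * reps)
  ids <- paste0(rep(bio_ids, each = reps), "_r", rep(seq_len(reps), n_bio))
  x <- 2^(x + baseline_log2) # latent log2 signal -> raw intensity
  if (params$missing_rate > 0) {
    x[matrix(stats::runif(length(x)) < params$missing_rate, nrow(x))] <- NA_real_
  }

  labels <- genes
  n_grouped <- floor(params$gene_group_rate * p)
  if (n_grouped > 0) {
    grouped <- sample(seq_len(p), n_grouped)
    partners <- vapply(grouped, function(i) sample(setdiff(seq_len(p), grouped)[1:10], 1L), integer(1))
    labels[grouped] <- paste(genes[partners], genes[grouped], sep = ",")
  }
  dimnames(x) <- list(labels, ids)

  meta <- sample_metadata(tibble::tibble(
    sample_id = ids,
    donor_id = rep(rep(donors, each = length(tissues)), each = reps),
    sex = rep(bio_sex, each = reps),
    tissue = rep(rep(tissues, n_donors), each = reps),
    replicate = rep(seq_len(reps), n_bio)
  ))
  list(
    matrix = expr_mat(x),
    metadata = meta,
    truth = list(phi = phi, psi = psi, scores = f, sex = bio_sex, genes = genes)
  )
}

#' Simulate phospho-kinase array membranes
#'
#' Emulates the chemiluminescent membrane readout: each membrane (one
#' sample) has its own PBS background level; each phosphorylation site spot
#' has mean pixel intensity `background - signal`, where the signal carries
#' a site effect, a sex-by-site interaction effect, and Gaussian noise.
#'
#' @param n_per_sex Membranes (samples) per sex.
#' @param n_sites Number of phosphorylation sites.
#' @param site_effects Numeric vector (length `n_sites`) of baseline site
#'   signals.
#' @param sex_site_interaction Numeric 2 x `n_sites` matrix with rownames
#'   `"F"` and `"M"`: additive signal per sex and site (sex main effects can
#'   be encoded as constant rows). `NULL` means no sex effect.
#' @param noise_sd Spot noise standard deviation.
#' @param background_mean,background_sd PBS background distribution across
#'   membranes.
#' @param n_duplicate_spots Number of printed spots per site (arrays print
#'   duplicates; they share the true signal, with independent noise).
#' @param seed Integer seed.
#' @return A spot-intensity tibble with columns `membrane`, `sex`, `site`,
#'   `roi_mean`, including one `site == "PBS"` row per membrane.
#' @export
simulate_phospho_membranes <- function(n_per_sex = 4L,
                                       n_sites = 10L,
                                       site_effects = rep(50, n_sites),
                                       sex_site_interaction = NULL,
                                       noise_sd = 5,
                                       background_mean = 200,
                                       background_sd = 3,
                                       n_duplicate_spots = 2L,
                                       seed = 1L) {
  stopifnot(length(site_effects) == n_sites)
  if (is.null(sex_site_interaction)) {
    sex_site_interaction <- matrix(0, 2, n_sites, dimnames = list(c("F", "M"), NULL))
  }
  stopifnot(nrow(sex_site_interaction) == 2, ncol(sex_site_interaction) == n_sites)
  if (is.null(rownames(sex_site_interaction))) {
    rownames(sex_site_interaction) <- c("F", "M")
  }
  set.seed(seed)
  sites <- sprintf("site_%02d", seq_len(n_sites))
  rows <- list()
  for (sex in c("F", "M")) {
    for (i in seq_len(n_per_sex)) {
      membrane <- sprintf("%s%d", sex, i)
      pbs <- stats::rnorm(1, background_mean, background_sd)
      signal <- site_effects + sex_site_interaction[sex, ]
      roi <- matrix(
        rep(pbs - signal, n_duplicate_spots) +
          stats::rnorm(n_sites * n_duplicate_spots, sd = noise_sd),
        nrow = n_sites
      )
      rows[[length(rows) + 1L]] <- tibble::tibble(
        membrane = membrane, sex = sex,
        site = c(rep(sites, n_duplicate_spots), "PBS"),
        roi_mean = c(as.vector(roi), pbs)
      )
    }
  }
  dplyr::bind_rows(rows)
}
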