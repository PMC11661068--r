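#' Run the full cross-omic sexual-dimorphism pipeline
#'
#' Orchestrates the stages in their analysis order: proteomic
#' preprocessing (log2, gene-group dedup, completeness filter, replicate
#' merge), moderated differential testing by sex, enrichment (GSEA on the
#' ranked fold changes; over-representation of differential features
#' against the tested background), supervised PCA on an external feature
#' list, multi-study factor analysis with Bartlett scores, sign alignment
#' to males, sex-by-factor testing and factor-loading GSEA, and the
#' phospho-array sex-by-site analysis. In `synthetic` mode all inputs come
#' from the generators with known ground truth; in `files` mode they are
#' read from disk.
#'
#' One global seed (from `config`) fans out to per-stage derived seeds, so
#' adding or skipping a stage never perturbs another stage's random
#' stream, and a re-run with the same seed reproduces every number.
#'
#' @param config An [analysis_config()].
#' @param params A [sim_params()] (synthetic mode only).
#' @param mode `"synthetic"` or `"files"`.
#' @param inputs For `files` mode, a list of paths:
#'   `proteomics_matrix`, `proteomics_metadata`, `rna_matrix` (already
#'   normalized abundance), `rna_metadata`, `gene_sets` (GMT),
#'   `feature_list` (gene list / BED-like), optional `phospho_table`.
#' @param stages Character vector of stages to run, a subset of
#'   `c("de", "enrichment", "spca", "msfa", "phospho")`; omitted stages are
#'   skipped and noted in the manifest.
#' @param phospho_effect In synthetic mode, the male-minus-female signal
#'   added on alternating sites of the simulated membranes (0 for a null
#'   array).
#' @param out_dir Optional directory; result tables are written there as
#'   TSVs and their paths recorded in the manifest.
#' @return A `dimorph_run` manifest: config and parameter snapshot, seeds,
#'   per-stage dimensions, all result tables, and output paths.
#' @export
run_pipeline <- function(config = analysis_config(),
                         params = sim_params(seed = config$seed),
                         mode = c("synthetic", "files"),
                         inputs = NULL,
                         stages = c("de", "enrichment", "spca", "msfa", "phospho"),
                         phospho_effect = 15,
                         out_dir = NULL) {
  mode <- match.arg(mode)
  stages <- match.arg(stages, several.ok = TRUE)
  manifest <- list(
    config = config, mode = mode, stages_run = character(0),
    stages_skipped = setdiff(c("de", "enrichment", "spca", "msfa", "phospho"), stages),
    seeds = list(global = config$seed), dims = list(), results = list(),
    outputs = character(0), started = format(Sys.time())
  )

  if (mode == "synthetic") {
    manifest$params <- params
    sim <- simulate_msfa_studies(params)
    pe <- simulate_proteomics_experiment(params)
    gene_sets <- sim$gene_sets
    feature_list <- if (length(sim$truth$planted)) {
      sim$truth$planted[[1]]$genes
    } else {
      rownames(sim$studies[[1]]$matrix$values)[1:30]
    }
    msfa_raw <- sim$studies
    phospho_tbl <- if ("phospho" %in% stages) {
      inter <- matrix(0, 2, 10, dimnames = list(c("F", "M"), NULL))
      inter["M", seq(1, 10, by = 2)] <- phospho_effect
      simulate_phospho_membranes(
        n_per_sex = 4, n_sites = 10, sex_site_interaction = inter,
        noise_sd = 5, seed = stage_seed(config$seed, "phospho")
      )
    }
    manifest$truth <- sim$truth
  } else {
    stopifnot(!is.null(inputs))
    pe <- list(
      matrix = read_expression(inputs$proteomics_matrix),
      metadata = read_metadata(inputs$proteomics_metadata)
    )
    msfa_raw <- list(
      proteomics = pe,
      rna = list(
        matrix = read_expression(inputs$rna_matrix),
        metadata = read_metadata(inputs$rna_metadata)
      )
    )
    gene_sets <- read_gmt(inputs$gene_sets)
    feature_list <- read_gene_list(inputs$feature_list)
    phospho_tbl <- if (!is.null(inputs$phospho_table) && "phospho" %in% stages) {
      tibble::as_tibble(utils::read.delim(inputs$phospho_table))
    }
  }

  # ---- proteomic preprocessing (shared by de / spca) ----------------------
  prot <- log2_transform(pe$matrix, pseudocount = 0)
  manifest$dims$input_proteomics <- dim(prot)
  prot <- dedup_gene_groups(prot, config$dedup_policy)
  prot <- completeness_filter(prot, config$completeness)
  merged <- merge_replicates(prot, pe$metadata)
  manifest$dims$preprocessed_proteomics <- dim(merged$matrix)

  fit <- NULL
  if ("de" %in% stages) {
    groups <- factor(merged$metadata$sex, levels = c("M", "F")) # male-positive lfc
    fit <- moderated_two_group(merged$matrix, groups)
    deps <- differential_features(fit, config$lfc_cut, config$fdr_cut)
    manifest$results$de <- tidy(fit)
    manifest$results$de_prior <- glance(fit)
    manifest$results$deps <- deps
    manifest$dims$de <- c(nrow(fit$table), nrow(deps))
    manifest$stages_run <- c(manifest$stages_run, "de")
  }

  if ("enrichment" %in% stages && !is.null(fit)) {
    ranked <- ranked_list(fit$table$feature, fit$table$lfc)
    manifest$results$gsea_lfc <- gsea(
      ranked, gene_sets,
      nperm = config$gsea_nperm, weight = config$gsea_weight,
      min_size = config$gsea_min_size, max_size = config$gsea_max_size,
      seed = stage_seed(config$seed, "gsea_lfc")
    )
    manifest$results$ora <- ora_hypergeometric(
      manifest$results$deps$feature, fit$table$feature, gene_sets
    )
    manifest$dims$enrichment <- nrow(manifest$results$gsea_lfc)
    manifest$stages_run <- c(manifest$stages_run, "enrichment")
  }

  if ("spca" %in% stages) {
    sp <- spca(merged$matrix, feature_list, merged$metadata$sex)
    manifest$results$spca_scores <- tidy(sp)
    manifest$results$spca_summary <- glance(sp)
    manifest$results$spca_loadings <- sp$loadings
    manifest$stages_run <- c(manifest$stages_run, "spca")
  }

  if ("msfa" %in% stages) {
    if (mode == "files") {
      # the factor model consumes the preprocessed (merged, log2) proteome
      msfa_raw$proteomics <- list(matrix = merged$matrix, metadata = merged$metadata)
    }
    msfa_in <- prepare_msfa_inputs(msfa_raw, mode)
    manifest$dims$msfa_panel <- nrow(msfa_in$matrices[[1]]$values)
    manifest$results$kmo <- tibble::tibble(
      study = names(msfa_in$matrices),
      kmo = vapply(msfa_in$matrices, function(m) suppressWarnings(kmo(m)$kmo), numeric(1))
    )
    low <- manifest$results$kmo$kmo < config$kmo_min
    if (any(low)) {
      warning("KMO below ", config$kmo_min, " for: ",
        paste(manifest$results$kmo$study[low], collapse = ", "),
        call. = FALSE
      )
    }
    scree_j <- vapply(msfa_in$matrices, function(m) {
      scree_factor_count(m, rule = "elbow")$n_factors
    }, integer(1))
    j <- pmax(1L, pmin(scree_j, 2L))
    k <- if (mode == "synthetic") params$k else 3L
    model <- msfa_fit(msfa_in$matrices,
      k = k, j = j,
      max_iter = config$msfa_max_iter, tol = config$msfa_tol
    )
    scores <- pooled_factor_scores(model, model$data, msfa_in$sex)
    al <- align_sign_to_class(model, scores, positive_class = "M")
    st <- factor_sex_test(al$scores, q_cut = config$q_cut)
    loading_gsea <- lapply(seq_len(k), function(kk) {
      gsea(loadings_to_ranked(al$model, kk), gene_sets,
        nperm = config$gsea_nperm, weight = config$gsea_weight,
        min_size = config$gsea_loading_min_size,
        seed = stage_seed(config$seed, paste0("gsea_loading_", kk))
      )
    })
    names(loading_gsea) <- paste0("factor", seq_len(k))
    manifest$results$msfa <- model
    manifest$results$factor_scores <- al$scores
    manifest$results$factor_flips <- al$flipped
    manifest$results$factor_anova <- st$anova
    manifest$results$factor_contrasts <- st$contrasts
    manifest$results$gsea_loadings <- loading_gsea
    manifest$dims$msfa <- c(nrow(model$phi), ncol(model$phi), model$n_iter)
    manifest$stages_run <- c(manifest$stages_run, "msfa")
  }

  if ("phospho" %in% stages && !is.null(phospho_tbl)) {
    quants <- quantify_membranes(phospho_tbl)
    ph <- phospho_sex_anova(quants)
    manifest$results$phospho_quants <- quants
    manifest$results$phospho_anova <- ph$anova
    manifest$results$phospho_sites <- ph$site_contrasts
    manifest$dims$phospho <- c(
      dplyr::n_distinct(quants$membrane), dplyr::n_distinct(quants$site)
    )
    manifest$stages_run <- c(manifest$stages_run, "phospho")
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(manifest$results)) {
      obj <- manifest$results[[nm]]
      if (is.data.frame(obj)) {
        path <- file.path(out_dir, paste0(nm, ".tsv"))
        flat <- obj
        for (col in names(flat)) {
          if (is.list(flat[[col]])) {
            flat[[col]] <- vapply(flat[[col]], paste, character(1), collapse = ",")
          }
        }
        utils::write.table(flat, path,
          sep = "\t", quote = FALSE, row.names = FALSE
        )
        manifest$outputs <- c(manifest$outputs, path)
      }
    }
    if (!is.null(manifest$results$msfa)) {
      path <- file.path(out_dir, "msfa_shared_loadings.tsv")
      utils::write.table(
        data.frame(feature = rownames(manifest$results$msfa$phi),
                   manifest$results$msfa$phi),
        path, sep = "\t", quote = FALSE, row.names = FALSE
      )
      manifest$outputs <- c(manifest$outputs, path)
    }
  }
  class(manifest) <- "dimorph_run"
  manifest
}

# Assemble centred, complete, aligned study matrices for the factor model:
# keep genes observed in every study (complete cases across datasets), and
# in synthetic/files RNA mode route counts through TPM -> quantile
# normalization -> log2, the abundance scale the transcriptome enters on.
prepare_msfa_inputs <- function(msfa_raw, mode) {
  mats <- lapply(msfa_raw, function(s) s$matrix$values)
  feats <- Reduce(intersect, lapply(mats, rownames))
  mats <- lapply(mats, function(m) m[feats, , drop = FALSE])
  complete <- Reduce(`&`, lapply(mats, function(m) rowSums(is.na(m)) == 0))
  mats <- lapply(mats, function(m) m[complete, , drop = FALSE])
  if (mode == "synthetic" && "rna" %in% names(mats)) {
    counts <- expr_mat(round(2^(mats$rna + 6))) # log-normal counts
    qn <- quantile_normalize(tpm_from_counts(counts, rep(1, nrow(counts$values))))
    mats$rna <- log2_transform(qn, pseudocount = 1)$values
  }
  sds_ok <- Reduce(`&`, lapply(mats, function(m) apply(m, 1, stats::sd) > 0))
  mats <- lapply(mats, function(m) m[sds_ok, , drop = FALSE])
  list(
    matrices = lapply(mats, expr_mat),
    sex = lapply(msfa_raw, function(s) s$metadata$sex)
  )
}

#' @export
print.dimorph_run <- function(x, ...) {
  cat("<dimorph_run>\n")
  cat("  stages run:    ", paste(x$stages_run, collapse = ", "), "\n")
  if (length(x$stages_skipped)) {
    cat("  stages skipped:", paste(x$stages_skipped, collapse = ", "), "\n")
  }
  if (!is.null(x$results$factor_contrasts)) {
    sig <- x$results$factor_contrasts$factor[x$results$factor_contrasts$significant]
    cat(
      "  sex-associated factor(s):",
      if (length(sig)) paste(sig, collapse = ", ") else "none", "\n"
    )
  }
  invisible(x)
}
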