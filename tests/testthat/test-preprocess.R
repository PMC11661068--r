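test_that("log2 transform maps values, keeps missing, and refuses a second pass", {
  m <- make_em(matrix(c(8, 0, NA, 3), 2, 2))
  out <- log2_transform(m, pseudocount = 0)
  expect_equal(out$values[1, 1], 3)
  expect_true(is.na(out$values[1, 2]))
  expect_equal(out$scale, "log2")
  expect_equal(log2_transform(m, pseudocount = 1)$values[2, 1], 0)
  expect_error(log2_transform(out), "log2")
  expect_error(log2_transform(make_em(matrix(-1, 1, 1))), "negative")
})

test_that("gene-group dedup applies both documented policies on the TRPV1 fixture", {
  v <- rbind(20, 25) %*% matrix(1, 1, 4) # constant rows: means 20 and 25
  m <- make_em(v, features = c("TRPV1", "TRPV1,TRPV2,TRPA1"))

  high <- dedup_gene_groups(m, "first_term_highest_abundance")
  expect_equal(rownames(high$values), "TRPV1")
  expect_equal(unname(high$values[1, 1]), 25) # higher-abundance row wins

  single <- dedup_gene_groups(m, "exact_single_term_preferred")
  expect_equal(rownames(single$values), "TRPV1")
  expect_equal(unname(single$values[1, 1]), 20) # the single-symbol row wins

  # already-unique single symbols: identity under either policy
  u <- make_em(matrix(rnorm(12), 3, 4), features = c("A", "B", "C"))
  expect_identical(dedup_gene_groups(u)$values, u$values)

  # exact_single_term_preferred falls back to abundance without a single row
  comp <- make_em(rbind(rep(1, 3), rep(9, 3)),
    features = c("TRPV1,TRPM8", "TRPV1,TRPA1")
  )
  out <- dedup_gene_groups(comp, "exact_single_term_preferred")
  expect_equal(unname(out$values[1, 1]), 9)
})

test_that("dedup never invents first terms and never grows the matrix", {
  set.seed(8)
  pm <- sim_params(p = 80, gene_group_rate = 0.3, planted_sets = list(), n_decoy_sets = 0, seed = 8)
  pe <- simulate_proteomics_experiment(pm)
  out <- dedup_gene_groups(pe$matrix)
  in_ft <- unique(sub(",.*", "", rownames(pe$matrix$values)))
  expect_lte(nrow(out$values), nrow(pe$matrix$values))
  expect_true(all(rownames(out$values) %in% in_ft))
  expect_false(anyDuplicated(rownames(out$values)) > 0)
})

test_that("completeness filter keeps the boundary and removes below it", {
  v <- matrix(1, 3, 8)
  v[1, 1:2] <- NA # observed 6/8 = 75%  -> removed
  v[2, 1] <- NA # observed 7/8 = 87.5% -> kept
  m <- make_em(v)
  out <- completeness_filter(m, 0.8)
  expect_equal(rownames(out$values), c("f02", "f03"))

  # threshold equal to the observed fraction exactly: kept (inclusive)
  v2 <- matrix(1, 1, 10)
  v2[1, 1:2] <- NA # 80% observed
  expect_equal(nrow(completeness_filter(make_em(v2), 0.8)$values), 1L)

  full <- make_em(matrix(1:6, 2, 3))
  expect_identical(completeness_filter(full, 0.8)$values, full$values)
  expect_warning(completeness_filter(make_em(matrix(NA_real_, 1, 4)), 0.5), "every")
})

test_that("replicate merging averages with missing-ignoring means", {
  v <- rbind(c(2, 4), c(2, NA))
  m <- make_em(v, samples = c("r1", "r2"))
  meta <- sample_metadata(tibble::tibble(
    sample_id = c("r1", "r2"), donor_id = "d1", sex = "F",
    tissue = "ganglia", replicate = 1:2
  ))
  out <- merge_replicates(m, meta)
  expect_equal(ncol(out$matrix$values), 1L)
  expect_equal(unname(out$matrix$values[, 1]), c(3, 2))

  # the 32 -> 16 design: 16 biological samples, 2 replicates each
  pe <- simulate_proteomics_experiment(sim_params(p = 40, seed = 5, planted_sets = list(), n_decoy_sets = 0))
  expect_equal(ncol(pe$matrix$values), 32L)
  merged <- merge_replicates(log2_transform(pe$matrix), pe$metadata)
  expect_equal(ncol(merged$matrix$values), 16L)
  expect_equal(nrow(merged$metadata), 16L)
})

test_that("rank_by_mean orders by decreasing mean with lexicographic ties", {
  m <- make_em(rbind(1, 3, 2), features = c("A", "B", "C"))
  expect_equal(rank_by_mean(m)$feature, c("B", "C", "A"))
  tie <- make_em(rbind(c(2, 2), c(2, 2)), features = c("B", "A"))
  expect_equal(rank_by_mean(tie)$feature, c("A", "B"))
  # permutation invariance of the output order
  set.seed(1)
  big <- make_em(matrix(rnorm(60), 20, 3))
  perm <- big$values[sample(20), ]
  expect_equal(rank_by_mean(big), rank_by_mean(expr_mat(perm)))
})

test_that("quantile normalization forces identical column multisets", {
  m <- make_em(cbind(c(1, 2, 3), c(4, 5, 6)))
  out <- quantile_normalize(m)
  expect_equal(unname(out$values[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(out$values[, 2]), c(2.5, 3.5, 4.5))

  # identical columns are a fixed point
  same <- make_em(cbind(c(5, 1, 7), c(5, 1, 7)))
  expect_equal(quantile_normalize(same)$values, same$values)

  set.seed(2)
  r <- make_em(matrix(rnorm(500), 50, 10))
  qn <- quantile_normalize(r)$values
  ref <- unname(sort(qn[, 1]))
  for (j in 2:10) expect_equal(unname(sort(qn[, j])), ref)
  # within-column order preserved
  expect_equal(order(qn[, 3]), order(r$values[, 3]))

  expect_error(quantile_normalize(make_em(matrix(c(1, NA), 1, 2))), "complete")
})

test_that("quantile normalization agrees with the limma reference", {
  skip_if_not_installed("limma")
  set.seed(3)
  v <- matrix(rnorm(200), 40, 5)
  ours <- quantile_normalize(make_em(v))$values
  theirs <- limma::normalizeQuantiles(v)
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-12)
})

test_that("TPM columns are rates scaled to one million", {
  one <- make_em(matrix(c(7, 3), 1, 2))
  expect_equal(unname(tpm_from_counts(one, 1)$values[1, ]), c(1e6, 1e6))

  two <- make_em(matrix(c(10, 10), 2, 1))
  tout <- tpm_from_counts(two, c(1, 2))
  expect_equal(unname(tout$values[, 1]), c(2e6 / 3, 1e6 / 3), tolerance = 1e-6)

  set.seed(4)
  big <- make_em(matrix(rpois(300, 40), 30, 10))
  expect_equal(
    unname(colSums(tpm_from_counts(big, runif(30, 0.5, 3))$values)),
    rep(1e6, 10),
    tolerance = 1e-6
  )
  expect_error(tpm_from_counts(make_em(matrix(0, 2, 1)), c(1, 1)), "zero")
})

test_that("median-ratio fold changes honour size-factor invariances", {
  v <- matrix(rep(c(4, 8, 16), 4), 3, 4)
  m <- make_em(v)
  groups <- c("A", "A", "B", "B")
  out <- median_ratio_lfc(m, groups)
  expect_equal(out$score, rep(0, 3))

  # doubling one column changes nothing after normalization
  v2 <- v
  v2[, 2] <- v2[, 2] * 2
  expect_equal(median_ratio_lfc(make_em(v2), groups)$score, rep(0, 3))

  # planted 4-fold change on one feature, no noise -> lfc exactly 2
  v3 <- matrix(rep(c(4, 8, 16, 32, 64), 6), 5, 6)
  v3[1, 1:3] <- v3[1, 1:3] * 4
  out3 <- median_ratio_lfc(make_em(v3), rep(c("A", "B"), each = 3))
  expect_equal(out3$score[out3$feature == "f01"], 2, tolerance = 1e-10)
  expect_equal(max(abs(out3$score[out3$feature != "f01"])), 0, tolerance = 1e-10)
})
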