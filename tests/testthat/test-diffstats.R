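make_null_matrix <- function(n_feat, n_per_group, d0, s02, seed) {
  set.seed(seed)
  s2g <- d0 * s02 / stats::rchisq(n_feat, d0)
  v <- matrix(stats::rnorm(n_feat * 2 * n_per_group, sd = sqrt(rep(s2g, 2 * n_per_group))),
    n_feat, 2 * n_per_group
  )
  make_em(v, scale = "log2", features = sprintf("g%04d", seq_len(n_feat)))
}

test_that("moderated t reduces to the ordinary t when shrinkage is off", {
  m <- make_null_matrix(50, 4, d0 = 4, s02 = 0.05, seed = 1)
  groups <- rep(c("M", "F"), each = 4)
  fit0 <- moderated_two_group(m, groups, prior_df = 0)
  tt <- apply(m$values, 1, function(x) {
    stats::t.test(x[5:8], x[1:4], var.equal = TRUE)$statistic
  })
  expect_equal(unname(fit0$table$statistic), unname(tt), tolerance = 1e-10)
})

test_that("full shrinkage pins every posterior variance at the prior", {
  m <- make_null_matrix(50, 4, d0 = 4, s02 = 0.05, seed = 2)
  fit <- moderated_two_group(m, rep(c("M", "F"), each = 4), prior_df = Inf)
  expect_equal(fit$table$post_var, rep(fit$s02, 50))
})

test_that("the variance prior is recovered and matches the limma reference", {
  skip_if_not_installed("limma")
  m <- make_null_matrix(2000, 4, d0 = 4, s02 = 0.05, seed = 3)
  groups <- rep(c("M", "F"), each = 4)
  fit <- moderated_two_group(m, groups)
  expect_lt(abs(fit$d0 - 4) / 4, 0.25)
  expect_lt(abs(fit$s02 - 0.05) / 0.05, 0.25)

  design <- stats::model.matrix(~ rep(c(0, 1), each = 4))
  eb <- limma::eBayes(limma::lmFit(m$values, design))
  expect_equal(fit$d0, unname(eb$df.prior), tolerance = 1e-6)
  expect_equal(fit$s02, unname(eb$s2.prior), tolerance = 1e-6)
  expect_equal(abs(unname(fit$table$statistic)), abs(unname(eb$t[, 2])), tolerance = 1e-8)
  expect_equal(unname(fit$table$p_value), unname(eb$p.value[, 2]), tolerance = 1e-3)
})

test_that("missing values are handled per feature without dropping the prior", {
  m <- make_null_matrix(200, 4, d0 = 4, s02 = 0.05, seed = 4)
  v <- m$values
  v[1, 1:2] <- NA
  fit <- moderated_two_group(expr_mat(v, scale = "log2"), rep(c("M", "F"), each = 4))
  expect_equal(nrow(fit$table), 200L)
  expect_false(anyNA(fit$table$p_value))
  expect_equal(fit$table$df[1], 4) # 2 + 4 observations -> df 4
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.73), 0.73)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.9, 0.04, 0.3)
  perm <- c(3, 1, 4, 2)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  expect_error(bh_adjust(c(0.5, NA)), "missing")
})

test_that("Welch test handles degenerate and separated samples", {
  w <- welch_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(w$statistic, 0)
  expect_equal(w$p_value, 1)
  expect_lt(welch_test(c(1, 2, 3), c(101, 102, 103))$p_value, 0.01)
  same <- welch_test(c(5, 5, 5), c(5, 5, 5))
  expect_equal(same$p_value, 1)
})

test_that("Welch p agrees with a permutation null within Monte-Carlo error", {
  set.seed(7)
  a <- rnorm(12, 0.4)
  b <- rnorm(12, 0)
  obs <- abs(welch_test(a, b)$statistic)
  pool <- c(a, b)
  perm_t <- replicate(20000, {
    ix <- sample(24, 12)
    abs(welch_test(pool[ix], pool[-ix])$statistic)
  })
  p_perm <- mean(perm_t >= obs)
  p_welch <- welch_test(a, b)$p_value
  expect_lt(abs(p_perm - p_welch), 0.03)
})

test_that("two-way ANOVA recovers closed-form structure", {
  # additive construction: interaction sum of squares is zero
  df <- expand.grid(a = c("x", "y"), b = c("u", "v", "w"), rep = 1:2)
  df$value <- c(1, 3)[as.integer(df$a)] + c(0, 2, 5)[as.integer(df$b)]
  # a perfect additive fit: anova warns about unreliable F on zero residual
  tab <- suppressWarnings(two_way_anova(df, "value", "a", "b", type = "I"))
  expect_lt(tab$sumsq[tab$term == "a:b"], 1e-20)

  # balanced 2x2: F = t^2 for each main effect
  set.seed(5)
  d2 <- expand.grid(a = c("x", "y"), b = c("u", "v"), rep = 1:5)
  d2$value <- rnorm(20) + (d2$a == "y") * 1.2
  tab2 <- two_way_anova(d2, "value", "a", "b")
  # hand-computed t for the marginal mean difference, on the full-model MSE:
  # in a balanced 2x2 design F(main) = t^2
  fit <- stats::lm(value ~ a * b, data = d2)
  mse <- sum(stats::residuals(fit)^2) / fit$df.residual
  d_marg <- mean(d2$value[d2$a == "y"]) - mean(d2$value[d2$a == "x"])
  t_hand <- d_marg / sqrt(mse * 4 / nrow(d2))
  expect_equal(tab2$statistic[tab2$term == "a"], t_hand^2, tolerance = 1e-8)

  bad <- df[df$a != "x" | df$b != "u", ]
  expect_error(two_way_anova(bad, "value", "a", "b"), "x.*u|empty cell")
})

test_that("Tukey HSD reduces to the pooled t-test for two groups", {
  set.seed(6)
  d <- data.frame(group = rep(c("a", "b"), each = 6), value = rnorm(12))
  hsd <- tukey_hsd(d)
  tt <- stats::t.test(value ~ group, data = d, var.equal = TRUE)$p.value
  expect_equal(hsd$adj_p, tt, tolerance = 1e-8)

  ident <- data.frame(group = rep(c("a", "b", "c"), each = 4), value = rep(1:4, 3))
  expect_equal(tukey_hsd(ident)$adj_p, rep(1, 3), tolerance = 1e-8)

  single <- data.frame(group = c("a", "a", "b"), value = 1:3)
  expect_error(tukey_hsd(single), "singleton")
})

test_that("Tukey adjusted p matches direct studentized-range evaluation", {
  set.seed(9)
  d <- data.frame(
    group = rep(c("a", "b", "c"), each = 5),
    value = rnorm(15) + rep(c(0, 0.5, 2), each = 5)
  )
  hsd <- tukey_hsd(d)
  fit <- stats::aov(value ~ group, data = d)
  mse <- sum(stats::residuals(fit)^2) / fit$df.residual
  means <- tapply(d$value, d$group, mean)
  q_bc <- abs(means["c"] - means["b"]) / sqrt(mse / 5)
  p_direct <- unname(stats::ptukey(q_bc, nmeans = 3, df = 12, lower.tail = FALSE))
  expect_equal(hsd$adj_p[hsd$contrast == "c-b"], p_direct, tolerance = 1e-8)
})

test_that("t-test power is exact at the null and monotone in n and d", {
  expect_equal(t_test_power(5, 0, alpha = 0.1), 0.1, tolerance = 1e-12)
  p1 <- t_test_power(4, 1)
  expect_gt(t_test_power(8, 1), p1)
  expect_gt(t_test_power(4, 2), p1)
  expect_gt(t_test_power(4, -2), p1) # symmetric in the sign of d
  # cross-check against the stats reference (which neglects the far-tail
  # rejection mass, hence the loose tolerance; ours keeps both tails)
  expect_equal(
    t_test_power(10, 1, 0.05),
    stats::power.t.test(n = 10, delta = 1, sd = 1, sig.level = 0.05)$power,
    tolerance = 1e-4
  )
})

test_that("tests are invariant to adding a constant to every observation", {
  set.seed(10)
  a <- rnorm(5)
  b <- rnorm(5)
  expect_equal(welch_test(a + 100, b + 100)$p_value, welch_test(a, b)$p_value)
  m <- make_null_matrix(100, 4, 4, 0.05, seed = 11)
  f1 <- moderated_two_group(m, rep(c("M", "F"), each = 4))
  f2 <- moderated_two_group(expr_mat(m$values + 50, scale = "log2"), rep(c("M", "F"), each = 4))
  expect_equal(f1$table$p_value, f2$table$p_value, tolerance = 1e-9)
})
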