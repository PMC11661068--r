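test_that("supervised PCA isolates a single varying feature", {
  set.seed(20)
  v <- matrix(5, 6, 8)
  v[3, ] <- c(1, 2, 3, 4, 5, 6, 7, 8) # only feature 3 varies
  v <- v + matrix(rnorm(48, sd = 1e-8), 6, 8)
  m <- make_em(v, scale = "log2")
  res <- spca(m, rownames(m$values), rep(c("F", "M"), 4))
  expect_equal(abs(res$loadings$loading[res$loadings$feature == "f03"]), 1, tolerance = 1e-6)
  expect_lt(max(abs(res$loadings$loading[res$loadings$feature != "f03"])), 1e-5)
  expect_gte(res$var_explained[1], max(res$var_explained))
})

test_that("PC1 scores equal centred data times loadings", {
  set.seed(21)
  m <- make_em(matrix(rnorm(60), 6, 10), scale = "log2")
  res <- spca(m, rownames(m$values), rep(c("F", "M"), 5))
  centred <- t(m$values - rowMeans(m$values))
  expect_equal(
    res$scores$score,
    unname(as.vector(centred %*% res$loadings$loading)),
    tolerance = 1e-10
  )
})

test_that("supervised PCA separates a class-shifted subset reliably", {
  hits <- 0L
  n_runs <- 200L
  for (i in seq_len(n_runs)) {
    set.seed(3000 + i)
    v <- matrix(rnorm(20 * 8, sd = 1), 20, 8)
    cls <- rep(c("F", "M"), each = 4)
    v[1:8, cls == "M"] <- v[1:8, cls == "M"] + 2 # shift = 2 x noise SD
    m <- make_em(v, scale = "log2")
    res <- spca(m, rownames(m$values)[1:8], cls)
    if (res$welch$p_value < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / n_runs, 0.8)
})

test_that("spca validates its feature list", {
  m <- make_em(matrix(rnorm(20), 4, 5), scale = "log2")
  expect_error(spca(m, c("nope", "f01"), rep(c("F", "M"), c(2, 3))), "nope")
  v <- m$values
  v[1, 1] <- NA
  expect_warning(
    spca(expr_mat(v, scale = "log2"), rownames(v), rep(c("F", "M"), c(2, 3))),
    "missing"
  )
})

test_that("KMO equals 1/2 for two correlated variables and stays in [0,1]", {
  set.seed(22)
  x <- rnorm(40)
  v <- rbind(x, 0.6 * x + rnorm(40, sd = 0.8))
  res <- kmo(make_em(v))
  expect_lt(abs(res$kmo - 0.5), 1e-10)

  for (i in 1:10) {
    set.seed(400 + i)
    r <- kmo(make_em(matrix(rnorm(8 * 30), 8, 30)))
    expect_gte(r$kmo, 0)
    expect_lte(r$kmo, 1)
    expect_true(all(r$msa$msa >= 0 & r$msa$msa <= 1))
  }

  # strong one-factor structure at large n: adequate sampling
  set.seed(23)
  f <- rnorm(500)
  v1 <- t(vapply(1:6, function(i) f + rnorm(500, sd = 0.4), numeric(500)))
  expect_gt(kmo(make_em(v1))$kmo, 0.7)

  const <- make_em(rbind(rep(1, 10), rnorm(10)))
  expect_error(kmo(const), "constant")
})

test_that("scree rules find the planted dimensionality", {
  set.seed(24)
  f <- rnorm(200)
  v <- t(vapply(1:8, function(i) 2 * f + rnorm(200, sd = 0.05), numeric(200)))
  sc <- scree_factor_count(make_em(v), rule = "elbow")
  expect_equal(sc$n_factors, 1L)
  expect_equal(sum(sc$eigenvalues), 8, tolerance = 1e-8) # trace identity

  set.seed(25)
  ind <- make_em(matrix(rnorm(6 * 400), 6, 400))
  ks <- scree_factor_count(ind, rule = "kaiser")
  expect_equal(ks$n_factors, sum(ks$eigenvalues > 1))
  expect_lte(ks$n_factors, 3L) # near zero for independent variables at large n
})

test_that("Bartlett scores reproduce the worked weighted-least-squares values", {
  model <- structure(
    list(phi = matrix(c(1, 1), 2, 1), psi = list(s = c(1, 1))),
    class = "msfa_model"
  )
  expect_equal(as.vector(bartlett_scores(model, c(2, 4), "s")), 3)
  model$psi$s <- c(1, 4)
  expect_equal(as.vector(bartlett_scores(model, c(2, 4), "s")), 2.4)
})

test_that("Bartlett scoring is a projection for orthonormal loadings and linear", {
  set.seed(26)
  q <- qr.Q(qr(matrix(rnorm(20), 10, 2)))
  model <- structure(list(phi = q, psi = list(s = rep(1, 10))), class = "msfa_model")
  x <- rnorm(10)
  expect_equal(as.vector(bartlett_scores(model, x, "s")), as.vector(crossprod(q, x)),
    tolerance = 1e-10
  )
  y <- rnorm(10)
  model$psi$s <- runif(10, 0.5, 2)
  lhs <- bartlett_scores(model, 2 * x + 3 * y, "s")
  rhs <- 2 * bartlett_scores(model, x, "s") + 3 * bartlett_scores(model, y, "s")
  expect_equal(lhs, rhs, tolerance = 1e-10)

  collinear <- structure(
    list(phi = cbind(q[, 1], q[, 1]), psi = list(s = rep(1, 10))),
    class = "msfa_model"
  )
  expect_error(bartlett_scores(collinear, x, "s"), "singular|collinear")
})

test_that("sign alignment flips relevant anticorrelated factors once", {
  set.seed(27)
  n <- 40
  sex <- rep(c("F", "M"), each = n / 2)
  ind <- as.numeric(sex == "M")
  s1 <- -1.2 * ind + rnorm(n, sd = 0.5) # strongly negative correlation
  s2 <- rnorm(n) # irrelevant
  scores <- tibble::tibble(
    study = "a", sample = rep(paste0("x", 1:n), 2), sex = rep(sex, 2),
    factor = rep(1:2, each = n), score = c(s1, s2)
  )
  model <- structure(
    list(phi = matrix(rnorm(20), 10, 2, dimnames = list(paste0("g", 1:10), NULL))),
    class = "msfa_model"
  )
  out <- suppressMessages(align_sign_to_class(model, scores, "M", relevance_r = 0.3))
  expect_equal(out$flipped, 1L)
  expect_gt(out$correlations[1], 0.3)
  expect_equal(out$model$phi[, 1], -model$phi[, 1])
  expect_equal(out$model$phi[, 2], model$phi[, 2])

  # idempotence: a second application changes nothing
  out2 <- align_sign_to_class(out$model, out$scores, "M", relevance_r = 0.3)
  expect_length(out2$flipped, 0L)
  expect_equal(out2$model$phi, out$model$phi)

  # a weak negative correlation below the relevance gate is left alone
  s3 <- -0.05 * ind + rnorm(n)
  scores3 <- dplyr::mutate(scores[1:n, ], score = s3)
  out3 <- align_sign_to_class(model, scores3, "M", relevance_r = 0.3)
  expect_length(out3$flipped, 0L)
})

test_that("factor sex test flags planted factors and stays quiet under the null", {
  make_scores <- function(shift, seed, k = 3, n_per_sex = 8) {
    set.seed(seed)
    sex <- rep(c("F", "M"), each = n_per_sex)
    purrr::map_dfr(seq_len(k), function(kk) {
      s <- rnorm(2 * n_per_sex)
      if (kk == 2) s <- s + shift * (sex == "M")
      tibble::tibble(
        study = "a", sample = paste0("x", 1:(2 * n_per_sex)),
        sex = sex, factor = kk, score = s
      )
    })
  }
  # power: planted shift of 2 score-SD on factor 2 only. The detection
  # ceiling for the "exactly one factor" event is the per-factor power
  # (~0.95 at this n) times the probability of no false flag among the
  # remaining factors under a familywise budget of q = 0.1 (~0.93), so the
  # asserted rate carries a margin below that product.
  exact <- 0L
  flagged2 <- 0L
  for (i in 1:200) {
    st <- factor_sex_test(make_scores(2, 5000 + i), q_cut = 0.1)
    sig <- st$contrasts$factor[st$contrasts$significant]
    if (identical(sig, 2L)) exact <- exact + 1L
    if (2L %in% sig) flagged2 <- flagged2 + 1L
  }
  expect_gte(flagged2 / 200, 0.9) # the planted factor is almost always found
  expect_gte(exact / 200, 0.85) # and usually alone

  # null: Holm keeps the familywise error within q, so flag-free runs sit
  # near 1 - q with binomial noise
  clean <- 0L
  for (i in 1:200) {
    st <- factor_sex_test(make_scores(0, 7000 + i), q_cut = 0.1)
    if (!any(st$contrasts$significant)) clean <- clean + 1L
  }
  expect_gte(clean / 200, 0.85)
})

test_that("factor sex test reduces to a two-group comparison for one factor", {
  set.seed(28)
  scores <- tibble::tibble(
    study = "a", sample = paste0("x", 1:16), sex = rep(c("F", "M"), 8),
    factor = 1L, score = rnorm(16)
  )
  expect_warning(st <- factor_sex_test(scores), "two-group")
  expect_equal(nrow(st$contrasts), 1L)
  expect_equal(st$anova$term, "sex")
})

test_that("loading ranking follows the chosen factor column", {
  phi <- matrix(c(0.9, -0.2, 0.5, 0, 0, 0), 3, 2,
    dimnames = list(c("A", "B", "C"), NULL)
  )
  model <- structure(list(phi = phi), class = "msfa_model")
  expect_equal(loadings_to_ranked(model, 1)$feature, c("A", "C", "B"))
  flipped <- model
  flipped$phi[, 1] <- -flipped$phi[, 1]
  expect_equal(loadings_to_ranked(flipped, 1)$feature, rev(c("A", "C", "B")))
  expect_error(loadings_to_ranked(model, 3), "1..2")
})
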