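test_that("a noiseless linear signal is recovered", {
  set.seed(1)
  n <- 60; q <- 10
  x <- matrix(runif(n * q), n, q)
  y <- 2 * x[, 3]
  fit <- fit_gene_model(x, y, seed = 2, alpha_grid = c(0.1, 0.55, 1))
  expect_true(fit$is_regulated)
  expect_true(fit$coefficients[3] != 0)
  pred <- as.numeric(x %*% fit$coefficients) + fit$intercept
  expect_gt(cor(pred, y)^2, 0.99)
})

test_that("pure-noise responses select no regulators", {
  set.seed(7)
  x <- matrix(runif(40 * 50), 40, 50)
  y <- rnorm(40)
  fit <- fit_gene_model(x, y, seed = 8)
  expect_false(fit$is_regulated)
  expect_true(all(fit$coefficients == 0))
})

test_that("ridge fits match the closed-form solution", {
  # alpha = 0: the fitted objective is 1/(2n) RSS + lambda/2 ||b||^2 with the
  # response standardized internally by its population sd, so on centred data
  # b = (Xc'Xc + n * lambda / sd_n(y) * I)^-1 Xc' yc
  set.seed(3)
  n <- 12; q <- 3
  x <- matrix(rnorm(n * q), n, q)
  y <- rnorm(n)
  fit <- fit_gene_model(x, y, cv_folds = 4, alpha_grid = 0, seed = 4,
                        standardize = FALSE, thresh = 1e-14)
  lam <- fit$lambda
  xc <- scale(x, scale = FALSE)
  yc <- y - mean(y)
  sy <- sqrt(mean(yc^2))
  b <- solve(crossprod(xc) + n * lam / sy * diag(q), crossprod(xc, yc))
  expect_equal(unname(fit$coefficients), as.numeric(b), tolerance = 1e-6)
})

test_that("constant responses give an intercept-only fit without error", {
  x <- matrix(runif(20 * 4), 20, 4)
  fit <- fit_gene_model(x, rep(2.5, 20))
  expect_false(fit$is_regulated)
  expect_equal(fit$intercept, 2.5)
})

test_that("fit_all_genes returns per-gene tuning and is deterministic", {
  cfg <- sim_config("I", n = 90, p = 12, q = 24, K = 2,
                    pcnt = 1 / 3, f = 0.5, seed = 5)
  d <- simulate_dataset(cfg)
  m1 <- fit_all_genes(d, seed = 9)
  m2 <- fit_all_genes(d, seed = 9)
  expect_identical(m1$yhat, m2$yhat)
  td <- tidy(m1)
  expect_equal(nrow(td), 12)
  expect_true(all(c("lambda", "alpha") %in% names(td)))
  expect_equal(nrow(m1$yhat), d$layout$n2 + d$layout$n3)

  # CV selections do not depend on gene order: one shared fold assignment
  d_perm <- d
  perm <- c(5, 1, 7, 3, 12, 9, 2, 11, 4, 10, 6, 8)
  d_perm$y <- d$y[, perm]
  m3 <- fit_all_genes(d_perm, seed = 9)
  expect_equal(unname(m3$lambda), unname(m1$lambda[perm]))
})

test_that("regulated_genes filters on regulator coefficients", {
  cfg <- sim_config("I", n = 90, p = 12, q = 24, K = 2, seed = 5)
  d <- simulate_dataset(cfg)
  m <- fit_all_genes(d, seed = 9)
  rg <- regulated_genes(m)
  expect_setequal(rg, names(m$is_regulated)[m$is_regulated])

  m_none <- m
  m_none$is_regulated[] <- FALSE
  expect_error(regulated_genes(m_none), "filter")
})

test_that("imputation quality matches the direct Pearson formula", {
  pred <- c(1, 2, 3, 4, 5)
  obs <- c(2, 4, 6, 8, 12)
  # hand formula: r = cov / (sd sd)
  num <- sum((pred - mean(pred)) * (obs - mean(obs)))
  den <- sqrt(sum((pred - mean(pred))^2) * sum((obs - mean(obs))^2))
  r2_hand <- (num / den)^2
  expect_equal(pancut:::r_squared(pred, obs), r2_hand)
  expect_equal(pancut:::r_squared(rep(1, 5), obs), 0)   # constant prediction
  expect_equal(pancut:::r_squared(obs, obs), 1)
})

test_that("imputation quality modes run and report in [0, 1]", {
  cfg <- sim_config("I", n = 120, p = 15, q = 24, K = 3, seed = 13)
  d <- simulate_dataset(cfg)
  m <- fit_all_genes(d, seed = 14)
  ins <- imputation_quality(m, d, mode = "overlap_in_sample")
  expect_true(all(ins$quality$r_squared >= 0 & ins$quality$r_squared <= 1))
  ho <- suppressWarnings(imputation_quality(m, d, mode = "holdout", seed = 15))
  expect_true(all(ho$quality$r_squared >= 0 & ho$quality$r_squared <= 1))
  expect_match(ho$mode, "holdout")
  # holdout refits on fewer individuals, so in-sample should not be worse
  expect_gte(ins$summary["median"], ho$summary["median"] - 0.05)
})

test_that("well-predicted genes outperform ordinary genes in R^2", {
  # scenario I plants 12 regulators and halved error variance in 5% of the
  # genes; their imputation quality should dominate the 3-regulator genes
  cfg <- sim_config("I", n = 300, p = 120, q = 80, K = 2,
                    pcnt = 1 / 3, f = 0.5, seed = 71)
  d <- simulate_dataset(cfg)
  hi <- attr(d$beta_true, "high_signal")
  m <- fit_all_genes(d, seed = 72)
  iq <- imputation_quality(m, d, mode = "overlap_in_sample")
  r2 <- iq$quality$r_squared
  expect_gt(median(r2[hi]), median(r2[!hi]))
})
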