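test_that("layout arithmetic follows the printed proportions", {
  l <- overlap_layout(300, 1 / 3, 0.5)
  expect_equal(unlist(l[c("n1", "n2", "n3")]),
               c(n1 = 100, n2 = 100, n3 = 100))

  l2 <- overlap_layout(300, 1, 0.5)
  expect_equal(unlist(l2[c("n1", "n2", "n3")]), c(n1 = 0, n2 = 300, n3 = 0))

  l3 <- overlap_layout(900, 1 / 9, 0.7)
  expect_equal(unlist(l3[c("n1", "n2", "n3")]),
               c(n1 = 560, n2 = 100, n3 = 240))

  expect_equal(l3$n1 + l3$n2 + l3$n3, l3$n)
  expect_error(overlap_layout(100, 0.001, 0.5), "overlap is empty")
  expect_error(overlap_layout(100, 1.5, 0.5), "pcnt")
})

test_that("regulator profiles are beta values with block correlation", {
  cfg <- sim_config("I", n = 20000, p = 10, q = 20, K = 2, seed = 11)
  X <- simulate_regulators(cfg, seed = 11)
  expect_true(all(X > 0 & X < 1))

  L <- simulate_regulators(cfg, latent = TRUE, seed = 11)
  cw <- cor(L)
  within <- c(cw[1, 2:10], cw[11, 12:20])
  between <- cw[1:10, 11:20]
  expect_true(abs(mean(within) - 0.1) < 0.02)
  expect_true(max(abs(between)) < 0.03)
})

test_that("scenario I transition matrix has the planted sparsity", {
  cfg <- sim_config("I", n = 50, p = 500, q = 200, K = 5, seed = 3)
  beta <- simulate_transition(cfg, seed = 3)
  pb <- rep(1:5, each = 100)
  qb <- rep(1:5, each = 40)
  nnz <- colSums(beta != 0)
  for (k in 1:5) {
    expect_equal(sum(nnz[pb == k] == 3), 95)
    expect_equal(sum(nnz[pb == k] == 12), 5)
    # off-block entries exactly zero
    expect_true(all(beta[qb != k, pb == k] == 0))
  }
  expect_equal(sum(attr(beta, "high_signal")), 25)
  expect_equal(unname(which(nnz == 12)), which(attr(beta, "high_signal")))
})

test_that("scenario II transition matrix has 2 nonzeros per block", {
  cfg <- sim_config("II", n = 50, p = 60, q = 40, K = 4, seed = 5)
  beta <- simulate_transition(cfg, seed = 5)
  expect_equal(sum(beta != 0), 2 * 4)
  qb <- rep(1:4, each = 10); pb <- rep(1:4, each = 15)
  for (k in 1:4) expect_true(all(beta[qb != k, pb == k] == 0))
})

test_that("error covariance matches the stated diagonal and is PD", {
  cfg <- sim_config("I", n = 50, p = 400, q = 100, K = 4, seed = 7)
  beta <- simulate_transition(cfg, seed = 7)
  hi <- attr(beta, "high_signal")
  Sigma <- simulate_error_cov(cfg, high_signal = hi, seed = 8)
  sq <- attr(Sigma, "sqrt")
  expect_equal(sq %*% sq, unclass(Sigma), ignore_attr = TRUE,
               tolerance = 1e-8)
  attr(Sigma, "sqrt") <- NULL
  expect_equal(Sigma, t(Sigma))
  expect_equal(unname(diag(Sigma)[hi]), rep(1 / 8, sum(hi)), tolerance = 1e-8)
  expect_equal(unname(diag(Sigma)[!hi]), rep(1 / 4, sum(!hi)),
               tolerance = 1e-8)
  expect_no_error(chol(Sigma))

  # sign census of the sampled correlations (projection perturbs zeros only
  # slightly; count entries clearly away from zero)
  off <- Sigma[upper.tri(Sigma)] / (1 / 4)   # mostly 1/4-variance genes
  frac_pos <- mean(off > 0.01)
  frac_neg <- mean(off < -0.01)
  expect_true(frac_pos > 0.02 && frac_pos < 0.09)
  expect_true(frac_neg > 0.005 && frac_neg < 0.05)

  cfg2 <- sim_config("II", n = 50, p = 200, q = 100, K = 4, seed = 9)
  Sigma2 <- simulate_error_cov(cfg2, seed = 9)
  expect_equal(unname(diag(Sigma2)), rep(1 / 2, 200), tolerance = 1e-8)
  expect_no_error(chol(Sigma2))
})

test_that("simulated datasets have the layout-implied shapes and are reproducible", {
  cfg <- sim_config("I", n = 300, p = 100, q = 60, K = 3,
                    pcnt = 1 / 3, f = 0.5, seed = 21)
  d <- simulate_dataset(cfg)
  expect_equal(dim(d$y), c(200, 100))
  expect_equal(dim(d$x), c(200, 60))
  expect_equal(d$layout$n2, 100)
  expect_length(intersect(rownames(d$y), rownames(d$x)), 100)

  d2 <- simulate_dataset(cfg)
  expect_identical(d, d2)

  # true partition matches the block structure of beta: each gene's nonzero
  # regulators sit in its own cluster's regulator block
  qb <- block_labels_for_test(60, 3)
  for (j in seq_len(100)) {
    nz <- which(d$beta_true[, j] != 0)
    expect_true(all(qb[nz] == d$true_partition[j]))
  }
})

test_that("expression equals regulated signal plus correlated noise", {
  # subtracting the regulated component X beta leaves noise whose empirical
  # covariance converges to the projected error covariance
  cfg <- sim_config("I", n = 4000, p = 40, q = 30, K = 2, seed = 31)
  d <- simulate_dataset(cfg)
  resid <- d$y_full - d$x_full %*% d$beta_true
  emp <- cov(resid)
  expect_true(mean(abs(emp - d$error_cov)) < 0.02)
})
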