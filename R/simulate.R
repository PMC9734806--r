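#' Three-block individual layout for partially overlapping omics
#'
#' Splits `n` individuals into the three contiguous blocks used throughout the
#' package: `n1` individuals with expression only, `n2` with both expression
#' and regulators (the overlap), and `n3` with regulators only.  `pcnt` is the
#' overlap fraction; `f` is the share of the non-overlapping individuals that
#' carry expression data, so the missing fractions are `f*(1-pcnt)` for the
#' regulators and `(1-f)*(1-pcnt)` for expression.
#'
#' Counts are rounded half-up (`n2 = round(pcnt*n)`, `n1 = round(f*(n-n2))`)
#' and the remainder is absorbed by `n3`.
#'
#' @param n total number of individuals (>= 2).
#' @param pcnt overlap fraction in (0, 1].
#' @param f expression share of the non-overlapping individuals, in [0, 1].
#' @return An object of class `overlap_layout`: a list with elements `n1`,
#'   `n2`, `n3` and `n`.
#' @examples
#' overlap_layout(300, 1 / 3, 0.5)
#' @export
overlap_layout <- function(n, pcnt, f) {
  stopifnot(is.numeric(n), length(n) == 1, n >= 2)
  if (!(pcnt > 0 && pcnt <= 1)) stop("`pcnt` must be in (0, 1]", call. = FALSE)
  if (!(f >= 0 && f <= 1)) stop("`f` must be in [0, 1]", call. = FALSE)
  n <- as.integer(n)
  n2 <- as.integer(round_half_up(pcnt * n))
  if (n2 == 0) {
    stop("overlap is empty (round(pcnt * n) == 0); the regulation model ",
         "cannot be fitted", call. = FALSE)
  }
  n1 <- as.integer(round_half_up(f * (n - n2)))
  n3 <- n - n2 - n1
  structure(list(n1 = n1, n2 = n2, n3 = n3, n = n), class = "overlap_layout")
}

#' @export
print.overlap_layout <- function(x, ...) {
  cat(sprintf(
    "<overlap_layout> n = %d: %d expression-only | %d overlap | %d regulator-only\n",
    x$n, x$n1, x$n2, x$n3))
  invisible(x)
}

#' Configuration for the synthetic benchmark scenarios
#'
#' Captures every parameter of the two generative scenarios.  Scenario `"I"`
#' plants `K` regulator blocks whose CpGs regulate the matching expression
#' block (3 regulators per gene, 12 for a well-predicted 5% subset); scenario
#' `"II"` keeps the regulator blocks but almost removes the regulation signal
#' (2 non-zero transition entries per block) while the error covariance
#' carries dense random correlation, so the expression correlation structure
#' is dominated by noise.
#'
#' `p` and `q` need not be divisible by `K`; blocks are then near-equal
#' (sizes differing by at most one).
#'
#' @param scenario `"I"` or `"II"`.
#' @param n,p,q,K number of individuals, genes, regulators and clusters.
#' @param pcnt overlap fraction in (0, 1].
#' @param f expression share of non-overlapping individuals, in [0, 1].
#' @param block_corr latent within-block regulator correlation (default 0.1).
#' @param seed optional integer seed used by [simulate_dataset()].
#' @return An object of class `sim_config`.
#' @examples
#' sim_config("I", n = 300, p = 500, q = 200, K = 3, pcnt = 1 / 3, f = 0.5)
#' @export
sim_config <- function(scenario = c("I", "II"), n, p, q, K,
                       pcnt = 1 / 3, f = 0.5, block_corr = 0.1, seed = NULL) {
  scenario <- match.arg(scenario)
  stopifnot(n >= 2, p >= 2, q >= 1, K >= 1, K <= p, K <= q)
  if (!(block_corr >= 0 && block_corr < 1)) {
    stop("`block_corr` must be in [0, 1)", call. = FALSE)
  }
  layout <- overlap_layout(n, pcnt, f)  # validates pcnt, f, overlap size
  structure(
    list(scenario = scenario, n = as.integer(n), p = as.integer(p),
         q = as.integer(q), K = as.integer(K), pcnt = pcnt, f = f,
         block_corr = block_corr, seed = seed, layout = layout),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> scenario %s: n = %d, p = %d genes, q = %d regulators, K = %d\n",
    x$scenario, x$n, x$p, x$q, x$K))
  cat(sprintf("  pcnt = %.4g, f = %.4g, block_corr = %.3g\n",
              x$pcnt, x$f, x$block_corr))
  print(x$layout)
  invisible(x)
}

#' Simulate block-correlated regulator profiles
#'
#' Draws an `n x q` latent Gaussian matrix with block-diagonal equicorrelation
#' (`K` near-equal blocks, within-block correlation `block_corr`) and applies
#' the logistic (expit) transform so values lie in (0, 1), the scale of
#' methylation beta values.  The latent matrix is used by
#' [simulate_dataset()] to build expression; set `latent = TRUE` to obtain it.
#'
#' @param config a [sim_config()].
#' @param latent return the pre-transform Gaussian matrix instead.
#' @param seed optional integer seed.
#' @return An `n x q` matrix.
#' @export
simulate_regulators <- function(config, latent = FALSE, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n; q <- config$q; K <- config$K; rho <- config$block_corr
  blk <- block_labels(q, K)
  # equicorrelated blocks via a shared factor: exact, no Cholesky needed
  Z <- matrix(rnorm(n * q), n, q)
  G <- matrix(rnorm(n * K), n, K)
  X <- sqrt(1 - rho) * Z + sqrt(rho) * G[, blk, drop = FALSE]
  dimnames(X) <- list(sprintf("ind%04d", seq_len(n)),
                      sprintf("cpg%04d", seq_len(q)))
  if (latent) X else expit(X)
}

#' Simulate the sparse regulator-to-gene transition matrix
#'
#' Scenario I: block-diagonal `q x p` matrix; within each block 95% of gene
#' columns receive 3 non-zero coefficients and the remaining 5% receive 12,
#' drawn from N(0.5, 0.75).  Scenario II: each block carries only 2 non-zero
#' entries in total, so most genes are unregulated.
#'
#' @inheritParams simulate_regulators
#' @return A `q x p` matrix with attribute `high_signal`, a logical vector
#'   marking the 12-regulator genes (all `FALSE` under scenario II).
#' @export
simulate_transition <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  p <- config$p; q <- config$q; K <- config$K
  qb <- block_labels(q, K); pb <- block_labels(p, K)
  beta <- matrix(0, q, p)
  high <- logical(p)
  for (k in seq_len(K)) {
    qi <- which(qb == k); pi <- which(pb == k)
    if (config$scenario == "I") {
      n_high <- round_half_up(0.05 * length(pi))
      if (length(qi) < 12 && n_high > 0) {
        stop("block has fewer than 12 regulators; cannot place the ",
             "well-predicted genes", call. = FALSE)
      }
      hg <- if (n_high > 0) sample(pi, n_high) else integer(0)
      for (g in pi) {
        nnz <- if (g %in% hg) 12L else 3L
        beta[sample(qi, nnz), g] <- rnorm(nnz, 0.5, sqrt(0.75))
      }
      high[hg] <- TRUE
    } else {
      # exactly 2 distinct non-zero cells anywhere in the block
      cells <- sample(length(qi) * length(pi), 2)
      rows <- qi[(cells - 1) %% length(qi) + 1]
      cols <- pi[(cells - 1) %/% length(qi) + 1]
      beta[cbind(rows, cols)] <- rnorm(2, 0.5, sqrt(0.75))
    }
  }
  dimnames(beta) <- list(sprintf("cpg%04d", seq_len(q)),
                         sprintf("gene%04d", seq_len(p)))
  attr(beta, "high_signal") <- high
  beta
}

#' Simulate the structured error covariance
#'
#' Builds the `p x p` error covariance: a sparse random correlation matrix
#' (scenario I: 5% positive entries ~ N(0.05, 0.02), 2% negative
#' ~ N(-0.05, 0.02); scenario II: 50% positive ~ N(0.30, 0.10), 40% negative
#' ~ N(-0.30, 0.10)) sampled on the upper triangle and mirrored, projected to
#' the positive-definite cone by eigenvalue clipping at `1e-6`, then rescaled
#' to the stated variances (scenario I: 1/4, or 1/8 for the well-predicted
#' genes; scenario II: 1/2).
#'
#' @inheritParams simulate_regulators
#' @param high_signal logical vector marking the 12-regulator genes
#'   (variance 1/8 under scenario I); defaults to none.
#' @return A symmetric positive-definite `p x p` matrix.
#' @export
simulate_error_cov <- function(config, high_signal = NULL, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  p <- config$p
  high_signal <- high_signal %||% logical(p)
  stopifnot(length(high_signal) == p)
  C <- diag(p)
  iu <- which(upper.tri(C))
  u <- runif(length(iu))
  if (config$scenario == "I") {
    pos <- u < 0.05
    neg <- u >= 0.05 & u < 0.07
    C[iu[pos]] <- rnorm(sum(pos), 0.05, sqrt(0.02))
    C[iu[neg]] <- rnorm(sum(neg), -0.05, sqrt(0.02))
    v <- ifelse(high_signal, 1 / 8, 1 / 4)
  } else {
    pos <- u < 0.5
    neg <- u >= 0.5 & u < 0.9
    C[iu[pos]] <- rnorm(sum(pos), 0.30, sqrt(0.10))
    C[iu[neg]] <- rnorm(sum(neg), -0.30, sqrt(0.10))
    v <- rep(1 / 2, p)
  }
  C[lower.tri(C)] <- t(C)[lower.tri(C)]
  e <- eigen(C, symmetric = TRUE)
  lam <- pmax(e$values, 1e-6)
  Cpd <- e$vectors %*% (lam * t(e$vectors))
  d <- sqrt(diag(Cpd))
  Cpd <- Cpd / outer(d, d)
  Sigma <- Cpd * outer(sqrt(v), sqrt(v))
  Sigma <- (Sigma + t(Sigma)) / 2
  dimnames(Sigma) <- list(sprintf("gene%04d", seq_len(p)),
                          sprintf("gene%04d", seq_len(p)))
  # carry the symmetric square root so callers need not re-factorise
  es <- eigen(Sigma, symmetric = TRUE)
  attr(Sigma, "sqrt") <- es$vectors %*% (sqrt(pmax(es$values, 0)) *
                                           t(es$vectors))
  Sigma
}

#' Simulate a partially overlapping expression / regulator dataset
#'
#' Draws latent block-correlated regulators, transforms them to beta values
#' with the logistic function, builds the sparse transition matrix and the
#' structured error covariance, forms expression as `Y = X %*% beta + eps` on
#' all `n` individuals, then applies the missingness layout: expression is
#' kept for the first `n1 + n2` individuals and regulators for the last
#' `n2 + n3`.
#'
#' @inheritParams simulate_regulators
#' @param seed integer seed; defaults to `config$seed`.
#' @return An object of class `omics_dataset` with elements
#'   \describe{
#'     \item{y}{observed expression, `(n1+n2) x p`.}
#'     \item{x}{observed regulators, `(n2+n3) x q`, values in (0, 1).}
#'     \item{layout}{the [overlap_layout()].}
#'     \item{beta_true}{the `q x p` transition matrix used.}
#'     \item{true_partition}{integer cluster labels, one per gene.}
#'     \item{error_cov}{the projected `p x p` error covariance used.}
#'     \item{y_full, x_full}{complete `n`-row matrices, available for the
#'       full-overlap comparator.}
#'   }
#' @examples
#' cfg <- sim_config("I", n = 60, p = 40, q = 30, K = 2, seed = 1)
#' d <- simulate_dataset(cfg)
#' dim(d$y); dim(d$x)
#' @export
simulate_dataset <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  seed <- seed %||% config$seed
  if (!is.null(seed)) set.seed(seed)
  lay <- config$layout
  n <- config$n; p <- config$p
  L <- simulate_regulators(config, latent = TRUE)
  X <- expit(L)
  beta <- simulate_transition(config)
  high <- attr(beta, "high_signal")
  Sigma <- simulate_error_cov(config, high_signal = high)
  Sig_sqrt <- attr(Sigma, "sqrt")
  attr(Sigma, "sqrt") <- NULL
  eps <- matrix(rnorm(n * p), n, p) %*% Sig_sqrt
  Y <- X %*% beta + eps
  dimnames(Y) <- list(rownames(X), colnames(beta))
  idx_expr <- seq_len(lay$n1 + lay$n2)
  idx_reg <- (lay$n1 + 1):n
  truth <- block_labels(p, config$K)
  names(truth) <- colnames(beta)
  structure(
    list(y = Y[idx_expr, , drop = FALSE],
         x = X[idx_reg, , drop = FALSE],
         layout = lay,
         beta_true = beta,
         true_partition = truth,
         error_cov = Sigma,
         y_full = Y,
         x_full = X,
         config = config),
    class = "omics_dataset")
}

#' @export
print.omics_dataset <- function(x, ...) {
  cat(sprintf("<omics_dataset> %d genes, %d regulators\n",
              ncol(x$y), ncol(x$x)))
  print(x$layout)
  if (!is.null(x$config)) {
    cat(sprintf("  simulated (scenario %s, K = %d)\n",
                x$config$scenario, x$config$K))
  }
  invisible(x)
}

# overlap rows within each observed matrix
overlap_rows_y <- function(dataset) {
  lay <- dataset$layout
  (lay$n1 + 1):(lay$n1 + lay$n2)
}
overlap_rows_x <- function(dataset) seq_len(dataset$layout$n2)
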