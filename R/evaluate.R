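#' Co-membership adjacency matrix
#'
#' `+1` where two genes share a cluster (including the diagonal), `-1`
#' otherwise.
#'
#' @param partition integer cluster labels, or any object with a
#'   `$partition` element.
#' @return A `p x p` matrix with entries in `{-1, +1}`.
#' @export
adjacency <- function(partition) {
  lab <- partition_labels(partition)
  A <- outer(lab, lab, "==") * 2 - 1
  diag(A) <- 1
  A
}

#' Clustering accuracy against a reference partition
#'
#' The agreement between the two co-membership adjacency matrices,
#' `sum(C_T * C_hat) / sum(C_T * C_T)` with `*` the elementwise product; the
#' denominator is `p^2`.  Equal to 1 when the partitions coincide (up to
#' label permutation) and at most 1 in general.
#'
#' @param truth reference partition (labels or object with `$partition`).
#' @param estimate estimated partition over the same genes.
#' @return An object of class `accuracy_report`: list with `m_accuracy`,
#'   `p`, `k_true` and `k_est`.
#' @examples
#' clustering_accuracy(c(1, 1, 2, 2), c(2, 2, 1, 1))$m_accuracy  # 1
#' @export
clustering_accuracy <- function(truth, estimate) {
  lt <- partition_labels(truth); le <- partition_labels(estimate)
  if (length(lt) != length(le)) {
    stop("partitions cover different numbers of genes", call. = FALSE)
  }
  if (!is.null(names(lt)) && !is.null(names(le))) {
    if (!setequal(names(lt), names(le))) {
      stop("partitions cover different gene sets", call. = FALSE)
    }
    le <- le[names(lt)]
  }
  p <- length(lt)
  m <- sum(adjacency(lt) * adjacency(le)) / p^2
  structure(list(m_accuracy = m, p = p,
                 k_true = length(unique(lt)), k_est = length(unique(le))),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("<accuracy_report> M_accuracy = %.4f (p = %d, K_true = %d, K_est = %d)\n",
              x$m_accuracy, x$p, x$k_true, x$k_est))
  invisible(x)
}

#' Agreement between two partitions
#'
#' Fraction of adjacency-matrix entries (diagonal included) on which two
#' partitions agree: `(1 + sum(C1 * C2) / p^2) / 2`.
#'
#' @param p1,p2 partitions over the same genes.
#' @return A fraction in [0, 1].
#' @export
partition_agreement <- function(p1, p2) {
  l1 <- partition_labels(p1); l2 <- partition_labels(p2)
  if (length(l1) != length(l2)) {
    stop("partitions cover different numbers of genes", call. = FALSE)
  }
  if (!is.null(names(l1)) && !is.null(names(l2))) {
    if (!setequal(names(l1), names(l2))) {
      stop("partitions cover different gene sets", call. = FALSE)
    }
    l2 <- l2[names(l1)]
  }
  p <- length(l1)
  (1 + sum(adjacency(l1) * adjacency(l2)) / p^2) / 2
}

batch_methods <- c("ancut", "ancut_subset", "ancut_overlap",
                   "ancut_silh", "ancut_elbow", "kmeans")

#' Run a replicated simulation benchmark
#'
#' For each replicate: simulate a dataset from `config` (with a child seed),
#' fit the per-gene regulation models once, cluster with every requested
#' method on the same dataset (paired comparison), and score each result
#' against the planted partition.  Methods:
#' `"ancut"` (complete data, K known), `"ancut_subset"` (overlap individuals
#' only), `"ancut_overlap"` (the partial-overlap method, K known),
#' `"ancut_silh"` / `"ancut_elbow"` (K selected by silhouette / elbow),
#' and `"kmeans"` (observed expression only).
#'
#' @param config a [sim_config()].
#' @param methods subset of the method names above.
#' @param replicates number of simulation replicates.
#' @param sa an [sa_config()] used by all assisted methods.
#' @param seed master seed; each replicate r uses `seed + 7919 * r`.
#' @param k_candidates candidate grid for the selection methods.
#' @param cv_folds,alpha_grid regression settings.
#' @param epsilon,scale_genes similarity settings.
#' @param kmeans_restarts restarts for the K-means baseline.
#' @param quality also record the median holdout imputation R-squared per
#'   replicate.
#' @return An object of class `simulation_batch`: tibble `results` with one
#'   row per replicate x method (`replicate`, `method`, `accuracy`,
#'   `k_est`, `r2_median`), plus `config` and `summary` (per-method median
#'   and range of accuracy).
#' @export
run_simulation_batch <- function(config, methods = c("ancut_overlap", "kmeans"),
                                 replicates = 10, sa = sa_config(),
                                 seed = 1, k_candidates = 2:10,
                                 cv_folds = 5, alpha_grid = c(0.1, 0.55, 1),
                                 epsilon = 0.1, scale_genes = TRUE,
                                 kmeans_restarts = 10, quality = FALSE) {
  stopifnot(inherits(config, "sim_config"), replicates >= 1)
  methods <- match.arg(methods, batch_methods, several.ok = TRUE)
  rows <- list()
  for (r in seq_len(replicates)) {
    child <- (seed + 7919 * r) %% .Machine$integer.max
    res <- tryCatch(
      run_one_replicate(config, methods, sa, child, k_candidates,
                        cv_folds, alpha_grid, epsilon, scale_genes,
                        kmeans_restarts, quality),
      error = function(e) {
        warning(sprintf("replicate %d failed and was excluded: %s",
                        r, conditionMessage(e)), call. = FALSE)
        NULL
      })
    if (!is.null(res)) {
      res$replicate <- r
      rows[[length(rows) + 1]] <- res
    }
  }
  if (length(rows) == 0) {
    stop("all replicates failed; see the warnings above", call. = FALSE)
  }
  results <- dplyr::bind_rows(rows)
  summary <- results |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      median_accuracy = median(.data$accuracy),
      min_accuracy = min(.data$accuracy),
      max_accuracy = max(.data$accuracy),
      n = dplyr::n(), .groups = "drop")
  structure(list(results = results, summary = summary, config = config),
            class = "simulation_batch")
}

run_one_replicate <- function(config, methods, sa, child_seed, k_candidates,
                              cv_folds, alpha_grid, epsilon, scale_genes,
                              kmeans_restarts, quality) {
  dataset <- simulate_dataset(config, seed = child_seed)
  truth <- dataset$true_partition
  needs_reg <- any(methods %in% c("ancut_subset", "ancut_overlap",
                                  "ancut_silh", "ancut_elbow"))
  reg <- NULL
  S_ov <- Shat_ov <- NULL
  if (needs_reg) {
    reg <- fit_all_genes(dataset, cv_folds = cv_folds,
                         alpha_grid = alpha_grid, seed = child_seed + 1)
    S_ov <- similarity_from_expression(dataset$y, epsilon = epsilon,
                                       scale_genes = scale_genes,
                                       source = "observed")
    Shat_ov <- similarity_from_expression(reg$yhat, epsilon = epsilon,
                                          scale_genes = scale_genes,
                                          source = "predicted")
  }
  r2_median <- NA_real_
  if (quality && !is.null(reg)) {
    iq <- imputation_quality(reg, dataset, mode = "holdout",
                             seed = child_seed + 2)
    r2_median <- unname(iq$summary["median"])
  }
  sa_r <- function(offset) {
    cfg <- sa; cfg$seed <- child_seed + offset; cfg
  }
  out <- list()
  for (m in methods) {
    lab <- k_est <- NULL
    if (m == "ancut") {
      fit <- assisted_cluster(dataset, config$K, mode = "full",
                              sa = sa_r(10), epsilon = epsilon,
                              scale_genes = scale_genes,
                              cv_folds = cv_folds, alpha_grid = alpha_grid)
      lab <- fit$partition
    } else if (m == "ancut_subset") {
      fit <- assisted_cluster(dataset, config$K, mode = "subset",
                              sa = sa_r(11), regulation = reg,
                              epsilon = epsilon, scale_genes = scale_genes)
      lab <- fit$partition
    } else if (m == "ancut_overlap") {
      fit <- sa_optimize(S_ov, Shat_ov, config$K, sa_r(12))
      lab <- fit$partition
    } else if (m %in% c("ancut_silh", "ancut_elbow")) {
      ks <- select_k(S_ov, Shat_ov, k_candidates = k_candidates,
                     method = if (m == "ancut_silh") "silhouette" else "elbow",
                     sa = sa_r(if (m == "ancut_silh") 13 else 14))
      lab <- ks$partitions[[as.character(ks$chosen_k)]]
      k_est <- ks$chosen_k
    } else if (m == "kmeans") {
      km <- kmeans_baseline(dataset$y, config$K, seed = child_seed + 15,
                            restarts = kmeans_restarts)
      lab <- km$partition
    }
    acc <- clustering_accuracy(truth, lab)
    out[[m]] <- tibble::tibble(
      method = m, accuracy = acc$m_accuracy,
      k_est = k_est %||% acc$k_est, r2_median = r2_median)
  }
  dplyr::bind_rows(out)
}

#' @export
print.simulation_batch <- function(x, ...) {
  cat(sprintf("<simulation_batch> scenario %s, %d replicate(s)\n",
              x$config$scenario, max(x$results$replicate)))
  print(x$summary)
  invisible(x)
}
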