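#' Tidy a regulation model
#'
#' One row per gene with its selected tuning parameters and sparsity.
#'
#' @param x a `regulation_model`.
#' @param ... unused.
#' @return A tibble with columns `gene`, `n_regulators`, `lambda`, `alpha`,
#'   `is_regulated`.
#' @method tidy regulation_model
#' @export
tidy.regulation_model <- function(x, ...) {
  tibble::tibble(
    gene = colnames(x$coefficients),
    n_regulators = Matrix::colSums(x$coefficients != 0),
    lambda = unname(x$lambda),
    alpha = unname(x$alpha),
    is_regulated = unname(x$is_regulated))
}

#' @method glance regulation_model
#' @export
glance.regulation_model <- function(x, ...) {
  tibble::tibble(
    n_genes = ncol(x$coefficients),
    n_regulators = nrow(x$coefficients),
    n_regulated = sum(x$is_regulated),
    n_overlap = x$layout$n2 %||% NA_integer_,
    cv_folds = x$cv_folds)
}

#' Tidy an assisted-clustering fit
#'
#' @param x an `ancut_fit`.
#' @param ... unused.
#' @return A tibble with one row per cluster: `cluster`, `size`,
#'   `objective` (the cluster's cut/cutvol ratio).
#' @method tidy ancut_fit
#' @export
tidy.ancut_fit <- function(x, ...) {
  tibble::tibble(
    cluster = seq_len(x$K),
    size = tabulate(x$partition, x$K),
    objective = unname(x$per_cluster))
}

#' @method glance ancut_fit
#' @export
glance.ancut_fit <- function(x, ...) {
  tibble::tibble(
    K = x$K, total_objective = x$total, accepted_moves = x$accepted,
    iterations = x$config$iterations, schedule = x$config$schedule)
}

#' @method tidy k_selection
#' @export
tidy.k_selection <- function(x, ...) x$criteria

#' @method glance k_selection
#' @export
glance.k_selection <- function(x, ...) {
  tibble::tibble(method = x$method, chosen_k = x$chosen_k,
                 n_candidates = nrow(x$criteria))
}

#' @method tidy imputation_quality
#' @export
tidy.imputation_quality <- function(x, ...) x$quality

#' @method glance imputation_quality
#' @export
glance.imputation_quality <- function(x, ...) {
  tibble::tibble(mode = x$mode,
                 median_r_squared = unname(x$summary["median"]),
                 min_r_squared = unname(x$summary["min"]),
                 max_r_squared = unname(x$summary["max"]))
}

#' @method tidy simulation_batch
#' @export
tidy.simulation_batch <- function(x, ...) x$results

#' @method glance simulation_batch
#' @export
glance.simulation_batch <- function(x, ...) x$summary

#' Objective trace of a simulated-annealing run
#'
#' @param object an `ancut_fit`.
#' @param ... unused.
#' @return A ggplot of the objective and best-so-far traces.
#' @method autoplot ancut_fit
#' @export
autoplot.ancut_fit <- function(object, ...) {
  df <- tibble::tibble(
    iteration = rep(seq_along(object$trace), 2),
    objective = c(object$trace, object$best_trace),
    series = rep(c("current", "best so far"), each = length(object$trace)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$objective,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "iteration", y = "total objective", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Criterion curve of a K selection
#'
#' @param object a `k_selection`.
#' @param ... unused.
#' @return A ggplot of the criterion against K, with the chosen K marked.
#' @method autoplot k_selection
#' @export
autoplot.k_selection <- function(object, ...) {
  lab <- if (object$method == "silhouette") "average silhouette" else "total WCSS"
  ggplot2::ggplot(object$criteria,
                  ggplot2::aes(x = .data$K, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$chosen_k, linetype = 2) +
    ggplot2::labs(x = "number of clusters K", y = lab) +
    ggplot2::theme_minimal()
}

#' Distribution of per-gene imputation quality
#'
#' @param object an `imputation_quality`.
#' @param ... unused.
#' @return A ggplot histogram of per-gene R-squared values.
#' @method autoplot imputation_quality
#' @export
autoplot.imputation_quality <- function(object, ...) {
  ggplot2::ggplot(object$quality, ggplot2::aes(x = .data$r_squared)) +
    ggplot2::geom_histogram(bins = 40) +
    ggplot2::geom_vline(xintercept = object$summary["median"], linetype = 2) +
    ggplot2::labs(x = expression(R^2), y = "genes") +
    ggplot2::theme_minimal()
}

#' Accuracy by method across a simulation batch
#'
#' @param object a `simulation_batch`.
#' @param ... unused.
#' @return A ggplot boxplot of per-replicate accuracy by method.
#' @method autoplot simulation_batch
#' @export
autoplot.simulation_batch <- function(object, ...) {
  ggplot2::ggplot(object$results,
                  ggplot2::aes(x = .data$method, y = .data$accuracy)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "M_accuracy") +
    ggplot2::theme_minimal()
}
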