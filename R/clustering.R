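#' Between-cluster similarity mass (cut)
#'
#' Sum of the observed similarity over ordered pairs with the first gene in
#' cluster `k` and the second outside it.
#'
#' @param labels integer cluster labels, one per gene.
#' @param k cluster index.
#' @param S gene-gene similarity matrix (observed).
#' @return A non-negative number.
#' @export
cut_value <- function(labels, k, S) {
  S <- unclass(S)
  ink <- labels == k
  sum(S[ink, !ink, drop = FALSE])
}

#' Within-cluster similarity mass (cutvol)
#'
#' Sum of the predicted similarity over all ordered pairs of genes inside
#' cluster `k`.  The similarity diagonal is zero, so self-pairs contribute
#' nothing.
#'
#' @param labels integer cluster labels.
#' @param k cluster index.
#' @param Shat gene-gene similarity matrix (predicted).
#' @return A non-negative number.
#' @export
cutvol_value <- function(labels, k, Shat) {
  Shat <- unclass(Shat)
  ink <- labels == k
  sum(Shat[ink, ink, drop = FALSE])
}

ratio_term <- function(cut, vol) {
  if (vol <= 0) {
    if (cut <= 0) 0 else Inf
  } else {
    cut / vol
  }
}

#' Assisted-cut objective
#'
#' Per-cluster ratio of between-cluster similarity (on the observed matrix
#' `S`) to within-cluster similarity (on the predicted matrix `Shat`), and
#' their sum, the total objective minimised by [sa_optimize()].  A cluster
#' with zero within-cluster similarity contributes `Inf` unless its cut is
#' also zero (the single-cluster case, which contributes 0).
#'
#' @param labels integer cluster labels.
#' @param S observed similarity matrix.
#' @param Shat predicted similarity matrix.
#' @return A list with `per_cluster` (named numeric vector) and `total`.
#' @export
ancut_objective <- function(labels, S, Shat) {
  K <- max(labels)
  per <- vapply(seq_len(K), function(k) {
    ratio_term(cut_value(labels, k, S), cutvol_value(labels, k, Shat))
  }, numeric(1))
  names(per) <- paste0("cluster", seq_len(K))
  list(per_cluster = per, total = sum(per))
}

#' Simulated-annealing settings
#'
#' @param iterations number of single-gene moves proposed (default 10000).
#' @param L temperature constant (default 10000).
#' @param schedule acceptance schedule for worsening moves of size `d > 0` at
#'   iteration `t`:
#'   \describe{
#'     \item{`"anneal"` (default)}{`exp(-d * L * log(t + 1))`, i.e.
#'       `L * log(t + 1)` acting as an inverse temperature that grows with
#'       `t`.  This is the only reading under which the stated constants
#'       (`L = 10000`) produce an optimizer rather than a random walk; see
#'       the methods vignette.}
#'     \item{`"as_printed"`}{`exp(-d / (L * log(t + 1)))`: `L log(t+1)` used
#'       directly as a temperature.  With large `L` nearly every move is
#'       accepted.}
#'     \item{`"cooling"`}{`exp(-d / (L / log(t + 1)))`.}
#'   }
#' @param seed optional integer seed.
#' @param return_best return the best partition visited rather than the
#'   final state.
#' @param restarts number of independent annealing runs (with seeds
#'   `seed`, `seed + 1`, ...); the run with the lowest objective is
#'   returned.  Useful on small instances where a random initial partition
#'   can be a strict local minimum of single-gene moves.
#' @return An object of class `sa_config`.
#' @export
sa_config <- function(iterations = 10000, L = 10000,
                      schedule = c("anneal", "as_printed", "cooling"),
                      seed = NULL, return_best = TRUE, restarts = 1) {
  schedule <- match.arg(schedule)
  stopifnot(iterations >= 1, L > 0, restarts >= 1)
  structure(list(iterations = as.integer(iterations), L = L,
                 schedule = schedule, seed = seed,
                 return_best = isTRUE(return_best),
                 restarts = as.integer(restarts)),
            class = "sa_config")
}

# random initial partition with every cluster non-empty
init_partition <- function(p, K) {
  repeat {
    lab <- sample.int(K, p, replace = TRUE)
    if (length(unique(lab)) == K) return(lab)
  }
}

#' Minimise the assisted-cut objective by simulated annealing
#'
#' Starts from a random partition of the `p` genes into `K` non-empty
#' clusters and proposes single-gene moves: a donor cluster is drawn with
#' probability proportional to its number of within-cluster gene pairs
#' `m_k = size_k * (size_k - 1) / 2` (clusters of size < 2 are excluded so no
#' cluster empties), a receiver with probability proportional to
#' `1 / max(m_k, 1)`, and a uniformly drawn gene moves donor to receiver.
#' Moves that do not increase the objective are always accepted; worsening
#' moves are accepted with the Metropolis probability of the chosen schedule
#' (see [sa_config()]).  The objective change is computed incrementally from
#' maintained per-cluster sums, so each iteration costs O(p).
#'
#' @param S observed similarity matrix.
#' @param Shat predicted similarity matrix.
#' @param K number of clusters (>= 1).
#' @param config an [sa_config()].
#' @return An object of class `ancut_fit` with elements `partition` (named
#'   integer labels), `per_cluster`, `total`, `trace` (objective after each
#'   iteration), `best_trace` (best-so-far), `accepted` (number of accepted
#'   moves), `K` and `config`.
#' @examples
#' set.seed(1)
#' S <- similarity_from_expression(matrix(rnorm(40), 5, 8))
#' fit <- sa_optimize(S, S, K = 2, sa_config(iterations = 200, seed = 2))
#' fit$total
#' @export
sa_optimize <- function(S, Shat, K, config = sa_config()) {
  restarts <- config$restarts %||% 1L
  if (restarts > 1) {
    best <- NULL
    for (r in seq_len(restarts)) {
      cfg <- config
      cfg$restarts <- 1L
      if (!is.null(cfg$seed)) cfg$seed <- cfg$seed + r - 1L
      fit <- sa_optimize(S, Shat, K, cfg)
      if (is.null(best) || fit$total < best$total) best <- fit
    }
    best$config <- config
    return(best)
  }
  S <- unclass(S); Shat <- unclass(Shat)
  p <- nrow(S)
  stopifnot(nrow(Shat) == p, ncol(S) == p, ncol(Shat) == p, K >= 1)
  if (K > p) stop("K exceeds the number of genes", call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)
  gene_ids <- colnames(S) %||% sprintf("gene%04d", seq_len(p))

  lab <- init_partition(p, K)
  # per-gene similarity mass into each cluster; O(p) to update per move
  gS <- vapply(seq_len(K), function(k) rowSums(S[, lab == k, drop = FALSE]),
               numeric(p))
  gSh <- vapply(seq_len(K), function(k) rowSums(Shat[, lab == k, drop = FALSE]),
                numeric(p))
  gS <- matrix(gS, p, K); gSh <- matrix(gSh, p, K)
  rtS <- rowSums(S)
  sz <- tabulate(lab, K)
  WS <- vapply(seq_len(K), function(k) sum(gS[lab == k, k]), numeric(1))
  WSh <- vapply(seq_len(K), function(k) sum(gSh[lab == k, k]), numeric(1))
  TS <- vapply(seq_len(K), function(k) sum(rtS[lab == k]), numeric(1))
  terms <- mapply(ratio_term, TS - WS, WSh)
  obj <- sum(terms)

  best_lab <- lab; best_obj <- obj
  trace <- numeric(config$iterations)
  best_trace <- numeric(config$iterations)
  accepted <- 0L
  B <- config$iterations; L <- config$L; schedule <- config$schedule
  warned <- FALSE

  for (t in seq_len(B)) {
    m <- sz * (sz - 1) / 2
    donor_ok <- sz >= 2
    if (K < 2 || !any(donor_ok)) {
      if (!warned) {
        warning("no admissible donor cluster; iterations skipped",
                call. = FALSE)
        warned <- TRUE
      }
      trace[t] <- obj; best_trace[t] <- best_obj
      next
    }
    wd <- ifelse(donor_ok, m, 0)
    a <- sample.int(K, 1, prob = wd)
    wr <- 1 / pmax(m, 1); wr[a] <- 0
    b <- sample.int(K, 1, prob = wr)
    in_a <- which(lab == a)
    i <- in_a[sample.int(length(in_a), 1)]

    WS_a <- WS[a] - 2 * gS[i, a];  WSh_a <- WSh[a] - 2 * gSh[i, a]
    WS_b <- WS[b] + 2 * gS[i, b];  WSh_b <- WSh[b] + 2 * gSh[i, b]
    TS_a <- TS[a] - rtS[i];        TS_b <- TS[b] + rtS[i]
    new_a <- ratio_term(TS_a - WS_a, WSh_a)
    new_b <- ratio_term(TS_b - WS_b, WSh_b)
    d <- (new_a + new_b) - (terms[a] + terms[b])

    take <- if (is.nan(d)) {
      FALSE
    } else if (d <= 0) {
      TRUE
    } else {
      pr <- switch(schedule,
                   anneal     = exp(-d * L * log(t + 1)),
                   as_printed = exp(-d / (L * log(t + 1))),
                   cooling    = exp(-d / (L / log(t + 1))))
      runif(1) < pr
    }
    if (take) {
      accepted <- accepted + 1L
      lab[i] <- b
      gS[, a] <- gS[, a] - S[, i]; gS[, b] <- gS[, b] + S[, i]
      gSh[, a] <- gSh[, a] - Shat[, i]; gSh[, b] <- gSh[, b] + Shat[, i]
      WS[a] <- WS_a; WS[b] <- WS_b; WSh[a] <- WSh_a; WSh[b] <- WSh_b
      TS[a] <- TS_a; TS[b] <- TS_b
      sz[a] <- sz[a] - 1L; sz[b] <- sz[b] + 1L
      terms[a] <- new_a; terms[b] <- new_b
      obj <- sum(terms)
      if (obj < best_obj) { best_obj <- obj; best_lab <- lab }
    }
    trace[t] <- obj
    best_trace[t] <- best_obj
  }

  out_lab <- if (config$return_best) best_lab else lab
  names(out_lab) <- gene_ids
  final <- ancut_objective(out_lab, S, Shat)
  structure(
    list(partition = out_lab, per_cluster = final$per_cluster,
         total = final$total, trace = trace, best_trace = best_trace,
         accepted = accepted, K = K, config = config),
    class = "ancut_fit")
}

#' @export
print.ancut_fit <- function(x, ...) {
  cat(sprintf("<ancut_fit> %d genes in %d clusters; objective = %.4f\n",
              length(x$partition), x$K, x$total))
  cat("  sizes:", paste(tabulate(x$partition, x$K), collapse = ", "), "\n")
  cat(sprintf("  accepted moves: %d / %d\n",
              x$accepted, x$config$iterations))
  invisible(x)
}

#' Assisted clustering of a partially overlapping dataset
#'
#' Builds the observed and predicted similarity matrices for the requested
#' mode and minimises the assisted-cut objective.
#'
#' Modes:
#' \describe{
#'   \item{`"overlap"`}{observed similarity from all expression-bearing
#'     individuals; predicted similarity from elastic-net predictions on all
#'     regulator-bearing individuals (regressions fitted on the overlap).}
#'   \item{`"full"`}{both matrices from the complete `n`-individual data; only
#'     available when the dataset has no missingness (or carries the complete
#'     simulated matrices).}
#'   \item{`"subset"`}{both matrices restricted to the overlap individuals.}
#' }
#'
#' @param dataset an `omics_dataset`.
#' @param K number of clusters.
#' @param mode `"overlap"`, `"full"` or `"subset"`.
#' @param sa an [sa_config()].
#' @param regulation optional pre-computed [fit_all_genes()] result matching
#'   `dataset` (for `"overlap"`/`"subset"`); refitted when `NULL`.
#' @param epsilon distance floor for the similarity matrices.
#' @param scale_genes standardize gene profiles before computing distances
#'   (default `TRUE`; see the methods vignette).
#' @param cv_folds,alpha_grid passed to [fit_all_genes()] when refitting.
#' @return An `ancut_fit`, with the fitted `regulation` model attached.
#' @export
assisted_cluster <- function(dataset, K,
                             mode = c("overlap", "full", "subset"),
                             sa = sa_config(), regulation = NULL,
                             epsilon = 0.1, scale_genes = TRUE,
                             cv_folds = 5, alpha_grid = c(0.1, 0.55, 1)) {
  stopifnot(inherits(dataset, "omics_dataset"))
  mode <- match.arg(mode)
  lay <- dataset$layout

  if (mode == "full") {
    complete <- !is.null(dataset$y_full) && !is.null(dataset$x_full)
    if (!complete && (lay$n1 > 0 || lay$n3 > 0)) {
      stop("full mode requires complete overlap (n1 = n3 = 0) or a ",
           "simulated dataset carrying the complete matrices", call. = FALSE)
    }
    y_all <- dataset$y_full %||% dataset$y
    x_all <- dataset$x_full %||% dataset$x
    reg <- fit_genes_matrix(x_all, y_all, x_all,
                            cv_folds = cv_folds, alpha_grid = alpha_grid)
    S <- similarity_from_expression(y_all, epsilon = epsilon,
                                    scale_genes = scale_genes,
                                    source = "observed")
    Shat <- similarity_from_expression(reg$yhat, epsilon = epsilon,
                                       scale_genes = scale_genes,
                                       source = "predicted")
  } else {
    if (is.null(regulation)) {
      regulation <- fit_all_genes(dataset, cv_folds = cv_folds,
                                  alpha_grid = alpha_grid)
    }
    if (mode == "overlap") {
      S <- similarity_from_expression(dataset$y, epsilon = epsilon,
                                      scale_genes = scale_genes,
                                      source = "observed")
      Shat <- similarity_from_expression(regulation$yhat, epsilon = epsilon,
                                         scale_genes = scale_genes,
                                         source = "predicted")
    } else {
      y_ov <- dataset$y[overlap_rows_y(dataset), , drop = FALSE]
      yhat_ov <- regulation$yhat[overlap_rows_x(dataset), , drop = FALSE]
      S <- similarity_from_expression(y_ov, epsilon = epsilon,
                                      scale_genes = scale_genes,
                                      source = "observed")
      Shat <- similarity_from_expression(yhat_ov, epsilon = epsilon,
                                         scale_genes = scale_genes,
                                         source = "predicted")
    }
    reg <- regulation
  }
  fit <- sa_optimize(S, Shat, K, config = sa)
  fit$mode <- mode
  fit$regulation <- reg
  fit
}

#' K-means baseline on observed expression
#'
#' Clusters genes as points in individual space using only the observed
#' expression matrix.  Gene profiles are mean-centred by default so that the
#' partition reflects co-variation rather than arbitrary baseline levels.
#' Uses [stats::kmeans()] (Hartigan-Wong by default) with `restarts` random
#' starts, keeping the solution with the lowest within-cluster sum of
#' squares.
#'
#' @param expr individuals x genes matrix of observed expression.
#' @param K number of clusters.
#' @param seed optional integer seed.
#' @param restarts number of random starts (default 10).
#' @param center mean-centre each gene profile first (default `TRUE`).
#' @param algorithm passed to [stats::kmeans()].
#' @return An object of class `kmeans_partition`: list with `partition`
#'   (named integer labels), `K`, `tot_withinss` and the `kmeans` object.
#' @export
kmeans_baseline <- function(expr, K, seed = NULL, restarts = 10,
                            center = TRUE,
                            algorithm = c("Hartigan-Wong", "Lloyd",
                                          "Forgy", "MacQueen")) {
  algorithm <- match.arg(algorithm)
  expr <- as.matrix(expr)
  stopifnot(K <= ncol(expr))
  if (!is.null(seed)) set.seed(seed)
  M <- t(expr)
  if (center) M <- M - rowMeans(M)
  km <- suppressWarnings(
    kmeans(M, centers = K, nstart = restarts, iter.max = 50,
           algorithm = algorithm))
  lab <- km$cluster
  names(lab) <- colnames(expr) %||% sprintf("gene%04d", seq_len(ncol(expr)))
  structure(list(partition = lab, K = K, tot_withinss = km$tot.withinss,
                 kmeans = km),
            class = "kmeans_partition")
}

#' @export
print.kmeans_partition <- function(x, ...) {
  cat(sprintf("<kmeans_partition> %d genes in %d clusters; total WCSS %.3f\n",
              length(x$partition), x$K, x$tot_withinss))
  invisible(x)
}

# labels from any partition-like object
partition_labels <- function(x) {
  if (is.list(x) && !is.null(x$partition)) x$partition
  else if (is.numeric(x) || is.integer(x)) x
  else stop("cannot extract cluster labels", call. = FALSE)
}
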