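#' Silhouette scores for a gene partition
#'
#' For gene `i` in cluster `C_i`, `a(i)` is its mean distance to the other
#' members of `C_i` and `b(i)` the smallest mean distance to any other
#' cluster; the silhouette is `(b - a) / max(a, b)`, defined as 0 when `C_i`
#' is a singleton.
#'
#' @param labels integer cluster labels.
#' @param D symmetric non-negative distance matrix with zero diagonal.
#' @return List with `scores` (per gene) and `average`.
#' @export
silhouette_scores <- function(labels, D) {
  D <- unclass(D)
  p <- length(labels)
  stopifnot(nrow(D) == p, ncol(D) == p)
  K <- max(labels)
  if (length(unique(labels)) < 2) {
    stop("silhouette is undefined for a single-cluster partition",
         call. = FALSE)
  }
  sizes <- tabulate(labels, K)
  # mean distance from every gene to every cluster, self excluded within
  sums <- vapply(seq_len(K),
                 function(k) rowSums(D[, labels == k, drop = FALSE]),
                 numeric(p))
  sums <- matrix(sums, p, K)
  scores <- vapply(seq_len(p), function(i) {
    k <- labels[i]
    if (sizes[k] == 1) return(0)
    a <- sums[i, k] / (sizes[k] - 1)
    others <- setdiff(which(sizes > 0), k)
    b <- min(sums[i, others] / sizes[others])
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
  list(scores = scores, average = mean(scores))
}

#' Total within-cluster sum of squares
#'
#' Per-cluster WCSS is the sum of squared distances over unordered
#' within-cluster gene pairs divided by the total number of genes `p`
#' (the global divisor, not the cluster size); the total is the sum over
#' clusters.
#'
#' @param labels integer cluster labels.
#' @param D symmetric distance matrix with zero diagonal.
#' @return A non-negative number.
#' @export
total_wcss <- function(labels, D) {
  D <- unclass(D)
  p <- length(labels)
  stopifnot(nrow(D) == p)
  K <- max(labels)
  total <- 0
  for (k in seq_len(K)) {
    ink <- labels == k
    if (sum(ink) > 1) {
      Dk <- D[ink, ink, drop = FALSE]
      total <- total + sum(Dk[upper.tri(Dk)]^2) / p
    }
  }
  total
}

#' Select the number of clusters
#'
#' Runs [sa_optimize()] for each candidate `K` and scores the partitions on
#' distances derived from the predicted similarity matrix (elementwise
#' inverse with the same epsilon cap).  `"silhouette"` picks the `K`
#' maximising the average silhouette; `"elbow"` picks the interior candidate
#' maximising the discrete second difference
#' `WCSS(K-1) - 2 WCSS(K) + WCSS(K+1)`.  Ties go to the smallest `K`.
#'
#' @param S observed similarity matrix.
#' @param Shat predicted similarity matrix.
#' @param k_candidates candidate cluster numbers (default `2:10`).
#' @param method `"silhouette"` or `"elbow"`.
#' @param sa an [sa_config()]; each candidate `K` runs with the same
#'   settings.
#' @return An object of class `k_selection`: tibble `criteria` with columns
#'   `K` and `value`, `chosen_k`, `method`, and `partitions` (list of label
#'   vectors indexed by `K`).
#' @export
select_k <- function(S, Shat, k_candidates = 2:10,
                     method = c("silhouette", "elbow"),
                     sa = sa_config()) {
  method <- match.arg(method)
  k_candidates <- sort(unique(as.integer(k_candidates)))
  if (method == "elbow" && length(k_candidates) < 3) {
    stop("the elbow method needs at least 3 candidate values of K",
         call. = FALSE)
  }
  D <- distance_from_similarity(Shat)
  fits <- lapply(k_candidates, function(K) sa_optimize(S, Shat, K, sa))
  partitions <- lapply(fits, function(f) f$partition)
  names(partitions) <- k_candidates
  value <- vapply(seq_along(k_candidates), function(i) {
    lab <- partitions[[i]]
    if (method == "silhouette") {
      if (length(unique(lab)) < 2) return(NA_real_)
      silhouette_scores(lab, D)$average
    } else {
      total_wcss(lab, D)
    }
  }, numeric(1))
  criteria <- tibble::tibble(K = k_candidates, value = value)
  if (length(k_candidates) == 1) {
    chosen <- k_candidates
  } else if (method == "silhouette") {
    chosen <- k_candidates[which.max(value)]
  } else {
    second <- rep(NA_real_, length(k_candidates))
    for (i in seq_along(k_candidates)[-c(1, length(k_candidates))]) {
      second[i] <- value[i - 1] - 2 * value[i] + value[i + 1]
    }
    chosen <- k_candidates[which.max(second)]
    criteria$second_difference <- second
  }
  structure(
    list(criteria = criteria, chosen_k = chosen, method = method,
         partitions = partitions),
    class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  cat(sprintf("<k_selection> method = %s; chosen K = %d\n",
              x$method, x$chosen_k))
  print(x$criteria, n = nrow(x$criteria))
  invisible(x)
}
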