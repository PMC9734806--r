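# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: plain loops and direct formula evaluation.

# triple-loop cut: sum of S over ordered pairs (j in cluster k, l outside)
brute_cut <- function(labels, k, S) {
  total <- 0
  for (j in which(labels == k)) {
    for (l in which(labels != k)) total <- total + S[j, l]
  }
  total
}

brute_cutvol <- function(labels, k, Shat) {
  ink <- which(labels == k)
  total <- 0
  for (j in ink) for (l in ink) total <- total + Shat[j, l]
  total
}

brute_objective <- function(labels, S, Shat) {
  K <- max(labels)
  terms <- numeric(K)
  for (k in seq_len(K)) {
    cut <- brute_cut(labels, k, S)
    vol <- brute_cutvol(labels, k, Shat)
    terms[k] <- if (vol <= 0) { if (cut <= 0) 0 else Inf } else cut / vol
  }
  list(per_cluster = terms, total = sum(terms))
}

# all partitions of p items into exactly 2 non-empty clusters
all_bipartitions <- function(p) {
  out <- list()
  for (code in 1:(2^(p - 1) - 1)) {
    bits <- as.integer(intToBits(code))[seq_len(p)]
    out[[length(out) + 1]] <- bits + 1L
  }
  out
}

# direct Eq.-style silhouette, one gene at a time
direct_silhouette <- function(labels, D) {
  p <- length(labels)
  scores <- numeric(p)
  for (i in seq_len(p)) {
    own <- which(labels == labels[i])
    if (length(own) == 1) { scores[i] <- 0; next }
    a <- mean(D[i, setdiff(own, i)])
    b <- Inf
    for (k in setdiff(unique(labels), labels[i])) {
      b <- min(b, mean(D[i, which(labels == k)]))
    }
    scores[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  scores
}

direct_wcss <- function(labels, D) {
  p <- length(labels)
  total <- 0
  for (k in unique(labels)) {
    ink <- which(labels == k)
    if (length(ink) > 1) {
      for (a in seq_along(ink)) for (b in seq_along(ink)) {
        if (a < b) total <- total + D[ink[a], ink[b]]^2 / p
      }
    }
  }
  total
}

# similarity matrices with a planted two-block structure
planted_similarity <- function(p, within = 1, between = 0.01,
                               block = rep(1:2, each = p / 2)) {
  S <- matrix(between, p, p)
  for (k in unique(block)) {
    ink <- block == k
    S[ink, ink] <- within
  }
  diag(S) <- 0
  S
}

# random symmetric non-negative similarity with zero diagonal
random_similarity <- function(p) {
  S <- matrix(runif(p * p), p, p)
  S <- (S + t(S)) / 2
  diag(S) <- 0
  S
}

random_equal_partition <- function(p, K) {
  sample(rep(seq_len(K), length.out = p))
}

# near-equal contiguous blocks, mirroring the generator's convention
block_labels_for_test <- function(total, K) {
  sizes <- rep(total %/% K, K)
  extra <- total - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  rep(seq_len(K), sizes)
}
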