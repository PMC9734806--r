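#' Pairwise gene distances
#'
#' Euclidean distance between gene columns of an individuals-by-genes
#' expression matrix.  With `normalize = TRUE` distances are divided by the
#' square root of the number of individuals (root-mean-square scale), so
#' matrices built on different numbers of individuals are commensurable --
#' the observed matrix uses the expression-bearing individuals while the
#' predicted matrix uses the regulator-bearing ones.  With
#' `scale_genes = TRUE` each gene profile is centred and scaled to unit
#' variance first, so distances reflect profile shape (co-expression) rather
#' than baseline level or amplitude; zero-variance profiles are left as
#' centred zero vectors.
#'
#' @param expr numeric matrix, individuals x genes.
#' @param normalize divide distances by `sqrt(nrow(expr))`.
#' @param scale_genes standardize gene profiles before computing distances.
#' @return A symmetric `p x p` matrix with zero diagonal.
#' @export
pairwise_gene_distance <- function(expr, normalize = TRUE,
                                   scale_genes = FALSE) {
  expr <- as.matrix(expr)
  stopifnot(nrow(expr) >= 2, all(is.finite(expr)))
  M <- expr
  degenerate <- rep(FALSE, ncol(M))
  if (scale_genes) {
    s <- apply(M, 2, sd)
    degenerate <- s < 1e-12
    M <- scale(M, center = colMeans(M), scale = ifelse(degenerate, 1, s))
  }
  D <- as.matrix(dist(t(M)))
  if (normalize) D <- D / sqrt(nrow(M))
  attr(D, "degenerate") <- degenerate
  D
}

#' Gene-gene similarity from expression
#'
#' The similarity between two genes is the inverse of their Euclidean
#' distance, `s_jl = 1 / max(d_jl, epsilon)`, with the diagonal forced to
#' zero so that within-cluster similarity sums exclude self-pairs.  The
#' `epsilon` floor caps the similarity of (near-)identical profiles.  When
#' `scale_genes = TRUE`, genes whose profiles have zero variance (for
#' example, predicted expression of genes whose regression selected no
#' regulator) carry no co-expression information and are assigned zero
#' similarity to every other gene.
#'
#' @inheritParams pairwise_gene_distance
#' @param epsilon distance floor; similarities are capped at `1/epsilon`.
#' @param source optional tag, `"observed"` or `"predicted"`.
#' @return An object of class `gene_similarity`: the `p x p` matrix with
#'   attributes `epsilon`, `normalized`, `scaled` and `source`.
#' @examples
#' expr <- cbind(a = c(0, 0), b = c(3, 4))
#' similarity_from_expression(expr, epsilon = 1e-8, normalize = FALSE)
#' @export
similarity_from_expression <- function(expr, epsilon = 1e-8,
                                       normalize = TRUE,
                                       scale_genes = FALSE,
                                       source = NULL) {
  stopifnot(epsilon > 0)
  D <- pairwise_gene_distance(expr, normalize = normalize,
                              scale_genes = scale_genes)
  degenerate <- attr(D, "degenerate")
  S <- 1 / pmax(D, epsilon)
  diag(S) <- 0
  if (any(degenerate)) {
    S[degenerate, ] <- 0
    S[, degenerate] <- 0
  }
  structure(S, class = c("gene_similarity", "matrix"),
            epsilon = epsilon, normalized = normalize,
            scaled = scale_genes, source = source)
}

#' @export
print.gene_similarity <- function(x, ...) {
  cat(sprintf("<gene_similarity> %d genes%s (epsilon = %g%s%s)\n",
              nrow(x),
              if (!is.null(attr(x, "source"))) paste0(", ", attr(x, "source")) else "",
              attr(x, "epsilon"),
              if (isTRUE(attr(x, "normalized"))) ", RMS-normalized" else "",
              if (isTRUE(attr(x, "scaled"))) ", standardized profiles" else ""))
  invisible(x)
}

# distance matrix for K selection: elementwise inverse of the predicted
# similarity, with the same epsilon cap and zero diagonal
distance_from_similarity <- function(S, epsilon = NULL) {
  epsilon <- epsilon %||% attr(S, "epsilon") %||% 1e-8
  D <- 1 / pmax(unclass(S), epsilon)
  diag(D) <- 0
  D
}
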