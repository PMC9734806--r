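#' Read a labeled numeric matrix from delimited text
#'
#' Expects a header row of column identifiers and a first column of row
#' identifiers.  Tab-delimited by default; a comma delimiter is detected
#' automatically.
#'
#' @param path file path.
#' @return A numeric matrix with row and column names.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1)
  if (length(first) == 0) stop("empty file: ", path, call. = FALSE)
  sep <- if (!grepl("\t", first) && grepl(",", first)) "," else "\t"
  df <- read.delim(path, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("no data columns in ", path, call. = FALSE)
  ids <- as.character(df[[1]])
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate row identifier(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  cn <- colnames(df)[-1]
  dupc <- cn[duplicated(cn)]
  if (length(dupc)) {
    stop("duplicate column identifier(s): ",
         paste(unique(dupc), collapse = ", "), call. = FALSE)
  }
  body <- df[, -1, drop = FALSE]
  nonnum <- !vapply(body, is.numeric, logical(1))
  if (any(nonnum)) {
    stop("non-numeric column(s): ", paste(cn[nonnum], collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(body)
  rownames(m) <- ids
  m
}

#' Write a labeled matrix as tab-delimited text
#'
#' Row identifiers go in a first column named `id`; values are written at
#' full precision so the file round-trips losslessly through
#' [read_matrix()].
#'
#' @param x numeric matrix with dimnames.
#' @param path output file path.
#' @export
write_matrix <- function(x, path) {
  stopifnot(is.matrix(x))
  df <- data.frame(id = rownames(x) %||% as.character(seq_len(nrow(x))),
                   x, check.names = FALSE)
  write.table(format(df, digits = 17, trim = TRUE), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align expression and regulator matrices into a dataset
#'
#' Matches individuals by row identifier and derives the three-block layout:
#' expression-only individuals first, the overlap in the middle, and
#' regulator-only individuals last.  The overlap must be non-empty.
#'
#' @param expr expression matrix (individuals x genes) or a file path.
#' @param reg regulator matrix (individuals x regulators) or a file path.
#' @return An `omics_dataset` (without simulation-only fields).
#' @export
align_datasets <- function(expr, reg) {
  if (is.character(expr)) expr <- read_matrix(expr)
  if (is.character(reg)) reg <- read_matrix(reg)
  stopifnot(is.matrix(expr), is.matrix(reg))
  if (is.null(rownames(expr)) || is.null(rownames(reg))) {
    stop("both matrices need row identifiers", call. = FALSE)
  }
  both <- intersect(rownames(expr), rownames(reg))
  if (length(both) == 0) {
    stop("no overlapping individuals between the two matrices; the ",
         "regulation model needs a non-empty overlap", call. = FALSE)
  }
  expr_only <- setdiff(rownames(expr), both)
  reg_only <- setdiff(rownames(reg), both)
  lay <- structure(list(n1 = length(expr_only), n2 = length(both),
                        n3 = length(reg_only),
                        n = length(expr_only) + length(both) + length(reg_only)),
                   class = "overlap_layout")
  structure(
    list(y = expr[c(expr_only, both), , drop = FALSE],
         x = reg[c(both, reg_only), , drop = FALSE],
         layout = lay,
         beta_true = NULL, true_partition = NULL, error_cov = NULL,
         y_full = NULL, x_full = NULL, config = NULL),
    class = "omics_dataset")
}

default_pipeline_config <- function() {
  list(
    scenario = "I", n = 300, p = 100, q = 100, K = 3, pcnt = 1 / 3, f = 0.5,
    block_corr = 0.1, seed = 1,
    expression = NULL, regulators = NULL,
    mode = "overlap", k = NULL, k_min = 2, k_max = 10,
    select_k = NULL,                    # NULL, "silhouette" or "elbow"
    iterations = 10000, L = 10000, schedule = "anneal",
    cv_folds = 5, alpha_grid = c(0.1, 0.55, 1),
    epsilon = 0.1, scale_genes = TRUE,
    quality = TRUE, holdout_fraction = 0.35)
}

#' Run the simulate / fit / cluster / evaluate pipeline
#'
#' Executes the full pipeline from a configuration list (or a YAML file with
#' the same keys) and writes its artifacts to `out_dir`: the effective
#' configuration (`config.yaml`), the partition (`partition.tsv`), the
#' objective summary (`result.json`), per-gene imputation quality
#' (`quality.tsv`) and a stage log (`log.txt`).  Unknown configuration keys
#' are rejected before any computation.  When `expression`/`regulators`
#' paths are given the data are read and aligned; otherwise a dataset is
#' simulated from the scenario settings and the planted-truth accuracy is
#' also recorded.
#'
#' @param config named list or path to a YAML file.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the output directory.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- default_pipeline_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "log.txt")
  log <- function(...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"),
                sprintf(...)), file = logf, append = TRUE)
  }
  yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))

  if (!is.null(cfg$expression)) {
    log("stage align: reading %s and %s", cfg$expression, cfg$regulators)
    dataset <- align_datasets(cfg$expression, cfg$regulators)
  } else {
    log("stage simulate: scenario %s, n=%d p=%d q=%d K=%d seed=%d",
        cfg$scenario, cfg$n, cfg$p, cfg$q, cfg$K, cfg$seed)
    sc <- sim_config(cfg$scenario, n = cfg$n, p = cfg$p, q = cfg$q,
                     K = cfg$K, pcnt = cfg$pcnt, f = cfg$f,
                     block_corr = cfg$block_corr, seed = cfg$seed)
    dataset <- simulate_dataset(sc)
  }

  log("stage fit: %d genes, %d regulators, %d overlap individuals",
      ncol(dataset$y), ncol(dataset$x), dataset$layout$n2)
  reg <- fit_all_genes(dataset, cv_folds = cfg$cv_folds,
                       alpha_grid = cfg$alpha_grid, seed = cfg$seed + 1)
  if (isTRUE(cfg$quality)) {
    iq <- imputation_quality(reg, dataset, mode = "holdout",
                             holdout_fraction = cfg$holdout_fraction,
                             seed = cfg$seed + 2)
    utils::write.table(iq$quality, file.path(out_dir, "quality.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log("stage quality: median R^2 = %.4f", iq$summary["median"])
  }

  sa <- sa_config(iterations = cfg$iterations, L = cfg$L,
                  schedule = cfg$schedule, seed = cfg$seed + 3)
  k_used <- cfg$k %||% cfg$K
  if (!is.null(cfg$select_k)) {
    S <- similarity_from_expression(dataset$y, epsilon = cfg$epsilon,
                                    scale_genes = cfg$scale_genes)
    Shat <- similarity_from_expression(reg$yhat, epsilon = cfg$epsilon,
                                       scale_genes = cfg$scale_genes)
    ks <- select_k(S, Shat, k_candidates = cfg$k_min:cfg$k_max,
                   method = cfg$select_k, sa = sa)
    k_used <- ks$chosen_k
    log("stage select-k (%s): chose K = %d", cfg$select_k, k_used)
    fit <- sa_optimize(S, Shat, k_used, sa)
    fit$regulation <- reg
  } else {
    fit <- assisted_cluster(dataset, k_used, mode = cfg$mode, sa = sa,
                            regulation = reg, epsilon = cfg$epsilon,
                            scale_genes = cfg$scale_genes,
                            cv_folds = cfg$cv_folds,
                            alpha_grid = cfg$alpha_grid)
  }
  log("stage cluster: K = %d, objective = %.4f, accepted = %d",
      k_used, fit$total, fit$accepted)

  part <- data.frame(gene = names(fit$partition),
                     cluster = unname(fit$partition))
  utils::write.table(part, file.path(out_dir, "partition.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  result <- list(K = k_used, objective = fit$total,
                 per_cluster = as.list(fit$per_cluster),
                 accepted_moves = fit$accepted,
                 best_trace_tail = unname(utils::tail(fit$best_trace, 5)))
  if (!is.null(dataset$true_partition)) {
    acc <- clustering_accuracy(dataset$true_partition, fit$partition)
    result$m_accuracy <- acc$m_accuracy
    log("stage evaluate: M_accuracy = %.4f", acc$m_accuracy)
  }
  jsonlite::write_json(result, file.path(out_dir, "result.json"),
                       auto_unbox = TRUE, digits = NA)
  log("done")
  invisible(out_dir)
}
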