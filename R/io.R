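#' Write a directed score matrix as delimited text
#'
#' Regulators as rows, targets as columns; a comment header line records
#' the method, lag order, and shrinkage intensity so the file is
#' self-describing.
#'
#' @param scores a `"dpc_scores"` object.
#' @param path output file.
#' @param what `"p"` (raw p-values, default), `"adjusted"`, or
#'   `"statistic"`.
#' @export
write_scores <- function(scores, path, what = c("p", "adjusted", "statistic")) {
  what <- match.arg(what)
  if (!inherits(scores, "dpc_scores")) stop("expected a dpc_scores object")
  mat <- switch(what, p = scores$pvalues, adjusted = scores$adjusted,
                statistic = scores$statistic)
  if (is.null(mat)) stop("scores do not contain a '", what, "' matrix")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# method=", scores$method,
                    " q=", scores$q %||% "NA",
                    " lambda=", signif(scores$lambda %||% NA_real_, 8),
                    " matrix=", what), con)
  df <- data.frame(regulator = rownames(mat), mat, check.names = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a directed edge list
#'
#' Three tab-separated columns (regulator, target, adjusted_p) with a
#' header, in the deterministic order produced by [fdr_adjust()].
#'
#' @param edges data.frame from [fdr_adjust()] (or a `"dpc_scores"` /
#'   `"dpcnet"` object carrying one).
#' @param path output file.
#' @export
write_edges <- function(edges, path) {
  if (inherits(edges, "dpcnet")) edges <- edges$scores$edges
  if (inherits(edges, "dpc_scores")) edges <- edges$edges
  if (is.null(edges)) stop("no edge list present; run fdr_adjust() first")
  utils::write.table(edges[, c("regulator", "target", "adjusted_p")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a truth network as an edge list
#' @param net a `"directed_network"`.
#' @param path output file.
#' @export
write_truth <- function(net, path) {
  idx <- which(net$adjacency > 0, arr.ind = TRUE)
  df <- data.frame(regulator = net$gene_names[idx[, 1L]],
                   target = net$gene_names[idx[, 2L]])
  df <- df[order(df$regulator, df$target), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a truth network edge list over a known gene set
#' @param path edge-list file (columns regulator, target).
#' @param gene_names the full gene set of the network.
#' @return a `"directed_network"`.
#' @export
read_truth <- function(path, gene_names) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  adj <- matrix(0L, length(gene_names), length(gene_names),
                dimnames = list(gene_names, gene_names))
  ri <- match(df$regulator, gene_names)
  ci <- match(df$target, gene_names)
  if (anyNA(ri) || anyNA(ci))
    stop("edge list names genes outside the provided gene set")
  adj[cbind(ri, ci)] <- 1L
  directed_network(adj, gene_names)
}

#' Write a benchmark suite to a directory tree
#'
#' One subdirectory per dataset containing `expression.tsv`,
#' `truth_edges.tsv`, and `meta.txt` (flat key-value text: seeds,
#' dimensions, perturbation).
#'
#' @param suite list from [make_benchmark_suite()].
#' @param dir output directory (created if needed).
#' @export
write_suite <- function(suite, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ds in suite) {
    d <- file.path(dir, ds$meta$dataset_id)
    dir.create(d, showWarnings = FALSE)
    write_expression(ds$expression, file.path(d, "expression.tsv"))
    write_truth(ds$truth, file.path(d, "truth_edges.tsv"))
    meta <- ds$meta
    meta$targets <- paste(meta$targets, collapse = ",")
    writeLines(paste0(names(meta), "=", unlist(meta)),
               file.path(d, "meta.txt"))
  }
  invisible(dir)
}

#' Run a full inference pass and write its artifacts
#'
#' Thin reproducible wrapper over [dpcnet()]: checks method preconditions
#' up front (notably the GC-VAR sample-size rule), fixes the seed, fits,
#' and writes the raw score matrix, the BH-adjusted matrix, the edge list
#' at the requested FDR level, and a plain-text log recording method, lag,
#' shrinkage intensity, seed, and package version.
#'
#' @param x expression matrix or path to an expression table.
#' @param out_dir output directory.
#' @param method,q,fdr see [dpcnet()].
#' @param seed RNG seed recorded in the log (the estimators themselves are
#'   deterministic).
#' @return the `"dpcnet"` fit, invisibly.
#' @export
run_infer <- function(x, out_dir, method = "dpc", q = 1L, fdr = 0.05,
                      seed = 1L) {
  if (is.character(x) && length(x) == 1L) x <- read_expression(x)
  x <- validate_expression(x)
  if (method == "gcvar" && ncol(x) - 1L <= nrow(x) + 1L)
    stop("GC-VAR requires m - 1 > p + 1 (here p = ", nrow(x), ", m = ",
         ncol(x), "); it can only be applied to long time series")
  set.seed(seed)
  fit <- dpcnet(x, method = method, q = q, fdr = fdr)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_scores(fit$scores, file.path(out_dir, "scores_raw.tsv"), "p")
  write_scores(fit$scores, file.path(out_dir, "scores_adjusted.tsv"),
               "adjusted")
  write_edges(fit, file.path(out_dir, "edges.tsv"))
  writeLines(c(paste0("method=", method), paste0("q=", q),
               paste0("fdr=", fdr), paste0("seed=", seed),
               paste0("lambda=", fit$scores$lambda %||% NA),
               paste0("genes=", length(fit$scores$genes)),
               paste0("dpcnet_version=",
                      as.character(utils::packageVersion("dpcnet"))),
               paste0("r_version=", R.version.string)),
             file.path(out_dir, "run_log.txt"))
  invisible(fit)
}
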