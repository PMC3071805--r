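# Strength matrix for ranking: larger = stronger evidence, orientation
# carried by the method tag so the evaluator never guesses.
edge_strength <- function(scores) {
  if (inherits(scores, "dpc_scores")) {
    if (scores$method == "GCVAR") scores$statistic else -scores$pvalues
  } else if (is.matrix(scores)) {
    scores
  } else stop("expected a dpc_scores object or a strength matrix")
}

#' ROC evaluation of a directed score matrix against a known network
#'
#' Ranks all candidate edges by score strength (p-values: smaller is
#' stronger; variance-ratio scores: larger is stronger) and computes the
#' ROC curve over all unique thresholds, the area under it by the midrank
#' (Mann-Whitney) formulation, the maximum F-score (balanced harmonic mean
#' of precision and recall) over the sweep, and the true positive rate at
#' a 0.2 false positive rate by linear interpolation. Autoregulatory
#' self-edges are excluded by default.
#'
#' @param scores a `"dpc_scores"` object (or a strength matrix, larger =
#'   stronger) over the same genes as `truth`.
#' @param truth a `"directed_network"` ground truth.
#' @param exclude_diagonal drop self-edges from the evaluation
#'   (default TRUE).
#' @return object of class `"roc_result"`: `thresholds`, `tpr`, `fpr`,
#'   `auc`, `max_f`, `tpr_at_fpr02`, `n_pos`, `n_neg`.
#' @export
roc_evaluate <- function(scores, truth, exclude_diagonal = TRUE) {
  if (!inherits(truth, "directed_network"))
    stop("truth must be a directed_network")
  s <- edge_strength(scores)
  if (inherits(scores, "dpc_scores")) {
    if (!identical(scores$genes, truth$gene_names))
      stop("gene sets of scores and truth do not match")
  } else if (!all(dim(s) == dim(truth$adjacency)))
    stop("score matrix and truth dimensions do not match")
  keep <- if (exclude_diagonal) row(s) != col(s) else
    matrix(TRUE, nrow(s), ncol(s))
  keep <- keep & !is.na(s)
  sv <- s[keep]
  lab <- truth$adjacency[keep] > 0
  n_pos <- sum(lab); n_neg <- sum(!lab)
  if (n_pos == 0L || n_neg == 0L)
    stop("truth must contain at least one edge and one non-edge")
  # midrank (Mann-Whitney) AUC
  rk <- rank(sv)
  auc <- (sum(rk[lab]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  # threshold sweep over unique scores, strongest first
  ord <- order(sv, decreasing = TRUE)
  svo <- sv[ord]; labo <- lab[ord]
  cum_tp <- cumsum(labo); cum_fp <- cumsum(!labo)
  last <- cumsum(rle(svo)$lengths)             # last index of each tie block
  tp <- c(0, cum_tp[last]); fp <- c(0, cum_fp[last])
  tpr <- tp / n_pos; fpr <- fp / n_neg
  thresholds <- c(Inf, svo[last])
  precision <- ifelse(tp + fp == 0, 1, tp / (tp + fp))
  f <- ifelse(tp == 0, 0, 2 * precision * tpr / (precision + tpr))
  tpr02 <- stats::approx(fpr, tpr, xout = 0.2, ties = "ordered")$y
  structure(list(thresholds = thresholds, tpr = tpr, fpr = fpr,
                 auc = auc, max_f = max(f), tpr_at_fpr02 = tpr02,
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("ROC evaluation:", x$n_pos, "true edges,", x$n_neg, "non-edges\n")
  cat(sprintf("  AUC = %.4f  max F = %.4f  TPR@FPR0.2 = %.4f\n",
              x$auc, x$max_f, x$tpr_at_fpr02))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  plot(x$fpr, x$tpr, type = "l", xlab = "False positive rate",
       ylab = "True positive rate", xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  graphics::legend("bottomright", bty = "n",
                   legend = sprintf("AUC = %.3f", x$auc))
  invisible(x)
}

#' Welch two-sample test (unequal variances, Satterthwaite df)
#'
#' @param x,y numeric samples.
#' @param alternative `"greater"` (mean of `x` greater, default),
#'   `"less"`, or `"two.sided"`.
#' @return list with `t`, `df`, `p`.
#' @export
welch_test <- function(x, y, alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  ht <- stats::t.test(x, y, alternative = alternative, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Hub validation: do known regulators carry heavier score rows?
#'
#' A gene's row of the score matrix holds the evidence for that gene
#' regulating every other gene, so its row sum is proportional to the
#' probability of the gene being a regulator. Known regulators' row sums
#' are compared against all genes' row sums with a Welch unequal-variance
#' t-test (Satterthwaite degrees of freedom), one-sided for "regulators
#' greater". P-values are mapped to strengths via 1 - p before summing;
#' variance-ratio scores are summed as-is.
#'
#' @param scores a `"dpc_scores"` object.
#' @param regulators gene names or indices of known regulators (nonempty,
#'   strict subset of the genes).
#' @param exclude_diagonal drop self-scores from the row sums
#'   (default TRUE).
#' @return list with `t`, `df`, `p` (one-sided), and `strength` (the
#'   per-gene row sums).
#' @export
hub_welch_test <- function(scores, regulators, exclude_diagonal = TRUE) {
  if (!inherits(scores, "dpc_scores")) stop("expected a dpc_scores object")
  genes <- scores$genes
  if (is.character(regulators)) regulators <- match(regulators, genes)
  regulators <- unique(as.integer(regulators))
  if (length(regulators) == 0L || anyNA(regulators) ||
      any(regulators < 1L) || any(regulators > length(genes)))
    stop("regulators must be a nonempty set of valid gene indices or names")
  if (length(regulators) >= length(genes))
    stop("regulators must be a strict subset of the genes")
  s <- if (scores$method == "GCVAR") scores$statistic else 1 - scores$pvalues
  if (exclude_diagonal) diag(s) <- 0
  strength <- rowSums(s, na.rm = TRUE)
  res <- welch_test(strength[regulators], strength, alternative = "greater")
  res$strength <- stats::setNames(strength, genes)
  res
}

#' Run inference methods across a benchmark suite
#'
#' Applies each requested method to every dataset of a suite from
#' [make_benchmark_suite()], evaluates against the dataset's ground truth,
#' and tabulates AUC, maximum F-score, TPR at FPR 0.2, and wall time.
#' GC-VAR is recorded as not applicable (NA metrics) on datasets that fail
#' its sample-size precondition m - 1 > p + 1 rather than silently
#' dropped; if a method is inapplicable on every dataset that is reported
#' in the `"inapplicable"` attribute.
#'
#' @param suite list of datasets from [make_benchmark_suite()].
#' @param methods subset of `c("dpc", "dpc0", "svar", "gcvar")`.
#' @param q lag order for the DPC(q) method.
#' @return data.frame with one row per (dataset, method):
#'   dataset_id, method, p, m, perturbation, auc, max_f, tpr_at_fpr02,
#'   seconds, seed.
#' @export
benchmark_harness <- function(suite, methods = c("dpc", "svar"), q = 1L) {
  if (length(suite) == 0L) stop("benchmark suite is empty")
  methods <- match.arg(methods, c("dpc", "dpc0", "svar", "gcvar"),
                       several.ok = TRUE)
  rows <- list()
  applicable <- stats::setNames(logical(length(methods)), methods)
  for (ds in suite) {
    p <- ds$meta$p; m <- ds$meta$m
    for (method in methods) {
      t0 <- proc.time()[["elapsed"]]
      sc <- switch(method,
        dpc = dpcq_scores(ds$expression, q = q),
        dpc0 = dpc0_scores(ds$expression),
        svar = svar_scores(ds$expression),
        gcvar = if (m - 1L > p + 1L) gcvar_scores(ds$expression) else NULL)
      if (is.null(sc)) {
        rows[[length(rows) + 1L]] <- data.frame(
          dataset_id = ds$meta$dataset_id, method = method, p = p, m = m,
          perturbation = ds$meta$perturbation, auc = NA_real_,
          max_f = NA_real_, tpr_at_fpr02 = NA_real_, seconds = NA_real_,
          seed = ds$meta$seed, stringsAsFactors = FALSE)
        next
      }
      applicable[method] <- TRUE
      ev <- roc_evaluate(sc, ds$truth)
      rows[[length(rows) + 1L]] <- data.frame(
        dataset_id = ds$meta$dataset_id, method = method, p = p, m = m,
        perturbation = ds$meta$perturbation, auc = ev$auc, max_f = ev$max_f,
        tpr_at_fpr02 = ev$tpr_at_fpr02,
        seconds = proc.time()[["elapsed"]] - t0, seed = ds$meta$seed,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (any(!applicable))
    attr(out, "inapplicable") <- names(applicable)[!applicable]
  out
}
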