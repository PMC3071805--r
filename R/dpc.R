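#' Paired t-test p-value for two groups of coefficients
#'
#' The DPC edge score is the p-value of a paired t-test comparing a
#' target's partial-correlation profile before and after removing a
#' candidate regulator from the conditioning set. Degenerate cases follow
#' a fixed convention so scores are never missing: zero-variance
#' differences with zero mean give p = 1 (no change at all), zero-variance
#' differences with nonzero mean give p = 0 (a uniform, hence maximally
#' consistent, shift).
#'
#' @param before,after equal-length numeric vectors (length >= 2) of
#'   paired coefficients.
#' @param sided `"two"` (default) or `"one"` (alternative: mean difference
#'   greater than zero).
#' @return p-value in [0, 1].
#' @export
paired_t_pvalue <- function(before, after, sided = c("two", "one")) {
  sided <- match.arg(sided)
  if (length(before) != length(after))
    stop("paired groups must have equal length")
  k <- length(before)
  if (k < 2L) stop("paired groups need length >= 2, got ", k)
  d <- before - after
  md <- mean(d)
  sdd <- stats::sd(d)
  # degenerate conventions (exact, so tiny genuine differences still count):
  # no change at all -> 1; an exactly uniform shift -> 0
  if (sdd == 0) {
    if (md == 0) return(1)
    if (sided == "two") return(0)
    return(if (md > 0) 0 else 1)
  }
  tval <- md / (sdd / sqrt(k))
  if (sided == "two") 2 * stats::pt(-abs(tval), df = k - 1L)
  else stats::pt(tval, df = k - 1L, lower.tail = FALSE)
}

# Internal constructor for a directed score matrix. Row = candidate
# regulator, column = target; diagonal is the sentinel 1 (p-values) / 0
# (variance ratios) and excluded from testing.
.new_scores <- function(pvalues, method, genes, q = NULL, lambda = NULL,
                        statistic = NULL, n_used = NULL) {
  dimnames(pvalues) <- list(genes, genes)
  if (!is.null(statistic)) dimnames(statistic) <- list(genes, genes)
  structure(list(pvalues = pvalues, statistic = statistic, method = method,
                 q = q, lambda = lambda, genes = genes, n_used = n_used,
                 adjusted = NULL),
            class = "dpc_scores")
}

#' @export
print.dpc_scores <- function(x, ...) {
  p <- length(x$genes)
  cat("Directed edge scores (", x$method, "): ", p, " genes, ",
      p * (p - 1L), " candidate edges\n", sep = "")
  if (!is.null(x$q)) cat("  lag order q =", x$q, "\n")
  if (!is.null(x$lambda))
    cat("  shrinkage intensity lambda =", signif(x$lambda, 4), "\n")
  off <- x$pvalues[row(x$pvalues) != col(x$pvalues)]
  cat("  raw p-values: min", signif(min(off), 3),
      "median", signif(stats::median(off), 3), "\n")
  invisible(x)
}

# Drop zero-variance genes (flagged by standardize_expression) before
# estimation; scores for them are reported as missing by the callers.
.prepare_expression <- function(x, standardize = TRUE) {
  x <- validate_expression(x)
  if (standardize) x <- standardize_expression(x)
  flat <- attr(x, "zero_variance")
  if (is.null(flat)) {
    sds <- apply(x, 1L, stats::sd)
    flat <- stats::setNames(sds < .Machine$double.eps^0.5, rownames(x))
  }
  list(x = x[!flat, , drop = FALSE], dropped = names(flat)[flat],
       genes = names(flat))
}

# Re-embed a score matrix over the retained genes into the full gene set,
# NA rows/columns for dropped genes.
.embed_scores <- function(mat, kept, genes, diag_value = 1) {
  if (length(kept) == length(genes)) return(mat)
  full <- matrix(NA_real_, length(genes), length(genes),
                 dimnames = list(genes, genes))
  full[kept, kept] <- mat
  diag(full) <- diag_value
  full
}

#' Zero-order directed partial correlation scores
#'
#' For each ordered gene pair (j -> i), compares the target i's row of the
#' full partial-correlation matrix (coefficients linking i to every other
#' gene k, k != i, j) against the same coefficients recomputed with gene j
#' deleted from the conditioning set. A regulator whose removal reshapes
#' many of those conditional dependencies yields a small paired-t p-value.
#' Both groups have length p - 2, so at least 4 genes are required.
#'
#' @param x expression matrix (p genes x m time points), p >= 4.
#' @param standardize standardize genes first (default TRUE).
#' @param lambda optional fixed shrinkage intensity.
#' @param sided sidedness of the paired t-test, see [paired_t_pvalue()].
#' @param use_abs compare absolute coefficient magnitudes (default TRUE):
#'   removing a true regulator systematically inflates the magnitude of the
#'   target's remaining conditional dependencies, a shift the signed
#'   comparison cancels out; set FALSE to compare signed coefficients.
#' @return a `"dpc_scores"` object; `pvalues[j, i]` is the evidence that
#'   gene j influences gene i (diagonal sentinel 1).
#' @export
dpc0_scores <- function(x, standardize = TRUE, lambda = NULL,
                        sided = c("two", "one"), use_abs = TRUE) {
  sided <- match.arg(sided)
  prep <- .prepare_expression(x, standardize)
  xs <- prep$x
  p <- nrow(xs)
  if (p < 4L)
    stop("DPC(0) needs at least 4 (non-constant) genes, got ", p)
  C <- shrinkage_covariance(xs, lambda = lambda)
  omega <- partial_correlation(C)
  P <- attr(omega, "precision")
  pv <- matrix(1, p, p)
  for (j in seq_len(p)) {
    om_j <- delete_variable_partial_correlation(C, j, precision = P)
    # row index map: variables after deleting j
    keep <- setdiff(seq_len(p), j)
    for (i in keep) {
      ks <- setdiff(seq_len(p), c(i, j))
      before <- omega[i, ks]
      after <- om_j[match(i, keep), match(ks, keep)]
      if (use_abs) { before <- abs(before); after <- abs(after) }
      pv[j, i] <- paired_t_pvalue(before, after, sided)
    }
  }
  pv <- .embed_scores(pv, rownames(xs), prep$genes)
  .new_scores(pv, "DPC0", prep$genes, q = 0L, lambda = C$lambda, n_used = C$n)
}

# Shared joint-matrix partial correlation for DPC(q) and SVAR: build the
# lag-q joint state matrix, estimate the shrinkage covariance, return the
# partial-correlation matrix with its precision and bookkeeping attached.
joint_partial_correlation <- function(x, q = 1L, lambda = NULL) {
  z <- build_joint_matrix(x, q)
  C <- shrinkage_covariance(z, lambda = lambda)
  omega <- partial_correlation(C)
  list(omega = omega, C = C, p = attr(z, "p"), q = attr(z, "lag_order"),
       n = ncol(z))
}

#' Lagged directed partial correlation scores
#'
#' DPC(q): present and past states are stacked into a joint matrix so that
#' the past -> present cross-block of its partial-correlation matrix
#' carries the lagged conditional dependencies. For each ordered pair
#' (j -> i), the coefficients linking present-of-i to every past variable
#' (except past-of-j) are compared, by paired t-test, before and after the
#' past copies of gene j are deleted from the joint matrix. Only the
#' past -> present sub-block is ever read. By default only the PAST copy
#' of the candidate regulator is removed (its present copy stays in the
#' conditioning set), mirroring how Granger-style arguments remove "the
#' past of" a predictor; the autoregressive term past-of-i is kept in both
#' groups.
#'
#' @param x expression matrix (p genes x m time points).
#' @param q lag order, `1 <= q <= m - 2`.
#' @param standardize standardize genes first (default TRUE).
#' @param lambda optional fixed shrinkage intensity.
#' @param sided sidedness of the paired t-test.
#' @param use_abs compare absolute coefficient magnitudes (default TRUE);
#'   see [dpc0_scores()].
#' @param delete which copies of the candidate regulator to delete:
#'   `"past"` (default) or `"both"` (past and present).
#' @param keep_autoregressive keep the target's own past (the
#'   autoregressive coefficient) in the compared groups (default TRUE).
#' @return a `"dpc_scores"` object with `pvalues[j, i]` the evidence that
#'   gene j influences gene i.
#' @export
dpcq_scores <- function(x, q = 1L, standardize = TRUE, lambda = NULL,
                        sided = c("two", "one"), use_abs = TRUE,
                        delete = c("past", "both"),
                        keep_autoregressive = TRUE) {
  sided <- match.arg(sided)
  delete <- match.arg(delete)
  q <- as.integer(q)
  prep <- .prepare_expression(x, standardize)
  xs <- prep$x
  p <- nrow(xs); m <- ncol(xs)
  if (q < 1L || q > m - 2L)
    stop("lag order q must satisfy 1 <= q <= m - 2 (q = ", q, ", m = ", m, ")")
  group_len <- q * (p - 1L) - (if (keep_autoregressive) 0L else q)
  if (group_len < 2L)
    stop("paired groups would have length ", group_len,
         "; need more genes for this q")
  jp <- joint_partial_correlation(xs, q = q, lambda = lambda)
  omega <- jp$omega
  P <- attr(omega, "precision")
  pp <- (q + 1L) * p
  past_of <- function(g) p * (1:q) + g      # joint-row indices of gene g's past
  all_past <- (p + 1L):pp
  pv <- matrix(1, p, p)
  for (j in seq_len(p)) {
    del <- if (delete == "past") past_of(j) else c(j, past_of(j))
    om_j <- delete_variable_partial_correlation(jp$C, del, precision = P)
    keep <- setdiff(seq_len(pp), del)
    cols_j <- setdiff(all_past, past_of(j))
    for (i in seq_len(p)) {
      if (i == j) next
      cols <- if (keep_autoregressive) cols_j else setdiff(cols_j, past_of(i))
      before <- omega[i, cols]
      after <- om_j[match(i, keep), match(cols, keep)]
      if (use_abs) { before <- abs(before); after <- abs(after) }
      pv[j, i] <- paired_t_pvalue(before, after, sided)
    }
  }
  pv <- .embed_scores(pv, rownames(xs), prep$genes)
  .new_scores(pv, "DPCq", prep$genes, q = q, lambda = jp$C$lambda,
              n_used = jp$n)
}

#' Benjamini-Hochberg edge selection on a directed score matrix
#'
#' Adjusts the p x p off-diagonal p-values by the Benjamini-Hochberg
#' step-up procedure (the diagonal, i.e. autoregulation, is excluded from
#' testing by default) and returns the edges significant at the requested
#' false discovery rate, deterministically ordered by adjusted p, then raw
#' p, then (regulator, target) lexical order.
#'
#' @param scores a `"dpc_scores"` object with p-values.
#' @param level FDR level alpha in (0, 1).
#' @param include_diagonal also test autoregulatory self-edges.
#' @return the input object with `adjusted` (matrix of BH-adjusted
#'   p-values) and `edges` (data.frame: regulator, target, p, adjusted_p)
#'   filled in.
#' @export
fdr_adjust <- function(scores, level = 0.05, include_diagonal = FALSE) {
  if (!inherits(scores, "dpc_scores")) stop("expected a dpc_scores object")
  if (!is.finite(level) || level <= 0 || level >= 1)
    stop("FDR level must lie in (0, 1)")
  pm <- scores$pvalues
  off <- if (include_diagonal) matrix(TRUE, nrow(pm), ncol(pm))
         else row(pm) != col(pm)
  off <- off & !is.na(pm)
  adj <- matrix(NA_real_, nrow(pm), ncol(pm), dimnames = dimnames(pm))
  adj[off] <- stats::p.adjust(pm[off], method = "BH")
  if (!include_diagonal) diag(adj) <- 1
  idx <- which(off & adj <= level, arr.ind = TRUE)
  edges <- data.frame(regulator = scores$genes[idx[, 1L]],
                      target = scores$genes[idx[, 2L]],
                      p = pm[idx], adjusted_p = adj[idx],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$adjusted_p, edges$p, edges$regulator,
                       edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  scores$adjusted <- adj
  scores$edges <- edges
  scores$fdr_level <- level
  scores
}
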