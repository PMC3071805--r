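#' Fit a directed gene regulatory network model
#'
#' The main entry point: infers directed edge scores from a gene
#' expression time series with one of four methods, adjusts them for
#' multiple testing, and returns a fitted-model object.
#'
#' Methods:
#' \describe{
#'   \item{`"dpc"`}{lagged directed partial correlation DPC(q) — scores a
#'     regulator by how strongly deleting its past state reshapes the
#'     target's lagged partial-correlation profile (paired t-test on
#'     shrinkage partial correlations); the default, suited to short
#'     series with many genes.}
#'   \item{`"dpc0"`}{zero-order DPC — same comparison on the
#'     contemporaneous partial-correlation matrix.}
#'   \item{`"svar"`}{shrinkage-VAR — tests the past-to-present cross-block
#'     partial correlations of the lag-1 joint matrix directly.}
#'   \item{`"gcvar"`}{Granger-causality VAR — log residual-variance ratio
#'     of nested least-squares VAR(1) fits; needs m - 1 > p + 1.}
#' }
#'
#' @param x expression matrix (p genes x m time points), a data.frame
#'   coercible to one, or a path to a delimited expression table.
#' @param method inference method (see Details).
#' @param q lag order for `"dpc"` (default 1, appropriate for short
#'   microarray series).
#' @param fdr false discovery rate for edge selection (default 0.05).
#' @param standardize per-gene standardization before estimation.
#' @param ... passed to the method-specific scoring function.
#' @return object of class `"dpcnet"`: the `"dpc_scores"` object in
#'   `$scores` (with BH-adjusted p-values and the significant edge list
#'   filled in), plus `method`, `fdr`, and the matched `call`.
#' @seealso [dpcq_scores()], [dpc0_scores()], [svar_scores()],
#'   [gcvar_scores()], [fdr_adjust()], [roc_evaluate()]
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(8 * 30), 8, 30,
#'             dimnames = list(paste0("g", 1:8), NULL))
#' x[2, -1] <- 0.8 * x[1, -30] + 0.3 * rnorm(29)  # g1 regulates g2
#' fit <- dpcnet(x, method = "dpc", q = 1)
#' fit
#' head(summary(fit)$edges)
#' @export
dpcnet <- function(x, method = c("dpc", "dpc0", "svar", "gcvar"), q = 1L,
                   fdr = 0.05, standardize = TRUE, ...) {
  method <- match.arg(method)
  if (is.character(x) && length(x) == 1L) x <- read_expression(x)
  if (is.data.frame(x)) x <- as.matrix(x)
  scores <- switch(method,
    dpc = dpcq_scores(x, q = q, standardize = standardize, ...),
    dpc0 = dpc0_scores(x, standardize = standardize, ...),
    svar = svar_scores(x, standardize = standardize, ...),
    gcvar = gcvar_scores(x, standardize = standardize, ...))
  scores <- fdr_adjust(scores, level = fdr)
  structure(list(scores = scores, method = method, fdr = fdr,
                 call = match.call()),
            class = "dpcnet")
}

#' @export
print.dpcnet <- function(x, ...) {
  cat("Directed network inference fit\n")
  cat("  method:", x$scores$method,
      if (!is.null(x$scores$q)) paste0("(q = ", x$scores$q, ")"), "\n")
  cat("  genes:", length(x$scores$genes),
      " time points used:", x$scores$n_used, "\n")
  if (!is.null(x$scores$lambda))
    cat("  shrinkage intensity lambda:", signif(x$scores$lambda, 4), "\n")
  cat("  edges at FDR", x$fdr, ":", nrow(x$scores$edges), "\n")
  invisible(x)
}

#' @export
summary.dpcnet <- function(object, n = 10L, ...) {
  s <- object$scores
  off <- s$pvalues[row(s$pvalues) != col(s$pvalues)]
  structure(list(method = s$method, q = s$q, lambda = s$lambda,
                 n_genes = length(s$genes), n_used = s$n_used,
                 fdr = object$fdr, n_edges = nrow(s$edges),
                 edges = s$edges,
                 p_quantiles = stats::quantile(off, c(0, .25, .5, .75, 1),
                                               na.rm = TRUE),
                 n_show = n),
            class = "summary.dpcnet")
}

#' @export
print.summary.dpcnet <- function(x, ...) {
  cat("Method:", x$method, if (!is.null(x$q)) paste0("(q = ", x$q, ")"), "\n")
  cat("Genes:", x$n_genes, " samples used:", x$n_used, "\n")
  if (!is.null(x$lambda))
    cat("Shrinkage intensity:", signif(x$lambda, 4), "\n")
  cat("Raw p-value quantiles:\n")
  print(signif(x$p_quantiles, 3))
  cat("Significant edges at FDR ", x$fdr, ": ", x$n_edges, "\n", sep = "")
  if (x$n_edges > 0L) {
    cat("Top edges:\n")
    print(utils::head(x$edges, x$n_show), row.names = FALSE)
  }
  invisible(x)
}

#' Extract the directed score matrix from a fit
#'
#' @param object a `"dpcnet"` fit.
#' @param type `"p"` for raw p-values (default), `"adjusted"` for
#'   BH-adjusted p-values, `"statistic"` for the method's coefficient or
#'   variance-ratio matrix where available.
#' @param ... unused.
#' @return p x p matrix, regulator rows by target columns.
#' @export
coef.dpcnet <- function(object, type = c("p", "adjusted", "statistic"), ...) {
  type <- match.arg(type)
  switch(type,
         p = object$scores$pvalues,
         adjusted = object$scores$adjusted,
         statistic = object$scores$statistic %||%
           stop("method ", object$scores$method,
                " has no statistic matrix; use type = \"p\""))
}

#' Plot a fitted directed network model
#'
#' Without a ground-truth network, shows the histogram of raw off-diagonal
#' p-values (a well-calibrated null is flat; signal piles up near zero).
#' With `truth`, draws the ROC curve against it instead.
#'
#' @param x a `"dpcnet"` fit.
#' @param truth optional `"directed_network"` ground truth.
#' @param ... passed to the underlying plot.
#' @export
plot.dpcnet <- function(x, truth = NULL, ...) {
  if (!is.null(truth)) {
    return(plot(roc_evaluate(x$scores, truth), ...))
  }
  pm <- x$scores$pvalues
  off <- pm[row(pm) != col(pm)]
  graphics::hist(off, breaks = 20, main = paste(x$scores$method, "raw p-values"),
                 xlab = "p-value", ...)
  invisible(x)
}
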