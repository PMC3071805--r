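#' Ordinary least squares fit of a first-order vector autoregression
#'
#' Regresses each gene's present value X_i(t) on the past values of all
#' genes (optionally excluding one predictor) plus an intercept, over the
#' m - 1 usable transitions. Residual variance is the residual sum of
#' squares divided by (n_used - #predictors - 1), the intercept costing
#' one degree of freedom.
#'
#' @param x expression matrix (p genes x m time points).
#' @param exclude optional predictor (gene index or name) whose past is
#'   left out of every regression.
#' @return object of class `"var_fit"`: `coefficients` (p x #predictors,
#'   row i = equation for gene i), `intercepts`, `residual_variances`,
#'   `rss`, `n_used`, `predictors`.
#' @export
fit_var1_ols <- function(x, exclude = NULL) {
  x <- validate_expression(x)
  p <- nrow(x); m <- ncol(x)
  if (is.character(exclude)) exclude <- match(exclude, rownames(x))
  if (!is.null(exclude)) {
    exclude <- as.integer(exclude)
    if (length(exclude) != 1L || is.na(exclude) || exclude < 1L || exclude > p)
      stop("excluded predictor index out of range")
  }
  n <- m - 1L
  k <- if (is.null(exclude)) p else p - 1L
  if (n <= k + 1L)
    stop("VAR(1) least squares needs m - 1 > #predictors + 1 ",
         "(m = ", m, ", predictors = ", k, "); ",
         "this method can only be applied to long time series")
  pred_rows <- if (is.null(exclude)) seq_len(p) else setdiff(seq_len(p), exclude)
  design <- cbind(1, t(x[pred_rows, 1L:(m - 1L), drop = FALSE]))
  response <- t(x[, 2L:m, drop = FALSE])
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design))
    stop("rank-deficient design matrix: VAR(1) OLS requires m - 1 > ",
         "#predictors + 1 with linearly independent predictors")
  beta <- qr.coef(qr_d, response)              # (k+1) x p
  resid <- qr.resid(qr_d, response)            # n x p
  rss <- colSums(resid^2)
  sigma2 <- rss / (n - k - 1L)
  coefs <- t(beta[-1L, , drop = FALSE])        # p targets x k predictors
  dimnames(coefs) <- list(rownames(x), rownames(x)[pred_rows])
  structure(list(coefficients = coefs,
                 intercepts = stats::setNames(beta[1L, ], rownames(x)),
                 residual_variances = stats::setNames(sigma2, rownames(x)),
                 rss = stats::setNames(rss, rownames(x)),
                 n_used = n, predictors = rownames(x)[pred_rows],
                 excluded = if (is.null(exclude)) NULL else rownames(x)[exclude]),
            class = "var_fit")
}

#' @export
print.var_fit <- function(x, ...) {
  cat("VAR(1) OLS fit:", nrow(x$coefficients), "targets,",
      length(x$predictors), "predictors,", x$n_used, "transitions\n")
  if (!is.null(x$excluded)) cat("  excluded predictor:", x$excluded, "\n")
  invisible(x)
}

#' Granger-causality scores from nested VAR(1) fits
#'
#' The predictive power of gene j for gene i is the log ratio of gene i's
#' residual variance without j's past in the model to its residual
#' variance with it (clamped below at zero): if adding j's past improves
#' the forecast of i, the ratio exceeds one. A companion p-value comes
#' from the nested-model F-test on (1, n_used - p - 1) degrees of freedom.
#' Requires long series (m - 1 > p + 1) because the full model regresses
#' on every gene's past.
#'
#' @param x expression matrix (p genes x m time points).
#' @param standardize standardize genes first (default TRUE).
#' @return `"dpc_scores"` object, method `"GCVAR"`: `statistic[j, i]` is
#'   the nonnegative log variance ratio (larger = stronger evidence that j
#'   influences i; diagonal 0), `pvalues[j, i]` the F-test p-value
#'   (diagonal 1).
#' @export
gcvar_scores <- function(x, standardize = TRUE) {
  prep <- .prepare_expression(x, standardize)
  xs <- prep$x
  p <- nrow(xs); m <- ncol(xs)
  full <- fit_var1_ols(xs)                     # errors out if m too short
  n <- full$n_used
  df2 <- n - p - 1L
  score <- matrix(0, p, p)
  pv <- matrix(1, p, p)
  for (j in seq_len(p)) {
    red <- fit_var1_ols(xs, exclude = j)
    for (i in seq_len(p)) {
      if (i == j) next
      score[j, i] <- max(0, log(red$residual_variances[i] /
                                full$residual_variances[i]))
      fstat <- (red$rss[i] - full$rss[i]) / (full$rss[i] / df2)
      pv[j, i] <- stats::pf(max(0, fstat), 1L, df2, lower.tail = FALSE)
    }
  }
  pv <- .embed_scores(pv, rownames(xs), prep$genes)
  stat <- .embed_scores(score, rownames(xs), prep$genes, diag_value = 0)
  out <- .new_scores(pv, "GCVAR", prep$genes, q = 1L, n_used = n,
                     statistic = stat)
  out
}

#' Shrinkage-VAR directed coefficient scores
#'
#' Reads the past -> present cross-block of the lag-1 joint
#' partial-correlation matrix (estimated with the same shrinkage
#' covariance DPC uses) as the directed coefficient from each gene's past
#' to each target's present, and converts each coefficient to a p-value
#' through the Fisher z-transform with effective sample size m - 1.
#'
#' @param x expression matrix (p genes x m time points), m >= 5.
#' @param standardize standardize genes first (default TRUE).
#' @param lambda optional fixed shrinkage intensity.
#' @param joint optional precomputed result of the internal lag-1 joint
#'   partial-correlation step, so SVAR and DPC(1) can share it.
#' @return `"dpc_scores"` object, method `"SVAR"`: `statistic[j, i]` is
#'   the signed cross-block partial correlation (diagonal 0),
#'   `pvalues[j, i]` its Fisher-z p-value (diagonal 1).
#' @export
svar_scores <- function(x, standardize = TRUE, lambda = NULL, joint = NULL) {
  prep <- .prepare_expression(x, standardize)
  xs <- prep$x
  p <- nrow(xs); m <- ncol(xs)
  if (m < 5L)
    stop("SVAR needs at least 5 time points for the Fisher-z test, got ", m)
  jp <- if (is.null(joint)) joint_partial_correlation(xs, q = 1L, lambda = lambda)
        else joint
  omega <- jp$omega
  # cross-block: rows = present of target i, columns = past of regulator j
  cross <- omega[seq_len(p), p + seq_len(p), drop = FALSE]
  coefm <- t(cross)                            # [j, i] = past-j -> present-i
  n_eff <- m - 1L
  z <- atanh(pmin(pmax(coefm, -1 + 1e-15), 1 - 1e-15)) * sqrt(n_eff - 3L)
  pv <- 2 * stats::pnorm(-abs(z))
  diag(pv) <- 1
  diag(coefm) <- 0
  pv <- .embed_scores(pv, rownames(xs), prep$genes)
  stat <- .embed_scores(coefm, rownames(xs), prep$genes, diag_value = 0)
  .new_scores(pv, "SVAR", prep$genes, q = 1L, lambda = jp$C$lambda,
              n_used = jp$n, statistic = stat)
}
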