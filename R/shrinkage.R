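#' Stack present and lagged states into a joint state matrix
#'
#' Builds the joint matrix whose column t aligns the present state X(t)
#' with the past states X(t-1), ..., X(t-q), so that lagged dependencies
#' become ordinary cross-block partial correlations. Rows are ordered by
#' lag block: genes at lag 0, then lag 1, and so on; row names are
#' `<gene>.l<lag>` for positive lags.
#'
#' @param x expression matrix (p genes x m time points).
#' @param q lag order, `0 <= q <= m - 2`.
#' @return a `(q+1)*p x (m-q)` matrix with attributes `lag_order`, `p`,
#'   and `block_index` (a data.frame mapping each row to its gene and lag).
#' @export
build_joint_matrix <- function(x, q) {
  x <- validate_expression(x)
  p <- nrow(x); m <- ncol(x)
  q <- as.integer(q)
  if (q < 0L || q > m - 2L)
    stop("lag order q must satisfy 0 <= q <= m - 2 (q = ", q, ", m = ", m, ")")
  if (q == 0L) {
    z <- x
  } else {
    blocks <- lapply(0:q, function(l) x[, (q + 1L - l):(m - l), drop = FALSE])
    z <- do.call(rbind, blocks)
    rownames(z) <- unlist(lapply(0:q, function(l)
      if (l == 0L) rownames(x) else paste0(rownames(x), ".l", l)))
    colnames(z) <- colnames(x)[(q + 1L):m]
  }
  attr(z, "lag_order") <- q
  attr(z, "p") <- p
  attr(z, "block_index") <- data.frame(
    gene = rep(rownames(x), q + 1L),
    lag = rep(0:q, each = p),
    row = seq_len((q + 1L) * p),
    stringsAsFactors = FALSE)
  z
}

#' Shrinkage estimate of a covariance matrix
#'
#' Well-conditioned covariance estimation for the small-sample regime
#' (variables >> samples): the sample correlation matrix is shrunk toward
#' the identity with the analytic optimal intensity
#' \eqn{\lambda^* = \sum_{i \ne j} \widehat{Var}(r_{ij}) / \sum_{i \ne j} r_{ij}^2},
#' clamped to [0, 1], then rescaled by the sample standard deviations.
#' The sample covariance uses the unbiased (n-1) denominator. The result
#' is positive definite whenever the intensity is positive and no variable
#' is constant.
#'
#' @param z matrix of variables (rows) x observations (columns), e.g. a
#'   joint state matrix from [build_joint_matrix()].
#' @param lambda optional fixed shrinkage intensity in [0, 1]; by default
#'   the analytic estimate is used.
#' @param target shrinkage target for the correlation scale: `"identity"`
#'   (default) leaves only the diagonal, i.e. shrinks all correlations
#'   toward zero.
#' @return an object of class `"shrinkage_cov"`: a list with `matrix`
#'   (covariance), `lambda`, `n` (observations used).
#' @export
shrinkage_covariance <- function(z, lambda = NULL, target = c("identity")) {
  target <- match.arg(target)
  if (!is.matrix(z) || !is.numeric(z)) stop("z must be a numeric matrix")
  n <- ncol(z)
  if (n < 3L) stop("shrinkage estimation needs at least 3 observations, got ", n)
  pp <- nrow(z)
  mu <- rowMeans(z)
  zc <- z - mu
  sds <- sqrt(rowSums(zc^2) / (n - 1L))
  if (any(sds < .Machine$double.eps^0.5))
    stop("constant variable(s) in input; drop zero-variance genes first")
  zs <- zc / sds
  r <- tcrossprod(zs) / (n - 1L)     # sample correlation
  if (is.null(lambda)) {
    # analytic intensity: sum of Var-hat(r_ij) over sum of r_ij^2, off-diagonal
    # Var-hat(r_ij) = n / (n-1)^3 * sum_t (w_ijt - wbar_ij)^2, w_ijt = z_it z_jt
    sw2 <- tcrossprod(zs^2)                    # sum_t w_ijt^2
    vr <- n / (n - 1L)^3 * (sw2 - (n - 1L)^2 / n * r^2)
    num <- sum(vr) - sum(diag(vr))
    den <- sum(r^2) - pp               # off-diagonal sum of squares (diag = 1)
    # cap the analytic estimate strictly below 1: full shrinkage would
    # discard the data entirely and degenerate every downstream comparison,
    # while the paired tests and rankings are insensitive to the exact cap
    cap <- 1 - 1e-3
    lambda <- if (den <= .Machine$double.eps) cap else num / den
    lambda <- min(cap, max(0, lambda))
  } else {
    if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  }
  rstar <- (1 - lambda) * r
  diag(rstar) <- 1
  cov <- rstar * tcrossprod(sds)
  dimnames(cov) <- list(rownames(z), rownames(z))
  structure(list(matrix = cov, lambda = lambda, n = n),
            class = "shrinkage_cov")
}

#' @export
print.shrinkage_cov <- function(x, ...) {
  cat("Shrinkage covariance:", nrow(x$matrix), "variables,",
      x$n, "observations, lambda =", signif(x$lambda, 4), "\n")
  invisible(x)
}

# precision matrix -> partial correlations: Omega_ij = -P_ij / sqrt(P_ii P_jj)
.prec_to_pcor <- function(P) {
  d <- 1 / sqrt(diag(P))
  omega <- -P * tcrossprod(d)
  diag(omega) <- 1
  omega
}

.cov_matrix <- function(C) {
  if (inherits(C, "shrinkage_cov")) C$matrix
  else if (is.matrix(C) && is.numeric(C)) C
  else stop("expected a covariance matrix or shrinkage_cov object")
}

#' Partial correlations from a covariance matrix
#'
#' The full partial-correlation matrix: the correlation between every pair
#' of variables after the linear effects of all remaining variables are
#' removed, obtained by standardizing the negated precision (inverse
#' covariance) matrix. Symmetric with unit diagonal.
#'
#' @param C covariance matrix or a `"shrinkage_cov"` object (must be
#'   positive definite).
#' @return symmetric partial-correlation matrix with unit diagonal.
#' @export
partial_correlation <- function(C) {
  cm <- .cov_matrix(C)
  P <- tryCatch(chol2inv(chol(cm)), error = function(e)
    stop("covariance is not positive definite (", conditionMessage(e),
         "); use shrinkage intensity lambda > 0"))
  dimnames(P) <- dimnames(cm)
  omega <- .prec_to_pcor(P)
  attr(omega, "precision") <- P
  attr(omega, "excluded_variable") <- NULL
  omega
}

#' Partial correlations after deleting variables from the conditioning set
#'
#' Recomputes the partial-correlation matrix of the remaining variables
#' after removing variable(s) `j` entirely, i.e. `j` no longer takes part
#' in any prediction. The default route downdates the full precision
#' matrix by a Schur complement, which is algebraically exact and avoids
#' re-inverting the reduced covariance; `method = "direct"` inverts the
#' principal submatrix instead (same result, kept as an independent
#' cross-check). The shrinkage intensity is not re-estimated, which is
#' what makes the downdate exact.
#'
#' @param C covariance matrix or `"shrinkage_cov"` object.
#' @param j variable index/indices (or names) to delete.
#' @param method `"downdate"` (Schur complement of the precision, default)
#'   or `"direct"` (invert the reduced covariance).
#' @param precision optional precomputed precision matrix of `C` (used to
#'   amortize repeated deletions).
#' @return partial-correlation matrix of the remaining variables, with
#'   attribute `excluded_variable = j`.
#' @export
delete_variable_partial_correlation <- function(C, j,
                                                method = c("downdate", "direct"),
                                                precision = NULL) {
  method <- match.arg(method)
  cm <- .cov_matrix(C)
  pp <- nrow(cm)
  if (is.character(j)) j <- match(j, rownames(cm))
  j <- as.integer(j)
  if (length(j) < 1L || anyNA(j) || any(j < 1L) || any(j > pp))
    stop("variable index out of range")
  if (length(j) >= pp - 1L)
    stop("cannot delete ", length(j), " of ", pp, " variables")
  if (method == "direct") {
    red <- cm[-j, -j, drop = FALSE]
    Pr <- chol2inv(chol(red))
    dimnames(Pr) <- dimnames(red)
  } else {
    P <- if (is.null(precision)) {
      Pf <- chol2inv(chol(cm)); dimnames(Pf) <- dimnames(cm); Pf
    } else precision
    A <- P[-j, -j, drop = FALSE]
    B <- P[-j, j, drop = FALSE]
    D <- P[j, j, drop = FALSE]
    Pr <- A - B %*% solve(D, t(B))
  }
  omega <- .prec_to_pcor(Pr)
  attr(omega, "excluded_variable") <- j
  omega
}
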