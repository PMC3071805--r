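# Shared fixtures: small generators used across test files.

# random positive-definite covariance via A %*% t(A) + ridge
rand_pd <- function(d, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- matrix(rnorm(d * d), d)
  cm <- tcrossprod(a) + diag(0.5, d)
  dimnames(cm) <- list(paste0("v", 1:d), paste0("v", 1:d))
  cm
}

# 3-variable chain correlation matrix: r12 = r23 = 0.5, r13 = 0.25,
# so variables 1 and 3 are conditionally independent given 2
chain_cor <- function() {
  matrix(c(1, .5, .25,
           .5, 1, .5,
           .25, .5, 1), 3, 3,
         dimnames = list(paste0("v", 1:3), paste0("v", 1:3)))
}

# named white-noise expression matrix
noise_expr <- function(p, m, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(rnorm(p * m), p, m,
         dimnames = list(paste0("g", 1:p), paste0("t", 1:m)))
}

# sparse stable random VAR(1) system; returns data + truth network
gen_var1_system <- function(p, density, m, seed, coef_range = c(0.5, 1),
                            radius = 0.9) {
  set.seed(seed)
  A <- matrix(0, p, p)                       # A[i, j]: past j -> present i
  off <- which(row(A) != col(A))
  on <- sample(off, round(density * length(off)))
  A[on] <- sample(c(-1, 1), length(on), TRUE) *
    runif(length(on), coef_range[1], coef_range[2])
  rho <- max(Mod(eigen(A, only.values = TRUE)$values))
  if (rho > 0) A <- A * (radius / rho)
  x <- matrix(0, p, m)
  x[, 1] <- rnorm(p)
  for (t in 2:m) x[, t] <- A %*% x[, t - 1] + rnorm(p)
  rownames(x) <- paste0("g", 1:p)
  colnames(x) <- paste0("t", 1:m)
  list(x = x, A = A,
       truth = directed_network((t(A) != 0) + 0L, rownames(x)))
}

# two-gene lagged system x -> y with independent decoys
gen_lagged_pair <- function(m, coef = 0.8, n_decoys = 4, seed = NULL,
                            noise_sd = 1) {
  if (!is.null(seed)) set.seed(seed)
  x <- rnorm(m)
  y <- c(rnorm(1), coef * x[-m] + noise_sd * rnorm(m - 1))
  dat <- rbind(x, y, matrix(rnorm(n_decoys * m), n_decoys, m))
  rownames(dat) <- c("x", "y", paste0("d", seq_len(n_decoys)))
  colnames(dat) <- paste0("t", 1:m)
  dat
}
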