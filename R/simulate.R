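#' Construct a directed network object
#'
#' @param adjacency p x p 0/1 matrix, regulator rows -> target columns;
#'   diagonal entries (autoregulation) are allowed and kept.
#' @param gene_names optional identifiers (defaults to existing dimnames
#'   or `g1..gp`).
#' @param edge_signs optional matrix of per-edge signs (+1/-1).
#' @return object of class `"directed_network"`.
#' @export
directed_network <- function(adjacency, gene_names = NULL, edge_signs = NULL) {
  if (!is.matrix(adjacency) || nrow(adjacency) != ncol(adjacency))
    stop("adjacency must be a square matrix")
  adjacency <- (adjacency != 0) + 0L
  if (is.null(gene_names))
    gene_names <- rownames(adjacency) %||% paste0("g", seq_len(nrow(adjacency)))
  dimnames(adjacency) <- list(gene_names, gene_names)
  structure(list(adjacency = adjacency, gene_names = gene_names,
                 edge_signs = edge_signs),
            class = "directed_network")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.directed_network <- function(x, ...) {
  cat("Directed network:", length(x$gene_names), "genes,",
      sum(x$adjacency), "edges (", sum(diag(x$adjacency)),
      "autoregulatory )\n")
  invisible(x)
}

#' Scale-free directed scaffold network
#'
#' Grows a directed preferential-attachment graph in which early,
#' well-connected genes accumulate many outgoing edges, giving the
#' heavy-tailed out-degree (regulatory hub) structure characteristic of
#' transcriptional networks. Used as the large source network from which
#' benchmark subnetworks are sampled.
#'
#' @param p_total number of genes (>= 10).
#' @param avg_degree average number of edges contributed per added gene.
#' @param seed RNG seed (integer) for reproducibility.
#' @return a `"directed_network"`.
#' @export
generate_scaffold <- function(p_total, avg_degree = 2, seed = NULL) {
  if (p_total < 10L) stop("scaffold needs at least 10 genes")
  if (avg_degree >= p_total) stop("avg_degree must be below p_total")
  if (!is.null(seed)) set.seed(seed)
  g <- igraph::sample_pa(p_total, power = 1, m = avg_degree, directed = TRUE)
  # sample_pa points new -> old; reverse so hubs are regulators (out-degree)
  adj <- t(igraph::as_adjacency_matrix(g, sparse = FALSE))
  adj <- (adj != 0) + 0L
  directed_network(adj, gene_names = paste0("g", seq_len(p_total)))
}

#' Sample a connected subnetwork biased toward hubs
#'
#' Grows a gene set from a random seed gene: at each step the genes
#' neighbouring the current selection are ranked by their total
#' connectivity in the scaffold and the next gene is drawn uniformly from
#' the top `k_top`. This keeps the sampled subnetwork connected and
#' scale-free-like while still admitting small hubs and their targets.
#' Returns the induced subgraph.
#'
#' @param net a `"directed_network"` scaffold.
#' @param n target number of genes (<= network size).
#' @param k_top pool size for the ranked draw (default 20).
#' @param seed RNG seed.
#' @return a `"directed_network"` on `n` genes.
#' @export
sample_subnetwork <- function(net, n, k_top = 20L, seed = NULL) {
  if (!inherits(net, "directed_network")) stop("expected a directed_network")
  p <- length(net$gene_names)
  if (n > p) stop("requested subnetwork size ", n, " exceeds network size ", p)
  if (!is.null(seed)) set.seed(seed)
  if (n == p) return(net)
  adj <- net$adjacency
  undirected <- (adj + t(adj)) > 0
  degree <- rowSums(undirected)
  in_sel <- logical(p)
  nbr_count <- integer(p)                      # links into the current selection
  start <- sample.int(p, 1L)
  selected <- start
  in_sel[start] <- TRUE
  nbr_count <- nbr_count + undirected[start, ]
  while (length(selected) < n) {
    boundary <- which(nbr_count > 0L & !in_sel)
    if (length(boundary) == 0L) {              # disconnected scaffold: restart
      boundary <- which(!in_sel)
      pick <- if (length(boundary) == 1L) boundary else sample(boundary, 1L)
    } else {
      ord <- boundary[order(degree[boundary], decreasing = TRUE)]
      pool <- ord[seq_len(min(k_top, length(ord)))]
      pick <- if (length(pool) == 1L) pool else sample(pool, 1L)
    }
    selected <- c(selected, pick)
    in_sel[pick] <- TRUE
    nbr_count <- nbr_count + undirected[pick, ]
  }
  selected <- sort(selected)
  directed_network(adj[selected, selected, drop = FALSE],
                   gene_names = net$gene_names[selected])
}

#' Simulate noise-free network dynamics under a perturbation
#'
#' A stable linear stochastic system stands in for full ordinary
#' differential equation kinetics: each edge receives a random sign and a
#' magnitude uniform in `weight_range`, the weight matrix is rescaled to
#' spectral radius `spectral_radius` (< 1) so the dynamics are stationary,
#' and the system x(t) = b + W x(t-1) + process noise is iterated from its
#' unperturbed fixed point with the perturbation applied at t = 0:
#' \describe{
#'   \item{multifactorial}{every gene's baseline is jittered at t = 0;}
#'   \item{knockout}{the target gene is clamped to zero for all t;}
#'   \item{knockdown}{the target gene's production term is halved;}
#'   \item{dual_knockout}{two genes are clamped to zero.}
#' }
#'
#' @param net a `"directed_network"` (adjacency `[j, i]` = j regulates i).
#' @param perturbation list with `kind` (one of the four above) and
#'   `targets` (gene indices; 1 for knockout/knockdown, 2 for
#'   dual_knockout, none for multifactorial).
#' @param n_steps internal sampling grid (default 100 steps, t = 1..100).
#' @param weight_range magnitude band for edge weights.
#' @param spectral_radius stationarity rescaling of the weight matrix.
#' @param process_sd standard deviation of per-step process noise.
#' @param init_sd standard deviation of the multifactorial baseline jitter.
#' @param seed RNG seed.
#' @return latent (noise-free) expression matrix, p genes x n_steps.
#' @export
simulate_dynamics <- function(net, perturbation = list(kind = "multifactorial",
                                                       targets = integer(0)),
                              n_steps = 100L, weight_range = c(0.5, 1),
                              spectral_radius = 0.9, process_sd = 0.05,
                              init_sd = 1, seed = NULL) {
  if (!inherits(net, "directed_network")) stop("expected a directed_network")
  p <- length(net$gene_names)
  if (p < 1L || sum(net$adjacency) == 0L) stop("network has no edges")
  kind <- match.arg(perturbation$kind,
                    c("multifactorial", "knockout", "knockdown",
                      "dual_knockout"))
  targets <- as.integer(perturbation$targets %||% integer(0))
  need <- c(multifactorial = 0L, knockout = 1L, knockdown = 1L,
            dual_knockout = 2L)[[kind]]
  if (length(targets) != need)
    stop(kind, " perturbation names ", need, " target gene(s), got ",
         length(targets))
  if (!is.null(seed)) set.seed(seed)
  # signed, weighted update matrix W[i, j]: effect of x_j(t-1) on x_i(t)
  A <- t(net$adjacency)
  idx <- which(A != 0)
  signs <- if (is.null(net$edge_signs)) sample(c(-1, 1), length(idx),
                                               replace = TRUE)
           else t(net$edge_signs)[idx]
  W <- matrix(0, p, p)
  W[idx] <- signs * stats::runif(length(idx), weight_range[1L],
                                 weight_range[2L])
  rho <- max(Mod(eigen(W, only.values = TRUE)$values))
  if (rho > 0) W <- W * (spectral_radius / rho)
  b <- rep(1, p)                                # basal production
  prod_scale <- rep(1, p)
  clamp <- rep(FALSE, p)
  xstar <- solve(diag(p) - W, b)                # unperturbed fixed point
  x <- xstar
  if (kind == "multifactorial") {
    x <- x + stats::rnorm(p, 0, init_sd)
  } else if (kind == "knockdown") {
    prod_scale[targets] <- 0.5
  } else {                                      # knockout / dual_knockout
    clamp[targets] <- TRUE
    x[targets] <- 0
  }
  out <- matrix(0, p, n_steps,
                dimnames = list(net$gene_names, paste0("t", seq_len(n_steps))))
  for (t in seq_len(n_steps)) {
    x <- prod_scale * (b + W %*% x) + stats::rnorm(p, 0, process_sd)
    x[clamp] <- 0
    out[, t] <- x
  }
  attr(out, "perturbation") <- list(kind = kind, targets = targets)
  out
}

#' Add microarray-style measurement noise and normalize
#'
#' Subsamples the internal simulation grid to the requested series length
#' (equispaced), applies a mix of lognormal (multiplicative) and normal
#' (additive) measurement noise,
#' `observed = latent * exp(eta) + xi` with
#' `eta ~ N(0, log_sd * sqrt(w))` and `xi ~ N(0, additive_sd * sqrt(1-w))`
#' for mixing weight `w`, and finally standardizes each gene — the
#' normalization happens after the experimental noise is added.
#'
#' @param latent latent expression matrix from [simulate_dynamics()].
#' @param length number of retained time points (<= grid size; typical
#'   values 21 or 100).
#' @param additive_sd standard deviation of the additive component.
#' @param log_sd log-scale standard deviation of the multiplicative
#'   component.
#' @param mix_weight weight w in [0, 1] of the multiplicative component.
#' @param seed RNG seed.
#' @return standardized observed expression matrix (p x length).
#' @export
add_noise_and_normalize <- function(latent, length = 21L, additive_sd = 0.3,
                                    log_sd = 0.2, mix_weight = 0.5,
                                    seed = NULL) {
  if (length > ncol(latent))
    stop("requested series length ", length, " exceeds simulation grid ",
         ncol(latent))
  if (mix_weight < 0 || mix_weight > 1) stop("mix_weight must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  keep <- round(seq(1L, ncol(latent), length.out = length))
  sub <- latent[, keep, drop = FALSE]
  eta <- stats::rnorm(base::length(sub), 0, log_sd * sqrt(mix_weight))
  xi <- stats::rnorm(base::length(sub), 0, additive_sd * sqrt(1 - mix_weight))
  obs <- sub * exp(eta) + xi
  standardize_expression(obs, warn = FALSE)
}

#' Benchmark configuration
#'
#' Collects the factors of the benchmark grid. Defaults reproduce the
#' study-shaped grid: network sizes 50/100/200/500, the four perturbation
#' kinds, series lengths 21 and 100, five replicates per cell (160
#' datasets).
#'
#' @param sizes network sizes.
#' @param lengths series lengths (each <= 100, the internal grid).
#' @param perturbations perturbation kinds to include.
#' @param replicates simulations per grid cell (>= 1).
#' @param noise list: `additive_sd`, `log_sd`, `mix_weight`.
#' @param seed master seed; every dataset's own seed derives from it.
#' @param scaffold_size,avg_degree,k_top scaffold generation and
#'   subnetwork sampling parameters.
#' @param variance_quantile optional screen: drop datasets whose median
#'   per-gene latent variance falls below this quantile of the suite
#'   (default `NULL`, no screen).
#' @return a `"benchmark_config"` list.
#' @export
benchmark_config <- function(sizes = c(50L, 100L, 200L, 500L),
                             lengths = c(21L, 100L),
                             perturbations = c("multifactorial", "knockout",
                                               "knockdown", "dual_knockout"),
                             replicates = 5L,
                             noise = list(additive_sd = 0.3, log_sd = 0.2,
                                          mix_weight = 0.5),
                             seed = 1L, scaffold_size = 1000L,
                             avg_degree = 2, k_top = 20L,
                             variance_quantile = NULL) {
  if (length(sizes) == 0L || length(lengths) == 0L ||
      length(perturbations) == 0L)
    stop("sizes, lengths, and perturbations must be nonempty")
  if (replicates < 1L) stop("replicates must be >= 1")
  if (any(lengths > 100L)) stop("series lengths cannot exceed the 100-step grid")
  if (max(sizes) > scaffold_size)
    stop("scaffold_size must be at least the largest network size")
  structure(list(sizes = as.integer(sizes), lengths = as.integer(lengths),
                 perturbations = perturbations,
                 replicates = as.integer(replicates), noise = noise,
                 seed = as.integer(seed),
                 scaffold_size = as.integer(scaffold_size),
                 avg_degree = avg_degree, k_top = as.integer(k_top),
                 variance_quantile = variance_quantile),
            class = "benchmark_config")
}

#' Generate the full benchmark suite
#'
#' Full factorial grid of sizes x perturbations x lengths x replicates.
#' One scale-free scaffold is generated from the master seed; each dataset
#' gets its own subnetwork, perturbation targets, dynamics, and noise,
#' driven by a per-dataset seed recorded in its metadata, so the whole
#' suite is reproducible from the configuration alone.
#'
#' @param cfg a `"benchmark_config"`.
#' @return list of datasets, each a list with `expression` (standardized
#'   observed matrix), `truth` (the `"directed_network"` ground truth),
#'   and `meta` (dataset_id, p, m, perturbation, targets, seed).
#' @export
make_benchmark_suite <- function(cfg = benchmark_config()) {
  if (!inherits(cfg, "benchmark_config")) stop("expected a benchmark_config")
  scaffold <- generate_scaffold(cfg$scaffold_size, cfg$avg_degree,
                                seed = cfg$seed)
  grid <- expand.grid(replicate = seq_len(cfg$replicates),
                      length = cfg$lengths,
                      perturbation = cfg$perturbations,
                      size = cfg$sizes,
                      stringsAsFactors = FALSE)
  datasets <- vector("list", nrow(grid))
  med_var <- numeric(nrow(grid))
  for (k in seq_len(nrow(grid))) {
    row <- grid[k, ]
    ds_seed <- (cfg$seed + 7919L * k) %% .Machine$integer.max
    set.seed(ds_seed)
    net <- sample_subnetwork(scaffold, row$size, k_top = cfg$k_top)
    targets <- switch(row$perturbation,
                      multifactorial = integer(0),
                      dual_knockout = sample.int(row$size, 2L),
                      sample.int(row$size, 1L))
    latent <- simulate_dynamics(net, list(kind = row$perturbation,
                                          targets = targets))
    expr <- add_noise_and_normalize(latent, length = row$length,
                                    additive_sd = cfg$noise$additive_sd,
                                    log_sd = cfg$noise$log_sd,
                                    mix_weight = cfg$noise$mix_weight)
    med_var[k] <- stats::median(apply(latent, 1L, stats::var))
    datasets[[k]] <- list(
      expression = expr, truth = net,
      meta = list(dataset_id = sprintf("p%d_%s_m%d_r%d", row$size,
                                       row$perturbation, row$length,
                                       row$replicate),
                  p = row$size, m = row$length,
                  perturbation = row$perturbation, targets = targets,
                  seed = ds_seed, median_latent_variance = med_var[k]))
  }
  if (!is.null(cfg$variance_quantile)) {
    keep <- med_var >= stats::quantile(med_var, cfg$variance_quantile)
    datasets <- datasets[keep]
  }
  attr(datasets, "config") <- cfg
  datasets
}
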