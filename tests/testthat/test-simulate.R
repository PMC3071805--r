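test_that("scaffold has the requested edge budget, hubs, and determinism", {
  net <- generate_scaffold(1000, avg_degree = 2, seed = 1)
  ecount <- sum(net$adjacency)
  expect_true(abs(ecount - 2000) / 2000 < 0.1)
  net2 <- generate_scaffold(1000, avg_degree = 2, seed = 1)
  expect_identical(net$adjacency, net2$adjacency)
  # hub emergence: max out-degree well above the mean
  hubby <- sapply(1:20, function(s) {
    g <- generate_scaffold(1000, avg_degree = 2, seed = 100 + s)
    outd <- rowSums(g$adjacency)
    max(outd) > 5 * mean(outd)
  })
  expect_gte(mean(hubby), 0.9)
  expect_error(generate_scaffold(5), "at least 10")
  expect_error(generate_scaffold(20, avg_degree = 30), "below p_total")
})

test_that("subnetwork sampling respects size and hub bias", {
  net <- generate_scaffold(200, seed = 2)
  expect_identical(sample_subnetwork(net, 200, seed = 3), net)
  one <- sample_subnetwork(net, 1, seed = 3)
  expect_equal(length(one$gene_names), 1L)
  expect_equal(sum(one$adjacency), 0L)
  sub <- sample_subnetwork(net, 50, seed = 4)
  expect_equal(nrow(sub$adjacency), 50L)
  expect_true(all(sub$gene_names %in% net$gene_names))
  # induced subgraph: edges agree with the scaffold
  idx <- match(sub$gene_names, net$gene_names)
  expect_identical(sub$adjacency, net$adjacency[idx, idx])
  expect_error(sample_subnetwork(net, 500), "exceeds")
  # greedy hub bias: k_top = 1 gives denser subnetworks than k_top = 20
  dens <- function(k) mean(sapply(1:20, function(s) {
    sb <- sample_subnetwork(net, 40, k_top = k, seed = 700 + s)
    sum(sb$adjacency) / (40 * 39)
  }))
  expect_gt(dens(1), dens(20))
})

test_that("dynamics are stationary, clamp knockouts, and rest at equilibrium", {
  net <- sample_subnetwork(generate_scaffold(100, seed = 5), 20, seed = 6)
  # equilibrium: no perturbation term, no process noise -> constant at the
  # fixed point
  lat <- simulate_dynamics(net, list(kind = "multifactorial",
                                     targets = integer(0)),
                           process_sd = 0, init_sd = 0, seed = 7)
  expect_true(all(abs(lat - lat[, 1]) < 1e-8))
  # knockout clamps the row to zero
  ko <- simulate_dynamics(net, list(kind = "knockout", targets = 3L), seed = 8)
  expect_true(all(ko[3, ] == 0))
  dko <- simulate_dynamics(net, list(kind = "dual_knockout", targets = c(2L, 5L)),
                           seed = 9)
  expect_true(all(dko[c(2, 5), ] == 0))
  # stationarity: a 10x longer run stays bounded
  bounded <- sapply(1:10, function(s) {
    lat10 <- simulate_dynamics(net, list(kind = "multifactorial",
                                         targets = integer(0)),
                               n_steps = 1000L, seed = 900 + s)
    max(abs(lat10)) < 100
  })
  expect_true(all(bounded))
  expect_error(simulate_dynamics(net, list(kind = "knockout",
                                           targets = c(1L, 2L))),
               "1 target")
})

test_that("knockdown halves the perturbed gene's production", {
  net <- sample_subnetwork(generate_scaffold(100, seed = 5), 15, seed = 10)
  kd <- simulate_dynamics(net, list(kind = "knockdown", targets = 4L),
                          process_sd = 0, seed = 11)
  full <- simulate_dynamics(net, list(kind = "multifactorial",
                                      targets = integer(0)),
                            process_sd = 0, init_sd = 0, seed = 11)
  # knocked-down gene settles below its unperturbed steady level
  expect_lt(abs(kd[4, 100]), abs(full[4, 100]) + 1e-9)
  expect_false(isTRUE(all.equal(kd[4, ], full[4, ])))
})

test_that("noise model subsamples, perturbs, then standardizes", {
  net <- sample_subnetwork(generate_scaffold(100, seed = 5), 10, seed = 12)
  lat <- simulate_dynamics(net, list(kind = "multifactorial",
                                     targets = integer(0)), seed = 13)
  # zero noise: equals the standardized subsampled latent signal
  obs0 <- add_noise_and_normalize(lat, length = 21, additive_sd = 0,
                                  log_sd = 0, seed = 14)
  keep <- round(seq(1, 100, length.out = 21))
  expect_equal(unname(obs0),
               unname(standardize_expression(lat[, keep], warn = FALSE)),
               tolerance = 1e-12)
  # post-normalization invariant
  obs <- add_noise_and_normalize(lat, length = 21, seed = 15)
  expect_equal(unname(rowMeans(obs)), rep(0, 10), tolerance = 1e-12)
  expect_equal(unname(apply(obs, 1, var)), rep(1, 10), tolerance = 1e-12)
  expect_error(add_noise_and_normalize(lat, length = 200), "exceeds")
})

test_that("benchmark suite has factorial arithmetic and determinism", {
  cfg <- benchmark_config(sizes = c(20, 30), lengths = 21,
                          perturbations = c("knockout", "multifactorial"),
                          replicates = 2, scaffold_size = 100, seed = 5)
  suite <- make_benchmark_suite(cfg)
  expect_length(suite, 2 * 1 * 2 * 2)
  one <- make_benchmark_suite(benchmark_config(sizes = 20, lengths = 21,
                                               perturbations = "knockout",
                                               replicates = 1,
                                               scaffold_size = 100, seed = 5))
  expect_length(one, 1L)
  suite2 <- make_benchmark_suite(cfg)
  expect_identical(suite, suite2)
  # truth and metadata travel with each dataset; knockout target recorded
  for (ds in suite) {
    expect_s3_class(ds$truth, "directed_network")
    expect_equal(nrow(ds$expression), ds$meta$p)
    expect_equal(ncol(ds$expression), ds$meta$m)
    if (ds$meta$perturbation == "knockout")
      expect_length(ds$meta$targets, 1L)
  }
  expect_error(benchmark_config(sizes = integer(0)), "nonempty")
})

test_that("heavier measurement noise degrades DPC(1) recovery", {
  net <- sample_subnetwork(generate_scaffold(1000, seed = 1), 50, seed = 2)
  mean_auc <- sapply(c(0.1, 1.0), function(sdv) {
    mean(sapply(1:5, function(s) {
      lat <- simulate_dynamics(net, list(kind = "multifactorial",
                                         targets = integer(0)),
                               seed = 10 + s)
      ex <- add_noise_and_normalize(lat, 100, additive_sd = sdv,
                                    seed = 20 + s)
      roc_evaluate(dpcq_scores(ex, q = 1), net)$auc
    }))
  })
  expect_gt(mean_auc[1], mean_auc[2])
})
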