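test_that("ROC endpoints: perfect and reversed rankings", {
  set.seed(1)
  adj <- matrix(0L, 6, 6)
  adj[cbind(c(1, 2, 3), c(2, 3, 4))] <- 1L
  truth <- directed_network(adj, paste0("g", 1:6))
  s <- matrix(-1, 6, 6)
  s[adj == 1] <- 1                      # every true edge above every non-edge
  perfect <- roc_evaluate(s, truth)
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$max_f, 1)
  reversed <- roc_evaluate(-s, truth)
  expect_equal(reversed$auc, 0)
})

test_that("rank AUC equals trapezoidal AUC and nulls sit at 0.5", {
  aucs <- numeric(100)
  for (s in 1:100) {
    set.seed(2000 + s)
    p <- 50
    adj <- matrix(rbinom(p * p, 1, 0.05), p, p)
    diag(adj) <- 0
    if (sum(adj[row(adj) != col(adj)]) == 0) adj[1, 2] <- 1
    truth <- directed_network(adj, paste0("g", 1:p))
    sc <- matrix(runif(p * p), p, p)
    r <- roc_evaluate(sc, truth)
    trap <- sum(diff(r$fpr) * (head(r$tpr, -1) + tail(r$tpr, -1)) / 2)
    expect_equal(r$auc, trap, tolerance = 1e-10)
    expect_true(!is.unsorted(r$tpr) && !is.unsorted(r$fpr))
    expect_equal(c(r$fpr[1], r$tpr[1]), c(0, 0))
    expect_equal(c(tail(r$fpr, 1), tail(r$tpr, 1)), c(1, 1))
    aucs[s] <- r$auc
  }
  expect_equal(mean(aucs), 0.5, tolerance = 0.02)
})

test_that("predict-everything F-score equals 2*prev/(prev + 1)", {
  set.seed(3)
  p <- 20
  adj <- matrix(rbinom(p * p, 1, 0.1), p, p); diag(adj) <- 0
  truth <- directed_network(adj, paste0("g", 1:p))
  r <- roc_evaluate(matrix(runif(p * p), p, p), truth)
  prev <- r$n_pos / (r$n_pos + r$n_neg)
  # the final sweep point predicts every edge
  f_all <- 2 * prev / (prev + 1)
  expect_gte(r$max_f + 1e-12, f_all)
  # recompute the all-in F from the curve tail: tpr=1, precision=prev
  expect_equal(2 * prev * 1 / (prev + 1), f_all)
})

test_that("diagonal handling only matters through autoregulatory entries", {
  set.seed(4)
  p <- 12
  adj <- matrix(rbinom(p * p, 1, 0.15), p, p)
  diag(adj) <- 0                         # no autoregulation in truth
  truth <- directed_network(adj, paste0("g", 1:p))
  sc <- matrix(runif(p * p), p, p)
  diag(sc) <- -Inf                       # diagonal ranked last either way
  with_d <- roc_evaluate(sc, truth, exclude_diagonal = FALSE)
  without_d <- roc_evaluate(sc, truth, exclude_diagonal = TRUE)
  expect_equal(without_d$n_neg + p, with_d$n_neg)
  expect_equal(without_d$n_pos, with_d$n_pos)
})

test_that("Welch test reproduces the direct Satterthwaite evaluation", {
  res <- welch_test(c(1, 2, 3), c(2, 3, 4), alternative = "greater")
  # direct formulas: t = (mx - my)/sqrt(vx/nx + vy/ny), Satterthwaite df
  se2 <- 1 / 3 + 1 / 3
  t_direct <- (2 - 3) / sqrt(se2)
  df_direct <- se2^2 / ((1 / 3)^2 / 2 + (1 / 3)^2 / 2)
  expect_equal(res$t, t_direct, tolerance = 1e-10)
  expect_equal(res$t, -1.2247, tolerance = 1e-4)
  expect_equal(res$df, df_direct, tolerance = 1e-10)
  expect_equal(res$df, 4.0, tolerance = 1e-10)
  expect_equal(res$p, pt(t_direct, df_direct, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(res$p, 0.856, tolerance = 1e-3)
})

test_that("hub test flags shifted regulator rows and not null ones", {
  set.seed(5)
  p <- 40
  mk_scores <- function(shift) {
    pv <- matrix(runif(p * p), p, p)
    diag(pv) <- 1
    pv[1:6, ] <- pmax(pv[1:6, ] - shift, 1e-6)   # stronger rows -> smaller p
    structure(list(pvalues = pv, statistic = NULL, method = "DPC0",
                   genes = paste0("g", 1:p), q = 0L),
              class = "dpc_scores")
  }
  shifted <- hub_welch_test(mk_scores(0.45), 1:6)
  expect_lt(shifted$p, 0.01)
  nulls <- sapply(1:40, function(s) {
    set.seed(6000 + s)
    hub_welch_test(mk_scores(0), sample(p, 6))$p
  })
  expect_equal(mean(nulls), 0.5, tolerance = 0.12)
  expect_error(hub_welch_test(mk_scores(0), integer(0)), "nonempty")
  expect_error(hub_welch_test(mk_scores(0), 1:p), "strict subset")
})

test_that("benchmark harness runs methods, records rows, flags inapplicable", {
  cfg <- benchmark_config(sizes = 15, lengths = c(21, 100),
                          perturbations = "multifactorial", replicates = 2,
                          scaffold_size = 60, seed = 9)
  suite <- make_benchmark_suite(cfg)
  tab <- benchmark_harness(suite, methods = c("dpc", "svar"))
  expect_equal(nrow(tab), length(suite) * 2)
  expect_true(all(tab$auc >= 0 & tab$auc <= 1))
  expect_named(tab, c("dataset_id", "method", "p", "m", "perturbation",
                      "auc", "max_f", "tpr_at_fpr02", "seconds", "seed"))
  # GC-VAR inapplicable on every p=30 > m dataset
  cfg2 <- benchmark_config(sizes = 30, lengths = 21,
                           perturbations = "multifactorial", replicates = 1,
                           scaffold_size = 60, seed = 10)
  tab2 <- benchmark_harness(make_benchmark_suite(cfg2), methods = "gcvar")
  expect_true(all(is.na(tab2$auc)))
  expect_equal(attr(tab2, "inapplicable"), "gcvar")
  # single dataset, single method -> one row
  tab3 <- benchmark_harness(make_benchmark_suite(cfg2), methods = "svar")
  expect_equal(nrow(tab3), 1L)
  # pure function of suite + config
  expect_equal(benchmark_harness(suite, methods = "svar")$auc,
               benchmark_harness(suite, methods = "svar")$auc)
})
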