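test_that("the exact test is 1 for symmetric and degenerate inputs", {
  expect_equal(nb_exact_test(7, 7, 1, 1), 1)
  expect_equal(nb_exact_test(0, 0, 1, 1), 1)
  expect_error(nb_exact_test(3, 4, 1, 1, dispersion = 0), "positive")
  expect_error(nb_exact_test(-1, 4, 1, 1), "nonnegative")
})

test_that("exact-test p-values match the conditional-pmf enumeration oracle", {
  set.seed(5)
  for (i in 1:50) {
    y1 <- rpois(1, 20); y2 <- rpois(1, 20)
    p <- nb_exact_test(y1, y2, 1, 1, dispersion = 0.01)
    expect_equal(p, nb_exact_oracle(y1, y1 + y2, 0.01), tolerance = 1e-10)
  }
  # a strongly unbalanced pair at equal libraries
  expect_equal(nb_exact_test(20, 2, 1, 1, 0.01),
               nb_exact_oracle(20, 22, 0.01), tolerance = 1e-12)
})

test_that("the exact test is symmetric under swapping the two libraries", {
  set.seed(6)
  for (i in 1:25) {
    y1 <- rpois(1, 30); y2 <- rpois(1, 10)
    l1 <- runif(1, 0.5, 2); l2 <- runif(1, 0.5, 2)
    expect_equal(nb_exact_test(y1, y2, l1, l2),
                 nb_exact_test(y2, y1, l2, l1), tolerance = 1e-12)
  }
})

test_that("as dispersion vanishes the test approaches the binomial exact test", {
  binom_two_sided <- function(y1, s) {
    if (s == 0) return(1)
    pk <- dbinom(0:s, s, 0.5)
    min(1, sum(pk[log(pk) <= log(pk[y1 + 1]) + 1e-9]))
  }
  for (y1 in 0:12) for (y2 in c(0, 3, 9)) {
    expect_equal(nb_exact_test(y1, y2, 1, 1, dispersion = 1e-8),
                 binom_two_sided(y1, y1 + y2), tolerance = 1e-4)
  }
})

test_that("log2 fold change matches its closed form", {
  expect_equal(log2_fold_change(10, 5, 2, 1, prior = 0), 0)
  expect_equal(log2_fold_change(8, 2, 1, 1, prior = 0), 2)
  expect_equal(log2_fold_change(7, 3, 1, 1, prior = 0.5), log2(7.5 / 3.5))
})

test_that("BH step-up matches the closed form and the reference implementation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(8)
  p <- runif(100)
  expect_equal(bh_adjust(p), p.adjust(p, "BH"), tolerance = 1e-14)
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("run_de calls no direction for identical counts and needs controls", {
  sim <- simulate_experiment(sim_config(n_genes = 30, seed = 15, pi_de = 0,
                                        pi_bias = 0, switch_gain = 0))
  cnt <- sim$gene_counts
  cnt[, ] <- cnt[, "control_24h"]   # all libraries identical
  de <- run_de(cnt, sim$samples)
  expect_true(all(de$results$direction == "ns"))
  expect_true(all(de$results$p_value == 1))

  no_ctrl <- sim$samples[sim$samples$treatment != "control" |
                           sim$samples$time_h != 24, ]
  expect_error(run_de(cnt[, no_ctrl$sample_id], no_ctrl),
               class = "haplodyn_validation_error")
})

test_that("overlap accounting equals brute-force set algebra", {
  sim <- simulate_experiment(sim_config(n_genes = 400, seed = 16, pi_de = 0.3))
  de <- run_de(sim$gene_counts, sim$samples)
  res <- de$results
  for (tr in c("NaCl", "PEG")) {
    sets <- lapply(c(24, 48, 72), function(tp) {
      res$gene_id[res$treatment == tr & res$time_h == tp &
                    res$direction == "up"]
    })
    names(sets) <- paste0(tr, "_", c(24, 48, 72), "h")
    ws <- de$summary$within_stress
    ws <- ws[ws$treatment == tr & ws$direction == "up", ]
    # brute-force exclusive-region membership over the union
    ids <- unique(unlist(sets))
    memb <- sapply(sets, function(s) ids %in% s)
    if (length(ids) == 1) memb <- matrix(memb, 1, dimnames = list(NULL, names(sets)))
    for (i in seq_len(nrow(ws))) {
      inset <- strsplit(ws$combo[i], "&", fixed = TRUE)[[1]]
      expected <- sum(rowSums(memb[, inset, drop = FALSE]) == length(inset) &
                        rowSums(memb[, setdiff(names(sets), inset),
                                     drop = FALSE]) == 0)
      expect_identical(ws$n_exclusive[i], as.integer(expected))
    }
  }
})

test_that("power increases with the true effect size", {
  power_at <- function(fc, seed) {
    cfg <- sim_config(n_genes = 2000, seed = seed, pi_de = 0.5,
                      log2_de_range = c(fc, fc), pi_bias = 0, switch_gain = 0,
                      n_modules = 0)
    sim <- simulate_experiment(cfg)
    de <- run_de(sim$gene_counts, sim$samples)
    truth <- sim$truth$conditions
    truth <- truth[truth$treatment == "NaCl" & truth$time_h == 24, ]
    res <- de$results[de$results$treatment == "NaCl" & de$results$time_h == 24, ]
    hit <- res$q_value <= 0.05
    mean(hit[match(truth$gene_id[truth$de], res$gene_id)])
  }
  p1 <- power_at(0.5, 18); p2 <- power_at(1.0, 18); p3 <- power_at(2.0, 18)
  expect_lte(p1, p2 + 0.01)
  expect_lte(p2, p3 + 0.01)
  expect_gt(p3, 0.9)
})

test_that("empirical FDR stays controlled on a DE simulation", {
  cfg <- sim_config(n_genes = 4000, seed = 19, pi_de = 0.1,
                    log2_de_range = c(1.5, 3), pi_bias = 0, switch_gain = 0,
                    n_modules = 0)
  sim <- simulate_experiment(cfg)
  de <- run_de(sim$gene_counts, sim$samples)
  truth <- sim$truth$conditions
  fdrs <- sapply(c("NaCl", "PEG"), function(tr) {
    tt <- truth[truth$treatment == tr & truth$time_h == 24, ]
    res <- de$results[de$results$treatment == tr & de$results$time_h == 24, ]
    called <- res$gene_id[res$q_value <= 0.05]
    if (!length(called)) return(0)
    mean(!called %in% tt$gene_id[tt$de])
  })
  expect_true(all(fdrs <= 0.10))
})

test_that("exact-test p-values agree with the published package's double-tail test", {
  pairs <- list(c(20, 2), c(5, 9), c(100, 80), c(0, 7), c(15, 15), c(1, 40))
  for (pr in pairs) {
    mine <- nb_exact_test(pr[1], pr[2], 1e6, 1e6, dispersion = 0.01)
    ref <- edgeR::exactTestDoubleTail(matrix(pr[1]), matrix(pr[2]),
                                      dispersion = 0.01)
    expect_equal(mine, as.numeric(ref), tolerance = 1e-8)
  }
})
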