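test_that("call_bias implements the twofold rule with floor and boundary", {
  expect_identical(as.character(call_bias(10, 4)), "BIAS_A")     # ratio 2.5
  expect_identical(as.character(call_bias(6, 6)), "NO_BIAS")
  expect_identical(as.character(call_bias(0.1, 0.3)), "NOT_EXPRESSED")
  expect_identical(as.character(call_bias(2, 1)), "BIAS_A")      # inclusive
  expect_identical(as.character(call_bias(1, 2)), "BIAS_B")
  expect_identical(as.character(call_bias(1.9, 1)), "NO_BIAS")
  expect_error(call_bias(-1, 2), "nonnegative")
  expect_error(call_bias(1, 2, fold = 1), "fold")
})

test_that("call_bias is label-symmetric and scale-invariant", {
  set.seed(23)
  a <- rlnorm(200, 1, 1); b <- rlnorm(200, 1, 1)
  s1 <- as.character(call_bias(a, b))
  s2 <- as.character(call_bias(b, a))
  swap <- c(BIAS_A = "BIAS_B", BIAS_B = "BIAS_A", NO_BIAS = "NO_BIAS",
            NOT_EXPRESSED = "NOT_EXPRESSED")
  expect_identical(s2, unname(swap[s1]))
  # scaling both alleles leaves calls unchanged while above the floor
  above <- pmax(a, b) * 3 >= 0.5 & pmax(a, b) >= 0.5
  s3 <- as.character(call_bias(a * 3, b * 3))
  expect_identical(s3[above], s1[above])
})

test_that("trajectory classification matches the exhaustive truth table", {
  # oracle over the 2^3 collapsed statuses
  for (c1 in c("B", "N")) for (c2 in c("B", "N")) for (c3 in c("B", "N")) {
    st <- function(x) if (x == "B") "BIAS_A" else "NO_BIAS"
    got <- classify_trajectory(st(c1), st(c2), st(c3))
    trip <- paste0(c1, c2, c3)
    if (trip == "NNN") {
      expect_true(is.na(got$category))
      expect_identical(as.character(got$responsiveness), "excluded")
    } else {
      expect_identical(as.character(got$category),
                       ifelse(trip == "BBB", "CCC", trip))
      expected_resp <-
        if (trip == "BBB") "conserved"
        else if (c2 != c1 && c3 != c1) "both"
        else if (c2 != c1) "salt_specific"
        else "drought_specific"
      expect_identical(as.character(got$responsiveness), expected_resp)
    }
  }
  # spot checks pinned by the published accounting
  expect_identical(
    as.character(classify_trajectory("BIAS_A", "NO_BIAS", "NO_BIAS")$responsiveness),
    "both")
  expect_identical(
    as.character(classify_trajectory("BIAS_A", "NO_BIAS", "BIAS_A")$responsiveness),
    "salt_specific")
  expect_identical(
    as.character(classify_trajectory("NO_BIAS", "BIAS_A", "BIAS_B")$responsiveness),
    "both")
  expect_identical(
    as.character(classify_trajectory("BIAS_A", "BIAS_A", "BIAS_A")$category), "CCC")
})

test_that("NOT_EXPRESSED in any condition excludes the trajectory", {
  got <- classify_trajectory("NOT_EXPRESSED", "BIAS_A", "BIAS_A")
  expect_identical(as.character(got$responsiveness), "excluded")
  expect_true(is.na(got$category))
})

test_that("direction flips are flagged but classified as conserved bias", {
  got <- classify_trajectory("BIAS_A", "BIAS_B", "BIAS_A")
  expect_identical(as.character(got$category), "CCC")
  expect_identical(as.character(got$responsiveness), "conserved")
  expect_true(got$direction_flip)
  expect_false(classify_trajectory("BIAS_A", "BIAS_A", "NO_BIAS")$direction_flip)
})

test_that("responsiveness accounting identities hold on random fixtures", {
  set.seed(29)
  statuses <- c("BIAS_A", "BIAS_B", "NO_BIAS", "NOT_EXPRESSED")
  for (i in 1:40) {
    n <- sample(20:200, 1)
    tr <- tibble::tibble(
      gene_id = paste0("g", seq_len(n)),
      time_h = 24L,
      status_control = sample(statuses, n, TRUE),
      status_nacl = sample(statuses, n, TRUE),
      status_peg = sample(statuses, n, TRUE))
    tr <- dplyr::bind_cols(
      tr, classify_trajectory(tr$status_control, tr$status_nacl, tr$status_peg))
    s <- summarize_ase(tr)$responsiveness
    expect_identical(s$n_salt_responsive, s$n_both + s$n_salt_specific)
    expect_identical(s$n_drought_responsive, s$n_both + s$n_drought_specific)
    expect_identical(s$n_responsive,
                     s$n_both + s$n_salt_specific + s$n_drought_specific)
    cats <- summarize_ase(tr)$categories
    expect_identical(sum(cats$n), s$n_universe)
  }
})

test_that("summarize_ase handles an empty trajectory set", {
  tr <- trajectories_from_categories(
    tibble::tibble(time_h = 24L, category = "CCC", n = 0L))
  expect_identical(nrow(tr), 0L)
  tr2 <- tibble::tibble(gene_id = character(), time_h = integer(),
                        category = factor(character(),
                                          levels = c("CCC", "BBN", "BNN", "BNB",
                                                     "NBN", "NBB", "NNB")),
                        responsiveness = character())
  s <- summarize_ase(tr2)
  expect_identical(nrow(s$responsiveness), 0L)
})

test_that("run_ase finds no ASE genes in an unbiased simulation", {
  # well-measured genes (deep counts, narrow spread) so allelic ratios are
  # estimated rather than Poisson noise and the degenerate truth is exact
  sim <- simulate_experiment(sim_config(n_genes = 150, seed = 33, pi_bias = 0,
                                        switch_gain = 0, switch_loss = 0,
                                        baseline_logmean_mu = 7,
                                        baseline_logmean_sd = 0.5))
  ase <- run_ase(sim$allele_counts, sim$models, sim$samples)
  expect_identical(sum(ase$summary$responsiveness$n_universe), 0L)
  expect_length(ase$sets$salt_union, 0)
})

test_that("run_ase recovers strong allelic bias with high sensitivity", {
  cfg <- sim_config(n_genes = 3000, seed = 34, pi_bias = 0.5,
                    log2_bias_range = c(1.5, 3.5), pi_de = 0)
  sim <- simulate_experiment(cfg)
  ase <- run_ase(sim$allele_counts, sim$models, sim$samples)
  gene_fpkm <- fpkm(sim$gene_counts, models = sim$models)
  mean_fpkm <- rowMeans(gene_fpkm)
  truth <- sim$truth$conditions
  truth24 <- truth[truth$treatment == "control" & truth$time_h == 24, ]
  target <- truth24$gene_id[truth24$biased &
                              mean_fpkm[truth24$gene_id] >= 10]
  traj <- ase$trajectories[ase$trajectories$time_h == 24, ]
  called <- traj$gene_id[traj$status_control %in% c("BIAS_A", "BIAS_B")]
  expect_gte(mean(target %in% called), 0.9)
})

test_that("run_ase warns on unpaired alleles and errors past 50 percent", {
  sim <- simulate_experiment(sim_config(n_genes = 40, seed = 35))
  drop <- sim$models$allele_b[1:4]
  cnt <- sim$allele_counts[!rownames(sim$allele_counts) %in% drop, ]
  expect_warning(run_ase(cnt, sim$models, sim$samples), "dropped")
  cnt2 <- sim$allele_counts[sim$models$allele_a[1:15], ]
  expect_error(run_ase(cnt2, sim$models, sim$samples), "half")
})

test_that("chromosome distribution covers responsive genes by stress", {
  sim <- simulate_experiment(sim_config(n_genes = 500, seed = 36))
  ase <- run_ase(sim$allele_counts, sim$models, sim$samples)
  chr <- ase$summary$chromosomes
  expect_true(!is.null(chr))
  salt_total <- sum(chr$n[chr$stress == "salt"])
  resp <- ase$trajectories
  salt_genes <- unique(resp$gene_id[resp$responsiveness %in%
                                      c("both", "salt_specific")])
  expect_identical(salt_total, length(salt_genes))
})
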