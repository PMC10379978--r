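test_that("topological overlap matches brute-force evaluation", {
  set.seed(41)
  for (i in 1:10) {
    a <- random_adjacency(sample(6:12, 1))
    tom <- topological_overlap(a)
    expect_equal(unname(tom), tom_brute(a), tolerance = 1e-12)
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  }
})

test_that("topological overlap handles degenerate graphs", {
  a0 <- diag(5); dimnames(a0) <- list(paste0("g", 1:5), paste0("g", 1:5))
  t0 <- topological_overlap(a0)
  expect_equal(unname(t0), diag(5))
  a1 <- matrix(1, 4, 4, dimnames = list(paste0("g", 1:4), paste0("g", 1:4)))
  expect_equal(unname(topological_overlap(a1)), matrix(1, 4, 4))
  bad <- matrix(runif(16), 4)
  expect_error(topological_overlap(bad), "symmetric")
})

test_that("soft-threshold selection follows the scale-free fit rule", {
  sim <- simulate_experiment(sim_config(n_genes = 300, seed = 43,
                                        n_modules = 2, module_size = 60,
                                        pi_de = 0, n_reps = 2))
  e <- fpkm(sim$gene_counts, models = sim$models)
  ps <- pick_soft_threshold(e, powers = 1:12)
  expect_true(ps$power %in% 1:12)
  expect_identical(nrow(ps$fit), 12L)
  # mean connectivity must decrease with the power
  expect_true(all(diff(ps$fit$mean_connectivity) < 0))
  # selection is reproducible from the reported fit table
  ok <- which(!is.na(ps$fit$r_squared) & ps$fit$r_squared >= 0.85)
  expected <- if (length(ok)) ps$fit$power[ok[1]] else
    ps$fit$power[which.max(ps$fit$r_squared)]
  expect_identical(ps$power, expected)
  # the fit statistic itself matches a direct log-log regression
  ac <- abs(stats::cor(t(e[apply(e, 1, sd) > 0, ]))); diag(ac) <- 0
  k <- rowSums(ac^6)
  bins <- cut(k[k > 0], 10)
  freq <- tapply(k[k > 0], bins, length); mk <- tapply(k[k > 0], bins, mean)
  ok2 <- !is.na(freq)
  fit <- lm(log10(freq[ok2]) ~ log10(mk[ok2]))
  expect_equal(ps$fit$r_squared[ps$fit$power == 6],
               -sign(coef(fit)[[2]]) * summary(fit)$r.squared,
               tolerance = 1e-10)
  expect_error(pick_soft_threshold(e[1:2, ]), "50 genes")
})

test_that("module detection greys out undersized clusters", {
  sim <- simulate_experiment(sim_config(n_genes = 100, seed = 44))
  e <- fpkm(sim$gene_counts, models = sim$models)
  adj <- adjacency_matrix(e, 6)
  tom <- topological_overlap(adj)
  expect_warning(det <- detect_modules(tom, e, min_module_size = 1000),
                 "grey")
  expect_true(all(det$modules$module == "grey"))
})

test_that("strongly correlated planted modules merge by eigengene similarity", {
  set.seed(45)
  ns <- 20
  z <- rnorm(ns)
  z2 <- 0.95 * z + sqrt(1 - 0.95^2) * rnorm(ns)  # eigengene cor ~ 0.95
  mk <- function(base, n) t(sapply(seq_len(n), function(i) {
    exp(3 + base + rnorm(ns, 0, 0.2))
  }))
  e <- rbind(mk(z, 30), mk(z2, 30))
  rownames(e) <- paste0("g", 1:60)
  colnames(e) <- paste0("s", 1:ns)
  adj <- adjacency_matrix(e, 6)
  tom <- topological_overlap(adj)
  det <- detect_modules(tom, e, min_module_size = 10, branch_cut = 0.6,
                        merge_cut_height = 0.3)
  got <- det$modules$module
  expect_identical(length(unique(got[got != "grey"])), 1L)
})

test_that("the eigengene is the leading principal component", {
  sim <- simulate_experiment(sim_config(n_genes = 200, seed = 46,
                                        n_modules = 1, module_size = 80,
                                        pi_de = 0, n_reps = 3))
  e <- fpkm(sim$gene_counts, models = sim$models)
  genes <- sim$models$gene_id[1:80]
  em <- scale(t(e[genes, ]))
  eig <- haplodyn:::module_eigengene(e, genes)
  # variance explained by the eigengene >= by any single member profile
  expl <- function(u) sum((t(em) %*% u / sqrt(sum(u^2)))^2)
  e_eig <- expl(eig)
  for (g in sample(genes, 10)) expect_gte(e_eig + 1e-8, expl(em[, g]))
  # sign convention: positive correlation with the module mean profile
  expect_gt(cor(eig, rowMeans(em)), 0)
})

test_that("module labels are invariant to gene order", {
  sim <- simulate_experiment(sim_config(n_genes = 300, seed = 47,
                                        n_modules = 2, module_size = 80,
                                        pi_de = 0, n_reps = 3))
  e <- fpkm(sim$gene_counts, models = sim$models)
  tom <- topological_overlap(adjacency_matrix(e, 6))
  det1 <- detect_modules(tom, e, min_module_size = 40)
  set.seed(48)
  perm <- sample(nrow(e))
  det2 <- detect_modules(tom[perm, perm], e[perm, ], min_module_size = 40)
  m1 <- det1$modules$module[match(rownames(e), det1$modules$gene_id)]
  m2 <- det2$modules$module[match(rownames(e), det2$modules$gene_id)]
  expect_equal(mclust::adjustedRandIndex(m1, m2), 1)
})

test_that("module-trait correlation matches the closed-form t test", {
  sim <- simulate_experiment(sim_config(n_genes = 60, seed = 49))
  samples <- sim$samples
  tr <- haplodyn:::trait_matrix(samples)
  # eigengene equal to a trait indicator: r = 1
  me <- cbind(module_1 = tr[, "NaCl_24h"])
  mt <- module_trait(me, samples)
  expect_equal(mt$r[mt$trait == "NaCl_24h"], 1)
  # orthogonal contrast: zero correlation
  x <- rep(c(1, -1), 5); x <- x - mean(x)
  ind <- tr[, "PEG_48h"] - mean(tr[, "PEG_48h"])
  x <- x - sum(x * ind) / sum(ind^2) * ind
  me2 <- cbind(module_1 = x)
  mt2 <- module_trait(me2, samples)
  expect_lt(abs(mt2$r[mt2$trait == "PEG_48h"]), 1e-12)
  # p matches cor.test
  set.seed(50)
  me3 <- cbind(module_1 = rnorm(10))
  mt3 <- module_trait(me3, samples)
  for (g in c("control_0h", "NaCl_72h")) {
    ct <- cor.test(me3[, 1], tr[, g])
    expect_equal(mt3$r[mt3$trait == g], unname(ct$estimate), tolerance = 1e-12)
    expect_equal(mt3$p_value[mt3$trait == g], ct$p.value, tolerance = 1e-12)
  }
})

test_that("hub screening applies strict GS/MM thresholds and counts edges", {
  sim <- simulate_experiment(sim_config(n_genes = 300, seed = 51,
                                        n_modules = 2, module_size = 80,
                                        pi_de = 0.2, n_reps = 3))
  e <- fpkm(sim$gene_counts, models = sim$models)
  net <- build_coexpression_network(e, sim$samples, power = 6,
                                    min_module_size = 40)
  hb <- hub_screen(net, edge_weight_min = 0.3)
  # edge counts equal brute-force thresholded row counts within modules
  mods <- net$modules
  for (m in setdiff(unique(mods$module), "grey")) {
    g <- mods$gene_id[mods$module == m]
    a <- net$adjacency[g, g]
    diag(a) <- 0
    brute <- rowSums(a >= 0.3)
    got <- hb$edge_counts$n_edges[match(g, hb$edge_counts$gene_id)]
    expect_identical(got, as.integer(brute))
  }
  # strictly-greater screening: a gene at GS exactly 0.2 or MM 0.8 is out
  net2 <- net
  gene1 <- hb$edge_counts$gene_id[hb$edge_counts$module != "grey"][1]
  net2$gs[gene1, ] <- 0.19
  hb2 <- hub_screen(net2)
  expect_false(gene1 %in% hb2$hubs$gene_id)
  # no edges above an impossible threshold
  hb3 <- hub_screen(net, edge_weight_min = 1.01)
  expect_identical(nrow(hb3$edges), 0L)
  expect_true(all(hb3$edge_counts$n_edges == 0L))
})
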