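#' Soft-threshold adjacency matrix
#'
#' Unsigned weighted adjacency `|cor(g_i, g_j)|^power` between gene
#' expression profiles (Pearson), with unit diagonal.
#'
#' @param expr Expression matrix (genes x samples), e.g. FPKM.
#' @param power Soft-threshold exponent beta.
#' @return Symmetric adjacency matrix in `[0, 1]`.
#' @export
adjacency_matrix <- function(expr, power) {
  if (ncol(expr) < 4) stop_hd("need at least 4 samples")
  sds <- apply(expr, 1, stats::sd)
  if (any(sds == 0)) stop_hd("constant-expression genes present; drop them first")
  a <- abs(stats::cor(t(expr)))^power
  diag(a) <- 1
  a
}

# signed scale-free topology fit index: R^2 of log10(freq) on log10(k) over
# equal-width connectivity bins, negated when the slope is positive
scale_free_r2 <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < 3) return(NA_real_)
  bins <- cut(k, breaks = n_bins)
  freq <- tapply(k, bins, length)
  mean_k <- tapply(k, bins, mean)
  ok <- !is.na(freq) & freq > 0
  if (sum(ok) < 3) return(NA_real_)
  fit <- stats::lm(log10(freq[ok]) ~ log10(mean_k[ok]))
  r2 <- summary(fit)$r.squared
  unname(-sign(stats::coef(fit)[2]) * r2)
}

#' Choose the soft-threshold power by scale-free fit
#'
#' For each candidate power, computes the connectivity distribution of the
#' unsigned adjacency and its scale-free topology fit (signed R^2 of the
#' log-log frequency/connectivity regression over binned connectivities).
#' Returns the smallest power whose fit reaches `target_r2`; if none does,
#' the power maximising the fit (preferring 6 on ties).
#'
#' @param expr Expression matrix (genes x samples); at least 4 samples and
#'   50 genes. Constant-expression genes are dropped with a warning.
#' @param powers Candidate integer powers.
#' @param target_r2 Fit threshold, default 0.85.
#' @param n_bins Connectivity bins for the fit.
#' @return List: `power` (selected), `fit` tibble (power, r_squared,
#'   mean_connectivity).
#' @export
pick_soft_threshold <- function(expr, powers = 1:20, target_r2 = 0.85,
                                n_bins = 10) {
  if (ncol(expr) < 4) stop_hd("need at least 4 samples")
  sds <- apply(expr, 1, stats::sd)
  if (any(sds == 0)) {
    warn(sprintf("dropping %d constant-expression gene(s)", sum(sds == 0)))
    expr <- expr[sds > 0, , drop = FALSE]
  }
  if (nrow(expr) < 50) stop_hd("need at least 50 genes for scale-free fitting")
  ac <- abs(stats::cor(t(expr)))
  diag(ac) <- 0
  fit <- purrr::map_dfr(powers, function(b) {
    k <- rowSums(ac^b)
    tibble(power = b, r_squared = scale_free_r2(k, n_bins),
           mean_connectivity = mean(k))
  })
  ok <- which(!is.na(fit$r_squared) & fit$r_squared >= target_r2)
  if (length(ok)) {
    power <- fit$power[ok[1]]
  } else {
    best <- which(fit$r_squared == max(fit$r_squared, na.rm = TRUE))
    power <- if (length(best) > 1 && 6 %in% fit$power[best]) 6L else fit$power[best[1]]
  }
  list(power = power, fit = fit)
}

#' Topological overlap matrix
#'
#' Unsigned TOM of a weighted network:
#' `tom_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for
#' `i != j` (connectivities `k` and shared-neighbour sums exclude the
#' diagonal), `tom_ii = 1`.
#'
#' @param adjacency Symmetric matrix in `[0, 1]`.
#' @return Symmetric TOM matrix in `[0, 1]` with unit diagonal.
#' @export
topological_overlap <- function(adjacency) {
  if (!isSymmetric(unname(adjacency), tol = 1e-10)) {
    stop_hd("adjacency must be symmetric")
  }
  a <- adjacency
  diag(a) <- 0
  shared <- a %*% a
  k <- rowSums(a)
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (shared + a) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

# first principal component of the module's standardized expression
# (samples-length), sign-aligned with the module mean profile
module_eigengene <- function(expr, genes) {
  e <- t(expr[genes, , drop = FALSE])
  e <- scale(e)
  e[is.na(e)] <- 0
  sv <- svd(e, nu = 1, nv = 0)
  eig <- sv$u[, 1]
  mean_profile <- rowMeans(e)
  if (stats::cor(eig, mean_profile) < 0) eig <- -eig
  stats::setNames(eig, colnames(expr))
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering on `1 - TOM`, cut at a static
#' height (`branch_cut`); clusters smaller than `min_module_size` become
#' `grey` (unassigned). Module eigengenes (first PC of the standardized
#' module expression, sign-aligned with the module mean profile) are then
#' iteratively merged closest-pair-first while the eigengene dissimilarity
#' `1 - cor` is below `merge_cut_height`, recomputing eigengenes after each
#' merge.
#'
#' @param tom TOM matrix from [topological_overlap()].
#' @param expr Expression matrix used to build the network (genes x samples).
#' @param min_module_size Minimum module size, default 80.
#' @param merge_cut_height Eigengene-dissimilarity merge threshold,
#'   default 0.3.
#' @param branch_cut Static tree-cut height on `1 - TOM`, default 0.95.
#' @return List: `modules` tibble (`gene_id`, `module`; `grey` =
#'   unassigned), `eigengenes` (samples x modules matrix), `hclust`.
#' @export
detect_modules <- function(tom, expr, min_module_size = 80,
                           merge_cut_height = 0.3, branch_cut = 0.95) {
  stopifnot(identical(rownames(tom), rownames(expr)))
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  cl <- stats::cutree(hc, h = branch_cut)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_module_size]
  lab <- rep("grey", nrow(tom))
  if (length(keep)) {
    ord <- keep[order(-sizes[keep])]
    for (i in seq_along(ord)) lab[cl == as.integer(ord[i])] <- sprintf("module_%d", i)
  }
  names(lab) <- rownames(tom)

  if (!any(lab != "grey")) {
    warn("no module reaches min_module_size; all genes grey")
    return(list(modules = tibble(gene_id = rownames(tom), module = lab),
                eigengenes = NULL, hclust = hc))
  }

  eigs <- function(labels) {
    mods <- setdiff(unique(labels), "grey")
    sapply(stats::setNames(mods, mods), function(m) {
      module_eigengene(expr, names(labels)[labels == m])
    })
  }
  me <- eigs(lab)
  # closest-pair-first eigengene merging
  repeat {
    if (ncol(me) < 2) break
    cc <- stats::cor(me)
    diag(cc) <- -Inf
    top <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    if (1 - max(cc) >= merge_cut_height) break
    m1 <- colnames(me)[top[1]]; m2 <- colnames(me)[top[2]]
    lab[lab == m2] <- m1
    me <- eigs(lab)
  }
  # relabel by decreasing size for stable naming
  mods <- setdiff(unique(lab), "grey")
  mods <- mods[order(-vapply(mods, function(m) sum(lab == m), numeric(1)))]
  new <- stats::setNames(sprintf("module_%d", seq_along(mods)), mods)
  lab[lab != "grey"] <- new[lab[lab != "grey"]]
  me <- eigs(lab)
  list(modules = tibble(gene_id = rownames(tom), module = unname(lab)),
       eigengenes = me, hclust = hc)
}

# one-hot trait indicators, one per (treatment, time) library group
trait_matrix <- function(samples) {
  grp <- condition_id(samples$treatment, samples$time_h)
  lev <- unique(grp)
  tr <- sapply(stats::setNames(lev, lev), function(g) as.numeric(grp == g))
  rownames(tr) <- samples$sample_id
  tr
}

#' Module-trait correlation
#'
#' Pearson correlation between each module eigengene and one-hot indicators
#' of the (treatment, time) sample groups, with two-sided p-values from the
#' t distribution on `n - 2` degrees of freedom.
#'
#' @param eigengenes Samples x modules matrix from [detect_modules()].
#' @param samples Sample sheet matching the eigengene rows.
#' @return Tibble: `module`, `trait`, `r`, `p_value` (`NA` for
#'   zero-variance traits).
#' @export
module_trait <- function(eigengenes, samples) {
  samples <- validate_sample_sheet(samples)
  tr <- trait_matrix(samples)[rownames(eigengenes) %||% samples$sample_id, , drop = FALSE]
  n <- nrow(tr)
  purrr::map_dfr(colnames(eigengenes), function(m) {
    purrr::map_dfr(colnames(tr), function(g) {
      x <- tr[, g]
      if (stats::sd(x) == 0) return(tibble(module = m, trait = g,
                                           r = NA_real_, p_value = NA_real_))
      r <- stats::cor(eigengenes[, m], x)
      tt <- r * sqrt((n - 2) / (1 - r^2))
      tibble(module = m, trait = g, r = r,
             p_value = 2 * stats::pt(-abs(tt), df = n - 2))
    })
  })
}

#' Build the full weighted co-expression network
#'
#' Convenience wrapper: drops constant genes, picks the soft-threshold power
#' (unless given), computes adjacency and TOM, detects and merges modules,
#' and attaches module-trait correlations, gene significance (GS: gene-trait
#' correlation) and module membership (MM: gene-eigengene correlation).
#'
#' @param expr Expression matrix (genes x samples), typically FPKM after
#'   [low_expression_filter()].
#' @param samples Sample sheet for the columns of `expr`.
#' @param power Soft threshold; `NULL` to select via
#'   [pick_soft_threshold()].
#' @param powers,target_r2 Passed to [pick_soft_threshold()].
#' @param min_module_size,merge_cut_height,branch_cut Passed to
#'   [detect_modules()].
#' @return Object of class `hd_network` with elements `gene_ids`, `power`,
#'   `adjacency`, `tom`, `connectivity`, `modules`, `eigengenes`,
#'   `module_trait`, `gs`, `mm`, `samples`, `soft_fit`.
#' @export
build_coexpression_network <- function(expr, samples, power = NULL,
                                       powers = 1:20, target_r2 = 0.85,
                                       min_module_size = 80,
                                       merge_cut_height = 0.3,
                                       branch_cut = 0.95) {
  samples <- validate_sample_sheet(samples)
  expr <- expr[, samples$sample_id, drop = FALSE]
  sds <- apply(expr, 1, stats::sd)
  if (any(sds == 0)) {
    warn(sprintf("dropping %d constant-expression gene(s)", sum(sds == 0)))
    expr <- expr[sds > 0, , drop = FALSE]
  }
  soft_fit <- NULL
  if (is.null(power)) {
    ps <- pick_soft_threshold(expr, powers = powers, target_r2 = target_r2)
    power <- ps$power
    soft_fit <- ps$fit
  }
  adj <- adjacency_matrix(expr, power)
  tom <- topological_overlap(adj)
  det <- detect_modules(tom, expr, min_module_size = min_module_size,
                        merge_cut_height = merge_cut_height,
                        branch_cut = branch_cut)
  traits <- trait_matrix(samples)
  gs <- stats::cor(t(expr), traits)
  mt <- NULL; mm <- NULL
  if (!is.null(det$eigengenes)) {
    mt <- module_trait(det$eigengenes, samples)
    mm <- stats::cor(t(expr), det$eigengenes)
  }
  structure(list(gene_ids = rownames(expr), power = power,
                 adjacency = adj, tom = tom,
                 connectivity = rowSums(adj) - 1,
                 modules = det$modules, eigengenes = det$eigengenes,
                 hclust = det$hclust, module_trait = mt,
                 gs = gs, mm = mm, expr = expr, samples = samples,
                 soft_fit = soft_fit),
            class = "hd_network")
}

#' @export
print.hd_network <- function(x, ...) {
  tab <- table(x$modules$module)
  cat(sprintf("<hd_network> %d genes, power %d, %d module(s)\n",
              length(x$gene_ids), x$power, sum(names(tab) != "grey")))
  print(tab)
  invisible(x)
}

#' Hub-gene screening and edge export
#'
#' Exports within-module edges whose adjacency weight is at least
#' `edge_weight_min`, counts per-gene edges at that threshold, and screens
#' hub genes: module members passing `|GS| > gs_min` (for any trait) and
#' `|MM| > mm_min` (own module), ranked by edge count. Per-gene edge-count
#' tiers at `tiers` support connectivity-intersection reports.
#'
#' @param network `hd_network` from [build_coexpression_network()].
#' @param gs_min,mm_min Screening thresholds (strict inequalities),
#'   defaults 0.2 and 0.8.
#' @param edge_weight_min Minimum adjacency for an exported edge,
#'   default 0.3.
#' @param top_k Hubs reported per module, default 20.
#' @param tiers Edge-count tiers, default `c(5, 50)`.
#' @return List of class `hd_hubs`: `edges` tibble (source, target, weight,
#'   module), `edge_counts` tibble (gene_id, module, n_edges, plus one
#'   logical column per tier), `hubs` tibble.
#' @export
hub_screen <- function(network, gs_min = 0.2, mm_min = 0.8,
                       edge_weight_min = 0.3, top_k = 20, tiers = c(5, 50)) {
  stopifnot(inherits(network, "hd_network"))
  if (is.null(network$eigengenes)) stop_hd("network has no modules with eigengenes")
  mods <- network$modules
  edges <- purrr::map_dfr(setdiff(unique(mods$module), "grey"), function(m) {
    g <- mods$gene_id[mods$module == m]
    a <- network$adjacency[g, g, drop = FALSE]
    idx <- which(upper.tri(a) & a >= edge_weight_min, arr.ind = TRUE)
    if (!nrow(idx)) return(tibble(source = character(), target = character(),
                                  weight = numeric(), module = character()))
    tibble(source = g[idx[, 1]], target = g[idx[, 2]],
           weight = a[idx], module = m)
  })
  counts <- table(factor(c(edges$source, edges$target), levels = mods$gene_id))
  edge_counts <- tibble(gene_id = mods$gene_id, module = mods$module,
                        n_edges = as.integer(counts[mods$gene_id]))
  for (t in tiers) edge_counts[[paste0("ge_", t)]] <- edge_counts$n_edges >= t

  max_gs <- apply(abs(network$gs), 1, max)
  own_mm <- rep(NA_real_, nrow(mods))
  member <- mods$module != "grey"
  own_mm[member] <- network$mm[cbind(match(mods$gene_id[member], rownames(network$mm)),
                                     match(mods$module[member], colnames(network$mm)))]
  hubs <- tibble(gene_id = mods$gene_id, module = mods$module,
                 n_edges = edge_counts$n_edges,
                 max_abs_gs = max_gs[mods$gene_id],
                 abs_mm = abs(own_mm))
  hubs <- hubs[member & hubs$max_abs_gs > gs_min & hubs$abs_mm > mm_min, ]
  hubs <- dplyr::slice_head(
    dplyr::arrange(dplyr::group_by(hubs, .data$module),
                   dplyr::desc(.data$n_edges)), n = top_k)
  hubs <- dplyr::ungroup(hubs)
  structure(list(edges = edges, edge_counts = edge_counts, hubs = hubs,
                 edge_weight_min = edge_weight_min),
            class = "hd_hubs")
}
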