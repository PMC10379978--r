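#' Fixed-dispersion negative-binomial exact test for two libraries
#'
#' Exact test for a difference in expression between two libraries without
#' replicates, assuming a known negative-binomial dispersion (the square of
#' the biological coefficient of variation). Counts are first rescaled to a
#' common effective library size (the geometric mean of `lib1` and `lib2`)
#' by mean-preserving scaling and rounding. Conditional on the rescaled sum
#' `s`, the null distribution of the first count is the two-group NB
#' conditional with equal size parameters `1/dispersion` (a beta-binomial
#' form), and the two-sided p-value sums the probabilities of all outcomes
#' no more likely than the observed one, capped at 1.
#'
#' @param y1,y2 Nonnegative integer counts (vectorised; recycled pairwise).
#' @param lib1,lib2 Positive library sizes.
#' @param dispersion NB dispersion phi (default `0.01`, i.e. BCV 0.1).
#' @return Vector of two-sided p-values.
#' @examples
#' nb_exact_test(20, 2, 1e6, 1e6, dispersion = 0.01)
#' @export
nb_exact_test <- function(y1, y2, lib1 = 1, lib2 = 1, dispersion = 0.01) {
  if (dispersion <= 0) stop_hd("dispersion must be positive")
  if (any(y1 < 0) || any(y2 < 0)) stop_hd("counts must be nonnegative")
  if (lib1 <= 0 || lib2 <= 0) stop_hd("library sizes must be positive")
  n <- max(length(y1), length(y2))
  y1 <- rep_len(y1, n); y2 <- rep_len(y2, n)
  L <- sqrt(as.numeric(lib1) * as.numeric(lib2))
  y1p <- round(y1 * L / lib1)
  y2p <- round(y2 * L / lib2)
  vapply(seq_len(n), function(i) {
    nb_exact_p(y1p[i], y1p[i] + y2p[i], 1 / dispersion)
  }, numeric(1))
}

# conditional two-sided p for observing y1 of s under equal-size NB groups
nb_exact_p <- function(y1, s, r) {
  if (s == 0) return(1)
  k <- 0:s
  logp <- lchoose(k + r - 1, k) + lchoose(s - k + r - 1, s - k) -
    lchoose(s + 2 * r - 1, s)
  obs <- logp[y1 + 1]
  # log-scale tolerance so exactly tied (mirror-image) outcomes are included
  p <- sum(exp(logp[logp <= obs + 1e-9]))
  if (p >= 1 - 1e-12) 1 else p
}

#' Normalized log2 fold change between two libraries
#'
#' `log2((y_t + prior)/lib_t) - log2((y_c + prior)/lib_c)`; the prior count
#' keeps zero counts finite.
#'
#' @param y_treated,y_control Counts (vectorised).
#' @param lib_treated,lib_control Positive library sizes.
#' @param prior Prior count, default 0.5.
#' @return Numeric vector of log2 fold changes (treated over control).
#' @export
log2_fold_change <- function(y_treated, y_control, lib_treated = 1,
                             lib_control = 1, prior = 0.5) {
  if (lib_treated <= 0 || lib_control <= 0) stop_hd("library sizes must be positive")
  log2((y_treated + prior) / lib_treated) - log2((y_control + prior) / lib_control)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min_{j >= i} (m/j) p_(j)` on the sorted p-values, mapped back to
#' the input order and capped at 1.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Vector of q-values in input order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop_hd("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(m / (m:1) * p[o]))
  q[order(o)]
}

#' Pairwise treated-vs-control differential expression
#'
#' Runs the fixed-dispersion NB exact test for every gene in every
#' (treatment, time) library against its same-time control, adjusts p-values
#' by Benjamini-Hochberg within each comparison, calls direction at
#' `q <= alpha`, and assembles the overlap accounting: up/down counts per
#' comparison, exclusive-region intersections across the three time points
#' within each stress and across stresses at matched time points, and the
#' direction-consistent pooled union DEG sets.
#'
#' @param gene_counts Gene-level count matrix.
#' @param samples Validated sample sheet covering the matrix columns.
#' @param alpha FDR threshold, default 0.05.
#' @param bcv Biological coefficient of variation, default 0.1
#'   (dispersion `bcv^2`).
#' @param prior Prior count for fold changes.
#' @return An object of class `hd_de`: `results` tibble (gene_id, treatment,
#'   time_h, log2fc, p_value, q_value, direction), and `summary` with
#'   `counts`, `within_stress`, `between_stress` upset tibbles and
#'   `union_up` / `union_down` gene sets.
#' @export
run_de <- function(gene_counts, samples, alpha = 0.05, bcv = 0.1, prior = 0.5) {
  assert_matrix_counts(gene_counts, "gene count matrix")
  samples <- validate_sample_sheet(samples)
  samples <- bind_library_sizes(samples, gene_counts)
  phi <- bcv^2
  treated <- samples[samples$treatment != "control", ]
  results <- purrr::pmap_dfr(
    treated[, c("sample_id", "treatment", "time_h")],
    function(sample_id, treatment, time_h) {
      ctrl <- samples$sample_id[samples$treatment == "control" &
                                  samples$time_h == time_h]
      if (length(ctrl) != 1) {
        stop_hd(sprintf("no unique control library at %d h", time_h))
      }
      yt <- gene_counts[, sample_id]
      yc <- gene_counts[, ctrl]
      lt <- samples$library_size[samples$sample_id == sample_id]
      lc <- samples$library_size[samples$sample_id == ctrl]
      p <- nb_exact_test(yt, yc, lt, lc, dispersion = phi)
      q <- bh_adjust(p)
      lfc <- log2_fold_change(yt, yc, lt, lc, prior = prior)
      tibble(gene_id = rownames(gene_counts),
             treatment = as.character(treatment), time_h = time_h,
             log2fc = lfc, p_value = p, q_value = q,
             direction = dplyr::case_when(
               q <= alpha & lfc > 0 ~ "up",
               q <= alpha & lfc < 0 ~ "down",
               TRUE ~ "ns"))
    })

  de_sets <- function(dir) {
    res <- results[results$direction == dir, ]
    split(res$gene_id, paste0(res$treatment, "_", res$time_h, "h"))
  }
  sets_up <- de_sets("up"); sets_down <- de_sets("down")
  counts <- dplyr::summarise(
    dplyr::group_by(results, .data$treatment, .data$time_h),
    n_up = sum(.data$direction == "up"),
    n_down = sum(.data$direction == "down"), .groups = "drop")

  pad <- function(sets, keys) {
    out <- stats::setNames(vector("list", length(keys)), keys)
    for (k in keys) out[[k]] <- if (k %in% names(sets)) sets[[k]] else character(0)
    out
  }
  within_stress <- purrr::map_dfr(c("NaCl", "PEG"), function(tr) {
    keys <- paste0(tr, "_", c(24, 48, 72), "h")
    dplyr::bind_rows(
      dplyr::mutate(upset_counts(pad(sets_up, keys)), direction = "up", treatment = tr),
      dplyr::mutate(upset_counts(pad(sets_down, keys)), direction = "down", treatment = tr))
  })
  between_stress <- purrr::map_dfr(c(24, 48, 72), function(tp) {
    keys <- paste0(c("NaCl", "PEG"), "_", tp, "h")
    dplyr::bind_rows(
      dplyr::mutate(upset_counts(pad(sets_up, keys)), direction = "up", time_h = tp),
      dplyr::mutate(upset_counts(pad(sets_down, keys)), direction = "down", time_h = tp))
  })
  all_up <- unique(unlist(sets_up)); all_down <- unique(unlist(sets_down))
  structure(list(
    results = results,
    summary = list(counts = counts,
                   within_stress = within_stress,
                   between_stress = between_stress,
                   union_up = sort(setdiff(all_up, all_down)),
                   union_down = sort(setdiff(all_down, all_up))),
    alpha = alpha, bcv = bcv), class = "hd_de")
}

#' @export
print.hd_de <- function(x, ...) {
  cat(sprintf("<hd_de> %d tests, alpha = %g, BCV = %g\n",
              nrow(x$results), x$alpha, x$bcv))
  print(x$summary$counts)
  invisible(x)
}
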