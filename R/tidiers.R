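#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy differential-expression results
#'
#' @param x An `hd_de` from [run_de()].
#' @param ... Unused.
#' @return The per-gene, per-comparison results tibble.
#' @export
tidy.hd_de <- function(x, ...) x$results

#' One-row-per-comparison DE summary
#'
#' @param x An `hd_de`.
#' @param ... Unused.
#' @return Tibble of up/down counts per comparison with the union set sizes.
#' @export
glance.hd_de <- function(x, ...) {
  dplyr::mutate(x$summary$counts,
                n_union_up = length(x$summary$union_up),
                n_union_down = length(x$summary$union_down),
                alpha = x$alpha, bcv = x$bcv)
}

#' Tidy ASE trajectories
#'
#' @param x An `hd_ase` from [run_ase()].
#' @param ... Unused.
#' @return The per-gene, per-time trajectory tibble.
#' @export
tidy.hd_ase <- function(x, ...) x$trajectories

#' Per-time-point ASE responsiveness summary
#'
#' @param x An `hd_ase` or `hd_ase_summary`.
#' @param ... Unused.
#' @return The responsiveness accounting tibble.
#' @export
glance.hd_ase <- function(x, ...) x$summary$responsiveness

#' @rdname glance.hd_ase
#' @export
glance.hd_ase_summary <- function(x, ...) x$responsiveness

#' Tidy network module assignments
#'
#' @param x An `hd_network`.
#' @param ... Unused.
#' @return Tibble of gene-module assignments with connectivity and own-module
#'   membership.
#' @export
tidy.hd_network <- function(x, ...) {
  out <- x$modules
  out$connectivity <- x$connectivity[out$gene_id]
  if (!is.null(x$mm)) {
    member <- out$module != "grey"
    mm <- rep(NA_real_, nrow(out))
    mm[member] <- x$mm[cbind(match(out$gene_id[member], rownames(x$mm)),
                             match(out$module[member], colnames(x$mm)))]
    out$module_membership <- mm
  }
  out
}

#' One-row-per-module network summary
#'
#' @param x An `hd_network`.
#' @param ... Unused.
#' @return Tibble with module sizes and the strongest trait correlation per
#'   module.
#' @export
glance.hd_network <- function(x, ...) {
  sizes <- table(x$modules$module)
  out <- tibble(module = names(sizes), n_genes = as.integer(sizes),
                power = x$power)
  if (!is.null(x$module_trait)) {
    best <- dplyr::slice_max(dplyr::group_by(x$module_trait, .data$module),
                             abs(.data$r), n = 1, with_ties = FALSE)
    out <- dplyr::left_join(out,
                            dplyr::select(dplyr::ungroup(best), "module",
                                          best_trait = "trait", best_r = "r",
                                          best_p = "p_value"),
                            by = "module")
  }
  out
}

#' Bias-category composition plot
#'
#' Stacked per-time-point bars of the seven bias-trajectory categories.
#'
#' @param object An `hd_ase_summary` (or `hd_ase`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hd_ase_summary <- function(object, ...) {
  d <- object$categories
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$time_h),
                                  y = .data$n, fill = .data$category)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = "time (h)", y = "genes",
                  fill = "bias category",
                  title = "Bias-trajectory categories per time point") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.hd_ase_summary
#' @export
autoplot.hd_ase <- function(object, ...) autoplot(object$summary, ...)

#' Differential-expression count plot
#'
#' Up/down DEG counts per treated-vs-control comparison.
#'
#' @param object An `hd_de`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hd_de <- function(object, ...) {
  d <- tidyr::pivot_longer(object$summary$counts, c("n_up", "n_down"),
                           names_to = "direction", values_to = "n")
  d$direction <- sub("n_", "", d$direction)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$time_h), y = .data$n,
                                  fill = .data$direction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~treatment) +
    ggplot2::labs(x = "time (h)", y = "DEGs",
                  title = "Differentially expressed genes per comparison") +
    ggplot2::theme_minimal()
}

#' Module-trait correlation heatmap
#'
#' @param object An `hd_network` with detected modules.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hd_network <- function(object, ...) {
  if (is.null(object$module_trait)) stop_hd("network has no modules")
  d <- object$module_trait
  ggplot2::ggplot(d, ggplot2::aes(x = .data$trait, y = .data$module,
                                  fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f\n(%.1g)", .data$r, .data$p_value)), size = 2.6) +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", limits = c(-1, 1)) +
    ggplot2::labs(title = "Module-trait correlation", x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Sample-correlation heatmap
#'
#' @param object An `hd_sample_cor` from [sample_correlation()].
#' @param ... Unused.
#' @return A ggplot of the Spearman correlation matrix, samples ordered by
#'   the dendrogram.
#' @export
autoplot.hd_sample_cor <- function(object, ...) {
  ord <- object$hclust$labels[object$hclust$order]
  d <- tibble::as_tibble(as.data.frame(object$cor), rownames = "sample_a")
  d <- tidyr::pivot_longer(d, -"sample_a", names_to = "sample_b",
                           values_to = "rho")
  d$sample_a <- factor(d$sample_a, levels = ord)
  d$sample_b <- factor(d$sample_b, levels = ord)
  ggplot2::ggplot(d, ggplot2::aes(.data$sample_a, .data$sample_b,
                                  fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "#B2182B") +
    ggplot2::labs(title = "Spearman sample correlation", x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
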