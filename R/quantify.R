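#' FPKM from a fragment-count matrix
#'
#' `FPKM(g, j) = count(g, j) * 1e9 / (length_bp(g) * library_size(j))`,
#' where the library size is the column sum of assigned fragments.
#'
#' @param counts Integer matrix (features x samples).
#' @param models Gene-model tibble giving `length_bp` per feature id. For
#'   allele-level matrices the gene length is used for both alleles unless
#'   the models table lists the allele ids themselves.
#' @param lengths Optional named numeric vector of feature lengths,
#'   overriding `models`.
#' @return Numeric matrix of FPKM values, same dimnames as `counts`.
#' @examples
#' m <- matrix(c(100L, 0L), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
#' fpkm(m, lengths = c(g1 = 1000, g2 = 500))
#' @export
fpkm <- function(counts, models = NULL, lengths = NULL) {
  assert_matrix_counts(counts, "count matrix")
  if (is.null(lengths)) {
    if (is.null(models)) stop_hd("either 'models' or 'lengths' is required")
    lengths <- feature_lengths(models, rownames(counts))
  }
  miss <- setdiff(rownames(counts), names(lengths))
  if (length(miss)) {
    stop_hd(sprintf("no length for feature(s): %s",
                    paste(utils::head(miss, 5), collapse = ", ")))
  }
  lib <- colSums(counts)
  zero <- names(lib)[lib == 0]
  if (length(zero)) {
    stop_hd(sprintf("zero library size for sample(s): %s",
                    paste(zero, collapse = ", ")))
  }
  len <- lengths[rownames(counts)]
  out <- counts * 1e9 / outer(len, lib)
  dimnames(out) <- dimnames(counts)
  out
}

# lengths for gene ids or allele ids (alleles inherit the gene length)
feature_lengths <- function(models, ids) {
  len <- stats::setNames(as.numeric(models$length_bp), models$gene_id)
  if ("allele_a" %in% names(models)) {
    ok_a <- !is.na(models$allele_a)
    ok_b <- !is.na(models$allele_b)
    len <- c(len,
             stats::setNames(as.numeric(models$length_bp[ok_a]), models$allele_a[ok_a]),
             stats::setNames(as.numeric(models$length_bp[ok_b]), models$allele_b[ok_b]))
  }
  len
}

#' Per-sample expression-class profile
#'
#' Counts genes per sample in four expression classes:
#' low (FPKM <= 5), medium-low (5 < FPKM <= 20), medium (20 < FPKM <= 100)
#' and high (FPKM > 100).
#'
#' @param expr FPKM matrix from [fpkm()].
#' @param breaks Class boundaries (right-closed), default `c(5, 20, 100)`.
#' @return Tibble with columns `sample_id`, `class`, `n`; per-sample counts
#'   sum to the number of genes.
#' @export
expression_classes <- function(expr, breaks = c(5, 20, 100)) {
  labs <- c("low", "medium_low", "medium", "high")
  out <- purrr::map_dfr(colnames(expr), function(s) {
    cls <- cut(expr[, s], breaks = c(-Inf, breaks, Inf), labels = labs,
               right = TRUE)
    tibble(sample_id = s, class = labs, n = as.integer(table(cls)[labs]))
  })
  out$class <- factor(out$class, levels = labs)
  out
}

#' Spearman sample-correlation matrix and clustering
#'
#' Filters genes by FPKM, computes Spearman rank correlation between sample
#' columns (average ranks for ties) and clusters samples by average-linkage
#' hierarchical clustering on `1 - rho`.
#'
#' @param expr FPKM matrix.
#' @param min_fpkm Retain genes with FPKM strictly above this value
#'   (default 1).
#' @param filter_rule `"any"` (default): keep a gene if it passes the filter
#'   in at least one sample; `"all"`: must pass in every sample.
#' @return List of class `hd_sample_cor`: `cor` (symmetric matrix, unit
#'   diagonal), `hclust`, `n_genes` used.
#' @export
sample_correlation <- function(expr, min_fpkm = 1, filter_rule = c("any", "all")) {
  filter_rule <- match.arg(filter_rule)
  if (ncol(expr) < 2) stop_hd("need at least 2 samples")
  pass <- expr > min_fpkm
  keep <- if (filter_rule == "any") rowSums(pass) > 0 else rowSums(pass) == ncol(expr)
  if (sum(keep) < 2) stop_hd("fewer than 2 genes pass the expression filter")
  rho <- stats::cor(expr[keep, , drop = FALSE], method = "spearman")
  hc <- stats::hclust(stats::as.dist(1 - rho), method = "average")
  structure(list(cor = rho, hclust = hc, n_genes = sum(keep)),
            class = "hd_sample_cor")
}

#' @export
print.hd_sample_cor <- function(x, ...) {
  cat(sprintf("<hd_sample_cor> %d samples, %d genes\n", ncol(x$cor), x$n_genes))
  print(round(x$cor, 3))
  invisible(x)
}

#' Export a sample dendrogram as Newick text
#'
#' @param x An `hd_sample_cor` (or `hclust`).
#' @param path Optional file to write; otherwise the string is returned.
#' @return Newick string, invisibly if written to file.
#' @export
dendrogram_newick <- function(x, path = NULL) {
  hc <- if (inherits(x, "hd_sample_cor")) x$hclust else x
  phy <- ape::as.phylo(hc)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Low-expression filter
#'
#' Removes genes with low expression in every library: a gene is retained
#' iff its FPKM is at least `threshold` in at least one sample (the
#' "FPKM < 5 in all samples" removal rule).
#'
#' @param expr FPKM matrix.
#' @param threshold Default 5.
#' @return Character vector of retained gene ids.
#' @export
low_expression_filter <- function(expr, threshold = 5) {
  rownames(expr)[apply(expr, 1, max) >= threshold]
}
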