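#' @importFrom rlang abort warn .data :=
#' @importFrom tibble tibble as_tibble
NULL

# round half away from zero at `digits` decimals; base round() half-to-even
# would print 0.125 -> 0.12, which disagrees with how tables report percentages
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# percentage of a count over a total, half-up to 2 decimals; 0/0 -> 0
pct2 <- function(k, n) {
  out <- 100 * k / n
  out[!is.finite(out)] <- 0
  round_half_up(out, 2)
}

stop_hd <- function(msg, class = "haplodyn_error") {
  abort(msg, class = class)
}

assert_matrix_counts <- function(x, what = "count matrix") {
  if (!is.matrix(x)) stop_hd(sprintf("%s must be a matrix", what))
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop_hd(sprintf("%s must have row and column names", what))
  }
  if (anyNA(x)) stop_hd(sprintf("%s contains missing values", what))
  if (any(x < 0)) stop_hd(sprintf("%s contains negative values", what))
  invisible(x)
}

TREATMENTS <- c("control", "NaCl", "PEG")

# the seven observable bias-trajectory categories: letters are the collapsed
# biased (B) / no-bias (N) status in (control, NaCl, PEG) order; CCC = biased
# in all three ("conserved bias")
BIAS_CATEGORIES <- c("CCC", "BBN", "BNN", "BNB", "NBN", "NBB", "NNB")
TIMES_H <- c(0L, 24L, 48L, 72L)

# canonical sample id for a pooled (treatment, time) library
condition_id <- function(treatment, time_h) paste0(treatment, "_", time_h, "h")
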