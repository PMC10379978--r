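# shared fixture builders; everything is generated in code at test time

write_tsv_lines <- function(lines) {
  tf <- tempfile(fileext = ".tsv")
  writeLines(lines, tf)
  tf
}

tiny_count_tsv <- function() {
  write_tsv_lines(c("id\ts1\ts2", "g1\t10\t0", "g2\t5\t2", "g3\t0\t7"))
}

# the pooled ten-library design
design10 <- function() {
  tibble::tibble(
    sample_id = c("control_0h", "control_24h", "control_48h", "control_72h",
                  "NaCl_24h", "NaCl_48h", "NaCl_72h",
                  "PEG_24h", "PEG_48h", "PEG_72h"),
    treatment = c(rep("control", 4), rep("NaCl", 3), rep("PEG", 3)),
    time_h = c(0, 24, 48, 72, 24, 48, 72, 24, 48, 72)
  )
}

# independent conditional-pmf oracle for the NB exact test, built from
# stats::dnbinom rather than the implementation's lchoose form
nb_exact_oracle <- function(y1, s, phi, mu = 10) {
  if (s == 0) return(1)
  r <- 1 / phi
  k <- 0:s
  pk <- stats::dnbinom(k, size = r, mu = mu) *
    stats::dnbinom(s - k, size = r, mu = mu) /
    stats::dnbinom(s, size = 2 * r, mu = 2 * mu)
  obs <- pk[y1 + 1]
  min(1, sum(pk[log(pk) <= log(obs) + 1e-9]))
}

# strip reader bookkeeping attributes for exact matrix comparison
strip_attrs <- function(m) {
  attr(m, "id_kind") <- NULL
  unname(m)
}

random_adjacency <- function(n) {
  a <- matrix(runif(n * n), n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  dimnames(a) <- list(paste0("g", 1:n), paste0("g", 1:n))
  a
}

# brute-force triple-loop topological overlap
tom_brute <- function(a) {
  diag(a) <- 0
  n <- nrow(a)
  k <- rowSums(a)
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    num <- sum(a[i, ] * a[, j]) + a[i, j]
    tom[i, j] <- num / (min(k[i], k[j]) + 1 - a[i, j])
  }
  tom
}

# exhaustive hypergeometric upper-tail oracle via log binomial coefficients
hyper_tail_oracle <- function(k, K, N, n) {
  kk <- k:min(K, n)
  sum(exp(lchoose(K, kk) + lchoose(N - K, n - kk) - lchoose(N, n)))
}
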