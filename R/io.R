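#' Read a fragment-count matrix from TSV
#'
#' Reads a tab-separated table whose header row holds sample ids and whose
#' first column holds feature (gene or allele) ids, as exported by
#' featureCounts-style pipelines. Lines starting with `#` are ignored and the
#' first header cell is arbitrary.
#'
#' @param path Path to a TSV file.
#' @param id_kind `"gene"` or `"allele"`; recorded as an attribute and used in
#'   error messages only — values are opaque nonnegative integer fragments.
#' @return An integer matrix (features x samples) with row and column names.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("id\ts1\ts2", "g1\t10\t0", "g2\t5\t2"), tf)
#' read_count_matrix(tf)
#' @export
read_count_matrix <- function(path, id_kind = c("gene", "allele")) {
  id_kind <- match.arg(id_kind)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) {
    stop_hd(sprintf("'%s': empty or header-only count matrix", path),
            class = "haplodyn_format_error")
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  ncol_expect <- length(header)
  if (ncol_expect < 2) {
    stop_hd(sprintf("'%s': header has no sample columns", path),
            class = "haplodyn_format_error")
  }
  bad <- which(lengths(fields[-1]) != ncol_expect)
  if (length(bad)) {
    stop_hd(sprintf("'%s': line %d has %d fields, expected %d",
                    path, bad[1] + 1L, lengths(fields[-1])[bad[1]], ncol_expect),
            class = "haplodyn_format_error")
  }
  body <- fields[-1]
  ids <- vapply(body, `[[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop_hd(sprintf("'%s': duplicated %s id(s): %s", path, id_kind,
                    paste(unique(dup), collapse = ", ")),
            class = "haplodyn_validation_error")
  }
  raw <- vapply(body, function(f) f[-1], character(ncol_expect - 1L))
  vals <- suppressWarnings(as.numeric(raw))
  if (anyNA(vals)) {
    stop_hd(sprintf("'%s': non-numeric count value(s), e.g. '%s'",
                    path, raw[which(is.na(vals))[1]]),
            class = "haplodyn_validation_error")
  }
  if (any(vals < 0) || any(vals != trunc(vals))) {
    stop_hd(sprintf("'%s': counts must be nonnegative integers", path),
            class = "haplodyn_validation_error")
  }
  m <- matrix(as.integer(vals), nrow = length(ids), ncol = ncol_expect - 1L,
              byrow = TRUE, dimnames = list(ids, header[-1]))
  attr(m, "id_kind") <- id_kind
  m
}

#' Write a count matrix as TSV
#'
#' Inverse of [read_count_matrix()]: round-trips cell values and orderings.
#'
#' @param x Integer matrix with row and column names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(x, path) {
  assert_matrix_counts(x)
  df <- data.frame(id = rownames(x), x, check.names = FALSE)
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read gene models (id, chromosome, length, allele pairing)
#'
#' Two formats are supported. A 5-column TSV (`gene_id`, `chromosome`,
#' `length_bp`, `allele_a`, `allele_b`; header optional, `NA`/empty allele
#' fields mean no haplotype resolution), or GFF3. For GFF3, the transcript
#' length used for FPKM is the merged (union) exon length of the longest
#' transcript of the gene, falling back to the gene span when no exons are
#' annotated; GFF3 coordinates are 1-based inclusive.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"tsv"` or `"gff3"`.
#' @return A tibble with columns `gene_id`, `chromosome`, `length_bp`,
#'   `allele_a`, `allele_b`.
#' @export
read_gene_models <- function(path, format = c("auto", "tsv", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE)) "gff3" else "tsv"
  }
  models <- if (format == "gff3") read_gene_models_gff3(path) else read_gene_models_tsv(path)
  validate_gene_models(models)
}

read_gene_models_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("gene_id", first, fixed = TRUE)
  cols <- c("gene_id", "chromosome", "length_bp", "allele_a", "allele_b")
  df <- if (has_header) {
    utils::read.delim(path, header = TRUE, comment.char = "#",
                      stringsAsFactors = FALSE)
  } else {
    utils::read.delim(path, header = FALSE, comment.char = "#",
                      stringsAsFactors = FALSE)
  }
  names(df) <- cols[seq_len(ncol(df))]
  if (!"allele_a" %in% names(df)) df$allele_a <- NA_character_
  if (!"allele_b" %in% names(df)) df$allele_b <- NA_character_
  df$allele_a[!is.na(df$allele_a) & df$allele_a == ""] <- NA_character_
  df$allele_b[!is.na(df$allele_b) & df$allele_b == ""] <- NA_character_
  as_tibble(df[cols])
}

read_gene_models_gff3 <- function(path) {
  for (pkg in c("rtracklayer", "GenomicRanges", "S4Vectors")) {
    if (!requireNamespace(pkg, quietly = TRUE)) {
      stop_hd(sprintf("GFF3 input requires the '%s' package", pkg))
    }
  }
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  if (any(GenomicRanges::end(gr) < GenomicRanges::start(gr))) {
    stop_hd("GFF3 feature with end < start", class = "haplodyn_validation_error")
  }
  is_gene <- type == "gene"
  if (!any(is_gene)) stop_hd("no gene features in GFF3", class = "haplodyn_format_error")
  gene_id <- as.character(md$ID[is_gene])
  if (anyNA(gene_id) || any(gene_id == "")) {
    stop_hd("gene feature without ID attribute", class = "haplodyn_format_error")
  }
  gene_span <- GenomicRanges::width(gr[is_gene])
  gene_chr <- as.character(GenomicRanges::seqnames(gr[is_gene]))

  parent1 <- vapply(as.list(md$Parent), function(p) {
    if (length(p)) as.character(p[1]) else NA_character_
  }, character(1))
  is_tx <- !is_gene & !is.na(parent1) & parent1 %in% gene_id & type != "exon"
  tx_id <- as.character(md$ID[is_tx])
  tx_gene <- parent1[is_tx]
  is_exon <- type == "exon"

  len <- gene_span
  names(len) <- gene_id
  if (any(is_exon) && length(tx_id)) {
    exon_tx <- parent1[is_exon]
    exon_gr <- gr[is_exon]
    keep <- exon_tx %in% tx_id
    exon_tx <- exon_tx[keep]; exon_gr <- exon_gr[keep]
    if (length(exon_gr)) {
      # merged-exon length per transcript, then longest transcript per gene
      red <- GenomicRanges::reduce(GenomicRanges::split(exon_gr, exon_tx))
      tx_len <- vapply(as.list(red), function(g) sum(GenomicRanges::width(g)), numeric(1))
      gene_of_tx <- tx_gene[match(names(tx_len), tx_id)]
      best <- tapply(tx_len, gene_of_tx, max)
      len[names(best)] <- as.numeric(best)
    }
  }
  tibble(gene_id = gene_id, chromosome = gene_chr,
         length_bp = as.integer(len),
         allele_a = NA_character_, allele_b = NA_character_)
}

validate_gene_models <- function(models) {
  models <- as_tibble(models)
  need <- c("gene_id", "chromosome", "length_bp")
  miss <- setdiff(need, names(models))
  if (length(miss)) stop_hd(paste("gene models missing column(s):", paste(miss, collapse = ", ")))
  if (anyDuplicated(models$gene_id)) {
    stop_hd("duplicated gene_id in gene models", class = "haplodyn_validation_error")
  }
  if (any(models$length_bp < 1 | is.na(models$length_bp))) {
    stop_hd("gene model length_bp must be >= 1", class = "haplodyn_validation_error")
  }
  al <- c(models$allele_a, models$allele_b)
  al <- al[!is.na(al)]
  if (anyDuplicated(al)) {
    stop_hd("allele ids must be unique across gene models",
            class = "haplodyn_validation_error")
  }
  both <- !is.na(models$allele_a) & !is.na(models$allele_b)
  if (any(both & models$allele_a == models$allele_b)) {
    stop_hd("allele_a and allele_b must differ within a pair",
            class = "haplodyn_validation_error")
  }
  models
}

#' Read and validate a sample sheet
#'
#' Expects TSV columns `sample_id`, `treatment` (control/NaCl/PEG) and
#' `time_h` (0/24/48/72). The pooled design has one library per
#' (treatment, time) pair, and every treated time point must have a
#' same-time control.
#'
#' @param path TSV path.
#' @return A validated tibble (`sample_id`, `treatment`, `time_h`).
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  validate_sample_sheet(df)
}

#' Validate a sample-sheet data frame
#'
#' @param samples Data frame with `sample_id`, `treatment`, `time_h` (and
#'   optionally `replicate` for replicated designs).
#' @return The validated tibble, with `treatment` as a factor.
#' @export
validate_sample_sheet <- function(samples) {
  samples <- as_tibble(samples)
  need <- c("sample_id", "treatment", "time_h")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop_hd(paste("sample sheet missing column(s):", paste(miss, collapse = ", ")))
  if (anyDuplicated(samples$sample_id)) {
    stop_hd("duplicated sample_id", class = "haplodyn_validation_error")
  }
  bad_t <- setdiff(unique(samples$treatment), TREATMENTS)
  if (length(bad_t)) {
    stop_hd(sprintf("unknown treatment label(s): %s", paste(bad_t, collapse = ", ")),
            class = "haplodyn_validation_error")
  }
  samples$time_h <- as.integer(samples$time_h)
  bad_h <- setdiff(unique(samples$time_h), TIMES_H)
  if (length(bad_h)) {
    stop_hd(sprintf("unsupported time point(s): %s h", paste(bad_h, collapse = ", ")),
            class = "haplodyn_validation_error")
  }
  has_rep <- "replicate" %in% names(samples)
  key <- paste(samples$treatment, samples$time_h,
               if (has_rep) samples$replicate else "")
  if (anyDuplicated(key)) {
    stop_hd("duplicated (treatment, time_h) library in pooled design",
            class = "haplodyn_validation_error")
  }
  treated <- samples[samples$treatment != "control", ]
  ctrl_times <- samples$time_h[samples$treatment == "control"]
  orphan <- setdiff(unique(treated$time_h), ctrl_times)
  if (length(orphan)) {
    stop_hd(sprintf("treated sample(s) at %s h without a matching control",
                    paste(orphan, collapse = ", ")),
            class = "haplodyn_validation_error")
  }
  samples$treatment <- factor(samples$treatment, levels = TREATMENTS)
  samples
}

#' Read a term-to-gene annotation map
#'
#' Two-column TSV (`term`, `gene`), optionally with a third `term_name`
#' column. Used as the annotation input for [fisher_enrich()].
#'
#' @param path TSV path.
#' @return Tibble with columns `term`, `gene` and (if present) `term_name`.
#' @export
read_term_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 2) stop_hd("term map needs at least two columns (term, gene)",
                            class = "haplodyn_format_error")
  names(df)[1:2] <- c("term", "gene")
  if (ncol(df) >= 3) names(df)[3] <- "term_name"
  as_tibble(df)
}

#' Read a plain gene list (one id per line)
#'
#' @param path Text file, one gene id per line; blank and `#` lines ignored.
#' @return Character vector of unique gene ids.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  unique(x[nzchar(x) & !startsWith(x, "#")])
}

#' Bind library sizes from a count matrix onto a sample sheet
#'
#' Library size is the column sum of assigned fragments.
#'
#' @param samples Validated sample sheet.
#' @param counts Count matrix whose columns cover `samples$sample_id`.
#' @return `samples` with a `library_size` column.
#' @export
bind_library_sizes <- function(samples, counts) {
  assert_matrix_counts(counts)
  miss <- setdiff(samples$sample_id, colnames(counts))
  if (length(miss)) {
    stop_hd(sprintf("count matrix lacks sample column(s): %s",
                    paste(miss, collapse = ", ")))
  }
  samples$library_size <- colSums(counts)[samples$sample_id]
  samples
}
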