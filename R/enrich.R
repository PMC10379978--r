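#' Term over-representation by the hypergeometric (Fisher) test
#'
#' For each term with `K` annotated genes in a universe of size `N`, and a
#' gene set of interest of size `n` containing `k` annotated genes, the
#' one-sided p-value is the hypergeometric upper tail `P(X >= k)`.
#' Benjamini-Hochberg adjustment is applied across all tested terms; terms
#' with no annotated universe genes are skipped.
#'
#' @param interest Character vector of genes of interest (must be a subset
#'   of `universe`).
#' @param universe Character vector, the gene universe.
#' @param term_map Tibble/data frame with columns `term`, `gene` and
#'   optionally `term_name` (see [read_term_map()]); genes outside the
#'   universe are ignored.
#' @param alpha Significance threshold on q, default 0.05.
#' @return Tibble: `term`, `term_name`, `k`, `n`, `K`, `N`, `p_value`,
#'   `q_value`, `enriched`, sorted by p.
#' @export
fisher_enrich <- function(interest, universe, term_map, alpha = 0.05) {
  interest <- unique(interest); universe <- unique(universe)
  out <- setdiff(interest, universe)
  if (length(out)) {
    stop_hd(sprintf("interest gene(s) not in universe: %s%s",
                    paste(utils::head(out, 5), collapse = ", "),
                    if (length(out) > 5) sprintf(" (+%d more)", length(out) - 5) else ""),
            class = "haplodyn_validation_error")
  }
  tm <- as_tibble(term_map)
  if (!all(c("term", "gene") %in% names(tm))) {
    stop_hd("term_map needs 'term' and 'gene' columns")
  }
  tm <- tm[tm$gene %in% universe, ]
  tm <- dplyr::distinct(tm, .data$term, .data$gene, .keep_all = TRUE)
  if (!nrow(tm)) return(tibble(term = character(), term_name = character(),
                               k = integer(), n = integer(), K = integer(),
                               N = integer(), p_value = numeric(),
                               q_value = numeric(), enriched = logical()))
  N <- length(universe); n <- length(interest)
  by_term <- split(tm$gene, tm$term)
  res <- purrr::imap_dfr(by_term, function(genes, term) {
    K <- length(genes)
    k <- sum(genes %in% interest)
    tibble(term = term, k = k, n = n, K = K, N = N,
           p_value = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE))
  })
  res$q_value <- bh_adjust(res$p_value)
  res$enriched <- res$q_value < alpha
  if ("term_name" %in% names(tm)) {
    nm <- dplyr::distinct(tm, .data$term, .data$term_name)
    res$term_name <- nm$term_name[match(res$term, nm$term)]
  } else {
    res$term_name <- NA_character_
  }
  res <- res[order(res$p_value), c("term", "term_name", "k", "n", "K", "N",
                                   "p_value", "q_value", "enriched")]
  res
}

#' Exclusive-region intersection counts (upset form)
#'
#' For named sets, reports the cardinality of every exclusive region (genes
#' in exactly that combination of sets) for each nonempty combination, plus
#' per-set totals; the regions partition the union.
#'
#' @param sets Named list of character vectors (>= 2 sets).
#' @return Tibble: `combo` (set names joined by `&`), `degree`,
#'   `n_exclusive`, and `set_total` (`NA` except for degree-1 rows, where it
#'   is the full size of that set).
#' @examples
#' upset_counts(list(A = c("1", "2", "3"), B = c("2", "3", "4")))
#' @export
upset_counts <- function(sets) {
  if (length(sets) < 2 || is.null(names(sets))) {
    stop_hd("need a named list of at least 2 sets")
  }
  sets <- lapply(sets, unique)
  ids <- unique(unlist(sets))
  member <- vapply(sets, function(s) ids %in% s, logical(length(ids)))
  if (length(ids) == 1) member <- matrix(member, nrow = 1, dimnames = list(NULL, names(sets)))
  combos <- unlist(lapply(seq_along(sets), function(d) {
    utils::combn(names(sets), d, simplify = FALSE)
  }), recursive = FALSE)
  purrr::map_dfr(combos, function(cm) {
    inside <- rowSums(member[, cm, drop = FALSE]) == length(cm)
    outside <- rowSums(member[, setdiff(names(sets), cm), drop = FALSE]) == 0
    tibble(combo = paste(cm, collapse = "&"), degree = length(cm),
           n_exclusive = sum(inside & outside),
           set_total = if (length(cm) == 1) length(sets[[cm]]) else NA_integer_)
  })
}

#' ASE-class connectivity fractions
#'
#' Fraction of each ASE gene class whose co-expression edge count reaches
#' each threshold (the "highly connected" accounting).
#'
#' @param ase_sets Named list of gene-id vectors (e.g. `salt_specific`,
#'   `drought_specific`, `both`).
#' @param edge_counts Named integer vector (gene -> edge count) or the
#'   `edge_counts` tibble from [hub_screen()]; genes absent from it count 0
#'   edges.
#' @param thresholds Edge-count thresholds, default `c(5, 50)`.
#' @return Tibble: `set`, `threshold`, `n`, `n_over`, `pct` (half-up, 2
#'   decimals).
#' @export
ase_network_overlap <- function(ase_sets, edge_counts, thresholds = c(5, 50)) {
  if (is.data.frame(edge_counts)) {
    edge_counts <- stats::setNames(edge_counts$n_edges, edge_counts$gene_id)
  }
  purrr::imap_dfr(ase_sets, function(genes, nm) {
    genes <- unique(genes)
    ec <- edge_counts[genes]
    ec[is.na(ec)] <- 0L
    purrr::map_dfr(thresholds, function(th) {
      tibble(set = nm, threshold = th, n = length(genes),
             n_over = sum(ec >= th), pct = pct2(sum(ec >= th), length(genes)))
    })
  })
}

#' Overlap of responsive ASE sets with an external gene list
#'
#' Reports `|salt intersect external|` as a count and as a percentage of the
#' salt set (half-up, 2 decimals), likewise for drought, plus the three-way
#' exclusive regions. Warns when both sides are nonempty but disjoint,
#' which usually indicates mismatched id namespaces.
#'
#' @param ase_salt,ase_drought Responsive ASE gene sets.
#' @param external External gene list (e.g. a published heterosis-related
#'   ASE set).
#' @return List: `summary` tibble (set, n, n_in_external, pct) and
#'   `regions` ([upset_counts()] of the three sets).
#' @export
external_list_overlap <- function(ase_salt, ase_drought, external) {
  ase_salt <- unique(ase_salt); ase_drought <- unique(ase_drought)
  external <- unique(external)
  both_sets <- length(external) > 0 && (length(ase_salt) > 0 || length(ase_drought) > 0)
  if (both_sets && !length(intersect(c(ase_salt, ase_drought), external))) {
    warn("no overlap with the external list; check that gene-id namespaces match")
  }
  summary <- purrr::imap_dfr(list(salt = ase_salt, drought = ase_drought),
                             function(s, nm) {
    k <- length(intersect(s, external))
    tibble(set = nm, n = length(s), n_in_external = k, pct = pct2(k, length(s)))
  })
  regions <- upset_counts(list(salt = ase_salt, drought = ase_drought,
                               external = external))
  list(summary = summary, regions = regions)
}
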