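BIAS_STATUSES <- c("BIAS_A", "BIAS_B", "NO_BIAS", "NOT_EXPRESSED")

#' Call allelic bias for one condition
#'
#' The twofold criterion: with allele FPKMs `a` and `b`, the gene is
#' `NOT_EXPRESSED` when `max(a, b) < floor`; otherwise `BIAS_A` when
#' `a >= fold * b`, `BIAS_B` when `b >= fold * a` (boundary inclusive, so a
#' ratio of exactly `fold` is biased), else `NO_BIAS`. The comparison is
#' multiplicative and therefore zero-safe; the pseudocount is only used for
#' the reported log2 allelic ratio.
#'
#' @param fpkm_a,fpkm_b Nonnegative allele FPKM values (vectorised).
#' @param fold Fold-change criterion, default 2.
#' @param floor Expression floor on the higher allele (FPKM), default 0.5.
#' @param pseudo Pseudocount for the log2 ratio attribute, default 0.001.
#' @return Factor with levels `BIAS_A`, `BIAS_B`, `NO_BIAS`,
#'   `NOT_EXPRESSED`, carrying a `log2_ratio` attribute.
#' @examples
#' call_bias(c(10, 6, 0.1, 2), c(4, 6, 0.3, 1))
#' @export
call_bias <- function(fpkm_a, fpkm_b, fold = 2, floor = 0.5, pseudo = 0.001) {
  if (any(fpkm_a < 0) || any(fpkm_b < 0)) stop_hd("FPKM values must be nonnegative")
  if (fold <= 1) stop_hd("fold must exceed 1")
  n <- max(length(fpkm_a), length(fpkm_b))
  a <- rep_len(fpkm_a, n); b <- rep_len(fpkm_b, n)
  status <- rep("NO_BIAS", n)
  status[a >= fold * b & a > b] <- "BIAS_A"
  status[b >= fold * a & b > a] <- "BIAS_B"
  status[pmax(a, b) < floor] <- "NOT_EXPRESSED"
  out <- factor(status, levels = BIAS_STATUSES)
  attr(out, "log2_ratio") <- log2((a + pseudo) / (b + pseudo))
  out
}

#' Classify a (control, NaCl, PEG) bias-status triplet
#'
#' Collapses `BIAS_A`/`BIAS_B` to "B" and maps the triplet to one of the
#' seven observable categories (`CCC` = biased in all three, then `BBN`,
#' `BNN`, `BNB`, `NBN`, `NBB`, `NNB` with letters in control/NaCl/PEG
#' order). Responsiveness compares collapsed statuses to the control:
#' `conserved` (CCC), `salt_specific` (only NaCl differs), `drought_specific`
#' (only PEG differs), `both` (both differ). Triplets with no bias anywhere
#' or any `NOT_EXPRESSED` status are `excluded` (category `NA`).
#'
#' @param status_control,status_nacl,status_peg Bias statuses (vectorised),
#'   as returned by [call_bias()].
#' @return Tibble with columns `category` (factor over the 7 categories) and
#'   `responsiveness` (factor: conserved, salt_specific, drought_specific,
#'   both, excluded), plus `direction_flip`: `TRUE` when two biased
#'   conditions favour opposite alleles (categories are direction-blind;
#'   the flag preserves the information).
#' @examples
#' classify_trajectory("BIAS_A", "NO_BIAS", "NO_BIAS")
#' @export
classify_trajectory <- function(status_control, status_nacl, status_peg) {
  n <- max(length(status_control), length(status_nacl), length(status_peg))
  sc <- rep_len(as.character(status_control), n)
  sn <- rep_len(as.character(status_nacl), n)
  sp <- rep_len(as.character(status_peg), n)
  bad <- setdiff(unique(c(sc, sn, sp)), BIAS_STATUSES)
  if (length(bad)) stop_hd(sprintf("unknown bias status: %s", paste(bad, collapse = ", ")))

  collapse <- function(s) ifelse(s %in% c("BIAS_A", "BIAS_B"), "B", "N")
  trip <- paste0(collapse(sc), collapse(sn), collapse(sp))
  excluded <- trip == "NNN" | sc == "NOT_EXPRESSED" | sn == "NOT_EXPRESSED" |
    sp == "NOT_EXPRESSED"
  category <- ifelse(trip == "BBB", "CCC", trip)
  category[excluded] <- NA

  nacl_differs <- substr(trip, 2, 2) != substr(trip, 1, 1)
  peg_differs <- substr(trip, 3, 3) != substr(trip, 1, 1)
  responsiveness <- dplyr::case_when(
    excluded ~ "excluded",
    nacl_differs & peg_differs ~ "both",
    nacl_differs ~ "salt_specific",
    peg_differs ~ "drought_specific",
    TRUE ~ "conserved"
  )
  any_a <- sc == "BIAS_A" | sn == "BIAS_A" | sp == "BIAS_A"
  any_b <- sc == "BIAS_B" | sn == "BIAS_B" | sp == "BIAS_B"
  direction_flip <- any_a & any_b
  tibble(
    category = factor(category, levels = BIAS_CATEGORIES),
    responsiveness = factor(responsiveness,
                            levels = c("conserved", "salt_specific",
                                       "drought_specific", "both", "excluded")),
    direction_flip = direction_flip & !excluded
  )
}

#' Build a bias-trajectory table realizing given category multiplicities
#'
#' Expands a `(time_h, category, n)` table — such as [table1_counts()] —
#' into per-gene (control, NaCl, PEG) status triplets (`BIAS_A` for biased,
#' `NO_BIAS` otherwise), classifies them with [classify_trajectory()], and
#' returns a trajectory table ready for [summarize_ase()]. Useful for exact
#' accounting checks against printed category tables.
#'
#' @param category_counts Tibble with columns `time_h`, `category`
#'   (one of the seven category codes), `n`.
#' @return Trajectory tibble (`gene_id`, `time_h`, statuses, `category`,
#'   `responsiveness`, `direction_flip`).
#' @examples
#' glance(summarize_ase(trajectories_from_categories(table1_counts())))
#' @export
trajectories_from_categories <- function(category_counts) {
  cc <- as_tibble(category_counts)
  stopifnot(all(c("time_h", "category", "n") %in% names(cc)))
  purrr::pmap_dfr(cc, function(time_h, category, n) {
    if (n == 0) return(NULL)
    letters3 <- letters_from_category(category)[1, ]
    st <- ifelse(letters3 == "B", "BIAS_A", "NO_BIAS")
    out <- tibble(
      gene_id = sprintf("%s_%dh_%s_%05d", "fix", time_h, category, seq_len(n)),
      time_h = as.integer(time_h),
      status_control = st[1], status_nacl = st[2], status_peg = st[3])
    dplyr::bind_cols(out, classify_trajectory(st[1], st[2], st[3])[rep(1, n), ])
  })
}

#' Responsiveness accounting over bias trajectories
#'
#' Computes, per time point, the seven-category counts and the
#' responsiveness statistics: `n_responsive` (universe minus conserved),
#' `n_salt_responsive` (NaCl status differs from control =
#' both + salt-specific), `n_drought_responsive` (both + drought-specific),
#' `n_both`, the specific counts, and the corresponding percentages
#' (half-up, 2 decimals). The universe at a time point is the set of
#' non-excluded trajectories. With gene models, per-chromosome counts of
#' salt-/drought-responsive genes are added.
#'
#' @param trajectories Tibble with columns `gene_id`, `time_h`, `category`,
#'   `responsiveness` (as produced by [run_ase()] or [classify_trajectory()]
#'   bound to gene/time columns).
#' @param models Optional gene-model tibble (for chromosome distribution).
#' @return Object of class `hd_ase_summary`: tibbles `categories`
#'   (time_h, category, n, pct), `responsiveness` (one row per time point),
#'   and optionally `chromosomes`.
#' @export
summarize_ase <- function(trajectories, models = NULL) {
  tr <- as_tibble(trajectories)
  need <- c("gene_id", "time_h", "category", "responsiveness")
  miss <- setdiff(need, names(tr))
  if (length(miss)) stop_hd(paste("trajectories missing column(s):",
                                  paste(miss, collapse = ", ")))
  tr$responsiveness <- as.character(tr$responsiveness)
  kept <- tr[tr$responsiveness != "excluded", ]

  categories <- purrr::map_dfr(sort(unique(tr$time_h)), function(tp) {
    d <- kept[kept$time_h == tp, ]
    nn <- table(factor(as.character(d$category), levels = BIAS_CATEGORIES))
    tibble(time_h = tp, category = BIAS_CATEGORIES, n = as.integer(nn),
           pct = pct2(as.integer(nn), nrow(d)))
  })

  responsiveness <- purrr::map_dfr(sort(unique(tr$time_h)), function(tp) {
    d <- kept[kept$time_h == tp, ]
    r <- d$responsiveness
    n_uni <- nrow(d)
    n_both <- sum(r == "both")
    n_salt_spec <- sum(r == "salt_specific")
    n_drought_spec <- sum(r == "drought_specific")
    n_resp <- n_both + n_salt_spec + n_drought_spec
    tibble(
      time_h = tp, n_universe = n_uni,
      n_responsive = n_resp, pct_responsive = pct2(n_resp, n_uni),
      n_salt_responsive = n_both + n_salt_spec,
      n_drought_responsive = n_both + n_drought_spec,
      n_both = n_both, pct_both_of_responsive = pct2(n_both, n_resp),
      n_salt_specific = n_salt_spec, n_drought_specific = n_drought_spec,
      n_direction_flips = if ("direction_flip" %in% names(d)) sum(d$direction_flip) else NA_integer_
    )
  })

  chromosomes <- NULL
  if (!is.null(models)) {
    resp_sets <- list(
      salt = unique(kept$gene_id[kept$responsiveness %in% c("both", "salt_specific")]),
      drought = unique(kept$gene_id[kept$responsiveness %in% c("both", "drought_specific")])
    )
    chromosomes <- purrr::imap_dfr(resp_sets, function(g, nm) {
      d <- models[models$gene_id %in% g, ]
      cnt <- table(d$chromosome)
      tibble(stress = nm, chromosome = names(cnt), n = as.integer(cnt))
    })
  }
  structure(list(categories = categories, responsiveness = responsiveness,
                 chromosomes = chromosomes),
            class = "hd_ase_summary")
}

#' @export
print.hd_ase_summary <- function(x, ...) {
  cat("<hd_ase_summary>\n")
  print(x$responsiveness)
  invisible(x)
}

#' Allele-specific expression analysis over the stress time course
#'
#' Computes allele-level FPKM (allele length = gene length for both alleles),
#' calls allelic bias in every condition by the twofold criterion, builds the
#' per-time-point (control, NaCl, PEG) bias trajectories — comparing each
#' treated library to the control at the same time point, falling back to the
#' 0 h control only when no same-time control exists — and assembles the
#' responsiveness summary and per-time salt-/drought-responsive gene sets
#' plus their cross-time unions.
#'
#' @param allele_counts Allele-level count matrix.
#' @param models Gene models with `allele_a`/`allele_b` pairing.
#' @param samples Validated sample sheet.
#' @param fold,floor,pseudo Passed to [call_bias()].
#' @return Object of class `hd_ase`: `trajectories` tibble (gene_id, time_h,
#'   statuses, category, responsiveness, direction_flip), `summary`
#'   ([summarize_ase()] result), `sets` (per-time and union responsive gene
#'   sets), `allele_fpkm`.
#' @export
run_ase <- function(allele_counts, models, samples, fold = 2, floor = 0.5,
                    pseudo = 0.001) {
  assert_matrix_counts(allele_counts, "allele count matrix")
  samples <- validate_sample_sheet(samples)
  models <- validate_gene_models(models)

  paired <- models[!is.na(models$allele_a) & !is.na(models$allele_b), ]
  have <- paired$allele_a %in% rownames(allele_counts) &
    paired$allele_b %in% rownames(allele_counts)
  if (mean(have) < 0.5) {
    stop_hd("more than half of the allele pairs are missing from the count matrix")
  }
  if (any(!have)) {
    warn(sprintf("%d gene(s) dropped: allele rows missing from the count matrix",
                 sum(!have)))
    paired <- paired[have, ]
  }

  expr <- fpkm(allele_counts, models = models)
  cond_of <- function(tr, tp) {
    id <- samples$sample_id[samples$treatment == tr & samples$time_h == tp]
    if (length(id)) id[1] else NA_character_
  }

  times <- sort(intersect(unique(samples$time_h[samples$treatment != "control"]),
                          c(24L, 48L, 72L)))
  trajectories <- purrr::map_dfr(times, function(tp) {
    ctrl <- cond_of("control", tp)
    if (is.na(ctrl)) ctrl <- cond_of("control", 0L)
    if (is.na(ctrl)) stop_hd(sprintf("no control library usable at %d h", tp))
    status_of <- function(sid) {
      call_bias(expr[paired$allele_a, sid], expr[paired$allele_b, sid],
                fold = fold, floor = floor, pseudo = pseudo)
    }
    sc <- status_of(ctrl)
    sn_id <- cond_of("NaCl", tp); sp_id <- cond_of("PEG", tp)
    if (is.na(sn_id) || is.na(sp_id)) {
      stop_hd(sprintf("missing treated library at %d h", tp))
    }
    sn <- status_of(sn_id); sp <- status_of(sp_id)
    cls <- classify_trajectory(sc, sn, sp)
    dplyr::bind_cols(
      tibble(gene_id = paired$gene_id, time_h = tp,
             status_control = sc, status_nacl = sn, status_peg = sp),
      cls)
  })

  summary <- summarize_ase(trajectories, models = models)
  resp <- as.character(trajectories$responsiveness)
  set_at <- function(tp, which) {
    lv <- c(which, "both")
    unique(trajectories$gene_id[trajectories$time_h == tp & resp %in% lv])
  }
  sets <- list(
    salt = lapply(stats::setNames(times, paste0("t", times)), set_at,
                  which = "salt_specific"),
    drought = lapply(stats::setNames(times, paste0("t", times)), set_at,
                     which = "drought_specific")
  )
  sets$salt_union <- sort(unique(unlist(sets$salt)))
  sets$drought_union <- sort(unique(unlist(sets$drought)))

  structure(list(trajectories = trajectories, summary = summary, sets = sets,
                 allele_fpkm = expr, fold = fold, floor = floor),
            class = "hd_ase")
}

#' @export
print.hd_ase <- function(x, ...) {
  cat(sprintf("<hd_ase> %d gene trajectories, fold = %g, floor = %g FPKM\n",
              nrow(x$trajectories), x$fold, x$floor))
  print(x$summary$responsiveness)
  invisible(x)
}
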