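#' Per-gene competitiveness analysis from gene-level counts
#'
#' Implements the fold-change-concordance screen for conditional gene
#' requirement:
#'
#' 1. Genes with a normalized input (starting-culture) count below
#'    `under_threshold` in either biological replicate are set aside as
#'    underrepresented — essential, pseudoessential, or recalcitrant to
#'    insertion — because their counts are too low to score.
#' 2. Genes whose disruption already costs more than a twofold loss of
#'    competitiveness without treatment (normalized nontreated/input ratio
#'    below `growth_cutoff`) are set aside as growth-impaired, so that
#'    general fitness defects are not mistaken for treatment sensitivity.
#' 3. For each remaining (analyzable) gene and each treatment, the
#'    competition index CI = normalized treated count / normalized
#'    nontreated count is computed per replicate. CI = 1 means the insertion
#'    neither helped nor hurt under treatment.
#' 4. A gene is classified `REDUCED_COMPETITIVENESS` when CI <= `ci_low` in
#'    both replicates (disruption sensitizes: the gene protects),
#'    `INCREASED_COMPETITIVENESS` when CI >= `ci_high` in both (the gene
#'    costs fitness under treatment), otherwise `NO_CHANGE`. Genes failing a
#'    filter, or with an undefined CI (nontreated count 0), are
#'    `NOT_ANALYZED`.
#'
#' @param gene_counts Long tibble from [count_genes()] (columns `gene_id`,
#'   `condition`, `replicate`, `norm_count`; conditions `"input"`,
#'   `"nontreated"`, plus one or more treatment labels).
#' @param under_threshold Underrepresentation threshold on normalized input
#'   counts (default 100).
#' @param under_cmp `"lt"` (default; flag when count < threshold) or `"le"`
#'   (flag when count <= threshold).
#' @param growth_cutoff Nontreated/input ratio below which a gene is
#'   growth-impaired (default 0.5, i.e. more than twofold loss).
#' @param growth_mode Flag when the ratio falls below the cutoff in
#'   `"either"` replicate (default, conservative) or only when in `"both"`.
#' @param ci_low,ci_high Classification cutoffs, boundaries inclusive
#'   (defaults 0.5 and 2).
#' @param pseudocount Added to treated and nontreated normalized counts
#'   before the CI ratio; default 0 (genes with nontreated count 0 are
#'   excluded rather than imputed).
#' @return An object of class `tn_ci`; use [generics::tidy()] for the
#'   per-gene table, [generics::glance()] for the one-row summary,
#'   [ggplot2::autoplot()] for the replicate-concordance plot.
#' @export
competitiveness <- function(gene_counts,
                            under_threshold = 100,
                            under_cmp = c("lt", "le"),
                            growth_cutoff = 0.5,
                            growth_mode = c("either", "both"),
                            ci_low = 0.5, ci_high = 2,
                            pseudocount = 0) {
  under_cmp <- match.arg(under_cmp)
  growth_mode <- match.arg(growth_mode)
  stopifnot(ci_low > 0, ci_high > ci_low)
  conds <- unique(gene_counts$condition)
  for (needed in c("input", "nontreated")) {
    if (!needed %in% conds) abort(paste0("missing condition: ", needed))
  }
  treatments <- setdiff(conds, c("input", "nontreated"))
  if (length(treatments) == 0) abort("no treated condition present")
  reps <- sort(unique(gene_counts$replicate))
  if (!identical(reps, c(1L, 2L))) {
    abort("competitiveness requires exactly biological replicates 1 and 2")
  }
  if (any(gene_counts$norm_count < 0)) abort("negative counts")

  wide <- gene_counts %>%
    select("gene_id", "condition", "replicate", "norm_count") %>%
    tidyr::pivot_wider(names_from = c("condition", "replicate"),
                       values_from = "norm_count", names_sep = "__",
                       values_fill = 0)
  need <- as.vector(outer(c("input", "nontreated"), reps, paste, sep = "__"))
  miss <- setdiff(need, names(wide))
  if (length(miss)) abort(paste0("missing sample for ", miss[1]))

  under_fun <- if (under_cmp == "lt") {
    function(x) x < under_threshold
  } else {
    function(x) x <= under_threshold
  }
  flags <- wide %>%
    mutate(
      underrepresented = under_fun(.data$input__1) | under_fun(.data$input__2),
      growth_ratio_1 = if_else(.data$input__1 > 0,
                               .data$nontreated__1 / .data$input__1, NA_real_),
      growth_ratio_2 = if_else(.data$input__2 > 0,
                               .data$nontreated__2 / .data$input__2, NA_real_)
    )
  gi <- if (growth_mode == "either") {
    (!is.na(flags$growth_ratio_1) & flags$growth_ratio_1 < growth_cutoff) |
      (!is.na(flags$growth_ratio_2) & flags$growth_ratio_2 < growth_cutoff)
  } else {
    (!is.na(flags$growth_ratio_1) & flags$growth_ratio_1 < growth_cutoff) &
      (!is.na(flags$growth_ratio_2) & flags$growth_ratio_2 < growth_cutoff)
  }
  # growth impairment is only assessed for genes that passed the
  # underrepresentation filter; an analyzable gene cannot have input 0
  flags <- mutate(flags, growth_impaired = !.data$underrepresented & gi,
                  analyzable = !.data$underrepresented & !.data$growth_impaired)
  stopifnot(all(!flags$analyzable |
                  (flags$input__1 > 0 & flags$input__2 > 0)))

  records <- purrr::map_dfr(treatments, function(tr) {
    t1 <- wide[[paste0(tr, "__1")]] %||% rep(0, nrow(wide))
    t2 <- wide[[paste0(tr, "__2")]] %||% rep(0, nrow(wide))
    ci1 <- compute_ci(t1, flags$nontreated__1, pseudocount)
    ci2 <- compute_ci(t2, flags$nontreated__2, pseudocount)
    tibble(
      gene_id = wide$gene_id, treatment = tr,
      input_1 = flags$input__1, input_2 = flags$input__2,
      nontreated_1 = flags$nontreated__1, nontreated_2 = flags$nontreated__2,
      treated_1 = t1, treated_2 = t2,
      underrepresented = flags$underrepresented,
      growth_impaired = flags$growth_impaired,
      analyzable = flags$analyzable,
      ci_rep1 = if_else(flags$analyzable, ci1, NA_real_),
      ci_rep2 = if_else(flags$analyzable, ci2, NA_real_),
      classification = classify_ci(
        if_else(flags$analyzable, ci1, NA_real_),
        if_else(flags$analyzable, ci2, NA_real_),
        ci_low, ci_high)
    )
  }) %>% arrange(.data$treatment, .data$gene_id)

  structure(list(
    records = records,
    treatments = treatments,
    params = list(under_threshold = under_threshold, under_cmp = under_cmp,
                  growth_cutoff = growth_cutoff, growth_mode = growth_mode,
                  ci_low = ci_low, ci_high = ci_high,
                  pseudocount = pseudocount)
  ), class = "tn_ci")
}

#' Competition index: treated over untreated
#'
#' @param treated,untreated Normalized per-gene counts (vectors).
#' @param pseudocount Added to both before the ratio (default 0).
#' @return CI values; NA (undefined) where the untreated count plus
#'   pseudocount is 0.
#' @export
compute_ci <- function(treated, untreated, pseudocount = 0) {
  stopifnot(all(treated >= 0, na.rm = TRUE),
            all(untreated >= 0, na.rm = TRUE))
  t <- treated + pseudocount
  u <- untreated + pseudocount
  if_else(u > 0, t / u, NA_real_)
}

#' Classify a gene by two-replicate CI concordance
#'
#' `REDUCED_COMPETITIVENESS` iff CI <= `low` in both replicates;
#' `INCREASED_COMPETITIVENESS` iff CI >= `high` in both; `NO_CHANGE`
#' otherwise; `NOT_ANALYZED` where either CI is undefined. Boundaries are
#' inclusive.
#'
#' @param ci_rep1,ci_rep2 CI vectors (NA = undefined).
#' @param low,high Cutoffs (defaults 0.5 and 2).
#' @return Character vector of classifications.
#' @export
classify_ci <- function(ci_rep1, ci_rep2, low = 0.5, high = 2) {
  case_when(
    is.na(ci_rep1) | is.na(ci_rep2) ~ "NOT_ANALYZED",
    ci_rep1 <= low & ci_rep2 <= low ~ "REDUCED_COMPETITIVENESS",
    ci_rep1 >= high & ci_rep2 >= high ~ "INCREASED_COMPETITIVENESS",
    TRUE ~ "NO_CHANGE"
  )
}

#' @export
print.tn_ci <- function(x, ...) {
  cat("tn_ci:", length(unique(x$records$gene_id)), "genes,",
      length(x$treatments), "treatment(s):",
      paste(x$treatments, collapse = ", "), "\n")
  print(glance(x))
  invisible(x)
}

#' Tidy the per-gene CI records
#'
#' @param x A `tn_ci` object.
#' @param ... Unused.
#' @return The per-gene tibble: counts, filter flags, per-replicate CIs and
#'   classification, one row per gene × treatment.
#' @method tidy tn_ci
#' @export
tidy.tn_ci <- function(x, ...) x$records

#' One-row-per-treatment summary of a competitiveness analysis
#'
#' @param x A `tn_ci` object.
#' @param ... Unused.
#' @return A tibble with gene totals: analyzable, excluded
#'   (underrepresented / growth-impaired), and classified counts per
#'   direction.
#' @method glance tn_ci
#' @export
glance.tn_ci <- function(x, ...) {
  x$records %>%
    group_by(.data$treatment) %>%
    summarise(
      n_genes = n(),
      n_analyzable = sum(.data$analyzable),
      n_underrepresented = sum(.data$underrepresented),
      n_growth_impaired = sum(.data$growth_impaired),
      n_reduced = sum(.data$classification == "REDUCED_COMPETITIVENESS"),
      n_increased = sum(.data$classification == "INCREASED_COMPETITIVENESS"),
      n_no_change = sum(.data$classification == "NO_CHANGE"),
      .groups = "drop"
    )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Write the gene-level report files for each treatment
#'
#' Three TSVs per treatment, sorted by gene id: the excluded-genes table
#' (filter flags and reason), the full CI table, and the hit list split by
#' direction.
#'
#' @param fit A `tn_ci` object.
#' @param dir Output directory (created if needed).
#' @return Tibble of written paths, invisibly.
#' @export
write_ci_reports <- function(fit, dir) {
  stopifnot(inherits(fit, "tn_ci"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- purrr::map_dfr(fit$treatments, function(tr) {
    rec <- filter(fit$records, .data$treatment == tr) %>%
      arrange(.data$gene_id)
    excl <- rec %>%
      filter(.data$classification == "NOT_ANALYZED") %>%
      mutate(reason = case_when(
        .data$underrepresented ~ "underrepresented_in_input",
        .data$growth_impaired ~ "growth_impaired_untreated",
        TRUE ~ "undefined_ci"
      )) %>%
      select("gene_id", "treatment", "input_1", "input_2",
             "nontreated_1", "nontreated_2", "reason")
    hits <- rec %>%
      filter(.data$classification %in%
               c("REDUCED_COMPETITIVENESS", "INCREASED_COMPETITIVENESS")) %>%
      select("gene_id", "treatment", "ci_rep1", "ci_rep2", "classification")
    p1 <- file.path(dir, paste0(tr, "_excluded_genes.tsv"))
    p2 <- file.path(dir, paste0(tr, "_ci_table.tsv"))
    p3 <- file.path(dir, paste0(tr, "_hits.tsv"))
    readr::write_tsv(excl, p1)
    readr::write_tsv(rec, p2)
    readr::write_tsv(hits, p3)
    tibble(treatment = tr, path = c(p1, p2, p3))
  })
  invisible(paths)
}
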