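#' Assign insertion sites to gene core regions and tally per-gene raw counts
#'
#' A site contributes to a gene iff its position lies inside the gene's core
#' region (central 80% of the ORF), regardless of the site's strand or the
#' gene's strand: a transposon knocks a gene out whichever way it faces. A
#' site inside two overlapping cores credits both genes.
#'
#' @param profile A `tn_profile`.
#' @param genes Gene tibble with `core_start`/`core_end` from
#'   [core_regions()].
#' @return A tibble `gene_id`, `raw_count` covering every gene (zero where no
#'   site falls in the core).
#' @export
gene_raw_counts <- function(profile, genes) {
  stopifnot(all(c("core_start", "core_end") %in% names(genes)))
  sites <- profile$sites
  counts <- numeric(nrow(genes))
  for (rid in unique(genes$replicon_id)) {
    gi <- which(genes$replicon_id == rid)
    g <- genes[gi, ]
    s <- filter(sites, .data$replicon_id == rid)
    if (nrow(s) == 0) next
    valid <- g$core_start <= g$core_end
    cores <- IRanges::IRanges(g$core_start[valid], g$core_end[valid])
    hits <- IRanges::findOverlaps(IRanges::IRanges(s$position, s$position),
                                  cores)
    if (length(hits) == 0) next
    agg <- tapply(s$count[S4Vectors::queryHits(hits)],
                  S4Vectors::subjectHits(hits), sum)
    counts[gi[which(valid)][as.integer(names(agg))]] <-
      counts[gi[which(valid)][as.integer(names(agg))]] + as.numeric(agg)
  }
  tibble(gene_id = genes$gene_id, raw_count = counts)
}

#' Total reads at intergenic insertion sites
#'
#' Sums raw counts at sites whose position lies outside every annotated gene
#' interval (full interval, not just the core — gene edges belong to genes).
#'
#' @param profile A `tn_profile`.
#' @param mask Intergenic mask tibble from [intergenic_mask()].
#' @return A single number of reads.
#' @export
intergenic_total <- function(profile, mask) {
  sites <- profile$sites
  total <- 0
  for (rid in unique(mask$replicon_id)) {
    m <- filter(mask, .data$replicon_id == rid)
    s <- filter(sites, .data$replicon_id == rid)
    if (nrow(s) == 0 || nrow(m) == 0) next
    ov <- IRanges::overlapsAny(IRanges::IRanges(s$position, s$position),
                               IRanges::IRanges(m$start, m$end))
    total <- total + sum(s$count[ov])
  }
  total
}

#' Intergenic-read normalization factors across samples
#'
#' Each sample is scaled so that its intergenic read total matches the sample
#' with the lowest intergenic total, on the premise that insertions between
#' genes are selectively neutral and should be equally represented in every
#' sample: `NF(s) = min_t intergenic(t) / intergenic(s)`. Exactly the
#' minimal sample(s) get NF = 1. The grouping spans all samples passed in
#' (normally both biological replicates and all conditions together).
#'
#' @param profiles List of `tn_profile` objects.
#' @param mask Intergenic mask tibble.
#' @return A tibble of class `tn_normalization`: `sample_id`, `condition`,
#'   `replicate`, `intergenic_total`, `nf`, `is_reference`.
#' @export
normalization_factors <- function(profiles, mask) {
  stats <- purrr::map_dfr(profiles, function(p) {
    tibble(sample_id = p$sample_id, condition = p$condition,
           replicate = p$replicate,
           intergenic_total = intergenic_total(p, mask))
  })
  if (any(stats$intergenic_total == 0)) {
    abort(paste0("sample '",
                 stats$sample_id[stats$intergenic_total == 0][1],
                 "' has zero intergenic reads; normalization undefined"))
  }
  ref <- min(stats$intergenic_total)
  out <- mutate(stats, nf = ref / .data$intergenic_total,
                is_reference = .data$intergenic_total == ref)
  class(out) <- c("tn_normalization", class(out))
  out
}

#' Per-gene raw and normalized counts for a set of samples
#'
#' @param profiles List of `tn_profile` objects.
#' @param genes Gene tibble with core regions.
#' @param normset Normalization tibble from [normalization_factors()].
#' @return A long tibble: `gene_id`, `sample_id`, `condition`, `replicate`,
#'   `raw_count`, `norm_count` (raw × sample NF, kept as a real).
#' @export
count_genes <- function(profiles, genes, normset) {
  purrr::map_dfr(profiles, function(p) {
    nf <- normset$nf[normset$sample_id == p$sample_id]
    if (length(nf) != 1) abort(paste0("no NF for sample ", p$sample_id))
    gene_raw_counts(p, genes) %>%
      mutate(sample_id = p$sample_id, condition = p$condition,
             replicate = p$replicate, norm_count = .data$raw_count * nf)
  })
}

#' Per-sample sequencing statistics table
#'
#' Reproduces the standard per-sample Tn-seq report: total reads, % reads
#' with no transposon sequence, reads too short, reads used, alignment rate,
#' normalization factor, total normalized reads, and reads per insertion
#' site. The normalized total is `round(total_reads × NF)` (half away from
#' zero) and reads/site is the normalized total divided by the number of
#' distinct observed sites, rounded the same way.
#'
#' @param profiles List of `tn_profile` objects.
#' @param normset Tibble from [normalization_factors()].
#' @param nf_digits NF is reported (and applied to the printed normalized
#'   total) at this many decimals; statistical computation elsewhere always
#'   uses full precision. Default 3, the conventional print precision.
#' @return A tibble with one row per sample and the eight report columns.
#' @export
sample_stats <- function(profiles, normset, nf_digits = 3) {
  purrr::map_dfr(profiles, function(p) {
    nf <- round(normset$nf[normset$sample_id == p$sample_id], nf_digits)
    acc <- p$accounting
    norm_total <- round_half_away(acc$total_reads * nf)
    tibble(
      sample_id = p$sample_id,
      condition = p$condition,
      replicate = p$replicate,
      total_reads = acc$total_reads,
      pct_no_tn = round(100 * acc$reads_no_tn / max(acc$total_reads, 1), 2),
      reads_too_short = acc$reads_too_short,
      reads_used = acc$reads_used,
      alignment_rate = round(p$alignment_rate, 2),
      nf = nf,
      norm_total = norm_total,
      reads_per_site = if (p$n_sites > 0)
        round_half_away(norm_total / p$n_sites) else 0
    )
  })
}
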