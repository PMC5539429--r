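#' Load a reference genome, annotation, core regions, mask and tag index
#'
#' @param fasta Path to the genome FASTA.
#' @param annotations List of annotation specs, each a list with `path`,
#'   `format` (`"ptt"`/`"gff3"`) and, for PTT, `replicon_id`.
#' @param tag_length Tag index k (default 17).
#' @param edge_fraction Gene-edge fraction excluded from cores (default 0.1).
#' @return List of class `tn_reference`: `replicons`, `genes` (with cores),
#'   `mask`, `index`.
#' @export
tn_reference <- function(fasta, annotations, tag_length = 17L,
                         edge_fraction = 0.1) {
  replicons <- read_genome(fasta)
  genes <- purrr::map_dfr(annotations, function(a) {
    rid <- a$replicon_id %||% replicons$replicon_id[1]
    len <- replicons$length[match(rid, replicons$replicon_id)]
    read_annotation(a$path, a$format %||% "ptt", replicon_id = rid,
                    replicon_length = len)
  })
  genes <- core_regions(genes, edge_fraction)
  structure(list(
    replicons = replicons, genes = genes,
    mask = intergenic_mask(replicons, genes),
    index = build_tag_index(replicons, tag_length)
  ), class = "tn_reference")
}

#' Run the shared post-mapping analysis on a set of sample profiles
#'
#' Computes intergenic normalization factors, per-gene raw and normalized
#' counts, per-sample statistics, and the competitiveness classification.
#' This is the common back half of the pipeline, whether the profiles came
#' from FASTQ mapping or from the count-level simulator.
#'
#' @param profiles List of `tn_profile` objects (both replicates, all
#'   conditions).
#' @param replicons,genes Reference tibbles (genes with core regions).
#' @param ... Passed to [competitiveness()].
#' @param nf_digits NF print precision for the statistics table.
#' @return List of class `tn_analysis`: `normset`, `gene_counts`, `stats`,
#'   `fit` (a `tn_ci`).
#' @export
analyze_profiles <- function(profiles, replicons, genes, ...,
                             nf_digits = 3) {
  mask <- intergenic_mask(replicons, genes)
  normset <- normalization_factors(profiles, mask)
  gene_counts <- count_genes(profiles, genes, normset)
  stats <- sample_stats(profiles, normset, nf_digits = nf_digits)
  fit <- competitiveness(gene_counts, ...)
  structure(list(normset = normset, gene_counts = gene_counts,
                 stats = stats, fit = fit),
            class = "tn_analysis")
}

#' Validate a run configuration
#'
#' Checks, before any file I/O, that each replicate has exactly one input
#' and one nontreated sample, that at least one treated condition is
#' present, and that required fields exist.
#'
#' @param config A run configuration list (see [run_tnseq()]).
#' @return The configuration, invisibly, or an error.
#' @export
validate_run_config <- function(config) {
  for (field in c("genome", "annotations", "samples", "outdir")) {
    if (is.null(config[[field]])) abort(paste0("config missing '", field, "'"))
  }
  samples <- purrr::map_dfr(config$samples, function(s) {
    for (field in c("sample_id", "fastq", "condition", "replicate")) {
      if (is.null(s[[field]])) {
        abort(paste0("sample entry missing '", field, "'"))
      }
    }
    tibble(sample_id = s$sample_id, fastq = s$fastq,
           condition = s$condition, replicate = as.integer(s$replicate))
  })
  if (anyDuplicated(samples$sample_id)) abort("duplicate sample_id")
  if (!all(samples$replicate >= 1)) abort("replicates must be >= 1")
  for (r in unique(samples$replicate)) {
    sub <- filter(samples, .data$replicate == r)
    for (role in c("input", "nontreated")) {
      if (sum(sub$condition == role) != 1) {
        abort(paste0("replicate ", r, " must have exactly one '", role,
                     "' sample"))
      }
    }
  }
  if (!any(!samples$condition %in% c("input", "nontreated"))) {
    abort("config must declare at least one treated condition")
  }
  invisible(config)
}

#' Run the full Tn-seq competitiveness pipeline from a configuration
#'
#' The run has three phases: prealignment (FASTQ processing — transposon
#' detection, trimming and tag extraction with full accounting), alignment
#' (exact unique tag mapping and per-site tallies), and postalignment
#' (normalization, gene-level aggregation, CI computation and
#' classification, reports). Outputs are written under `config$outdir`:
#' per-sample site tables and WIG tracks, the per-sample statistics table,
#' the per-gene count matrix, CI reports per treatment, and a run log (plain
#' text plus a YAML sidecar of every parameter and statistic).
#'
#' @param config A configuration list, or the path to a YAML file with the
#'   same structure: `genome` (FASTA path), `annotations` (list of
#'   `path`/`format`/`replicon_id`), `samples` (list of `sample_id`,
#'   `fastq`, `condition`, `replicate`), `outdir`, and optional `params`
#'   (any of `tn_sequence`, `max_mismatches`, `tag_length`, `revcomp`,
#'   `anchor0`, `edge_fraction`, `under_threshold`, `under_cmp`,
#'   `growth_cutoff`, `growth_mode`, `ci_low`, `ci_high`, `pseudocount`,
#'   `nf_digits`).
#' @return A `tn_analysis` (invisibly), with `profiles` and `reference`
#'   attached.
#' @export
run_tnseq <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_run_config(config)
  p <- config$params %||% list()
  prep <- read_prep_params(
    tn_sequence = p$tn_sequence %||% "CGATCTAGACCGGGGACTTATCATCCAACCTG",
    max_mismatches = p$max_mismatches %||% 3L,
    tag_length = p$tag_length %||% 17L,
    revcomp_input = p$revcomp %||% FALSE,
    anchor0 = p$anchor0 %||% FALSE
  )
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c("tncomp run", paste0("  genome: ", config$genome))

  ref <- tn_reference(config$genome, config$annotations,
                      tag_length = prep$tag_length,
                      edge_fraction = p$edge_fraction %||% 0.1)
  profiles <- purrr::map(config$samples, function(s) {
    tags <- tryCatch(
      process_fastq(s$fastq, prep),
      error = function(e) abort(paste0("prealignment failed for sample '",
                                       s$sample_id, "': ", conditionMessage(e)))
    )
    prof <- tryCatch(
      tally_sites(tags, ref$index, s$sample_id, s$condition,
                  as.integer(s$replicate)),
      error = function(e) abort(paste0("alignment failed for sample '",
                                       s$sample_id, "': ", conditionMessage(e)))
    )
    write_site_table(prof, file.path(outdir, paste0(s$sample_id, "_sites.tsv")),
                     ref$replicons)
    write_igv_track(prof, file.path(outdir, paste0(s$sample_id, ".wig")))
    prof
  })

  analysis <- analyze_profiles(
    profiles, ref$replicons, ref$genes,
    under_threshold = p$under_threshold %||% 100,
    under_cmp = p$under_cmp %||% "lt",
    growth_cutoff = p$growth_cutoff %||% 0.5,
    growth_mode = p$growth_mode %||% "either",
    ci_low = p$ci_low %||% 0.5,
    ci_high = p$ci_high %||% 2,
    pseudocount = p$pseudocount %||% 0,
    nf_digits = p$nf_digits %||% 3
  )

  readr::write_tsv(table1_report(analysis$stats),
                   file.path(outdir, "sample_statistics.tsv"))
  counts_wide <- analysis$gene_counts %>%
    select("gene_id", "sample_id", "raw_count", "norm_count") %>%
    tidyr::pivot_wider(names_from = "sample_id",
                       values_from = c("raw_count", "norm_count"))
  readr::write_tsv(counts_wide, file.path(outdir, "gene_counts.tsv"))
  write_ci_reports(analysis$fit, outdir)

  log_lines <- c(
    log_lines,
    paste0("  parameters: tn_sequence=", prep$tn_sequence,
           " max_mismatches=", prep$max_mismatches,
           " tag_length=", prep$tag_length),
    paste0("  thresholds: ",
           paste(names(analysis$fit$params),
                 unlist(analysis$fit$params), sep = "=", collapse = " ")),
    "  samples:",
    sprintf("    %s (%s, rep %d): total=%d used=%d aligned=%.2f%% NF=%.3f",
            analysis$stats$sample_id, analysis$stats$condition,
            analysis$stats$replicate, analysis$stats$total_reads,
            analysis$stats$reads_used, analysis$stats$alignment_rate,
            analysis$stats$nf)
  )
  writeLines(log_lines, file.path(outdir, "run_log.txt"))
  yaml::write_yaml(
    list(parameters = c(prep[c("tn_sequence", "max_mismatches", "tag_length",
                               "revcomp_input", "anchor0")],
                        analysis$fit$params),
         statistics = as.list(analysis$stats)),
    file.path(outdir, "run_log.yaml")
  )
  analysis$profiles <- profiles
  analysis$reference <- ref
  invisible(analysis)
}

#' Per-sample statistics report in the standard eight-column layout
#'
#' @param stats Tibble from [sample_stats()].
#' @return Tibble with display columns: total reads, % reads with no Tn
#'   sequence (2 dp), reads too short, reads used, alignment rate % (2 dp),
#'   NF (3 dp), total normalized reads, reads per Tn site.
#' @export
table1_report <- function(stats) {
  if (any(stats$reads_used == 0)) {
    warning("sample with zero used reads; alignment rate reported as 0.00")
  }
  tibble(
    sample = stats$sample_id,
    condition = stats$condition,
    replicate = stats$replicate,
    total_reads = stats$total_reads,
    pct_no_tn = sprintf("%.2f", stats$pct_no_tn),
    reads_too_short = stats$reads_too_short,
    reads_used = stats$reads_used,
    alignment_rate = sprintf("%.2f", stats$alignment_rate),
    nf = sprintf("%.3f", stats$nf),
    norm_total = stats$norm_total,
    reads_per_site = stats$reads_per_site
  )
}
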