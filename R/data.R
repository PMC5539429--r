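#' Published per-sample statistics from an S. meliloti Tn-seq screen
#'
#' The per-sample sequencing statistics reported for a published
#' Sinorhizobium meliloti mariner Tn-seq competitiveness screen under
#' cationic antimicrobial peptide challenge (NCR247 and polymyxin B): two
#' biological replicates, each with an input library, an untreated
#' outgrowth control, and the two treated cultures. Columns follow the
#' standard report layout ([table1_report()]): total reads, percent of
#' reads without the transposon sequence, reads too short, reads used,
#' alignment rate, intergenic normalization factor (printed at 3 decimals),
#' total normalized reads and reads per insertion site.
#'
#' These rows serve as reference inputs for checking the report arithmetic:
#' the printed normalized total equals `round(total_reads * nf)` with
#' half-away-from-zero rounding in every row.
#'
#' @return A tibble with 8 rows and 10 columns.
#' @examples
#' stats <- published_run_stats()
#' all(round(stats$total_reads * stats$nf) == stats$norm_total)
#' @export
published_run_stats <- function() {
  readr::read_tsv(
    system.file("extdata", "smeliloti_tnseq_run_stats.tsv",
                package = "tncomp"),
    show_col_types = FALSE
  )
}
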