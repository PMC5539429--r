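#' Map genomic tags exactly against the tag index
#'
#' Mapping is exact (zero mismatches) and unique-only: a tag absent from the
#' genome is `unmapped`, a tag occurring at more than one location (counting
#' both strands of all replicons) is `ambiguous` and is counted but never
#' located, and a tag with exactly one occurrence yields its location.
#'
#' @param tags Character vector of tags, or the tibble (`tag`, `count`) from
#'   [process_fastq()].
#' @param index A [build_tag_index()] object.
#' @return A tibble: `tag`, `count`, `status`
#'   (`unique`/`ambiguous`/`unmapped`), and for unique hits `replicon_id`,
#'   `start` (forward-strand start of the k-mer window), `strand`.
#' @export
map_tags <- function(tags, index) {
  stopifnot(inherits(index, "tag_index"))
  if (is.character(tags)) tags <- tibble(tag = tags) %>% count(.data$tag, name = "count")
  if (any(nchar(tags$tag) != index$k)) {
    abort(paste0("all tags must have length k = ", index$k))
  }
  uniq <- filter(index$locations, .data$multiplicity == 1L)
  ambig_tags <- distinct(
    filter(index$locations, .data$multiplicity > 1L), .data$tag
  )$tag
  out <- tags %>%
    left_join(select(uniq, "tag", "replicon_id", "start", "strand"),
              by = "tag") %>%
    mutate(status = case_when(
      !is.na(.data$replicon_id) ~ "unique",
      .data$tag %in% ambig_tags ~ "ambiguous",
      TRUE ~ "unmapped"
    ))
  out
}

#' Insertion-site coordinate of a mapped tag
#'
#' The site coordinate is the genomic base abutting the transposon junction:
#' for a forward-strand match starting at `s` the site is `(s, +)`; for a
#' reverse-strand match whose k-mer occupies forward coordinates
#' `[s, s + k - 1]` the site is `(s + k - 1, -)`.
#'
#' @param mapped Tibble from [map_tags()] (unique rows used).
#' @param k Tag length of the index used.
#' @return The input with a `position` column added for unique hits.
#' @export
site_of <- function(mapped, k) {
  mutate(mapped, position = if_else(
    .data$strand == "+", .data$start, .data$start + as.integer(k) - 1L
  ))
}

#' Tally mapped tags into an insertion-site profile
#'
#' @param tag_set A `tag_set` from [process_fastq()], or a tibble
#'   (`tag`, `count`).
#' @param index A [build_tag_index()] object.
#' @param sample_id,condition,replicate Sample metadata. `condition` is one
#'   of `"input"`, `"nontreated"` or a treatment label (e.g. `"NCR247"`).
#' @return An object of class `tn_profile`: `sites` tibble
#'   (`replicon_id`, `position`, `strand`, `count`), `accounting`,
#'   `aligned_reads`, `ambiguous_reads`, `unmapped_reads`, `alignment_rate`
#'   (percent of used reads aligned), `n_sites`, plus the metadata.
#' @export
tally_sites <- function(tag_set, index, sample_id = "sample",
                        condition = "input", replicate = 1L) {
  if (inherits(tag_set, "tag_set")) {
    tags <- tag_set$tags
    accounting <- tag_set$accounting
  } else {
    tags <- tag_set
    accounting <- tibble(total_reads = sum(tags$count), reads_no_tn = 0L,
                         reads_too_short = 0L, reads_used = sum(tags$count))
  }
  mapped <- site_of(map_tags(tags, index), index$k)
  aligned <- sum(mapped$count[mapped$status == "unique"])
  ambiguous <- sum(mapped$count[mapped$status == "ambiguous"])
  unmapped <- sum(mapped$count[mapped$status == "unmapped"])
  sites <- mapped %>%
    filter(.data$status == "unique") %>%
    group_by(.data$replicon_id, .data$position, .data$strand) %>%
    summarise(count = sum(.data$count), .groups = "drop") %>%
    arrange(.data$replicon_id, .data$position, .data$strand)
  new_tn_profile(sites, accounting, sample_id, condition, replicate,
                 aligned, ambiguous, unmapped)
}

new_tn_profile <- function(sites, accounting, sample_id, condition,
                           replicate, aligned, ambiguous, unmapped) {
  used <- accounting$reads_used
  structure(list(
    sample_id = sample_id, condition = condition,
    replicate = as.integer(replicate),
    sites = sites, accounting = accounting,
    aligned_reads = aligned, ambiguous_reads = ambiguous,
    unmapped_reads = unmapped,
    alignment_rate = if (used > 0) 100 * aligned / used else 0,
    n_sites = nrow(sites)
  ), class = "tn_profile")
}

#' @export
print.tn_profile <- function(x, ...) {
  cat("tn_profile", x$sample_id, sprintf("(%s, replicate %d)", x$condition,
      x$replicate), "\n")
  cat(sprintf("  reads: %d total, %d used, %d aligned (%.2f%%)\n",
              x$accounting$total_reads, x$accounting$reads_used,
              x$aligned_reads, x$alignment_rate))
  cat(sprintf("  %d insertion sites\n", x$n_sites))
  invisible(x)
}

#' Write an IGV-compatible WIG track of insertion density
#'
#' One `variableStep` section per replicon; the value at each position is the
#' raw read count with opposite-strand sites at the same position summed.
#'
#' @param profile A `tn_profile`.
#' @param path Output path (`.wig`).
#' @param track_name Track name (defaults to the sample id).
#' @return `path`, invisibly.
#' @export
write_igv_track <- function(profile, path, track_name = profile$sample_id) {
  per_pos <- profile$sites %>%
    group_by(.data$replicon_id, .data$position) %>%
    summarise(count = sum(.data$count), .groups = "drop") %>%
    arrange(.data$replicon_id, .data$position)
  lines <- sprintf('track type=wiggle_0 name="%s"', track_name)
  for (rid in unique(per_pos$replicon_id)) {
    sub <- filter(per_pos, .data$replicon_id == rid)
    lines <- c(lines, sprintf("variableStep chrom=%s", rid),
               sprintf("%d %d", sub$position, sub$count))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a per-site TSV table
#'
#' Columns: replicon, 1-based position, strand, raw count, and whether the
#' junction base begins a TA dinucleotide on its strand (the mariner target
#' motif), when the genome is supplied.
#'
#' @param profile A `tn_profile`.
#' @param path Output path.
#' @param replicons Optional replicon tibble to annotate TA sites.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(profile, path, replicons = NULL) {
  sites <- profile$sites
  if (!is.null(replicons)) {
    sites <- left_join(sites,
                       select(replicons, "replicon_id", "sequence", "length"),
                       by = "replicon_id") %>%
      mutate(is_TA = if_else(
        .data$strand == "+",
        substring(.data$sequence, .data$position, .data$position + 1L) == "TA",
        substring(.data$sequence, pmax(.data$position - 1L, 1L),
                  .data$position) == "TA"
      )) %>%
      select(-"sequence", -"length")
  }
  readr::write_tsv(sites, path)
  invisible(path)
}
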