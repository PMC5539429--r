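#' Parameters for transposon detection and tag extraction
#'
#' The expected read structure is: transposon end sequence (32 nt construct
#' sequence liberated by MmeI digestion), followed immediately by the genomic
#' tag — the few bases of chromosomal DNA adjacent to the junction that
#' localize the insertion — followed by downstream adapter/filler. Detection
#' allows a bounded number of mismatches in the transposon sequence; the tag
#' is mapped exactly downstream, so no mismatch budget applies to it.
#'
#' The tag length defaults to 17 nt. MmeI liberates 16–18 bp of flanking DNA,
#' and published protocols variously quote 16 or 17; the parameter exists
#' because the correct value is a property of the library construction, not
#' of this software.
#'
#' @param tn_sequence Transposon end sequence expected at the 5' end of the
#'   genomic junction (default the 32-nt HIMAR1 construct sequence).
#' @param max_mismatches Maximum Hamming mismatches tolerated when locating
#'   the transposon sequence (default 3).
#' @param tag_length Genomic tag length in nt (default 17).
#' @param revcomp_input Reverse-complement every read before scanning
#'   (for libraries sequenced from the opposite end).
#' @param anchor0 Only accept the transposon at read offset 0 instead of
#'   scanning all offsets.
#' @return A list of class `read_prep_params`.
#' @export
read_prep_params <- function(tn_sequence = "CGATCTAGACCGGGGACTTATCATCCAACCTG",
                             max_mismatches = 3L,
                             tag_length = 17L,
                             revcomp_input = FALSE,
                             anchor0 = FALSE) {
  tn_sequence <- toupper(tn_sequence)
  if (stringi::stri_detect_regex(tn_sequence, "[^ACGT]")) {
    abort("tn_sequence must be over {A,C,G,T}")
  }
  if (max_mismatches < 0) abort("max_mismatches must be >= 0")
  if (tag_length < 1) abort("tag_length must be >= 1")
  structure(list(tn_sequence = tn_sequence,
                 max_mismatches = as.integer(max_mismatches),
                 tag_length = as.integer(tag_length),
                 revcomp_input = isTRUE(revcomp_input),
                 anchor0 = isTRUE(anchor0)),
            class = "read_prep_params")
}

#' Hamming distance between equal-length DNA strings
#'
#' Vectorized over pairs. `N` never matches anything, including another `N`.
#'
#' @param a,b Character vectors of equal-length strings (recycled to common
#'   length).
#' @return Integer vector of mismatch counts.
#' @export
hamming <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n); b <- rep_len(as.character(b), n)
  if (any(nchar(a) != nchar(b))) abort("hamming: unequal string lengths")
  cpp_hamming(a, b)
}

#' Locate the transposon end sequence in reads
#'
#' Scans every offset of each read and returns the leftmost offset achieving
#' the minimum Hamming distance to the transposon sequence, provided that
#' minimum is within the mismatch budget; NA otherwise. With
#' `params$anchor0` only offset 0 is considered, and with
#' `params$revcomp_input` reads are reverse-complemented before scanning.
#'
#' @param reads Character vector of read sequences.
#' @param params [read_prep_params()].
#' @return A tibble with columns `offset` (0-based match start, NA = no
#'   match) and `mismatches`.
#' @export
find_transposon <- function(reads, params = read_prep_params()) {
  reads <- toupper(as.character(reads))
  if (params$revcomp_input) reads <- revcomp(reads)
  res <- cpp_scan_pattern(reads, params$tn_sequence,
                          params$max_mismatches, params$anchor0)
  tibble(offset = res$offset - 1L, mismatches = res$mismatches)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Extract the genomic tag downstream of a transposon match
#'
#' @param reads Character vector of read sequences (after any
#'   reverse-complementing).
#' @param offset 0-based transposon match offsets from [find_transposon()].
#' @param params [read_prep_params()].
#' @return Character vector of tags; NA where fewer than `tag_length` bases
#'   remain after the transposon (too short) or where `offset` is NA.
#' @export
extract_tag <- function(reads, offset, params = read_prep_params()) {
  start <- offset + nchar(params$tn_sequence) + 1L
  end <- start + params$tag_length - 1L
  tag <- substring(reads, start, end)
  tag[is.na(offset) | nchar(tag) < params$tag_length] <- NA_character_
  tag
}

#' Process a FASTQ file into genomic tags with full read accounting
#'
#' Every read lands in exactly one bucket: `no_tn` (transposon sequence not
#' found within the mismatch budget), `too_short` (transposon found but fewer
#' than `tag_length` bases follow it), or `used` (a tag was extracted).
#' Quality scores are read but not used — no quality filtering is applied.
#'
#' @param path FASTQ file (plain or gzip), Phred+33, 4-line records.
#' @param params [read_prep_params()].
#' @param chunk_size Reads processed per chunk (memory control).
#' @return A list of class `tag_set`: `tags` — tibble `tag`, `count`
#'   (multiset of extracted tags); `accounting` — one-row tibble
#'   `total_reads`, `reads_no_tn`, `reads_too_short`, `reads_used`.
#' @export
process_fastq <- function(path, params = read_prep_params(),
                          chunk_size = 500000L) {
  if (!file.exists(path)) abort(paste0("FASTQ file not found: ", path))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  total <- no_tn <- too_short <- used <- 0
  tag_tallies <- list()
  n_done <- 0L
  repeat {
    lines <- readLines(con, n = chunk_size * 4L)
    if (length(lines) == 0) break
    if (length(lines) %% 4L != 0L) {
      abort(paste0("truncated FASTQ record at read ",
                   n_done + length(lines) %/% 4L + 1L, " in ", path))
    }
    heads <- lines[seq(1, length(lines), by = 4L)]
    if (any(substr(heads, 1, 1) != "@")) {
      abort(paste0("malformed FASTQ record at read ",
                   n_done + which(substr(heads, 1, 1) != "@")[1], " in ", path))
    }
    reads <- toupper(lines[seq(2, length(lines), by = 4L)])
    n <- length(reads)
    if (params$revcomp_input) reads <- revcomp(reads)
    hit <- cpp_scan_pattern(reads, params$tn_sequence,
                            params$max_mismatches, params$anchor0)
    off0 <- hit$offset - 1L
    tags <- extract_tag(reads, off0, params)
    is_no_tn <- is.na(off0)
    is_short <- !is_no_tn & is.na(tags)
    total <- total + n
    no_tn <- no_tn + sum(is_no_tn)
    too_short <- too_short + sum(is_short)
    used <- used + sum(!is_no_tn & !is_short)
    kept <- tags[!is.na(tags)]
    if (length(kept)) {
      tag_tallies[[length(tag_tallies) + 1L]] <-
        tibble(tag = kept) %>% count(.data$tag, name = "count")
    }
    n_done <- n_done + n
  }
  tags <- if (length(tag_tallies)) {
    bind_rows(tag_tallies) %>%
      group_by(.data$tag) %>%
      summarise(count = sum(.data$count), .groups = "drop")
  } else {
    tibble(tag = character(), count = integer())
  }
  structure(list(
    tags = tags,
    accounting = tibble(total_reads = total, reads_no_tn = no_tn,
                        reads_too_short = too_short, reads_used = used)
  ), class = "tag_set")
}
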