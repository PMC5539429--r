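# small in-code fixtures shared across test files

write_tmp_fasta <- function(records, dir = tempdir()) {
  path <- tempfile(fileext = ".fa", tmpdir = dir)
  writeLines(unlist(purrr::imap(records, function(seq, id) {
    c(paste0(">", id), seq)
  })), path)
  path
}

write_tmp_fastq <- function(reads, dir = tempdir()) {
  path <- tempfile(fileext = ".fastq", tmpdir = dir)
  n <- length(reads)
  out <- character(4 * n)
  out[seq(1, length.out = n, by = 4)] <- paste0("@read", seq_len(n))
  out[seq(2, length.out = n, by = 4)] <- reads
  out[seq(3, length.out = n, by = 4)] <- "+"
  out[seq(4, length.out = n, by = 4)] <- strrep("I", nchar(reads))
  writeLines(out, path)
  path
}

make_genes <- function(start, end, strand = "+", replicon_id = "chr",
                       gene_id = NULL) {
  n <- length(start)
  tibble::tibble(
    gene_id = gene_id %||% paste0("g", seq_len(n)),
    replicon_id = rep_len(replicon_id, n),
    start = as.integer(start), end = as.integer(end),
    strand = rep_len(strand, n),
    product = rep(NA_character_, n)
  )
}

make_replicon <- function(sequence, id = "chr") {
  tibble::tibble(replicon_id = id, sequence = sequence,
                 length = nchar(sequence))
}

make_profile <- function(positions, counts, strand = "+",
                         replicon_id = "chr", sample_id = "s",
                         condition = "input", replicate = 1L,
                         total = sum(counts)) {
  sites <- tibble::tibble(
    replicon_id = rep_len(replicon_id, length(positions)),
    position = as.integer(positions),
    strand = rep_len(strand, length(positions)),
    count = counts
  )
  acc <- tibble::tibble(total_reads = total, reads_no_tn = 0L,
                        reads_too_short = 0L, reads_used = total)
  tncomp:::new_tn_profile(sites, acc, sample_id, condition, replicate,
                          aligned = sum(counts), ambiguous = 0L,
                          unmapped = 0L)
}

random_dna <- function(n, len) {
  stringi::stri_rand_strings(n, len, "[ACGT]")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
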