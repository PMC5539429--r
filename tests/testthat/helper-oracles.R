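# independent brute-force oracles, deliberately naive

# leftmost offset (0-based) with the minimum Hamming distance <= max_mm,
# computed position by position in plain R; N never matches
oracle_scan <- function(read, pattern, max_mm) {
  rs <- strsplit(read, "")[[1]]
  ps <- strsplit(pattern, "")[[1]]
  plen <- length(ps)
  best_off <- NA_integer_; best_d <- Inf
  if (length(rs) >= plen) {
    for (o in 0:(length(rs) - plen)) {
      w <- rs[(o + 1):(o + plen)]
      d <- sum(w != ps | w == "N" | ps == "N")
      if (d < best_d) { best_d <- d; best_off <- o }
    }
  }
  if (is.infinite(best_d) || best_d > max_mm) {
    c(offset = NA_integer_, mismatches = NA_integer_)
  } else {
    c(offset = best_off, mismatches = best_d)
  }
}

oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# enumerate every k-mer of both strands of every replicon with locations
oracle_kmers <- function(replicons, k) {
  out <- list()
  for (i in seq_len(nrow(replicons))) {
    seq <- replicons$sequence[i]
    len <- nchar(seq)
    for (s in seq_len(len - k + 1)) {
      fwd <- substr(seq, s, s + k - 1)
      if (!grepl("N", fwd, fixed = TRUE)) {
        out[[length(out) + 1]] <- data.frame(
          tag = fwd, replicon_id = replicons$replicon_id[i],
          start = s, strand = "+")
        out[[length(out) + 1]] <- data.frame(
          tag = oracle_revcomp(fwd), replicon_id = replicons$replicon_id[i],
          start = s, strand = "-")
      }
    }
  }
  df <- do.call(rbind, out)
  mult <- table(df$tag)
  df$multiplicity <- as.integer(mult[df$tag])
  df
}
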