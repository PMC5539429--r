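#' Read a reference genome from a multi-record FASTA file
#'
#' Each FASTA record becomes one replicon. Sequences are upper-cased and must
#' consist of A, C, G, T and N only; anything else (e.g. RNA `U`, IUPAC
#' ambiguity codes other than N) is rejected with an error naming the
#' offending record.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `replicon_id`, `sequence` (character) and
#'   `length` (bases), one row per record, in file order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr", "ACGTACGT"), fa)
#' read_genome(fa)
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  # read as plain strings first so validation errors can name the record
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0) abort(paste0("FASTA file has no records: ", path))
  ids <- sub("\\s.*$", "", names(recs))
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate FASTA record id: ", ids[duplicated(ids)][1]))
  }
  seqs <- unname(toupper(as.character(recs)))
  bad <- stringi::stri_detect_regex(seqs, "[^ACGTN]")
  if (any(bad)) {
    abort(paste0("record '", ids[which(bad)[1]],
                 "' contains characters outside {A,C,G,T,N}"))
  }
  if (any(nchar(seqs) == 0)) {
    abort(paste0("record '", ids[which(nchar(seqs) == 0)[1]], "' is empty"))
  }
  tibble(replicon_id = ids, sequence = unname(seqs), length = nchar(seqs))
}

#' Read gene annotation (PTT or GFF3)
#'
#' PTT is the NCBI protein-table dialect: header lines above the column
#' header are skipped, fields are tab-separated and the `Location` column
#' holds `start..end` (1-based inclusive). GFF3 rows of type `gene` or `CDS`
#' are used; when both annotate the same locus the `gene` rows win. Gene ids
#' come from the PTT `Synonym` column or the GFF3 `locus_tag`/`ID` attribute.
#'
#' @param path Annotation file path.
#' @param format `"ptt"` or `"gff3"`.
#' @param replicon_id Replicon the annotation belongs to (PTT files carry no
#'   sequence name; for GFF3 this filters to one seqid, default all).
#' @param replicon_length Optional length used to validate coordinates.
#' @return A tibble of gene records: `gene_id`, `replicon_id`, `start`,
#'   `end`, `strand` (`"+"`/`"-"`), `product`, sorted by `start`.
#' @export
read_annotation <- function(path, format = c("ptt", "gff3"),
                            replicon_id = NULL, replicon_length = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("annotation file not found: ", path))
  genes <- switch(format,
    ptt = read_ptt(path, replicon_id %||% "unknown"),
    gff3 = read_gff3_genes(path, replicon_id)
  )
  if (!is.null(replicon_length)) {
    over <- genes$end > replicon_length
    if (any(over)) {
      abort(paste0("gene '", genes$gene_id[which(over)[1]],
                   "' extends beyond replicon length ", replicon_length))
    }
  }
  if (anyDuplicated(genes$gene_id)) {
    abort(paste0("duplicate gene_id: ",
                 genes$gene_id[duplicated(genes$gene_id)][1]))
  }
  arrange(genes, .data$start)
}

read_ptt <- function(path, replicon_id) {
  lines <- readLines(path)
  hdr <- grep("^Location\\t", lines)
  if (length(hdr) == 0) abort(paste0("no PTT column header in ", path))
  hdr <- hdr[1]
  body_idx <- seq.int(hdr + 1, length.out = max(0, length(lines) - hdr))
  body <- lines[body_idx]
  keep <- nzchar(body)
  body <- body[keep]; body_idx <- body_idx[keep]
  if (length(body) == 0) {
    return(tibble(gene_id = character(), replicon_id = character(),
                  start = integer(), end = integer(), strand = character(),
                  product = character()))
  }
  fields <- stringi::stri_split_fixed(body, "\t")
  nf <- lengths(fields)
  if (any(nf < 9)) {
    abort(paste0("PTT line ", body_idx[which(nf < 9)[1]],
                 ": expected 9 tab-separated fields"))
  }
  m <- do.call(rbind, fields)
  loc <- stringi::stri_match_first_regex(m[, 1], "^(\\d+)\\.\\.(\\d+)$")
  bad <- is.na(loc[, 1])
  if (any(bad)) {
    abort(paste0("PTT line ", body_idx[which(bad)[1]],
                 ": malformed Location '", m[which(bad)[1], 1], "'"))
  }
  start <- as.integer(loc[, 2]); end <- as.integer(loc[, 3])
  rev <- start > end
  if (any(rev)) {
    abort(paste0("PTT line ", body_idx[which(rev)[1]],
                 ": start > end in Location '", m[which(rev)[1], 1], "'"))
  }
  syn <- m[, 6]
  gene_id <- if_else(is.na(syn) | syn == "-" | syn == "",
                     paste0("gene_", seq_along(start)), syn)
  tibble(gene_id = gene_id, replicon_id = replicon_id,
         start = start, end = end, strand = m[, 2], product = m[, 9])
}

read_gff3_genes <- function(path, replicon_id = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type %in% c("gene", "CDS")]
  if (!is.null(replicon_id)) {
    gr <- gr[as.character(GenomicRanges::seqnames(gr)) == replicon_id]
  }
  if (length(gr) == 0) {
    return(tibble(gene_id = character(), replicon_id = character(),
                  start = integer(), end = integer(), strand = character(),
                  product = character()))
  }
  meta <- S4Vectors::mcols(gr)
  id <- if ("locus_tag" %in% names(meta)) as.character(meta$locus_tag) else NA
  if (all(is.na(id)) && "ID" %in% names(meta)) id <- as.character(meta$ID)
  id[is.na(id)] <- paste0("gene_", which(is.na(id)))
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*")) {
    abort("GFF3 gene/CDS feature without a strand")
  }
  product <- if ("product" %in% names(meta)) {
    as.character(meta$product)
  } else rep(NA_character_, length(gr))
  out <- tibble(
    gene_id = id,
    replicon_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = strand,
    product = product,
    .type = as.character(gr$type)
  )
  # prefer gene rows over CDS rows for the same locus id
  out <- out %>%
    arrange(match(.data$.type, c("gene", "CDS"))) %>%
    distinct(.data$gene_id, .keep_all = TRUE) %>%
    select(-".type")
  out
}

#' Central core region of each gene
#'
#' Insertions in the first and last 10% of an open reading frame often leave
#' gene function intact, so only the central 80% counts toward a gene's
#' insertion tally. With gene length `L` and edge width `e = floor(0.1 * L)`,
#' the core is `[start + e, end - e]`; for genes under 10 bp the edge width
#' is 0 and the core is the whole gene.
#'
#' @param genes Gene tibble from [read_annotation()].
#' @param edge_fraction Fraction of the gene length excluded at each end
#'   (default 0.1).
#' @return The input with `core_start` and `core_end` columns added. An empty
#'   core (possible only for `edge_fraction > 1/3`... never with the default)
#'   has `core_start > core_end`.
#' @examples
#' genes <- tibble::tibble(gene_id = "g1", replicon_id = "chr",
#'                         start = 101L, end = 400L, strand = "+",
#'                         product = NA_character_)
#' core_regions(genes) # core 131..370
#' @export
core_regions <- function(genes, edge_fraction = 0.1) {
  stopifnot(edge_fraction >= 0, edge_fraction < 0.5)
  e <- floor(edge_fraction * (genes$end - genes$start + 1))
  mutate(genes, core_start = .data$start + e, core_end = .data$end - e)
}

#' Intergenic intervals of a genome
#'
#' A position is intergenic iff it lies inside no annotated gene's full
#' interval (gene edges belong to genes, not to the intergenic mask, even
#' though they are excluded from gene cores).
#'
#' @param replicons Replicon tibble from [read_genome()].
#' @param genes Gene tibble.
#' @return A tibble of disjoint sorted intervals: `replicon_id`, `start`,
#'   `end` (1-based inclusive).
#' @export
intergenic_mask <- function(replicons, genes) {
  purrr::map_dfr(seq_len(nrow(replicons)), function(i) {
    rid <- replicons$replicon_id[i]
    len <- replicons$length[i]
    g <- filter(genes, .data$replicon_id == rid)
    gaps <- IRanges::gaps(
      IRanges::reduce(IRanges::IRanges(g$start, g$end)),
      start = 1L, end = len
    )
    tibble(replicon_id = rid,
           start = IRanges::start(gaps), end = IRanges::end(gaps))
  })
}

#' Build an exact-match index of genomic k-mers
#'
#' Indexes every k-mer of the forward and reverse-complement strand of every
#' replicon, recording where each occurs and how many times in total. This is
#' the lookup structure for mapping the short genomic tags adjacent to
#' transposon junctions; because mapping is exact and unique-only, the index
#' stores full multiplicities. k-mers containing N are unmappable and
#' excluded. A palindromic k-mer at one physical location is listed once per
#' strand (multiplicity 2), so it can never map uniquely.
#'
#' @param replicons Replicon tibble from [read_genome()].
#' @param k Tag length in nucleotides (default 17).
#' @return An object of class `tag_index`: list with `k`, `locations`
#'   (tibble `tag`, `replicon_id`, `start` = 1-based forward-strand start of
#'   the k-mer window, `strand`, `multiplicity`).
#' @export
build_tag_index <- function(replicons, k = 17L) {
  k <- as.integer(k)
  if (is.na(k) || k < 1) abort("tag length k must be a positive integer")
  if (any(replicons$length < k)) {
    abort("all replicon lengths must be >= k")
  }
  loc <- purrr::map_dfr(seq_len(nrow(replicons)), function(i) {
    seq <- replicons$sequence[i]
    len <- replicons$length[i]
    starts <- seq_len(len - k + 1L)
    fwd <- substring(seq, starts, starts + k - 1L)
    rev <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(fwd)
    ))
    tibble(
      tag = c(fwd, rev),
      replicon_id = replicons$replicon_id[i],
      start = c(starts, starts),
      strand = rep(c("+", "-"), each = length(starts))
    )
  })
  loc <- filter(loc, !stringi::stri_detect_fixed(.data$tag, "N"))
  mult <- loc %>% count(.data$tag, name = "multiplicity")
  loc <- left_join(loc, mult, by = "tag")
  structure(list(k = k, locations = loc), class = "tag_index")
}

#' @export
print.tag_index <- function(x, ...) {
  cat("tag_index: k =", x$k, "|", nrow(x$locations), "indexed locations |",
      sum(x$locations$multiplicity == 1), "uniquely mappable\n")
  invisible(x)
}
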