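#' Configuration for the transposon-library selection simulator
#'
#' The generative model mirrors a mariner (HIMAR1) Tn-seq competition
#' experiment: a random genome with non-overlapping ORFs, an insertion
#' library drawn from TA dinucleotides (the mariner target site), log-normal
#' initial clone abundances, deterministic exponential selection over a few
#' population doublings (each insertion's abundance multiplied by
#' `w^doublings` for relative fitness `w`), and multinomial sequencing of
#' the selected pools. Two biological replicates are independent multinomial
#' draws from independently jittered abundance vectors.
#'
#' @param seed Integer seed; every simulator output is deterministic given
#'   the configuration and seed.
#' @param genome_length Genome size in bp (default 200000, a single
#'   replicon).
#' @param n_genes Number of ORFs (default 150).
#' @param gene_length_range ORF length range in bp (default 300–3000; drawn
#'   lengths are rescaled toward the minimum when a draw cannot fit in the
#'   genome with the required gaps).
#' @param min_gap Minimum intergenic gap in bp (default 50).
#' @param library_size Number of insertions (default 5000).
#' @param abundance_sigma Log-normal sigma of initial clone abundances
#'   (default 0.5).
#' @param doublings Net population doublings during selection (default 3;
#'   competition experiments of this design conclude two to four doublings).
#' @param read_depth Reads sequenced per sample (default 2e6).
#' @param read_length Read length in nt (default 60).
#' @param tn_error_rate Per-base substitution rate inside the transposon end
#'   sequence (default 0.01).
#' @param tag_error_rate Per-base substitution rate inside the genomic tag
#'   (default 0).
#' @param replicate_jitter_sigma Per-site log-normal sigma applied
#'   independently per biological replicate (default 0.1).
#' @param treatments Character vector of treated-condition labels (default
#'   `"treated"`).
#' @param w_untreated Named numeric vector of per-gene relative fitness in
#'   the untreated culture; genes not named have w = 1.
#' @param w_treated Named list (one element per treatment label) of named
#'   numeric per-gene fitness under treatment; unnamed genes have w = 1.
#' @param prep [read_prep_params()] describing the read structure to emit.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 200000L,
                       n_genes = 150L,
                       gene_length_range = c(300L, 3000L),
                       min_gap = 50L,
                       library_size = 5000L,
                       abundance_sigma = 0.5,
                       doublings = 3,
                       read_depth = 2e6,
                       read_length = 60L,
                       tn_error_rate = 0.01,
                       tag_error_rate = 0,
                       replicate_jitter_sigma = 0.1,
                       treatments = "treated",
                       w_untreated = numeric(),
                       w_treated = list(),
                       prep = read_prep_params()) {
  stopifnot(genome_length > 0, n_genes >= 0, library_size > 0,
            doublings >= 0, doublings <= 10,
            tn_error_rate >= 0, tn_error_rate < 1,
            tag_error_rate >= 0, tag_error_rate < 1,
            length(treatments) >= 1,
            !treatments %in% c("input", "nontreated"))
  if (length(w_treated) == 0) {
    w_treated <- setNames(rep(list(numeric()), length(treatments)),
                          treatments)
  }
  stopifnot(all(treatments %in% names(w_treated)))
  structure(list(
    seed = as.integer(seed), genome_length = as.integer(genome_length),
    n_genes = as.integer(n_genes),
    gene_length_range = as.integer(gene_length_range),
    min_gap = as.integer(min_gap), library_size = as.integer(library_size),
    abundance_sigma = abundance_sigma, doublings = doublings,
    read_depth = read_depth, read_length = as.integer(read_length),
    tn_error_rate = tn_error_rate, tag_error_rate = tag_error_rate,
    replicate_jitter_sigma = replicate_jitter_sigma,
    treatments = treatments, w_untreated = w_untreated,
    w_treated = w_treated, prep = prep
  ), class = "sim_config")
}

#' Generate a synthetic genome with annotated ORFs
#'
#' An i.i.d.-uniform ACGT sequence carrying `n_genes` non-overlapping ORFs
#' separated by gaps of at least `min_gap` bp. The genome is regenerated if
#' fewer than 99% of its k-mers (both strands, tag length from
#' `config$prep`) are unique, so exact tag mapping stays nearly always
#' unambiguous.
#'
#' @param config A [sim_config()].
#' @return List with `replicons` (tibble as from [read_genome()]) and
#'   `genes` (tibble as from [read_annotation()], with core regions).
#' @export
sim_genome <- function(config) {
  set.seed(config$seed)
  k <- config$prep$tag_length
  for (attempt in 1:5) {
    seq <- paste(sample(c("A", "C", "G", "T"), config$genome_length,
                        replace = TRUE), collapse = "")
    replicons <- tibble(replicon_id = "chr1", sequence = seq,
                        length = config$genome_length)
    starts <- seq_len(config$genome_length - k + 1L)
    fwd <- substring(seq, starts, starts + k - 1L)
    # reverse-complement k-mers that already occur forward collide with them;
    # counting the pooled multiset covers both strands
    rev <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(fwd)))
    mult <- table(c(fwd, rev))
    frac_unique <- sum(mult == 1) / (2 * length(starts))
    if (frac_unique >= 0.99) break
    if (attempt == 5) abort("could not generate a genome with >=99% unique tags")
  }
  genes <- place_genes(config)
  list(replicons = replicons, genes = genes)
}

place_genes <- function(config) {
  n <- config$n_genes
  empty <- tibble(gene_id = character(), replicon_id = character(),
                  start = integer(), end = integer(), strand = character(),
                  product = character())
  if (n == 0) return(core_regions(empty))
  lmin <- config$gene_length_range[1]; lmax <- config$gene_length_range[2]
  budget <- config$genome_length - config$min_gap * (n + 1L)
  if (budget < lmin * n) {
    abort(paste0("cannot fit ", n, " genes of >=", lmin,
                 " bp into a ", config$genome_length, " bp genome"))
  }
  raw <- runif(n, lmin, lmax + 1)
  if (sum(raw) > budget) {
    # rescale the draw toward the minimum length so the packing fits while
    # keeping relative length differences
    s <- (budget - lmin * n) / (sum(raw) - lmin * n)
    len <- floor(lmin + (raw - lmin) * s)
  } else {
    len <- floor(raw)
  }
  len <- pmin(pmax(len, lmin), lmax)
  slack <- config$genome_length - sum(len) - config$min_gap * (n + 1L)
  extra <- as.vector(rmultinom(1, slack, rep(1, n + 1L)))
  gaps <- config$min_gap + extra
  start <- cumsum(c(gaps[1] + 1L,
                    if (n > 1) head(len, -1) + gaps[2:n] else NULL))
  genes <- tibble(
    gene_id = sprintf("SG%04d", seq_len(n)),
    replicon_id = "chr1",
    start = as.integer(start),
    end = as.integer(start + len - 1L),
    strand = sample(c("+", "-"), n, replace = TRUE),
    product = "simulated protein"
  )
  stopifnot(all(genes$end <= config$genome_length))
  core_regions(genes)
}

#' Draw a transposon insertion library over TA sites
#'
#' Insertion sites are sampled uniformly without replacement from the
#' genome's TA dinucleotides (restricted to positions where a full genomic
#' tag fits on either strand), with strand chosen uniformly, and initial
#' clone abundances drawn log-normal and normalized to sum 1. The junction
#' coordinate is the genomic base abutting the transposon: the T of the TA
#' for a plus-strand insertion, the A for a minus-strand one.
#'
#' @param genome Output of [sim_genome()].
#' @param config A [sim_config()].
#' @return Tibble: `site_id`, `replicon_id`, `ta_pos`, `position` (junction
#'   coordinate), `strand`, `abundance`, `gene_id` (core the junction falls
#'   in, NA otherwise).
#' @export
sim_library <- function(genome, config) {
  set.seed(config$seed + 1L)
  seq <- genome$replicons$sequence[1]
  len <- genome$replicons$length[1]
  k <- config$prep$tag_length
  ta <- stringi::stri_locate_all_fixed(seq, "TA", overlap = TRUE)[[1]][, 1]
  ta <- ta[!is.na(ta)]
  ta <- ta[ta >= k - 1L & ta <= len - k + 1L]  # full tag fits on both strands
  if (length(ta) < config$library_size) {
    abort(paste0("genome has only ", length(ta), " usable TA sites; ",
                 config$library_size, " requested"))
  }
  pos <- sort(sample(ta, config$library_size))
  strand <- sample(c("+", "-"), config$library_size, replace = TRUE)
  junction <- ifelse(strand == "+", pos, pos + 1L)
  ab <- exp(rnorm(config$library_size, 0, config$abundance_sigma))
  lib <- tibble(
    site_id = sprintf("ins%05d", seq_len(config$library_size)),
    replicon_id = genome$replicons$replicon_id[1],
    ta_pos = as.integer(pos), position = as.integer(junction),
    strand = strand, abundance = ab / sum(ab)
  )
  # core membership determines which gene's fitness the insertion inherits
  g <- genome$genes
  lib$gene_id <- NA_character_
  if (nrow(g) > 0) {
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(lib$position, lib$position),
      IRanges::IRanges(g$core_start, g$core_end),
      select = "first"
    )
    lib$gene_id <- g$gene_id[hits]
  }
  lib
}

fitness_of <- function(lib, w_map) {
  w <- rep(1, nrow(lib))
  named <- !is.na(lib$gene_id) & lib$gene_id %in% names(w_map)
  w[named] <- w_map[lib$gene_id[named]]
  w
}

#' Apply deterministic exponential selection to a library
#'
#' Each insertion's abundance is multiplied by `w^doublings` and the vector
#' renormalized; insertions in gene cores inherit that gene's fitness, edge
#' and intergenic insertions are neutral (w = 1).
#'
#' @param lib Library tibble from [sim_library()] (an `abundance` column is
#'   used as the starting state).
#' @param w_map Named per-gene fitness vector; unnamed genes have w = 1.
#' @param doublings Net population doublings.
#' @return The post-selection abundance vector (sums to 1).
#' @export
sim_selection <- function(lib, w_map, doublings) {
  w <- fitness_of(lib, w_map)
  ab <- lib$abundance * w^doublings
  ab / sum(ab)
}

#' Ground-truth expected competition index per gene
#'
#' Under exponential selection the expected treated/untreated fold change of
#' an insertion is `(w_treated / w_untreated)^doublings`.
#'
#' @param config A [sim_config()].
#' @param genes Gene tibble (ids define the rows).
#' @return Tibble `gene_id`, `treatment`, `expected_ci`.
#' @export
sim_expected_ci <- function(config, genes) {
  purrr::map_dfr(config$treatments, function(tr) {
    wu <- rep(1, nrow(genes)); wt <- rep(1, nrow(genes))
    iu <- genes$gene_id %in% names(config$w_untreated)
    wu[iu] <- config$w_untreated[genes$gene_id[iu]]
    it <- genes$gene_id %in% names(config$w_treated[[tr]])
    wt[it] <- config$w_treated[[tr]][genes$gene_id[it]]
    tibble(gene_id = genes$gene_id, treatment = tr,
           expected_ci = (wt / wu)^config$doublings)
  })
}

sim_sample_plan <- function(config) {
  conds <- c("input", "nontreated", config$treatments)
  tidyr::expand_grid(replicate = 1:2, condition = conds) %>%
    mutate(sample_id = paste0(.data$condition, "_", .data$replicate))
}

#' Simulate sequenced site counts for a full experiment (count level)
#'
#' Draws the complete two-replicate experiment — input, nontreated and every
#' treated condition — as multinomial read counts over the library's
#' junction sites. This is the simulator's error-free sequencing mode: with
#' no transposon or tag errors, read generation, trimming and exact mapping
#' are lossless, so the multinomial site counts are exactly what the read
#' stage would recover; use [sim_fastq()] to exercise that stage explicitly.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_experiment`: `genome`, `library`, `profiles`
#'   (list of `tn_profile`, one per sample), `truth` (expected CI tibble),
#'   `plan` (sample sheet).
#' @export
sim_counts <- function(config) {
  genome <- sim_genome(config)
  lib <- sim_library(genome, config)
  plan <- sim_sample_plan(config)
  set.seed(config$seed + 2L)
  profiles <- vector("list", nrow(plan))
  for (r in 1:2) {
    jit <- exp(rnorm(nrow(lib), 0, config$replicate_jitter_sigma))
    ab0 <- lib$abundance * jit
    lib_r <- mutate(lib, abundance = ab0 / sum(ab0))
    for (i in which(plan$replicate == r)) {
      cond <- plan$condition[i]
      ab <- switch(cond,
        input = lib_r$abundance,
        nontreated = sim_selection(lib_r, config$w_untreated,
                                   config$doublings),
        sim_selection(lib_r, config$w_treated[[cond]], config$doublings)
      )
      counts <- as.vector(rmultinom(1, config$read_depth, ab))
      keep <- counts > 0
      sites <- tibble(replicon_id = lib$replicon_id[keep],
                      position = lib$position[keep],
                      strand = lib$strand[keep],
                      count = counts[keep]) %>%
        arrange(.data$position, .data$strand)
      acc <- tibble(total_reads = config$read_depth, reads_no_tn = 0L,
                    reads_too_short = 0L, reads_used = config$read_depth)
      profiles[[i]] <- new_tn_profile(sites, acc, plan$sample_id[i], cond, r,
                                      aligned = config$read_depth,
                                      ambiguous = 0L, unmapped = 0L)
    }
  }
  structure(list(genome = genome, library = lib, profiles = profiles,
                 truth = sim_expected_ci(config, genome$genes), plan = plan),
            class = "sim_experiment")
}

#' Simulate a full experiment to FASTQ files on disk
#'
#' Writes the genome (FASTA), annotation (PTT), one FASTQ per sample, the
#' sample sheet, and the ground-truth expected CI table. Each read is the
#' transposon end sequence (with per-base substitution errors at
#' `tn_error_rate`), the genomic tag downstream of the junction on the
#' site's strand (errors at `tag_error_rate`), and random filler up to
#' `read_length`, with constant quality `I`.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created).
#' @param samples Optional subset of sample ids to emit (default all).
#' @return List of class `sim_fastq_run`: paths (`fasta`, `ptt`, `truth`,
#'   `samples` tibble with `fastq` column) plus the in-memory `genome`,
#'   `library` and `truth`.
#' @export
sim_fastq <- function(config, dir, samples = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  genome <- sim_genome(config)
  lib <- sim_library(genome, config)
  plan <- sim_sample_plan(config)
  if (!is.null(samples)) plan <- filter(plan, .data$sample_id %in% samples)
  seq <- genome$replicons$sequence[1]
  k <- config$prep$tag_length
  tag <- character(nrow(lib))
  plus <- lib$strand == "+"
  tag[plus] <- substring(seq, lib$position[plus], lib$position[plus] + k - 1L)
  tag[!plus] <- revcomp(substring(seq, lib$position[!plus] - k + 1L,
                                  lib$position[!plus]))
  fasta <- file.path(dir, "genome.fasta")
  ptt <- file.path(dir, "genome.ptt")
  truth_path <- file.path(dir, "truth.tsv")
  write_fasta(genome$replicons, fasta)
  write_ptt(genome$genes, genome$replicons, ptt)
  truth <- sim_expected_ci(config, genome$genes)
  readr::write_tsv(truth, truth_path)

  set.seed(config$seed + 2L)
  tn <- config$prep$tn_sequence
  filler_len <- config$read_length - nchar(tn) - k
  plan$fastq <- NA_character_
  for (r in sort(unique(plan$replicate))) {
    jit <- exp(rnorm(nrow(lib), 0, config$replicate_jitter_sigma))
    ab0 <- lib$abundance * jit
    lib_r <- mutate(lib, abundance = ab0 / sum(ab0))
    for (i in which(plan$replicate == r)) {
      cond <- plan$condition[i]
      ab <- switch(cond,
        input = lib_r$abundance,
        nontreated = sim_selection(lib_r, config$w_untreated,
                                   config$doublings),
        sim_selection(lib_r, config$w_treated[[cond]], config$doublings)
      )
      counts <- as.vector(rmultinom(1, config$read_depth, ab))
      site_idx <- sample(rep.int(seq_along(counts), counts))
      n <- length(site_idx)
      tn_part <- if (config$tn_error_rate > 0) {
        cpp_mutate_bases(rep(tn, n), config$tn_error_rate)
      } else rep(tn, n)
      tag_part <- tag[site_idx]
      if (config$tag_error_rate > 0) {
        tag_part <- cpp_mutate_bases(tag_part, config$tag_error_rate)
      }
      reads <- if (filler_len > 0) {
        paste0(tn_part, tag_part,
               stringi::stri_rand_strings(n, filler_len, "[ACGT]"))
      } else paste0(tn_part, tag_part)
      path <- file.path(dir, paste0(plan$sample_id[i], ".fastq"))
      qual <- strrep("I", nchar(reads[1]))
      out <- character(4L * n)
      out[seq(1, 4 * n, 4)] <- paste0("@", plan$sample_id[i], ":", seq_len(n))
      out[seq(2, 4 * n, 4)] <- reads
      out[seq(3, 4 * n, 4)] <- "+"
      out[seq(4, 4 * n, 4)] <- qual
      writeLines(out, path)
      plan$fastq[i] <- path
    }
  }
  structure(list(fasta = fasta, ptt = ptt, truth_path = truth_path,
                 samples = plan, genome = genome, library = lib,
                 truth = truth),
            class = "sim_fastq_run")
}

write_fasta <- function(replicons, path) {
  recs <- Biostrings::DNAStringSet(setNames(replicons$sequence,
                                            replicons$replicon_id))
  Biostrings::writeXStringSet(recs, path, width = 80)
  invisible(path)
}

write_ptt <- function(genes, replicons, path) {
  lines <- c(
    paste0(replicons$replicon_id[1], " - 1..", replicons$length[1]),
    paste0(nrow(genes), " proteins"),
    paste("Location", "Strand", "Length", "PID", "Gene", "Synonym", "Code",
          "COG", "Product", sep = "\t")
  )
  if (nrow(genes) > 0) {
    aalen <- floor((genes$end - genes$start + 1) / 3) - 1
    lines <- c(lines, paste(
      paste0(genes$start, "..", genes$end), genes$strand, aalen,
      "-", "-", genes$gene_id, "-", "-",
      if_else(is.na(genes$product), "-", genes$product),
      sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
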