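small_cfg <- function(seed = 5, genome_length = 30000L, n_genes = 20L,
                      library_size = 400L, read_depth = 40000, ...) {
  sim_config(seed = seed, genome_length = genome_length, n_genes = n_genes,
             gene_length_range = c(300L, 1200L), library_size = library_size,
             read_depth = read_depth, ...)
}

test_that("genome generation is deterministic and respects the gene layout", {
  cfg <- small_cfg()
  g1 <- sim_genome(cfg)
  g2 <- sim_genome(cfg)
  expect_identical(g1$replicons$sequence, g2$replicons$sequence)
  expect_identical(g1$genes, g2$genes)
  genes <- g1$genes
  expect_equal(nrow(genes), 20L)
  # pairwise disjoint with >= 50 bp gaps, inside the replicon
  expect_true(all(genes$start[-1] - genes$end[-nrow(genes)] - 1L >= 50L))
  expect_true(all(genes$start >= 1 & genes$end <= 30000))
  expect_true(all(genes$end - genes$start + 1 >= 300))
  # n_genes = 0 gives an all-intergenic genome
  g0 <- sim_genome(small_cfg(n_genes = 0L))
  expect_equal(nrow(g0$genes), 0L)
  mask <- intergenic_mask(g0$replicons, g0$genes)
  expect_equal(mask$start, 1L)
  expect_equal(mask$end, 30000L)
})

test_that("default-scale genome packs 150 genes into 200 kb", {
  genes <- sim_genome(sim_config(seed = 2))$genes
  expect_equal(nrow(genes), 150L)
  expect_true(all(genes$start[-1] - genes$end[-150] - 1L >= 50L))
})

test_that("infeasible gene packing is a config error", {
  expect_error(sim_genome(sim_config(seed = 1, genome_length = 5000L,
                                     n_genes = 20L)),
               "cannot fit")
})

test_that("every library site sits on a TA with its junction convention", {
  cfg <- small_cfg()
  genome <- sim_genome(cfg)
  lib <- sim_library(genome, cfg)
  expect_equal(nrow(lib), 400L)
  seq <- genome$replicons$sequence
  expect_true(all(substring(seq, lib$ta_pos, lib$ta_pos + 1L) == "TA"))
  expect_equal(lib$position, ifelse(lib$strand == "+", lib$ta_pos,
                                    lib$ta_pos + 1L))
  expect_equal(sum(lib$abundance), 1)
  expect_false(any(duplicated(lib$ta_pos)))
  # different seeds give different site sets
  lib2 <- sim_library(genome, small_cfg(seed = 6))
  expect_false(identical(lib$ta_pos, lib2$ta_pos))
  # a single-insertion library carries all the abundance
  lib1 <- sim_library(genome, small_cfg(library_size = 1L))
  expect_equal(lib1$abundance, 1)
})

test_that("selection follows w^doublings and neutral insertions are untouched", {
  cfg <- small_cfg()
  genome <- sim_genome(cfg)
  lib <- sim_library(genome, cfg)
  # all-neutral: abundances unchanged
  expect_equal(sim_selection(lib, c(), 3), lib$abundance)
  # one gene at w = 0.63, D = 3: its insertions drop to ~0.25x relative to
  # the rest (up to renormalization)
  target <- lib$gene_id[!is.na(lib$gene_id)][1]
  post <- sim_selection(lib, setNames(0.63, target), 3)
  in_t <- !is.na(lib$gene_id) & lib$gene_id == target
  ratio <- (post[in_t] / lib$abundance[in_t])[1] /
    (post[!in_t] / lib$abundance[!in_t])[1]
  expect_equal(ratio, 0.63^3, tolerance = 1e-12)
  # w = 0 wipes the insertions out
  post0 <- sim_selection(lib, setNames(0, target), 3)
  expect_true(all(post0[in_t] == 0))
})

test_that("expected CI is the closed form (w_t/w_u)^D", {
  genes <- make_genes(c(1, 101, 201), c(90, 190, 290),
                      gene_id = c("a", "b", "c"))
  cfg <- sim_config(doublings = 2,
                    w_untreated = c(b = 1),
                    w_treated = list(treated = c(a = 0.5, b = 2)))
  ci <- sim_expected_ci(cfg, genes)
  expect_equal(ci$expected_ci[ci$gene_id == "a"], 0.25)
  expect_equal(ci$expected_ci[ci$gene_id == "b"], 4)
  expect_equal(ci$expected_ci[ci$gene_id == "c"], 1)
  cfg1 <- sim_config(doublings = 1, w_treated = list(treated = c(a = 0.5)))
  expect_equal(
    sim_expected_ci(cfg1, genes)$expected_ci[1], 0.5)
})

test_that("count-level sampling stays inside multinomial envelopes", {
  cfg <- small_cfg(read_depth = 1e5)
  ex <- sim_counts(cfg)
  expect_length(ex$profiles, 6L)
  p <- ex$profiles[[1]]
  expect_equal(sum(p$sites$count), 1e5)
  # per-site counts should sit within 99.9% normal envelopes of the
  # jittered expectations in almost all cases; allow a small overflow
  lib <- ex$library
  m <- dplyr::left_join(lib, p$sites,
                        by = c("replicon_id", "position", "strand"))
  cnt <- ifelse(is.na(m$count), 0, m$count)
  # jitter sigma 0.1 widens the envelope; use 5 sd of the pure multinomial
  # plus the jitter scale as a crude but conservative band
  expected <- 1e5 * lib$abundance
  sd <- sqrt(expected) + 0.35 * expected
  expect_gt(mean(abs(cnt - expected) <= 5 * sd + 5), 0.995)
})

test_that("simulate then analyze recovers ground-truth CIs end to end", {
  cfg <- small_cfg(read_depth = 2e5, seed = 9,
                   w_treated = list(treated = c(SG0003 = 0.63,
                                                SG0007 = 2)))
  ex <- sim_counts(cfg)
  an <- analyze_profiles(ex$profiles, ex$genome$replicons, ex$genome$genes)
  td <- tidy(an$fit)
  expect_equal(td$classification[td$gene_id == "SG0003"],
               "REDUCED_COMPETITIVENESS")
  expect_equal(td$classification[td$gene_id == "SG0007"],
               "INCREASED_COMPETITIVENESS")
  joined <- dplyr::inner_join(ex$truth, td, by = c("gene_id", "treatment"))
  est <- (joined$ci_rep1 + joined$ci_rep2) / 2
  ok <- joined$analyzable
  expect_true(all(abs(log2(est[ok]) - log2(joined$expected_ci[ok])) < 1))
})

test_that("FASTQ output is deterministic and round-trips through the pipeline", {
  cfg <- sim_config(seed = 15, genome_length = 20000L, n_genes = 10L,
                    gene_length_range = c(300L, 900L), library_size = 150L,
                    read_depth = 8000, tn_error_rate = 0,
                    tag_error_rate = 0)
  d1 <- file.path(tempdir(), "fq1"); d2 <- file.path(tempdir(), "fq2")
  r1 <- sim_fastq(cfg, d1, samples = "input_1")
  r2 <- sim_fastq(cfg, d2, samples = "input_1")
  expect_identical(readLines(r1$samples$fastq[1]),
                   readLines(r2$samples$fastq[1]))
  expect_identical(readLines(r1$fasta), readLines(r2$fasta))

  # with zero error rates every read passes prep and maps uniquely back to
  # its true junction (no ambiguous tags expected at 99%+ unique k-mers)
  ts <- process_fastq(r1$samples$fastq[1], cfg$prep)
  expect_equal(ts$accounting$reads_no_tn, 0)
  expect_equal(ts$accounting$reads_used, 8000)
  ref <- tn_reference(r1$fasta,
                      list(list(path = r1$ptt, format = "ptt",
                                replicon_id = "chr1")))
  prof <- tally_sites(ts, ref$index, "input_1", "input", 1L)
  expect_equal(prof$unmapped_reads, 0)
  # recovered site keys match the library exactly (restricted to sites
  # that received reads; ambiguous-tag sites would be silently dropped)
  lib_sites <- dplyr::select(r1$library, replicon_id, position, strand)
  rec <- dplyr::anti_join(prof$sites, lib_sites,
                          by = c("replicon_id", "position", "strand"))
  expect_equal(nrow(rec), 0L)
  expect_equal(sum(prof$sites$count) + prof$ambiguous_reads, 8000)
})

test_that("transposon errors land reads in the right accounting buckets", {
  cfg <- sim_config(seed = 16, genome_length = 20000L, n_genes = 10L,
                    gene_length_range = c(300L, 900L), library_size = 150L,
                    read_depth = 5000, tn_error_rate = 0.05)
  run <- sim_fastq(cfg, file.path(tempdir(), "fq_err"), samples = "input_1")
  ts <- process_fastq(run$samples$fastq[1], cfg$prep)
  acc <- ts$accounting
  expect_equal(acc$total_reads,
               acc$reads_no_tn + acc$reads_too_short + acc$reads_used)
  # at 5% per-base error some reads must exceed three mismatches
  expect_gt(acc$reads_no_tn, 0)
})
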