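# build a long gene-count tibble from a wide spec:
# list(gene_id = c(input1, input2, nt1, nt2, tr1, tr2))
make_counts <- function(spec, treatment = "NCR247") {
  purrr::imap_dfr(spec, function(v, g) {
    tibble::tibble(
      gene_id = g,
      condition = rep(c("input", "nontreated", treatment), each = 2),
      replicate = rep(1:2, 3),
      norm_count = v,
      raw_count = v,
      sample_id = paste0(condition, "_", replicate)
    )
  })
}

test_that("underrepresentation flags genes below threshold in either replicate", {
  fit <- competitiveness(make_counts(list(
    ok = c(250, 103, 200, 200, 100, 100),
    low2 = c(250, 99.4, 200, 200, 100, 100),
    zero = c(0, 0, 0, 0, 0, 0)
  )))
  td <- tidy(fit)
  expect_equal(td$underrepresented[td$gene_id == "ok"], FALSE)
  expect_equal(td$underrepresented[td$gene_id == "low2"], TRUE)
  expect_equal(td$underrepresented[td$gene_id == "zero"], TRUE)
  expect_equal(td$classification[td$gene_id == "low2"], "NOT_ANALYZED")
  # boundary: exactly 100 passes under the default strict-less-than rule
  fit2 <- competitiveness(make_counts(list(b = c(100, 100, 100, 100, 1, 1))))
  expect_false(tidy(fit2)$underrepresented)
  fit3 <- competitiveness(make_counts(list(b = c(100, 100, 100, 100, 1, 1))),
                          under_cmp = "le")
  expect_true(tidy(fit3)$underrepresented)
})

test_that("growth impairment uses the nontreated/input ratio with either/both modes", {
  spec <- list(
    fine = c(1000, 1000, 900, 1100, 500, 500),     # ratios 0.9, 1.1
    one_bad = c(1000, 1000, 400, 900, 500, 500),   # ratios 0.4, 0.9
    both_bad = c(1000, 1000, 490, 490, 500, 500)   # ratios 0.49, 0.49
  )
  either <- tidy(competitiveness(make_counts(spec), growth_mode = "either"))
  expect_equal(either$growth_impaired[match(c("fine", "one_bad", "both_bad"),
                                            either$gene_id)],
               c(FALSE, TRUE, TRUE))
  both <- tidy(competitiveness(make_counts(spec), growth_mode = "both"))
  expect_equal(both$growth_impaired[match(c("fine", "one_bad", "both_bad"),
                                          both$gene_id)],
               c(FALSE, FALSE, TRUE))
  expect_equal(either$classification[either$gene_id == "one_bad"],
               "NOT_ANALYZED")
})

test_that("competition index is treated over untreated with undefined at zero", {
  expect_equal(compute_ci(500, 1000), 0.5)
  expect_equal(compute_ci(750, 750), 1.0)
  expect_true(is.na(compute_ci(10, 0)))
  expect_equal(compute_ci(10, 0, pseudocount = 1), 11)
  expect_error(compute_ci(-1, 10))
})

test_that("classification needs twofold concordance in both replicates", {
  expect_equal(classify_ci(0.3, 0.45), "REDUCED_COMPETITIVENESS")
  expect_equal(classify_ci(0.3, 1.2), "NO_CHANGE")
  expect_equal(classify_ci(2.0, 3.5), "INCREASED_COMPETITIVENESS")
  expect_equal(classify_ci(0.5, 0.5), "REDUCED_COMPETITIVENESS")  # inclusive
  expect_equal(classify_ci(NA, 0.3), "NOT_ANALYZED")
  # symmetric under replicate exchange
  set.seed(4)
  a <- runif(50, 0, 4); b <- runif(50, 0, 4)
  expect_equal(classify_ci(a, b), classify_ci(b, a))
})

test_that("genes with zero nontreated counts are excluded, not imputed", {
  fit <- competitiveness(make_counts(list(
    z = c(1000, 1000, 0, 900, 500, 500)
  )))
  td <- tidy(fit)
  # ratio 0 < 0.5 makes it growth-impaired under 'either'; with mode 'both'
  # the CI itself is undefined and the gene still drops out
  expect_equal(td$classification, "NOT_ANALYZED")
  fit2 <- competitiveness(make_counts(list(
    z = c(1000, 1000, 0, 900, 500, 500)
  )), growth_mode = "both")
  expect_equal(tidy(fit2)$classification, "NOT_ANALYZED")
})

test_that("decreasing a treated count never flips REDUCED toward INCREASED", {
  base <- c(1000, 1000, 900, 1100, 450, 500)
  fit <- competitiveness(make_counts(list(g = base)))
  expect_equal(tidy(fit)$classification, "REDUCED_COMPETITIVENESS")
  for (scale in c(0.8, 0.5, 0.1, 0)) {
    v <- base; v[5:6] <- v[5:6] * scale
    cls <- tidy(competitiveness(make_counts(list(g = v))))$classification
    expect_true(cls %in% c("REDUCED_COMPETITIVENESS", "NOT_ANALYZED"))
  }
})

test_that("multiple treatments are scored independently", {
  counts <- dplyr::bind_rows(
    make_counts(list(g = c(1000, 1000, 1000, 1000, 200, 220)), "NCR247"),
    dplyr::filter(make_counts(list(g = c(1000, 1000, 1000, 1000, 4000, 4100)),
                              "PMB"), condition == "PMB")
  )
  fit <- competitiveness(counts)
  td <- tidy(fit)
  expect_setequal(fit$treatments, c("NCR247", "PMB"))
  expect_equal(td$classification[td$treatment == "NCR247"],
               "REDUCED_COMPETITIVENESS")
  expect_equal(td$classification[td$treatment == "PMB"],
               "INCREASED_COMPETITIVENESS")
  g <- glance(fit)
  expect_equal(nrow(g), 2L)
  expect_equal(g$n_reduced[g$treatment == "NCR247"], 1L)
})

test_that("report files are deterministic and partition genes correctly", {
  fit <- competitiveness(make_counts(list(
    hitA = c(1000, 1000, 1000, 1000, 300, 400),
    hitB = c(1000, 1000, 1000, 1000, 100, 200),
    flat = c(1000, 1000, 1000, 1000, 950, 1050),
    excl = c(10, 10, 10, 10, 10, 10)
  )))
  d1 <- file.path(tempdir(), "rep1"); d2 <- file.path(tempdir(), "rep2")
  write_ci_reports(fit, d1)
  write_ci_reports(fit, d2)
  hits <- readr::read_tsv(file.path(d1, "NCR247_hits.tsv"),
                          show_col_types = FALSE)
  expect_equal(hits$gene_id, c("hitA", "hitB"))
  excl <- readr::read_tsv(file.path(d1, "NCR247_excluded_genes.tsv"),
                          show_col_types = FALSE)
  expect_equal(excl$gene_id, "excl")
  expect_equal(excl$reason, "underrepresented_in_input")
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("missing replicates or conditions raise analysis errors", {
  counts <- make_counts(list(g = c(1000, 1000, 900, 1100, 500, 500)))
  expect_error(competitiveness(dplyr::filter(counts, replicate == 1)),
               "replicates")
  expect_error(competitiveness(dplyr::filter(counts, condition != "input")),
               "input")
  expect_error(
    competitiveness(dplyr::filter(counts,
                                  condition %in% c("input", "nontreated"))),
    "treated")
})
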