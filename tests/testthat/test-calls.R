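# Call-table I/O, QC filtering, allele collapsing, duplicate
# resolution, arm exclusions and per-sample summaries.

make_call_table <- function(tl = c(4000, 6000), arm = "7q",
                            sample = "s1") {
  data.frame(sample_id = sample, arm = arm,
             allele = seq_along(tl), tl_p75_bp = tl, tvr_len_bp = 100,
             n_supporting_reads = 5, mapping_ambiguous = FALSE,
             stringsAsFactors = FALSE)
}

test_that("call tables round-trip through TSV", {
  calls <- rbind(make_call_table(c(3100, 5200), "1p"),
                 make_call_table(4400, "2q"))
  calls$extra_column <- c("a", "b", "c")
  path <- tempfile(fileext = ".tsv")
  write_calls(calls, path)
  back <- read_calls(path)
  expect_equal(back[names(calls)], calls)

  # empty file with header
  empty <- calls[0, ]
  write_calls(empty, path)
  expect_equal(nrow(read_calls(path)), 0L)
})

test_that("missing mandatory columns and malformed rows are reported", {
  calls <- make_call_table()
  path <- tempfile(fileext = ".tsv")
  write_calls(calls[, setdiff(names(calls), "tvr_len_bp")], path)
  expect_error(read_calls(path), "tvr_len_bp")

  bad <- rbind(make_call_table(c(3000, 4000), "1p"), make_call_table(5000))
  bad$n_supporting_reads[2] <- -3
  write_calls(bad, path)
  expect_warning(rows <- read_calls(path), "line\\(s\\): 3")
  expect_equal(nrow(rows), 2L)
})

test_that("QC retains exactly the stated calls and is idempotent", {
  calls <- make_call_table(c(99, 100, 101), "5p")
  kept <- qc_filter(calls)
  expect_equal(kept$tl_p75_bp, c(100, 101))

  calls$tvr_len_bp <- c(-1, 0, 50)
  kept <- qc_filter(calls)
  expect_equal(kept$tl_p75_bp, c(100, 101))  # -1 TVR dropped anyway

  calls$mapping_ambiguous <- c(FALSE, TRUE, FALSE)
  kept <- qc_filter(calls)
  expect_equal(kept$tl_p75_bp, 101)

  expect_identical(qc_filter(kept), kept)
})

test_that("allele estimates collapse to the arm mean", {
  expect_equal(collapse_to_arm(make_call_table(c(4000, 6000)))$cstl, 5000)
  one <- collapse_to_arm(make_call_table(3200))
  expect_equal(one$cstl, 3200)
  expect_equal(one$n_allele_estimates, 1L)
  three <- collapse_to_arm(make_call_table(c(3000, 4000, 5000)))
  expect_equal(three$cstl, 4000)
})

test_that("read-level reduction uses the type-7 75th percentile", {
  reads <- data.frame(sample_id = "s1", arm = "7q", allele = 1L,
                      read_tl_bp = c(1000, 2000, 3000, 4000),
                      read_len_bp = 9000)
  calls <- reads_to_calls(reads, min_reads = 4)
  expect_equal(calls$tl_p75_bp, 3250)
  expect_equal(calls$tl_p75_bp, quantile75_oracle(reads$read_tl_bp))
  # randomized cases against the oracle
  set.seed(42)
  for (n in c(3, 5, 8, 17)) {
    x <- stats::rnorm(n, 4000, 600)
    r <- data.frame(sample_id = "s", arm = "1q", allele = 1L,
                    read_tl_bp = x, read_len_bp = 9000)
    expect_equal(reads_to_calls(r, 1)$tl_p75_bp, quantile75_oracle(x))
  }
  # below-threshold clusters emit nothing (not an error)
  expect_equal(nrow(reads_to_calls(reads, min_reads = 5)), 0L)
})

test_that("QC-then-collapse equals collapse of pre-filtered calls", {
  set.seed(8)
  calls <- do.call(rbind, lapply(1:20, function(i) {
    make_call_table(stats::runif(2, 0, 6000), sample = sprintf("s%d", i),
                    arm = sample(arm_labels(), 1))
  }))
  calls$tvr_len_bp <- sample(c(-5, 0, 100), nrow(calls), replace = TRUE)
  a <- collapse_to_arm(qc_filter(calls))
  b <- collapse_to_arm(qc_filter(qc_filter(calls)))
  expect_identical(a, b)
})

test_that("duplicate-platform individuals resolve deterministically", {
  meta <- data.frame(sample_id = c("r1", "r2"),
                     individual_id = "p1",
                     platform = c("SequelIIe", "ONT"),
                     stringsAsFactors = FALSE)
  calls <- rbind(
    do.call(rbind, lapply(paste0(1:20, "p"), make_call_table,
                          tl = 4000, sample = "r1")),
    do.call(rbind, lapply(paste0(1:22, "q"), make_call_table,
                          tl = 4000, sample = "r2")))
  kept <- resolve_duplicate_samples(calls, meta)
  expect_setequal(unique(kept$sample_id), "r1")  # PacBio over ONT

  # both PacBio: more arms wins
  meta$platform <- c("Revio", "SequelIIe")
  kept <- resolve_duplicate_samples(calls, meta)
  expect_setequal(unique(kept$sample_id), "r2")

  # no duplicates: identity
  meta1 <- data.frame(sample_id = "r1", individual_id = "p1",
                      platform = "Revio")
  expect_identical(resolve_duplicate_samples(calls[calls$sample_id ==
                                                     "r1", ], meta1),
                   calls[calls$sample_id == "r1", ])

  # >2 runs: unmodeled
  meta3 <- data.frame(sample_id = c("r1", "r2", "r3"),
                      individual_id = "p1", platform = "Revio")
  expect_error(resolve_duplicate_samples(calls, meta3), "3 runs")
})

test_that("arm exclusions leave the documented label sets", {
  full <- data.frame(sample_id = "s1", arm = arm_labels(),
                     cstl = 4000, stringsAsFactors = FALSE)
  ana <- exclude_arms(full, "analysis")
  expect_equal(nrow(ana), 39L)
  expect_setequal(ana$arm, analysis_arms())
  acro <- exclude_arms(full, "acrocentric_p")
  expect_equal(nrow(acro), 43L)
  expect_error(exclude_arms(full, "everything"), "arg")

  # a sample left with nothing is dropped and counted
  lonely <- data.frame(sample_id = c("s1", "s2"), arm = c("1p", "14p"),
                       cstl = 4000)
  expect_message(out <- exclude_arms(lonely, "analysis"), "dropped")
  expect_equal(attr(out, "n_samples_dropped"), 1L)
  expect_setequal(out$sample_id, "s1")
})

test_that("sample summaries aggregate coverage, mean and minimum", {
  tab <- data.frame(sample_id = c("s1", "s1", "s1", "s2"),
                    arm = c("1p", "2q", "3p", "1p"),
                    cstl = c(2000, 4000, 6000, 3500),
                    n_supporting_reads = c(4, 6, 5, 8))
  s <- sample_summaries(tab)
  expect_equal(s$mean_tl, c(4000, 3500))
  expect_equal(s$shortest_tl, c(2000, 3500))
  expect_equal(s$telomeric_coverage, c(15, 8))
  expect_equal(s$n_arms_with_estimate, c(3L, 1L))
  expect_true(all(s$shortest_tl <= s$mean_tl))
})

test_that("telomeric coverage tracks arm completeness on a cohort", {
  cfg <- tiny_config(n = 200, seed = 31,
                     coverage_model = c(high = 6, mid = 3))
  coh <- make_cohort(cfg)
  reads <- emit_reads(coh)
  tab <- exclude_arms(collapse_to_arm(reads, min_reads = 3), "analysis")
  s <- sample_summaries(tab)
  rho <- stats::cor(s$telomeric_coverage, s$n_arms_with_estimate,
                    method = "spearman")
  expect_gt(rho, 0)
})

test_that("arm call rates are proportions, order-invariant", {
  tab <- data.frame(sample_id = c("s1", "s2", "s1"),
                    arm = c("17q", "17q", "1p"), cstl = 4000)
  cr <- arm_call_rate(tab)
  expect_equal(cr$call_rate[cr$arm == "17q"], 1.0)
  expect_equal(cr$call_rate[cr$arm == "Yp"], 0.0)
  expect_true(all(cr$call_rate >= 0 & cr$call_rate <= 1))
  cr2 <- arm_call_rate(tab[c(3, 1, 2), ])
  expect_equal(cr, cr2)
})
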