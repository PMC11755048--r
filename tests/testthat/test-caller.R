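make_counts <- function(...) {
  # counts from named chromosome vectors, one row per sample
  rows <- list(...)
  dplyr::bind_cols(
    tibble::tibble(sample_id = paste0("s", seq_along(rows))),
    dplyr::bind_rows(rows)
  )
}

test_that("chromosome ratios are plain count shares that sum to one", {
  cnt <- make_counts(c(A = 30, B = 70))
  expect_equal(chromosome_ratio(cnt, "A"), 0.30)
  expect_equal(chromosome_ratio(cnt, "B"), 0.70)
  expect_error(chromosome_ratio(cnt, "C"), "unknown chromosome")

  single <- make_counts(c(A = 55))
  expect_equal(chromosome_ratio(single, "A"), 1)

  r <- chromosome_ratios(toy_counts())
  sums <- tapply(r$ratio, r$sample_id, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_error(chromosome_ratios(make_counts(c(A = 0, B = 0))), "zero total")
})

test_that("reference panel statistics match hand arithmetic (n-1 SD)", {
  # two profiles with chr21 ratios 0.014 and 0.016 over a 1000-read toy genome
  cnt <- make_counts(c(chr21 = 14, rest = 986), c(chr21 = 16, rest = 984))
  panel <- build_reference(cnt)
  p21 <- panel[panel$chrom == "chr21", ]
  expect_equal(p21$mu, 0.015)
  expect_equal(p21$sigma, sd(c(0.014, 0.016)))
  expect_equal(p21$sigma, 0.0014142, tolerance = 1e-4)
  expect_equal(p21$n_reference, 2L)
})

test_that("identical profiles produce a degenerate-panel error", {
  cnt <- make_counts(c(chr21 = 14, rest = 986), c(chr21 = 14, rest = 986))
  expect_error(build_reference(cnt), "degenerate panel")
  expect_error(build_reference(toy_counts()[1, ]), ">= 2 profiles")
})

test_that("z scores match an independent one-line oracle to 12 digits", {
  sp <- test_seq()
  ref <- generate_reference_cohort(30, sp, seed = 51)
  panel <- build_reference(ref$counts)
  test <- simulate_read_counts(generate_cohort(cohort_params(5, seed = 52)),
                               sp, seed = 53)
  z <- z_scores(test, panel)
  for (i in sample(nrow(z), 20)) {
    row <- z[i, ]
    # oracle: direct recomputation from raw counts and panel columns
    raw <- test[test$sample_id == row$sample_id, ]
    ratio <- raw[[row$chrom]] / sum(as.numeric(raw[, -1]))
    mu <- panel$mu[panel$chrom == row$chrom]
    sigma <- panel$sigma[panel$chrom == row$chrom]
    expect_equal(row$z, (ratio - mu) / sigma, tolerance = 1e-12)
  }
  # exact standardisation identities
  expect_equal(z_scores(make_counts(c(chr21 = 15, rest = 985)),
                        build_reference(make_counts(c(chr21 = 14, rest = 986),
                                                    c(chr21 = 16, rest = 984))))$z[1],
               0)
})

test_that("a ratio exactly 3 panel SDs above the mean scores z = 3", {
  panel <- build_reference(make_counts(c(chr21 = 14, rest = 986),
                                       c(chr21 = 16, rest = 984)))
  p21 <- panel[panel$chrom == "chr21", ]
  target_ratio <- p21$mu + 3 * p21$sigma
  n_total <- 1e6
  cnt <- make_counts(c(chr21 = round(target_ratio * n_total),
                       rest = n_total - round(target_ratio * n_total)))
  z <- z_scores(cnt, panel)
  expect_equal(z$z[z$chrom == "chr21"], 3, tolerance = 1e-4)
})

test_that("classification applies the z >= 3 rule with QC gates", {
  sp <- test_seq()
  ref <- generate_reference_cohort(60, sp, seed = 61)
  panel <- build_reference(ref$counts)
  cnt <- simulate_read_counts(t21_samples(c(0.15, 0.15, 0.15)), sp, seed = 62)

  # pass: high FF, full budget; chr21 flagged at this strong signal
  calls <- classify_samples(cnt, panel, ff = 0.15, min_reads = sp$total_unique_reads)
  c21 <- calls[calls$chrom == "chr21", ]
  expect_true(all(c21$qc_status == "pass"))
  expect_true(all(c21$call == "high_risk"))

  # low-FF alert is strict: 3.4% alerts, exactly 3.5% does not
  alert <- classify_samples(cnt, panel, ff = 0.034,
                            min_reads = sp$total_unique_reads)
  expect_true(all(alert$qc_status == "low_ff_alert"))
  expect_true(all(alert$call == "no_call"))
  pass <- classify_samples(cnt, panel, ff = 0.035,
                           min_reads = sp$total_unique_reads)
  expect_true(all(pass$qc_status == "pass"))

  # insufficient reads precedes the FF gate
  short <- classify_samples(cnt, panel, ff = 0.01,
                            min_reads = sp$total_unique_reads + 1)
  expect_true(all(short$qc_status == "insufficient_reads"))

  # unknown FF is not gated on FF
  unk <- classify_samples(cnt, panel, ff = NA_real_,
                          min_reads = sp$total_unique_reads)
  expect_true(all(unk$qc_status == "pass"))
})

test_that("the z threshold boundary is inclusive", {
  # mu/sigma/ratios picked to be exact in binary so z = 3 is hit exactly
  panel <- tibble::tibble(chrom = c("chr21", "rest"),
                          mu = c(0.25, 0.75), sigma = c(0.125, 0.125),
                          n_reference = 412L)
  n_total <- 2e6
  mk <- function(z) {
    r <- 0.25 + z * 0.125
    make_counts(c(chr21 = r * n_total, rest = (1 - r) * n_total))
  }
  at3 <- classify_samples(mk(3), panel, ff = 0.06, chromosomes = "chr21",
                          min_reads = 1e6)
  expect_equal(at3$call, "high_risk")
  below <- classify_samples(mk(2.99), panel, ff = 0.06, chromosomes = "chr21",
                            min_reads = 1e6)
  expect_equal(below$call, "low_risk")
})

test_that("false-positive rate on held-out euploids is at most 1%", {
  sp <- seq_params()
  panel <- build_reference(generate_reference_cohort(412, sp, seed = 71)$counts)
  held <- generate_cohort(cohort_params(1000, seed = 72))
  cnt <- simulate_read_counts(held, sp, seed = 73)
  calls <- classify_samples(cnt, panel, ff = held$ff)
  fpr <- mean(calls$call[calls$chrom == "chr21"] == "high_risk")
  expect_lte(fpr, 0.01)
})

test_that("the published T21 z values yield 16 high-risk and 1 low-risk call", {
  t21 <- load_table2()
  call <- ifelse(t21$z >= 3, "high_risk", "low_risk")
  expect_equal(sum(call == "high_risk"), 16)
  expect_equal(sum(call == "low_risk"), 1)
  expect_equal(t21$status[call == "low_risk"], "false_negative")
})
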