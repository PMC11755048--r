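test_that("FF summaries are integer-exact on the counts", {
  rec <- tibble::tibble(ff = c(0.03, 0.11, 0.12))
  s <- summarize_ff(rec, threshold = 0.05)
  expect_equal(s$median_ff, 0.11)
  expect_equal(s$n_below, 1)
  expect_equal(s$pct_below, 100 * 1 / 3)

  all_high <- summarize_ff(tibble::tibble(ff = c(0.1, 0.2)), 0.05)
  expect_equal(all_high$pct_below, 0)
  expect_error(summarize_ff(tibble::tibble(ff = numeric(0))), "empty")

  # percentage formula on arbitrary counts
  rec2 <- tibble::tibble(ff = c(rep(0.03, 214), rep(0.10, 4827 - 214)))
  s2 <- summarize_ff(rec2)
  expect_equal(s2$pct_below, 100 * 214 / 4827)
  expect_equal(round(s2$pct_below, 2), 4.43)
})

test_that("low-FF group comparison runs Welch t tests per variable", {
  co <- generate_cohort(cohort_params(4827, seed = 141))
  cmp <- compare_low_ff_group(co)
  expect_setequal(cmp$variable,
                  c("gestational_age", "maternal_age", "maternal_weight"))
  w <- cmp[cmp$variable == "maternal_weight", ]
  # the generating law makes low-FF pregnancies heavier, decisively so
  expect_gt(w$mean_low_ff, w$mean_near_median)
  expect_lt(w$p_value, 1e-4)
  # maternal age does not enter the FF law
  expect_gt(cmp$p_value[cmp$variable == "maternal_age"], 1e-4)

  # identical groups: t = 0, p = 1 (both groups = whole toy cohort)
  toy <- tibble::tibble(ff = rep(c(0.04, 0.05), 5),
                        gestational_age_weeks = rep(c(15, 17), 5),
                        maternal_age_years = rep(c(28, 32), 5),
                        maternal_weight_kg = rep(c(50, 60), 5))
  cmp0 <- compare_low_ff_group(toy, threshold = 0.2, median_window = 1)
  expect_true(all(cmp0$t_statistic == 0))
  expect_true(all(cmp0$p_value == 1))
  expect_error(compare_low_ff_group(toy, threshold = 0.001), ">= 2 members")
})

test_that("matching the t test against the textbook formula", {
  set.seed(151)
  for (i in 1:5) {
    # low-FF group x must be the minority so the cohort median sits at 0.10
    x <- rnorm(10 + i); y <- rnorm(25 + i, 0.5)
    rec <- tibble::tibble(
      ff = c(rep(0.01, length(x)), rep(0.10, length(y))),
      gestational_age_weeks = c(x, y),
      maternal_age_years = rnorm(length(x) + length(y)),
      maternal_weight_kg = rnorm(length(x) + length(y), 56)
    )
    cmp <- compare_low_ff_group(rec, threshold = 0.05, median_window = 0.001)
    # Welch statistic recomputed from first principles
    tw <- (mean(x) - mean(y)) / sqrt(var(x) / length(x) + var(y) / length(y))
    got <- cmp$t_statistic[cmp$variable == "gestational_age"]
    expect_equal(got, tw, tolerance = 1e-12)
  }
})

test_that("gestational-age binning is a half-open partition", {
  co <- generate_cohort(cohort_params(500, seed = 161))
  tr <- ga_trend(co, week_edges = c(12, 20, 23, Inf))
  expect_equal(sum(tr$n), nrow(co))

  edge <- tibble::tibble(ff = c(0.1, 0.2), gestational_age_weeks = c(20, 23))
  tr2 <- ga_trend(edge, week_edges = c(12, 20, 23, Inf))
  expect_equal(tr2$n, c(0, 1, 1)) # boundary samples land in the upper bin

  single <- tibble::tibble(ff = 0.1, gestational_age_weeks = 16)
  tr3 <- ga_trend(single, week_edges = c(12, 20, 23, Inf))
  expect_equal(tr3$n, c(1, 0, 0))
  expect_true(is.na(tr3$mean_ff[2]))
  expect_error(ga_trend(single, week_edges = c(17, 20)), "cover")
})

test_that("the piecewise gestational-age profile is recovered from bins", {
  # flat 12-19, slight dip 20-22, rise from 23: encoded by the default
  # per-stratum laws; recovered segment means must keep that rank order
  co <- generate_cohort(cohort_params(
    6000, ga_law = list(mean = 19, sd = 5, min = 12, max = 32), seed = 171))
  tr <- ga_trend(co, week_edges = c(12, 20, 23, Inf))
  expect_equal(order(tr$mean_ff), c(2, 1, 3))
})

test_that("weight-FF regression recovers noise-free and noisy lines", {
  # exact line FF% = 16.52 - 0.12 w
  w <- seq(50, 90, by = 5)
  rec <- tibble::tibble(maternal_weight_kg = w,
                        ff = (16.52 - 0.12 * w) / 100,
                        gestational_age_weeks = 15)
  fit <- weight_ff_regression(rec, c(12, 20))
  expect_equal(fit$slope_pct_per_kg, -0.12, tolerance = 1e-10)
  expect_equal(fit$intercept_pct, 16.52, tolerance = 1e-10)
  expect_equal(fit$pearson_r, -1)
  expect_equal(suppressWarnings(weight_at_ff(fit, 0.05)), 96, tolerance = 1e-8)

  # slope recovery at n = 2000, noise SD 3 points: each seed's estimate has
  # SE ~ 0.008, so per-seed estimates stay within broad bounds and the mean
  # over 10 seeds recovers the slope within 10%
  slopes <- vapply(1:10, function(s) {
    co <- generate_cohort(cohort_params(
      2000, ga_law = list(mean = 16, sd = 2, min = 12, max = 19.9), seed = s))
    f <- weight_ff_regression(co, "12-19wk")
    expect_equal(sign(f$pearson_r), sign(f$slope_pct_per_kg))
    f$slope_pct_per_kg
  }, numeric(1))
  expect_true(all(abs(slopes + 0.12) < 0.04))
  expect_equal(mean(slopes), -0.12, tolerance = 0.1)
  expect_error(weight_ff_regression(rec[1, ], NULL), "fewer than 3")
  rec_const <- rec; rec_const$maternal_weight_kg <- 60
  expect_error(weight_ff_regression(rec_const, NULL), "constant")
})

test_that("tidy and glance expose the fit in broom style", {
  co <- generate_cohort(cohort_params(500, seed = 181))
  fit <- weight_ff_regression(co, "12-19wk")
  td <- tidy(fit)
  expect_equal(td$term, c("intercept_pct", "slope_pct_per_kg"))
  expect_true(all(c("estimate", "std_error", "p_value") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n, fit$n)
  expect_equal(gl$slope_pct_per_kg, td$estimate[2])
  expect_equal(gl$pearson_r^2, gl$r_squared, tolerance = 1e-10)
})

test_that("inverse prediction warns on extrapolation and positive slopes", {
  w <- seq(50, 70, by = 2)
  rec <- tibble::tibble(maternal_weight_kg = w, ff = (16 - 0.12 * w) / 100,
                        gestational_age_weeks = 15)
  fit <- weight_ff_regression(rec)
  expect_warning(weight_at_ff(fit, 0.05), "outside the observed")
  # target equal to the intercept crosses at weight 0, flagged
  expect_warning(out <- weight_at_ff(fit, 0.16), "outside the observed")
  expect_equal(out, 0, tolerance = 1e-10)

  rec_pos <- rec; rec_pos$ff <- rev(rec$ff)
  fit_pos <- weight_ff_regression(rec_pos)
  warns <- testthat::capture_warnings(weight_at_ff(fit_pos, 0.05))
  expect_true(any(grepl("positive", warns)))
})

test_that("non-pregnant correlations match cor.test and handle edge cases", {
  co <- generate_nonpregnant_cohort(71, seed = 191)
  res <- nonpregnant_correlations(co)
  expect_true("age_years" %in% res$covariate)
  ct <- cor.test(co$cfdna_ng_ml, co$age_years)
  row <- res[res$covariate == "age_years", ]
  expect_equal(row$pearson_r, unname(ct$estimate))
  expect_equal(row$p_value, ct$p.value)

  # perfectly anticorrelated toy pair
  toy <- tibble::tibble(cfdna_ng_ml = 10:1, age_years = 1:10)
  expect_equal(nonpregnant_correlations(toy)$pearson_r, -1)

  toy$age_years <- 5
  expect_warning(out <- nonpregnant_correlations(toy), "constant")
  expect_equal(nrow(out), 0)

  # independent covariates stay weak at n = 71 for most seeds
  weak <- vapply(1:60, function(s) {
    co <- generate_nonpregnant_cohort(71, seed = 1000 + s)
    abs(cor(co$cfdna_ng_ml, co$weight_kg)) < 0.25
  }, logical(1))
  expect_gte(mean(weak), 0.95)
})
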