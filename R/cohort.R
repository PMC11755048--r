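#' Summarise the fetal-fraction distribution of a cohort
#'
#' Median FF, and the count and percentage of samples with FF strictly
#' below a threshold (default 5%, the fraction of pregnancies where
#' trisomy-21 sensitivity is no longer guaranteed).
#'
#' @param records Cohort tibble with an `ff` column (fractions).
#' @param threshold FF threshold (fraction, default 0.05).
#' @return One-row tibble: `n`, `median_ff`, `n_below`, `pct_below`.
#' @examples
#' summarize_ff(generate_cohort(cohort_params(100, seed = 1)))
#' @export
summarize_ff <- function(records, threshold = 0.05) {
  if (nrow(records) == 0) stop("empty cohort", call. = FALSE)
  if (!"ff" %in% names(records)) stop("`records` needs an `ff` column", call. = FALSE)
  tibble::tibble(
    n = nrow(records),
    median_ff = stats::median(records$ff),
    n_below = sum(records$ff < threshold),
    pct_below = 100 * sum(records$ff < threshold) / nrow(records)
  )
}

#' Compare low-FF pregnancies with those near the median FF
#'
#' Splits the cohort into a low-FF group (FF below `threshold`) and a
#' near-median group (FF within `median_window` of the cohort median FF),
#' then runs an unpaired two-sided t test per maternal variable
#' (gestational age, maternal age, maternal weight). Welch's correction
#' is the default; set `var_equal = TRUE` for the pooled-variance test.
#'
#' @param records Cohort tibble (needs `ff`, `gestational_age_weeks`,
#'   `maternal_age_years`, `maternal_weight_kg`).
#' @param threshold Low-FF threshold (fraction, default 0.05).
#' @param median_window Half-width of the near-median window, on the FF
#'   fraction scale (default 0.01, i.e. +/- 1 percentage point).
#' @param var_equal Pooled-variance t test instead of Welch.
#' @return Tibble, one row per variable: group means and sizes,
#'   `t_statistic`, `p_value`.
#' @export
compare_low_ff_group <- function(records, threshold = 0.05,
                                 median_window = 0.01, var_equal = FALSE) {
  vars <- c(gestational_age = "gestational_age_weeks",
            maternal_age = "maternal_age_years",
            maternal_weight = "maternal_weight_kg")
  miss <- setdiff(c("ff", vars), names(records))
  if (length(miss)) {
    stop("`records` is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  med <- stats::median(records$ff)
  low <- records[records$ff < threshold, ]
  near <- records[abs(records$ff - med) <= median_window, ]
  if (nrow(low) < 2 || nrow(near) < 2) {
    stop("both groups need >= 2 members (low-FF: ", nrow(low),
         ", near-median: ", nrow(near), ")", call. = FALSE)
  }
  purrr::imap(vars, function(col, label) {
    tt <- stats::t.test(low[[col]], near[[col]], var.equal = var_equal)
    tibble::tibble(
      variable = label,
      mean_low_ff = mean(low[[col]]),
      mean_near_median = mean(near[[col]]),
      n_low_ff = nrow(low),
      n_near_median = nrow(near),
      t_statistic = unname(tt$statistic),
      p_value = tt$p.value
    )
  }) |>
    dplyr::bind_rows()
}

#' Mean fetal fraction per gestational-week bin
#'
#' Bins are half-open `[lo, hi)`, so every sample lands in exactly one
#' bin. Empty bins are reported with `n = 0` and `NA` statistics rather
#' than dropped.
#'
#' @param records Cohort tibble (needs `ff`, `gestational_age_weeks`).
#' @param week_edges Increasing bin edges in weeks; the last edge may be
#'   `Inf`. Default: single weeks from 12 to 28 plus an open top bin.
#' @return Tibble: `ga_lo`, `ga_hi`, `n`, `mean_ff`, `sd_ff`.
#' @export
ga_trend <- function(records, week_edges = c(12:28, Inf)) {
  stopifnot(all(diff(week_edges) > 0), length(week_edges) >= 2)
  ga <- records$gestational_age_weeks
  if (any(ga < week_edges[1] | ga >= week_edges[length(week_edges)])) {
    stop("`week_edges` must cover the cohort's gestational-age range",
         call. = FALSE)
  }
  idx <- findInterval(ga, week_edges, rightmost.closed = FALSE)
  purrr::map(seq_len(length(week_edges) - 1), function(b) {
    ff <- records$ff[idx == b]
    tibble::tibble(
      ga_lo = week_edges[b], ga_hi = week_edges[b + 1],
      n = length(ff),
      mean_ff = if (length(ff)) mean(ff) else NA_real_,
      sd_ff = if (length(ff) > 1) stats::sd(ff) else NA_real_
    )
  }) |>
    dplyr::bind_rows()
}

#' Gestational-age strata of the weight-FF analysis
#'
#' The three strata in which the weight-FF regression is reported:
#' 12-19 weeks, 20-22 weeks, and 23 weeks onward (half-open intervals).
#'
#' @return Tibble: `stratum`, `ga_lo`, `ga_hi`.
#' @export
ga_strata <- function() {
  tibble::tibble(
    stratum = c("12-19wk", "20-22wk", ">=23wk"),
    ga_lo = c(12, 20, 23),
    ga_hi = c(20, 23, Inf)
  )
}

#' Regress fetal fraction on maternal weight within a stratum
#'
#' Ordinary least squares of FF (percentage points) on maternal weight
#' (kg), restricted to a gestational-age stratum, with the Pearson
#' correlation attached. The fitted line is the basis for inverse
#' prediction of the weight at which FF crosses a threshold
#' ([weight_at_ff()]).
#'
#' @param records Cohort tibble (needs `ff`, `maternal_weight_kg`,
#'   `gestational_age_weeks`).
#' @param stratum Length-2 numeric `[lo, hi)` gestational-age interval in
#'   weeks, or a `stratum` label from [ga_strata()]. `NULL` uses all rows.
#' @return Object of class `ff_weight_fit`; supports [generics::tidy()],
#'   [generics::glance()], `predict()`, [weight_at_ff()] and
#'   [ggplot2::autoplot()].
#' @examples
#' cohort <- generate_cohort(cohort_params(500, seed = 1))
#' fit <- weight_ff_regression(cohort, stratum = c(12, 20))
#' glance(fit)
#' weight_at_ff(fit, 0.05)
#' @export
weight_ff_regression <- function(records, stratum = NULL) {
  lab <- "all"
  if (is.character(stratum)) {
    row <- ga_strata()[ga_strata()$stratum == stratum, ]
    if (nrow(row) != 1) stop("unknown stratum label: ", stratum, call. = FALSE)
    lab <- stratum
    stratum <- c(row$ga_lo, row$ga_hi)
  } else if (!is.null(stratum)) {
    stopifnot(length(stratum) == 2, stratum[1] < stratum[2])
    lab <- paste0("[", stratum[1], ",", stratum[2], ")wk")
  }
  dat <- records
  if (!is.null(stratum)) {
    dat <- dat[dat$gestational_age_weeks >= stratum[1] &
                 dat$gestational_age_weeks < stratum[2], ]
  }
  if (nrow(dat) < 3) stop("stratum has fewer than 3 samples", call. = FALSE)
  if (length(unique(dat$maternal_weight_kg)) < 2) {
    stop("maternal weight is constant within the stratum", call. = FALSE)
  }
  df <- data.frame(weight = dat$maternal_weight_kg, ff_pct = 100 * dat$ff)
  lm_fit <- stats::lm(ff_pct ~ weight, data = df)
  structure(
    list(
      lm = lm_fit,
      stratum = lab,
      ga_range = if (is.null(stratum)) c(-Inf, Inf) else stratum,
      intercept_pct = unname(stats::coef(lm_fit)[1]),
      slope_pct_per_kg = unname(stats::coef(lm_fit)[2]),
      pearson_r = stats::cor(df$weight, df$ff_pct),
      n = nrow(df),
      residual_sd_pct = stats::sigma(lm_fit),
      weight_range = range(df$weight),
      data = tibble::as_tibble(df)
    ),
    class = "ff_weight_fit"
  )
}

#' @export
print.ff_weight_fit <- function(x, ...) {
  cat("<ff_weight_fit> stratum", x$stratum, "(n =", x$n, ")\n")
  cat(sprintf("  FF%% = %.3f %+.4f * weight_kg   (Pearson r = %.3f)\n",
              x$intercept_pct, x$slope_pct_per_kg, x$pearson_r))
  invisible(x)
}

#' @rdname weight_ff_regression
#' @param x An `ff_weight_fit` object.
#' @param ... Unused.
#' @export
tidy.ff_weight_fit <- function(x, ...) {
  s <- summary(x$lm)$coefficients
  tibble::tibble(
    term = c("intercept_pct", "slope_pct_per_kg"),
    estimate = unname(s[, 1]),
    std_error = unname(s[, 2]),
    statistic = unname(s[, 3]),
    p_value = unname(s[, 4])
  )
}

#' @rdname weight_ff_regression
#' @export
glance.ff_weight_fit <- function(x, ...) {
  tibble::tibble(
    stratum = x$stratum,
    n = x$n,
    intercept_pct = x$intercept_pct,
    slope_pct_per_kg = x$slope_pct_per_kg,
    pearson_r = x$pearson_r,
    r_squared = summary(x$lm)$r.squared,
    residual_sd_pct = x$residual_sd_pct
  )
}

#' Maternal weight at which a fitted FF line crosses a threshold
#'
#' Inverse prediction from a [weight_ff_regression()] fit:
#' `weight = (target - intercept) / slope`, on the percent FF scale.
#' Crossings outside the observed weight range are returned with an
#' extrapolation warning; a non-negative slope draws a warning too, since
#' the clinical reading (heavier women dilute the fetal signal) assumes a
#' negative slope.
#'
#' @param fit An `ff_weight_fit`.
#' @param target_ff Target fetal fraction as a fraction (default 0.05).
#' @return Weight in kg (scalar).
#' @export
weight_at_ff <- function(fit, target_ff = 0.05) {
  stopifnot(inherits(fit, "ff_weight_fit"))
  if (fit$slope_pct_per_kg == 0) stop("zero slope: no crossing", call. = FALSE)
  target_pct <- 100 * target_ff
  w <- (target_pct - fit$intercept_pct) / fit$slope_pct_per_kg
  if (fit$slope_pct_per_kg > 0) {
    warning("positive weight-FF slope: crossing direction is inconsistent ",
            "with the expected negative correlation", call. = FALSE)
  }
  if (w < fit$weight_range[1] || w > fit$weight_range[2]) {
    warning(sprintf(
      "crossing at %.1f kg lies outside the observed weight range [%.1f, %.1f]: extrapolation",
      w, fit$weight_range[1], fit$weight_range[2]), call. = FALSE)
  }
  w
}

#' Correlates of cfDNA level in non-pregnant women
#'
#' Pearson correlation (with two-sided p) of cfDNA concentration against
#' each available covariate: age, height, weight, BMI, body-fat
#' percentage, basal metabolism. Constant covariates are skipped with a
#' warning.
#'
#' @param records Tibble as from [generate_nonpregnant_cohort()] (needs a
#'   `cfdna_ng_ml` column plus covariates).
#' @return Tibble: `covariate`, `n`, `pearson_r`, `p_value`.
#' @export
nonpregnant_correlations <- function(records) {
  if (!"cfdna_ng_ml" %in% names(records)) {
    stop("`records` needs a `cfdna_ng_ml` column", call. = FALSE)
  }
  if (nrow(records) < 3) stop("need >= 3 records", call. = FALSE)
  covars <- intersect(
    c("age_years", "height_cm", "weight_kg", "bmi", "body_fat_pct",
      "basal_metabolism_kcal"),
    names(records)
  )
  purrr::map(covars, function(v) {
    x <- records[[v]]
    if (stats::sd(x) == 0) {
      warning("covariate `", v, "` is constant; skipped", call. = FALSE)
      return(NULL)
    }
    ct <- stats::cor.test(records$cfdna_ng_ml, x)
    tibble::tibble(covariate = v, n = nrow(records),
                   pearson_r = unname(ct$estimate), p_value = ct$p.value)
  }) |>
    dplyr::bind_rows()
}
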