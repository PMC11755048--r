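#' Default per-stratum fetal-fraction law
#'
#' The cohort generator's linear weight-to-FF model, one line per
#' gestational-age stratum: `FF% = intercept + slope * weight_kg + noise`.
#' Defaults anchor each line at the weight where it crosses 5% FF — 96 kg
#' for 12-19 weeks, 93 kg for 20-22 weeks, 162 kg for >= 23 weeks — with a
#' common slope of -0.12 percentage points per kg and residual SD of 3
#' points. The intercepts are derived as `5 - slope * crossing`.
#'
#' @param slope_pct_per_kg Slope(s) in FF percentage points per kg.
#' @param crossing_weight_kg Weight(s) in kg at which each stratum line
#'   crosses 5% FF.
#' @param residual_sd_pct Residual SD(s) in percentage points.
#' @return Tibble with columns `ga_lo`, `ga_hi`, `slope_pct_per_kg`,
#'   `intercept_pct`, `residual_sd_pct`.
#' @export
default_ff_law <- function(slope_pct_per_kg = -0.12,
                           crossing_weight_kg = c(96, 93, 162),
                           residual_sd_pct = 3) {
  tibble::tibble(
    ga_lo = c(0, 20, 23),
    ga_hi = c(20, 23, Inf),
    slope_pct_per_kg = rep_len(slope_pct_per_kg, 3),
    intercept_pct = 5 - rep_len(slope_pct_per_kg, 3) * crossing_weight_kg,
    residual_sd_pct = rep_len(residual_sd_pct, 3)
  )
}

#' Cohort generator parameters
#'
#' @param n_samples Number of pregnancies to simulate.
#' @param ff_law Per-stratum linear FF law, as from [default_ff_law()].
#' @param weight_law Maternal weight distribution: list with `mean`, `sd`
#'   (kg) and truncation bounds `min`, `max`.
#' @param ga_law Gestational-age distribution (decimal weeks): list with
#'   `mean`, `sd`, `min`, `max`.
#' @param age_law Maternal age distribution (years): list with `mean`,
#'   `sd`, `min`, `max`.
#' @param male_prob Probability of a male fetus.
#' @param twin_rate Probability of a twin pregnancy (flag only; twins get
#'   no special dosage model).
#' @param karyotype Karyotype assigned to every sample (`"euploid"`,
#'   `"T21"`, `"T18"` or `"T13"`).
#' @param seed Integer seed; mandatory for reproducibility.
#' @return An object of class `cohort_params`.
#' @export
cohort_params <- function(n_samples,
                          ff_law = default_ff_law(),
                          weight_law = list(mean = 56, sd = 8, min = 40, max = 110),
                          ga_law = list(mean = 16.5, sd = 3, min = 12, max = 40),
                          age_law = list(mean = 30.9, sd = 4, min = 18, max = 48),
                          male_prob = 0.5,
                          twin_rate = 0.012,
                          karyotype = "euploid",
                          seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  if (!is.numeric(n_samples) || length(n_samples) != 1 || n_samples < 1) {
    stop("`n_samples` must be a positive count", call. = FALSE)
  }
  for (law in list(weight_law, ga_law, age_law)) {
    if (!all(c("mean", "sd", "min", "max") %in% names(law))) {
      stop("each law needs `mean`, `sd`, `min`, `max`", call. = FALSE)
    }
    if (law$min >= law$max) stop("truncation bounds must be ordered", call. = FALSE)
    if (law$sd < 0) stop("law `sd` must be >= 0", call. = FALSE)
  }
  req <- c("ga_lo", "ga_hi", "slope_pct_per_kg", "intercept_pct", "residual_sd_pct")
  if (!all(req %in% names(ff_law))) {
    stop("`ff_law` must have columns ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (any(ff_law$residual_sd_pct < 0)) stop("residual SD must be >= 0", call. = FALSE)
  structure(
    list(n_samples = as.integer(n_samples), ff_law = ff_law,
         weight_law = weight_law, ga_law = ga_law, age_law = age_law,
         male_prob = male_prob, twin_rate = twin_rate,
         karyotype = karyotype, seed = as.integer(seed)),
    class = "cohort_params"
  )
}

# truncated normal by inverse-CDF; degenerates to the mean when sd = 0
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  p <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(p, mean, sd)
}

#' Simulate a pregnancy cohort
#'
#' Draws maternal weight, gestational age and age from truncated normal
#' laws, then fetal fraction from the per-stratum linear weight law with
#' Gaussian residuals, truncated to `[0, 0.5]`. FF is returned as a
#' fraction; the law operates on the percent scale.
#'
#' @param params A [cohort_params()] object.
#' @return Tibble with one row per pregnancy: `sample_id`, `ff`,
#'   `gestational_age_weeks`, `maternal_age_years`, `maternal_weight_kg`,
#'   `fetal_sex`, `karyotype`, `twin`.
#' @examples
#' cohort <- generate_cohort(cohort_params(5, seed = 1))
#' @export
generate_cohort <- function(params) {
  if (!inherits(params, "cohort_params")) {
    stop("`params` must be built with cohort_params()", call. = FALSE)
  }
  withr::with_seed(params$seed, {
    n <- params$n_samples
    wl <- params$weight_law; gl <- params$ga_law; al <- params$age_law
    weight <- rtruncnorm(n, wl$mean, wl$sd, wl$min, wl$max)
    ga <- rtruncnorm(n, gl$mean, gl$sd, gl$min, gl$max)
    age <- rtruncnorm(n, al$mean, al$sd, al$min, al$max)
    law <- params$ff_law
    stratum <- findInterval(ga, c(law$ga_lo, Inf), rightmost.closed = FALSE)
    stratum[stratum < 1 | stratum > nrow(law)] <- NA_integer_
    if (anyNA(stratum)) stop("gestational ages fall outside the FF law strata", call. = FALSE)
    ff_pct <- law$intercept_pct[stratum] +
      law$slope_pct_per_kg[stratum] * weight +
      stats::rnorm(n, 0, law$residual_sd_pct[stratum])
    ff <- pmin(pmax(ff_pct / 100, 0), 0.5)
    tibble::tibble(
      sample_id = sprintf("S%05d", seq_len(n)),
      ff = ff,
      gestational_age_weeks = ga,
      maternal_age_years = age,
      maternal_weight_kg = weight,
      fetal_sex = ifelse(stats::runif(n) < params$male_prob, "male", "female"),
      karyotype = params$karyotype,
      twin = stats::runif(n) < params$twin_rate
    )
  })
}

# weight vector for one sample row, gamma-jittered when cv > 0
sample_weights <- function(ff, fetal_sex, karyotype, seq) {
  w <- chromosome_weights(ff, fetal_sex, karyotype, seq)
  jitter_weights(w, seq$overdispersion_cv)
}

jitter_weights <- function(w, cv) {
  if (cv > 0) {
    shape <- 1 / cv^2
    w <- w * stats::rgamma(length(w), shape = shape, rate = shape)
    w <- w / sum(w)
  }
  w
}

#' Simulate per-chromosome unique read counts
#'
#' One multinomial draw of the read budget per sample over the expected
#' chromosome weights ([chromosome_weights()]), after per-sample gamma
#' jitter of the weights when `overdispersion_cv > 0`. Counts always sum
#' exactly to `seq$total_unique_reads`.
#'
#' @param samples Tibble with columns `sample_id`, `ff`, `fetal_sex`,
#'   `karyotype` (e.g. from [generate_cohort()]).
#' @param seq A [seq_params()] object.
#' @param seed Integer seed.
#' @return Wide tibble of counts: `sample_id` plus one column per
#'   chromosome (`chr1` ... `chrY`).
#' @examples
#' cohort <- generate_cohort(cohort_params(3, seed = 1))
#' counts <- simulate_read_counts(cohort, seq_params(), seed = 2)
#' @export
simulate_read_counts <- function(samples, seq = seq_params(), seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  req <- c("sample_id", "ff", "fetal_sex", "karyotype")
  miss <- setdiff(req, names(samples))
  if (length(miss)) {
    stop("`samples` is missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  chroms <- chrom_names(seq)
  withr::with_seed(as.integer(seed), {
    counts <- purrr::pmap(
      list(samples$ff, samples$fetal_sex, samples$karyotype),
      function(ff, sex, kt) {
        w <- sample_weights(ff, sex, kt, seq)
        drop(stats::rmultinom(1, seq$total_unique_reads, w))
      }
    )
  })
  mat <- do.call(rbind, counts)
  colnames(mat) <- chroms
  dplyr::bind_cols(tibble::tibble(sample_id = samples$sample_id),
                   tibble::as_tibble(mat))
}

#' Simulate a euploid reference cohort of read-count profiles
#'
#' Convenience wrapper: draws `n` euploid pregnancies from the default
#' cohort law (mixed fetal sex, FF from the weight law) and simulates their
#' read-count profiles. The screening pipeline builds its reference panel
#' from 412 such samples.
#'
#' @param n Number of euploid reference samples (>= 2).
#' @param seq A [seq_params()] object.
#' @param seed Integer seed.
#' @param fetal_sex Optionally restrict to `"male"` or `"female"` fetuses
#'   (e.g. a female-only panel for the chrY sex check).
#' @return List with elements `samples` (metadata tibble) and `counts`
#'   (wide count tibble).
#' @export
generate_reference_cohort <- function(n, seq = seq_params(), seed,
                                      fetal_sex = NULL) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  if (n < 2) stop("a reference cohort needs n >= 2 (SD undefined below that)", call. = FALSE)
  male_prob <- if (is.null(fetal_sex)) 0.5 else if (fetal_sex == "male") 1 else 0
  cp <- cohort_params(n, male_prob = male_prob, karyotype = "euploid",
                      seed = child_seed(seed, 1))
  samples <- generate_cohort(cp)
  counts <- simulate_read_counts(samples, seq, seed = child_seed(seed, 2))
  list(samples = samples, counts = counts)
}

#' Fragment-length mixture parameters
#'
#' Two log-normal-like unimodal components: a fetal component with mode
#' 143 bp and a maternal component with mode 166 bp, each with a full width
#' at half maximum of about 20 bp. These are the modal sizes of
#' placentally derived versus maternal cell-free DNA fragments.
#'
#' @param fetal_mode_bp Fetal component mode (bp).
#' @param maternal_mode_bp Maternal component mode (bp).
#' @param fwhm_bp Approximate full width at half maximum of each component.
#' @return An object of class `fragment_params`.
#' @export
fragment_params <- function(fetal_mode_bp = 143, maternal_mode_bp = 166,
                            fwhm_bp = 20) {
  stopifnot(fetal_mode_bp > 0, maternal_mode_bp > 0, fwhm_bp > 0)
  structure(
    list(fetal_mode_bp = fetal_mode_bp, maternal_mode_bp = maternal_mode_bp,
         fwhm_bp = fwhm_bp),
    class = "fragment_params"
  )
}

# lognormal with given mode; sdlog chosen so FWHM ~ fwhm (small-sd normal
# approximation: FWHM = 2.3548 * mode * sdlog)
rlnorm_mode <- function(n, mode, fwhm) {
  sdlog <- fwhm / (2.3548 * mode)
  meanlog <- log(mode) + sdlog^2
  stats::rlnorm(n, meanlog, sdlog)
}

#' Simulate cell-free DNA fragment lengths
#'
#' Draws integer fragment lengths from the two-component mixture
#' `ff * Fetal(mode 143) + (1 - ff) * Maternal(mode 166)`.
#'
#' @param ff Fetal fraction in `[0, 1]`.
#' @param n Number of fragments (>= 1).
#' @param frag A [fragment_params()] object.
#' @param seed Integer seed.
#' @return Integer vector of lengths (bp).
#' @examples
#' len <- simulate_fragment_lengths(0.1, 1000, seed = 1)
#' @export
simulate_fragment_lengths <- function(ff, n, frag = fragment_params(), seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  stopifnot(ff >= 0, ff <= 1)
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    fetal <- stats::runif(n) < ff
    len <- numeric(n)
    len[fetal] <- rlnorm_mode(sum(fetal), frag$fetal_mode_bp, frag$fwhm_bp)
    len[!fetal] <- rlnorm_mode(sum(!fetal), frag$maternal_mode_bp, frag$fwhm_bp)
    as.integer(round(len))
  })
}

#' Simulate a non-pregnant reference cohort
#'
#' Emulates a small study of circulating cfDNA levels in non-pregnant
#' women: cfDNA concentration weakly anticorrelated with age (default
#' population r of about -0.25) and independent of height, weight, BMI,
#' body-fat percentage and basal metabolism. Used to exercise
#' [nonpregnant_correlations()].
#'
#' @param n Cohort size (default 71).
#' @param age_r Population correlation between age and cfDNA level.
#' @param seed Integer seed.
#' @return Tibble with columns `subject_id`, `cfdna_ng_ml`, `age_years`,
#'   `height_cm`, `weight_kg`, `bmi`, `body_fat_pct`,
#'   `basal_metabolism_kcal`.
#' @export
generate_nonpregnant_cohort <- function(n = 71, age_r = -0.25, seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  stopifnot(n >= 3, abs(age_r) < 1)
  withr::with_seed(as.integer(seed), {
    age <- rtruncnorm(n, 30.8, 6, 20, 45)
    height <- rtruncnorm(n, 160, 6, 145, 180)
    weight <- rtruncnorm(n, 54.8, 7, 40, 85)
    bmi <- weight / (height / 100)^2
    body_fat <- rtruncnorm(n, 27, 5, 15, 42)
    basal <- 370 + 21.6 * (weight * (1 - body_fat / 100)) +
      stats::rnorm(n, 0, 40)
    z_age <- (age - mean(age)) / stats::sd(age)
    cfdna <- 10 + 2 * (age_r * z_age +
                         sqrt(1 - age_r^2) * stats::rnorm(n))
    tibble::tibble(
      subject_id = sprintf("NP%03d", seq_len(n)),
      cfdna_ng_ml = cfdna,
      age_years = age,
      height_cm = height,
      weight_kg = weight,
      bmi = bmi,
      body_fat_pct = body_fat,
      basal_metabolism_kcal = basal
    )
  })
}
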