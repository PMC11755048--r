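#' chrY baselines for fetal-fraction estimation
#'
#' The two anchor points of the linear chrY fetal-fraction estimator: the
#' chrY read ratio of a confirmed-female-fetus pregnancy (mis-mapping
#' background only) and the chrY ratio expected at fetal fraction 1 (a
#' pure male genome under the configured chromosome weights). By default
#' both are derived from the simulator's own generative weights, which
#' makes the estimator exactly consistent with the simulator up to the
#' weight-vector renormalisation.
#'
#' @param seq A [seq_params()] object, or `NULL` when supplying both
#'   ratios explicitly.
#' @param female_background_ratio Override for the female baseline.
#' @param male_full_ratio Override for the ff = 1 baseline.
#' @return An object of class `y_baselines`.
#' @export
y_baselines <- function(seq = seq_params(), female_background_ratio = NULL,
                        male_full_ratio = NULL) {
  if (is.null(female_background_ratio)) {
    female_background_ratio <-
      chromosome_weights(0, "female", "euploid", seq)[["chrY"]]
  }
  if (is.null(male_full_ratio)) {
    male_full_ratio <- chromosome_weights(1, "male", "euploid", seq)[["chrY"]]
  }
  if (!(male_full_ratio > female_background_ratio) || female_background_ratio < 0) {
    stop("baselines must satisfy male_full_ratio > female_background_ratio >= 0",
         call. = FALSE)
  }
  structure(
    list(female_background_ratio = female_background_ratio,
         male_full_ratio = male_full_ratio),
    class = "y_baselines"
  )
}

#' Estimate fetal fraction from chrY representation
#'
#' For a male-fetus pregnancy, the chrY read ratio grows linearly with the
#' fetal fraction between the female background and the pure-male-genome
#' ratio. The estimator interpolates:
#' `ff = (r_Y - background) / (full - background)`, clipped to `[0, 1]`.
#'
#' @param counts Wide count tibble (must include a `chrY` column).
#' @param baselines A [y_baselines()] object.
#' @return Tibble: `sample_id`, `chry_ratio`, `ff_est`.
#' @examples
#' b <- y_baselines()
#' # ff = (0.0023 - 0.0005) / (0.0185 - 0.0005) = 0.10 for such baselines
#' @export
ff_from_chry <- function(counts, baselines = y_baselines()) {
  if (!inherits(baselines, "y_baselines")) {
    stop("`baselines` must come from y_baselines()", call. = FALSE)
  }
  if (!"chrY" %in% names(counts)) stop("count table lacks a chrY column", call. = FALSE)
  ratios <- chromosome_ratios(counts) |>
    dplyr::filter(.data$chrom == "chrY")
  lo <- baselines$female_background_ratio
  hi <- baselines$male_full_ratio
  ratios |>
    dplyr::transmute(
      sample_id = .data$sample_id,
      chry_ratio = .data$ratio,
      ff_est = pmin(pmax((.data$ratio - lo) / (hi - lo), 0), 1)
    )
}

#' Confirm fetal sex from the chrY z score
#'
#' z score of chrY against a panel built from female-fetus euploid
#' pregnancies. A male fetus is confirmed when z strictly exceeds
#' `z_threshold` (default 15); artificial-mixture inputs to the
#' limit-of-detection experiment are required to pass this check.
#'
#' @param counts Wide count tibble.
#' @param female_panel A [build_reference()] panel from female-fetus
#'   euploid profiles.
#' @param z_threshold Confirmation threshold, strict (default 15).
#' @return Tibble: `sample_id`, `z_chry`, `male_confirmed`.
#' @export
chry_sex_check <- function(counts, female_panel, z_threshold = 15) {
  z_scores(counts, female_panel) |>
    dplyr::filter(.data$chrom == "chrY") |>
    dplyr::transmute(
      sample_id = .data$sample_id,
      z_chry = .data$z,
      male_confirmed = .data$z > z_threshold
    )
}
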