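#' Expected fetal fraction of a two-library mixture
#'
#' The dilution arithmetic used to design artificial mixtures of a
#' trisomy-21 male-fetus library (concentration `c1`, volume `v1`, fetal
#' fraction `ff1`) with a euploid female-fetus library (`c2`, `v2`):
#' `expected FF = c1*v1*ff1 / (c1*v1 + c2*v2)`. Scale-invariant in
#' (concentration, volume) units.
#'
#' @param c1,v1 Concentration (pM) and volume (uL) of the trisomic library.
#' @param ff1 Fetal fraction of the trisomic library, in `[0, 1]`.
#' @param c2,v2 Concentration and volume of the diluent euploid library.
#' @return Expected fetal fraction (fraction).
#' @examples
#' expected_ff(20, 5, 0.12, 10, 20) # 0.04
#' @export
expected_ff <- function(c1, v1, ff1, c2, v2) {
  stopifnot(c1 >= 0, v1 >= 0, c2 >= 0, v2 >= 0, ff1 >= 0, ff1 <= 1)
  total <- c1 * v1 + c2 * v2
  if (total <= 0) stop("total library mass must be positive", call. = FALSE)
  c1 * v1 * ff1 / total
}

#' Library specification for an artificial mixture
#'
#' @param concentration_pm Library concentration (pM; pooled libraries
#'   below 10 pM draw a QC warning, mirroring wet-lab practice).
#' @param volume_ul Volume (uL).
#' @param ff Fetal fraction of the source pregnancy.
#' @param karyotype `"T21"` or `"euploid"`.
#' @param fetal_sex `"male"` or `"female"`.
#' @return An object of class `library_spec`.
#' @export
library_spec <- function(concentration_pm, volume_ul, ff,
                         karyotype = c("euploid", "T21"),
                         fetal_sex = c("female", "male")) {
  karyotype <- match.arg(karyotype)
  fetal_sex <- match.arg(fetal_sex)
  stopifnot(concentration_pm > 0, volume_ul >= 0, ff >= 0, ff <= 1)
  if (concentration_pm < 10) {
    warning("library concentration below 10 pM; pooled-library QC would flag this",
            call. = FALSE)
  }
  structure(
    list(concentration_pm = concentration_pm, volume_ul = volume_ul,
         ff = ff, karyotype = karyotype, fetal_sex = fetal_sex),
    class = "library_spec"
  )
}

#' Design an artificial two-library mixture
#'
#' Pairs a trisomy-21 male library with a euploid female diluent library
#' and records the expected fetal fraction of the pool.
#'
#' @param lib1 [library_spec()] of the trisomic (T21 male) library.
#' @param lib2 [library_spec()] of the euploid (female) diluent library.
#' @return An object of class `mixture_design` with an `expected_ff`
#'   element.
#' @export
mixture_design <- function(lib1, lib2) {
  stopifnot(inherits(lib1, "library_spec"), inherits(lib2, "library_spec"))
  eff <- expected_ff(lib1$concentration_pm, lib1$volume_ul, lib1$ff,
                     lib2$concentration_pm, lib2$volume_ul)
  if (eff > lib1$ff + 1e-12) stop("expected FF cannot exceed lib1's FF", call. = FALSE)
  structure(list(lib1 = lib1, lib2 = lib2, expected_ff = eff),
            class = "mixture_design")
}

#' Simulate sequencing of an artificial mixture
#'
#' In-silico analogue of pooling two libraries and sequencing the pool:
#' the per-chromosome weight vector is the mass-weighted
#' (concentration x volume) average of the two source weight vectors,
#' jittered by the overdispersion model, then one multinomial draw of the
#' read budget. The resulting expected chr21 lift and chrY ratio both
#' correspond to the design's expected fetal fraction.
#'
#' @param design A [mixture_design()] object.
#' @param seq A [seq_params()] object.
#' @param seed Integer seed.
#' @param sample_id Sample name for the output row.
#' @return One-row wide count tibble.
#' @export
mix_profiles <- function(design, seq = seq_params(), seed,
                         sample_id = "mixture") {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  stopifnot(inherits(design, "mixture_design"))
  m1 <- design$lib1$concentration_pm * design$lib1$volume_ul
  m2 <- design$lib2$concentration_pm * design$lib2$volume_ul
  w1 <- chromosome_weights(design$lib1$ff, design$lib1$fetal_sex,
                           design$lib1$karyotype, seq)
  w2 <- chromosome_weights(design$lib2$ff, design$lib2$fetal_sex,
                           design$lib2$karyotype, seq)
  w <- (m1 * w1 + m2 * w2) / (m1 + m2)
  withr::with_seed(as.integer(seed), {
    w <- jitter_weights(w, seq$overdispersion_cv)
    cnt <- drop(stats::rmultinom(1, seq$total_unique_reads, w))
  })
  dplyr::bind_cols(tibble::tibble(sample_id = sample_id),
                   tibble::as_tibble(as.list(cnt)))
}

#' Default fetal-fraction bins of the limit-of-detection experiment
#'
#' The dilution series targets: below 3%, 3-4%, 4-5%, 5-6% and above 8%
#' (6-8% deliberately unsampled, mirroring the published design). The
#' open-ended bins carry the ranges the dilution targets are drawn from.
#'
#' @param low_floor Lower draw edge of the `<3%` bin (default 0.01).
#' @param over8_range Draw range for the `>8%` bin (default 8-15%).
#' @return Tibble: `bin`, `bin_lo`, `bin_hi`, `draw_lo`, `draw_hi`.
#' @export
default_lod_bins <- function(low_floor = 0.01, over8_range = c(0.08, 0.15)) {
  tibble::tibble(
    bin = c("<3%", "3-4%", "4-5%", "5-6%", ">8%"),
    bin_lo = c(0, 0.03, 0.04, 0.05, 0.08),
    bin_hi = c(0.03, 0.04, 0.05, 0.06, Inf),
    draw_lo = c(low_floor, 0.03, 0.04, 0.05, over8_range[1]),
    draw_hi = c(0.03, 0.04, 0.05, 0.06, over8_range[2])
  )
}

#' Run the in-silico limit-of-detection experiment
#'
#' For each fetal-fraction bin, repeatedly: draw a target FF uniformly
#' within the bin's draw range, design a dilution of a T21 male library
#' (source fetal fraction `source_ff`) with a euploid female library that
#' achieves that expected FF, simulate sequencing of the mixture, classify
#' it against the reference panel, and tally chr21 high-risk calls.
#' Mixtures below the FF alert threshold are gated by QC, as they would be
#' in production, and count as not detected.
#'
#' @param panel A [build_reference()] panel.
#' @param bins Bin table as from [default_lod_bins()].
#' @param replicates Mixtures per bin (the bench experiment used 6).
#' @param seq A [seq_params()] object.
#' @param seed Integer seed.
#' @param source_ff Fetal fraction of the undiluted T21 library
#'   (default 0.20, in the upper range seen in confirmed T21 pregnancies;
#'   must be at least the largest draw edge).
#' @param ... Passed to [classify_samples()] (e.g. `z_threshold`).
#' @return Tibble of class `lod_table`: `bin`, `bin_lo`, `bin_hi`,
#'   `n_replicates`, `n_detected`, `detection_rate_pct`.
#' @examples
#' \donttest{
#' panel <- build_reference(generate_reference_cohort(100, seed = 1)$counts)
#' lod <- run_lod_experiment(panel, replicates = 6, seed = 2)
#' estimate_lod(lod)
#' }
#' @export
run_lod_experiment <- function(panel, bins = default_lod_bins(),
                               replicates = 6, seq = seq_params(), seed,
                               source_ff = 0.20, ...) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  if (nrow(bins) == 0) stop("`bins` must be nonempty", call. = FALSE)
  if (replicates < 1) stop("`replicates` must be >= 1", call. = FALSE)
  if (any(bins$draw_hi > source_ff)) {
    stop("`source_ff` must be at least the largest draw edge", call. = FALSE)
  }
  check_panel(panel)
  withr::with_seed(as.integer(seed), {
    res <- purrr::pmap(
      list(bins$bin, bins$draw_lo, bins$draw_hi),
      function(bin, lo, hi) {
        detected <- logical(replicates)
        for (i in seq_len(replicates)) {
          target <- stats::runif(1, lo, hi)
          # c1 = c2, v1 fixed: v2 solves expected_ff(target)
          v2 <- 10 * (source_ff - target) / target
          d <- mixture_design(
            library_spec(15, 10, source_ff, "T21", "male"),
            library_spec(15, v2, 0, "euploid", "female")
          )
          cnt <- mix_profiles(d, seq,
                              seed = sample.int(.Machine$integer.max, 1),
                              sample_id = sprintf("%s_r%03d", bin, i))
          calls <- classify_samples(cnt, panel, ff = d$expected_ff,
                                    chromosomes = "chr21", ...)
          detected[i] <- any(calls$call == "high_risk")
        }
        tibble::tibble(bin = bin, n_replicates = replicates,
                       n_detected = sum(detected))
      }
    )
  })
  out <- dplyr::bind_cols(
    bins[, c("bin", "bin_lo", "bin_hi")],
    dplyr::bind_rows(res)[, c("n_replicates", "n_detected")]
  ) |>
    dplyr::mutate(detection_rate_pct = 100 * .data$n_detected / .data$n_replicates)
  structure(out, class = c("lod_table", class(out)))
}

#' Limit of detection from an LoD table
#'
#' The lowest fetal-fraction bin at and above which the detection rate is
#' 100% (contiguity required: every higher bin must also be at 100%).
#'
#' @param table An [run_lod_experiment()] result (bins in increasing FF
#'   order).
#' @return One-row tibble (the LoD bin), or a zero-row tibble with a
#'   warning when no contiguous 100% run reaches the top.
#' @export
estimate_lod <- function(table) {
  req <- c("bin", "detection_rate_pct")
  if (!all(req %in% names(table)) || nrow(table) == 0) {
    stop("`table` must be a populated LoD table", call. = FALSE)
  }
  full <- table$detection_rate_pct == 100
  # longest suffix of bins all at 100%
  run <- rev(cumprod(rev(full))) == 1
  if (!any(run)) {
    warning("limit of detection not reached: no bin has 100% detection ",
            "contiguous to the top", call. = FALSE)
    return(table[0, ])
  }
  table[which(run)[1], ]
}
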