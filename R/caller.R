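#' Per-chromosome read ratios
#'
#' Each chromosome's share of a sample's unique reads,
#' `counts[chrom] / total`. The ratio is the quantity standardised by the
#' z test.
#'
#' @param counts Wide count tibble (`sample_id` plus chromosome columns),
#'   as from [simulate_read_counts()] or [read_count_matrix()].
#' @return Long tibble: `sample_id`, `chrom`, `ratio`.
#' @export
chromosome_ratios <- function(counts) {
  chroms <- count_chrom_cols(counts)
  long <- tidyr::pivot_longer(counts, dplyr::all_of(chroms),
                              names_to = "chrom", values_to = "count")
  if (any(long$count < 0)) stop("negative read counts", call. = FALSE)
  out <- long |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(total = sum(.data$count)) |>
    dplyr::ungroup()
  if (any(out$total == 0)) stop("sample with zero total reads", call. = FALSE)
  out |>
    dplyr::mutate(ratio = .data$count / .data$total) |>
    dplyr::select("sample_id", "chrom", "ratio")
}

#' Ratio of a single chromosome for a single profile
#'
#' @param counts One-row wide count tibble.
#' @param chrom Chromosome name, e.g. `"chr21"`.
#' @return Scalar ratio in `[0, 1]`.
#' @export
chromosome_ratio <- function(counts, chrom) {
  if (nrow(counts) != 1) stop("`counts` must have exactly one row", call. = FALSE)
  chroms <- count_chrom_cols(counts)
  if (!chrom %in% chroms) stop("unknown chromosome: ", chrom, call. = FALSE)
  total <- sum(as.numeric(counts[1, chroms]))
  if (total == 0) stop("sample with zero total reads", call. = FALSE)
  as.numeric(counts[[chrom]][1]) / total
}

count_chrom_cols <- function(counts) {
  chroms <- setdiff(names(counts), "sample_id")
  if (!"sample_id" %in% names(counts) || length(chroms) == 0) {
    stop("count table needs a `sample_id` column plus chromosome columns",
         call. = FALSE)
  }
  chroms
}

#' Build a euploid reference panel
#'
#' Per-chromosome mean and sample SD (n - 1 denominator) of the chromosome
#' ratios over a set of euploid profiles. A sample's z score is its ratio
#' standardised against this panel.
#'
#' @param counts Wide count tibble of the euploid reference samples
#'   (>= 2 rows).
#' @return Tibble of class `reference_panel`: `chrom`, `mu`, `sigma`,
#'   `n_reference`.
#' @examples
#' ref <- generate_reference_cohort(50, seed = 1)
#' panel <- build_reference(ref$counts)
#' @export
build_reference <- function(counts) {
  if (nrow(counts) < 2) stop("a reference panel needs >= 2 profiles", call. = FALSE)
  panel <- chromosome_ratios(counts) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(mu = mean(.data$ratio), sigma = stats::sd(.data$ratio),
                     n_reference = dplyr::n(), .groups = "drop")
  # preserve input chromosome order
  panel <- panel[match(count_chrom_cols(counts), panel$chrom), ]
  if (any(panel$sigma == 0)) {
    stop("degenerate panel: zero SD for ",
         paste(panel$chrom[panel$sigma == 0], collapse = ", "), call. = FALSE)
  }
  structure(panel, class = c("reference_panel", class(panel)))
}

#' Chromosomal z scores against a reference panel
#'
#' `z = (ratio - mu) / sigma` per chromosome, where `mu` and `sigma` are
#' the panel's euploid mean and SD of the chromosome's read ratio.
#'
#' @param counts Wide count tibble.
#' @param panel A [build_reference()] panel.
#' @return Long tibble: `sample_id`, `chrom`, `ratio`, `z`.
#' @export
z_scores <- function(counts, panel) {
  check_panel(panel)
  ratios <- chromosome_ratios(counts)
  miss <- setdiff(unique(ratios$chrom), panel$chrom)
  if (length(miss)) {
    stop("panel lacks chromosome(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  ratios |>
    dplyr::inner_join(panel, by = "chrom") |>
    dplyr::mutate(z = (.data$ratio - .data$mu) / .data$sigma) |>
    dplyr::select("sample_id", "chrom", "ratio", "z")
}

check_panel <- function(panel) {
  req <- c("chrom", "mu", "sigma", "n_reference")
  if (!all(req %in% names(panel))) {
    stop("panel needs columns ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (any(panel$sigma <= 0)) stop("panel sigma must be > 0", call. = FALSE)
  if (any(panel$n_reference < 2)) stop("panel n_reference must be >= 2", call. = FALSE)
  invisible(panel)
}

#' Call chromosomal aneuploidy risk with QC gates
#'
#' The screening decision rule: a chromosome is flagged high risk when its
#' z score is greater than or equal to `z_threshold` (boundary inclusive)
#' and the sample passes QC. QC fails as `insufficient_reads` when the
#' sample has fewer than `min_reads` unique reads, else as `low_ff_alert`
#' when the fetal fraction is known and strictly below `ff_alert` (an
#' alert recommends blood re-collection; no calls are issued). Samples
#' with unknown FF (e.g. female fetuses without an FF model) are not
#' gated on FF.
#'
#' @param counts Wide count tibble.
#' @param panel A [build_reference()] panel.
#' @param ff Fetal fractions: either a single value recycled to all
#'   samples, a vector aligned with `counts` rows, or a tibble with
#'   `sample_id` and `ff`. `NA` means unknown.
#' @param chromosomes Chromosomes to score (default chr13, chr18, chr21).
#' @param z_threshold High-risk threshold (default 3, inclusive).
#' @param min_reads Minimum unique reads (default 1.5e6).
#' @param ff_alert Low-FF alert threshold (default 0.035, exclusive:
#'   FF exactly at the threshold passes).
#' @return Tibble: `sample_id`, `chrom`, `z`, `call`
#'   (`high_risk`/`low_risk`/`no_call`), `qc_status`
#'   (`pass`/`low_ff_alert`/`insufficient_reads`), `ff`.
#' @examples
#' ref <- generate_reference_cohort(50, seed = 1)
#' panel <- build_reference(ref$counts)
#' case <- generate_cohort(cohort_params(1, karyotype = "T21", seed = 2))
#' case$ff <- 0.1
#' calls <- classify_samples(simulate_read_counts(case, seed = 3), panel,
#'                           ff = case$ff)
#' @export
classify_samples <- function(counts, panel, ff = NA_real_,
                             chromosomes = c("chr13", "chr18", "chr21"),
                             z_threshold = 3, min_reads = 1500000,
                             ff_alert = 0.035) {
  check_panel(panel)
  ff_tbl <- normalize_ff(ff, counts)
  totals <- tibble::tibble(sample_id = counts$sample_id,
                           total = rowSums(counts[count_chrom_cols(counts)]))
  zs <- z_scores(counts, panel) |>
    dplyr::filter(.data$chrom %in% chromosomes)
  zs |>
    dplyr::inner_join(totals, by = "sample_id") |>
    dplyr::left_join(ff_tbl, by = "sample_id") |>
    dplyr::mutate(
      qc_status = dplyr::case_when(
        .data$total < min_reads ~ "insufficient_reads",
        !is.na(.data$ff) & .data$ff < ff_alert ~ "low_ff_alert",
        TRUE ~ "pass"
      ),
      call = dplyr::case_when(
        .data$qc_status != "pass" ~ "no_call",
        .data$z >= z_threshold ~ "high_risk",
        TRUE ~ "low_risk"
      )
    ) |>
    dplyr::select("sample_id", "chrom", "z", "call", "qc_status", "ff")
}

normalize_ff <- function(ff, counts) {
  if (is.data.frame(ff)) {
    if (!all(c("sample_id", "ff") %in% names(ff))) {
      stop("`ff` tibble needs `sample_id` and `ff` columns", call. = FALSE)
    }
    return(tibble::as_tibble(ff[, c("sample_id", "ff")]))
  }
  if (length(ff) == 1) ff <- rep(ff, nrow(counts))
  if (length(ff) != nrow(counts)) {
    stop("`ff` must be length 1 or one value per sample", call. = FALSE)
  }
  tibble::tibble(sample_id = counts$sample_id, ff = as.numeric(ff))
}
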