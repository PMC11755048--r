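#' GRCh38 chromosome lengths
#'
#' Named vector of chromosome lengths in bp for chr1-chr22, chrX and chrY
#' (GRCh38 primary assembly). Used to derive the baseline per-chromosome
#' read proportions of the simulator; mappability weighting is deliberately
#' omitted and can be emulated by passing a custom `chromosome_lengths`
#' vector to [seq_params()].
#'
#' @return Named integer-valued numeric vector of length 24.
#' @export
grch38_chromosome_lengths <- function() {
  c(
    chr1 = 248956422, chr2 = 242193529, chr3 = 198295559, chr4 = 190214555,
    chr5 = 181538259, chr6 = 170805979, chr7 = 159345973, chr8 = 145138636,
    chr9 = 138394717, chr10 = 133797422, chr11 = 135086622, chr12 = 133275309,
    chr13 = 114364328, chr14 = 107043718, chr15 = 101991189, chr16 = 90338345,
    chr17 = 83257441, chr18 = 80373285, chr19 = 58617616, chr20 = 64444167,
    chr21 = 46709983, chr22 = 50818468, chrX = 156040895, chrY = 57227415
  )
}

#' Sequencing and simulator parameters
#'
#' Bundles the read budget and noise model of the read-count simulator.
#' Defaults describe the screening protocol modelled throughout the package:
#' 1.5 million unique single-end 45 bp reads per sample (6 bp of which are
#' sample barcode), allocated over chr1-chr22, chrX, chrY in proportion to
#' GRCh38 chromosome length.
#'
#' `overdispersion_cv` is the extra coefficient of variation of a
#' chromosomal ratio beyond multinomial counting noise, implemented as a
#' per-sample gamma jitter of the weight vector. The default (`NULL`) is
#' calibrated at construction time by [calibrate_overdispersion()] so that
#' the expected chr21 z score of a trisomy-21 sample equals 3 at fetal
#' fraction 4.5% under the default read budget, i.e. 50% detection at the
#' midpoint of the 4-5% fetal-fraction bin.
#'
#' @param total_unique_reads Unique reads per sample (default 1.5e6).
#' @param read_length_bp Read length in bp (default 45).
#' @param barcode_length_bp Barcode bp removed before alignment (default 6).
#' @param genome_length_bp Genome size in bp (default 3e9).
#' @param chromosome_lengths Named vector of chromosome lengths; the
#'   multinomial weights are these lengths renormalised.
#' @param chry_female_background chrY weight in a female-fetus pregnancy
#'   (mis-mapping background), as a fraction of reads. Default 5e-4.
#' @param overdispersion_cv Extra ratio CV (unitless), or `NULL` to
#'   calibrate (see above).
#' @return An object of class `seq_params` (a list).
#' @examples
#' sp <- seq_params()
#' sp$overdispersion_cv # calibrated, ~0.0036
#' @export
seq_params <- function(total_unique_reads = 1500000,
                       read_length_bp = 45,
                       barcode_length_bp = 6,
                       genome_length_bp = 3e9,
                       chromosome_lengths = grch38_chromosome_lengths(),
                       chry_female_background = 5e-4,
                       overdispersion_cv = NULL) {
  stopifnot(
    total_unique_reads >= 1,
    read_length_bp > 0, barcode_length_bp >= 0,
    barcode_length_bp < read_length_bp,
    genome_length_bp > 0,
    all(chromosome_lengths > 0),
    chry_female_background >= 0
  )
  if (is.null(names(chromosome_lengths)) || anyNA(names(chromosome_lengths))) {
    stop("`chromosome_lengths` must be a named vector", call. = FALSE)
  }
  if (!"chrY" %in% names(chromosome_lengths)) {
    stop("`chromosome_lengths` must include chrY", call. = FALSE)
  }
  sp <- structure(
    list(
      total_unique_reads = total_unique_reads,
      read_length_bp = read_length_bp,
      barcode_length_bp = barcode_length_bp,
      genome_length_bp = genome_length_bp,
      chromosome_lengths = chromosome_lengths,
      chry_female_background = chry_female_background,
      overdispersion_cv = overdispersion_cv
    ),
    class = "seq_params"
  )
  if (is.null(overdispersion_cv)) {
    sp$overdispersion_cv <- calibrate_overdispersion(sp)
  }
  stopifnot(sp$overdispersion_cv >= 0)
  sp
}

#' @export
print.seq_params <- function(x, ...) {
  cat("<seq_params>\n")
  cat("  unique reads/sample:", format(x$total_unique_reads, big.mark = ","), "\n")
  cat("  read length:", x$read_length_bp, "bp (", x$barcode_length_bp, "bp barcode )\n")
  cat("  chromosomes:", length(x$chromosome_lengths), "\n")
  cat("  overdispersion CV:", signif(x$overdispersion_cv, 4), "\n")
  invisible(x)
}

chrom_names <- function(seq) names(seq$chromosome_lengths)

trisomy_chrom <- function(karyotype) {
  switch(karyotype, T21 = "chr21", T18 = "chr18", T13 = "chr13",
         euploid = NA_character_,
         stop("unknown karyotype: ", karyotype, call. = FALSE))
}

#' Expected chromosome weight vector for one sample
#'
#' The generative model behind the simulator: baseline weights proportional
#' to chromosome length; chrY replaced by `p_Y * ff` for a male fetus (the
#' fetal contribution of one Y per diploid genome-equivalent at fetal
#' fraction `ff`) plus a small female mis-mapping background; the trisomic
#' chromosome lifted by `(1 + ff/2)`; everything renormalised to sum to 1.
#'
#' @param ff Fetal fraction in `[0, 1]`.
#' @param fetal_sex `"male"` or `"female"`.
#' @param karyotype One of `"euploid"`, `"T21"`, `"T18"`, `"T13"`.
#' @param seq A [seq_params()] object.
#' @return Named numeric vector of weights summing to 1.
#' @export
chromosome_weights <- function(ff, fetal_sex = c("female", "male"),
                               karyotype = "euploid", seq = seq_params()) {
  fetal_sex <- match.arg(fetal_sex)
  stopifnot(ff >= 0, ff <= 1)
  p <- seq$chromosome_lengths / sum(seq$chromosome_lengths)
  w <- p
  w[["chrY"]] <- if (fetal_sex == "male") {
    p[["chrY"]] * ff + seq$chry_female_background
  } else {
    seq$chry_female_background
  }
  tc <- trisomy_chrom(karyotype)
  if (!is.na(tc)) {
    if (!tc %in% names(w)) stop("chromosome ", tc, " not in weight vector", call. = FALSE)
    w[[tc]] <- w[[tc]] * (1 + ff / 2)
  }
  w / sum(w)
}

#' Calibrate the inter-run overdispersion of chromosomal ratios
#'
#' Solves for the extra ratio CV such that the expected chr21 z score of a
#' trisomy-21 male-fetus sample equals `target_z` at fetal fraction `ff`,
#' given the read budget. The total ratio SD is modelled as
#' `sqrt(r(1-r)/N + (cv * r * (1-r))^2)` (multinomial counting noise plus
#' gamma weight jitter, with the `(1-r)` renormalisation factor), and the z
#' numerator is the exact renormalised dosage lift. This is the only
#' handle the published limit-of-detection pattern gives on run-to-run
#' variance: 50% detection at the 4-5% bin midpoint.
#'
#' @param seq A [seq_params()] object (its `overdispersion_cv` is ignored).
#' @param target_z Expected z at the calibration point (default 3).
#' @param ff Calibration fetal fraction (default 0.045).
#' @param chrom Chromosome being calibrated (default `"chr21"`).
#' @return The extra CV (unitless scalar).
#' @export
calibrate_overdispersion <- function(seq, target_z = 3, ff = 0.045,
                                     chrom = "chr21") {
  n <- seq$total_unique_reads
  w_eu <- chromosome_weights(ff, "male", "euploid", strip_od(seq))
  w_t21 <- chromosome_weights(ff, "male", "T21", strip_od(seq))
  r0 <- w_eu[[chrom]]
  delta <- w_t21[[chrom]] - r0
  sd_needed <- delta / target_z
  var_multinom <- r0 * (1 - r0) / n
  extra_var <- sd_needed^2 - var_multinom
  if (extra_var <= 0) {
    stop("read budget alone already exceeds the calibration target; ",
         "no non-negative overdispersion solves it", call. = FALSE)
  }
  sqrt(extra_var) / (r0 * (1 - r0))
}

# seq_params copy with overdispersion forced to 0 (avoids recursion in
# calibrate_overdispersion, which only needs the weight vector)
strip_od <- function(seq) {
  seq$overdispersion_cv <- 0
  seq
}

#' Sequencing depth of a low-pass run
#'
#' Fold-coverage implied by a unique-read budget:
#' `reads * (read_length - barcode_length) / genome_length`. With the
#' default protocol (1.5 M unique reads, 45 bp single-end reads carrying a
#' 6 bp barcode, 3 Gb genome) this is 0.0195x.
#'
#' @param unique_reads Unique read count.
#' @param read_length_bp Read length (bp).
#' @param barcode_length_bp Barcode length removed in analysis (bp).
#' @param genome_length_bp Genome length (bp).
#' @return Depth (unitless fold-coverage).
#' @examples
#' sequencing_depth(1.5e6, 45, 6, 3e9) # 0.0195
#' @export
sequencing_depth <- function(unique_reads, read_length_bp = 45,
                             barcode_length_bp = 6, genome_length_bp = 3e9) {
  stopifnot(unique_reads >= 0, read_length_bp > 0, barcode_length_bp >= 0,
            genome_length_bp > 0)
  if (barcode_length_bp >= read_length_bp) {
    stop("`barcode_length_bp` must be smaller than `read_length_bp`", call. = FALSE)
  }
  unique_reads * (read_length_bp - barcode_length_bp) / genome_length_bp
}
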