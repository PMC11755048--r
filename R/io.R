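#' Deterministic child seed
#'
#' Derives per-stage seeds from one top-level seed so that every source of
#' randomness in a pipeline flows from a single integer. Stays within the
#' 32-bit integer range.
#'
#' @param seed Top-level integer seed.
#' @param k Stage index (integer >= 0).
#' @return Integer seed.
#' @export
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + as.double(k) * 16807) %% 2147483647)
}

#' Parse gestational age in "weeks+days" notation
#'
#' `"17+3"` means 17 weeks 3 days, i.e. `17 + 3/7 = 17.4286` decimal
#' weeks; a bare `"16"` is 16.0 weeks. Vectorised.
#'
#' @param x Character vector of gestational ages.
#' @return Numeric decimal weeks.
#' @examples
#' parse_ga(c("17+3", "16")) # 17.42857 16.00000
#' @export
parse_ga <- function(x) {
  parts <- strsplit(as.character(x), "+", fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) == 1) return(as.numeric(p))
    if (length(p) != 2) stop("malformed gestational age: ", paste(p, collapse = "+"),
                             call. = FALSE)
    d <- as.numeric(p[2])
    if (is.na(d) || d < 0 || d >= 7) stop("days must be in 0-6: ", p[2], call. = FALSE)
    as.numeric(p[1]) + d / 7
  }, numeric(1))
}

metadata_schema <- c("sample_id", "ff", "gestational_age_weeks",
                     "maternal_age_years", "maternal_weight_kg",
                     "fetal_sex", "karyotype", "twin")

check_schema <- function(df, required, what) {
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(what, " is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  invisible(df)
}

#' Read and write the pipeline's tab-separated tables
#'
#' Schema-validated TSV round-trips for the pipeline artefacts: sample
#' metadata, per-chromosome count matrices (rows = samples, columns =
#' chr1..chr22, chrX, chrY), reference panels, call tables,
#' limit-of-detection tables, and one-length-per-line fragment files.
#' Read-after-write is the identity on values; a missing column raises an
#' error naming it.
#'
#' @param path File path.
#' @param x Table (or numeric vector for fragment lengths) to write.
#' @param chromosomes Chromosome columns a count matrix must contain.
#' @return Readers return tibbles (or a numeric vector of lengths);
#'   writers return `x` invisibly.
#' @name nipt_io
NULL

#' @rdname nipt_io
#' @export
read_sample_metadata <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  check_schema(df, metadata_schema, "sample metadata")
  df
}

#' @rdname nipt_io
#' @export
write_sample_metadata <- function(x, path) {
  check_schema(x, metadata_schema, "sample metadata")
  readr::write_tsv(x[, metadata_schema], path)
  invisible(x)
}

#' @rdname nipt_io
#' @export
read_count_matrix <- function(path, chromosomes = names(grch38_chromosome_lengths())) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  check_schema(df, c("sample_id", chromosomes), "count matrix")
  df
}

#' @rdname nipt_io
#' @export
write_count_matrix <- function(x, path) {
  check_schema(x, "sample_id", "count matrix")
  readr::write_tsv(x, path)
  invisible(x)
}

#' @rdname nipt_io
#' @export
read_panel <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  check_schema(df, c("chrom", "mu", "sigma", "n_reference"), "panel")
  structure(df, class = c("reference_panel", class(df)))
}

#' @rdname nipt_io
#' @export
write_panel <- function(x, path) {
  check_schema(x, c("chrom", "mu", "sigma", "n_reference"), "panel")
  readr::write_tsv(tibble::as_tibble(x), path)
  invisible(x)
}

#' @rdname nipt_io
#' @export
read_calls <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  check_schema(df, c("sample_id", "chrom", "z", "call", "qc_status"), "call table")
  df
}

#' @rdname nipt_io
#' @export
write_calls <- function(x, path) {
  check_schema(x, c("sample_id", "chrom", "z", "call", "qc_status"), "call table")
  readr::write_tsv(x, path)
  invisible(x)
}

#' @rdname nipt_io
#' @export
read_lod_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  check_schema(df, c("bin", "bin_lo", "bin_hi", "n_replicates", "n_detected",
                     "detection_rate_pct"), "LoD table")
  structure(df, class = c("lod_table", class(df)))
}

#' @rdname nipt_io
#' @export
write_lod_table <- function(x, path) {
  check_schema(x, c("bin", "bin_lo", "bin_hi", "n_replicates", "n_detected",
                    "detection_rate_pct"), "LoD table")
  readr::write_tsv(tibble::as_tibble(x), path)
  invisible(x)
}

#' @rdname nipt_io
#' @export
read_fragment_lengths <- function(path) {
  as.numeric(readr::read_lines(path))
}

#' @rdname nipt_io
#' @export
write_fragment_lengths <- function(x, path) {
  readr::write_lines(format(x, scientific = FALSE, trim = TRUE), path)
  invisible(x)
}

#' Load the packaged trisomy-21 outcome table
#'
#' The 17 published clinical T21 results shipped with the package: 14 true
#' positives, 2 false positives and 1 false negative, each with maternal
#' age, gestational age (weeks+days, also parsed to decimal weeks), the
#' chr21 z value, and the fetal fraction in percent. The minimum FF among
#' the true positives is 4.88%; the single false negative (later explained
#' by confined placental mosaicism) sits at z = 1.78 with FF 8.13%.
#'
#' @return Tibble: `case_index`, `status`, `age_years`,
#'   `gestational_age`, `ga_weeks`, `z`, `ff_pct`.
#' @examples
#' t21 <- load_table2()
#' min(t21$ff_pct[t21$status == "true_positive"]) # 4.88
#' @export
load_table2 <- function() {
  path <- system.file("extdata", "t21_outcomes.tsv", package = "niptsim",
                      mustWork = TRUE)
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(gestational_age = "c"))
  check_schema(df, c("case_index", "status", "age_years", "gestational_age",
                     "z", "ff_pct"), "T21 outcome fixture")
  df$ga_weeks <- parse_ga(df$gestational_age)
  df[, c("case_index", "status", "age_years", "gestational_age", "ga_weeks",
         "z", "ff_pct")]
}

#' Read a pipeline configuration file
#'
#' JSON configuration with a mandatory top-level `seed`. Unknown keys are
#' preserved; known blocks (`sequencing`, `cohort`) are passed to the
#' corresponding constructors by the caller.
#'
#' @param path Path to a JSON config file.
#' @return Named list.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$seed)) stop("config must set `seed`", call. = FALSE)
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1) {
    stop("config `seed` must be a single integer", call. = FALSE)
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg
}
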