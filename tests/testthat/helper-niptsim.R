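# Shared test fixtures, built in code.

# Reduced read budget for tests that only need the mechanics, not the
# default protocol's power. The default calibration is unsolvable at small
# budgets (counting noise alone exceeds the target), so the jitter CV is
# set explicitly.
test_seq <- function(total_unique_reads = 2e5, overdispersion_cv = 0.003) {
  seq_params(total_unique_reads = total_unique_reads,
             overdispersion_cv = overdispersion_cv)
}

# Tiny deterministic count table for IO / ratio arithmetic.
toy_counts <- function() {
  chroms <- names(grch38_chromosome_lengths())
  m <- matrix(1000, nrow = 3, ncol = length(chroms),
              dimnames = list(NULL, chroms))
  m[1, "chr21"] <- 1500
  m[2, "chrY"] <- 40
  dplyr::bind_cols(tibble::tibble(sample_id = c("a", "b", "c")),
                   tibble::as_tibble(m))
}

# T21 cohort tibble at given fetal fractions (no metadata noise).
t21_samples <- function(ff, fetal_sex = "male") {
  tibble::tibble(
    sample_id = sprintf("T%05d", seq_along(ff)),
    ff = ff,
    fetal_sex = rep_len(fetal_sex, length(ff)),
    karyotype = "T21"
  )
}
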