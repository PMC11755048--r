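#' Fragment-length histogram
#'
#' Bins integer fragment lengths at a fixed width (default 1 bp, the
#' in-silico analogue of a capillary-electrophoresis trace). Counts
#' partition the sample exactly for any bin width.
#'
#' @param lengths_bp Vector of positive fragment lengths (bp).
#' @param bin_bp Bin width in bp (default 1).
#' @return Tibble of class `size_histogram`: `bin_lo`, `bin_hi`,
#'   `bin_mid`, `count`. Bins are half-open `[lo, hi)`. Total is stored
#'   in the `total` attribute.
#' @examples
#' h <- size_histogram(simulate_fragment_lengths(1, 10000, seed = 1))
#' histogram_mode(h)
#' @export
size_histogram <- function(lengths_bp, bin_bp = 1) {
  if (length(lengths_bp) == 0) stop("empty length sample", call. = FALSE)
  stopifnot(all(lengths_bp > 0), bin_bp >= 1)
  lo <- floor(min(lengths_bp) / bin_bp) * bin_bp
  hi <- floor(max(lengths_bp) / bin_bp) * bin_bp + bin_bp
  edges <- seq(lo, hi, by = bin_bp)
  idx <- findInterval(lengths_bp, edges, rightmost.closed = FALSE)
  cnt <- tabulate(idx, nbins = length(edges) - 1)
  out <- tibble::tibble(
    bin_lo = edges[-length(edges)],
    bin_hi = edges[-1],
    bin_mid = edges[-length(edges)] + (bin_bp - 1) / 2,
    count = cnt
  )
  structure(out, total = length(lengths_bp), bin_bp = bin_bp,
            class = c("size_histogram", class(out)))
}

#' Modal fragment length of a histogram
#'
#' Centre of the bin with the maximal count (at 1 bp bins: the most
#' frequent integer length). Ties resolve to the shortest bin.
#'
#' @param hist A [size_histogram()].
#' @return Length in bp (scalar).
#' @export
histogram_mode <- function(hist) {
  stopifnot(inherits(hist, "size_histogram"))
  hist$bin_mid[which.max(hist$count)]
}

#' Zone area ratio of a fragment-size histogram
#'
#' Fraction of fragments whose length falls inside a size window
#' (inclusive on both ends). The default zone, 120-155 bp, brackets the
#' 143 bp fetal mode while excluding the 166 bp maternal mode, so the
#' ratio grows with fetal fraction.
#'
#' @param hist A [size_histogram()].
#' @param zone Length-2 numeric window in bp (default `c(120, 155)`).
#' @return Fraction in `[0, 1]` (0 with a warning when the zone misses the
#'   histogram's support).
#' @export
zone_area_ratio <- function(hist, zone = c(120, 155)) {
  stopifnot(inherits(hist, "size_histogram"), length(zone) == 2,
            zone[1] <= zone[2])
  inside <- hist$bin_lo >= zone[1] & hist$bin_hi - 1 <= zone[2]
  if (!any(inside & hist$count > 0)) {
    warning("zone does not intersect the histogram support", call. = FALSE)
  }
  sum(hist$count[inside]) / attr(hist, "total")
}
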