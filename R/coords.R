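#' Coordinate conventions
#'
#' All genomic intervals inside the package are 0-based half-open
#' (`start` inclusive, `end` exclusive), the BED convention.  Files that
#' print human-readable coordinates (panel manifests, VCF positions) are
#' 1-based inclusive and are converted exactly once, at the IO boundary.
#'
#' `from_printed()` converts a printed 1-based inclusive pair `[a, b]` to
#' `[a - 1, b)`; `to_printed()` inverts it.  Length is preserved:
#' `b - a + 1 == end - start`.
#'
#' @param start,end integer vectors, one interval per element.
#' @return A list with integer vectors `start` and `end`.
#' @examples
#' from_printed(38597041, 38597372)  # list(start = 38597040, end = 38597372)
#' @export
from_printed <- function(start, end) {
  list(start = as.integer(start) - 1L, end = as.integer(end))
}

#' @rdname from_printed
#' @export
to_printed <- function(start, end) {
  list(start = as.integer(start) + 1L, end = as.integer(end))
}

# Validate a set of parallel interval columns (0-based half-open).
check_intervals <- function(contig, start, end, what = "interval") {
  bad <- which(!nzchar(contig) | is.na(start) | is.na(end) |
                 start < 0L | start >= end)
  if (length(bad)) {
    stop(sprintf("invalid %s at row %d: need non-empty contig and 0 <= start < end",
                 what, bad[1]), call. = FALSE)
  }
  invisible(TRUE)
}

# Round half away from zero (commercial rounding).  Base round() does
# banker's rounding, which would print 0.765 -> 0.76; panel percentages
# follow the half-up convention.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# GRanges from internal 0-based half-open columns (GRanges is 1-based
# inclusive internally).
granges0 <- function(contig, start, end) {
  GenomicRanges::GRanges(contig, IRanges::IRanges(start = start + 1L, end = end))
}
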