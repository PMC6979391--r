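#' Genomic interval (0-based, half-open)
#'
#' All coordinates inside the package are 0-based, half-open, on the forward
#' strand of the named chromosome; conversions from 1-based inclusive formats
#' (RepeatMasker) happen at the I/O boundary only.
#'
#' @param chrom Chromosome name.
#' @param start 0-based inclusive start offset.
#' @param end Exclusive end offset; must exceed `start`.
#' @param strand One of `"+"`, `"-"`, `"."`.
#' @return An object of class `"gi"`.
#' @export
gi <- function(chrom, start, end, strand = ".") {
  stopifnot(is.character(chrom), length(chrom) == 1L,
            length(start) == 1L, length(end) == 1L,
            strand %in% c("+", "-", "."))
  start <- as.numeric(start); end <- as.numeric(end)
  if (is.na(start) || is.na(end) || start < 0 || start >= end)
    stop("invalid interval: require 0 <= start < end, got [", start, ", ", end, ")")
  structure(list(chrom = chrom, start = start, end = end, strand = strand),
            class = "gi")
}

#' @export
print.gi <- function(x, ...) {
  cat(sprintf("%s:%d-%d(%s)\n", x$chrom, x$start, x$end, x$strand))
  invisible(x)
}

#' Interval length in bp
#' @param x A [gi()] interval.
#' @return Numeric length `end - start`.
#' @export
gi_length <- function(x) x$end - x$start

#' Interval midpoint
#' @param x A [gi()] interval.
#' @return Numeric midpoint `(start + end) / 2`.
#' @export
gi_midpoint <- function(x) (x$start + x$end) / 2

#' Overlap in bp between two intervals (0 when on different chromosomes)
#' @param a,b [gi()] intervals.
#' @return Non-negative numeric overlap width.
#' @export
gi_overlap <- function(a, b) {
  if (a$chrom != b$chrom) return(0)
  max(0, min(a$end, b$end) - max(a$start, b$start))
}

# Vectorized overlap of one interval against columns of a data.frame
# (chrom/start/end). Returns numeric vector of overlap widths.
overlap_widths <- function(chrom, start, end, df,
                           cols = c("chrom", "start", "end")) {
  same <- df[[cols[1]]] == chrom
  w <- pmax(0, pmin(df[[cols[3]]], end) - pmax(df[[cols[2]]], start))
  w[!same] <- 0
  w
}
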