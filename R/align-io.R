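# Repeat-to-consensus alignment blocks (.align). The dialect is a
# simplified RepeatMasker alignment layout: a one-line header per element
# followed by interleaved genomic/consensus sequence lines (wrapped), a
# blank line terminating each block. Coordinates in the file are 1-based
# inclusive and converted at the boundary.
#
# Header: score div del ins chrom begin end (left) [C] subfam#class/family
#         cbegin cend (cleft) element_id
# Sequence line: "  name  start  ALIGNEDSEQ  end"

#' Read repeat-to-consensus alignments
#'
#' @param path Path to an `.align` file (see the package vignette for the
#'   dialect).
#' @return A list of alignment records; each is a list with `element_id`,
#'   `consensus_id`, `chrom`, `start`, `end` (0-based half-open), `strand`,
#'   `g_aligned`, `c_aligned` (equal-length aligned strings, gaps as `-`).
#' @export
read_align <- function(path) {
  lines <- readLines(path)
  records <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    if (startsWith(lines[i], " "))
      stop("expected alignment header at line ", i, " of ", path)
    h <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    strand <- "+"
    if (length(h) >= 9L && h[9L] == "C") { strand <- "-"; h <- h[-9L] }
    if (length(h) < 12L) stop("short alignment header at line ", i)
    chrom <- h[5L]; begin1 <- as.numeric(h[6L]); end1 <- as.numeric(h[7L])
    name_tok <- strsplit(h[9L], "#", fixed = TRUE)[[1L]]
    consensus_id <- name_tok[1L]
    element_id <- h[13L]
    i <- i + 1L
    g_chunks <- character(); c_chunks <- character()
    while (i <= n && startsWith(lines[i], " ")) {
      p <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
      if (length(p) != 4L) stop("malformed sequence line at line ", i)
      if (p[1L] == chrom) g_chunks <- c(g_chunks, p[3L])
      else if (p[1L] == consensus_id) c_chunks <- c(c_chunks, p[3L])
      else stop("sequence line names neither genome nor consensus at line ", i)
      i <- i + 1L
    }
    g <- paste(g_chunks, collapse = "")
    c_ <- paste(c_chunks, collapse = "")
    if (nchar(g) != nchar(c_))
      stop("aligned sequences differ in length for element ", element_id)
    records[[length(records) + 1L]] <- list(
      element_id = element_id, consensus_id = consensus_id,
      chrom = chrom, start = begin1 - 1, end = end1, strand = strand,
      g_aligned = toupper(g), c_aligned = toupper(c_))
  }
  records
}

#' Write repeat-to-consensus alignments
#' @param records List of alignment records (see [read_align()]).
#' @param path Output path.
#' @param width Wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_align <- function(records, path, width = 50L) {
  out <- character()
  for (r in records) {
    g <- r$g_aligned; c_ <- r$c_aligned
    glen <- sum(strsplit(g, "")[[1L]] != "-")
    clen <- sum(strsplit(c_, "")[[1L]] != "-")
    strand_tok <- if (identical(r$strand, "-")) "C " else ""
    hdr <- sprintf("225 0.00 0.00 0.00 %s %d %d (0) %s%s#Unknown %d %d (0) %s",
                   r$chrom, r$start + 1, r$end, strand_tok,
                   r$consensus_id, 1L, clen, r$element_id)
    out <- c(out, hdr)
    gpos <- r$start  # 0-based, will print 1-based
    cpos <- 0
    for (off in seq(1L, nchar(g), by = width)) {
      gseq <- substr(g, off, min(off + width - 1L, nchar(g)))
      cseq <- substr(c_, off, min(off + width - 1L, nchar(c_)))
      g_n <- sum(strsplit(gseq, "")[[1L]] != "-")
      c_n <- sum(strsplit(cseq, "")[[1L]] != "-")
      out <- c(out,
               sprintf("  %-12s %8d %s %d", r$chrom, gpos + 1, gseq, gpos + g_n),
               sprintf("  %-12s %8d %s %d", r$consensus_id, cpos + 1, cseq,
                       cpos + c_n))
      gpos <- gpos + g_n
      cpos <- cpos + c_n
    }
    out <- c(out, "")
  }
  writeLines(out, path)
  invisible(path)
}
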