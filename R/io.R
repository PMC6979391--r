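# Readers/writers for the interchange formats the pipeline touches.
# Internal convention: 0-based half-open coordinates everywhere; 1-based
# inclusive formats (RepeatMasker .out/.align) are converted on read and
# restored on write.

.known_repeat_classes <- c("SINE", "LINE", "LTR", "DNA")

.split_class_family <- function(token) {
  parts <- strsplit(token, "/", fixed = TRUE)
  cls <- vapply(parts, `[`, "", 1L)
  fam <- vapply(parts, function(p) if (length(p) >= 2L) p[2L] else p[1L], "")
  unknown <- !(cls %in% .known_repeat_classes)
  if (any(unknown)) {
    warning("unknown repeat class token(s): ",
            paste(unique(cls[unknown]), collapse = ", "),
            "; recorded as 'other'", call. = FALSE)
    cls[unknown] <- "other"
  }
  list(class = cls, family = fam)
}

#' Read a RepeatMasker .out annotation
#'
#' Parses the standard whitespace-delimited RepeatMasker `.out` layout
#' (3 header lines, 14-15 columns). 1-based inclusive coordinates are
#' converted to 0-based half-open; strand `"C"` is mapped to `"-"`;
#' the class/family column is split into class and family, with unknown
#' class tokens recorded as `"other"` (with a warning).
#'
#' @param path Path to a RepeatMasker `.out` file.
#' @return A data.frame of repeat elements with columns `chrom`, `start`,
#'   `end`, `strand`, `subfamily`, `family`, `class`, `pct_div`,
#'   `element_id`, `consensus_id`.
#' @export
read_repeatmasker_out <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L)
    stop("RepeatMasker .out file must have 3 header lines: ", path)
  body <- lines[-(1:3)]
  body <- body[nzchar(trimws(body))]
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      strand = character(), subfamily = character(),
                      family = character(), class = character(),
                      pct_div = numeric(), element_id = character(),
                      consensus_id = character(), stringsAsFactors = FALSE)
  if (length(body) == 0L) return(empty)
  rows <- strsplit(trimws(body), "\\s+")
  nf <- lengths(rows)
  bad <- which(nf < 14L)
  if (length(bad))
    stop("malformed RepeatMasker row at line ", bad[1L] + 3L, ": ",
         body[bad[1L]])
  get <- function(i) vapply(rows, `[`, "", i)
  begin1 <- suppressWarnings(as.numeric(get(6L)))
  end1 <- suppressWarnings(as.numeric(get(7L)))
  pct_div <- suppressWarnings(as.numeric(get(2L)))
  bad <- which(is.na(begin1) | is.na(end1) | is.na(pct_div))
  if (length(bad))
    stop("malformed RepeatMasker row at line ", bad[1L] + 3L, ": ",
         body[bad[1L]])
  strand <- get(9L)
  strand[strand == "C"] <- "-"
  if (!all(strand %in% c("+", "-")))
    stop("malformed strand in RepeatMasker .out (expected + or C)")
  cf <- .split_class_family(get(11L))
  id_col <- ifelse(nf >= 15L, vapply(rows, function(r) r[15L], ""), as.character(seq_along(rows)))
  out <- data.frame(
    chrom = get(5L), start = begin1 - 1, end = end1, strand = strand,
    subfamily = get(10L), family = cf$family, class = cf$class,
    pct_div = pct_div,
    element_id = paste0(get(10L), "|", get(5L), ":", begin1 - 1, "-", end1,
                        "|", id_col),
    consensus_id = get(10L), stringsAsFactors = FALSE)
  if (any(out$start < 0 | out$start >= out$end))
    stop("invalid repeat coordinates in ", path)
  out
}

#' Write repeats in RepeatMasker .out layout
#' @param repeats Data.frame as returned by [read_repeatmasker_out()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_repeatmasker_out <- function(repeats, path) {
  hdr <- c(
    "   SW   perc perc perc  query     position in query              matching  repeat        position in repeat",
    "score   div. del. ins.  sequence  begin end    (left)   strand   repeat    class/family  begin end    (left)  ID",
    "")
  fam_tok <- ifelse(repeats$class == repeats$family, repeats$class,
                    paste0(repeats$class, "/", repeats$family))
  id_tok <- sub("^.*\\|", "", repeats$element_id)
  rows <- sprintf("  225 %5.1f  0.0  0.0  %s %d %d (0) %s %s %s 1 100 (0) %s",
                  repeats$pct_div, repeats$chrom, repeats$start + 1,
                  repeats$end, ifelse(repeats$strand == "-", "C", "+"),
                  repeats$subfamily, fam_tok, id_tok)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

.loop_columns <- c("loop_id", "chrom", "start1", "end1", "start2", "end2",
                   "motif1_start", "motif1_end", "motif1_strand",
                   "motif2_start", "motif2_end", "motif2_strand",
                   "origin1", "subfamily1", "element_id1",
                   "origin2", "subfamily2", "element_id2")

.empty_loops <- function() {
  df <- data.frame(loop_id = character(), chrom = character(),
                   start1 = numeric(), end1 = numeric(),
                   start2 = numeric(), end2 = numeric(),
                   motif1_start = numeric(), motif1_end = numeric(),
                   motif1_strand = character(),
                   motif2_start = numeric(), motif2_end = numeric(),
                   motif2_strand = character(),
                   origin1 = character(), subfamily1 = character(),
                   element_id1 = character(),
                   origin2 = character(), subfamily2 = character(),
                   element_id2 = character(), stringsAsFactors = FALSE)
  df
}

#' Read chromatin loops from a BEDPE-style file
#'
#' Tab-delimited BEDPE: `chrom1 start1 end1 chrom2 start2 end2 name score
#' strand1 strand2`, optionally followed by eight motif columns
#' (`motif1_chrom motif1_start motif1_end motif1_strand` and the same for
#' motif 2; `"."` marks an absent motif). Interchromosomal records are
#' skipped with a warning; duplicated loop ids are an error. Loops are
#' returned sorted by `(chrom, start1)`, anchors ordered left-to-right,
#' with anchor origins initialised to `"unidentified"`.
#'
#' @param path Path to a BEDPE file (lines starting with `#` are ignored).
#' @return A loop data.frame (one row per loop).
#' @export
read_loops_bedpe <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(.empty_loops())
  rows <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(rows)
  if (any(nf < 7L)) stop("BEDPE rows need at least 7 columns")
  get <- function(i) vapply(rows, function(r) if (length(r) >= i) r[i] else ".", "")
  chrom1 <- get(1L); chrom2 <- get(4L)
  inter <- chrom1 != chrom2
  if (any(inter)) {
    warning(sum(inter), " interchromosomal loop record(s) skipped",
            call. = FALSE)
  }
  keep <- !inter
  if (!any(keep)) return(.empty_loops())
  num <- function(v) suppressWarnings(as.numeric(v))
  opt_num <- function(v) { v[v == "."] <- NA; num(v) }
  opt_chr <- function(v) { v[v == "."] <- NA; v }
  s1 <- num(get(2L))[keep]; e1 <- num(get(3L))[keep]
  s2 <- num(get(5L))[keep]; e2 <- num(get(6L))[keep]
  df <- data.frame(
    loop_id = get(7L)[keep], chrom = chrom1[keep],
    start1 = s1, end1 = e1, start2 = s2, end2 = e2,
    motif1_start = opt_num(get(12L))[keep], motif1_end = opt_num(get(13L))[keep],
    motif1_strand = opt_chr(get(14L))[keep],
    motif2_start = opt_num(get(16L))[keep], motif2_end = opt_num(get(17L))[keep],
    motif2_strand = opt_chr(get(18L))[keep],
    stringsAsFactors = FALSE)
  # enforce left anchor upstream of right anchor
  flip <- df$start1 > df$start2
  if (any(flip)) {
    tmp <- df[flip, c("start1", "end1", "motif1_start", "motif1_end", "motif1_strand")]
    df[flip, c("start1", "end1", "motif1_start", "motif1_end", "motif1_strand")] <-
      df[flip, c("start2", "end2", "motif2_start", "motif2_end", "motif2_strand")]
    df[flip, c("start2", "end2", "motif2_start", "motif2_end", "motif2_strand")] <- tmp
  }
  if (anyDuplicated(df$loop_id))
    stop("duplicate loop_id in ", path, ": ",
         df$loop_id[duplicated(df$loop_id)][1L])
  if (any(df$end1 > df$start2))
    stop("overlapping anchors in loop ",
         df$loop_id[which(df$end1 > df$start2)[1L]])
  df$origin1 <- ifelse(is.na(df$motif1_start), "unidentified", "unidentified")
  df$subfamily1 <- NA_character_; df$element_id1 <- NA_character_
  df$origin2 <- "unidentified"
  df$subfamily2 <- NA_character_; df$element_id2 <- NA_character_
  df <- df[order(df$chrom, df$start1), , drop = FALSE]
  rownames(df) <- NULL
  df[, .loop_columns]
}

#' Write loops to BEDPE
#' @param loops Loop data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_loops_bedpe <- function(loops, path) {
  dot <- function(v) ifelse(is.na(v), ".", format(v, scientific = FALSE, trim = TRUE))
  lines <- paste(loops$chrom, dot(loops$start1), dot(loops$end1),
                 loops$chrom, dot(loops$start2), dot(loops$end2),
                 loops$loop_id, "0", ".", ".",
                 ifelse(is.na(loops$motif1_start), ".", loops$chrom),
                 dot(loops$motif1_start), dot(loops$motif1_end),
                 dot(loops$motif1_strand),
                 ifelse(is.na(loops$motif2_start), ".", loops$chrom),
                 dot(loops$motif2_start), dot(loops$motif2_end),
                 dot(loops$motif2_strand), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Loop length (anchor midpoint distance)
#' @param loops Loop data.frame.
#' @return Numeric vector of midpoint distances in bp.
#' @export
loop_length <- function(loops) {
  (loops$start2 + loops$end2) / 2 - (loops$start1 + loops$end1) / 2
}

#' Read a UCSC chain file
#'
#' Chains map the *source* genome (the `t` fields of the header, as in
#' liftOver over.chain files) to the *target* genome (`q` fields).
#' Negative-strand target blocks are pre-flipped to forward-strand target
#' coordinates at read time; the orientation is kept as a flag.
#'
#' @param path Path to a chain file.
#' @return An object of class `chain_map`: a list of chains, each with
#'   `score`, `s_chrom`, `s_size`, `t_chrom`, `t_size`, `t_strand` and a
#'   `blocks` data.frame (`s_start`, `t_start` forward-strand, `size`).
#' @export
read_chain <- function(path) {
  lines <- readLines(path)
  chains <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) { i <- i + 1L; next }
    if (!startsWith(ln, "chain "))
      stop("expected chain header at line ", i, " of ", path)
    h <- strsplit(ln, "\\s+")[[1L]]
    if (length(h) < 12L) stop("short chain header at line ", i)
    score <- as.numeric(h[2L])
    s_chrom <- h[3L]; s_size <- as.numeric(h[4L])
    s_strand <- h[5L]; s_start <- as.numeric(h[6L]); s_end <- as.numeric(h[7L])
    t_chrom <- h[8L]; t_size <- as.numeric(h[9L])
    t_strand <- h[10L]; t_start <- as.numeric(h[11L]); t_end <- as.numeric(h[12L])
    if (s_strand != "+") stop("source strand must be + in chain files")
    sizes <- numeric(); dts <- numeric(); dqs <- numeric()
    i <- i + 1L
    repeat {
      if (i > length(lines)) stop("truncated chain block in ", path)
      parts <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
      i <- i + 1L
      if (length(parts) == 1L && nzchar(parts)) {
        sizes <- c(sizes, as.numeric(parts)); dts <- c(dts, NA); dqs <- c(dqs, NA)
        break
      }
      if (length(parts) != 3L) stop("malformed chain block line in ", path)
      sizes <- c(sizes, as.numeric(parts[1L]))
      dts <- c(dts, as.numeric(parts[2L]))
      dqs <- c(dqs, as.numeric(parts[3L]))
    }
    n <- length(sizes)
    s_starts <- s_start + c(0, cumsum(sizes[-n] + dts[-n]))
    tq_starts <- t_start + c(0, cumsum(sizes[-n] + dqs[-n]))
    if (s_starts[n] + sizes[n] != s_end)
      stop("chain block sizes do not sum to source span in ", path)
    if (tq_starts[n] + sizes[n] != t_end)
      stop("chain block sizes do not sum to target span in ", path)
    t_fwd <- if (t_strand == "+") tq_starts else t_size - (tq_starts + sizes)
    blocks <- data.frame(s_start = s_starts, t_start = t_fwd, size = sizes)
    chains[[length(chains) + 1L]] <- list(
      score = score, s_chrom = s_chrom, s_size = s_size,
      s_start = s_start, s_end = s_end,
      t_chrom = t_chrom, t_size = t_size, t_strand = t_strand,
      blocks = blocks)
  }
  structure(list(chains = chains), class = "chain_map")
}

#' Write a chain_map to UCSC chain format
#' @param cm A `chain_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chain <- function(cm, path) {
  stopifnot(inherits(cm, "chain_map"))
  out <- character()
  for (k in seq_along(cm$chains)) {
    ch <- cm$chains[[k]]
    b <- ch$blocks
    n <- nrow(b)
    tq_start <- if (ch$t_strand == "+") b$t_start else ch$t_size - (b$t_start + b$size)
    ord <- order(b$s_start)
    b <- b[ord, ]; tq_start <- tq_start[ord]
    hdr <- sprintf("chain %s %s %s + %s %s %s %s %s %s %s %d",
                   format(ch$score, scientific = FALSE),
                   ch$s_chrom, format(ch$s_size, scientific = FALSE),
                   format(b$s_start[1L], scientific = FALSE),
                   format(b$s_start[n] + b$size[n], scientific = FALSE),
                   ch$t_chrom, format(ch$t_size, scientific = FALSE),
                   ch$t_strand,
                   format(tq_start[1L], scientific = FALSE),
                   format(tq_start[n] + b$size[n], scientific = FALSE), k)
    body <- character(n)
    if (n > 1L) {
      dt <- b$s_start[-1L] - (b$s_start[-n] + b$size[-n])
      dq <- tq_start[-1L] - (tq_start[-n] + b$size[-n])
      body[seq_len(n - 1L)] <- paste(b$size[-n], dt, dq, sep = "\t")
    }
    body[n] <- as.character(b$size[n])
    out <- c(out, hdr, body, "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Read an ENCODE narrowPeak file
#' @param path Path to a 10-column narrowPeak BED file.
#' @return Data.frame with `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`, `signal`, `pvalue`, `qvalue`, `summit` (offset, -1 if absent).
#' @export
read_narrowpeak <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "name",
                                        "score", "strand", "signal",
                                        "pvalue", "qvalue", "summit"))
  df
}

#' Write a narrowPeak file
#' @param peaks Data.frame as from [read_narrowpeak()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  utils::write.table(peaks, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a methylation bedGraph
#'
#' Four columns `chrom start end fraction`, with an optional fifth
#' `coverage` column (defaults to 1). Records are sorted by position;
#' fractions outside `[0, 1]` or duplicated positions are an error.
#'
#' @param path Path to a bedGraph file.
#' @return Data.frame `chrom`, `start`, `end`, `fraction`, `coverage`.
#' @export
read_bedgraph <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) < 4L) stop("bedGraph needs at least 4 columns")
  names(df)[1:4] <- c("chrom", "start", "end", "fraction")
  df$coverage <- if (ncol(df) >= 5L) df[[5L]] else 1L
  df <- df[, c("chrom", "start", "end", "fraction", "coverage")]
  if (any(df$fraction < 0 | df$fraction > 1))
    stop("methylation fractions must lie in [0, 1]")
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  if (any(duplicated(df[, c("chrom", "start")])))
    stop("duplicated methylation positions in ", path)
  rownames(df) <- NULL
  df
}

#' Write a methylation bedGraph (with coverage column)
#' @param track Data.frame as from [read_bedgraph()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  utils::write.table(track, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
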