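# TE-mediated CTCF binding-site turnover among orthologous loops, candidate
# filtering against the local ChIP landscape, and the motif-orientation
# contingency statistics.

#' Pearson chi-square test on a 2x2 table (no continuity correction)
#'
#' Closed form `N (ad - bc)^2 / (r1 r2 c1 c2)` with df = 1; the p-value is
#' the upper tail of chi-square(1). No Yates correction is applied.
#'
#' @param counts 2x2 matrix of non-negative counts.
#' @return List `chi2`, `p` (`p` is `NA` when a margin is zero), and
#'   `low_count` flag (TRUE when any margin is zero).
#' @export
pearson_chi2 <- function(counts) {
  stopifnot(is.matrix(counts), all(dim(counts) == c(2L, 2L)),
            all(counts >= 0))
  n <- sum(counts)
  if (n == 0) stop("empty table")
  r <- rowSums(counts); c_ <- colSums(counts)
  low <- any(r == 0) || any(c_ == 0)
  if (low) return(list(chi2 = 0, p = NA_real_, low_count = TRUE))
  chi2 <- n * (counts[1, 1] * counts[2, 2] - counts[1, 2] * counts[2, 1])^2 /
    prod(r, c_)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       low_count = FALSE)
}

#' Detect TE-mediated loop-anchor turnover events
#'
#' For each orthologous loop pair, an anchor of the species-A loop yields a
#' turnover event when (i) its CTCF motif is RE-derived, (ii) the
#' underlying TE locus is species-specific — its interval lifts to the B
#' genome with a matched fraction below `specific_max_frac`, or lifts to a
#' region carrying no repeat of the same family — and (iii) the matched B
#' anchor's motif does not fall inside an orthologous copy of that TE.
#' A loop can contribute up to two events (one per anchor side).
#'
#' @param calls Orthology calls ([loop_orthology()]).
#' @param loops_a,loops_b Annotated loop data.frames for the two species.
#' @param repeats_a,repeats_b Repeat data.frames for the two genomes.
#' @param chain_ab Chain lifting A coordinates to B.
#' @param specific_max_frac TE lift fraction below which the locus counts
#'   as species-specific (default 0.1).
#' @return Data.frame of events: `loop_a`, `loop_b`, `side`, `element_id`,
#'   `subfamily`, `orientation`, `anchor_key`, `species_specific`.
#' @export
detect_turnover <- function(calls, loops_a, loops_b, repeats_a, repeats_b,
                            chain_ab, specific_max_frac = 0.1) {
  if (is.null(chain_ab)) stop("chain required for species-specificity test")
  empty <- data.frame(loop_a = character(), loop_b = character(),
                      side = character(), element_id = character(),
                      subfamily = character(), orientation = character(),
                      anchor_key = character(), species_specific = logical(),
                      stringsAsFactors = FALSE)
  res <- list()
  for (k in seq_len(nrow(calls))) {
    ra <- loops_a[loops_a$loop_id == calls$loop_a[k], , drop = FALSE]
    rb <- loops_b[loops_b$loop_id == calls$loop_b[k], , drop = FALSE]
    if (nrow(ra) != 1L || nrow(rb) != 1L) next
    for (side in 1:2) {
      if (ra[[paste0("origin", side)]] != "RE_derived") next
      te <- repeats_a[repeats_a$element_id == ra[[paste0("element_id", side)]], ,
                      drop = FALSE]
      if (nrow(te) != 1L) next
      lift <- lift_interval(chain_ab, gi(te$chrom, te$start, te$end),
                            min_match = 1e-9)
      specific <- lift$matched_fraction < specific_max_frac
      b_motif_in_ortholog <- FALSE
      if (!specific) {
        # the TE locus lifts: look for a same-family repeat at the lifted locus
        w <- overlap_widths(lift$mapped$chrom, lift$mapped$start,
                            lift$mapped$end, repeats_b)
        same_fam <- w > 0 & repeats_b$family == te$family
        specific <- !any(same_fam)
        bms <- rb[[paste0("motif", side, "_start")]]
        if (!specific && !is.na(bms)) {
          bme <- rb[[paste0("motif", side, "_end")]]
          wm <- overlap_widths(rb$chrom, bms, bme, repeats_b)
          b_motif_in_ortholog <- any(same_fam & wm > 0)
        }
      }
      if (!specific || b_motif_in_ortholog) next
      ms <- ra[[paste0("motif", side, "_start")]]
      me <- ra[[paste0("motif", side, "_end")]]
      res[[length(res) + 1L]] <- data.frame(
        loop_a = ra$loop_id, loop_b = rb$loop_id,
        side = c("left", "right")[side],
        element_id = te$element_id, subfamily = te$subfamily,
        orientation = ra[[paste0("motif", side, "_strand")]],
        anchor_key = paste0(ra$chrom, ":", ms, "-", me),
        species_specific = TRUE, stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Filter turnover candidates against the local CTCF ChIP landscape
#'
#' Classifies events by the number of *other* CTCF peaks within `window`
#' bp of the turnover anchor: zero others gives class `"replacement"`
#' (the TE site is the only local anchor candidate); exactly one other
#' peak that overlaps an annotated ancestral site gives `"redundant"`;
#' anything else is dropped.
#'
#' @param events Turnover events ([detect_turnover()]).
#' @param chip_peaks narrowPeak data.frame for species A.
#' @param ancestral_sites Data.frame `chrom`, `start`, `end` of annotated
#'   ancestral motif positions (may have zero rows).
#' @param window Vicinity window in bp (default 50 kb).
#' @param loops_a Annotated loop data.frame (to locate anchor motifs).
#' @return The surviving events with a `candidate_class` column.
#' @export
filter_candidates <- function(events, chip_peaks, ancestral_sites,
                              window = 50000, loops_a) {
  if (nrow(events) == 0L) {
    events$candidate_class <- character(0)
    return(events)
  }
  keep <- logical(nrow(events))
  cls <- character(nrow(events))
  for (k in seq_len(nrow(events))) {
    ra <- loops_a[loops_a$loop_id == events$loop_a[k], , drop = FALSE]
    side <- match(events$side[k], c("left", "right"))
    ms <- ra[[paste0("motif", side, "_start")]]
    me <- ra[[paste0("motif", side, "_end")]]
    mid <- (ms + me) / 2
    near <- chip_peaks$chrom == ra$chrom &
      pmax(chip_peaks$start, mid - window) < pmin(chip_peaks$end, mid + window)
    own <- overlap_widths(ra$chrom, ms, me, chip_peaks) > 0
    others <- chip_peaks[near & !own, , drop = FALSE]
    if (nrow(others) == 0L) {
      keep[k] <- TRUE; cls[k] <- "replacement"
    } else if (nrow(others) == 1L && nrow(ancestral_sites) > 0L) {
      anc <- overlap_widths(others$chrom[1L], others$start[1L], others$end[1L],
                            ancestral_sites) > 0
      if (any(anc)) { keep[k] <- TRUE; cls[k] <- "redundant" }
    }
  }
  events <- events[keep, , drop = FALSE]
  events$candidate_class <- cls[keep]
  rownames(events) <- NULL
  events
}

#' Motif-orientation by anchor-side contingency table of turnover events
#'
#' Events are de-duplicated to unique anchors (an anchor tethering several
#' loops counts once) and tallied into a 2x2 table of motif orientation
#' (+/-) by anchor side (left/right), with the Pearson chi-square test
#' attached.
#'
#' @param events Turnover events ([detect_turnover()]).
#' @return List `counts` (2x2 matrix), `n` (unique anchors), `chi2`, `p`,
#'   `low_count`.
#' @export
orientation_table <- function(events) {
  counts <- matrix(0, 2, 2,
                   dimnames = list(orientation = c("+", "-"),
                                   side = c("left", "right")))
  if (nrow(events) > 0L) {
    uniq <- events[!duplicated(events$anchor_key), , drop = FALSE]
    for (k in seq_len(nrow(uniq)))
      counts[uniq$orientation[k], uniq$side[k]] <-
        counts[uniq$orientation[k], uniq$side[k]] + 1
  }
  if (sum(counts) == 0)
    return(list(counts = counts, n = 0L, chi2 = NA_real_, p = NA_real_,
                low_count = TRUE))
  ct <- pearson_chi2(counts)
  list(counts = counts, n = sum(counts), chi2 = ct$chi2, p = ct$p,
       low_count = ct$low_count)
}
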