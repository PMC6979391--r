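# Cross-genome loop orthology: minMatch calibration by shuffling, loop
# lifting, vicinity-window matching, vicinity calibration by FDR, and
# reciprocal best hits.

#' Lift a set of loops to the other genome
#'
#' Both anchors must lift for a loop to be considered liftable, must land
#' on the same target chromosome, and anchors are re-ordered left-to-right
#' (anti-sense chains flip the anchor order).
#'
#' @param cm A `chain_map`.
#' @param loops Loop data.frame on the source genome.
#' @param min_match minMatch gate passed to [lift_interval()].
#' @return Data.frame `loop_id`, `lifted` (logical), `chrom`, `mid1`,
#'   `mid2` (lifted anchor midpoints), `length` (lifted midpoint distance),
#'   `matched_fraction` (min over the two anchors).
#' @export
lift_loops <- function(cm, loops, min_match = 0.1) {
  n <- nrow(loops)
  out <- data.frame(loop_id = loops$loop_id, lifted = logical(n),
                    chrom = NA_character_, mid1 = NA_real_, mid2 = NA_real_,
                    length = NA_real_, matched_fraction = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_len(n)) {
    l1 <- lift_interval(cm, gi(loops$chrom[k], loops$start1[k], loops$end1[k]),
                        min_match)
    l2 <- lift_interval(cm, gi(loops$chrom[k], loops$start2[k], loops$end2[k]),
                        min_match)
    out$matched_fraction[k] <- min(l1$matched_fraction, l2$matched_fraction)
    if (is.null(l1$mapped) || is.null(l2$mapped)) next
    if (l1$mapped$chrom != l2$mapped$chrom) next
    m1 <- gi_midpoint(l1$mapped); m2 <- gi_midpoint(l2$mapped)
    out$lifted[k] <- TRUE
    out$chrom[k] <- l1$mapped$chrom
    out$mid1[k] <- min(m1, m2)
    out$mid2[k] <- max(m1, m2)
    out$length[k] <- abs(m2 - m1)
  }
  out
}

#' Shuffle features within their chromosome of origin
#'
#' Each feature keeps its chromosome and length and receives a uniform
#' random start such that it still fits on the chromosome (the behaviour
#' of `bedtools shuffle -chrom`).
#'
#' @param features Data.frame with `chrom`, `start`, `end` (additional
#'   columns are preserved).
#' @param chrom_lengths Named numeric vector of chromosome lengths.
#' @param seed Integer seed.
#' @return The shuffled data.frame.
#' @export
shuffle_features <- function(features, chrom_lengths, seed) {
  set.seed(as.integer(seed))
  len <- features$end - features$start
  L <- chrom_lengths[features$chrom]
  if (any(is.na(L))) stop("feature chromosome missing from chrom_lengths")
  if (any(len > L)) stop("feature longer than its chromosome")
  new_start <- floor(stats::runif(nrow(features)) * (L - len + 1))
  features$start <- new_start
  features$end <- new_start + len
  features
}

#' Shuffle loops within their chromosome (anchors move rigidly)
#'
#' The whole loop (left anchor start to right anchor end, motifs included)
#' is translated to a uniform random offset on its chromosome, preserving
#' loop length and anchor geometry.
#'
#' @param loops Loop data.frame.
#' @param chrom_lengths Named numeric vector.
#' @param seed Integer seed.
#' @return Shuffled loop data.frame.
#' @export
shuffle_loops <- function(loops, chrom_lengths, seed) {
  set.seed(as.integer(seed))
  span <- loops$end2 - loops$start1
  L <- chrom_lengths[loops$chrom]
  if (any(is.na(L))) stop("loop chromosome missing from chrom_lengths")
  if (any(span > L)) stop("loop longer than its chromosome")
  shift <- floor(stats::runif(nrow(loops)) * (L - span + 1)) - loops$start1
  for (col in c("start1", "end1", "start2", "end2", "motif1_start",
                "motif1_end", "motif2_start", "motif2_end"))
    loops[[col]] <- loops[[col]] + shift
  loops
}

#' Choose the minMatch liftOver gate by shuffling
#'
#' For each candidate gate, `n_shuffles` shuffled copies of the features
#' are lifted and the mean and coefficient of variation of the lifted
#' counts recorded. The candidate maximizing the mean lifted count wins;
#' ties break to lower CV, then to the larger gate.
#'
#' @param features Interval data.frame (`chrom`, `start`, `end`).
#' @param cm A `chain_map`.
#' @param candidate_values Numeric vector of gates in (0, 1], length >= 2.
#' @param chrom_lengths Named numeric vector for shuffling.
#' @param n_shuffles Number of shuffled feature sets (default 10).
#' @param seed Integer seed.
#' @return List `chosen` and `table` (per-candidate mean/CV of lifted
#'   counts).
#' @export
optimize_min_match <- function(features, cm, candidate_values, chrom_lengths,
                               n_shuffles = 10, seed = 1) {
  stopifnot(length(candidate_values) >= 2L)
  fracs <- matrix(0, nrow = nrow(features), ncol = n_shuffles)
  for (s in seq_len(n_shuffles)) {
    sh <- shuffle_features(features, chrom_lengths, seed + s - 1L)
    fracs[, s] <- vapply(seq_len(nrow(sh)), function(k) {
      lift_interval(cm, gi(sh$chrom[k], sh$start[k], sh$end[k]),
                    min_match = 1e-9)$matched_fraction
    }, 0)
  }
  tab <- data.frame(min_match = sort(candidate_values))
  counts <- sapply(tab$min_match, function(mm) colSums(fracs >= mm & fracs > 0))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = n_shuffles)
  tab$mean_lifted <- colMeans(counts)
  sds <- apply(counts, 2, stats::sd)
  tab$cv <- ifelse(tab$mean_lifted > 0, sds / tab$mean_lifted, NA_real_)
  if (all(tab$mean_lifted == 0)) stop("no candidate lifts any feature")
  ord <- order(-tab$mean_lifted, tab$cv, -tab$min_match)
  list(chosen = tab$min_match[ord[1L]], table = tab)
}

#' Match lifted loops to target-genome loops within a vicinity window
#'
#' A target loop matches a lifted query when both anchor midpoints lie
#' within `w = min(query loop length / 2, vicinity)` of the corresponding
#' lifted anchor midpoints. All matching targets are returned per query.
#'
#' @param lifted Output of [lift_loops()] (only `lifted == TRUE` rows are
#'   considered).
#' @param targets Loop data.frame on the target genome.
#' @param vicinity Vicinity threshold in bp (default 50 kb).
#' @return Data.frame `query_id`, `target_id`, `left_offset`,
#'   `right_offset`, `window`.
#' @export
match_loops <- function(lifted, targets, vicinity = 50000) {
  stopifnot(vicinity > 0)
  tmid1 <- (targets$start1 + targets$end1) / 2
  tmid2 <- (targets$start2 + targets$end2) / 2
  res <- list()
  for (k in which(lifted$lifted)) {
    w <- min(lifted$length[k] / 2, vicinity)
    same <- targets$chrom == lifted$chrom[k]
    lo <- abs(tmid1 - lifted$mid1[k])
    ro <- abs(tmid2 - lifted$mid2[k])
    hit <- which(same & lo <= w & ro <= w)
    if (length(hit))
      res[[length(res) + 1L]] <- data.frame(
        query_id = lifted$loop_id[k], target_id = targets$loop_id[hit],
        left_offset = lo[hit], right_offset = ro[hit], window = w,
        stringsAsFactors = FALSE)
  }
  if (!length(res))
    return(data.frame(query_id = character(), target_id = character(),
                      left_offset = numeric(), right_offset = numeric(),
                      window = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Calibrate the vicinity threshold by shuffled-set FDR
#'
#' `FDR(t)` is the mean number of shuffled queries with a match divided by
#' the number of real queries with a match at threshold `t`. The chosen
#' threshold is the largest one with `FDR < fdr_max`; thresholds where the
#' real matched count is zero are excluded.
#'
#' @param real_lifted Lifted real query loops ([lift_loops()]).
#' @param shuffled_lifted_sets List of lifted shuffled query sets.
#' @param targets Target loop data.frame.
#' @param thresholds Numeric vector of vicinity thresholds to test.
#' @param fdr_max FDR cutoff (default 0.1).
#' @return List `chosen` (threshold or NA) and `table`
#'   (`threshold`, `real_matched`, `mean_shuffled_matched`, `fdr`).
#' @export
calibrate_vicinity <- function(real_lifted, shuffled_lifted_sets, targets,
                               thresholds, fdr_max = 0.1) {
  stopifnot(length(shuffled_lifted_sets) >= 1L)
  n_matched <- function(lifted, t)
    length(unique(match_loops(lifted, targets, t)$query_id))
  tab <- data.frame(threshold = sort(thresholds))
  tab$real_matched <- vapply(tab$threshold,
                             function(t) n_matched(real_lifted, t), 0L)
  tab$mean_shuffled_matched <- vapply(tab$threshold, function(t)
    mean(vapply(shuffled_lifted_sets, function(s) n_matched(s, t), 0L)), 0)
  tab$fdr <- ifelse(tab$real_matched > 0,
                    tab$mean_shuffled_matched / tab$real_matched, NA_real_)
  ok <- which(!is.na(tab$fdr) & tab$fdr < fdr_max)
  list(chosen = if (length(ok)) max(tab$threshold[ok]) else NA_real_,
       table = tab)
}

#' Reciprocal best hits between two match tables
#'
#' The best match of a query is the target with the smallest summed
#' absolute anchor offsets. A pair (a, b) is kept when b is a's best match
#' in the A-to-B direction and a is b's best in B-to-A; each loop appears
#' in at most one call.
#'
#' @param matches_ab [match_loops()] output for A queries vs B targets.
#' @param matches_ba [match_loops()] output for B queries vs A targets.
#' @return Data.frame `loop_a`, `loop_b`, `left_offset`, `right_offset`,
#'   `window` (offsets/window from the A-to-B direction).
#' @export
reciprocal_best_hits <- function(matches_ab, matches_ba) {
  best_of <- function(m) {
    if (nrow(m) == 0L) return(m)
    tot <- m$left_offset + m$right_offset
    ord <- order(m$query_id, tot, m$target_id)
    m <- m[ord, , drop = FALSE]
    m[!duplicated(m$query_id), , drop = FALSE]
  }
  ab <- best_of(matches_ab)
  ba <- best_of(matches_ba)
  if (nrow(ab) == 0L || nrow(ba) == 0L)
    return(data.frame(loop_a = character(), loop_b = character(),
                      left_offset = numeric(), right_offset = numeric(),
                      window = numeric(), stringsAsFactors = FALSE))
  back <- ba$target_id[match(ab$target_id, ba$query_id)]
  keep <- !is.na(back) & back == ab$query_id
  out <- data.frame(loop_a = ab$query_id[keep], loop_b = ab$target_id[keep],
                    left_offset = ab$left_offset[keep],
                    right_offset = ab$right_offset[keep],
                    window = ab$window[keep], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Call conserved loops between two genomes
#'
#' Lifts A loops to the B genome and vice versa, matches within the
#' vicinity window, and keeps reciprocal best hits.
#'
#' @param loops_a,loops_b Loop data.frames for the two genomes.
#' @param chain_ab Chain lifting A coordinates to B.
#' @param chain_ba Chain lifting B coordinates to A.
#' @param min_match minMatch gate (default 0.1).
#' @param vicinity Vicinity threshold in bp (default 50 kb).
#' @return Data.frame of orthology calls ([reciprocal_best_hits()]).
#' @export
loop_orthology <- function(loops_a, loops_b, chain_ab, chain_ba,
                           min_match = 0.1, vicinity = 50000) {
  lifted_a <- lift_loops(chain_ab, loops_a, min_match)
  lifted_b <- lift_loops(chain_ba, loops_b, min_match)
  m_ab <- match_loops(lifted_a, loops_b, vicinity)
  m_ba <- match_loops(lifted_b, loops_a, vicinity)
  reciprocal_best_hits(m_ab, m_ba)
}
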