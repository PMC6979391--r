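# TE evolutionary analytics: global realignment to consensus, substitution
# spectrum profiling, methylation-signature permutation tests, nucleotide
# distances, age estimation, and LINE consensus stitching.

# EDNAFULL (NUC.4.4) nucleotide scoring matrix: +5 self-match, -4
# transition/transversion mismatch, with the standard IUPAC ambiguity rows.
.ednafull <- local({
  bases <- c("A", "T", "G", "C", "S", "W", "R", "Y", "K", "M",
             "B", "V", "H", "D", "N")
  v <- c(
     5, -4, -4, -4, -4,  1,  1, -4, -4,  1, -4, -1, -1, -1, -2,
    -4,  5, -4, -4, -4,  1, -4,  1,  1, -4, -1, -4, -1, -1, -2,
    -4, -4,  5, -4,  1, -4,  1, -4,  1, -4, -1, -1, -4, -1, -2,
    -4, -4, -4,  5,  1, -4, -4,  1, -4,  1, -1, -1, -1, -4, -2,
    -4, -4,  1,  1, -1, -4, -2, -2, -2, -2, -1, -1, -3, -3, -1,
     1,  1, -4, -4, -4, -1, -2, -2, -2, -2, -3, -3, -1, -1, -1,
     1, -4,  1, -4, -2, -2, -1, -4, -2, -2, -3, -1, -3, -1, -1,
    -4,  1, -4,  1, -2, -2, -4, -1, -2, -2, -1, -3, -1, -3, -1,
    -4,  1,  1, -4, -2, -2, -2, -2, -1, -4, -1, -3, -3, -1, -1,
     1, -4, -4,  1, -2, -2, -2, -2, -4, -1, -3, -1, -1, -3, -1,
    -4, -1, -1, -1, -1, -3, -3, -1, -1, -3, -1, -2, -2, -2, -1,
    -1, -4, -1, -1, -1, -3, -1, -3, -3, -1, -2, -1, -2, -2, -1,
    -1, -1, -4, -1, -3, -1, -3, -1, -3, -1, -2, -2, -1, -2, -1,
    -1, -1, -1, -4, -3, -1, -1, -3, -1, -3, -2, -2, -2, -1, -1,
    -2, -2, -2, -2, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1)
  matrix(v, 15, 15, byrow = TRUE, dimnames = list(bases, bases))
})

#' Global affine-gap alignment under the EDNAFULL scoring matrix
#'
#' Needleman-Wunsch global alignment with affine gaps: a gap of length L
#' costs `gap_open + gap_extend * L` (the first gap base pays both the
#' opening and the extension penalty). Scoring follows the EDNAFULL
#' nucleotide matrix (+5 self-match, -4 mismatch, standard IUPAC rows).
#'
#' @param seq_a,seq_b Non-empty DNA strings (IUPAC letters).
#' @param gap_open Gap opening penalty (default 10).
#' @param gap_extend Per-base gap extension penalty (default 0.5).
#' @return List `a_aligned`, `b_aligned` (equal-length strings with `-`
#'   gaps) and `score`.
#' @export
needle_align <- function(seq_a, seq_b, gap_open = 10, gap_extend = 0.5) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("empty sequence")
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(toupper(seq_a)),
    subject = Biostrings::DNAString(toupper(seq_b)),
    type = "global", substitutionMatrix = .ednafull,
    gapOpening = gap_open, gapExtension = gap_extend)
  list(a_aligned = as.character(Biostrings::alignedPattern(aln)),
       b_aligned = as.character(Biostrings::alignedSubject(aln)),
       score = Biostrings::score(aln))
}

.sub_categories <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                   paste0))
.sub_categories <- .sub_categories[substr(.sub_categories, 1, 1) !=
                                   substr(.sub_categories, 2, 2)]

#' Count substitutions and indels in a consensus/genomic alignment
#'
#' Tallies the 12 substitution categories (first letter = ancestral
#' consensus base, second = genomic base), skipping columns with a
#' non-ACGT character on either side. Insertions are gap runs in the
#' consensus, deletions gap runs in the genomic sequence. Rates are
#' normalized by the genomic (ungapped) sequence length.
#'
#' @param c_aligned Aligned consensus (ancestral) string.
#' @param g_aligned Aligned genomic string of the same length.
#' @return List with `counts` (named 12-vector), `rates`, `insertions`,
#'   `deletions` (run counts), `insertion_bases`, `deletion_bases`,
#'   `genomic_length`, `consensus_length`, `aligned_acgt_columns`,
#'   `p_mismatch`, `p_transition`, `p_transversion`.
#' @export
count_substitutions <- function(c_aligned, g_aligned) {
  stopifnot(nchar(c_aligned) == nchar(g_aligned))
  cc <- strsplit(toupper(c_aligned), "")[[1L]]
  gg <- strsplit(toupper(g_aligned), "")[[1L]]
  cgap <- cc == "-"; ggap <- gg == "-"
  if (any(cgap & ggap)) stop("column with gaps on both sides")
  acgt <- c("A", "C", "G", "T")
  both <- cc %in% acgt & gg %in% acgt
  counts <- stats::setNames(numeric(12), .sub_categories)
  sub <- both & cc != gg
  if (any(sub)) {
    t <- table(paste0(cc[sub], gg[sub]))
    counts[names(t)] <- as.numeric(t)
  }
  runs <- function(gap) { r <- rle(gap); sum(r$values) }
  glen <- sum(!ggap)
  clen <- sum(!cgap)
  ncols <- sum(both)
  transitions <- sum(counts[c("AG", "GA", "CT", "TC")])
  list(counts = counts,
       rates = if (glen > 0) counts / glen else counts * NA,
       insertions = runs(cgap), deletions = runs(ggap),
       insertion_bases = sum(cgap), deletion_bases = sum(ggap),
       genomic_length = glen, consensus_length = clen,
       aligned_acgt_columns = ncols,
       p_mismatch = if (ncols > 0) sum(counts) / ncols else NA_real_,
       p_transition = if (ncols > 0) transitions / ncols else NA_real_,
       p_transversion = if (ncols > 0) (sum(counts) - transitions) / ncols
                        else NA_real_)
}

#' Per-element substitution profiles for a set of alignment records
#'
#' Runs [count_substitutions()] on each record and assembles one row per
#' element with the 12 per-bp substitution rates, the methylation-
#' associated rate (mean of the C-to-T and G-to-A rates), the
#' non-methylation rate (mean of the other ten), indel rates, and the
#' mismatch proportions feeding the distance corrections.
#'
#' @param records List of alignment records ([read_align()]).
#' @return Data.frame, one row per element.
#' @export
substitution_profiles <- function(records) {
  rows <- lapply(records, function(r) {
    cs <- count_substitutions(r$c_aligned, r$g_aligned)
    rates <- as.list(cs$rates)
    names(rates) <- paste0("rate_", names(cs$rates))
    meth <- (cs$rates[["CT"]] + cs$rates[["GA"]]) / 2
    other <- setdiff(names(cs$rates), c("CT", "GA"))
    data.frame(element_id = r$element_id, subfamily = r$consensus_id,
               as.data.frame(rates),
               meth_rate = meth,
               nonmeth_rate = mean(cs$rates[other]),
               ins_per_bp = cs$insertions / cs$genomic_length,
               del_per_bp = cs$deletions / cs$genomic_length,
               genomic_length = cs$genomic_length,
               consensus_length = cs$consensus_length,
               p_mismatch = cs$p_mismatch,
               p_transition = cs$p_transition,
               p_transversion = cs$p_transversion,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Drop genomic TEs much shorter than their consensus
#'
#' Removes profiles whose genomic length is below `min_fraction` of the
#' consensus length (strictly less than; the boundary case is kept).
#' Set `enabled = FALSE` for the realignment path, which does not apply
#' the filter.
#'
#' @param profiles Data.frame from [substitution_profiles()].
#' @param min_fraction Length-fraction cutoff (default 0.2).
#' @param enabled Apply the filter (default TRUE).
#' @return The filtered data.frame.
#' @export
filter_short <- function(profiles, min_fraction = 0.2, enabled = TRUE) {
  if (!enabled) return(profiles)
  keep <- profiles$genomic_length >= min_fraction * profiles$consensus_length
  out <- profiles[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.test_stats <- c(paste0("rate_", .sub_categories), "meth_rate", "nonmeth_rate")

#' Left-tailed permutation z-test of turnover substitution rates
#'
#' The observed statistic is the mean over turnover elements of each of
#' the 12 substitution rates plus the methylation-associated and
#' non-methylation rates. Each permutation draws, per subfamily, as many
#' background elements (TEs not involved in loop anchoring) as appear in
#' the turnover set; the z-score compares the observed mean with the
#' permutation means, and `p_left = Phi(z)` tests for a *lower* observed
#' rate. Bonferroni adjustment is applied across the 12 single-
#' substitution hypotheses. A naive one-sample KS probability of normality
#' of each permutation distribution is reported (not asserted).
#'
#' @param turnover_profiles Profiles of TEs mediating turnover events.
#' @param pool_profiles Background profiles (must exclude loop-anchoring
#'   TEs and cover every turnover subfamily).
#' @param n_perms Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return Data.frame, one row per statistic: `statistic`, `observed`,
#'   `perm_mean`, `perm_sd`, `z`, `p_left`, `p_adjusted`, `ks_p`.
#' @export
substitution_test <- function(turnover_profiles, pool_profiles,
                              n_perms = 1000, seed = 1) {
  freq <- table(turnover_profiles$subfamily)
  missing <- setdiff(names(freq), unique(pool_profiles$subfamily))
  if (length(missing))
    stop("subfamily missing from background pool: ",
         paste(missing, collapse = ", "))
  obs <- colMeans(turnover_profiles[, .test_stats, drop = FALSE])
  pool_mat <- as.matrix(pool_profiles[, .test_stats, drop = FALSE])
  idx_by_subfam <- split(seq_len(nrow(pool_profiles)),
                         pool_profiles$subfamily)
  set.seed(as.integer(seed))
  with_repl <- names(freq)[vapply(names(freq), function(s)
    length(idx_by_subfam[[s]]) < freq[[s]], TRUE)]
  if (length(with_repl))
    message("pool smaller than turnover count for subfamily(ies) ",
            paste(with_repl, collapse = ", "), "; sampling with replacement")
  perm_means <- matrix(0, n_perms, length(.test_stats),
                       dimnames = list(NULL, .test_stats))
  for (p in seq_len(n_perms)) {
    idx <- unlist(lapply(names(freq), function(s) {
      pool_idx <- idx_by_subfam[[s]]
      k <- freq[[s]]
      if (length(pool_idx) == 1L)
        rep(pool_idx, k)
      else
        sample(pool_idx, k, replace = length(pool_idx) < k)
    }))
    perm_means[p, ] <- colMeans(pool_mat[idx, , drop = FALSE])
  }
  mu <- colMeans(perm_means)
  sd_ <- apply(perm_means, 2, stats::sd)
  z <- ifelse(sd_ > 0, (obs - mu) / sd_, NA_real_)
  p_left <- stats::pnorm(z)
  is_single <- .test_stats %in% paste0("rate_", .sub_categories)
  p_adj <- ifelse(is_single, pmin(1, p_left * sum(is_single)), p_left)
  ks_p <- vapply(seq_along(.test_stats), function(k) {
    if (sd_[k] == 0) return(NA_real_)
    suppressWarnings(
      stats::ks.test(perm_means[, k], "pnorm", mu[k], sd_[k])$p.value)
  }, 0)
  data.frame(statistic = .test_stats, observed = unname(obs),
             perm_mean = unname(mu), perm_sd = unname(sd_),
             z = unname(z), p_left = unname(p_left),
             p_adjusted = unname(p_adj), ks_p = ks_p,
             stringsAsFactors = FALSE)
}

#' Jukes-Cantor distance from a mismatch proportion
#' @param p Observed mismatch proportion (`0 <= p < 0.75`).
#' @return `-(3/4) ln(1 - 4p/3)`, or `NA` outside the domain.
#' @export
jukes_cantor <- function(p) {
  ifelse(p >= 0 & p < 0.75, -0.75 * log(1 - 4 * p / 3), NA_real_)
}

#' Kimura two-parameter distance
#' @param P Transition proportion.
#' @param Q Transversion proportion.
#' @return `-(1/2) ln((1 - 2P - Q) sqrt(1 - 2Q))`, or `NA` outside the log
#'   domain.
#' @export
kimura_2p <- function(P, Q) {
  ok <- (1 - 2 * P - Q) > 0 & (1 - 2 * Q) > 0
  ifelse(ok, -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q)), NA_real_)
}

#' TE age from percent divergence and a neutral substitution rate
#'
#' `age = (pct_divergence / 100) / rate`. Canonical neutral rates:
#' human 2.2e-9, mouse 4.5e-9 substitutions/site/year.
#'
#' @param pct_divergence Percent divergence from consensus (0-100).
#' @param rate Neutral substitution rate in substitutions/site/year.
#' @return Age in years.
#' @export
estimate_age <- function(pct_divergence, rate) {
  stopifnot(all(rate > 0), all(pct_divergence >= 0 & pct_divergence <= 100))
  (pct_divergence / 100) / rate
}

# Ungapped suffix-prefix overlap score scan between two fragments:
# +5 per match, -4 per mismatch over the overlapped bases.
.best_overlap <- function(a, b, min_overlap) {
  la <- nchar(a); lb <- nchar(b)
  lens <- seq.int(min_overlap, min(la, lb))
  if (!length(lens) || min(la, lb) < min_overlap)
    return(list(len = 0L, ties = integer()))
  av <- strsplit(toupper(a), "")[[1L]]
  bv <- strsplit(toupper(b), "")[[1L]]
  scores <- vapply(lens, function(o) {
    sa <- av[(la - o + 1L):la]; sb <- bv[1:o]
    sum(ifelse(sa == sb, 5, -4))
  }, 0)
  best <- max(scores)
  if (best <= 0) return(list(len = 0L, ties = integer()))
  hits <- lens[scores == best]
  list(len = hits[1L], ties = hits)
}

#' Stitch fragmented LINE consensus pieces into a full-length consensus
#'
#' Adjacent fragments (5' end, ORF2, 3' end) are joined by their best
#' terminal overlap (ungapped, +5/-4 scoring, minimum `min_overlap` bp);
#' overlapping bases are kept once with the upstream fragment taking
#' precedence. Fragments with no positive-scoring overlap are simply
#' concatenated. Equal-best overlaps at different offsets are ambiguous
#' and raise an error listing the candidates.
#'
#' @param five_prime,orf2,three_prime Fragment sequences, 5' to 3'.
#' @param min_overlap Minimum overlap length considered (default 10).
#' @return The stitched full-length consensus string.
#' @export
stitch_line_consensus <- function(five_prime, orf2, three_prime,
                                  min_overlap = 10) {
  join <- function(a, b) {
    ov <- .best_overlap(a, b, min_overlap)
    if (length(ov$ties) > 1L)
      stop("ambiguous overlap between fragments; candidate lengths: ",
           paste(ov$ties, collapse = ", "))
    if (ov$len == 0L) paste0(a, b) else paste0(a, substring(b, ov$len + 1L))
  }
  join(join(five_prime, orf2), three_prime)
}
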