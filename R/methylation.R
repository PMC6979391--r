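# CTCF-centered CpG methylation metaplot, segmented by anchor origin.

#' Methylation metaplot around CTCF motifs
#'
#' Lays sliding windows (width `window`, step `step`) on a motif-centered,
#' strand-oriented axis from `-flank` to `+flank` (minus-strand motifs are
#' flipped). Within a window, the unweighted mean of CpG methylation
#' fractions (coverage >= `min_coverage`) is taken per site; sites are then
#' averaged within each origin category. Windows with no covered CpG at a
#' site are excluded from that site's contribution.
#'
#' @param track Methylation track ([read_bedgraph()]).
#' @param sites CTCF site data.frame (`chrom`, `start`, `end`, `strand`,
#'   `origin`), e.g. [unique_anchor_sites()].
#' @param flank Half-width of the profiled region in bp (default 2000).
#' @param window Window width in bp (default 20).
#' @param step Sliding step in bp (default 10).
#' @param min_coverage Minimum read coverage for a CpG record (default 1).
#' @param categories Origin categories to profile (default: those present
#'   in `sites`); a requested category with no sites is omitted with a
#'   warning.
#' @return Data.frame `category`, `offset` (window center, bp), `value`
#'   (mean fraction, NA when no site contributes), `n_sites`.
#' @export
metaplot <- function(track, sites, flank = 2000, window = 20, step = 10,
                     min_coverage = 1, categories = unique(sites$origin)) {
  offsets <- seq(-flank, flank, by = step)
  track <- track[track$coverage >= min_coverage, , drop = FALSE]
  cats <- categories
  out <- list()
  for (cat in cats) {
    ss <- sites[sites$origin == cat, , drop = FALSE]
    if (nrow(ss) == 0L) {
      warning("category with zero sites omitted: ", cat, call. = FALSE)
      next
    }
    rel <- list()
    for (k in seq_len(nrow(ss))) {
      center <- floor((ss$start[k] + ss$end[k]) / 2)
      lo <- center - flank - window; hi <- center + flank + window
      sel <- track$chrom == ss$chrom[k] & track$start >= lo & track$start <= hi
      if (!any(sel)) next
      sgn <- if (identical(ss$strand[k], "-")) -1 else 1
      rel[[length(rel) + 1L]] <- data.frame(
        site = k, r = sgn * (track$start[sel] - center),
        frac = track$fraction[sel])
    }
    vals <- rep(NA_real_, length(offsets))
    if (length(rel)) {
      rel <- do.call(rbind, rel)
      for (w in seq_along(offsets)) {
        o <- offsets[w]
        sel <- rel$r >= o - window / 2 & rel$r < o + window / 2
        if (any(sel)) {
          per_site <- tapply(rel$frac[sel], rel$site[sel], mean)
          vals[w] <- mean(per_site)
        }
      }
    }
    out[[length(out) + 1L]] <- data.frame(
      category = cat, offset = offsets, value = vals, n_sites = nrow(ss),
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(category = character(), offset = numeric(),
                      value = numeric(), n_sites = integer(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
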