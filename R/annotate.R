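# Repeat-origin annotation of loop-anchor CTCF motifs and ChIP peaks, and
# class/family enrichment against the length-weighted genomic background.

# Assign the repeat origin of one motif interval. Overlap is measured on
# the core motif; a repeat qualifies with >= min_overlap bp. Ties go to
# maximal overlap, then lower percent divergence, then leftmost start.
.assign_origin <- function(chrom, mstart, mend, repeats, min_overlap = 10) {
  if (is.na(mstart))
    return(list(origin = "unidentified", subfamily = NA_character_,
                element_id = NA_character_))
  w <- overlap_widths(chrom, mstart, mend, repeats)
  ok <- which(w >= min_overlap)
  if (!length(ok))
    return(list(origin = "non_RE", subfamily = NA_character_,
                element_id = NA_character_))
  cand <- repeats[ok, , drop = FALSE]
  ord <- order(-w[ok], cand$pct_div, cand$start)
  best <- cand[ord[1L], ]
  list(origin = "RE_derived", subfamily = best$subfamily,
       element_id = best$element_id)
}

#' Annotate the repeat origin of a single CTCF motif
#'
#' A motif is RE-derived when at least `min_overlap` bp of its core overlap
#' a repeat element; among multiple qualifying repeats the one with maximal
#' overlap wins (ties: lower divergence, then leftmost).
#'
#' @param motif A [gi()] interval for the core motif, or `NULL` (origin
#'   stays `"unidentified"`).
#' @param repeats Repeat data.frame ([read_repeatmasker_out()]).
#' @param min_overlap Minimum overlap in bp (default 10).
#' @return List `origin`, `subfamily`, `element_id`.
#' @export
annotate_anchor_origin <- function(motif, repeats, min_overlap = 10) {
  if (is.null(motif))
    return(list(origin = "unidentified", subfamily = NA_character_,
                element_id = NA_character_))
  .assign_origin(motif$chrom, motif$start, motif$end, repeats, min_overlap)
}

#' Annotate anchor origins for every loop
#'
#' Applies [annotate_anchor_origin()] to both anchor motifs of each loop,
#' filling the `origin*`, `subfamily*` and `element_id*` columns.
#'
#' @param loops Loop data.frame ([read_loops_bedpe()]).
#' @param repeats Repeat data.frame.
#' @param min_overlap Minimum overlap in bp (default 10).
#' @return The loop data.frame with origin columns set.
#' @export
annotate_loops <- function(loops, repeats, min_overlap = 10) {
  for (side in 1:2) {
    ms <- loops[[paste0("motif", side, "_start")]]
    me <- loops[[paste0("motif", side, "_end")]]
    res <- lapply(seq_len(nrow(loops)), function(k)
      .assign_origin(loops$chrom[k], ms[k], me[k], repeats, min_overlap))
    loops[[paste0("origin", side)]] <- vapply(res, `[[`, "", "origin")
    loops[[paste0("subfamily", side)]] <-
      vapply(res, function(r) r$subfamily, NA_character_)
    loops[[paste0("element_id", side)]] <-
      vapply(res, function(r) r$element_id, NA_character_)
  }
  loops
}

#' Partition loops by repeat origin of their anchors
#'
#' A loop is `RE_derived` when at least one anchor CTCF site is RE-derived;
#' `non_RE` when both anchors are non-RE; otherwise `excluded`
#' (both unidentified, or one unidentified plus one non-RE), since the
#' unidentified anchor could still be repeat-derived.
#'
#' @param loops Annotated loop data.frame ([annotate_loops()]).
#' @return The loop data.frame with a `class` column
#'   (`RE_derived`/`non_RE`/`excluded`).
#' @export
classify_loops <- function(loops) {
  o1 <- loops$origin1; o2 <- loops$origin2
  cls <- rep("excluded", nrow(loops))
  cls[o1 == "RE_derived" | o2 == "RE_derived"] <- "RE_derived"
  cls[o1 == "non_RE" & o2 == "non_RE"] <- "non_RE"
  loops$class <- cls
  loops
}

#' Annotate ChIP peaks by repeat origin of the peak center
#'
#' A peak is RE-derived iff its single center base lies inside a repeat.
#' The center is the summit (`start + summit`) when a non-negative summit
#' offset is present, else `floor(start + length/2)`.
#'
#' @param peaks narrowPeak data.frame ([read_narrowpeak()]).
#' @param repeats Repeat data.frame.
#' @return `peaks` with `origin` and `subfamily` columns.
#' @export
annotate_peak_origin <- function(peaks, repeats) {
  center <- ifelse(!is.null(peaks$summit) & peaks$summit >= 0,
                   peaks$start + peaks$summit,
                   floor(peaks$start + (peaks$end - peaks$start) / 2))
  res <- lapply(seq_len(nrow(peaks)), function(k) {
    w <- overlap_widths(peaks$chrom[k], center[k], center[k] + 1, repeats)
    ok <- which(w > 0)
    if (!length(ok))
      return(list(origin = "non_RE", subfamily = NA_character_,
                  element_id = NA_character_))
    cand <- repeats[ok, , drop = FALSE]
    ord <- order(cand$pct_div, cand$start)
    list(origin = "RE_derived", subfamily = cand$subfamily[ord[1L]],
         element_id = cand$element_id[ord[1L]])
  })
  peaks$origin <- vapply(res, `[[`, "", "origin")
  peaks$subfamily <- vapply(res, function(r) r$subfamily, NA_character_)
  peaks$element_id <- vapply(res, function(r) r$element_id, NA_character_)
  peaks
}

#' Unique anchor CTCF sites of a loop set
#'
#' De-duplicates anchor motifs by exact motif coordinates (a site shared by
#' several loops appears once).
#'
#' @param loops Annotated loop data.frame.
#' @return Data.frame `chrom`, `start`, `end`, `strand`, `origin`,
#'   `subfamily`, `element_id`, one row per unique motif.
#' @export
unique_anchor_sites <- function(loops) {
  one <- function(side) {
    data.frame(chrom = loops$chrom,
               start = loops[[paste0("motif", side, "_start")]],
               end = loops[[paste0("motif", side, "_end")]],
               strand = loops[[paste0("motif", side, "_strand")]],
               origin = loops[[paste0("origin", side)]],
               subfamily = loops[[paste0("subfamily", side)]],
               element_id = loops[[paste0("element_id", side)]],
               stringsAsFactors = FALSE)
  }
  sites <- rbind(one(1), one(2))
  sites <- sites[!is.na(sites$start), , drop = FALSE]
  sites <- sites[!duplicated(sites[, c("chrom", "start", "end")]), ,
                 drop = FALSE]
  rownames(sites) <- NULL
  sites
}

#' Class/family enrichment of RE-derived calls over genomic background
#'
#' Observed fractions are shares of RE-derived calls per group; background
#' fractions are the group's share of total repeat bp in the genome
#' (length-weighted); enrichment is their ratio.
#'
#' @param origin_calls Data.frame with `origin` and `element_id` columns
#'   (e.g. [unique_anchor_sites()] or [annotate_peak_origin()] output).
#' @param repeats Repeat data.frame for the genome-wide background.
#' @param level `"class"` or `"family"`.
#' @return Data.frame `group`, `observed_fraction`, `background_fraction`,
#'   `enrichment` (NA when the group is absent from the background).
#' @export
enrichment_table <- function(origin_calls, repeats, level = c("class", "family")) {
  level <- match.arg(level)
  derived <- origin_calls[origin_calls$origin == "RE_derived", , drop = FALSE]
  if (nrow(derived) == 0L) stop("no RE-derived calls to tabulate")
  grp_of <- repeats[[level]][match(derived$element_id, repeats$element_id)]
  obs <- table(grp_of)
  obs_frac <- as.numeric(obs) / sum(obs)
  lens <- repeats$end - repeats$start
  bg <- tapply(lens, repeats[[level]], sum)
  bg_frac <- bg / sum(lens)
  groups <- union(names(obs), names(bg))
  data.frame(
    group = groups,
    observed_fraction = ifelse(groups %in% names(obs),
                               obs_frac[match(groups, names(obs))], 0),
    background_fraction = ifelse(groups %in% names(bg),
                                 as.numeric(bg_frac[match(groups, names(bg))]),
                                 NA_real_),
    enrichment = ifelse(groups %in% names(bg) & groups %in% names(obs),
                        obs_frac[match(groups, names(obs))] /
                          as.numeric(bg_frac[match(groups, names(bg))]),
                        ifelse(groups %in% names(obs), NA_real_, 0)),
    stringsAsFactors = FALSE)
}
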