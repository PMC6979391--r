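# minMatch-gated interval lifting through a block chain alignment,
# mirroring what liftOver does with an over.chain file.

#' Lift an interval through a chain map
#'
#' The best-scoring chain whose source span overlaps the query is used.
#' The matched fraction is the share of query bases inside that chain's
#' ungapped blocks; the mapped interval spans the first to the last lifted
#' base on the target (forward strand). The mapping is gated: `mapped` is
#' reported only when `matched_fraction >= min_match`.
#'
#' @param cm A `chain_map` from [read_chain()].
#' @param query A [gi()] interval on the source genome.
#' @param min_match Minimum fraction of query bases that must lift
#'   (`0 < min_match <= 1`); 0.1 is the working default for cross-species
#'   lifts.
#' @return List with `query`, `mapped` ([gi()] or `NULL`),
#'   `matched_fraction`, and `orientation` (`"+"`/`"-"`/`NA`).
#' @export
lift_interval <- function(cm, query, min_match = 0.1) {
  stopifnot(inherits(cm, "chain_map"), inherits(query, "gi"),
            min_match > 0, min_match <= 1)
  best <- NULL
  for (ch in cm$chains) {
    if (ch$s_chrom != query$chrom) next
    if (ch$s_end <= query$start || ch$s_start >= query$end) next
    if (is.null(best) || ch$score > best$score) best <- ch
  }
  none <- list(query = query, mapped = NULL, matched_fraction = 0,
               orientation = NA_character_)
  if (is.null(best)) return(none)
  b <- best$blocks
  o_s <- pmax(b$s_start, query$start)
  o_e <- pmin(b$s_start + b$size, query$end)
  hit <- o_e > o_s
  covered <- sum(pmax(0, o_e - o_s))
  frac <- covered / gi_length(query)
  if (covered == 0 || frac < min_match) {
    none$matched_fraction <- frac
    return(none)
  }
  if (best$t_strand == "+") {
    t_lo <- b$t_start[hit] + (o_s[hit] - b$s_start[hit])
    t_hi <- b$t_start[hit] + (o_e[hit] - b$s_start[hit])
  } else {
    t_lo <- b$t_start[hit] + (b$s_start[hit] + b$size[hit] - o_e[hit])
    t_hi <- b$t_start[hit] + (b$s_start[hit] + b$size[hit] - o_s[hit])
  }
  list(query = query,
       mapped = gi(best$t_chrom, min(t_lo), max(t_hi), query$strand),
       matched_fraction = frac,
       orientation = best$t_strand)
}

#' Invert a chain map (swap source and target genomes)
#' @param cm A `chain_map`.
#' @return A `chain_map` lifting in the opposite direction.
#' @export
invert_chain <- function(cm) {
  stopifnot(inherits(cm, "chain_map"))
  inv <- lapply(cm$chains, function(ch) {
    b <- data.frame(s_start = ch$blocks$t_start, t_start = ch$blocks$s_start,
                    size = ch$blocks$size)
    b <- b[order(b$s_start), , drop = FALSE]
    rownames(b) <- NULL
    list(score = ch$score, s_chrom = ch$t_chrom, s_size = ch$t_size,
         s_start = min(b$s_start), s_end = max(b$s_start + b$size),
         t_chrom = ch$s_chrom, t_size = ch$s_size, t_strand = ch$t_strand,
         blocks = b)
  })
  structure(list(chains = inv), class = "chain_map")
}
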