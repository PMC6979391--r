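# Binned intrachromosomal contact matrices, stored upper-triangle sparse
# (bin index i <= j) and symmetrized on access.

#' Construct a contact matrix
#'
#' @param chrom Chromosome name.
#' @param start,end Region covered (0-based half-open); `end - start` must be
#'   a multiple of `bin_size`.
#' @param bin_size Bin width in bp.
#' @param i,j 1-based bin indices of nonzero entries (any order; folded to
#'   the upper triangle, duplicate pairs summed).
#' @param x Contact values (non-negative).
#' @param normalization `"raw"` or `"VC_sqrt"`.
#' @return Object of class `contact_matrix`.
#' @export
contact_matrix <- function(chrom, start, end, bin_size, i = integer(),
                           j = integer(), x = numeric(),
                           normalization = "raw") {
  stopifnot((end - start) %% bin_size == 0, end > start)
  n_bins <- as.integer((end - start) / bin_size)
  if (any(x < 0)) stop("negative contact value")
  if (any(i < 1L | i > n_bins | j < 1L | j > n_bins))
    stop("bin index outside region")
  ii <- pmin(i, j); jj <- pmax(i, j)
  if (length(ii)) {
    key <- paste(ii, jj)
    agg <- rowsum(x, key)
    ks <- strsplit(rownames(agg), " ", fixed = TRUE)
    ii <- as.integer(vapply(ks, `[`, "", 1L))
    jj <- as.integer(vapply(ks, `[`, "", 2L))
    x <- as.numeric(agg)
    ord <- order(ii, jj)
    ii <- ii[ord]; jj <- jj[ord]; x <- x[ord]
  }
  structure(list(chrom = chrom, start = start, end = end,
                 bin_size = bin_size, n_bins = n_bins,
                 i = ii, j = jj, x = x,
                 normalization = normalization),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact_matrix %s:%d-%d bin=%d (%d bins, %d nonzero pairs, %s, total %.4g)\n",
              x$chrom, x$start, x$end, x$bin_size, x$n_bins, length(x$x),
              x$normalization, sum(x$x)))
  invisible(x)
}

#' Total contact count
#' @param map A `contact_matrix`.
#' @return Sum of all stored (upper-triangle) values.
#' @export
cm_total <- function(map) sum(map$x)

#' Dense symmetric matrix view
#' @param map A `contact_matrix`.
#' @return An `n_bins` x `n_bins` base matrix, symmetrized.
#' @export
cm_dense <- function(map) {
  m <- as.matrix(Matrix::sparseMatrix(i = map$i, j = map$j, x = map$x,
                                      dims = c(map$n_bins, map$n_bins),
                                      symmetric = TRUE))
  unname(m)
}

#' Read Juicer-dump-style contact triples
#'
#' Lines `pos1 pos2 value` where positions are genomic bin start
#' coordinates. Values must be non-negative; entries given for (a, b) and
#' (b, a) are summed into the upper triangle.
#'
#' @param path Path to a triple text file.
#' @inheritParams contact_matrix
#' @return A `contact_matrix`.
#' @export
read_contact_triples <- function(path, chrom, start, end, bin_size,
                                 normalization = "raw") {
  df <- utils::read.table(path, col.names = c("p1", "p2", "value"))
  if (any(df$value < 0)) stop("negative contact value in ", path)
  i <- as.integer((df$p1 - start) %/% bin_size) + 1L
  j <- as.integer((df$p2 - start) %/% bin_size) + 1L
  contact_matrix(chrom, start, end, bin_size, i, j, df$value, normalization)
}

#' Write contact triples
#' @param map A `contact_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contact_triples <- function(map, path) {
  p1 <- map$start + (map$i - 1L) * map$bin_size
  p2 <- map$start + (map$j - 1L) * map$bin_size
  writeLines(paste(format(p1, scientific = FALSE, trim = TRUE),
                   format(p2, scientific = FALSE, trim = TRUE),
                   format(map$x, scientific = FALSE, trim = TRUE)), path)
  invisible(path)
}

#' Merge raw contact maps by count summation
#' @param maps List of `contact_matrix` objects over the same region/binning.
#' @return The element-wise sum as a `contact_matrix`.
#' @export
merge_maps <- function(maps) {
  stopifnot(length(maps) >= 1L)
  ref <- maps[[1L]]
  for (m in maps[-1L]) {
    if (m$chrom != ref$chrom || m$start != ref$start || m$end != ref$end ||
        m$bin_size != ref$bin_size)
      stop("mismatched binning: maps must share region and bin size")
    if (m$normalization != "raw" || ref$normalization != "raw")
      stop("merge_maps requires raw counts")
  }
  contact_matrix(ref$chrom, ref$start, ref$end, ref$bin_size,
                 i = unlist(lapply(maps, `[[`, "i")),
                 j = unlist(lapply(maps, `[[`, "j")),
                 x = unlist(lapply(maps, `[[`, "x")), "raw")
}

#' Subsample a raw contact map to a fixed read depth
#'
#' Draws `n_reads` read pairs without replacement from the multiset of
#' observed pairs (sequential multivariate hypergeometric), so the output
#' total equals `n_reads` exactly.
#'
#' @param map A raw-count `contact_matrix` with integer counts.
#' @param n_reads Number of read pairs to keep; must not exceed the total.
#' @param seed Integer seed.
#' @return A `contact_matrix` with total `n_reads`.
#' @export
subsample <- function(map, n_reads, seed) {
  if (map$normalization != "raw") stop("subsample requires raw counts")
  total <- cm_total(map)
  if (n_reads > total) stop("n_reads exceeds map total")
  if (n_reads == total) return(map)
  set.seed(as.integer(seed))
  counts <- map$x
  remaining <- total
  to_draw <- n_reads
  out <- numeric(length(counts))
  for (k in seq_along(counts)) {
    if (to_draw == 0) break
    # draw from this cell vs the rest, without replacement
    drawn <- stats::rhyper(1L, counts[k], remaining - counts[k], to_draw)
    out[k] <- drawn
    to_draw <- to_draw - drawn
    remaining <- remaining - counts[k]
  }
  keep <- out > 0
  contact_matrix(map$chrom, map$start, map$end, map$bin_size,
                 map$i[keep], map$j[keep], out[keep], "raw")
}

#' VC-sqrt (square-root vanilla coverage) normalization
#'
#' `N_ij = C_ij / sqrt(s_i * s_j)` where `s_i` is the symmetric row sum of
#' bin `i` over the region. Bins with zero coverage are excluded (their
#' entries are dropped).
#'
#' @param map A raw-count `contact_matrix`.
#' @return A `contact_matrix` with `normalization = "VC_sqrt"`.
#' @export
vc_sqrt_normalize <- function(map) {
  if (cm_total(map) == 0) stop("cannot normalize an all-zero matrix")
  s <- cm_row_sums(map)
  keep <- s[map$i] > 0 & s[map$j] > 0
  x <- map$x[keep] / sqrt(s[map$i[keep]] * s[map$j[keep]])
  contact_matrix(map$chrom, map$start, map$end, map$bin_size,
                 map$i[keep], map$j[keep], x, "VC_sqrt")
}

#' Symmetric row sums (coverage) per bin
#' @param map A `contact_matrix`.
#' @return Numeric vector of length `n_bins`; the diagonal counts once.
#' @export
cm_row_sums <- function(map) {
  s <- numeric(map$n_bins)
  off <- map$i != map$j
  t <- rowsum(c(map$x, map$x[off]), c(map$i, map$j[off]))
  s[as.integer(rownames(t))] <- t[, 1L]
  s
}

#' Virtual 4C profile from an anchor window
#'
#' Sums contacts emanating from the bins overlapping `anchor_window` and
#' expresses each bin's share as a percentage of the total (the profile
#' sums to 100).
#'
#' @param map A `contact_matrix`.
#' @param anchor_window A [gi()] interval inside the map region.
#' @return Data.frame `bin_start`, `percent`.
#' @export
virtual_4c <- function(map, anchor_window) {
  if (anchor_window$chrom != map$chrom ||
      anchor_window$start < map$start || anchor_window$end > map$end)
    stop("anchor window outside map region")
  a0 <- as.integer((anchor_window$start - map$start) %/% map$bin_size) + 1L
  a1 <- as.integer((anchor_window$end - 1 - map$start) %/% map$bin_size) + 1L
  anchor <- a0:a1
  prof <- numeric(map$n_bins)
  sel_i <- map$i %in% anchor
  sel_j <- map$j %in% anchor
  # contacts (a, j): count each stored pair once toward its non-anchor end;
  # within-anchor pairs contribute to the anchor bins themselves
  add <- function(idx, bins) {
    if (any(idx)) {
      t <- rowsum(map$x[idx], bins[idx])
      at <- as.integer(rownames(t))
      prof[at] <<- prof[at] + t[, 1L]
    }
  }
  add(sel_i & !sel_j, map$j)
  add(sel_j & !sel_i, map$i)
  add(sel_i & sel_j, map$j)
  tot <- sum(prof)
  if (tot == 0) stop("no interactions emanate from the anchor window")
  data.frame(bin_start = map$start + (seq_len(map$n_bins) - 1L) * map$bin_size,
             percent = 100 * prof / tot)
}

#' Percentage of cross-domain interactions
#'
#' `inter * 100 / (intra + inter)` where intra-domain pairs have both ends
#' inside domain 1 or both inside domain 2 and inter-domain pairs have one
#' end in each. Diagonal pairs count as intra-domain.
#'
#' @param map A `contact_matrix` (raw or normalized values are tallied
#'   as given).
#' @param domain1,domain2 [gi()] intervals, `domain1` upstream of
#'   `domain2`, both inside the map region.
#' @return Percentage in `[0, 100]`.
#' @export
cross_domain_pct <- function(map, domain1, domain2) {
  bins_of <- function(d) {
    if (d$chrom != map$chrom || d$start < map$start || d$end > map$end)
      stop("domain outside map region")
    b0 <- as.integer((d$start - map$start) %/% map$bin_size) + 1L
    b1 <- as.integer((d$end - 1 - map$start) %/% map$bin_size) + 1L
    b0:b1
  }
  b1 <- bins_of(domain1); b2 <- bins_of(domain2)
  if (length(intersect(b1, b2))) stop("domains overlap")
  in1_i <- map$i %in% b1; in1_j <- map$j %in% b1
  in2_i <- map$i %in% b2; in2_j <- map$j %in% b2
  intra <- sum(map$x[(in1_i & in1_j) | (in2_i & in2_j)])
  inter <- sum(map$x[(in1_i & in2_j) | (in2_i & in1_j)])
  if (intra + inter == 0) stop("no interactions within the domain pair")
  inter * 100 / (intra + inter)
}

#' Welch's unequal-variance two-sample t test
#'
#' Two-sided test with the Welch-Satterthwaite degrees of freedom.
#'
#' @param group1,group2 Numeric vectors (each of length >= 2).
#' @return List `t`, `df`, `p` (two-tailed).
#' @export
welch_t_test <- function(group1, group2) {
  stopifnot(length(group1) >= 2L, length(group2) >= 2L)
  m1 <- mean(group1); m2 <- mean(group2)
  v1 <- stats::var(group1); v2 <- stats::var(group2)
  n1 <- length(group1); n2 <- length(group2)
  se2 <- v1 / n1 + v2 / n2
  if (se2 == 0) {
    return(list(t = 0, df = n1 + n2 - 2, p = 1))
  }
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}
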