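# Fully synthetic two-species dataset with implanted ground truth: an
# ancestral backbone accumulates lineage-specific TE insertions and spacer
# breaks in each descendant genome, so the chain covers exactly the
# syntenic sequence and species-specific TEs lie outside chain blocks.
# Convergent-CTCF loops, implanted turnover events, methylation valleys,
# consensus alignments and distance-decay contact maps are emitted in the
# same formats the real pipeline consumes.

.ctcf_motif_seq <- "TGGCCACCAGGGGGCGCTA"  # 19-bp core, planted on + strand

#' Simulation configuration with study-scale defaults
#'
#' @param seed Root integer seed; every stream derives from it.
#' @param n_chromosomes Number of chromosomes (default 2).
#' @param chrom_length Ancestral chromosome length in bp (default 2.5 Mb).
#' @param n_synteny_blocks Syntenic blocks per chromosome; block boundaries
#'   carry independent unalignable spacers in both genomes (default 3).
#' @param te_subfamilies Data.frame `subfamily`, `family`, `class`,
#'   `consensus_length`, `n_background` (shared non-anchor copies per
#'   genome), `divergence` (percent), describing the simulated TE
#'   repertoire.
#' @param n_loops Number of conserved, non-turnover loops (default 24).
#' @param fraction_te_anchored Fraction of conserved loops whose left
#'   anchor motif sits inside a shared TE (default 0.3).
#' @param n_turnover_events Implanted turnover events; each degrades the
#'   ancestral motif in genome A and re-anchors the loop in a
#'   species-A-specific TE 1-5 kb away, orientation matched to the side
#'   (left +, right -) (default 10).
#' @param n_specific_loops Species-specific decoy loops per genome
#'   (default 8).
#' @param decay Contact distance-decay exponent (default 1).
#' @param reads_per_map Read pairs per simulated contact map (default 2e6).
#' @param contact_bin_size Contact-map bin width in bp (default 5000).
#' @param meth_background,meth_valley Background methylation fraction and
#'   valley fraction at bound motifs (defaults 0.8 / 0.1).
#' @param meth_valley_halfwidth Valley half-width in bp (default 150).
#' @param meth_multiplier_background,meth_multiplier_turnover Scaling of
#'   the C-to-T / G-to-A substitution channel for background (methylated)
#'   versus turnover (hypomethylated) TE cohorts (defaults 4 / 1).
#' @return A validated `sim_config` list.
#' @export
simulation_config <- function(seed = 1,
                              n_chromosomes = 2,
                              chrom_length = 2.5e6,
                              n_synteny_blocks = 3,
                              te_subfamilies = NULL,
                              n_loops = 24,
                              fraction_te_anchored = 0.3,
                              n_turnover_events = 10,
                              n_specific_loops = 8,
                              decay = 1,
                              reads_per_map = 2e6,
                              contact_bin_size = 5000,
                              meth_background = 0.8,
                              meth_valley = 0.1,
                              meth_valley_halfwidth = 150,
                              meth_multiplier_background = 4,
                              meth_multiplier_turnover = 1) {
  if (is.null(te_subfamilies)) {
    te_subfamilies <- data.frame(
      subfamily = c("B2_Mm2", "B3", "L1M3f", "LTR41", "MER20"),
      family = c("B2", "B2", "L1", "ERVL", "hAT-Charlie"),
      class = c("SINE", "SINE", "LINE", "LTR", "DNA"),
      consensus_length = c(190, 200, 400, 250, 220),
      n_background = c(40, 30, 30, 30, 30),
      divergence = c(9, 12, 18, 15, 20),
      stringsAsFactors = FALSE)
  }
  cfg <- list(seed = as.integer(seed), n_chromosomes = n_chromosomes,
              chrom_length = chrom_length,
              n_synteny_blocks = n_synteny_blocks,
              te_subfamilies = te_subfamilies, n_loops = n_loops,
              fraction_te_anchored = fraction_te_anchored,
              n_turnover_events = n_turnover_events,
              n_specific_loops = n_specific_loops, decay = decay,
              reads_per_map = reads_per_map,
              contact_bin_size = contact_bin_size,
              meth_background = meth_background, meth_valley = meth_valley,
              meth_valley_halfwidth = meth_valley_halfwidth,
              meth_multiplier_background = meth_multiplier_background,
              meth_multiplier_turnover = meth_multiplier_turnover)
  stopifnot(cfg$n_chromosomes >= 1, cfg$chrom_length > 1e5,
            cfg$n_loops >= 0, cfg$n_turnover_events >= 0,
            cfg$n_specific_loops >= 0,
            cfg$fraction_te_anchored >= 0, cfg$fraction_te_anchored <= 1,
            cfg$meth_background >= 0, cfg$meth_background <= 1,
            cfg$meth_valley >= 0, cfg$meth_valley <= 1,
              all(cfg$te_subfamilies$n_background >= 0))
  class(cfg) <- "sim_config"
  cfg
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate diverged copies of a TE consensus
#'
#' Each site mutates independently with probability `divergence/100`; the
#' substitution target is drawn with the C-to-T (and G-to-A) channel
#' weighted by `meth_multiplier` relative to the other two targets, so a
#' methylated history (`meth_multiplier > 1`) inflates the
#' CpG-deamination-like categories. True per-copy substitution counts are
#' recorded. Copies carry no indels.
#'
#' @param consensus Consensus DNA string (length >= 50).
#' @param n Number of copies.
#' @param divergence Percent divergence in (0, 50) (0 allowed: identical
#'   copies).
#' @param meth_multiplier Weight of the C-to-T/G-to-A channel (default 1).
#' @param seed Integer seed.
#' @return List `seqs` (character vector) and `counts` (n x 12 matrix of
#'   true substitution counts, ancestral-to-genomic).
#' @export
simulate_te_copies <- function(consensus, n, divergence,
                               meth_multiplier = 1, seed = 1) {
  stopifnot(nchar(consensus) >= 50, divergence >= 0, divergence < 50)
  set.seed(as.integer(seed))
  cons <- strsplit(toupper(consensus), "")[[1L]]
  L <- length(cons)
  d <- divergence / 100
  alts <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
               G = c("A", "C", "T"), T = c("A", "C", "G"))
  wts <- list(A = c(1, 1, 1), C = c(1, 1, meth_multiplier),
              G = c(meth_multiplier, 1, 1), T = c(1, 1, 1))
  counts <- matrix(0, n, 12, dimnames = list(NULL, .sub_categories))
  seqs <- character(n)
  for (k in seq_len(n)) {
    copy <- cons
    mut <- which(stats::runif(L) < d)
    for (b in c("A", "C", "G", "T")) {
      at <- mut[cons[mut] == b]
      if (!length(at)) next
      tgt <- sample(alts[[b]], length(at), replace = TRUE,
                    prob = wts[[b]] / sum(wts[[b]]))
      copy[at] <- tgt
      t <- table(paste0(b, tgt))
      counts[k, names(t)] <- counts[k, names(t)] + as.numeric(t)
    }
    seqs[k] <- paste(copy, collapse = "")
  }
  list(seqs = seqs, counts = counts)
}

#' Simulate a binned contact map with domains and focal loops
#'
#' Expected counts follow `(distance_bins + 1)^-decay`, multiplied by
#' `domain_factor` for bin pairs inside the same domain and `loop_factor`
#' at loop-anchor bin pairs; `reads` read pairs are drawn multinomially,
#' so the total equals `reads` exactly.
#'
#' @param chrom,start,end Region covered (0-based half-open).
#' @param bin_size Bin width in bp.
#' @param domains List of [gi()] intervals (may be empty).
#' @param loop_anchors Data.frame with columns `a1`, `a2`: genomic
#'   positions of the paired anchors (must lie in the region).
#' @param reads Total read pairs.
#' @param decay Distance-decay exponent (default 1).
#' @param domain_factor,loop_factor Enrichment factors (defaults 3 / 30).
#' @param seed Integer seed.
#' @return A raw-count `contact_matrix`.
#' @export
simulate_contact_map <- function(chrom, start, end, bin_size, domains = list(),
                                 loop_anchors = NULL, reads = 1e6, decay = 1,
                                 domain_factor = 3, loop_factor = 30,
                                 seed = 1) {
  n <- as.integer((end - start) / bin_size)
  ut <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  i <- ut[, 1L]; j <- ut[, 2L]
  e <- (abs(j - i) + 1)^(-decay)
  bin_of <- function(pos) as.integer((pos - start) %/% bin_size) + 1L
  for (d in domains) {
    if (d$chrom != chrom || d$start < start || d$end > end)
      stop("domain outside region")
    b0 <- bin_of(d$start); b1 <- bin_of(d$end - 1)
    inside <- i >= b0 & i <= b1 & j >= b0 & j <= b1
    e[inside] <- e[inside] * domain_factor
  }
  if (!is.null(loop_anchors) && nrow(loop_anchors)) {
    if (any(loop_anchors$a1 < start | loop_anchors$a1 >= end |
            loop_anchors$a2 < start | loop_anchors$a2 >= end))
      stop("loop anchor outside region")
    for (k in seq_len(nrow(loop_anchors))) {
      bi <- min(bin_of(loop_anchors$a1[k]), bin_of(loop_anchors$a2[k]))
      bj <- max(bin_of(loop_anchors$a1[k]), bin_of(loop_anchors$a2[k]))
      at <- i == bi & j == bj
      e[at] <- e[at] * loop_factor
    }
  }
  set.seed(as.integer(seed))
  counts <- as.numeric(stats::rmultinom(1L, size = reads, prob = e / sum(e)))
  keep <- counts > 0
  contact_matrix(chrom, start, end, bin_size, i[keep], j[keep], counts[keep],
                 "raw")
}

# Rejection-sample a position whose padded interval avoids all occupied
# intervals; returns NA after max_tries.
.place <- function(occupied, width, lo, hi, pad = 1000, max_tries = 200) {
  for (t in seq_len(max_tries)) {
    p <- floor(stats::runif(1, lo, hi - width))
    if (!nrow(occupied) ||
        all(p - pad >= occupied$end | p + width + pad <= occupied$start))
      return(p)
  }
  NA_real_
}

#' Simulate the full two-species dataset
#'
#' Builds the ancestral backbone, lineage-specific TE insertions, synteny
#' spacers, conserved/turnover/species-specific loops with convergent
#' CTCF motifs, ChIP peaks, a CpG methylation track with valleys at bound
#' motifs, repeat-to-consensus alignments for the turnover and background
#' TE cohorts, the chain connecting the genomes, and WT/KO contact maps
#' around the first implanted turnover anchor.
#'
#' @param cfg A [simulation_config()].
#' @return A list with `genome_a`, `genome_b` (`DNAStringSet`),
#'   `chain_ab`, `chain_ba`, `loops_a`, `loops_b`, `repeats_a`,
#'   `repeats_b`, `peaks_a`, `peaks_b`, `methylation_a`, `aligns_a`,
#'   `consensi`, `contacts` (WT/KO maps and domain/anchor metadata or
#'   NULL), and `ground_truth`.
#' @export
simulate_dataset <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  tf <- cfg$te_subfamilies
  consensi <- stats::setNames(
    vapply(tf$consensus_length, .random_dna, ""), tf$subfamily)

  chrom_names <- paste0("chr", seq_len(cfg$n_chromosomes))
  L <- cfg$chrom_length
  motif_len <- nchar(.ctcf_motif_seq)
  anchor_half <- 5000

  # per-loop bookkeeping across chromosomes
  loops_meta <- list()   # ancestral loop definitions
  inserts <- list()      # per chromosome: point insertions (p, lenA, lenB, what)
  shared_tes <- list()   # ancestral-interval TEs present in both genomes
  occupied <- list()
  for (cn in chrom_names) {
    inserts[[cn]] <- data.frame(p = numeric(), lenA = numeric(),
                                lenB = numeric(), what = character(),
                                stringsAsFactors = FALSE)
    occupied[[cn]] <- data.frame(start = numeric(), end = numeric())
    shared_tes[[cn]] <- list()
  }
  occupy <- function(cn, s, e) {
    occupied[[cn]] <<- rbind(occupied[[cn]], data.frame(start = s, end = e))
  }

  # turnover loops are placed first so the implanted event count matches
  # the request even when later decoys fail rejection sampling
  n_total_loops <- cfg$n_loops + cfg$n_turnover_events +
    2L * cfg$n_specific_loops
  loop_chrom <- sample(chrom_names, n_total_loops, replace = TRUE)
  kinds <- c(rep("turnover", cfg$n_turnover_events),
             rep("conserved", cfg$n_loops),
             rep("specific_a", cfg$n_specific_loops),
             rep("specific_b", cfg$n_specific_loops))
  te_anchored <- kinds == "conserved" &
    stats::runif(n_total_loops) < cfg$fraction_te_anchored

  te_registry <- list()  # every TE copy: genome presence + cohort
  new_te <- function(subfam_row, chrom, anc_start, present, cohort,
                     strand = "+") {
    id <- paste0(subfam_row$subfamily, "_", length(te_registry) + 1L)
    te_registry[[length(te_registry) + 1L]] <<- list(
      element_id = id, subfamily = subfam_row$subfamily,
      family = subfam_row$family, class = subfam_row$class,
      consensus_length = subfam_row$consensus_length,
      divergence = subfam_row$divergence,
      chrom = chrom, anc_start = anc_start, present = present,
      cohort = cohort, strand = strand)
    id
  }

  loop_id_counter <- 0L
  for (k in seq_len(n_total_loops)) {
    cn <- loop_chrom[k]
    span <- floor(stats::runif(1, 1e5, min(3e5, 0.4 * L)))
    la <- .place(occupied[[cn]], motif_len, 0.03 * L, 0.95 * L - span,
                 pad = 8000, max_tries = 500)
    if (is.na(la)) next
    ra <- la + span
    if (nrow(occupied[[cn]]) &&
        !all(ra - 8000 >= occupied[[cn]]$end |
             ra + motif_len + 8000 <= occupied[[cn]]$start)) next
    occupy(cn, la - 6000, la + motif_len + 6000)
    occupy(cn, ra - 6000, ra + motif_len + 6000)
    loop_id_counter <- loop_id_counter + 1L
    meta <- list(loop_id = sprintf("loop_%03d", loop_id_counter),
                 chrom = cn, kind = kinds[k],
                 anc_left = la, anc_right = ra,
                 te_anchored = te_anchored[k],
                 turnover_side = NA_character_,
                 turnover_te = NA_character_,
                 anchor_te = NA_character_)
    if (kinds[k] == "turnover") {
      meta$turnover_side <- sample(c("left", "right"), 1L)
      subfam_row <- tf[sample(nrow(tf), 1L), ]
      d <- floor(stats::runif(1, 1000, 5000))
      anc_motif <- if (meta$turnover_side == "left") la else ra
      ins_p <- if (meta$turnover_side == "left") anc_motif - d
               else anc_motif + d
      meta$turnover_te <- new_te(subfam_row, cn, ins_p,
                                 present = "A_specific", cohort = "turnover",
                                 strand = if (meta$turnover_side == "left")
                                   "+" else "-")
      meta$turnover_ins_p <- ins_p
      meta$turnover_motif_offset <-
        floor((subfam_row$consensus_length - motif_len) / 2)
      inserts[[cn]] <- rbind(inserts[[cn]], data.frame(
        p = ins_p, lenA = subfam_row$consensus_length, lenB = 0,
        what = meta$turnover_te, stringsAsFactors = FALSE))
    } else if (te_anchored[k]) {
      subfam_row <- tf[sample(nrow(tf), 1L), ]
      te_start <- la - floor((subfam_row$consensus_length - motif_len) / 2)
      meta$anchor_te <- new_te(subfam_row, cn, te_start, present = "both",
                               cohort = "anchor")
      shared_tes[[cn]][[length(shared_tes[[cn]]) + 1L]] <-
        list(element_id = meta$anchor_te, start = te_start,
             len = subfam_row$consensus_length)
    }
    loops_meta[[length(loops_meta) + 1L]] <- meta
  }

  # background shared TEs (the permutation pool)
  for (r in seq_len(nrow(tf))) {
    for (b in seq_len(tf$n_background[r])) {
      cn <- sample(chrom_names, 1L)
      p <- .place(occupied[[cn]], tf$consensus_length[r], 0.02 * L, 0.98 * L)
      if (is.na(p)) next
      occupy(cn, p, p + tf$consensus_length[r])
      id <- new_te(tf[r, ], cn, p, present = "both", cohort = "background")
      shared_tes[[cn]][[length(shared_tes[[cn]]) + 1L]] <-
        list(element_id = id, start = p, len = tf$consensus_length[r])
    }
  }

  # synteny-block spacers (unalignable in both genomes)
  for (cn in chrom_names) {
    if (cfg$n_synteny_blocks < 2) next
    cuts <- L * seq_len(cfg$n_synteny_blocks - 1) / cfg$n_synteny_blocks
    for (cut in cuts) {
      p <- .place(occupied[[cn]], 1, cut - 0.02 * L, cut + 0.02 * L,
                  pad = 6000)
      if (is.na(p)) next
      occupy(cn, p, p + 1)
      inserts[[cn]] <- rbind(inserts[[cn]], data.frame(
        p = p, lenA = floor(stats::runif(1, 5000, 20000)),
        lenB = floor(stats::runif(1, 5000, 20000)), what = "spacer",
        stringsAsFactors = FALSE))
    }
  }

  # generate TE copy sequences (true substitution counts recorded)
  te_registry <- lapply(te_registry, function(te) {
    mult <- if (te$cohort == "turnover") cfg$meth_multiplier_turnover
            else cfg$meth_multiplier_background
    cp <- simulate_te_copies(consensi[[te$subfamily]], 2L, te$divergence,
                             mult, seed = sample.int(2^30, 1L))
    te$seq_a <- cp$seqs[1L]; te$counts_a <- cp$counts[1L, ]
    te$seq_b <- cp$seqs[2L]; te$counts_b <- cp$counts[2L, ]
    te$meth_multiplier <- mult
    te
  })
  te_by_id <- stats::setNames(te_registry,
                              vapply(te_registry, `[[`, "", "element_id"))

  # assemble genomes, chain, per-genome coordinates
  genome_a <- character(); genome_b <- character()
  chains <- list()
  posA_of <- list(); posB_of <- list()
  for (cn in chrom_names) {
    anc <- strsplit(.random_dna(L), "")[[1L]]
    anc_a <- anc; anc_b <- anc
    # overwrite shared TE intervals with per-genome diverged copies
    for (st in shared_tes[[cn]]) {
      te <- te_by_id[[st$element_id]]
      idx <- (st$start + 1):(st$start + st$len)
      anc_a[idx] <- strsplit(te$seq_a, "")[[1L]]
      anc_b[idx] <- strsplit(te$seq_b, "")[[1L]]
    }
    # plant ancestral motifs (degraded in A for turnover loops)
    motif_chars <- strsplit(.ctcf_motif_seq, "")[[1L]]
    rc <- rev(chartr("ACGT", "TGCA", motif_chars))
    for (m in loops_meta) {
      if (m$chrom != cn) next
      for (side in c("left", "right")) {
        pos <- if (side == "left") m$anc_left else m$anc_right
        chars <- if (side == "left") motif_chars else rc
        idx <- (pos + 1):(pos + motif_len)
        degrade_a <- identical(m$turnover_side, side)
        planted_a <- chars
        if (degrade_a) {
          hit <- sample(motif_len, 3L)
          planted_a[hit] <- vapply(planted_a[hit], function(ch)
            sample(setdiff(c("A", "C", "G", "T"), ch), 1L), "")
        }
        if (m$kind != "specific_b") anc_a[idx] <- planted_a
        if (m$kind != "specific_a") anc_b[idx] <- chars
      }
    }
    ins <- inserts[[cn]]
    ins <- ins[order(ins$p), , drop = FALSE]
    # coordinate maps: ancestral -> per-genome offsets (bind this
    # chromosome's insertion table, not the loop variable)
    make_shift <- function(tab, col) {
      force(tab); force(col)
      function(x) x + if (nrow(tab)) sum(tab[[col]][tab$p <= x]) else 0
    }
    posA_of[[cn]] <- make_shift(ins, "lenA")
    posB_of[[cn]] <- make_shift(ins, "lenB")
    # build sequences by interleaving segments and insertions
    seg_a <- character(); seg_b <- character()
    prev <- 0
    if (nrow(ins)) for (t in seq_len(nrow(ins))) {
      seg <- if (ins$p[t] > prev) (prev + 1):(ins$p[t]) else integer()
      seg_a <- c(seg_a, paste(anc_a[seg], collapse = ""))
      seg_b <- c(seg_b, paste(anc_b[seg], collapse = ""))
      if (ins$what[t] == "spacer") {
        seg_a <- c(seg_a, .random_dna(ins$lenA[t]))
        seg_b <- c(seg_b, .random_dna(ins$lenB[t]))
      } else {
        te <- te_by_id[[ins$what[t]]]
        m <- loops_meta[[which(vapply(loops_meta, function(x)
          identical(x$turnover_te, ins$what[t]), TRUE))[1L]]]
        chars <- strsplit(te$seq_a, "")[[1L]]
        mo <- m$turnover_motif_offset
        chars[(mo + 1):(mo + motif_len)] <-
          if (te$strand == "+") motif_chars else rc
        seg_a <- c(seg_a, paste(chars, collapse = ""))
      }
      prev <- ins$p[t]
    }
    seg_a <- c(seg_a, paste(anc_a[(prev + 1):L], collapse = ""))
    seg_b <- c(seg_b, paste(anc_b[(prev + 1):L], collapse = ""))
    seq_a <- paste(seg_a, collapse = ""); seq_b <- paste(seg_b, collapse = "")
    genome_a[cn] <- seq_a; genome_b[cn] <- seq_b
    # chain blocks between consecutive insertion points
    pts <- if (nrow(ins)) ins$p else numeric()
    blocks <- data.frame(s_start = numeric(), t_start = numeric(),
                         size = numeric())
    a_off <- 0; b_off <- 0
    prev <- 0
    for (bd in c(pts, L)) {
      if (bd > prev)
        blocks <- rbind(blocks, data.frame(
          s_start = prev + a_off, t_start = prev + b_off, size = bd - prev))
      if (bd < L) {
        row <- ins[ins$p == bd, ][1L, ]
        a_off <- a_off + row$lenA; b_off <- b_off + row$lenB
      }
      prev <- bd
    }
    chains[[length(chains) + 1L]] <- list(
      score = L, s_chrom = cn, s_size = nchar(seq_a),
      s_start = blocks$s_start[1L],
      s_end = blocks$s_start[nrow(blocks)] + blocks$size[nrow(blocks)],
      t_chrom = cn, t_size = nchar(seq_b), t_strand = "+", blocks = blocks)
  }
  chain_ab <- structure(list(chains = chains), class = "chain_map")
  chain_ba <- invert_chain(chain_ab)

  # repeat tables per genome (genome coordinates)
  rep_rows <- function(genome) {
    rows <- lapply(te_registry, function(te) {
      in_a <- te$present %in% c("both", "A_specific")
      in_b <- te$present == "both"
      if ((genome == "A" && !in_a) || (genome == "B" && !in_b)) return(NULL)
      pos_fun <- if (genome == "A") posA_of[[te$chrom]] else posB_of[[te$chrom]]
      start <- if (te$present == "A_specific" && genome == "A")
        pos_fun(te$anc_start) - te$consensus_length  # insertion precedes point shift
      else pos_fun(te$anc_start)
      cnts <- if (genome == "A") te$counts_a else te$counts_b
      data.frame(chrom = te$chrom, start = start,
                 end = start + te$consensus_length, strand = te$strand,
                 subfamily = te$subfamily, family = te$family,
                 class = te$class,
                 pct_div = round(100 * sum(cnts) / te$consensus_length, 1),
                 element_id = te$element_id, consensus_id = te$subfamily,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
    out <- out[order(out$chrom, out$start), , drop = FALSE]
    rownames(out) <- NULL
    out
  }

  # loop tables per genome
  mk_loops <- function(genome) {
    rows <- list()
    for (m in loops_meta) {
      if (genome == "A" && m$kind == "specific_b") next
      if (genome == "B" && m$kind == "specific_a") next
      pos_fun <- if (genome == "A") posA_of[[m$chrom]] else posB_of[[m$chrom]]
      lm <- pos_fun(m$anc_left); rm_ <- pos_fun(m$anc_right)
      lstrand <- "+"; rstrand <- "-"
      if (genome == "A" && !is.na(m$turnover_side)) {
        te <- te_by_id[[m$turnover_te]]
        ins_a <- pos_fun(m$turnover_ins_p) - te$consensus_length
        te_motif <- ins_a + m$turnover_motif_offset
        if (m$turnover_side == "left") lm <- te_motif else rm_ <- te_motif
      }
      rows[[length(rows) + 1L]] <- data.frame(
        loop_id = m$loop_id, chrom = m$chrom,
        start1 = lm + floor(motif_len / 2) - anchor_half,
        end1 = lm + floor(motif_len / 2) + anchor_half,
        start2 = rm_ + floor(motif_len / 2) - anchor_half,
        end2 = rm_ + floor(motif_len / 2) + anchor_half,
        motif1_start = lm, motif1_end = lm + motif_len, motif1_strand = "+",
        motif2_start = rm_, motif2_end = rm_ + motif_len,
        motif2_strand = "-",
        origin1 = "unidentified", subfamily1 = NA_character_,
        element_id1 = NA_character_,
        origin2 = "unidentified", subfamily2 = NA_character_,
        element_id2 = NA_character_, stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    out <- out[order(out$chrom, out$start1), , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  loops_a <- mk_loops("A"); loops_b <- mk_loops("B")

  # ChIP peaks at every bound motif (the degraded ancestral motif in A has
  # no peak, so implanted events are of the "replacement" class)
  mk_peaks <- function(loops, genome) {
    sites <- unique_anchor_sites(loops)
    data.frame(chrom = sites$chrom, start = sites$start - 150,
               end = sites$end + 150,
               name = paste0("peak_", genome, "_", seq_len(nrow(sites))),
               score = 500, strand = ".", signal = 10, pvalue = -1,
               qvalue = -1,
               summit = floor((sites$end - sites$start) / 2) + 150,
               stringsAsFactors = FALSE)
  }
  peaks_a <- mk_peaks(loops_a, "A"); peaks_b <- mk_peaks(loops_b, "B")

  # CpG methylation track for genome A: background with valleys at bound
  # motifs, CpG positions taken from the actual sequence near each site
  meth_rows <- list()
  sites_a <- unique_anchor_sites(loops_a)
  for (k in seq_len(nrow(sites_a))) {
    center <- floor((sites_a$start[k] + sites_a$end[k]) / 2)
    lo <- max(0, center - 2500)
    windowseq <- substr(genome_a[[sites_a$chrom[k]]], lo + 1, center + 2500)
    cg <- gregexpr("CG", windowseq)[[1L]]
    if (cg[1L] == -1L) next
    pos <- lo + as.integer(cg) - 1L
    frac <- ifelse(abs(pos - center) <= cfg$meth_valley_halfwidth,
                   cfg$meth_valley, cfg$meth_background)
    frac <- pmin(1, pmax(0, frac + stats::rnorm(length(pos), 0, 0.02)))
    meth_rows[[length(meth_rows) + 1L]] <- data.frame(
      chrom = sites_a$chrom[k], start = pos, end = pos + 2,
      fraction = round(frac, 3), coverage = 1L + stats::rpois(length(pos), 25),
      stringsAsFactors = FALSE)
  }
  methylation_a <- do.call(rbind, meth_rows)
  methylation_a <- methylation_a[!duplicated(
    methylation_a[, c("chrom", "start")]), , drop = FALSE]
  methylation_a <- methylation_a[order(methylation_a$chrom,
                                       methylation_a$start), , drop = FALSE]
  rownames(methylation_a) <- NULL

  repeats_a <- rep_rows("A"); repeats_b <- rep_rows("B")

  # consensus alignments for genome-A TE copies (turnover + background)
  aligns_a <- lapply(te_registry, function(te) {
    if (!(te$present %in% c("both", "A_specific"))) return(NULL)
    row <- repeats_a[repeats_a$element_id == te$element_id, ]
    if (nrow(row) != 1L) return(NULL)
    list(element_id = te$element_id, consensus_id = te$subfamily,
         chrom = row$chrom, start = row$start, end = row$end,
         strand = te$strand, g_aligned = te$seq_a,
         c_aligned = consensi[[te$subfamily]])
  })
  aligns_a <- aligns_a[!vapply(aligns_a, is.null, TRUE)]

  # ground truth
  turnover_truth <- do.call(rbind, lapply(loops_meta, function(m) {
    if (is.na(m$turnover_side)) return(NULL)
    data.frame(loop_id = m$loop_id, side = m$turnover_side,
               element_id = m$turnover_te,
               subfamily = te_by_id[[m$turnover_te]]$subfamily,
               orientation = if (m$turnover_side == "left") "+" else "-",
               stringsAsFactors = FALSE)
  }))
  if (is.null(turnover_truth))
    turnover_truth <- data.frame(loop_id = character(), side = character(),
                                 element_id = character(),
                                 subfamily = character(),
                                 orientation = character(),
                                 stringsAsFactors = FALSE)
  loop_truth <- do.call(rbind, lapply(loops_meta, function(m)
    data.frame(loop_id = m$loop_id, chrom = m$chrom, kind = m$kind,
               te_anchored = m$te_anchored, stringsAsFactors = FALSE)))
  te_truth <- do.call(rbind, lapply(te_registry, function(te)
    data.frame(element_id = te$element_id, subfamily = te$subfamily,
               cohort = te$cohort, present = te$present,
               meth_multiplier = te$meth_multiplier,
               divergence = te$divergence, stringsAsFactors = FALSE)))

  # WT/KO contact maps around the first turnover anchor (if any)
  contacts <- NULL
  if (nrow(turnover_truth)) {
    m <- loops_meta[[which(vapply(loops_meta, function(x)
      identical(x$loop_id, turnover_truth$loop_id[1L]), TRUE))[1L]]]
    pos_fun <- posA_of[[m$chrom]]
    anchor <- pos_fun(if (m$turnover_side == "left") m$anc_left
                      else m$anc_right)
    bs <- cfg$contact_bin_size
    reg_start <- max(0, floor((anchor - 1e6) / bs) * bs)
    reg_end <- reg_start + 2e6
    boundary <- floor((anchor - reg_start) / bs) * bs + reg_start
    partner <- pos_fun(if (m$turnover_side == "left") m$anc_right
                       else m$anc_left)
    loop_tab <- data.frame(a1 = min(anchor, partner),
                           a2 = max(anchor, partner))
    # control domain pair in the larger boundary-free flank, clear of the
    # edited boundary and the target domains
    if (boundary - reg_start >= reg_end - boundary)
      ctrl0 <- reg_start + 5e4
    else
      ctrl0 <- min(boundary + 4e5 + 5e4, reg_end - 4.5e5)
    ctrl_b <- ctrl0 + 2e5
    domains_wt <- list(gi(m$chrom, reg_start, boundary),
                       gi(m$chrom, boundary, reg_end))
    wt <- simulate_contact_map(m$chrom, reg_start, reg_end, bs,
                               domains = domains_wt, loop_anchors = loop_tab,
                               reads = cfg$reads_per_map, decay = cfg$decay,
                               seed = cfg$seed + 101L)
    ko <- simulate_contact_map(m$chrom, reg_start, reg_end, bs,
                               domains = list(gi(m$chrom, reg_start, reg_end)),
                               loop_anchors = NULL,
                               reads = cfg$reads_per_map, decay = cfg$decay,
                               seed = cfg$seed + 202L)
    contacts <- list(
      wt = wt, ko = ko, boundary = boundary,
      target = list(domain1 = gi(m$chrom, max(reg_start, boundary - 4e5),
                                 boundary),
                    domain2 = gi(m$chrom, boundary,
                                 min(reg_end, boundary + 4e5))),
      control = list(domain1 = gi(m$chrom, ctrl0, ctrl_b),
                     domain2 = gi(m$chrom, ctrl_b, ctrl_b + 2e5)),
      anchor_window = gi(m$chrom, floor(anchor / bs) * bs,
                         floor(anchor / bs) * bs + bs))
  }

  list(config = cfg,
       genome_a = Biostrings::DNAStringSet(genome_a),
       genome_b = Biostrings::DNAStringSet(genome_b),
       chain_ab = chain_ab, chain_ba = chain_ba,
       loops_a = loops_a, loops_b = loops_b,
       repeats_a = repeats_a, repeats_b = repeats_b,
       peaks_a = peaks_a, peaks_b = peaks_b,
       methylation_a = methylation_a,
       aligns_a = aligns_a,
       consensi = Biostrings::DNAStringSet(consensi),
       contacts = contacts,
       ground_truth = list(loops = loop_truth, turnover = turnover_truth,
                           tes = te_truth))
}

#' Simulate a genome pair (genomes, chain, ground truth)
#'
#' Convenience wrapper around [simulate_dataset()] returning the sequence
#' and alignment layer only.
#'
#' @param cfg A [simulation_config()].
#' @return List `genome_a`, `genome_b`, `chain_ab`, `chain_ba`,
#'   `ground_truth`.
#' @export
simulate_genome_pair <- function(cfg = simulation_config()) {
  sim <- simulate_dataset(cfg)
  sim[c("genome_a", "genome_b", "chain_ab", "chain_ba", "ground_truth")]
}
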