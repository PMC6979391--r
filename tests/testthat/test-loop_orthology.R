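test_that("lifting through an identity chain is the identity", {
  cm <- identity_chain()
  q <- gi("chr1", 12345, 23456)
  res <- lift_interval(cm, q, min_match = 1)
  expect_equal(res$mapped$start, q$start)
  expect_equal(res$mapped$end, q$end)
  expect_equal(res$matched_fraction, 1)
})

test_that("the minMatch gate suppresses partial lifts", {
  # chain covering 40% of the query
  cm <- structure(list(chains = list(list(
    score = 100, s_chrom = "chr1", s_size = 1000, s_start = 0, s_end = 40,
    t_chrom = "chr1", t_size = 1000, t_strand = "+",
    blocks = data.frame(s_start = 0, t_start = 0, size = 40)))),
    class = "chain_map")
  res <- lift_interval(cm, gi("chr1", 0, 100), min_match = 0.5)
  expect_null(res$mapped)
  expect_equal(res$matched_fraction, 0.4)
  res2 <- lift_interval(cm, gi("chr1", 0, 100), min_match = 0.4)
  expect_false(is.null(res2$mapped))
})

test_that("two-block chains map spans by block arithmetic", {
  cm <- two_block_chain()
  res <- lift_interval(cm, gi("chr1", 50, 250), min_match = 0.1)
  expect_equal(res$mapped$start, 1050)
  expect_equal(res$mapped$end, 1200)
  # 50 bases lift in each block: 100 of 200 query bases
  expect_equal(res$matched_fraction, 0.5)
  # absent chromosome
  res2 <- lift_interval(cm, gi("chrX", 50, 250), min_match = 0.1)
  expect_null(res2$mapped)
  expect_equal(res2$matched_fraction, 0)
})

test_that("lift then reverse-lift returns to the block-covered origin", {
  sim <- shared_sim()
  loops <- sim$loops_a
  for (k in sample(nrow(loops), 5)) {
    q <- gi(loops$chrom[k], loops$start1[k], loops$end1[k])
    fwd <- lift_interval(sim$chain_ab, q, 0.1)
    if (is.null(fwd$mapped)) next
    back <- lift_interval(sim$chain_ba, fwd$mapped, 0.1)
    expect_false(is.null(back$mapped))
    expect_lte(back$mapped$start, q$start + 1)
    expect_gte(back$mapped$end, q$end - 1)
  }
})

test_that("chromosome-preserving shuffles conserve lengths and are uniform", {
  feats <- data.frame(chrom = rep(c("chr1", "chr2"), c(30, 20)),
                      start = seq(0, by = 1000, length.out = 50))
  feats$end <- feats$start + rep(c(100, 250), 25)
  lens <- c(chr1 = 1e6, chr2 = 5e5)
  sh <- shuffle_features(feats, lens, seed = 4)
  expect_equal(table(sh$chrom), table(feats$chrom))
  expect_equal(sort(sh$end - sh$start), sort(feats$end - feats$start))
  expect_true(all(sh$start >= 0 & sh$end <= lens[sh$chrom]))
  expect_identical(shuffle_features(feats, lens, seed = 4), sh)
  # uniformity of a single feature's start over many shuffles
  one <- data.frame(chrom = "chr1", start = 0, end = 100)
  starts <- vapply(1:2000, function(s)
    shuffle_features(one, c(chr1 = 1e4), seed = s)$start, 0)
  ct <- table(cut(starts, breaks = seq(0, 1e4 - 99, length.out = 11),
                  include.lowest = TRUE))
  expect_gt(stats::chisq.test(ct)$p.value, 1e-4)
  expect_error(shuffle_features(data.frame(chrom = "chr1", start = 0,
                                           end = 2e4), c(chr1 = 1e4), 1),
               "longer")
})

test_that("minMatch optimization: identity ties break to the largest gate", {
  feats <- data.frame(chrom = "chr1", start = seq(1e4, 9e5, by = 5e4))
  feats$end <- feats$start + 1000
  res <- optimize_min_match(feats, identity_chain(), c(0.1, 0.5, 1),
                            c(chr1 = 1e6), n_shuffles = 4, seed = 2)
  expect_equal(res$chosen, 1)
  expect_true(all(res$table$mean_lifted == nrow(feats)))
})

test_that("lifted counts are non-increasing in minMatch", {
  sim <- shared_sim()
  feats <- data.frame(chrom = sim$repeats_a$chrom,
                      start = pmax(0, sim$repeats_a$start - 2000),
                      end = sim$repeats_a$end + 2000)
  res <- optimize_min_match(feats, sim$chain_ab, c(0.05, 0.1, 0.5, 0.9, 1),
                            c(chr1 = 2.6e6, chr2 = 2.6e6),
                            n_shuffles = 3, seed = 8)
  expect_true(all(diff(res$table$mean_lifted) <= 0))
})

test_that("the vicinity window is min(half loop length, threshold) on both anchors", {
  # query loop 80 kb long: w = 40 kb
  lifted <- data.frame(loop_id = "q", lifted = TRUE, chrom = "chr1",
                       mid1 = 1e6, mid2 = 1.08e6, length = 8e4,
                       matched_fraction = 1, stringsAsFactors = FALSE)
  targets <- toy_loops()
  targets$chrom <- "chr1"
  targets[1, c("start1", "end1")] <- c(1e6 - 39000 - 5000, 1e6 - 39000 + 5000)
  targets[1, c("start2", "end2")] <- c(1.08e6 + 39000 - 5000,
                                       1.08e6 + 39000 + 5000)
  m <- match_loops(lifted, targets[1, ], vicinity = 50000)
  expect_equal(nrow(m), 1L)
  expect_equal(m$window, 40000)
  # query loop 200 kb: w capped at the 50 kb vicinity
  lifted$length <- 2e5; lifted$mid2 <- 1.2e6
  targets[1, c("start2", "end2")] <- c(1.2e6 + 49000 - 5000,
                                       1.2e6 + 49000 + 5000)
  m2 <- match_loops(lifted, targets[1, ], vicinity = 50000)
  expect_equal(m2$window, 50000)
  # conjunction rule: offsets (39 kb, 51 kb) fail on the right anchor
  targets[1, c("start2", "end2")] <- c(1.2e6 + 51000 - 5000,
                                       1.2e6 + 51000 + 5000)
  targets[1, c("start1", "end1")] <- c(1e6 - 39000 - 5000,
                                       1e6 - 39000 + 5000)
  expect_equal(nrow(match_loops(lifted, targets[1, ], 50000)), 0L)
})

test_that("vicinity calibration: null shuffles give FDR 0, saturation rejects", {
  lifted <- data.frame(loop_id = "q", lifted = TRUE, chrom = "chr1",
                       mid1 = 1e6, mid2 = 1.1e6, length = 1e5,
                       matched_fraction = 1, stringsAsFactors = FALSE)
  target <- toy_loops()[1, ]
  target[, c("start1", "end1")] <- c(1e6 - 5000, 1e6 + 5000)
  target[, c("start2", "end2")] <- c(1.1e6 - 5000, 1.1e6 + 5000)
  far <- transform(lifted, mid1 = 2e6, mid2 = 2.1e6)
  res <- calibrate_vicinity(lifted, list(far), target, c(500, 5000, 50000))
  expect_true(all(res$table$fdr == 0))
  expect_equal(res$chosen, 50000)  # largest threshold under the cutoff
  # shuffled matches equal to real matches saturate the FDR
  res2 <- calibrate_vicinity(lifted, list(lifted), target, c(500, 50000))
  expect_true(all(na.omit(res2$table$fdr) >= 1))
  expect_true(is.na(res2$chosen))
})

test_that("reciprocal best hits form a partial matching with distance tie-break", {
  mk <- function(q, t, lo, ro) data.frame(query_id = q, target_id = t,
                                          left_offset = lo, right_offset = ro,
                                          window = 5e4,
                                          stringsAsFactors = FALSE)
  # unique mutual match
  rbh <- reciprocal_best_hits(mk("a", "b", 1, 1), mk("b", "a", 1, 1))
  expect_equal(nrow(rbh), 1L)
  expect_equal(rbh$loop_a, "a")
  # reciprocity violation: b prefers a2
  ab <- mk("a", "b", 1, 1)
  ba <- rbind(mk("b", "a2", 1, 1), mk("b", "a", 10, 10))
  expect_equal(nrow(reciprocal_best_hits(ab, ba)), 0L)
  # multi-match: a pairs with the closer b1
  ab2 <- rbind(mk("a", "b1", 5000, 5000), mk("a", "b2", 20000, 20000))
  ba2 <- rbind(mk("b1", "a", 5000, 5000), mk("b2", "a", 20000, 20000))
  rbh2 <- reciprocal_best_hits(ab2, ba2)
  expect_equal(rbh2$loop_b, "b1")
  # brute-force check: the kept pair minimizes the summed offsets among
  # all mutual candidates
  tot <- ab2$left_offset + ab2$right_offset
  expect_equal(rbh2$loop_b, ab2$target_id[which.min(tot)])
  expect_false(any(duplicated(rbh2$loop_a)) || any(duplicated(rbh2$loop_b)))
})

test_that("orthology calls on synthetic data pair conserved loops", {
  sim <- shared_sim()
  la <- annotate_loops(sim$loops_a, sim$repeats_a)
  lb <- annotate_loops(sim$loops_b, sim$repeats_b)
  calls <- loop_orthology(la, lb, sim$chain_ab, sim$chain_ba)
  truth <- sim$ground_truth$loops
  conserved <- truth$loop_id[truth$kind %in% c("conserved", "turnover")]
  # every called pair links a loop to itself (ids are shared across genomes)
  expect_true(all(calls$loop_a == calls$loop_b))
  expect_true(all(calls$loop_a %in% conserved))
  expect_gte(nrow(calls), 0.9 * length(conserved))
  # no loop appears twice
  expect_false(any(duplicated(calls$loop_a)))
  expect_false(any(duplicated(calls$loop_b)))
})
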