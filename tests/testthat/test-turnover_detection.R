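test_that("Pearson chi-square matches its closed form and the stats oracle", {
  # hand-checked closed form N(ad-bc)^2/(r1 r2 c1 c2)
  res <- pearson_chi2(matrix(c(20, 10, 10, 20), 2))
  expect_equal(res$chi2, 20 / 3, tolerance = 1e-12)
  # independence
  flat <- pearson_chi2(matrix(c(10, 10, 10, 10), 2))
  expect_equal(flat$chi2, 0)
  expect_equal(flat$p, 1)
  # zero margin flagged
  degenerate <- pearson_chi2(matrix(c(5, 0, 3, 0), 2))
  expect_true(degenerate$low_count)
  expect_true(is.na(degenerate$p))
  # 1000 random tables against the expected-count oracle and chisq.test
  set.seed(99)
  for (k in 1:1000) {
    tab <- matrix(rpois(4, 20) + 1, 2)
    mine <- pearson_chi2(tab)
    expect_equal(mine$chi2, oracle_chi2(tab), tolerance = 1e-12)
    if (k <= 50) {
      ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      expect_equal(mine$chi2, unname(ref$statistic), tolerance = 1e-10)
      expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
    }
  }
})

test_that("turnover detection recovers implanted events without false calls", {
  sim <- shared_sim()
  la <- annotate_loops(sim$loops_a, sim$repeats_a)
  lb <- annotate_loops(sim$loops_b, sim$repeats_b)
  calls <- loop_orthology(la, lb, sim$chain_ab, sim$chain_ba)
  events <- detect_turnover(calls, la, lb, sim$repeats_a, sim$repeats_b,
                            sim$chain_ab)
  truth <- sim$ground_truth$turnover
  key <- function(l, s) paste(l, s)
  hits <- key(events$loop_a, events$side) %in% key(truth$loop_id, truth$side)
  expect_true(all(hits))                      # no false discoveries
  expect_gte(sum(hits), 0.9 * nrow(truth))    # high recall
  expect_equal(events$element_id,
               truth$element_id[match(events$loop_a, truth$loop_id)])
  expect_error(detect_turnover(calls, la, lb, sim$repeats_a, sim$repeats_b,
                               NULL), "chain")
})

test_that("conserved non-RE loops yield no events; two-sided loops yield two", {
  sim <- shared_sim()
  la <- annotate_loops(sim$loops_a, sim$repeats_a)
  lb <- annotate_loops(sim$loops_b, sim$repeats_b)
  calls <- loop_orthology(la, lb, sim$chain_ab, sim$chain_ba)
  non_re <- la$loop_id[la$origin1 == "non_RE" & la$origin2 == "non_RE"]
  ev <- detect_turnover(calls[calls$loop_a %in% non_re, , drop = FALSE],
                        la, lb, sim$repeats_a, sim$repeats_b, sim$chain_ab)
  expect_equal(nrow(ev), 0L)
  # construct a loop (present in both genomes) whose both anchors are
  # RE-derived species-specific TEs
  la2 <- la[la$loop_id == calls$loop_a[1], , drop = FALSE]
  te <- sim$ground_truth$turnover$element_id[1:2]
  rep_rows <- sim$repeats_a[sim$repeats_a$element_id %in% te, ]
  la2$origin1 <- la2$origin2 <- "RE_derived"
  la2$element_id1 <- rep_rows$element_id[1]
  la2$element_id2 <- rep_rows$element_id[2]
  lb2 <- lb[lb$loop_id == la2$loop_id, , drop = FALSE]
  calls2 <- data.frame(loop_a = la2$loop_id, loop_b = la2$loop_id,
                       left_offset = 0, right_offset = 0, window = 5e4,
                       stringsAsFactors = FALSE)
  ev2 <- detect_turnover(calls2, la2, lb2, sim$repeats_a, sim$repeats_b,
                         sim$chain_ab)
  expect_equal(nrow(ev2), 2L)
  expect_setequal(ev2$side, c("left", "right"))
})

test_that("candidate filtering separates replacement from redundant events", {
  loops <- toy_loops()
  loops$origin1 <- "RE_derived"
  mk_event <- function(id) data.frame(
    loop_a = id, loop_b = id, side = "left", element_id = "te1",
    subfamily = "B2_Mm2", orientation = "+",
    anchor_key = paste0("k", id), species_specific = TRUE,
    stringsAsFactors = FALSE)
  peak <- function(s, e, nm) data.frame(
    chrom = "chr1", start = s, end = e, name = nm, score = 0, strand = ".",
    signal = 0, pvalue = -1, qvalue = -1, summit = -1,
    stringsAsFactors = FALSE)
  own <- peak(14980, 15020, "own")      # overlaps the L1 left motif
  anc <- peak(17000, 17400, "anc")      # a nearby ancestral site peak
  extra <- peak(30000, 30400, "extra")
  ancestral <- data.frame(chrom = "chr1", start = 17000, end = 17400)
  # no other peak in the window -> replacement
  got <- filter_candidates(mk_event("L1"), own, ancestral, 50000, loops)
  expect_equal(got$candidate_class, "replacement")
  # exactly one other peak, flagged ancestral -> redundant
  got2 <- filter_candidates(mk_event("L1"), rbind(own, anc), ancestral,
                            50000, loops)
  expect_equal(got2$candidate_class, "redundant")
  # one other peak that is not ancestral -> dropped
  got3 <- filter_candidates(mk_event("L1"), rbind(own, extra), ancestral,
                            50000, loops)
  expect_equal(nrow(got3), 0L)
  # two other peaks -> dropped
  got4 <- filter_candidates(mk_event("L1"), rbind(own, anc, extra),
                            ancestral, 50000, loops)
  expect_equal(nrow(got4), 0L)
})

test_that("orientation tables tally unique anchors and attach the chi-square", {
  mk <- function(n, side, orient, key0) data.frame(
    loop_a = paste0("l", seq_len(n)), loop_b = paste0("l", seq_len(n)),
    side = side, element_id = "te", subfamily = "s", orientation = orient,
    anchor_key = paste0(key0, seq_len(n)), species_specific = TRUE,
    stringsAsFactors = FALSE)
  ev <- rbind(mk(53, "left", "+", "a"), mk(8, "left", "-", "b"),
              mk(18, "right", "+", "c"), mk(45, "right", "-", "d"))
  tab <- orientation_table(ev)
  expect_equal(unname(tab$counts["+", "left"]), 53)
  expect_equal(unname(tab$counts["-", "right"]), 45)
  expect_equal(tab$n, 124)
  # an anchor tethering two loops counts once
  twice <- mk(1, "left", "+", "a")
  dup <- rbind(twice, transform(twice, loop_a = "other"))
  expect_equal(orientation_table(dup)$n, 1)
  # empty input gives the all-zero table with missing p
  empty <- orientation_table(ev[0, ])
  expect_equal(sum(empty$counts), 0)
  expect_true(is.na(empty$p))
})

test_that("implanted orientation bias yields positive association with growing power", {
  mk <- function(n, side, orient, key0) data.frame(
    loop_a = paste0("l", seq_len(n)), loop_b = paste0("l", seq_len(n)),
    side = side, element_id = "te", subfamily = "s", orientation = orient,
    anchor_key = paste0(key0, seq_len(n)), species_specific = TRUE,
    stringsAsFactors = FALSE)
  p_at <- function(n) {
    ev <- rbind(mk(round(0.85 * n), "left", "+", "a"),
                mk(round(0.15 * n), "left", "-", "b"),
                mk(round(0.15 * n), "right", "+", "c"),
                mk(round(0.85 * n), "right", "-", "d"))
    orientation_table(ev)$p
  }
  expect_lt(p_at(40), 0.05)
  expect_lt(p_at(160), p_at(40))  # p decreases with n
})
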