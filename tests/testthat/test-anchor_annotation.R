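test_that("the 10-bp motif-repeat overlap rule is a sharp threshold", {
  reps <- data.frame(chrom = "chr1", start = 100, end = 300, strand = "+",
                     subfamily = "B2_Mm2", family = "B2", class = "SINE",
                     pct_div = 10, element_id = "te1",
                     consensus_id = "B2_Mm2", stringsAsFactors = FALSE)
  # 19-bp motif overlapping the repeat by exactly 10 bp
  hit <- annotate_anchor_origin(gi("chr1", 91, 110, "+"), reps)
  expect_equal(hit$origin, "RE_derived")
  expect_equal(hit$subfamily, "B2_Mm2")
  # 9 bp of overlap is not enough
  miss <- annotate_anchor_origin(gi("chr1", 90, 109, "+"), reps)
  expect_equal(miss$origin, "non_RE")
  # absent motif stays unidentified
  expect_equal(annotate_anchor_origin(NULL, reps)$origin, "unidentified")
})

test_that("multi-repeat overlaps resolve by maximal overlap, then divergence, then position", {
  reps <- data.frame(
    chrom = "chr1", start = c(100, 104), end = c(115, 116), strand = "+",
    subfamily = c("A15", "B12"), family = c("B2", "B2"), class = "SINE",
    pct_div = c(20, 1), element_id = c("teA", "teB"),
    consensus_id = c("A15", "B12"), stringsAsFactors = FALSE)
  # motif 100-119: overlaps teA by 15, teB by 12 -> teA wins on overlap
  got <- annotate_anchor_origin(gi("chr1", 100, 119, "+"), reps)
  # brute-force enumeration oracle
  ov <- pmin(reps$end, 119) - pmax(reps$start, 100)
  expect_equal(got$element_id, reps$element_id[which.max(ov)])
  expect_equal(got$element_id, "teA")
  # equal overlaps: lower divergence wins
  reps2 <- transform(reps, start = c(100, 100), end = c(119, 119))
  expect_equal(annotate_anchor_origin(gi("chr1", 100, 119, "+"),
                                      reps2)$element_id, "teB")
})

test_that("loop classification follows the anchor-evidence rules and partitions", {
  combos <- expand.grid(o1 = c("RE_derived", "non_RE", "unidentified"),
                        o2 = c("RE_derived", "non_RE", "unidentified"),
                        stringsAsFactors = FALSE)
  loops <- toy_loops()[rep(1, nrow(combos)), ]
  loops$loop_id <- paste0("L", seq_len(nrow(combos)))
  loops$origin1 <- combos$o1
  loops$origin2 <- combos$o2
  got <- classify_loops(loops)
  expect_equal(got$class[combos$o1 == "RE_derived" |
                           combos$o2 == "RE_derived"],
               rep("RE_derived", 5))
  expect_equal(got$class[combos$o1 == "non_RE" & combos$o2 == "non_RE"],
               "non_RE")
  both_unid <- combos$o1 == "unidentified" & combos$o2 == "unidentified"
  one_unid <- (combos$o1 == "unidentified" & combos$o2 == "non_RE") |
    (combos$o2 == "unidentified" & combos$o1 == "non_RE")
  expect_equal(got$class[both_unid | one_unid], rep("excluded", 3))
  # partition property
  expect_equal(sum(table(got$class)), nrow(combos))
})

test_that("annotation is order-independent with respect to repeat input order", {
  sim <- shared_sim()
  reps <- sim$repeats_a
  a <- annotate_loops(sim$loops_a, reps)
  b <- annotate_loops(sim$loops_a, reps[rev(seq_len(nrow(reps))), ])
  expect_equal(a$origin1, b$origin1)
  expect_equal(a$element_id1, b$element_id1)
  expect_equal(a$origin2, b$origin2)
})

test_that("peak origin uses the single center base", {
  reps <- toy_repeats()[3, ]  # repeat at [400000, 400200)
  mk <- function(s, e, summit = -1)
    data.frame(chrom = "chr1", start = s, end = e, name = "p", score = 0,
               strand = ".", signal = 0, pvalue = -1, qvalue = -1,
               summit = summit, stringsAsFactors = FALSE)
  # center at start + length/2
  inside <- annotate_peak_origin(mk(399990, 400190), reps)   # center 400090
  expect_equal(inside$origin, "RE_derived")
  # center one base left of the repeat start
  left <- annotate_peak_origin(mk(399899, 400099), reps)     # center 399999
  expect_equal(left$origin, "non_RE")
  at_start <- annotate_peak_origin(mk(399900, 400100), reps) # center 400000
  expect_equal(at_start$origin, "RE_derived")
  # an explicit summit overrides the midpoint
  summit <- annotate_peak_origin(mk(399899, 400099, summit = 150), reps)
  expect_equal(summit$origin, "RE_derived")
})

test_that("enrichment is observed share over length-weighted background share", {
  # 65 of 100 calls in family F whose background bp share is 0.05 -> 13x
  reps <- data.frame(
    chrom = "chr1", start = 0, end = c(rep(50, 100), rep(950, 1)),
    strand = "+", subfamily = c(rep("F1", 100), "G1"),
    family = c(rep("F", 100), "G"), class = "SINE", pct_div = 5,
    element_id = paste0("te", 1:101), consensus_id = "x",
    stringsAsFactors = FALSE)
  # family F: 100 * 50 bp = 5000 bp of 100000 bp total -> share 0.05
  reps$end <- c(rep(50, 100), 95000)
  calls <- data.frame(origin = "RE_derived",
                      element_id = c(rep("te1", 65), rep("te101", 35)),
                      stringsAsFactors = FALSE)
  tab <- enrichment_table(calls, reps, level = "family")
  expect_equal(tab$enrichment[tab$group == "F"], 0.65 / 0.05, tolerance = 1e-12)
  expect_equal(tab$enrichment[tab$group == "F"], 13)
  # observed fractions sum to one
  expect_equal(sum(tab$observed_fraction), 1)
  # null case: observed share equals background share -> enrichment 1
  calls2 <- data.frame(origin = "RE_derived",
                       element_id = c(rep("te1", 5), rep("te101", 95)),
                       stringsAsFactors = FALSE)
  tab2 <- enrichment_table(calls2, reps, level = "family")
  expect_equal(tab2$enrichment[tab2$group == "F"], 1)
})

test_that("uniform families with uniform calls give enrichment near one", {
  set.seed(1)
  fams <- paste0("fam", 1:4)
  reps <- data.frame(
    chrom = "chr1", start = seq(0, by = 1000, length.out = 400))
  reps$end <- reps$start + 200
  reps$strand <- "+"
  reps$subfamily <- sample(fams, 400, replace = TRUE)
  reps$family <- reps$subfamily
  reps$class <- "SINE"
  reps$pct_div <- 5
  reps$element_id <- paste0("te", 1:400)
  reps$consensus_id <- reps$subfamily
  calls <- data.frame(origin = "RE_derived",
                      element_id = sample(reps$element_id, 200, replace = TRUE),
                      stringsAsFactors = FALSE)
  tab <- enrichment_table(calls, reps, level = "family")
  expect_true(all(abs(tab$enrichment - 1) < 0.35))
})

test_that("unique anchor sites de-duplicate by exact motif coordinates", {
  loops <- toy_loops()
  loops <- rbind(loops, loops[1, ])
  loops$loop_id[3] <- "L3"
  sites <- unique_anchor_sites(loops)
  expect_equal(nrow(sites), 4L)  # 2 loops x 2 anchors, duplicates collapsed
})
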