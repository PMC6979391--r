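test_that("RepeatMasker .out parsing converts coordinates, strand and class", {
  f <- withr::local_tempfile()
  writeLines(c(
    "   SW   perc perc perc  query ...", "score   div. del. ins. ...", "",
    "  225  9.2  0.0  0.0  chr1 101 200 (0) + B2_Mm2 SINE/B2 1 100 (0) 1",
    "  310 15.0  0.1  0.2  chr1 501 700 (0) C L1M3f LINE/L1 1 200 (0) 2",
    "  120  2.0  0.0  0.0  chr2 11 60 (0) + (TA)n Simple_repeat 1 50 (0) 3"),
    f)
  expect_warning(reps <- read_repeatmasker_out(f), "Simple_repeat")
  expect_equal(nrow(reps), 3L)
  expect_equal(reps$start[1], 100)   # 1-based inclusive -> 0-based half-open
  expect_equal(reps$end[1], 200)
  expect_equal(reps$end[1] - reps$start[1], 100)
  expect_equal(reps$subfamily[1], "B2_Mm2")
  expect_equal(reps$family[1], "B2")
  expect_equal(reps$class[1], "SINE")
  expect_equal(reps$strand[2], "-")   # "C" means minus
  expect_equal(reps$class[3], "other")
})

test_that("RepeatMasker .out handles empty bodies and names malformed lines", {
  f <- withr::local_tempfile()
  writeLines(c("h1", "h2", ""), f)
  expect_equal(nrow(read_repeatmasker_out(f)), 0L)
  writeLines(c("h1", "h2", "", "garbage row"), f)
  expect_error(read_repeatmasker_out(f), "line 4")
})

test_that("RepeatMasker round trip is an involution on coordinates", {
  sim <- shared_sim()
  f <- withr::local_tempfile()
  write_repeatmasker_out(sim$repeats_a, f)
  back <- read_repeatmasker_out(f)
  expect_equal(back$start, sim$repeats_a$start)
  expect_equal(back$end, sim$repeats_a$end)
  expect_equal(back$subfamily, sim$repeats_a$subfamily)
  expect_equal(back$family, sim$repeats_a$family)
  expect_equal(back$strand, sim$repeats_a$strand)
  expect_equal(back$pct_div, sim$repeats_a$pct_div)
})

test_that("BEDPE loops: length arithmetic, missing motifs, duplicates", {
  f <- withr::local_tempfile()
  writeLines(c(
    paste("chr1", 10000, 20000, "chr1", 110000, 120000, "La", 0, ".", ".",
          "chr1", 14990, 15009, "+", "chr1", 114990, 115009, "-", sep = "\t"),
    paste("chr1", 300000, 310000, "chr1", 500000, 510000, "Lb", 0, ".", ".",
          sep = "\t")), f)
  loops <- read_loops_bedpe(f)
  expect_equal(nrow(loops), 2L)
  expect_equal(loop_length(loops)[1], 100000)
  expect_true(is.na(loops$motif1_start[loops$loop_id == "Lb"]))
  expect_equal(loops$origin1[loops$loop_id == "Lb"], "unidentified")
  # duplicated ids rejected
  writeLines(rep(paste("chr1", 1, 100, "chr1", 5000, 5100, "dup", 0,
                       sep = "\t"), 2), f)
  expect_error(read_loops_bedpe(f), "duplicate")
  # interchromosomal rows skipped with a warning
  writeLines(paste("chr1", 1, 100, "chr2", 5000, 5100, "x", 0, sep = "\t"), f)
  expect_warning(skipped <- read_loops_bedpe(f), "interchromosomal")
  expect_equal(nrow(skipped), 0L)
})

test_that("BEDPE round trip preserves loops and motif annotations", {
  sim <- shared_sim()
  f <- withr::local_tempfile()
  write_loops_bedpe(sim$loops_a, f)
  back <- read_loops_bedpe(f)
  for (col in c("loop_id", "chrom", "start1", "end1", "start2", "end2",
                "motif1_start", "motif1_end", "motif1_strand",
                "motif2_start", "motif2_end", "motif2_strand"))
    expect_equal(back[[col]], sim$loops_a[[col]], info = col)
})

test_that("chain parsing validates block sums and round trips", {
  f <- withr::local_tempfile()
  writeLines(c("chain 200 chr1 1000 + 0 300 chr1 2000 + 1000 1250 1",
               "100\t100\t50", "100", ""), f)
  cm <- read_chain(f)
  expect_equal(length(cm$chains), 1L)
  expect_equal(cm$chains[[1]]$blocks$s_start, c(0, 200))
  expect_equal(cm$chains[[1]]$blocks$t_start, c(1000, 1150))
  f2 <- withr::local_tempfile()
  write_chain(cm, f2)
  back <- read_chain(f2)
  expect_equal(back$chains[[1]]$blocks, cm$chains[[1]]$blocks)
  # corrupt block sums
  writeLines(c("chain 200 chr1 1000 + 0 300 chr1 2000 + 1000 1250 1",
               "100\t100\t50", "90", ""), f)
  expect_error(read_chain(f), "sum")
})

test_that("minus-strand chain targets are pre-flipped to forward coordinates", {
  f <- withr::local_tempfile()
  # target block on - strand: reversed coords 100-200 of a 1000 bp target
  writeLines(c("chain 100 chr1 500 + 0 100 chrT 1000 - 100 200 1",
               "100", ""), f)
  cm <- read_chain(f)
  expect_equal(cm$chains[[1]]$blocks$t_start, 1000 - 200)  # forward strand
  lifted <- lift_interval(cm, gi("chr1", 0, 10), 0.5)
  expect_equal(lifted$mapped$start, 890)
  expect_equal(lifted$mapped$end, 900)
  expect_equal(lifted$orientation, "-")
  # write/read round trip restores reversed representation
  f2 <- withr::local_tempfile()
  write_chain(cm, f2)
  expect_equal(read_chain(f2)$chains[[1]]$blocks, cm$chains[[1]]$blocks)
})

test_that("contact triples complete symmetry and reject negatives", {
  f <- withr::local_tempfile()
  writeLines(c("0 0 5", "0 5000 3"), f)
  map <- read_contact_triples(f, "chr1", 0, 20000, 5000)
  d <- cm_dense(map)
  expect_equal(d[1, 1], 5)
  expect_equal(d[2, 1], 3)   # symmetric completion
  expect_equal(d[1, 2], 3)
  expect_equal(cm_total(map), 8)
  writeLines("0 0 -2", f)
  expect_error(read_contact_triples(f, "chr1", 0, 20000, 5000), "negative")
  # round trip conserves total raw count
  f2 <- withr::local_tempfile()
  write_contact_triples(map, f2)
  back <- read_contact_triples(f2, "chr1", 0, 20000, 5000)
  expect_equal(cm_dense(back), d)
})

test_that(".align blocks pair consensus and genomic lines with gap bookkeeping", {
  rec <- list(element_id = "te_1", consensus_id = "B2_Mm2", chrom = "chr1",
              start = 1000, end = 1004, strand = "+",
              g_aligned = "ACAGT", c_aligned = "AC-GT")
  f <- withr::local_tempfile()
  write_align(list(rec), f)
  back <- read_align(f)
  expect_length(back, 1L)
  expect_equal(back[[1]]$g_aligned, "ACAGT")
  expect_equal(back[[1]]$c_aligned, "AC-GT")
  cs <- count_substitutions(back[[1]]$c_aligned, back[[1]]$g_aligned)
  expect_equal(cs$insertions, 1)
  expect_equal(sum(cs$counts), 0)
})

test_that(".align round trip reproduces the simulated alignments", {
  sim <- shared_sim()
  f <- withr::local_tempfile()
  write_align(sim$aligns_a[1:10], f)
  back <- read_align(f)
  for (k in 1:10) {
    expect_equal(back[[k]]$g_aligned, sim$aligns_a[[k]]$g_aligned)
    expect_equal(back[[k]]$c_aligned, sim$aligns_a[[k]]$c_aligned)
    expect_equal(back[[k]]$element_id, sim$aligns_a[[k]]$element_id)
    expect_equal(back[[k]]$start, sim$aligns_a[[k]]$start)
  }
})

test_that("narrowPeak and bedGraph round trips preserve records", {
  sim <- shared_sim()
  f <- withr::local_tempfile()
  write_narrowpeak(sim$peaks_a, f)
  expect_equal(read_narrowpeak(f), sim$peaks_a)
  f2 <- withr::local_tempfile()
  write_bedgraph(sim$methylation_a, f2)
  back <- read_bedgraph(f2)
  expect_equal(back$start, sim$methylation_a$start)
  expect_equal(back$fraction, sim$methylation_a$fraction)
  expect_equal(back$coverage, sim$methylation_a$coverage)
})

test_that("bedGraph rejects fractions outside [0, 1] and duplicate positions", {
  f <- withr::local_tempfile()
  writeLines("chr1\t10\t12\t1.2\t5", f)
  expect_error(read_bedgraph(f), "\\[0, 1\\]")
  writeLines(c("chr1\t10\t12\t0.5\t5", "chr1\t10\t12\t0.6\t5"), f)
  expect_error(read_bedgraph(f), "duplicated")
})

test_that("genomic interval atoms enforce their invariants", {
  expect_error(gi("chr1", 10, 10), "invalid")
  expect_error(gi("chr1", -1, 10), "invalid")
  x <- gi("chr1", 100, 200, "+")
  expect_equal(gi_length(x), 100)
  expect_equal(gi_midpoint(x), 150)
  expect_equal(gi_overlap(x, gi("chr1", 150, 300)), 50)
  expect_equal(gi_overlap(x, gi("chr2", 150, 300)), 0)
})
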