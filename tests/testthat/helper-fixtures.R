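# Programmatic fixtures shared across test files. The medium simulated
# dataset is built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

shared_sim <- function() {
  if (is.null(.fixture_env$sim))
    .fixture_env$sim <- simulate_dataset(simulation_config(seed = 42))
  .fixture_env$sim
}

small_config <- function(seed = 7, ...) {
  args <- list(
    seed = seed, n_chromosomes = 1, chrom_length = 8e5,
    n_loops = 4, n_turnover_events = 2, n_specific_loops = 2,
    reads_per_map = 2e5,
    te_subfamilies = data.frame(
      subfamily = c("B2_Mm2", "L1M3f"), family = c("B2", "L1"),
      class = c("SINE", "LINE"), consensus_length = c(190, 300),
      n_background = c(10, 10), divergence = c(10, 15),
      stringsAsFactors = FALSE))
  do.call(simulation_config, utils::modifyList(args, list(...)))
}

# A hand-built loop table with explicit motifs (coordinates chosen so the
# anchors sit apart on one chromosome).
toy_loops <- function() {
  df <- data.frame(
    loop_id = c("L1", "L2"), chrom = "chr1",
    start1 = c(10000, 300000), end1 = c(20000, 310000),
    start2 = c(110000, 500000), end2 = c(120000, 510000),
    motif1_start = c(14990, 304990), motif1_end = c(15009, 305009),
    motif1_strand = "+",
    motif2_start = c(114990, 504990), motif2_end = c(115009, 505009),
    motif2_strand = "-",
    origin1 = "unidentified", subfamily1 = NA_character_,
    element_id1 = NA_character_,
    origin2 = "unidentified", subfamily2 = NA_character_,
    element_id2 = NA_character_, stringsAsFactors = FALSE)
  df
}

toy_repeats <- function() {
  data.frame(
    chrom = "chr1",
    start = c(14980, 14995, 400000), end = c(15180, 15007, 400200),
    strand = "+",
    subfamily = c("B2_Mm2", "B3", "L1M3f"),
    family = c("B2", "B2", "L1"), class = c("SINE", "SINE", "LINE"),
    pct_div = c(8.5, 5.0, 20.1),
    element_id = c("te1", "te2", "te3"),
    consensus_id = c("B2_Mm2", "B3", "L1M3f"),
    stringsAsFactors = FALSE)
}

# An identity chain over [0, size) on one chromosome.
identity_chain <- function(chrom = "chr1", size = 1e6) {
  structure(list(chains = list(list(
    score = size, s_chrom = chrom, s_size = size, s_start = 0, s_end = size,
    t_chrom = chrom, t_size = size, t_strand = "+",
    blocks = data.frame(s_start = 0, t_start = 0, size = size)))),
    class = "chain_map")
}

# Two-block chain: 0-100 -> 1000-1100 and 200-300 -> 1150-1250.
two_block_chain <- function() {
  structure(list(chains = list(list(
    score = 200, s_chrom = "chr1", s_size = 1000, s_start = 0, s_end = 300,
    t_chrom = "chr1", t_size = 2000, t_strand = "+",
    blocks = data.frame(s_start = c(0, 200), t_start = c(1000, 1150),
                        size = c(100, 100))))),
    class = "chain_map")
}
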