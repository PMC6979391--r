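# End-to-end orchestration: simulate -> annotate -> orthology -> turnover
# -> contacts -> evolve -> methylation, driven by a single config, with a
# manifest of outputs.

#' Write a simulated dataset to disk in the standard interchange formats
#'
#' @param sim Output of [simulate_dataset()].
#' @param outdir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_dataset <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  files <- c(
    genome_a = p("genome_a.fa"), genome_b = p("genome_b.fa"),
    chain_ab = p("a_to_b.chain"), chain_ba = p("b_to_a.chain"),
    loops_a = p("loops_a.bedpe"), loops_b = p("loops_b.bedpe"),
    repeats_a = p("repeats_a.out"), repeats_b = p("repeats_b.out"),
    peaks_a = p("peaks_a.narrowPeak"), peaks_b = p("peaks_b.narrowPeak"),
    methylation_a = p("methylation_a.bedGraph"),
    aligns_a = p("repeats_a.align"), consensi = p("consensi.fa"),
    ground_truth = p("ground_truth.json"))
  Biostrings::writeXStringSet(sim$genome_a, files["genome_a"])
  Biostrings::writeXStringSet(sim$genome_b, files["genome_b"])
  write_chain(sim$chain_ab, files["chain_ab"])
  write_chain(sim$chain_ba, files["chain_ba"])
  write_loops_bedpe(sim$loops_a, files["loops_a"])
  write_loops_bedpe(sim$loops_b, files["loops_b"])
  write_repeatmasker_out(sim$repeats_a, files["repeats_a"])
  write_repeatmasker_out(sim$repeats_b, files["repeats_b"])
  write_narrowpeak(sim$peaks_a, files["peaks_a"])
  write_narrowpeak(sim$peaks_b, files["peaks_b"])
  write_bedgraph(sim$methylation_a, files["methylation_a"])
  write_align(sim$aligns_a, files["aligns_a"])
  Biostrings::writeXStringSet(sim$consensi, files["consensi"])
  jsonlite::write_json(sim$ground_truth, files["ground_truth"],
                       dataframe = "columns")
  if (!is.null(sim$contacts)) {
    files <- c(files, contacts_wt = p("contacts_wt.txt"),
               contacts_ko = p("contacts_ko.txt"))
    write_contact_triples(sim$contacts$wt, files["contacts_wt"])
    write_contact_triples(sim$contacts$ko, files["contacts_ko"])
  }
  invisible(files)
}

#' Run the full analysis pipeline from a single configuration
#'
#' Stages run in dependency order: simulate, annotate, orthology, turnover,
#' contacts, evolve, methylation. Each stage writes its outputs under
#' `outdir` and is skipped on rerun when its outputs already exist (unless
#' `force`). The returned manifest records per-stage outputs, their md5
#' hashes, and wall status.
#'
#' @param config A YAML file path or a list with (optionally) `seed`,
#'   `outdir`, `vicinity`, `min_match`, `n_perms`, and any
#'   [simulation_config()] field under `generator`.
#' @param force Rerun stages whose outputs already exist (default FALSE).
#' @return The manifest (list), invisibly written to
#'   `file.path(outdir, "manifest.json")`.
#' @export
run_pipeline <- function(config = list(), force = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- as.integer(config$seed %||% 1L)
  outdir <- config$outdir %||% file.path(tempdir(), "loopover_run")
  vicinity <- config$vicinity %||% 50000
  min_match <- config$min_match %||% 0.1
  n_perms <- config$n_perms %||% 200L
  gen <- config$generator %||% list()
  gen$seed <- seed
  cfg <- do.call(simulation_config, gen)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = seed, outdir = outdir, stages = list())
  t0 <- Sys.time()
  stage <- function(name, outputs, fun) {
    paths <- file.path(outdir, outputs)
    if (!force && all(file.exists(paths))) {
      manifest$stages[[name]] <<- list(status = "skipped", outputs = paths)
      return(invisible(NULL))
    }
    res <- fun(paths)
    manifest$stages[[name]] <<- list(
      status = "done", outputs = paths,
      md5 = unname(tools::md5sum(paths[file.exists(paths)])))
    res
  }

  # simulate
  sim <- NULL
  stage("simulate", "ground_truth.json", function(paths) {
    sim <<- simulate_dataset(cfg)
    write_dataset(sim, outdir)
  })
  if (is.null(sim)) sim <- simulate_dataset(cfg)  # reruns still need objects

  # annotate
  loops_a <- classify_loops(annotate_loops(sim$loops_a, sim$repeats_a))
  loops_b <- classify_loops(annotate_loops(sim$loops_b, sim$repeats_b))
  stage("annotate", c("annotated_a.tsv", "annotated_b.tsv"), function(paths) {
    utils::write.table(loops_a, paths[1L], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(loops_b, paths[2L], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  })

  # orthology
  calls <- loop_orthology(loops_a, loops_b, sim$chain_ab, sim$chain_ba,
                          min_match = min_match, vicinity = vicinity)
  stage("orthology", "orthologs.tsv", function(paths)
    utils::write.table(calls, paths, sep = "\t", quote = FALSE,
                       row.names = FALSE))

  # turnover
  events <- detect_turnover(calls, loops_a, loops_b, sim$repeats_a,
                            sim$repeats_b, sim$chain_ab)
  otab <- orientation_table(events)
  stage("turnover", c("events.tsv", "orientation_stats.json"),
        function(paths) {
    utils::write.table(events, paths[1L], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    jsonlite::write_json(list(counts = otab$counts, n = otab$n,
                              chi2 = otab$chi2, p = otab$p),
                         paths[2L], auto_unbox = TRUE, digits = NA)
  })

  # contacts
  contacts_stats <- NULL
  if (!is.null(sim$contacts)) {
    ct <- sim$contacts
    pcts <- function(map, pair)
      cross_domain_pct(vc_sqrt_normalize(map), pair$domain1, pair$domain2)
    contacts_stats <- list(
      target_wt = pcts(ct$wt, ct$target), target_ko = pcts(ct$ko, ct$target),
      control_wt = pcts(ct$wt, ct$control),
      control_ko = pcts(ct$ko, ct$control))
    stage("contacts", "contact_stats.json", function(paths)
      jsonlite::write_json(contacts_stats, paths, auto_unbox = TRUE,
                           digits = NA))
  }

  # evolve
  profiles <- substitution_profiles(sim$aligns_a)
  truth_te <- sim$ground_truth$tes
  cohort <- truth_te$cohort[match(profiles$element_id, truth_te$element_id)]
  sub_report <- NULL
  if (any(cohort == "turnover") && any(cohort == "background")) {
    sub_report <- substitution_test(
      profiles[cohort == "turnover", , drop = FALSE],
      profiles[cohort == "background", , drop = FALSE],
      n_perms = n_perms, seed = seed + 7L)
  }
  stage("evolve", c("profiles.tsv", "substitution_test.tsv"),
        function(paths) {
    utils::write.table(profiles, paths[1L], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (!is.null(sub_report))
      utils::write.table(sub_report, paths[2L], sep = "\t", quote = FALSE,
                         row.names = FALSE)
    else writeLines(character(), paths[2L])
  })

  # methylation
  sites <- unique_anchor_sites(loops_a)
  mp <- metaplot(sim$methylation_a, sites)
  stage("methylation", "metaplot.tsv", function(paths)
    utils::write.table(mp, paths, sep = "\t", quote = FALSE,
                       row.names = FALSE))

  manifest$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(manifest = manifest, loops_a = loops_a, loops_b = loops_b,
                 calls = calls, events = events, orientation = otab,
                 contacts = contacts_stats, profiles = profiles,
                 substitution = sub_report, metaplot = mp, sim = sim))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
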