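#' Pipeline configuration
#'
#' Reads the single structured config file (YAML: key-value with nested
#' blocks) that drives [run_screen()] and [run_acquisition()], or builds one
#' from a named list. Parameter blocks mirror the per-stage function
#' arguments; anything omitted falls back to the stage defaults.
#'
#' @param x Path to a YAML file, or a named list.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(x) {
  cfg <- if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) abort(sprintf("config file '%s' does not exist", x))
    yaml::read_yaml(x)
  } else {
    as.list(x)
  }
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$out_dir <- cfg$out_dir %||% "spacerscreen_out"
  structure(cfg, class = "pipeline_config")
}

check_paths_exist <- function(paths) {
  missing <- paths[!file.exists(unlist(paths))]
  if (length(missing) > 0) {
    abort(sprintf("missing input path(s): %s",
                  paste(unlist(missing), collapse = ", ")))
  }
  invisible(paths)
}

config_hash <- function(cfg) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, force = TRUE,
                              digits = NA), tf)
  unname(tools::md5sum(tf))
}

stage <- function(name, expr) {
  inform(sprintf("[%s] starting", name))
  tryCatch(expr, error = function(e) {
    abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

write_run_manifest <- function(cfg, dir, inputs, outputs) {
  jsonlite::write_json(
    list(tool = "spacerscreen", version = pkg_version(),
         seed = cfg$seed, config_hash = config_hash(cfg),
         parameters = unclass(cfg),
         input_checksums = as.list(tools::md5sum(unlist(inputs))),
         outputs = outputs),
    file.path(dir, "run_manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run the screen-analysis pipeline
#'
#' Orchestrates extract -> frequencies -> enrichment -> annotate ->
#' summarize over one pre-infection (t0) and one or more post-infection
#' FASTQ samples. Deterministic given fixed inputs; every output table
#' carries a header naming the tool version, config hash and seed, and a
#' run manifest records parameters and input checksums.
#'
#' Required config fields: `genome` (FASTA), `operons` (TSV), `library`
#' (manifest TSV), `repeat_seq`, `t0` (FASTQ) and `post` (named list of
#' FASTQ paths). Optional: `extraction`, `enrichment` blocks, `pe_split`,
#' `compare` (two group labels), `out_dir`, `seed`.
#'
#' @param cfg A [pipeline_config()], path, or named list.
#' @return Invisibly, a list with the per-stage objects and output paths.
#' @export
run_screen <- function(cfg) {
  cfg <- pipeline_config(cfg)
  inputs <- list(genome = cfg$genome, operons = cfg$operons,
                 library = cfg$library, t0 = cfg$t0)
  inputs <- c(inputs, setNames(cfg$post, paste0("post_", names(cfg$post))))
  check_paths_exist(inputs)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  h <- config_hash(cfg)
  ex <- cfg$extraction %||% list()

  genome <- stage("load", read_genome(cfg$genome, operons = read_operons(cfg$operons)))
  lib <- read_library(cfg$library)
  extract1 <- function(path, id) {
    ct <- extract_spacers(
      path, repeat_seq = cfg$repeat_seq,
      max_repeat_mismatches = ex$max_repeat_mismatches %||% 1L,
      spacer_len_bounds = unlist(ex$spacer_len_bounds %||% c(20L, 50L)),
      search_both_orientations = ex$search_both_orientations %||% TRUE,
      sample_id = id)
    g <- glance(ct)
    inform(sprintf(
      "[extract] %s: %d reads, %d spacers extracted, %d unique",
      id, g$total_reads, g$total_extracted, g$unique_spacers))
    write_counts(ct, file.path(cfg$out_dir, sprintf("counts_%s.tsv", id)),
                 json = file.path(cfg$out_dir, sprintf("counts_%s.json", id)),
                 seed = cfg$seed, config_hash = h)
    ct
  }
  ct0 <- stage("extract", extract1(cfg$t0, "t0"))
  posts <- stage("extract", purrr::imap(cfg$post, extract1))

  en <- cfg$enrichment %||% list()
  results <- stage("enrich", purrr::imap(posts, function(ct, id) {
    e <- compute_enrichment(ct, ct0,
                            zero_policy = en$zero_policy %||% "na",
                            alpha = en$alpha %||% 0.5)
    ann <- annotate_spacers(e, lib, genome, pe_split = cfg$pe_split)
    write_enrichment(ann, file.path(cfg$out_dir, sprintf("enrichment_%s.tsv", id)),
                     seed = cfg$seed, config_hash = h)
    ann
  }))
  summaries <- stage("summarize", purrr::imap(results, function(ann, id) {
    s <- summarize_groups(ann, log_scale = en$log_scale %||% FALSE)
    if (!is.null(cfg$compare)) {
      wt <- compare_enrichment(ann, cfg$compare[[1]], cfg$compare[[2]],
                               log_scale = en$log_scale %||% FALSE)
      s <- bind_rows(s, tidy(wt) |>
        mutate(group = sprintf("%s_vs_%s", cfg$compare[[1]], cfg$compare[[2]])) |>
        select("group", "statistic", "parameter", "p.value"))
    }
    write_tsv_with_header(s, file.path(cfg$out_dir, sprintf("groups_%s.tsv", id)),
                          seed = cfg$seed, config_hash = h)
    s
  }))
  outputs <- list.files(cfg$out_dir, full.names = FALSE)
  write_run_manifest(cfg, cfg$out_dir, inputs, outputs)
  invisible(list(counts = c(list(t0 = ct0), posts), enrichment = results,
                 summaries = summaries, out_dir = cfg$out_dir))
}

#' Run the acquisition-mapping pipeline
#'
#' extract -> map -> RPM coverage + source fractions for a naive-acquisition
#' FASTQ against phage and plasmid replicons.
#'
#' Required config fields: `acquisition_fastq`, `phage` (FASTA), `plasmid`
#' (FASTA), `repeat_seq`. Optional: `extraction` block, `max_mismatches`,
#' `out_dir`, `seed`.
#'
#' @inheritParams run_screen
#' @return Invisibly, list with `counts`, `alignments`, `profile`, paths.
#' @export
run_acquisition <- function(cfg) {
  cfg <- pipeline_config(cfg)
  inputs <- list(fastq = cfg$acquisition_fastq, phage = cfg$phage,
                 plasmid = cfg$plasmid)
  check_paths_exist(inputs)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  h <- config_hash(cfg)
  ex <- cfg$extraction %||% list()
  replicons <- stage("load", list(read_genome(cfg$phage), read_genome(cfg$plasmid)))
  ct <- stage("extract", extract_spacers(
    cfg$acquisition_fastq, repeat_seq = cfg$repeat_seq,
    max_repeat_mismatches = ex$max_repeat_mismatches %||% 1L,
    spacer_len_bounds = unlist(ex$spacer_len_bounds %||% c(20L, 50L)),
    sample_id = "acquisition"))
  if (nrow(ct) == 0L) abort("stage 'extract' failed: no spacers extracted")
  g <- glance(ct)
  inform(sprintf("[extract] acquisition: %d reads, %d spacers, %d unique",
                 g$total_reads, g$total_extracted, g$unique_spacers))
  aln <- stage("map", map_spacers(ct, replicons,
                                  max_mismatches = cfg$max_mismatches %||% 0L))
  inform(sprintf("[map] unique %d / ambiguous %d / unaligned %d spacers",
                 sum(aln$status == "unique"), sum(aln$status == "ambiguous"),
                 sum(aln$status == "unaligned")))
  prof <- stage("profile", position_coverage_rpm(aln, replicons))
  write_counts(ct, file.path(cfg$out_dir, "acquisition_counts.tsv"),
               json = file.path(cfg$out_dir, "acquisition_counts.json"),
               seed = cfg$seed, config_hash = h)
  write_tsv_with_header(as_tibble(aln),
                        file.path(cfg$out_dir, "alignments.tsv"),
                        seed = cfg$seed, config_hash = h)
  write_profile(prof, file.path(cfg$out_dir, "acquisition_rpm.tsv"),
                json = file.path(cfg$out_dir, "source_fractions.json"),
                seed = cfg$seed, config_hash = h)
  outputs <- list.files(cfg$out_dir, full.names = FALSE)
  write_run_manifest(cfg, cfg$out_dir, inputs, outputs)
  invisible(list(counts = ct, alignments = aln, profile = prof,
                 out_dir = cfg$out_dir))
}

#' End-to-end demo on simulated data
#'
#' Simulates a complete (scaled-down) experiment, then runs the screen and
#' acquisition pipelines on the emitted files and calls operons from the
#' simulated RNA-seq coverage. The default scale (40 kb genome tiled every
#' 40 nt, ~2,000 spacers, 2 x 10^4 reads per sample) keeps the full run
#' around a minute.
#'
#' @param dir Output directory.
#' @param seed Master seed.
#' @param genotype Genotype preset for the simulation.
#' @param step,depth Library tiling step and per-sample read depth.
#' @return Invisibly, list with `screen`, `acquisition`, `called_operons`
#'   and the fixture paths.
#' @export
run_demo <- function(dir = "spacerscreen_demo", seed = 1L, genotype = "WT",
                     step = 40L, depth = 2e4) {
  cfg <- sim_config(seed = seed, genotype = genotype, step = step,
                    depth = depth)
  fixture_dir <- file.path(dir, "fixture")
  paths <- simulate_experiment(cfg, fixture_dir, n_acquisition_reads = 5e3)
  screen <- run_screen(list(
    seed = seed, out_dir = file.path(dir, "screen"),
    genome = paths$genome, operons = paths$operons, library = paths$library,
    repeat_seq = cfg$dr, t0 = paths$fastq_t0,
    post = list(t5h = paths$fastq_t5h, t24h = paths$fastq_t24h),
    pe_split = cfg$pe_split, compare = c("PE_minus", "PL_minus")))
  acq <- run_acquisition(list(
    seed = seed, out_dir = file.path(dir, "acquisition"),
    acquisition_fastq = paths$fastq_acquisition,
    phage = paths$genome, plasmid = paths$plasmid, repeat_seq = cfg$dr))
  called <- call_operons(read_coverage(paths$coverage))
  write_operons(called, file.path(dir, "called_operons.tsv"),
                replicon = "phage_sim", seed = seed)
  invisible(list(screen = screen, acquisition = acq,
                 called_operons = called, paths = paths))
}
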