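test_that("generators are byte-deterministic under a fixed seed", {
  cfg <- sim_config(seed = 9, genome_length = 1000, step = 40,
                    operons = empty_operons())
  expect_identical(simulate_genome(cfg)$sequence, simulate_genome(cfg)$sequence)
  g <- simulate_genome(sim_config(seed = 9, genome_length = 2000,
                                  operons = toy_operons(pe = c(100L, 800L),
                                                        pl = c(800L, 2000L))))
  cfg2 <- sim_config(seed = 9, genome_length = 2000, step = 20, depth = 5000,
                     operons = toy_operons(pe = c(100L, 800L),
                                           pl = c(800L, 2000L)))
  lib <- design_tiling_library(g, k = cfg2$k, step = cfg2$step)
  a <- simulate_screen(lib, g, cfg2, emit_reads = TRUE)
  b <- simulate_screen(lib, g, cfg2, emit_reads = TRUE)
  expect_identical(a$counts$t0$count, b$counts$t0$count)
  expect_identical(a$reads$t5h, b$reads$t5h)
  # different seeds diverge
  cfg3 <- sim_config(seed = 10, genome_length = 2000, step = 20, depth = 5000,
                     operons = cfg2$operons)
  expect_false(identical(simulate_screen(lib, g, cfg3)$counts$t0$count,
                         a$counts$t0$count))
})

test_that("simulated genomes have the configured structure and composition", {
  cfg <- sim_config(seed = 3)
  g <- simulate_genome(cfg)
  expect_identical(g$length, 40000L)
  expect_equal(as.data.frame(g$operons), as.data.frame(default_operon_plan()))
  # GC fraction of a long simulated genome within 3 binomial SE of 0.5
  big <- simulate_genome(sim_config(seed = 4, genome_length = 100000L,
                                    operons = empty_operons()))
  gc <- sum(strsplit(big$sequence, "")[[1]] %in% c("G", "C")) / big$length
  expect_lt(abs(gc - 0.5), 3 * sqrt(0.25 / big$length))
  expect_error(sim_config(genome_length = 10000), "outside")
})

test_that("one planted high-fitness spacer enriches by the closed form", {
  # E(s) = w / w_bar: w = 10 among 99 neutral spacers -> 10 * 100/109
  cfg <- sim_config(seed = 15, genome_length = 233, step = 2, depth = 1e6,
                    operons = empty_operons(), fitness_noise_sdlog = 0,
                    dispersion_shape = Inf, error_rate = 0,
                    rounds = c(t5h = 1))
  g <- simulate_genome(cfg)
  lib <- design_tiling_library(g, k = 35, step = 2, strands = "plus")
  expect_identical(nrow(lib), 100L)
  w <- c(10, rep(1, 99))
  scr <- simulate_screen(lib, g, cfg, fitness = w)
  e <- compute_enrichment(scr$counts$t5h, scr$counts$t0)
  obs <- e$enrichment[match(lib$spacer_seq[1], e$spacer)]
  expected <- 10 * 100 / 109
  # 3 SE of the multinomial ratio at this depth
  c_post <- 1e6 * (10 / 109) / 100 * 100  # ~91.7k reads on the planted spacer
  expect_lt(abs(obs - expected), 3 * expected * sqrt(2 / c_post))
})

test_that("genotype presets reproduce the screen's enrichment geography", {
  run_preset <- function(genotype, seed) {
    cfg <- sim_config(seed = seed, step = 40, genotype = genotype,
                      depth = 2e5, error_rate = 0)
    g <- simulate_genome(cfg)
    lib <- design_tiling_library(g, k = cfg$k, step = cfg$step)
    scr <- simulate_screen(lib, g, cfg)
    e <- compute_enrichment(scr$counts$t5h, scr$counts$t0)
    annotate_spacers(e, lib, g, pe_split = cfg$pe_split)
  }
  wt <- run_preset("WT", 16)
  s <- summarize_groups(wt)
  m <- setNames(s$mean, s$group)
  expect_gt(m[["PE_minus"]], m[["PL_minus"]])
  expect_gt(m[["PE_minus"]], m[["PE_plus"]])
  expect_gt(m[["PE_minus"]], m[["PL_plus"]])
  # dcsm6: upstream-PE targets stay selected, downstream-PE targets do not
  dc <- run_preset("dcsm6", 17)
  s2 <- summarize_groups(dplyr::filter(dc, targeting),
                         grouping = "region_class")
  m2 <- setNames(s2$mean, s2$region_class)
  expect_gt(m2[["PE_upstream"]], m2[["PE_downstream"]])
  # cas10HD: late-operon targets outrank early-operon targets
  hd <- run_preset("cas10HD", 18)
  w <- compare_enrichment(hd, "PL_minus", "PE_minus")
  expect_gt(w$estimate[[1]], w$estimate[[2]])
  expect_lt(w$p.value, 0.05)
})

test_that("acquisition source split follows the configured odds", {
  base <- list(genome_length = 2000L, plasmid_length = 1000L,
               operons = toy_operons(pe = c(100L, 800L), pl = c(800L, 2000L)))
  cfg <- do.call(sim_config, c(base, list(seed = 19, theta = 48)))
  g <- simulate_genome(cfg); pl <- simulate_plasmid(cfg)
  acq <- simulate_acquisition(cfg, g, pl, n_reads = 10000)
  frac <- mean(acq$truth$replicon == "phage_sim")
  p <- 48 / 49
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / 10000))
  # WT preset biases phage picks toward the PE minus strand
  pe_minus <- with(acq$truth, replicon == "phage_sim" & strand == "-" &
                     (start + end) / 2 >= 100 & (start + end) / 2 < 800)
  expect_gt(mean(pe_minus), 0.35)  # PE holds ~35% of positions, bias x10
  # cas10HD-like odds: phage fraction collapses
  cfg2 <- do.call(sim_config, c(base, list(seed = 20, genotype = "cas10HD")))
  acq2 <- simulate_acquisition(cfg2, g, pl, n_reads = 10000)
  frac2 <- mean(acq2$truth$replicon == "phage_sim")
  expect_lt(abs(frac2 - 0.0095 / 1.0095), 3 * sqrt(0.0094 * 0.9906 / 10000))
  expect_error(do.call(sim_config, c(base, list(theta = 0))), "theta")
})

test_that("simulated coverage is stepped by operon activation time", {
  cfg <- sim_config(seed = 21, genome_length = 8000,
                    operons = toy_operons(pe = c(500L, 3000L),
                                          pl = c(3000L, 8000L)),
                    rnaseq_decay_rate = 0)
  g <- simulate_genome(cfg)
  cov <- simulate_rnaseq(cfg, g)
  plus <- cov[cov$strand == "+", ]
  mean_in <- function(tp, a, b) {
    with(plus[plus$timepoint == tp, ], mean(count[position >= a & position < b]))
  }
  # at 5 min only the early operon is hot
  expect_gt(mean_in(5, 500, 3000), cfg$rnaseq_baseline + 0.8 * cfg$rnaseq_amplitude)
  expect_lt(mean_in(5, 3000, 8000), 3 * cfg$rnaseq_baseline)
  # the late operon gains coverage only from 15 min
  expect_gt(mean_in(15, 3000, 8000), cfg$rnaseq_baseline + 0.8 * cfg$rnaseq_amplitude)
  # zero amplitude -> flat Poisson baseline everywhere
  flat_cfg <- sim_config(seed = 22, genome_length = 8000,
                         operons = cfg$operons, rnaseq_amplitude = 0)
  flat <- simulate_rnaseq(flat_cfg, g)
  expect_lt(abs(mean(flat$count) - flat_cfg$rnaseq_baseline), 0.05)
})

test_that("fitness weights must be positive and preset table is complete", {
  cfg <- sim_config(seed = 23, genome_length = 300, step = 50,
                    operons = empty_operons())
  g <- simulate_genome(cfg)
  lib <- design_tiling_library(g, k = 35, step = 50)
  expect_error(simulate_screen(lib, g, cfg, fitness = c(0, rep(1, nrow(lib) - 1))),
               "> 0")
  presets <- fitness_presets()
  expect_identical(nrow(presets), 4L * 5L)
  expect_true(all(presets$w > 0))
})

test_that("a fixture directory contains every pipeline input", {
  withr::local_dir(withr::local_tempdir())
  cfg <- sim_config(seed = 24, genome_length = 1500, step = 100, depth = 2000,
                    operons = toy_operons(pe = c(100L, 700L),
                                          pl = c(700L, 1500L)),
                    timepoints = c(5, 15))
  paths <- simulate_experiment(cfg, "fix", n_acquisition_reads = 200)
  expect_true(all(file.exists(unlist(paths))))
  js <- jsonlite::read_json(paths$provenance)
  expect_identical(js$seed, 24L)
  expect_match(js$note, "synthetic")
  # the fixture extracts back to the planted counts
  ct <- extract_spacers(paths$fastq_t0, cfg$dr)
  expect_identical(attr(ct, "total_reads"), 2000L)
})
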