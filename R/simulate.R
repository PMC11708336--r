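#' Synthetic direct repeat used by the simulator
#'
#' A fixed 36-nt sequence with the length and base composition typical of a
#' type III-A CRISPR direct repeat. It is an arbitrary design constant of
#' this package's synthetic data generator, not the repeat of any natural
#' locus (real analyses must supply their own repeat sequence).
#'
#' @return A 36-nt DNA string.
#' @export
synthetic_dr <- function() {
  "GATCACCTTAAGGTATGAGGTAGACTCCATGAAGGC"
}

#' Default operon plan of the simulated phage
#'
#' An early operon over `[1000, 15000)` activating at 5 minutes
#' post-infection and a late operon over `[15000, 40000)` activating at 15
#' minutes, both on the plus strand — the two-promoter (PE/PL) architecture
#' of the staphylococcal phages the screen interrogates.
#'
#' @return Operon tibble.
#' @export
default_operon_plan <- function() {
  tibble(
    start = c(1000L, 15000L), end = c(15000L, 40000L),
    name = c("PE", "PL"), activation_time = c(5, 15),
    strand = c("+", "+")
  )
}

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic infection/selection experiment.
#' All randomness downstream flows from `seed` (each generator draws from a
#' fixed offset of it, so individual stages are independently reproducible).
#'
#' @param seed Integer master seed.
#' @param genome_length Phage genome length (nt).
#' @param operons Operon plan (see [default_operon_plan()]).
#' @param k,step Spacer length and tiling step (nt).
#' @param depth Reads per screen sample.
#' @param error_rate Per-base substitution error rate of simulated reads.
#' @param dr Direct repeat flanking every simulated spacer amplicon.
#' @param genotype Host genotype preset: `"WT"`, `"dcsm6"`, `"cas10HD"` or
#'   `"cas10HD_dcsm6"`.
#' @param rounds Named effective selection rounds per post-infection
#'   timepoint.
#' @param fitness_noise_sdlog Lognormal sd of per-spacer fitness noise.
#' @param dispersion_shape Gamma shape of the pre-selection (t0) abundance
#'   dispersion; `Inf` gives an exactly uniform library.
#' @param pe_split Coordinate splitting PE into upstream/downstream fitness
#'   classes; default midpoint of the PE operon.
#' @param theta Phage:plasmid acquisition odds; default set by genotype
#'   (WT/dcsm6 48, cas10HD 0.0095 — calibration constants of the presets).
#' @param acquisition_bias Weight multiplier for favoured protospacer
#'   positions (PE minus strand for WT, upstream-PE minus strand for dcsm6).
#' @param plasmid_length Length of the simulated CRISPR plasmid.
#' @param rnaseq_baseline,rnaseq_amplitude Poisson mean coverage off/on
#'   transcribed regions.
#' @param rnaseq_decay_rate Exponential 3'-decay rate of coverage with
#'   distance from the operon start (models lower read abundance far
#'   downstream of the promoter).
#' @param timepoints RNA-seq sampling times (minutes).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 40000L,
                       operons = default_operon_plan(),
                       k = 35L, step = 2L,
                       depth = 2e5,
                       error_rate = 0.001,
                       dr = synthetic_dr(),
                       genotype = c("WT", "dcsm6", "cas10HD", "cas10HD_dcsm6"),
                       rounds = c(t5h = 1, t24h = 2),
                       fitness_noise_sdlog = 0.25,
                       dispersion_shape = 100,
                       pe_split = NULL,
                       theta = NULL,
                       acquisition_bias = 10,
                       plasmid_length = 3000L,
                       rnaseq_baseline = 2,
                       rnaseq_amplitude = 100,
                       rnaseq_decay_rate = log(2) / 20000,
                       timepoints = c(5, 15, 30)) {
  genotype <- match.arg(genotype)
  if (is.null(pe_split)) {
    pe <- operons[operons$name == "PE", ]
    pe_split <- if (nrow(pe) > 0) as.integer((pe$start[1] + pe$end[1]) / 2) else NA_integer_
  }
  if (is.null(theta)) {
    theta <- c(WT = 48, dcsm6 = 48, cas10HD = 0.0095,
               cas10HD_dcsm6 = 0.0095)[[genotype]]
  }
  if (theta <= 0) abort("theta must be > 0")
  if (max(c(0L, operons$end)) > genome_length) {
    abort("operon outside [0, genome_length)")
  }
  structure(
    list(seed = as.integer(seed), genome_length = as.integer(genome_length),
         operons = operons, k = as.integer(k), step = as.integer(step),
         depth = depth, error_rate = error_rate, dr = dr,
         genotype = genotype, rounds = rounds,
         fitness_noise_sdlog = fitness_noise_sdlog,
         dispersion_shape = dispersion_shape, pe_split = pe_split,
         theta = theta, acquisition_bias = acquisition_bias,
         plasmid_length = as.integer(plasmid_length),
         rnaseq_baseline = rnaseq_baseline,
         rnaseq_amplitude = rnaseq_amplitude,
         rnaseq_decay_rate = rnaseq_decay_rate,
         timepoints = timepoints),
    class = "sim_config"
  )
}

#' Genotype fitness presets
#'
#' Relative fitness of a spacer-carrying cell during the infection, by
#' genotype and spacer class. These are calibration constants chosen to
#' reproduce the qualitative enrichment geography of the screen — strong
#' positive selection of early-operon-targeting spacers in the wild type,
#' loss of selection for downstream-PE targets without Csm6, and a
#' reversed PE < PL ordering in the Cas10 nuclease-dead background (there
#' the values are calibrated analytically so the expected group means under
#' the default genome geometry equal 0.78 for PE and 1.96 for PL targets) —
#' never measured values.
#'
#' @return Tibble with columns `genotype`, `class`, `w`.
#' @export
fitness_presets <- function() {
  tidyr::expand_grid(
    genotype = c("WT", "dcsm6", "cas10HD", "cas10HD_dcsm6"),
    class = c("PE_upstream", "PE_downstream", "PL", "other", "nontarget")
  ) |>
    mutate(w = case_when(
      genotype == "WT" & class %in% c("PE_upstream", "PE_downstream") ~ 10,
      genotype == "dcsm6" & class == "PE_upstream" ~ 10,
      genotype == "cas10HD" & class %in% c("PE_upstream", "PE_downstream") ~ 1.5926,
      genotype == "cas10HD" & class == "PL" ~ 4.0019,
      TRUE ~ 1
    ))
}

# Fitness class of every library spacer: region (midpoint rule) x targeting,
# with PE split into upstream/downstream at cfg$pe_split.
spacer_classes <- function(lib, genome, cfg) {
  region <- region_of(lib, genome)
  targ <- is_targeting(lib, genome)
  mid <- spacer_midpoint(lib$start, lib$end)
  case_when(
    !targ ~ "nontarget",
    region == "PE" & mid < cfg$pe_split ~ "PE_upstream",
    region == "PE" ~ "PE_downstream",
    region == "PL" ~ "PL",
    TRUE ~ "other"
  )
}

#' Simulate the phage genome (and CRISPR plasmid)
#'
#' Uniform-random ACGT sequence with the configured operon map;
#' byte-identical for a fixed seed.
#'
#' @param cfg A [sim_config()].
#' @return A [genome_annotation()].
#' @export
simulate_genome <- function(cfg) {
  withr::with_seed(cfg$seed + 101L, {
    genome_annotation("phage_sim", random_dna(cfg$genome_length),
                      operons = cfg$operons)
  })
}

#' @rdname simulate_genome
#' @export
simulate_plasmid <- function(cfg) {
  withr::with_seed(cfg$seed + 103L, {
    genome_annotation("plasmid_sim", random_dna(cfg$plasmid_length))
  })
}

# Apply per-base substitution errors to reads (vectorised over the
# error-free majority; only reads drawn to carry errors are edited).
mutate_reads <- function(reads, rate) {
  if (rate <= 0) return(reads)
  n_err <- rbinom(length(reads), nchar(reads), rate)
  idx <- which(n_err > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    pos <- sample.int(nchar(reads[i]), n_err[i])
    for (p in pos) {
      cur <- substr(reads[i], p, p)
      substr(reads[i], p, p) <- sample(setdiff(bases, cur), 1L)
    }
  }
  reads
}

amplicon_reads <- function(spacers, counts, dr, error_rate) {
  reads <- paste0(dr, rep.int(spacers, counts), dr)
  reads <- mutate_reads(reads, error_rate)
  sample(reads)
}

#' Simulate the pooled selection screen
#'
#' Selection is modeled as one effective multinomial reweighting per
#' timepoint: t0 counts are multinomial over near-uniform library
#' proportions (Gamma-dispersed), and each post-infection timepoint draws
#' counts with expected frequencies proportional to
#' `f_t0(s) * w(s)^rounds`, where `w` is the genotype's fitness for the
#' spacer's class times per-spacer lognormal noise. For one round the
#' expected enrichment is the closed form `w / w_bar` with `w_bar` the
#' library-mean fitness.
#'
#' @param lib A `spacer_library` for the simulated genome.
#' @param genome The [simulate_genome()] result.
#' @param cfg A [sim_config()].
#' @param fitness Optional per-spacer fitness vector overriding the preset
#'   (e.g. proportional to measured expression); noise still applies.
#' @param emit_reads Also emit error-carrying `DR·spacer·DR` amplicon reads
#'   per sample.
#' @return List with `counts` (named list of [count_table()]s: `t0` plus one
#'   per configured round), `truth` (spacer, class, fitness), `mean_fitness`
#'   and, if requested, `reads` (named list of character vectors).
#' @export
simulate_screen <- function(lib, genome, cfg, fitness = NULL,
                            emit_reads = FALSE) {
  withr::with_seed(cfg$seed + 107L, {
    n <- nrow(lib)
    cls <- spacer_classes(lib, genome, cfg)
    if (is.null(fitness)) {
      preset <- fitness_presets() |> filter(.data$genotype == cfg$genotype)
      w <- preset$w[match(cls, preset$class)]
      if (anyNA(w)) {
        abort(sprintf("no fitness value for class '%s' in genotype '%s'",
                      cls[is.na(w)][1], cfg$genotype))
      }
    } else {
      w <- rep_len(fitness, n)
    }
    if (any(w <= 0)) abort("fitness weights must be > 0")
    if (cfg$fitness_noise_sdlog > 0) {
      w <- w * rlnorm(n, 0, cfg$fitness_noise_sdlog)
    }
    p0 <- if (is.finite(cfg$dispersion_shape)) {
      rgamma(n, shape = cfg$dispersion_shape)
    } else {
      rep(1, n)
    }
    p0 <- p0 / sum(p0)
    counts <- list(t0 = rmultinom(1, cfg$depth, p0)[, 1])
    for (tp in names(cfg$rounds)) {
      pt <- p0 * w^cfg$rounds[[tp]]
      counts[[tp]] <- rmultinom(1, cfg$depth, pt / sum(pt))[, 1]
    }
    tables <- purrr::imap(counts, function(ct, nmx) {
      count_table(setNames(as.integer(ct), lib$spacer_seq), sample_id = nmx)
    })
    out <- list(
      counts = tables,
      truth = tibble(spacer = lib$spacer_seq, class = cls, fitness = w),
      mean_fitness = sum(p0 * w)
    )
    if (emit_reads) {
      out$reads <- purrr::map(counts, function(ct) {
        amplicon_reads(lib$spacer_seq, ct, cfg$dr, cfg$error_rate)
      })
    }
    out
  })
}

# Per-start sampling weights for acquisition on one replicon: one weight per
# (strand, start) pair, classed by the midpoint of the prospective spacer.
acquisition_start_weights <- function(genome, cfg, biased) {
  L <- genome$length
  starts <- 0:(L - cfg$k)
  mid <- spacer_midpoint(starts, starts + cfg$k)
  w_minus <- rep(1, length(starts))
  if (biased && nrow(genome$operons) > 0) {
    pe <- genome$operons[genome$operons$name == "PE", ]
    if (nrow(pe) > 0) {
      upto <- if (cfg$genotype == "dcsm6") cfg$pe_split else pe$end[1]
      hot <- mid >= pe$start[1] & mid < upto
      w_minus[hot] <- cfg$acquisition_bias
    }
  }
  tibble(
    start = rep(starts, 2L),
    strand = rep(c("+", "-"), each = length(starts)),
    weight = c(rep(1, length(starts)), w_minus)
  )
}

#' Simulate naive spacer acquisition amplicons
#'
#' Each surviving colony contributes one newly acquired spacer drawn from
#' the phage with probability `theta / (1 + theta)` and otherwise from the
#' plasmid. Protospacer positions are drawn from per-position weights: the
#' WT and dcsm6 presets skew phage picks toward the (upstream-)PE minus
#' strand — the spacers that let the infected cell survive — while the
#' Cas10 nuclease-dead presets sample the phage uniformly. Reads are
#' emitted as `DR·spacer·DR` with substitution errors.
#'
#' @inheritParams simulate_screen
#' @param phage,plasmid [genome_annotation()]s.
#' @param n_reads Number of acquisition reads.
#' @return List with `reads` (character vector) and `truth` (tibble:
#'   replicon, start, strand per read).
#' @export
simulate_acquisition <- function(cfg, phage, plasmid, n_reads = 1e4) {
  withr::with_seed(cfg$seed + 109L, {
    biased <- cfg$genotype %in% c("WT", "dcsm6")
    wp <- acquisition_start_weights(phage, cfg, biased)
    wq <- acquisition_start_weights(plasmid, cfg, biased = FALSE)
    if (sum(wp$weight) <= 0 || sum(wq$weight) <= 0) {
      abort("degenerate acquisition weight vector")
    }
    from_phage <- runif(n_reads) < cfg$theta / (1 + cfg$theta)
    pick <- function(wtab, m) wtab[sample.int(nrow(wtab), m, replace = TRUE,
                                              prob = wtab$weight), ]
    truth <- bind_rows(
      pick(wp, sum(from_phage)) |> mutate(replicon = phage$name),
      pick(wq, sum(!from_phage)) |> mutate(replicon = plasmid$name)
    )[sample.int(n_reads), c("replicon", "start", "strand")]
    truth$end <- truth$start + cfg$k
    seqs <- character(n_reads)
    for (rn in unique(truth$replicon)) {
      g <- if (rn == phage$name) phage else plasmid
      i <- truth$replicon == rn
      seqs[i] <- spacer_sequence_at(truth[i, ], g)
    }
    reads <- mutate_reads(paste0(cfg$dr, seqs, cfg$dr), cfg$error_rate)
    list(reads = reads, truth = truth)
  })
}

#' Simulate stepped time-course RNA-seq coverage
#'
#' Expected coverage at each position and timepoint is a baseline plus, for
#' positions inside an operon whose promoter has fired by that time, an
#' amplitude that decays exponentially with distance from the operon start
#' (3'-decay); observed counts are Poisson. Signal lands on the operon's
#' mRNA strand; the baseline covers both strands.
#'
#' @inheritParams simulate_screen
#' @param genome A [genome_annotation()].
#' @return A [coverage_profile()] (raw counts; normalize before calling
#'   operons).
#' @export
simulate_rnaseq <- function(cfg, genome) {
  withr::with_seed(cfg$seed + 113L, {
    L <- genome$length
    pos <- 0:(L - 1L)
    purrr::map_dfr(cfg$timepoints, function(tp) {
      purrr::map_dfr(c("+", "-"), function(st) {
        mu <- rep(cfg$rnaseq_baseline, L)
        ops <- genome$operons
        for (i in seq_len(nrow(ops))) {
          if (ops$strand[i] == st && ops$activation_time[i] <= tp) {
            span <- (ops$start[i] + 1L):ops$end[i]
            mu[span] <- mu[span] + cfg$rnaseq_amplitude *
              exp(-cfg$rnaseq_decay_rate * (span - 1L - ops$start[i]))
          }
        }
        tibble(replicon = genome$name, position = pos, strand = st,
               timepoint = tp, count = rpois(L, mu))
      })
    }) |> coverage_profile()
  })
}

#' Write a complete simulated fixture directory
#'
#' Emits everything the pipeline consumes: genome and plasmid FASTA, operon
#' TSV, library manifest and oligo FASTA, per-sample screen FASTQ,
#' acquisition FASTQ, raw coverage TSV, and a provenance JSON recording the
#' configuration and seed.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created).
#' @param n_acquisition_reads Reads in the acquisition FASTQ.
#' @return Invisibly, a named list of the written paths.
#' @export
simulate_experiment <- function(cfg, dir, n_acquisition_reads = 1e4) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  genome <- simulate_genome(cfg)
  plasmid <- simulate_plasmid(cfg)
  lib <- design_tiling_library(genome, k = cfg$k, step = cfg$step)
  write_genome(genome, p("phage.fa"))
  write_genome(plasmid, p("plasmid.fa"))
  write_operons(cfg$operons, p("operons.tsv"), replicon = genome$name,
                seed = cfg$seed)
  write_library(lib, p("library.tsv"), fasta = p("oligos.fa"),
                seed = cfg$seed)
  scr <- simulate_screen(lib, genome, cfg, emit_reads = TRUE)
  paths <- list(genome = p("phage.fa"), plasmid = p("plasmid.fa"),
                operons = p("operons.tsv"), library = p("library.tsv"),
                oligos = p("oligos.fa"))
  for (nmx in names(scr$reads)) {
    paths[[paste0("fastq_", nmx)]] <- p(sprintf("screen_%s.fastq", nmx))
    write_fastq(scr$reads[[nmx]], paths[[paste0("fastq_", nmx)]])
  }
  acq <- simulate_acquisition(cfg, genome, plasmid,
                              n_reads = n_acquisition_reads)
  paths$fastq_acquisition <- p("acquisition.fastq")
  write_fastq(acq$reads, paths$fastq_acquisition)
  cov <- simulate_rnaseq(cfg, genome)
  paths$coverage <- p("coverage.tsv")
  write_coverage(cov, paths$coverage, seed = cfg$seed)
  paths$provenance <- p("provenance.json")
  jsonlite::write_json(
    list(tool = "spacerscreen", version = pkg_version(),
         seed = cfg$seed, genotype = cfg$genotype,
         note = "synthetic data; fitness presets and theta are calibration artifacts",
         config = unclass(cfg)[setdiff(names(cfg), "operons")],
         operons = cfg$operons),
    paths$provenance, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(paths)
}
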