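#' Time-course coverage profile
#'
#' Tidy container for per-position, per-strand, per-timepoint read coverage
#' over one replicon: a tibble with columns `replicon`, `position` (0-based),
#' `strand`, `timepoint` (minutes post-infection), `count` and, after
#' [normalize_coverage()], `norm`.
#'
#' @param x Tibble with at least `position`, `strand`, `timepoint`, `count`.
#' @param replicon Replicon name filled in when absent.
#' @return A `coverage_profile` tibble.
#' @export
coverage_profile <- function(x, replicon = "replicon") {
  x <- as_tibble(x)
  needed <- c("position", "strand", "timepoint", "count")
  if (!all(needed %in% names(x))) {
    abort(sprintf("coverage needs columns: %s", paste(needed, collapse = ", ")))
  }
  if (!"replicon" %in% names(x)) x$replicon <- replicon
  if (any(x$count < 0)) abort("coverage counts must be >= 0")
  x <- x |> arrange(.data$timepoint, .data$strand, .data$position)
  class(x) <- unique(c("coverage_profile", class(x)))
  x
}

#' Per-million normalization of time-course coverage
#'
#' Scales each timepoint so its total coverage (summed over positions and
#' both strands) equals 10^6, removing the library-size variability between
#' sequencing runs of different timepoints.
#'
#' @param raw A [coverage_profile()].
#' @return The profile with a `norm` column.
#' @export
normalize_coverage <- function(raw) {
  raw <- coverage_profile(raw)
  totals <- raw |>
    group_by(.data$timepoint) |>
    summarise(total = sum(.data$count), .groups = "drop")
  zero <- totals$timepoint[totals$total == 0]
  if (length(zero) > 0) {
    abort(sprintf("timepoint %s has zero total coverage",
                  paste(zero, collapse = ", ")))
  }
  out <- raw |>
    left_join(totals, by = "timepoint") |>
    mutate(norm = .data$count * 1e6 / .data$total) |>
    select(-"total")
  class(out) <- unique(c("coverage_profile", class(out)))
  out
}

# Dense per-position matrix (positions x timepoints) for one strand.
strand_matrix <- function(cov, strand, L, value) {
  tps <- sort(unique(cov$timepoint))
  m <- matrix(0, nrow = L, ncol = length(tps),
              dimnames = list(NULL, as.character(tps)))
  s <- cov[cov$strand == strand, ]
  m[cbind(s$position + 1L, match(s$timepoint, tps))] <- s[[value]]
  m
}

#' Call early/late transcribed regions from time-course coverage
#'
#' Formalises promoter-structure annotation as a smoothing + threshold
#' change-point rule. Per strand: normalized coverage at each timepoint is
#' smoothed with a centred running mean; a position is "on" at timepoint t
#' if its smoothed value exceeds `threshold_factor` times a genome-wide
#' baseline: the minimum over timepoints of the per-timepoint
#' `baseline_quantile` (default lower quartile) of smoothed coverage. A
#' per-timepoint median saturates once half the genome is transcribed —
#' which the late operon guarantees here — so the baseline must come from
#' the least-transcribed timepoint and a quantile low enough to sit in
#' untranscribed territory whenever at least a quarter of the genome is
#' quiet at the first sampled timepoint. Each position's
#' activation time is the earliest timepoint at which it is on; maximal
#' runs of positions sharing one activation time that are at least
#' `min_region` long become regions (so two adjacent operons firing at
#' different times are split at the change point), and regions are named
#' `early` (activating at the first sampled timepoint) or `late`. A
#' region's reported `activation_time` is the earliest timepoint at which
#' at least half of its positions are on.
#'
#' @param cov A [coverage_profile()]; raw profiles are normalized first.
#' @param threshold_factor On/off threshold as a multiple of the baseline.
#' @param smoothing_window Running-mean window (odd, nt).
#' @param baseline_quantile Quantile of smoothed coverage used as the
#'   untranscribed baseline level.
#' @param min_region Minimum region length (nt).
#' @param genome_length Replicon length; defaults to `max(position) + 1`.
#' @return Operon tibble (`start`, `end`, `name`, `activation_time`,
#'   `strand`) as consumed by [genome_annotation()]; empty when coverage is
#'   all zero.
#' @export
call_operons <- function(cov, threshold_factor = 5, smoothing_window = 501L,
                         min_region = 500L, genome_length = NULL,
                         baseline_quantile = 0.25) {
  cov <- coverage_profile(cov)
  if (length(unique(cov$timepoint)) < 2L) abort("need >= 2 timepoints")
  if (sum(cov$count) == 0) return(empty_operons())
  if (!"norm" %in% names(cov)) cov <- normalize_coverage(cov)
  L <- genome_length %||% (max(cov$position) + 1L)
  tps <- sort(unique(cov$timepoint))
  out <- purrr::map_dfr(intersect(c("+", "-"), unique(cov$strand)), function(st) {
    m <- strand_matrix(cov, st, L, "norm")
    sm <- apply(m, 2, running_mean, window = smoothing_window)
    baseline <- min(apply(sm, 2, stats::quantile, probs = baseline_quantile))
    thr <- threshold_factor * baseline
    on <- sm > thr
    # first timepoint index at which each position switches on (0 = never)
    first_on <- apply(on, 1, function(z) if (any(z)) which(z)[1L] else 0L)
    r <- rle(first_on)
    seg_end <- cumsum(r$lengths)
    seg_start <- seg_end - r$lengths
    keep <- which(r$values > 0L & r$lengths >= min_region)
    if (length(keep) == 0L) return(NULL)
    runs <- tibble(start = seg_start[keep], end = seg_end[keep])
    runs$activation_time <- vapply(seq_len(nrow(runs)), function(i) {
      idx <- (runs$start[i] + 1L):runs$end[i]
      frac <- colMeans(on[idx, , drop = FALSE])
      t_on <- tps[frac >= 0.5]
      if (length(t_on) == 0) tps[r$values[keep[i]]] else min(t_on)
    }, double(1))
    runs$strand <- st
    runs
  })
  if (is.null(out) || nrow(out) == 0L) return(empty_operons())
  out |>
    mutate(name = if_else(.data$activation_time == min(tps), "early", "late")) |>
    select("start", "end", "name", "activation_time", "strand") |>
    arrange(.data$start)
}

#' Read / write coverage profiles as TSV
#'
#' Columns: replicon, position (0-based), strand, timepoint, count
#' (and norm when present).
#'
#' @param cov A `coverage_profile`.
#' @param path TSV path.
#' @param seed,config_hash Provenance recorded in the file header.
#' @export
write_coverage <- function(cov, path, seed = NA, config_hash = NA) {
  write_tsv_with_header(as_tibble(cov), path, seed, config_hash)
}

#' @rdname write_coverage
#' @export
read_coverage <- function(path) {
  coverage_profile(read_tsv_commented(path))
}
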