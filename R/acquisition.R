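#' Build a k-mer position index over a replicon
#'
#' Hash from every `width`-mer of the plus strand to its 1-based start
#' positions; the seed-and-verify mapper queries it. Kept exported because
#' the index is reusable across samples.
#'
#' @param genome A [genome_annotation()].
#' @param width Seed width in nt (default 12).
#' @return A `kmer_index` object.
#' @export
kmer_index <- function(genome, width = 12L) {
  L <- genome$length
  if (L < width) abort("replicon shorter than the index k-mer")
  starts <- seq_len(L - width + 1L)
  kmers <- substring(genome$sequence, starts, starts + width - 1L)
  env <- list2env(split(starts, kmers),
                  envir = new.env(parent = emptyenv(), size = length(kmers)))
  structure(list(env = env, width = width, genome = genome),
            class = "kmer_index")
}

# Candidate plus-strand start positions (1-based) for `query` via pigeonhole
# seeding: with m mismatches allowed, m+1 disjoint seeds guarantee at least
# one exact seed hit. Falls back to all positions when the query is too
# short to place m+1 seeds.
seed_candidates <- function(index, query, max_mismatches) {
  w <- index$width
  k <- nchar(query)
  L <- index$genome$length
  if (k < w) return(NULL)  # caller reports 'unaligned: shorter than index k-mer'
  n_seeds <- max_mismatches + 1L
  if (n_seeds * w > k) {
    return(seq_len(L - k + 1L))  # exhaustive scan; genomes here are small
  }
  offs <- as.integer(round(seq(0L, k - w, length.out = n_seeds)))
  cand <- integer(0)
  for (o in offs) {
    hit <- get0(substr(query, o + 1L, o + w), envir = index$env)
    if (!is.null(hit)) cand <- c(cand, hit - o)
  }
  unique(cand[cand >= 1L & cand + k - 1L <= L])
}

# All placements of `query` on the plus strand of one replicon within
# max_mismatches: list(start (1-based), mism) — base vectors, this sits in
# the mapper's hot path.
query_placements <- function(index, query, max_mismatches) {
  cand <- seed_candidates(index, query, max_mismatches)
  if (is.null(cand) || length(cand) == 0L) {
    return(list(start = integer(), mism = integer()))
  }
  k <- nchar(query)
  windows <- substring(index$genome$sequence, cand, cand + k - 1L)
  mism <- hamming_to(windows, query)
  ok <- mism <= max_mismatches
  list(start = cand[ok], mism = mism[ok])
}

#' Map spacers to replicons with a seed-and-verify exact/near-exact mapper
#'
#' Each distinct spacer is searched on both strands of every replicon
#' through a k-mer index (pigeonhole seeding, full-length Hamming
#' verification; no indels). The lowest-mismatch placement wins; equal-best
#' placements at more than one locus make the spacer `ambiguous`; no
#' placement within `max_mismatches` leaves it `unaligned`. Acquired spacers
#' are copied from their protospacer, so the default is exact matching.
#'
#' @param table A [count_table()] (or tibble with `spacer`, `count`).
#' @param replicons List of [genome_annotation()]s (e.g. phage and plasmid).
#' @param max_mismatches Hamming tolerance (default 0).
#' @param seed_width k-mer width of the index.
#' @return A `spacer_alignment` tibble: `spacer`, `count`, `replicon`,
#'   `start`, `end` (0-based half-open), `strand`, `mismatches`, `status`
#'   (`unique`/`ambiguous`/`unaligned`), `n_best`, `reason`.
#' @export
map_spacers <- function(table, replicons, max_mismatches = 0L,
                        seed_width = 12L) {
  if (length(replicons) == 0L) abort("replicons must be non-empty")
  if (inherits(replicons, "genome_annotation")) replicons <- list(replicons)
  idx <- lapply(replicons, kmer_index, width = seed_width)
  nm <- vapply(replicons, function(g) g$name, character(1))
  n <- nrow(table)
  rep_out <- rep(NA_character_, n); start_out <- rep(NA_integer_, n)
  strand_out <- rep(NA_character_, n); mism_out <- rep(NA_integer_, n)
  status_out <- rep("unaligned", n); n_best <- integer(n)
  reason <- rep(NA_character_, n)
  rcs <- dna_revcomp(table$spacer)
  for (j in seq_len(n)) {
    sp <- table$spacer[j]
    k <- nchar(sp)
    if (k < seed_width) {
      reason[j] <- "shorter than index k-mer"
      next
    }
    starts <- integer(0); mism <- integer(0)
    strands <- character(0); reps <- integer(0)
    for (i in seq_along(idx)) {
      h <- query_placements(idx[[i]], sp, max_mismatches)
      starts <- c(starts, h$start); mism <- c(mism, h$mism)
      strands <- c(strands, rep("+", length(h$start)))
      reps <- c(reps, rep(i, length(h$start)))
      h <- query_placements(idx[[i]], rcs[j], max_mismatches)
      starts <- c(starts, h$start); mism <- c(mism, h$mism)
      strands <- c(strands, rep("-", length(h$start)))
      reps <- c(reps, rep(i, length(h$start)))
    }
    if (length(starts) == 0L) {
      reason[j] <- "no placement"
      next
    }
    best <- which(mism == min(mism))
    b <- best[order(reps[best], starts[best], strands[best])][1L]
    rep_out[j] <- nm[reps[b]]; start_out[j] <- starts[b] - 1L
    strand_out[j] <- strands[b]; mism_out[j] <- mism[b]
    status_out[j] <- if (length(best) > 1L) "ambiguous" else "unique"
    n_best[j] <- length(best)
  }
  res <- tibble(
    spacer = table$spacer, count = table$count, replicon = rep_out,
    start = start_out, end = start_out + nchar(table$spacer),
    strand = strand_out, mismatches = mism_out, status = status_out,
    n_best = n_best, reason = reason
  )
  class(res) <- c("spacer_alignment", class(res))
  res
}

#' Strand-separated single-nucleotide RPM coverage from spacer alignments
#'
#' Every uniquely aligned spacer with count `c` adds `c` to each position of
#' its interval on its strand ([IRanges::coverage()] does the
#' accumulation); positional totals are then scaled to reads per million
#' total uniquely aligned reads (the denominator pools all replicons).
#' Ambiguous spacers are excluded from the tracks but tallied, so
#' single-nucleotide maps never double-count.
#'
#' @param alignments A `spacer_alignment` tibble from [map_spacers()].
#' @param replicons The replicon list used for mapping (for lengths).
#' @return An `acquisition_profile`: list with `rpm` (tibble `replicon`,
#'   `position` (0-based), `strand`, `rpm`; nonzero positions only),
#'   `totals` (aligned read counts and percent per replicon, see
#'   [source_fractions()]), `ambiguous_reads`, `total_aligned`.
#' @export
position_coverage_rpm <- function(alignments, replicons) {
  if (inherits(replicons, "genome_annotation")) replicons <- list(replicons)
  uni <- alignments |> filter(.data$status == "unique")
  if (nrow(uni) == 0L) abort("no unique alignments to accumulate")
  total_aligned <- sum(uni$count)
  lens <- setNames(vapply(replicons, function(g) g$length, integer(1)),
                   vapply(replicons, function(g) g$name, character(1)))
  rpm <- purrr::map_dfr(names(lens), function(rn) {
    purrr::map_dfr(c("+", "-"), function(st) {
      a <- uni |> filter(.data$replicon == rn, .data$strand == st)
      if (nrow(a) == 0L) return(NULL)
      cov <- IRanges::coverage(
        IRanges::IRanges(start = a$start + 1L, end = a$end),
        weight = a$count, width = lens[[rn]]
      )
      v <- as.numeric(cov)
      nz <- which(v > 0)
      tibble(replicon = rn, position = nz - 1L, strand = st,
             rpm = v[nz] * 1e6 / total_aligned)
    })
  })
  structure(
    list(rpm = rpm,
         totals = source_fractions(alignments),
         ambiguous_reads = sum(alignments$count[alignments$status == "ambiguous"]),
         total_aligned = total_aligned),
    class = "acquisition_profile"
  )
}

#' @export
print.acquisition_profile <- function(x, ...) {
  cat(sprintf("<acquisition_profile> %d uniquely aligned reads (%d ambiguous)\n",
              x$total_aligned, x$ambiguous_reads))
  print(x$totals)
  invisible(x)
}

#' Fraction of aligned spacer reads per source replicon
#'
#' `100 * (uniquely aligned reads to replicon) / (total uniquely aligned
#' reads)`; ambiguous reads are reported separately, not in the
#' percentages.
#'
#' @param alignments A `spacer_alignment` tibble.
#' @return Tibble: `replicon`, `reads`, `percent`, plus attribute
#'   `ambiguous_reads`.
#' @export
source_fractions <- function(alignments) {
  uni <- alignments |> filter(.data$status == "unique")
  if (nrow(uni) == 0L) abort("no unique alignments")
  out <- uni |>
    group_by(.data$replicon) |>
    summarise(reads = sum(.data$count), .groups = "drop") |>
    mutate(percent = 100 * .data$reads / sum(.data$reads))
  attr(out, "ambiguous_reads") <-
    sum(alignments$count[alignments$status == "ambiguous"])
  out
}

#' Write an acquisition profile (wiggle-style TSV + JSON summary)
#'
#' @param profile An `acquisition_profile`.
#' @param path TSV path (`replicon`, `position`, `strand`, `rpm`).
#' @param json Optional JSON path for the source-fraction summary.
#' @param seed,config_hash Provenance recorded in the file header.
#' @export
write_profile <- function(profile, path, json = NULL,
                          seed = NA, config_hash = NA) {
  write_tsv_with_header(profile$rpm, path, seed, config_hash)
  if (!is.null(json)) {
    jsonlite::write_json(
      list(total_aligned = profile$total_aligned,
           ambiguous_reads = profile$ambiguous_reads,
           source_fractions = profile$totals),
      json, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(path)
}
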