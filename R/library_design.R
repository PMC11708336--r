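#' Default oligo flank scheme
#'
#' Each synthesis oligo is assembled as
#' `priming_left + bsai_left + repeat_left + spacer + repeat_right +
#' bsai_right + priming_right`, totalling 90 nt with a 35-nt spacer
#' (5 + 6 + 17 + 35 + 17 + 6 + 4). The BsaI recognition site (`GGTCTC`)
#' appears once per flank, oriented inward so that digestion cuts into the
#' repeat-homology arms and releases overhangs compatible with Golden Gate
#' insertion between two direct repeats. Plus- and minus-strand schemes use
#' distinct universal priming sequences so the two half-libraries can be
#' amplified without cross-priming.
#'
#' The repeat-homology arms are the terminal 17 nt of the package's synthetic
#' direct repeat ([synthetic_dr()]); they are design constants, not sequences
#' from any natural CRISPR locus.
#'
#' @return Named list with `plus` and `minus` sub-lists, each holding
#'   `priming_left`, `bsai_left`, `repeat_left`, `repeat_right`,
#'   `bsai_right`, `priming_right`.
#' @export
default_flank_scheme <- function() {
  dr <- synthetic_dr()
  arm_l <- substr(dr, nchar(dr) - 16L, nchar(dr))  # last 17 nt of the repeat
  arm_r <- substr(dr, 1L, 17L)                     # first 17 nt of the repeat
  list(
    plus = list(
      priming_left = "ACGCA", bsai_left = "GGTCTC",
      repeat_left = arm_l, repeat_right = arm_r,
      bsai_right = "GAGACC", priming_right = "TGGA"
    ),
    minus = list(
      priming_left = "GTCCA", bsai_left = "GGTCTC",
      repeat_left = arm_l, repeat_right = arm_r,
      bsai_right = "GAGACC", priming_right = "CAAC"
    )
  )
}

flank_parts <- c("priming_left", "bsai_left", "repeat_left",
                 "repeat_right", "bsai_right", "priming_right")

scheme_for_strand <- function(flank_scheme, strand) {
  key <- if (strand == "+") "plus" else "minus"
  sc <- flank_scheme[[key]]
  if (is.null(sc)) abort(sprintf("no flank scheme defined for strand '%s'", strand))
  if (!all(flank_parts %in% names(sc))) {
    abort(sprintf("flank scheme for strand '%s' is missing parts", strand))
  }
  sc
}

#' Assemble the synthesis oligo for spacers
#'
#' @param spacer_seq Character vector of spacer sequences.
#' @param strand Strand of each spacer (`"+"`/`"-"`), recycled.
#' @param flank_scheme Flank scheme as from [default_flank_scheme()], or
#'   `NULL` for a degenerate pass-through (oligo equals the spacer).
#' @param oligo_length Required total oligo length (synthesis constraint).
#' @return Character vector of oligos.
#' @export
build_oligo <- function(spacer_seq, strand = "+",
                        flank_scheme = default_flank_scheme(),
                        oligo_length = 90L) {
  if (is.null(flank_scheme)) return(spacer_seq)
  strand <- rep_len(strand, length(spacer_seq))
  out <- character(length(spacer_seq))
  for (s in unique(strand)) {
    sc <- scheme_for_strand(flank_scheme, s)
    i <- strand == s
    flank_nt <- sum(nchar(unlist(sc[flank_parts])))
    bad <- nchar(spacer_seq[i]) + flank_nt != oligo_length
    if (any(bad)) {
      abort(sprintf(
        "flank scheme (%d nt) + spacer (%d nt) does not total %d nt",
        flank_nt, nchar(spacer_seq[i][bad][1]), oligo_length
      ))
    }
    out[i] <- paste0(sc$priming_left, sc$bsai_left, sc$repeat_left,
                     spacer_seq[i], sc$repeat_right, sc$bsai_right,
                     sc$priming_right)
  }
  out
}

#' Recover the spacer from an emitted oligo
#'
#' Inverse of [build_oligo()]: strips the flanks of the given scheme.
#'
#' @param oligo Character vector of oligos.
#' @inheritParams build_oligo
#' @export
oligo_spacer <- function(oligo, strand = "+",
                         flank_scheme = default_flank_scheme()) {
  if (is.null(flank_scheme)) return(oligo)
  strand <- rep_len(strand, length(oligo))
  out <- character(length(oligo))
  for (s in unique(strand)) {
    sc <- scheme_for_strand(flank_scheme, s)
    i <- strand == s
    left <- nchar(sc$priming_left) + nchar(sc$bsai_left) + nchar(sc$repeat_left)
    right <- nchar(sc$repeat_right) + nchar(sc$bsai_right) + nchar(sc$priming_right)
    out[i] <- substr(oligo[i], left + 1L, nchar(oligo[i]) - right)
  }
  out
}

#' Design a genome-tiling spacer library
#'
#' Tiles spacers of length `k` every `step` nt along the replicon, on the
#' requested strand(s). Tiling anchors at plus-strand position 0 for both
#' strands: the minus-strand spacer over window `[p, p+k)` is the reverse
#' complement of the plus-strand substring, so both half-libraries share one
#' coordinate grid. Per strand there are `floor((L - k)/step) + 1` spacers.
#' Spacers whose sequence occurs more than once in the designed set (genomic
#' repeats, or local reverse-complement palindromes) are kept but flagged
#' `duplicate = TRUE`.
#'
#' @param genome A [genome_annotation()].
#' @param k Spacer length in nt (default 35, the canonical type III-A size).
#' @param step Tiling step in nt (default 2).
#' @param strands `"both"`, `"plus"` or `"minus"`.
#' @inheritParams build_oligo
#' @return A tibble (class `spacer_library`) with columns `id`, `replicon`,
#'   `start`, `end` (0-based half-open), `strand`, `spacer_seq`, `oligo_seq`,
#'   `duplicate`. Design parameters are attached as attribute `design`.
#' @export
design_tiling_library <- function(genome, k = 35L, step = 2L,
                                  strands = c("both", "plus", "minus"),
                                  flank_scheme = default_flank_scheme(),
                                  oligo_length = 90L) {
  strands <- match.arg(strands)
  k <- as.integer(k); step <- as.integer(step)
  if (k < 15L) abort("spacer length k must be >= 15 nt")
  if (step < 1L) abort("step must be >= 1 nt")
  L <- genome$length
  if (L < k) abort(sprintf("genome length %d < spacer length %d", L, k))
  starts <- seq.int(0L, L - k, by = step)
  window <- substring(genome$sequence, starts + 1L, starts + k)
  rows <- list()
  if (strands %in% c("both", "plus")) {
    rows$plus <- tibble(
      replicon = genome$name, start = starts, end = starts + k,
      strand = "+", spacer_seq = window
    )
  }
  if (strands %in% c("both", "minus")) {
    rows$minus <- tibble(
      replicon = genome$name, start = starts, end = starts + k,
      strand = "-", spacer_seq = dna_revcomp(window)
    )
  }
  lib <- bind_rows(rows)
  lib <- lib |>
    mutate(
      id = sprintf("%s_%07d_%s", .data$replicon, .data$start,
                   if_else(.data$strand == "+", "p", "m")),
      oligo_seq = build_oligo(.data$spacer_seq, .data$strand,
                              flank_scheme, oligo_length),
      duplicate = .data$spacer_seq %in%
        .data$spacer_seq[duplicated(.data$spacer_seq)]
    ) |>
    select("id", "replicon", "start", "end", "strand",
           "spacer_seq", "oligo_seq", "duplicate")
  attr(lib, "design") <- list(k = k, step = step, strands = strands,
                              oligo_length = oligo_length,
                              flank_scheme = flank_scheme)
  class(lib) <- c("spacer_library", class(lib))
  lib
}

#' Read / write a spacer library manifest
#'
#' The manifest is a TSV with columns id, replicon, start, end, strand,
#' spacer_seq, oligo_seq, duplicate (0-based half-open coordinates); the
#' oligos can additionally be written as FASTA for synthesis ordering.
#'
#' @param lib A `spacer_library` tibble.
#' @param path Manifest TSV path.
#' @param fasta Optional path for an oligo FASTA.
#' @param seed,config_hash Provenance recorded in the file header.
#' @export
write_library <- function(lib, path, fasta = NULL, seed = NA, config_hash = NA) {
  write_tsv_with_header(as_tibble(lib), path, seed, config_hash)
  if (!is.null(fasta)) {
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(setNames(lib$oligo_seq, lib$id)), fasta)
  }
  invisible(path)
}

#' @rdname write_library
#' @export
read_library <- function(path) {
  x <- read_tsv_commented(path)
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  class(x) <- c("spacer_library", class(x))
  x
}
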