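#' Construct a spacer count table
#'
#' The unit of exchange between extraction and the enrichment statistics:
#' one row per distinct spacer sequence with its read count, plus sample
#' totals carried as attributes.
#'
#' @param counts Named integer vector or two-column tibble (`spacer`,
#'   `count`).
#' @param sample_id Sample label.
#' @param total_reads Number of reads scanned (defaults to the number of
#'   extracted spacers when unknown).
#' @param skips Named list of skip tallies from extraction.
#' @return A `count_table` tibble with columns `spacer`, `count`.
#' @export
count_table <- function(counts, sample_id = "sample",
                        total_reads = NULL, skips = list()) {
  if (is.data.frame(counts)) {
    tab <- tibble(spacer = as.character(counts$spacer),
                  count = as.integer(counts$count))
  } else {
    tab <- tibble(spacer = names(counts) %||% character(),
                  count = as.integer(counts))
  }
  if (any(tab$count < 0)) abort("counts must be non-negative")
  tab <- tab |> arrange(dplyr::desc(.data$count), .data$spacer)
  total_extracted <- sum(tab$count)
  structure(
    tab,
    class = c("count_table", class(tab)),
    sample_id = sample_id,
    total_reads = total_reads %||% total_extracted,
    total_extracted = total_extracted,
    skips = skips
  )
}

#' @rdname count_table
#' @param x A `count_table`.
#' @export
total_extracted <- function(x) {
  attr(x, "total_extracted") %||% sum(x$count)
}

#' Summarise a count table
#' @param x A `count_table`.
#' @param ... Unused.
#' @return One-row tibble: sample, totals, unique spacer count.
#' @method glance count_table
#' @export
glance.count_table <- function(x, ...) {
  tibble(
    sample_id = attr(x, "sample_id") %||% NA_character_,
    total_reads = attr(x, "total_reads") %||% NA_integer_,
    total_extracted = total_extracted(x),
    unique_spacers = detected_unique_spacers(x)
  )
}

#' Number of distinct spacers at or above a count threshold
#'
#' @param table A `count_table` (or any tibble with a `count` column).
#' @param min_count Minimum count for a spacer to be called detected.
#' @export
detected_unique_spacers <- function(table, min_count = 1L) {
  sum(table$count >= min_count)
}

#' Read amplicon sequences from FASTQ
#'
#' Sequence parsing is done by [Biostrings::readDNAStringSet()]
#' (`format = "fastq"`, plain or gzip), preceded by a structural check of
#' the four-line record layout so that truncated or shuffled records —
#' which the parser would silently tolerate — error with the index of the
#' offending record.
#'
#' @param path FASTQ path.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) {
    abort(sprintf("malformed FASTQ '%s': truncated record %d",
                  path, length(lines) %/% 4L + 1L))
  }
  rec <- matrix(lines, nrow = 4L)
  bad <- which(!startsWith(rec[1L, ], "@") | !startsWith(rec[3L, ], "+") |
                 nchar(rec[2L, ]) != nchar(rec[4L, ]))
  if (length(bad) > 0L) {
    abort(sprintf("malformed FASTQ '%s': record %d", path, bad[1L]))
  }
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq"),
    error = function(e) abort(sprintf("malformed FASTQ '%s': %s",
                                      path, conditionMessage(e)))
  )
  as.character(seqs)
}

#' Write sequences as FASTQ (constant quality)
#'
#' @param seqs Character vector of read sequences.
#' @param path Output path (`.gz` suffix gzips).
#' @param ids Read identifiers.
#' @param quality_char Single Phred+33 character used for every base.
#' @export
write_fastq <- function(seqs, path, ids = sprintf("read%07d", seq_along(seqs)),
                        quality_char = "I") {
  x <- Biostrings::DNAStringSet(setNames(seqs, ids))
  qual <- Biostrings::BStringSet(strrep(quality_char, nchar(seqs)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

# Find direct-repeat occurrences in each read: vmatchPattern does the
# C-level Hamming-window search; per-occurrence mismatch counts are then
# recomputed vectorised so overlapping candidates can be resolved
# deterministically (lowest mismatch wins, leftmost on ties, greedily
# left-to-right).
dr_occurrences <- function(seqs, repeat_seq, max_mismatches) {
  d <- nchar(repeat_seq)
  hits <- Biostrings::vmatchPattern(repeat_seq, Biostrings::DNAStringSet(seqs),
                                    max.mismatch = max_mismatches)
  nhit <- S4Vectors::elementNROWS(hits)
  if (sum(nhit) == 0L) {
    return(tibble(read = integer(), start = integer(), mism = integer()))
  }
  u <- unlist(hits)
  read <- rep.int(seq_along(seqs), nhit)
  starts <- BiocGenerics::start(u)
  keep <- starts >= 1L & starts + d - 1L <= nchar(seqs)[read]
  read <- read[keep]; starts <- starts[keep]
  mism <- if (max_mismatches > 0L) {
    hamming_to(substr(seqs[read], starts, starts + d - 1L), repeat_seq)
  } else {
    integer(length(starts))
  }
  tibble(read = read, start = starts, mism = mism)
}

# Greedy resolution of overlapping DR candidates within one read:
# repeatedly take the leftmost unresolved candidate's overlap cluster,
# accept its lowest-mismatch member (leftmost on ties), drop everything
# overlapping the accepted window, continue rightwards.
resolve_overlaps <- function(starts, mism, d) {
  keep <- logical(length(starts))
  avail <- rep(TRUE, length(starts))
  while (any(avail)) {
    i <- which(avail)[1L]
    cluster <- which(avail & starts < starts[i] + d & starts + d > starts[i])
    best <- cluster[order(mism[cluster], starts[cluster])][1L]
    keep[best] <- TRUE
    avail[avail & starts < starts[best] + d & starts + d > starts[best]] <- FALSE
  }
  which(keep)
}

# One scanning pass over reads in their given orientation. Returns per-read
# spacer hits and the out-of-bounds gap tally.
scan_orientation <- function(seqs, repeat_seq, max_mismatches, bounds) {
  d <- nchar(repeat_seq)
  occ <- dr_occurrences(seqs, repeat_seq, max_mismatches)
  if (nrow(occ) == 0L) {
    return(list(hits = tibble(read = integer(), spacer = character()),
                out_of_bounds = 0L))
  }
  occ <- occ |> arrange(.data$read, .data$start)
  # fast path: resolve only the reads where candidate windows overlap
  same_read <- occ$read == lag(occ$read, default = -1L)
  overlapping <- same_read & occ$start < lag(occ$start, default = -1L) + d
  if (any(overlapping)) {
    bad_reads <- unique(occ$read[overlapping])
    fix <- occ$read %in% bad_reads
    fixed <- occ[fix, ] |>
      group_by(.data$read) |>
      slice(resolve_overlaps(.data$start, .data$mism, d)) |>
      ungroup()
    occ <- bind_rows(occ[!fix, ], fixed) |> arrange(.data$read, .data$start)
  }
  # spacers = gaps between consecutive accepted DRs within a read
  pair <- which(occ$read == lead(occ$read, default = -1L))
  if (length(pair) == 0L) {
    return(list(hits = tibble(read = integer(), spacer = character()),
                out_of_bounds = 0L, reads_with_pairs = integer()))
  }
  gap_len <- occ$start[pair + 1L] - occ$start[pair] - d
  ok <- gap_len >= bounds[1] & gap_len <= bounds[2]
  list(
    hits = tibble(
      read = occ$read[pair][ok],
      spacer = substr(seqs[occ$read[pair][ok]],
                      occ$start[pair][ok] + d,
                      occ$start[pair + 1L][ok] - 1L)
    ),
    out_of_bounds = sum(!ok),
    reads_with_pairs = unique(occ$read[pair])
  )
}

#' Extract repeat-flanked spacers from amplicon reads
#'
#' Scans each read for runs of the form `DR · spacer · DR` where every direct
#' repeat (DR) occurrence is within `max_repeat_mismatches` Hamming distance
#' of `repeat_seq` (full-length windows, no indels). An expanded array read
#' `DR·S1·DR·S2·DR` yields both S1 and S2 (the middle repeat is shared).
#' Overlapping DR candidates are resolved greedily left-to-right, lowest
#' mismatch count first (leftmost on ties). Spacers outside
#' `spacer_len_bounds` are skipped and tallied. When
#' `search_both_orientations` is `TRUE`, reads without any forward DR pair
#' are rescanned as their reverse complement, so spacers are
#' always reported in the forward amplicon orientation.
#'
#' @param reads FASTQ path (plain or `.gz`) or a character vector of read
#'   sequences.
#' @param repeat_seq The direct repeat sequence (>= 12 nt).
#' @param max_repeat_mismatches Per-occurrence Hamming tolerance (default 1).
#' @param spacer_len_bounds Inclusive `[min, max]` spacer length in nt.
#' @param search_both_orientations Also scan reverse-complemented reads.
#' @param sample_id Sample label stored on the result.
#' @param min_mean_quality Reserved for quality filtering; qualities are
#'   ignored by default (`NULL`) as base-call quality plays no role in the
#'   repeat-anchored search.
#' @return A [count_table()] with attributes `total_reads`,
#'   `total_extracted` and `skips` (reads shorter than the repeat,
#'   out-of-bounds gaps).
#' @export
extract_spacers <- function(reads, repeat_seq,
                            max_repeat_mismatches = 1L,
                            spacer_len_bounds = c(20L, 50L),
                            search_both_orientations = TRUE,
                            sample_id = "sample",
                            min_mean_quality = NULL) {
  if (length(reads) == 1L && grepl("\\.(fastq|fq)(\\.gz)?$", reads)) {
    reads <- read_fastq(reads)
  }
  repeat_seq <- toupper(repeat_seq)
  check_dna(repeat_seq, "repeat_seq")
  if (nchar(repeat_seq) < 12L) abort("repeat_seq must be >= 12 nt")
  if (length(reads) == 0L) abort("no reads supplied")
  if (spacer_len_bounds[1] > spacer_len_bounds[2]) {
    abort("spacer_len_bounds must satisfy min <= max")
  }
  reads <- toupper(reads)
  n_reads <- length(reads)
  too_short <- nchar(reads) < nchar(repeat_seq)
  skipped_short <- sum(too_short)
  seqs <- reads[!too_short]

  fwd <- scan_orientation(seqs, repeat_seq, max_repeat_mismatches,
                          spacer_len_bounds)
  oob <- fwd$out_of_bounds
  spacers <- fwd$hits$spacer
  if (search_both_orientations) {
    # a read with any forward DR pair is already amplicon-oriented; only
    # reads without one can be reverse-orientation amplicons
    miss <- setdiff(seq_along(seqs), fwd$reads_with_pairs)
    if (length(miss) > 0L) {
      rev <- scan_orientation(dna_revcomp(seqs[miss]), repeat_seq,
                              max_repeat_mismatches, spacer_len_bounds)
      oob <- oob + rev$out_of_bounds
      spacers <- c(spacers, rev$hits$spacer)
    }
  }
  counts <- table(spacers)
  count_table(
    setNames(as.integer(counts), names(counts)),
    sample_id = sample_id,
    total_reads = n_reads,
    skips = list(read_shorter_than_repeat = skipped_short,
                 spacer_out_of_bounds = as.integer(oob))
  )
}

#' Read / write count tables as TSV (+ JSON summary)
#'
#' @param ct A `count_table`.
#' @param path TSV path (columns `spacer`, `count`).
#' @param json Optional path for a JSON summary of totals and skip tallies.
#' @param seed,config_hash Provenance recorded in the file header.
#' @export
write_counts <- function(ct, path, json = NULL, seed = NA, config_hash = NA) {
  write_tsv_with_header(as_tibble(ct), path, seed, config_hash)
  if (!is.null(json)) {
    jsonlite::write_json(
      list(sample_id = attr(ct, "sample_id"),
           total_reads = attr(ct, "total_reads"),
           total_extracted = total_extracted(ct),
           unique_spacers = detected_unique_spacers(ct),
           skips = attr(ct, "skips")),
      json, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_counts
#' @param sample_id Sample label for the read table.
#' @export
read_counts <- function(path, sample_id = NULL) {
  x <- read_tsv_commented(path)
  count_table(x, sample_id = sample_id %||% sub("\\.tsv$", "", basename(path)))
}
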