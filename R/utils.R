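#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over a character vector of DNA sequences.
#' Delegates to [Biostrings::reverseComplement()] so IUPAC ambiguity codes are
#' handled correctly.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @export
#' @examples
#' dna_revcomp(c("ACGT", "AAAC"))
dna_revcomp <- function(x) {
  if (length(x) == 0L) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Validate a DNA string over {A,C,G,T}; errors name the first offending
# position (1-based within the string) so bad FASTA inputs are easy to locate.
check_dna <- function(x, what = "sequence") {
  bad <- regexpr("[^ACGT]", x)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    abort(sprintf(
      "%s contains a non-ACGT character ('%s') at position %d%s",
      what, substr(x[i], bad[i], bad[i]), bad[i],
      if (length(x) > 1L) sprintf(" of element %d", i) else ""
    ))
  }
  invisible(x)
}

# Random DNA string(s) of length n (uniform base composition).
random_dna <- function(n, m = 1L) {
  vapply(seq_len(m), function(i) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  }, character(1))
}

# Centered running mean with a shrinking window at the edges (window must be
# odd). Implemented with cumulative sums: O(n) and exact at the boundaries.
running_mean <- function(x, window) {
  stopifnot(window >= 1L, window %% 2L == 1L)
  n <- length(x)
  if (window == 1L || n == 0L) return(x)
  h <- (window - 1L) %/% 2L
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Maximal runs of TRUE in a logical vector, as a tibble of 0-based half-open
# [start, end) intervals.
true_runs <- function(on) {
  r <- rle(on)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  tibble(start = starts[keep] - 1L, end = ends[keep])
}

# Hamming mismatch counts between equal-length strings `windows` and a single
# `pattern`, fully vectorised over windows (column-by-column comparison).
hamming_to <- function(windows, pattern) {
  d <- nchar(pattern)
  mism <- integer(length(windows))
  for (j in seq_len(d)) {
    mism <- mism + (substr(windows, j, j) != substr(pattern, j, j))
  }
  mism
}

pkg_version <- function() {
  as.character(utils::packageVersion("spacerscreen"))
}

# Standard provenance header written atop every emitted table.
output_header <- function(seed = NA, config_hash = NA) {
  sprintf(
    "# spacerscreen v%s | coordinates: 0-based half-open | seed=%s | config_hash=%s",
    pkg_version(), as.character(seed), as.character(config_hash)
  )
}

write_tsv_with_header <- function(x, path, seed = NA, config_hash = NA) {
  writeLines(output_header(seed, config_hash), path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

read_tsv_commented <- function(path, ...) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE, ...)
}
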