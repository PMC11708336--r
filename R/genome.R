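#' Genome annotation: replicon sequence plus operon map
#'
#' Bundles a replicon sequence with a map of transcribed regions (operons),
#' each carrying the strand that equals the mRNA sequence and the time
#' post-infection at which its promoter fires. All coordinates throughout the
#' package are 0-based half-open `[start, end)`.
#'
#' @param name Replicon identifier.
#' @param sequence DNA string over `{A,C,G,T}`.
#' @param operons Tibble with columns `start`, `end` (0-based half-open,
#'   integer nt), `name` (e.g. `"PE"`, `"PL"`), `activation_time` (minutes
#'   post-infection) and `strand` (`"+"` or `"-"`, the strand whose sequence
#'   equals the mRNA). May be empty.
#' @return A `genome_annotation` object (list with `name`, `sequence`,
#'   `operons`, `length`).
#' @export
#' @examples
#' g <- genome_annotation("toy", "ACGTACGTAC",
#'   operons = tibble::tibble(start = 0L, end = 8L, name = "PE",
#'                            activation_time = 5, strand = "+"))
#' g$length
genome_annotation <- function(name, sequence,
                              operons = empty_operons()) {
  sequence <- toupper(sequence)
  check_dna(sequence, sprintf("genome '%s'", name))
  operons <- as_tibble(operons)
  needed <- c("start", "end", "name", "activation_time", "strand")
  if (!all(needed %in% names(operons))) {
    abort(sprintf("operon table must have columns: %s",
                  paste(needed, collapse = ", ")))
  }
  L <- nchar(sequence)
  if (nrow(operons) > 0) {
    if (any(operons$start >= operons$end)) {
      abort("operon intervals must satisfy start < end")
    }
    if (any(operons$start < 0L) || any(operons$end > L)) {
      abort(sprintf("operon interval outside [0, %d)", L))
    }
    if (any(operons$activation_time < 0)) {
      abort("operon activation_time must be >= 0")
    }
    if (!all(operons$strand %in% c("+", "-"))) {
      abort("operon strand must be '+' or '-'")
    }
    # same-strand operons must not overlap
    for (s in unique(operons$strand)) {
      o <- operons[operons$strand == s, ]
      o <- o[order(o$start), ]
      if (nrow(o) > 1 && any(o$start[-1] < o$end[-nrow(o)])) {
        abort(sprintf("operons on strand '%s' overlap", s))
      }
    }
  }
  structure(
    list(name = name, sequence = sequence,
         operons = operons[order(operons$start), ], length = L),
    class = "genome_annotation"
  )
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> %s: %d nt, %d operon(s)\n",
              x$name, x$length, nrow(x$operons)))
  if (nrow(x$operons) > 0) print(x$operons)
  invisible(x)
}

#' Empty operon table with the canonical columns
#' @return Zero-row operon tibble.
#' @export
empty_operons <- function() {
  tibble(start = integer(), end = integer(), name = character(),
         activation_time = double(), strand = character())
}

#' Read / write genomes as FASTA
#'
#' @param path FASTA file path.
#' @param operons Optional operon tibble attached to the first record.
#' @return `read_genome()` returns a [genome_annotation()] for the first
#'   record (multi-record files: use `which`).
#' @param which Record index to take from a multi-FASTA.
#' @export
read_genome <- function(path, operons = empty_operons(), which = 1L) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) < which) abort(sprintf("FASTA '%s' has no record %d", path, which))
  nm <- sub("\\s.*$", "", names(seqs)[which])
  genome_annotation(nm, as.character(seqs[[which]]), operons = operons)
}

#' @rdname read_genome
#' @param genome A `genome_annotation`.
#' @export
write_genome <- function(genome, path) {
  x <- Biostrings::DNAStringSet(setNames(genome$sequence, genome$name))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read / write operon maps as BED-like TSV
#'
#' Columns: replicon, start, end, name, activation_time, strand
#' (0-based half-open intervals).
#'
#' @param path TSV path.
#' @export
read_operons <- function(path) {
  x <- read_tsv_commented(path)
  tibble(start = as.integer(x$start), end = as.integer(x$end),
         name = as.character(x$name),
         activation_time = as.double(x$activation_time),
         strand = as.character(x$strand))
}

#' @rdname read_operons
#' @param operons Operon tibble.
#' @param replicon Replicon name written in the first column.
#' @param seed,config_hash Provenance recorded in the file header.
#' @export
write_operons <- function(operons, path, replicon = "replicon",
                          seed = NA, config_hash = NA) {
  out <- tibble(replicon = replicon, start = operons$start, end = operons$end,
                name = operons$name, activation_time = operons$activation_time,
                strand = operons$strand)
  write_tsv_with_header(out, path, seed, config_hash)
}

# Midpoint of 0-based half-open spacer intervals (floor of the centre; a
# midpoint landing exactly on an operon boundary belongs to the downstream
# region because intervals are half-open).
spacer_midpoint <- function(start, end) {
  as.integer(floor((start + end) / 2))
}

check_mapped <- function(spacers, genome) {
  if (!all(c("start", "end", "strand") %in% names(spacers))) {
    abort("spacer table must have columns start, end, strand")
  }
  src <- spacers[["replicon"]] %||% spacers[["source"]]
  if (!is.null(src) && any(src != genome$name | is.na(src))) {
    abort(sprintf("spacer(s) not mapped to genome '%s'", genome$name))
  }
  if (any(is.na(spacers$start)) || any(spacers$start < 0) ||
      any(spacers$end > genome$length)) {
    abort(sprintf("spacer interval outside genome '%s'", genome$name))
  }
  invisible(spacers)
}

#' Transcribed-region label of mapped spacers
#'
#' Assigns each spacer the operon whose interval contains the spacer's
#' midpoint, or `"untranscribed"` if no operon does. A midpoint exactly on a
#' shared boundary goes to the downstream region (half-open intervals).
#'
#' @param spacers Tibble with `start`, `end`, `strand` columns (and optionally
#'   `replicon`, checked against `genome$name`).
#' @param genome A [genome_annotation()].
#' @return Character vector of region labels, one per spacer row.
#' @export
region_of <- function(spacers, genome) {
  check_mapped(spacers, genome)
  mid <- spacer_midpoint(spacers$start, spacers$end)
  lab <- rep("untranscribed", nrow(spacers))
  ops <- genome$operons
  for (i in seq_len(nrow(ops))) {
    hit <- mid >= ops$start[i] & mid < ops$end[i]
    lab[hit] <- ops$name[i]
  }
  lab
}

#' Does a spacer's crRNA target a transcript?
#'
#' `TRUE` iff the spacer midpoint lies in an operon and the spacer strand is
#' opposite to the operon's mRNA strand, so the crRNA (whose sequence equals
#' the spacer) can base-pair with the transcript. Type III-A targeting needs
#' no PAM/PFS, so strand complementarity inside a transcribed region is the
#' whole rule.
#'
#' @inheritParams region_of
#' @return Logical vector, one per spacer row.
#' @export
is_targeting <- function(spacers, genome) {
  check_mapped(spacers, genome)
  mid <- spacer_midpoint(spacers$start, spacers$end)
  out <- rep(FALSE, nrow(spacers))
  ops <- genome$operons
  for (i in seq_len(nrow(ops))) {
    hit <- mid >= ops$start[i] & mid < ops$end[i]
    out[hit] <- spacers$strand[hit] != ops$strand[i]
  }
  out
}

#' Reconstruct spacer sequences from coordinates
#'
#' Plus-strand spacers equal the genome substring over their interval;
#' minus-strand spacers equal its reverse complement.
#'
#' @inheritParams region_of
#' @return Character vector of spacer sequences.
#' @export
spacer_sequence_at <- function(spacers, genome) {
  check_mapped(spacers, genome)
  fwd <- substring(genome$sequence, spacers$start + 1L, spacers$end)
  ifelse(spacers$strand == "+", fwd, dna_revcomp(fwd))
}
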