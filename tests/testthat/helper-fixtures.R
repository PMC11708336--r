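# Fixtures and independent oracles used across the suite. Oracles are kept
# deliberately naive (position-by-position scans, direct formula sums) so
# they share no code with the implementation paths they check.

toy_genome <- function(seq = NULL, L = 200, seed = 42,
                       operons = empty_operons(), name = "toy") {
  if (is.null(seq)) {
    seq <- withr::with_seed(seed, paste(
      sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""))
  }
  genome_annotation(name, seq, operons = operons)
}

# Two plus-strand operons mirroring the early/late architecture, scaled to
# a genome of length L.
toy_operons <- function(pe = c(1000L, 15000L), pl = c(15000L, 40000L)) {
  tibble::tibble(start = c(pe[1], pl[1]), end = c(pe[2], pl[2]),
                 name = c("PE", "PL"), activation_time = c(5, 15),
                 strand = c("+", "+"))
}

# Naive revcomp, independent of dna_revcomp().
rc_naive <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vapply(strsplit(x, ""), function(ch)
    paste(rev(unname(comp[ch])), collapse = ""), character(1))
}

# Hamming distance by character comparison.
hamming_naive <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Sliding-window DR search + greedy non-overlap + gap collection: the
# brute-force oracle for spacer extraction on a single read.
extract_oracle <- function(read, dr, max_mm = 1, bounds = c(20, 50)) {
  d <- nchar(dr)
  n <- nchar(read)
  if (n < d) return(character())
  cand <- data.frame(start = seq_len(n - d + 1L))
  cand$mism <- vapply(cand$start, function(s)
    hamming_naive(substr(read, s, s + d - 1L), dr), numeric(1))
  cand <- cand[cand$mism <= max_mm, ]
  accepted <- integer()
  while (nrow(cand) > 0) {
    first <- cand$start[1]
    cluster <- cand[cand$start < first + d, ]
    best <- cluster$start[order(cluster$mism, cluster$start)][1]
    accepted <- c(accepted, best)
    cand <- cand[!(cand$start < best + d & cand$start + d > best), ]
  }
  accepted <- sort(accepted)
  out <- character()
  for (i in seq_along(accepted)[-1]) {
    len <- accepted[i] - accepted[i - 1] - d
    if (len >= bounds[1] && len <= bounds[2]) {
      out <- c(out, substr(read, accepted[i - 1] + d, accepted[i] - 1))
    }
  }
  out
}

# Position-by-position mapper oracle over both strands of every replicon,
# via Biostrings::matchPattern (independent of the k-mer index path).
map_oracle <- function(spacer, replicons, max_mm = 0) {
  hits <- list()
  for (g in replicons) {
    subj <- Biostrings::DNAString(g$sequence)
    for (st in c("+", "-")) {
      q <- if (st == "+") spacer else rc_naive(spacer)
      m <- Biostrings::matchPattern(q, subj, max.mismatch = max_mm)
      if (length(m) > 0) {
        mm <- vapply(as.character(m), hamming_naive, numeric(1), b = q)
        hits[[length(hits) + 1L]] <- data.frame(
          replicon = g$name, start = Biostrings::start(m) - 1L,
          strand = st, mism = unname(mm))
      }
    }
  }
  if (length(hits) == 0) {
    return(list(status = "unaligned", best = NULL))
  }
  h <- do.call(rbind, hits)
  h <- h[h$mism == min(h$mism), ]
  list(status = if (nrow(h) > 1) "ambiguous" else "unique",
       best = h[order(h$replicon, h$start, h$strand), ][1, ])
}

# Error-free DR.spacer.DR amplicons with planted multiplicities.
planted_amplicons <- function(spacers, counts, dr) {
  paste0(dr, rep.int(spacers, counts), dr)
}

# m random DNA strings of length len.
random_dna_vec <- function(len, m) {
  vapply(seq_len(m), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}
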