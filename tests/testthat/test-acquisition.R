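test_that("exact placements resolve position, strand and status", {
  g <- toy_genome(L = 500, seed = 41)
  s <- substr(g$sequence, 1, 35)
  ct <- count_table(setNames(c(1L, 1L), c(s, dna_revcomp(s))))
  aln <- map_spacers(ct, g)
  plus <- aln[aln$spacer == s, ]
  expect_identical(plus$status, "unique")
  expect_identical(plus$start, 0L)
  expect_identical(plus$end, 35L)
  expect_identical(plus$strand, "+")
  expect_identical(plus$mismatches, 0L)
  minus <- aln[aln$spacer == dna_revcomp(s), ]
  expect_identical(minus$status, "unique")
  expect_identical(minus$start, 0L)
  expect_identical(minus$strand, "-")
})

test_that("a spacer present in two replicons is ambiguous", {
  shared <- strrep("ACGTG", 7)
  g1 <- genome_annotation("phage", paste0(shared, strrep("T", 30)))
  g2 <- genome_annotation("plasmid", paste0(strrep("C", 30), shared))
  aln <- map_spacers(count_table(setNames(1L, shared)), list(g1, g2))
  expect_identical(aln$status, "ambiguous")
  expect_identical(aln$n_best, 2L)
  # brute-force confirmation of two best placements
  expect_identical(map_oracle(shared, list(g1, g2))$status, "ambiguous")
})

test_that("mapper agrees with a brute-force scan on random spacers", {
  withr::local_seed(43)
  g <- toy_genome(L = 10000, seed = 43, name = "rand")
  # half real substrings (either strand), half random sequences
  n <- 1000
  starts <- sample(0:(10000 - 35), n / 2)
  real <- substring(g$sequence, starts + 1, starts + 35)
  flip <- sample(c(TRUE, FALSE), n / 2, replace = TRUE)
  real[flip] <- dna_revcomp(real[flip])
  rand <- random_dna_vec(35, n / 2)
  spacers <- unique(c(real, rand))
  aln <- map_spacers(count_table(setNames(rep(1L, length(spacers)), spacers)), g)
  for (i in seq_len(nrow(aln))) {
    o <- map_oracle(aln$spacer[i], list(g))
    expect_identical(aln$status[i], o$status)
    if (o$status == "unique") {
      expect_identical(aln$start[i], o$best$start)
      expect_identical(aln$strand[i], o$best$strand)
    }
  }
})

test_that("near-exact mode finds mismatched placements pigeonhole-style", {
  g <- toy_genome(L = 3000, seed = 44)
  s <- substr(g$sequence, 101, 135)
  substr(s, 3, 3) <- if (substr(s, 3, 3) == "A") "C" else "A"
  ct <- count_table(setNames(1L, s))
  expect_identical(map_spacers(ct, g, max_mismatches = 0)$status, "unaligned")
  hit <- map_spacers(ct, g, max_mismatches = 2)
  expect_identical(hit$status, "unique")
  expect_identical(hit$start, 100L)
  expect_identical(hit$mismatches, 1L)
})

test_that("spacers shorter than the index k-mer are unaligned with reason", {
  g <- toy_genome(L = 100, seed = 45)
  aln <- map_spacers(count_table(setNames(1L, "ACGTACG")), g)
  expect_identical(aln$status, "unaligned")
  expect_match(aln$reason, "shorter than index k-mer")
  expect_error(map_spacers(count_table(setNames(1L, "ACGT")), list()),
               "non-empty")
})

test_that("single-read RPM normalization and strand separation are exact", {
  g <- toy_genome(L = 200, seed = 46)
  s <- substr(g$sequence, 11, 45)
  one <- position_coverage_rpm(
    map_spacers(count_table(setNames(1L, s)), g), g)
  expect_identical(nrow(one$rpm), 35L)
  expect_true(all(one$rpm$rpm == 1e6))
  expect_identical(one$rpm$position, 10:44)
  # two reads on opposite strands at the same locus: each track 0.5e6
  two <- position_coverage_rpm(
    map_spacers(count_table(setNames(c(1L, 1L), c(s, dna_revcomp(s)))), g), g)
  expect_true(all(two$rpm$rpm == 5e5))
  expect_setequal(unique(two$rpm$strand), c("+", "-"))
  # conservation: all 35-nt reads on one replicon
  expect_equal(sum(one$rpm$rpm), 1e6 * 35)
})

test_that("RPM sums obey the per-replicon conservation identity", {
  withr::local_seed(47)
  g1 <- toy_genome(L = 4000, seed = 47, name = "phage")
  g2 <- toy_genome(L = 1500, seed = 48, name = "plasmid")
  pick <- function(g, n, k) {
    st <- sample(0:(g$length - k), n)
    substring(g$sequence, st + 1, st + k)
  }
  sp <- c(pick(g1, 40, 35), pick(g2, 15, 35), pick(g1, 10, 30))
  cts <- sample(1:20, length(sp), replace = TRUE)
  tab <- count_table(setNames(cts, sp))
  aln <- map_spacers(tab, list(g1, g2))
  prof <- position_coverage_rpm(aln, list(g1, g2))
  uni <- aln[aln$status == "unique", ]
  for (rn in unique(uni$replicon)) {
    d <- uni[uni$replicon == rn, ]
    kbar <- sum(d$count * (d$end - d$start)) / sum(d$count)
    expected <- 1e6 * kbar * sum(d$count) / prof$total_aligned
    got <- sum(prof$rpm$rpm[prof$rpm$replicon == rn])
    expect_lt(abs(got - expected), 1e-9 * expected)
  }
})

test_that("source fractions are percentages of uniquely aligned reads", {
  g1 <- toy_genome(L = 2000, seed = 49, name = "phage")
  g2 <- toy_genome(L = 800, seed = 50, name = "plasmid")
  s_ph <- substr(g1$sequence, 101, 135)
  s_pl <- substr(g2$sequence, 51, 85)
  tab <- count_table(setNames(c(97L, 3L), c(s_ph, s_pl)))
  sf <- source_fractions(map_spacers(tab, list(g1, g2)))
  expect_equal(sf$percent[sf$replicon == "phage"], 97)
  expect_equal(sf$percent[sf$replicon == "plasmid"], 3)
  only <- source_fractions(map_spacers(count_table(setNames(5L, s_ph)),
                                       list(g1, g2)))
  expect_equal(only$percent, 100)
})

test_that("acquisition profile writes a wiggle TSV and JSON summary", {
  withr::local_dir(withr::local_tempdir())
  g <- toy_genome(L = 300, seed = 51)
  s <- substr(g$sequence, 21, 55)
  prof <- position_coverage_rpm(map_spacers(count_table(setNames(2L, s)), g), g)
  write_profile(prof, "rpm.tsv", json = "sf.json")
  rt <- readr::read_tsv("rpm.tsv", comment = "#", show_col_types = FALSE)
  expect_equal(as.data.frame(rt), as.data.frame(prof$rpm))
  js <- jsonlite::read_json("sf.json")
  expect_identical(js$total_aligned, 2L)
})
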