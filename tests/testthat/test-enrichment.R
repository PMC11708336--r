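test_that("frequencies are counts over extracted total and sum to one", {
  f <- compute_frequencies(count_table(c(A = 90L, B = 10L)))
  expect_equal(f$frequency[f$spacer == "A"], 0.9)
  expect_equal(f$frequency[f$spacer == "B"], 0.1)
  expect_identical(compute_frequencies(count_table(c(A = 1L)))$frequency, 1)
  expect_error(compute_frequencies(count_table(integer())), "empty")
  withr::local_seed(31)
  big <- count_table(setNames(rpois(5000, 20) + 1L, paste0("s", 1:5000)))
  expect_equal(sum(compute_frequencies(big)$frequency), 1, tolerance = 1e-12)
})

test_that("enrichment ratios follow frequency arithmetic", {
  pre <- count_table(c(A = 50L, B = 50L))
  post <- count_table(c(A = 90L, B = 10L))
  e <- compute_enrichment(post, pre)
  expect_equal(e$enrichment[e$spacer == "A"], 1.8)
  expect_equal(e$enrichment[e$spacer == "B"], 0.2)
  same <- compute_enrichment(pre, pre)
  expect_true(all(same$enrichment == 1))
})

test_that("zero-at-t0 policy yields NA, pseudocount converges to it", {
  pre <- count_table(c(A = 0L, B = 100L))
  post <- count_table(c(A = 5L, B = 95L))
  e <- expect_silent(compute_enrichment(post, pre))
  expect_true(is.na(e$enrichment[e$spacer == "A"]))
  expect_false(is.na(e$enrichment[e$spacer == "B"]))
  # pseudocount: finite everywhere; as alpha -> 0 it converges to the NA-policy
  # values for spacers detected at t0
  e1 <- compute_enrichment(post, pre, zero_policy = "pseudocount", alpha = 0.5)
  expect_true(all(is.finite(e1$enrichment)))
  e_small <- compute_enrichment(post, pre, zero_policy = "pseudocount",
                                alpha = 1e-8)
  expect_equal(e_small$enrichment[e_small$spacer == "B"],
               e$enrichment[e$spacer == "B"], tolerance = 1e-6)
})

test_that("mismatched spacer sets warn and fall back to the union", {
  pre <- count_table(c(A = 10L, B = 10L))
  post <- count_table(c(A = 10L, C = 10L))
  expect_warning(e <- compute_enrichment(post, pre), "union")
  expect_setequal(e$spacer, c("A", "B", "C"))
  expect_identical(e$count_post[e$spacer == "B"], 0L)
})

test_that("annotation joins coordinates and classes regions by strand", {
  g <- toy_genome(L = 40000, seed = 13, operons = toy_operons())
  lib <- design_tiling_library(g, k = 35, step = 500)
  ct <- count_table(setNames(rep(10L, nrow(lib)), lib$spacer_seq))
  e <- compute_enrichment(ct, ct)
  ann <- annotate_spacers(e, lib, g, pe_split = 8000)
  expect_true(all(!is.na(ann$region)))
  expect_identical(sort(unique(ann$group)),
                   sort(c("PE_minus", "PE_plus", "PL_minus", "PL_plus",
                          "untranscribed_minus", "untranscribed_plus")))
  pe_rows <- ann[ann$region == "PE", ]
  expect_identical(unique(pe_rows$region_class[pe_rows$midpoint < 8000]),
                   "PE_upstream")
  expect_true(all(ann$targeting == (ann$strand == "-" &
                                      ann$region %in% c("PE", "PL"))))
})

test_that("group summaries and the Welch comparison match a closed form", {
  e <- tibble::tibble(
    spacer = letters[1:6],
    enrichment = c(1, 2, 3, 4, 5, 6),
    group = rep(c("g1", "g2"), each = 3)
  )
  s <- summarize_groups(e)
  expect_equal(s$mean, c(2, 5))
  expect_equal(s$sd, c(1, 1))
  expect_identical(s$n, c(3L, 3L))
  w <- compare_enrichment(e, "g1", "g2")
  r <- stats::t.test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$statistic, unname(r$statistic), tolerance = 1e-12)
  expect_equal(w$df, unname(r$parameter), tolerance = 1e-12)
  # identical groups: t = 0, p = 1
  e2 <- tibble::tibble(spacer = letters[1:6], enrichment = rep(c(1, 2, 3), 2),
                       group = rep(c("g1", "g2"), each = 3))
  w2 <- compare_enrichment(e2, "g1", "g2")
  expect_identical(w2$statistic, 0)
  expect_identical(w2$p.value, 1)
  # groups with n < 2 are flagged untestable
  e3 <- tibble::tibble(spacer = "a", enrichment = 2, group = "solo")
  expect_false(summarize_groups(e3)$testable)
})

test_that("enrichment-expression correlation hits the closed-form anchors", {
  g <- toy_genome(L = 1000, seed = 14, operons = tibble::tibble(
    start = 0L, end = 1000L, name = "PE", activation_time = 5, strand = "+"))
  lib <- design_tiling_library(g, k = 35, step = 100, strands = "minus")
  n <- nrow(lib)
  # coverage proportional to position index -> expression varies by interval
  cov <- tibble::tibble(
    replicon = "toy", position = rep(0:999, 2),
    strand = rep(c("+", "-"), each = 1000),
    timepoint = 5, count = rep(1 + (0:999), 2)
  ) |> normalize_coverage()
  expr <- vapply(seq_len(n), function(i) {
    with(cov[cov$strand == "+", ],
         mean(norm[position >= lib$start[i] & position < lib$end[i]]) +
           mean(cov$norm[cov$strand == "-"][lib$start[i]:(lib$end[i] - 1) + 1]))
  }, double(1))
  enr <- tibble::tibble(spacer = lib$spacer_seq, start = lib$start,
                        end = lib$end, enrichment = 2 * expr + 3)
  res <- correlate_with_expression(enr, cov)
  expect_equal(res$r, 1, tolerance = 1e-9)
  expect_identical(res$n, n)
  res_neg <- correlate_with_expression(
    dplyr::mutate(enr, enrichment = -enrichment), cov)
  expect_equal(res_neg$r, -1, tolerance = 1e-9)
  # r for a 10-point toy set matches the direct covariance formula
  enr10 <- enr[1:10, ]
  enr10$enrichment <- c(5, 3, 8, 1, 9, 2, 7, 4, 6, 10)
  res10 <- correlate_with_expression(enr10, cov)
  expect_equal(res10$r, stats::cor(enr10$enrichment, expr[1:10]),
               tolerance = 1e-9)
  expect_error(correlate_with_expression(enr10[1:2, ], cov), "fewer than 3")
})

test_that("neutral selection leaves enrichment centred at one", {
  cfg <- sim_config(seed = 5, genome_length = 4000, step = 8, depth = 2e5,
                    operons = toy_operons(pe = c(100L, 1500L),
                                          pl = c(1500L, 4000L)),
                    fitness_noise_sdlog = 0, error_rate = 0)
  g <- simulate_genome(cfg)
  lib <- design_tiling_library(g, k = cfg$k, step = cfg$step)
  scr <- simulate_screen(lib, g, cfg, fitness = rep(1, nrow(lib)))
  e <- compute_enrichment(scr$counts$t5h, scr$counts$t0)
  em <- e$enrichment[!is.na(e$enrichment)]
  se <- stats::sd(em) / sqrt(length(em))
  expect_lt(abs(mean(em) - 1), 3 * se)
  p_up <- mean(em > 1)
  expect_lt(abs(p_up - 0.5), 3 * sqrt(0.25 / length(em)))
})
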