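#' Per-spacer frequencies in a sample
#'
#' Frequencies are computed over the spacers extracted in that sample:
#' `f(s) = count(s) / total_extracted`, so they sum to 1.
#'
#' @param table A [count_table()].
#' @return Tibble with columns `spacer`, `count`, `frequency`.
#' @export
#' @examples
#' compute_frequencies(count_table(c(A = 90, B = 10)))
compute_frequencies <- function(table) {
  total <- sum(table$count)
  if (nrow(table) == 0L || total == 0L) abort("empty count table")
  tibble(spacer = table$spacer, count = table$count,
         frequency = table$count / total)
}

#' Post/pre enrichment ratios per spacer
#'
#' `E(s) = f_post(s) / f_pre(s)` where each frequency is taken over its own
#' sample. Under the default `zero_policy = "na"`, spacers absent at t0 get
#' `NA` (they cannot be ratioed); under `"pseudocount"`, frequencies become
#' `(c + alpha) / (total + alpha * N)` with `N` the library size, so every
#' spacer gets a finite ratio. Spacer sets are merged by union; a warning is
#' raised when they differ (e.g. library dropout or sequencing-error
#' singletons).
#'
#' @param post,pre [count_table()]s for the post-infection and uninfected
#'   (t0) samples.
#' @param zero_policy `"na"` or `"pseudocount"`.
#' @param alpha Pseudocount (default 0.5).
#' @param library_size `N` used by the pseudocount policy; defaults to the
#'   number of union spacers.
#' @return An `enrichment_table` tibble: `spacer`, `count_pre`, `count_post`,
#'   `f_pre`, `f_post`, `enrichment`.
#' @export
compute_enrichment <- function(post, pre,
                               zero_policy = c("na", "pseudocount"),
                               alpha = 0.5, library_size = NULL) {
  zero_policy <- match.arg(zero_policy)
  pre_t <- tibble(spacer = pre$spacer, count_pre = pre$count)
  post_t <- tibble(spacer = post$spacer, count_post = post$count)
  if (!setequal(pre_t$spacer, post_t$spacer)) {
    warn("pre and post samples contain different spacer sets; using their union")
  }
  m <- full_join(pre_t, post_t, by = "spacer") |>
    mutate(count_pre = dplyr::coalesce(.data$count_pre, 0L),
           count_post = dplyr::coalesce(.data$count_post, 0L))
  tot_pre <- sum(m$count_pre); tot_post <- sum(m$count_post)
  if (tot_pre == 0L || tot_post == 0L) abort("a sample has zero extracted spacers")
  if (zero_policy == "pseudocount") {
    N <- library_size %||% nrow(m)
    m <- m |> mutate(
      f_pre = (.data$count_pre + alpha) / (tot_pre + alpha * N),
      f_post = (.data$count_post + alpha) / (tot_post + alpha * N),
      enrichment = .data$f_post / .data$f_pre
    )
  } else {
    m <- m |> mutate(
      f_pre = .data$count_pre / tot_pre,
      f_post = .data$count_post / tot_post,
      enrichment = if_else(.data$f_pre > 0, .data$f_post / .data$f_pre,
                           NA_real_)
    )
  }
  class(m) <- c("enrichment_table", class(m))
  m
}

#' Annotate enrichment rows with genome coordinates and region classes
#'
#' Joins the library manifest onto an enrichment (or count) table by spacer
#' sequence, then labels each mapped spacer with its transcribed region
#' (midpoint rule), whether its crRNA targets a transcript, and — when
#' `pe_split` is given — whether a PE-targeting spacer lies upstream or
#' downstream of that coordinate (the distinction that matters for
#' Csm6-dependent defense).
#'
#' @param enr An `enrichment_table` (or any tibble with a `spacer` column).
#' @param library A `spacer_library` manifest.
#' @param genome A [genome_annotation()] with the operon map.
#' @param pe_split Optional coordinate splitting the PE operon into
#'   `PE_upstream` / `PE_downstream` sub-classes.
#' @return The input with added columns `replicon`, `start`, `end`, `strand`,
#'   `midpoint`, `region`, `targeting`, `group` (region x strand class) and,
#'   with `pe_split`, `region_class`.
#' @export
annotate_spacers <- function(enr, library, genome, pe_split = NULL) {
  ann <- enr |>
    left_join(
      as_tibble(library) |>
        select("spacer_seq", "replicon", "start", "end", "strand",
               dplyr::any_of("duplicate")),
      by = c(spacer = "spacer_seq")
    )
  mapped <- !is.na(ann$start)
  ann$midpoint <- NA_integer_
  ann$midpoint[mapped] <- spacer_midpoint(ann$start[mapped], ann$end[mapped])
  ann$region <- NA_character_
  ann$targeting <- NA
  if (any(mapped)) {
    ann$region[mapped] <- region_of(ann[mapped, ], genome)
    ann$targeting[mapped] <- is_targeting(ann[mapped, ], genome)
  }
  ann$group <- if_else(
    mapped,
    paste0(ann$region, "_", if_else(ann$strand == "+", "plus", "minus")),
    NA_character_
  )
  if (!is.null(pe_split)) {
    ann$region_class <- ann$region
    pe <- !is.na(ann$region) & ann$region == "PE"
    ann$region_class[pe] <- if_else(ann$midpoint[pe] < pe_split,
                                    "PE_upstream", "PE_downstream")
  }
  ann
}

#' Group-level enrichment summaries
#'
#' Mean, SD and n of (non-`NA`) enrichments per group, on the natural
#' enrichment scale by default. Groups with fewer than two values are
#' flagged (`testable = FALSE`).
#'
#' @param enr Annotated enrichment table.
#' @param grouping Column name(s) to group by (default `"group"`, the
#'   region x strand class).
#' @param value Column holding the per-spacer statistic.
#' @param log_scale Summarise `log(enrichment)` instead of enrichment.
#' @return Tibble: one row per group with `n`, `mean`, `sd`, `testable`.
#' @export
summarize_groups <- function(enr, grouping = "group", value = "enrichment",
                             log_scale = FALSE) {
  v <- enr[[value]]
  if (log_scale) v <- log(v)
  enr |>
    mutate(.value = v) |>
    filter(!is.na(.data$.value),
           !dplyr::if_any(dplyr::all_of(grouping), is.na)) |>
    group_by(across(dplyr::all_of(grouping))) |>
    summarise(n = dplyr::n(), mean = mean(.data$.value),
              sd = sd(.data$.value), .groups = "drop") |>
    mutate(testable = .data$n >= 2L)
}

#' Welch comparison between two enrichment groups
#'
#' @inheritParams summarize_groups
#' @param group_a,group_b Group labels to compare.
#' @return A [welch_t_test()] result.
#' @export
compare_enrichment <- function(enr, group_a, group_b, grouping = "group",
                               value = "enrichment", log_scale = FALSE) {
  g <- enr[[grouping]]
  v <- enr[[value]]
  if (log_scale) v <- log(v)
  x <- v[!is.na(g) & g == group_a & !is.na(v)]
  y <- v[!is.na(g) & g == group_b & !is.na(v)]
  welch_t_test(x, y)
}

#' Correlate spacer enrichment with target expression
#'
#' Summarises each mapped spacer's expression as the mean per-position
#' normalized RNA-seq coverage over its target interval (both strands
#' summed), then returns the Pearson correlation with enrichment over
#' spacers with non-`NA` enrichment.
#'
#' @param enr Annotated enrichment table (needs `start`, `end`,
#'   `enrichment`).
#' @param coverage A `coverage_profile` tibble restricted to (or filtered
#'   for) one timepoint; must carry a `norm` column (see
#'   [normalize_coverage()]).
#' @param timepoint Timepoint (minutes) to use when `coverage` holds several.
#' @return List with `r`, `n` and the per-spacer tibble used.
#' @export
correlate_with_expression <- function(enr, coverage, timepoint = NULL) {
  cov <- coverage
  if (!is.null(timepoint)) cov <- cov |> filter(.data$timepoint == !!timepoint)
  if (!"norm" %in% names(cov)) abort("coverage must be normalized first")
  if (length(unique(cov$timepoint)) != 1L) {
    abort("coverage must be restricted to a single timepoint")
  }
  # per-position totals over strands, then interval means via cumsum
  tot <- cov |>
    group_by(.data$position) |>
    summarise(norm = sum(.data$norm), .groups = "drop") |>
    arrange(.data$position)
  L <- max(tot$position) + 1L
  vec <- numeric(L)
  vec[tot$position + 1L] <- tot$norm
  cs <- c(0, cumsum(vec))
  ok <- !is.na(enr$enrichment) & !is.na(enr$start)
  d <- enr[ok, ]
  d$expression <- (cs[pmin(d$end, L) + 1L] - cs[d$start + 1L]) /
    (pmin(d$end, L) - d$start)
  n <- nrow(d)
  if (n < 3L) abort("fewer than 3 spacers available for correlation")
  list(r = pearson_r(d$enrichment, d$expression), n = n, data = as_tibble(d))
}

#' Write / read an enrichment table as TSV
#' @param enr Enrichment tibble.
#' @param path TSV path.
#' @param seed,config_hash Provenance recorded in the file header.
#' @export
write_enrichment <- function(enr, path, seed = NA, config_hash = NA) {
  write_tsv_with_header(as_tibble(enr), path, seed, config_hash)
}

#' @rdname write_enrichment
#' @export
read_enrichment <- function(path) {
  x <- read_tsv_commented(path)
  class(x) <- c("enrichment_table", class(x))
  x
}
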