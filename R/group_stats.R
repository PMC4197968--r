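#' Thresholds of the intron architecture grouping
#'
#' @param large_intron_min Minimum length (nt) for a "large" intron
#'   (default 2,000, i.e. > 2 kb).
#' @param huge_intron_min Minimum length (nt) for a "huge" intron
#'   (default 10,000, i.e. > 10 kb).
#' @return List of class `group_scheme`.
#' @export
group_scheme <- function(large_intron_min = 2000L, huge_intron_min = 10000L) {
  if (large_intron_min >= huge_intron_min) {
    abort_data("large_intron_min must be < huge_intron_min")
  }
  structure(list(large_intron_min = as.integer(large_intron_min),
                 huge_intron_min = as.integer(huge_intron_min)),
            class = "group_scheme")
}

#' The architecture group labels
#' @return Character vector of label names.
#' @export
intron_group_labels <- function() {
  c("first", "first_before_large_second", "internal_after_large",
    "internal_before_large", "large", "in_transcript_with_huge_intron",
    "poor_py")
}

#' Classify introns into architecture groups
#'
#' Labels are not mutually exclusive. `first`: ordinal 1.
#' `first_before_large_second`: ordinal 1 and the second intron of the
#' transcript is large (> `large_intron_min`). `internal_after_large` /
#' `internal_before_large`: neither first nor last, and the immediately
#' preceding / following intron is large. `large`: the intron itself is
#' large. `in_transcript_with_huge_intron`: any intron of the transcript
#' exceeds `huge_intron_min`. `poor_py`: no good polypyrimidine tract
#' (requires sequences, or a precomputed logical `poor_py` column).
#'
#' @param introns Intron tibble ([extract_introns()]).
#' @param scheme [group_scheme()].
#' @param params [splice_rule_params()] for the pY scan.
#' @return The tibble with one logical column per label.
#' @export
classify_intron_groups <- function(introns, scheme = group_scheme(),
                                   params = splice_rule_params()) {
  check_columns(introns, c("intron_id", "transcript_id", "length", "ordinal",
                           "is_first", "is_last",
                           "upstream_intron_length",
                           "downstream_intron_length"), "introns")
  if (!"poor_py" %in% names(introns)) {
    introns <- add_py_status(introns, params)
  }
  lg <- scheme$large_intron_min
  introns |>
    group_by(.data$transcript_id) |>
    mutate(in_transcript_with_huge_intron =
             any(.data$length > scheme$huge_intron_min)) |>
    ungroup() |>
    mutate(
      first = .data$is_first,
      first_before_large_second = .data$is_first &
        !is.na(.data$downstream_intron_length) &
        .data$downstream_intron_length > lg,
      internal_after_large = !.data$is_first & !.data$is_last &
        !is.na(.data$upstream_intron_length) &
        .data$upstream_intron_length > lg,
      internal_before_large = !.data$is_first & !.data$is_last &
        !is.na(.data$downstream_intron_length) &
        .data$downstream_intron_length > lg,
      large = .data$length > lg)
}

#' Long (intron_id, group) membership from a classified intron table
#'
#' @param classified Result of [classify_intron_groups()].
#' @return Tibble `intron_id`, `group` with one row per membership.
#' @export
group_membership <- function(classified) {
  labels <- intersect(intron_group_labels(), names(classified))
  classified |>
    select("intron_id", dplyr::all_of(labels)) |>
    tidyr::pivot_longer(-"intron_id", names_to = "group",
                        values_to = "member") |>
    filter(.data$member) |>
    select("intron_id", "group")
}

#' Rank-sum p-value with a degenerate-tie guard
#'
#' stats::wilcox.test computes the exact null distribution for small
#' untied samples and a tie-corrected normal approximation otherwise; when
#' every observation in both groups is identical its variance is zero, in
#' which case the two distributions are indistinguishable and p = 1.
#' @noRd
ranksum_p <- function(x, y, alternative = "two.sided") {
  if (length(unique(c(x, y))) == 1L) return(1)
  suppressWarnings(wilcox.test(x, y, alternative = alternative)$p.value)
}

#' Test retention fold-change shifts of intron groups
#'
#' For each group (and knockdown, when the fold table carries several), the
#' member fold changes are compared with those of all analyzed non-member
#' introns by a two-sample Wilcoxon rank-sum (Mann-Whitney U) test; the
#' group median fold is reported alongside. P-values are raw by default, as
#' is conventional for this analysis; Benjamini-Hochberg adjustment is
#' available.
#'
#' @param folds Tibble `intron_id`, `fold` and optionally `knockdown`
#'   (e.g. from [retention_results()]).
#' @param membership Long membership tibble ([group_membership()]) or a
#'   classified intron table with logical label columns.
#' @param alternative Sidedness of the test, default `"two.sided"`.
#' @param p_adjust `"none"` (default) or a [stats::p.adjust()] method.
#' @return Object of class `retention_group_test`; use [tidy()] for the
#'   per-group table and [glance()] for a one-row summary.
#' @export
group_retention_test <- function(folds, membership,
                                 alternative = "two.sided",
                                 p_adjust = "none") {
  check_columns(folds, c("intron_id", "fold"), "folds")
  if (!"knockdown" %in% names(folds)) folds$knockdown <- "knockdown"
  if (!"group" %in% names(membership)) membership <- group_membership(membership)
  groups <- unique(membership$group)
  res <- purrr::map_dfr(unique(folds$knockdown), function(kd) {
    f <- folds |> filter(.data$knockdown == kd)
    purrr::map_dfr(groups, function(g) {
      ids <- membership$intron_id[membership$group == g]
      memb <- f$fold[f$intron_id %in% ids]
      comp <- f$fold[!f$intron_id %in% ids]
      if (length(memb) == 0 || length(comp) == 0) {
        return(tibble(group = g, knockdown = kd, n = length(memb),
                      median_fold = NA_real_, comparison_n = length(comp),
                      comparison_median = NA_real_, p_value = NA_real_,
                      status = if (length(memb) == 0) "empty_group"
                               else "empty_comparison"))
      }
      tibble(group = g, knockdown = kd, n = length(memb),
             median_fold = median(memb), comparison_n = length(comp),
             comparison_median = median(comp),
             p_value = ranksum_p(memb, comp, alternative), status = "ok")
    })
  })
  if (p_adjust != "none") {
    res <- res |>
      group_by(.data$knockdown) |>
      mutate(p_adjusted = p.adjust(.data$p_value, method = p_adjust)) |>
      ungroup()
  }
  structure(list(results = res, alternative = alternative,
                 p_adjust = p_adjust,
                 n_introns = dplyr::n_distinct(folds$intron_id)),
            class = "retention_group_test")
}

#' @export
print.retention_group_test <- function(x, ...) {
  cat(sprintf("<retention_group_test> %d group x knockdown cells over %d introns (%s)\n",
              nrow(x$results), x$n_introns, x$alternative))
  print(x$results, n = 20)
  invisible(x)
}

#' @rdname group_retention_test
#' @param x A `retention_group_test`.
#' @param ... Unused.
#' @export
tidy.retention_group_test <- function(x, ...) x$results

#' @rdname group_retention_test
#' @export
glance.retention_group_test <- function(x, ...) {
  ok <- x$results |> filter(.data$status == "ok")
  tibble(n_groups = dplyr::n_distinct(x$results$group),
         n_knockdowns = dplyr::n_distinct(x$results$knockdown),
         n_introns = x$n_introns,
         min_p = if (nrow(ok)) min(ok$p_value) else NA_real_,
         alternative = x$alternative)
}

#' Bin transcripts by their largest intron
#'
#' Every analyzed multi-exon transcript falls in exactly one of four bins
#' by the length x of its largest intron (kb): (0, 0.5], (0.5, 2],
#' (2, 10], (10, Inf) — right edges closed, so a 2,000-nt largest intron is
#' in the second bin. Intron-less transcripts are excluded with a message.
#'
#' @param introns Intron tibble covering the transcripts of interest.
#' @param transcripts Optional character vector restricting the transcript
#'   set (e.g. the analyzed transcripts).
#' @return Tibble `transcript_id`, `largest_intron`, `bin` (ordered factor).
#' @export
transcript_intron_size_bins <- function(introns, transcripts = NULL) {
  tx <- introns |>
    group_by(.data$transcript_id) |>
    summarise(largest_intron = max(.data$length), .groups = "drop")
  if (!is.null(transcripts)) {
    absent <- setdiff(transcripts, tx$transcript_id)
    if (length(absent) > 0) {
      message(sprintf("excluding %d intron-less transcript(s) from binning",
                      length(absent)))
    }
    tx <- tx |> filter(.data$transcript_id %in% transcripts)
  }
  breaks <- c(0, 500, 2000, 10000, Inf)
  labels <- c("(0,0.5]", "(0.5,2]", "(2,10]", ">10")
  tx |>
    mutate(bin = cut(.data$largest_intron, breaks = breaks, labels = labels,
                     right = TRUE, ordered_result = TRUE))
}

#' Test transcript-level fold changes across largest-intron bins
#'
#' For each bin (and knockdown) the transcript RPKM fold changes of bin
#' members are compared with those of all other analyzed transcripts by the
#' Wilcoxon rank-sum test, mirroring the group retention test at the
#' transcript level.
#'
#' @param tx_folds Tibble `transcript_id`, `fold`, optional `knockdown`
#'   (from [transcript_fold_changes()]).
#' @param bins Result of [transcript_intron_size_bins()].
#' @inheritParams group_retention_test
#' @return A `retention_group_test` whose groups are the bins.
#' @export
transcript_level_test <- function(tx_folds, bins,
                                  alternative = "two.sided",
                                  p_adjust = "none") {
  check_columns(tx_folds, c("transcript_id", "fold"), "tx_folds")
  membership <- bins |>
    select(intron_id = "transcript_id", group = "bin") |>
    mutate(group = as.character(.data$group))
  folds <- tx_folds |> rename(intron_id = "transcript_id")
  out <- group_retention_test(folds, membership, alternative = alternative,
                              p_adjust = p_adjust)
  out$results <- out$results |>
    mutate(group = factor(.data$group,
                          levels = c("(0,0.5]", "(0.5,2]", "(2,10]", ">10"),
                          ordered = TRUE)) |>
    arrange(.data$knockdown, .data$group)
  out
}
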