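fake_intron <- function(id, ordinal, n_introns, length = 100L,
                        up = NA_integer_, down = NA_integer_,
                        poor_py = FALSE, tx = "t") {
  tibble(intron_id = id, transcript_id = tx, length = length,
         ordinal = ordinal, n_introns = n_introns,
         is_first = ordinal == 1L, is_last = ordinal == n_introns,
         upstream_intron_length = up, downstream_intron_length = down,
         poor_py = poor_py)
}

test_that("architecture labels follow the 2 kb / 10 kb thresholds", {
  intr <- bind_rows(
    fake_intron("a", 1L, 2L, down = 3000L),          # first before large second
    fake_intron("b", 1L, 2L, down = 1500L, tx = "t2"),
    fake_intron("c", 2L, 3L, length = 2500L, up = 100L, down = 100L,
                tx = "t3"),
    fake_intron("d", 2L, 3L, up = 2500L, down = 100L, tx = "t4"),
    fake_intron("e", 2L, 3L, up = 100L, down = 12000L, tx = "t5",
                poor_py = TRUE),
    fake_intron("f", 3L, 3L, length = 12000L, up = 100L, tx = "t5"))
  cls <- classify_intron_groups(intr)
  lab <- function(id, l) cls[[l]][cls$intron_id == id]
  expect_true(lab("a", "first") && lab("a", "first_before_large_second"))
  expect_true(lab("b", "first"))
  expect_false(lab("b", "first_before_large_second"))
  expect_true(lab("c", "large"))
  expect_false(lab("c", "internal_after_large"))   # 2 kb is not > 2 kb? up=100
  expect_true(lab("d", "internal_after_large"))
  expect_true(lab("e", "internal_before_large"))   # downstream 12 kb > 2 kb
  expect_true(lab("e", "in_transcript_with_huge_intron"))
  expect_true(lab("e", "poor_py"))
  expect_false(lab("a", "in_transcript_with_huge_intron"))
})

test_that("label consistency holds on simulated annotations", {
  sim <- simulate_annotation(simulation_config(n_genes = 60, seed = 31,
                                               with_genome = FALSE))
  cls <- classify_intron_groups(
    sim$annotation$introns |>
      left_join(sim$truth$intron_features, by = "intron_id"))
  expect_true(all(cls$first[cls$first_before_large_second]))
  expect_false(any(cls$internal_after_large & (cls$is_first | cls$is_last)))
  expect_false(any(cls$internal_before_large & (cls$is_first | cls$is_last)))
  # every huge-intron transcript labels all of its introns
  huge_tx <- cls$transcript_id[cls$length > 10000]
  expect_true(all(cls$in_transcript_with_huge_intron[cls$transcript_id %in% huge_tx]))
})

test_that("rank-sum p-values match full enumeration (members {1,2,3} vs {4,5,6} and beyond)", {
  folds <- tibble(intron_id = letters[1:6], fold = 1:6)
  membership <- tibble(intron_id = letters[1:3], group = "g")
  res <- tidy(group_retention_test(folds, membership))
  expect_equal(res$p_value, ranksum_enum(1:3, 4:6))
  expect_equal(res$p_value, 0.1)   # 2/20 assignments at or beyond U = 0
  expect_equal(res$median_fold, 2)
  expect_equal(res$n, 3L)
})

test_that("degenerate groups are handled: all ties give p = 1, empty groups a status", {
  folds <- tibble(intron_id = letters[1:5], fold = rep(1.3, 5))
  membership <- tibble(intron_id = letters[1:2], group = "g")
  res <- tidy(group_retention_test(folds, membership))
  expect_equal(res$p_value, 1)
  expect_equal(res$median_fold, 1.3)

  res2 <- tidy(group_retention_test(
    tibble(intron_id = "z", fold = 1),
    tibble(intron_id = "q", group = "g")))
  expect_equal(res2$status, "empty_group")
  expect_true(is.na(res2$p_value))
})

test_that("under the null, group test p-values are approximately uniform", {
  withr::with_seed(32, {
    ps <- replicate(300, {
      folds <- tibble(intron_id = as.character(1:90),
                      fold = rlnorm(90, 0, 0.4))
      membership <- tibble(intron_id = as.character(1:25), group = "g")
      tidy(group_retention_test(folds, membership))$p_value
    })
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("transcript bins partition by largest intron with closed right edges", {
  intr <- tibble(transcript_id = c("t1", "t1", "t2", "t3", "t4"),
                 length = c(400L, 100L, 2000L, 15000L, 501L))
  bins <- transcript_intron_size_bins(intr)
  expect_equal(as.character(bins$bin),
               c("(0,0.5]", "(0.5,2]", ">10", "(0.5,2]"))
  expect_message(
    b2 <- transcript_intron_size_bins(intr, transcripts = c("t1", "t9")),
    "intron-less")
  expect_equal(b2$transcript_id, "t1")
  # exhaustive and mutually exclusive over simulated transcripts
  sim <- simulate_annotation(simulation_config(n_genes = 40, seed = 33,
                                               with_genome = FALSE))
  bb <- transcript_intron_size_bins(sim$annotation$introns)
  expect_false(anyNA(bb$bin))
  expect_equal(nrow(bb), dplyr::n_distinct(sim$annotation$introns$transcript_id))
})

test_that("transcript-level test detects a planted halving and handles tiny bins", {
  withr::with_seed(34, {
    tx_folds <- tibble(
      transcript_id = sprintf("t%03d", 1:260),
      fold = c(rlnorm(200, 0, 0.15), rlnorm(60, log(0.5), 0.15)))
  })
  bins <- tibble(transcript_id = sprintf("t%03d", 1:260),
                 length = c(rep(300L, 200), rep(15000L, 60))) |>
    transcript_intron_size_bins()
  res <- tidy(transcript_level_test(tx_folds, bins)) |>
    filter(status == "ok")
  big <- res |> filter(group == ">10")
  expect_lt(abs(big$median_fold - 0.5), 0.1)
  expect_lt(big$p_value, 1e-6)
  small <- res |> filter(group == "(0,0.5]")
  expect_lt(abs(small$median_fold - 1), 0.1)

  # single transcript per bin still yields a defined median and exact p
  lone <- tibble(transcript_id = c("a", "b"), fold = c(0.4, 1.1))
  lbins <- tibble(transcript_id = c("a", "b"),
                  length = c(300L, 15000L)) |>
    transcript_intron_size_bins()
  lr <- tidy(transcript_level_test(lone, lbins))
  expect_equal(lr$median_fold[!is.na(lr$median_fold)], c(0.4, 1.1))
  expect_true(all(lr$p_value[lr$status == "ok"] == 1))
})

test_that("tidy and glance expose the test results", {
  folds <- tibble(intron_id = as.character(1:20), fold = rlnorm(20),
                  knockdown = rep(c("tsu", "acn"), each = 10))
  membership <- tibble(intron_id = as.character(c(1:3, 11:13)), group = "g")
  gt <- group_retention_test(folds, membership)
  td <- tidy(gt)
  expect_s3_class(td, "tbl_df")
  expect_setequal(td$knockdown, c("tsu", "acn"))
  gl <- glance(gt)
  expect_equal(gl$n_knockdowns, 2L)
  expect_equal(gl$n_groups, 1L)
  # BH adjustment adds a column
  expect_true("p_adjusted" %in%
                names(tidy(group_retention_test(folds, membership,
                                                p_adjust = "BH"))))
})
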