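make_read <- function(id, start, end, strand = "+", blocks = NULL,
                      chrom = "chr1", n_hits = 1L) {
  tibble(read_id = id, chrom = chrom, start = start, end = end,
         strand = strand,
         blocks = blocks %||% sprintf("%d-%d", start, end), n_hits = n_hits)
}

test_that("exonic and intronic counting follows the block rules", {
  ann <- toy_annotation()
  reads <- bind_rows(
    make_read("in_exon2", 310L, 360L),                       # within exon 2 of t1
    make_read("boundary", 380L, 430L),                       # spans exon2/intron2
    make_read("junction", 150L, 350L, blocks = "150-200,300-350"),  # compatible
    make_read("bad_junction", 150L, 340L, blocks = "150-190,290-340"),
    make_read("wrong_strand", 320L, 370L, strand = "-"),
    make_read("multimapped", 310L, 360L, n_hits = 2L))
  q <- count_features(reads, ann, "s1")
  cnt <- setNames(q$count, q$feature_id)
  expect_equal(cnt[["t1"]], 2L)         # in_exon2 + junction
  expect_equal(cnt[["t1:i2"]], 1L)      # boundary read
  expect_equal(cnt[["t1:i1"]], 1L)      # bad_junction block overlaps intron 1
  expect_equal(q$library_size[1], 5L)   # multimapped excluded

  # unstranded counting accepts the antisense read
  qu <- count_features(reads, ann, "s1", stranded = FALSE)
  expect_equal(qu$count[qu$feature_id == "t1"], 3L)
})

test_that("a paired fragment counts once per feature and needs both mates exonic", {
  ann <- toy_annotation()
  both_ok <- bind_rows(make_read("f1", 110L, 160L), make_read("f1", 310L, 360L))
  q <- count_features(both_ok, ann, "s")
  expect_equal(q$count[q$feature_id == "t1"], 1L)
  expect_equal(q$library_size[1], 1L)

  one_intronic <- bind_rows(make_read("f2", 110L, 160L),
                            make_read("f2", 380L, 430L))
  q2 <- count_features(one_intronic, ann, "s")
  expect_equal(q2$count[q2$feature_id == "t1"], 0L)
  expect_equal(q2$count[q2$feature_id == "t1:i2"], 1L)
})

test_that("reads on unknown chromosomes are skipped with a warning", {
  ann <- toy_annotation()
  reads <- bind_rows(make_read("a", 310L, 360L),
                     make_read("b", 10L, 60L, chrom = "chrUn"))
  expect_warning(q <- count_features(reads, ann, "s"), "chrUn")
  expect_equal(q$count[q$feature_id == "t1"], 1L)
})

test_that("RPKM follows count / (kb x million mapped reads)", {
  ann <- genome_annotation(tibble(
    transcript_id = c("a", "a", "b"), gene_id = c("ga", "ga", "gb"),
    chrom = "chr1", strand = "+",
    start = c(0L, 2000L, 4000L), end = c(500L, 2500L, 4500L)),
    seqlengths = c(chr1 = 10000L))
  # transcript a: exonic length 1000; 10 reads, library 1e6 -> RPKM 10
  q <- tibble(sample_id = "s",
              feature_id = c("a", "b", "a:i1"),
              feature_type = c("transcript", "transcript", "intron"),
              transcript_id = c("a", "b", "a"),
              count = c(10L, 0L, 50L), library_size = 1000000L)
  r <- compute_rpkm(q, ann)
  expect_equal(r$rpkm[r$feature_id == "a"], 10)
  expect_equal(r$rpkm[r$feature_id == "b"], 0)
  # intron a:i1 is 1500 nt: 50 / (1.5 * 1) at 1e6; with library 2e6 and
  # a 500-nt feature, 50 reads give RPKM 50
  q2 <- q |> mutate(count = c(10L, 50L, 0L), library_size = 2000000L)
  expect_equal(r$rpkm[r$feature_id == "a:i1"], 50 / 1.5)
  expect_equal(compute_rpkm(q2, ann)$rpkm[2], 50)
  expect_error(compute_rpkm(q |> mutate(library_size = 0L), ann), "library")
})

test_that("RPKM and retention index are invariant to count scaling", {
  study <- simulate_count_study(
    simulation_config(n_genes = 12, depth = 5e4, knockdowns = "kd",
                      with_genome = FALSE, seed = 21), "kd")
  for (k in c(2L, 10L)) {
    scaled <- study$rpkm |>
      mutate(count = count * k, library_size = library_size * k)
    ann <- study$sim$annotation
    expect_equal(compute_rpkm(scaled |> select(-length, -rpkm), ann)$rpkm,
                 study$rpkm$rpkm)
  }
})

test_that("analysis filters use strict thresholds and any-replicate logic", {
  ann <- toy_annotation()
  sheet <- tibble(sample_id = c("c1", "c2", "k1"),
                  condition = c("control", "control", "kd"),
                  replicate = c(1L, 2L, 1L))
  base <- tidyr::expand_grid(
    sample_id = sheet$sample_id,
    feature_id = c("t1", "t2", "t1:i1", "t1:i2", "t2:i1")) |>
    mutate(feature_type = ifelse(grepl(":i", feature_id), "intron", "transcript"),
           transcript_id = sub(":i.*", "", feature_id),
           library_size = 1000000L, count = 0L)
  rpkm_of <- function(tbl, vals) {
    tbl$count <- vals[match(paste(tbl$sample_id, tbl$feature_id),
                            names(vals))]
    compute_rpkm(tbl, ann)
  }
  # t1 control mean RPKM: counts chosen so rpkm = count/(len_kb)
  # t1 len 300 -> rpkm = count/0.3; want means 12 (pass) then exactly 10
  v <- c("c1 t1" = 4L, "c2 t1" = 3L, "k1 t1" = 0L,
         "c1 t2" = 1L, "c2 t2" = 1L, "k1 t2" = 0L,
         "c1 t1:i1" = 0L, "c2 t1:i1" = 0L, "k1 t1:i1" = 0L,
         "c1 t1:i2" = 1L, "c2 t1:i2" = 0L, "k1 t1:i2" = 0L,
         "c1 t2:i1" = 1L, "c2 t2:i1" = 1L, "k1 t2:i1" = 1L)
  r <- rpkm_of(base, v)
  aset <- apply_analysis_filters(r, sheet)
  # t1 control mean = (13.33+10)/2 = 11.67 > 10 -> pass; t2 mean 5 -> drop
  expect_equal(aset$transcripts, "t1")
  # t1:i2 rpkm 2 vs t1 13.33 in c1 -> 15% in one replicate -> retained
  expect_equal(aset$introns, "t1:i2")

  # exactly 10 RPKM is dropped (strict >): t1 rpkm = 3/0.3 = 10 in both
  v10 <- v; v10[c("c1 t1", "c2 t1")] <- 3L
  expect_equal(apply_analysis_filters(rpkm_of(base, v10), sheet)$transcripts,
               character(0))
  # an intron at 8% of transcript RPKM in every replicate is dropped
  expect_false("t1:i1" %in% aset$introns)
  expect_error(apply_analysis_filters(r, sheet |> mutate(condition = "kd")),
               "control")
})

test_that("raising the transcript RPKM threshold never adds transcripts", {
  study <- simulate_count_study(
    simulation_config(n_genes = 30, depth = 2e5, knockdowns = "kd",
                      with_genome = FALSE, seed = 22), "kd")
  prev <- NULL
  for (thr in c(1, 5, 10, 20, 50)) {
    cur <- apply_analysis_filters(study$rpkm, study$sheet,
                                  min_transcript_rpkm = thr)$transcripts
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("retention index and fold change follow their definitions", {
  expect_equal(retention_index(2, 10), 0.2)
  expect_equal(retention_index(10, 10), 1.0)
  expect_equal(retention_index(0, 10), 0.0)
  expect_error(retention_index(1, 0), "undefined")

  expect_equal(fold_retention_change(0.3, 0.3, 0.01), 1.0)
  expect_equal(fold_retention_change(0.4, 0.1, 0), 4.0)
  expect_equal(fold_retention_change(0, 0, 0.01), 1.0)

  expect_true(flag_affected(c(3.5, 1.1)))
  expect_false(flag_affected(c(1.5, 1.8)))
  expect_false(flag_affected(c(12, 1.0)))   # above the window cap
  expect_true(flag_affected(c(12, 2)))
})

test_that("retention_results averages replicates before the index", {
  ann <- toy_annotation()
  sheet <- tibble(sample_id = c("c1", "c2", "k1", "k2"),
                  condition = c("control", "control", "kd", "kd"),
                  replicate = c(1L, 2L, 1L, 2L))
  rpkm <- tidyr::expand_grid(sample_id = sheet$sample_id,
                             feature_id = c("t1", "t1:i1")) |>
    mutate(feature_type = ifelse(feature_id == "t1", "transcript", "intron"),
           transcript_id = "t1", count = 1L, library_size = 1000000L,
           length = 100L,
           rpkm = c(20, 2, 20, 1, 20, 6, 20, 10)[row_number()])
  aset <- list(transcripts = "t1", introns = "t1:i1")
  res <- retention_results(rpkm, sheet, aset, epsilon = 0.01)
  # control index = mean(2,1)/mean(20,20) = 0.075; kd = mean(6,10)/20 = 0.4
  expect_equal(res$index_control, 0.075)
  expect_equal(res$index_knockdown, 0.4)
  expect_equal(res$fold, (0.4 + 0.01) / (0.075 + 0.01))
  expect_true(res$affected)
})

test_that("zero planted retention gives zero intron counts", {
  cfg <- simulation_config(n_genes = 10, depth = 5e4, knockdowns = "kd",
                           retention_shape1 = 1, retention_shape2 = 1,
                           seed = 23)
  sim <- simulate_annotation(cfg)
  sim$truth$retention$r <- 0
  reads <- simulate_reads(sim, "control", 1)
  q <- count_features(reads, sim$annotation, "s")
  expect_equal(sum(q$count[q$feature_type == "intron"]), 0L)
  expect_gt(sum(q$count[q$feature_type == "transcript"]), 0L)
})
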