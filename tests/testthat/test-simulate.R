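test_that("fixed seeds give byte-identical annotation, genome and reads", {
  cfg <- simulation_config(n_genes = 8, depth = 2e4, knockdowns = "kd",
                           seed = 41)
  s1 <- simulate_annotation(cfg)
  s2 <- simulate_annotation(cfg)
  expect_identical(s1$annotation$exons, s2$annotation$exons)
  expect_identical(as.character(s1$annotation$genome),
                   as.character(s2$annotation$genome))
  expect_identical(s1$truth, s2$truth)

  f1 <- tempfile(); f2 <- tempfile()
  write_placements(simulate_reads(s1, "control", 1), f1)
  write_placements(simulate_reads(s2, "control", 1), f2)
  expect_identical(readLines(f1), readLines(f2))

  fa1 <- tempfile(); fa2 <- tempfile()
  write_genome_fasta(s1, fa1); write_genome_fasta(s2, fa2)
  expect_identical(readLines(fa1), readLines(fa2))

  # a different seed changes the draw
  s3 <- simulate_annotation(simulation_config(n_genes = 8, depth = 2e4,
                                              knockdowns = "kd", seed = 42))
  expect_false(identical(as.character(s3$annotation$genome),
                         as.character(s1$annotation$genome)))
})

test_that("gene structure follows the config and introns are GT..AG", {
  cfg <- simulation_config(n_genes = 10, exon_count_range = c(2L, 2L),
                           seed = 43)
  sim <- simulate_annotation(cfg)
  expect_equal(nrow(sim$annotation$transcripts), 10)
  expect_true(all(sim$annotation$transcripts$n_exons == 2))
  expect_equal(nrow(sim$annotation$introns), 10)
  seqs <- sim$annotation$introns$sequence
  expect_true(all(substr(seqs, 1, 2) == "GT"))
  expect_true(all(substr(seqs, nchar(seqs) - 1, nchar(seqs)) == "AG"))
})

test_that("planted pY status is realized in the synthesized sequences", {
  all_poor <- simulate_annotation(
    simulation_config(n_genes = 15, frac_poor_py = 1, seed = 44))
  expect_false(any(has_py_tract(all_poor$annotation$introns$sequence)))
  all_good <- simulate_annotation(
    simulation_config(n_genes = 15, frac_poor_py = 0, seed = 44))
  expect_true(all(has_py_tract(all_good$annotation$introns$sequence)))
  # sequence-derived classification agrees with the planted truth
  mixed <- simulate_annotation(
    simulation_config(n_genes = 30, frac_poor_py = 0.5, seed = 45))
  scanned <- !has_py_tract(mixed$annotation$introns$sequence)
  planted <- mixed$truth$intron_features$poor_py[
    match(mixed$annotation$introns$intron_id,
          mixed$truth$intron_features$intron_id)]
  expect_equal(scanned, planted)
})

test_that("plant_group_effect multiplies only labeled knockdown retention, clipped at 1", {
  cfg <- simulation_config(n_genes = 40, knockdowns = "kd",
                           with_genome = FALSE, seed = 46)
  sim <- simulate_annotation(cfg)
  same <- plant_group_effect(sim, "first_before_large_second", 1)
  expect_equal(same$truth$retention, sim$truth$retention)

  cls <- classify_intron_groups(
    sim$annotation$introns |>
      left_join(sim$truth$intron_features, by = "intron_id"))
  target <- cls$intron_id[cls$first_before_large_second]
  expect_gt(length(target), 0)
  sim$truth$retention$r[sim$truth$retention$intron_id == target[1]] <- 0.5

  planted <- plant_group_effect(sim, "first_before_large_second", 3)
  rt0 <- sim$truth$retention
  rt1 <- planted$truth$retention
  expect_equal(rt1 |> filter(condition == "control"),
               rt0 |> filter(condition == "control"))
  untouched <- !rt0$intron_id %in% target
  expect_equal(rt1$r[untouched], rt0$r[untouched])
  kd_target <- rt1$condition == "kd" & rt1$intron_id %in% target
  expect_equal(rt1$r[kd_target], pmin(rt0$r[kd_target] * 3, 1))
  expect_equal(rt1$r[rt1$condition == "kd" & rt1$intron_id == target[1]], 1)
})

test_that("read-level and count-level simulation agree exactly through the counter", {
  cfg <- simulation_config(n_genes = 15, depth = 4e4, knockdowns = "kd",
                           seed = 47)
  sim <- simulate_annotation(cfg)
  reads <- simulate_reads(sim, "control", 1, sample_id = "s")
  counted <- count_features(reads, sim$annotation, "s")
  direct <- simulate_counts(sim, "control", 1, sample_id = "s")
  merged <- counted |>
    inner_join(direct, by = "feature_id", suffix = c("_read", "_direct"))
  expect_equal(merged$count_read, merged$count_direct)
  expect_equal(counted$library_size[1], direct$library_size[1])
})

test_that("a fully retained intron recovers an index near 1", {
  cfg <- simulation_config(n_genes = 12, depth = 2e5, knockdowns = "kd",
                           seed = 48)
  sim <- simulate_annotation(cfg)
  target <- sim$annotation$introns$intron_id[1]
  sim$truth$retention <- sim$truth$retention |>
    mutate(r = ifelse(intron_id == target, 1, r))
  q <- count_features(simulate_reads(sim, "control", 1), sim$annotation, "s")
  rk <- compute_rpkm(q, sim$annotation)
  tx_id <- sim$annotation$introns$transcript_id[1]
  idx <- retention_index(rk$rpkm[rk$feature_id == target],
                         rk$rpkm[rk$feature_id == tx_id])
  expect_lt(abs(idx - 1), 0.1)
})

test_that("quadrupling depth about halves the retention-index error", {
  errs <- sapply(c(5e4, 2e5), function(depth) {
    mean(sapply(1:12, function(s) {
      cfg <- simulation_config(n_genes = 15, depth = depth, knockdowns = "kd",
                               retention_shape1 = 2, retention_shape2 = 10,
                               with_genome = FALSE, seed = 400 + s)
      sim <- simulate_annotation(cfg)
      q <- simulate_counts(sim, "control", 1, "s")
      rk <- compute_rpkm(q, sim$annotation)
      tx <- rk |> filter(feature_type == "transcript") |>
        select(transcript_id = feature_id, tx_rpkm = rpkm)
      est <- rk |> filter(feature_type == "intron") |>
        left_join(tx, by = "transcript_id") |>
        filter(tx_rpkm > 0) |>
        mutate(est = rpkm / tx_rpkm) |>
        left_join(sim$truth$retention |> filter(condition == "control"),
                  by = c(feature_id = "intron_id"))
      mean(abs(est$est - est$r))
    }))
  })
  ratio <- errs[2] / errs[1]
  expect_lt(ratio, 0.7)   # 1/sqrt(4) = 0.5 expected under Poisson noise
  expect_gt(ratio, 0.3)
})

test_that("negative binomial noise overdisperses relative to Poisson", {
  cfg_p <- simulation_config(n_genes = 20, depth = 1e5, knockdowns = "kd",
                             with_genome = FALSE, seed = 49)
  cfg_nb <- simulation_config(n_genes = 20, depth = 1e5, knockdowns = "kd",
                              with_genome = FALSE, noise = "nb",
                              nb_dispersion = 0.3, seed = 49)
  sim_p <- simulate_annotation(cfg_p)
  sim_nb <- simulate_annotation(cfg_nb)
  reps <- function(sim) sapply(1:20, function(r) {
    q <- simulate_counts(sim, "control", r, "s")
    q$count[q$feature_type == "transcript"]
  })
  vp <- apply(reps(sim_p), 1, var) / pmax(rowMeans(reps(sim_p)), 1)
  vnb <- apply(reps(sim_nb), 1, var) / pmax(rowMeans(reps(sim_nb)), 1)
  expect_gt(median(vnb), 2 * median(vp))
})
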