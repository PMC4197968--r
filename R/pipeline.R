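#' Assemble a pipeline run configuration
#'
#' All analysis thresholds default to the values of the published analysis
#' design: transcripts above 10 RPKM in the control, introns above 10% of
#' their transcript RPKM in any replicate, retention fold pseudo-count
#' 0.01, affected window 2-10 fold, large/huge intron thresholds 2/10 kb,
#' pY rule of 7 pyrimidines in the last 50 nt. Overrides are recorded in
#' the run manifest.
#'
#' @param gtf,fasta Annotation and genome paths.
#' @param sample_sheet Path to a TSV (or a tibble) with columns
#'   `sample_id`, `condition`, `replicate`, `path` (read placements, TSV or
#'   SAM per sample).
#' @param out_dir Output directory (created if missing).
#' @param stranded Strand-specific counting.
#' @param min_transcript_rpkm,min_intron_fraction,intron_filter_scope
#'   Filter parameters, see [apply_analysis_filters()].
#' @param epsilon,fold_window Fold-change parameters.
#' @param control_condition Control condition name.
#' @param splice_params [splice_rule_params()].
#' @param scheme [group_scheme()].
#' @param seed Seed recorded in the manifest (the analysis itself is
#'   deterministic).
#' @return List of class `run_config`.
#' @export
run_config <- function(gtf, fasta, sample_sheet, out_dir,
                       stranded = TRUE,
                       min_transcript_rpkm = 10,
                       min_intron_fraction = 0.10,
                       intron_filter_scope = "any_sample",
                       epsilon = 0.01,
                       fold_window = c(2, 10),
                       control_condition = "control",
                       splice_params = splice_rule_params(),
                       scheme = group_scheme(),
                       seed = 1L) {
  structure(as.list(environment()), class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file with the [run_config()] fields.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_data("config file not found: %s", path)
  y <- yaml::read_yaml(path)
  needed <- c("gtf", "fasta", "sample_sheet", "out_dir")
  missing <- setdiff(needed, names(y))
  if (length(missing) > 0) {
    abort_data("config is missing field(s): %s", paste(missing, collapse = ", "))
  }
  args <- y[intersect(names(y), names(formals(run_config)))]
  if (!is.null(args$fold_window)) args$fold_window <- as.numeric(args$fold_window)
  do.call(run_config, args)
}

#' @noRd
log_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the retention analysis end to end
#'
#' Stages: quantify (exonic/intronic counting per sample) -> RPKM ->
#' analysis filters -> isoform-shared intron deduplication -> retention
#' indices and fold changes -> architecture classification -> group and
#' transcript-bin rank-sum tests. Writes per-intron results
#' (`introns.tsv`), group tests (`group_tests.tsv`/`.json`), transcript
#' bin tests (`transcript_tests.tsv`), the filter summary
#' (`analysis_summary.tsv`) and a machine-readable `manifest.json`
#' (package version, parameters, input checksums, stage counts). Stage
#' progress and filter counts are logged via `message()`.
#'
#' @param config A [run_config()] or path to its YAML form.
#' @return Invisibly, a list with the in-memory results (`rpkm`,
#'   `analysis_set`, `retention`, `classified`, `group_tests`,
#'   `transcript_tests`, `manifest`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  for (p in c(config$gtf, config$fasta)) {
    if (!file.exists(p)) abort_data("[input] missing input file: %s", p)
  }
  sheet <- config$sample_sheet
  if (is.character(sheet)) {
    if (!file.exists(sheet)) abort_data("[input] missing sample sheet: %s", sheet)
    sheet <- readr::read_tsv(sheet, show_col_types = FALSE)
  }
  check_columns(sheet, c("sample_id", "condition", "replicate", "path"),
                "sample_sheet")
  absent <- sheet$path[!file.exists(sheet$path)]
  if (length(absent) > 0) {
    abort_data("[input] missing read placement file(s): %s",
               paste(absent, collapse = ", "))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  log_stage("annotation", "reading %s", config$gtf)
  ann <- read_annotation(config$gtf, config$fasta)
  log_stage("annotation", "%d transcripts, %d introns",
            nrow(ann$transcripts), nrow(ann$introns))

  log_stage("quantify", "counting %d sample(s)", nrow(sheet))
  reads <- setNames(as.list(sheet$path), sheet$sample_id)
  reads <- purrr::map(reads, function(p) {
    if (grepl("\\.(sam|bam)$", p, ignore.case = TRUE)) read_alignments_sam(p)
    else read_placements(p)
  })
  quant <- quantify_samples(reads, ann, stranded = config$stranded)
  rpkm <- compute_rpkm(quant, ann)

  aset <- apply_analysis_filters(
    rpkm, sheet, min_transcript_rpkm = config$min_transcript_rpkm,
    min_intron_fraction = config$min_intron_fraction,
    control_condition = config$control_condition,
    scope = config$intron_filter_scope)
  log_stage("filter", "transcripts %d -> %d, introns %d -> %d",
            aset$summary$n[1], aset$summary$n[2],
            aset$summary$n[3], aset$summary$n[4])

  ctrl_expr <- rpkm |>
    inner_join(sheet |> select("sample_id", "condition"), by = "sample_id") |>
    filter(.data$feature_type == "transcript",
           .data$condition == config$control_condition) |>
    group_by(transcript_id = .data$feature_id) |>
    summarise(rpkm = mean(.data$rpkm), .groups = "drop")
  dedup <- dedup_introns(ann$introns, ctrl_expr)
  aset$introns <- intersect(aset$introns, dedup$intron_id)
  log_stage("dedup", "%d analyzed introns after isoform deduplication",
            length(aset$introns))

  retention <- retention_results(
    rpkm, sheet, aset, epsilon = config$epsilon,
    fold_window = config$fold_window,
    control_condition = config$control_condition)
  log_stage("retention", "%d introns x %d knockdown(s); %d affected",
            dplyr::n_distinct(retention$intron_id),
            dplyr::n_distinct(retention$knockdown),
            dplyr::n_distinct(retention$intron_id[retention$affected]))

  # classify the full deduplicated table (transcript-level labels need all
  # introns), then group tests see only the analyzed subset via the folds
  classified <- classify_intron_groups(dedup, scheme = config$scheme,
                                       params = config$splice_params)
  membership <- group_membership(classified)
  folds <- retention |> select("intron_id", "knockdown", "fold")
  group_tests <- group_retention_test(folds, membership)

  tx_folds <- transcript_fold_changes(
    rpkm, sheet, aset, epsilon = config$epsilon,
    control_condition = config$control_condition)
  bins <- transcript_intron_size_bins(
    dedup |> filter(.data$transcript_id %in% aset$transcripts),
    transcripts = aset$transcripts)
  tx_tests <- transcript_level_test(tx_folds, bins)
  log_stage("test", "%d group tests, %d transcript-bin tests",
            nrow(tidy(group_tests)), nrow(tidy(tx_tests)))

  per_intron <- retention |>
    left_join(classified |>
                select("intron_id", "length", "ordinal", "py_run",
                       dplyr::all_of(intron_group_labels())),
              by = "intron_id")
  out <- function(f) file.path(config$out_dir, f)
  readr::write_tsv(per_intron, out("introns.tsv"))
  readr::write_tsv(tidy(group_tests), out("group_tests.tsv"))
  jsonlite::write_json(tidy(group_tests), out("group_tests.json"),
                       dataframe = "rows", na = "null", digits = NA)
  readr::write_tsv(tidy(tx_tests), out("transcript_tests.tsv"))
  readr::write_tsv(aset$summary, out("analysis_summary.tsv"))

  params <- config[setdiff(names(config), c("gtf", "fasta", "sample_sheet",
                                            "out_dir"))]
  params$splice_params <- unclass(params$splice_params)
  params$scheme <- unclass(params$scheme)
  manifest <- list(
    package = "intronret",
    version = as.character(utils::packageVersion("intronret")),
    parameters = params,
    inputs = list(gtf = unname(tools::md5sum(config$gtf)),
                  fasta = unname(tools::md5sum(config$fasta)),
                  reads = as.list(setNames(unname(tools::md5sum(sheet$path)),
                                           sheet$sample_id))),
    counts = setNames(as.list(aset$summary$n), aset$summary$stage))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  log_stage("done", "results in %s", config$out_dir)

  invisible(list(annotation = ann, rpkm = rpkm, analysis_set = aset,
                 retention = per_intron, classified = classified,
                 group_tests = group_tests, transcript_tests = tx_tests,
                 manifest = manifest))
}
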