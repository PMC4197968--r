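#' Read or write the tabular read-placement format
#'
#' The inter-stage contract for alignments is a TSV with one row per aligned
#' read (or mate): `read_id`, `chrom`, `start`, `end` (0-based half-open
#' span), `strand`, `blocks` (comma-separated `start-end` aligned blocks,
#' 0-based half-open; gaps between blocks are splice junctions) and
#' `n_hits` (number of alignments of that read; only `n_hits == 1` reads
#' are counted). Mates of one fragment share a `read_id`.
#'
#' @param path TSV path.
#' @return Tibble of read placements.
#' @export
read_placements <- function(path) {
  if (!file.exists(path)) abort_data("read placement file not found: %s", path)
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    read_id = readr::col_character(),
                    chrom = readr::col_character(),
                    start = readr::col_integer(),
                    end = readr::col_integer(),
                    strand = readr::col_character(),
                    blocks = readr::col_character(),
                    n_hits = readr::col_integer()))
}

#' @rdname read_placements
#' @param reads Read-placement tibble.
#' @export
write_placements <- function(reads, path) {
  readr::write_tsv(reads, path)
  invisible(path)
}

#' Import a SAM/BAM file as read placements
#'
#' Alignments are trusted as given; reads with mapping quality below
#' `min_mapq` are treated as multi-mapped and dropped. Mates keep their
#' query name as `read_id`, so a proper pair counts once per feature.
#'
#' @param path SAM or BAM file.
#' @param min_mapq Minimum mapping quality for a read to count as unique.
#' @return Read-placement tibble (see [read_placements()]).
#' @export
read_alignments_sam <- function(path, min_mapq = 10L) {
  if (!file.exists(path)) abort_data("alignment file not found: %s", path)
  fmt <- if (grepl("\\.sam$", path, ignore.case = TRUE)) "sam" else "bam"
  if (fmt == "sam") {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  } else bam <- path
  gal <- GenomicAlignments::readGAlignments(
    bam, use.names = TRUE,
    param = Rsamtools::ScanBamParam(mapqFilter = min_mapq))
  blocks <- GenomicAlignments::grglist(gal, order.as.in.query = FALSE)
  block_str <- vapply(as.list(IRanges::ranges(blocks)), function(r) {
    paste(sprintf("%d-%d", IRanges::start(r) - 1L, IRanges::end(r)), collapse = ",")
  }, character(1))
  tibble(read_id = names(gal),
         chrom = as.character(GenomicAlignments::seqnames(gal)),
         start = GenomicAlignments::start(gal) - 1L,
         end = GenomicAlignments::end(gal),
         strand = as.character(GenomicAlignments::strand(gal)),
         blocks = unname(block_str),
         n_hits = 1L)
}

#' Parse the blocks column into one row per aligned block
#' @noRd
parse_blocks <- function(reads) {
  multi <- grepl(",", reads$blocks, fixed = TRUE)
  simple <- reads[!multi, ]
  out <- list()
  if (nrow(simple) > 0) {
    parts <- stringr::str_split_fixed(simple$blocks, "-", 2)
    out$simple <- tibble(row = which(!multi),
                         bstart = as.integer(parts[, 1]),
                         bend = as.integer(parts[, 2]))
  }
  if (any(multi)) {
    idx <- which(multi)
    pieces <- strsplit(reads$blocks[idx], ",", fixed = TRUE)
    lens <- lengths(pieces)
    flat <- stringr::str_split_fixed(unlist(pieces), "-", 2)
    out$multi <- tibble(row = rep(idx, lens),
                        bstart = as.integer(flat[, 1]),
                        bend = as.integer(flat[, 2]))
  }
  bind_rows(out) |> arrange(.data$row, .data$bstart)
}

#' Build a CIGAR string per read from its blocks (M runs, N gaps)
#'
#' `block_tbl` must be sorted by (row, bstart); single-block reads are
#' vectorized, multi-block reads collapsed via data.table.
#' @noRd
blocks_to_cigar <- function(block_tbl) {
  rl <- rle(block_tbl$row)
  first_idx <- cumsum(rl$lengths) - rl$lengths + 1L
  w <- block_tbl$bend - block_tbl$bstart
  cig <- character(length(rl$values))
  single <- rl$lengths == 1L
  cig[single] <- sprintf("%dM", w[first_idx[single]])
  if (any(!single)) {
    multi_rows <- rep(!single, rl$lengths)
    grp <- rep(seq_along(rl$values), rl$lengths)[multi_rows]
    is_first <- !duplicated(grp)
    gap <- block_tbl$bstart[multi_rows] -
      c(0L, block_tbl$bend[multi_rows][-sum(multi_rows)])
    piece <- paste0(ifelse(is_first, "", paste0(gap, "N")),
                    w[multi_rows], "M")
    dt <- data.table::data.table(grp = grp, piece = piece)
    coll <- dt[, list(cigar = paste(piece, collapse = "")), by = "grp"]
    cig[coll$grp] <- coll$cigar
  }
  tibble(row = rl$values, cigar = cig, gstart = block_tbl$bstart[first_idx])
}

#' Count reads per exonic transcript and per intron
#'
#' Implements the counting rules of the retention analysis: only uniquely
#' aligned reads are used; a fragment increments a transcript's exonic
#' count when every aligned block of every mate lies within that
#' transcript's exons and every junction in the read matches an intron of
#' the exon chain exactly (block-compatible); it increments an intron's
#' count when any aligned base of any mate overlaps the intron interval.
#' A fragment counts at most once per feature. With a strand-specific
#' library only same-strand reads count.
#'
#' @param reads Read-placement tibble (see [read_placements()]).
#' @param annotation A [genome_annotation()].
#' @param sample_id Sample label attached to the output.
#' @param stranded Is the library strand-specific? Default `TRUE`.
#' @param introns Intron tibble to count against; defaults to the
#'   annotation's (pass a deduplicated table to avoid double counting).
#' @return Tibble `sample_id`, `feature_id`, `feature_type`
#'   (transcript/intron), `transcript_id` (parent), `count`,
#'   `library_size` (number of uniquely aligned fragments), with a row for
#'   every feature including zero counts.
#' @export
count_features <- function(reads, annotation, sample_id = "sample",
                           stranded = TRUE, introns = NULL) {
  check_columns(reads, c("read_id", "chrom", "strand", "blocks"), "reads")
  introns <- introns %||% annotation$introns
  if (!is.null(reads$n_hits)) reads <- reads |> filter(.data$n_hits <= 1L)
  known <- names(annotation$seqlengths)
  unknown <- setdiff(unique(reads$chrom), known)
  if (length(unknown) > 0) {
    warning(sprintf("skipping reads on chromosome(s) absent from annotation: %s",
                    paste(unknown, collapse = ", ")), call. = FALSE)
    reads <- reads |> filter(.data$chrom %in% known)
  }
  frag_of_row <- match(reads$read_id, unique(reads$read_id))
  n_frags <- if (nrow(reads)) max(frag_of_row) else 0L
  library_size <- n_frags

  skeleton <- bind_rows(
    annotation$transcripts |>
      mutate(feature_id = .data$transcript_id, feature_type = "transcript") |>
      select("feature_id", "feature_type", "transcript_id"),
    introns |>
      mutate(feature_id = .data$intron_id, feature_type = "intron") |>
      select("feature_id", "feature_type", "transcript_id"))

  counts <- tibble(feature_id = character(), nfrag = integer())
  if (nrow(reads) > 0 && nrow(skeleton) > 0) {
    blocks <- parse_blocks(reads)
    block_gr <- GenomicRanges::GRanges(
      reads$chrom[blocks$row],
      IRanges::IRanges(blocks$bstart + 1L, blocks$bend),
      strand = reads$strand[blocks$row])

    # intronic: any 1-nt overlap of any block
    intron_counts <- NULL
    if (nrow(introns) > 0) {
      intron_gr <- GenomicRanges::GRanges(
        introns$chrom, IRanges::IRanges(introns$start + 1L, introns$end),
        strand = introns$strand)
      hits <- GenomicRanges::findOverlaps(block_gr, intron_gr,
                                          ignore.strand = !stranded)
      ni <- nrow(introns)
      key <- (as.numeric(frag_of_row[blocks$row[S4Vectors::queryHits(hits)]]) - 1) *
        ni + S4Vectors::subjectHits(hits)
      ukey <- unique(key)
      nfrag <- tabulate(as.integer((ukey - 1) %% ni) + 1L, nbins = ni)
      intron_counts <- tibble(feature_id = introns$intron_id,
                              nfrag = nfrag) |>
        filter(.data$nfrag > 0)
    }

    # exonic: every row (mate) of the fragment block-compatible with the chain
    cig <- blocks_to_cigar(blocks)
    gal <- GenomicAlignments::GAlignments(
      seqnames = reads$chrom[cig$row], pos = cig$gstart + 1L,
      cigar = cig$cigar,
      strand = factor(reads$strand[cig$row], levels = c("+", "-", "*")))
    # exons ordered by transcript rank (descending genomic on "-"), as the
    # compatibility encoding expects
    ex <- annotation$exons |> arrange(.data$transcript_id, .data$exon_rank)
    ex_gr <- GenomicRanges::GRanges(
      ex$chrom, IRanges::IRanges(ex$start + 1L, ex$end), strand = ex$strand)
    exbytx <- S4Vectors::split(ex_gr, ex$transcript_id)
    # findCompatibleOverlaps is strand-blind; enforce strand match here
    h <- GenomicAlignments::findCompatibleOverlaps(gal, exbytx)
    pairs <- tibble(row = cig$row[S4Vectors::queryHits(h)],
                    feature_id = names(exbytx)[S4Vectors::subjectHits(h)])
    if (stranded) {
      tx_strand <- annotation$transcripts$strand[
        match(pairs$feature_id, annotation$transcripts$transcript_id)]
      pairs <- pairs[reads$strand[pairs$row] == tx_strand, ]
    }
    # a fragment is exonic for a transcript when every one of its rows
    # (mates) is block-compatible with that transcript
    tx_counts <- NULL
    if (nrow(pairs) > 0) {
      nt <- length(exbytx)
      txi <- match(pairs$feature_id, names(exbytx))
      rowtx <- unique((as.numeric(pairs$row) - 1) * nt + txi)
      row_u <- as.integer((rowtx - 1) %/% nt) + 1L
      tx_u <- as.integer((rowtx - 1) %% nt) + 1L
      fragtx <- (as.numeric(frag_of_row[row_u]) - 1) * nt + tx_u
      compat_rows <- table_counts(fragtx)
      rows_per_frag <- tabulate(frag_of_row, nbins = n_frags)
      frag_u <- as.integer((compat_rows$key - 1) %/% nt) + 1L
      keep_tx <- as.integer((compat_rows$key - 1) %% nt) + 1L
      full <- compat_rows$n == rows_per_frag[frag_u]
      nfrag_tx <- tabulate(keep_tx[full], nbins = nt)
      tx_counts <- tibble(feature_id = names(exbytx), nfrag = nfrag_tx) |>
        filter(.data$nfrag > 0)
    }
    counts <- bind_rows(intron_counts, tx_counts)
  }

  skeleton |>
    left_join(counts, by = "feature_id") |>
    mutate(count = dplyr::coalesce(.data$nfrag, 0L),
           sample_id = sample_id, library_size = library_size) |>
    select("sample_id", "feature_id", "feature_type", "transcript_id",
           "count", "library_size")
}

#' Quantify several samples against one annotation
#'
#' @param reads_by_sample Named list of read-placement tibbles, or of paths
#'   to placement TSVs; names are sample ids.
#' @inheritParams count_features
#' @return Row-bound [count_features()] tibbles.
#' @export
quantify_samples <- function(reads_by_sample, annotation, stranded = TRUE,
                             introns = NULL) {
  if (is.null(names(reads_by_sample))) {
    abort_data("reads_by_sample must be a named list (names are sample ids)")
  }
  purrr::imap_dfr(reads_by_sample, function(r, sid) {
    if (is.character(r)) r <- read_placements(r)
    count_features(r, annotation, sample_id = sid, stranded = stranded,
                   introns = introns)
  })
}

#' Add feature lengths and RPKM to a count table
#'
#' RPKM = count / (feature length in kb x library size in millions).
#' Transcript length is the exonic length (introns excluded); intron length
#' is the intron interval length.
#'
#' @param quant Count tibble from [count_features()]/[quantify_samples()].
#' @param annotation The matching [genome_annotation()].
#' @return The tibble with `length` and `rpkm` columns added.
#' @export
compute_rpkm <- function(quant, annotation) {
  check_columns(quant, c("feature_id", "feature_type", "count", "library_size"),
                "quant")
  if (any(quant$library_size == 0)) abort_data("sample with zero library size")
  lengths <- bind_rows(
    annotation$transcripts |>
      select(feature_id = "transcript_id", length = "exonic_length"),
    annotation$introns |>
      select(feature_id = "intron_id", "length") |>
      distinct(.data$feature_id, .keep_all = TRUE))
  out <- quant |> left_join(lengths, by = "feature_id")
  if (anyNA(out$length)) {
    abort_data("feature(s) without a length in the annotation (e.g. %s)",
               out$feature_id[which(is.na(out$length))[1]])
  }
  if (any(out$length <= 0)) abort_data("zero-length feature")
  out |>
    mutate(rpkm = .data$count / ((.data$length / 1000) *
                                   (.data$library_size / 1e6)))
}

#' Apply the analysis filters of the retention pipeline
#'
#' A transcript enters the analysis when its mean control RPKM exceeds
#' `min_transcript_rpkm` (strict `>`). An intron enters when its parent
#' transcript passes and its RPKM exceeds `min_intron_fraction` of the
#' transcript RPKM in the same sample, in at least one replicate — of any
#' sample by default (`scope = "any_sample"`) or of the control replicates
#' only (`scope = "control_only"`).
#'
#' @param rpkm RPKM tibble from [compute_rpkm()] covering all samples.
#' @param sample_sheet Tibble `sample_id`, `condition`, `replicate`.
#' @param min_transcript_rpkm Transcript expression cutoff (RPKM).
#' @param min_intron_fraction Intron/transcript RPKM ratio cutoff.
#' @param control_condition Name of the control condition.
#' @param scope Which samples the intron ratio test may use.
#' @return An `analysis_set`: list with character vectors `transcripts` and
#'   `introns` plus a `summary` tibble of stage counts.
#' @export
apply_analysis_filters <- function(rpkm, sample_sheet,
                                   min_transcript_rpkm = 10,
                                   min_intron_fraction = 0.10,
                                   control_condition = "control",
                                   scope = c("any_sample", "control_only")) {
  scope <- match.arg(scope)
  check_columns(sample_sheet, c("sample_id", "condition", "replicate"),
                "sample_sheet")
  ctrl_samples <- sample_sheet$sample_id[sample_sheet$condition == control_condition]
  if (length(ctrl_samples) == 0) {
    abort_data("no samples with control condition '%s'", control_condition)
  }

  tx_pass <- rpkm |>
    filter(.data$feature_type == "transcript",
           .data$sample_id %in% ctrl_samples) |>
    group_by(.data$feature_id) |>
    summarise(ctrl_rpkm = mean(.data$rpkm)) |>
    filter(.data$ctrl_rpkm > min_transcript_rpkm) |>
    pull("feature_id")

  use_samples <- if (scope == "control_only") ctrl_samples else sample_sheet$sample_id
  tx_rpkm <- rpkm |>
    filter(.data$feature_type == "transcript") |>
    select("sample_id", parent_rpkm = "rpkm", transcript_id = "feature_id")
  intron_pass <- rpkm |>
    filter(.data$feature_type == "intron",
           .data$sample_id %in% use_samples,
           .data$transcript_id %in% tx_pass) |>
    left_join(tx_rpkm, by = c("sample_id", "transcript_id")) |>
    filter(.data$rpkm > min_intron_fraction * .data$parent_rpkm) |>
    distinct(.data$feature_id) |>
    pull("feature_id")

  n_tx_all <- dplyr::n_distinct(rpkm$feature_id[rpkm$feature_type == "transcript"])
  n_in_all <- dplyr::n_distinct(rpkm$feature_id[rpkm$feature_type == "intron"])
  structure(
    list(transcripts = sort(tx_pass), introns = sort(intron_pass),
         summary = tibble(
           stage = c("transcripts_total", "transcripts_analyzed",
                     "introns_total", "introns_analyzed"),
           n = c(n_tx_all, length(tx_pass), n_in_all, length(intron_pass)))),
    class = "analysis_set")
}

#' @export
print.analysis_set <- function(x, ...) {
  cat(sprintf("<analysis_set> %d/%d transcripts, %d/%d introns analyzed\n",
              length(x$transcripts), x$summary$n[1],
              length(x$introns), x$summary$n[3]))
  invisible(x)
}

#' Intron retention index
#'
#' The retention index of an intron in a sample (or condition) is its RPKM
#' divided by the exonic RPKM of its transcript: ~0 for a fully spliced
#' intron, ~1 for a fully retained one.
#'
#' @param intron_rpkm,transcript_rpkm Numeric vectors.
#' @return Numeric vector of indices.
#' @export
retention_index <- function(intron_rpkm, transcript_rpkm) {
  if (any(transcript_rpkm == 0)) {
    abort_data("retention index undefined at transcript RPKM 0 (filter first)")
  }
  intron_rpkm / transcript_rpkm
}

#' Knockdown/control fold change of a retention index
#'
#' A pseudo-count `epsilon` keeps fully spliced control introns finite:
#' fold = (index_kd + epsilon) / (index_ctrl + epsilon).
#'
#' @param index_kd,index_ctrl Numeric vectors of condition-level indices.
#' @param epsilon Pseudo-count, default 0.01.
#' @return Numeric fold changes (> 0).
#' @export
fold_retention_change <- function(index_kd, index_ctrl, epsilon = 0.01) {
  (index_kd + epsilon) / (index_ctrl + epsilon)
}

#' Flag an intron as affected by the knockdown(s)
#'
#' An intron is affected when any knockdown's retention fold change falls
#' inside the window (default 2- to 10-fold above control; values above the
#' cap are not flagged).
#'
#' @param folds Numeric vector of fold changes (one per knockdown).
#' @param window Length-2 numeric, inclusive bounds.
#' @return Single logical.
#' @export
flag_affected <- function(folds, window = c(2, 10)) {
  any(folds >= window[1] & folds <= window[2], na.rm = TRUE)
}

#' Per-condition mean RPKM of each feature
#' @noRd
condition_means <- function(rpkm, sample_sheet) {
  rpkm |>
    inner_join(sample_sheet |> select("sample_id", "condition"),
               by = "sample_id") |>
    group_by(.data$feature_id, .data$feature_type, .data$transcript_id,
             .data$condition) |>
    summarise(rpkm = mean(.data$rpkm), .groups = "drop")
}

#' Retention indices, fold changes and affected flags per intron
#'
#' Replicate RPKMs are combined by arithmetic mean per condition before the
#' index; each non-control condition is treated as a knockdown and compared
#' with the control.
#'
#' @param rpkm RPKM tibble over all samples ([compute_rpkm()]).
#' @param sample_sheet Tibble `sample_id`, `condition`, `replicate`.
#' @param analysis_set Result of [apply_analysis_filters()] (or a list with
#'   an `introns` character vector).
#' @param epsilon Pseudo-count for the fold change.
#' @param fold_window Affected window, passed to [flag_affected()].
#' @param control_condition Name of the control condition.
#' @return Tibble, one row per analyzed intron per knockdown: `intron_id`,
#'   `transcript_id`, `knockdown`, `index_control`, `index_knockdown`,
#'   `fold`, `affected` (per intron, across knockdowns).
#' @export
retention_results <- function(rpkm, sample_sheet, analysis_set,
                              epsilon = 0.01, fold_window = c(2, 10),
                              control_condition = "control") {
  means <- condition_means(rpkm, sample_sheet)
  kds <- setdiff(unique(sample_sheet$condition), control_condition)
  if (length(kds) == 0) abort_data("no knockdown conditions in sample sheet")

  tx_means <- means |>
    filter(.data$feature_type == "transcript") |>
    select(transcript_id = "feature_id", "condition", tx_rpkm = "rpkm")
  idx <- means |>
    filter(.data$feature_type == "intron",
           .data$feature_id %in% analysis_set$introns) |>
    left_join(tx_means, by = c("transcript_id", "condition")) |>
    mutate(index = retention_index(.data$rpkm, .data$tx_rpkm)) |>
    select(intron_id = "feature_id", "transcript_id", "condition", "index")

  ctrl <- idx |>
    filter(.data$condition == control_condition) |>
    select("intron_id", "transcript_id", index_control = "index")
  out <- idx |>
    filter(.data$condition %in% kds) |>
    select("intron_id", knockdown = "condition", index_knockdown = "index") |>
    inner_join(ctrl, by = "intron_id") |>
    mutate(fold = fold_retention_change(.data$index_knockdown,
                                        .data$index_control, epsilon))
  flags <- out |>
    group_by(.data$intron_id) |>
    summarise(affected = flag_affected(.data$fold, fold_window))
  out |>
    left_join(flags, by = "intron_id") |>
    select("intron_id", "transcript_id", "knockdown", "index_control",
           "index_knockdown", "fold", "affected") |>
    arrange(.data$intron_id, .data$knockdown)
}

#' Transcript-level RPKM fold changes (knockdown vs control)
#'
#' Uses the same pseudo-count rule as the intron fold change.
#'
#' @inheritParams retention_results
#' @return Tibble `transcript_id`, `knockdown`, `rpkm_control`,
#'   `rpkm_knockdown`, `fold`.
#' @export
transcript_fold_changes <- function(rpkm, sample_sheet, analysis_set,
                                    epsilon = 0.01,
                                    control_condition = "control") {
  means <- condition_means(rpkm, sample_sheet) |>
    filter(.data$feature_type == "transcript",
           .data$feature_id %in% analysis_set$transcripts)
  kds <- setdiff(unique(sample_sheet$condition), control_condition)
  ctrl <- means |>
    filter(.data$condition == control_condition) |>
    select(transcript_id = "feature_id", rpkm_control = "rpkm")
  means |>
    filter(.data$condition %in% kds) |>
    select(transcript_id = "feature_id", knockdown = "condition",
           rpkm_knockdown = "rpkm") |>
    inner_join(ctrl, by = "transcript_id") |>
    mutate(fold = (.data$rpkm_knockdown + epsilon) /
                  (.data$rpkm_control + epsilon)) |>
    select("transcript_id", "knockdown", "rpkm_control", "rpkm_knockdown",
           "fold") |>
    arrange(.data$transcript_id, .data$knockdown)
}
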