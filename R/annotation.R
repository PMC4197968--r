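#' Build a genome annotation from exon tables
#'
#' The central container of the package: transcript models (ordered exon
#' chains) plus the introns derived from them, with optional genome sequence
#' for strand-aware intron sequence extraction. All internal coordinates are
#' 0-based half-open; GTF input/output converts at the boundary.
#'
#' @param exons Tibble with columns `transcript_id`, `gene_id`, `chrom`,
#'   `strand` ("+" or "-"), `start`, `end` (0-based half-open genomic).
#' @param genome Optional [Biostrings::DNAStringSet] of chromosome sequences,
#'   or `NULL`. Chromosome names must cover every `chrom` in `exons`.
#' @param seqlengths Optional named integer vector of chromosome lengths;
#'   derived from `genome` when absent.
#'
#' @return An object of class `genome_annotation`: a list with tibbles
#'   `transcripts`, `exons`, `introns` (see [introns()]), the `genome`, and
#'   `seqlengths`.
#' @export
genome_annotation <- function(exons, genome = NULL, seqlengths = NULL) {
  exons <- as_tibble(exons)
  check_columns(exons, c("transcript_id", "gene_id", "chrom", "strand",
                         "start", "end"), "exons")
  if (nrow(exons) > 0 && !all(exons$strand %in% c("+", "-"))) {
    abort_data("exon strand must be '+' or '-'")
  }
  if (any(exons$end <= exons$start)) {
    abort_data("exon intervals must be non-empty (end > start, half-open)")
  }
  if (is.null(seqlengths)) {
    if (!is.null(genome)) {
      seqlengths <- setNames(Biostrings::width(genome), names(genome))
    } else if (nrow(exons) > 0) {
      seqlengths <- tapply(exons$end, exons$chrom, max)
      seqlengths <- setNames(as.integer(seqlengths), names(seqlengths))
    } else {
      seqlengths <- integer(0)
    }
  }
  if (nrow(exons) > 0) {
    bad <- setdiff(unique(exons$chrom), names(seqlengths))
    if (length(bad) > 0) {
      abort_data("chromosome(s) missing from genome/seqlengths: %s",
                 paste(bad, collapse = ", "))
    }
    over <- exons$end > unname(seqlengths[exons$chrom])
    if (any(over)) {
      abort_data("exon beyond chromosome bounds (first offender: %s on %s)",
                 exons$transcript_id[which(over)[1]],
                 exons$chrom[which(over)[1]])
    }
  }

  # genomic order within transcript; exon_rank is 1-based in transcript
  # orientation (reversed on the minus strand)
  exons <- if (nrow(exons) == 0) {
    exons |> mutate(exon_rank = integer(0))
  } else {
    exons |>
      arrange(.data$transcript_id, .data$start) |>
      group_by(.data$transcript_id) |>
      mutate(exon_rank = if (dplyr::first(.data$strand) == "+") row_number()
                         else rev(row_number())) |>
      ungroup()
  }

  overlapping <- exons |>
    group_by(.data$transcript_id) |>
    summarise(bad = any(lead(.data$start) < .data$end, na.rm = TRUE)) |>
    filter(.data$bad)
  if (nrow(overlapping) > 0) {
    abort_data("overlapping exons within transcript(s): %s",
               paste(overlapping$transcript_id, collapse = ", "))
  }

  transcripts <- if (nrow(exons) == 0) {
    tibble(transcript_id = character(), gene_id = character(),
           chrom = character(), strand = character(), n_exons = integer(),
           exonic_length = integer(), start = integer(), end = integer())
  } else exons |>
    group_by(.data$transcript_id) |>
    summarise(gene_id = dplyr::first(.data$gene_id),
              chrom = dplyr::first(.data$chrom),
              strand = dplyr::first(.data$strand),
              n_exons = n(),
              exonic_length = sum(.data$end - .data$start),
              start = min(.data$start), end = max(.data$end)) |>
    ungroup()

  ann <- structure(
    list(transcripts = transcripts, exons = exons, introns = NULL,
         genome = genome, seqlengths = seqlengths),
    class = "genome_annotation")
  ann$introns <- extract_introns(ann)
  ann
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf(
    "<genome_annotation> %d transcripts, %d exons, %d introns on %d sequence(s)%s\n",
    nrow(x$transcripts), nrow(x$exons), nrow(x$introns),
    length(x$seqlengths),
    if (is.null(x$genome)) " (no genome sequence)" else ""))
  invisible(x)
}

#' Read a GTF (and optional FASTA) into a genome annotation
#'
#' GTF is taken in the Ensembl dialect (1-based inclusive coordinates,
#' `gene_id`/`transcript_id` attributes); only `exon` features are used.
#' Coordinates are converted to the package's 0-based half-open convention.
#' Exon lines may appear in any order. When a FASTA is given, every GTF
#' chromosome must be present in it and intron sequences are extracted
#' strand-aware.
#'
#' @param gtf_path Path to a GTF file.
#' @param fasta_path Optional path to an (uncompressed or gzipped) FASTA file.
#' @return A [genome_annotation()] object.
#' @export
read_annotation <- function(gtf_path, fasta_path = NULL) {
  if (!file.exists(gtf_path)) abort_data("GTF not found: %s", gtf_path)
  genome <- NULL
  if (!is.null(fasta_path)) {
    if (!file.exists(fasta_path)) abort_data("FASTA not found: %s", fasta_path)
    genome <- Biostrings::readDNAStringSet(fasta_path)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  n_lines <- length(readLines(gtf_path, n = 1L))
  if (n_lines == 0L) {
    return(genome_annotation(
      tibble(transcript_id = character(), gene_id = character(),
             chrom = character(), strand = character(),
             start = integer(), end = integer()),
      genome = genome))
  }
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0) {
    return(genome_annotation(
      tibble(transcript_id = character(), gene_id = character(),
             chrom = character(), strand = character(),
             start = integer(), end = integer()),
      genome = genome))
  }
  if (is.null(gr$gene_id) || is.null(gr$transcript_id) ||
      anyNA(gr$gene_id) || anyNA(gr$transcript_id)) {
    abort_data("GTF exon lines must carry gene_id and transcript_id attributes")
  }
  exons <- tibble(
    transcript_id = gr$transcript_id,
    gene_id = gr$gene_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,   # 1-based inclusive -> 0-based half-open
    end = GenomicRanges::end(gr))
  if (any(exons$strand == "*")) abort_data("GTF exon without strand")
  genome_annotation(exons, genome = genome)
}

#' Derive introns from the exon chains of an annotation
#'
#' Introns are the gaps between genomically consecutive exons of one
#' transcript, ordered and numbered 5'->3' in transcript orientation, with
#' neighbour intron lengths filled in and (when the annotation carries a
#' genome) the intron sequence in transcript orientation, i.e. starting at
#' the donor (canonically GT) and ending at the acceptor (canonically AG).
#' Zero-length gaps (abutting exon records) are skipped with a warning.
#'
#' @param annotation A [genome_annotation()].
#' @return Tibble with one row per intron: `intron_id` (transcript_id:iN),
#'   `transcript_id`, `gene_id`, `chrom`, `strand`, `start`, `end`
#'   (0-based half-open), `length`, `ordinal`, `n_introns`, `is_first`,
#'   `is_last`, `upstream_intron_length`, `downstream_intron_length`
#'   (NA at the transcript ends), `sequence` (NA without a genome).
#' @export
extract_introns <- function(annotation) {
  ex <- annotation$exons
  empty <- tibble(intron_id = character(), transcript_id = character(),
                  gene_id = character(), chrom = character(),
                  strand = character(), start = integer(), end = integer(),
                  length = integer(), ordinal = integer(),
                  n_introns = integer(), is_first = logical(),
                  is_last = logical(), upstream_intron_length = integer(),
                  downstream_intron_length = integer(), sequence = character())
  if (nrow(ex) == 0) return(empty)

  gaps <- ex |>
    arrange(.data$transcript_id, .data$start) |>
    group_by(.data$transcript_id) |>
    mutate(gap_start = .data$end, gap_end = lead(.data$start)) |>
    filter(!is.na(.data$gap_end)) |>
    ungroup() |>
    select("transcript_id", "gene_id", "chrom", "strand",
           start = "gap_start", end = "gap_end")

  abutting <- gaps |> filter(.data$end == .data$start)
  if (nrow(abutting) > 0) {
    warning(sprintf("skipping %d zero-length gap(s) between abutting exons (e.g. %s)",
                    nrow(abutting), abutting$transcript_id[1]), call. = FALSE)
    gaps <- gaps |> filter(.data$end > .data$start)
  }
  if (nrow(gaps) == 0) return(empty)

  introns <- gaps |>
    group_by(.data$transcript_id) |>
    mutate(n_introns = n(),
           ordinal = if (dplyr::first(.data$strand) == "+") row_number()
                     else rev(row_number())) |>
    arrange(.data$ordinal, .by_group = TRUE) |>
    mutate(length = .data$end - .data$start,
           is_first = .data$ordinal == 1L,
           is_last = .data$ordinal == .data$n_introns,
           upstream_intron_length = lag(.data$length),
           downstream_intron_length = lead(.data$length)) |>
    ungroup() |>
    mutate(intron_id = paste0(.data$transcript_id, ":i", .data$ordinal))

  introns$sequence <- intron_sequences(introns, annotation$genome)
  introns |>
    select("intron_id", "transcript_id", "gene_id", "chrom", "strand",
           "start", "end", "length", "ordinal", "n_introns", "is_first",
           "is_last", "upstream_intron_length", "downstream_intron_length",
           "sequence") |>
    arrange(.data$transcript_id, .data$ordinal)
}

#' Extract feature sequences in transcript orientation
#' @noRd
intron_sequences <- function(feats, genome) {
  if (is.null(genome) || nrow(feats) == 0) return(rep(NA_character_, nrow(feats)))
  out <- character(nrow(feats))
  for (chr in unique(feats$chrom)) {
    i <- which(feats$chrom == chr)
    at <- IRanges::IRanges(feats$start[i] + 1L, feats$end[i])
    seqs <- Biostrings::extractAt(genome[[chr]], at)
    minus <- feats$strand[i] == "-"
    if (any(minus)) seqs[minus] <- Biostrings::reverseComplement(seqs[minus])
    out[i] <- as.character(seqs)
  }
  out
}

#' Accessor for the intron table of an annotation
#' @param annotation A [genome_annotation()].
#' @return The intron tibble (see [extract_introns()]).
#' @export
introns <- function(annotation) annotation$introns

#' Deduplicate isoform-shared introns
#'
#' Introns with identical genomic coordinates shared by several isoforms of
#' one gene are collapsed to a single record, attached to the isoform with
#' the highest control-condition expression (ties broken by transcript_id so
#' the result is deterministic). Without an expression table the
#' lexicographically first transcript_id wins.
#'
#' @param introns Intron tibble as from [extract_introns()].
#' @param expression Optional tibble `transcript_id`, `rpkm` (control-mean
#'   RPKM) used to rank isoforms.
#' @return Filtered intron tibble.
#' @export
dedup_introns <- function(introns, expression = NULL) {
  rank_tbl <- if (!is.null(expression)) {
    check_columns(expression, c("transcript_id", "rpkm"), "expression")
    expression |> select("transcript_id", "rpkm")
  } else {
    tibble(transcript_id = unique(introns$transcript_id), rpkm = 0)
  }
  introns |>
    left_join(rank_tbl, by = "transcript_id") |>
    mutate(rpkm = dplyr::coalesce(.data$rpkm, 0)) |>
    group_by(.data$gene_id, .data$chrom, .data$start, .data$end, .data$strand) |>
    arrange(dplyr::desc(.data$rpkm), .data$transcript_id, .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup() |>
    select(-"rpkm") |>
    arrange(.data$transcript_id, .data$ordinal)
}

#' Write an annotation back to GTF (1-based inclusive, Ensembl dialect)
#'
#' Only exon features are written; reloading the file with
#' [read_annotation()] reproduces the transcript models exactly.
#'
#' @param annotation A [genome_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_gtf <- function(annotation, path) {
  ex <- annotation$exons |> arrange(.data$transcript_id, .data$start)
  lines <- sprintf(
    '%s\tintronret\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
    ex$chrom, ex$start + 1L, ex$end, ex$strand, ex$gene_id, ex$transcript_id)
  writeLines(lines, path)
  invisible(path)
}

#' Export introns as BED6 (0-based half-open, strand in column 6)
#' @param introns Intron tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intron_bed <- function(introns, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                   introns$chrom, introns$start, introns$end,
                   introns$intron_id, introns$strand)
  writeLines(lines, path)
  invisible(path)
}
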