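#' Configuration of the synthetic RNA-seq study
#'
#' Defaults emulate the study design the pipeline targets: two knockdown
#' conditions plus a control, two biological replicates each, 50-nt
#' strand-specific reads, and a per-sample depth proportional to a
#' 10-20M-read library scaled to the simulated gene count. Gene
#' architecture uses 2-8 exons, lognormal exon/intron lengths, an explicit
#' fraction of planted large (> 2 kb) and huge (> 10 kb) introns, and a
#' fraction of introns synthesized without a good polypyrimidine tract.
#' Baseline retention fractions r are Beta-distributed near zero (most
#' introns are efficiently spliced); a planted effect multiplies r in the
#' knockdown conditions for one architecture group.
#'
#' @param n_genes Number of genes (one transcript each).
#' @param exon_count_range Inclusive range exon numbers are drawn from.
#' @param exon_length_meanlog,exon_length_sdlog,exon_length_min Lognormal
#'   exon length model (nt).
#' @param intron_length_meanlog,intron_length_sdlog,intron_length_min,intron_length_cap
#'   Lognormal baseline intron length model (nt); baseline draws are capped
#'   below the large-intron threshold so large/huge introns are planted
#'   explicitly.
#' @param frac_large_introns,frac_huge_introns Fractions of introns redrawn
#'   uniformly from (2000, 8000] and (10000, 20000] respectively.
#' @param frac_poor_py Fraction of introns synthesized with a poor pY tract.
#' @param abundance_meanlog,abundance_sdlog Lognormal transcript abundance
#'   model (arbitrary expression units, shared across conditions).
#' @param retention_shape1,retention_shape2 Beta parameters of the baseline
#'   per-intron retention fraction r.
#' @param knockdowns Names of the knockdown conditions.
#' @param replicates Replicates per condition.
#' @param depth Expected fragments per sample.
#' @param read_length Read length (nt).
#' @param noise `"poisson"` or `"nb"` (negative binomial).
#' @param nb_dispersion NB dispersion (size = 1/dispersion).
#' @param planted_effect `NULL` or `list(group = <label>, multiplier = k)`,
#'   applied to knockdown-condition r of that group's introns.
#' @param with_genome Synthesize the genome sequence? Count-level studies
#'   that never place reads can skip it (`FALSE`) for speed; the pY truth
#'   is still planted in the truth tables.
#' @param seed Base seed; every derived stream is a deterministic function
#'   of it, so a fixed seed gives byte-identical outputs.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 200L,
                              exon_count_range = c(2L, 8L),
                              exon_length_meanlog = log(300),
                              exon_length_sdlog = 0.45,
                              exon_length_min = 100L,
                              intron_length_meanlog = log(300),
                              intron_length_sdlog = 0.9,
                              intron_length_min = 62L,
                              intron_length_cap = 1900L,
                              frac_large_introns = 0.15,
                              frac_huge_introns = 0.03,
                              frac_poor_py = 0.2,
                              abundance_meanlog = log(30),
                              abundance_sdlog = 1,
                              retention_shape1 = 1.5,
                              retention_shape2 = 30,
                              knockdowns = c("tsu", "acn"),
                              replicates = 2L,
                              depth = 1e6,
                              read_length = 50L,
                              noise = c("poisson", "nb"),
                              nb_dispersion = 0.1,
                              planted_effect = NULL,
                              with_genome = TRUE,
                              seed = 1L) {
  noise <- match.arg(noise)
  cfg <- as.list(environment())
  if (cfg$depth <= 0) abort_data("depth must be positive")
  if (cfg$intron_length_min < 62L) {
    abort_data("intron_length_min below 62 nt cannot host the engineered 3' window")
  }
  if (cfg$exon_length_min <= cfg$read_length) {
    abort_data("exon_length_min must exceed the read length")
  }
  structure(cfg, class = "simulation_config")
}

#' Random DNA of given lengths
#' @noRd
random_dna <- function(lengths) {
  total <- sum(pmax(lengths, 0L))
  if (total == 0) return(rep("", length(lengths)))
  pool <- sample(c("A", "C", "G", "T"), total, replace = TRUE)
  ends <- cumsum(pmax(lengths, 0L))
  starts <- ends - pmax(lengths, 0L) + 1L
  big <- paste(pool, collapse = "")
  out <- stringr::str_sub(big, starts, ends)
  out[lengths <= 0] <- ""
  out
}

#' Engineered 3'-terminal 50-nt intron window (including the AG acceptor)
#'
#' Good-pY windows embed a 10-nt pyrimidine run; poor-pY windows force a
#' purine at every 7th position so no run of 7 pyrimidines can occur.
#' @noRd
intron_tail50 <- function(poor) {
  if (poor) {
    chars <- sample(c("A", "C", "G", "T"), 48, replace = TRUE,
                    prob = c(0.35, 0.15, 0.35, 0.15))
    chars[seq(1, 48, by = 6)] <- sample(c("A", "G"), 8, replace = TRUE)
    paste0(paste(chars, collapse = ""), "AG")
  } else {
    pre <- sample(c("A", "C", "G", "T"), 20, replace = TRUE)
    run <- sample(c("C", "T"), 10, replace = TRUE)
    post <- sample(c("A", "C", "G", "T"), 18, replace = TRUE)
    paste0(paste(c(pre, run, post), collapse = ""), "AG")
  }
}

#' Simulate an annotated genome with planted retention truth
#'
#' Draws gene structures from the config distributions, synthesizes a
#' genome in which every intron begins with the GT donor and ends with the
#' AG acceptor, engineers polypyrimidine-tract quality into the intron 3'
#' ends, and records the ground truth: per-transcript abundance and
#' per-intron retention fraction r for every condition, plus the planted pY
#' status. Strands are assigned at random; minus-strand genes are written
#' to the genome as the reverse complement of their transcript-orientation
#' sequence.
#'
#' @param config A [simulation_config()].
#' @return List of class `retention_simulation`: `annotation`
#'   ([genome_annotation()] with genome sequence), `truth` (list of tibbles
#'   `abundance`, `retention`, `intron_features`), `config`.
#' @export
simulate_annotation <- function(config = simulation_config()) {
  withr::local_seed(derive_seed(config$seed, 1L))
  ng <- config$n_genes
  ex_choices <- seq(config$exon_count_range[1], config$exon_count_range[2])
  n_ex <- ex_choices[sample.int(length(ex_choices), ng, replace = TRUE)]
  strand <- sample(c("+", "-"), ng, replace = TRUE)

  total_introns <- sum(n_ex - 1L)
  in_len_all <- pmin(pmax(round(rlnorm(total_introns,
                                       config$intron_length_meanlog,
                                       config$intron_length_sdlog)),
                          config$intron_length_min),
                     config$intron_length_cap)
  u <- runif(total_introns)
  huge <- u < config$frac_huge_introns
  large <- !huge & u < config$frac_huge_introns + config$frac_large_introns
  in_len_all[large] <- round(runif(sum(large), 2001, 8000))
  in_len_all[huge] <- round(runif(sum(huge), 10001, 20000))
  poor_all <- runif(total_introns) < config$frac_poor_py
  if (any(in_len_all < 62L)) abort_data("infeasible intron length constraints")

  gene_seqs <- character(ng)
  exon_rows <- vector("list", ng)
  chrom <- "chrSim"
  spacer <- 300L
  pos <- 100L   # 0-based start of the first gene
  ii <- 0L
  for (g in seq_len(ng)) {
    k <- n_ex[g]
    ex_len <- pmax(round(rlnorm(k, config$exon_length_meanlog,
                                config$exon_length_sdlog)),
                   config$exon_length_min)
    idx <- ii + seq_len(k - 1L); ii <- ii + k - 1L
    in_len <- in_len_all[idx]
    feat_len <- integer(2 * k - 1)
    feat_len[seq(1, 2 * k - 1, 2)] <- ex_len
    if (k > 1) feat_len[seq(2, 2 * k - 2, 2)] <- in_len
    glen <- sum(feat_len)
    off_end <- cumsum(feat_len)              # transcript-orientation offsets
    off_start <- off_end - feat_len
    ex_i <- seq(1, 2 * k - 1, 2)

    if (config$with_genome) {
      in_seq <- if (k > 1) {
        paste0("GT", random_dna(in_len - 52L),
               vapply(poor_all[idx], intron_tail50, character(1)))
      } else character(0)
      feat_seq <- character(2 * k - 1)
      feat_seq[ex_i] <- random_dna(ex_len)
      if (k > 1) feat_seq[seq(2, 2 * k - 2, 2)] <- in_seq
      tx_seq <- paste(feat_seq, collapse = "")
      gene_seqs[g] <- if (strand[g] == "+") tx_seq else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(tx_seq)))
    }
    if (strand[g] == "+") {
      gs <- pos + off_start[ex_i]; ge <- pos + off_end[ex_i]
    } else {
      gs <- pos + glen - off_end[ex_i]; ge <- pos + glen - off_start[ex_i]
    }
    exon_rows[[g]] <- tibble(
      transcript_id = sprintf("tx%04d", g), gene_id = sprintf("g%04d", g),
      chrom = chrom, strand = strand[g],
      start = as.integer(gs), end = as.integer(ge))
    pos <- pos + glen + spacer
  }

  genome <- NULL
  seqlens <- setNames(as.integer(pos), chrom)
  if (config$with_genome) {
    chrom_seq <- paste0(random_dna(100L), paste0(
      paste0(gene_seqs, random_dna(rep(spacer, ng))), collapse = ""))
    genome <- Biostrings::DNAStringSet(setNames(chrom_seq, chrom))
    seqlens <- NULL
  }
  ann <- genome_annotation(bind_rows(exon_rows), genome = genome,
                           seqlengths = seqlens)

  conditions <- c("control", config$knockdowns)
  abund <- rlnorm(ng, config$abundance_meanlog, config$abundance_sdlog)
  abundance <- tidyr::expand_grid(
    transcript_id = sprintf("tx%04d", seq_len(ng)),
    condition = conditions) |>
    left_join(tibble(transcript_id = sprintf("tx%04d", seq_len(ng)),
                     abundance = abund), by = "transcript_id")
  r0 <- stats::rbeta(nrow(ann$introns), config$retention_shape1,
                     config$retention_shape2)
  retention <- tidyr::expand_grid(
    intron_id = ann$introns$intron_id, condition = conditions) |>
    left_join(tibble(intron_id = ann$introns$intron_id, r = r0),
              by = "intron_id")

  # planted pY status in annotation (genomic) order of the introns
  feats <- ann$introns |> select("intron_id", "transcript_id", "ordinal")
  plan <- bind_rows(purrr::map(seq_len(ng), function(g) {
    k <- n_ex[g]
    if (k < 2) return(NULL)
    tibble(transcript_id = sprintf("tx%04d", g), ordinal = seq_len(k - 1L))
  })) |>
    mutate(poor_py = poor_all)
  feats <- feats |> left_join(plan, by = c("transcript_id", "ordinal"))

  sim <- structure(
    list(annotation = ann,
         truth = list(abundance = abundance, retention = retention,
                      intron_features = feats |>
                        select("intron_id", "poor_py")),
         config = config),
    class = "retention_simulation")
  if (!is.null(config$planted_effect)) {
    sim <- plant_group_effect(sim, config$planted_effect$group,
                              config$planted_effect$multiplier)
  }
  sim
}

#' @export
print.retention_simulation <- function(x, ...) {
  cat(sprintf("<retention_simulation> %d transcripts, %d introns, conditions: %s\n",
              nrow(x$annotation$transcripts), nrow(x$annotation$introns),
              paste(unique(x$truth$abundance$condition), collapse = ", ")))
  invisible(x)
}

#' Plant a retention effect in one architecture group
#'
#' Multiplies the knockdown-condition retention fractions of introns
#' carrying the given group label (clipped to 1); control and all other
#' introns are untouched.
#'
#' @param sim A `retention_simulation`.
#' @param group One of [intron_group_labels()].
#' @param multiplier Fold multiplier on r (>= 0).
#' @param scheme [group_scheme()] used for the labels.
#' @return The simulation with updated truth.
#' @export
plant_group_effect <- function(sim, group, multiplier,
                               scheme = group_scheme()) {
  stopifnot(group %in% intron_group_labels(), multiplier >= 0)
  classified <- classify_intron_groups(
    sim$annotation$introns |>
      left_join(sim$truth$intron_features, by = "intron_id"),
    scheme = scheme)
  ids <- classified$intron_id[classified[[group]]]
  sim$truth$retention <- sim$truth$retention |>
    mutate(r = if_else(.data$intron_id %in% ids & .data$condition != "control",
                       pmin(.data$r * multiplier, 1), .data$r))
  sim
}

#' Expected fragment rates per feature for one sample
#'
#' Expected counts are proportional to abundance x feature length
#' (x retention fraction r for introns), normalized so they sum to the
#' configured depth; this makes the RPKM-ratio retention index an unbiased
#' estimator of r.
#' @noRd
feature_rates <- function(sim, condition) {
  ab <- sim$truth$abundance |> filter(.data$condition == !!condition)
  if (nrow(ab) == 0) abort_data("unknown condition '%s'", condition)
  tx <- sim$annotation$transcripts |>
    left_join(ab |> select("transcript_id", "abundance"), by = "transcript_id") |>
    mutate(weight = .data$abundance * .data$exonic_length)
  rr <- sim$truth$retention |> filter(.data$condition == !!condition)
  intr <- sim$annotation$introns |>
    left_join(rr |> select("intron_id", "r"), by = "intron_id") |>
    left_join(ab |> select("transcript_id", "abundance"), by = "transcript_id") |>
    mutate(weight = .data$abundance * .data$r * .data$length)
  cc <- sim$config$depth / (sum(tx$weight) + sum(intr$weight))
  list(tx = tx |> mutate(lambda = .data$weight * cc),
       intr = intr |> mutate(lambda = .data$weight * cc))
}

#' Draw feature counts under the configured noise law
#' @noRd
draw_counts <- function(lambda, config) {
  if (config$noise == "poisson") rpois(length(lambda), lambda)
  else rnbinom(length(lambda), mu = lambda, size = 1 / config$nb_dispersion)
}

#' Simulate per-feature fragment counts for one sample
#'
#' The count-level fast path of the generator: identical count
#' distributions to [simulate_reads()] without materializing placements.
#' Output plugs directly into [compute_rpkm()].
#'
#' @param sim A `retention_simulation`.
#' @param condition Condition name present in the truth.
#' @param replicate Replicate index (enters the random stream).
#' @param sample_id Sample label; default `condition_rep<replicate>`.
#' @return Count tibble in the [count_features()] layout.
#' @export
simulate_counts <- function(sim, condition, replicate = 1L,
                            sample_id = sprintf("%s_rep%d", condition, replicate)) {
  cond_i <- match(condition, unique(sim$truth$abundance$condition))
  withr::local_seed(derive_seed(sim$config$seed,
                                1000L + 100L * cond_i + replicate))
  rates <- feature_rates(sim, condition)
  tx_counts <- draw_counts(rates$tx$lambda, sim$config)
  in_counts <- draw_counts(rates$intr$lambda, sim$config)
  out <- bind_rows(
    tibble(feature_id = rates$tx$transcript_id, feature_type = "transcript",
           transcript_id = rates$tx$transcript_id, count = tx_counts),
    tibble(feature_id = rates$intr$intron_id, feature_type = "intron",
           transcript_id = rates$intr$transcript_id, count = in_counts))
  out |>
    mutate(sample_id = sample_id,
           library_size = sum(out$count)) |>
    select("sample_id", "feature_id", "feature_type", "transcript_id",
           "count", "library_size")
}

#' Project transcript-coordinate intervals to genomic blocks
#'
#' `starts`/`ends` are 0-based half-open positions on the mature transcript
#' (exonic coordinates, transcript orientation).
#' @noRd
project_to_genome <- function(tx_id, starts, ends, annotation) {
  ex <- annotation$exons |>
    arrange(.data$transcript_id, .data$exon_rank) |>
    group_by(.data$transcript_id) |>
    mutate(w = .data$end - .data$start,
           cum_end = cumsum(.data$w), cum_start = .data$cum_end - .data$w) |>
    ungroup()
  tx_off <- ex |>
    group_by(.data$transcript_id) |>
    summarise(tx_len = sum(.data$w), .groups = "drop") |>
    mutate(offset = cumsum(dplyr::lag(.data$tx_len, default = 0)))
  ex <- ex |> left_join(tx_off, by = "transcript_id")

  off <- tx_off$offset[match(tx_id, tx_off$transcript_id)]
  read_rng <- IRanges::IRanges(off + starts + 1L, off + ends)
  exon_rng <- IRanges::IRanges(ex$offset + ex$cum_start + 1L,
                               ex$offset + ex$cum_end)
  hits <- IRanges::findOverlaps(read_rng, exon_rng)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  # overlap in mature coordinates, as 0-based offsets within the exon
  ms <- pmax(starts[qi], ex$cum_start[si]) - ex$cum_start[si]
  me <- pmin(ends[qi], ex$cum_end[si]) - ex$cum_start[si]
  plus <- ex$strand[si] == "+"
  bstart <- ifelse(plus, ex$start[si] + ms, ex$end[si] - me)
  bend <- ifelse(plus, ex$start[si] + me, ex$end[si] - ms)
  dt <- data.table::data.table(read = qi, bstart = as.integer(bstart),
                               bend = as.integer(bend))
  data.table::setorder(dt, read, bstart)
  single <- !(duplicated(dt$read) | duplicated(dt$read, fromLast = TRUE))
  bs <- sprintf("%d-%d", dt$bstart, dt$bend)
  out_s <- tibble(read = dt$read[single], blocks = bs[single],
                  span_start = dt$bstart[single], span_end = dt$bend[single])
  out_m <- NULL
  if (any(!single)) {
    dm <- dt[!single]
    dm$bs <- bs[!single]
    out_m <- as_tibble(dm[, list(blocks = paste(bs, collapse = ","),
                                 span_start = min(bstart),
                                 span_end = max(bend)), by = "read"])
  }
  bind_rows(out_s, out_m) |> arrange(.data$read)
}

#' Simulate strand-specific read placements for one sample
#'
#' Per-feature fragment counts are drawn as in [simulate_counts()]; exonic
#' fragments are placed uniformly on the mature transcript and projected to
#' the genome (splitting into blocks across junctions), intron-overlapping
#' fragments uniformly among the single-block genomic placements that
#' overlap the intron by at least one base. Read strand is the transcript
#' strand. Fixed seeds give byte-identical output.
#'
#' @inheritParams simulate_counts
#' @return Read-placement tibble (see [read_placements()]).
#' @export
simulate_reads <- function(sim, condition, replicate = 1L,
                           sample_id = sprintf("%s_rep%d", condition, replicate)) {
  cond_i <- match(condition, unique(sim$truth$abundance$condition))
  withr::local_seed(derive_seed(sim$config$seed,
                                1000L + 100L * cond_i + replicate))
  L <- sim$config$read_length
  rates <- feature_rates(sim, condition)
  tx_counts <- draw_counts(rates$tx$lambda, sim$config)
  in_counts <- draw_counts(rates$intr$lambda, sim$config)
  ann <- sim$annotation

  # exonic fragments: uniform starts on the mature transcript
  tx_rep <- rep(seq_len(nrow(rates$tx)), tx_counts)
  n_ex_reads <- length(tx_rep)
  ex_part <- NULL
  if (n_ex_reads > 0) {
    exlen <- rates$tx$exonic_length[tx_rep]
    s <- floor(runif(n_ex_reads) * pmax(exlen - L + 1L, 1L))
    e <- pmin(s + L, exlen)
    proj <- project_to_genome(rates$tx$transcript_id[tx_rep], s, e, ann)
    ex_part <- tibble(
      chrom = rates$tx$chrom[tx_rep][proj$read],
      strand = rates$tx$strand[tx_rep][proj$read],
      start = proj$span_start, end = proj$span_end, blocks = proj$blocks)
  }

  # intron-overlapping fragments: uniform single-block genomic placements
  in_rep <- rep(seq_len(nrow(rates$intr)), in_counts)
  in_part <- NULL
  if (length(in_rep) > 0) {
    is0 <- rates$intr$start[in_rep]; ie0 <- rates$intr$end[in_rep]
    lo <- pmax(is0 - L + 1L, 0L)
    s <- lo + floor(runif(length(in_rep)) * (ie0 - lo))
    e <- s + L
    in_part <- tibble(
      chrom = rates$intr$chrom[in_rep],
      strand = rates$intr$strand[in_rep],
      start = as.integer(s), end = as.integer(e),
      blocks = sprintf("%d-%d", as.integer(s), as.integer(e)))
  }

  out <- bind_rows(ex_part, in_part)
  if (nrow(out) == 0) {
    return(tibble(read_id = character(), chrom = character(),
                  start = integer(), end = integer(), strand = character(),
                  blocks = character(), n_hits = integer()))
  }
  out |>
    mutate(read_id = sprintf("%s_%07d", sample_id, row_number()),
           n_hits = 1L) |>
    select("read_id", "chrom", "start", "end", "strand", "blocks", "n_hits")
}

#' Write the simulated genome as FASTA
#' @param sim A `retention_simulation` (or a [genome_annotation()]).
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(sim, path) {
  genome <- if (inherits(sim, "retention_simulation")) sim$annotation$genome
            else sim$genome
  if (is.null(genome)) abort_data("no genome sequence to write")
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Write the truth tables of a simulation as TSV
#'
#' Emits `<prefix>_abundance.tsv`, `<prefix>_retention.tsv` and
#' `<prefix>_intron_features.tsv`.
#'
#' @param sim A `retention_simulation`.
#' @param prefix Output path prefix.
#' @return Character vector of the written paths, invisibly.
#' @export
write_truth <- function(sim, prefix) {
  paths <- c(abundance = paste0(prefix, "_abundance.tsv"),
             retention = paste0(prefix, "_retention.tsv"),
             intron_features = paste0(prefix, "_intron_features.tsv"))
  readr::write_tsv(sim$truth$abundance, paths[["abundance"]])
  readr::write_tsv(sim$truth$retention, paths[["retention"]])
  readr::write_tsv(sim$truth$intron_features, paths[["intron_features"]])
  invisible(paths)
}

#' Emit a sample's placements as a minimal SAM file
#'
#' Unsorted single-end SAM with an @SQ header derived from the annotation;
#' sequences and qualities are omitted (`*`), flags encode strand only.
#'
#' @param reads Read-placement tibble.
#' @param annotation The matching [genome_annotation()].
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_reads_sam <- function(reads, annotation, path) {
  header <- c("@HD\tVN:1.6",
              sprintf("@SQ\tSN:%s\tLN:%d", names(annotation$seqlengths),
                      unname(annotation$seqlengths)))
  blocks <- parse_blocks(reads)
  cig <- blocks_to_cigar(blocks)
  flag <- ifelse(reads$strand[cig$row] == "-", 16L, 0L)
  body <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t*\t*",
                  reads$read_id[cig$row], flag, reads$chrom[cig$row],
                  cig$gstart + 1L, cig$cigar)
  writeLines(c(header, body), path)
  invisible(path)
}
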