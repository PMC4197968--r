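suppressPackageStartupMessages({
  library(dplyr)
  library(tibble)
})

`%||%` <- function(a, b) if (is.null(a)) b else a

# three-exon + strand transcript and two-exon - strand transcript on one
# 2 kb chromosome; GTF coordinates 1-based inclusive
toy_exon_tbl <- function() {
  bind_rows(
    tibble(transcript_id = "t1", gene_id = "g1", chrom = "chr1", strand = "+",
           start = c(100L, 300L, 900L), end = c(200L, 400L, 1000L)),
    tibble(transcript_id = "t2", gene_id = "g2", chrom = "chr1", strand = "-",
           start = c(1100L, 1300L), end = c(1200L, 1400L)))
}

toy_genome <- function(len = 2000L, seed = 42L) {
  withr::with_seed(seed, {
    Biostrings::DNAStringSet(c(chr1 = paste(
      sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")))
  })
}

toy_annotation <- function() genome_annotation(toy_exon_tbl(), toy_genome())

write_toy_gtf <- function(path = tempfile(fileext = ".gtf"),
                          reversed = FALSE) {
  ex <- toy_exon_tbl()
  if (reversed) ex <- ex[rev(seq_len(nrow(ex))), ]
  lines <- sprintf(
    '%s\ttest\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
    ex$chrom, ex$start + 1L, ex$end, ex$strand, ex$gene_id, ex$transcript_id)
  writeLines(lines, path)
  path
}

write_toy_fasta <- function(path = tempfile(fileext = ".fa"),
                            genome = toy_genome()) {
  Biostrings::writeXStringSet(genome, path)
  path
}

# independent oracle: longest pyrimidine run in the last `window` nt by
# enumeration of all substrings
brute_py_run <- function(s, window) {
  s <- substr(s, max(1L, nchar(s) - window + 1L), nchar(s))
  best <- 0L
  if (nchar(s) == 0) return(best)
  for (i in seq_len(nchar(s))) {
    for (j in i:nchar(s)) {
      if (grepl("^[CT]+$", substr(s, i, j))) best <- max(best, j - i + 1L)
    }
  }
  best
}

# independent oracle: exact two-sided rank-sum p by full enumeration of all
# choose(m+n, m) member/comparison assignments of the pooled values
ranksum_enum <- function(x, y) {
  pooled <- c(x, y)
  m <- length(x)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - m * (m + 1) / 2
  }
  obs <- u_of(seq_len(m))
  combos <- utils::combn(length(pooled), m)
  us <- apply(combos, 2, u_of)
  p_le <- mean(us <= obs)
  p_ge <- mean(us >= obs)
  min(1, 2 * min(p_le, p_ge))
}

# count-level simulation of a knockdown study; returns the pieces every
# downstream stage needs
simulate_count_study <- function(config, knockdown = "tsu") {
  sim <- simulate_annotation(config)
  sheet <- tidyr::expand_grid(condition = c("control", knockdown),
                              replicate = seq_len(config$replicates)) |>
    mutate(sample_id = sprintf("%s_rep%d", condition, replicate))
  quant <- purrr::pmap_dfr(sheet, function(condition, replicate, sample_id) {
    simulate_counts(sim, condition, replicate, sample_id)
  })
  list(sim = sim, sheet = sheet, rpkm = compute_rpkm(quant, sim$annotation))
}
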