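#' Parameters of the rule-based splice-competence model
#'
#' Defaults encode the model's constants: an intron 3' end is counted as
#' having a good polypyrimidine (pY) tract when it carries a run of at least
#' `min_py_run` consecutive pyrimidines (C/T) within the last `py_window`
#' nucleotides; a poor-pY intron can still splice autonomously when shorter
#' than `autonomous_max_length` (strict `<`, so 90 itself is not
#' autonomous); otherwise splicing can be rescued by an exon junction
#' complex (EJC) deposited `ejc_offset` nt upstream of a flanking exon-exon
#' junction, provided the deposition site lies within `rescue_distance` nt
#' of the intron's 3' splice site on the pre-mRNA.
#'
#' @param min_py_run Minimum pyrimidine run length (nt) for a good tract.
#' @param py_window Window from the intron 3' end scanned for the run (nt).
#' @param autonomous_max_length Length (nt) below which a poor-pY intron
#'   splices without help.
#' @param ejc_offset Distance (nt) upstream of an exon-exon junction at
#'   which the EJC is deposited.
#' @param rescue_distance Maximum distance (nt) from an EJC deposition site
#'   to the 3' splice site for rescue.
#' @return A list of class `splice_rule_params`.
#' @export
splice_rule_params <- function(min_py_run = 7L, py_window = 50L,
                               autonomous_max_length = 90L,
                               ejc_offset = 24L, rescue_distance = 250L) {
  p <- list(min_py_run = as.integer(min_py_run),
            py_window = as.integer(py_window),
            autonomous_max_length = as.integer(autonomous_max_length),
            ejc_offset = as.integer(ejc_offset),
            rescue_distance = as.integer(rescue_distance))
  if (any(unlist(p) <= 0L)) abort_data("all splice rule parameters must be positive")
  if (p$py_window < p$min_py_run) {
    abort_data("py_window (%d) must be >= min_py_run (%d)", p$py_window, p$min_py_run)
  }
  structure(p, class = "splice_rule_params")
}

#' Longest pyrimidine run near a sequence 3' end
#'
#' Scans the final `window` nucleotides of each sequence (the whole sequence
#' when shorter) and returns the longest run of consecutive C/T characters.
#' `N` breaks a run; any character outside `ACGTN` is an error.
#'
#' @param sequence Character vector of uppercase ACGTN sequences.
#' @param window Number of 3'-terminal nucleotides to scan (>= 1).
#' @return Integer vector of maximal pyrimidine run lengths.
#' @export
#' @examples
#' longest_pyrimidine_run("AAACCCCCCCCAG", 50)  # 8
longest_pyrimidine_run <- function(sequence, window = 50L) {
  stopifnot(is.character(sequence), window >= 1)
  bad <- grepl("[^ACGTN]", sequence)
  if (any(bad)) {
    abort_data("sequence contains non-ACGTN characters (first offender index %d)",
               which(bad)[1])
  }
  tail_seq <- stringr::str_sub(sequence, -window)
  vapply(tail_seq, function(s) {
    if (is.na(s) || nchar(s) == 0) return(0L)
    runs <- gregexpr("[CT]+", s)[[1]]
    if (runs[1] == -1L) return(0L)
    max(attr(runs, "match.length"))
  }, integer(1), USE.NAMES = FALSE)
}

#' Does an intron carry a good polypyrimidine tract?
#'
#' @param sequence Intron sequence(s) in transcript orientation (donor to
#'   acceptor; the terminal AG is part of the scanned window).
#' @param params [splice_rule_params()].
#' @return Logical vector.
#' @export
has_py_tract <- function(sequence, params = splice_rule_params()) {
  longest_pyrimidine_run(sequence, params$py_window) >= params$min_py_run
}

#' Annotate an intron table with polypyrimidine-tract status
#'
#' @param introns Intron tibble with a `sequence` column.
#' @param params [splice_rule_params()].
#' @return The tibble with `py_run` and `poor_py` columns added.
#' @export
add_py_status <- function(introns, params = splice_rule_params()) {
  check_columns(introns, "sequence", "introns")
  if (anyNA(introns$sequence)) {
    abort_data("intron sequences are missing; load the annotation with a FASTA")
  }
  introns |>
    mutate(py_run = longest_pyrimidine_run(.data$sequence, params$py_window),
           poor_py = .data$py_run < params$min_py_run)
}

#' Predict splice competence of intron constructs
#'
#' Applies the rule model to a construct table. Rules fire in order:
#' a good pY tract makes the intron autonomous; a poor-pY intron shorter
#' than `autonomous_max_length` is autonomous; otherwise the intron is
#' EJC-dependent when any flanking exon-exon junction places an EJC within
#' `rescue_distance` of the 3' splice site, and defective when none does.
#'
#' Junction distances are given on the pre-mRNA from the flanking exon-exon
#' junction to the target intron's 3' splice site; the EJC sits `ejc_offset`
#' nt upstream of that junction, so the effective deposition distance is
#' `distance - ejc_offset` for a downstream junction and
#' `distance + ejc_offset` for an upstream one.
#'
#' @param constructs Tibble with columns `construct_id`, `length` (nt),
#'   `py` ("good"/"poor"), and optional list-columns `junction_side`
#'   (character vectors of "upstream"/"downstream") and `junction_distance`
#'   (numeric vectors, nt), one element per flanking junction.
#' @param params [splice_rule_params()].
#' @return Tibble `construct_id`, `verdict` (AUTONOMOUS, EJC_DEPENDENT,
#'   DEFECTIVE), `rule_fired`.
#' @export
predict_splice_competence <- function(constructs, params = splice_rule_params()) {
  constructs <- as_tibble(constructs)
  check_columns(constructs, c("construct_id", "length", "py"), "constructs")
  if (!all(constructs$py %in% c("good", "poor"))) {
    abort_data("construct py status must be 'good' or 'poor'")
  }
  has_junc <- all(c("junction_side", "junction_distance") %in% names(constructs))
  one <- function(i) {
    len <- constructs$length[i]
    py <- constructs$py[i]
    if (py == "good") return(c("AUTONOMOUS", "good_pY"))
    if (len < params$autonomous_max_length) return(c("AUTONOMOUS", "short_intron"))
    if (has_junc) {
      sides <- constructs$junction_side[[i]]
      dists <- constructs$junction_distance[[i]]
      if (length(sides) != length(dists)) {
        abort_data("construct %s: junction_side and junction_distance differ in length",
                   constructs$construct_id[i])
      }
      if (any(dists < 0)) abort_data("junction distances must be non-negative")
      if (length(sides) > 0) {
        eff <- ifelse(sides == "downstream",
                      pmax(dists - params$ejc_offset, 0),
                      dists + params$ejc_offset)
        if (any(eff <= params$rescue_distance)) {
          return(c("EJC_DEPENDENT", "ejc_rescue"))
        }
      }
    }
    c("DEFECTIVE", "no_rescue")
  }
  res <- vapply(seq_len(nrow(constructs)), one, character(2))
  tibble(construct_id = constructs$construct_id,
         verdict = res[1, ], rule_fired = res[2, ])
}

#' Read a construct description table
#'
#' TSV with columns `construct_id`, `length`, `py`, and optional
#' `junction_side`/`junction_distance` holding comma-separated per-junction
#' values (empty for an isolated intron). A YAML file with a `constructs`
#' list of the same fields is accepted too.
#'
#' @param path TSV or YAML (.yml/.yaml) file.
#' @return Constructs tibble suitable for [predict_splice_competence()].
#' @export
read_constructs <- function(path) {
  if (!file.exists(path)) abort_data("construct file not found: %s", path)
  if (grepl("\\.ya?ml$", path)) {
    y <- yaml::read_yaml(path)$constructs
    if (is.null(y)) abort_data("YAML construct file needs a top-level 'constructs' list")
    df <- purrr::map_dfr(y, function(cc) {
      tibble(construct_id = cc$construct_id, length = as.numeric(cc$length),
             py = cc$py,
             junction_side = list(as.character(cc$junction_side %||% character(0))),
             junction_distance = list(as.numeric(cc$junction_distance %||% numeric(0))))
    })
    return(df)
  }
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  check_columns(raw, c("construct_id", "length", "py"), "construct file")
  split_field <- function(x, conv) {
    purrr::map(x, function(v) {
      if (is.na(v) || v == "") return(conv(character(0)))
      conv(strsplit(v, ",", fixed = TRUE)[[1]])
    })
  }
  out <- tibble(construct_id = raw$construct_id,
                length = as.numeric(raw$length), py = raw$py)
  out$junction_side <- if ("junction_side" %in% names(raw)) {
    split_field(raw$junction_side, as.character)
  } else rep(list(character(0)), nrow(raw))
  out$junction_distance <- if ("junction_distance" %in% names(raw)) {
    split_field(raw$junction_distance, as.numeric)
  } else rep(list(numeric(0)), nrow(raw))
  out
}

#' The published shortened piwi intron4 construct sequences
#'
#' Returns the two shortened Drosophila melanogaster piwi intron4 variants
#' used as worked examples: each was built by fusing a donor-side and an
#' acceptor-side fragment of the wild-type intron (internal deletion). The
#' concatenated sequences are 60 and 106 nt, start with the canonical GT
#' donor and end with the AG acceptor, and both lack a good pY tract.
#'
#' @return Tibble `construct_id`, `fragment_5p`, `fragment_3p`, `sequence`,
#'   `length`.
#' @export
piwi_int4_constructs <- function() {
  path <- system.file("extdata", "piwi_int4_fragments.tsv", package = "intronret")
  frags <- readr::read_tsv(path, show_col_types = FALSE)
  frags |>
    mutate(sequence = paste0(.data$fragment_5p, .data$fragment_3p),
           length = nchar(.data$sequence))
}
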