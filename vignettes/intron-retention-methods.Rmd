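---
title: "Methods: quantifying differential intron retention and rule-based splice competence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying differential intron retention and rule-based splice competence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intronret)
```

This vignette is the package's own account of its methods: the retention
model and its assumptions, the rule-based splice-competence model, the
statistical conventions, what the synthetic-data generator does and does
not emulate, and the design choices made where the design was genuinely
open.

## The retention model

The unit of analysis is the intron of a transcript model. An annotation
(GTF, Ensembl dialect) is read into 0-based half-open coordinates;
introns are the gaps between consecutive exons, numbered 1..n−1 in
transcript orientation, each carrying its neighbours' lengths and its
sequence in transcript orientation (donor GT … acceptor AG). Abutting
exon records are treated as no intron, with a warning, because real
annotations contain them. Introns with identical genomic coordinates
shared by isoforms of one gene are deduplicated to the isoform with the
highest control-condition expression (ties broken lexicographically) so
that one physical intron enters the group statistics once. How shared
introns should be attributed is genuinely open — annotations do not say —
and attaching them to the dominant isoform is the choice that best matches
what the reads actually sampled.

Counting is asymmetric by design. A fragment increments a transcript's
exonic count only when every aligned block of every mate lies within the
transcript's exons **and** every junction in the read matches an intron of
the exon chain exactly (block compatibility, computed with
`GenomicAlignments::findCompatibleOverlaps`; the package enforces strand
match separately because that encoding is strand-blind). A fragment
increments an intron's count when any aligned base overlaps the intron
interval. The asymmetry is deliberate: intronic signal is the quantity of
interest, and a single overlapping base is unambiguous evidence of
retention, whereas an exonic count should not be contaminated by reads
that straddle an exon boundary. Only uniquely aligned fragments count
(`n_hits == 1` in the tabular read format, a mapping-quality cutoff for
SAM/BAM input), and a fragment counts at most once per feature.

Both feature classes are normalized as RPKM — count / (feature length in
kb × library size in millions), with library size the number of uniquely
aligned fragments. The **retention index** of an intron in a condition is
its RPKM divided by its transcript's exonic RPKM, after averaging
replicate RPKMs arithmetically within the condition. The arithmetic mean
is the simplest symmetric way to combine biological duplicates; computing
per-replicate indices first and averaging those gives more weight to
noisy low-coverage replicates and was not used.

Analysis filters: a transcript enters the analysis when its mean control
RPKM exceeds 10 (strictly); an intron enters when its parent passes and
its RPKM exceeds 10% of the transcript's RPKM in the same sample for at
least one replicate. By default "at least one replicate" ranges over all
samples (`scope = "any_sample"`), which is the literal reading of
"any of biological duplicates" when knockdown samples exist; a
control-only scope is available because the narrower reading is also
defensible.

Fold changes use a pseudo-count: `fold = (IRI_kd + ε)/(IRI_ctrl + ε)` with
ε = 0.01, keeping fully spliced control introns finite. An intron is
flagged *affected* when any knockdown's fold lies within [2, 10]; the
upper cap is part of the definition (extreme ratios at tiny denominators
are usually artefacts of near-zero control indices), and both bounds are
configurable.

## Architecture groups and tests

Groups (not mutually exclusive): `first` (ordinal 1);
`first_before_large_second` (ordinal 1 with a > 2 kb second intron);
`internal_after_large` / `internal_before_large` (internal introns whose
immediately preceding/following intron is > 2 kb); `large` (> 2 kb
itself); `in_transcript_with_huge_intron` (any intron of the transcript
> 10 kb); `poor_py` (no run of ≥ 7 pyrimidines within the intron's last
50 nt). Classification should be run on a transcript's complete intron
table — the transcript-level label needs all introns — and the analyzed
subset is selected afterwards through the fold-change table.

Each group is compared against **all analyzed non-member introns** with a
two-sided Wilcoxon rank-sum test on the retention fold changes, and the
group median fold is reported alongside. The complement as comparison set
keeps the contrast symmetric and mirrors the usual box-plot presentation
of such analyses. `stats::wilcox.test` supplies the machinery: the exact
null distribution for small untied samples (which is what makes the
small-sample p-values match full enumeration), a tie-corrected normal
approximation with continuity correction otherwise. One degenerate case
is special-cased: when every observation in both groups is identical the
rank-sum variance is zero and the two distributions are indistinguishable,
so p = 1. P-values are reported raw, as is conventional for this kind of
exploratory group analysis; Benjamini–Hochberg adjustment is available
but off by default.

The transcript-level analysis bins every analyzed multi-intron transcript
by its largest intron — (0, 0.5], (0.5, 2], (2, 10], (10, ∞) kb, right
edges closed so a 2,000-nt largest intron falls in the second bin — and
tests each bin's transcript RPKM fold changes (same ε rule) against all
other analyzed transcripts with the same rank-sum machinery.

## The splice-competence rule model

The model condenses intron behaviour into three constants plus a
geometry rule, all configurable via `splice_rule_params()`:

| parameter | default | meaning |
|---|---|---|
| `min_py_run` | 7 nt | pyrimidine run length defining a good pY tract |
| `py_window` | 50 nt | 3′-terminal window scanned for the run |
| `autonomous_max_length` | 90 nt | poor-pY introns shorter than this splice unaided (strict <) |
| `ejc_offset` | 24 nt | EJC deposition point upstream of an exon–exon junction |
| `rescue_distance` | 250 nt | maximum EJC-to-3′ss distance for rescue |

Rules fire in order: good pY → AUTONOMOUS; poor pY and length < 90 nt →
AUTONOMOUS; otherwise EJC_DEPENDENT if any flanking junction deposits an
EJC within `rescue_distance` of the target 3′ splice site, else
DEFECTIVE. The scanned window includes the terminal AG (the G breaks any
run, so the effect is negligible, and including it keeps the definition
simple). `N` breaks a run; non-ACGTN characters are an error rather than
silently ignored.

Construct files give, per flanking junction, the pre-mRNA distance from
the exon–exon junction to the target intron's 3′ splice site; the package
applies the deposition offset internally (−24 nt for a downstream
junction, whose EJC sits between the junction and the target; +24 nt for
an upstream junction, whose EJC sits further away). A 200-nt downstream
exon spacer therefore yields an effective deposition distance of 176 nt
(rescued), while 500- and 900-nt spacers yield 476 and 876 nt (not
rescued).

One geometric corner is knowingly tight: rescue of a ~235-nt intron by an
*upstream* junction requires 24 + exon + 235 nt ≤ rescue distance, which a
literal 250-nt threshold cannot satisfy for any positive exon length.
Observed upstream rescue of such introns implies either a softer distance
threshold or a different effective geometry for upstream deposition; the
package keeps the literal rule, exposes `rescue_distance` as a parameter,
and does not tune it silently.

## The synthetic-data generator

`simulation_config()` defaults emulate the targeted study design: a
control plus two knockdown conditions, two biological replicates each,
50-nt strand-specific single-end reads, and 10^6 expected fragments per
sample — a 10–20M-read library scaled to the 200-gene default gene count.
Genes carry 2–8 exons; exon and baseline intron lengths are lognormal
(medians ~300 nt, exons ≥ 100 nt, introns ≥ 62 nt so the engineered
3′-terminal window always fits); 15% of introns are planted large
(2–8 kb) and 3% huge (10–20 kb) so the architecture groups are populated;
20% of introns are synthesized with a poor pY tract (a purine forced at
every 7th position of the 3′ window makes a ≥ 7 run impossible — a
construction guarantee, not a probabilistic one). Transcript abundances
are lognormal (median 30, sdlog 1) and shared across conditions unless
edited; baseline retention fractions r are Beta(1.5, 30) — most introns
nearly fully spliced, as in real libraries — and a planted effect
multiplies r in the knockdown conditions for one group, clipped at 1.

Expected fragment counts are proportional to abundance × feature length
(× r for introns), with placements uniform over the eligible start
positions: uniform on the mature transcript for exonic fragments
(projected to genomic blocks across junctions), uniform over the
single-block genomic placements overlapping the intron for intronic
fragments. Making counts proportional to length — rather than to the
number of eligible start positions, length + L − 1 — is a deliberate
choice: it makes the RPKM-ratio retention index an unbiased estimator of
the planted r, whereas edge-position inflation would bias short introns
upward by a factor ≈ 1 + (L−1)/length. Count noise is Poisson by default;
a negative-binomial option (dispersion 0.1) stresses the rank-sum test
under overdispersion. `simulate_counts()` is a count-level fast path with
the identical count distribution (and, by construction, identical draws
under the same seed) used for replicated power studies;
`simulate_reads()` materializes the placements and exercises the full
counting machinery. A fixed seed yields byte-identical outputs; every
stream (per condition and replicate) derives its seed deterministically
from the base seed.

What the generator does **not** emulate: retention is drawn independently
per intron, not per pre-mRNA molecule, so within-molecule correlation of
retained introns is absent; there are no sequencing errors, quality
scores, alignment artefacts, multimapping reads, isoform mixtures, or
positional coverage biases. Passing tests therefore demonstrate that the
estimator and tests recover a planted signal under idealized sampling
noise — they bound implementation error, not the biases real libraries
add.

## Numerical choices and problem sizes

* Retention-index recovery is checked at 200 genes, 2 conditions × 2
  replicates, 10^6 fragments per sample, regressing estimates on truth;
  the slope is required within 1 ± 0.1. At these depths the Poisson noise
  on a typical intron's index is a few percent.
* Power of the group test is checked over 20 seeded count-level
  simulations of 1,000 genes with a 3× effect planted in
  `first_before_large_second` (≥ 50 analyzed members against ≥ 500
  analyzed background introns per run); the 1,000-gene size is what makes
  those membership counts hold after the 10% filter at baseline
  Beta(1.5, 30) retention. Type-I behaviour is checked by 200 null draws
  (60 members vs 600 background from one lognormal fold distribution)
  against uniformity with a Kolmogorov–Smirnov test.
* Small-sample correctness of the rank-sum p-values is checked by full
  enumeration of every member/background split with total n ≤ 8.
* Degenerate inputs: empty groups produce a status row rather than an
  error; all-tied folds give p = 1; zero library sizes, zero-length
  features, and transcript RPKM of zero at index time are hard errors;
  reads on unannotated chromosomes are skipped with a warning.

## Known limitations

The pipeline quantifies retention only — no junction-level
percent-spliced-in, no exon-skipping calls, no isoform deconvolution; a
transcript's exonic RPKM mixes isoforms when several overlap. The
rule-based competence model is a coarse screen: it ignores branch-point
strength, splice-site scores and RNA structure, and its constants are
step functions where biology is graded. The generator's independence
assumptions mean pipeline validation should be read as a correctness
check of the computation, not as evidence about any particular biological
library.
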