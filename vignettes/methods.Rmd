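---
title: "Methods: footprint quantification, offset calibration and binned z-score differential translation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: footprint quantification, offset calibration and binned z-score differential translation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribotally)
```

# Scope and data model

`ribotally` consumes transcriptome-aligned ribosome profiling (and matched
RNA-Seq) alignments; adapter trimming, rRNA depletion and the alignment
itself are upstream concerns for standard tools. Everything downstream runs
in **transcript coordinates**: 1-based, inclusive, position 1 is the first
transcript nucleotide. `cds_start` is the first nucleotide of the start
codon, `cds_stop` the first nucleotide of the stop codon, so the translated
span excluding the stop codon is `[cds_start, cds_stop - 1]` and
`(cds_stop - cds_start) mod 3 = 0` for any valid annotation.

The central container is the end-count store: a tibble of counts keyed by
(transcript, read length, position, end, ambiguity). Storing both read ends
per alignment costs a factor of two but makes 5′- and 3′-based offset
calibration, and their cross-validation, symmetric and cheap. The invariant
"sum of 5′ counts = sum of 3′ counts = retained reads" is asserted
throughout and is the backbone of the conservation tests.

## GTF stop-codon conventions

GTF dialects disagree on whether CDS features include the stop codon
(Gencode excludes it). Both conventions produce CDS feature lengths
divisible by three, so no arithmetic can distinguish them. `read_reference()`
therefore checks the transcript sequence: if the codon immediately after the
projected CDS end is a stop codon the convention is "excluded", if the last
projected codon is a stop codon it is "included"; when neither matches (rare
annotation defects) the Gencode convention is assumed. Transcripts whose CDS
length is not a multiple of three, or whose CDS cannot be projected through
the exon chain, are demoted to non-coding with a warning rather than
discarded — their sequence is still valid for profiling.

## Ambiguity

A read is *ambiguous* iff the aligner reported more than one alignment for
it (secondary flag, or the same query name at several locations). Each
distinct location is counted once under the ambiguous flag; no fractional
weights are distributed, because any weighting scheme would be a modelling
choice the data cannot justify at this layer. All analyses default to
unambiguous counts with an `ambiguity = "both"` escape hatch.

# Offset calibration

For each read length $L$, the start-codon metagene of 5′ ends shows a peak
$d_5(L)$ nt upstream of the start codon, produced by initiating ribosomes
whose P-site holds the start codon. The package sets
$\mathrm{offset}_5(L) = d_5(L) + 3$, stepping one codon from P-site to
A-site; symmetrically $\mathrm{offset}_3(L) = d_3(L) - 3$ for the 3′-end
peak downstream. Choices within that rule:

- **Search ranges** are $[-w, -1]$ upstream and $[+1, +w]$ downstream with
  window $w = 100$ nt by default — wide enough to contain the peak for any
  plausible footprint geometry, narrow enough that CDS-internal structure
  does not dominate.
- **Transcript eligibility**: only coding transcripts with at least $w$ nt
  on both sides of the anchor contribute, so every contributing transcript
  covers the whole window and edge effects cannot tilt the peak.
- **Ties** break toward the smallest absolute distance, favouring the
  canonical ~12 nt geometry and making the result deterministic.
- **Degenerate lengths**: a read length whose search range is all zero (or
  whose inferred offset falls outside $[1, L]$) receives a fallback offset
  of 15 nt with a warning — the common default geometry for ~28–31 nt
  footprints. The offset table records `source` per length so fallbacks are
  visible.
- Offsets are inferred from **unambiguous** counts only.

Downstream analyses use A-site positions by default; a `site = "p"` switch
shifts 3 nt upstream for P-site densities, since initiation-focused analyses
prefer the P-site anchor.

# Periodicity QC

Triplet periodicity is computed on **offset-adjusted A-sites** restricted to
`[cds_start, cds_stop - 1]` (the stop codon is excluded: the terminating
ribosome's A-site holds a release factor, not a sense codon, and its dwell
signature would blur the phase measure). Phase is
`(asite - cds_start) mod 3`. A `positions = "raw"` mode phases unadjusted 5′
ends instead, which is useful for judging how much of the phase signal the
offsets themselves contribute. The in-frame fraction `max(f0,f1,f2)/total`
equals the simulator's in-frame probability in expectation, which is what
the calibration tests assert binomially.

# Transcript profiles and frame decomposition

The frame of a position is purely positional: `(position - 1) mod 3`. The
profile's three frame series are the A-site vector masked by frame, so their
sum reconstructs the vector exactly (asserted on every profile). "Dominant
frame" calls are made per codon by `dominant_frames()`, with an optional
odd-width codon-window majority smoother for display; the default is no
smoothing, because smoothing trades boundary precision for visual stability
and the boundary is what nested-ORF detection needs. RNA-Seq comparison
tracks use full-read coverage reconstructed from the 5′ end and read length —
offsets are a ribosome concept and do not apply. Per-million normalization
multiplies each group's vector by $10^6$ divided by its retained-read total.
Read-length filters are applied before summing across lengths.

# Differential expression

Counts per transcript (whole transcript by default, CDS-restricted A-sites
optionally) are compared with the binned z-score transformation:
log ratios $\log_2(B/A)$, geometric means $\sqrt{AB}$, transcripts ranked by
descending geometric mean and partitioned into consecutive bins of 300
(non-overlapping; a sliding-window variant would correlate neighbouring
z-scores and complicate calibration), z-scores standardized within bins
using the unbiased (n−1) standard deviation. Numerical choices:

- Transcripts with a raw count below `min_count = 1` in either condition are
  excluded; zeros would make ratios infinite and a pseudocount would bias
  bin statistics silently. A `pseudocount` option exists for users who
  prefer to keep zeros.
- A final partial bin with fewer than 30 transcripts is merged into its
  predecessor: standard deviations over a handful of transcripts are too
  unstable to standardize against.
- A bin with zero log-ratio variance (e.g. duplicated inputs) yields z = 0
  with a warning rather than NaN.
- Ties in the geometric-mean ranking break by transcript ID, making the
  partition a deterministic function of the inputs.
- With unequal library sizes, `normalize_totals = TRUE` converts both
  conditions to counts per million before ratios.

Per-bin standardization guarantees mean 0 / sd 1 within each complete bin to
machine precision, and under a Poisson null the flagged fraction at
$|z| \ge 1.96$ matches the two-sided normal tail within binomial error —
both are regression-tested. This method deliberately has no replicate-aware
variance model; it is a ranking and flagging device, not an inference
engine, and users with replicates should confirm candidates with a count
model.

# The simulator

The simulator generates what the analyses assume: transcripts with UTRs
(110–140 nt by default, leaving room for the 100-nt metagene window) flanking
an in-frame ATG…stop CDS of 100–200 sense codons; footprints whose A-site is
drawn over CDS codons with a 5× weight on codon 2 (the initiation peak that
offset calibration reads), phase error applied with probability
$1 - p$ split evenly between +1 and +2 nt, read lengths 25–35 drawn from a
distribution peaked near 29 nt, and the 5′ end placed at A-site −
$\delta(L)$ with $\delta = 12$ nt by default. Two-exon transcripts on both
strands exercise genomic-to-transcript CDS projection. Nested ORFs add
shifted-frame A-site positions at a configurable relative density and are
realized at sequence level (ATG, clean internal codons, stop) by rejection
sampling. Per-transcript RNG streams keep earlier transcripts byte-identical
when the transcriptome grows.

What it does **not** emulate: sequence composition and ligation biases,
nuclease footprint heterogeneity beyond the length distribution, dwell-time
variation across codons, UTR/ncRNA background reads, or alignment error.
Tests passing on simulated data therefore demonstrate that the bookkeeping,
geometry and statistics are correct — not that offsets or periodicity will
be as clean on any given real library.

Differential-expression calibration runs at transcriptome scale use a
count-level Poisson generator (`simulate_de_counts()`: means log-uniform on
[20, 2000], optional spike-ins at a common fold change) rather than
generating millions of reads; the footprint simulator's `fold_changes`
argument covers the read-level path at small scale.

# Problem sizes and determinism

The shipped tests run the full pipeline at 6 transcripts × 20,000–50,000
reads (offset recovery over 5 seeds at 50,000 reads; periodicity at 30,000;
nested-ORF delineation at 40,000 on a single 150-codon transcript;
differential expression at 3,000 transcripts), sizes at which every binomial
tolerance in the tests is a 3σ bound. All randomness flows from explicit
seeds; identical seeds produce byte-identical FASTA/GTF/SAM artifacts.

# Known limitations

- One transcript per profile; gene-level queries return all isoforms and the
  caller chooses (no "principal isoform" heuristic is imposed).
- Genome-space views and intron-retention analysis are out of scope: the
  engine is transcriptome-aligned by design.
- Multimapper weight is never distributed across locations.
- The binned z-score has no dispersion model; replicates are merged, not
  modelled.
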