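---
title: "Methods: nucleosome profiles, slab domains and intron retention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nucleosome profiles, slab domains and intron retention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slabir)
library(dplyr)
```

This vignette is the package's own account of the models and procedures
it implements, the parameters that matter, the design choices made where
the design was genuinely open, and what the simulation-based tests do
and do not show about real data.

## Coordinates and formats

All coordinates are 0-based half-open internally, matching BED/bedGraph
arithmetic. GTF (1-based closed) is converted at the parse/write
boundary only. Tag files are 6-column BED-like text (BED6 or tagAlign;
the strand column is mandatory because the 3′ extension is undefined
without it); coverage is read and written as bedGraph or fixedStep
wiggle. Overlapping bedGraph intervals are an error rather than being
summed: a per-base track with two values at one base is ill-formed, and
quiet repair would hide upstream mistakes.

## Gene models, internal exons, non-overlapping introns

Transcripts are ordered 5′→3′ in transcription direction, so
`exon_index = 1` is the rightmost exon on the minus strand. "mRNA"
denotes every transcript whose biotype is not in the lncRNA label set —
the complement convention, not just protein-coding transcripts.

*Internal* exons (`1 < exon_index < n_exons`) are judged per transcript
and then deduplicated by exact coordinates, keeping the first transcript
id. An exon internal in one isoform but terminal in another is therefore
retained. This is a choice: the alternative (dropping any exon that is
terminal somewhere) discards a large fraction of heavily overlapping
annotations, and the analysis counts exons, not exon–isoform pairs.

Candidate introns are the per-transcript inter-exon gaps; a candidate is
discarded when it overlaps *any* exon of any transcript of any gene,
which is what "non-overlapping introns" means here. The implementation
uses interval trees (IRanges); the test suite checks it against a
brute-force all-pairs scan.

Two boundary rules are fixed once and used everywhere: gap filters are
inclusive ("separated by at least 500 bp" keeps a gap of exactly 500),
and the first-intron length partition assigns ties at the cutoff to the
long (≥) group, for consistency with the gap filter. The GC
stratification splits at the median GC of the input set — the only
parameter-free two-group split; the low group takes `gc < median`.

## Tag extension and metagene profiles

Sequenced nucleosome tags mark fragment ends, and plus/minus tags of the
same nucleosome sit ~150 bp apart, so each tag is extended to 150 bp in
its 3′ direction (`+`: `[start, start+150)`; `−`: `[end−150, end)`,
clipped at chromosome ends). The minus-strand rule anchors at the tag's
recorded end — the standard reading of "3′ extension" for BED-recorded
reads.

A profile window covers 500 bp of intronic flank plus 80 bp of exon edge
(580 positions), oriented in transcription direction. The density at
position *i* is

$$\mathrm{density}_i = \frac{\sum_{w} \mathrm{cov}(w_i)}{n_{\mathrm{windows}}\; (L/10^6)}$$

with *L* the library tag count: mean per-window coverage in
counts-per-million. The scale is a convention (the quantities of
interest are ratios); per-window and per-depth normalization are what
make libraries and exon sets comparable. Exons shorter than 80 bp, and
windows leaving the chromosome, are excluded per side rather than
zero-padded — padding would deflate densities, and per-side exclusion is
why upstream and downstream window counts differ.

Exonic enrichment is `100·(mean over all 160 exonic positions / mean
over all 1000 intronic positions − 1)`, pooling the upstream and
downstream profiles of the same exon set. Defining it on window means
(rather than peak heights) is our operationalization; it is stable at
realistic library sizes. Profile windows deliberately take the genomic
flank even when it overlaps a neighbouring exon; the isolation filter
(`filter_isolated_exons`, ≥ 500 bp to both neighbours) is the variant
analysis that removes such contamination, and enrichment measurements in
the tests use it.

## Slab detection

A slab is a maximal run of bases with signal ≥ threshold, merged across
sub-threshold gaps ≤ `max_gap` (default 100 bp, linker scale — MNase
sampling leaves short gaps inside genuinely contiguous domains), kept
when the merged length is ≥ `min_length` (default 1 kb: several marked
nucleosomes clustered, not a point peak).

The threshold is a required parameter because "high signal" depends on
the library's units. Two helpers are provided:

* `track_quantile(track, q = 0.99)` — an upper quantile of nonzero
  values, the natural "saturating signal" reading.
* `slab_threshold(track)` — the geometric midpoint between the median
  nonzero value (typical background) and the 0.999 quantile (saturating
  signal). This is the orchestration default, for a concrete reason: a
  single upper quantile falls *inside* the slab signal distribution as
  soon as slabs cover more than that quantile's tail fraction of the
  covered genome (at 3% slab coverage a 0.99 quantile sits mid-slab and
  fragments every call). The midpoint rule is insensitive to the slab
  fraction because it anchors on both ends of the signal mixture.

Slab calls are strandless; region annotation uses half-open overlap with
a 1 bp minimum, so a slab ending exactly where a region starts does not
count.

## Intron retention

The per-intron score is
`SIR = d_i / (d_i + (d_u + d_d)/2)` where `d_i` is the mean per-base
RNA-seq depth over the intron and `d_u`, `d_d` over its two flanking
exons (the exons at ordinals `k` and `k+1` of the intron's source
transcript). It is bounded in [0, 1], zero exactly when the intron has
no coverage, and invariant to rescaling the whole track — sequencing
depth cancels. Downstream analysis uses only the dichotomy `SIR > 0`
("any level of retention"). An optional `min_depth` floor (default 0)
lets noisy libraries require more than spurious single-read coverage
before calling retention; the default reproduces the strict rule.
RNA-seq input is a coverage track; junction-read evidence is outside
scope, so the score is declared coverage-only.

## Association statistics

The slab × retention table is tested with the plain Pearson chi-squared
statistic, **without** Yates continuity correction, on 1 df. This is the
single most consequential numerical choice in the module: on the table
(57, 10, 52, 81) the uncorrected statistic is 37.98 with p ≈ 7×10⁻¹⁰,
while the corrected one gives ≈ 2×10⁻⁹. For 2×2 tables the statistic
equals `n(ad−bc)²/((a+b)(c+d)(a+c)(b+d))`, which the tests use as a
closed-form oracle, alongside `chisq.test(correct = FALSE)` and a
seeded permutation null as independent cross-checks. Concordance is the
agreement fraction `(n₁₁ + n₂₂)/n`. "Standard error" in the group
summaries is the sample `sd/√n`. Degenerate tables with a zero margin
report concordance with an `NA` statistic and a warning rather than
failing, since agreement is still well defined.

## The synthetic-data generator

The generator is first-class, tested code. It emulates the statistical
structure the analysis assumes, with defaults fixed once as the study
conditions:

* **Genes.** 200 lncRNA + 50 mRNA multi-exonic genes (3–6 exons) packed
  without overlap on two 3 Mb chromosomes, random strands. Exons are
  140–160 bp — the mononucleosome scale on which internal exons sit,
  which is precisely the phenomenon under study. Introns are log-normal:
  retained ones median 192 bp, other lncRNA introns median 2181 bp, mRNA
  introns median 6 kb.
* **Surveyed regions and labels.** Each surveyed gene contributes one
  exon–intron–exon block. Its joint (M, IR) state is drawn with
  probabilities 57:10:52:81 / 200; the surveyed intron is the first
  intron with probability 73/109 given IR and 24/91 given no IR; its
  length comes from the retained (short) or non-retained (long)
  distribution according to the IR label. Because per-class intron
  lengths are conditional on the retention label, labels are assigned
  during gene-model simulation and recorded in the truth table, which
  the tag and RNA simulators then honour — the one place the generator's
  stage order deviates from a strictly sequential design.
* **Tag libraries.** Tags are 25 bp reads whose 150 bp 3′ extension
  reconstructs a footprint. Background footprints are centred uniformly
  over the genome; slab-level intensity (default 20×) is overlaid
  uniformly over M-positive surveyed introns ± 900 bp (total ≥ 1 kb
  comfortably). The exonic excess (enrichment factor 1.28) is modelled
  as nucleosome-positioned footprints centred on each exon rather than
  as centre-sampled intensity: centre-sampling convolves any density
  step over ± 75 bp, which would smear most of an 80 bp exon edge and
  make a programmed 1.28-fold contrast measure as ~20%; positioned
  footprints on nucleosome-sized exons realise the step sharply, so the
  measured window-mean enrichment matches the programmed factor to
  within sampling error (± ~1 percentage point at 10⁵ tags).
* **RNA coverage.** Constant exonic depth per gene (uniform 10–50);
  retained introns get 0.3× that depth, non-retained introns exactly
  zero, so truth recovery by the classifier is exact by construction.
  `poisson = TRUE` and `noise_rate` add per-base Poisson sampling and
  spurious background for robustness tests.

What the generator does **not** emulate: phased nucleosome periodicity,
MNase sequence bias, duplicate reads, isoform-level expression, junction
reads, mappability gaps, and the heavy isoform overlap of real
annotations. Tests passing on these fixtures therefore establish that
the code computes its definitions correctly and recovers programmed
contrasts at realistic sampling depth — not that the biological effect
sizes would be recovered from any particular real library.

## Problem sizes and runtime choices

The default simulated conditions are 250 genes on 6 Mb with 10⁵-tag
libraries — large enough that window-mean sampling error on the
enrichment is well under one percentage point, small enough that the
whole pipeline runs in seconds. The oracle-equivalence property for the
slab caller uses 200 random step tracks of 10⁵ bp; the association
recovery property uses 100 seeded replicates of 200-region label draws
(the track stages are deterministic given the labels and are exercised
end-to-end once). Retention robustness is checked at 20× exon depth
with Poisson noise and a 0.5 mean-depth floor.

## Known limitations

* The annotation module resolves isoform-ambiguous internal/terminal
  exons per transcript before deduplication; other resolutions are
  defensible and would change exon counts (though not the profile
  definitions).
* The retention score uses coverage only; a junction-aware score would
  discriminate retention from overlapping transcription.
* Slab calling has no input/control normalization or replicate
  reconciliation; the threshold helpers assume a background/high-signal
  mixture with a real gap between the modes.
* bigWig input/output is not supported; convert to bedGraph upstream.
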