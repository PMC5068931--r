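---
title: "Evaluating de novo transcriptome assemblies with transeval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating de novo transcriptome assemblies with transeval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transeval)
library(dplyr)
```

## The problem

A de novo transcriptome assembly — for a non-model plant with no reference
genome, say — cannot be judged against a genome. The practical alternative is
a battery of internal and reference-based metrics computed from the contigs
themselves and from alignments of the contigs to curated ortholog or protein
sets: how long are the contigs (N50), how much of the contig set is pure
redundancy, what fraction of known conserved transcripts is recovered, in how
many pieces, and how often has the assembler glued unrelated transcripts into
one chimeric contig. transeval implements this battery, together with the
expression-quantification arithmetic that typically accompanies such a
project: FPKM normalization of fragment counts, efficiency-corrected relative
RT-qPCR quantification, and pairwise Ka/Ks for diverged coding sequences.

All user-facing functions take plain tibbles and return tibbles, so a whole
evaluation composes with dplyr verbs; fitted objects (calibration curves,
Ka/Ks results, evaluation reports) carry `tidy()`/`glance()` methods and
`autoplot()`/`plot_*()` graphics.

## Length statistics and redundancy

`length_stats()` reports contig counts, total and mean length, and N50 — the
largest length L such that contigs of at least L still hold half of all
assembled bases. The mean length is rounded to whole bases, matching how
such tables are conventionally printed.

Redundancy removal (`deduplicate()`) follows the contract of CD-HIT-style
clustering at 100% identity: a contig is redundant when its sequence is
identical to, or an exact substring of, another retained contig *on either
strand*. Within a redundancy cluster the longest sequence is kept; equal
lengths are broken by the lexicographically smallest id so the result is
deterministic. We deliberately model the *contract* (no retained contig
identical to or contained in another) rather than any particular clustering
tool's index parameters such as word size: the nonredundant count is what the
comparison tables measure, and the contract is testable against a naive
quadratic scan, which the test suite does on hundreds of random sets.

The implementation scans candidates in decreasing length order against the
concatenation of already-kept sequences with a separator character, so a
match can never span two contigs. This is quadratic in total bases in the
worst case but fast at the set sizes where exact dedup is used in practice.

## Reference-based metrics

All reference-based metrics start from a 12-column tabular hit table (the
standard BLAST-style tabular output dialect). Coordinates are converted
*once*, in `normalize_hits()`, from the 1-based inclusive convention (with
reverse subject orientation encoded as `s_start > s_end`) to 0-based
half-open forward-strand intervals. Every downstream computation consumes
the normalized columns, which removes the usual source of off-by-one drift.

Coverage is always measured on the subject (reference) axis. Overlapping
HSPs are **union-merged, never summed** — summed coverage can exceed the
reference length and double-counts rearranged hits — and fractions are
capped at 1.

* **Ortholog Hit Ratio (OHR)**: for each contig, the fraction of its best
  reference subject covered by the union of that contig-subject pair's
  intervals. "Best" is the subject with the highest summed bitscore (ties:
  lowest evalue, then lexicographic subject id) — the standard ranking when
  no explicit selection rule is given. An OHR near 1 means the transcript
  was assembled to full length.
* **Completeness at threshold t**: the percentage of *expressed* reference
  transcripts whose union coverage by all contigs is at least t.
* **Contiguity at threshold t**: the same percentage, but using the single
  best-covering contig per reference.

Thresholds are compared inclusively (`>=`): "80%" columns mean *at least*
80% covered. Because a single contig's intervals are a subset of all
contigs' intervals, contiguity can never exceed completeness, and both are
non-increasing in the threshold; these two laws are enforced as
property-style tests at every threshold.

The "expressed" denominator deserves a note: it is under-determined by hit
tables alone, so it is a caller-supplied set, defaulting to every reference
hit by *any* assembly under comparison. Computing it once across all
assemblies (as `evaluate_assemblies()` does) keeps the denominators — and
therefore the rows of a comparison table — commensurable.

## Chimera detection

A chimeric contig joins pieces that do not belong together: parts of two
different transcripts (*trans*), or a duplicated/inverted region of one
transcript (*self*). Detection works on each contig's hit table:

1. Hits are filtered (`min_identity`, default 30%, permissive enough for
   cross-species protein hits; `min_seg_len`, default 100 query units).
2. Hits to the same subject in the same orientation are chained into
   segments when the subject interval progresses with the query — a
   collinear multi-HSP structure is one segment, never a chimera signal.
3. Adjacent segments that are query-disjoint (overlap at most
   `max_q_overlap`, default 60) are evidence of a join: different subjects
   give a *trans* call; the same subject with mutually overlapping subject
   intervals (fraction at least `min_self_overlap`, default 0.2) or
   opposite orientations gives a *self* call.

The breakpoint is placed at the midpoint of the query gap between the
offending segments; a zero gap puts it exactly at the boundary. Without
per-base evidence inside the gap, the midpoint minimizes the worst-case
error, which is therefore at most half the gap. `cut_chimeras()` replaces
each called contig by its pieces (`_part1..k`), conserving total bases.

These thresholds are configuration, not claims: the cited class of methods
does not fix universal values, so the defaults are chosen to be robust on
idealized alignments, every one is overridable through `chimera_params()`,
and all quantitative tests run on synthetic data where the planted truth is
threshold-robust. The chimera *percentage* divides by the **nonredundant**
contig count — the only denominator consistent with published comparison
tables that report both counts. Whether self-chimeras should be included in
a headline percentage is genuinely ambiguous in the literature; transeval
reports the kinds separately in its calls table and sums them by default.

## qPCR quantification

Amplification efficiency is estimated per gene from a serial-dilution
calibration curve: ordinary least squares of Cp on log10(dilution), with
`efficiency = 10^(-1/slope)` (fold per cycle; 2 is perfect doubling, giving
the textbook slope of −3.3219). Curves with non-negative slope are flagged
invalid, and efficiencies above 2.2 draw a warning since chemistry cannot
meaningfully exceed doubling.

Relative expression uses the efficiency-corrected ratio

\[
\mathrm{ratio} = \frac{E_R^{\,Cp_R}}{E_T^{\,Cp_T}}
\]

computed in log space. Replicate aggregation follows the physical structure
of the experiment: technical replicates are averaged on the Cp scale within
each reverse-transcription (RT) replicate; one ratio is formed per RT
replicate against the reference gene's Cp *from the same sample, run and RT
replicate*, so cDNA-load variation cancels inside the physical specimen;
the mean and sd across RT replicates are reported. The aggregation order is
not dictated by the ratio formula itself; this pairing-first order was
chosen because it is the one that makes the cDNA load drop out.

Run-to-run variation is treated as a multiplicative effect on the ratio
(equivalently, an additive Cp offset): a calibrator sample measured in every
run rescales each run's ratios to a chosen baseline run
(`calibrator_normalize()`). When the reference gene is unusable (dry/imbibed
seeds with negligible actin expression), `cdna_rescale()` bridges
cDNA-normalized ratios into the reference-gene scale with the geometric mean
of `actin_value / cdna_value` over samples measured both ways — a deliberate
minimal reading of "recalculation with regard to actin-normalized samples",
since no formula for it is in circulation; the bridge contract (a single
positive per-dataset scale factor) is the part that is testable.

FPKM is the plain definition
`fragments / ((length/10^3) * (mapped/10^6))`, with raw transcript length by
default — effective lengths can be supplied as the length column where a
caller prefers them.

## Ka/Ks

`kaks()` implements the counting method of Nei and Gojobori with equal
pathway weighting and Jukes–Cantor correction — the standard default of the
popular desktop tools for pairwise CDS comparisons. Per codon, each position
contributes the fraction of its three possible changes that are synonymous
to the synonymous site count (S), the rest to N, so S + N = 3 per codon.
Differences between a codon pair are classified along all minimal mutational
pathways, averaged with equal weights; pathways through stop codons are
excluded. Two conventions had to be fixed:

* changes *to* stop codons count as nonsynonymous in site counting (the
  alternative, excluding them from the denominator, is available via
  `stop_handling = "exclude"`; both keep S + N = 3);
* if *every* pathway between a codon pair passes through a stop (possible
  only at 2–3 differences, and rare), the pair falls back to averaging over
  all pathways rather than being silently dropped.

Codons containing gaps or ambiguity characters in either sequence, and pairs
involving stop codons, are removed pairwise before counting. Proportions
pS = Sd/S and pN = Nd/N are corrected as d = −(3/4)·ln(1 − (4/3)p); the
correction is undefined at p ≥ 3/4 and the ratio at Ks = 0, both flagged as
`NA` rather than guessed. The implementation is checked against an
independent brute-force oracle (exhaustive pathway enumeration) to 1e-9 on
random codon pairs.

## What the generators emulate — and what they do not

`simulate_reference()` + `simulate_assembly()` produce a reference set and a
contig set *with attached ground truth*: per-reference designed union and
best-single-contig coverage (realized exactly, in whole bases, and recorded
as realized), planted exact/contained/reverse-complement duplicates, and
planted trans/self chimeras with true breakpoints. The emitted hit table is
an exact image of the construction — every interval corresponds to the
matching substring, which `validate_sim_hits()` verifies. Chimera parts are
drawn from *uncovered* reference regions where possible, so planting
chimeras perturbs neither the coverage truth nor the dedup truth.

Idealized hits (identity 100, no spurious alignments) are the default
because they separate algorithmic correctness from robustness. The `noise`
option adds downward identity jitter, interval trimming (bounded so planted
segments stay above the detection floor), and decoy hits below the identity
threshold. What the generators do **not** model: sequencing errors and
read-level coverage variation, alignment heuristics (soft-clipping, spurious
high-identity hits), paralogy, or real codon usage and transition/
transversion bias. Tests passing on this synthetic data therefore
demonstrate that the *computations* are correct and internally consistent —
not that any particular thresholds are optimal on real alignments.

`simulate_qpcr()` uses the model
`Cp = base_cp(gene) + run_offset − log_E(amount) + N(0, sd)`. Per-gene base
Cp values are chosen so that `E_g^{base_cp}` is one shared constant (a
perfect-doubling gene sits at Cp 25) and the first run carries offset 0;
under this calibration convention the efficiency-corrected ratio in the
baseline run equals the designed ratio *exactly*, which is what makes the
noiseless-inversion test exact rather than approximate. Default noise is
sd = 0.15 cycles with two RT and two technical replicates, typical of a
careful plate design.

`simulate_divergent_pair()` plants at most one single-base change per codon,
classified at planting time, so the planted (Sd, Nd) are recovered exactly
by `kaks()`; targets are met up to whole-change rounding.

## Problem sizes and numerical choices

The test suite exercises the metric laws on five seeds of a
1,000-reference / ~20,000-contig synthetic assembly, chimera recovery on ten
seeds of ~1,500-contig assemblies with 5% planted chimeras (recall and
precision are exactly 1 with idealized hits), dedup/N50 oracle agreement on
200 random sets of up to 500 contigs, qPCR ratio recovery over 200 noise
seeds (mean within 10% of truth), and Ka/Ks oracle agreement on 100 random
50-codon pairs at 1e-9. Filler fragments are kept at 25 bases or more so
that chance containment between unrelated random fragments is negligible
and redundancy truth stays exact.

Percentages are rounded half away from zero (`round_half_up()`), chimera
percentages to 2 decimals and pass rates to 1, matching the conventions of
the tables this package is built to reproduce. Interval unions go through
IRanges; the generators' truth-side unions use an independent sort-and-merge
so that truth and implementation never share a code path.

## Known limitations

* Dedup is exact-identity/containment only; clustering at <100% identity is
  out of scope (use a dedicated clusterer and feed its output in).
* Chimera detection cannot distinguish genuine fusion transcripts from
  misassemblies, and its defaults are tuned for translated-search hit
  tables with nucleotide query coordinates.
* `aggregate_sample()` expects the reference gene in every (sample, run,
  RT) combination and errors otherwise, by design — silently dropping
  unmatched replicates would bias ratios.
* Ka/Ks is the pairwise counting estimator; maximum-likelihood codon models
  and sliding-window scans are out of scope.
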