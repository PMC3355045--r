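---
title: "Methods: discriminative sequence words, OPLS-DA and motif assembly for MSL targeting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discriminative sequence words, OPLS-DA and motif assembly for MSL targeting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the statistical machinery it
implements: the word-frequency model and its normalizations, the OPLS-DA
discriminant analysis, the iterative word-to-PWM motif assembler, the tiling
signal analytics, and the synthetic-data generator that makes all of it
testable. It also records the numerical conventions and the genuinely open
design choices, so a maintainer can see which behaviour is principled and
which is a documented convention.

## The word-frequency model

A *sequence word* is a DNA k-mer with 2 ≤ k ≤ 6. Every window of width k,
sliding one nucleotide at a time, contributes one count; a word and its
reverse complement are treated as one because hybridization-based data and
double-stranded binding have no strand identity. Frequencies divide the
merged count by the full sequence length L (not L − k + 1) — a deliberate
convention kept uniform across k so frequencies of different word lengths
share one denominator. Windows containing N are skipped while the
denominator keeps the full length; this keeps frequencies comparable across
sequences with sparse masked bases (relevant after motif masking, which
writes Ns).

Two matrix layouts are provided. The `as_published` layout carries one
column per literal word (16 + 64 + 256 + 1024 + 4096 = 5456 columns for
k = 2..6), with a word and its complement holding identical merged values.
The `canonical` layout keeps one column per complement-equivalence class
(2770 columns). The layouts are related by a column duplication: weighting
each duplicated pair by 1/√2 makes the two Gram matrices — and hence all
PCA/OPLS-DA scores — identical up to sign, which the test suite verifies.
The published layout is the default for reproducing the 5456-variable
matrix; the canonical layout is used for per-gene modeling where the
duplication only costs memory.

*Pooled observations* (for example "all strong-gene promoters of one arm")
sum the member counts and member lengths. Counting members separately is
exactly equivalent to concatenating them with an N separator — no
junction-spanning word is ever counted — and is how the package implements
it.

### AT-normalization and scaling

AT content dominates raw word frequencies. The normalization divides each
observed frequency by its expectation under independent bases with the
observation's own mononucleotide composition:
`E(w) = Π_i p(base_i)`, merged with the reverse complement's expectation
unless the word is self-complementary. Base probabilities are floored at
1e-6 so degenerate compositions stay finite. No (L − k + 1)/L edge
correction is applied, mirroring the count/L frequency convention.

Scaling follows standard chemometric convention:
AT-normalized ratios are *center-scaled* (mean zero per column; the ratios
are already on a common scale), while raw frequencies are *unit-variance
scaled* (centered and divided by the column standard deviation;
zero-variance columns are set to exactly zero rather than dividing by
zero). The fitted column statistics are stored on the matrix so held-out
observations receive the identical transformation.

## PCA and OPLS-DA

PCA is the singular value decomposition of the scaled matrix; cumulative
explained variance (R2cum) comes from the squared singular values. Loadings
are sign-fixed so the largest-magnitude entry of each component is positive,
making exported word lists stable across runs and platforms.

OPLS-DA separates the class-predictive variation from systematic variation
orthogonal to the class. The implementation is the NIPALS orthogonal
projection: with Y coded +1/−1 and centered, each round computes the PLS
weight `w ∝ X'y`, extracts the loading of its score, removes from it the
part along `w` to get an orthogonal weight, and deflates X by that
orthogonal component; after `n_orth` rounds a single predictive component
is fit (binary Y needs only one). With zero orthogonal components the model
equals single-component PLS, which the tests check against an independent
NIPALS oracle. Prediction applies the stored column scaling, removes the
stored orthogonal components in order, and projects onto the predictive
weight; positive scores mean the positive (strong) class.

Predictive power is the cross-validated `Q2 = 1 − PRESS/SS` over stratified
folds (7 by default), with Y centered on the training folds; values at or
below zero mean no predictive power. When `n_orth = "auto"`, the number of
orthogonal components (0–5) maximizing Q2 is chosen. Permutation and
random-group null analyses deliberately fix `n_orth = 0`: selecting the
component count by maximum Q2 *inside* a null would bias the null Q2
upward, which is the opposite of what a calibration control is for. Column
scaling is computed once on the full training matrix rather than per fold;
this matches the workflow the models emulate and keeps Q2 deterministic
given the fold seed.

The random-group control draws seven disjoint groups of 100 sequences and
fits all 21 pairwise models. On label-free data every pair should produce a
negative Q2; the test suite and the acceptance script verify this, along
with the Spearman correlation of each model's scores with AT content that
flags AT-driven separations.

## The motif assembler

The aligner turns the top-loaded words of an OPLS-DA model into position
weight matrices. The PWM is accumulated in "loading space": each cell holds
the summed loadings of the words aligned over it, and the probability view
renormalizes every position to sum to one. Scoring multiplies the PWM
values of the matching bases at each offset (an N scores zero — there are no
pseudocounts, so a zero cell is a hard mismatch), scans both strands, takes
the better strand per position, and sums the best `best_scores_per_seq`
per-position scores (one, by default).

One iteration ranks every unconsumed word's admissible alignments — both
orientations, every offset sharing at least ⌈word length/2⌉ positions with
the PWM (overhangs extend it), plus one candidate combining the best two
distinct offsets ("up to two simultaneous alignments") — by a cheap
compatibility score: the dot product of the word's letters with the
overlapped PWM columns. The logistic gate is then evaluated on the
`gate_pool` (default 50) most compatible candidates, and the best accepted
candidate extends the PWM. Ranking all words but gating only the pool keeps
the per-iteration cost bounded while every word remains a potential
extension every iteration.

The gate fits `class ~ score` by logistic regression (scores standardized
first; the deviance is invariant to that) and accepts an update only when
(i) the candidate's score is significant against the intercept-only model
by a likelihood-ratio test at `improvement_alpha` (0.05), and (ii) the
candidate's deviance improves on the current PWM's by at least the
χ²₁ quantile at the same level. Requiring a *significant* deviance drop —
not merely a numerically lower one — is the package's reading of
"predictive improvement": with any-decrease acceptance the PWM keeps
absorbing near-noise words from a 1000-word list almost indefinitely,
growing an unrealistically long, flat motif; the χ²₁ threshold stops
extension as soon as a word stops adding measurable signal. A hard cap
(`max_extensions`, default 40) guards pathological inputs.

When no candidate passes, the motif is finished: its cutoff is calibrated
on the weakly bound promoters as the smallest observed best-score with at
most `target_fpr` (5%) of them at or above it, its above-cutoff occurrences
are masked (replaced by N) in all sequences, and the next motif is seeded
from the top unconsumed word that itself passes the gate. Words consumed by
one motif are never reused. Iteration stops at `max_motifs`, when no seed
passes, or when the top unconsumed loading falls below 10% of the maximum.

Two consequences of the cutoff's order-statistic definition are worth
knowing. If even the maximum score is too frequent among the negatives, the
cutoff lands just above the maximum and the presence fraction is zero —
conservative by design. On synthetic data this happens systematically when
the weak class carries planted consensus instances: identical instances
produce *identical* best scores, so a tie of more than 5% cannot be split
by any threshold. This is a discreteness artifact of planting exact motif
instances, not of the calibration rule; real promoter scores are spread by
sequence context and motif degeneracy.

## Tiling-signal analytics

Gene binding values average the top 50% (⌈n/2⌉ for odd n) of a gene's exon
probe values, damping the influence of unspliced or alternatively spliced
probes. Region calling extracts probes at least three standard deviations
above the genomic average (mean/SD over all probes of all chromosomes;
per-chromosome statistics are available but off by default), chains them
while consecutive qualifying probes are within 360 bp, and drops chains
under 360 bp span or five probes. A region's value is the mean of its
highest six consecutive probe values and its center their mid-position;
five-probe regions use all five, and ties between equal windows resolve to
the leftmost. Dual-antibody confirmation intersects two region sets,
emitting the union span with the larger value and the mean center. TSS
distances take the nearest same-chromosome peak center. Co-localization
profiles assign probe values to 100-bp bins by signed distance from each
anchor center, mirroring anchors on minus-strand genes so the TSS is always
rightward, and average per bin over anchors.

## Gene classes, thirds and codon usage

Expression is the median over replicates; genes below 6 are unexpressed,
above 10 expressed-but-excluded (their response cannot be estimated
accurately), and in [6, 10] eligible. Strong means all three MSL proteins
above 1.0 (log2), weak all below 0.5; anything else is intermediate and
excluded from model sets. CDS thirds split the coding sequence into three
parts ordered 5′→3′ with remainder bases assigned 5′-first, so the 3′ third
is never the longest; the 3′-bias test scores each third with the whole-CDS
model and runs a paired t-test of 3′ against 5′ scores.

Codon usage is compared by relative synonymous codon usage (RSCU) computed
from each set's pooled codons, with a paired t-test across the 59 degenerate
sense codons — applied on the log2 scale. The log transform matters: raw
RSCU values sum to a fixed constant within every synonymous family in both
sets, so raw across-codon differences sum to exactly zero and a paired t on
them is identically null. Log-RSCU breaks that linear constraint while
keeping "no preference shift" as the null; values are floored at 0.01
before the log.

## The synthetic-data generator

The generator emulates the statistical structure the pipeline consumes,
with ground truth recorded for every planted feature. The defaults are the
conditions used throughout: 150 genes per class (strong / weak / unexpressed)
distributed over five chromosome arms; two-exon genes with mean 5′ UTR
200 bp, CDS 900 bp, intron 300 bp, 3′ UTR 300 bp and a mean 1.2 kb
intergenic gap (chosen so divergent promoter pairs rarely need truncation);
background base composition 60% AT. Strong and weak promoters carry a
planted 10-column PWM with probability 0.44 and 0.18; strong promoters
additionally carry ten hexamers at three-fold the baseline planting rate
(the class-dependent compositional bias), and strong CDS carry ten other
hexamers at rates rising 1/2/3 across the 5′/middle/3′ thirds. Probe tracks
at 100 bp spacing get per-gene exonic enrichment around 1.2 (strong) and
0.2 (weak) log2 units with 0.1 log2 probe noise; insulator-like Gaussian
peaks (amplitude 4, width 250 bp) sit 150 bp upstream of the TSS in 49% /
13% / 10% of strong / weak / unexpressed genes, with a smaller MOF co-bump
for the co-localization profile. Expression draws around 8.37 (strong) and
7.44 (weak), clamped into [6, 10]; unexpressed genes stay below 6.

Two defaults deserve their rationale. The planted PWM uses 0.95 consensus
probability per position (~15 bits over 10 columns): a sharp,
insulator-class motif. At desk scale — a few hundred genes instead of a
genome — a soft motif's constituent words never rise above the sampling
noise of 2770 word frequencies, so a recoverable planted signal requires
the high-information end of realistic motifs. The peak amplitude (4 log2
units) reflects that the calling threshold is mean + 3 SD where the SD
itself includes the planted peaks; on a small synthetic genome the peak
mass inflates the SD noticeably, and weaker bumps at 100 bp probe spacing
cannot satisfy the five-probe/360-bp rules.

What the generator does *not* emulate: probe-level chemistry and
normalization artifacts, alternative transcripts and nested genes, real
chromatin context, linkage between expression level and binding strength,
and continuous motif-instance degeneracy (planted instances are exact draws
from the PWM, which is what makes score ties possible). Passing tests
therefore demonstrate that the machinery recovers known structure under the
stated noise model — not that the biological conclusions transfer to any
particular real dataset.

## Numerical conventions and reproducibility

Internal coordinates are 0-based half-open; GFF3 (1-based inclusive) and
bedGraph (0-based half-open) are converted at the boundary. Multiple
transcripts collapse to the longest (largest summed exon length); within a
gene, CDS > UTR > intron precedence resolves conflicting annotations.
Promoters are clipped at neighbouring gene bodies, keeping the TSS-adjacent
piece; promoter–promoter overlaps (divergent TSSs closer than 1 kb) are
clipped at the midpoint of the mutual overlap; a promoter entirely inside a
neighbouring gene flags its gene as excluded from model sets. PCA/OPLS
components are sign-fixed by their largest-magnitude loading. The
train/test split (two thirds/one third) and all cross-validation folds are
stratified by class. All randomness flows from one master seed fanned out
into named sub-streams (synthesis, splits, CV folds), so stages can be
re-run independently and a full pipeline run is bit-reproducible per seed.

Problem sizes in the shipped tests and the acceptance script — 150 genes
per class in the default pipeline, 300 + 300 promoters for motif recovery,
seven groups of 100 for the null, 500 kb tracks for peak recovery — were
chosen as the smallest sizes at which each effect is comfortably detected
under the default noise model, keeping a complete run in the minutes range
on a single core.

## Interfaces

The package is tidyverse-shaped: tabular results are tibbles, fitted models
have `tidy()`/`glance()` methods, result types have `autoplot()`/`plot_*()`
functions, and the pipeline is driven from R (`run_pipeline()` plus the
stage functions); `scripts/acceptance.R` is the reproducible entry point
for the headline numbers. Standard formats go through the standard tools:
FASTA and genome arithmetic via Biostrings/IRanges, GFF3 and bedGraph via
rtracklayer, motifs exported in MEME minimal format, word matrices and
derived coordinates as TSV/BED.
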