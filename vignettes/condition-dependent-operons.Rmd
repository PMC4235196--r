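---
title: "Predicting condition-dependent operons from RNA-seq coverage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting condition-dependent operons from RNA-seq coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(operomap)
```

## The problem

Bacterial operons are not fixed objects: the same gene cluster can emit
different transcriptional units under different growth conditions, so a
static operon annotation (a DOOR-style reference map) and a single RNA-seq
experiment routinely disagree. `operomap` reconciles the two. From one
per-base coverage profile plus the genome annotation and a reference operon
map it (1) locates transcription start and end points, (2) confirms the
subset of reference operons that the experiment actually supports, (3)
labels every adjacent same-strand gene pair, (4) re-classifies the uncertain
pairs with an ensemble of three classifiers, and (5) assembles a
condition-specific operon map.

## Breakpoint detection

The detector slides a 100 nt window (stride 1 nt) along the depth profile
and correlates the depth segment with the step template
$x = [0_{50}, 1_{50}]$. Windows with Pearson $r > 0.7$ and a two-sided
correlation-test p-value below $10^{-7}$ (from
$t = r\sqrt{(n-2)/(1-r^2)}$ with $n-2$ df) mark sharp coverage increases;
$r < -0.7$ marks decreases. Runs of overlapping significant same-sign
windows are merged; within the strongest window of a run (maximal $|r|$,
leftmost on ties) the breakpoint is localized by the CUSUM change-point
statistic, and the reported base is on the transcribed side (first plateau
base for a rise, last for a fall).

Two numerical choices deserve comment. Zero-variance windows have undefined
correlation and are skipped, which is forced mathematically. And we localize
with CUSUM rather than reporting the raw window center: when two
transcription units are separated by less than half a window the maximal-$|r|$
window is asymmetrically contaminated by the neighbouring plateau and its
center is biased by up to 10 nt, whereas the CUSUM argmax/argmin is exact on
a clean step and is the standard change-point estimator under counting
noise. On ideal steps both conventions coincide.

## Expression and thresholds

Expression of every CDS and intergenic region (IGR) is computed with the
RPKM estimate $C/((L/1000)(N/10^6))$, where the read count $C$ is summed
depth over the interval divided by the read length (default 50 nt) and $N$
is total mapped bases over read length. Values are reported as
$\log_2(\mathrm{RPKM}+1)$; the pseudocount of 1 keeps silent IGRs finite
while leaving expressed features essentially unchanged. Minimum expression
thresholds are the 10th percentile (type-7 linear interpolation) of the CDS
and of the IGR distribution respectively; the same percentile rule is
applied to both classes because the IGR rule is otherwise unspecified.

## Confirmation and pair labels

An increase breakpoint becomes an operon start point (OSP) when its depth
fold change — (mean of the rising half + 1)/(mean of the falling half + 1) —
exceeds 2, the nearest downstream gene in transcription order is expressed
above the CDS threshold, that gene belongs to a reference operon, and the
gap leaves at most `max_utr` (300 nt, configurable) of 5' UTR. Minus-strand
genes mirror everything: their 5' rise is a genomic-coordinate *decrease*.
Anchoring is allowed at any structural gene of the reference operon, not
only the first, so condition-dependent internal starts confirm suffix runs;
a `first_gene_only` flag restores the stricter behaviour.

From each anchor the next reference gene is linked while the intervening
IGR is expressed above the IGR threshold, the next gene is expressed above
the CDS threshold, and no breakpoint lies inside the IGR; junctions without
an IGR (abutting or co-directionally overlapping genes) pass vacuously,
since there is no region to test and such overlap is itself strong operon
evidence. No end-point check is made after the last linked gene. Runs
shorter than two genes are dropped.

Labels then partition the adjacent same-strand pairs: **OP** (consecutive
in a confirmed operon), **NOP** (a breakpoint inside the IGR; expression of
the genes is deliberately not required), **POP** (both genes expressed,
not co-operonic in the reference — candidate novel operons or extensions),
**EGP** (both expressed and co-operonic in the reference but never linked
to a start point), otherwise unlabeled. A pair that is both confirmed and
breakpoint-split takes OP with a warning, because confirmation rests on
more evidence. We require *both* genes expressed for POP/EGP, and we allow
reference co-operonic pairs to become NOP when a breakpoint splits them —
that is precisely the condition-dependent case of interest.

## Pair features

Four features feed the classifiers: the intergenic distance
$\mathrm{start}_{i+1}-\mathrm{end}_i-1$ (negative for overlaps); the codon
usage score $\sum_c \mathrm{RSCU}_c(g_i)\,\mathrm{RSCU}_c(g_{i+1})$ summed
over the 61 sense codons ($\mathrm{RSCU}_c = n_c k_a / n_a$, absent
families 0 by convention so the sum is total and symmetric; an
amino-acid-level variant that averages within families first is available
as a mode flag); the absolute difference of the genes'
$\log_2(\mathrm{RPKM}+1)$; and the IGR expression, which for overlapping
pairs falls back to the smaller of the two gene values — a co-transcribed
overlap behaves like a maximally expressed IGR relative to its genes.

## Classifiers, validation, voting

A 500-tree random forest, a single-hidden-layer perceptron (hidden units
from {2, 4, 6, 8}) and an RBF SVM (cost {0.1, 1, 10, 100} × width
{0.01, 0.1, 1}) are trained on the confirmed OP/NOP pairs. NN/SVM features
are standardized with training-fold statistics only, and hyperparameters
are picked by grid search on an internal stratified 70/30 holdout — the
grids are recorded defaults, since no canonical values exist for this
problem. Validation holds out 30% stratified, then runs 5-fold
cross-validation 10 times on the rest; the random forest is instead refit
10 times and evaluated on its out-of-bag predictions, which estimate the
same quantity without an outer fold. Metrics are TPR, PPV, error rate,
accuracy, and two false-positive-rate variants reported side by side:
`fpr_paper` = FP/(FP+FN), a form that appears in the operon literature,
and the standard `fpr_standard` = FP/(FP+TN); neither is silently
corrected into the other. Ratios with zero denominators are `NaN`, never 0.
ROC curves pool the held-out scores of all 50 folds; the AUC is computed by
the midrank Mann–Whitney statistic and agrees with trapezoidal integration
of the curve to numerical precision. Class imbalance is left untouched and
classes are assigned at probability 0.5.

Uncertain pairs (POP/EGP) are then tagged OP when at least two of the three
classifiers vote OP — with three voters no tie is possible. Confirmed-OP
and voted-OP junctions are chained into maximal operon calls (`confirmed`,
`putative` or `mixed`), and optional promoter/terminator intervals from
external predictors flag junctions whose IGR they overlap by at least 1 bp
(stranded signals must match the call's strand). Flagged junctions stay in
the map — signals add confidence, they do not filter — and operon flanks
are not checked.

One-dimensional sensitivity analysis perturbs one feature at a time over a
7-level grid spanning its observed range, holds the others at their
training means, and scores importance as the variance of the model's
response; importances are also reported normalized to sum one. The
cross-dataset harness draws 50 bootstrap samples (70% of the table, with
replacement — our reading of an underspecified protocol) from each of two
datasets and compares the two accuracy vectors with a Welch t-test.

## The synthetic generator

`simulate_transcriptome()` emulates the structure of the bacterial RNA-seq
profiles the method targets: 120 transcription units with geometric(0.45)
sizes truncated to 1–8 genes on both strands; intra-operon IGRs
N(20, 15) nt floored at −20 (allowing overlaps); inter-TU gaps N(150, 60)
floored at 40; per-TU log2 depth N(6, 2), floored at 2 so that an
"expressed" truth label always means a plateau well above background —
silence is governed by the silent fraction, not by the tail of the level
distribution; 15% silent TUs per condition;
per-base Poisson noise over a background of 0.2 (a negative-binomial
dispersion knob is available); ideal step edges by default with a
configurable ramp. Genes are 100–300 codons; UTRs are drawn from 20–80 nt
but bounded so that at least ~60 nt of silent spacer survives between
neighbouring plateaus and so that every UTR is at least 1 nt — adjacent
transcripts must not fuse, and boundary breakpoints belong strictly inside
intergenic regions. Within-operon codon bias comes from per-operon
Dirichlet(0.5) family preferences; co-operonic genes share a preference
vector. The reference table is the true operon set corrupted at rate 0.10
by splits (creating POP opportunities) and merges of adjacent same-strand
TUs (creating NOP/EGP opportunities). 10% of expressed multi-gene TUs use
an internal start, placed only at junctions with a positive intergenic gap
— an internal promoter needs intergenic sequence, and a start "inside" an
overlapping upstream gene would define ground truth that no coverage-based
method could reproduce. Genome layout, sequences and the reference table depend
only on the seed; the silent set, expression levels and internal starts are
re-drawn per condition, which is how condition dependence is exercised.

What the generator does *not* emulate: non-uniform read distribution along
transcripts, GC/mappability bias, antisense transcription overlapping genes,
rRNA contamination, or multi-replicon genomes. Passing tests therefore
demonstrate correctness of the algorithmic chain under the stated noise
model, not performance on any particular real library.

## Problem sizes and determinism

Tests and the acceptance script run the generator at its defaults
(~260 genes, ~180 kb) and classifier experiments at roughly 400 pairs,
sizes chosen to exercise every code path while keeping a full run in the
minutes range. All randomness flows from one master seed through a
deterministic seed-derivation chain, so every split, fold, refit and
bootstrap is reproducible; reruns of a pipeline configuration are
hash-identical.

## Known limitations

Single replicon only; no de novo operon discovery without a reference
table; each coverage profile is an independent run (conditions are not
modelled jointly); promoter/terminator prediction itself is out of scope —
predicted intervals are consumed, not produced; and detection reports
breakpoints wherever they occur, leaving any filtering of intra-genic
candidates to the downstream rules.
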