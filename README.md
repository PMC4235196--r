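# operomap

Condition-dependent operon maps for bacterial genomes from a single RNA-seq
coverage profile.

Bacterial operons emit different transcriptional units depending on growth
conditions, so a static reference operon annotation (a DOOR-style map) and
any one RNA-seq experiment disagree by construction. `operomap` integrates
the two sources: it detects transcription start/end points in the per-base
coverage signal, confirms the reference operons the experiment supports,
extracts genomic and transcriptomic features for every adjacent same-strand
gene pair, re-classifies the uncertain pairs with a voted ensemble, and
emits a condition-specific operon map. It is aimed at microbial
transcriptomics groups who have a coverage track (pileup or
position/depth), a GFF3 annotation, CDS sequences and a reference operon
table, and want to know which operons were actually transcribed — and in
which form — under their condition.

## Method

1. **Breakpoints.** A 100 nt window slides along the depth profile (stride
   1 nt) and is correlated with the step template *x* = [0₅₀, 1₅₀]. Windows
   with Pearson *r* > 0.7 and correlation-test p < 10⁻⁷ (two-sided t with
   *n*−2 df) mark sharp increases in transcription; *r* < −0.7 marks
   decreases. Significant same-sign runs are merged and the breakpoint is
   localized by the CUSUM change-point inside the strongest window.
2. **Expression.** RPKM of every CDS and intergenic region (IGR) from the
   summed depth (`C/((L/1000)(N/10⁶))`), reported as log₂(RPKM+1);
   expression thresholds are the 10th percentile of each class.
3. **Confirmation.** An increase breakpoint with >2-fold depth change,
   an expressed downstream gene that is a structural gene of a reference
   operon, and ≤300 nt of 5′UTR room is an operon start point; genes are
   linked while the IGR is expressed, the next gene is expressed, and no
   breakpoint splits the IGR. Pairs are labeled OP (confirmed), NOP
   (breakpoint in the IGR), POP (expressed, not co-operonic in the
   reference), EGP (expressed, co-operonic, never anchored), or unlabeled.
4. **Classification.** Four features per pair — intergenic distance
   (start₍ᵢ₊₁₎ − endᵢ − 1), codon-usage similarity
   Σ꜀ RSCU꜀(gᵢ)·RSCU꜀(gᵢ₊₁), |Δ log₂RPKM|, and IGR expression — train a
   random forest, a neural network and an RBF SVM on the OP/NOP pairs
   (30% holdout + 10×5 cross-validation; out-of-bag refits for the RF).
   POP/EGP pairs are tagged OP when ≥2 of the 3 classifiers agree.
5. **Map.** Confirmed and voted OP junctions are chained into maximal
   operon calls, optionally checked for predicted promoter/terminator
   intervals overlapping their IGRs.

A synthetic transcriptome generator (`simulate_transcriptome()`) with full
ground truth — step-shaped coverage with Poisson noise, shared within-operon
codon bias, deliberately corrupted reference tables, per-condition silent
sets and internal starts — makes the whole chain testable offline.

## Worked example

```r
library(operomap)

# simulated study condition with ground truth; on real data pass gff =,
# cds_fasta =, coverage =, operon_table = paths instead (simulate = FALSE)
res <- run_pipeline(run_config(out_dir = "run1", seed = 1))

head(res$breakpoints, 3)
#>   position     kind          r      p_value fold_change strand
#> 1      487 increase  0.9878258 5.218299e-81    65.37288      *
#> 2      939 decrease -0.9863053 1.608478e-78    62.16129      *
#> 3     1000 increase  0.9939581 7.436083e-96   111.42857      *

table(res$pairs$label)
#>       NOP        OP       POP unlabeled
#>        73       108         2        16

str(res$summary)
#> List of 7
#>  $ confirmed_junctions: int 108
#>  $ putative_junctions : int 2
#>  $ total_junctions    : int 110
#>  $ n_operons          : int 57
#>  $ pct_confirmed      : num 54.3
#>  $ pct_putative       : num 1.01
#>  $ pct_total          : num 55.3

map_calls(res$map)[1:3, ]
#>   call_id       genes n_genes strand    status
#> 1 OPN0001 g0007,g0008       2      + confirmed
#> 2 OPN0002 g0015,g0016       2      + confirmed
#> 3 OPN0003 g0018,g0019       2      +  putative
```

The first breakpoint is a transcription start (sharp rise, 65-fold change)
at base 487; 108 junctions were confirmed directly from coverage plus the
reference map and 2 more were added by the classifier vote, chaining into
57 operon calls covering 55.3% of adjacent same-strand pairs. Against the
generator's ground truth this run's map reaches junction precision 1.000
and recall 1.000, with 99.5% of TU boundaries localized within ±50 nt
(`truth_compare(res$map, res$sim$truth, breakpoints = res$breakpoints)`).

A thin CLI wraps the same functions:

```sh
exec/operomap simulate --seed 1 --out data/
exec/operomap run --seed 1 --out run1/
```

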