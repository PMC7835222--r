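# coevkit

Does a protein region coevolve with an interaction partner? **coevkit** is
an R pipeline for testing whether a query protein's region of interest is
under elevated evolutionary constraint specifically in organisms that also
possess the partner protein — the phylogenetic-profile signature of an
interaction surface — together with two companion analyses from the same
study design: directionality testing of retinoic-acid (RA) target genes
across regulator-defined expression conditions, and enzyme initial-rate /
inhibition analysis from NADH time courses. The motivating case is the
PRMT3-interacting C-terminal region of human ALDH1A1, but every stage is
generic and fully exercisable on generated synthetic data with planted
ground truth.

It is aimed at molecular evolution and protein-interaction researchers who
have: ortholog sequence sets (e.g. from an orthology database), a list of
organisms carrying the partner, pre-aligned FASTA for the two organism
sets, precomputed differential-expression tables, and/or plate-reader time
courses.

## The statistics at the core

**Conservation.** Each alignment column `c` is scored by the base-2
Jensen–Shannon divergence between its (sequence-weighted, pseudocounted)
residue distribution `p_c` and the BLOSUM62 background `q`, linearly
penalized by the gap fraction `g_c`:

    S_c = JSD(p_c || q) * (1 - g_c),   JSD in [0, 1]

followed by window smoothing `S'_c = 0.5 S_c + 0.5 mean(window of radius 3)`.
Position-based sequence weights down-weight redundant sequences.

**Coevolution.** With organisms partitioned into partner-positive and
partner-negative sets (after one-to-one ortholog curation by affine-gap
pairwise identity, with strain deduplication and a strict
better-than-every-paralog rule), the statistic is the mean over region
residues of `S'(positive) - S'(negative)`. Uncertainty comes from a
label-permutation test (two-sided add-one p over 999 set-label
reassignments) and a paired Wilcoxon signed-rank test.

**Expression.** Conditions are classified by regulator fold-change signs
(ALDH1A1 up + PRMT3 down vs both up); shared literature up-targets are
compared between conditions by median log2 fold change, Wilcoxon rank-sum,
and Fisher's exact test on up/down counts.

**Rates.** Initial velocities are OLS slopes of NADH concentration vs time
over the first 6 points (0–10 min at 2-min cadence); inhibition is the
percent rate reduction vs control, compared by two-tailed t tests.

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
data (stage 1 writes the inputs under `results/data/`):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_coevolution.R
Rscript analysis/03_expression.R
Rscript analysis/04_rates.R
```

Stage 2 prints:

```
curation: 60/60 organisms assigned a one-to-one ortholog (paralog assigned: FALSE)
partition: 30 partner-positive vs 30 partner-negative organisms
<region_comparison> residues 101-130 (30 compared)
  delta_mean = 0.2551, permutation p = 0.001 (N = 999), signed-rank p = 1.825e-06
```

All 60 organisms received their planted ortholog (the 50%-diverged human
paralog decoy was never assigned); the planted 30-residue interface region
is more conserved in partner-positive organisms by 0.26 JSD units on
average, and no label permutation reached that difference (p = 1/1000, the
smallest value 999 permutations can report). Stage 3 prints:

```
<partition_report> 33 shared targets (AL1High_PR3Low vs AL1High_PR3High)
  medians: 2.49 / -2.53; up: 31/33 vs 0/33
  rank-sum p = 9.77e-12; Fisher p = 1.65e-16
```

i.e. the planted median fold changes (+2.5 / −2.6) are recovered and the
directionality split between the condition classes is overwhelming. Stage 4
reports `29.1% inhibition vs control (t-test p = 0.00016)` against a
planted 30% inhibition at 1 µM/min.

The same machinery is available programmatically:

```r
library(coevkit)
fam <- simulate_ortholog_families(msa_sim_config(seed = 1))
res <- run_coevolution(list(sim = msa_sim_config(seed = 1), seed = 2,
                            out_dir = "my_run"))
res$comparison$permutation_p
```

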