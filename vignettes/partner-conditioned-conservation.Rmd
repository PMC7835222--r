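---
title: "Partner-conditioned conservation and companion analyses: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partner-conditioned conservation and companion analyses: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question the pipeline answers

When two proteins interact, the interaction surface of one is expected to be
under elevated purifying selection — but only in lineages where the partner
exists. coevkit operationalizes this phylogenetic-profile argument for a
query protein (the motivating case is the C-terminal region of human
ALDH1A1, the retinaldehyde dehydrogenase, and its partner PRMT3): organisms
carrying a one-to-one ortholog of the query are split by whether they also
carry the partner, residue conservation is scored per alignment column in
each set, and the region of interest is compared between sets. Two companion
analyses complete the picture painted by the motivating study: a
transcriptome-level test of whether retinoic-acid (RA) target genes move in
opposite directions under opposite regulator configurations, and an enzyme
initial-rate analysis of NADH accumulation time courses with inhibition.

Everything downstream of raw inputs is computed by this package; the only
external steps are multiple-sequence-alignment construction (the pipeline
consumes pre-aligned FASTA; synthetic families are columnwise-alignable by
construction) and differential-expression calling (DE tables arrive
precomputed).

## Ortholog curation

Candidates are first reduced to one sequence per species: the species key
defaults to the lower-cased first two whitespace tokens of the organism name
(so strain records collapse), overridable by curated metadata. Per species,
the record kept is the one with the highest pairwise identity to the query;
ties go to the longer sequence, then the lexicographically smallest id.

Identity comes from our own affine-gap global aligner (Gotoh three-state
recurrence, BLOSUM62, gap open 11, extend 1; a gap of length $k$ costs
$11 + k$). Identity is defined as identical columns divided by **all**
alignment columns — conventions vary, so ours is stated and fixed. The
traceback tie-break (diagonal over gap-in-second over gap-in-first) makes
alignments byte-reproducible.

An organism's best candidate is assigned as the one-to-one ortholog only if
its identity to the query **strictly** exceeds its identity to every human
paralog of the query; equality rejects (reason `paralog_closer`). The
partner-organism list supplied to the partition step is treated as
authoritative — absence from it is read as true absence of the partner, not
as missed detection — and that assumption is recorded in output headers.
A partition with an empty side is an error: the comparison is undefined.

## Conservation scoring

Each alignment column is scored by the Jensen–Shannon divergence between its
residue distribution and a background, in base 2:

$$
S_c = \mathrm{JSD}(p_c \,\|\, q) \cdot (1 - g_c), \qquad
\mathrm{JSD}(p\|q) = \tfrac12 KL(p\|r) + \tfrac12 KL(q\|r),\;
r = \tfrac{p+q}{2}
$$

* **Background $q$** — the marginal amino-acid frequencies underlying the
  BLOSUM62 matrix, shipped as packaged constants and renormalized to sum
  exactly to 1. A column that looks like the background scores near 0; a
  conserved column scores near 1 (the base-2 JSD is bounded in $[0,1]$).
* **Sequence weighting** — position-based weights: in a column with $r$
  distinct symbols (gap included) where sequence $i$'s symbol occurs $s$
  times, sequence $i$ earns $1/(rs)$; per-sequence means are normalized to
  sum to 1. Redundant sequences (over-sampled clades, residual strain
  duplicates) are thereby down-weighted. The motivating analysis names only
  the weighting goal ("reward surprising sequences"); the position-based
  scheme is the standard choice of the scoring approach and is flagged as
  such in profile headers.
* **Gap handling** — gaps are excluded from the 20-letter distribution and
  penalized linearly through the weighted gap fraction $g_c$; an all-gap
  column scores exactly 0.
* **Pseudocount** — $\varepsilon = 10^{-7}$ per residue (the scoring
  approach's default), added before normalization so the divergence is
  finite on any column.
* **Window smoothing** — $S'_c = (1-\lambda) S_c + \lambda \cdot
  \mathrm{mean}(S_{c-w..c+w} \setminus S_c)$ with radius $w = 3$ and
  $\lambda = 0.5$, truncated at the edges; a column with no neighbors keeps
  its raw score. Only the window size is named by the motivating analysis;
  the mixing weight follows the approach's published default. Both are
  parameters, echoed into every output.

Columns are mapped to the 1-based residue numbering of a chosen reference
sequence in the alignment; user-facing coordinates are always reference
coordinates (the C-terminal interface presets are 336–501 and, for the
two-hybrid clone boundary, 371–501).

## The coevolution comparison

The statistic is $\bar\Delta$, the mean over region residues of
(windowed score in the partner-positive alignment) minus (partner-negative).
The motivating study reports the comparison without naming a test, so two
are always reported and neither is privileged:

* **Label permutation test** — organisms (never the reference) are pooled
  and set labels reassigned preserving sizes; profiles and $\bar\Delta$ are
  recomputed per reassignment; the two-sided add-one estimate is
  $p = (1 + \#\{|\bar\Delta^*| \ge |\bar\Delta|\})/(N+1)$, with $N = 999$ by
  default and a mandatory seed. The pooled rows are canonicalized by
  sequence content before drawing, so exchanging the two input sets leaves
  the p-value exactly unchanged. $N < 19$ is refused (the p floor would
  exceed 0.05).
* **Wilcoxon signed-rank** on the paired per-residue deltas — exact null for
  $n \le 25$ without ties in $|\Delta|$, else a normal approximation with
  continuity correction and tie-corrected variance; zero deltas are dropped
  and an all-zero input is flagged degenerate with $p = 1$.

## Statistical core

The named tests are implemented in-package with stated conventions, and are
verified in the test suite against both brute-force enumeration and the
standard library routines:

* Fisher's exact 2×2, two-sided by the probability rule (sum of
  hypergeometric probabilities $\le$ the observed one, with $1 + 10^{-7}$
  relative slack), computed in log space.
* Wilcoxon rank-sum, two-sided; exact (Mann–Whitney null) for combined
  $n \le 20$ without ties, else tie-corrected normal approximation with 0.5
  continuity correction. The cutover balances runtime against exactness and
  is recorded in each result's `method` field.
* Two-sample t, two-tailed; Student's pooled form by default ("t test"
  without qualification is read as the textbook form), Welch behind a flag.
* Benjamini–Hochberg step-up q-values.

## Expression directionality

Conditions are classified by regulator rules (e.g. ALDH1A1 up **and** PRMT3
down, both significant, gives the AL1-high/PR3-low class; both up gives
AL1-high/PR3-high). Significance defaults to adjusted $p \le 0.05$.
Literature targets of the requested direction present in every table form
the shared set; a direction class smaller than 6 genes is excluded outright
(the motivating analysis could not use its 5 known down-targets, and no
robust statement is possible at that size — the threshold is configurable).
Per condition the analysis reports the median log2 fold change, up/down
counts (log2FC $> 0$ is "up"; exact zeros are counted as up and flagged —
they are vanishingly rare in continuous fold-change data), the rank-sum
comparison of the two fold-change vectors, Fisher's exact test on the
condition × direction table, and the per-gene fold-change difference table
ordered by difference (the heatmap input). Gene matching is case-insensitive;
alias/synonym resolution is out of scope.

## Enzyme rates

NADH standard curves are ordinary least squares with intercept (not forced
through the origin unless requested); absorbance readings without a standard
curve are a hard error rather than a silent unit guess; negative computed
concentrations are retained with a warning. The initial velocity is the OLS
slope of concentration on time over the first 6 points by default — 0–10 min
at the 2-min cadence of the motivating assay, inside the linear phase — and
the window is an explicit parameter settable by count or by time bound.
Replicate slopes are summarized as mean ± SD ($n-1$), percent inhibition is
$100\,(v_{ctrl} - v_{cond})/v_{ctrl}$, conditions are compared to the
control by the two-tailed t test, and dose series get a Spearman
monotonicity diagnostic. Michaelis–Menten or $K_i$ fitting is deliberately
out of scope: the analysis reports initial rates and relative inhibition
only.

## What the synthetic data emulate — and what they do not

The generators plant the exact structure each analysis assumes, so every
stage can be scored against known truth without downloads:

* **Ortholog families** — a uniform-random 200-residue reference; each of
  30 partner-positive and 30 partner-negative organisms substitutes each
  site independently (probability 0.02 inside the 30-residue interface
  region for partner-positive organisms, 0.3 otherwise), uniformly over the
  19 alternative residues; 3 strain duplicates share species keys with
  hosts; a decoy paralog diverges at 0.5. Uniform substitution (rather than
  matrix-weighted) keeps binomial oracles exact; no indels are simulated —
  the conservation signal is columnwise, and gap handling is exercised with
  hand-built fixtures instead.
* **DE tables** — 33 shared up-targets at Normal(+2.5, 1.5) in one condition
  and Normal(−2.6, 1.5) in the other, 500 null background genes, 5
  literature down-targets (to exercise the small-class exclusion), and
  regulators planted per condition class (ALDH1A1 at +3.8 / +1.4).
* **Time courses** — concentration $= v(1-\phi)t + \mathcal N(0, 0.2)$ µM at
  2-min cadence for 60 min, $v = 1$ µM/min, three replicates, with a
  30%-inhibited condition by default and optional dose series.

These emulations are deliberately idealized. Real ortholog sets evolve on a
shared tree, so sequences are phylogenetically correlated rather than
independent — the permutation null is exactly exchangeable here but only
approximately so on real data. Real fold-change distributions are
heavier-tailed than a normal: under the default generator nearly all planted
targets fall on their planted side of zero (about 95% for a mean of 2.5 and
sd of 1.5), a cleaner directionality split than published contrasts show.
Real plate-reader series have baseline drift and saturation that the linear
generator omits. Passing tests therefore demonstrate correctness of the
computations and calibration under the stated generative model, not
robustness to every property of real data.

Every generator draws from its own explicitly seeded stream and restores the
caller's RNG state; identical configs and seeds give byte-identical outputs.

## Numerical and design choices

* Integer alignment coding (gap = 0) with fully vectorized column engines;
  the permutation test recomputes only the region plus its smoothing margin,
  which is exactly equal to the full-profile result because every region
  column keeps its complete neighborhood.
* Ambiguity codes (X, B, Z, J, U, O) are rejected in strict mode; under the
  lenient flag they are retained in sequences but masked (treated as
  missing) by all frequency counts.
* One gap dialect: `-` only; `.` is rejected.
* Deterministic tie-breaks everywhere (alignment traceback, strain
  deduplication, candidate ordering), so curation is order-invariant.
* All tabular outputs carry a `#`-prefixed parameter header and each
  pipeline run writes a JSON manifest with the package version, the config
  echo and the completed stages; failed runs keep partial outputs and record
  the failing stage.

Test problem sizes are chosen to keep the default suite fast while leaving
the oracle comparisons exhaustive where exhaustiveness is the point:
enumeration oracles run at sequence lengths ≤ 6 (alignment), margins ≤ 12
(Fisher), combined $n \le 10$ (rank-sum labelings), and the
parameter-recovery studies use 20 seeds at the full study geometry (30 + 30
organisms, 999 permutations).

## Known limitations

* The pipeline consumes pre-aligned ortholog sets; alignment quality is the
  caller's responsibility, and column scores are only as good as the
  columns.
* Phylogeny is ignored both in weighting (position-based, not tree-based)
  and in the permutation null; strongly clustered partner presence (e.g.
  partner loss in a single clade) will inflate apparent signal on real data.
* One-to-one orthology is decided purely by pairwise identity against the
  query and its paralogs; no orthology-graph reconciliation.
* The expression analysis performs no DE calling, no synonym resolution and
  no enrichment; it tests directionality of a supplied target list only.
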