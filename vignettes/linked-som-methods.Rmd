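---
title: "Linked self-organizing maps for regulatory network inference: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linked self-organizing maps for regulatory network inference: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical machinery: the
models, the tunable parameters and why their defaults are what they are,
what the synthetic-data generator does and does not emulate, and the design
choices made where several reasonable options existed.

## 1. Overview of the procedure

The pipeline integrates two data modalities.  Chromatin experiments (TF
ChIP-seq, histone-mark ChIP-seq, Ep300 ChIP-seq, ATAC-seq) are summarized
as an RPKM matrix over a genome partition derived from peak calls; RNA
experiments (temporal wild-type series, tissue dissections,
morpholino-knockdown/control pairs) are summarized as a TPM matrix over
genes.  Each matrix is clustered with a self-organizing map (SOM); SOM
units are grouped into lattice-contiguous metaclusters; the two
metaclusterings are linked by assigning every genome partition to its
nearest transcription start site within 1 Mb.  The resulting *linked
metaclusters* (LMs) — one bin per (RNA metacluster, DNA metacluster) pair —
are the unit of motif-density enrichment.  Enriched motif instances then
pass a cascade of activity and expression filters before becoming TF →
target edges.

## 2. The SOM layer

Training is the classical sequential Kohonen procedure.  Units live on an
"odd-r" offset hexagonal lattice; lattice distance is the cube-coordinate
hexagonal distance, so interior units have six equidistant neighbours.  At
presentation $t$ a data row $x$ is drawn (each training row once per
epoch, random order), the Euclidean-nearest unit wins, and every unit
moves by

$$\Delta w_u = \alpha(t)\, \exp\!\left(-\frac{d(u, u^*)^2}{2\sigma(t)^2}\right) (x - w_u),$$

with $\alpha(t) = \alpha_0 e^{-t/\lambda}$ and $\sigma(t) =
\max(\sigma_0 e^{-t/\lambda}, \sigma_{\min})$.

Parameter defaults and rationale:

* $\alpha_0 = 0.1$ — standard Kohonen learning rate; the result is
  insensitive over 0.05–0.5 on the synthetic bundles.
* $\sigma_0 = \max(\text{rows}, \text{cols})/2$ (lattice units) — the
  neighbourhood initially spans the map, enforcing global topological
  order.
* $\sigma_{\min} = 0.25$ — the floor matters.  With a floor of 1 the
  nearest neighbour of the winner keeps an update weight of
  $e^{-1/2} \approx 0.61$ relative to the winner *forever*, so unit
  weights equilibrate between their own data and the global mean and never
  localize; a floor well below ~0.3 makes late training effectively
  winner-only, and a 1×2 map on two separated point clouds converges to
  the 2-means centroids (a property the test suite checks).
* $\lambda = T / \log(\sigma_0/\sigma_{\min})$, where $T$ is the total
  number of presentations — chosen so the radius reaches its floor exactly
  at the end of training.
* `train_fraction = 0.5` — training uses a seeded uniform half of the
  rows; the quantization score (mean distance of *every* row to its
  nearest unit) always uses the full matrix, and the best of `trials`
  independently-initialized trainings is kept.
* Default preprocessing is $\log_2(x+1)$: TPM/RPKM span four orders of
  magnitude and Euclidean distance on the raw scale would be dominated by
  the top percentile of rows.  Identity and per-row max-normalization are
  available.

At full scale the original analyses used 60×90 and 40×60 maps with 100
epochs and 100 trials.  This package's tests and acceptance runs use 12×18
maps, 30 epochs and 5 trials — sizes chosen so a complete 20-seed
end-to-end study runs in minutes on one CPU while every planted structure
is still comfortably resolvable.

## 3. Lattice-constrained metaclustering and the choice of k

Metaclusters must be connected on the lattice.  The constrained k-means is
greedy region growing (seed k distinct units; repeatedly attach the
frontier unit closest in weight space to an adjacent cluster's centroid)
followed by boundary refinement (reassign a boundary unit to a
neighbouring cluster whenever that lowers the residual sum of squares and
the donor remains connected and non-empty; sweeps repeat until no move
helps, at most 100).  Both phases preserve contiguity by construction; the
best of several restarts by RSS is kept.  On 4×4 lattices with planted
2-block structure the result matches the exhaustively-enumerated optimal
contiguous bipartition exactly.

Model selection uses a spherical-Gaussian likelihood with pooled variance
$\hat\sigma^2 = \mathrm{RSS}/(nd)$ and parameter count $p = k(d+1)$:
$\mathrm{AIC} = -2L + 2p$, $\mathrm{BIC} = -2L + p\ln n$.  Two caveats
discovered during development are worth recording:

* **AIC over-selects k at desk scale.**  On planted-block lattices AIC
  marches to the top of the candidate range.  The pipeline keeps AIC as
  its default (the full-scale analyses report AIC-selected counts of 84
  and 88), but recovery of a *planted* cluster count is tested with BIC,
  whose $\ln n$ penalty is the consistent choice for structure recovery —
  and which the method's general description also names.
* **In very low weight dimension the criterion cannot win.**  The RSS
  log-ratio gained by optimally splitting an iid-noise cluster is
  scale-invariant and, in $d = 2$, regularly exceeds the BIC penalty — a
  selection bias, since the split is the best of many.  In realistic
  experiment-space dimensions (the matrices here have 10–20 columns) the
  bias is negligible: at $d = 10$ BIC recovers a planted $k = 3$ in 20/20
  seeds at 10× separation and within ±1 in 20/20 at 5×.  Planted-recovery
  fixtures therefore use $d = 10$.

Per-metacluster statistics follow the definitions exactly: eigen-profiles
are means of member-unit weights; condition contrasts use a two-sided
paired Wilcoxon signed-rank on member genes (exact null for $n \le 25$,
normal approximation with continuity correction above, zero differences
dropped) with BH correction across metaclusters; fold changes are mean
$\log_2((a+1)/(b+1))$; experiment hierarchies are average-linkage trees on
$1 - r$ (Pearson) over metacluster profiles.

## 4. Linking and motif enrichment

A partition is linked to the gene minimizing |region midpoint − TSS| on
the same chromosome, capped at 1 Mb; ties break to the lexicographically
smaller gene id.  The midpoint anchor is a deliberate choice (edge or
summit anchors are also defensible); it is symmetric and deterministic.
Strand never affects distance.

Motif scanning scores $\sum_i \log_2 P_{\mathrm{pwm}}(b_i)/P_{\mathrm{bg}}(b_i)$
at every offset on both strands.  P-values are exact: per-position scores
are discretized to $10^{-3}$ bits and convolved under the background
model, giving the full null distribution of the discretized score; for
every width ≤ 8 PWM tested, the DP tail equals brute-force enumeration of
all $4^w$ sequences to machine precision.  Zero-probability bases
(pseudocount 0) are floored at −30 bits so consensus-only PWMs remain
scannable.  The BH family is *per motif across all scanned positions of
the region set* — pooling gives the q-values power and determinism, at the
cost of mixing regions of different LMs in one family; hits keep
$q < 0.1$.

Density enrichment per (LM, motif) compares the proportion of the LM's
regions carrying a hit with the global proportion by a one-tailed z-test,
BH-corrected over all (LM, motif) pairs, retaining $q < 0.05$ (a p-mode is
available; under a uniform-hit null the p-mode retention rate calibrates
to α within Monte-Carlo error).  The normal approximation is the method's
definition; an exact binomial tail serves as the testing cross-check.

## 5. The filter cascade

"Enriched" TF ChIP and Ep300 signal are both formalized as: compute the
mean RPKM of the experiment per DNA metacluster over member regions, and
retain metaclusters at or above the 75th percentile (linear interpolation,
type-7 quantile) of those means.  Expression filtering retains RNA
metaclusters whose mean member TPM exceeds 1 in at least one of the
configured stages.  Gene-list restriction (gastrulation regulators, then
TFs/growth factors) is applied last; the synthetic runs derive both lists
from the planted network plus seeded non-target padding.  Every stage's
instance and gene counts are reported, and monotonicity of the cascade is
asserted in tests.

The percentile rule has one scale sensitivity worth knowing: it retains
the top quarter of *metaclusters*, so if truly-active regions occupy more
than a quarter of region-bearing metaclusters, active metaclusters are
necessarily dropped.  In real genomes active ME enhancers are a small
minority of peak-covered chromatin; the synthetic generator mirrors this
(≈ 240 background/decoy regions against ≈ 60 CRMs across seven chromatin
states).

## 6. Error estimation

The equivalence ("unchanging gene") test is a TOST: with moderated
per-gene variance $\tilde s^2$ (empirical-Bayes shrinkage via
`limma::squeezeVar` — essential at 2–3 replicates, where a raw 4-df
variance estimate makes equivalence uncertifiable) the SE is
$\sqrt{\tilde s^2 (1/n_1 + 1/n_2) + c^2}$ with stabilizer $c = 0.05$, and
the p-value is the larger of the two one-sided normal tests against
$\pm 0.5$ log₂ units.  BH-corrected $q < 0.05$ calls a gene unchanging.
Note the information limit: with 3 replicates of log₂-scale SD 0.25 the
standard error of the fold change (~0.2) makes the ±0.5 bound
uncertifiable for *any* test; the power properties quoted in the test
suite use replicate SD 0.15, typical of biological replicates of
well-expressed genes.  On negative-binomial simulations the calls agree
with DESeq2's `lessAbs` test on both clear nulls and strong changes.

True negatives are the intersection of unchanging calls across knockdown
conditions; FPR and FDR are simple set ratios reported in percent.  The
overlap of predicted CRMs with hold-out peak sets is tested by per-
chromosome circular shifts with wrap-around,
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(n_{\mathrm{perm}} + 1)$; the
count statistic is discrete, so near-uniform null p-values require region
sets dense enough for the statistic to spread (the calibration test uses
50 regions per set).

## 7. The synthetic-data generator

The generator emulates the *statistical structure* the analysis assumes:

* a uniform-random genome (2 × 750 kb by default) with 100 non-overlapping
  genes, TSS at the 5′ gene end;
* a planted network of 3 TFs × 20 targets; each target's CRM is placed
  1–50 kb from its TSS **and within 45% of the gap to the neighbouring
  TSS** — without that constraint nearest-TSS linking could not recover
  planted edges even in principle, which would test the generator rather
  than the method;
* full-length binding-site consensi whose cores are published
  reporter-mutagenesis motifs (e.g. the forkhead core AATMHACA inside
  GTAATMHACAG).  A bare 7–8 bp degenerate core has an exact-match p-value
  of ~$10^{-4}$, which no genome-scale BH family can carry below
  $q = 0.1$ — at any scale; PWMs derived from real ChIP data are longer
  and sharper, and the extended consensi model that.  Two instances are
  planted per CRM (homotypic clustering, common in real enhancers);
* decoy CRMs that look chromatically identical to true CRMs but carry the
  published knockout substitution of the core (AATMHACA → AAGMHAAA,
  ACAAWRG → ATAGWRG) — hard negatives for the motif stage;
* seven chromatin states (active enhancer, poised enhancer, promoter,
  transcribed, polycomb, primed, heterochromatin) as mean-RPKM signatures
  over the experiments; ~15% of true CRMs are poised, so the Ep300 filter
  has genuine true misses and end-to-end recall tops out near 0.85;
* log-normal multiplicative noise on expression (log₂-scale SD 0.25) —
  positive, heavy-tailed, like sequencing signal; MO columns multiply
  target means by 0.25 with paired controls; tissue columns apply planted
  spatial offsets;
* Poisson read placements (50 bp) whose expectation reproduces each
  state's RPKM signature at the nominal library size, plus ±20 bp peak
  boundary jitter so partitioning has real work to do.

Everything is a deterministic function of one seed; the full bundle is
byte-identical across runs.

What it does **not** emulate — and what passing tests therefore do not
show: read-level sequencing error, mappability and GC bias, diploid
variation, isoform structure, correlated replicate noise, motif
cooperativity, or 3D-contact-based enhancer–gene assignment.  Recovery of
a planted network under the generator's assumptions is a correctness check
of the pipeline, not evidence about biological accuracy on real data.

## 8. Degenerate inputs and tie-breaks

Assignment ties go to the lowest unit index (row-major).  Covered segments
shorter than the minimum partition size merge into their contiguous
predecessor, else their follower; an isolated short segment is kept,
padded symmetrically, and clipped at chromosome ends (flagged).  Reads are
counted by strand-aware 5′ end; reads on unknown chromosomes are skipped
with a warning and counted.  All-zero expression profiles are dropped by
the `> min_tpm` filter even at `min_tpm = 0` (strict inequality).
Zero-variance experiment columns get correlation distance 1 with a
warning.  Degenerate Wilcoxon contrasts (all differences zero) report
p = 1 and a flag; degenerate global hit proportions (0 or 1) flag the
(LM, motif) pair rather than producing infinite z.
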