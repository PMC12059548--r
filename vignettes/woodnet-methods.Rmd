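---
title: "Models and methods behind woodnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind woodnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

woodnet infers cell-wall gene regulatory networks in woody stems from two
signals that must agree before an edge is called: tight co-expression of a
transcription factor (TF) with a candidate target across tissue fractions,
and the presence of the TF's binding motif in the target's promoter. Around
that core sit the stages a comparative study needs: expression
normalization, two clustering routes (tight clusters with unclustered genes
and signed weighted-correlation modules), motif and GO enrichment, a
nested-regression screen for regulators without known motifs, cross-species
conservation scoring through orthogroups, and Ks-spectrum dating of
whole-genome-multiplication (WGM) duplicates. A synthetic-data generator
with full ground truth makes every stage testable; this vignette explains
the models, the defaults, and the choices made where the design was open.

## The synthetic study design

The generator emulates a developmental gradient through a tree stem: eight
tissue fractions (`F1`-`F8`, phellem to mature xylem) with three RNA-seq
replicates each. Gene expression is simulated on the log2 scale as
`baseline + amplitude * module_profile + N(0, noise_sd)` per sample and
exported as TPM = 2^x - 1 (clipped at 0), the unit the correlation stages
consume. Module profiles come from a fixed library of smooth shapes: a
bimodal phloem + xylem profile first (mirroring the bimodal expression of
secondary-wall master regulators such as NST/SND homologs), then staggered
unimodal peaks; the first six shapes have pairwise |r| at most 0.45 on
eight fractions, so planted modules are genuinely separable and recovery
failures indicate method problems, not confounded truth.

Defaults are the study conditions: 600 genes, 6 modules, 25 planted
TF-to-target interactions, `noise_sd = 0.25`, and a null motif-planting
rate of 0.02. Half of the genes are pure noise — unassigned to any module —
mirroring the share of a stem transcriptome that falls outside tight
co-expression clusters in practice (roughly 12k of >20k expressed genes);
half of those are additionally flat and lowly expressed so the expression
filter has real work to do. Amplitudes are drawn from U(0.8, 1.6) (TFs from
U(1.0, 1.6)), which keeps the population correlation of every planted
regulator-target pair at or above 0.9 at the default noise — the generative
contract all recovery thresholds rest on. TFs are organized in chains of
three (layers 1-3, one module per chain), so the planted network has the
layered master → second-layer → third-layer structure typical of
secondary-cell-wall regulation.

Promoters are i.i.d. backgrounds (configurable GC) of 1 kb; every planted
interaction's target receives one instance sampled from the interaction's
PWM at a recorded position and strand, and every non-target receives one at
the null rate. PWMs are 12-bp with 0.98 probability mass on the consensus
base per column — informative motifs, as curated plant cistrome matrices
are. The second species keeps a 1:1 ortholog per gene (optionally 1:2 to
emulate a lineage-specific WGD); a fixed count
`round(conservation_fraction * n)` of interactions stays intact, and the
rest are broken either by removing the target ortholog's motif (default)
or by rewiring its expression to another module. Syntelog pairs draw
log10(Ks) from a Gaussian mixture with a gamma-like component at 0.0128
and an older one at 0.45; Ka = Ks × ω with ω log-normal (median 0.25,
purifying selection).

What the generator does *not* emulate matters for interpreting green
tests: no sequence evolution behind Ks (values are drawn, not evolved), no
repeats or chromatin context in promoters, no batch structure or
library-size artifacts in expression, and noise is Gaussian and
homoscedastic on the log scale. Passing recovery tests show the methods are
correct and calibrated under these conditions; they do not certify
performance on real tissue dissections, where profile shapes are less
clean and motif presence is a weaker proxy for binding.

## Normalization

`clust_normalize()` applies log2(TPM + 1), quantile normalization across
columns, then a per-gene z-score, recording the order in a `provenance`
attribute. This chain is often quoted in the other order (quantile,
z-score, log2), which cannot be executed literally — a log after z-scoring
hits negative values; the order implemented here is the one the clustering
tools actually apply. Quantile ties share the mean of the pooled
reference values at the tied ranks, which keeps the step deterministic and
column-order independent. Constant genes are flagged on the *input* scale
— after quantile mapping a constant gene would look variable — and set to
an all-zero profile. One practical caveat: on very small, all-signal gene
sets the rank-based quantile map distorts profiles noticeably (with only a
few distinct shapes the pooled rank distribution is lumpy); at realistic
gene counts with noise the effect is negligible.

## Tight clusters and signed modules

`tight_clusters()` builds tight cores by average-linkage hierarchical
clustering of the profile-correlation dissimilarity `1 - r`, cut at the
absolute height `1 - tau`, with `tau = 1 - 0.3 t` clipped to [0.5, 1].
Cores smaller than `min_size` (11) are dissolved, cores whose mean pairwise
member correlation falls below `tau` are rejected, and everything else is
unclustered — the defining behaviours of tight clustering: a gene must earn
its membership, and the tightness knob `t` trades coverage against
coherence. An earlier design iterated k-means over a grid of K and
thresholded the co-clustering frequency, but that construction is unsound
at both ends of the noise range: with zero noise, any K above the true
module count splits a zero-variance cloud along a run-varying boundary, so
within-module co-clustering frequencies drop to ~0.4; with realistic noise,
pure-noise genes co-cluster consistently on a fixed dataset (frequency
~0.85) while their profiles barely correlate (~0.54). The correlation-
linkage form has neither failure mode, needs no random number generator,
and is invariant to gene order.

The tightness default is an open design choice — practitioners tune it per
dataset — and this package ships `t = 0.5` (tau = 0.85): at the
generator's study conditions it keeps every true module member clustered
(ARI 1.0 against the planted modules) while leaving ~96-98% of pure-noise
genes unclustered; loosening to `t = 1` buys no coverage and degrades
noise rejection to ~75-85%.

The signed network route follows the weighted-correlation-network
convention: adjacency `a_ij = ((1 + r_ij)/2)^beta` with the soft power
`beta = 10`; `pick_soft_power()` implements
the scale-free criterion for choosing it (smallest power with R^2 of the log-log
connectivity fit at or above 0.8), topological overlap

```
TOM_ij = (sum_{u != i,j} a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij),
```

average-linkage clustering of `1 - TOM`, and a static cut at
`cut_height * max(merge height)` with `cut_height = 0.75` — i.e. one
quarter down from the top of the tree. The static cut is deterministic and
fully specified, unlike the dynamic hybrid cut; raising `cut_height`
merges more and never increases the module count. Modules below 30 genes
dissolve to unclustered. Eigengenes are the first right-singular vector of
the gene-centered member-by-fraction submatrix, sign-aligned with the
module mean profile and unit-normed.

## Promoter scanning

Promoter windows are the W bases strictly upstream of the annotated TSS
(gene-feature 5' end): `[TSS - W, TSS)` on the + strand, `[TSS, TSS + W)`
reverse-complemented on the − strand, clipped and flagged at contig edges,
with W = 1000 by default and 2000 as the variant used when 1 kb has poor
recall. Scanning scores every offset on both strands with the log2
likelihood ratio against the background; `N` bases contribute zero, so
clipped promoters stay usable. P-values are exact tail probabilities of
the score discretized to 1/1000 bit, computed by convolving per-column
score distributions under the background — the same construction the
standard motif-scanning tools use, and the discretization error is below
the 1e-3-bit level the tests assert. The default report threshold is
p <= 1e-4, the common scanning default;
the network-construction pipeline uses 1e-5, where the expected number of
random background hits per kilobase-scale promoter is ~0.004 and motif
presence is a trustworthy binary signal. PWMs are regularized with a
pseudocount of 0.01 per cell; the background defaults to uniform and the
minus strand is scored with the reverse-complemented matrix (exact for
complement-symmetric backgrounds).

## Enrichment

Motif enrichment is a one-sided (greater) Fisher exact test per
(cluster, motif) on the 2x2 table of cluster membership versus motif
presence, with unclustered genes counting only in the population, and
Benjamini-Hochberg adjustment jointly across all cluster-by-motif tests
(conservative relative to per-cluster families, and deterministic).
One-sided Fisher p-values are hypergeometric upper tails and are computed
as such. GO enrichment propagates annotations to all ancestors through
`is_a` and `part_of` before counting, tests terms with at least one study
gene by the hypergeometric upper tail, applies Bonferroni over the tested
terms, and keeps only `biological_process` terms by default. The
population defaults to all annotated genes.

## Network construction and the dual-regulator screen

An interaction `tf -> target` for motif m requires the motif upstream of
the target and |Pearson r| > 0.7 between TF and target, computed on raw
fraction-averaged TPM (eight points) — not on normalized values. Candidate
TFs are those whose motifs are enriched in at least one cluster; targets
are screened across all clusters (cross-cluster edges flagged), with a
switch to include unclustered genes. When several same-family TFs share a
motif and pass for one target, the highest-|r| TF wins, ties broken by
gene id, so the network is deterministic under input permutation.

For regulator pairs without known binding motifs (the KNAT7/KNAT3 case),
`knat_screen()` fits four nested OLS models — `y ~ k7`, `y ~ k3`,
`y ~ k7 + k3`, `y ~ k7 * k3` — and gates targets at best-R^2 > 0.7. Model
choice is by closed testing against the full model: each reduced model is
compared with FULL via the Gaussian likelihood-ratio statistic
`n log(RSS_reduced / RSS_full)`, and the most parsimonious non-rejected
model is chosen (the two single-regulator models are tied in size and
resolved by R^2; if everything is rejected FULL stays). Two calibration
choices matter at the n = 16 observations typical here. First, p-values
use the exact finite-sample distribution of the statistic — it is a
monotone function of the partial F, so `P(F_{df, n-p} >= F_obs)` is exact
under Gaussian errors, where the chi-square limit is anticonservative
(~8-10% type I at n = 16). Second, testing reductions against the full
model rather than walking a serial backward path means a single-regulator
truth survives one test instead of two, keeping per-structure selection
accuracy at ~95% instead of capping it at (1-alpha)^2. With collinear
regulators (|r| > 0.999) the interaction model is refused and the additive
model takes the full model's role. `alpha` defaults to 0.05.

Trait profiles (for example percent-normalized xylan mass-spectrometry
peaks, via `peak_ratio_normalize()`: peak/internal-standard ratios scaled
to sum to 100 per sample) are correlated with fraction-level expression;
genes with |r| > 0.7 are reported.

## Conservation across species

An inferred interaction is conserved in a second species iff *some*
ortholog pair of its TF and target passes the same two criteria there:
|r| > threshold in the species-2 expression and — unless relaxed — the
same motif within the species-2 promoter window. The match is existential
over orthogroup members, so adding candidate orthologs can only help;
interactions without an expressed ortholog pair are reported as
non-evaluable rather than counted against conservation.
`threshold_sensitivity()` sweeps {0.7, 0.8, 0.9}; because the criteria are
nested in the threshold the conserved fraction is necessarily
non-increasing, and the implementation asserts it. Cross-species motif
identity is assumed (one PWM library for all species), matching how the
same cistrome collections are applied across poplar and *Eucalyptus*-like
comparisons. `conserved_modules()` clusters each species independently and
calls an orthogroup conserved when every species has a clustered member
and the matched clusters' centroid profiles pairwise correlate above
`centroid_r_min`; fractions align by shared labels when any are shared,
else positionally by rank order of the developmental gradient — the honest
option when one species is sampled as sections and another as fractions.

## Duplicate dating and divergence

`ks_peaks()` estimates the Ks spectrum by Gaussian KDE on log10(Ks)
(bin-free, unlike raw histogram peaks; bandwidth from Silverman's rule),
keeping pairs with Ks in (0, 5] — older pairs are saturated. Peaks are
local density maxima with topographic prominence at least 5% of the
maximum density. Ages are calibrated linearly in Ks against the
core-eudicot gamma triplication at 125 Ma:
`age = 125 * Ks(peak) / Ks(gamma)`. Pairs join their nearest peak within
0.15 log10 units, equidistant ties going to the older peak.
Duplicate-class enrichment per cluster uses the one-sided Fisher test with
raw p < 0.05 flags (the convention for this screen) plus BH-adjusted
values for reference. The syntelog motif-conservation test counts distinct
motifs present upstream of *both* genes of a pair (identity, not position
— a positional variant would need instance matching the data cannot
support) and compares same-cluster pairs against different-cluster and
unclustered pairs with a one-sided Wilcoxon rank-sum test: full
enumeration (ties exact) when both groups have at most 10 observations,
the exact Wilcoxon distribution when tie-free and both at most 25, and a
tie-corrected, continuity-corrected normal approximation otherwise —
count data with unequal group sizes is exactly the regime that forces
this laddering. Ka:Ks > 1 flags candidate positive selection; pairs with
Ks = 0 are excluded from the ratio and counted separately.

## Problem sizes and determinism

The shipped tests and the acceptance script run the full pipeline at the
generator's study conditions (600 genes for network and clustering
recovery, 1000 genes / 200 interactions for conservation calibration,
1000 syntelog pairs for the Ks spectrum, 100 replicates for power and
selection-accuracy estimates) — sizes chosen so each stage's recovery
statistics are stable across seeds while a complete run stays in the
minutes range on a laptop. Every stochastic step draws from an explicit
seed: the five generators derive independent streams from
`simulation_config(seed = ...)` via fixed offsets, and rerunning with the
same seed is bit-identical. The clustering, scanning and testing stages
are seed-free and deterministic.

## Known limitations

Motif presence is treated as binary evidence; affinity differences, motif
clustering and distance-to-TSS effects are out of scope. TSSs are taken
from the gene-feature 5' end, not UTR-aware annotation. The GO parser
handles the OBO 1.2 constructs actually used in GO releases (`is_a`,
`relationship: part_of`, namespaces, obsoletion), not the full spec.
Conservation scoring presumes the ortholog table is trustworthy; no
reconciliation is attempted. The Ks pipeline dates events from the
provided Ks values — it does not estimate Ks from sequence, nor fit
mixture models; KDE peaks are the estimator, and components closer than
roughly one bandwidth will merge.
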