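---
title: "Genotype-based demultiplexing with annealed K-Harmonic Means"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotype-based demultiplexing with annealed K-Harmonic Means}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(demuxkhm)
```

## The problem

Pooling cells from many individuals into one single-cell RNA-seq run is
cheap and removes batch effects, but every cell barcode must afterwards be
assigned back to its donor. When reference genotypes are unavailable, the
assignment has to come from clustering cells on the natural genetic
variation visible in their reads. The observations are, for each cell $i$
and biallelic SNP $v$, a reference read count $r_{iv}$ and an alternate
read count $a_{iv}$. These matrices are extremely sparse — in droplet data
only about 5% of (cell, variant) pairs carry any reads — and the covered
sites hold only a handful of reads each. The number of donors $k$ is known
from the experimental design and is a required input.

This regime breaks the standard clustering toolkit. Distance-to-point
initialization heuristics (kmeans++) need a value for a center in the ~95%
of dimensions where the seeding cell has no data, and two random cells
share so few covered sites (~0.25% of variants at 5% coverage) that
cell-to-cell distances are mostly noise. As the donor count grows toward
64, local optima multiply: clusters that absorb two donors ("incorrectly
merged") or split one donor across two clusters become the dominant failure
modes.

## The count model

A cluster (candidate donor) is a vector $p_j \in [\epsilon, 1-\epsilon]^V$
of alt-allele fractions. Under the binomial family, a cell's fit to a
cluster is

$$\ell_{ij} = \sum_{v:\,a_{iv}+r_{iv}\ge 1}
  \log \binom{a_{iv}+r_{iv}}{a_{iv}} + a_{iv}\log p_{jv} +
  r_{iv}\log(1-p_{jv}),$$

summed only over the cell's covered sites. Fractions are clamped into
$[\epsilon, 1-\epsilon]$ with $\epsilon$ = `fraction_floor` (default 0.01)
so no center can assign probability zero to an observed allele. A
beta-binomial family (mean $p$, concentration `dispersion`, default 100) is
available for overdispersed data; it converges to the binomial as the
concentration grows. Likelihoods are deliberately not normalized by the
number of covered sites: a deeper cell carries more evidence, which is what
likelihood semantics require.

The clustering distance is $d_{ij} = -\ell_{ij} + \varepsilon_d$ with
$\varepsilon_d$ = `distance_epsilon` (default $10^{-6}$), which keeps every
distance strictly positive — cells with no covered variants would otherwise
sit at distance zero from every center and break the harmonic-mean
machinery below.

## K-Harmonic Means and its temperature

K-Harmonic Means (KHM) replaces the k-means objective with
$\sum_i k / \sum_j d_{ij}^{-p}$, the harmonic mean of each cell's distances
to *all* centers. Every center feels every cell, which makes the method far
less sensitive to initialization. The implementation uses the standard KHM
quantities, computed in log space: memberships
$m_{ij} \propto d_{ij}^{-p-2}$ and per-cell weights
$w_i = \sum_j d_{ij}^{-p-2} / (\sum_j d_{ij}^{-p})^2$, which boost cells
far from all centers. The center update is the closed-form weighted
binomial MLE with add-one smoothing,
$p_{jv} = (\sum_i q_{ij} a_{iv} + 1)/(\sum_i q_{ij}(a_{iv}+r_{iv}) + 2)$
with $q_{ij} = m_{ij} w_i$ — exact for the default family and stable on
sparse data, unlike a gradient step.

**Choice of the exponent p.** For Euclidean distances the KHM literature
recommends $p \approx 3.5$. Count log-likelihood distances behave
differently: the membership contrast between clusters is
$(d_{ij}/d_{il})^{p+2}$, and because $-\ell_{ij}$ carries a large
cell-specific offset (the binomial coefficients and the entropy of the
cell's own counts), those ratios hover near 1. Both the offset and the
between-cluster gap scale with the number of covered sites, so the ratio is
roughly coverage-independent — and small. At $p = 3$ the memberships are so
flat that all centers receive near-identical updates and collapse onto the
pooled mean, a symmetric fixed point the deterministic dynamics cannot
leave; we observed exactly this at high donor counts. At very large $p$ the
assignment hardens before any structure exists and freezes noise instead.
The default `power = 8` sits in the regime where the dynamics still
self-organize from weak centers but sharpen enough to keep donors apart; it
was chosen on simulated mixtures spanning 2–64 donors and is exposed in
`khm_config()`.

**Annealing.** Deterministic annealing evaluates memberships on
$d^{1/T}$ — equivalently it scales the membership exponent to $(p+2)/T$ —
with $T$ decaying geometrically to 1. Because the membership landscape on
log-likelihood distances is already nearly flat, only a gentle schedule is
productive: large starting temperatures push the system into the collapsed
symmetric state described above. The default schedule starts at
$T = 1.2$ with decay 0.8 and three sweeps per stage, then iterates at
$T = 1$ until the relative loss change falls below `tol` ($10^{-7}$) or a
600-sweep cap; hitting the cap returns the best state with a warning
rather than an error. The loss trace is always recorded at $T = 1$
distances.

## Initialization: 10× merge

`initialize_10x()` over-generates $10k$ preliminary centers and greedily
merges the closest pair — under the coverage-weighted squared difference
$\sum_v w_v (a_v - b_v)^2$, $w_v$ = total reads at variant $v$ — replacing
it by the per-variant mean, until $k$ remain. Merging is deterministic
(ties break on the lowest index pair), and the survivors are pairwise
well-separated, which protects against seeding two centers inside one
donor.

Each preliminary center is seeded from one uniformly sampled cell (without
replacement): covered sites take the smoothed cell fraction
$(a+1)/(a+r+2)$, uncovered sites fall back to the dataset-wide smoothed
alt fraction of that variant. This directly answers the sparse-data
objection to kmeans++-style seeding — every dimension of the seed has a
defined, sensible value. "Number of alleles" in the merge weight is read as
total read count; `variant_weights(mode = "cells")` provides the
covered-cell count alternative.

## The full pipeline

`demux()` runs five stages. The middle three are the package's own design
choices, made because a single KHM fit at exactly $k$ centers still merges
donors at high $k$:

1. **Organizing fit at 2k centers.** The 10× merge initializer and the
   annealed KHM fit run with `overcluster * k` centers (default factor 2).
   With spare centers available, the soft dynamics almost never leave a
   donor uncovered: the typical failure pattern becomes duplicated donors
   plus starved junk centers — both much easier to repair than merged
   donors.
2. **Reduction to k.** Centers are hard-assigned; a center is pruned as
   junk when its occupancy falls below `prune_occupancy` (default 0.25) of
   the median occupancy *and* it fits its members worse than the median
   center. The second condition protects genuine minority-donor clusters,
   which are small but internally coherent. Surviving centers — real
   donors, some represented twice — are then merged down to $k$ with the
   same closest-pair machinery; duplicate centers sit at tiny distances
   and merge first.
3. **Hard polish.** Alternating hard maximum-likelihood assignment with
   the smoothed MLE update (`polish_centers(mode = "mle")`) removes the
   blending that soft memberships leave in the centers. On simulations,
   assignment against sharp centers is dramatically more accurate than
   against soft ones.
4. **Refinement** (below).
5. **Genotype polish.** Donors are diploid, so true alt fractions lie at
   dosage values $\{\epsilon, 1/2, 1-\epsilon\}$. The final polish
   (`polish_centers(mode = "genotype")`) replaces each (cluster, variant)
   fraction by the posterior mean of the three dosage fractions given the
   cluster's pooled counts, under a Hardy–Weinberg prior computed from the
   pooled population alt frequency. This empirical-Bayes shrinkage is most
   valuable for small clusters: a 20-cell minority donor pools only ~2–3
   reads per site, and its raw MLE center is noisy enough to strand its own
   cells in neighboring clusters.

## Refinement with locking

After the polish, `score_clusters()` rates every cluster by hard-assigned
size and by the mean distance of its members to their own center. Outliers
are robust-z outliers — below $-2.5$ on $\log(1+\text{size})$ (or empty),
or above $+2.5$ on mean loss — using median/MAD so the outliers being
hunted cannot distort the yardstick. With zero MAD only empty clusters are
size outliers.

Each refinement round rebuilds the $m$ outlier centers by the 10× merge
recipe ($10m$ preliminary centers, merged to $m$), seeded from the cells
currently assigned to the outlier clusters: those are by construction the
worst-explained cells, and restricting the rebuild to them (including a
small KHM fit plus polish against that cell pool) lets two donors trapped
in one merged cluster actually separate — preliminary centers drawn from
the whole dataset merely reproduce the global mean. All non-outlier
clusters are locked (their fraction rows are bit-identical through the
refit; `lock_fraction` exposes partial locking, and locks are released
between rounds), and the annealed fit plus polish reruns. A round is
accepted only if the total best-assignment log-likelihood improves;
otherwise it is rolled back and the next round draws different seeds. The
loop stops when no outliers remain, after `max_rounds` (default 10), or
after three consecutive rejected rounds. The acceptance guard makes
refinement monotone: it can repair a clustering but never quietly damage
one.

## Doublet calling

A cross-donor doublet contains two cells' RNA, so its expected alt fraction
is the mean of the two donors' fractions (equal mixing — the standard
troublet assumption; unequal mixtures are out of scope). `call_cells()`
computes each cell's best singlet log-likelihood over $k$ clusters and best
doublet log-likelihood over all $k(k-1)/2$ pairs (exact search), then the
log-space posterior with prior doublet rate `doublet_prior` (default 0.08,
the expectation for a ~20,000-cell load). Cells covering fewer than
`min_coverage` variants (default 10) are reported `unassigned` — calls from
fewer sites are noise. Same-donor doublets are genotypically invisible and
are not modeled.

## The simulator

`simulate_mixture()` generates the benchmark regime the clustering is
designed for: per variant a population alt frequency
$f \sim \mathrm{Beta}(1, 3)$ (skewed to low-frequency variants, as SNP
panels are); per donor a dosage $\sim \mathrm{Binomial}(2, f)$
(Hardy–Weinberg); each barcode draws its donor(s) from the loading
proportions, becoming a doublet with the configured probability; each
(cell, variant) pair is covered independently with probability
`coverage_density` (default 0.05); covered sites draw
$1 + \mathrm{Poisson}(\text{depth\_mean} - 1)$ reads (default mean 2) with
a symmetric per-read miscall rate (default 0.005); alt counts are binomial
around the dosage fraction (doublets: the mean of the two donors'
dosages). All draws are seeded and reproducible.

What it deliberately does not model: gene-expression structure (coverage is
independent across sites, whereas real coverage concentrates in expressed
genes), ambient RNA, UMI duplication, linkage between nearby SNPs, and
unequal RNA content within doublets. Tests passing on these simulations
therefore demonstrate the clustering mechanics — initialization, escape
from merged-donor optima, minority-donor retention, doublet geometry — not
robustness to those real-data artifacts.

## Evaluation metrics

`adjusted_rand_index()` implements the Hubert–Arabie chance-corrected form
from the contingency table; the test suite checks it against brute-force
pair counting and an independent implementation. `incorrectly_merged_count()`
maps every true donor to its modal predicted cluster and counts predicted
clusters claimed by two or more donors — the deterministic, scale-free
formalization of the merged-cluster artifact. A donor whose cells are less
than 60% concentrated in its modal cluster is reported by the secondary
`split_donor_count()` diagnostic. Metrics are computed on true singlets
that the pipeline also called singlet (`evaluate_calls()`, with a switch to
score all true singlets).

## Problem sizes and numerical choices

The test suite exercises the pipeline at the scales a single desk machine
handles comfortably: mixtures from 2 to 64 donors, up to 3,200 cells and
2,000 variants for the high-donor runs (about 50 cells per donor at 5%
coverage), and 1,500–2,400-cell runs for the unbalanced-mixture checks
with a 0.84% minority donor. Degenerate inputs are defined behavior:
zero-coverage cells carry uniform memberships, never move centers, and are
reported `unassigned`; empty clusters fall to the smoothing prior (fraction
1/2) and are flagged by scoring; ties in hard assignment and closest-pair
merging break deterministically toward the lowest index. All stochastic
steps draw from locally seeded RNG, so a fit is a pure function of inputs
and seeds.

## Known limitations

The donor count is an input, not inferred. Ambient RNA is not modeled, and
heavily contaminated data will blur centers toward the pooled mean. The
doublet model assumes equal RNA contribution from both cells. The
beta-binomial path is evaluated per covered entry and is markedly slower
than the linear-algebra binomial path; it is intended for moderate problem
sizes. Above roughly $10^4$ cells the exact all-pairs doublet search at
$k = 64$ (2,016 synthetic centers) becomes the dominant cost of calling.
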