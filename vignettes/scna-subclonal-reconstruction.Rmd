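---
title: "Reconstructing tumor subclones from somatic copy-number alterations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing tumor subclones from somatic copy-number alterations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scnapop)
```

## The problem

A bulk tumor sample is a mixture: normal cells plus one or more tumor
subclones related by an evolutionary tree.  A somatic copy-number alteration
(SCNA) carried by a clone is carried by all of that clone's descendants, so
each SCNA `j` has a *subclonal frequency* `phi_j` — the fraction of cells in
the sample carrying it — and an integer *absolute copy number* `C_j` in
those cells (normal cells carry 2 copies).  Whole-genome sequencing of the
tumor and its matched normal observes two summaries per segment:

* the tumor/normal read-count ratio, proportional (after bias correction)
  to the population-averaged copy number
  `cbar_j = phi_j * C_j + (1 - phi_j) * 2`, and
* the B-allele frequencies (BAF) of heterozygous germline SNPs inside the
  segment, whose average reflects the allelic composition
  `mu_bar = (phi_j * C_j * mu_T + (1 - phi_j)) / cbar_j`, where
  `mu_T = n_M / C_j` is the fraction of maternal copies in the tumor
  genotype.  Because the B allele sits on either haplotype, only the folded
  value `min(mu, 1 - mu)` is informative.

`scnapop` estimates `(phi_j, C_j)` jointly for all segments, under a
tree-structured stick-breaking (TSSB) Dirichlet-process prior over the
clone tree, and provides the supporting stages a real pipeline needs:
GC-bias correction, removal of false-positive breakpoints produced by
over-sensitive segmentation, and detection of the copy-neutral "baseline"
segments that anchor the ratio scale.

## Solution multiplicity

Eliminating `phi_j` from the two observation equations shows that two
states `(C', mu')` and `(C'', mu'')` can explain the same observation
`(cbar, mu_hat)` exactly when they share the invariant

```
xi = (C * mu_hat_T - 1) / (C - 2).
```

`enumerate_curves()` enumerates the family of observation curves indexed by
`xi` over all genotype-realizable pairs up to a copy-number cap:

```{r curves}
cv <- enumerate_curves(15)
nrow(cv)
sum(cv$multi_solution)
```

Of the 43 curves at `c_max = 15`, seven admit multiple frequency solutions
in the amplified region (`cbar > 2` with `cbar >= 1/mu_hat`); deletions
(`cbar < 2`) are always uniquely solvable, as `classify_solutions()`
reports case by case.  The enumeration excludes `C = 0` and `C = 1` by
default: pure deletions carry no heterozygous B allele and hence no BAF
curve (an `include_deletions` flag restores `C = 1` for completeness).

This is not a technicality.  In the validation scenario below, four of the
six simulated SCNAs lie on the worst curve (`xi = 0`, one minority copy),
and their posterior is a ladder of exactly likelihood-equivalent `(phi, C)`
rungs; see *Limitations*.

## The probability model

For segment `j` with tumor/normal counts `(D_S, D_N)` and SNP counts
`{(b_k, d_k)}`:

* `D_S ~ Poisson(invert_bias((cbar_j / 2) * theta) * D_N)`, where `theta`
  is the geometric mean of the corrected ratios of the baseline segments
  and `invert_bias` maps the expectation back to the raw scale of the
  observed counts;
* `b_k ~ 0.5 * Binom(d_k, mu_hat) + 0.5 * Binom(d_k, 1 - mu_hat)` with
  `mu_hat` the expected folded BAF of the genotype at `phi`.  The
  symmetric two-component mixture encodes that each SNP's B allele sits on
  either haplotype with equal probability; it normalizes exactly, reduces
  to `Binom(d, 1/2)` for balanced states, and makes mirrored genotypes
  (swapping P and M) exactly equivalent — which is why both are retained
  in `genotype_set()` without harm;
* the copy-number support is split by the baseline scale (ratio below
  `theta`: `C` in {0, 1, 2}; above: {2, ..., c_max}, equality assigned to
  the amplification branch so that the shared neutral state `C = 2` is
  always available);
* the marginal segment likelihood sums read-count and BAF terms over the
  support and over all genotypes of each copy number, unweighted, in
  log-sum-exp form.  One genotype applies to the whole segment (allelic
  imbalance is a property of the segment, not of a locus).  A segment with
  no SNPs contributes its read-count term once per copy number.

The prior over trees is the TSSB construction: depth sticks
`nu ~ Beta(1, alpha * lambda^depth)` and branch sticks `psi ~ Beta(1,
gamma)` give every node of an infinite tree a prior mass.  Each node also
carries a subpopulation weight; weights live on the simplex with a flat
Dirichlet prior, the remainder being normal cells plus uninstantiated
clones, and `phi(node)` is the node's subtree weight sum — so
`phi(parent) >= phi(child)` by construction.

### The sampler

Each MCMC cycle runs three kernels:

1. *Assignments*: Gibbs over instantiated nodes (prior mass times the
   segment's marginal likelihood at the node's `phi`) plus a handful of
   lazily instantiated fresh candidates carrying equal shares of the
   residual stick mass; a chosen fresh node is funded by a uniform slice of
   its parent's own weight, leaving every existing `phi` unchanged.
2. *Weights*: Metropolis transfers of weight between two random slots
   (nodes or the residual) with step sizes drawn from a fixed ladder
   (0.002–0.2), so both fine conditioning and mode jumps are proposed.
   Only segments on the two affected root paths need likelihood updates.
3. *Sticks*: conjugate Beta updates given the assignment counts.

Defaults follow the study design: burn-in 50 cycles, 300 recorded cycles,
`alpha = gamma = 1`, uniform base distribution, `c_max = 15`.  Every
recorded state stores, per segment, the assigned node, its `phi`, and the
maximum-likelihood `(C, genotype)` at that `phi`; `map_state()` returns the
highest-posterior recorded state, and `edge_probabilities()` estimates the
partial order of clones by counting directed edges across recorded trees,
matching nodes between states by maximal Jaccard overlap of their segment
sets (node identity across MCMC states is otherwise undefined).

For samples that violate the infinite-sites assumption (each clone carrying
many SCNAs, e.g. mixtures of cell lines), `flat_infer()` replaces the tree
prior with a uniform one and maximizes each segment's marginal likelihood
on a `phi` grid (default step 0.01); `flat_population_clusters()` then
groups segments into population-level frequencies.

## Supporting stages

**GC-bias correction.**  The raw log ratio is fit against GC content by
least squares with iterated 3-MAD trimming of residuals (at most 10 passes,
until the kept set stabilizes): copy-altered segments are ratio outliers
that would otherwise tilt the slope, and the trim converges on the
copy-neutral majority.  The model is anchored at the length-weighted mean
GC, making `bias_correct()`/`bias_invert()` exact inverses — the inverse is
required by the Poisson mean above.  Correction runs before all other
stages, matching the pipeline's stage order.

**Breakpoint filter.**  Over-sensitive segmentation splits one SCNA into
fragments that share `cbar` and folded BAF, so the filter (i) clusters
segments on log corrected ratio, (ii) splits each cluster by the BAF modes
of its pooled SNPs (1-D Gaussian mean-shift, implemented here as no
installed package provides it), and (iii) merges adjacent fragments of the
same cell.  Design choices where the procedure itself is underdetermined:

* *Aggregation metric*: the clustering distance is the log-ratio difference
  divided by the pooled counting standard error
  `sqrt(1/D_S + 1/D_N)` of the two segments, with average linkage and a
  cut at 4 noise units (cluster count capped at `c_max * tau`).  Cutting
  the tree at a fixed cluster *count* equal to the cap would leave nearly
  every fragment alone and defeat merging; a fixed *height* in log-ratio
  units would either shred high-noise small fragments or fuse distinct
  states — the noise-normalized metric adapts to fragment size by
  construction.
* *Bandwidth*: Silverman's rule on the pooled folded BAFs, floored at half
  the median per-locus binomial noise `sqrt(0.25 / depth)`; a narrower
  kernel resolves sampling noise, not genotype structure.
* *Untyped fragments*: a fragment with fewer than `min_baf_snps = 3` loci
  cannot vote reliably; it is reported as BAF-untyped (label 0) and treated
  as compatible with either adjacent neighbor of its ratio cluster during
  merging.  Strictly isolating untyped fragments would leave most tiny
  split products unmerged, since short fragments often contain 0–2 SNPs.
* *Merge gap*: `rho = 1` bp by default — only book-ended fragments (the
  products of a split) merge; no stated default exists, and a larger `rho`
  risks bridging real gaps.

Merging never crosses chromosomes or ratio clusters and conserves read
counts, lengths and SNPs exactly.

**Baseline detection.**  Copy-neutral segments are found in two steps.
First, balanced BAF: folding biases any naive distance from 1/2 (the median
folded BAF of a truly balanced segment sits below 0.5 by the half-normal
median), so the test instead averages the unbiased per-locus estimator of
`(mu - 1/2)^2`, `1/4 - b(d - b)/(d(d - 1))`, and accepts within
`baf_tol^2` (default `baf_tol = 0.03`) plus twice the standard error of
that average — the sampling allowance keeps true baselines from failing by
noise.  Second, depth: balanced aberrations (homozygous deletions diluted
by normal cells, PPMM-like gains) also show BAF 1/2 but scale the SNP depth
by `cbar / 2`, so segments whose mean SNP depth is not within `depth_tol`
(default 0.1, relative) of the expected copy-neutral coverage are dropped.
Exact equality tests are meaningless on counts; both tolerances are
explicit, documented defaults.

## The synthetic-data generator

`simulate_scna()` emulates, at count level, the data a segmenter and an
allele counter would produce: Poisson normal reads (`coverage * length`),
Poisson tumor reads conditioned on the realized normal count with an
injected log-linear GC effect, and binomial SNP counts at
`snp_rate` loci per base with Poisson depths (floored at 1) scaled by
`cbar / 2`.  `inject_false_breakpoints()` splits segments at Poisson-many
uniform positions, apportioning counts multinomially — the count-level
analogue of an over-sensitive segmenter.  What it does *not* emulate:
alignment and mappability artifacts, overdispersion beyond Poisson,
sequencing error in allele counts, segmentation boundary jitter (injected
breakpoints are exact), and linked haplotype structure.  Tests passing on
this generator therefore validate the inference machinery, not robustness
to every artifact of real data.

The standard validation scenario (`six_scna_scenario()`) places six SCNAs
on chromosome 21 — a homozygous deletion at frequency 0.95, gains of 3, 4,
5 (genotype PMMMM) and 7 (MPPPPPP) copies at 0.30, 0.10, 0.50 and 0.10,
and a single-copy loss at 0.30 — plus 24 copy-neutral 500-kb segments.
The clone tree is reconstructed from the stated frequencies under the
simplex constraint (subpopulation weights must be positive and sum to at
most 1): the deletion clone is the root (weight 0.15), with children at
subclonal frequency 0.50 (carrying the PMMMM gain) and 0.30 (the
single-copy loss); the 3-copy clone (0.30) descends from the 0.50 clone
and carries the 4-copy clone (0.10); the 7-copy clone (0.10) descends from
the loss clone.  Defaults chosen once for the scenario: coverage 0.03
reads/bp (about 15,000 normal reads per 500-kb segment), one heterozygous
SNP per 10 kb, SNP depth 30 (a typical whole-genome depth), GC slope 0.5.

## Problem sizes and runtime

The validation scenario is 30 segments and roughly 1,500 SNP loci; a full
tree-mode run (50 + 300 cycles) takes a few minutes on one core, the
breakpoint-filter and solution-space analyses take seconds, and the test
suite uses shorter chains for everything except the single end-to-end
recovery run.

## Numerical choices

* All likelihoods in natural log; mixtures via log-sum-exp.
* `ratio = theta` is assigned to the amplification support (which contains
  the neutral `C = 2`, so the choice cannot bias a truly neutral segment).
* Ties in `map_copy_number()` break toward smaller `C`, then smaller
  maternal count; ties in the per-segment BAF vote toward the lowest
  cluster label; `map_state()` ties toward the earliest iteration.
* `mu_T` for `C = 0` is algebraically irrelevant (the tumor term vanishes);
  the degenerate `phi = 1, C = 0` case returns folded BAF 0.5 with a flag.
* Segments with zero tumor reads keep a positive ratio by flooring the
  numerator at one read; the Poisson likelihood still sees the raw count.
* xi curves are grouped by exact reduced fractions, never by floating
  comparison.

## Limitations

* Segments on multi-solution curves are not identifiable from one sample.
  In the validation scenario the 3-, 4-, 5- and 7-copy SCNAs all lie on
  `xi = 0`, so each has a ladder of `(phi, C)` explanations with equal
  maximum likelihood (`phi = (cbar - 2)/(C - 2)`); the unweighted genotype
  sum further rewards the low-`phi` region where neighboring rungs overlap
  within counting noise, and the tree prior rewards sharing a node with an
  identifiable segment whose `phi` matches a rung.  The reported MAP for
  such segments is therefore one admissible rung — reproducibly the shared
  or low-frequency one — rather than necessarily the generating state.
  The uniquely solvable segments (the deletion at 0.95, the single-copy
  loss) are recovered robustly.  Multi-sample designs or SNV co-assignment,
  both out of scope here, are the standard remedies.
* The GC model is a single log-linear term; position-dependent (wave) and
  mappability biases are not corrected.
* Count-level simulation understates real-data dispersion; tolerances
  validated here may be optimistic for noisy libraries.
* The flat mode treats segments independently and will not resolve clones
  closer in frequency than its grid step and the data's own resolution.
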