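---
title: "Demographic inference for Chinese bayberry domestication: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Demographic inference for Chinese bayberry domestication: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Chinese bayberry (*Morella rubra*) was domesticated from wild
populations of southeastern China, and its cultivated germplasm falls
into recognizable tiers: landraces (PL), the elite cultivar groups FH,
DK ('Dongkui') and BQ ('Biqi'), and a small set of recent hybrids (HY).
RAD-seq SNP panels from these groups carry the footprint of that
history: a domestication split between wild and landrace populations a
few thousand years ago, successive "improvement" splits that carved the
elite cultivars out of the landrace gene pool, drastic reductions in
effective size caused by clonal propagation of elite material, and a
very recent hybridization pulse between BQ and FH that produced HY.

This package implements the full quantitative machinery needed to study
that history on SNP data: a structured-coalescent simulator for the
six-population model, summary statistics (nucleotide diversity π,
Weir–Cockerham and Hudson F~ST~, LD pruning, allele-sharing distances),
site-frequency-spectrum (SFS) construction with hypergeometric
projection, composite-likelihood demographic inference with parametric
bootstrap, ancestry-coefficient estimation under the ADMIXTURE model,
and neighbor-joining trees.

# The demographic model

Six present-day populations with constant diploid effective sizes
(`N_Wild`, `N_PL`, `N_FH`, `N_DK`, `N_BQ`, `N_HY`) are connected,
backward in time, by five events at times expressed in years:

1. `T_hybridization` — HY is resolved as an admixture pulse: each HY
   lineage traces to BQ with probability `r` and to FH otherwise.
2. `T_improvement3` — BQ and DK merge into their common recent
   cultivar.
3. `T_improvement2` — that ancestor merges with FH.
4. `T_improvement1` — the cultivar ancestor merges into PL.
5. `T_domestication` — PL merges into the wild population.

Times are converted to generations with `generation_time` (default 10
years; bayberry is a long-lived grafted tree and no generation time is
canonically established, but every recovery analysis in this package is
invariant to the choice because it cancels between simulation and
fitting). The `parameter_set()` defaults are the best-fit values of
this model (sizes 4526, 1504, 25, 16, 20, 37; `r = 0.54397`; times 60,
100, 240, 1890, 3270 years), so the default simulator output *is* the
study condition the package is built to reproduce.

## Ancestral ("stem") sizes

Only the six present-day sizes are free parameters, so the sizes of the
internal branches must be fixed by convention. We chose, once:

* the BQ+DK ancestor keeps `N_DK` — it represents a single recent
  cultivar, so a clone-scale size is the natural choice;
* at the `T_improvement2` merge the cultivar stem is resized to `N_PL`
  — before distinct elite cultivars were singled out, cultivated
  bayberry was a landrace-scale population, and a clone-scale stem
  lasting the ~165 generations between `T_improvement2` and
  `T_improvement1` would erase essentially all cultivar diversity,
  contradicting the observed π ratios (~0.0013–0.0017 in cultivars vs
  0.0021 in the wild group);
* the PL stem and the root keep `N_PL` and `N_Wild`.

Under this convention the simulated per-group diversity reproduces the
published ranking (Wild ≈ PL ≈ HY > FH > DK ≈ BQ). No convention we
examined reproduces the published *F*~ST~ ordering among cultivars
(0.45 for BQ–DK exceeding 0.31 for BQ–FH): for any stem sizes,
F~ST~(BQ, DK) ≈ 1 − (s~BQ~ + s~DK~)/2, where s~X~ = exp(−t~X~/2N~X~) is
the terminal-branch pair-survival, which is ~0.25 at the best-fit sizes
and times, while F~ST~(BQ, FH) ≥ 0.30 always. The published 0.45 was
measured on the real data, which the fitted model evidently does not
fully capture in this respect; the package reports this ordering check
honestly rather than forcing it.

# The simulator

`simulate_genotypes()` runs an independent structured-coalescent tree
per locus (free recombination between loci, none within — the unlinked-
SNP regime SFS inference assumes). Within a population of diploid size
N, each lineage pair coalesces at rate 1/(2N) per generation;
divergence events move all lineages of the derived population into the
ancestral one; admixture events route each lineage independently.
Mutations fall on branches as Poisson with rate μ per generation under
infinite sites, each becoming one biallelic SNP column (ALT = derived).
Haplotypes are paired into diploids at random within populations. The
default `mutation_rate = 5e-7` per locus corresponds to a ~50 bp RAD
tag at 10^-8^ per site per generation; with the default 150 000 loci
this yields panels of roughly 5 000–6 000 SNPs, the desk-scale analogue
of the study's 67 064-SNP panel. `add_missingness()` emulates RAD-seq
sparsity by masking genotypes independently.

The simulator is validated against closed forms (E[TMRCA] = 2N,
E[π] = 4Nμ, E[ξ~i~] = θ/i, Watterson unbiasedness, split-model F~ST~ =
t/(t+2N)) and against msprime as an independent coalescent
implementation.

# Spectra

`build_sfs()` tabulates derived-allele counts per site and group,
down-projecting sites with missing data to a fixed haploid size via the
hypergeometric expectation (fractional mass over compatible cells;
sites below the projection size are dropped). Spectra are folded by
default — REF/ALT polarity in real panels carries no ancestral
information — with cells mapped to their minor-allele-total equivalent
and ties at the fold axis resolved lexicographically. Joint spectra
over more than three populations are stored sparsely. The default
projection is the 10th percentile of per-site called-allele counts, so
at most ~10% of sites are lost to projection.

Inference uses the composite of all 15 pairwise two-dimensional folded
spectra (`build_pairwise_sfs()`) rather than the six-dimensional joint
spectrum, which is hopelessly sparse at desk sample sizes.

# The likelihood and its scale anchor

`expected_sfs()` estimates cell probabilities by simulating `n_sims`
trees and accumulating each branch's *length* into the frequency cell
of its descendant set. Because a mutation lands on a branch with
probability proportional to its length, the normalized mass is exactly
the low-mutation-limit conditional SFS; compared with literally
dropping mutations this removes all mutation-sampling noise at equal
cost, which matters because the optimizer sees a stochastic surface.
Never-hit cells receive a floor of `0.1/n_sims` before renormalization.

`composite_loglik()` is the multinomial composite log-likelihood
Σ m~i~ log p̂~i~ over polymorphic cells (cells monomorphic within a
pair are masked on both sides).

A spectrum of *polymorphic* cells alone cannot identify the absolute
scale: multiplying every size and time by a constant leaves the
normalized SFS unchanged (coalescent scale invariance). SNP-only
composite likelihoods therefore need one extra piece of information.
Since the simulated panels know their total locus count L and mutation
rate μ — both are study conditions, exactly as a fixed per-site μ is in
real fastsimcoal analyses — the fit adds a Poisson term on the observed
SNP count S with mean L·μ·E[total tree length]. This anchors the scale
without touching the monomorphic spectrum cells.

# Optimization

The likelihood surface is stochastic, 12-dimensional, and has a long
soft ridge coupling (`N_Wild`, `N_PL`, `T_improvement1`,
`T_domestication`). Three choices matter:

* **Bounded sigmoid coordinates.** Each parameter is optimized as a
  sigmoid-transformed coordinate inside its box (geometric
  interpolation for sizes and time gaps, arithmetic for `r`); times are
  parameterized as the five positive gaps between consecutive events,
  so the event ordering holds by construction.
* **An explicit-step Nelder–Mead.** `stats::optim`'s simplex is built
  proportionally to the starting values; in centred transformed
  coordinates that yields a minuscule simplex that stalls far from the
  optimum (we observed stable stalls 50–150 log-units below the truth).
  `nelder_mead()` sets the initial simplex edge explicitly and uses the
  Gao–Han dimension-adaptive coefficients.
* **Seed-refreshed refinement.** With a single fixed simulation seed
  the optimizer eventually climbs into wrinkles of that particular
  noise realization: points can appear ~100 log-units better under the
  optimization seed than under fresh seeds. The fit therefore explores
  with multi-start Nelder–Mead on a cheap surface (`warm_sims` trees,
  common random numbers within the stage), then runs `n_cycles`
  full-fidelity refinements, each under a fresh common-random-number
  seed; a point that only looked good by noise is devalued at the next
  cycle, while genuine optima persist.

Default bounds (`bayberry_par_table()`) are the published confidence
bands widened fourfold. Model comparison (`compare_models()`) ranks
candidates by AIC computed from the composite log-likelihood — a
standard, if nominal, treatment since composite likelihoods are not
full likelihoods — with ties broken toward fewer parameters.
Confidence intervals come from `parametric_bootstrap()` (simulate under
the fitted parameters, refit, percentile intervals), which is labelled
as such; how the original study's intervals were produced is not
something this package claims to replicate.

# The recovery study

`parameter_recovery()` is the package's core self-consistency check and
what `scripts/acceptance.R` runs: five replicate panels of 10 diploids
per group over 125 000 loci (~5 000–5 500 SNPs) simulated at the
default parameter values, each refit with `n_sims = 10^4`, 5 starts,
`maxit = 180`, 3 refinement cycles — about 2–3 minutes per replicate on
one CPU. For fitting, the wild and PL samples are kept in full while
the cultivar groups are subsampled to 5 diploids: the deep-time signal
lives in the wild/landrace spectra, the drifted cultivar spectra
saturate at small sample sizes, and halving the tree size roughly
halves the cost of every likelihood evaluation. Sites monomorphic
within the retained samples are dropped and the SNP-count anchor is
computed on the same subsample, keeping observed and expected
quantities exactly comparable.

What passing recovery does and does not show: the synthetic panels
share the study's group structure, SNP sparsity and parameter scale,
but they are generated by the very model being fitted — no model
misspecification, no linkage within RAD tags, no SNP-calling error, no
reference bias, and missingness only under an independent-masking
model. Recovery inside the published confidence bands demonstrates that
the inference machinery is consistent at the study's scale, not that
the published history is correct.

# Numerical choices and degenerate inputs

* Genotype codes count ALT alleles; half-calls are treated as fully
  missing (conservative, standard practice).
* π uses the unbiased per-site estimator 2j(n−j)/(n(n−1)) over called
  alleles; the denominator is `total_sites` when supplied (per-total-
  site π, the scale on which ~0.002 is printed) and otherwise the
  variant count, flagged as variant-only.
* Negative F~ST~ estimates are clipped to 0 for reporting with the raw
  value retained.
* LD pruning removes, within each 50-SNP window (step 10), the
  lower-MAF member of the worst pair above r² = 0.2 until none remains
  (the de-facto standard triple; deterministic tie-breaks: worst pair
  first in site order, equal-MAF ties drop the later site).
* NJ trees clamp negative branch lengths to zero with a message;
  quoting in Newick output follows the single-quote convention.
* EM ancestry clamps F to [10^-6^, 1−10^-6^] and floors Q at 10^-9^
  before renormalizing; the log-likelihood is asserted non-decreasing
  at every iteration.
* The pipeline derives per-stage seeds as `seed + 100 × stage index`,
  so any stage can be reproduced in isolation.

# Known limitations

* Constant population sizes per branch; no growth, no migration other
  than the single HY pulse, no selection — matching the fitted model's
  own assumptions.
* The composite likelihood double-counts information across the 15
  pairs; its AIC and bootstrap intervals are therefore approximate
  tools, adequate for model ranking and order-of-magnitude uncertainty.
* ML phylogenetics is deliberately out of scope; the NJ tree is a
  qualitative topology check, not a reproduction of the published ML
  tree's support values.
* The published cultivar F~ST~ ordering is unreachable under the
  published best-fit parameters (see above); the package reports this
  rather than papering over it.
* Likewise for the published K = 2 ancestry pattern in which HY shares
  the wild/landrace component: under the fitted model HY *is* a
  BQ/FH mixture, and the EM faithfully recovers it as such (Q ≈ 0.56
  toward BQ's cluster, tracking `r = 0.544`), so on model-simulated
  data HY's dominant component sides with the cultivars. The real HY
  accessions are plausibly wild × cultivar hybrids — a feature the
  best-fit model topology does not encode. Self-consistency checks on
  simulated data can only validate the machinery against the model,
  not the model against the data it was fitted to.
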