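---
title: "Detecting intramolecular coevolution around a focal residue: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting intramolecular coevolution around a focal residue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coevoscan)
```

# The problem

A recurring question in protein molecular evolution is whether a focal
residue — here the archetype is site 122 of vertebrate rhodopsin (bovine RH1
numbering), a determinant of both spectral tuning and the stability of the
light-activated metarhodopsin-II conformation — is embedded in a network of
*coevolving* sites. Such networks arise by entrenchment: once a substitution
is fixed in a lineage, compensatory residues at structurally interacting
positions are themselves driven to fixation, and the whole motif becomes
mutually constrained.

No single statistic settles the question, so `coevoscan` combines three
independent lines of phylogenetic evidence, a structural filter, ancestral
reconstruction, and in-vitro photochemistry curve fits:

1. **Codon site-class models of dN/dS** (M-series and Clade Model C) detect
   lineage-specific shifts in purifying selection at candidate sites.
2. **Weighted, average-product-corrected mutual information** (MI) between
   alignment columns detects statistical covariation with the focal column.
3. **Pagel-type tests of correlated evolution** between binary
   consensus/variant encodings of two sites detect correlated substitution
   histories on the tree.

The evidence synthesis is deliberately a *join*, not a combined score: each
line is reported per site and read together, mirroring how such tables are
interpreted in practice.

# Codon site-class models

## Rate matrix

Substitution between sense codons $i \to j$ follows a GY94-style generator:
zero unless $i$ and $j$ differ at exactly one nucleotide, and otherwise
proportional to $\pi_j$, times $\kappa$ for transitions and $\omega = d_N/d_S$
for nonsynonymous changes. Stationary frequencies $\pi$ default to F3x4
(position-specific nucleotide frequencies with a single pseudocount; F61 is
available via `freq = "F61"`). The matrix exponential is computed through the
symmetric eigendecomposition of $D^{1/2} Q D^{-1/2}$ ($D = \mathrm{diag}(\pi)$),
which is exact for these reversible generators; transition matrices are cached
per unique (generator, branch length) pair.

```{r rate-matrix}
spec <- codon_rate_spec(kappa = 2, pi = rep(1 / 61, 61), omega = 0.4)
Q <- build_codon_Q(spec)
range(rowSums(Q)) # rows sum to zero
```

## Site classes and normalization

The fitted models are M0, M1a, M2a, M3, M7, M8, M8a, M2a_rel and Clade Model
C (CmC). Beta-distributed classes (M7/M8/M8a) use $K$ equal-probability
categories represented by their medians ($K = 10$ by default, the common
default of codon-model software; `n_beta_cat` exposes it). The beta shape
parameters are bounded in $[0.005, 100]$, and the extra-class $\omega_p \ge 1$
is enforced in M8 (exactly 1 in M8a). All class generators share one
mixture-average rate normalization (for branch-heterogeneous classes, using
the background $\omega$), so branch lengths are expected substitutions per
codon across the mixture, and simulation and inference use identical units.

CmC has three classes: $0 < \omega_0 < 1$ and $\omega_1 = 1$ shared across the
tree, and a divergent class whose $\omega_d$ takes a separate value in each
named foreground partition and in the background. Constraining all divergent
values equal recovers M2a_rel, so the CmC-vs-M2a_rel likelihood-ratio test has
one degree of freedom per foreground.

## Optimization and parameter counting

Free parameters are optimized with `nlminb` on unconstrained transforms
(softmax proportions, logit for $(0,1)$ omegas, bounded-log for beta shapes,
$\log$ for $\kappa$ and the branch scale), from the heuristic default start,
deterministic alternates at informative corners (M8 from the near-M8a corner;
CmC from the no-divergence corner), and random perturbations, for at least
three starts by default. Convergence is declared when the best restarts agree
to $10^{-4}$ in log-likelihood or the optimizer reports success; an invariant
alignment sets an identifiability flag instead of pretending $\omega$ is
estimable.

Branch lengths are taken from the input tree up to a single free scale factor
re-optimized per model (the fast path); full per-branch re-optimization is not
implemented — with trees from the same inference pipeline the scale factor is
the component that varies detectably between models, and none of the reported
quantities depend on per-branch refinements. `count_free_params()` counts
every free parameter identically across models (mixture parameters + $\kappa$
+ one per branch), so AIC differences and LRT degrees of freedom follow one
convention: CmC with one foreground vs M2a_rel gives df 1, two foregrounds
df 2, M8 vs M7 df 2, M8 vs M8a df 1. The `fix_kappa` option holds $\kappa$ at
a supplied value (e.g. an M0 estimate) for replicated null simulations, where
it is shared by both members of a nested pair and leaves the contrast valid.

Per-site classification is **naive empirical Bayes at the MLEs** (posterior
over classes given the fitted parameters). Full Bayes empirical Bayes
integration over parameter uncertainty is out of scope; every CmC fit carries
a flag saying so, and posteriors near 0.5 should be read with that in mind.

# Mutual information with a randomization cutoff

Columns are translated to amino acids; sequences are weighted by
single-linkage clustering at 62% identity (weight $1/$cluster size), the
conventional weighting of corrected-MI tools. Joint frequencies of a column
pair (pairwise deletion of gaps) are shrunk toward independence with
$\tilde f_{ab} = (1-\lambda) f_{ab} + \lambda f_a f_b$, $\lambda = 0.05$,
which leaves marginals unchanged; MI is in nats internally and only z-scores
are user-facing. The average-product correction (APC) subtracts
$\bar M_i \bar M_j / \bar M$ from each pair to remove shared background.

Corrected MI is standardized against a null of within-column shuffles of the
alignment (default 100), which destroy covariation while preserving each
column's composition. The family-wise cutoff $z^*$ is the maximum $|z|$ over
all pairs across fully randomized datasets (default 150, the headline
setting); because a within-column shuffle of a shuffled alignment is itself a
within-column shuffle, all randomized replicates share one shuffle null pool,
which is what makes the cutoff affordable without changing its definition. A
pair is significant only if $z > z^*$.

Two limitations are inherited from the method itself: MI is a qualitative
guide, not a calibrated test; and shared phylogeny inflates the MI of *all*
pairs relative to the shuffle null — the weighting and the APC absorb much of
this, the cutoff absorbs the rest family-wise, but on strongly structured
trees the per-pair z-scores should not be read as p-values.

# Correlated evolution of binary traits

Each candidate site is encoded 0 (consensus residue; ties broken
alphabetically by one-letter code) / 1 (variant) / missing (gap), and tested
against the focal site's encoding under the Pagel framework: a joint 4-state
chain over (00, 01, 10, 11) with single-trait transitions only; 4 free rates
under independence, 8 under dependence. Root state probabilities default to
the chain's stationary distribution (option: uniform). Rates are bounded in
$[10^{-6}, 100]$ on the tree rescaled to unit height.

The likelihood-ratio statistic is calibrated by parametric bootstrap
("Monte-Carlo test"): `n_sim` (default 1000) trait pairs are simulated under
the independent model at its MLEs, both models are refitted to each
replicate, and $p = (1 + \#\{\text{sim} \ge \text{obs}\}) / (n_\text{sim}+1)$,
which can never return 0. Replicates are redrawn until both traits are
polymorphic, because the observed test is only run on polymorphic traits
(monomorphic inputs are reported untestable, not forced). The observed fits
and the replicate fits share one optimizer budget (Nelder–Mead on log rates
with fresh-simplex restarts, implemented in C++), so the observed statistic
is exchangeable with the simulated ones — the property on which bootstrap
validity rests. The asymptotic $\chi^2_4$ p-value is reported alongside for
reference, and Bonferroni correction over the scanned sites (`bonferroni()`)
always reports the family size $m$ it used.

# Ancestral reconstruction

`marginal_reconstruct()` computes, per internal node and site, the marginal
posterior over the 61 codons by combining below-node partial likelihoods with
the likelihood of the rest of the tree (root prior $\pi$), per site class,
and collapsing classes with weights equal to the site's empirical-Bayes class
posteriors. The reported state is the posterior mode; ties are broken by
codon lexicographic order and flagged. `motif_report()` concatenates MAP
residues over a site quartet (default 119-122-123-124, the rhodopsin
coevolving motif positions) with the minimum codon posterior as the
uncertainty summary.

# Structural neighborhood

Distances are minimum heavy-atom (non-hydrogen) inter-residue distances on
one chain (first alternate locations), reported to 0.1 Å — the convention
most consistent with published inter-residue tables. The scan set around the
focal site is every residue within the radius (default 6 Å, the
distance range of van der Waals and hydrophobic contacts) plus the ±2
sequence neighbors regardless of measured side-chain distance, flagged as
such. Minimum distances do not satisfy the triangle inequality; nothing in
the package assumes they do. `write_synthetic_structure()` emits a clearly
labelled synthetic helix bundle used to exercise this machinery when no
experimental structure file is available.

# Photochemistry fits

**Absorbance template.** Dark spectra are fitted with the standard A1
visual-pigment nomogram (Govardovskii-type): the alpha band
$S(x) = 1/(e^{A(a-x)} + e^{B(b-x)} + e^{C(c-x)} + D)$ with
$x = \lambda_{max}/\lambda$, $A = 69.7$, $B = 28$, $C = -14.9$, $D = 0.674$,
$b = 0.922$, $c = 1.104$,
$a = 0.8795 + 0.0459\,e^{-(\lambda_{max}-300)^2/11940}$, plus a Gaussian beta
band (amplitude 0.26 at $189 + 0.315\,\lambda_{max}$ nm, width
$-40.5 + 0.195\,\lambda_{max}$ nm), included by default. The scale has a
closed form given $\lambda_{max}$, so the fit is a 0.1 nm grid search over
the window (default 450–550 nm) plus local refinement, and is invariant to
overall absorbance scaling. Baseline correction / normalization of measured
spectra is left to the caller — both conventions exist in practice, and the
fit itself is scale-free.

**Retinal release.** Fluorescence rise curves are fitted to
$y = y_0 + a(1 - e^{-bt})$ by Levenberg–Marquardt least squares
(`minpack.lm`), with $y_0$ started at the first point, $a$ at the range, $b$
from a log-linearized tail, and $b$ bounded in $(10^{-4}, 10)$ per min. The
half-life is $t_{1/2} = \ln 2 / b$ exactly. Fits with $r^2 \le 0.95$ are
flagged as failing the conventional quality gate; constant traces,
amplitudes indistinguishable from the residual noise, and rate constants at
their bounds are errors, not numbers. Groups of replicate half-lives are
compared with the two-tailed Welch t test, starred at 0.05/0.01/0.001.

```{r photochem}
tr <- simulate_release_trace(y0 = 1, a = 2, b = log(2) / 13.3, noise_sd = 0,
                             t_end = 60)
fit_retinal_release(tr$time_min, tr$fluorescence)
```

# The synthetic-data generators

Every input the pipeline consumes can be generated with known ground truth:
codon alignments evolved along a tree under a site-class mixture (optionally
with clade-shifted divergent omegas), planted covarying column pairs (a
residue-level bijection applied to the target column, which preserves the
source column's amino-acid entropy exactly; optional per-taxon noise),
correlated or independent binary trait pairs (exact transition-kernel
sampling along branches, equivalent in law to event-by-event simulation),
release traces sampled every 0.5 min (30 s recording intervals), and
template spectra with Gaussian noise. All simulators are pure functions of
their arguments and seed.

The default benchmark tree is a 30-taxon balanced topology of unit
root-to-tip height split into two named clades, mimicking a two-lineage
(e.g. teleost vs tetrapod) partition at desk scale; `equal_branches = TRUE`
gives every edge the same length, which keeps the benchmark ultrametric (at
power-of-two tip counts) while letting replicated fits share one transition
matrix per generator.

What the generators do *not* emulate: indels and alignment error, sequencing
error, codon usage bias beyond the stationary frequencies handed to the
simulator, selection regimes outside the fitted model families, and
tree-estimation error (trees are taken as known). Green tests therefore
demonstrate the correctness and calibration of the statistics under their
own assumptions, not robustness to real-data artifacts.

# Problem sizes used by the test and acceptance suites

These are the package's benchmark choices:

* Parameter recovery: 30 taxa, 300 codons; M0, M8 ($K = 5$), and CmC at a
  background/foreground divergent-omega contrast of 0.24 vs 0.13.
* Null calibration of M8 vs M8a: 6 taxa, 60 codons, $K = 2$, 200 replicates,
  $\kappa$ fixed per replicate at its M0 estimate (shared by both models of
  the nested pair). Because the null data are simulated from the same
  discretized M8a family that is fitted, the null is exact at any $K$; the
  small $K$ only coarsens the beta representation, identically for both
  models. Rejection uses the conventional boundary null (an equal mixture of
  $\chi^2_0$ and $\chi^2_1$).
* Null calibration of the correlated-evolution test: 12 taxa, 199 bootstrap
  replicates per test, 200 outer replicates.
* MI planted-pair detection: 40 independent lineages (star tree), 25
  columns, exact residue bijection; shuffle null of 30, 15 randomized
  datasets; the star design makes the non-planted pairs genuinely
  independent so family-wise uniqueness is a meaningful target.
* Photochemistry: 100 noisy replicates at 2%-of-peak spectral noise and at
  the wild-type half-life scale with 3% trace noise.

# Known limitations

* Site classification is NEB, not BEB; borderline posteriors are optimistic
  about parameter certainty.
* Branch lengths are rescaled, not re-optimized per branch and per model.
* MI z-scores on deeply structured trees are inflated pair-wide; only the
  randomized-dataset cutoff, not the z-scores themselves, controls errors.
* The Pagel bootstrap conditions on trait polymorphism; tests on traits that
  barely vary have little power and wide Monte-Carlo granularity.
* The A1 template constants are fixed; pigments outside the A1 chromophore
  family need a different nomogram.
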