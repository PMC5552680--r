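---
title: "Methods: the characteristic direction and its companions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the characteristic direction and its companions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chardir)
```

This vignette explains the statistical machinery the package implements,
the assumptions behind it, the tunable parameters that matter, and the
design decisions taken where several constructions were defensible.  The
running application is the comparison of tumorigenic cell lines against
healthy dividing cells (stem and progenitor cell types) from bulk
expression data, but every function is generic over the two-class design.

## The characteristic direction

With expression profiles $x_s \in \mathbb{R}^p$ (one coordinate per gene)
and two sample classes, the *characteristic direction* is the unit normal
$b$ of the hyperplane that best separates the classes — a regularised
linear discriminant:

$$ b \;\propto\; \big((1-\gamma)\,\hat\Sigma_{\text{pooled}} +
   \gamma I\big)^{-1}\,(\hat\mu_{\text{case}} - \hat\mu_{\text{ctrl}}),
   \qquad \lVert b\rVert_2 = 1 . $$

The per-gene components $b_i$ measure each gene's contribution to the
separation; their signs encode up- versus down-regulation in the case
class.

**Why shrinkage.** With tens of thousands of genes and tens of samples the
pooled covariance $\hat\Sigma$ is massively rank-deficient, so classical
LDA ($\gamma = 0$) is undefined; the identity target makes the system
well-posed for any $\gamma > 0$.  The mixing weight is exposed everywhere
as `gamma` (default 0.5, valid range $[0,1]$).  Two limits anchor the
scale: $\gamma = 1$ is the raw class-mean difference, and small $\gamma$
approaches whitened (Mahalanobis) discrimination.  Internally the inverse
is applied through the Woodbury identity on the low-rank factor of
$\hat\Sigma$, so fitting costs $O(pn^2)$, never $O(p^3)$; the dense and
low-rank code paths are tested against each other.

**Sign convention.** $b$ is flipped, if necessary, so that the mean
projection score of case samples is at least that of controls.  This makes
positive components "up in cancer" by construction and is asserted as an
invariant.

**Choosing $\gamma$ is analysis-dependent.**  For *discrimination* —
separating the classes, ranking genes by contribution — moderate shrinkage
(default $0.5$) works well and is what the discovery pipeline uses.  For
*latent-activity estimation* (next section) the whitening term is actively
harmful: a coordinated gene module has, by definition, a large shared
within-class variance component, and $\hat\Sigma^{-1}$ estimated from
$n \ll p$ samples suppresses exactly that direction while amplifying
sampling noise.  In simulations with two 100-gene modules driven by
correlated latent factors, the planted activity correlation of $0.95$ is
recovered to within $\pm 0.01$ at $\gamma = 1$ but is erratic at
$\gamma = 0.5$ (runs ranged from $-0.66$ to $0.95$).  The package's
documented recipe is therefore: discrimination and gene ranking at
$\gamma = 0.5$, regulon-activity estimation on the mean-difference
direction $\gamma = 1$.

## Permutation significance and FDR

The null distribution of $|b_i|$ is estimated by refitting the direction
under random permutations of the class labels.  The two-sided p-value uses
the standard add-one pseudocount,
$p_i = (1 + \#\{|b^{\text{perm}}_i| \ge |b_i|\})/(n_{\text{perm}} + 1)$,
with ties counted against the observed value (conservative).
Benjamini–Hochberg step-up converts p-values to FDR q-values.

Two practical consequences deserve emphasis:

* **Granularity.** The smallest attainable p-value is
  $1/(n_{\text{perm}}+1)$.  After BH adjustment over $m$ genes, a set of
  $k$ true signals can only clear $q < 0.05$ if
  $m/(k\,(n_{\text{perm}}+1)) < 0.05$.  With 1000 genes and 20 signals
  this requires $n_{\text{perm}} \ge 1000$; the default (and the CLI
  default) is 1000.  Fewer permutations silently cost sensitivity, which
  is why `gene_significance()` refuses `n_perm < 100` outright.
* **Exactness at the ceiling.** A gene with zero observed contribution is
  tied by every permutation and gets $p = 1$ exactly — asserted in tests.

## Projections and validation

The projection score of sample $s$ is
$\text{score}_s = \sum_i b_i\,(x_{is} - \bar x_{i\cdot})$, centring each
gene on the *projected matrix's own* mean.  Independently normalised
validation datasets therefore need no parameters from the discovery data —
nothing leaks across datasets; this mirrors how validation cohorts are
normalised separately in practice.  Restricting the sum to a regulon's
genes gives the transcription-factor activity estimate; the restricted
direction is deliberately **not** renormalised, so a regulon's score keeps
its relative magnitude within the global direction.

## Regulon activities and their correlations

Activities of two factors are compared by Pearson (or Spearman)
correlation of their per-sample scores; to avoid trivially induced
correlation the shared target genes can be removed first with
`exclusive_regulon()` (compare A without B's targets against B).
Correlation p-values use the $t$ transform.

## RNA-seq differential expression

Between-class tests on RPKM matrices use Welch's unequal-variance $t$ on
$\log_2(\text{RPKM} + c)$ with pseudocount $c = 1$ by default: RPKM data
are heavy-tailed and heteroskedastic, the log stabilises variance, and the
pseudocount guards zeros.  Fold changes are reported on the linear scale
as the ratio of group means (pseudocount added to both), matching how fold
changes are conventionally quoted for RPKM.  Direction calls require both
$q < \alpha$ (default 0.05) and a linear fold change beyond a threshold
(default 2); both knobs are config-exposed because volcano-style class
boundaries are conventions, not statistics.  Genes at zero in every sample
carry no information and are dropped before testing; constant non-zero
genes get $p = 1$.  Under a global-null simulation (log-normal RPKM, 6 vs
44 samples) the raw $p < 0.05$ rate and the realised false-discovery
proportion are verified to be calibrated in the test suite.

## Overlap statistics

Consensus genes are those called in the same direction on both platforms.
Enrichment of an observed overlap $k$ between a size-$n$ query and $D$
annotated genes in a universe of $N$ uses the exact hypergeometric tail
($P[X \ge k]$ or $P[X \le k]$; one-sided by design, because enrichment and
depletion are directional claims), together with the fold-enrichment ratio
$k/(nD/N)$.  The universe defaults to the genes measured on *both*
platforms — the defensible choice when the universe is left implicit — and
is overridable.  The tail probabilities are property-tested against
exhaustive subset enumeration for every universe size up to 25.

## Flux fitting and ATP attribution

The metabolic module answers: given measured exchange rates (uptake
negative, secretion positive), how much ATP does a cell line make, and
what fraction comes from lactate fermentation versus branched-chain
amino-acid (BCAA) degradation?

1. **Parsimonious flux fit.** `fit_fluxes()` solves
   $\min \sum_r |v_r|$ subject to $S v = 0$, bounds, and every measured
   exchange pinned to its value.  Absolute values are linearised by
   splitting each flux into forward/backward parts.  The steady-state
   residual $\lVert S v\rVert_\infty \le 10^{-9}$ is enforced, not
   assumed.
2. **Total ATP.** Production is the positive part of the ATP row,
   $\sum_r \max(0, S_{\text{ATP},r} v_r)$; by steady state this equals
   consumption.
3. **Attribution.** Lactate-linked ATP is credited at 1 ATP per secreted
   lactate (the canonical Embden–Meyerhof substrate-level yield, i.e.
   2 ATP per glucose fermented to 2 lactate; the coefficient is an
   argument).  Each BCAA contributes its uptake rate times the
   *model-derived* maximal ATP yield per unit uptake
   (`substrate_atp_yield()`: uptake fixed at 1, all other organic uptakes
   closed, inorganic exchanges open, ATP production maximised) — the
   yields are recomputed per model, never hard-coded.  The unattributed
   remainder is `frac_other`; tiny negative residuals (magnitude below
   $10^{-6}$) are clamped to zero, larger ones are an error.

The LP layer is a compact dense two-phase tableau simplex with Bland's
anti-cycling rule, adequate for the tens-of-variables problems this
module creates, and is cross-checked in the tests against an independent
LP solver (scipy's HiGHS, via a differently formulated program without
flux splitting), against hand-derived closed-form solutions, and against
parallel-pathway models whose parsimonious optimum is known by
inspection.  Non-finite bounds are capped at $\pm 10^6$ internally; an
optimum touching the cap is reported as an unbounded model defect (for
example an uncapped energy-generating cycle).

## The toy core network

The shipped model is a deliberately small, fully auditable network —
glycolysis lump (glc $\to$ 2 lac + 2 ATP), lactate oxidation lump
(lac + 3 O$_2$ $\to$ 3 CO$_2$ + 14 ATP), a transamination step plus an
oxidation lump per BCAA, and a lumped ATP demand.  The BCAA yields
(Leu 27, Ile 32, Val 24 ATP per unit) are *authored fixture constants*
in the physiological ballpark, not claims about human metabolism; what
the tests verify are structural identities (fermentation-only yield
exactly 2 ATP per glucose, closed pathway means zero yield, doubled
oxphos ATP coefficient doubles a yield), which hold for any coefficients.
Genome-scale SBML models can be imported with `read_model_sbml()`.

## Synthetic data: what it does and does not emulate

* `simulate_two_class()` draws log-normal baseline gene means with
  Gaussian log-scale noise and plants symmetric up/down shifts (in noise-SD
  units) in the case class.  This captures what rank and linear statistics
  need — location shifts against realistic mean spread — but not probe
  effects, batch structure, or count noise; passing tests therefore
  demonstrate correctness of the machinery, not performance on any real
  cohort.
* `simulate_latent_regulons()` plants module structure: per-sample latent
  activities shared within a regulon, correlated across regulons, with a
  class-mean shift.  The within-class correlation is adjusted so the
  *marginal* correlation across all samples equals the requested coupling
  exactly (the quantity an estimator should recover; verified
  $0.950 \pm 0.011$ in simulation).  The class shift (default 1.5 SD)
  must stay small enough for that adjustment to remain a valid
  correlation, and the generator refuses impossible combinations.
* `simulate_uptake_profiles()` draws glucose uptake, a fermented fraction
  (lactate $\le 2\times$ glucose by construction, so every profile is
  feasible for the toy network), and BCAA uptakes uniformly within
  documented ranges.  The default ranges give BCAA ATP shares spanning
  roughly 0.1–0.6 across lines; `bcaa_sweep_profiles()` is the documented
  one-dimensional family along which the BCAA share rises strictly from 0
  to about 0.72.

All generators require an explicit seed, are pure functions of their
arguments, and restore the caller's RNG state.

## Numerical choices and degenerate inputs

* Ties in permutation counting use $\ge$ (conservative p-values).
* Duplicate gene rows collapse by arithmetic mean on the stored scale;
  gene identifiers are opaque case-sensitive strings (no probe mapping).
* PCA component signs are fixed by making the largest-magnitude loading
  positive, so plots reproduce across platforms.
* Zero-variance score vectors, empty gene-set intersections, classes with
  fewer than two samples, infeasible exchange sets, and inconsistent
  contingency counts are all rejected with specific errors rather than
  propagating NaNs.

## Problem sizes

The shipped simulations use 1000 genes with 20+20 (discrimination) or
30+30 (latent recovery) samples, 20 replicate datasets for calibration
summaries, 200 overlap-enumeration draws, and 50 random flux profiles.
These sizes make every distributional claim in the test suite stable
under seed changes while keeping a full run in well under a minute each.

## Known limitations

* Two classes only; no multi-class or kernel discriminants.
* The permutation null refits the direction per permutation under the
  global-null hypothesis; planted-signal datasets make it conservative
  for the non-signal genes rather than exact.
* DE is two-group Welch-$t$ on RPKM; count-based negative-binomial
  modelling is out of scope.
* The flux module fits a single parsimonious distribution; flux
  variability, thermodynamics, and sub-network searches are out of scope.
* The ATP attribution convention (1 ATP per lactate; maximal-yield BCAA
  credit) is one defensible accounting of shared machinery; fractions
  should be read comparatively, not as absolute bioenergetics.
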