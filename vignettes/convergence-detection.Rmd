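---
title: "Detecting convergent evolution in phylogenetic shape data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting convergent evolution in phylogenetic shape data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(convergr)
```

## The problem

Convergent evolution — distantly related lineages arriving at similar
phenotypes — is a central line of evidence for adaptation. `convergr`
implements a complete analysis chain for detecting and quantifying
convergence in landmark-based shape data on a time-calibrated phylogeny,
of the kind used to ask whether, say, the inner-ear shapes of deep-diving
toothed whales from separate clades have been pulled toward a common form.
The chain is:

1. **Geometric morphometrics** — generalised Procrustes alignment (GPA) of
   3-D landmark configurations, optionally with sliding semilandmarks, and a
   PCA of the aligned shapes (`gpa()`, `slide_semilandmarks()`,
   `shape_pca()`).
2. **Phylogenetic signal** — the multivariate statistic $K_{mult}$ with a
   tip-permutation test (`kmult()`).
3. **Adaptive-regime detection** — Brownian motion (BM), single-optimum
   Ornstein–Uhlenbeck (OU1) and multi-peak Hansen OU models, with a
   two-phase stepwise AICc search that first adds regime shifts branch by
   branch and then collapses regime pairs into *convergent* regimes
   (`bm_fit()`, `hansen_fit()`, `surface_forward()`, `surface_backward()`).
4. **Convergence measures** — Stayton's distance-based $C_1$–$C_4$ with
   BM-simulation significance (`c_metrics_significance()`), and the
   Wheatsheaf index of convergence strength with jackknife confidence
   intervals and a bootstrap p-value (`wheatsheaf()`).
5. **Ecological correlates** — $\chi^2$ tests of regime membership against
   ecological factors with Bonferroni correction, and ANOVA of log body
   mass (`chi_square_tests()`, `body_size_anova()`).

A seeded synthetic-data generator (`simulate_dataset()` and friends)
produces trees, regime paintings, traits, landmark sets and ecology tables
with the statistical structure these methods assume, so the whole chain is
testable end to end without any external data.

## Models and assumptions

### Procrustes alignment and shape space

`gpa()` iteratively centres each configuration, scales it to unit centroid
size, rotates it onto the running consensus by least squares, and
recomputes the consensus until the consensus change falls below $10^{-8}$.
Reflections are never introduced (rotation determinants are constrained to
$+1$): left/right chirality is biological information and must be
harmonised upstream, not silently flipped by the optimiser. Semilandmarks
slide along the chord between their curve neighbours by the closed-form
projection that minimises their Procrustes distance to the consensus — the
Procrustes-distance criterion rather than bending energy — alternating
with re-alignment (three outer iterations by default). `shape_pca()` works
in the tangent-space approximation (PCA of the flattened aligned
coordinates); each component's sign is fixed so its largest-magnitude
loading is positive, making scores deterministic across platforms.

### The multi-peak OU model

On an ultrametric tree of depth $T$, a trait under a Hansen model with
adaptation rate $\alpha$, diffusion $\sigma^2$ and per-regime optima
$\theta_r$ has tip expectation $E[y] = W\theta$, where row $i$ of the
design matrix $W$ integrates $e^{-\alpha(T-t)}$ over the segments of
lineage $i$ painted in each regime, with the residual root weight
$e^{-\alpha T}$ assigned to the root regime (so rows sum to one and the
process starts at the root-regime optimum). The covariance is
$V_{ij} = \frac{\sigma^2}{2\alpha} e^{-\alpha d_{ij}}
(1 - e^{-2\alpha s_{ij}})$ with $d_{ij}$ the patristic distance and
$s_{ij}$ the shared path length. $\theta$ is estimated by GLS and
$\sigma^2$ profiled in closed form, leaving a one-dimensional likelihood
in $\alpha$ that is maximised on the log scale with a coarse restart grid
plus local refinement. Traits are fitted independently (one $\alpha$,
$\sigma^2$, $\theta_r$ each; model AICc is the sum over traits). That
independence assumption is the reason the regime search should be run on
only the first few principal components — with many traits the assumption
is both biologically doubtful and statistically expensive.

Parameter counts per trait: BM $k=2$, OU1 $k=3$, multi-peak $k=2+R$ for
$R$ regimes. The phylogenetic half-life is $t_{1/2} = \ln 2 / \alpha$:
with $\alpha = 3.055$ on a tree measured in Myr, $t_{1/2} = 0.227$ Myr —
adaptation essentially instantaneous relative to the tree.

### The stepwise search

The forward phase starts from one regime, evaluates a brand-new regime at
the origin of every branch (repainting the branch and all descendants not
already overridden by a later shift), accepts the largest AICc improvement
(ties break toward the earliest branch in preorder), and stops when no
candidate strictly improves. The backward phase repeatedly evaluates all
pairwise regime collapses and accepts the best strict improvement.
Convergent regimes are those retained by two or more independent shifts;
the convergence fraction is the number of shifts into convergent regimes
divided by all shifts (6 of 8 shifts gives 0.75).

One numerical choice matters here and deviates from the obvious default.
The profiled OU likelihood has a degenerate ridge as $\alpha \to 0$: the
design weights of all regimes collapse toward zero and the GLS optima
diverge to compensate, so a model with several spurious regimes and absurd
optima can edge out well-behaved models on raw likelihood. `hansen_fit()`
searches $\alpha \in [10^{-8}, 10^{3}/T]$ by default, but the regime
search bounds $\alpha$ below at $2\ln 2/T$ (half-life at most half the
tree depth): a multi-peak model adapting more slowly than that cannot
distinguish optima from drift, and that region of model space is exactly
what the separate BM and OU1 comparison fits cover. Without this bound the
backward phase regularly fails to collapse genuinely convergent regimes
because the ridge solution misrepresents their optima.

Like any greedy stepwise-AICc procedure, the search tends to accept one or
two marginal extra shifts on 30-ish-tip trees (gains from the maximum of
many candidate improvements exceed the per-regime penalty more often than
a global criterion would allow). The recovery experiments below quantify
this; users should read the shift count as an upper bound on the number of
well-supported regimes.

### Convergence measures

For a focal pair of tips, `c_metrics()` reconstructs ancestral states
under BM (`asr_bm()`, a joint-Gaussian GLS identical to the standard
ML reconstruction), takes $D_{tip}$ as the present-day phenotypic
distance and $D_{max}$ as the maximum distance between reconstructed
states along the two lineages back to their MRCA, **excluding** the
contemporary tip–tip pair. The exclusion matters: it allows
$C_1 = 1 - D_{tip}/D_{max}$ to go negative when lineages have diverged
beyond any ancestral separation, which is how a non-convergent regime
should behave; with the tip pair included $C_1$ would be floored at zero.
$C_2 = D_{max} - D_{tip}$; $C_3$ and $C_4$ scale $C_2$ by the summed
phenotypic branch lengths of the MRCA's clade and of the whole tree.
Multi-tip focal groups average over all unordered pairs (unweighted — the
choice is arbitrary and documented). Significance comes from simulating
BM on the tree with the GLS-estimated evolutionary rate matrix
$\hat R = (Y-\hat a)^{\mathsf T} C^{-1} (Y-\hat a)/N$ and recomputing the
metrics per simulation; the reported p is the raw proportion of simulated
values at or above the observed (it can be exactly 0), with the protected
$(s+1)/(n+1)$ estimate carried alongside.

### The Wheatsheaf index

`wheatsheaf_index()` standardises each trait column, computes pairwise
Euclidean distances, and corrects each by the multiplicative kernel
$d'_{ij} = d_{ij}\,(1 + s_{ij}/T)$, which inflates the distances of close
relatives (kernel in $[1,2]$) so that relatedness-driven similarity is not
mistaken for convergence. The index is the mean corrected distance over
all pairs divided by that over focal pairs; $w>1$ means the focal species
are phenotypically tighter than average after the correction. The kernel
is a documented, swappable choice (`correct = FALSE` removes it): the
primary-literature formulation of the correction is not restated in the
sources this package follows, so a bounded multiplicative kernel was
chosen that avoids the singularity a division by patristic distance would
create for sister tips. Confidence intervals are leave-one-tip-out
jackknife percentiles — with a two-taxon focal group the two focal
deletions leave no focal pair, so the upper bound is $+\infty$ by
construction, a behaviour users of this index will recognise. The p-value
bootstraps trait rows onto tips.

### Ecology tests

Species listed under several categories of a factor (e.g. both nearshore
and oceanic) generate assignment variants: variant $k$ analyses every
ambiguous species as its $k$-th listed category, so such a factor is
tested once per listing position (first-listed, then second-listed). The
realised number of tests per regime sets the Bonferroni correction; with
two ambiguous factors among four this reproduces the familiar six tests
per regime. Pearson $\chi^2$ is used without continuity correction.

## The synthetic-data generator

`simulate_dataset()` emulates the statistical structure of a
48-species, ~36-Myr odontocete-scale study at desk scale:

* **Tree**: pure-birth, rescaled to exact depth (default 32 tips, depth
  36 time units).
* **Painting**: default two shifts forming one convergent pair; the two
  shifts of a pair are placed in different root halves — convergence means
  *distant* clades arriving at one optimum, and adjacent subtrees would
  form a single connected regime instead.
* **Traits**: exact OU transition sampling along branches. Defaults
  $\alpha = 3$, $\sigma^2 = 0.05$, optima contrast 1: a half-life of 0.23
  time units and an optima separation of ~11 stationary standard
  deviations, a rate regime typical of strongly adapting
  cochlear-shape axes and comfortably inside the strong-shift conditions
  ($\alpha T \ge 5$, $|\Delta\theta| \ge 5\,\sigma_{stat}$) the recovery
  experiments assume. Much slower rates (say $\alpha T \lesssim 10$) would
  leave shift placement along long interior branches close to
  unidentifiable — equivalent repaintings of a branch chain fit equally
  well — so recovery experiments run there would measure the generator,
  not the method.
* **Landmarks**: a helix-like base curve sampled along the scheme (default
  4 curves × 5 points), a smooth per-group deformation field, iid
  coordinate noise, and a random similarity transform per specimen so GPA
  has real work to do.
* **Ecology**: per-regime preferred categories taken with probability
  `strength`, uniform otherwise; the first shifted regime plays the
  oceanic / very-deep / suction-feeding role. Masses are log-normal per
  regime. `strength = 0` gives the independence null; `strength = 1` is
  deterministic.

Every generator is bit-reproducible under a fixed seed, and a dataset seed
derives per-component sub-seeds deterministically. What the generator does
**not** emulate: measurement error in landmark placement, missing
landmarks, fossil (non-contemporaneous) tips, trait covariance across PCs,
and realistic cochlear geometry. Tests passing on these data therefore
validate the estimators and the search logic under the stated model, not
robustness to those real-data complications.

## Problem sizes used by the test-suite experiments

The packaged experiments run at sizes a single CPU handles in minutes, and
state their conditions explicitly rather than inheriting whatever the
defaults happen to be:

* regime recovery: 20 replicates, 32 tips, 2 planted convergent shifts at
  the default strong-adaptation parameters; success means both planted
  branches (or an immediate neighbour) are recovered *and* end in one
  shared regime. Across wider seed sweeps the rate sits near 75–85%: the
  planted branches are essentially always found, and every failure is a
  backward collapse rejected by a small AICc margin when a two- or
  three-tip planted clade's optimum estimate fluctuates — the intrinsic
  cost of a greedy stepwise criterion at this sample size, not an
  estimation defect (the likelihoods match brute-force oracles to
  machine precision).
* $K_{mult}$ calibration: 100 BM replicates on a 64-tip tree (expectation
  1 under BM; exact identity 1 on star trees).
* $C$-metric calibration: 50 BM nulls with 200 simulations each
  (type-I rate at $p \le 0.05$ expected in the few-percent range), and 20
  planted-convergence replicates for power.
* Wheatsheaf: planted tight clusters among dispersed species, 200
  bootstraps.

## Worked example

```{r example, eval = FALSE}
ds <- simulate_dataset(n_tips = 32, seed = 1, with_ecology = TRUE)
res <- surface_search(ds$traits, ds$tree)
glance(res)

conv <- convergent_regime_tips(res)
cm <- c_metrics_significance(ds$traits, ds$tree, conv[[1]],
                             n_sim = 1000, seed = 2)
tidy(cm)
ws <- wheatsheaf(ds$traits, ds$tree, conv[[1]], n_boot = 1000, seed = 3)
tidy(ws)
```

`run_pipeline()` chains all stages from a single declarative config (R or
YAML) and writes the model-comparison, C-metric, Wheatsheaf and
association tables as plain CSV/JSON, byte-identical under a fixed seed.

## Known limitations

* The stepwise search inherits the overfitting tendency of greedy AICc
  selection; shift counts are optimistic and near-tied collapses can go
  either way.
* Per-trait OU independence ignores trait covariance; use few PCs.
* The Wheatsheaf phylogenetic correction kernel is one defensible choice
  among several; conclusions about *strength* of convergence should be
  checked against `correct = FALSE`.
* Only contemporaneous (ultrametric) tips are supported for OU fitting;
  fossil tips are out of scope.
* When reading published tables of this kind, note that prose summaries
  and table columns occasionally disagree (e.g. a pair of relative-
  convergence percentages swapped between two regimes); this package
  follows the table convention of reporting per-regime metric values.
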