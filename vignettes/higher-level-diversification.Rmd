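---
title: "Estimating diversification-rate shifts from higher-level phylogenies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating diversification-rate shifts from higher-level phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divshift)
```

## The model

divshift implements likelihood inference for the **birth–death–skyline
process** observed through a **higher-level phylogeny**. The process starts
from one lineage (stem) or two (crown) some time in the past; each lineage
speciates at rate $\lambda$ and goes extinct at rate $\mu$. Time is
measured backwards from the present (age $0$). The skyline generalisation
lets the rates be piecewise constant: shift times
$0 = t_0 < t_1 < \dots < t_m$ partition time into intervals, interval $i$
spanning ages $(t_i, t_{i+1}]$ with rates $(\lambda_i, \mu_i)$; index $0$
is the most recent interval, matching the "young"/"old" naming used for
one-shift scenarios. Estimates are reported as the net diversification
rate $r_i = \lambda_i - \mu_i$ and turnover
$\varepsilon_i = \mu_i/\lambda_i$.

A *higher-level phylogeny* is what one typically has for genus- or
family-level data: the tree is fully resolved above a cut age
$x_{\text{cut}}$, and every lineage crossing that age is collapsed to a
single sampled tip annotated with the number $n_i$ of extant species in
its clade. The data are therefore the branching times
$x_1 > \dots > x_{n-1}$ (all $> x_{\text{cut}}$), the cut age, and the
clade sizes with total $m = \sum_i n_i$. A complete species-level tree is
the special case $x_{\text{cut}} = 0$, all $n_i = 1$.

## The likelihood and why it is computed through ZMG distributions

All descendant-count laws of a linear birth–death process are
**zero-modified geometric** (ZMG): the number of extant descendants of a
lineage alive at age $t$ satisfies $P(0) = a$,
$P(k) = (1-a)(1-b)\,b^{k-1}$ for $k \ge 1$. For one constant-rate
interval of duration $\Delta$,
$$a = \frac{\mu(e^{r\Delta}-1)}{\lambda e^{r\Delta}-\mu},\qquad
  b = \frac{\lambda(e^{r\Delta}-1)}{\lambda e^{r\Delta}-\mu},\qquad
  r = \lambda - \mu,$$
with $a = b = \lambda\Delta/(1+\lambda\Delta)$ at criticality. The ZMG
family is closed under composition across adjacent time intervals: the
probability generating function of a ZMG is a fractional-linear map, and
composing maps across intervals is again fractional-linear. The package
therefore never transcribes per-interval probability formulas; it
composes interval ZMGs. This has three consequences we rely on:

* **Numerical stability**: stable exponential forms per interval
  ($e^{-r\Delta}$ for $r>0$, $e^{r\Delta}$ for $r<0$, a series form when
  $|r|\Delta < 10^{-8}$), and log-space accessors
  ($\log b$, $\log(1-a)$) so clade factors survive $m \gg n$.
* **Structural invariances**: splitting an interval, or inserting a shift
  time with unchanged rates, cannot change any probability (semigroup
  property) — these are tested, not hoped for.
* **Partition invariance for free**: the product of tip factors
  $\prod_i p_{n_i}(x_{\text{cut}})$ equals
  $[(1-a)(1-b)]^{\,n}\, b^{\,m-n}$ at the cut age, so the likelihood
  depends on the clade sizes only through their total $m$. Knowing the
  individual sizes adds nothing.

The tree density itself telescopes. Writing $p_k(t)$ for the descendant
distribution of the full (multi-interval) process, the factor contributed
by an observed branch from age $s$ down to age $e$ is $p_1(s)/p_1(e)$,
so the product over all branches collapses to factors at the event ages
only — the density does not depend on the topology, only on the
branching times:
$$\mathcal{L} \;\propto\; p_1(x_1)^2 \prod_{i=2}^{n-1} \lambda(x_i)\,
  p_1(x_i) \prod_{i=1}^{n} \frac{p_{n_i}(x_{\text{cut}})}
  {p_1(x_{\text{cut}})}$$
for the crown form; the stem form replaces $p_1(x_1)^2$ by
$p_1(x_0)\,\lambda(x_1)p_1(x_1)$. Both the per-tip and the $m$-only
clade-factor routes are implemented and must agree — a permanent
regression check on the partition-invariance property. Densities are
reported up to a parameter-free constant (labelled-tree orientation
factor), which cancels from likelihood ratios and ML locations.

### Conditioning

What exactly the published tools condition on is an implementation detail
rarely printed. The package exposes it as an explicit argument:

* `crown_survival` (default): condition on both lineages descending the
  root leaving at least one sampled descendant, the usual choice when the
  stem age is unknown and the standard survival conditioning in
  maximum-likelihood diversification software;
* `stem_survival`: condition on survival of the stem lineage (requires a
  stem age);
* `none`: the unconditioned density.

The default was validated, not hard-coded blindly: the simulator draws
trees conditioned on the number of extant species, and the crown-survival
likelihood recovers the generating parameters without visible bias in the
acceptance experiments. Rate intervals older than the root are legal (the
oldest interval extends to infinity), so shift-time grids can probe
near-root ages safely.

## Simulation

`sim_free()` is a plain forward Gillespie simulation from a single
lineage at a fixed stem age, returning the complete tree with extinct
lineages — the oracle side of many tests. `rbd_count()` is an independent
Rcpp implementation that tracks only the population count, used to
cross-check the closed-form $p_k$ by brute force.

`sim_conditioned()` draws a reconstructed tree with exactly `n` extant
tips. Because shift times are ages *before the present*, a forward
simulation would have to anchor its rate schedule at a stopping time it
does not yet know. We avoid that fixed point entirely by sampling
backwards from the present, which is exact for this model class:

1. draw the crown (or stem) age from its conditional density given $n$
   under a uniform prior on the age — for the crown,
   $(n-1)\,p_1(x)^2\,b(x)^{n-2}$ — the distribution that
   general-sampling-approach (span-weighted stopping) simulators target;
2. given that age, draw the remaining $n-2$ branching ages i.i.d. with
   density $\propto \lambda(x)p_1(x)$, whose CDF is exactly
   $b(x)/b(x_1)$ (the identity $\mathrm{d}b/\mathrm{d}x = \lambda\,p_1$
   holds for the composed skyline process, not just constant rates);
3. assemble a uniform ranked topology by backward merging of uniformly
   chosen pairs.

Both inversions use dense-grid interpolation (8192 points), introducing
discretisation error far below the stochastic tolerances of any
experiment here. The construction is validated against the forward
simulator by rejection sampling: among free forward runs with exactly two
surviving species, the reconstructed branching time must have CDF
$b(x)/b(x_0)$ — a goodness-of-fit test in the suite exercises the
likelihood, the sampler mathematics and the Gillespie simulator jointly.

`collapse_tree()` collapses each lineage crossing `x_cut` to its
lexicographically smallest descendant label, carrying the clade's extant
species count; `quartile_xcut()` produces cut ages at quantiles of the
tree age, nudging toward the present (to the midpoint of the adjacent
younger inter-branching gap) when a quantile collides with a branching
time.

### What the generator does and does not emulate

Defaults mirror the simulation study the method was validated on: trees
conditioned on a fixed number of extant species under six one-shift
scenarios (decreasing and increasing diversification with shifts at ages
2 and 3.5, a high-turnover variant with $\mu = 0.4$ and shift at 8, and a
varying-extinction variant $\mu: 0.6 \to 0.1$ at 2), each chosen so the
young-interval lineage accumulation (shift age $\times$ recent $r$)
matches across comparable settings. The generator emulates exactly the
model assumed by the likelihood: time-homogeneous rates within intervals,
no lineage-specific rates, exactly one sampled species per collapsed
clade, complete extant sampling within clades. Green tests therefore
establish internal consistency and correct parameter recovery under the
model's own assumptions — they say nothing about robustness to
clade-dependent rates, incomplete sampling within clades, or
phylogenetic error, all of which are outside this package's scope.

## Inference

Optimization is over $(r_i, \varepsilon_i)$ per interval — the scale on
which results are reported — with bounds $r \in (-10, 10)$,
$\varepsilon \in [0, 0.999]$ and a flat penalty where the implied
$\lambda \le 0$. The likelihood is smooth but can be flat in
$\varepsilon$, so reproducibility comes from *deterministic* multistarts
(five for the constant model) followed by bounded L-BFGS-B and one tight
final polish (`factr = 100`). The shift time is the genuinely multi-modal
direction; it is profiled over a deterministic grid (default: 20 points
between $x_{\text{cut}}$ and $0.9\,x_1$, a declared default — the
published workflow uses a user grid whose range is not printed), each
candidate's four rates optimized warm-started from its neighbour, and the
winner refined once by a bounded one-dimensional search between its grid
neighbours. `greedy_shift_search()` adds shifts one at a time with
previous shift times frozen, accepting while the likelihood-ratio test
against the previous model has $p < \alpha$ at 3 degrees of freedom per
shift (speciation rate, extinction rate, shift time). The $\chi^2_3$
reference follows the published convention; with a shift time that is
unidentified under the null it is a convention, not an exact asymptotic
result. The test suite measures this directly: at a *fixed* shift time
the statistic for the two extra rate parameters is well calibrated
against $\chi^2_2$ (empirical rejection $\approx 0.05$–$0.07$), but the
*profiled* statistic — the supremum over the shift-time grid — is
stochastically larger than $\chi^2_3$ (Davies' problem), giving an
empirical type-I error of roughly $0.15$–$0.25$ at $\alpha = 0.05$ on
constant-rate trees of 200 tips. Users should read borderline
single-shift p-values conservatively; strong signals (as in the recovery
experiments, $p < 10^{-5}$) are unaffected.

Numerical corner cases handled deliberately: $\mu = 0$ (Yule) sits on the
$\varepsilon = 0$ boundary and is allowed; $\varepsilon$ is capped at
0.999; a candidate shift equal to a branching time is legal for the
likelihood (ages belong to the younger interval, a documented
convention); `x_cut` equal to a branching time is rejected at collapse
time because the crossing set is ambiguous there; slightly negative LRT
statistics from optimizer noise are clamped to zero with a warning.

## Scope and limitations

* One sampled lineage per clade, complete sampling inside clades; no
  uniform incomplete sampling fraction.
* No fossils, no clade-dependent or heritable rates; the skyline model is
  a null model for those questions.
* Multi-shift search is greedy, not joint; with several true shifts the
  frozen-shift approximation can miss the joint optimum.
* The type-I error experiment fixes the constant-rate world at
  $\lambda = 1$, $\mu = 0.1$ (the background extinction rate of the
  simulation scenarios), 200 trees of 200 tips.
* On moderate trees (hundreds of tips) the young-interval diversification
  and turnover estimates lie on a likelihood ridge: the young speciation
  rate $\lambda_y$ is pinned sharply, but $\varepsilon_y$ spreads upward,
  which pulls $\hat r_y = \hat\lambda_y(1-\hat\varepsilon_y)$ below the
  truth. The effect shrinks with tree size; on 500-tip trees the
  replication harness shows the young-rate median a little low while the
  old rate and the shift time are recovered accurately. Report
  $\hat\lambda$ alongside $\hat r$ when the young interval is short.
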