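---
title: "Phylogeny-based trait prediction: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogeny-based trait prediction: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`phylopred` treats a rooted phylogeny with branch lengths as a statistical
model for a continuous trait observed at some of its tips. This vignette
explains the model, the algorithms, the defaults, and the choices made where
the design was genuinely open — in enough detail that every number the
package produces can be traced to a formula.

## The Brownian-motion model and its GLS machinery

Under Brownian motion (BM), a trait evolves along the tree by independent
Gaussian increments with variance $\sigma^2$ per unit branch length. The tip
values $x$ are then jointly Gaussian,
$x \sim \mathcal{N}(a\,\mathbf{1},\ \sigma^2 V)$, where $a$ is the root
state and $V_{ij}$ is the root-to-tip path length shared by tips $i$ and $j$
(`vcv_matrix()`). Everything else in the package is generalized least
squares (GLS) on this covariance:

* **Phylogenetic mean** (root estimate):
  $\hat a = (\mathbf{1}^\top V^{-1} x)/(\mathbf{1}^\top V^{-1}\mathbf{1})$,
  with variance $\hat\sigma^2/(\mathbf{1}^\top V^{-1}\mathbf{1})$.
* **Rate**: $\hat\sigma^2 = (x-\hat a\mathbf{1})^\top V^{-1}
  (x-\hat a\mathbf{1})/(n-1)$. The $n-1$ denominator is the
  residual-maximum-likelihood (REML) convention; point estimates of root and
  ancestral states do not depend on it, only reported variances do.

None of this is computed with dense matrices in production. A
Felsenstein-style pruning pass propagates, for every node, the Gaussian
message from the tips below it; the root message yields $\hat a$ and
$1/(\mathbf{1}^\top V^{-1}\mathbf{1})$, and the GLS sum of squares
decomposes edge-wise as
$\sum_{\text{edges}} (\mu_c - \mu_p)^2 / v'_c$ over the up-message means.
The pass is linear in the number of edges and handles polytomies and
unifurcating nodes natively — no polytomy resolution is ever needed, because
any resolution with zero-length branches leaves $V$, and therefore every GLS
quantity, unchanged. The dense-matrix route is retained (`method = "gls"` in
`blomberg_k()`, plus the test suite's independent oracles) and the two are
required to agree to $10^{-8}$.

## Blomberg's K

`blomberg_k()` implements
$$K = \frac{\mathrm{MSE}_0/\mathrm{MSE}}
 {\left[\mathrm{tr}(V) - n/(\mathbf{1}^\top V^{-1}\mathbf{1})\right]/(n-1)}$$
with $\mathrm{MSE}_0$ the ordinary mean squared deviation from $\hat a$ and
$\mathrm{MSE}$ the phylogenetically corrected one. $K = 1$ is the BM
expectation on the given tree; the package's calibration checks confirm a
mean $K$ within $[0.85, 1.15]$ over BM simulations on 100-tip Yule trees.
$K$ is invariant to affine trait transforms and to global branch-length
rescaling (both tested), which is also why the synthetic generator can place
traits on a realistic positive scale without affecting any statistic.

**Permutation test.** Significance is assessed by shuffling trait values
across tips. The statistic is the GLS MSE (smaller = stronger signal; this
matches the convention of the `picante` implementation that popularized the
test), and $p = (1 + \#\{\mathrm{MSE}_\text{perm} \le
\mathrm{MSE}_\text{obs}\})/(n_\text{perm}+1)$, ties counted. The default is
999 permutations. Permuted statistics reuse one $V^{-1}$: each permutation
is a quadratic form, so all of them evaluate as a single matrix product.
Two subtleties are worth recording:

* On an *equal-branch* star tree the MSE is permutation-invariant, so the
  test is degenerate there ($p = 1$). The type-I calibration therefore uses
  star trees with unequal terminal branches — the non-degenerate "no
  phylogenetic structure" null — where the rejection rate at
  $\alpha = 0.05$ is within $5\% \pm 2\%$ over 500 runs.
* Perfectly clade-clustered traits do not reach the theoretical floor
  $1/(n_\text{perm}+1)$: relabelings that preserve (or mirror) the clade
  partition tie the statistic exactly and are counted. The tests pin the
  attainable $p$ by exhaustive enumeration on small trees instead.

## Ancestral state estimation

The BM estimate of the trait at an internal node equals the phylogenetic
mean of the tree *rerooted* at that node. `ancestral_estimates()` computes
all nodes at once with a second, downward message-passing sweep (the
combination of the up- and down-messages at a node is exactly the rerooted
root estimate); `method = "reroot"` performs the literal construction node
by node and the two must agree to $10^{-10}$. Estimates are convex
combinations of tip values, hence always inside the observed trait range;
variances are REML-based ($\hat\sigma^2$ times the combined message
variance). Estimation is per community and condition — each community's own
pruned tree and trait vector — so that cross-community comparisons compare
genuinely independent reconstructions.

## Hidden-tip prediction and its identity with the BLUP

To predict an unobserved tip, `predict_tip()` prunes the tree to the
observed tips plus the single target, reroots at the target's parent, and
reports the root REML estimate computed from the observed tips. The squared
standard error is the prediction variance at that root plus
$\hat\sigma^2$ times the target's terminal branch. This prune-and-reroot
construction is algebraically the conditional-Gaussian best linear unbiased
predictor with the GLS plug-in mean,
$\hat a + V_{to} V_{oo}^{-1}(x - \hat a\mathbf{1})$ — an identity the test
suite verifies against a dense oracle on random instances to $10^{-8}$.

Because the identity is exact, `exclusion_validation()` and
`cross_predict()` default to the dense evaluation (`method = "blup"`), which
shares one covariance matrix across replicates or targets and is orders of
magnitude faster at validation scale; `method = "reroot"` runs the literal
procedure and is tested equal. Within a validation replicate each excluded
tip is predicted *alone* (only that target plus the non-excluded tips),
never jointly with other unobserved tips.

## Exclusion validation

Each replicate excludes $\max(1, \mathrm{round}(f \cdot n))$ tips uniformly
without replacement ($f = 0.2$ by default, 1000 replicates); accuracy is the
squared Pearson correlation between per-taxon mean predictions (over the
replicates in which the taxon was excluded) and observations. Squared
Pearson is symmetric in the two variables, which sidesteps the question of
which way the accuracy regression "should" run. Replicate $r$ draws its own
sub-seed from the master seed, so results do not depend on the total
replicate count and are exactly reproducible.

One genuine limitation, documented rather than hidden: under a *signal-free*
null, the per-taxon mean prediction converges (as replicates grow) to the
community mean *excluding that taxon*, which is weakly anti-correlated with
the taxon's own value. Squared-Pearson null accuracy therefore does not
converge to zero; the honest null signatures are a negative correlation and
near-flat predictions, and that is what the tests assert. At realistic
community sizes and with genuine signal present the artifact is negligible
(its scale is $1/n_\text{obs}$ against the signal's $O(1)$).

## Shared nodes and cross-community transfer

Communities are tip subsets of one master tree, and every node carries a
stable identifier that survives pruning (surviving branching nodes keep
their ids; suppressed unifurcations vanish with their branch lengths summed).
A node is *shared* by two communities when it remains a branching node in
both pruned community trees. Note that pruning roots each community tree at
the most recent common ancestor of its tips, so a community nested entirely
inside one side of the master root does not retain the master root — the
shared-node set is exactly the intersection of retained branching nodes, a
definition the tests check against a brute-force subtree-membership oracle.

Cross-community prediction is directional: community A's observations
predict every tip of community B, substituting A's observed value (standard
error 0) where B's tip was also observed in A, and using the phylogenetic
predictor otherwise. Substituted tips are included in the accuracy
regression. Agreement of ancestral estimates at shared nodes is summarized
by Pearson's $r$ with the usual $t$ test on $n-2$ degrees of freedom; no
multiple-testing correction is applied across pair-condition cells, matching
the way such tables are conventionally reported.

## The synthetic-data generator

The generator exists so that every stage is testable, with known truth,
without external data. It emulates a multi-ecosystem trait survey:

* **Master tree**: pure-birth (Yule) tree, exponential waiting times at rate
  `birth_rate` per lineage, grown to `master_n_tips` plus one final waiting
  time so terminal branches are never zero. Default 1000 tips.
* **Heritable component**: one BM realization on the master tree
  (`simulate_bm_traits()`), with all internal node states recorded for
  recovery tests.
* **Communities**: four communities with sizes 207, 182, 378, 260 — inside
  the 165–381 range typical of per-ecosystem tip counts in qSIP growth-rate
  surveys —
  drawn as a shared core of master tips (core size = overlap target times
  mean community size; default pairwise overlap 0.10, within the observed
  1.5–26% range) plus disjoint community-exclusive sets. The core
  construction hits the overlap target exactly, at the cost of every pair
  sharing the *same* tips; that is a deliberate simplification.
* **Traits**: for community $i$, condition $j$, tip $t$:
  $\text{trait} = \mu_j + s\,(\sqrt{h}\, z_t + \sqrt{1-h}\,\varepsilon)$,
  where $z_t$ is the community-standardized BM tip state,
  $\varepsilon \sim \mathcal{N}(0,1)$ is drawn independently per community
  and condition, $s = 0.05$ and $\mu_j \in \{0.03, 0.12, 0.18, 0.22\}$
  (proportion day⁻¹, rising across conditions the way growth rates rise with
  incubation temperature; 5 °C incubations sit far below the rest in such
  experiments). The *heritable fraction* $h$ is the single signal dial:
  it is the share of within-community trait variance attributable to shared
  evolutionary history. $h$ was chosen over a Pagel-$\lambda$ branch
  transform because it cleanly models environmental trait plasticity as
  additive noise on a fixed evolutionary history; the default is 0.6, an
  intermediate value that yields $K$ in the low tenths at these community
  sizes — the regime (roughly 0.17–0.66) reported for soil bacterial growth
  rates in the field.
* **Conditions** shift only the mean, not $h$, so condition cells are
  replicate draws of the same signal structure unless the user supplies a
  per-cell $h$ matrix.

What the generator does *not* emulate: abundance-based tip filtering,
varying community membership across conditions, non-Brownian evolution
(e.g. Ornstein–Uhlenbeck pull or rate shifts), correlated environmental
responses across communities, and measurement error with replicate
structure (replicate trait columns are accepted on input but are averaged
before analysis). Passing tests on synthetic data therefore demonstrate
correctness of the machinery and calibration under the stated model, not
that real traits follow BM.

## Numerical choices

* **Zero-length terminal branches** make $V$ singular and are rejected by
  the GLS operations; `jitter = TRUE` adds $10^{-8}$ times the tree depth
  instead, for trees (like reference guide trees) that contain them.
* **Permutation ties** are counted as "at least as extreme" with a relative
  tolerance of $10^{-12}$, so algebraically tied arrangements computed by
  different code paths compare equal.
* **Polytomies** are handled natively by the pruning passes (no resolution);
  basal multifurcations (as produced by rerooting a binary tree) count as
  rooted.
* **Seeds**: every stochastic function takes an explicit seed; replicated
  procedures derive one sub-seed per replicate up front, so individual
  replicates are reproducible in isolation.

## Problem sizes used by the checks

The test suite and `scripts/acceptance.R` run at deliberately desk-sized
scales, chosen as the package's own reporting conventions: oracle
equivalence on 50 random trees of up to 64 tips; type-I calibration over
500 permutation tests (199 permutations each); BM calibration over 200
simulations on 100-tip trees; the within-community accuracy–signal
relationship on an 8-level $h$ grid (0.2–0.95) with ten 100-tip communities
per level and 200 exclusion replicates; the cross-community
accuracy–$r$ relationship over 24 community pairs; and one full
four-community, four-condition study at the default sizes with 100
exclusion replicates and 199 permutations per cell. The full-scale defaults
(1000 replicates, 999 permutations) remain the function defaults.

## Known limitations

* Single-rate BM only; no OU, rate heterogeneity, or multivariate traits.
* Prediction uncertainty uses the REML plug-in $\hat\sigma^2$; it does not
  propagate rate uncertainty.
* The exclusion-validation null artifact described above means its R²
  should not be interpreted as zero-baselined at very small signal.
* The shared-core overlap construction makes all community pairs share the
  same tips; pairwise-varying overlap requires a custom sampling step.
* Reported ancestral variances are REML-based; an ML convention would scale
  them by $(n-1)/n$.
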