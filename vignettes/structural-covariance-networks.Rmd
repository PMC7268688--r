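---
title: "Structural covariance networks from regional brain volumes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural covariance networks from regional brain volumes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(volnet)
```

## The analysis chain

`volnet` implements a group-level *structural covariance network* analysis
for regional brain volumes, of the kind used to study how preprocessing
choices (here: skull-stripping workflows) propagate into network topology.
The chain is:

1. **Regional volumes.** Each subject's regional volume is estimated in
   template space from a label map and the Jacobian determinant of the
   nonlinear registration component,
   $$V_i = \frac{\sum_{V_t} J_F \cdot v}{\left|A^{rigid}_{3\times3}\right|
   \left|A^{affine}_{3\times3}\right|},$$
   where the sum runs over the template voxels of region $i$, $v$ is the
   voxel volume, and the denominator removes the volume change of the
   linear (rigid + affine) part of the individual-to-template transform.
2. **Edges.** Across subjects, the partial correlation between every pair
   of regional volumes (from the inverse of a shrinkage-regularized
   covariance matrix) defines a weighted, signed 64-node network.
3. **Binarization.** The weighted network is thresholded to fixed edge
   densities (sparsities) over a grid, keeping the strongest edges.
4. **Topology.** At every sparsity: clustering coefficient $C_p$,
   characteristic path length $L_p$, global efficiency $E_{glob}$, local
   efficiency $E_{loc}$, and the small-world ratios
   $\gamma = C_p/C_{rand}$, $\lambda = L_p/L_{rand}$ against
   degree-preserving rewired null graphs.
5. **Statistics.** Test–retest repeatability (ICC, Bland–Altman limits of
   agreement), per-region one-way ANOVA across workflows, and permutation
   tests on network-metric differences.

The node set is a fixed, packaged list of 64 grey-matter regions (32 per
hemisphere: cortical gyri plus thalamus, basal ganglia, amygdala,
hippocampus, entorhinal cortex and the cerebellar hemispheres), loaded with
`load_region_atlas()`. Label-map codes are assigned 1..64 in atlas row
order; external label maps must be remapped to this convention.

## Volume estimation conventions

The volume formula is ambiguous about what $J_F$ means when the
registration is purely linear: read literally, a constant
$J_F = 1/(|A^{rigid}||A^{affine}|)$ *and* the determinant denominator would
double-count linear scaling. `region_volume()` therefore adopts the
canonical decomposition: the stored Jacobian field describes the nonlinear
(post-affine) warp only, so $J_F \equiv 1$ for a purely linear registration
and linear scale enters once, through the denominator. Under this
convention an exact affine scaling $s$ of the template changes every
estimate by $1/s^3$, which the test suite asserts for
$s \in \{0.5, 1, 2\}$. `eq1_literal = TRUE` reproduces the literal reading
for comparison.

Further conventions: transforms map the individual to the template; the
regional sum runs over template-space voxels; voxels are assigned by exact
label equality (no partial-volume weighting); regions absent from a label
map are reported as missing rather than zero.

## Edge estimation: why shrinkage is not optional

With $n = 22$ subjects and $p = 64$ regions the sample covariance is
singular, so raw partial correlations do not exist. This is the largest
methodological gap left open by typical descriptions of volume-covariance
networks, and the package makes the choice explicit:
`partial_correlation_matrix()` shrinks the covariance toward a scaled
identity, $(1-\rho) S + \rho \mu I$, with the analytic Ledoit–Wolf
intensity $\rho$ by default. `shrinkage = "none"` is available and fails
loudly on singular input; a fixed intensity in $[0, 1]$ can be supplied for
sensitivity analyses. On well-conditioned problems the unshrunk estimate
matches brute-force residual-regression partial correlation to $10^{-8}$,
and the estimate converges to it as the intensity goes to zero (both
tested).

Binarization keeps the top $\mathrm{round}(s \cdot 2016)$ of the 2016
possible edges. Two rankings are provided: `"positive"` (signed weight;
negative partial correlations enter last; the default, since negative
volume-covariance edges have no agreed interpretation) and `"abs"`.
Ties are broken deterministically (lower first-node index, then higher
second-node index), making the edge count exact and the selection total.
The default sparsity grid is 0.10–0.46 in steps of 0.02 (19 levels), a
common working range for structural covariance networks: below ~0.10 the
graph fragments, above ~0.5 topology is dominated by density. All levels
are configurable.

## Graph metrics and null models

Metrics are computed on binary adjacency matrices. The clustering
coefficient is printed in the geometric-mean (Onnela) weighted form in
much of the literature; on a binary graph that form reduces *exactly* to
triangle counting, which is what the implementation uses (the weighted
form is retained internally and the reduction is asserted in tests).
Shortest paths are breadth-first distances; $L_p$ averages over pairs at
finite distance and flags disconnected graphs (efficiencies need no
convention, since $1/\infty = 0$). Nodes of degree $< 2$ contribute 0 to
clustering and local efficiency.

Null calibration uses Maslov–Sneppen edge swaps: 10 attempted swaps per
edge, rejecting self-loops and multi-edges, preserving each node's degree
exactly; 100 null graphs by default. Rigid degree sequences (e.g. complete
graphs) return the input's own metrics. The small-world verdict is
$\gamma > 1$ together with $\lambda \le 1.5$; the $\lambda$ tolerance
operationalizes "path length approximately random" and is configurable,
since no quantitative criterion is standard. Across a sparsity grid,
metrics are aggregated by trapezoidal AUC, and the overall small-world
verdict is a majority vote over levels.

## The synthetic cohort generator

No real cohort ships with the package, so validation rests on a generator
whose defaults define the study conditions: 22 subjects, 64 regions, three
skull-stripping workflows. Log-volumes are multivariate Gaussian with an
exchangeable block-correlation structure (4 contiguous modules,
within-module correlation 0.6, between-module 0.1), so volumes are
strictly positive, biases act multiplicatively, and the resulting
covariance network inherits community structure — which is what makes it
small-world. Region means are round, order-of-magnitude-plausible neonatal
constants (e.g. thalamus 4200 mm³, cerebellar hemisphere 9500 mm³) with
SDs of 12% of the mean; they are deliberately arbitrary and make no claim
of matching real volumetry.

Workflow effects have two parts:

* **Deterministic bias** (`workflow_bias`): BET shrinks all but the deep
  grey nuclei by 5%; iBEAT inflates the ten skull-base-adjacent regions
  (inferior temporal, fusiform, parahippocampal, entorhinal, cerebellum)
  by 5%; the manually corrected workflow is the unbiased reference. The
  magnitudes are placeholders — the direction, not the size, is the
  modelled phenomenon — and are fully configurable.
* **Subject-varying stripping noise** (`workflow_noise_sd`, log-scale SD,
  default 0). A purely deterministic rescaling of a region leaves every
  correlation — and therefore the network — exactly unchanged, so
  deterministic bias alone cannot produce workflow differences in
  topology. Run-to-run variability of automatic stripping is what does,
  and enabling noise for the automatic workflows (the default pipeline
  uses 0.05 for BET, 0.03 for iBEAT) dilutes the modular covariance
  signal, lowering clustering and efficiency relative to the clean
  workflow. Noise factors are mean-corrected so the expected bias stays at
  `workflow_bias`.

Repeated measurements share one latent draw and add independent Gaussian
noise (`repeat_sd`, default 50 mm³, ~1–2% of a typical region) on the raw
scale, so the population ICC of each region is
$\sigma_b^2 / (\sigma_b^2 + \sigma_w^2)$. With between-subject SD 2.905
and repeat SD 1 (arbitrary units) that ratio is 0.894; note the ICC(A,1)
*estimator* carries a small negative bias at $n = 22, k = 2$, so recovered
averages sit just below the population value (~0.885), within the
package's stated ±0.01 recovery band.

What the generator does **not** emulate: image intensity, tissue contrast,
actual registration error fields, age or sex structure, non-Gaussian
volume distributions, or spatially correlated (rather than region-block)
covariance. Passing tests therefore demonstrate that the pipeline recovers
the properties of this generative model — not that any particular real
cohort is small-world.

Registration fixtures for the volume stage are built by packing the
requested voxel count per region into disjoint runs of a cuboid grid
(overlap is impossible by construction), with an identity rigid transform,
an isotropic affine scale, and a uniform or smooth random Jacobian field
(sum of integer-frequency random-phase sinusoids, amplitude 0.15 per axis,
hence strictly positive with spatial mean ≈ 1).

## Statistical components

* **ICC**: two-way random effects, absolute agreement, single measures —
  ICC(A,1), the standard test–retest form — computed from closed-form
  balanced two-way mean squares and tagged in the output so alternative
  forms can be added. Zero-variance regions report ICC 1 with a
  degenerate-data flag.
* **Bland–Altman**: mean difference, SD ($n-1$), limits of agreement at
  ±1.96 SD, and the percentage of pairs inside the limits. Whole-brain
  volume, where needed, is the sum of the 64 regional volumes.
* **Per-region ANOVA**: one-way fixed-effects F test per region
  (`stats::oneway.test`, equal variances), counted significant at raw
  p < 0.05 by default; Benjamini–Hochberg adjustment by flag. The raw
  default mirrors common practice of reporting unadjusted per-region
  significance over 64 regions.
* **Network comparison**: group-level covariance networks have one value
  per group, so inference uses subject-label permutation: workflow labels
  are swapped within subject (subjects are paired across workflows, having
  shared latent anatomy) and both networks are rebuilt from scratch each
  permutation; the two-sided p-value uses the add-one convention
  $(1 + \#\{|d^*| \ge |d|\})/(B + 1)$. This is a reconstruction of a
  standard structural-covariance approach, documented as such rather than
  as a reproduction of any specific software's behaviour.

## Numerical choices and degenerate inputs

* Edge counts are exact: `round(s * 2016)` with a total tie order.
* Volume summation uses R's long-double accumulating `sum()`, so voxel
  order cannot change results at the $10^{-9}$ relative level.
* Weight matrices are symmetrized as $(P + P^\top)/2$ and clamped to
  $[-1, 1]$ after the precision-matrix transform to absorb roundoff.
* An edgeless graph reports $L_p$ as NaN with a flag, $E_{glob} = 0$;
  a graph compared against a rigid null family reports $\gamma = 1$ and is
  therefore never small-world.
* All sampling flows from one seed per object (cohort, null ensemble,
  permutation test, pipeline manifest); sub-seeds are derived
  deterministically, and identical seeds reproduce results to the last
  bit.

## Problem sizes used by the test suite

The validation suite runs at deliberately modest sizes chosen as the
package's own verification budget: graph-metric oracle equivalence on 200
random graphs of ≤ 12 nodes (tolerance $10^{-10}$); small-world recovery
on 20 cohort seeds across the full 19-level grid with 50 nulls per level;
ICC recovery over 200 replicate cohorts; ANOVA calibration over 1500
null cohorts (rejection rate 0.05 ± 0.01); permutation validity over 250
runs of 100 permutations each. Larger ensembles tighten the Monte-Carlo
bands but do not change any verdict.

## Known limitations

* The package consumes transforms and Jacobian fields; it does not solve
  registrations, segment tissue, or touch image intensities.
* Group-level networks only: no individual-subject networks, and no nodal
  statistics (betweenness, modularity, hubs) beyond the four global
  metrics.
* The shrinkage target (scaled identity) is one defensible choice; with 22
  subjects the network depends materially on the regularizer, and results
  should be read as conditional on it.
* No covariate regression (age, sex) is applied before correlation; the
  hook exists in the design but defaults off.
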