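---
title: "Multinomial tensor regression: model, estimation, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multinomial tensor regression: model, estimation, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtreg)
```

## The model

`mtreg` classifies subjects into $K \ge 2$ diagnostic groups from a 3D
image covariate $X_i \in \mathbb{R}^{d_1 \times d_2 \times d_3}$ (for
example a spatially normalized T1-weighted brain volume) and, optionally,
a vector of scalar covariates $Z_i$.  The label $Y_i$ follows a
multinomial distribution whose log-odds against a reference class are
linear in the image:

$$\log\frac{\mu_{ik}}{\mu_{iK}} \;=\; \alpha_k + \langle \gamma_k, Z_i\rangle
  + \langle B_k, X_i \rangle, \qquad k = 1, \dots, K-1,$$

where $\langle B_k, X_i\rangle = \sum_{abc} B_{k,abc} X_{i,abc}$.  An
unstructured $B_k$ would have one coefficient per voxel (592,895 of them
for a $79 \times 95 \times 79$ volume), which no cohort-sized sample can
support.  The package therefore constrains every $B_k$ to a rank-$R$ CP
(CANDECOMP/PARAFAC) form

$$B_k \;=\; \sum_{r=1}^{R} \beta_{k,r}^{1} \circ \beta_{k,r}^{2} \circ
  \beta_{k,r}^{3},$$

a sum of outer products of one vector per mode.  This reduces the image
part of the parameter count to $(K-1)\,R\,(d_1+d_2+d_3)$ — for three
classes, rank 1 and a $79 \times 95 \times 79$ volume, 506 parameters.
The cost is an assumption: discriminative structure must be expressible
as a few separable (axis-aligned, low-rank) spatial patterns.  The gain
is interpretability: every mode-3 slice of a rank-1 $B_k$ is a scalar
multiple of $\beta_k^1 \circ \beta_k^2$, so three small matrices
($\beta^1\circ\beta^2$, $\beta^1\circ\beta^3$, $\beta^2\circ\beta^3$)
summarize where in the volume the model discriminates
(`export_surfaces()`).

By default the model carries no intercepts and no scalar covariates,
matching the pure-image three-class form; `intercepts = TRUE` and
`covariates = TRUE` in `mtr_fit()` enable the general form.  The
reference class defaults to the last label level and is configurable
(`reference`); with $K = 2$ the model is exactly binary logistic
regression on the vectorized volume with a rank-constrained coefficient
vector, and the test suite pins this equivalence against `glm.fit`.

CP representations are scale-indeterminate (multiplying one mode's
vector by $c$ and another's by $1/c$ changes nothing), so all comparisons
between coefficient tensors use scale-invariant quantities: the cosine
similarity between materialized tensors, computed exactly in factored
form (`cp_cosine()`), and correlations between coefficient surfaces.

## Estimation

Parameters are estimated by maximizing the multinomial log-likelihood
$\ell(\Theta) = \sum_i \sum_k y_{ik} \log \mu_{ik}$ with block
relaxation: the factor blocks $\beta_k^j$ ($j = 1,2,3$ within each
non-reference class $k$, plus the intercept/covariate block when
enabled) are visited cyclically, each visit updating one block with all
others held fixed.  Within a block the predictor is linear,
$\langle\beta_k^j,\; X_{i(j)}(\beta_k^{j''}\!\odot\beta_k^{j'})\rangle$,
where $X_{i(j)}$ is the mode-$j$ unfolding and $\odot$ the Khatri–Rao
product of the other two factors, so the per-block design matrix is
formed once per visit and reused.  The outer loop stops when the
log-likelihood changes by less than `epsilon` between sweeps, or after
`max_outer` sweeps; the best-seen parameters are returned.

An exact argmax per block is not available in the multinomial case, so
the block update is defined as a fixed number of first-order steps
(`inner_steps`).  Two inner solvers are provided:

* `solver = "adam"` (default): adaptive per-coordinate steps with the
  standard moment parameters.  Robust to the scale of the data, since
  step sizes are normalized coordinate-wise.
* `solver = "gd"`: plain gradient ascent.  Steps preserve the gradient's
  relative magnitudes across coordinates, which matters when the goal is
  to *recover* a localized coefficient pattern rather than only to
  classify (see "Known limitations"); the learning rate must then be
  scaled to the data, for which `tune_learning_rate()` is provided.

Tunable parameters, defaults, and rationale:

| parameter | default | meaning / rationale |
|---|---|---|
| `rank` | 1 | CP rank of each $B_k$; rank 1 is the configuration used throughout validation, higher ranks are supported |
| `epsilon` | `1e-4` | absolute log-likelihood change (nats) that counts as convergence |
| `max_outer` | 100 | cap on outer sweeps |
| `inner_steps` | 25 | first-order steps per block visit; acts as a trust region so no single block saturates the fit |
| `learning_rate` | 0.01 | Adam step size; cross-validate on a grid for gradient ascent |
| `init_scale` | 0.01 | sd of the random normal initialization; small, so initial predictors are near 0 and all classes start near probability $1/K$ |
| `beta1`, `beta2`, `adam_eps` | 0.9, 0.999, `1e-8` | standard Adam moments |
| `standardize` | `FALSE` | optional global z-scoring by training mean/sd, stored with the parameters so prediction reuses the training statistics |

The learning rate can be selected by stratified $k$-fold
cross-validation (`tune_learning_rate()`, default 10 folds), maximizing
mean held-out prediction accuracy with ties broken toward the smaller
rate.  A `mode = "joint"` fit (one first-order run over all parameters
at once) is included as a cross-check on the block scheme.

Everything is deterministic given the seed in `mtr_control()`: identical
seed and configuration reproduce the fit bit for bit on the same
platform.

## Numerical choices

* Probabilities are computed as a softmax over
  $(\eta_1,\dots,\eta_{K-1}, 0)$ with row-wise max subtraction, so
  predictors of any magnitude cannot overflow.  Inside the likelihood
  (never inside gradients) $\log\mu$ is floored at the log of the
  smallest positive normal double.
* The mode-$j$ unfolding orders columns with the lower remaining mode
  varying fastest, and `khatri_rao()` uses the matching order (second
  argument fastest).  This convention lives in exactly two functions and
  is pinned by an identity test,
  $\langle u\circ v\circ w, X\rangle = u^\top X_{(1)}(w \otimes v)$, on
  random instances.
* `inner_product()` contracts mode 3, then 2, then 1 and never
  materializes the CP tensor; it agrees with full materialization to
  relative tolerance `1e-10` in tests.
* A diverging fit (non-finite predictor or factor) aborts with an error
  naming the sweep, class and mode.  Ties in `predict()` go to the
  lowest class index; an all-zero coefficient surface yields an empty
  mask rather than an arbitrary one.
* `stratified_split()` uses largest-remainder rounding of the per-class
  test quotas, so each class's test count differs from its exact quota
  by less than one subject and the total equals `round(f * n)` (an
  84:192:200 cohort at 20% yields test counts 17/38/40).

## The synthetic-data generator

`mtr_scenario()` / `mtr_simulate()` produce datasets with exactly the
statistical structure the model assumes, so that estimation can be
validated against known ground truth without any external data.  Volumes
are i.i.d. Gaussian voxel noise; each non-reference class adds a planted
rank-1 signal $S_k$, an outer product of smooth half-sine bumps over a
contiguous window per axis, at a class-specific location.  Under the
`"planted"` mechanism (the default), labels are assigned first and class
$k$'s subjects receive mean signal with peak voxel amplitude
`amplitude * noise_sd`; the exact Bayes log-odds —
$(\mathrm{amplitude}/\sigma) S_k$ with intercept
$-\mathrm{amplitude}^2\|S_k\|^2/2$ — are returned as the ground truth.
Under `"model"`, volumes are pure noise and labels are drawn from the
model's own softmax at true parameters scaled so the linear predictors
have standard deviation `amplitude`.

Defaults are fixed once: shape $(20, 24, 20)$ — a desk-scale stand-in
that preserves the 3-way structure and unequal dimensions of normalized
brain volumes — 100 subjects per class, three classes, rank 1, peak
amplitude 5 noise-sd units (a strongly separated design), window
fraction 0.4.  The generator emulates localized low-rank class effects
in registered volumes; it does **not** emulate anatomy, spatially
correlated noise, registration or intensity-inhomogeneity artifacts, or
partial-volume effects.  Passing tests therefore demonstrate
correctness of the model, optimizer and metrics under the model's own
assumptions — not robustness to the ways real sMRI violates them.

## Evaluation metrics

`mtr_evaluate()` reports prediction accuracy (correct classifications
over sample size), the plain (unadjusted) Rand index between the true
and predicted partitions (an adjusted variant is exported but not used
in the standard report), and the multi-class AUC of Hand and Till:
for every unordered class pair the separability is
$[\hat A(i|j) + \hat A(j|i)]/2$, each $\hat A$ computed from the
Mann–Whitney rank statistic on that class's own probability column with
ties credited one half; the MAUC is the mean over all $K(K-1)/2$ pairs
and reduces exactly to the standard AUC when $K = 2$.

## Design choices that were genuinely open

* **Reference class**: configurable, default the last label level; the
  three-class application fixes the non-depressed patient group as the
  baseline, which corresponds to ordering the labels accordingly.
* **Intercepts**: off by default, mirroring the pure-image probability
  equations; the general form is one flag away.
* **Block-update depth**: `inner_steps` fixed steps rather than solving
  each block subproblem to optimality.  Near-exact block solves were
  tried and are counterproductive on separable data: a single block can
  saturate the likelihood before the other modes have left their random
  initialization.
* **CV criterion**: held-out accuracy; MAUC is available via the
  returned probability matrix if a different criterion is wanted.
* **Surface threshold**: the "most discriminative" mask marks the top
  5% of cells by absolute value by default; the choice is reported in
  the export metadata and configurable.

## Known limitations

* **Classification versus recovery.**  On strongly separated data the
  training likelihood saturates: the data are linearly separable, the
  MLE direction is a margin maximizer, and continued optimization loads
  progressively on noise voxels when the voxel count far exceeds the
  sample size (thousands of voxels against a few hundred subjects).
  The package's own acceptance checks show both sides of this coin on
  the default scenario: the fit reaches perfect training accuracy,
  while the cosine between fitted and planted coefficient tensors ends
  well below what a well-posed regime yields (the same estimator
  reaches cosine $> 0.99$ when the voxel count is small relative to
  $n$, which the test suite verifies at a $3\times2\times2$ shape).
  Alignment is highest partway through the fit and degrades as margin
  pursuit takes over; `solver = "gd"` degrades more slowly than Adam,
  whose per-coordinate normalization moves noise and signal coordinates
  at equal speed.  Penalized estimation would stabilize recovery but is
  deliberately out of scope here (it is flagged as future work for this
  model family); treat exported coefficient surfaces from
  high-dimensional fits as localization summaries, not as consistent
  coefficient estimates.
* **Problem sizes.**  The test suite and the reproduction script run at
  desk scale by choice: shapes from $3\times2\times2$ to
  $20\times24\times20$ and up to 300 subjects, where a full fit takes
  seconds.  The implementation handles full-size volumes
  ($79\times95\times79$) with identical code paths.
* The generator's simplifications listed above; no spatial smoothness
  penalty ties neighboring voxels; $N$-way tensors beyond 3 modes and
  CP *decomposition* of a given dense tensor are out of scope.

## Reproducing the reference numbers

`scripts/acceptance.R` regenerates the default planted scenario, fits
the model with the default configuration, and writes the training-set
prediction accuracy as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
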