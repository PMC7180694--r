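---
title: "Suppressing concentration interference and drift in E-nose data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Suppressing concentration interference and drift in E-nose data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micfifld)
```

## The problem

An electronic nose (E-nose) couples an array of cross-sensitive metal-oxide
semiconductor (MOS) gas sensors with a pattern-recognition model. Two
interferences degrade the calibrated model over time:

* **Concentration interference.** A MOS sensor's response grows with analyte
  concentration, approximately as a power law, and the exponent differs
  between sensors. The array's *fingerprint* — the response pattern across
  sensors — therefore changes with concentration, so samples of the same gas
  at different concentrations occupy different regions of feature space.
  When deployment concentrations are unknown and differ from calibration,
  this within-class spread dominates the class signal.
* **Long-term drift.** Aging, poisoning and environmental change shift the
  response distribution between acquisition batches, so the target
  (deployment) batches are distributed differently from the labeled source
  (calibration) batch.

The setting is *transductive*: unlabeled target samples are available at
training time, their labels and concentrations are not. The package
implements a two-stage answer — MICF, a kernel subspace maximally
independent of concentration-level features, followed by IFLD, an
iterative pseudo-label Fisher discriminant that aligns class structure
across domains — together with the standard train-on-first-batch
evaluation protocol and a simulator that reproduces both interferences.

## Concentration features and the MICF subspace

Each labeled sample at concentration $c_j$ ppm is assigned the level
$\lfloor \ln c_j \rfloor$ (log binning: sensors discriminate concentration
ratios), and the levels present are re-indexed contiguously as
$1,\dots,c$. The level-coding matrix $Y \in \mathbb{R}^{c \times n}$ holds
a one-hot column per labeled sample and an all-zero column per unlabeled
sample, and its linear kernel $K_y = Y^\top Y$ is a binary
same-level-indicator over samples (`concentration_levels()`,
`build_concentration_features()`, `concentration_kernel()`).

Dependence between projected sensor features and the levels is measured by
the empirical Hilbert–Schmidt Independence Criterion (HSIC),

$$\widehat{\mathrm{HSIC}}(K, L) = (n-1)^{-2}\,\mathrm{tr}(K H L H),
\qquad H = I - n^{-1}\mathbf{1}\mathbf{1}^\top,$$

which is nonnegative for positive semidefinite kernels and zero exactly
when the doubly centered kernels are orthogonal (`hsic_estimate()`).

With a sample kernel $K_x$ built over source *and* target jointly (the
transductive contract — no out-of-sample extension is offered), MICF seeks
an orthonormal $W \in \mathbb{R}^{n \times h}$ for the projection
$Z = W^\top K_x$ that trades maximal projected variance against minimal
HSIC-dependence on the levels:

$$\max_{W^\top W = I}\;
\mathrm{tr}\!\left(-W^\top K_x H K_y H K_x W
 + \mu\, W^\top K_x H K_x W\right),$$

whose maximizer is the set of top-$h$ eigenvectors of the symmetric matrix
$K_x(-H K_y H + \mu H)K_x$ (`fit_micf()`). With $K_y = 0$, or as
$\mu \to \infty$, the problem reduces to kernel PCA on $K_x H K_x$; both
limits are tested.

### Tunable parameters

* **$\mu > 0$** (default 1) weighs variance preservation against
  concentration independence. With the one-hot level kernel, the HSIC term
  scales with level-group sizes, so at realistic group sizes the default
  suppresses level-dependent directions decisively while ranking the
  remaining directions by variance.
* **$h$** (default: automatic). When unset, the retained dimension is the
  number of *strictly positive* eigenvalues. This is the unconstrained-
  dimension optimum of the trace objective: a direction with a negative
  eigenvalue lowers the objective, i.e. its concentration dependence
  outweighs its variance reward, so appending it is never advantageous.
  The rule also guarantees $h \le \mathrm{rank}(K_x)$ — with a linear
  kernel, at most the sensor count — without a user-supplied cap. A fixed
  alternative such as $h = \min(m, n-1)$ was rejected: with a linear
  kernel it retains an invertible linear image of the standardized feature
  space, so the concentration subspace is never actually discarded and
  affine-equivariant classifiers are provably unaffected (see below).
* **Kernel for $K_x$** (default linear; polynomial and RBF with the
  median-distance heuristic are provided). Linear keeps the subspace
  interpretable as a sensor-space projection and ties its rank to the
  sensor count.
* **Level coding**: `level_coded = TRUE` replaces the one-hot value 1 by
  the literal level index, a sensitivity variant; the default follows the
  one-hot scheme.

Levels are computed from **source concentrations only**; target columns of
$Y$ are zero. Zero columns contribute nothing to $K_y$, which is exactly
the information state of an unlabeled sample.

## Fisher discriminant and iterative pseudo-labeling (IFLD)

The Fisher linear discriminant uses the pooled within-class scatter
$S_w = \sum_i \sum_{z \in Z_i}(z-\mu_i)(z-\mu_i)^\top$ and the weighted
between-class scatter
$S_b = \sum_i \lambda_i(\mu_i-\mu)(\mu_i-\mu)^\top$ with
$\lambda_i = n_i/n$ by default (`scatter_matrices()`), and solves
$S_b V = \lambda (S_w + \varepsilon I)V$ for the $k$ leading eigenpairs
via the Cholesky reduction of the regularized pencil (`solve_fld()`). The
ridge $\varepsilon = 10^{-6}\,\mathrm{tr}(S_w)/d$ (with an absolute floor
when $S_w = 0$) guards singular scatter; $k$ defaults to one less than the
number of classes, the rank bound of $S_b$.

IFLD (`run_ifld()`) is EM-like: a benchmark classifier trained on labeled
source features predicts target pseudo-labels (iteration 0); each
iteration then rebuilds $S_w, S_b$ on the union of true source labels and
current pseudo-labels, solves for $V$, refits the classifier on the
$V$-projected source, and re-predicts. The loop stops when two consecutive
iterations produce identical pseudo-labels (or a change fraction at most
`tol`), so the shortest converged run has two iterations; at `tol = 0`
convergence is a fixed point — the final classifier reproduces the final
pseudo-labels exactly. $V$ is recomputed from the input features every
iteration, never composed across iterations. Monotone improvement is not
guaranteed (as for EM-like schemes generally) and is not asserted;
termination within `max_iter` (default 20) is.

### The benchmark classifier, and who can benefit at all

The classifier behind IFLD is a fit/predict contract. The default is
multinomial logistic regression (`classifier_multinom()`): deterministic
and convex. A seeded single-hidden-layer network (`classifier_mlp()`) and
a minimum-distance (nearest class mean) classifier
(`classifier_nearest_mean()`) are also provided.

One structural fact shapes every end-to-end experiment in the package:
with a **linear** $K_x$, the MICF projection is a linear map of the
standardized features, so a classifier whose decisions are invariant
under invertible affine feature maps — unregularized multinomial logistic
regression at its optimum — gains nothing from MICF by construction.
The interference-suppression benefit is real for classifiers that are
sensitive to nuisance variance: distance-based rules most of all, and
capacity-limited networks to a lesser degree at small sensor counts. The
package's protocol studies therefore use the minimum-distance benchmark
(identical in every arm), which isolates the documented mechanism; it is
also deterministic, which keeps the whole evaluation reproducible without
per-run network initialization effects. The same reasoning applies to the
refinement property of IFLD: with a near-optimal boundary classifier the
±1-sample noise of refitting masks the small, systematic refinement
gains, while the deterministic benchmark shows them cleanly.

## The evaluation protocol

`run_batch_protocol()` implements the standard drift protocol: the batch
with the smallest id is the fully labeled source; every later batch is
adapted and scored separately against it (a pooled variant is available),
and the reported average is the unweighted mean of per-batch accuracies.
Before any kernel is built, each feature is standardized to zero mean and
unit variance *within each batch* (population convention, $10^{-12}$
guard; constant features map to zero). Projected features are
re-standardized over the union before classification — an affine step
that only conditions the classifier fit.

Hidden target labels live in separate evaluation fields of the
`sample_set` container which no fitting routine reads; they are consulted
once, when scoring returned predictions. A dedicated test corrupts the
hidden labels and verifies the predictions are unchanged.

## The simulator: what it emulates, and what it does not

`simulate_enose()` generates multi-batch datasets under a power-law
response abstraction: sensor $s$ exposed to gas $g$ at $c$ ppm in batch
$b$ reads

$$x_s = a_{sg}\, c^{\beta_{sg}} \cdot \mathrm{gain}_b + \mathrm{offset}_b
+ \mathcal{N}(0, \sigma^2).$$

The per-(sensor, gas) exponent is the minimal mechanism producing the
concentration-dependent fingerprint change MICF targets; the per-batch
gain/offset sequences produce batch-coherent drift.

The reference scenario (the defaults) uses 3 gas classes, 8 sensors,
5 batches, 40 samples per class per batch, concentrations log-uniform on
10–1000 ppm, gain drifting linearly from 1 to 1.6, and noise at 5% of the
mean clean signal. Unset instrument parameters are drawn once from the
seed under a *weak-selectivity* model: per-sensor bases
$A_s \sim 10^{U(-0.25, 0.25)}$ and $B_s \sim U(0.6, 0.95)$ shared across
gases, with small per-gas deviations
$a_{sg} = A_s(1 + U(-0.1, 0.1))$ and
$\beta_{sg} = B_s + U(-0.03, 0.03)$ clamped to $(0, 1]$. This is the
regime MOS arrays actually operate in: sensors respond to everything,
concentration moves every class along a dominant shared response surface,
and gas identity is a small pattern difference riding on top. An earlier,
more selective parameterization (independent gains spread over a decade)
was discarded because it made classes separable at a glance — an
implausibly good instrument on which no interference-suppression method
has anything to do.

Deliberate omissions, which bound what passing tests can show about real
data: no transient-feature dynamics (steady-state abstraction only), no
humidity or temperature covariates, no per-sensor aging (batch drift is
array-coherent, and a scalar batch gain/offset is largely removed by
per-batch standardization — in this simulator the residual cross-batch
shift comes mainly from batch-specific concentration draws), no class
imbalance across batches, and no physically calibrated response model.
Real archives also interleave concentration set-points with acquisition
sessions in ways the log-uniform draw only approximates.

## Numerical choices

* Symmetric eigenproblems are solved densely (`eigen(symmetric = TRUE)`);
  the MICF matrix is explicitly symmetrized before decomposition.
* Eigenvector sign is canonicalized (largest-magnitude entry positive)
  and ties in eigenvalues are ordered lexicographically, so fits are
  bit-stable across runs on the same platform.
* The generalized FLD problem is reduced by Cholesky of
  $S_w + \varepsilon I$, guaranteeing real eigenpairs for the PSD pencil.
* Degenerate inputs: constant features standardize to zero; $S_w = 0$
  falls back to an absolute ridge floor; a single concentration level
  yields $H K_y H = 0$ and MICF degrades gracefully to kernel PCA.
* Problem sizes in the tests and the acceptance script — oracle checks at
  $n \le 10$, optimality sweeps over 50 instances × 1000 random maps,
   20-seed protocol studies on the 600-sample reference scenario — were
  chosen so the full suite exercises every claim at desk scale.

## Known limitations

* With a linear kernel and an affine-equivariant classifier the pipeline
  cannot (and should not be expected to) beat the raw-feature baseline;
  see above.
* Concentration independence is enforced only at the source's observed
  levels; target concentrations far outside the source range remain
  extrapolations.
* The level binning $\lfloor \ln c \rfloor$ is coarse near bin
  boundaries; `level_coded` offers a sensitivity check, not a remedy.
* IFLD inherits the usual self-training caveat: pseudo-label errors can
  reinforce; convergence is to a fixed point, not a guaranteed optimum.
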