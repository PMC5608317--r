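---
title: "Dynamical-texture classification on the Grassmann manifold: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamical-texture classification on the Grassmann manifold: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

grassvlad classifies RGB images — its motivating application is grading of
H&E-stained invasive breast carcinoma sections — by treating each image
patch as a *spatially evolving multidimensional signal*. Scanning the
pixels of an $N \times N \times 3$ patch in row-major order gives a
sequence $I(1), \dots, I(N^2) \in \mathbb{R}^3$, which is modeled by a
linear dynamical system

$$x(i+1) = A\,x(i) + \text{noise}, \qquad
  I(i) = \bar I + C\,x(i) + \text{noise},$$

with a hidden 3-dimensional state $x(i)$, transition matrix
$A \in \mathbb{R}^{3\times 3}$ and an orthonormal mapping matrix
$C \in \mathbb{R}^{3\times 3}$. The pair $(A, C)$ is a compact texture
descriptor that captures both appearance ($C$, the channel mixing) and
dynamics ($A$, how the signal evolves across pixels).

### Identification through the higher-order SVD

Rather than vectorizing the patch (which discards the coupling between the
color channels), the patch is kept as a third-order tensor
$Y \in \mathbb{R}^{N\times N\times 3}$ and decomposed by the Tucker /
higher-order SVD
$Y = S \times_1 U^{(1)} \times_2 U^{(2)} \times_3 U^{(3)}$.
Because the mapping matrix must have orthonormal columns, the mode-3
factor is taken as $C = U^{(3)}$, and the state sequence is read off the
mode-3 unfolding: $X_{(3)} = C^\top Y_{(3)}$, one state per pixel in scan
order. The transition matrix is the least-squares minimizer of
$\lVert X_\text{next} - A X_\text{prev}\rVert_F^2$.

Two implementation choices deserve justification:

* **Intercept in the transition regression.** The per-channel sample mean
  is subtracted before the decomposition, so the centered state sequence
  obeys an *affine* recurrence $x(i+1) = A x(i) + c$ with
  $c = (A - I)\bar x$, where $\bar x$ is the trajectory's sample mean —
  which is not zero for a decaying trajectory. A regression without an
  intercept is therefore biased (by roughly $10^{-3}$ in subspace distance
  even on noiseless data); with the intercept, identification of noiseless
  data is exact to machine precision. `fit_hlds()` fits the affine model
  and keeps the linear part; the textbook no-intercept estimator remains
  available as `least_squares_transition()`.
* **Scale-relative ridge.** A ridge of `1e-8` times the mean diagonal of
  the state Gram matrix guards near-rank-deficient regressions without
  biasing well-posed fits, whatever the amplitude of the state sequence.
  A fixed absolute ridge would dominate strongly decayed trajectories.

Every patch is additionally modeled in four scan directions (the patch and
its three successive 90° clockwise rotations), so a patch contributes four
systems. Constant patches have no identifiable dynamics; they are excluded
by the degeneracy test (`is_degenerate()`: centered Frobenius norm below
$10^{-8} N$) and counted in the report.

### Stability

A usable descriptor requires a stable system: the spectral radius of $A$
must not exceed 1, which is certified by $\sigma_1(A) \le 1$. When the
least-squares $A$ violates this, the objective is re-minimized under
accumulated linear constraints $\langle u_1 v_1^\top, A\rangle \le 1$,
where $(u_1, v_1)$ is the top singular pair of each visited iterate — a
constraint-generation scheme whose quadratic program

$$\min_\alpha \; \alpha^\top P \alpha - 2 q^\top \alpha + r, \qquad
  g_j^\top \alpha \le 1,$$

with $\alpha = \mathrm{vec}(A)$, $P = (X_p X_p^\top) \otimes I_3$,
$q = \mathrm{vec}(X_n X_p^\top)$, is solved exactly by a dual active-set
method (each active set yields a small linear system; constraints with
negative multipliers are dropped, the most violated one added). A single
constraint only caps $\sigma_1$ along one direction pair, so the scheme is
iterated until $\sigma_1 \le 1 + 10^{-6}$; because the naive rescaling
$A/\sigma_1(A)$ is feasible for every constraint set, the returned matrix
never has a worse objective than rescaling. Stabilization is applied only
when needed — an already-stable $A$ is optimal and feasible as is.

## Grassmannian embedding

The observability matrix $O_m = [C;\, CA;\, \dots;\, CA^{m-1}]$
($3m \times 3$; the package default is $m = 3$, giving $9 \times 3$)
has a column span invariant under state-basis changes
$(A, C) \mapsto (T^\top A T, C T)$, so the *subspace* spanned by $O_m$ is a
canonical signature of the system. Orthonormalizing $O_m$ (QR with the
R-diagonal forced positive, a deterministic equivalent of Gram-Schmidt)
yields a point on the Grassmann manifold $\mathrm{Gr}(3m, 3)$. An image
becomes a cloud of such points.

The Riemannian toolbox uses the standard geodesic (arc-length) geometry:

* `grassmann_log(base, target)`: $\Delta = U \arctan(\Sigma) V^\top$ from
  the thin SVD of $T(B^\top T)^{-1} - B$; its Frobenius norm is
  $\sqrt{\sum_i \theta_i^2}$ with $\theta_i$ the principal angles.
* `grassmann_exp(base, tangent)`:
  $B V \cos(\Sigma) V^\top + U \sin(\Sigma) V^\top$, re-orthonormalized.
* `grassmann_distance(a, b)`: the log-map norm. The independent
  cross-check used throughout the tests is the principal-angle closed form
  $\sqrt{\sum_i \arccos^2 \sigma_i(a^\top b)}$ (`principal_angles()`).
* Cut locus: when any principal angle reaches $\pi/2$ (within $10^{-10}$)
  the log map is undefined; such pairs raise a flagged condition instead of
  silently wrapping around, since a wrapped branch would corrupt means.
  During clustering, where an error would abort a whole run for one
  pathological pair, the distance is replaced by its supremum
  $\tfrac{\pi}{2}\sqrt{r}$ and the event is logged.
* `karcher_mean()`: the classical fixed-point iteration
  $\mu \leftarrow \exp_\mu\!\big(\tfrac1n \sum_i \log_\mu p_i\big)$ with
  unit step, stopped when the mean tangent norm falls below `1e-6`
  (default) — auditable through the returned residual. Convergence is
  guaranteed for clouds inside an injectivity-radius ball, which the
  codebook clusters satisfy in practice.

## Codebook and VLAD encoding

The visual vocabulary is a set of $k$ Karcher means. Initialization is
deliberately deterministic: a seeded farthest-point k-medoids on the
pooled training points picks representative *actual* points, and each
medoid seeds the Karcher mean of its cluster. The package then runs up to
10 refinement rounds of {reassign to nearest word, recompute means},
stopping early once assignments stabilize — resolving, as an explicit
design choice, whether the medoid-to-mean procedure should iterate (a
manifold k-means). Emptied clusters are re-seeded to the point farthest
from its nearest word.

Costs grow quadratically in the number of points through the pairwise
distance matrix, so codebook learning uniformly subsamples the pooled
training cloud to `subsample_cap` points (default 3000, seeded). With
hundreds of points per word this estimates $k \le 32$ words accurately
while keeping learning to seconds; the cap is configurable for larger
vocabularies.

Two encodings are implemented because the aggregation form is genuinely
ambiguous in this family of methods:

* `variant = "scalar"` (default): component $i$ of the raw code is
  $\sum_{j : NN(G_j) = m_i} \lVert \log_{m_i} G_j \rVert_F$ — a sum of
  geodesic distances, giving a $k$-dimensional code. This is the literal
  manifold form of the aggregation.
* `variant = "tangent"`: block $i$ is
  $\sum_{j : NN(G_j) = m_i} \log_{m_i} G_j$, flattened row-major and
  concatenated ($k \cdot 3m \cdot 3$ dimensions) — the classical VLAD
  shape, aggregating difference *vectors* in the tangent space.

Either raw vector is L2-normalized; a cloud that aggregates to zero (for
example, every point exactly on a word) is returned as a flagged zero code
rather than normalized. Summation runs in ascending point index so codes
are reproducible to the last bit; both variants share assignments, since
assignment depends only on distances.

## Classification and protocols

Codes are classified by an RBF-kernel SVM (`e1071`, one-vs-one
multiclass). No hyperparameters are inherited: cost
$\in \{1, 10, 100\}$ and kernel width $\in \{0.01, 0.1, 1, 10\}$ scaled by
the squared median pairwise code distance are selected by an inner seeded
3-fold grid search on the training set only.

Two evaluation protocols are provided: stratified image-level 5-fold
cross-validation (for graded datasets), and a patient-holdout protocol
that splits *patients* ~70/30 per class over five seeded trials — no
patient's images ever appear on both sides of a split, which the split
constructor asserts. Metrics are the image classification rate
$N_c / N_\text{all}$, the per-patient score $N_c / N_P$, and the global
patient rate (mean of patient scores).

The orchestrator (`run_pipeline()`) learns a *fresh codebook inside every
training fold* by default: the vocabulary is part of the model, and
learning it on test images would leak. A `shared_codebook` switch
reproduces the laxer single-vocabulary protocol for comparison and is
recorded in the report's config echo.

## The synthetic generator

Real histology datasets are external inputs; the package's testbed is a
generator that emulates their structure with *known* class-conditional
dynamics, so that every stage has a ground truth:

* `make_stable_system()` draws $A = s\,O R(\theta) O^\top$ with a random
  rotation frame $O \in SO(3)$, rotation angle
  $\theta \sim U(0.3, \pi - 0.3)$ and scale $s = \rho u$,
  $u \sim U(0.7, 1)$, $\rho = 0.97$ — so $\sigma_1(A) < 1$ by
  construction. Bounding $\theta$ away from 0 and $\pi$ matters: a
  near-identity rotation produces nearly collinear state trajectories for
  *every* initial state, making $A$ unidentifiable from a single patch.
  $C$ is a random orthogonal matrix; channel means are uniform in
  $[0.2, 0.8]$.
* `synth_patch()` runs the recurrence over the scan order. The initial
  state is $N(0, 0.25^2 I)$, chosen as the best-conditioned of up to 100
  seeded draws (trajectory $\sigma_3/\sigma_1 \ge 0.12$, early-stopped) —
  a persistent-excitation condition. The noiseless signal is rescaled by
  one constant per patch when needed so it stays within $[0.02, 0.98]$;
  scaling all states together preserves the recurrence exactly, so
  clipping only ever acts on added noise and noiseless patches are
  identified exactly. Observation noise ($\sigma_w$, dataset default 0.02)
  and process noise ($\sigma_v$, default 0) are then added and the result
  clipped to $[0, 1]$, mirroring 8-bit quantization downstream.
* `synth_image()` tiles a 128×128 image with 8×8 tiles, each with a fresh
  initial state — tiles are i.i.d. realizations of the class system, the
  structure the per-patch pipeline assumes. `make_dataset()` draws class
  systems by seeded rejection until all pairwise class-subspace distances
  exceed `class_separation` (default 0.5), writes PNGs and a manifest, and
  stores the ground truth in a separate sidecar so the pipeline cannot
  accidentally consume it. Patients are assigned round-robin within class.

What the generator does *not* emulate: spatial structure beyond the tile
grid (nuclei, stroma, staining variation), patch content that straddles
distinct textures, non-stationarity across an image, and label noise.
A passing benchmark therefore shows that the chain
identification → embedding → encoding → classification is correct and
discriminates dynamics that differ by the configured separation — not that
any particular accuracy will be reached on real stained tissue.

## Benchmark study conditions and numerical choices

The package's default benchmark is 3 classes × 30 images of 128×128
pixels, 8×8 overlapping patches with 50% overlap (stride 4, 961 origins,
×4 directions ≈ 3.8k points per image), $m = 3$, $k = 16$, scalar
variant, stratified 5-fold cross-validation; robustness is checked at
$k = 8$ and $k = 32$ on the same embeddings. These sizes keep the full
suite in the minutes range on a single CPU while exercising every stage at
realistic point-cloud scales.

Other fixed numerical choices: SVD singular-vector signs are fixed by
making the largest-magnitude entry positive (bitwise-deterministic
factors); ties in nearest-word assignment break to the lowest index;
grid origins anchor at pixel (0,0) and trailing pixels that do not fit a
full patch are discarded (no padding, which would change the tensor
shape); pixel intensities are divided by the dtype maximum.

## Known limitations

* The state dimension is fixed at 3 (the color channels); the model does
  not capture longer-range spatial dependencies than the first-order
  recurrence expresses.
* Agreement between the pure-R and fused compiled fit paths is numerical
  (≤ 1e-6 in subspace distance), not bitwise: BLAS kernels may differ with
  memory alignment. Within one path, results are bitwise reproducible.
* Cut-locus pairs abort Karcher means by design; for adversarial clouds
  (antipodal subspaces) codebook learning can therefore fail loudly.
* The patient-holdout protocol assumes each patient's images share one
  label, as in the binary benign/malignant setting it models.
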