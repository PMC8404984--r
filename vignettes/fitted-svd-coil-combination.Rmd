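---
title: "Phase-sensitive coil combination with fitted SVD sensitivities"
author: "coilfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-sensitive coil combination with fitted SVD sensitivities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coilfit)
```

## The problem

Multi-element receive arrays (32+ coils at 7 T) measure the magnetization
through complex, spatially varying coil sensitivities. Naively summing the
coil signals lets the unknown sensitivity phases interfere destructively:
the combined magnitude collapses and, in the worst case, phase
singularities appear — points where the magnitude vanishes and the phase
winds by $\pm 2\pi$, which break spatial unwrapping, high-pass filtering,
and every downstream use of phase (QSM, phase fMRI, velocity encoding).
At high field there is no homogeneous body coil to serve as a phase
reference, and the robust offline combinations are too expensive to run on
every volume of a long functional time series.

`coilfit` implements a prescan-based solution: estimate *relative*
sensitivities once per session from any multi-image prescan, compress them
into a smooth physical basis, and apply the cheap stored representation to
every subsequent acquisition, whatever its resolution or field of view.

## The model, stage by stage

**Voxel-wise SVD.** At a voxel, the signal of coil $i$ in image $j$
separates as $s_{ij} = \bar c_i \bar m_j$ when either factor is uniform
over the voxel, so the coil-by-image matrix $S = c\,m^T$ has rank one.
With i.i.d. Gaussian noise the best least-squares rank-1 factorization is
the truncated SVD: the unit-norm first left singular vector estimates the
sensitivity direction, the first singular value carries the combined
magnitude $\lambda_1 = (c^Hc\, m^Hm)^{1/2}$, and with a single image
$\lambda_1$ reduces to the root-sum-of-squares combination. Estimation
improves with more images and more contrast variation, which is what makes
B1+-shimming prescans (one AFI map plus Fourier-encoded B1+ images) good
inputs. The SVD sign/phase ambiguity is fixed by zeroing the phase of the
first image's magnetization, which pushes that arbitrary phase
$\varphi_m$ — B1+ phase, off-resonance, timing — into the sensitivity
estimate $c'$.

**Minimax virtual reference coil.** $\varphi_m$ is common to all coils and
can contain transmit-phase vortices that are not magnitude nulls, so it
must be removed before any smooth-basis fit can succeed. Any fixed coil
combination $w^Hc'$ carries the same $\varphi_m$; dividing it out via
$\tilde c = (w^H c')^H c'$ cancels $\varphi_m$ exactly while preserving
every between-coil relative phase. The danger is picking a $w$ whose
combination has nulls inside the object — each null would stamp a
singularity into every coil. We therefore choose $w$ to maximize
$\min_k |w^H c'_k|$ over an SNR-masked region (the singular-value ratio
$\lambda_1/\lambda_2$ thresholded at 20 by default). The objective is
piecewise smooth; the solver ascends a log-sum-exp softened minimum with
sharpness annealed from 2 to 64 (doubling), projected onto the unit
sphere, with backtracking accepted only on the true objective — so the
achieved minimum is monotone within a run. It initializes from the
dominant left singular vector of the masked sensitivity stack and takes 8
seeded random restarts, keeping the best; by construction the result is at
least as good as the initialization and strictly positive, which is the
contract later stages rely on.

**Solid-harmonic fitting by variable exchange.** Receive fields obey a
Helmholtz equation whose wavenumber is awkward to estimate; dropping the
wavenumber leaves Laplace's equation, whose regular solutions are the
solid harmonics $\sqrt{4\pi/(2l+1)}\, r^l Y_{lm}$ — an efficient,
physically plausible basis for spheroidal objects. We use the real
(cosine/sine) combinations, which are harmonic polynomials with identical
span, ordered $l$ ascending and $m=-l..l$ within $l$ (negative $m$ = sine
terms); the order-$N$ basis has $(N+1)^2$ columns. After reference
alignment, $\tilde C$ still contains an unknown voxel-wise complex scaling
$d$ (the reference-coil profile itself), which carries no relative-phase
information. The fit therefore solves

$$\min_{X, d}\ \big\lVert W\,(A X - \mathrm{diag}(d)\,\tilde C)\big\rVert_F^2
\quad \text{s.t.}\quad d^H d = k,$$

with per-voxel weights $W = \mathrm{diag}(\sqrt{\lambda_1})$ to discount
low-signal voxels and $k$ the number of fitted voxels; the norm constraint
excludes the trivial $X=0, d=0$ solution. Variable exchange alternates a
weighted complex least-squares update of the coefficients $X$ with an
update of $d$. The $d$-step is solved *exactly* under its norm
constraint: the objective is separable per voxel plus one sphere
constraint, giving $d_v = n_v/(a_v + \mu)$ with the Lagrange multiplier
$\mu$ found by safeguarded root finding so that $\lVert d\rVert^2 = k$
holds after every iteration. Both half-steps minimize the same objective,
so the recorded residual history is non-increasing by construction — a
property the test suite asserts on seeded problems. (A simpler
unconstrained $d$-update followed by renormalization does not guarantee
monotonicity, because the rescaling can inflate the residual; that is why
the constrained step is used.) Iteration starts from $d = \mathbf{1}$ and
stops when the residual changes by less than 0.01% (relative), with a cap
of 100 iterations and an honest `converged` flag — near the noise floor
the residual can keep creeping below the threshold for a while, which is
reported, not hidden.

**Application and combination.** Polynomial bases extrapolate poorly, so
the convex hull of the fitted voxels is stored with the fit (computed by
an incremental quickhull written for this package; no installed R package
provides a 3-D hull). A target voxel inside the hull evaluates the basis
at its own mm coordinate; an exterior voxel evaluates it at the
Euclidean-closest point on the hull surface (face/edge/vertex case
analysis; ties across faces are broken by the fixed face enumeration, a
measure-zero event). Coordinates are normalized by the centroid $c_0$ and
maximal radius $r_0$ of the fitted voxels — recorded in the sidecar — to
condition the $r^l$ terms. The combination itself is the matched filter
$v = \tilde c^H s / \lVert\tilde c\rVert$: the phrase "normalized
conjugate … complex sum" describes exactly this inner product, and only
this reading makes the method attain the voxel-wise SVD magnitude (quality
ratio 1) when sensitivities are exact, since
$|\hat c^H c|/(\lVert\hat c\rVert\,\lVert c\rVert) \le 1$ with equality at
perfect alignment. Coils whose fitted magnitude falls below a relative
floor (`eps_combine`, default $10^{-6}$ of the per-voxel maximum) are
dropped from the sum.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| fit order $N$ | 6 | – | $(N+1)^2 = 49$ coefficients/coil; high enough for products of smooth coil fields, low enough to stay conditioned on a 32³ prescan mask |
| minimax SNR threshold | 20 | ratio $\lambda_1/\lambda_2$ | restricts the null-free guarantee to voxels with real signal |
| fit SNR threshold | 20 | ratio | voxels entering the least squares |
| stopping tolerance | $10^{-4}$ | relative residual change | the 0.01% criterion |
| smoothing FWHM (VRC baseline) | 10 | mm | phase-offset smoothing of the comparison method |
| eval-mask threshold | 3% | of median reference magnitude | excludes veins/air where magnitude comparison is meaningless |
| eval-mask erosions | 1 | – | trims the partial-volume rim |

## The synthetic phantom

No public multi-coil 7 T dataset accompanies the method, so the package
carries a generator whose defaults define its standard study conditions:
an ellipsoid object (semi-axes 0.42 of the field of view) over a 256 mm
FOV; 32 coils whose ground-truth sensitivities are seeded complex
harmonic fields of order 3 (i.i.d. standard complex Gaussian
coefficients — independent coefficients across coils give the strongly
varying per-coil phases that make naive complex summation interfere
destructively, the motivating failure); a 9-image 32³ prescan at 8 mm
resolution emulating an AFI + 8 Fourier-encoded-B1+ series, with per-image
complex contrasts of magnitude 0.2–1 and uniform phase (the method only
needs "large" contrast variation; the exact distribution of a scanner's
shimming prescan is not public, so these ranges are a stand-in); a
5-volume 64³ target sharing the same physical sensitivity fields; complex
Gaussian noise at SNR 50 (mean in-object magnitude over noise standard
deviation) on both; and a transmit-phase field made of a smooth quadratic
plus optional `atan2`-style vortex lines. Problem sizes (32³/64³, 5
volumes) are the package's desk-scale choice for routine reproducibility;
all stages are resolution-agnostic.

Three deliberate design points:

* **Truth in span.** Order-3 truth lies inside the order-6 fit basis, so
  the standard conditions measure the pipeline (estimation, alignment,
  fitting, transfer) rather than basis mismatch. The `loops` truth model
  (inverse-distance magnitude, distance-dependent phase) is provided
  precisely to stress out-of-span behaviour when wanted.
* **Destructive interference can be constructed exactly.** With i.i.d.
  coefficient draws the coil-sum field happens to have an interior zero
  curve only in a minority of seeds. For singularity experiments the
  generator therefore offers `sum_vortex_mm`: the coefficients are
  redistributed so that the coil sum is exactly a first-order vortex
  field $(x-x_0) + i(y-y_0)$ — itself a harmonic polynomial, so every
  coil stays smooth and in span — guaranteeing that naive complex
  summation carries a winding-one null line through the object while any
  phase-correct combination does not.
* **Vortex cores sit outside the object in the singularity experiments.**
  A transmit-phase vortex is common to all coils *and to the
  magnetization*: no receive combination can remove a residue whose core
  lies inside the evaluation mask, because it is part of the image phase
  itself, not of the coil phases. The fitted method's claim is to add no
  receiver-induced singularities and to survive vortex-contaminated
  *estimation*; placing cores just outside the support contaminates
  $\varphi_m$ everywhere inside (stressing alignment and fitting) while
  keeping the claim well-posed.

What the phantom does not emulate: k-space sampling and reconstruction
artifacts (Gibbs, GRAPPA noise amplification), coil coupling, motion
*during* a scan, spatially varying noise covariance, and physical
Biot–Savart coil fields. Passing tests therefore demonstrate the estimator and
combiner logic under the stated signal model, not scanner-grade
validation.

## Numerical choices and degenerate inputs

* All-zero (air) voxels yield zeroed sensitivity estimates and
  $\lambda_1 = 0$ rather than errors; the SNR masks remove them. Voxels
  with zero aligned sensitivity or zero weight are excluded from the fit
  rows and the $d$-update.
* $\lambda_2 := 0$ for single-image inputs; the SNR map then degenerates,
  so masking requires at least two prescan images.
* The SNR ratio guard `eps` defaults to machine epsilon scaled by the
  largest $\lambda_1$.
* VRC baseline smoothing operates on complex exponentials of the offsets
  (smooth $e^{i\Delta}$, then take the argument) to avoid wrap artifacts.
* The evaluation-mask median is taken over the mask *after* erosion (the
  alternative — before erosion — changes little and is noted in the code).
* Coordinates, bases and hulls always live in physical mm (RAS+, the
  NIfTI sform convention; voxel indices are 0-based), so prescan and
  target grids of different resolution align without registration.
* Singularity detection sums wrapped phase differences around every 2×2
  plaquette in all three slice orientations and counts windings of
  $\pm 2\pi$ whose four corners lie in the mask — an operationalization of
  the visual singularity inspection the method's evaluation calls for.
* Phase-noise ratios remove the first volume's phase, unwrap along time
  (successive differences forced into $(-\pi,\pi]$), remove a linear
  trend per voxel, and only then take temporal standard deviations.

## Known limitations

* The minimax solver is a smoothed local ascent with restarts, not a
  global optimizer; its contract is "at least as good as the SVD
  initialization and null-free", not certified optimality.
* An incompletely removed reference profile leaves a smooth common phase
  offset in combined images; applications should use phase differences
  over time or high-pass filtering, as is standard for QSM-type
  processing. The quality ratio is immune to it (magnitudes only), and
  the resolution-transfer test removes the per-voxel common component
  before measuring phase error, since relative phase between coils is
  what determines combination quality.
* Noise-covariance prewhitening is deliberately out of scope; with
  strongly coupled arrays the combination is not SNR-optimal.
* At 32³ prescan resolution the hull is coarse; exterior projection makes
  application safe but constant-extrapolates beyond the fitted region.

## A worked run

```{r, eval = FALSE}
ph <- standard_phantom(seed = 1)
res <- run_pipeline(ph$prescan, ph$target, pipeline_config(),
                    brain_mask = ph$support)
print(res)
csum <- combine_complex_sum(ph$target)
count_singularities(Arg(csum$values[, 1]), mask = res$eval_mask,
                    geometry = ph$target_geometry)$total
```

The printed report carries the mean quality ratio, its coefficient of
variation and the residue count of the combined phase; the complex-sum
baseline on the same scene shows the interference nulls the method is
designed to remove. `scripts/acceptance.R` reruns exactly this experiment
from scratch with a caller-supplied seed.
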