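# coilfit

Phase-sensitive combination of multi-channel MRI data from fitted,
SVD-derived receive-coil sensitivities.

## The problem

Ultra-high-field MRI arrays (32+ receive coils) measure the magnetization
through complex, spatially varying coil sensitivities $c_i(\mathbf r)$.
Summing coil signals without aligning their phases lets the sensitivities
interfere destructively, collapsing the combined magnitude and stamping
*phase singularities* — points of zero magnitude around which the phase
winds by $\pm 2\pi$ — into the image. Singularities break phase unwrapping,
high-pass filtering and every quantitative use of phase (QSM, phase fMRI,
flow). At 7 T there is no homogeneous body coil to use as a phase
reference, and robust offline combinations are too slow for long
multi-volume time series.

`coilfit` is for researchers who need a push-button, reference-free phase
combination that is estimated once per session from a routine prescan and
then applied cheaply to every acquisition, whatever its resolution or
field of view.

## The method

1. **Voxel-wise SVD.** At each voxel the coil-by-image prescan matrix is
   $S = c\,m^T$ (rank one); its truncated SVD gives the unit-norm
   sensitivity direction $c'$, the magnetization series $m$, and
   $\lambda_1 = (c^Hc\,m^Hm)^{1/2}$. The SVD phase ambiguity is fixed by
   zeroing the first image's magnetization phase, which moves the
   arbitrary common phase $\varphi_m$ (B1+ phase, off-resonance) into
   $c'$.
2. **Minimax virtual reference coil.** Weights $w$ maximizing
   $\min_k |w^H c'_k|$ over an SNR mask
   ($\lambda_1/\lambda_2 \ge$ threshold) give a null-free reference;
   $\tilde c = (w^H c')^H c'$ removes $\varphi_m$ exactly while
   preserving all between-coil relative phases.
3. **Solid-harmonic fit by variable exchange.** The aligned sensitivities
   are compressed into the regular solid harmonics
   $\sqrt{4\pi/(2l+1)}\,r^l Y_{lm}$ (order 6 by default, $(N+1)^2$
   complex coefficients per coil) by alternating least squares over the
   coefficients $X$ and a free per-voxel scaling $d$ with
   $\lVert d\rVert^2 = k$, weighted by $\sqrt{\lambda_1}$, until the
   residual changes by less than 0.01%.
4. **Application.** On any target geometry, voxels inside the convex hull
   of the fitted region evaluate the basis directly; exterior voxels use
   the nearest hull-surface point. The combination is the matched filter
   $v = \hat c^H s / \lVert\hat c\rVert$, which attains the voxel-wise
   SVD magnitude when the sensitivities are exact.

The evaluation suite implements the quality ratio
$Q = |S_{method}|/|S_{VSVD}|$ with a 3%-of-median exclusion and its
coefficient of variation, residue-based singularity counting, and the
temporal phase-noise ratio $\sigma_{method}/\sigma_{VSVD}$ after temporal
unwrapping and linear detrending. A synthetic phantom generator (ground
truth sensitivities, ellipsoid object, AFI-like prescan contrasts,
transmit-phase vortex scenes) makes every stage testable without scanner
data.

## Worked example

```r
library(coilfit)
ph  <- standard_phantom(seed = 1)   # 32 coils, 9-image 32^3 prescan @ SNR 50,
                                    # 5-volume 64^3 target, shared ground truth
res <- run_pipeline(ph$prescan, ph$target, pipeline_config(),
                    brain_mask = ph$support)
print(res)
#> pipeline_result (order 6, thresholds 20/20)
#> quality_report: mean Q = 1.0000, sd = 0.0000, CV = 0.00% (n = 369960, excluded = 0)
#> singularities in combined phase: 0

csum <- combine_complex_sum(ph$target)
quality_ratio(csum, res$reference, res$eval_mask)
#> quality_report: mean Q = 0.3529, sd = 0.1286, CV = 36.45% (n = 369960, excluded = 0)
count_singularities(Arg(csum$values[, 1]), mask = res$eval_mask,
                    geometry = ph$target_geometry)$total
#> [1] 84
```

Reading: the prescan-fitted combination retains the full voxel-wise SVD
magnitude (mean quality ratio 1.0000 over ~370k masked voxel-volumes)
with no phase singularities, while the naive complex sum on the same
scene keeps only ~35% of the magnitude and contains 84 residues inside
the evaluation mask. The minimax reference lifts the worst-case masked
combination magnitude from 0.082 (plain SVD initialization) to 0.854,
which is what guarantees no nulls are injected during phase alignment.

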