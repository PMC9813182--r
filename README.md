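# ssmpose — robust statistical shape models for animal pose reconstruction

Markerless pose tracking (e.g. DeepLabCut keypoints, optionally triangulated
to 3D) fails systematically when body parts are occluded: landmarks come back
**missing** or grossly misplaced (**outliers**), and triangulation amplifies
single-view mistakes. `ssmpose` recovers such landmark datasets with no
manual annotation and no temporal assumptions, using a statistical shape
model (SSM) estimated from the contaminated data itself.

**Who it is for:** anyone post-processing per-frame landmark coordinates of a
single deformable body — behavioural neuroscientists cleaning freely-moving
rodent recordings, morphometricians with partially observed landmark sets —
in 2D or 3D, with the identical code path.

## The model

Each pose (`n_bp` landmarks × `d` coordinates) is

```
X = (M + Σ_j P_j b_j) R + T + E
```

mean shape `M`, orthonormal *eigenposes* `P_j` with per-pose shape parameters
`b_j`, rigid nuisance motion `(R, T)`, isotropic noise `E`. Aligned
vectorised poses follow `N(mu, C~)` with the PPCA-regularized covariance
`C~ = sigma2·I + V diag(lambda − sigma2) V'`.

Estimation and recovery, per the flow: **RANSAC + Procrustes** consensus
mean pose → **KNN** pre-imputation → **OGK** robust covariance → **PPCA**
regularization → **Mahalanobis / chi-square** outlier detection with greedy
per-landmark removal → **conditional-Gaussian** maximum-likelihood
re-estimation of missing/outlier landmarks, mapped back to the original
frame. Details and the numerical choices are in
`vignettes/robust-shape-models.Rmd`.

## Worked example

Simulate a 10-vertex 3D body deformed along 5 known eigenposes, contaminate
25% of poses with outliers (sigma_o = 1.0) and 25% with missing landmarks,
then recover:

```r
library(ssmpose)
shape <- make_shape("poly", d = 3)
P     <- make_eigenposes(shape, n_ep = 5, seed = 2)
spec  <- contamination_spec(sigma_n = 0.1, sigma_o = 1.0,
                            p_op = 0.25, p_oep = 0.15,
                            p_mp = 0.25, p_mep = 0.15, seed = 42)
sim <- simulate_dataset(shape, P, 1000, spec = spec)
sim$dataset
#> <pose_dataset> 1000 frames, 10 points, d = 3; 461/10000 points missing (4.6%)

res <- recover_poses(sim$dataset, fit_config(seed = 1))
res
#> <ssm_recovery> 1000 frames; 923 landmarks re-estimated; 2 frames skipped
res$fit$model
#> <shape_model> 10 points, d = 3, r = 5 eigenposes
#>   eigenvalues: 0.9053 0.592 0.4178 0.2513 0.1748
#>   noise floor sigma2 = 0.008317, alignment = rigid
```

The model recovers the planted structure: the eigenvalues estimate the true
shape-parameter variances (`0.8^(2(j-1)) + 0.1^2` = 1.01, 0.65, 0.42, 0.27,
0.18) and `sigma2` the noise floor (`0.1^2`). Against the ground truth:

```r
rmse(sim$dataset$coords,   sim$truth$clean)   # contaminated input
#> 0.223
rmse(res$recovered$coords, sim$truth$clean)   # recovered output
#> 0.112
# restricted to the planted outlier entries: 0.957 -> 0.170
eigenpose_similarity(P, res$fit$model$eigenposes, mean_true = shape,
                     mean_est = mean_pose_matrix(res$fit$model))
#> 0.988 0.970 0.983 0.992 0.995
```

so the overall error halves (down to the sigma_n noise floor), the grossly
wrong entries improve ~6-fold, and all five eigenposes are recovered with
|scalar product| ≥ 0.97. The two skipped frames had too few credible
landmarks and are returned unchanged ("exhausted").

Real data enters through `read_pose_table()` (`long_csv`, `wide_csv`, or the
DeepLabCut three-header `dlc_csv` dialect with a likelihood cutoff).

## Command line

```sh
SSMPOSE=$(Rscript -e 'cat(system.file("exec", "ssmpose", package = "ssmpose"))')
Rscript $SSMPOSE simulate --config sim.cfg --out simdir
Rscript $SSMPOSE run --data simdir/dataset.csv --config sim.cfg --out-dir rundir
Rscript $SSMPOSE evaluate --truth simdir/truth.json \
        --recovered rundir/recovered.csv --model rundir/model.json --out metrics.csv
```

Configs are flat `key = value` files; every stage takes `--seed`, writes a
provenance JSON next to its outputs, and exits 0/1/2 (ok / data error /
usage error).

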