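# sempvc — partial-volume correction for ASL perfusion series

`sempvc` estimates separate gray-matter (GM) and white-matter (WM)
perfusion contributions in mixed voxels of arterial spin labeling (ASL)
data. Instead of correcting the time-averaged difference image, it fits
each voxel's full series of `T` label/control difference measurements
with a structure-based expectation-maximization (sEM) estimator, using
tissue-probability maps from structural segmentation as prior knowledge
of the mixture. The package also provides:

* the kernel-wise linear-regression (LR) comparator (5 × 5 × 1 kernel,
  no intercept) and the no-correction baseline,
* a digital head phantom (60 × 72 × 60 at 3 mm; GM 60 / WM 20
  mL/100 g/min; spherical and cubic lesions; Gaussian noise std 5/10/15;
  40 pairs) with a fully synthetic, brain-like tissue-probability
  stand-in,
* evaluation statistics (RMSE against truth, nine-bin GM-probability ROI
  curves, CBF-ratio dispersion) and the simulation table experiments,
* minimal NIfTI-1 I/O and a command-line interface.

**Audience:** ASL methods researchers who want a self-contained,
reproducible implementation of series-based PV correction and its
evaluation harness; no external data are required.

## The model

For voxel `i`, each measurement decomposes into latent tissue
components constrained to sum to the observation:

    Y_it = X_itGM + X_itWM,
    X_itGM ~ N(P_iGM * dM_iGM, P_iGM * S_iGM),
    X_itWM ~ N(P_iWM * dM_iWM, P_iWM * S_iWM),

with tissue proportions `P` fixed from segmentation. EM alternates the
conditional expectation of the components (innovation split by variance
shares, plus a shared conditional variance) with closed-form parameter
updates. CBF follows from `f = F_tissue * dM / M0`. At convergence the
tissue-weighted sums `P_GM*dM_GM + P_WM*dM_WM` and `P_GM*S_GM +
P_WM*S_WM` reproduce the voxel's sample mean and variance exactly; the
split between tissues is set by the initialization — either global
pure-region statistics of the averaged image (`sem`) or per-measurement
LR corrections (`sem_lr`). See the methods vignette
(`vignettes/sempvc-methods.Rmd`) for the full account.

## Worked example

```r
library(sempvc)

fractions <- synth_fractions(grid_shape = c(48, 56, 48), seed = 1)
truth     <- build_truth_sim1(fractions,
                              phantom_config(grid_shape = c(48, 56, 48)))
series    <- render_series(truth, noise_std = 10, n_pairs = 40, seed = 7)

for (m in c("none", "lr", "sem", "sem_lr")) {
  fit <- pv_correct(series, fractions, method = m)
  cat(sprintf("%-7s RMSE(GM) = %6.3f mL/100g/min\n", m, rmse_gm(fit, truth)))
}
```

prints

```
none    RMSE(GM) = 30.600 mL/100g/min
lr      RMSE(GM) =  2.946 mL/100g/min
sem     RMSE(GM) =  5.780 mL/100g/min
sem_lr  RMSE(GM) =  5.499 mL/100g/min
```

No correction is off by the full PV bias (~30: mixed voxels dilute GM
signal toward WM/background); all three corrections remove it. The ROI
curve shows the corrected GM CBF is flat across GM-probability bins,
i.e. independent of the mixing fraction:

```r
rc <- roi_curve(pv_correct(series, fractions, "sem_lr"), fractions)
round(rc$mean_cbf_per_bin, 1)
#> [1] 59.8 60.2 60.1 60.5 59.2 59.8 60.3 61.3 62.7
```

(true GM CBF is 60 away from lesions; bins run [0.1,0.2) … [0.9,1.0]).

## Command-line interface

```sh
Rscript inst/cli/sempvc simulate --sim 1 --noise-std 10 --pairs 40 \
    --seed 3 -o out/sim
Rscript inst/cli/sempvc correct --method sem-lr \
    --series out/sim/series.nii.gz --gm out/sim/p_gm.nii.gz \
    --wm out/sim/p_wm.nii.gz -o out/fit
Rscript inst/cli/sempvc evaluate --estimate out/fit --truth out/sim -o out/eval
Rscript inst/cli/sempvc reproduce-tables --seeds 5 -o out/tables
```

All volumes are single-file NIfTI-1 (`.nii`/`.nii.gz`); every run logs
its resolved configuration and seeds to `config.json`.

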