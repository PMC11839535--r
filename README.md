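# fractamorph

Brain morpho-structural complexity and behavior: 3-D box-counting fractal
dimension, ROI-mean fractional anisotropy, posturographic balance metrics,
and behavioral partial least squares correlation — as one tested, fully
synthetic-data-capable R pipeline.

## The problem

After traumatic brain injury, diffuse axonal injury degrades white-matter
microstructure (visible in DTI fractional anisotropy, FA) and alters the
morphometric complexity of gray and white matter (quantifiable by the
fractal dimension, FD). Relating many imaging features to a handful of
cognitive and balance outcomes in a small cohort calls for a multivariate
method that avoids per-feature multiple testing. This package implements
that full measurement-to-inference chain for researchers working with
ROI-based structural imaging and behavioral batteries:

* **FD by box counting.** Cover a binary structure with grids of cubes of
  side `r`; count occupied cubes `N(r)`. Under `N(r) = K r^-FD`,
  `ln N = FD · ln(1/r) + ln K`, and FD is the slope of the OLS fit. Three
  structural features per ROI: general structure, boundary surface
  (6-connectivity), and topological skeleton (26-connectivity-preserving
  thinning).
* **ROI-mean FA** from a scalar map plus an integer label atlas (18 named
  white-matter tracts by default), same-grid enforced, no silent resampling.
* **COP displacement**: epoch at perturbation onset → zero-phase 10 Hz
  Butterworth low-pass → linear detrend → average across trials → cumulative
  |ΔCOP| over the first 2 s.
* **Behavioral PLSC**: SVD of the cross-block covariance `R = Yzᵀ Xz` into
  saliences `U`, `V` and singular values Δ; component significance by
  permutation of Y's rows (add-one p); element reliability by bootstrap
  stability ratios (|BSR| ≥ 2 = stable); composite scores and loadings.
* **Welch group statistics + Cohen's d** computable directly from printed
  per-group summary tables.
* **Synthetic generators** for every input: fractal phantoms with known
  dimension (Menger sponge, cube, sheet, rod), rank-1 latent-variable
  cohorts (18 subjects = 8 HC + 10 TBI; 34 imaging features; 5 behavioral
  measures), labeled NIfTI volumes, and 0.5 Hz two-cycle perturbation
  traces — so everything runs and is testable with no external data.

## Worked example

Re-analyze the printed behavioral group table (8 controls vs 10 patients),
validate the FD estimator on an exact fractal, and run a PLSC on a
synthetic cohort:

```r
library(fractamorph)

## group statistics straight from the printed summary rows (TBI - HC)
tab <- compare_groups(table1_behavior_summary())
tab[, c("measure", "t", "df", "p", "d")]
#>   measure       t    df       p       d
#> 1     BBS -3.2752  9.00 0.00960 -1.3810
#> 2     COP  1.2352 15.59 0.23504  0.5600
#> 3     TMT -0.0259  7.97 0.97995 -0.0136
#> 4    SDMT -1.1113 12.79 0.28691 -0.5444
#> 5    SCWT  3.2209 15.98 0.00534  1.4812
```

The SCWT row reproduces the published p = 0.005 and effect size 1.5; SDMT
reproduces p = 0.3. The sign convention is TBI − HC, so the positive SCWT
t means patients scored higher (worse interference suppression), and the
negative BBS t means poorer balance.

```r
## exact fractal oracle: level-3 Menger sponge, {3^k} box sizes
sponge <- make_phantom(phantom_spec("menger_sponge", 3))
fit_fd(box_count(sponge, c(1, 3, 9, 27)))
#> <fd_estimate> FD = 2.7268 (ln K = 8.987, r^2 = 1.0000, 4 sizes)
```

2.7268 is `log(20)/log(3)`, the sponge's true dimension, recovered with a
perfect log-log fit.

```r
## PLSC on a synthetic 18-subject cohort with a planted rank-1 signal
co <- make_cohort(cohort_spec(effect = 2, noise_sd = 1, seed = 1))
m <- plsc(co$X, co$Y, n_perm = 1000, n_boot = 500, seed = 1)
m
#> <plsc_model> 5 component(s)
#>   singular_value cov_explained   perm_p
#> 1         63.919       0.82669 0.000999
#> 2         19.524       0.07713 0.872128
#> 3         15.874       0.05098 0.821179
#> 4         11.941       0.02885 0.642358
#> 5          8.987       0.01634 0.116883
rownames(m$V)[m$stable_img[, 1]]
#> [1] "fa_cst_l" "fa_cst_r" "fa_slf_l" "fa_slf_r" "fa_cc_genu" "fa_cc_body"
#> [6] "fa_inf_long_fasc_r" "fd_f05" "fd_f07"
```

One latent component is significant (permutation p ≈ 0.001) and carries
83 % of the cross-block covariance; the bootstrap flags the six features
carrying the planted salience (the first six imaging columns) as stable,
plus a few false positives — exactly the behavior the calibration tests
quantify.

## End-to-end demo and CLI

```r
cfg <- make_demo("demo", seed = 1)   # phantoms, atlas+FA, cohort, COP trials
report <- run_pipeline(cfg)          # fd/fa/cop/behavior/plsc -> demo/out/
validate_report("demo/out/report.json")
```

The same stages are scriptable via the installed launcher:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/fractamorph", package="fractamorph"))')
Rscript "$CLI" demo --out demo --seed 1
Rscript "$CLI" run --config demo/config.json
Rscript "$CLI" fd --masks demo/masks --out fd.tsv --features general,surface
```

Reports are schema-versioned JSON without timestamps: rerunning a config
with the same seed is byte-identical.

## Further reading

`vignettes/fractamorph-methods.Rmd` documents the models, every tunable
parameter and default, what the synthetic world does and does not emulate,
numerical edge-case policies, and known limitations.
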