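---
title: "Methods: box-counting fractal dimension, ROI fractional anisotropy, and behavioral PLS correlation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: box-counting fractal dimension, ROI fractional anisotropy, and behavioral PLS correlation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fractamorph)
```

# Scope and model

`fractamorph` links brain morpho-structural measures to cognitive and balance
outcomes in a small two-group (healthy control vs. traumatic brain injury)
setting. Three measurement families feed one multivariate analysis:

1. **Box-counting fractal dimension (FD)** of 3-D binary structures, as a
   single dimensionless index of morphometric complexity, computed for three
   structural features per region: the full voxel object ("general
   structure"), its boundary voxels ("surface"), and its thinned medial
   representation ("skeleton").
2. **ROI-mean fractional anisotropy (FA)** from a precomputed scalar FA map
   and an integer label atlas over white-matter tracts.
3. **A posturographic balance statistic**: the cumulative
   anterior/posterior center-of-pressure (COP) path length over the first
   2 s after a platform perturbation.

The imaging features (18 FA + 16 FD by default) form a subjects × features
block $X$, and five behavioral measures (BBS, COP, TMT, SDMT, SCWT) form a
block $Y$. **Behavioral partial least squares correlation (PLSC)** decomposes
the cross-block covariance $R = Y_z^\top X_z$ by SVD, $R = U \Delta V^\top$,
pairing behavioral saliences ($U$) with imaging saliences ($V$); component
$\ell$ explains $\delta_\ell^2 / \sum_k \delta_k^2$ of the cross-block
covariance. Component significance comes from permutation of the rows of
$Y$; elementwise reliability from bootstrap stability ratios (BSR), with
$|BSR| \ge 2$ marking a stable feature.

# Box counting

For box side $r$ (in voxels) the tight foreground bounding box is
partitioned into an axis-aligned grid of $r$-cubes and the occupied cells
$N(r)$ are counted. Under the scaling model $N(r) = K r^{-FD}$,

$$\ln N(r) = FD \cdot \ln(1/r) + \ln K,$$

so `fit_fd()` reports the OLS slope of $\ln N$ on $\ln(1/r)$, the intercept
$\ln K$, and the fit's $R^2$.

**Size schedule.** The default is dyadic, $r = 1, 2, 4, \dots$ up to half
the largest bounding-box side, extended by further doubling to at least four
sizes. A $\{3^k\}$ schedule is selectable; it matches the corner-anchored
Menger sponge's exact self-similarity, for which the counts follow the
closed form $N(3^k) = 20^{L-k}$ at level $L$ and the fitted dimension equals
$\log 20 / \log 3 = 2.7268\ldots$ with $R^2 = 1$.

**Grid anchoring.** Default is the bounding-box corner, which makes the
estimate deterministic and invariant to arbitrary translations of the mask.
An optional `min_over_offsets` policy takes the minimum count over grids
shifted by $0$ or $\lfloor r/2 \rfloor$ voxels per axis, trading a small
search for reduced quantization bias.

**Quantization bias is real and documented rather than hidden.** Two
worked consequences, both frozen in the test suite: (a) dyadic counting of
the level-3 Menger sponge yields $FD = 2.349$, well below the ideal
$2.727$, because $r = 2$ boxes absorb the sponge's size-1 holes
($N(2) = 1952$ instead of the ideally scaled $\approx 1205$); the $\{3^k\}$
schedule must be used for exact sponge validation. (b) The one-voxel-thick
surface shell of a 32-cube gives an OLS slope of $2.359$ rather than the
manifold dimension 2, because the shell's counts
$N(r) = m^3 - (m-2)^3$ (with $m = 32/r$) decay faster than $m^2$ once $m$
is small. Finite-size estimates on small solids should therefore be read
against oracle values for the same schedule, not against asymptotic
dimensions.

**Surface and skeleton.** Surface voxels are foreground voxels with at
least one face-adjacent (6-connectivity) background or out-of-bounds
neighbor. The skeleton is produced by sequential 3-D thinning with six
directional sub-iterations: a border voxel is deleted only if it is
*simple* — one 26-connected foreground component in its 26-neighborhood and
one 6-connected background component in its 18-neighborhood (the standard
two-condition characterization) — and not a curve endpoint (more than one
foreground 26-neighbor). Deletion is sequential with re-checking, so the
number of 26-connected components is provably preserved, and
already-thin curves are fixed points. The choice of 6-connectivity for
surfaces and 26-connectivity-preserving thinning for skeletons is a design
decision; the source material names the features but not the connectivity.

**Voxel anisotropy** is carried as metadata only; FD is computed on the
voxel lattice (the intended data are 1 mm isotropic).

# ROI-mean FA

`mean_fa_by_roi()` averages the scalar map over voxels carrying each named
label. The atlas and the map must share a voxel grid — a mismatch is an
error, never a silent resample, because registration belongs to the
upstream (out-of-scope) diffusion pipeline. Non-finite voxels are excluded
and counted; FA outside $[0, 1]$ is flagged, not fatal. The 18 default
tract names cover bilateral corticospinal tract, superior/inferior
longitudinal fasciculus, cingulum, inferior occipital fasciculus, corona
radiata and caudate, the three corpus callosum segments, and the middle
cerebellar peduncle. The mapping of the five cortical networks onto the 16
FD feature slots is deliberately *not* guessed; the cohort generator treats
the FD feature count as a parameter with generic names.

# COP displacement

Processing order per trial: epoch at the perturbation onset, zero-phase
low-pass filter, remove the least-squares linear trend; then average the
processed epochs across trials sample-wise and sum absolute consecutive
differences over the first `window_s` (default 2 s).

* **Filter**: 4th-order Butterworth at 10 Hz, applied forward-backward with
  odd-reflection padding and steady-state initial conditions. Only the
  cutoff is inherited from the protocol; order and the zero-phase policy
  are package choices, validated against an independent reference design
  (coefficients frozen in the tests) and against the analytic sinusoid:
  one 0.5 Hz cycle of amplitude $A$ inside the 2 s window yields a path
  length of $4A$ within 2 %.
* **Epoch length** defaults to 4 s — the full two-cycle perturbation. This
  matters: detrending exactly one sinusoid cycle would remove a line with
  slope $-6A/(\pi T)$ and inflate the path length by ≈ 4.6 %, while
  detrending the full two-cycle epoch leaves the 2 s window's path length
  within 0.3 % of $4A$.
* The statistic is invariant to constant offsets and to linear drift added
  to any trial (both are removed exactly by the detrend step, up to filter
  edge effects of order $10^{-4}$).

# Group statistics

Between-group comparisons are computed from per-group summary statistics
(mean, SD, n), in the fixed orientation TBI − HC, so printed summary tables
can be re-analyzed directly. The **Welch** statistic with Satterthwaite
degrees of freedom is used: on the SCWT summary row (38.9 ± 8.1, n = 8 vs
53.1 ± 10.6, n = 10) Welch gives p = 0.0053, matching the printed 0.005,
whereas the pooled-variance Student test gives ≈ 0.0066; this reconciles the
ambiguous "Student's t test" label with the printed value. The
effect size is the pooled-SD standardized mean difference (Cohen's d),
which reproduces the printed 1.5 on the same row; the source's undefined
effect-size symbol is interpreted as d (values above 1 rule out
eta-squared). The five behavioral tests are reported uncorrected at
$\alpha = 0.05$, mirroring the original analysis plan.

# PLSC inference

* **Preprocessing**: each column of both blocks is z-scored. The source is
  silent on preprocessing; z-scoring is the convention of the toolbox
  lineage the analysis follows, puts FA, FD and heterogeneous behavioral
  scales on one footing, and makes $R$ a correlation-scale matrix.
* **Sign convention**: each component is flipped so the largest-magnitude
  element of its imaging salience is positive, before any reporting.
* **Permutation test**: rows of $Y$ are permuted against $X$ and the SVD
  re-run; since column z-scoring commutes with row permutation, permuting
  the z-scored block is exactly equivalent to re-preprocessing the permuted
  raw block (and much cheaper). The add-one estimator
  $p_\ell = (1 + \#\{d^{perm}_\ell \ge d^{obs}_\ell\})/(1 + n_{perm})$
  avoids $p = 0$ and fixes the tail convention (non-strict inequality).
  No Procrustes re-alignment is applied to later components; the regime of
  interest has a single significant component, and this limitation is
  stated rather than papered over.
* **Bootstrap**: subjects are resampled with replacement, each resample is
  re-standardized and re-decomposed, and components are aligned to the
  original by the sign of the salience inner products (adequate in the
  rank-1 regime; no full Procrustes rotation). Resamples with a constant
  column are redrawn and counted. BSR = original salience / bootstrap SE,
  stability at $|BSR| \ge 2$.
* Both groups are pooled into a single PLSC, as in the original design.

# The synthetic world

The generators state the world the tests run in; their defaults are fixed
once and are not tuning knobs.

* **Cohort**: 18 subjects (8 HC + 10 TBI), 34 imaging features (18 named FA
  + 16 generic FD slots), 5 behavioral measures. Each subject has a latent
  $t_i \sim N(0,1)$; rows are $\text{effect} \cdot t_i \cdot
  \text{salience} + N(0, \text{noise\_sd})$ per block. The rank-1 structure
  mirrors the single significant latent component the analysis is expected
  to find; `effect = 0` yields exactly independent blocks for null
  calibration. The default planted imaging salience puts equal weight on
  the first 6 features (a sparse support, so "planted" vs "pure-noise"
  features are well defined); the behavioral salience is uniform over the 5
  measures. `noise_sd = 1` with `effect = 3` gives a strong but not
  degenerate signal (median cosine to truth ≈ 0.96 at n = 100). An optional
  per-measure TBI mean shift plants group differences for the group-stats
  tests.
* **COP traces**: 0.5 Hz, two cycles (4 s) of amplitude 2 cm starting 1 s
  into a 6 s trial at 100 Hz, with optional linear drift and Gaussian noise
  (default SD 0.05 cm, a realistic force-platform noise floor). Onset index
  and sampling rate are stored with the trace.
* **Phantoms**: Menger sponge (built by recursive subdivision keeping the
  20 subcells with at most one middle coordinate, anchored at the origin so
  corner-anchored $3^k$ counting is exact), solid cube, sheet, rod, single
  voxel.
* **Labeled volumes**: disjoint axis-aligned boxes with constant scalar
  values, so ROI means have exact expected answers; written and re-read as
  NIfTI-1.

What the generators do **not** emulate: MRI physics, diffusion tensors,
FreeSurfer surfaces, realistic spatial autocorrelation, non-Gaussian
behavioral distributions, or any individual-level resemblance to real
study data beyond block dimensions and group sizes. A green test therefore
establishes the *algorithmic* correctness and calibration of the pipeline
(exact oracles, type-I error in [0.02, 0.09], salience recovery, BSR
separation), not clinical reproduction of the published cohort — whose
subject-level data are not deposited, so its headline result (one
significant component at p = 0.03 explaining 50.7 % of covariance) is
covered by these property-based checks instead of value reproduction.

# Numerical choices and edge cases

* One global integer seed per stochastic entry point; each generator draws
  from an independent 31-bit sub-stream derived from it, and the caller's
  RNG state is always restored.
* FD estimates outside $[0, 3]$ (possible on pathological series) warn and
  return; an all-equal flat series fits slope 0 with $R^2$ defined as 1.
* Degenerate inputs are loud, named errors: empty masks, box sizes
  exceeding the mask extent, constant columns (named) before z-scoring,
  zero-voxel ROIs (named), mixed sampling rates, epochs that do not fit.
* `n_perm < 100` and `n_boot < 100` are rejected as unstably small.
* NIfTI-1 I/O is implemented in-package (no R NIfTI reader is available in
  the supported dependency set) and covers uncompressed and gzipped
  single-file volumes with plain voxel grids; it was cross-validated
  against an independent neuroimaging I/O library in both directions.
* The pipeline report contains no timestamps, so identical configs produce
  byte-identical reports; per-stage timing goes to the message log only.

# Known limitations

* Surface FD uses boundary voxels, not a reconstructed mesh; skeleton FD
  uses in-package thinning, not an external tract-skeleton pipeline.
* Bootstrap component alignment is sign-only; in genuinely multi-component
  regimes a Procrustes rotation would be needed.
* The COP statistic implements the single-axis, high-amplitude posterior
  condition only; the 2×2 perturbation design is out of scope.
* FD ignores voxel anisotropy, and no multiple-testing correction is
  applied across the five behavioral tests (by design parity with the
  original analysis).
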