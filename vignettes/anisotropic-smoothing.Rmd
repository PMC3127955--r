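---
title: "Anisotropic Gaussian smoothing as a model of perceived orientation"
author: "visaniso"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anisotropic Gaussian smoothing as a model of perceived orientation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(visaniso)
```

## The model

The package implements a scale-space account of visual orientation
anisotropy. The finite resolution of the visual system is modelled as
convolution of the retinal image with a Gaussian kernel; anisotropy enters
by making the kernel *elliptical*, with the vertical radius `a_v` larger
than the horizontal radius `a_h`. The test stimulus is a Gaussian luminance
profile (GLP): an elliptical 2-D Gaussian blob with major/minor radii and an
orientation `theta`.

Because the convolution of two Gaussians is Gaussian with summed
covariances, the perceived profile has covariance

$$\Sigma_{\text{perceived}} = \Sigma_{\text{glp}} + \Sigma_{\text{kernel}},
\qquad
\Sigma_{\text{kernel}} = \begin{pmatrix} a_h^2 & r \\ r & a_v^2 \end{pmatrix},$$

and the perceived orientation is the major principal axis of the sum,
$\tfrac12\,\mathrm{atan2}(2 s_{xy},\, s_{xx} - s_{yy})$. The illusory bias
is the signed difference between that axis and the stimulus orientation,
counterclockwise positive, wrapped to $(-90^\circ, 90^\circ]$. For a
vertically elongated kernel the bias is positive on $(0^\circ, 90^\circ)$
and negative on $(90^\circ, 180^\circ)$: orientations are attracted toward
the vertical, and more strongly the thicker (rounder) the GLP.

```{r bias}
k <- kernel_spec(0.84, 2.08)   # group-mean kernel of the adjustment study
sapply(c(0.5, 0.65, 0.8), function(q)
  predict_bias(glp(1.9, 1.9 * q, orientation = 22.5), k))
```

Two modelling conventions are worth stating explicitly:

* **Radii are standard deviations** of the Gaussian density. Any fixed
  iso-contour convention would rescale all radii by one constant; standard
  deviations are the choice that makes covariance addition exact, and the
  stimulus aspect ratios that define the experimental conditions are
  contour-independent.
* **Orientations live on a 180-degree circle** (a GLP rotated by 180 degrees
  is the same stimulus), measured counterclockwise from horizontal with the
  y axis up. Signed orientation differences are wrapped to
  $(-90^\circ, 90^\circ]$ with ties at $\pm 90^\circ$ mapped to
  $+90^\circ$, so the orientation space has one closed endpoint.

Two geometric consequences of the additive model are easily missed. At the
cardinal orientations mirror symmetry forbids any oblique rotation, but it
does not force a zero bias: if the kernel anisotropy $a_v^2 - a_h^2$
exceeds the stimulus anisotropy (for the study's stimuli, up to
$2.71\,\mathrm{deg}^2$, less than the group-mean kernel's
$3.62\,\mathrm{deg}^2$), a horizontal GLP's perceived axis flips outright
to vertical — a pure $+90^\circ$ bias. Likewise, response dispersion need
not grow with GLP thickness at every orientation once the kernel dominates
the smoothed shape; the package's tests assert these behaviours in the
regimes where they actually hold.

## The model hierarchy and its comparison

Five variants are supported, nested for F testing:

| kind                    | kernel parameters            | free parameters |
|-------------------------|------------------------------|-----------------|
| `isotropic`             | none (predicts zero bias)    | 0               |
| `homogeneous`           | `a_h, a_v`                   | 2               |
| `homogeneous_oriented`  | `a_h, a_v, r`                | 3               |
| `radial_heterogeneous`  | `a_h, a_v` per thickness     | 6               |
| `angular_heterogeneous` | `a_h, a_v, r` per orientation| 36 raw / 18 aggregated |

Heterogeneity is modelled per condition subset (one kernel per GLP
thickness, or per orientation subset assigned by the nominal stimulus
orientation), not as a spatially varying convolution of a single image.

Trials are aggregated over mirror-symmetric orientation pairs
($\theta$ with $180^\circ - \theta$, sign-flipped), exploiting the model's
predicted antisymmetry; twelve orientations collapse to six canonical
members in $(0^\circ, 90^\circ)$ and the angular model's parameter count
drops from 36 to 18. Cell means and variances are computed *circularly*
(each cell recentred on its circular mean before taking moments). Far from
the $\pm 90^\circ$ wrap point this is identical to the arithmetic mean and
variance; it matters only for strongly biased conditions whose response
distribution straddles the wrap, where arithmetic statistics would see a
spurious bimodal spread.

Fitting is weighted least squares with the inverse floored cell variances as
weights. The F statistic for nested fits is

$$F = \frac{(\mathrm{WRSS}_1 - \mathrm{WRSS}_2)/(p_2 - p_1)}
           {\mathrm{WRSS}_2/(n - p_2)},$$

with `n` the number of *trial-level* observations. WRSS is accordingly
computed at trial level through the identity
$\mathrm{WRSS} = \sum_c [(n_c - 1)\,s^2_c + n_c(\bar b_c - \hat b_c)^2]/w_c$
over cells (raw variance $s^2_c$, floored variance $w_c$); with the default
1080-trial design this yields the df shapes (2, 1078), (4, 1074) and
(15, 1062), and keeps the null distribution of the statistic honest — had
the within-cell residual mass been dropped while keeping trial-level df,
the test would be drastically anticonservative. Because the free-parameter
convention counts both radii per subset while the mean biases constrain
only one combination of them (next section), the heterogeneity tests are
mildly conservative: their empirical type-I rate sits below the nominal
level, which the test suite's 200-replicate null calibration confirms is
still statistically consistent with the nominal 0.01.

The three canonical comparisons (homogeneous vs isotropic, radial vs
homogeneous, angular vs homogeneous-oriented) are reported with raw
p-values; no multiplicity correction is applied.

## Identifiability: what the biases can and cannot pin down

Adding $\Sigma_{\text{kernel}}$ shifts $s_{xx} - s_{yy}$ by
$a_h^2 - a_v^2$ and $2 s_{xy}$ by $2r$, and the predicted orientation
depends on the kernel *only* through those shifts. For axis-aligned kernels
the mean biases therefore constrain only

$$d = a_v^2 - a_h^2,$$

and the WLS objective is exactly flat along the ridge
$a_v^2 - a_h^2 = \hat d$. `fit_model()` embraces this structure: it
optimizes the identifiable combination(s) $(d, r)$ per condition subset
(1-D: 97-point bracketing grid with Brent refinement of every local
minimum; 2-D: multistart Nelder–Mead, `r` started at 0, within radius
bounds 0.1–6 degrees and the positive-definiteness bound
$|r| < 0.99\,a_h a_v$, infeasible parameters receiving a finite penalty),
and then places the remaining degree of freedom — the kernel *scale*
$t = a_h^2$ — by a second source of information: the observed pattern of
response dispersions.

The dispersion law (below) predicts how the response SD varies over
conditions as a function of the smoothed covariance, which depends on $t$
and $d$ separately. Given $\hat d$, the scale is chosen to minimize the
(weighted) squared distance between observed and predicted log SDs, with
the dispersion scale profiled out and the roundness exponent held at the
package default. Because this information channel is weak, the plug-in
estimate of $t$ carries a noticeable finite-sample bias; `fit_model()`
removes most of it with a parametric-bootstrap correction (40 internally
seeded replicates of the SD profile under the fitted law). The practical
upshot, visible in any simulation study: $\hat a_v$ (dominated by $d$) is
precise, while $\hat a_h$ is intrinsically noisy — a fitted kernel's
anisotropy is far better determined than its absolute scale, and large
between-observer spread in $\hat a_h$ should be expected rather than read
as observer heterogeneity.

Degenerate cases are flagged rather than silently resolved: all-zero biases
pin $d = 0$ but leave the scale entirely free
(`dispersion_allocated = FALSE`), and a flat bias objective (nothing to fit)
sets `ridge_identifiable = FALSE`. An isotropic smoothed covariance has no
orientation; `orientation_of()` returns a flagged `NA` and `predict_bias()`
maps it to a zero bias with a warning instead of an arbitrary
$\pm 90^\circ$ jump.

## The synthetic observers

`simulate_experiment()` generates adjustment responses with exactly the
statistical structure the analysis assumes:

* **Design**: 12 reference orientations ($7.5^\circ + 15^\circ k$,
  cardinals excluded) × 3 aspect ratios (0.5, 0.65, 0.8; major radius
  1.9°) × 2 frame sessions × 3 blocks × 5 repetitions = 1080 trials per
  participant, trial order shuffled within block under a seed. The frame
  label has no effect in the generator, mirroring its role as a control
  variable.
* **Responses**: reference orientation + model bias + Gaussian noise on the
  180-degree circle, quantized to the probe's 1-degree lattice. Optional
  lapse trials (default rate 0) respond uniformly.
* **Dispersion law**: the response SD is
  $\sigma_{\text{base}}\,\rho^{\kappa}\,(1-\rho)^{-1/2}$ evaluated on the
  smoothed eigenvalue ratio $\rho = \lambda_{\min}/\lambda_{\max}$ —
  strictly increasing in $\rho$: the rounder the smoothed stimulus, the
  harder the adjustment. Defaults $\sigma_{\text{base}} = 4^\circ$,
  $\kappa = 0.5$, capped at 50° (just below the 52° SD of a uniform
  orientation response) near the degenerate limit. The defaults are
  calibrated to reproduce the qualitative dispersion pattern of the
  adjustment data — most spread for horizontal-adjacent GLPs, least for
  vertical-adjacent — not its absolute magnitudes.

What the generator deliberately does **not** emulate: learning or fatigue
across blocks, reaction times, cardinal-orientation discrimination
advantages beyond what the smoothing geometry itself produces, and —
importantly — the full response variability of human observers. Real
adjustment data contain noise sources beyond the condition-dependent
dispersion law, so the explained variances obtained on synthetic data
(~95–99% against a matching ceiling) are far higher than what human data
yield; passing recovery tests on this generator demonstrates correctness of
the estimation machinery, not that human data are this clean.

## Numerical choices

* **Numeric oracle**: the analytic covariance-addition route is validated
  against an independent path that renders the GLP
  (default 32 px/degree), convolves it with the sampled kernel (truncated
  at 4 SD and renormalized, zero-padded FFT; total mass conserved to
  0.1%), and extracts orientation from image second moments. The rendered
  extent covers 4 SD of the *smoothed* profile. Agreement is required to
  0.5° and achieved to better than 0.1° on all 36 conditions. Kernels whose
  smallest SD falls below one pixel are rejected as undersampled.
* **Moment accuracy**: point-sampled Gaussians are spectrally accurate, so
  the moment error of a render is governed by the finite extent, not the
  resolution — it falls from ~$10^{-3}$ at a 4-SD extent to machine
  precision at 8 SD. The tests assert this truncation-driven convergence
  and the 1% accuracy bound at the default settings.
* **Variance floor**: per-cell variances are floored at $(0.5^\circ)^2$
  (one probe step) before inversion into weights, since quantization bounds
  the true response variance away from zero.
* **Optimization tolerances**: Brent/Nelder–Mead relative tolerance
  $10^{-10}$–$10^{-12}$; a fit is `converged` when the optimizer terminates
  within tolerance. Ties along flat objectives are flagged, not broken
  arbitrarily.
* **Problem sizes**: the test suite and the recovery script use the study's
  own scale — six observers × 1080 trials — plus a 20-observer recovery
  property and a 200-replicate null calibration of the radial-vs-homogeneous
  F test; the full suite runs in well under a minute on one core.

## Known limitations

* The kernel scale $a_h$ is only weakly identified from a single observer's
  data (see above); treat per-observer $\hat a_h$ with its uncertainty in
  mind.
* Heterogeneous smoothing is per-subset, not a true position-dependent
  convolution; estimated subset kernels describe average smoothing for that
  subset and should not be read as a veridical map of resolution across the
  visual field.
* The dispersion law is a two-parameter phenomenological choice; only its
  ordering properties, not its magnitudes, are constrained by the
  experiment it emulates.
* Monitor physics (gamma, luminance calibration, viewing geometry) is
  retained only as configuration constants; all computation is in degrees
  of visual angle.
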