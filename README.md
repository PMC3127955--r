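# visaniso

Anisotropic Gaussian smoothing models of perceived orientation.

## The problem

Human vision is anisotropic: performance and perceptual biases depend on
stimulus orientation. One compact account models the finite resolution of
the visual system as Gaussian scale-space smoothing of the retinal image and
makes the smoothing kernel *elliptical* — more smoothing along the vertical
than the horizontal. A striking consequence is an illusory orientation bias:
an elongated Gaussian luminance profile (GLP) looks rotated toward the
vertical, and the thicker the GLP, the stronger the illusion.

`visaniso` is for psychophysicists and modellers who want to work with this
account quantitatively: predict biases in closed form, validate the
predictions against brute-force image convolution, simulate the adjustment
experiment that measures them, and compare nested variants of the smoothing
model on trial data.

## The model

A GLP with major/minor radii (standard deviations) and orientation θ has
density covariance Σ_glp = R(θ) diag(major², minor²) R(θ)ᵀ (degrees of
visual angle squared). Smoothing with an elliptical Gaussian kernel with
covariance

    Σ_kernel = [ a_h²  r ]
               [ r    a_v² ]

is a convolution of Gaussians, so the perceived profile is Gaussian with

    Σ_perceived = Σ_glp + Σ_kernel.

The perceived orientation is the major principal axis of Σ_perceived,
`atan2(2 s_xy, s_xx − s_yy) / 2`, and the illusory bias is its signed
difference from θ (counterclockwise positive, wrapped to (−90°, 90°]).
With a_v > a_h every oblique orientation is attracted toward the vertical.

Four nested model variants are fit by weighted least squares (weights =
inverse response variances) and compared by nested F tests: isotropic
(a_h = a_v, zero bias, 0 free parameters), homogeneous (a_h, a_v; 2),
homogeneous with an oriented kernel (adds r; 3), radial-heterogeneous (one
pair per GLP thickness; 6) and angular-heterogeneous (one triple per
orientation subset; 36 raw, 18 after mirror-pair aggregation). With the
experiment's 1080 trials per participant the three canonical comparisons
have F degrees of freedom (2, 1078), (4, 1074) and (15, 1062).

## Worked example

```r
library(visaniso)

# the illusion in closed form: a thin GLP at 22.5 deg under the group-mean
# kernel is perceived rotated a further 43 deg toward the vertical
predict_bias(glp(1.9, 0.95, orientation = 22.5), kernel_spec(0.84, 2.08))
#> [1] 43.35466

# simulate the full experiment: 6 observers x 1080 adjustment trials
k <- kernel_spec(0.84, 2.08)
obs <- lapply(1:6, function(i) observer_spec(k, seed = i))
trials <- simulate_experiment(design_schedule(), obs, schedule_seed = 1)

# fit the homogeneous anisotropic model to participant 1
tp <- trials[trials$participant == 1, ]
conds <- aggregate_pairs(tp, major_radius = 1.9)
fit <- fit_model(model_spec("homogeneous", conditions_grid(conds)), conds)
fit
#> Fit of 'homogeneous' model: WRSS = 1087 on n = 1080 trials (18 cells), 2 free parameter(s)
#>   group      a_h    a_v r
#> 1   all 0.733247 2.0292 0

# anisotropic vs isotropic smoothing
iso <- fit_model(model_spec("isotropic", conditions_grid(conds)), conds)
nested_f_test(iso, fit)
#> 	Nested F test for weighted least-squares smoothing models
#> data:  isotropic (restricted) vs homogeneous (full), n = 1080 trials
#> F = 37055, df1 = 2, df2 = 1078, p-value < 2.2e-16
```

The fitted radii recover the generating kernel: the anisotropy
d = a_v² − a_h² is pinned sharply by the mean biases, while the overall
kernel scale is inferred from the pattern of response dispersions (see the
methods vignette for why the scale is only weakly identified). The whole
simulate → fit → compare → report chain is also available as one call:

```r
res <- run_pipeline(default_config(seed = 1), outdir = "runs/demo")
```

which writes the trial table (CSV), per-participant fits (JSON), the F-test
and explained-variance tables (CSV) and a markdown report. The analytic
predictions can be checked against the independent numeric route (render the
stimulus, convolve with the sampled kernel, take image second moments) with
`oracle_check()`; all 36 experimental conditions agree to better than 0.1°
at 32 px/deg.

## Package layout

- `stimuli`: `glp()`, `glp_covariance()`, `design_schedule()`,
  `build_schedule()`, `render_glp()`, `image_moments()`
- `scale space`: `kernel_spec()`, `smooth_covariance()`, `orientation_of()`,
  `numeric_convolve()`
- `bias model`: `predict_bias()`, `model_spec()`, `predict_grid()`
- `observer simulation`: `observer_spec()`, `response_sd()`,
  `simulate_experiment()`
- `fitting`: `aggregate_pairs()`, `wls_objective()`, `fit_model()`,
  `nested_f_test()`, `explained_variance()`, `systematic_ceiling()`,
  `compare_models()`
- `pipeline`: `default_config()`, `run_pipeline()`, `oracle_check()`
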