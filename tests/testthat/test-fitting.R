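fake_fit <- function(kind, n_free, wrss, n_obs = 1080L, mean_bias = 1:3) {
  structure(list(model = list(kind = kind), n_free = n_free, wrss = wrss,
                 n_obs = n_obs, n_cells = length(mean_bias),
                 conditions = data.frame(mean_bias = mean_bias)),
            class = "fit_result")
}

test_that("mirror-pair aggregation averages sign-flipped biases", {
  tab <- data.frame(
    participant = 1L,
    orientation_deg = rep(c(7.5, 172.5, 22.5, 157.5), each = 2),
    aspect_ratio = 0.5,
    bias_deg = c(2, 2, -2, -2, 3, 3, -1, -1))
  ag <- aggregate_pairs(tab, major_radius = 1.9)
  expect_equal(ag$orientation_deg, c(7.5, 22.5))
  # perfectly antisymmetric pair keeps its magnitude
  expect_equal(ag$mean_bias[1], 2)
  # asymmetric pair: arithmetic mean after the sign flip
  expect_equal(ag$mean_bias[2], 2)
  expect_equal(ag$n, c(4L, 4L))
  expect_equal(ag$var_raw, c(0, 4 / 3))
  expect_equal(ag$variance, c(0.25, 4 / 3))  # floor at one probe step
})

test_that("unpaired orientations cannot be aggregated", {
  tab <- data.frame(participant = 1L, orientation_deg = c(7.5, 7.5),
                    aspect_ratio = 0.5, bias_deg = c(1, 2))
  expect_error(aggregate_pairs(tab), "unpaired")
  # raw (unpaired) aggregation still works
  ag <- aggregate_trials(tab, mirror_pairs = FALSE)
  expect_equal(ag$mean_bias, 1.5)
})

test_that("the experiment aggregates to 18 cells of 60 trials", {
  tr <- simulate_experiment(study_design(1L), default_observers(1L))
  ag <- aggregate_pairs(tr)
  expect_equal(nrow(ag), 18L)
  expect_true(all(ag$n == 60L))   # 30 per raw condition after frame pooling
  expect_equal(sum(ag$n), 1080L)
  expect_true(all(ag$orientation_deg < 90))
})

test_that("cell statistics are circular: wrap-straddling cells stay unimodal", {
  set.seed(31)
  b <- visaniso:::wrap_pm90(85 + rnorm(400, 0, 8))  # straddles +90
  st <- visaniso:::circ_cell_stats(b)
  expect_equal(unname(st["mean"]), 85, tolerance = 1.5)
  expect_lt(sqrt(unname(st["var"])), 10)
  # far from the wrap point they coincide with arithmetic statistics
  b2 <- rnorm(100, 10, 4)
  st2 <- visaniso:::circ_cell_stats(b2)
  expect_equal(unname(st2["mean"]), mean(b2), tolerance = 1e-10)
  expect_equal(unname(st2["var"]), var(b2), tolerance = 1e-8)
})

test_that("the WLS objective matches its closed-form special cases", {
  conds <- noiseless_conditions(study_kernel(), variance = 2, var_raw = 2)
  grid <- conditions_grid(conds)
  hom <- model_spec("homogeneous", grid)
  # predictions equal to the means give a zero objective
  expect_equal(wls_objective(hom, c(0.84, 2.08), conds), 0,
               tolerance = 1e-12)
  # the zero-parameter isotropic model leaves the total weighted signal
  iso <- model_spec("isotropic", grid)
  expect_equal(wls_objective(iso, NULL, conds),
               sum(conds$mean_bias^2 / conds$variance))
  # infeasible parameters get a finite penalty above any feasible value
  expect_gte(wls_objective(hom, c(-1, 2), conds), 1e10)
  ori <- model_spec("homogeneous_oriented", grid)
  expect_gte(wls_objective(ori, c(0.5, 0.5, 0.3), conds), 1e10)
})

test_that("noiseless data pin down the identifiable kernel combination", {
  conds <- noiseless_conditions(study_kernel())
  fit <- fit_model(model_spec("homogeneous", conditions_grid(conds)), conds)
  expect_lt(fit$wls, 1e-6)
  d_true <- 2.08^2 - 0.84^2
  expect_equal(unname(fit$d["all"]), d_true, tolerance = 1e-3)
  expect_equal(fit$params$a_v^2 - fit$params$a_h^2, d_true,
               tolerance = 1e-3)
  expect_true(fit$converged)

  # independent oracle: dense grid search over (a_h, a_v) bracketing the
  # generator finds its minimum on the same ridge a_v^2 - a_h^2 = d
  grid <- conditions_grid(conds)
  hom <- model_spec("homogeneous", grid)
  avals <- seq(0.3, 3, length.out = 41)
  obj <- outer(avals, avals, Vectorize(function(ah, av) {
    wls_objective(hom, c(ah, av), conds)
  }))
  best <- which(obj == min(obj), arr.ind = TRUE)[1, ]
  expect_lt(min(obj), 0.05)  # near-zero on the ridge at grid resolution
  expect_equal(avals[best[2]]^2 - avals[best[1]]^2, d_true,
               tolerance = 0.3)
})

test_that("all-zero biases leave the kernel scale non-identifiable", {
  conds <- noiseless_conditions(kernel_spec(1, 1))  # isotropic truth
  expect_true(all(abs(conds$mean_bias) < 1e-10))
  fit <- fit_model(model_spec("homogeneous", conditions_grid(conds)), conds)
  expect_lt(fit$wls, 1e-10)
  # zero biases pin the anisotropy at zero, so any a_h = a_v is optimal;
  # dispersion-free data cannot place the kernel scale on that ridge
  expect_equal(unname(fit$d["all"]), 0, tolerance = 1e-6)
  expect_equal(fit$params$a_h, fit$params$a_v, tolerance = 1e-8)
  expect_false(fit$dispersion_allocated[["all"]])
})

test_that("the nested F statistic follows the textbook formula", {
  r <- fake_fit("isotropic", 0L, 110)
  f <- fake_fit("homogeneous", 2L, 100)
  ht <- nested_f_test(r, f)
  expect_equal(unname(ht$statistic), (10 / 2) / (100 / 1078),
               tolerance = 1e-12)
  expect_equal(unname(ht$statistic), 53.9, tolerance = 1e-12)
  expect_equal(unname(ht$parameter), c(2, 1078))
  expect_equal(ht$p.value, pf(53.9, 2, 1078, lower.tail = FALSE))
  # identical fits: F = 0, p = 1
  ht0 <- nested_f_test(fake_fit("homogeneous", 2L, 100),
                       fake_fit("radial_heterogeneous", 6L, 100))
  expect_equal(unname(ht0$statistic), 0)
  expect_equal(ht0$p.value, 1)
  # a worse full model signals optimizer failure and clips at zero
  expect_warning(
    htw <- nested_f_test(fake_fit("homogeneous", 2L, 100),
                         fake_fit("radial_heterogeneous", 6L, 120)),
    "clipped")
  expect_equal(unname(htw$statistic), 0)
  # non-nested pairs are refused
  expect_error(nested_f_test(fake_fit("radial_heterogeneous", 6L, 90),
                             fake_fit("homogeneous_oriented", 3L, 80)),
               "not nested")
})

test_that("fits are monotone along the nesting hierarchy with trial-level dfs", {
  tr <- simulate_experiment(study_design(1L), default_observers(1L),
                            schedule_seed = 21)
  cmp <- compare_models(tr)
  fits <- cmp$fits[["1"]]
  expect_gte(fits$isotropic$wrss, fits$homogeneous$wrss)
  expect_gte(fits$homogeneous$wrss, fits$radial_heterogeneous$wrss - 1e-8)
  expect_gte(fits$homogeneous$wrss, fits$homogeneous_oriented$wrss - 1e-8)
  expect_gte(fits$homogeneous_oriented$wrss,
             fits$angular_heterogeneous$wrss - 1e-8)
  ft <- cmp$f_tests
  expect_equal(ft$df1, c(2L, 4L, 15L))
  expect_equal(ft$df2, c(1078L, 1074L, 1062L))
  expect_true(all(is.finite(ft$F) & ft$F >= 0))
  # the homogeneous improvement over isotropic is decisive
  expect_lt(ft$p_value[1], 1e-10)
  # explained variance never exceeds its systematic ceiling
  ev <- cmp$explained
  expect_true(all(ev$explained <= ev$ceiling + 1e-10))
})

test_that("the F statistic is invariant under uniform weight rescaling", {
  tr <- simulate_experiment(study_design(1L), default_observers(1L),
                            schedule_seed = 22)
  conds <- aggregate_pairs(tr)
  grid <- conditions_grid(conds)
  # weights are the inverse variances; the observed dispersions (var_raw)
  # are data and stay fixed
  scaled <- conds
  scaled$variance <- conds$variance * 5
  f_of <- function(cc) {
    iso <- fit_model(model_spec("isotropic", grid), cc)
    hom <- fit_model(model_spec("homogeneous", grid), cc, ridge_boot = 0L)
    unname(nested_f_test(iso, hom)$statistic)
  }
  expect_equal(f_of(conds), f_of(scaled), tolerance = 1e-8)
})

test_that("parameter recovery: median over 20 synthetic observers within 15%", {
  d <- study_design(participants = 20L)
  obs <- default_observers(20L)
  tr <- simulate_experiment(d, obs, schedule_seed = 17)
  est <- vapply(1:20, function(p) {
    fit <- fit_homogeneous(tr, p)
    c(fit$params$a_h, fit$params$a_v)
  }, numeric(2))
  expect_lt(abs(median(est[1, ]) - 0.84) / 0.84, 0.15)
  expect_lt(abs(median(est[2, ]) - 2.08) / 2.08, 0.15)
})

test_that("explained variance vanishes for zero predictions on unbiased data", {
  d <- study_design(1L)
  obs <- list(observer_spec(kernel_spec(1, 1), seed = 3))  # isotropic truth
  tr <- simulate_experiment(d, obs)
  conds <- aggregate_pairs(tr)
  iso <- fit_model(model_spec("isotropic", conditions_grid(conds)), conds)
  ev <- explained_variance(iso, tr)
  expect_lt(abs(as.numeric(ev)), 0.03)
  ceil <- systematic_ceiling(tr)
  expect_gte(as.numeric(ceil), as.numeric(ev))
  expect_true(is.numeric(attr(ev, "weighted")))
})
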