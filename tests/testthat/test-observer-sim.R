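test_that("simulation is reproducible bit-for-bit and sized by the design", {
  d <- study_design(participants = 2L)
  obs <- default_observers(2L)
  t1 <- simulate_experiment(d, obs, schedule_seed = 3)
  t2 <- simulate_experiment(d, obs, schedule_seed = 3)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 2160L)
  expect_equal(as.vector(table(t1$participant)), rep(1080L, 2))
  expect_true(all(t1$response_deg >= 0 & t1$response_deg < 180))
  expect_true(all(t1$response_deg == round(t1$response_deg)))
  expect_true(all(t1$bias_deg > -90 & t1$bias_deg <= 90))
  expect_equal(t1$bias_deg,
               visaniso:::wrap_pm90(t1$response_deg - t1$orientation_deg))
  # a different observer seed changes the responses
  t3 <- simulate_experiment(d, list(obs[[1]],
                                    observer_spec(study_kernel(), seed = 99)),
                            schedule_seed = 3)
  expect_identical(t3$response_deg[t3$participant == 1],
                   t1$response_deg[t1$participant == 1])
  expect_false(identical(t3$response_deg[t3$participant == 2],
                         t1$response_deg[t1$participant == 2]))
  expect_error(simulate_experiment(d, list(obs[[1]], obs[[1]])), "distinct")
})

test_that("the noiseless unquantized limit reproduces predict_bias exactly", {
  d <- study_design(participants = 1L)
  obs <- list(observer_spec(study_kernel(), sigma_base = 1e-12, seed = 1))
  tr <- simulate_experiment(d, obs, quantize = FALSE)
  pred <- vapply(seq_len(nrow(tr)), function(i) {
    predict_bias(study_glp(tr$orientation_deg[i], tr$aspect_ratio[i]),
                 study_kernel())
  }, numeric(1))
  expect_equal(tr$bias_deg, pred, tolerance = 1e-8)
})

test_that("response SD follows the dispersion law limits and ordering", {
  # needle limit with kappa = 0: SD -> sigma_base
  thin <- glp(1.9, 0.02, 45)
  o0 <- observer_spec(kernel_spec(1e-3, 2e-3), sigma_base = 4, kappa = 0)
  expect_equal(response_sd(thin, o0), 4, tolerance = 0.01)
  # horizontal GLPs are smoothed rounder than vertical ones
  o <- observer_spec(study_kernel())
  for (q in c(0.5, 0.65, 0.8)) {
    expect_gt(response_sd(glp(1.9, 1.9 * q, 0), o),
              response_sd(glp(1.9, 1.9 * q, 90), o))
  }
  # the law is strictly increasing in the smoothed roundness
  rho <- seq(0.05, 0.95, by = 0.05)
  law <- visaniso:::dispersion_law(rho, 4, 0.5, 50)
  expect_true(all(diff(law) > 0))
  # thickness monotonicity: thicker GLPs disperse more wherever the
  # smoothed roundness grows with thickness -- at every orientation under
  # stimulus-dominated smoothing, and from the obliques toward vertical
  # under the strong group-mean kernel (near-horizontal GLPs invert there
  # because thin stimuli end up rounder than thick ones after smoothing)
  weak <- observer_spec(kernel_spec(0.3, 0.6))
  for (th in seq(7.5, 82.5, by = 15)) {
    sds_w <- vapply(c(0.5, 0.65, 0.8),
                    function(q) response_sd(glp(1.9, 1.9 * q, th), weak),
                    numeric(1))
    expect_true(all(diff(sds_w) > 0))
  }
  for (th in c(37.5, 52.5, 67.5, 82.5)) {
    sds_p <- vapply(c(0.5, 0.65, 0.8),
                    function(q) response_sd(glp(1.9, 1.9 * q, th), o),
                    numeric(1))
    expect_true(all(diff(sds_p) > 0))
  }
})

test_that("predicted dispersion is ordered horizontal > oblique > vertical", {
  for (k in list(study_kernel(), kernel_spec(0.5, 1.0), kernel_spec(1.5, 3))) {
    o <- observer_spec(k)
    for (q in c(0.5, 0.65, 0.8)) {
      sds <- vapply(seq(7.5, 172.5, by = 15),
                    function(th) response_sd(glp(1.9, 1.9 * q, th), o),
                    numeric(1))
      horiz <- sds[c(1, 12)]   # 7.5, 172.5
      oblique <- sds[c(3, 4, 9, 10)]  # 37.5, 52.5, 127.5, 142.5
      vert <- sds[c(6, 7)]     # 82.5, 97.5
      expect_true(min(horiz) > max(oblique))
      expect_true(min(oblique) > max(vert))
    }
  }
})

test_that("simulated response spread reproduces the dispersion ordering", {
  d <- study_design(participants = 1L)
  tr <- simulate_experiment(d, default_observers(1L), schedule_seed = 8)
  sd_cell <- tapply(tr$bias_deg,
                    list(tr$orientation_deg, tr$aspect_ratio), stats::sd)
  for (q in as.character(c(0.5, 0.65, 0.8))) {
    horiz <- mean(sd_cell[c("7.5", "172.5"), q])
    vert <- mean(sd_cell[c("82.5", "97.5"), q])
    expect_gt(horiz, vert)
  }
})

test_that("per-condition means converge to the model prediction (CLT)", {
  d <- design_schedule(orientations = 22.5, aspect_ratios = 0.5,
                       frames = "circular", blocks_per_session = 1L,
                       reps_per_block = 30L, participants = 1L)
  obs <- list(observer_spec(study_kernel(), seed = 4))
  tr <- simulate_experiment(d, obs)
  pred <- predict_bias(study_glp(22.5, 0.5), study_kernel())
  sd_true <- response_sd(study_glp(22.5, 0.5), obs[[1]])
  # 3-sigma CLT band plus half a probe step for quantization
  expect_lt(abs(mean(tr$bias_deg) - pred), 3 * sd_true / sqrt(30) + 0.5)
})

test_that("quantization biases per-condition means by at most half a step", {
  d <- design_schedule(orientations = c(37.5, 142.5), aspect_ratios = 0.65,
                       frames = "circular", blocks_per_session = 1L,
                       reps_per_block = 200L, participants = 1L)
  obs <- list(observer_spec(study_kernel(), seed = 9))
  tq <- simulate_experiment(d, obs, quantize = TRUE)
  tc <- simulate_experiment(d, obs, quantize = FALSE)
  for (th in c(37.5, 142.5)) {
    expect_lt(abs(mean(tq$bias_deg[tq$orientation_deg == th]) -
                    mean(tc$bias_deg[tc$orientation_deg == th])), 0.5)
  }
})

test_that("lapses replace a seeded subset with uniform responses", {
  d <- study_design(participants = 1L)
  o_lapse <- list(observer_spec(study_kernel(), lapse_rate = 0.1, seed = 2))
  o_none <- list(observer_spec(study_kernel(), lapse_rate = 0, seed = 2))
  tl <- simulate_experiment(d, o_lapse, schedule_seed = 5)
  tn <- simulate_experiment(d, o_none, schedule_seed = 5)
  changed <- mean(tl$response_deg != tn$response_deg)
  expect_gt(changed, 0.05)
  expect_lt(changed, 0.15)
  expect_true(all(tl$bias_deg > -90 & tl$bias_deg <= 90))
  expect_error(observer_spec(study_kernel(), lapse_rate = 0.5), "lapse")
})

test_that("trial tables round-trip through CSV", {
  d <- study_design(participants = 1L)
  tr <- simulate_experiment(d, default_observers(1L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(tr, path)
  expect_equal(readLines(path, n = 1),
               "participant,frame,block,trial,orientation_deg,aspect_ratio,response_deg,bias_deg")
  back <- read_trials(path)
  expect_equal(back$response_deg, tr$response_deg)
  expect_equal(back$bias_deg, tr$bias_deg)
  expect_equal(attr(back, "major_radius"), 1.9)
})
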