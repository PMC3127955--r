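# Shared fixtures, built in code.

# group-mean smoothing kernel reported for the adjustment study
study_kernel <- function() kernel_spec(0.84, 2.08, 0)

study_design <- function(participants = 6L) {
  design_schedule(participants = participants)
}

study_glp <- function(orientation = 22.5, ratio = 0.5) {
  glp(1.9, 1.9 * ratio, orientation = orientation)
}

# observers generated by the group-mean kernel, seeds 1..n
default_observers <- function(n = 6L, kernel = study_kernel(), ...) {
  lapply(seq_len(n), function(i) observer_spec(kernel, seed = i, ...))
}

# homogeneous-model fit for one participant of a trial table
fit_homogeneous <- function(trials, participant = 1L, ...) {
  tp <- trials[trials$participant == participant, , drop = FALSE]
  attr(tp, "major_radius") <- attr(trials, "major_radius")
  conds <- aggregate_pairs(tp)
  fit_model(model_spec("homogeneous", conditions_grid(conds)), conds, ...)
}

# noiseless aggregated conditions whose means equal a kernel's predictions;
# var_raw = 0 reflects truly dispersion-free data (weights sit at the floor)
noiseless_conditions <- function(kernel, n = 60L, variance = 0.25,
                                 var_raw = 0) {
  grid <- condition_grid(aggregated = TRUE)
  m <- model_spec("homogeneous", grid,
                  params = data.frame(group = "all", a_h = kernel$a_h,
                                      a_v = kernel$a_v, r = kernel$r))
  data.frame(participant = 1L,
             orientation_deg = grid$orientation_deg,
             aspect_ratio = grid$aspect_ratio,
             major_radius = grid$major_radius,
             mean_bias = predict_grid(m),
             variance = variance, var_raw = var_raw, n = n)
}
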