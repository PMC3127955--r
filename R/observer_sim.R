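# Observer simulation: synthetic adjustment-task responses with the
# statistical structure the downstream analysis assumes (model-generated
# biases, orientation-dependent response dispersion, 1-degree probe
# quantization, optional lapses).

#' Synthetic observer
#'
#' An observer responds to a GLP with the model-predicted perceived
#' orientation plus Gaussian response noise on the 180-degree orientation
#' circle. The noise SD follows a two-factor dispersion law evaluated on the
#' smoothed covariance (see [response_sd()]): the rounder the smoothed
#' stimulus, the harder the adjustment and the larger the spread. Responses
#' are quantized to the 1-degree probe lattice.
#'
#' @param kernel Generating [kernel_spec()] (the observer's smoothing truth).
#' @param sigma_base Baseline response SD, degrees (> 0); default 4.
#' @param kappa Dispersion-roundness exponent (>= 0); default 0.5.
#' @param lapse_rate Probability of an unengaged trial with a uniform
#'   response; in `[0, 0.1]`, default 0.
#' @param seed Integer seed; distinct per observer.
#' @param sd_cap Upper bound on the response SD, degrees; applied for
#'   (near-)degenerate smoothed covariances where the law diverges. The
#'   default 50 sits just below the SD of a uniform orientation response
#'   (180 / sqrt(12) ~ 52).
#' @return An object of class `"observer_spec"`.
#' @export
observer_spec <- function(kernel, sigma_base = 4, kappa = 0.5,
                          lapse_rate = 0, seed = 1L, sd_cap = 50) {
  stopifnot(inherits(kernel, "kernel_spec"),
            is.numeric(sigma_base), length(sigma_base) == 1L, sigma_base > 0,
            is.numeric(kappa), length(kappa) == 1L, kappa >= 0,
            is.numeric(lapse_rate), length(lapse_rate) == 1L,
            lapse_rate >= 0, lapse_rate <= 0.1,
            is.numeric(seed), length(seed) == 1L, is.finite(seed),
            sd_cap > 0)
  structure(list(kernel = kernel, sigma_base = sigma_base, kappa = kappa,
                 lapse_rate = lapse_rate, seed = as.integer(seed),
                 sd_cap = sd_cap),
            class = "observer_spec")
}

#' @export
print.observer_spec <- function(x, ...) {
  cat(sprintf(
    "Synthetic observer: kernel (%.3g, %.3g, %.3g), sigma_base %.3g deg, kappa %.3g, lapse %.3g, seed %d\n",
    x$kernel$a_h, x$kernel$a_v, x$kernel$r, x$sigma_base, x$kappa,
    x$lapse_rate, x$seed))
  invisible(x)
}

# dispersion law on the smoothed eigenvalue ratio rho = lambda_min/lambda_max:
# sd = sigma_base * rho^kappa * (1 - rho)^(-1/2), capped at sd_cap.
dispersion_law <- function(rho, sigma_base, kappa, sd_cap) {
  sd <- ifelse(rho >= 1, Inf,
               sigma_base * rho^kappa * (1 - rho)^(-0.5))
  pmin(sd, sd_cap)
}

# eigenvalue ratio of smoothed covariances, vectorized over cells
smoothed_eigen_ratio <- function(theta, major, ratio, ah2, av2, r) {
  A <- major^2 * (1 - ratio^2)
  t2 <- deg2rad(2 * theta)
  sxx_syy <- A * cos(t2) + ah2 - av2        # s_xx - s_yy of the sum
  sxy2 <- A * sin(t2) + 2 * r               # 2 s_xy of the sum
  tr <- major^2 * (1 + ratio^2) + ah2 + av2
  root <- sqrt(sxx_syy^2 + sxy2^2)
  pmax((tr - root) / (tr + root), 0)
}

#' Response standard deviation for a stimulus
#'
#' Evaluates the dispersion law
#' `sigma_base * rho^kappa * (1 - rho)^(-1/2)` on the eigenvalue ratio
#' `rho = lambda_min / lambda_max` of the smoothed covariance. The law is
#' strictly increasing in `rho`: as the smoothed stimulus approaches
#' roundness the orientation becomes harder to adjust. The SD is capped at
#' `observer$sd_cap` near the degenerate limit.
#'
#' @param glp A [glp()] stimulus.
#' @param observer An [observer_spec()].
#' @return Response SD in degrees.
#' @export
response_sd <- function(glp, observer) {
  stopifnot(inherits(glp, "glp"), inherits(observer, "observer_spec"))
  k <- observer$kernel
  rho <- smoothed_eigen_ratio(glp$orientation, glp$major_radius,
                              aspect_ratio(glp), k$a_h^2, k$a_v^2, k$r)
  dispersion_law(rho, observer$sigma_base, observer$kappa, observer$sd_cap)
}

#' Simulate the adjustment experiment
#'
#' For every trial stub of the design (see [build_schedule()]), the response
#' is the reference orientation plus the model-predicted bias plus Gaussian
#' noise with the observer's condition-dependent SD, wrapped to the
#' orientation circle and quantized to the 1-degree probe lattice. Lapse
#' trials (probability `lapse_rate`) respond uniformly. The frame condition
#' has no effect in the generator. Identical seeds reproduce the table
#' bit-for-bit.
#'
#' @param design A [design_schedule()].
#' @param observers List of [observer_spec()], one per participant, with
#'   distinct seeds.
#' @param schedule_seed Seed for the trial-order shuffles.
#' @param quantize Quantize responses to the 1-degree lattice? (default TRUE;
#'   disable for the exact noiseless limit).
#' @return A trial table: data frame with columns `participant`, `frame`,
#'   `block`, `trial`, `orientation_deg`, `aspect_ratio`, `response_deg`,
#'   `bias_deg`, where `bias_deg = wrap(response - orientation)` in
#'   `(-90, 90]` and `response_deg` lies in `[0, 180)`.
#' @export
simulate_experiment <- function(design, observers, schedule_seed = 1L,
                                quantize = TRUE) {
  stopifnot(inherits(design, "design_schedule"), is.list(observers),
            length(observers) == design$participants)
  for (o in observers) stopifnot(inherits(o, "observer_spec"))
  seeds <- vapply(observers, function(o) o$seed, integer(1L))
  if (anyDuplicated(seeds)) {
    stop("observer seeds must be distinct", call. = FALSE)
  }
  stubs <- build_schedule(design, seed = schedule_seed)
  cells <- condition_grid(design$orientations, design$aspect_ratios,
                          design$major_radius)
  out <- vector("list", design$participants)
  for (p in seq_len(design$participants)) {
    obs <- observers[[p]]
    k <- obs$kernel
    bias <- as.numeric(bias_cells(cells$orientation_deg, cells$major_radius,
                                  cells$aspect_ratio, k$a_h^2, k$a_v^2, k$r))
    rho <- smoothed_eigen_ratio(cells$orientation_deg, cells$major_radius,
                                cells$aspect_ratio, k$a_h^2, k$a_v^2, k$r)
    sds <- dispersion_law(rho, obs$sigma_base, obs$kappa, obs$sd_cap)
    rows <- stubs[stubs$participant == p, , drop = FALSE]
    idx <- match(paste(rows$orientation_deg, rows$aspect_ratio),
                 paste(cells$orientation_deg, cells$aspect_ratio))
    n <- nrow(rows)
    draws <- with_seed(obs$seed, {
      list(eps = stats::rnorm(n),
           u_lapse = stats::runif(n),
           u_resp = stats::runif(n))
    })
    resp <- rows$orientation_deg + bias[idx] + draws$eps * sds[idx]
    lapse <- draws$u_lapse < obs$lapse_rate
    resp[lapse] <- draws$u_resp[lapse] * 180
    resp <- if (quantize) round(resp) %% 180 else wrap_180(resp)
    rows$response_deg <- resp
    rows$bias_deg <- wrap_pm90(resp - rows$orientation_deg)
    out[[p]] <- rows
  }
  tbl <- do.call(rbind, out)
  rownames(tbl) <- NULL
  attr(tbl, "major_radius") <- design$major_radius
  tbl
}

#' Read and write trial tables as CSV
#'
#' The CSV has the header
#' `participant,frame,block,trial,orientation_deg,aspect_ratio,response_deg,bias_deg`.
#'
#' @param table A trial table from [simulate_experiment()].
#' @param path File path.
#' @return `write_trials` returns `path` invisibly; `read_trials` returns the
#'   trial table.
#' @export
write_trials <- function(table, path) {
  cols <- c("participant", "frame", "block", "trial", "orientation_deg",
            "aspect_ratio", "response_deg", "bias_deg")
  stopifnot(all(cols %in% names(table)))
  utils::write.csv(table[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @param major_radius Major radius (degrees) to attach to the table read
#'   back (the CSV stores only the factorial condition labels).
#' @export
read_trials <- function(path, major_radius = 1.9) {
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  attr(tbl, "major_radius") <- major_radius
  tbl
}
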