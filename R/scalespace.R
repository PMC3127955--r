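# Scale space: elliptical Gaussian smoothing kernels, the covariance-addition
# smoothing rule, principal-axis orientation extraction, and an independent
# numeric convolution path used as an oracle for the analytic predictions.

#' Elliptical Gaussian smoothing kernel
#'
#' The smoothing aperture of the visual-resolution model. `a_h` and `a_v` are
#' the horizontal and vertical radii (standard deviations, degrees of visual
#' angle) of the Gaussian kernel; vertical smoothing in excess of horizontal
#' (`a_v > a_h`) is what draws perceived orientations toward the vertical.
#' The optional covariance term `r` (degrees squared) lets the kernel take an
#' oblique orientation; the kernel covariance is `[[a_h^2, r], [r, a_v^2]]`,
#' so positive-definiteness requires `|r| < a_h * a_v`.
#'
#' @param a_h Horizontal radius, degrees (> 0).
#' @param a_v Vertical radius, degrees (> 0).
#' @param r Covariance term, degrees squared (default 0: axis-aligned).
#' @return An object of class `"kernel_spec"`.
#' @examples
#' k <- kernel_spec(0.84, 2.08)
#' kernel_covariance(k)
#' @export
kernel_spec <- function(a_h, a_v, r = 0) {
  stopifnot(is.numeric(a_h), is.numeric(a_v), is.numeric(r),
            length(a_h) == 1L, length(a_v) == 1L, length(r) == 1L,
            is.finite(a_h), is.finite(a_v), is.finite(r))
  if (a_h <= 0 || a_v <= 0) {
    stop("kernel radii must be positive", call. = FALSE)
  }
  if (abs(r) >= a_h * a_v) {
    stop("kernel covariance term violates positive-definiteness: |r| < a_h * a_v",
         call. = FALSE)
  }
  structure(list(a_h = a_h, a_v = a_v, r = r), class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat(sprintf("Gaussian kernel: a_h = %.4g deg, a_v = %.4g deg, r = %.4g deg^2\n",
              x$a_h, x$a_v, x$r))
  invisible(x)
}

#' Covariance matrix of a smoothing kernel
#'
#' @param kernel A [kernel_spec()].
#' @return The 2x2 matrix `[[a_h^2, r], [r, a_v^2]]` (degrees squared).
#' @export
kernel_covariance <- function(kernel) {
  stopifnot(inherits(kernel, "kernel_spec"))
  matrix(c(kernel$a_h^2, kernel$r, kernel$r, kernel$a_v^2), 2L, 2L)
}

#' Principal-axis representation of a kernel
#'
#' Converts between the `(a_h, a_v, r)` covariance parameterization and the
#' equivalent `(radius_major, radius_minor, orientation)` triple (the
#' principal radii and the major-axis direction of the kernel ellipse).
#'
#' @param kernel A [kernel_spec()].
#' @return For `kernel_axes`: list with `radius_major`, `radius_minor`
#'   (degrees) and `orientation` (degrees in `[0, 180)`, `NA` if isotropic).
#' @export
kernel_axes <- function(kernel) {
  C <- kernel_covariance(kernel)
  e <- eigen(C, symmetric = TRUE)
  list(radius_major = sqrt(e$values[1L]),
       radius_minor = sqrt(e$values[2L]),
       orientation = orientation_of(C))
}

#' @rdname kernel_axes
#' @param radius_major,radius_minor Principal radii, degrees.
#' @param orientation Major-axis orientation, degrees.
#' @export
kernel_from_axes <- function(radius_major, radius_minor, orientation) {
  stopifnot(radius_major > 0, radius_minor > 0,
            radius_minor <= radius_major)
  R <- rotation_matrix(orientation)
  C <- R %*% diag(c(radius_major^2, radius_minor^2)) %*% t(R)
  kernel_spec(a_h = sqrt(C[1L, 1L]), a_v = sqrt(C[2L, 2L]), r = C[1L, 2L])
}

#' Smooth a covariance matrix with an elliptical Gaussian kernel
#'
#' The convolution of two Gaussians is Gaussian with summed covariances, so
#' the perceived (smoothed) stimulus covariance is simply the elementwise sum
#' of the stimulus covariance and the kernel covariance.
#'
#' @param glp_cov Symmetric positive-definite 2x2 stimulus covariance,
#'   degrees squared (see [glp_covariance()]).
#' @param kernel A [kernel_spec()].
#' @return The summed 2x2 covariance of the perceived Gaussian.
#' @examples
#' smooth_covariance(diag(c(3.61, 0.9025)), kernel_spec(0.84, 2.08))
#' @export
smooth_covariance <- function(glp_cov, kernel) {
  stopifnot_spd(glp_cov, "covariance")
  glp_cov + kernel_covariance(kernel)
}

#' Orientation of the major principal axis of a covariance matrix
#'
#' Returns `atan2(2 s_xy, s_xx - s_yy) / 2` mapped to `[0, 180)`, i.e. the
#' direction of the dominant eigenvector in degrees counterclockwise from
#' horizontal. For an isotropic covariance the orientation is undefined: the
#' function returns `NA` carrying attribute `degenerate = TRUE` rather than
#' an arbitrary angle, so downstream code can handle the case explicitly.
#'
#' @param cov Symmetric positive-semidefinite 2x2 matrix.
#' @param tol Relative tolerance (against the trace) below which the
#'   anisotropy is treated as zero.
#' @return Angle in degrees in `[0, 180)`, or degenerate `NA`.
#' @examples
#' orientation_of(diag(c(4, 1)))        # 0
#' orientation_of(diag(c(1, 4)))        # 90
#' orientation_of(matrix(c(2, 1, 1, 2), 2))  # 45
#' @export
orientation_of <- function(cov, tol = 1e-9) {
  if (!is_symmetric_2x2(cov)) {
    stop("invalid covariance: must be a finite symmetric 2x2 matrix",
         call. = FALSE)
  }
  num <- 2 * cov[1L, 2L]
  den <- cov[1L, 1L] - cov[2L, 2L]
  scale <- max(cov[1L, 1L] + cov[2L, 2L], .Machine$double.xmin)
  if (abs(num) <= tol * scale && abs(den) <= tol * scale) {
    return(structure(NA_real_, degenerate = TRUE))
  }
  wrap_180(rad2deg(atan2(num, den)) / 2)
}

#' Numerically convolve an image with an elliptical Gaussian kernel
#'
#' Discrete linear convolution with a sampled, unit-mass elliptical Gaussian,
#' evaluated by zero-padded FFT on the background-subtracted image. The
#' kernel is truncated at 4 standard deviations (along its widest axis) and
#' renormalized, which conserves total image mass to well within 0.1
#' percent. This path makes no use of the covariance-addition rule and is the
#' package's independent check on the analytic predictions.
#'
#' @param img Image matrix from [render_glp()] (attributes `x`, `y`,
#'   `resolution`, `background`).
#' @param kernel A [kernel_spec()].
#' @param resolution Pixels per degree; defaults to the image's resolution.
#' @return The smoothed image with the same dimensions and attributes.
#' @seealso [image_moments()], [oracle_check()]
#' @export
numeric_convolve <- function(img, kernel, resolution = NULL) {
  stopifnot(is.matrix(img), inherits(kernel, "kernel_spec"))
  resolution <- resolution %||% attr(img, "resolution")
  if (is.null(resolution)) stop("resolution is required", call. = FALSE)
  C <- kernel_covariance(kernel)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  sd_max <- sqrt(ev[1L]); sd_min <- sqrt(ev[2L])
  if (sd_min * resolution < 1) {
    stop("undersampled kernel: smallest kernel SD is below one pixel at this resolution",
         call. = FALSE)
  }
  hw <- as.integer(ceiling(4 * sd_max * resolution))
  u <- (-hw):hw / resolution
  P <- solve(C)
  q <- outer(P[1, 1] * u^2, P[2, 2] * u^2, "+") + 2 * P[1, 2] * outer(u, u)
  ker <- exp(-q / 2)
  ker <- ker / sum(ker)

  bg <- attr(img, "background") %||% 0
  w <- img - bg
  n1 <- nrow(w); n2 <- ncol(w); m <- 2L * hw + 1L
  p1 <- stats::nextn(n1 + m - 1L, c(2, 3))
  p2 <- stats::nextn(n2 + m - 1L, c(2, 3))
  pad <- function(a, d1, d2) {
    out <- matrix(0, d1, d2)
    out[seq_len(nrow(a)), seq_len(ncol(a))] <- a
    out
  }
  conv <- Re(stats::fft(stats::fft(pad(w, p1, p2)) * stats::fft(pad(ker, p1, p2)),
                        inverse = TRUE)) / (p1 * p2)
  # 'same' crop: the kernel center sits at offset hw in each dimension
  out <- conv[hw + seq_len(n1), hw + seq_len(n2)] + bg
  attributes(out) <- attributes(img)
  out
}
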