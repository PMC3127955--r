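# Stimuli: elongated Gaussian luminance profiles (GLPs), the factorial design
# of the adjustment experiment, and rasterization for the numeric oracle.

#' Gaussian luminance profile (GLP) stimulus
#'
#' A GLP is an elliptical two-dimensional Gaussian luminance blob. The radii
#' are the standard deviations of the Gaussian density along its principal
#' axes, in degrees of visual angle; the orientation is the direction of the
#' major axis, measured counterclockwise from the horizontal (+x) axis with
#' the y axis pointing up, and reduced modulo 180 degrees (a GLP rotated by
#' 180 degrees is identical).
#'
#' @param major_radius Major-axis standard deviation, degrees visual angle.
#' @param minor_radius Minor-axis standard deviation, degrees; must satisfy
#'   `0 < minor_radius <= major_radius`.
#' @param orientation Major-axis orientation, degrees counterclockwise from
#'   horizontal; reduced to `[0, 180)`.
#' @param amplitude Peak luminance above background (arbitrary units).
#' @param background Background luminance (arbitrary units).
#' @param center Center position `c(x, y)` in degrees.
#' @return An object of class `"glp"`.
#' @examples
#' g <- glp(1.9, 0.95, orientation = 22.5)
#' aspect_ratio(g)
#' glp_covariance(g)
#' @seealso [glp_covariance()], [render_glp()]
#' @export
glp <- function(major_radius, minor_radius, orientation = 0,
                amplitude = 1, background = 0, center = c(0, 0)) {
  if (!is.numeric(major_radius) || !is.numeric(minor_radius) ||
      length(major_radius) != 1L || length(minor_radius) != 1L ||
      !is.finite(major_radius) || !is.finite(minor_radius) ||
      major_radius <= 0 || minor_radius <= 0) {
    stop("invalid stimulus: radii must be positive finite scalars",
         call. = FALSE)
  }
  if (minor_radius > major_radius) {
    stop("invalid stimulus: minor_radius must not exceed major_radius",
         call. = FALSE)
  }
  stopifnot(is.numeric(orientation), length(orientation) == 1L,
            is.finite(orientation), length(center) == 2L)
  structure(
    list(major_radius = major_radius,
         minor_radius = minor_radius,
         orientation = wrap_180(orientation),
         amplitude = amplitude,
         background = background,
         center = as.numeric(center)),
    class = "glp"
  )
}

#' @export
print.glp <- function(x, ...) {
  cat(sprintf(
    "GLP: major %.3g deg, minor %.3g deg (aspect %.3g), orientation %.4g deg\n",
    x$major_radius, x$minor_radius, aspect_ratio(x), x$orientation))
  invisible(x)
}

#' Aspect ratio of a GLP
#'
#' @param x A [glp()] object.
#' @return `minor_radius / major_radius`, in `(0, 1]`.
#' @export
aspect_ratio <- function(x) {
  stopifnot(inherits(x, "glp"))
  x$minor_radius / x$major_radius
}

#' Covariance matrix of a GLP
#'
#' The density-related covariance of the stimulus:
#' `R(theta) diag(major^2, minor^2) R(theta)^T`, in squared degrees. This is
#' the left-hand summand of the covariance-addition smoothing rule.
#'
#' @param glp A [glp()] object.
#' @return Symmetric positive-definite 2x2 matrix (degrees squared).
#' @export
glp_covariance <- function(glp) {
  stopifnot(inherits(glp, "glp"))
  R <- rotation_matrix(glp$orientation)
  R %*% diag(c(glp$major_radius^2, glp$minor_radius^2)) %*% t(R)
}

#' Experimental design of the adjustment task
#'
#' Describes the factorial design: reference orientations (by default twelve
#' 15-degree steps starting at 7.5 degrees, excluding the cardinals), aspect
#' ratios (0.5, 0.65, 0.8 with the major radius fixed at 1.9 degrees), two
#' frame conditions (one session each), blocks per session, and repetitions of
#' each condition per block.
#'
#' @param orientations Reference orientations in degrees.
#' @param aspect_ratios Minor/major radius ratios.
#' @param major_radius Major radius in degrees (constant across conditions).
#' @param frames Frame-condition labels (one session per frame).
#' @param blocks_per_session Number of blocks in a session.
#' @param reps_per_block Repetitions of every condition within a block.
#' @param participants Number of participants.
#' @return An object of class `"design_schedule"`.
#' @examples
#' d <- design_schedule()
#' trials_per_participant(d)  # 1080
#' @export
design_schedule <- function(orientations = seq(7.5, 172.5, by = 15),
                            aspect_ratios = c(0.5, 0.65, 0.8),
                            major_radius = 1.9,
                            frames = c("circular", "square"),
                            blocks_per_session = 3L,
                            reps_per_block = 5L,
                            participants = 6L) {
  stopifnot(length(orientations) >= 1L, length(aspect_ratios) >= 1L,
            major_radius > 0, all(aspect_ratios > 0), all(aspect_ratios <= 1),
            length(frames) >= 1L, blocks_per_session >= 1L,
            reps_per_block >= 1L, participants >= 1L)
  structure(
    list(orientations = wrap_180(as.numeric(orientations)),
         aspect_ratios = as.numeric(aspect_ratios),
         major_radius = major_radius,
         frames = as.character(frames),
         blocks_per_session = as.integer(blocks_per_session),
         reps_per_block = as.integer(reps_per_block),
         participants = as.integer(participants)),
    class = "design_schedule"
  )
}

#' @export
print.design_schedule <- function(x, ...) {
  cat(sprintf(
    "Adjustment-task design: %d orientations x %d ratios x %d frames x %d blocks x %d reps\n",
    length(x$orientations), length(x$aspect_ratios), length(x$frames),
    x$blocks_per_session, x$reps_per_block))
  cat(sprintf("  %d trials per participant, %d participants\n",
              trials_per_participant(x), x$participants))
  invisible(x)
}

#' Trials per participant implied by a design
#'
#' @param design A [design_schedule()].
#' @return Integer trial count
#'   (frames x blocks x orientations x ratios x reps).
#' @export
trials_per_participant <- function(design) {
  stopifnot(inherits(design, "design_schedule"))
  length(design$frames) * design$blocks_per_session *
    length(design$orientations) * length(design$aspect_ratios) *
    design$reps_per_block
}

#' Build the randomized trial schedule
#'
#' Expands the factorial design into one stub per trial and shuffles the trial
#' order independently within each block, reproducibly under `seed`. Blocks
#' are visited in participant, frame (session), block order.
#'
#' @param design A [design_schedule()].
#' @param seed Integer seed controlling the within-block shuffles.
#' @return A data frame with columns `participant`, `frame`, `block`, `trial`,
#'   `orientation_deg`, `aspect_ratio`; one row per trial.
#' @export
build_schedule <- function(design, seed = 1L) {
  stopifnot(inherits(design, "design_schedule"))
  block_cells <- expand.grid(
    orientation_deg = design$orientations,
    aspect_ratio = design$aspect_ratios,
    rep = seq_len(design$reps_per_block),
    KEEP.OUT.ATTRS = FALSE
  )
  nb <- nrow(block_cells)
  out <- with_seed(seed, {
    pieces <- list()
    i <- 1L
    for (p in seq_len(design$participants)) {
      for (f in design$frames) {
        for (b in seq_len(design$blocks_per_session)) {
          ord <- sample.int(nb)
          pieces[[i]] <- data.frame(
            participant = p,
            frame = f,
            block = b,
            trial = seq_len(nb),
            orientation_deg = block_cells$orientation_deg[ord],
            aspect_ratio = block_cells$aspect_ratio[ord],
            stringsAsFactors = FALSE
          )
          i <- i + 1L
        }
      }
    }
    do.call(rbind, pieces)
  })
  rownames(out) <- NULL
  attr(out, "major_radius") <- design$major_radius
  out
}

#' Render a GLP to a luminance image
#'
#' Evaluates `background + amplitude * exp(-d' Sigma^-1 d / 2)` on a square
#' pixel grid, optionally adding seeded uniform pixel noise whose total range
#' is `noise_fraction` of the GLP amplitude (the default 2 percent emulates
#' the faint white noise used to mask luminance quantization on the display).
#'
#' @param glp A [glp()] object.
#' @param resolution Pixels per degree of visual angle.
#' @param extent Half-width of the rendered square, degrees; defaults to four
#'   major radii. A smaller extent truncates the 4-sigma support and triggers
#'   a warning.
#' @param noise_fraction Pixel-noise range as a fraction of the amplitude;
#'   0 disables noise.
#' @param seed Seed for the pixel noise (required when `noise_fraction > 0`).
#' @return A numeric matrix `img[ix, iy]` with attributes `x`, `y` (pixel
#'   center coordinates in degrees), `resolution`, and `background`.
#' @examples
#' img <- render_glp(glp(1.9, 0.95, 22.5), resolution = 8)
#' m <- image_moments(img)
#' m$cov
#' @export
render_glp <- function(glp, resolution = 32, extent = NULL,
                       noise_fraction = 0, seed = NULL) {
  stopifnot(inherits(glp, "glp"), resolution > 0,
            noise_fraction >= 0, noise_fraction < 1)
  if (is.null(extent)) extent <- 4 * glp$major_radius
  if (extent < 4 * glp$major_radius) {
    warning("extent truncates the 4-sigma support of the GLP", call. = FALSE)
  }
  n <- 2L * as.integer(ceiling(extent * resolution)) + 1L  # odd: center pixel
  x <- (seq_len(n) - (n + 1) / 2) / resolution + glp$center[1L]
  y <- (seq_len(n) - (n + 1) / 2) / resolution + glp$center[2L]
  P <- solve(glp_covariance(glp))  # precision matrix
  dx <- x - glp$center[1L]
  dy <- y - glp$center[2L]
  # quadratic form split over the separable grid
  q <- outer(P[1, 1] * dx^2, P[2, 2] * dy^2, "+") +
    2 * P[1, 2] * outer(dx, dy)
  img <- glp$background + glp$amplitude * exp(-q / 2)
  if (noise_fraction > 0) {
    if (is.null(seed)) stop("pixel noise requires a seed", call. = FALSE)
    half <- noise_fraction * glp$amplitude / 2
    img <- img + with_seed(seed, matrix(stats::runif(n * n, -half, half), n, n))
  }
  structure(img, x = x, y = y, resolution = resolution,
            background = glp$background)
}

#' Center and second central moments of a luminance image
#'
#' Treats the background-subtracted image as an unnormalized density on the
#' pixel grid and returns its mean and covariance; the moment covariance of a
#' rendered GLP converges to [glp_covariance()] as resolution increases.
#'
#' @param img An image from [render_glp()] or [numeric_convolve()], or any
#'   matrix with `x`/`y` coordinate attributes.
#' @param background Value to subtract before weighting; defaults to the
#'   image's `background` attribute (0 if absent).
#' @return List with `mass` (sum of weights), `center` (length-2), and `cov`
#'   (2x2 moment matrix, degrees squared).
#' @export
image_moments <- function(img, background = NULL) {
  x <- attr(img, "x"); y <- attr(img, "y")
  stopifnot(is.matrix(img), !is.null(x), !is.null(y))
  background <- background %||% (attr(img, "background") %||% 0)
  w <- img - background
  m0 <- sum(w)
  if (m0 <= 0) stop("image has no mass above background", call. = FALSE)
  wx <- rowSums(w); wy <- colSums(w)
  cx <- sum(wx * x) / m0
  cy <- sum(wy * y) / m0
  dx <- x - cx; dy <- y - cy
  sxx <- sum(wx * dx^2) / m0
  syy <- sum(wy * dy^2) / m0
  sxy <- sum((w * outer(dx, rep(1, length(dy)))) *
               outer(rep(1, length(dx)), dy)) / m0
  list(mass = m0, center = c(cx, cy),
       cov = matrix(c(sxx, sxy, sxy, syy), 2L, 2L))
}

#' Write an image as a plain-text PGM (P2) file
#'
#' Luminances are linearly rescaled to `[0, maxval]`. The header comment
#' records the sampling resolution and extent so renders are self-describing.
#'
#' @param img Image matrix from [render_glp()] or [numeric_convolve()].
#' @param path Output file path.
#' @param maxval Maximum gray value (default 255).
#' @return `path`, invisibly.
#' @export
write_pgm <- function(img, path, maxval = 255L) {
  stopifnot(is.matrix(img), maxval >= 1)
  rng <- range(img)
  scale <- if (diff(rng) > 0) maxval / diff(rng) else 0
  g <- round((img - rng[1L]) * scale)
  storage.mode(g) <- "integer"
  res <- attr(img, "resolution") %||% NA
  x <- attr(img, "x")
  ext <- if (!is.null(x)) diff(range(x)) / 2 else NA
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2",
               sprintf("# px_per_deg=%s half_extent_deg=%s",
                       format(res), format(ext)),
               sprintf("%d %d", nrow(g), ncol(g)),
               sprintf("%d", as.integer(maxval))), con)
  # raster rows top-to-bottom = decreasing y; matrix is img[ix, iy]
  for (iy in rev(seq_len(ncol(g)))) {
    writeLines(paste(g[, iy], collapse = " "), con)
  }
  invisible(path)
}
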