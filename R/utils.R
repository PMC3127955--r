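# Internal helpers shared across modules. Orientation space is periodic with
# period 180 deg (a GLP rotated by 180 deg is the same GLP), so all angular
# arithmetic lives on that circle.

#' Wrap an angle difference to (-90, 90]
#'
#' Signed orientation differences live on the 180-degree circle; this maps any
#' angle (in degrees) to the half-open interval (-90, 90], with exact ties at
#' +/-90 mapped to +90.
#'
#' @param x Numeric vector of angles in degrees.
#' @return Numeric vector in (-90, 90].
#' @examples
#' wrap_pm90(c(0, 91, -91, 90, -90, 179))
#' @export
wrap_pm90 <- function(x) {
  y <- ((x + 90) %% 180) - 90
  y[y == -90] <- 90
  y
}

# reduce an orientation to [0, 180)
wrap_180 <- function(x) x %% 180

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# 2x2 counterclockwise rotation matrix, angle in degrees
rotation_matrix <- function(theta_deg) {
  t <- deg2rad(theta_deg)
  matrix(c(cos(t), sin(t), -sin(t), cos(t)), 2L, 2L)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_symmetric_2x2 <- function(m, tol = 1e-8) {
  is.matrix(m) && all(dim(m) == c(2L, 2L)) && is.numeric(m) &&
    all(is.finite(m)) &&
    abs(m[1L, 2L] - m[2L, 1L]) <= tol * max(1, max(abs(m)))
}

stopifnot_spd <- function(m, what = "covariance") {
  if (!is_symmetric_2x2(m)) {
    stop("invalid ", what, ": must be a finite symmetric 2x2 matrix",
         call. = FALSE)
  }
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) {
    stop("invalid ", what, ": must be positive-definite", call. = FALSE)
  }
  invisible(m)
}
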