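# Bias model: predicted illusory orientation biases under the four nested
# smoothing models (isotropic, homogeneous, homogeneous with an oriented
# kernel, radial-heterogeneous, angular-heterogeneous).

# Vectorized closed form over condition cells. For a GLP with major radius M,
# aspect ratio q and orientation theta, the stimulus covariance terms are
#   s_xx - s_yy = M^2 (1 - q^2) cos 2theta,   2 s_xy = M^2 (1 - q^2) sin 2theta,
# and adding the kernel covariance shifts them by (a_h^2 - a_v^2) and 2r.
# The smoothed major-axis direction is atan2(num, den)/2.
bias_cells <- function(theta, major, ratio, ah2, av2, r) {
  A <- major^2 * (1 - ratio^2)
  t2 <- deg2rad(2 * theta)
  num <- A * sin(t2) + 2 * r
  den <- A * cos(t2) + ah2 - av2
  scale <- pmax(major^2 * (1 + ratio^2) + ah2 + av2, .Machine$double.xmin)
  degen <- abs(num) <= 1e-9 * scale & abs(den) <= 1e-9 * scale
  bias <- wrap_pm90(rad2deg(atan2(num, den)) / 2 - theta)
  bias[degen] <- 0
  attr(bias, "degenerate") <- degen
  bias
}

#' Predicted orientation bias of a smoothed GLP
#'
#' The perceived orientation is the major-axis direction of the smoothed
#' covariance ([smooth_covariance()] followed by [orientation_of()]); the
#' bias is its signed difference from the stimulus orientation, wrapped to
#' `(-90, 90]` with counterclockwise positive. An isotropic smoothed
#' covariance has no defined orientation; the bias is then reported as 0 with
#' attribute `degenerate = TRUE` and a warning.
#'
#' @param glp A [glp()] stimulus.
#' @param kernel A [kernel_spec()].
#' @return Signed bias in degrees in `(-90, 90]`.
#' @examples
#' predict_bias(glp(1.9, 0.95, 22.5), kernel_spec(0.84, 2.08))  # ~ +43.4
#' @export
predict_bias <- function(glp, kernel) {
  stopifnot(inherits(glp, "glp"))
  sc <- smooth_covariance(glp_covariance(glp), kernel)
  o <- orientation_of(sc)
  if (is.na(o)) {
    warning("smoothed covariance is isotropic; orientation bias undefined, returning 0",
            call. = FALSE)
    return(structure(0, degenerate = TRUE))
  }
  wrap_pm90(as.numeric(o) - glp$orientation)
}

#' Map an orientation to its mirror-pair canonical member
#'
#' Orientations reflected across the vertical axis (`theta` and
#' `180 - theta`) form a mirror pair; the canonical member is the one in
#' `(0, 90)`. Cardinal orientations map to themselves.
#'
#' @param theta Orientations in degrees.
#' @return Canonical orientations in `[0, 90]`.
#' @export
canonical_orientation <- function(theta) {
  th <- wrap_180(theta)
  ifelse(th > 90, 180 - th, th)
}

#' Grid of stimulus conditions
#'
#' The factorial crossing of reference orientations and aspect ratios at a
#' fixed major radius; the unit at which models predict biases. With
#' `aggregated = TRUE` the grid uses the canonical member of each mirror pair
#' (six orientations for the default twelve).
#'
#' @param orientations Orientations in degrees (default: the twelve
#'   15-degree steps from 7.5).
#' @param aspect_ratios Aspect ratios (default 0.5, 0.65, 0.8).
#' @param major_radius Major radius, degrees.
#' @param aggregated Collapse mirror pairs onto canonical members?
#' @return Data frame with columns `orientation_deg`, `aspect_ratio`,
#'   `major_radius` and attribute `aggregated`.
#' @export
condition_grid <- function(orientations = seq(7.5, 172.5, by = 15),
                           aspect_ratios = c(0.5, 0.65, 0.8),
                           major_radius = 1.9,
                           aggregated = FALSE) {
  ori <- wrap_180(as.numeric(orientations))
  if (aggregated) ori <- sort(unique(canonical_orientation(ori)))
  cells <- expand.grid(orientation_deg = ori,
                       aspect_ratio = as.numeric(aspect_ratios),
                       KEEP.OUT.ATTRS = FALSE)
  if (anyDuplicated(cells)) stop("condition cells must be unique", call. = FALSE)
  cells$major_radius <- major_radius
  attr(cells, "aggregated") <- aggregated
  cells
}

model_kinds <- c("isotropic", "homogeneous", "homogeneous_oriented",
                 "radial_heterogeneous", "angular_heterogeneous")

# condition subsets sharing one kernel, keyed by a label per cell
group_labels <- function(kind, grid) {
  switch(kind,
    isotropic = ,
    homogeneous = ,
    homogeneous_oriented = rep("all", nrow(grid)),
    radial_heterogeneous = format(grid$aspect_ratio),
    angular_heterogeneous = format(grid$orientation_deg)
  )
}

#' Specify a smoothing model
#'
#' The nested model hierarchy: `isotropic` (reference; predicts zero bias
#' everywhere, no free parameters), `homogeneous` (one axis-aligned kernel,
#' parameters `a_h`, `a_v`), `homogeneous_oriented` (adds the covariance term
#' `r`), `radial_heterogeneous` (one `(a_h, a_v)` pair per aspect-ratio
#' subset), and `angular_heterogeneous` (one `(a_h, a_v, r)` triple per
#' orientation subset; subsets are assigned by the nominal stimulus
#' orientation). The free-parameter count follows the kernel parameter
#' layout: 0, 2, 3, 2 per thickness, and 3 per orientation subset (36 for
#' twelve raw orientations, 18 for six aggregated pairs).
#'
#' @param kind One of `"isotropic"`, `"homogeneous"`,
#'   `"homogeneous_oriented"`, `"radial_heterogeneous"`,
#'   `"angular_heterogeneous"`.
#' @param grid A [condition_grid()] the model predicts on.
#' @param params Optional parameter table (data frame with columns `group`,
#'   `a_h`, `a_v`, `r`), e.g. from [fit_model()].
#' @return An object of class `"model_spec"` with elements `kind`, `grid`,
#'   `groups` (cell labels), `params`, `n_free`.
#' @examples
#' m <- model_spec("homogeneous", condition_grid(aggregated = TRUE))
#' n_free(m)
#' @export
model_spec <- function(kind = model_kinds, grid = condition_grid(),
                       params = NULL) {
  kind <- match.arg(kind)
  labels <- group_labels(kind, grid)
  groups <- unique(labels)
  per_group <- switch(kind, isotropic = 0L,
                      homogeneous = 2L, homogeneous_oriented = 3L,
                      radial_heterogeneous = 2L, angular_heterogeneous = 3L)
  m <- structure(
    list(kind = kind, grid = grid, labels = labels, groups = groups,
         params = NULL,
         n_free = if (kind == "isotropic") 0L else per_group * length(groups)),
    class = "model_spec"
  )
  if (!is.null(params)) m <- set_params(m, params)
  m
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("Smoothing model '%s': %d group(s), %d free parameter(s)%s\n",
              x$kind, length(x$groups), x$n_free,
              if (is.null(x$params)) " (unfitted)" else ""))
  if (!is.null(x$params)) print(x$params)
  invisible(x)
}

#' Number of free parameters of a model
#'
#' @param model A [model_spec()].
#' @return Integer count (0 / 2 / 3 / 2 per thickness / 3 per orientation
#'   subset).
#' @export
n_free <- function(model) {
  stopifnot(inherits(model, "model_spec"))
  model$n_free
}

# attach a validated parameter table (one row per group)
set_params <- function(model, params) {
  stopifnot(inherits(model, "model_spec"))
  if (model$kind == "isotropic") {
    model$params <- data.frame(group = character(), a_h = numeric(),
                               a_v = numeric(), r = numeric())
    return(model)
  }
  params <- as.data.frame(params)
  if (is.null(params$r)) params$r <- 0
  needed <- c("group", "a_h", "a_v", "r")
  if (!all(needed %in% names(params))) {
    stop("params must have columns group, a_h, a_v (and optionally r)",
         call. = FALSE)
  }
  params$group <- as.character(params$group)
  if (!setequal(params$group, model$groups) ||
      anyDuplicated(params$group)) {
    stop("model-specification error: params groups must match the model's condition subsets",
         call. = FALSE)
  }
  if (model$kind %in% c("homogeneous", "radial_heterogeneous") &&
      any(params$r != 0)) {
    stop("axis-aligned model: r must be 0", call. = FALSE)
  }
  for (i in seq_len(nrow(params))) {  # validates positivity / PSD
    kernel_spec(params$a_h[i], params$a_v[i], params$r[i])
  }
  model$params <- params[match(model$groups, params$group), needed]
  rownames(model$params) <- NULL
  model
}

# per-cell kernel parameter columns for a set of labels
params_for_labels <- function(model, labels) {
  if (model$kind == "isotropic") {
    return(data.frame(a_h = rep(1, length(labels)), a_v = 1, r = 0))
  }
  if (is.null(model$params)) {
    stop("model has no parameters; fit it or supply params", call. = FALSE)
  }
  idx <- match(labels, model$params$group)
  if (anyNA(idx)) {
    stop("model-specification error: condition cell not covered by any group",
         call. = FALSE)
  }
  model$params[idx, c("a_h", "a_v", "r")]
}

#' Predict biases for every cell of a condition grid
#'
#' Each cell's bias is computed with its group's kernel. The isotropic model
#' predicts zero bias for every condition irrespective of scale.
#'
#' @param model A [model_spec()] carrying parameters (except `isotropic`).
#' @param grid A [condition_grid()]; defaults to the model's own grid.
#' @return Numeric vector of predicted biases (degrees), one per cell.
#' @export
predict_grid <- function(model, grid = NULL) {
  stopifnot(inherits(model, "model_spec"))
  grid <- grid %||% model$grid
  if (model$kind == "isotropic") return(rep(0, nrow(grid)))
  labels <- group_labels(model$kind, grid)
  p <- params_for_labels(model, labels)
  as.numeric(bias_cells(grid$orientation_deg, grid$major_radius,
                        grid$aspect_ratio, p$a_h^2, p$a_v^2, p$r))
}

#' Serialize a model (with parameters) to JSON
#'
#' The JSON records the kind, the explicit group labels and the parameter
#' layout, so fitted kernels can be exchanged between runs.
#'
#' @param model A [model_spec()].
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return `path` (invisibly) or a JSON string.
#' @export
model_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "model_spec"))
  obj <- list(
    kind = model$kind,
    parameter_order = c("a_h", "a_v", "r"),
    groups = model$groups,
    grid = model$grid[, c("orientation_deg", "aspect_ratio", "major_radius")],
    aggregated = isTRUE(attr(model$grid, "aggregated")),
    params = model$params
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' @rdname model_to_json
#' @param json A JSON string or file path produced by `model_to_json`.
#' @export
model_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  grid <- condition_grid(unique(obj$grid$orientation_deg),
                         unique(obj$grid$aspect_ratio),
                         major_radius = obj$grid$major_radius[1L],
                         aggregated = isTRUE(obj$aggregated))
  model_spec(obj$kind, grid,
             params = if (!is.null(obj$params) && length(obj$params)) obj$params)
}
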