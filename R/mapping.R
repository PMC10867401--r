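# Full-foot pressure mapping: a cubic B-spline surface is fitted over the
# unit square so that it (a) interpolates the 8 discrete sensor readings
# exactly and (b) is maximally smooth elsewhere. With only 8 scattered sites
# a tensor-product spline is underdetermined, so the control net is chosen by
# minimizing a second-difference (thin-plate-like) roughness penalty subject
# to the interpolation constraints, solved as a small KKT system.

# cubic B-spline basis with n_ctrl functions on [0, 1] (clamped knot vector)
bspline_basis <- function(x, n_ctrl) {
  inner <- seq(0, 1, length.out = n_ctrl - 2L)
  knots <- c(rep(0, 3), inner, rep(1, 3))
  splines::splineDesign(knots, x, ord = 4L, outer.ok = FALSE)
}

# Roughness penalty for a K x K control net: second differences (curvature)
# plus a weaker first-difference (gradient) term that keeps the surface from
# swinging between the sparse interpolation constraints.
roughness_penalty <- function(K, gradient_weight = 0.5) {
  D2 <- crossprod(diff(diag(K), differences = 2L))
  D1 <- crossprod(diff(diag(K)))
  I <- diag(K)
  kronecker(D2, I) + kronecker(I, D2) +
    gradient_weight * (kronecker(D1, I) + kronecker(I, D1))
}

# Control net minimizing roughness plus a weak pull toward the frame mean
# (which tames the penalty's null space far from the sensors), subject to
# exact interpolation at the sensor sites.
fit_bspline_surface <- function(frame, layout, n_ctrl = 16L, ridge = 2e-2) {
  Bx <- bspline_basis(layout$x, n_ctrl)
  By <- bspline_basis(layout$y, n_ctrl)
  # row i of the constraint matrix: kron(Bx[i, ], By[i, ]) -> coefficient
  # vector ordered with the y-basis index varying fastest
  A <- t(vapply(seq_len(nrow(layout)),
                function(i) kronecker(Bx[i, ], By[i, ]), numeric(n_ctrl^2)))
  P <- roughness_penalty(n_ctrl) + ridge * diag(n_ctrl^2)
  K2 <- n_ctrl^2
  m <- nrow(A)
  mu <- mean(frame)
  KKT <- rbind(cbind(2 * P, t(A)),
               cbind(A, matrix(0, m, m)))
  rhs <- c(2 * ridge * rep(mu, K2), frame)
  sol <- solve(KKT, rhs)
  matrix(sol[seq_len(K2)], n_ctrl, n_ctrl)  # rows: y basis, cols: x basis
}

eval_bspline_surface <- function(ctrl, x, y) {
  n_ctrl <- nrow(ctrl)
  Bx <- bspline_basis(x, n_ctrl)
  By <- bspline_basis(y, n_ctrl)
  By %*% ctrl %*% t(Bx)           # length(y) x length(x)
}

#' Interpolate a full-foot pressure map from one 8-sensor frame
#'
#' Fits a cubic B-spline surface that passes exactly through the 8 sensor
#' readings at their layout coordinates (smoothness-penalized control net
#' with interpolation constraints), evaluates it on a regular grid, clips it
#' at 0 kPa and masks it to the insole silhouette.
#'
#' @param frame numeric vector of 8 non-negative pressures (kPa), ordered
#'   S1..S8.
#' @param layout a [default_sensor_layout()]-style layout.
#' @param resolution grid cells per unit axis (the map is
#'   `resolution x resolution`); at least 8.
#' @param n_ctrl control points per axis of the spline surface.
#' @param mask polygon used to mask the surface, or `NULL` for no mask.
#' @return An object of class `pressure_map`: list with `grid`
#'   (`resolution x resolution`, rows indexed by y, `NA` outside the mask),
#'   `x`, `y` (cell-centre coordinates), `ctrl` (spline control net),
#'   `layout`, `resolution`.
#' @examples
#' m <- interpolate_map(rep(100, 8), default_sensor_layout(), resolution = 40)
#' range(m$grid, na.rm = TRUE)  # c(100, 100)
#' @export
interpolate_map <- function(frame, layout = default_sensor_layout(),
                            resolution = 60L, n_ctrl = 16L,
                            mask = insole_outline()) {
  layout <- validate_sensor_layout(layout)
  frame <- as.numeric(frame)
  if (length(frame) != 8L) stop("frame must contain 8 sensor pressures")
  if (anyNA(frame) || any(!is.finite(frame))) stop("frame pressures must be finite")
  if (any(frame < 0)) stop("frame pressures must be non-negative")
  resolution <- as.integer(resolution)
  if (resolution < 8L) stop("resolution must be at least 8")
  d <- as.matrix(stats::dist(layout[, c("x", "y")]))
  if (any(d[upper.tri(d)] < 1e-9)) stop("sensor coordinates must be distinct")

  ctrl <- fit_bspline_surface(frame, layout, n_ctrl = n_ctrl)
  gx <- seq(0, 1, length.out = resolution)
  gy <- seq(0, 1, length.out = resolution)
  grid <- eval_bspline_surface(ctrl, gx, gy)
  grid <- pmax(grid, 0)
  inside <- NULL
  if (!is.null(mask)) {
    pts <- expand.grid(y = gy, x = gx)  # column-major over grid
    inside <- matrix(points_in_polygon(pts$x, pts$y, mask), resolution, resolution)
    grid[!inside] <- NA_real_
  }
  structure(
    list(grid = grid, x = gx, y = gy, ctrl = ctrl, layout = layout,
         resolution = resolution, mask_polygon = mask, inside = inside),
    class = "pressure_map"
  )
}

#' @export
print.pressure_map <- function(x, ...) {
  cat(sprintf("<pressure_map> %d x %d grid, %.0f%% inside mask, range [%.1f, %.1f] kPa\n",
              x$resolution, x$resolution,
              100 * mean(!is.na(x$grid)),
              min(x$grid, na.rm = TRUE), max(x$grid, na.rm = TRUE)))
  invisible(x)
}

#' Evaluate a pressure map surface at arbitrary coordinates
#'
#' Evaluates the underlying spline surface (unmasked, clipped at 0), e.g. at
#' the sensor sites, where it reproduces the input readings.
#'
#' @param map a [interpolate_map()] result.
#' @param x,y coordinates in the normalized insole frame.
#' @return Numeric vector of surface values, recycled over `x` and `y` pairs.
#' @export
map_value_at <- function(map, x, y) {
  stopifnot(inherits(map, "pressure_map"))
  stopifnot(length(x) == length(y))
  vapply(seq_along(x),
         function(i) max(0, eval_bspline_surface(map$ctrl, x[i], y[i])[1, 1]),
         numeric(1))
}

#' Classify static standing pronation from one frame
#'
#' Compares loading of the two sensors left of the foot axis (S6, S7) with
#' the two right of it (S1, S8). The asymmetry index is
#' `(P_left - P_right) / (P_left + P_right)` with `P_left = mean(S6, S7)`,
#' `P_right = mean(S1, S8)`. Overpronation loads the left side, and
#' underpronation the right side, under the default convention; flip
#' `side_convention` for the contralateral foot.
#'
#' @param frame numeric vector of 8 pressures (kPa), ordered S1..S8.
#' @param layout a sensor layout (provides the left/right sensor sets).
#' @param threshold `|index|` at or below which the posture is NORMAL.
#' @param side_convention `"left_over"` (default: left-loaded means
#'   overpronation) or `"left_under"`.
#' @return List of class `pronation_result` with `label` (NORMAL /
#'   UNDERPRONATION / OVERPRONATION) and `asymmetry_index` in `[-1, 1]`.
#' @examples
#' classify_pronation(c(50, 20, 80, 30, 20, 200, 200, 50))
#' @export
classify_pronation <- function(frame, layout = default_sensor_layout(),
                               threshold = 0.15,
                               side_convention = c("left_over", "left_under")) {
  side_convention <- match.arg(side_convention)
  frame <- as.numeric(frame)
  if (length(frame) != 8L) stop("frame must contain 8 sensor pressures")
  names(frame) <- paste0("S", 1:8)
  sets <- axis_sensor_sets(layout)   # default layout: S6,S7 vs S1,S8
  left <- sets$left
  right <- sets$right
  p_left <- mean(frame[left])
  p_right <- mean(frame[right])
  if (p_left + p_right == 0) {
    idx <- 0
  } else {
    idx <- (p_left - p_right) / (p_left + p_right)
  }
  if (side_convention == "left_under") idx <- -idx
  label <- if (abs(idx) <= threshold) "NORMAL"
           else if (idx > 0) "OVERPRONATION" else "UNDERPRONATION"
  structure(list(label = label, asymmetry_index = idx,
                 left_sensors = left, right_sensors = right),
            class = "pronation_result")
}

#' @export
print.pronation_result <- function(x, ...) {
  cat(sprintf("<pronation_result> %s (asymmetry index %+.3f)\n",
              x$label, x$asymmetry_index))
  invisible(x)
}

#' Pressure maps for a sequence of frames
#'
#' @param series a [pressure_series()].
#' @param layout sensor layout.
#' @param resolution grid resolution per axis.
#' @param stride frame stride; one map is produced per `stride` frames
#'   starting at the first, `ceiling(n_samples / stride)` maps in total.
#' @param ... passed to [interpolate_map()].
#' @return List of `pressure_map` objects.
#' @export
map_sequence <- function(series, layout = default_sensor_layout(),
                         resolution = 60L, stride = 1L, ...) {
  stopifnot(inherits(series, "pressure_series"))
  stride <- as.integer(stride)
  if (stride < 1L) stop("stride must be at least 1")
  n <- n_samples(series)
  if (n < 1L) stop("series is empty")
  idx <- seq(1L, n, by = stride)
  lapply(idx, function(i)
    interpolate_map(series$values[i, ], layout, resolution, ...))
}
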