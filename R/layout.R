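#' Default 8-sensor insole layout
#'
#' Sensor identities, anatomical regions, 2-D coordinates in the normalized
#' insole frame (x in `[0, 1]` across the foot, y in `[0, 1]` heel to toe)
#' and the left/right-of-axis grouping used by the pronation classifier and
#' the asymmetry alert: S6 and S7 sit left of the foot axis, S1 and S8 right
#' of it. Coordinates approximate the physical sensor placement: heel
#' (S7, S8), mid-foot contour line (S4), metatarsal (S1, S3, S6) and toe
#' (S2, S5) regions. The side convention is configuration, not anatomy: flip
#' it for the contralateral foot.
#'
#' @return A data.frame of class `sensor_layout` with columns `sensor`,
#'   `region`, `x`, `y`, `side`.
#' @export
default_sensor_layout <- function() {
  layout <- data.frame(
    sensor = paste0("S", 1:8),
    region = c("metatarsal", "toe", "metatarsal", "midfoot",
               "toe", "metatarsal", "heel", "heel"),
    x = c(0.30, 0.36, 0.50, 0.56, 0.64, 0.70, 0.62, 0.40),
    y = c(0.66, 0.88, 0.69, 0.42, 0.85, 0.66, 0.15, 0.13),
    side = c("RIGHT_OF_AXIS", "RIGHT_OF_AXIS", "RIGHT_OF_AXIS", "LEFT_OF_AXIS",
             "LEFT_OF_AXIS", "LEFT_OF_AXIS", "LEFT_OF_AXIS", "RIGHT_OF_AXIS"),
    stringsAsFactors = FALSE
  )
  validate_sensor_layout(layout)
}

#' Validate a sensor layout
#'
#' @param layout data.frame with columns `sensor`, `region`, `x`, `y`, `side`.
#' @return The layout, classed `sensor_layout`, invisibly checked.
#' @export
validate_sensor_layout <- function(layout) {
  need <- c("sensor", "region", "x", "y", "side")
  if (!all(need %in% names(layout))) stop("layout must have columns ",
                                          paste(need, collapse = ", "))
  if (nrow(layout) != 8L || anyDuplicated(layout$sensor))
    stop("layout must describe 8 uniquely named sensors")
  if (!setequal(layout$sensor, paste0("S", 1:8)))
    stop("sensors must be named S1..S8")
  if (any(layout$x < 0 | layout$x > 1 | layout$y < 0 | layout$y > 1))
    stop("sensor coordinates must lie in the unit square")
  reg <- setNames(layout$region, layout$sensor)
  if (!all(reg[c("S1", "S3", "S6")] == "metatarsal") ||
      !all(reg[c("S7", "S8")] == "heel") || reg[["S4"]] != "midfoot" ||
      !all(reg[c("S2", "S5")] == "toe"))
    stop("regions must follow the insole design: S1/S3/S6 metatarsal, ",
         "S7/S8 heel, S4 midfoot, S2/S5 toe")
  if (!all(layout$side %in% c("LEFT_OF_AXIS", "RIGHT_OF_AXIS")))
    stop("side must be LEFT_OF_AXIS or RIGHT_OF_AXIS")
  class(layout) <- c("sensor_layout", "data.frame")
  layout
}

#' Insole silhouette polygon
#'
#' Closed polygon (first vertex not repeated) outlining the insole in the
#' normalized frame; used to mask pressure maps to the foot shape.
#'
#' @return A two-column matrix of `(x, y)` vertices.
#' @export
insole_outline <- function() {
  cbind(
    x = c(0.36, 0.24, 0.18, 0.17, 0.22, 0.30, 0.26, 0.28, 0.36, 0.50,
          0.66, 0.78, 0.84, 0.85, 0.80, 0.72, 0.64, 0.50),
    y = c(0.02, 0.06, 0.18, 0.34, 0.52, 0.68, 0.80, 0.92, 0.99, 1.00,
          0.97, 0.88, 0.72, 0.50, 0.30, 0.12, 0.03, 0.01)
  )
}

#' Left/right sensor sets for asymmetry comparisons
#'
#' The left/right loading comparison (pronation classification, uneven
#' pressure alert) uses the outermost metatarsal sensor and the heel sensor
#' on each side of the foot axis: with the default layout, S6 and S7 on the
#' left versus S1 and S8 on the right.
#'
#' @param layout a sensor layout.
#' @return List with character vectors `left` and `right` (two sensors each).
#' @export
axis_sensor_sets <- function(layout = default_sensor_layout()) {
  met <- layout[layout$region == "metatarsal", ]
  heel <- layout[layout$region == "heel", ]
  lmet <- met[met$side == "LEFT_OF_AXIS", ]
  rmet <- met[met$side == "RIGHT_OF_AXIS", ]
  lheel <- heel[heel$side == "LEFT_OF_AXIS", ]
  rheel <- heel[heel$side == "RIGHT_OF_AXIS", ]
  list(
    left = c(lmet$sensor[which.max(lmet$x)], lheel$sensor[which.max(lheel$x)]),
    right = c(rmet$sensor[which.min(rmet$x)], rheel$sensor[which.min(rheel$x)])
  )
}

# even-odd ray-crossing point-in-polygon test, vectorized over query points
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}
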