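#' Construct a three-arm Y-maze geometry
#'
#' Builds a parametric Y-maze in maze-local coordinates (cm): a central
#' equilateral junction triangle whose three edges are the mouths of three
#' rectangular arms radiating at bearings 120 degrees apart. The origin is
#' the junction centroid. Defaults match a standard adult-zebrafish aquatic
#' Y-maze with arms 25 cm long and 8 cm wide.
#'
#' @param arm_length arm length in cm (mouth to distal wall), > 0.
#' @param arm_width arm width in cm, > 0.
#' @param bearings_deg outward bearings of the three arm axes in degrees,
#'   measured counter-clockwise from the +x axis. Must be three distinct
#'   angles; the default places arms at 90, 210 and 330 degrees.
#' @param arm_labels labels for the three arms, default `c("A","B","C")`.
#' @return an object of class `maze_geometry`: arm/junction polygons
#'   (counter-clockwise coordinate matrices), apothem of the junction
#'   triangle, and the generating parameters.
#' @examples
#' geom <- maze_geometry()
#' zone_at(geom, 0, 0)        # "junction"
#' zone_at(geom, 0, 20)       # arm at bearing 90
#' @export
maze_geometry <- function(arm_length = 25, arm_width = 8,
                          bearings_deg = c(90, 210, 330),
                          arm_labels = c("A", "B", "C")) {
  if (!is.numeric(arm_length) || arm_length <= 0 ||
      !is.numeric(arm_width) || arm_width <= 0) {
    stop_invalid("invalid-geometry: arm_length and arm_width must be > 0")
  }
  if (length(bearings_deg) != 3L || anyDuplicated(bearings_deg %% 360)) {
    stop_invalid("invalid-geometry: exactly three distinct arm bearings required")
  }
  stopifnot(length(arm_labels) == 3L, !anyDuplicated(arm_labels))

  w <- arm_width
  a <- w / (2 * sqrt(3))  # apothem of equilateral junction triangle, side w
  th <- bearings_deg * pi / 180
  u <- cbind(cos(th), sin(th))          # outward unit axis per arm
  p <- cbind(-sin(th), cos(th))         # left-hand perpendicular

  arms <- vector("list", 3L)
  mouth_mid <- a * u
  for (i in 1:3) {
    m <- mouth_mid[i, ]
    arms[[i]] <- rbind(
      m + (w / 2) * p[i, ],
      m - (w / 2) * p[i, ],
      m + arm_length * u[i, ] - (w / 2) * p[i, ],
      m + arm_length * u[i, ] + (w / 2) * p[i, ]
    )
  }
  names(arms) <- arm_labels
  # junction triangle vertices = mouth-edge endpoints (shared pairwise)
  verts <- rbind(mouth_mid[1, ] + (w / 2) * p[1, ],
                 mouth_mid[1, ] - (w / 2) * p[1, ],
                 mouth_mid[2, ] + (w / 2) * p[2, ],
                 mouth_mid[2, ] - (w / 2) * p[2, ],
                 mouth_mid[3, ] + (w / 2) * p[3, ],
                 mouth_mid[3, ] - (w / 2) * p[3, ])
  junction <- unique(round(verts, 10))
  if (nrow(junction) != 3L) {
    stop_invalid("invalid-geometry: arm bearings do not close a junction triangle (use bearings 120 degrees apart)")
  }

  structure(list(
    arm_length = arm_length, arm_width = arm_width,
    bearings_deg = bearings_deg, arm_labels = arm_labels,
    apothem = a, axes = u, perps = p,
    arms = arms, junction = junction
  ), class = "maze_geometry")
}

#' @export
print.maze_geometry <- function(x, ...) {
  cat(sprintf("Y-maze geometry: 3 arms %g x %g cm at bearings %s deg\n",
              x$arm_length, x$arm_width,
              paste(x$bearings_deg, collapse = "/")))
  invisible(x)
}

# Vectorized even-odd (ray crossing) point-in-polygon test. Points exactly
# on an edge count as inside (tolerance via >=/<= asymmetry is acceptable
# for this use: zone snapping resolves boundary ties downstream).
points_in_polygon <- function(x, y, poly) {
  n <- nrow(poly)
  px <- poly[, 1]; py <- poly[, 2]
  inside <- logical(length(x))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((py[i] > y) != (py[j] > y)) &
      (x < (px[j] - px[i]) * (y - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Minimal distance from points to a polygon boundary (vectorized over points).
dist_to_polygon <- function(x, y, poly) {
  n <- nrow(poly)
  d <- rep(Inf, length(x))
  j <- n
  for (i in seq_len(n)) {
    ax <- poly[j, 1]; ay <- poly[j, 2]
    bx <- poly[i, 1]; by <- poly[i, 2]
    vx <- bx - ax; vy <- by - ay
    len2 <- vx^2 + vy^2
    t <- pmin(1, pmax(0, ((x - ax) * vx + (y - ay) * vy) / len2))
    d <- pmin(d, sqrt((x - (ax + t * vx))^2 + (y - (ay + t * vy))^2))
    j <- i
  }
  d
}

#' Zone label of a single point (convenience wrapper around [assign_zones()])
#' @param geometry a [maze_geometry()].
#' @param x,y coordinates in maze cm.
#' @return `"junction"`, an arm label, or the nearest zone if outside.
#' @export
zone_at <- function(geometry, x, y) {
  zs <- assign_zones(data.frame(time_s = seq_along(x), x_cm = x, y_cm = y),
                     geometry)
  zs$zone
}

# Width available for lateral excursion at radial distance r along an arm
# axis: full arm half-width once inside the arm, linearly narrowing toward
# 2/3 of the mouth width at the junction centroid (cross-section of the
# equilateral junction triangle).
lateral_halfwidth <- function(geometry, r, margin) {
  a <- geometry$apothem
  w <- geometry$arm_width
  half <- ifelse(r >= a, w / 2, (w / 2) * (2 / 3 + pmax(r, 0) / (3 * a)))
  pmax(half - margin, 0.01)
}
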