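# 2D geometric primitives underlying every cephalometric measurement.
# Coordinate convention throughout the package: x increases anteriorly,
# y increases superiorly, units are millimetres, origin arbitrary
# (the default landmark template puts sella at the origin).

# Points closer than this (mm) are treated as coincident; lines whose
# defining points are this close are degenerate.
COINCIDENT_TOL <- 1e-9

.vnorm <- function(v) sqrt(sum(v * v))

.as_point <- function(p, what = "point") {
  p <- as.numeric(p)
  if (length(p) != 2L || any(!is.finite(p))) {
    stop(what, " must be a finite numeric (x, y) pair", call. = FALSE)
  }
  p
}

.check_arm <- function(u, what) {
  if (.vnorm(u) < COINCIDENT_TOL) {
    stop("degenerate geometry: ", what, " (points coincident within ",
         COINCIDENT_TOL, " mm)", call. = FALSE)
  }
}

.rad2deg <- function(x) x * 180 / pi

#' Interior angle at a vertex defined by three points
#'
#' Returns the interior angle, in degrees, between the rays
#' `vertex -> p_left` and `vertex -> p_right`. Computed with
#' `atan2(|cross|, dot)` for numerical stability near 0 and 180 degrees.
#'
#' @param p_left,vertex,p_right numeric (x, y) pairs in mm.
#' @return Angle in degrees, in \[0, 180\].
#' @export
three_point_angle <- function(p_left, vertex, p_right) {
  a <- .as_point(p_left, "p_left")
  v <- .as_point(vertex, "vertex")
  b <- .as_point(p_right, "p_right")
  u <- a - v
  w <- b - v
  .check_arm(u, "left arm of three-point angle")
  .check_arm(w, "right arm of three-point angle")
  .rad2deg(atan2(abs(u[1] * w[2] - u[2] * w[1]), sum(u * w)))
}

#' Signed angle at a vertex, from one ray to another
#'
#' Signed counterpart of [three_point_angle()]: the rotation, in degrees,
#' taking the ray `vertex -> b` onto the ray `vertex -> a`, positive
#' counter-clockwise in the (x anterior, y superior) frame. Used for
#' measurements whose sign encodes anteroposterior discrepancy, e.g. ANB.
#'
#' @inheritParams three_point_angle
#' @param a,b numeric (x, y) pairs; the angle runs from ray `vertex->b`
#'   to ray `vertex->a`.
#' @return Angle in degrees, in (-180, 180\].
#' @export
signed_three_point_angle <- function(a, vertex, b) {
  pa <- .as_point(a, "a")
  v <- .as_point(vertex, "vertex")
  pb <- .as_point(b, "b")
  u <- pa - v
  w <- pb - v
  .check_arm(u, "first arm of signed angle")
  .check_arm(w, "second arm of signed angle")
  ang <- .rad2deg(atan2(u[2], u[1]) - atan2(w[2], w[1]))
  wrap_angle_180(ang)
}

# wrap to (-180, 180]
wrap_angle_180 <- function(x) {
  x <- (x + 180) %% 360 - 180
  ifelse(x == -180, 180, x)
}

#' Angle between two directed rays
#'
#' Angle in degrees between the direction vectors `from1 -> to1` and
#' `from2 -> to2`, in \[0, 180\]. Unlike [line_line_angle()] this respects
#' ray direction, so it can express clinically conventional angles above
#' 90 degrees (e.g. U1 to SN).
#'
#' @param from1,to1,from2,to2 numeric (x, y) pairs in mm.
#' @return Angle in degrees, in \[0, 180\].
#' @export
ray_angle <- function(from1, to1, from2, to2) {
  u <- .as_point(to1, "to1") - .as_point(from1, "from1")
  w <- .as_point(to2, "to2") - .as_point(from2, "from2")
  .check_arm(u, "first ray")
  .check_arm(w, "second ray")
  .rad2deg(atan2(abs(u[1] * w[2] - u[2] * w[1]), sum(u * w)))
}

# Direction of the line through p, q normalised to point anteriorly
# (positive x; for exactly vertical lines, superiorly). Unit vector.
line_direction <- function(p, q) {
  d <- .as_point(q, "q") - .as_point(p, "p")
  .check_arm(d, "line")
  if (d[1] < 0 || (d[1] == 0 && d[2] < 0)) d <- -d
  d / .vnorm(d)
}

#' Angle between two lines
#'
#' Each line is given by two points. Directions are normalised to point
#' anteriorly (positive x), so the signed convention is well defined:
#' the signed angle is direction-angle(line1) minus direction-angle(line2),
#' wrapped to (-90, 90\]. Positive means line1 is rotated counter-clockwise
#' (anterior end tilted superiorly) relative to line2.
#'
#' @param l1p,l1q two points defining line 1.
#' @param l2p,l2q two points defining line 2.
#' @param convention `"unsigned"` (default) for \[0, 90\], or `"signed"`
#'   for (-90, 90\].
#' @return Angle in degrees.
#' @export
line_line_angle <- function(l1p, l1q, l2p, l2q,
                            convention = c("unsigned", "signed")) {
  convention <- match.arg(convention)
  d1 <- line_direction(l1p, l1q)
  d2 <- line_direction(l2p, l2q)
  a1 <- .rad2deg(atan2(d1[2], d1[1]))
  a2 <- .rad2deg(atan2(d2[2], d2[1]))
  diff <- a1 - a2
  # fold to (-90, 90]
  diff <- wrap_angle_180(diff)
  if (diff <= -90) diff <- diff + 180
  if (diff > 90) diff <- diff - 180
  if (convention == "signed") diff else abs(diff)
}

# Unit normal of the line through p, q oriented so that `positive` names
# the positive half-plane. Errors when the line is (near) parallel to the
# requested sign axis, because the convention is then meaningless.
.oriented_normal <- function(p, q, positive) {
  d <- line_direction(p, q)
  n <- c(-d[2], d[1])
  comp <- switch(positive,
    anterior = n[1], posterior = -n[1],
    superior = n[2], inferior = -n[2],
    stop("unknown sign convention: ", positive, call. = FALSE)
  )
  if (abs(comp) < 1e-6) {
    stop("sign convention '", positive,
         "' is degenerate for a line parallel to that axis", call. = FALSE)
  }
  if (comp < 0) n <- -n
  n
}

#' Signed perpendicular distance from a point to a line
#'
#' @param p the point, numeric (x, y) in mm.
#' @param lp,lq two points defining the line.
#' @param positive which half-plane counts as positive: `"anterior"`
#'   (+x side), `"posterior"`, `"superior"` (+y side) or `"inferior"`.
#' @return Signed distance in mm.
#' @export
signed_point_line_distance <- function(p, lp, lq,
                                       positive = c("anterior", "posterior",
                                                    "superior", "inferior")) {
  positive <- match.arg(positive)
  pt <- .as_point(p, "p")
  a <- .as_point(lp, "lp")
  n <- .oriented_normal(lp, lq, positive)
  sum((pt - a) * n)
}

#' Scalar projection of the vector q -> p onto a line direction
#'
#' The line direction is normalised to point anteriorly, so the result is
#' the anteroposterior offset of `p` relative to `q` measured along the
#' line (the Wits-appraisal construction when the line is the occlusal
#' plane).
#'
#' @param p,q numeric (x, y) pairs; the projected vector is `p - q`.
#' @param lp,lq two points defining the reference line.
#' @return Signed length in mm (positive = `p` anterior of `q` along the line).
#' @export
projection_length <- function(p, q, lp, lq) {
  u <- line_direction(lp, lq)
  sum((.as_point(p, "p") - .as_point(q, "q")) * u)
}

# Component of (p - q) along the oriented normal of a line: perpendicular
# offset with an explicit sign convention (used for incisor overbite).
perpendicular_offset <- function(p, q, lp, lq, positive = "superior") {
  n <- .oriented_normal(lp, lq, positive)
  sum((.as_point(p, "p") - .as_point(q, "q")) * n)
}

# Intersection of two lines given as point pairs; errors if near parallel.
line_intersection <- function(l1p, l1q, l2p, l2q) {
  p1 <- .as_point(l1p); d1 <- .as_point(l1q) - p1
  p2 <- .as_point(l2p); d2 <- .as_point(l2q) - p2
  .check_arm(d1, "line 1")
  .check_arm(d2, "line 2")
  det <- d1[1] * d2[2] - d1[2] * d2[1]
  if (abs(det) < 1e-12 * .vnorm(d1) * .vnorm(d2)) {
    stop("degenerate geometry: lines are parallel, no intersection",
         call. = FALSE)
  }
  t <- ((p2[1] - p1[1]) * d2[2] - (p2[2] - p1[2]) * d2[1]) / det
  p1 + t * d1
}

#' Interior angle of the triangle formed by three lines
#'
#' The three pairwise intersection points of three non-concurrent lines
#' form a triangle; this returns its interior angle at the intersection of
#' `line1` and `line2`. The Tweed diagnostic triangle (FMA, IMPA, FMIA over
#' the Frankfort horizontal, the mandibular plane and the lower-incisor
#' axis) is defined this way, which makes the 180-degree angle sum an exact
#' identity.
#'
#' @param l1,l2,l3 each a list of two (x, y) points defining a line; the
#'   angle is taken at the vertex where `l1` meets `l2`.
#' @return Interior angle in degrees, in (0, 180).
#' @export
triangle_interior_angle <- function(l1, l2, l3) {
  v12 <- line_intersection(l1[[1]], l1[[2]], l2[[1]], l2[[2]])
  v13 <- line_intersection(l1[[1]], l1[[2]], l3[[1]], l3[[2]])
  v23 <- line_intersection(l2[[1]], l2[[2]], l3[[1]], l3[[2]])
  three_point_angle(v13, v12, v23)
}

#' Euclidean distance between two points
#'
#' @param p,q numeric (x, y) pairs in mm.
#' @return Distance in mm.
#' @export
point_distance <- function(p, q) {
  .vnorm(.as_point(p, "p") - .as_point(q, "q"))
}

#' Apply a rigid motion (plus optional uniform scale) to landmark coordinates
#'
#' Utility for invariance checks: angles and ratios are unchanged under
#' rotation/translation/scaling; mm-valued measurements scale linearly.
#'
#' @param xy numeric matrix with two columns (x, y), one row per landmark.
#' @param angle_deg rotation angle, degrees counter-clockwise.
#' @param translation numeric (dx, dy) in mm.
#' @param scale uniform scale factor (> 0).
#' @return Transformed matrix, dimnames preserved.
#' @export
transform_points <- function(xy, angle_deg = 0, translation = c(0, 0),
                             scale = 1) {
  stopifnot(is.matrix(xy), ncol(xy) == 2L, scale > 0)
  th <- angle_deg * pi / 180
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  out <- scale * xy %*% t(rot)
  out[, 1] <- out[, 1] + translation[1]
  out[, 2] <- out[, 2] + translation[2]
  dimnames(out) <- dimnames(xy)
  out
}
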