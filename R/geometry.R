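# Geometry of the midbody imaginary line and limb features.
#
# A single frame is a 33 x 2 numeric matrix (rows = landmarks 0..32, columns
# x, y in normalized image coordinates). The midbody line runs through the
# shoulder midpoint (mean of landmarks 11, 12) and the hip midpoint (mean of
# landmarks 23, 24). It is stored as x = a*y + b: the supine top-down
# protocol makes the body axis near-vertical in the image, where the y = m*x
# + c form blows up; the two parameterizations are otherwise equivalent
# (a = 1/m, b = -c/m).

lm_row <- function(i) i + 1L  # 0-based landmark index -> matrix row

#' Extract one frame from a landmark series
#' @param series A [landmark_series()].
#' @param frame 0-based frame index.
#' @return A 33 x 2 matrix with columns `x`, `y` (rows = landmarks 0-32).
#' @export
get_frame <- function(series, frame) {
  stopifnot(inherits(series, "landmark_series"))
  i <- as.integer(frame) + 1L
  if (i < 1L || i > n_frames(series)) {
    stop_mtm(sprintf("frame %s out of range", format(frame)),
             "mtmpose_interval_error")
  }
  cbind(x = series$x[i, ], y = series$y[i, ])
}

#' Midpoint of two points
#' @param p,q Numeric length-2 vectors `(x, y)`.
#' @return The componentwise mean, a named numeric length-2 vector.
#' @examples
#' midpoint(c(0, 0), c(1, 1))
#' @export
midpoint <- function(p, q) {
  p <- as.numeric(p); q <- as.numeric(q)
  if (length(p) != 2L || length(q) != 2L || !all(is.finite(c(p, q)))) {
    stop_mtm("`p` and `q` must be finite (x, y) pairs",
             "mtmpose_invalid_coordinate_error")
  }
  stats::setNames((p + q) / 2, c("x", "y"))
}

#' Midbody imaginary line of a frame
#'
#' The line through the shoulder midpoint (landmarks 11, 12) and the hip
#' midpoint (landmarks 23, 24), parameterized as `x = a*y + b`. A body axis
#' horizontal in the image (the two midpoints at equal y within
#' `1e-6 * body_length`) or coincident midpoints are degenerate.
#'
#' @param frame A 33 x 2 landmark matrix (see [get_frame()]).
#' @return An object of class `midbody_line`: list with slope `a`, intercept
#'   `b`, and the two midpoints.
#' @export
midbody_line <- function(frame) {
  sh <- midpoint(frame[lm_row(11L), ], frame[lm_row(12L), ])
  hp <- midpoint(frame[lm_row(23L), ], frame[lm_row(24L), ])
  eps <- 1e-6 * body_length(frame)
  dy <- sh[["y"]] - hp[["y"]]
  if (abs(dy) <= eps) {
    stop_mtm(
      "degenerate midbody line: shoulder and hip midpoints at equal y (body axis horizontal in image)",
      "mtmpose_degeneracy_error"
    )
  }
  a <- (sh[["x"]] - hp[["x"]]) / dy
  b <- sh[["x"]] - a * sh[["y"]]
  structure(list(a = a, b = b, shoulder_mid = sh, hip_mid = hp),
            class = "midbody_line")
}

#' @export
print.midbody_line <- function(x, ...) {
  cat(sprintf("<midbody_line> x = %.6g * y + %.6g\n", x$a, x$b))
  invisible(x)
}

#' Signed distance from a landmark to the midbody line
#'
#' The horizontal offset `x_line(y) - x_landmark` evaluated at the
#' landmark's own y — the line's x at that height minus the landmark's x —
#' not the perpendicular point-line distance. Positive values lie left of
#' the line in image coordinates. Set `mode = "perpendicular"` for the
#' rotation-invariant perpendicular distance with the same sign convention.
#'
#' @param point Numeric `(x, y)` pair.
#' @param line A [midbody_line()].
#' @param mode `"x_offset"` (default) or `"perpendicular"`.
#' @return Signed distance (dimensionless, normalized-coordinate units).
#' @export
signed_distance <- function(point, line, mode = c("x_offset", "perpendicular")) {
  mode <- match.arg(mode)
  stopifnot(inherits(line, "midbody_line"))
  point <- as.numeric(point)
  if (length(point) != 2L || !all(is.finite(point))) {
    stop_mtm("`point` must be a finite (x, y) pair",
             "mtmpose_invalid_coordinate_error")
  }
  d <- line$a * point[2L] + line$b - point[1L]
  if (mode == "perpendicular") d <- d / sqrt(1 + line$a^2)
  unname(d)
}

#' Body length of a frame
#'
#' Mean of the two shoulder-to-hip Euclidean distances (landmarks 11-23 and
#' 12-24), the normalization unit for all distance and area features.
#'
#' @param frame A 33 x 2 landmark matrix.
#' @return Positive scalar; errors if the trunk is degenerate (zero length).
#' @export
body_length <- function(frame) {
  d <- function(i, j) sqrt(sum((frame[lm_row(i), ] - frame[lm_row(j), ])^2))
  len <- (d(11L, 23L) + d(12L, 24L)) / 2
  if (!is.finite(len) || len <= 0) {
    stop_mtm("degenerate body: shoulder-hip distances are zero or missing",
             "mtmpose_degenerate_body_error")
  }
  len
}

#' Body centre of a frame
#'
#' Arithmetic mean of all 33 landmark coordinates.
#'
#' @param frame A 33 x 2 landmark matrix.
#' @return Named numeric `(x, y)`.
#' @export
body_center <- function(frame) {
  if (any(!is.finite(frame))) {
    stop_mtm("body_center needs all 33 landmarks present",
             "mtmpose_invalid_frame_error")
  }
  c(x = mean(frame[, 1L]), y = mean(frame[, 2L]))
}

#' Quadrilateral limb area (shoelace)
#'
#' Absolute shoelace area of the polygon traversed in the fixed order
#' left wrist (15) -> right wrist (16) -> right ankle (28) -> left ankle
#' (27), the "whole area" enclosed by the four distal limb landmarks.
#'
#' @param p15,p16,p28,p27 Numeric `(x, y)` pairs in that traversal order.
#' @return Non-negative area; degenerate (collinear) configurations give 0.
#' @examples
#' quad_area(c(0, 0), c(1, 0), c(1, 1), c(0, 1)) # unit square
#' @export
quad_area <- function(p15, p16, p28, p27) {
  P <- rbind(p15, p16, p28, p27)
  if (any(!is.finite(P))) {
    stop_mtm("quad_area needs four finite points",
             "mtmpose_invalid_coordinate_error")
  }
  shoelace(P[, 1L], P[, 2L])
}

shoelace <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Triangle area from three points
#'
#' Half the absolute 2D cross product of the two edge vectors; used for the
#' upper-part area (wrists 15, 16 + body centre) and lower-part area
#' (ankles 27, 28 + body centre).
#'
#' @param p,q,r Numeric `(x, y)` pairs.
#' @return Non-negative area; collinear points give 0.
#' @export
tri_area <- function(p, q, r) {
  P <- rbind(p, q, r)
  if (any(!is.finite(P))) {
    stop_mtm("tri_area needs three finite points",
             "mtmpose_invalid_coordinate_error")
  }
  abs((q[1L] - p[1L]) * (r[2L] - p[2L]) -
        (r[1L] - p[1L]) * (q[2L] - p[2L])) / 2
}
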