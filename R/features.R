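#' Feature-extraction configuration
#'
#' @param visibility_threshold Minimum per-landmark pose-model confidence in
#'   \[0, 1\] below which a landmark counts as missing (default 0.5, the
#'   usual pose-detection cutoff).
#' @param area_norm_exponent Power `k` of body length used to normalize
#'   areas (`area / body_length^k`). Default `1` divides by body length;
#'   `k = 2` yields fully dimensionless areas.
#' @param distance_mode `"x_offset"` (default): the horizontal offset of a
#'   limb landmark from the midbody line at the landmark's own y.
#'   `"perpendicular"`: the perpendicular point-line distance (rotation
#'   invariant).
#' @param max_invalid_fraction A video whose fraction of invalid frames
#'   exceeds this is flagged unusable by [summarize_video()] (default 0.10).
#' @return A list of class `mtm_feature_config`.
#' @export
feature_config <- function(visibility_threshold = 0.5,
                           area_norm_exponent = 1,
                           distance_mode = c("x_offset", "perpendicular"),
                           max_invalid_fraction = 0.10) {
  distance_mode <- match.arg(distance_mode)
  stopifnot(visibility_threshold >= 0, visibility_threshold <= 1,
            area_norm_exponent >= 0,
            max_invalid_fraction >= 0, max_invalid_fraction <= 1)
  structure(
    list(visibility_threshold = visibility_threshold,
         area_norm_exponent = area_norm_exponent,
         distance_mode = distance_mode,
         max_invalid_fraction = max_invalid_fraction),
    class = "mtm_feature_config"
  )
}

DIST_LANDMARKS <- c(11L, 12L, 23L, 24L, 15L, 16L, 27L, 28L)

#' Per-frame geometric features of a landmark series
#'
#' For every frame: the signed, body-length-normalized distances of the four
#' distal limb landmarks (15 left wrist, 16 right wrist, 27 left ankle, 28
#' right ankle) to the midbody imaginary line; the body centre; and the
#' normalized whole (wrist-wrist-ankle-ankle quadrilateral), upper
#' (wrists + centre triangle) and lower (ankles + centre triangle) areas.
#'
#' Distance features need landmarks 11, 12, 23, 24 (line + body length) and
#' 15, 16, 27, 28; area features additionally need all 33 landmarks for the
#' body centre. Frames missing what a feature needs, or geometrically
#' degenerate (horizontal body axis, zero body length), get `NA` for that
#' feature and a `FALSE` validity flag instead of an error.
#'
#' @param series A [landmark_series()].
#' @param config A [feature_config()].
#' @return A `data.frame` with one row per frame: `frame`, `dlm15`, `dlm16`,
#'   `dlm27`, `dlm28`, `body_length`, `center_x`, `center_y`, `area_whole`,
#'   `area_upper`, `area_lower`, `valid_distance`, `valid_area`, `valid`.
#' @export
frame_features <- function(series, config = feature_config()) {
  stopifnot(inherits(series, "landmark_series"))
  if (!inherits(config, "mtm_feature_config")) config <- do.call(feature_config, config)
  X <- series$x; Y <- series$y
  col <- function(i) i + 1L
  thr <- config$visibility_threshold

  sh_x <- (X[, col(11L)] + X[, col(12L)]) / 2
  sh_y <- (Y[, col(11L)] + Y[, col(12L)]) / 2
  hp_x <- (X[, col(23L)] + X[, col(24L)]) / 2
  hp_y <- (Y[, col(23L)] + Y[, col(24L)]) / 2
  bl <- (sqrt((X[, col(11L)] - X[, col(23L)])^2 +
                (Y[, col(11L)] - Y[, col(23L)])^2) +
           sqrt((X[, col(12L)] - X[, col(24L)])^2 +
                  (Y[, col(12L)] - Y[, col(24L)])^2)) / 2

  ok_dist <- landmarks_available(series, DIST_LANDMARKS, thr)
  ok_all <- landmarks_available(series, 0:32, thr)
  nondegen <- is.finite(bl) & bl > 0 &
    abs(sh_y - hp_y) > 1e-6 * bl
  valid_distance <- ok_dist & nondegen
  valid_area <- ok_all & is.finite(bl) & bl > 0

  a <- (sh_x - hp_x) / (sh_y - hp_y)
  b <- sh_x - a * sh_y
  dof <- function(i) {
    d <- a * Y[, col(i)] + b - X[, col(i)]
    if (config$distance_mode == "perpendicular") d <- d / sqrt(1 + a^2)
    d / bl
  }
  dlm15 <- dof(15L); dlm16 <- dof(16L); dlm27 <- dof(27L); dlm28 <- dof(28L)

  cx <- rowMeans(X); cy <- rowMeans(Y)
  x1 <- X[, col(15L)]; y1 <- Y[, col(15L)]
  x2 <- X[, col(16L)]; y2 <- Y[, col(16L)]
  x3 <- X[, col(28L)]; y3 <- Y[, col(28L)]
  x4 <- X[, col(27L)]; y4 <- Y[, col(27L)]
  norm_a <- bl^config$area_norm_exponent
  area_whole <- abs(x1 * y2 - x2 * y1 + x2 * y3 - x3 * y2 +
                      x3 * y4 - x4 * y3 + x4 * y1 - x1 * y4) / 2 / norm_a
  area_upper <- abs((x2 - x1) * (cy - y1) - (cx - x1) * (y2 - y1)) / 2 / norm_a
  area_lower <- abs((x3 - x4) * (cy - y4) - (cx - x4) * (y3 - y4)) / 2 / norm_a

  blank <- function(v, ok) { v[!ok] <- NA_real_; v }
  data.frame(
    frame = 0:(n_frames(series) - 1L),
    dlm15 = blank(dlm15, valid_distance),
    dlm16 = blank(dlm16, valid_distance),
    dlm27 = blank(dlm27, valid_distance),
    dlm28 = blank(dlm28, valid_distance),
    body_length = blank(bl, is.finite(bl) & bl > 0),
    center_x = blank(cx, valid_area),
    center_y = blank(cy, valid_area),
    area_whole = blank(area_whole, valid_area),
    area_upper = blank(area_upper, valid_area),
    area_lower = blank(area_lower, valid_area),
    valid_distance = valid_distance,
    valid_area = valid_area,
    valid = valid_distance & valid_area
  )
}

#' Per-video feature summary
#'
#' Averages the per-frame features over valid frames so each video is
#' reduced to a single mean signed distance per limb landmark and a single
#' mean normalized area per region. Distance means use frames valid for
#' distances; area means use frames valid for areas. A video whose invalid
#' fraction exceeds `config$max_invalid_fraction` is flagged `usable =
#' FALSE` (incompletely analysable footage).
#'
#' @inheritParams frame_features
#' @return One-row `data.frame`: `video_id`, `mean_dlm15` ... `mean_dlm28`,
#'   `mean_area_whole`, `mean_area_upper`, `mean_area_lower`,
#'   `n_valid_frames`, `n_frames`, `usable`.
#' @export
summarize_video <- function(series, config = feature_config()) {
  ff <- frame_features(series, config)
  nf <- nrow(ff)
  nv <- sum(ff$valid)
  if (nv == 0L) {
    stop_mtm(sprintf("video %s has no valid frames", series$video_id),
             "mtmpose_no_data_error")
  }
  mean_over <- function(v, ok) mean(v[ok])
  data.frame(
    video_id = series$video_id,
    mean_dlm15 = mean_over(ff$dlm15, ff$valid_distance),
    mean_dlm16 = mean_over(ff$dlm16, ff$valid_distance),
    mean_dlm27 = mean_over(ff$dlm27, ff$valid_distance),
    mean_dlm28 = mean_over(ff$dlm28, ff$valid_distance),
    mean_area_whole = mean_over(ff$area_whole, ff$valid_area),
    mean_area_upper = mean_over(ff$area_upper, ff$valid_area),
    mean_area_lower = mean_over(ff$area_lower, ff$valid_area),
    n_valid_frames = nv,
    n_frames = nf,
    usable = (1 - nv / nf) <= config$max_invalid_fraction
  )
}
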