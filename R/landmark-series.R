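#' Construct a 33-landmark pose time series
#'
#' Container for the per-frame output of a 33-landmark 2D pose model
#' (nose = 0 ... right foot index = 32) on a single video. Coordinates are
#' normalized image coordinates (origin top-left, x rightward, y downward,
#' nominally in \[0, 1\] but values slightly outside are accepted because
#' pose models emit them). Frames are 0-based and contiguous.
#'
#' @param video_id Single string identifying the video.
#' @param x,y Numeric matrices, one row per frame and exactly 33 columns
#'   (column `j` holds landmark `j - 1`). `NA` marks a missing coordinate.
#' @param visibility Optional numeric matrix of per-landmark confidence
#'   scores in \[0, 1\] with the same shape as `x`, or `NULL`.
#' @param fps Frames per second (positive; 30 in the recording protocol the
#'   package targets).
#' @return An object of class `landmark_series`.
#' @examples
#' xy <- matrix(0.5, nrow = 2, ncol = 33)
#' s <- landmark_series("v1", xy, xy)
#' n_frames(s)
#' @export
landmark_series <- function(video_id, x, y, visibility = NULL, fps = 30) {
  if (!is.character(video_id) || length(video_id) != 1L || is.na(video_id)) {
    stop_mtm("`video_id` must be a single string", "mtmpose_schema_error")
  }
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0) {
    stop_mtm("`fps` must be a single positive number", "mtmpose_schema_error")
  }
  x <- as.matrix(x); y <- as.matrix(y)
  if (ncol(x) != 33L || ncol(y) != 33L || !identical(dim(x), dim(y))) {
    stop_mtm("`x` and `y` must be equal-shape matrices with 33 columns",
             "mtmpose_schema_error")
  }
  if (nrow(x) < 1L) {
    stop_mtm("a landmark series needs at least one frame",
             "mtmpose_schema_error")
  }
  if (!is.null(visibility)) {
    visibility <- as.matrix(visibility)
    if (!identical(dim(visibility), dim(x))) {
      stop_mtm("`visibility` must have the same shape as `x`",
               "mtmpose_schema_error")
    }
  }
  lmn <- paste0("lm", 0:32)
  dimnames(x) <- dimnames(y) <- list(NULL, lmn)
  if (!is.null(visibility)) dimnames(visibility) <- list(NULL, lmn)
  structure(
    list(video_id = video_id, fps = as.numeric(fps),
         x = x, y = y, visibility = visibility),
    class = "landmark_series"
  )
}

#' Number of frames in a landmark series
#' @param series A [landmark_series()].
#' @return Integer frame count.
#' @export
n_frames <- function(series) {
  stopifnot(inherits(series, "landmark_series"))
  nrow(series$x)
}

#' @export
print.landmark_series <- function(x, ...) {
  nf <- n_frames(x)
  cat(sprintf(
    "<landmark_series> video '%s': %d frames @ %g fps (%.1f s), %d coordinate records%s\n",
    x$video_id, nf, x$fps, nf / x$fps, nf * 33L,
    if (is.null(x$visibility)) "" else ", with visibility"
  ))
  invisible(x)
}

# Per-frame availability of the given 0-based landmark indices: coordinates
# finite and (when visibility is present) visibility >= threshold. Returns a
# logical vector over frames.
landmarks_available <- function(series, landmarks, visibility_threshold = 0.5) {
  cols <- landmarks + 1L
  ok <- rowSums(!is.finite(series$x[, cols, drop = FALSE]) |
                  !is.finite(series$y[, cols, drop = FALSE])) == 0L
  if (!is.null(series$visibility)) {
    v <- series$visibility[, cols, drop = FALSE]
    ok <- ok & rowSums(is.na(v) | v < visibility_threshold) == 0L
  }
  ok
}

#' Per-frame validity of a landmark series
#'
#' A frame is valid when every requested landmark has finite coordinates and,
#' if visibility scores are present, visibility at or above the threshold.
#' Raising the threshold can only invalidate frames, never the reverse.
#'
#' @param series A [landmark_series()].
#' @param landmarks Integer vector of 0-based landmark indices to require
#'   (default: all 33).
#' @param visibility_threshold Minimum per-landmark confidence in \[0, 1\].
#' @return Logical vector with one element per frame.
#' @export
frame_valid <- function(series, landmarks = 0:32, visibility_threshold = 0.5) {
  stopifnot(inherits(series, "landmark_series"))
  if (any(landmarks < 0L | landmarks > 32L)) {
    stop_mtm("landmark indices must lie in 0..32", "mtmpose_schema_error")
  }
  landmarks_available(series, as.integer(landmarks), visibility_threshold)
}
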