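# Shared fixtures: frames and series built in code.

# A plausible random non-degenerate frame: jittered template at random
# scale, orientation (away from the horizontal-axis degeneracy) and
# position.
random_frame <- function(jitter = 0.01) {
  tp <- template_pose(
    scale = stats::runif(1, 0.2, 0.4),
    orientation = stats::runif(1, -1, 1),
    center = c(stats::runif(1, 0.4, 0.6), stats::runif(1, 0.4, 0.6))
  )
  tp + matrix(stats::rnorm(66, 0, jitter), 33, 2)
}

# Wrap one or more 33 x 2 frames into a landmark_series.
series_from_frames <- function(frames, video_id = "test", fps = 30,
                               visibility = NULL) {
  if (is.matrix(frames)) frames <- list(frames)
  x <- do.call(rbind, lapply(frames, function(f) f[, 1L]))
  y <- do.call(rbind, lapply(frames, function(f) f[, 2L]))
  landmark_series(video_id, x, y, visibility, fps = fps)
}

# Reflect points (rows of a 33 x 2 matrix) across the line x = a*y + b.
reflect_across_line <- function(frame, line) {
  s2 <- 1 + line$a^2
  n <- c(-1, line$a) / sqrt(s2)
  p0 <- c(line$b, 0)
  d <- (frame[, 1L] - p0[1L]) * n[1L] + (frame[, 2L] - p0[2L]) * n[2L]
  frame - 2 * cbind(d * n[1L], d * n[2L])
}

# Swap left/right landmark labels (0-based MediaPipe pairs); nose stays.
swap_left_right <- function(frame) {
  left <- c(1L, 2L, 3L, 7L, 9L, 11L, 13L, 15L, 17L, 19L, 21L, 23L, 25L,
            27L, 29L, 31L)
  right <- c(4L, 5L, 6L, 8L, 10L, 12L, 14L, 16L, 18L, 20L, 22L, 24L, 26L,
             28L, 30L, 32L)
  out <- frame
  out[left + 1L, ] <- frame[right + 1L, ]
  out[right + 1L, ] <- frame[left + 1L, ]
  out
}

# One-row feature extraction for a single frame.
features_of_frame <- function(frame, config = feature_config()) {
  frame_features(series_from_frames(frame), config)
}
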