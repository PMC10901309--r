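#' Read a long-format 33-landmark pose CSV
#'
#' Expects header `frame,landmark,x,y[,visibility]`: one row per landmark per
#' frame, frames 0-based and contiguous from 0, landmarks 0-32. This is the
#' on-disk form of the per-video csv a 2D pose estimator produces (a 120 s
#' video at 30 fps gives 3600 frames and 118,800 coordinate rows).
#'
#' @param path Path to the CSV file.
#' @param fps Frames per second of the source video (default 30).
#' @param visibility_threshold Retained on the returned series for use by
#'   downstream validity checks.
#' @return A [landmark_series()]; the video id defaults to the file name
#'   without extension.
#' @seealso [write_landmark_csv()], [read_wide_landmark_csv()]
#' @export
read_landmark_csv <- function(path, fps = 30, visibility_threshold = 0.5) {
  if (!file.exists(path)) {
    stop_mtm(sprintf("file not found: %s", path), "mtmpose_io_error")
  }
  dt <- data.table::fread(path, showProgress = FALSE)
  need <- c("frame", "landmark", "x", "y")
  miss <- setdiff(need, names(dt))
  if (length(miss) > 0L) {
    stop_mtm(sprintf("landmark CSV %s lacks column(s): %s",
                     path, paste(miss, collapse = ", ")),
             "mtmpose_schema_error")
  }
  if (nrow(dt) == 0L) {
    stop_mtm(sprintf("landmark CSV %s has no data rows", path),
             "mtmpose_schema_error")
  }
  data.table::setorder(dt, frame, landmark)
  cnt <- dt[, .N, by = "frame"]
  bad <- cnt[cnt$N != 33L]
  if (nrow(bad) > 0L) {
    stop_mtm(sprintf(
      "frame %d of %s has %d landmark rows (33 expected)",
      bad$frame[1L], path, bad$N[1L]
    ), "mtmpose_malformed_frame_error")
  }
  frames <- cnt$frame
  if (!identical(as.integer(frames), seq_along(frames) - 1L)) {
    stop_mtm(sprintf("frame indices in %s are not contiguous from 0", path),
             "mtmpose_gap_error")
  }
  nf <- length(frames)
  if (!all(dt$landmark == rep.int(0:32, nf))) {
    stop_mtm(sprintf("landmark indices in %s are not 0..32 per frame", path),
             "mtmpose_malformed_frame_error")
  }
  x <- matrix(as.numeric(dt$x), nrow = nf, ncol = 33L, byrow = TRUE)
  y <- matrix(as.numeric(dt$y), nrow = nf, ncol = 33L, byrow = TRUE)
  vis <- NULL
  if ("visibility" %in% names(dt)) {
    vis <- matrix(as.numeric(dt$visibility), nrow = nf, ncol = 33L,
                  byrow = TRUE)
  }
  vid <- sub("\\.[^.]*$", "", basename(path))
  s <- landmark_series(vid, x, y, vis, fps = fps)
  s$visibility_threshold <- visibility_threshold
  s
}

#' Read a wide-format landmark CSV
#'
#' Convenience alias for files with one row per frame and columns
#' `frame, x0..x32, y0..y32[, v0..v32]`.
#'
#' @inheritParams read_landmark_csv
#' @return A [landmark_series()].
#' @export
read_wide_landmark_csv <- function(path, fps = 30, visibility_threshold = 0.5) {
  if (!file.exists(path)) {
    stop_mtm(sprintf("file not found: %s", path), "mtmpose_io_error")
  }
  dt <- data.table::fread(path, showProgress = FALSE)
  xc <- paste0("x", 0:32); yc <- paste0("y", 0:32); vc <- paste0("v", 0:32)
  miss <- setdiff(c("frame", xc, yc), names(dt))
  if (length(miss) > 0L) {
    stop_mtm(sprintf("wide landmark CSV %s lacks column(s): %s",
                     path, paste(utils::head(miss, 5L), collapse = ", ")),
             "mtmpose_schema_error")
  }
  data.table::setorder(dt, frame)
  if (!identical(as.integer(dt$frame), seq_len(nrow(dt)) - 1L)) {
    stop_mtm(sprintf("frame indices in %s are not contiguous from 0", path),
             "mtmpose_gap_error")
  }
  vis <- if (all(vc %in% names(dt))) as.matrix(dt[, vc, with = FALSE]) else NULL
  s <- landmark_series(sub("\\.[^.]*$", "", basename(path)),
                       as.matrix(dt[, xc, with = FALSE]),
                       as.matrix(dt[, yc, with = FALSE]),
                       vis, fps = fps)
  s$visibility_threshold <- visibility_threshold
  s
}

#' Write a landmark series to long-format CSV
#'
#' Coordinates are written with 17 significant digits so that
#' `read_landmark_csv(write_landmark_csv(s))` reproduces `s` exactly.
#'
#' @param series A [landmark_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_landmark_csv <- function(series, path) {
  stopifnot(inherits(series, "landmark_series"))
  nf <- n_frames(series)
  if (nf < 1L) stop_mtm("series has no frames", "mtmpose_io_error")
  fmt <- function(m) {
    out <- sprintf("%.17g", t(m))
    out[is.na(t(m))] <- ""
    out
  }
  dt <- data.table::data.table(
    frame = rep(0:(nf - 1L), each = 33L),
    landmark = rep.int(0:32, nf),
    x = fmt(series$x),
    y = fmt(series$y)
  )
  if (!is.null(series$visibility)) dt[, "visibility" := fmt(series$visibility)]
  ok <- tryCatch({
    data.table::fwrite(dt, path, quote = FALSE, showProgress = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop_mtm(sprintf("cannot write %s: %s", path, conditionMessage(ok)),
             "mtmpose_io_error")
  }
  invisible(path)
}

#' Read MTM event annotations
#'
#' Expects header `video_id,item,start_frame,end_frame`. Each row is one
#' observed midline-contact interval; intervals are half-open
#' `[start_frame, end_frame)` in 0-based frames. Items must belong to the
#' 10-item catalogue ([mtm_catalogue()]); matching is case-insensitive.
#'
#' @param path Path to the annotation CSV.
#' @param n_frames Optional video length in frames; when given, events must
#'   lie within `[0, n_frames]`.
#' @return A `data.frame` with columns `video_id`, `item` (canonical
#'   upper-case), `start_frame`, `end_frame`.
#' @export
read_annotations <- function(path, n_frames = NULL) {
  if (!file.exists(path)) {
    stop_mtm(sprintf("file not found: %s", path), "mtmpose_io_error")
  }
  dt <- data.table::fread(path, showProgress = FALSE,
                          colClasses = list(character = "video_id"))
  need <- c("video_id", "item", "start_frame", "end_frame")
  miss <- setdiff(need, names(dt))
  if (length(miss) > 0L) {
    stop_mtm(sprintf("annotation CSV %s lacks column(s): %s",
                     path, paste(miss, collapse = ", ")),
             "mtmpose_schema_error")
  }
  ev <- as.data.frame(dt[, need, with = FALSE])
  validate_events(ev, n_frames = n_frames)
}

#' Validate a table of MTM events
#'
#' @param events Data frame with columns `video_id`, `item`, `start_frame`,
#'   `end_frame` (half-open frame intervals).
#' @param n_frames Optional video length in frames used for range checks.
#' @return The validated data frame with canonical item labels.
#' @export
validate_events <- function(events, n_frames = NULL) {
  events <- as.data.frame(events)
  if (nrow(events) > 0L) {
    events$item <- canonical_items(events$item)
    events$start_frame <- as.integer(events$start_frame)
    events$end_frame <- as.integer(events$end_frame)
    bad <- events$end_frame <= events$start_frame | events$start_frame < 0L
    if (!is.null(n_frames)) bad <- bad | events$end_frame > n_frames
    if (any(bad)) {
      i <- which(bad)[1L]
      stop_mtm(sprintf(
        "invalid event interval [%d, %d) for item %s of video %s",
        events$start_frame[i], events$end_frame[i],
        events$item[i], events$video_id[i]
      ), "mtmpose_interval_error")
    }
  }
  rownames(events) <- NULL
  events
}

#' Write MTM event annotations to CSV
#' @param events Validated event data frame (see [validate_events()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(events, path) {
  events <- validate_events(events)
  data.table::fwrite(data.table::as.data.table(events), path,
                     quote = FALSE, showProgress = FALSE)
  invisible(path)
}
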