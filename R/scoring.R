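# Scoring of observed MTM events: whole seconds under the 30-consecutive-
# frame rule, occurrence percentage, and per-minute rates by limb group.

#' Whole seconds contributed by one MTM event
#'
#' An item must be present for `fps` consecutive frames (30 at 30 fps) to
#' count as one second; runs shorter than that contribute nothing. The
#' default `"floor"` rule therefore credits `floor(frames / fps)` whole
#' seconds per event. A `"fractional"` rule (`frames / fps`) is available
#' for sensitivity analysis.
#'
#' @param n_frames Event length in frames (or a one-event data frame with
#'   `start_frame`/`end_frame`, half-open).
#' @param fps Frames per second (default 30).
#' @param rule `"floor"` (default) or `"fractional"`.
#' @return Seconds credited (integer under `"floor"`).
#' @examples
#' event_seconds(29) # 0: below 30 frames, excluded
#' event_seconds(45) # 1
#' event_seconds(60) # 2
#' @export
event_seconds <- function(n_frames, fps = 30, rule = c("floor", "fractional")) {
  rule <- match.arg(rule)
  if (is.data.frame(n_frames)) {
    n_frames <- n_frames$end_frame - n_frames$start_frame
  }
  stopifnot(is.numeric(n_frames), all(n_frames >= 0), fps > 0)
  if (rule == "floor") floor(n_frames / fps) else n_frames / fps
}

# Merge overlapping/touching intervals of one item so a behaviour annotated
# twice is not double-counted. Returns matrix with columns start, end.
merge_intervals <- function(start, end) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1L]; me <- end[1L]
  out_s <- numeric(0); out_e <- numeric(0)
  if (length(start) > 1L) for (i in 2L:length(start)) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  cbind(start = c(out_s, ms), end = c(out_e, me))
}

#' Score one video's MTM events
#'
#' Sums each item's credited seconds (overlapping annotations of the same
#' item are merged first; simultaneous events of different items each count
#' in full), then derives the occurrence percentage
#' (total seconds / duration x 100) and the per-minute occurrence rates
#' (group seconds / duration x 60) for the total, lower-limb (FF, FL,
#' pedipulation) and upper-limb (the other seven items) groups. With the
#' protocol's 120 s videos the denominator is 120; other durations
#' substitute their own length.
#'
#' @param events Event data frame for a single video (columns `video_id`,
#'   `item`, `start_frame`, `end_frame`).
#' @param duration_s Video duration in seconds (default 120).
#' @param fps Frames per second (default 30).
#' @param rule Passed to [event_seconds()].
#' @param video_id Video id to use when `events` is empty.
#' @return One-row `data.frame`: `video_id`, one seconds column per
#'   catalogue item, `total_seconds`, `occurrence_percentage`, `rate_total`,
#'   `rate_lower`, `rate_upper`, `shows_total`, `shows_lower`, `shows_upper`.
#' @export
score_video <- function(events, duration_s = 120, fps = 30,
                        rule = c("floor", "fractional"), video_id = NULL) {
  rule <- match.arg(rule)
  stopifnot(duration_s > 0, fps > 0)
  n_total_frames <- as.integer(round(duration_s * fps))
  events <- validate_events(events, n_frames = n_total_frames)
  if (is.null(video_id)) {
    video_id <- if (nrow(events) > 0L) events$video_id[1L] else "video"
  }
  if (nrow(events) > 0L && length(unique(events$video_id)) > 1L) {
    stop_mtm("score_video expects events from a single video",
             "mtmpose_interval_error")
  }
  cat <- mtm_catalogue()
  secs <- stats::setNames(numeric(length(cat$items)), cat$items)
  for (it in unique(events$item)) {
    iv <- merge_intervals(events$start_frame[events$item == it],
                          events$end_frame[events$item == it])
    secs[[it]] <- sum(event_seconds(iv[, "end"] - iv[, "start"], fps, rule))
  }
  total <- sum(secs)
  lower <- sum(secs[cat$lower])
  upper <- sum(secs[cat$upper])
  out <- data.frame(video_id = video_id)
  for (it in cat$items) out[[it]] <- secs[[it]]
  out$total_seconds <- total
  out$occurrence_percentage <- total / duration_s * 100
  out$rate_total <- total / duration_s * 60
  out$rate_lower <- lower / duration_s * 60
  out$rate_upper <- upper / duration_s * 60
  out$shows_total <- out$rate_total > 0
  out$shows_lower <- out$rate_lower > 0
  out$shows_upper <- out$rate_upper > 0
  out
}

#' Score every video in an annotation table
#'
#' @param events Event data frame covering one or more videos.
#' @param video_ids Optional character vector of videos to score (videos
#'   with no events get all-zero scores); defaults to the ids present in
#'   `events`.
#' @inheritParams score_video
#' @return A `data.frame` with one [score_video()] row per video.
#' @export
score_videos <- function(events, duration_s = 120, fps = 30,
                         rule = c("floor", "fractional"), video_ids = NULL) {
  rule <- match.arg(rule)
  events <- validate_events(events)
  if (is.null(video_ids)) video_ids <- unique(events$video_id)
  if (length(video_ids) == 0L) {
    stop_mtm("no videos to score", "mtmpose_no_data_error")
  }
  do.call(rbind, lapply(video_ids, function(v) {
    score_video(events[events$video_id == v, , drop = FALSE],
                duration_s = duration_s, fps = fps, rule = rule,
                video_id = v)
  }))
}

#' Partition videos by MTM category
#'
#' Splits a cohort of scored videos into shows / does-not-show groups for
#' each of the three categories (Total, Lower, Upper MTM).
#'
#' @param scores Data frame from [score_videos()].
#' @return A `data.frame` with columns `category`, `n_show`, `n_noshow` and
#'   list-columns `show_ids`, `noshow_ids`.
#' @export
classify_videos <- function(scores) {
  stopifnot(is.data.frame(scores), nrow(scores) > 0L)
  one <- function(category, flag) {
    data.frame(
      category = category,
      n_show = sum(flag),
      n_noshow = sum(!flag),
      show_ids = I(list(scores$video_id[flag])),
      noshow_ids = I(list(scores$video_id[!flag]))
    )
  }
  rbind(one("Total", scores$shows_total),
        one("Lower", scores$shows_lower),
        one("Upper", scores$shows_upper))
}
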