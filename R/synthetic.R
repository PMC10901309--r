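# Seeded generator of synthetic supine-infant 33-landmark trajectories with
# ground-truth midline-contact events. The generator works in a body frame
# (u lateral, v axial with shoulders at v = 0 and hips at v = 1, so the
# trunk has unit length pre-scale), adds mean-reverting baseline limb
# wander, eases contact landmarks onto their targets during scheduled
# events, then maps to normalized image coordinates, applies a rigid
# per-frame camera jitter, and adds measurement noise last.

# 33-landmark template: infant's left side at +u (image right when the head
# points up). Units: trunk (shoulder line to hip line) = 1.
template_uv <- function() {
  m <- matrix(NA_real_, nrow = 33L, ncol = 2L,
              dimnames = list(paste0("lm", 0:32), c("u", "v")))
  set <- function(i, u, v) m[lm_row(i), ] <<- c(u, v)
  set(0L, 0, -0.55)                      # nose
  set(1L, 0.05, -0.63); set(2L, 0.08, -0.63); set(3L, 0.11, -0.63)  # L eye
  set(4L, -0.05, -0.63); set(5L, -0.08, -0.63); set(6L, -0.11, -0.63)
  set(7L, 0.16, -0.58); set(8L, -0.16, -0.58)   # ears
  set(9L, 0.04, -0.47); set(10L, -0.04, -0.47)  # mouth corners
  set(11L, 0.28, 0); set(12L, -0.28, 0)         # shoulders
  set(13L, 0.42, 0.25); set(14L, -0.42, 0.25)   # elbows
  set(15L, 0.50, 0.48); set(16L, -0.50, 0.48)   # wrists
  set(17L, 0.55, 0.56); set(18L, -0.55, 0.56)   # pinkies
  set(19L, 0.57, 0.54); set(20L, -0.57, 0.54)   # index fingers
  set(21L, 0.52, 0.52); set(22L, -0.52, 0.52)   # thumbs
  set(23L, 0.16, 1.00); set(24L, -0.16, 1.00)   # hips
  set(25L, 0.30, 1.35); set(26L, -0.30, 1.35)   # knees
  set(27L, 0.34, 1.70); set(28L, -0.34, 1.70)   # ankles
  set(29L, 0.36, 1.78); set(30L, -0.36, 1.78)   # heels
  set(31L, 0.32, 1.82); set(32L, -0.32, 1.82)   # foot indices
  m
}

# Map body-frame (u, v) to image coordinates: rotate by `orientation`
# radians, scale, and translate so the mid-trunk point sits at `center`.
uv_to_image <- function(u, v, scale, orientation, center) {
  vc <- v - 0.5
  list(x = center[1L] + scale * (u * cos(orientation) - vc * sin(orientation)),
       y = center[2L] + scale * (u * sin(orientation) + vc * cos(orientation)))
}

#' Template supine rest pose
#'
#' A bilaterally symmetric 33-landmark rest pose of a supine infant seen
#' top-down: left/right landmark pairs mirror about the body axis, so the
#' shoulder and hip midpoints (and the body centre) lie exactly on the
#' midbody line.
#'
#' @param scale Body scale: image-coordinate length of the trunk
#'   (shoulder-line to hip-line); default 0.3 of the frame.
#' @param orientation Body-axis rotation in radians (0 = head toward the
#'   top of the image).
#' @param center Image position of the mid-trunk point.
#' @return A 33 x 2 landmark matrix (see [get_frame()]).
#' @export
template_pose <- function(scale = 0.3, orientation = 0,
                          center = c(0.5, 0.5)) {
  stopifnot(scale > 0, length(center) == 2L)
  tp <- template_uv()
  p <- uv_to_image(tp[, "u"], tp[, "v"], scale, orientation, center)
  cbind(x = p$x, y = p$y)
}

# Contact choreography: which landmarks an item moves and where they go
# (body-frame targets computed from the template). One row per moving
# landmark.
item_contacts <- function(item) {
  tp <- template_uv()
  at <- function(i) tp[lm_row(i), ]
  v_ankle <- (at(27L)["v"] + at(28L)["v"]) / 2
  v_wrist <- (at(15L)["v"] + at(16L)["v"]) / 2
  mk <- function(lms, us, vs) {
    data.frame(landmark = lms, target_u = us, target_v = vs)
  }
  switch(item,
    FF = mk(c(27L, 28L), c(0, 0), c(v_ankle, v_ankle)),
    PEDIPULATION = mk(c(27L, 28L), c(0, 0), c(v_ankle, v_ankle)),
    FL = mk(27L, (at(26L)["u"] + at(28L)["u"]) / 2,
            (at(26L)["v"] + at(28L)["v"]) / 2),
    HH = mk(c(15L, 16L), c(0, 0), c(v_wrist, v_wrist)),
    MANIPULATION = mk(c(15L, 16L), c(0, 0), c(v_wrist, v_wrist)),
    HF = mk(15L, at(0L)["u"], at(0L)["v"]),
    HM = mk(16L, 0, (at(9L)["v"] + at(10L)["v"]) / 2),
    HT = mk(15L, 0, 0.5),
    HL = mk(15L, at(25L)["u"], at(25L)["v"]),
    FIDDLING = mk(16L, at(24L)["u"] - 0.05, at(24L)["v"]),
    stop_mtm(sprintf("no contact mapping for item %s", item),
             "mtmpose_catalogue_error")
  )
}

#' Synthetic-recording configuration
#'
#' Defines the conditions the generator emulates: a 120 s supine recording
#' at 30 fps, baseline limb motility as smooth mean-reverting wander,
#' hand-held camera jitter as a slow rigid rotation + translation, and
#' i.i.d. Gaussian landmark measurement noise. Amplitudes are in trunk
#' units (body frame) for limb motion and normalized image units for camera
#' and measurement noise.
#'
#' @param duration_s Video duration in seconds (default 120).
#' @param fps Frames per second (default 30).
#' @param seed Integer seed; the full bundle is deterministic given the
#'   configuration and seed.
#' @param baseline_amplitude Stationary SD of each distal limb landmark's
#'   wander, in trunk units (default 0.08; elbows/knees move at 60% of it).
#' @param baseline_timescale Wander correlation time in seconds (default 1.5).
#' @param noise_sigma Per-landmark measurement noise SD in normalized image
#'   units (default 0.002).
#' @param jitter_rot_sd Camera rotation jitter SD in radians (default 0.01).
#' @param jitter_trans_sd Camera translation jitter SD in image units
#'   (default 0.004).
#' @param jitter_timescale Camera jitter correlation time in seconds
#'   (default 2).
#' @param events Explicit event schedule: data frame with columns `item`,
#'   `start_s`, `duration_s` (durations at least 1 s), or `NULL` to draw
#'   from `event_rates`.
#' @param event_rates Named per-minute Poisson rates per MTM item (used when
#'   `events` is `NULL`; default all zero).
#' @param event_duration_mean Mean of the exponential excess over the 1 s
#'   minimum event duration (default 1.5 s).
#' @param body_scale,orientation,center Template placement; see
#'   [template_pose()].
#' @param contact_radius_factor Contact tolerance as a fraction of body
#'   length (default 0.25).
#' @param easing_s Ease-in/ease-out time on each side of an event (default
#'   0.3 s); easing happens outside the annotated interval so contact holds
#'   throughout it.
#' @param dropout_fraction Fraction of frames in which one distal landmark
#'   is dropped (coordinates missing, visibility 0), emulating pose-model
#'   failures (default 0).
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(duration_s = 120, fps = 30, seed = 1,
                             baseline_amplitude = 0.08,
                             baseline_timescale = 1.5,
                             noise_sigma = 0.002,
                             jitter_rot_sd = 0.01,
                             jitter_trans_sd = 0.004,
                             jitter_timescale = 2,
                             events = NULL,
                             event_rates = NULL,
                             event_duration_mean = 1.5,
                             body_scale = 0.3, orientation = 0,
                             center = c(0.5, 0.5),
                             contact_radius_factor = 0.25,
                             easing_s = 0.3,
                             dropout_fraction = 0) {
  stopifnot(duration_s > 0, fps > 0, baseline_amplitude >= 0,
            baseline_timescale > 0, noise_sigma >= 0, jitter_rot_sd >= 0,
            jitter_trans_sd >= 0, jitter_timescale > 0, body_scale > 0,
            contact_radius_factor > 0, easing_s >= 0,
            dropout_fraction >= 0, dropout_fraction <= 1)
  if (!is.null(events)) {
    events <- as.data.frame(events)
    stopifnot(all(c("item", "start_s", "duration_s") %in% names(events)))
    events$item <- canonical_items(events$item)
    if (any(events$duration_s < 1 / fps)) {
      stop_mtm("event durations must be at least one frame",
               "mtmpose_schedule_error")
    }
  }
  structure(as.list(environment()), class = "synthetic_config")
}

# Stationary AR(1) series of length n: correlation time `tau` seconds at
# `fps`, stationary SD `amp`.
ar1 <- function(n, amp, tau, fps) {
  if (amp == 0) return(numeric(n))
  phi <- exp(-1 / (fps * tau))
  innov_sd <- amp * sqrt(1 - phi^2)
  as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd), phi,
                           method = "recursive",
                           init = stats::rnorm(1, 0, amp)))
}

# Draw an event schedule from per-item Poisson rates; overlapping same-item
# candidates after the first are dropped.
draw_schedule <- function(rates, duration_s, fps, excess_mean) {
  out <- list()
  for (it in names(rates)) {
    lambda <- rates[[it]]
    if (lambda <= 0) next
    k <- stats::rpois(1L, lambda * duration_s / 60)
    if (k == 0L) next
    start <- sort(stats::runif(k, 0, duration_s))
    dur <- 1 + stats::rexp(k, 1 / excess_mean)
    keep_s <- numeric(0); keep_d <- numeric(0); busy_until <- -Inf
    for (i in seq_len(k)) {
      if (start[i] < busy_until) next
      end <- min(start[i] + dur[i], duration_s)
      if (end - start[i] < 1) next   # truncated below the 1 s minimum
      keep_s <- c(keep_s, start[i]); keep_d <- c(keep_d, end - start[i])
      busy_until <- end
    }
    if (length(keep_s) > 0L) {
      out[[it]] <- data.frame(item = it, start_s = keep_s,
                              duration_s = keep_d)
    }
  }
  if (length(out) == 0L) {
    data.frame(item = character(0), start_s = numeric(0),
               duration_s = numeric(0))
  } else {
    sched <- do.call(rbind, out)
    sched[order(sched$start_s, sched$item), , drop = FALSE]
  }
}

# Trapezoidal contact weight over frames 1..n (1-based): 1 on
# [start_f, end_f), linear easing over `ease` frames on each side.
contact_weight <- function(n, start_f, end_f, ease) {
  w <- numeric(n)
  idx <- seq_len(n)
  core <- idx >= start_f & idx < end_f
  w[core] <- 1
  if (ease > 0) {
    pre <- idx >= start_f - ease & idx < start_f
    w[pre] <- pmax(w[pre], (idx[pre] - (start_f - ease)) / ease)
    post <- idx >= end_f & idx < end_f + ease
    w[post] <- pmax(w[post], 1 - (idx[post] - end_f + 1) / ease)
  }
  w
}

#' Simulate one synthetic supine-infant video
#'
#' Deterministic given the configuration (including its seed). Baseline
#' limb wander is added to the template in the body frame; during each
#' scheduled event the item's contact landmarks ease onto their targets
#' (midline points or target landmarks) and hold there for the whole
#' annotated interval; hand/foot landmarks ride along with their wrist or
#' ankle; the whole skeleton is then placed in the image, rigidly jittered
#' per frame (hand-held camera), and measurement noise is added last.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `mtm_bundle`: `series` (a [landmark_series()]
#'   named `video_id`), `truth_events` (frame-interval annotations of the
#'   scheduled events), `config`.
#' @param video_id Identifier for the generated video.
#' @export
simulate_video <- function(config = synthetic_config(), video_id = "synthetic") {
  stopifnot(inherits(config, "synthetic_config"))
  with_private_seed(config$seed, {
    fps <- config$fps
    nf <- as.integer(round(config$duration_s * fps))
    tp <- template_uv()
    U <- matrix(rep(tp[, "u"], each = nf), nrow = nf)
    V <- matrix(rep(tp[, "v"], each = nf), nrow = nf)

    # Baseline motility: distal drivers wander; digits/feet follow.
    drivers <- c(13L, 14L, 15L, 16L, 25L, 26L, 27L, 28L)
    damp <- ifelse(drivers %in% c(13L, 14L, 25L, 26L), 0.6, 1) *
      config$baseline_amplitude
    dependents <- list(`15` = c(17L, 19L, 21L), `16` = c(18L, 20L, 22L),
                       `27` = c(29L, 31L), `28` = c(30L, 32L))
    for (k in seq_along(drivers)) {
      du <- ar1(nf, damp[k], config$baseline_timescale, fps)
      dv <- ar1(nf, damp[k], config$baseline_timescale, fps)
      cols <- lm_row(c(drivers[k], dependents[[as.character(drivers[k])]]))
      U[, cols] <- U[, cols] + du
      V[, cols] <- V[, cols] + dv
    }

    # Event schedule.
    sched <- if (!is.null(config$events)) {
      ev <- config$events
      ev$item <- canonical_items(ev$item)
      for (it in unique(ev$item)) {
        e <- ev[ev$item == it, , drop = FALSE]
        e <- e[order(e$start_s), , drop = FALSE]
        if (nrow(e) > 1L &&
            any(e$start_s[-1L] < (e$start_s + e$duration_s)[-nrow(e)])) {
          stop_mtm(sprintf("overlapping %s events in explicit schedule", it),
                   "mtmpose_schedule_error")
        }
      }
      if (any(ev$start_s < 0 | ev$start_s + ev$duration_s > config$duration_s)) {
        stop_mtm("event outside the video duration", "mtmpose_schedule_error")
      }
      ev[order(ev$start_s, ev$item), c("item", "start_s", "duration_s"),
         drop = FALSE]
    } else if (!is.null(config$event_rates)) {
      draw_schedule(config$event_rates, config$duration_s, fps,
                    config$event_duration_mean)
    } else {
      data.frame(item = character(0), start_s = numeric(0),
                 duration_s = numeric(0))
    }

    # Contact choreography: blend driver (and riders) toward targets.
    ease_f <- round(config$easing_s * fps)
    if (nrow(sched) > 0L) for (i in seq_len(nrow(sched))) {
      start_f <- round(sched$start_s[i] * fps) + 1L
      end_f <- round((sched$start_s[i] + sched$duration_s[i]) * fps) + 1L
      w <- contact_weight(nf, start_f, end_f, ease_f)
      act <- w > 0
      contacts <- item_contacts(sched$item[i])
      for (j in seq_len(nrow(contacts))) {
        drv <- contacts$landmark[j]
        cols <- lm_row(c(drv, dependents[[as.character(drv)]]))
        dc <- lm_row(drv)
        sh_u <- w[act] * (contacts$target_u[j] - U[act, dc])
        sh_v <- w[act] * (contacts$target_v[j] - V[act, dc])
        U[act, cols] <- U[act, cols] + sh_u
        V[act, cols] <- V[act, cols] + sh_v
      }
    }

    # Place in the image and apply rigid camera jitter about image centre.
    theta <- config$orientation +
      ar1(nf, config$jitter_rot_sd, config$jitter_timescale, fps)
    tx <- ar1(nf, config$jitter_trans_sd, config$jitter_timescale, fps)
    ty <- ar1(nf, config$jitter_trans_sd, config$jitter_timescale, fps)
    s <- config$body_scale
    Vc <- V - 0.5
    X <- config$center[1L] + s * (U * cos(theta) - Vc * sin(theta)) + tx
    Y <- config$center[2L] + s * (U * sin(theta) + Vc * cos(theta)) + ty

    # Measurement noise last.
    if (config$noise_sigma > 0) {
      X <- X + stats::rnorm(length(X), 0, config$noise_sigma)
      Y <- Y + stats::rnorm(length(Y), 0, config$noise_sigma)
    }

    vis <- matrix(1, nrow = nf, ncol = 33L)
    if (config$dropout_fraction > 0) {
      drop_frames <- sample.int(nf, round(config$dropout_fraction * nf))
      drop_lm <- sample(DIST_LANDMARKS, length(drop_frames), replace = TRUE)
      idx <- cbind(drop_frames, lm_row(drop_lm))
      X[idx] <- NA_real_; Y[idx] <- NA_real_; vis[idx] <- 0
    }

    truth <- if (nrow(sched) > 0L) {
      data.frame(video_id = video_id, item = sched$item,
                 start_frame = as.integer(round(sched$start_s * fps)),
                 end_frame = as.integer(round((sched$start_s +
                                                 sched$duration_s) * fps)))
    } else {
      data.frame(video_id = character(0), item = character(0),
                 start_frame = integer(0), end_frame = integer(0))
    }
    structure(
      list(series = landmark_series(video_id, X, Y, vis, fps = fps),
           truth_events = truth, config = config),
      class = "mtm_bundle"
    )
  })
}

#' @export
print.mtm_bundle <- function(x, ...) {
  cat(sprintf("<mtm_bundle> video '%s': %d frames, %d truth event(s)\n",
              x$series$video_id, n_frames(x$series), nrow(x$truth_events)))
  invisible(x)
}

#' Simulate a cohort of synthetic videos
#'
#' Draws per-video MTM burdens and simulates each video. With the default
#' `coupling = "kinematic"`, videos with lower-limb events mechanically
#' spend time with their ankles at the midline, so smaller mean lower areas
#' emerge from the kinematics rather than being painted onto the features.
#' With `coupling = "none"` every video draws from the same burden
#' distribution and the event annotations are randomly reassigned across
#' videos, decoupling scores from features (a null cohort).
#'
#' Per-video burden model: with probability `p_zero_lower` a video has no
#' lower-limb MTM at all, otherwise its lower items (FF, FL, pedipulation)
#' share a total rate drawn uniformly on (0.5, `lower_rate_max`) events/min,
#' weighted toward FF; likewise for the upper group with `p_zero_upper` and
#' `upper_rate_max`, weighted toward HT. The default zero-probabilities echo
#' the shows/no-shows mix reported for 8-16 week infants (roughly 40% of
#' videos showing lower-limb MTM and 80% upper-limb).
#'
#' @param n_videos Number of videos (at least 2).
#' @param seed Integer seed for the whole cohort.
#' @param coupling `"kinematic"` (default) or `"none"` (decoupled null).
#' @param p_zero_lower,p_zero_upper Probability of zero burden per group.
#' @param lower_rate_max,upper_rate_max Upper ends of the uniform total-rate
#'   draws, events/min.
#' @param ... Overrides passed to every video's [synthetic_config()]
#'   (e.g. `duration_s`, `noise_sigma`).
#' @return A list of class `mtm_cohort`: `bundles` (named list of
#'   [simulate_video()] bundles), `events` (combined truth annotations,
#'   reassigned when `coupling = "none"`), `video_ids`, `coupling`, `seed`.
#' @export
make_cohort <- function(n_videos, seed = 1,
                        coupling = c("kinematic", "none"),
                        p_zero_lower = 0.6, p_zero_upper = 0.2,
                        lower_rate_max = 3, upper_rate_max = 4, ...) {
  coupling <- match.arg(coupling)
  if (n_videos < 2L) {
    stop_mtm("make_cohort needs at least 2 videos",
             "mtmpose_insufficient_n_error")
  }
  dots <- list(...)
  cat <- mtm_catalogue()
  plan <- with_private_seed(seed, {
    video_seeds <- sample.int(.Machine$integer.max - 1L, n_videos)
    rates <- lapply(seq_len(n_videos), function(i) {
      r <- stats::setNames(numeric(length(cat$items)), cat$items)
      if (stats::runif(1) >= p_zero_lower) {
        tot <- stats::runif(1, 0.5, lower_rate_max)
        w <- c(FF = 0.6, FL = 0.2, PEDIPULATION = 0.2)
        r[names(w)] <- tot * w
      }
      if (stats::runif(1) >= p_zero_upper) {
        tot <- stats::runif(1, 0.5, upper_rate_max)
        w <- c(HT = 0.35, HH = 0.15, HF = 0.1, HM = 0.1, HL = 0.1,
               MANIPULATION = 0.1, FIDDLING = 0.1)
        r[names(w)] <- tot * w
      }
      r
    })
    perm <- sample.int(n_videos)
    list(video_seeds = video_seeds, rates = rates, perm = perm)
  })
  video_ids <- sprintf("v%03d", seq_len(n_videos))
  bundles <- vector("list", n_videos)
  names(bundles) <- video_ids
  for (i in seq_len(n_videos)) {
    cfg_args <- modifyList(
      list(seed = plan$video_seeds[i], event_rates = as.list(plan$rates[[i]])),
      dots
    )
    bundles[[i]] <- simulate_video(do.call(synthetic_config, cfg_args),
                                   video_id = video_ids[i])
  }
  events <- do.call(rbind, lapply(bundles, function(b) b$truth_events))
  rownames(events) <- NULL
  if (coupling == "none" && nrow(events) > 0L) {
    # Reassign whole event sets across videos: video i's annotations are
    # relabelled with a permuted id, severing the feature-score link.
    remap <- stats::setNames(video_ids[plan$perm], video_ids)
    events$video_id <- unname(remap[events$video_id])
  }
  structure(list(bundles = bundles, events = events, video_ids = video_ids,
                 coupling = coupling, seed = seed),
            class = "mtm_cohort")
}

#' @export
print.mtm_cohort <- function(x, ...) {
  cat(sprintf("<mtm_cohort> %d videos, %d truth events, coupling = %s\n",
              length(x$bundles), nrow(x$events), x$coupling))
  invisible(x)
}
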