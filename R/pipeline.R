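# Orchestration: landmark + annotation files -> per-video features and MTM
# scores -> correlation and group-comparison tables, with a JSON run
# manifest that makes per-video inclusion/exclusion auditable.

write_atomic_csv <- function(df, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".csv")
  data.table::fwrite(data.table::as.data.table(df), tmp, quote = FALSE,
                     showProgress = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

#' Analyse an in-memory synthetic cohort
#'
#' Runs the full analysis on a [make_cohort()] result: per-video feature
#' summaries, MTM scores from the truth annotations, the distance/score
#' correlation table and the shows-vs-no-shows area comparisons.
#'
#' @param cohort An `mtm_cohort` from [make_cohort()].
#' @param config A [feature_config()].
#' @return List with `features`, `scores`, `classification`,
#'   `correlations`, `comparisons`.
#' @export
analyze_cohort <- function(cohort, config = feature_config()) {
  stopifnot(inherits(cohort, "mtm_cohort"))
  features <- do.call(rbind, lapply(cohort$bundles, function(b) {
    summarize_video(b$series, config)
  }))
  rownames(features) <- NULL
  b1 <- cohort$bundles[[1L]]
  duration_s <- n_frames(b1$series) / b1$series$fps
  scores <- score_videos(cohort$events, duration_s = duration_s,
                         fps = b1$series$fps, video_ids = cohort$video_ids)
  list(features = features, scores = scores,
       classification = classify_videos(scores),
       correlations = correlate_features(features, scores),
       comparisons = compare_mtm_groups(features, scores))
}

#' Write a synthetic cohort to a directory tree
#'
#' One subdirectory per video holding its long-format landmark CSV, plus a
#' top-level `annotations.csv` and a `config.json` echo.
#'
#' @param cohort An `mtm_cohort` from [make_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "mtm_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (vid in names(cohort$bundles)) {
    vdir <- file.path(dir, vid)
    dir.create(vdir, showWarnings = FALSE)
    write_landmark_csv(cohort$bundles[[vid]]$series,
                       file.path(vdir, paste0(vid, ".csv")))
  }
  write_annotations(cohort$events, file.path(dir, "annotations.csv"))
  jsonlite::write_json(
    list(n_videos = length(cohort$bundles), seed = cohort$seed,
         coupling = cohort$coupling),
    file.path(dir, "config.json"), auto_unbox = TRUE
  )
  invisible(dir)
}

#' Run the full analysis over a directory of landmark files
#'
#' Reads every per-video landmark CSV under `landmark_dir` (searched
#' recursively; the file name stem is the video id), applies the exclusion
#' rules (unreadable/malformed coordinate files; videos whose invalid-frame
#' fraction exceeds the configured tolerance), scores the MTM annotations,
#' and runs the correlation and group-comparison analysis over the included
#' videos. All outputs are written atomically; identical inputs and
#' configuration give identical outputs.
#'
#' @param landmark_dir Directory containing per-video landmark CSVs.
#' @param annotation_file MTM annotation CSV ([read_annotations()] format).
#' @param output_dir Directory for the output tables and manifest.
#' @param config A [feature_config()].
#' @param fps Frames per second of the recordings (default 30).
#' @return Invisibly, a list with `features`, `scores`, `correlations`,
#'   `comparisons`, `manifest`. Side effects: `features.csv`, `scores.csv`,
#'   `correlations.csv`, `comparisons.csv`, `manifest.json` in `output_dir`.
#' @export
run_analysis <- function(landmark_dir, annotation_file, output_dir,
                         config = feature_config(), fps = 30) {
  files <- sort(list.files(landmark_dir, pattern = "\\.csv$",
                           full.names = TRUE, recursive = TRUE))
  files <- files[basename(files) != "annotations.csv"]
  if (length(files) == 0L) {
    stop_mtm(sprintf("no landmark CSV files under %s", landmark_dir),
             "mtmpose_io_error")
  }
  events <- read_annotations(annotation_file)

  status <- list()
  feats <- list()
  durations <- numeric(0)
  for (f in files) {
    vid <- sub("\\.[^.]*$", "", basename(f))
    res <- tryCatch({
      s <- read_landmark_csv(f, fps = fps,
                             visibility_threshold = config$visibility_threshold)
      sm <- summarize_video(s, config)
      if (!sm$usable) {
        list(status = "excluded", reason = "invalid_fraction_exceeded",
             summary = NULL, duration = NA_real_)
      } else {
        list(status = "included", reason = NA_character_, summary = sm,
             duration = n_frames(s) / fps)
      }
    }, mtmpose_no_data_error = function(e) {
      list(status = "excluded", reason = "no_valid_frames", summary = NULL,
           duration = NA_real_)
    }, mtmpose_error = function(e) {
      list(status = "excluded", reason = paste0("unreadable: ",
                                                conditionMessage(e)),
           summary = NULL, duration = NA_real_)
    })
    status[[vid]] <- list(file = f, status = res$status, reason = res$reason)
    if (res$status == "included") {
      feats[[vid]] <- res$summary
      durations[vid] <- res$duration
    }
  }
  if (length(feats) == 0L) {
    manifest <- build_manifest(files, annotation_file, config, fps, status, 0L)
    stop_mtm(paste0(
      "all videos were excluded: ",
      paste(vapply(names(status), function(v) {
        sprintf("%s (%s)", v, status[[v]]$reason)
      }, character(1)), collapse = "; ")
    ), "mtmpose_no_data_error")
  }
  features <- do.call(rbind, feats)
  rownames(features) <- NULL
  duration_s <- stats::median(durations)
  incl <- names(feats)
  scores <- score_videos(events[events$video_id %in% incl, , drop = FALSE],
                         duration_s = duration_s, fps = fps,
                         video_ids = incl)

  warns <- character(0)
  correlations <- tryCatch(
    correlate_features(features, scores),
    mtmpose_error = function(e) {
      warns <<- c(warns, paste0("correlations skipped: ",
                                conditionMessage(e)))
      empty_correlations()
    }
  )
  comparisons <- withCallingHandlers(
    tryCatch(
      compare_mtm_groups(features, scores),
      mtmpose_error = function(e) {
        warns <<- c(warns, paste0("comparisons skipped: ",
                                  conditionMessage(e)))
        empty_comparisons()
      }
    ),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )

  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  write_atomic_csv(features, file.path(output_dir, "features.csv"))
  write_atomic_csv(scores, file.path(output_dir, "scores.csv"))
  write_atomic_csv(correlations, file.path(output_dir, "correlations.csv"))
  write_atomic_csv(comparisons, file.path(output_dir, "comparisons.csv"))
  manifest <- build_manifest(files, annotation_file, config, fps, status,
                             length(incl), warns)
  tmp <- tempfile(tmpdir = output_dir, fileext = ".json")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  file.rename(tmp, file.path(output_dir, "manifest.json"))

  invisible(list(features = features, scores = scores,
                 correlations = correlations, comparisons = comparisons,
                 manifest = manifest))
}

empty_correlations <- function() {
  data.frame(landmark = character(0), metric = character(0), r = numeric(0),
             p = numeric(0), ci_low = numeric(0), ci_high = numeric(0),
             n = integer(0), significant = logical(0))
}

empty_comparisons <- function() {
  data.frame(category = character(0), measure = character(0),
             test = character(0), statistic = numeric(0), p = numeric(0),
             n_show = integer(0), n_noshow = integer(0),
             location_show = numeric(0), location_noshow = numeric(0))
}

build_manifest <- function(files, annotation_file, config, fps, status,
                           n_included, warnings = character(0)) {
  list(
    package = "mtmpose",
    version = as.character(utils::packageVersion("mtmpose")),
    fps = fps,
    config = unclass(config),
    inputs = lapply(stats::setNames(files, basename(files)), function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)))
    }),
    annotation_file = list(path = annotation_file,
                           md5 = unname(tools::md5sum(annotation_file))),
    videos = status,
    n_included = n_included,
    n_excluded = sum(vapply(status, function(s) s$status == "excluded",
                            logical(1))),
    warnings = warnings
  )
}
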