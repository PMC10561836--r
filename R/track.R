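#' Tracker configuration
#'
#' Greedy IoU-association tracking: detections are matched to live tracks
#' of the same class by highest IoU above the gate; unmatched detections
#' spawn tracks; tracks unseen for `max_age` frames retire. A track is
#' *confirmed* (and counted) once it has been matched in `min_hits`
#' frames.
#'
#' @param iou_gate Minimum IoU for associating a detection with a track.
#' @param min_hits Matched frames needed before a track counts.
#' @param max_age Consecutive missed frames before a track retires.
#' @return A `track_config` list.
#' @export
track_config <- function(iou_gate = 0.3, min_hits = 3L, max_age = 30L) {
  stopifnot(iou_gate > 0, iou_gate < 1, min_hits >= 1, max_age >= 1)
  structure(list(iou_gate = iou_gate, min_hits = as.integer(min_hits),
                 max_age = as.integer(max_age)),
            class = "track_config")
}

empty_tracks <- function() {
  tibble::tibble(track_id = integer(), class_id = integer(),
                 x1 = numeric(), y1 = numeric(), x2 = numeric(),
                 y2 = numeric(), hits = integer(), misses = integer(),
                 confirmed = logical())
}

new_track_state <- function(config = track_config()) {
  list(tracks = empty_tracks(), retired = empty_tracks(),
       next_id = 1L, config = config)
}

#' Advance the tracker by one frame
#'
#' Associates one frame's detections with the live tracks by greedy
#' highest-IoU matching above the gate (same class only, one detection per
#' track), spawns tracks for unmatched detections, increments misses on
#' unmatched tracks and retires those over `max_age`. Track ids are never
#' reused.
#'
#' @param state A tracker state from a previous call; pass `NULL` to
#'   start fresh.
#' @param detections One frame's detections (`x1, y1, x2, y2`, `class_id`,
#'   `confidence`).
#' @param config A [track_config()]; only read when `state` is `NULL`.
#' @return The updated state: `tracks` (live), `retired`, `next_id`,
#'   `config`.
#' @export
update_tracks <- function(state, detections, config = track_config()) {
  if (is.null(state)) state <- new_track_state(config)
  cfg <- state$config
  tracks <- state$tracks
  nd <- if (is.null(detections)) 0L else nrow(detections)
  matched_trk <- rep(FALSE, nrow(tracks))
  matched_det <- rep(FALSE, nd)
  if (nd > 0 && nrow(tracks) > 0) {
    db <- as_box_matrix(detections[, c("x1", "y1", "x2", "y2")])
    tb <- as_box_matrix(tracks[, c("x1", "y1", "x2", "y2")])
    iou <- box_iou(tb, db, pairwise = FALSE)
    iou[outer(tracks$class_id, detections$class_id, `!=`)] <- 0
    repeat {
      best <- which.max(iou)
      if (length(best) == 0L || iou[best] < cfg$iou_gate) break
      ti <- (best - 1L) %% nrow(tracks) + 1L
      di <- (best - 1L) %/% nrow(tracks) + 1L
      matched_trk[ti] <- TRUE; matched_det[di] <- TRUE
      tracks$x1[ti] <- detections$x1[di]; tracks$y1[ti] <- detections$y1[di]
      tracks$x2[ti] <- detections$x2[di]; tracks$y2[ti] <- detections$y2[di]
      tracks$hits[ti] <- tracks$hits[ti] + 1L
      tracks$misses[ti] <- 0L
      tracks$confirmed[ti] <- tracks$confirmed[ti] |
        tracks$hits[ti] >= cfg$min_hits
      iou[ti, ] <- -1; iou[, di] <- -1
    }
  }
  if (any(!matched_trk)) {
    tracks$misses[!matched_trk] <- tracks$misses[!matched_trk] + 1L
  }
  retire <- tracks$misses > cfg$max_age
  state$retired <- dplyr::bind_rows(state$retired, tracks[retire, ])
  tracks <- tracks[!retire, , drop = FALSE]
  if (nd > 0 && any(!matched_det)) {
    idx <- which(!matched_det)
    fresh <- tibble::tibble(
      track_id = state$next_id + seq_along(idx) - 1L,
      class_id = as.integer(detections$class_id[idx]),
      x1 = detections$x1[idx], y1 = detections$y1[idx],
      x2 = detections$x2[idx], y2 = detections$y2[idx],
      hits = 1L, misses = 0L, confirmed = cfg$min_hits <= 1L)
    state$next_id <- state$next_id + length(idx)
    tracks <- dplyr::bind_rows(tracks, fresh)
  }
  state$tracks <- tracks
  state
}

count_state <- function(state) {
  all_tracks <- dplyr::bind_rows(state$tracks, state$retired)
  confirmed <- all_tracks[all_tracks$confirmed, , drop = FALSE]
  dplyr::count(confirmed, .data$class_id, name = "count")
}

#' Track a sequence of per-frame detections and count unique targets
#'
#' Pure tracking/counting on already-computed detections: runs
#' [update_tracks()] over the frames and reports, per class, the number of
#' distinct confirmed track ids ever created — the unique-target count.
#'
#' @param detections_by_frame List of per-frame detection tibbles.
#' @param config A [track_config()].
#' @return A `count_report`: `per_class` counts, `total`, `frames`, and
#'   the non-decreasing `count_trace` over frames.
#' @export
track_sequence <- function(detections_by_frame, config = track_config()) {
  state <- new_track_state(config)
  trace <- integer(length(detections_by_frame))
  for (f in seq_along(detections_by_frame)) {
    state <- update_tracks(state, detections_by_frame[[f]])
    trace[f] <- sum(count_state(state)$count)
  }
  per_class <- count_state(state)
  structure(list(per_class = per_class, total = sum(per_class$count),
                 frames = length(detections_by_frame),
                 count_trace = trace, config = config),
            class = "count_report")
}

#' Detect, track and count fruit across a video
#'
#' Runs the detector on every frame of an image-sequence video, associates
#' detections into tracks, and reports unique confirmed-track counts per
#' class together with the measured detection speed.
#'
#' @param model A trained `fruit_detector`.
#' @param video A directory of `frame_*.png` files, or a list of frame
#'   arrays.
#' @param config A [track_config()].
#' @param conf_threshold Detection confidence threshold.
#' @return A `count_report` with a `speed` element ([speed_report()]).
#' @export
count_video <- function(model, video, config = track_config(),
                        conf_threshold = 0.25) {
  frames <- if (is.character(video)) {
    if (!dir.exists(video)) abort(sprintf("no such video directory: %s", video))
    paths <- sort(list.files(video, pattern = "^frame_.*\\.png$",
                             full.names = TRUE))
    if (length(paths) == 0L) abort(sprintf("no frames found in %s", video))
    lapply(paths, read_image)
  } else video
  t0 <- proc.time()[["elapsed"]]
  dets <- lapply(frames, function(fr) {
    predict_image(model, fr, conf_threshold = conf_threshold)
  })
  elapsed <- proc.time()[["elapsed"]] - t0
  report <- track_sequence(dets, config)
  report$speed <- speed_report(length(frames), elapsed)
  report
}

#' @export
print.count_report <- function(x, ...) {
  cat(sprintf("<count_report> %d unique confirmed targets over %d frames\n",
              x$total, x$frames))
  print(x$per_class)
  if (!is.null(x$speed)) print(x$speed)
  invisible(x)
}

#' @method tidy count_report
#' @export
tidy.count_report <- function(x, ...) x$per_class

#' @method glance count_report
#' @export
glance.count_report <- function(x, ...) {
  tibble::tibble(total = x$total, frames = x$frames,
                 fps = if (!is.null(x$speed)) x$speed$fps else NA_real_)
}

#' @method autoplot count_report
#' @export
autoplot.count_report <- function(object, ...) {
  df <- tibble::tibble(frame = seq_along(object$count_trace),
                       count = object$count_trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frame, y = .data$count)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Frame", y = "Unique confirmed targets",
                  title = "Cumulative target count")
}

#' Frames-per-second accounting
#'
#' @param frames Number of frames processed.
#' @param elapsed_seconds Wall time spent.
#' @return A one-row tibble with `frames`, `elapsed_seconds` and
#'   `fps = frames / elapsed_seconds`.
#' @export
speed_report <- function(frames, elapsed_seconds) {
  tibble::tibble(frames = as.integer(frames),
                 elapsed_seconds = elapsed_seconds,
                 fps = frames / elapsed_seconds)
}
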