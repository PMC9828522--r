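#' Construct a reference annotation track
#'
#' A track of manually coded smile intervals for one session, as produced by
#' trained FACS coders who mark the onset and cessation frame of each distinct
#' smiling episode. Frame bounds are 0-based and inclusive on both ends.
#' Intervals must not overlap; coders work under the convention that distinct
#' episodes are separated by a smile-free period of at least two seconds, so
#' when `fps` is supplied a separation shorter than `ceiling(2 * fps)` frames
#' raises a warning.
#'
#' @param intervals Data frame with integer columns `onset_frame` and
#'   `offset_frame` (`offset_frame >= onset_frame`). Rows are sorted by onset.
#' @param session_id Character session identifier.
#' @param fps Optional frame rate, used only for the separation check.
#' @param min_separation_s Minimum smile-free separation in seconds used for
#'   that check (default 2).
#' @return An object of class `annotation_track`.
#' @export
annotation_track <- function(intervals, session_id = "session", fps = NULL,
                             min_separation_s = 2) {
  intervals <- tibble::as_tibble(intervals)
  if (nrow(intervals) == 0L) {
    intervals <- tibble::tibble(onset_frame = integer(), offset_frame = integer())
  }
  if (!all(c("onset_frame", "offset_frame") %in% names(intervals))) {
    stop("annotation intervals need onset_frame and offset_frame columns",
         call. = FALSE)
  }
  intervals$onset_frame <- as.integer(intervals$onset_frame)
  intervals$offset_frame <- as.integer(intervals$offset_frame)
  if (any(intervals$onset_frame < 0L)) {
    stop("onset_frame must be >= 0", call. = FALSE)
  }
  bad <- which(intervals$offset_frame < intervals$onset_frame)
  if (length(bad) > 0L) {
    stop(sprintf("interval %d has offset_frame < onset_frame", bad[1L]),
         call. = FALSE)
  }
  intervals <- intervals[order(intervals$onset_frame), , drop = FALSE]
  if (nrow(intervals) >= 2L) {
    gap <- intervals$onset_frame[-1L] - intervals$offset_frame[-nrow(intervals)] - 1L
    if (any(gap < 1L)) {
      stop("reference smile intervals overlap", call. = FALSE)
    }
    if (!is.null(fps) && any(gap < ceiling(min_separation_s * fps))) {
      warning(sprintf(
        "reference intervals separated by less than %g s at %g fps",
        min_separation_s, fps), call. = FALSE)
    }
  }
  structure(list(session_id = as.character(session_id), intervals = intervals),
            class = "annotation_track")
}

#' @export
print.annotation_track <- function(x, ...) {
  cat(sprintf("<annotation_track> session '%s': %d reference smile interval(s)\n",
              x$session_id, nrow(x$intervals)))
  invisible(x)
}

#' Read manually coded smile intervals
#'
#' Expects a CSV with columns `session_id`, `onset_frame`, `offset_frame`
#' (0-based inclusive frame indices). A seconds-based dialect with columns
#' `onset_s`/`offset_s` is also accepted when `fps` is supplied; times are
#' converted by rounding to the nearest frame. An empty body yields an empty
#' track — a session in which the coders saw no smiles is legal.
#'
#' @param file Path or connection.
#' @param fps Frame rate, required only for the seconds dialect.
#' @param session_id Used when the file holds no `session_id` column or an
#'   empty body.
#' @return An [annotation_track()]; if the file contains several sessions, a
#'   named list of tracks.
#' @export
read_annotations <- function(file, fps = NULL, session_id = "session") {
  raw <- utils::read.csv(file, check.names = FALSE, strip.white = TRUE)
  names(raw) <- trimws(names(raw))
  if (all(c("onset_s", "offset_s") %in% names(raw)) &&
      !all(c("onset_frame", "offset_frame") %in% names(raw))) {
    if (is.null(fps)) {
      stop("annotations are given in seconds; supply fps to convert to frames",
           call. = FALSE)
    }
    raw$onset_frame <- as.integer(round(raw$onset_s * fps))
    raw$offset_frame <- as.integer(round(raw$offset_s * fps))
  }
  if (!all(c("onset_frame", "offset_frame") %in% names(raw))) {
    stop("annotation CSV needs onset_frame/offset_frame (or onset_s/offset_s) columns",
         call. = FALSE)
  }
  if (!"session_id" %in% names(raw)) raw$session_id <- session_id
  if (nrow(raw) == 0L) {
    return(annotation_track(raw[, c("onset_frame", "offset_frame")],
                            session_id = session_id, fps = fps))
  }
  tracks <- lapply(split(raw, raw$session_id), function(d) {
    annotation_track(d[, c("onset_frame", "offset_frame")],
                     session_id = d$session_id[1L], fps = fps)
  })
  if (length(tracks) == 1L) tracks[[1L]] else tracks
}

#' Expand reference intervals to frame-wise labels
#'
#' Converts interval annotations into the per-frame boolean reference used by
#' the frame-wise ROC analysis: frame `i` (0-based) is labelled `TRUE` iff it
#' lies inside some reference interval (inclusive bounds). The number of
#' `TRUE` labels therefore equals the summed interval lengths.
#'
#' @param track An [annotation_track()].
#' @param n_frames Total frame count of the session.
#' @return Logical vector of length `n_frames`; element `i + 1` refers to
#'   frame `i`.
#' @export
frame_labels <- function(track, n_frames) {
  stopifnot(inherits(track, "annotation_track"))
  n_frames <- as.integer(n_frames)
  iv <- track$intervals
  if (nrow(iv) > 0L && any(iv$offset_frame >= n_frames)) {
    stop("reference interval extends beyond the end of the series",
         call. = FALSE)
  }
  labels <- logical(n_frames)
  for (k in seq_len(nrow(iv))) {
    labels[(iv$onset_frame[k] + 1L):(iv$offset_frame[k] + 1L)] <- TRUE
  }
  labels
}

.task_names <- c("speaking", "yawning", "coughing", "mouth_covering",
                 "anger", "sadness", "fear", "surprise", "disgust",
                 "smiling", "neutral")

#' Construct a task-event schedule
#'
#' Post-video confounder tasks — jaw movements and posed expressions designed
#' to probe false-positive smile detection (speaking, yawning, coughing,
#' mouth covering, five posed negative emotions, posed smiling and neutral).
#' Events carry half-open time spans `[start, end)` on the session clock and
#' must not overlap.
#'
#' @param events Data frame with columns `name`, `start_s`, `end_s`.
#' @return A tibble of events sorted by start time, classed `task_events`.
#' @export
task_events <- function(events) {
  events <- tibble::as_tibble(events)
  need <- c("name", "start_s", "end_s")
  if (!all(need %in% names(events))) {
    stop("task schedule needs name, start_s and end_s columns", call. = FALSE)
  }
  events$name <- as.character(events$name)
  bad <- setdiff(unique(events$name), .task_names)
  if (length(bad) > 0L) {
    stop("unknown task name(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(events$end_s <= events$start_s)) {
    stop("task events must have end_s > start_s", call. = FALSE)
  }
  events <- events[order(events$start_s), , drop = FALSE]
  if (nrow(events) >= 2L &&
      any(events$start_s[-1L] < events$end_s[-nrow(events)])) {
    stop("task events overlap in time", call. = FALSE)
  }
  class(events) <- c("task_events", class(events))
  events
}

#' Read a task schedule CSV
#'
#' @param file Path or connection to a CSV with columns `name`, `start_s`,
#'   `end_s`.
#' @return A [task_events()] tibble.
#' @export
read_task_schedule <- function(file) {
  raw <- utils::read.csv(file, check.names = FALSE, strip.white = TRUE)
  names(raw) <- trimws(names(raw))
  task_events(raw)
}
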