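#' Construct an AU time series
#'
#' The central container of the package: one recording session's per-frame
#' facial action unit (AU) record. Holds a frame table with the session time
#' base plus the three smile-relevant AUs — AU6 ("cheek raiser", the Duchenne
#' marker of smile genuineness), AU12 ("lip corner puller", smile intensity),
#' both on the 0-5 FACS intensity scale, and the dichotomous AU25 ("lips
#' apart", teeth visible).
#'
#' Frame indices are 0-based and must be contiguous. Timestamps are frame
#' start times in seconds and must be strictly increasing; a frame spans
#' `[t, t + 1/fps)`, so all interval arithmetic downstream is half-open in
#' time and inclusive in frames.
#'
#' @param frames Data frame with columns `frame` (0-based contiguous integer),
#'   `timestamp` (seconds), `confidence` (0-1), `success` (logical; `FALSE`
#'   marks frames where face tracking failed), `au6`, `au12` (0-5 intensity)
#'   and `au25` (logical).
#' @param session_id Character scalar identifying the session.
#' @param fps Frames per second. Inferred from the timestamps (see
#'   [infer_frame_rate()]) when `NULL`; a supplied value must agree with the
#'   inferred one within 1%.
#' @param frame_origin Integer offset of the `frame` column in the source file
#'   (OpenFace numbers frames from 1); kept so a write/read round trip is the
#'   identity.
#' @return An object of class `au_timeseries`: a list with elements
#'   `session_id`, `frames` (tibble), `fps` and `frame_origin`.
#' @seealso [read_au_csv()], [detect()]
#' @export
au_timeseries <- function(frames, session_id = "session", fps = NULL,
                          frame_origin = 0L) {
  frames <- tibble::as_tibble(frames)
  required <- c("frame", "timestamp", "confidence", "success",
                "au6", "au12", "au25")
  missing <- setdiff(required, names(frames))
  if (length(missing) > 0L) {
    stop("frames table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(frames) == 0L) {
    stop("an AU time series must contain at least one frame", call. = FALSE)
  }
  frames$frame <- as.integer(frames$frame)
  frames$success <- as.logical(frames$success)
  frames$au25 <- as.logical(frames$au25)
  if (frames$frame[1L] != 0L || any(diff(frames$frame) != 1L)) {
    stop("frame indices must be contiguous and 0-based", call. = FALSE)
  }
  if (any(diff(frames$timestamp) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  if (any(frames$au6 < 0 | frames$au6 > 5) ||
      any(frames$au12 < 0 | frames$au12 > 5)) {
    stop("AU6 and AU12 intensities must lie in [0, 5]", call. = FALSE)
  }
  inferred <- if (nrow(frames) >= 2L) 1 / stats::median(diff(frames$timestamp))
              else NULL
  if (is.null(fps)) {
    if (is.null(inferred)) {
      stop("fps must be supplied for a single-frame series", call. = FALSE)
    }
    fps <- inferred
  } else if (!is.null(inferred) && abs(fps - inferred) > 0.01 * inferred) {
    stop(sprintf(
      "supplied fps (%.4g) disagrees with the timestamp spacing (%.4g) by more than 1%%",
      fps, inferred), call. = FALSE)
  }
  structure(
    list(session_id = as.character(session_id), frames = frames,
         fps = fps, frame_origin = as.integer(frame_origin)),
    class = "au_timeseries")
}

#' @export
print.au_timeseries <- function(x, ...) {
  cat(sprintf("<au_timeseries> session '%s': %d frames @ %.4g fps (%.1f s)\n",
              x$session_id, nrow(x$frames), x$fps,
              nrow(x$frames) / x$fps))
  n_bad <- sum(!x$frames$success)
  if (n_bad > 0L) cat(sprintf("  %d frame(s) with failed face tracking\n", n_bad))
  invisible(x)
}

#' Number of frames in an AU time series
#' @param ts An `au_timeseries`.
#' @return Integer frame count.
#' @export
n_frames <- function(ts) {
  stopifnot(inherits(ts, "au_timeseries"))
  nrow(ts$frames)
}

#' Session length in seconds
#'
#' Total spanned time of the series: frame count divided by the frame rate
#' (each frame occupies `1/fps` seconds).
#'
#' @param ts An `au_timeseries`.
#' @return Length in seconds.
#' @export
session_length <- function(ts) {
  n_frames(ts) / ts$fps
}

# OpenFace writes headers with a leading space (" timestamp"); match after
# trimming.
.openface_col <- function(header, name) {
  i <- which(trimws(header) == name)
  if (length(i) == 0L) NA_integer_ else i[1L]
}

#' Read an AU time series from an OpenFace output CSV
#'
#' Parses the OpenFace CSV dialect: comma-separated with a header row whose
#' names may carry surrounding whitespace. At minimum the columns `frame`,
#' `timestamp`, `success`, `AU06_r`, `AU12_r` and `AU25_c` must be present;
#' `confidence` is used when available and all other columns (landmarks, gaze,
#' head pose, other AUs) are ignored. The dichotomous `AU25_c` column is
#' authoritative for teeth visibility (values >= 0.5 map to `TRUE`); a
#' continuous `AU25_r` column, if present, is ignored.
#'
#' Frames with `success == 0` (face not tracked) are retained, so the session
#' time base stays intact, but are marked invalid and treated as sub-threshold
#' by the detector.
#'
#' @param file Path to (or connection for) the CSV file.
#' @param session_id Session identifier; defaults to the file name without
#'   extension.
#' @return An [au_timeseries()].
#' @examples
#' csv <- tempfile(fileext = ".csv")
#' writeLines(c("frame, timestamp, confidence, success, AU06_r, AU12_r, AU25_c",
#'              "1, 0.000, 0.98, 1, 0.0, 0.1, 0",
#'              "2, 0.033, 0.98, 1, 0.6, 2.0, 1",
#'              "3, 0.067, 0.98, 1, 0.0, 0.2, 0"), csv)
#' ts <- read_au_csv(csv, session_id = "demo")
#' ts$frames$au6
#' @export
read_au_csv <- function(file, session_id = NULL) {
  if (is.null(session_id)) {
    session_id <- if (is.character(file)) {
      sub("\\.[^.]*$", "", basename(file))
    } else "session"
  }
  raw <- utils::read.csv(file, check.names = FALSE, strip.white = TRUE)
  header <- names(raw)
  required <- c("frame", "timestamp", "success", "AU06_r", "AU12_r", "AU25_c")
  idx <- vapply(required, .openface_col, integer(1), header = header)
  if (anyNA(idx)) {
    stop("input is not in the OpenFace dialect: missing required column(s) ",
         paste(required[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  conf_idx <- .openface_col(header, "confidence")
  frame_raw <- as.integer(raw[[idx[["frame"]]]])
  if (length(frame_raw) == 0L) {
    stop("AU CSV contains a header but no frames", call. = FALSE)
  }
  origin <- frame_raw[1L]
  frames <- tibble::tibble(
    frame = frame_raw - origin,
    timestamp = as.numeric(raw[[idx[["timestamp"]]]]),
    confidence = if (!is.na(conf_idx)) as.numeric(raw[[conf_idx]]) else 1,
    success = as.numeric(raw[[idx[["success"]]]]) >= 0.5,
    au6 = as.numeric(raw[[idx[["AU06_r"]]]]),
    au12 = as.numeric(raw[[idx[["AU12_r"]]]]),
    au25 = as.numeric(raw[[idx[["AU25_c"]]]]) >= 0.5)
  if (any(diff(frames$timestamp) <= 0)) {
    stop(sprintf("timestamps in '%s' are not strictly increasing",
                 session_id), call. = FALSE)
  }
  au_timeseries(frames, session_id = session_id, frame_origin = origin)
}

#' Infer the frame rate of a series from its timestamps
#'
#' The frame rate is the reciprocal of the median inter-frame timestamp
#' difference; the median makes the estimate robust to isolated dropped
#' frames. This sets the temporal resolution of all episode onsets and
#' durations (one frame = `1/fps` seconds).
#'
#' @param x An `au_timeseries` or a numeric vector of timestamps (seconds).
#' @return Frames per second.
#' @export
infer_frame_rate <- function(x) {
  ts <- if (inherits(x, "au_timeseries")) x$frames$timestamp else as.numeric(x)
  if (length(ts) < 2L) {
    stop("at least two frames are required to infer a frame rate",
         call. = FALSE)
  }
  1 / stats::median(diff(ts))
}

#' Write an AU time series as an OpenFace-dialect CSV
#'
#' Writes `frame, timestamp, confidence, success, AU06_r, AU12_r, AU25_c`.
#' Numeric fields are written with 17 significant digits so that reading the
#' file back reproduces every modelled field exactly (round-trip identity).
#' The frame column is restored to the origin recorded at read time.
#'
#' @param ts An [au_timeseries()].
#' @param file Path or connection to write to.
#' @return `ts`, invisibly.
#' @export
write_au_csv <- function(ts, file) {
  stopifnot(inherits(ts, "au_timeseries"))
  if (nrow(ts$frames) == 0L) {
    stop("refusing to write an AU CSV with no frames", call. = FALSE)
  }
  f <- ts$frames
  num <- function(x) sprintf("%.17g", x)
  out <- data.frame(
    frame = f$frame + ts$frame_origin,
    timestamp = num(f$timestamp),
    confidence = num(f$confidence),
    success = as.integer(f$success),
    AU06_r = num(f$au6),
    AU12_r = num(f$au12),
    AU25_c = as.integer(f$au25),
    check.names = FALSE)
  utils::write.csv(out, file, row.names = FALSE, quote = FALSE)
  invisible(ts)
}
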