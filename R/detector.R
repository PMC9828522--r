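#' Detection configuration
#'
#' The three tunables of the episode detector. A frame counts as smiling when
#' the cheek raiser intensity exceeds `th1` AND the lip corner puller
#' intensity exceeds `th2` (strict inequalities, 0-5 FACS scale). An episode
#' ends when either AU stays sub-threshold for at least the stand-by time;
#' equivalently, smile runs separated by a sub-threshold gap strictly shorter
#' than `standby` are merged into one episode. The defaults 0.5 / 1.5 are the
#' operating point selected by Youden-index calibration against manual coding;
#' the 2 s stand-by mirrors the coders' rule that distinct episodes are
#' separated by at least two smile-free seconds.
#'
#' @param th1 AU6 activation threshold (genuineness / Duchenne marker),
#'   in `[0, 5]`. Default 0.5.
#' @param th2 AU12 activation threshold (smile intensity), in `[0, 5]`.
#'   Default 1.5.
#' @param standby Stand-by time in seconds (> 0). Default 2.
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(th1 = 0.5, th2 = 1.5, standby = 2) {
  if (th1 < 0 || th1 > 5 || th2 < 0 || th2 > 5) {
    stop("thresholds must lie in [0, 5]", call. = FALSE)
  }
  if (standby <= 0) stop("standby must be positive", call. = FALSE)
  structure(list(th1 = th1, th2 = th2, standby = standby),
            class = "detection_config")
}

#' @export
print.detection_config <- function(x, ...) {
  cat(sprintf("<detection_config> AU6 > %g, AU12 > %g, stand-by %g s\n",
              x$th1, x$th2, x$standby))
  invisible(x)
}

#' Frame-wise smile classification
#'
#' Applies the dual-threshold rule to every frame: smiling iff
#' `au6 > th1` and `au12 > th2` and the frame is valid (face tracking
#' succeeded). Invalid frames are conservatively treated as not smiling.
#'
#' @param ts An [au_timeseries()].
#' @param config A [detection_config()].
#' @return Logical vector, one element per frame.
#' @export
classify_frames <- function(ts, config = detection_config()) {
  stopifnot(inherits(ts, "au_timeseries"), inherits(config, "detection_config"))
  f <- ts$frames
  f$au6 > config$th1 & f$au12 > config$th2 & f$success
}

#' Segment a boolean smile signal into episodes
#'
#' Finds maximal runs of smiling frames and applies the stand-by merge rule:
#' two consecutive runs separated by a sub-threshold gap of duration
#' `gap_frames / fps` strictly less than `standby` seconds are merged into a
#' single episode, with the gap frames absorbed into its span. A gap of
#' exactly `standby` seconds separates episodes. Onset and offset are the
#' first and last smiling frame of the merged group.
#'
#' @param smile Logical vector (frame-wise smile classification).
#' @param fps Frames per second (> 0).
#' @param standby Stand-by time in seconds (> 0).
#' @return Tibble with 0-based inclusive columns `onset` and `offset`, one
#'   row per episode, in temporal order.
#' @export
segment_episodes <- function(smile, fps, standby = 2) {
  stopifnot(is.logical(smile), fps > 0, standby > 0)
  if (length(smile) == 0L || !any(smile)) {
    return(tibble::tibble(onset = integer(), offset = integer()))
  }
  r <- rle(smile)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  run_on <- starts[r$values] # 1-based positions of TRUE runs
  run_off <- ends[r$values]
  onset <- run_on[1L]
  offset <- run_off[1L]
  out_on <- integer()
  out_off <- integer()
  for (k in seq_along(run_on)[-1L]) {
    gap_frames <- run_on[k] - offset - 1L
    if (gap_frames / fps < standby) {
      offset <- run_off[k]
    } else {
      out_on <- c(out_on, onset)
      out_off <- c(out_off, offset)
      onset <- run_on[k]
      offset <- run_off[k]
    }
  }
  out_on <- c(out_on, onset)
  out_off <- c(out_off, offset)
  tibble::tibble(onset = out_on - 1L, offset = out_off - 1L)
}

#' Quantify one smile episode
#'
#' Computes the per-episode outcome measures over the inclusive frame span
#' `[onset_frame, offset_frame]` (0-based): mean AU6 activation (genuineness),
#' mean AU12 activation (intensity), and tooth show — the percentage of the
#' episode's frames on which AU25 (lips apart) is active. Frames absorbed from
#' merged sub-threshold gaps are part of the span and enter all denominators;
#' the averages run across the entire episode. Onset time is the timestamp of
#' the onset frame and duration is the frame count divided by the frame rate,
#' so both have a resolution of one frame.
#'
#' @param ts An [au_timeseries()].
#' @param onset_frame,offset_frame 0-based inclusive frame span.
#' @return One-row tibble with `onset_frame`, `offset_frame`, `onset_time`,
#'   `duration`, `mean_au6`, `mean_au12`, `tooth_show`.
#' @export
episode_metrics <- function(ts, onset_frame, offset_frame) {
  stopifnot(inherits(ts, "au_timeseries"))
  n <- n_frames(ts)
  if (onset_frame < 0L || offset_frame < onset_frame || offset_frame >= n) {
    stop("episode span lies outside the series", call. = FALSE)
  }
  pos <- (onset_frame + 1L):(offset_frame + 1L)
  f <- ts$frames[pos, ]
  tibble::tibble(
    onset_frame = as.integer(onset_frame),
    offset_frame = as.integer(offset_frame),
    onset_time = f$timestamp[1L],
    duration = length(pos) / ts$fps,
    mean_au6 = mean(f$au6),
    mean_au12 = mean(f$au12),
    tooth_show = 100 * mean(f$au25))
}

#' Detect smile episodes in a session
#'
#' The full detection pipeline: frame-wise dual-threshold classification,
#' stand-by segmentation/merging, and per-episode quantification. Analysis
#' can be restricted to a window of the recording via 0-based inclusive
#' `start_frame`/`end_frame`; episodes truncated by the window edges are
#' retained (no minimum-duration filter is applied).
#'
#' @param ts An [au_timeseries()].
#' @param config A [detection_config()].
#' @param start_frame,end_frame Optional analysis window (0-based inclusive
#'   frame indices); defaults cover the whole series.
#' @return A tibble of class `smile_episodes` with one row per episode:
#'   `index` (progressive count), `onset_frame`, `offset_frame`, `onset_time`,
#'   `duration`, `mean_au6`, `mean_au12`, `tooth_show`. Attributes carry the
#'   session id, fps and configuration.
#' @examples
#' cfg <- synthetic_config(seed = 42, session_length = 60)
#' sess <- simulate_session(cfg)
#' detect(sess$series)
#' @export
detect <- function(ts, config = detection_config(),
                   start_frame = NULL, end_frame = NULL) {
  stopifnot(inherits(ts, "au_timeseries"))
  n <- n_frames(ts)
  if (is.null(start_frame)) start_frame <- 0L
  if (is.null(end_frame)) end_frame <- n - 1L
  start_frame <- as.integer(start_frame)
  end_frame <- as.integer(end_frame)
  if (start_frame < 0L || end_frame >= n || end_frame < start_frame) {
    stop("analysis window lies outside the series", call. = FALSE)
  }
  smile <- classify_frames(ts, config)[(start_frame + 1L):(end_frame + 1L)]
  spans <- segment_episodes(smile, ts$fps, config$standby)
  rows <- lapply(seq_len(nrow(spans)), function(k) {
    episode_metrics(ts, spans$onset[k] + start_frame,
                    spans$offset[k] + start_frame)
  })
  episodes <- if (length(rows) > 0L) do.call(rbind, rows) else
    episode_metrics(ts, 0L, 0L)[0L, ]
  episodes <- tibble::add_column(episodes,
                                 index = seq_len(nrow(episodes)),
                                 .before = 1L)
  structure(episodes,
            class = c("smile_episodes", class(episodes)),
            session_id = ts$session_id, fps = ts$fps, config = config,
            window = c(start_frame, end_frame))
}

#' Summarise a session's smile episodes
#'
#' Session-level outcome measures: episode count, episodes per minute, mean
#' episode duration, relative smile time (the summed episode durations as a
#' percentage of the session length), and unweighted means of the per-episode
#' genuineness (AU6), intensity (AU12) and tooth-show metrics. With zero
#' episodes the rate metrics are 0 and the means are `NA` (undefined).
#'
#' @param episodes A tibble of detected episodes (from [detect()]).
#' @param session_length Session length in seconds (> 0); defaults to the
#'   window length recorded on `episodes` when available.
#' @return A list of class `session_summary`.
#' @export
summarize_session <- function(episodes, session_length = NULL) {
  if (is.null(session_length)) {
    w <- attr(episodes, "window")
    fps <- attr(episodes, "fps")
    if (is.null(w) || is.null(fps)) {
      stop("session_length must be supplied", call. = FALSE)
    }
    session_length <- (w[2L] - w[1L] + 1L) / fps
  }
  if (session_length <= 0) stop("session_length must be positive", call. = FALSE)
  n <- nrow(episodes)
  if (n > 0L && sum(episodes$duration) > session_length + 1e-9) {
    stop("episodes exceed the stated session length", call. = FALSE)
  }
  structure(list(
    n_episodes = n,
    episodes_per_minute = n / (session_length / 60),
    mean_duration = if (n > 0L) mean(episodes$duration) else NA_real_,
    relative_smile_time = 100 * sum(episodes$duration) / session_length,
    mean_au6 = if (n > 0L) mean(episodes$mean_au6) else NA_real_,
    mean_au12 = if (n > 0L) mean(episodes$mean_au12) else NA_real_,
    mean_tooth_show = if (n > 0L) mean(episodes$tooth_show) else NA_real_,
    session_length = session_length),
    class = "session_summary")
}

#' @export
print.session_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "<session_summary> %.1f s analysed\n",
    "  episodes: %d (%.2f per minute)\n",
    "  mean duration: %s s; relative smile time: %.1f%%\n",
    "  genuineness (AU6): %s; intensity (AU12): %s; tooth show: %s%%\n"),
    x$session_length, x$n_episodes, x$episodes_per_minute,
    .fmt(x$mean_duration), x$relative_smile_time,
    .fmt(x$mean_au6), .fmt(x$mean_au12), .fmt(x$mean_tooth_show)))
  invisible(x)
}

.fmt <- function(x) if (is.na(x)) "NA" else sprintf("%.2f", x)

#' Write detected episodes to CSV
#'
#' @param episodes A `smile_episodes` tibble from [detect()].
#' @param file Path or connection.
#' @return `episodes`, invisibly.
#' @export
write_episodes_csv <- function(episodes, file) {
  out <- as.data.frame(episodes)
  out <- cbind(session_id = attr(episodes, "session_id") %||% "session", out)
  names(out)[names(out) == "onset_time"] <- "onset_time_s"
  names(out)[names(out) == "duration"] <- "duration_s"
  names(out)[names(out) == "tooth_show"] <- "tooth_show_pct"
  utils::write.csv(out, file, row.names = FALSE, quote = FALSE)
  invisible(episodes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
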