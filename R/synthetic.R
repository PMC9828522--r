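#' Configuration of the synthetic session generator
#'
#' Full generative specification for a simulated recording session with known
#' ground truth. Defaults reproduce the study conditions of a spontaneous
#' smiling experiment: 30 fps video, a 264 s amusing stimulus, 1.6 smile
#' episodes per minute lasting 11.3 +/- 5.6 s, AU6/AU12 apex activations of
#' about 1.3 and 2.2 around the detection boundaries 0.5 and 1.5, and teeth
#' visible on 47.2% of smile frames.
#'
#' Episode trajectories are trapezoids: a linear onset ramp of `ramp` seconds
#' up to the apex, a plateau, and a linear offset ramp back to baseline. Each
#' episode's AU6 and AU12 apexes are jittered independently (uniform,
#' `+/- apex_jitter` relative) and each AU's onset/offset is shifted
#' independently by up to `timing_jitter` seconds, so the two AUs rise and
#' fall near-synchronously but not collinearly — as in real smiles, where the
#' Duchenne marker does not track lip-corner pull exactly. This
#' desynchronisation is what makes the two detection thresholds separately
#' identifiable by the calibration grid.
#'
#' @param seed Integer RNG seed; identical configurations reproduce sessions
#'   bit for bit.
#' @param fps Frames per second (default 30).
#' @param session_length Stimulus length in seconds (default 264).
#' @param episode_rate Expected smile episodes per minute (default 1.6).
#' @param duration_mean,duration_sd Episode duration moments in seconds
#'   (defaults 11.3, 5.6); durations are drawn from a log-normal law matched
#'   to these moments and truncated to the feasible range.
#' @param au6_boundary,au12_boundary Generative detection boundaries on the
#'   0-5 scale (defaults 0.5 and 1.5): noise-free trajectories exceed them
#'   inside ground-truth smile intervals and stay below outside.
#' @param au6_apex,au12_apex Nominal apex activations (defaults 1.3, 2.2).
#' @param ramp Onset/offset ramp time in seconds (default 0.5).
#' @param apex_jitter Relative apex jitter per episode and AU (default 0.2).
#' @param timing_jitter Onset/offset time jitter per episode and AU in
#'   seconds (default 0.25).
#' @param baseline_frac Baseline activation is uniform on
#'   `[0, baseline_frac * boundary]` (default 0.6).
#' @param noise_sd Additive Gaussian frame noise, intensity units
#'   (default 0.1); results are clipped to `[0, 5]`.
#' @param tooth_show_prob Probability a smile frame shows teeth (AU25;
#'   default 0.472).
#' @param tasks Append the post-video confounder task schedule
#'   (default `FALSE`).
#' @param session_id Session identifier; derived from the seed when `NULL`.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L, fps = 30, session_length = 264,
                             episode_rate = 1.6,
                             duration_mean = 11.3, duration_sd = 5.6,
                             au6_boundary = 0.5, au12_boundary = 1.5,
                             au6_apex = 1.3, au12_apex = 2.2,
                             ramp = 0.5, apex_jitter = 0.2,
                             timing_jitter = 0.25, baseline_frac = 0.6,
                             noise_sd = 0.1, tooth_show_prob = 0.472,
                             tasks = FALSE, session_id = NULL) {
  stopifnot(fps > 0, session_length > 0, episode_rate >= 0,
            duration_mean > 0, duration_sd >= 0,
            noise_sd >= 0, ramp > 0,
            apex_jitter >= 0, apex_jitter < 1,
            timing_jitter >= 0, baseline_frac >= 0, baseline_frac < 1,
            tooth_show_prob >= 0, tooth_show_prob <= 1)
  if (au6_boundary < 0 || au6_boundary > 5 ||
      au12_boundary < 0 || au12_boundary > 5) {
    stop("AU boundaries must lie in [0, 5]", call. = FALSE)
  }
  if (au6_apex * (1 - apex_jitter) <= au6_boundary ||
      au12_apex * (1 - apex_jitter) <= au12_boundary) {
    stop("apex activations must exceed the boundaries even at maximal downward jitter",
         call. = FALSE)
  }
  if (is.null(session_id)) session_id <- sprintf("synth_%d", seed)
  structure(list(
    seed = as.integer(seed), fps = fps, session_length = session_length,
    episode_rate = episode_rate, duration_mean = duration_mean,
    duration_sd = duration_sd, au6_boundary = au6_boundary,
    au12_boundary = au12_boundary, au6_apex = au6_apex,
    au12_apex = au12_apex, ramp = ramp, apex_jitter = apex_jitter,
    timing_jitter = timing_jitter, baseline_frac = baseline_frac,
    noise_sd = noise_sd, tooth_show_prob = tooth_show_prob,
    tasks = isTRUE(tasks), session_id = session_id),
    class = "synthetic_config")
}

#' The post-video confounder task schedule
#'
#' Thirteen scripted tasks presented after the stimulus: speaking (counting,
#' 10 s) then yawning, coughing, mouth covering, posed anger, sadness, fear,
#' surprise and disgust, posed smiling three times, and a neutral expression
#' (6 s each), with a 6 s inter-task interval throughout.
#'
#' @param start Start time of the first task on the session clock (seconds).
#' @param task_s Duration of the non-speaking tasks (default 6).
#' @param speaking_s Duration of the speaking task (default 10).
#' @param gap_s Inter-task interval (default 6).
#' @return A [task_events()] tibble of 13 events.
#' @export
default_task_schedule <- function(start = 270, task_s = 6, speaking_s = 10,
                                  gap_s = 6) {
  names <- c("speaking", "yawning", "coughing", "mouth_covering",
             "anger", "sadness", "fear", "surprise", "disgust",
             "smiling", "smiling", "smiling", "neutral")
  durs <- c(speaking_s, rep(task_s, length(names) - 1L))
  starts <- start + cumsum(c(0, durs[-length(durs)] + gap_s))
  task_events(tibble::tibble(name = names, start_s = starts,
                             end_s = starts + durs))
}

# Trapezoidal activation profile over support [a, b]: linear `ramp`-second
# rise to `apex`, plateau, linear fall. Zero outside the support.
.trapezoid <- function(t, a, b, apex, ramp) {
  frac <- pmin((t - a) / ramp, (b - t) / ramp, 1)
  apex * pmin(pmax(frac, 0), 1)
}

#' Simulate a session with known ground truth
#'
#' Generates one synthetic recording: an AU time series in the same shape the
#' OpenFace reader produces, the ground-truth smile annotation track, and
#' (optionally) the post-video confounder task schedule.
#'
#' The procedure: (1) the episode count is Poisson with mean
#' `episode_rate * session_length / 60`; (2) durations are log-normal matched
#' to `duration_mean`/`duration_sd`; (3) episodes are placed uniformly at
#' random subject to a minimum separation comfortably above the 2 s stand-by
#' window; (4) AU6/AU12 follow jittered trapezoids over each episode on top
#' of a sub-boundary uniform baseline; (5) Gaussian noise of sd `noise_sd` is
#' added and clipped to `[0, 5]`; (6) AU25 is true on each ground-truth smile
#' frame with probability `tooth_show_prob`; (7) with `tasks = TRUE` the
#' schedule from [default_task_schedule()] is appended, where yawning and
#' mouth covering raise AU12 (but not AU6) above its boundary, posed smiling
#' raises both, and all other tasks stay sub-boundary (invented signatures —
#' not claims about facial physiology).
#'
#' Ground truth is defined from the noise-free trajectories: a frame belongs
#' to a smile interval iff clean AU6 and AU12 both exceed their boundaries.
#' The posed-smiling task windows therefore appear in the truth track (they
#' are genuine supra-boundary smiles); the confound analysis excludes them by
#' name. With `noise_sd = 0` the detector run at the generative boundaries
#' reproduces the truth track exactly.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `synthetic_session` with elements `series`
#'   ([au_timeseries()]), `truth` ([annotation_track()]), `tasks`
#'   ([task_events()] or `NULL`) and `config`.
#' @examples
#' sess <- simulate_session(synthetic_config(seed = 7, session_length = 60))
#' sess$truth
#' @export
simulate_session <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(config$seed)
  fps <- config$fps
  len <- config$session_length

  # --- episode placement on the stimulus part -----------------------------
  n_ep <- stats::rpois(1L, config$episode_rate * len / 60)
  min_dur <- 2 * config$ramp + 0.7
  min_gap <- 2 + 2 / fps + 2 * config$timing_jitter + 0.2
  edge <- 0.5 + config$timing_jitter
  if (n_ep > 0L &&
      n_ep * min_dur + (n_ep - 1L) * min_gap + 2 * edge > len) {
    stop(sprintf(
      "infeasible configuration: %d episodes cannot fit in %g s with the separation constraint",
      n_ep, len), call. = FALSE)
  }
  durations <- numeric(0)
  if (n_ep > 0L) {
    cv <- config$duration_sd / config$duration_mean
    sdlog <- sqrt(log(1 + cv^2))
    meanlog <- log(config$duration_mean) - sdlog^2 / 2
    capacity <- len - 2 * edge - (n_ep - 1L) * min_gap
    for (try in seq_len(200L)) {
      durations <- pmin(pmax(stats::rlnorm(n_ep, meanlog, sdlog), min_dur),
                        len / 3)
      if (sum(durations) <= capacity) break
      durations <- numeric(0)
    }
    if (length(durations) == 0L) {
      stop("infeasible configuration: episode durations cannot fit the session",
           call. = FALSE)
    }
  }
  onsets <- numeric(0)
  if (n_ep > 0L) {
    free <- len - 2 * edge - sum(durations) - (n_ep - 1L) * min_gap
    slack <- diff(c(0, sort(stats::runif(n_ep)), 1)) * free
    onsets <- edge + cumsum(slack[seq_len(n_ep)]) +
      c(0, cumsum(durations[-n_ep] + min_gap))[seq_len(n_ep)]
  }

  # --- time base ----------------------------------------------------------
  schedule <- NULL
  total <- len
  if (config$tasks) {
    schedule <- default_task_schedule(start = len + 6)
    total <- max(schedule$end_s) + 2
  }
  n <- as.integer(round(total * fps))
  t <- (seq_len(n) - 1L) / fps

  # --- clean trajectories -------------------------------------------------
  clean6 <- stats::runif(n, 0, config$baseline_frac * config$au6_boundary)
  clean12 <- stats::runif(n, 0, config$baseline_frac * config$au12_boundary)
  add_smile <- function(s, e) {
    a6 <- config$au6_apex *
      stats::runif(1, 1 - config$apex_jitter, 1 + config$apex_jitter)
    a12 <- config$au12_apex *
      stats::runif(1, 1 - config$apex_jitter, 1 + config$apex_jitter)
    j <- stats::runif(4, -config$timing_jitter, config$timing_jitter)
    clean6 <<- pmax(clean6, .trapezoid(t, s + j[1], e + j[2], a6, config$ramp))
    clean12 <<- pmax(clean12, .trapezoid(t, s + j[3], e + j[4], a12, config$ramp))
  }
  for (k in seq_len(n_ep)) add_smile(onsets[k], onsets[k] + durations[k])

  if (!is.null(schedule)) {
    for (i in seq_len(nrow(schedule))) {
      s <- schedule$start_s[i]
      e <- schedule$end_s[i]
      nm <- schedule$name[i]
      if (nm %in% c("yawning", "mouth_covering")) {
        clean12 <- pmax(clean12, .trapezoid(t, s + 1, e - 1,
                                            config$au12_boundary + 0.6,
                                            config$ramp))
      } else if (nm == "smiling") {
        add_smile(s + 0.5, e - 0.5)
      } else if (nm != "neutral") {
        # mild sub-boundary perturbations: visible activity, no smile
        clean6 <- pmax(clean6, .trapezoid(t, s + 1, e - 1,
                                          0.6 * config$au6_boundary,
                                          config$ramp))
        clean12 <- pmax(clean12, .trapezoid(t, s + 1, e - 1,
                                            0.6 * config$au12_boundary,
                                            config$ramp))
      }
    }
  }

  # --- ground truth from the noise-free signals ---------------------------
  lab <- clean6 > config$au6_boundary & clean12 > config$au12_boundary
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  truth <- annotation_track(
    tibble::tibble(onset_frame = starts[r$values] - 1L,
                   offset_frame = ends[r$values] - 1L),
    session_id = config$session_id, fps = fps)

  # --- observation noise and AU25 -----------------------------------------
  au6 <- pmin(pmax(clean6 + stats::rnorm(n, 0, config$noise_sd), 0), 5)
  au12 <- pmin(pmax(clean12 + stats::rnorm(n, 0, config$noise_sd), 0), 5)
  au25 <- logical(n)
  au25[lab] <- stats::runif(sum(lab)) < config$tooth_show_prob

  series <- au_timeseries(
    tibble::tibble(frame = seq_len(n) - 1L, timestamp = t,
                   confidence = 0.98, success = TRUE,
                   au6 = au6, au12 = au12, au25 = au25),
    session_id = config$session_id, fps = fps)

  structure(list(series = series, truth = truth, tasks = schedule,
                 config = config),
            class = "synthetic_session")
}

#' @export
print.synthetic_session <- function(x, ...) {
  cat(sprintf("<synthetic_session> '%s': %d frames, %d truth smile interval(s)%s\n",
              x$config$session_id, n_frames(x$series),
              nrow(x$truth$intervals),
              if (!is.null(x$tasks)) sprintf(", %d task(s)", nrow(x$tasks))
              else ""))
  invisible(x)
}

#' Analytic expectations implied by a synthetic configuration
#'
#' Closed-form session-level expectations used to check the generator's
#' statistical calibration: episodes per minute equals the configured rate,
#' mean duration the configured mean, relative smile time the product
#' `rate * mean / 60` (as a capped percentage) and mean tooth show the
#' configured AU25 probability.
#'
#' @param config A [synthetic_config()].
#' @return A list with `n_episodes`, `episodes_per_minute`, `mean_duration`,
#'   `relative_smile_time` and `mean_tooth_show`.
#' @export
expected_session_summary <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  list(
    n_episodes = config$episode_rate * config$session_length / 60,
    episodes_per_minute = config$episode_rate,
    mean_duration = config$duration_mean,
    relative_smile_time =
      min(100, 100 * config$episode_rate * config$duration_mean / 60),
    mean_tooth_show = 100 * config$tooth_show_prob)
}

#' Write a synthetic session to disk
#'
#' Emits the OpenFace-dialect AU CSV, the ground-truth annotation CSV
#' (`session_id, onset_frame, offset_frame`) and, when present, the task
#' schedule CSV (`name, start_s, end_s`), so the file-based pipeline can be
#' exercised end to end.
#'
#' @param session A `synthetic_session` from [simulate_session()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of files written (`au`, `annotations`, and
#'   possibly `tasks`), invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "synthetic_session"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  id <- session$config$session_id
  au_file <- file.path(dir, paste0(id, ".csv"))
  ann_file <- file.path(dir, paste0(id, "_annotations.csv"))
  write_au_csv(session$series, au_file)
  iv <- session$truth$intervals
  utils::write.csv(
    data.frame(session_id = rep(id, nrow(iv)),
               onset_frame = iv$onset_frame, offset_frame = iv$offset_frame),
    ann_file, row.names = FALSE, quote = FALSE)
  files <- c(au = au_file, annotations = ann_file)
  if (!is.null(session$tasks)) {
    task_file <- file.path(dir, paste0(id, "_tasks.csv"))
    utils::write.csv(as.data.frame(session$tasks)[, c("name", "start_s", "end_s")],
                     task_file, row.names = FALSE, quote = FALSE)
    files <- c(files, tasks = task_file)
  }
  invisible(files)
}
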