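#' Episode-level agreement with manual coding
#'
#' Matches detected episodes to manually coded reference intervals one-to-one
#' by greedy assignment in decreasing frame-overlap order. A detected/reference
#' pair is matchable when their inclusive frame spans share at least one frame
#' and the overlap covers at least `min_overlap` of the reference interval's
#' length. The episode-level true-positive rate is the percentage of reference
#' episodes that received a match.
#'
#' @param detected A `smile_episodes` tibble from [detect()] (or any data
#'   frame with `onset_frame`/`offset_frame`).
#' @param reference An [annotation_track()].
#' @param fps Frame rate of the common time base; when both inputs carry one
#'   it is checked for agreement.
#' @param min_overlap Minimum overlap as a fraction of the reference interval
#'   length (default 0: any overlap counts).
#' @return A list of class `episode_match_report`: `n_reference`,
#'   `n_detected`, `n_matched`, `true_positive_rate` (percent, `NA` with no
#'   reference episodes), `unmatched_detected`, and a `matches` tibble
#'   (`detected_index`, `reference_index`, `overlap_frames`).
#' @export
match_episodes <- function(detected, reference, fps = NULL, min_overlap = 0) {
  stopifnot(inherits(reference, "annotation_track"))
  det_fps <- attr(detected, "fps")
  if (!is.null(fps) && !is.null(det_fps) &&
      abs(fps - det_fps) > 0.01 * fps) {
    stop("fps of detected episodes disagrees with the supplied fps",
         call. = FALSE)
  }
  ref <- reference$intervals
  nd <- nrow(detected)
  nr <- nrow(ref)
  pairs <- NULL
  if (nd > 0L && nr > 0L) {
    d_idx <- rep(seq_len(nd), times = nr)
    r_idx <- rep(seq_len(nr), each = nd)
    ov <- pmin(detected$offset_frame[d_idx], ref$offset_frame[r_idx]) -
      pmax(detected$onset_frame[d_idx], ref$onset_frame[r_idx]) + 1L
    ref_len <- ref$offset_frame[r_idx] - ref$onset_frame[r_idx] + 1L
    keep <- ov >= 1L & ov >= min_overlap * ref_len
    pairs <- data.frame(d = d_idx[keep], r = r_idx[keep], ov = ov[keep])
  }
  matches <- tibble::tibble(detected_index = integer(),
                            reference_index = integer(),
                            overlap_frames = integer())
  if (!is.null(pairs) && nrow(pairs) > 0L) {
    # greedy one-to-one by decreasing overlap; ties by earlier reference,
    # then earlier detected episode, for determinism
    pairs <- pairs[order(-pairs$ov, pairs$r, pairs$d), , drop = FALSE]
    used_d <- logical(nd)
    used_r <- logical(nr)
    for (i in seq_len(nrow(pairs))) {
      d <- pairs$d[i]
      r <- pairs$r[i]
      if (!used_d[d] && !used_r[r]) {
        used_d[d] <- TRUE
        used_r[r] <- TRUE
        matches <- rbind(matches, tibble::tibble(
          detected_index = d, reference_index = r,
          overlap_frames = as.integer(pairs$ov[i])))
      }
    }
  }
  n_matched <- nrow(matches)
  structure(list(
    n_reference = nr,
    n_detected = nd,
    n_matched = n_matched,
    true_positive_rate = if (nr > 0L) 100 * n_matched / nr else NA_real_,
    unmatched_detected = nd - n_matched,
    matches = matches),
    class = "episode_match_report")
}

#' @export
print.episode_match_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<episode_match_report> %d reference, %d detected, %d matched\n",
    "  episode true-positive rate: %s%%; unmatched detections: %d\n"),
    x$n_reference, x$n_detected, x$n_matched,
    if (is.na(x$true_positive_rate)) "NA" else
      sprintf("%.1f", x$true_positive_rate), x$unmatched_detected))
  invisible(x)
}

#' Confounder-task false-positive analysis
#'
#' Checks whether detected smile episodes spill into the post-video confounder
#' tasks (speaking, yawning, coughing, mouth covering, posed expressions).
#' Tasks named `smiling` are excluded — posed smiles are smiles, not
#' confounders. A task is flagged as a false positive when any detected
#' episode's time span `[onset_time, onset_time + duration)` intersects the
#' task window `[start_s, end_s)`.
#'
#' @param detected A `smile_episodes` tibble from [detect()].
#' @param tasks A [task_events()] schedule on the same session clock.
#' @param exclude Task names excluded from the analysis (default `"smiling"`).
#' @return A list of class `confound_report`: `n_tasks` (after exclusion),
#'   `n_flagged`, `false_positive_rate` (percent, `NA` when no tasks remain)
#'   and a `flagged` tibble of the flagged task windows.
#' @export
confound_fp_rate <- function(detected, tasks, exclude = "smiling") {
  stopifnot(inherits(tasks, "task_events"))
  t <- tasks[!(tasks$name %in% exclude), , drop = FALSE]
  nt <- nrow(t)
  flagged <- logical(nt)
  if (nt > 0L && nrow(detected) > 0L) {
    ep_start <- detected$onset_time
    ep_end <- detected$onset_time + detected$duration
    for (i in seq_len(nt)) {
      flagged[i] <- any(ep_start < t$end_s[i] & t$start_s[i] < ep_end)
    }
  }
  structure(list(
    n_tasks = nt,
    n_flagged = sum(flagged),
    false_positive_rate = if (nt > 0L) 100 * sum(flagged) / nt else NA_real_,
    flagged = tibble::as_tibble(t[flagged, , drop = FALSE])),
    class = "confound_report")
}

#' @export
print.confound_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<confound_report> %d confounder task(s), %d flagged as smiles\n",
    "  false-positive rate: %s%%\n"),
    x$n_tasks, x$n_flagged,
    if (is.na(x$false_positive_rate)) "NA" else
      sprintf("%.1f", x$false_positive_rate)))
  invisible(x)
}
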