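#' Frame-wise confusion counts
#'
#' Standard 2x2 tally of a frame-wise prediction against the frame-wise
#' reference labels derived from manual coding.
#'
#' @param pred Logical vector of predicted smile frames.
#' @param ref Logical vector of reference smile frames (same length).
#' @return Named integer vector with elements `tp`, `fp`, `tn`, `fn`; the
#'   four counts sum to the frame count.
#' @export
framewise_confusion <- function(pred, ref) {
  pred <- as.logical(pred)
  ref <- as.logical(ref)
  if (length(pred) != length(ref)) {
    stop("prediction and reference must have the same length", call. = FALSE)
  }
  c(tp = sum(pred & ref), fp = sum(pred & !ref),
    tn = sum(!pred & !ref), fn = sum(!pred & ref))
}

.threshold_lattice <- function(step, th_range) {
  if (step <= 0) stop("step must be positive", call. = FALSE)
  k <- floor((th_range[2L] - th_range[1L]) / step + 1e-9)
  th_range[1L] + step * (0:k)
}

.as_session_list <- function(sessions) {
  if (is.list(sessions) && !is.null(sessions$series)) sessions <- list(sessions)
  if (length(sessions) == 0L) {
    stop("at least one session is required", call. = FALSE)
  }
  for (s in sessions) {
    if (!inherits(s$series, "au_timeseries") ||
        !inherits(s$track, "annotation_track")) {
      stop("each session must be a list(series = <au_timeseries>, track = <annotation_track>)",
           call. = FALSE)
    }
  }
  sessions
}

#' Dual-threshold calibration grid
#'
#' Evaluates the frame-wise classifier at every point of the inclusive
#' (`th1`, `th2`) lattice — by default a 0.05 step over `[0, 5]` for both
#' thresholds, i.e. 101 x 101 points — against the reference labels, pooling
#' frames across all supplied sessions into a single confusion table.
#' Classification is the raw dual-threshold rule without stand-by merging:
#' calibration precedes episode logic. Frames with failed tracking count as
#' predicted-negative at every grid point.
#'
#' The grid is computed exactly via a two-dimensional suffix-sum histogram of
#' the (AU6, AU12) values, which is algebraically identical to re-running the
#' classifier at each lattice point.
#'
#' @param sessions Either one `list(series =, track =)` pair or a list of
#'   such pairs ([au_timeseries()] plus [annotation_track()]).
#' @param step Threshold increment (default 0.05).
#' @param th_range Inclusive threshold range for both AUs (default `c(0, 5)`).
#' @return Tibble with one row per lattice point: `th1`, `th2`, `tp`, `fp`,
#'   `tn`, `fn`, `sensitivity`, `specificity`, `youden`, `accuracy`.
#'   Sensitivity (and hence Youden) is `NA` when the pooled reference has no
#'   positive frames; specificity likewise with no negatives.
#' @export
threshold_grid <- function(sessions, step = 0.05, th_range = c(0, 5)) {
  sessions <- .as_session_list(sessions)
  thresholds <- .threshold_lattice(step, th_range)
  k <- length(thresholds)

  au6 <- unlist(lapply(sessions, function(s) s$series$frames$au6))
  au12 <- unlist(lapply(sessions, function(s) s$series$frames$au12))
  ok <- unlist(lapply(sessions, function(s) s$series$frames$success))
  ref <- unlist(lapply(sessions, function(s) {
    frame_labels(s$track, n_frames(s$series))
  }))

  # b = number of lattice thresholds strictly below the value; the frame is
  # predicted positive at lattice index i iff b >= i. Invalid frames are
  # never positive.
  b6 <- findInterval(au6, thresholds, left.open = TRUE)
  b12 <- findInterval(au12, thresholds, left.open = TRUE)
  b6[!ok] <- 0L
  b12[!ok] <- 0L

  hist2 <- function(sel) {
    m <- tabulate(b6[sel] * (k + 1L) + b12[sel] + 1L, nbins = (k + 1L)^2)
    matrix(m, nrow = k + 1L) # [b12 + 1, b6 + 1]
  }
  suffix2 <- function(m) {
    m <- m[nrow(m):1L, ncol(m):1L, drop = FALSE]
    m <- apply(m, 2L, cumsum)
    m <- t(apply(m, 1L, cumsum))
    m[nrow(m):1L, ncol(m):1L, drop = FALSE]
  }
  pos_suf <- suffix2(hist2(ref))
  neg_suf <- suffix2(hist2(!ref))
  # [i, j] = count with b6 >= i and b12 >= j
  tp_mat <- t(pos_suf[-1L, -1L, drop = FALSE])
  fp_mat <- t(neg_suf[-1L, -1L, drop = FALSE])

  p <- sum(ref)
  n <- length(ref) - p
  tp <- as.vector(tp_mat)
  fp <- as.vector(fp_mat)
  fn <- p - tp
  tn <- n - fp
  se <- if (p > 0L) tp / p else rep(NA_real_, length(tp))
  sp <- if (n > 0L) tn / n else rep(NA_real_, length(tp))
  tibble::tibble(
    th1 = rep(thresholds, times = k),
    th2 = rep(thresholds, each = k),
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = se, specificity = sp,
    youden = se + sp - 1,
    accuracy = (tp + tn) / (p + n))
}

#' ROC frontier of a two-threshold grid
#'
#' A grid over two thresholds produces a cloud of (false positive rate, true
#' positive rate) points rather than a one-dimensional curve. The ROC is
#' defined as the Pareto upper-left envelope of that cloud: for each achieved
#' FPR the maximal TPR is kept, dominated points are dropped, and the anchors
#' (0, 0) and (1, 1) are prepended/appended. The result is non-decreasing in
#' both coordinates.
#'
#' @param grid A grid tibble from [threshold_grid()] (needs `sensitivity` and
#'   `specificity` columns).
#' @return Tibble with columns `fpr` and `tpr`, ordered by `fpr`.
#' @export
roc_frontier <- function(grid) {
  if (nrow(grid) == 0L) stop("grid is empty", call. = FALSE)
  fpr <- 1 - grid$specificity
  tpr <- grid$sensitivity
  keep <- !is.na(fpr) & !is.na(tpr)
  if (!any(keep)) {
    stop("no grid point has defined sensitivity and specificity", call. = FALSE)
  }
  fpr <- fpr[keep]
  tpr <- tpr[keep]
  ord <- order(fpr, -tpr)
  fpr <- fpr[ord]
  tpr <- tpr[ord]
  sel <- logical(length(fpr))
  best <- -Inf
  last_fpr <- -1
  for (i in seq_along(fpr)) {
    if (fpr[i] > last_fpr && tpr[i] > best) {
      sel[i] <- TRUE
      best <- tpr[i]
      last_fpr <- fpr[i]
    }
  }
  fpr <- fpr[sel]
  tpr <- tpr[sel]
  if (fpr[1L] > 0 || tpr[1L] > 0) {
    fpr <- c(0, fpr)
    tpr <- c(0, tpr)
  }
  nlast <- length(fpr)
  if (fpr[nlast] < 1 || tpr[nlast] < 1) {
    fpr <- c(fpr, 1)
    tpr <- c(tpr, 1)
  }
  tibble::tibble(fpr = fpr, tpr = tpr)
}

#' Area under the ROC frontier
#'
#' Trapezoidal area under an ordered, monotone (FPR, TPR) frontier spanning
#' FPR 0 to 1.
#'
#' @param frontier Tibble from [roc_frontier()].
#' @return Area in `[0, 1]`.
#' @export
roc_auc <- function(frontier) {
  fpr <- frontier$fpr
  tpr <- frontier$tpr
  if (length(fpr) < 2L || any(diff(fpr) < 0) || any(diff(tpr) < -1e-12)) {
    stop("frontier must be monotone non-decreasing in FPR and TPR",
         call. = FALSE)
  }
  if (abs(fpr[1L]) > 1e-12 || abs(fpr[length(fpr)] - 1) > 1e-12) {
    stop("frontier must span FPR from 0 to 1", call. = FALSE)
  }
  sum(diff(fpr) * (tpr[-1L] + tpr[-length(tpr)]) / 2)
}

#' Youden-optimal operating point
#'
#' Selects the grid point maximising the Youden index (Se + Sp - 1). Ties are
#' broken deterministically: higher specificity first, then higher `th1`,
#' then higher `th2`.
#'
#' @param grid A grid tibble from [threshold_grid()].
#' @return The selected one-row grid tibble.
#' @export
youden_optimal <- function(grid) {
  ok <- !is.na(grid$youden)
  if (!any(ok)) {
    stop("no grid point has a defined Youden index", call. = FALSE)
  }
  g <- grid[ok, , drop = FALSE]
  ord <- order(-g$youden, -g$specificity, -g$th1, -g$th2)
  g[ord[1L], , drop = FALSE]
}

#' Calibrate the detector against manual coding
#'
#' Convenience wrapper running the full frame-wise validation: the dual
#' threshold grid ([threshold_grid()]), its ROC frontier and AUC, and the
#' Youden-optimal operating point.
#'
#' @inheritParams threshold_grid
#' @return A list of class `calibration_result` with elements `grid`,
#'   `frontier`, `auc` and `best`.
#' @export
calibrate <- function(sessions, step = 0.05, th_range = c(0, 5)) {
  grid <- threshold_grid(sessions, step = step, th_range = th_range)
  frontier <- roc_frontier(grid)
  structure(list(grid = grid, frontier = frontier,
                 auc = roc_auc(frontier), best = youden_optimal(grid)),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  b <- x$best
  cat(sprintf(paste0(
    "<calibration_result> %d grid points, AUC %.3f\n",
    "  Youden optimum: Th1 (AU6) = %g, Th2 (AU12) = %g\n",
    "  Se %.1f%%, Sp %.1f%%, accuracy %.1f%%\n"),
    nrow(x$grid), x$auc, b$th1, b$th2,
    100 * b$sensitivity, 100 * b$specificity, 100 * b$accuracy))
  invisible(x)
}

#' Write a calibration result to files
#'
#' Emits the grid CSV (`th1, th2, tp, fp, tn, fn, se, sp, youden, accuracy`),
#' the frontier CSV (`fpr, tpr`) and a flat JSON summary (AUC, best
#' thresholds, Se, Sp, accuracy).
#'
#' @param result A `calibration_result`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Character vector of the files written, invisibly.
#' @export
write_calibration <- function(result, dir, prefix = "calibration") {
  stopifnot(inherits(result, "calibration_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  grid_file <- file.path(dir, paste0(prefix, "_grid.csv"))
  frontier_file <- file.path(dir, paste0(prefix, "_frontier.csv"))
  summary_file <- file.path(dir, paste0(prefix, "_summary.json"))
  g <- result$grid
  names(g)[names(g) == "sensitivity"] <- "se"
  names(g)[names(g) == "specificity"] <- "sp"
  utils::write.csv(g, grid_file, row.names = FALSE, quote = FALSE)
  utils::write.csv(result$frontier, frontier_file, row.names = FALSE,
                   quote = FALSE)
  b <- result$best
  jsonlite::write_json(list(
    auc = result$auc, th1 = b$th1, th2 = b$th2,
    sensitivity = b$sensitivity, specificity = b$specificity,
    youden = b$youden, accuracy = b$accuracy),
    summary_file, auto_unbox = TRUE, digits = NA)
  invisible(c(grid_file, frontier_file, summary_file))
}
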