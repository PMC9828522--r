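test_that("frame-wise confusion counts match a per-frame tally", {
  expect_equal(framewise_confusion(c(T, F, T, F), c(T, T, F, F)),
               c(tp = 1L, fp = 1L, tn = 1L, fn = 1L))
  pred <- c(T, T, F)
  expect_equal(framewise_confusion(pred, pred)[c("fp", "fn")],
               c(fp = 0L, fn = 0L))
  expect_error(framewise_confusion(c(T, F), c(T)), "length")
  set.seed(21)
  for (i in 1:20) {
    p <- runif(30) < 0.5
    r <- runif(30) < 0.5
    manual <- c(tp = 0L, fp = 0L, tn = 0L, fn = 0L)
    for (k in 1:30) {
      cell <- if (p[k] && r[k]) "tp" else if (p[k]) "fp"
              else if (r[k]) "fn" else "tn"
      manual[cell] <- manual[cell] + 1L
    }
    expect_equal(framewise_confusion(p, r), manual)
  }
})

test_that("the 0.05-step lattice over [0,5] has 101 x 101 points", {
  sess <- list(series = make_series(c(0.6, 0.2), c(2, 0.5), fps = 2),
               track = annotation_track(
                 data.frame(onset_frame = 0, offset_frame = 0)))
  grid <- threshold_grid(sess)
  expect_equal(nrow(grid), 101L * 101L)
  expect_equal(sort(unique(grid$th1)), seq(0, 5, by = 0.05))
  grid_coarse <- threshold_grid(sess, step = 0.25)
  expect_equal(nrow(grid_coarse), 21L * 21L)
  expect_error(threshold_grid(list()), "at least one session")
})

test_that("grid cells equal the direct classify-and-count route", {
  sessions <- make_calibration_batch(n_sessions = 2, seed_base = 700)
  grid <- threshold_grid(sessions)
  total <- sum(vapply(sessions, function(s) n_frames(s$series), integer(1)))
  expect_true(all(grid$tp + grid$fp + grid$tn + grid$fn == total))
  expect_true(all(grid$accuracy == (grid$tp + grid$tn) / total))
  expect_true(all(grid$sensitivity >= 0 & grid$sensitivity <= 1))
  expect_true(all(grid$specificity >= 0 & grid$specificity <= 1))

  set.seed(31)
  for (i in sample(nrow(grid), 12)) {
    cm <- Reduce(`+`, lapply(sessions, function(s) {
      framewise_confusion(
        classify_frames(s$series, detection_config(grid$th1[i], grid$th2[i])),
        frame_labels(s$track, n_frames(s$series)))
    }))
    expect_equal(c(grid$tp[i], grid$fp[i], grid$tn[i], grid$fn[i]),
                 unname(cm[c("tp", "fp", "tn", "fn")]))
  }
})

test_that("pooled confusion equals the sum of per-session confusions", {
  sessions <- make_calibration_batch(n_sessions = 3, seed_base = 800)
  pooled <- threshold_grid(sessions, step = 1)
  per <- lapply(sessions, function(s) threshold_grid(list(s), step = 1))
  for (col in c("tp", "fp", "tn", "fn")) {
    expect_equal(pooled[[col]], Reduce(`+`, lapply(per, `[[`, col)))
  }
})

test_that("sensitivity is reported as absent when the reference has no positives", {
  sess <- list(series = make_series(c(0.6, 0.2, 0.1), c(2, 0.5, 0.2), fps = 3),
               track = annotation_track(
                 data.frame(onset_frame = integer(), offset_frame = integer())))
  grid <- threshold_grid(sess, step = 1)
  expect_true(all(is.na(grid$sensitivity)))
  expect_true(all(!is.na(grid$specificity)))
  expect_error(youden_optimal(grid), "Youden")
  expect_error(roc_frontier(grid), "defined")
})

test_that("the ROC frontier is the dominance envelope with anchors", {
  cloud <- tibble::tibble(specificity = 1 - c(0.1, 0.1, 0.3),
                          sensitivity = c(0.8, 0.6, 0.9),
                          th1 = 1:3, th2 = 1:3)
  fr <- roc_frontier(cloud)
  expect_equal(fr$fpr, c(0, 0.1, 0.3, 1))
  expect_equal(fr$tpr, c(0, 0.8, 0.9, 1))
  expect_true(all(diff(fr$fpr) >= 0) && all(diff(fr$tpr) >= 0))

  perfect <- tibble::tibble(specificity = c(1, 0.5), sensitivity = c(1, 0.7))
  fp <- roc_frontier(perfect)
  expect_true(any(fp$fpr == 0 & fp$tpr == 1))
  expect_equal(roc_auc(fp), 1.0)

  degenerate <- roc_frontier(tibble::tibble(specificity = 0, sensitivity = 1))
  expect_equal(roc_auc(degenerate), 0.5) # only (0,0)-(1,1) chance diagonal
})

test_that("AUC is the trapezoid area and rejects bad frontiers", {
  expect_equal(roc_auc(tibble::tibble(fpr = c(0, 1), tpr = c(0, 1))), 0.5)
  expect_equal(roc_auc(tibble::tibble(fpr = c(0, 0, 1), tpr = c(0, 1, 1))), 1.0)
  expect_equal(roc_auc(tibble::tibble(fpr = c(0, 0.2, 1), tpr = c(0, 0.8, 1))), 0.8)
  expect_error(roc_auc(tibble::tibble(fpr = c(0, 0.5, 0.2, 1),
                                      tpr = c(0, 0.5, 0.6, 1))), "monotone")
  expect_error(roc_auc(tibble::tibble(fpr = c(0.2, 1), tpr = c(0, 1))), "span")
  # frontier AUC dominates every single-point trapezoid through the grid
  sessions <- make_calibration_batch(n_sessions = 2, seed_base = 900)
  grid <- threshold_grid(sessions, step = 0.25)
  fr <- roc_frontier(grid)
  a <- roc_auc(fr)
  one_point <- function(se, sp) {
    roc_auc(roc_frontier(tibble::tibble(sensitivity = se, specificity = sp)))
  }
  ok <- !is.na(grid$youden)
  singles <- mapply(one_point, grid$sensitivity[ok], grid$specificity[ok])
  expect_gte(a, max(singles) - 1e-12)
})

test_that("Youden optimisation uses the documented tie-breaks", {
  g <- tibble::tibble(th1 = c(1, 2, 2, 2), th2 = c(1, 1, 1, 2),
                      sensitivity = c(0.9, 0.8, 0.7, 0.7),
                      specificity = c(0.7, 0.8, 0.9, 0.9))
  g$youden <- g$sensitivity + g$specificity - 1
  best <- youden_optimal(g)
  expect_equal(best$specificity, 0.9) # equal Youden: higher Sp wins
  expect_equal(best$th2, 2)           # then higher thresholds
})

test_that("a noise-free separable session has a zero-error grid point", {
  s <- simulate_session(synthetic_config(seed = 55, session_length = 60,
                                         noise_sd = 0))
  grid <- threshold_grid(list(list(series = s$series, track = s$truth)))
  at <- grid[grid$th1 == 0.5 & grid$th2 == 1.5, ]
  expect_equal(at$fp, 0L)
  expect_equal(at$fn, 0L)
  res <- calibrate(list(list(series = s$series, track = s$truth)))
  expect_equal(res$auc, 1.0)
  expect_equal(res$best$youden, 1.0)
})
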