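test_that("frame classification uses strict dual thresholds and validity", {
  cfg <- detection_config(th1 = 0.5, th2 = 1.5)
  expect_true(classify_frames(make_series(0.6, 2.0), cfg))
  expect_false(classify_frames(make_series(0.6, 1.0), cfg)) # AU12 below
  expect_false(classify_frames(make_series(0.4, 2.0), cfg)) # AU6 below
  # boundary values are NOT above the threshold
  expect_false(classify_frames(make_series(0.5, 1.5), cfg))
  # failed tracking is treated as sub-threshold
  expect_equal(
    classify_frames(make_series(c(2, 2), c(3, 3), success = c(TRUE, FALSE)), cfg),
    c(TRUE, FALSE))
})

test_that("segmentation merges gaps strictly shorter than the stand-by time", {
  # 1 s gap < 2 s stand-by: merged, gap absorbed
  one <- segment_episodes(c(F, T, T, F, T, T, F), fps = 1, standby = 2)
  expect_equal(one, tibble::tibble(onset = 1L, offset = 5L))
  # exactly 2 s: split
  two <- segment_episodes(c(T, T, F, F, T, T), fps = 1, standby = 2)
  expect_equal(two$onset, c(0L, 4L))
  expect_equal(two$offset, c(1L, 5L))
  expect_equal(nrow(segment_episodes(rep(FALSE, 10), 1, 2)), 0L)
  # the same gap pattern at higher fps is shorter in seconds, hence merged
  expect_equal(nrow(segment_episodes(c(T, T, F, F, T, T), fps = 30, standby = 2)), 1L)
})

test_that("segmentation agrees with the brute-force run-and-merge oracle", {
  set.seed(303)
  for (i in 1:200) {
    n <- sample(1:50, 1)
    smile <- runif(n) < runif(1, 0.2, 0.8)
    fps <- sample(c(1, 2, 10, 30), 1)
    standby <- sample(c(0.5, 1, 2, 3), 1)
    expect_equal(segment_episodes(smile, fps, standby),
                 oracle_segment(smile, fps, standby))
  }
})

test_that("episode metrics average across the entire episode span", {
  ts <- make_series(au6 = c(1, 1, 2, 2), au12 = c(2, 2, 3, 3),
                    au25 = c(TRUE, TRUE, FALSE, FALSE))
  m <- episode_metrics(ts, 0, 3)
  expect_equal(m$mean_au6, 1.5)
  expect_equal(m$mean_au12, 2.5)
  expect_equal(m$tooth_show, 50) # teeth visible half the episode
  expect_equal(m$duration, 4)
  expect_equal(m$onset_time, 0)

  single <- episode_metrics(make_series(1.0, 2.0, TRUE, fps = 30), 0, 0)
  expect_equal(single$mean_au6, 1.0)
  expect_equal(single$tooth_show, 100)
  expect_equal(single$duration, 1 / 30)

  expect_error(episode_metrics(ts, 2, 5), "outside")
})

test_that("detect composes classification, merging and metrics", {
  # three well-separated synthetic smiles, noise-free
  sess <- simulate_session(synthetic_config(seed = 18, session_length = 60,
                                            noise_sd = 0))
  truth <- sess$truth$intervals
  expect_equal(nrow(truth), 3L)
  ep <- detect(sess$series)
  expect_equal(ep$onset_frame, truth$onset_frame)
  expect_equal(ep$offset_frame, truth$offset_frame)
  expect_equal(ep$index, seq_len(nrow(ep)))
  # onsets and durations are integer multiples of 1/fps
  fps <- sess$series$fps
  expect_equal(ep$duration * fps, round(ep$duration * fps))
  expect_equal(ep$onset_time * fps, round(ep$onset_time * fps))

  # a window covering only the second smile yields exactly that episode
  win <- detect(sess$series, start_frame = truth$onset_frame[2] - 5,
                end_frame = truth$offset_frame[2] + 5)
  expect_equal(nrow(win), 1L)
  expect_equal(win$onset_frame, truth$onset_frame[2])
  expect_error(detect(sess$series, start_frame = -1), "window")

  # an all-zero series has no episodes
  flat <- make_series(rep(0, 100), rep(0, 100), fps = 10)
  expect_equal(nrow(detect(flat)), 0L)
})

test_that("session summaries follow the definitions exactly", {
  # 8 episodes in a 300 s session = 1.6 per minute
  ep <- tibble::tibble(duration = rep(5, 8), mean_au6 = 1, mean_au12 = 2,
                       tooth_show = 50)
  s <- summarize_session(ep, 300)
  expect_equal(s$episodes_per_minute, 1.6)
  # durations 30 + 60 in 300 s = 30% relative smile time
  s2 <- summarize_session(tibble::tibble(duration = c(30, 60),
                                         mean_au6 = c(1, 2),
                                         mean_au12 = c(2, 3),
                                         tooth_show = c(0, 100)), 300)
  expect_equal(s2$relative_smile_time, 30)
  expect_equal(s2$mean_au6, 1.5)
  # zero episodes: rates 0, means undefined
  s0 <- summarize_session(ep[0, ], 120)
  expect_equal(s0$n_episodes, 0L)
  expect_equal(s0$episodes_per_minute, 0)
  expect_equal(s0$relative_smile_time, 0)
  expect_true(is.na(s0$mean_duration) && is.na(s0$mean_au6))
})

test_that("raising thresholds never increases smiling; raising stand-by never increases episodes", {
  set.seed(77)
  sess <- simulate_session(synthetic_config(seed = 9, session_length = 60))
  ts <- sess$series
  for (i in 1:20) {
    th <- sort(runif(2, 0, 3))
    t2 <- sort(runif(2, 0, 3))
    lo <- classify_frames(ts, detection_config(th[1], t2[1]))
    hi <- classify_frames(ts, detection_config(th[2], t2[2]))
    expect_true(all(lo | !hi)) # hi is a pointwise subset of lo
  }
  smile <- classify_frames(ts)
  standbys <- c(0.2, 0.5, 1, 2, 4, 8)
  counts <- vapply(standbys,
                   function(sb) nrow(segment_episodes(smile, ts$fps, sb)),
                   integer(1))
  expect_true(all(diff(counts) <= 0L))
})

test_that("episode spans conserve classified smile frames and smile time", {
  set.seed(404)
  for (i in 1:20) {
    n <- sample(50:200, 1)
    smile <- runif(n) < 0.4
    fps <- sample(c(5, 10, 30), 1)
    spans <- segment_episodes(smile, fps, 2)
    covered <- sum(spans$offset - spans$onset + 1L)
    expect_gte(covered, sum(smile))
    # every classified smile frame lies inside some episode
    in_ep <- logical(n)
    for (k in seq_len(nrow(spans))) {
      in_ep[(spans$onset[k] + 1L):(spans$offset[k] + 1L)] <- TRUE
    }
    expect_true(all(in_ep[smile]))
    # relative smile time identity
    s <- summarize_session(
      tibble::tibble(duration = (spans$offset - spans$onset + 1L) / fps,
                     mean_au6 = 1, mean_au12 = 1, tooth_show = 0),
      n / fps)
    expect_equal(s$relative_smile_time, 100 * covered / n)
  }
})

test_that("episode CSV export carries the session metadata", {
  sess <- simulate_session(synthetic_config(seed = 18, session_length = 60))
  ep <- detect(sess$series)
  f <- withr::local_tempfile(fileext = ".csv")
  write_episodes_csv(ep, f)
  back <- utils::read.csv(f)
  expect_equal(nrow(back), nrow(ep))
  expect_equal(back$session_id, rep("synth_18", nrow(ep)))
  expect_named(back, c("session_id", "index", "onset_frame", "offset_frame",
                       "onset_time_s", "duration_s", "mean_au6", "mean_au12",
                       "tooth_show_pct"))
})
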