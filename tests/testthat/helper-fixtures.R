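# Build a small AU time series directly from AU vectors (fps defaults to 1
# so frame indices double as seconds).
make_series <- function(au6, au12, au25 = rep(FALSE, length(au6)),
                        success = rep(TRUE, length(au6)), fps = 1,
                        session_id = "fixture") {
  n <- length(au6)
  au_timeseries(tibble::tibble(
    frame = seq_len(n) - 1L,
    timestamp = (seq_len(n) - 1L) / fps,
    confidence = 0.99,
    success = success,
    au6 = au6, au12 = au12, au25 = au25),
    session_id = session_id, fps = fps)
}

# Write an OpenFace-style CSV (with the dialect's leading-space headers).
write_openface_fixture <- function(file, frame, timestamp, au6, au12, au25,
                                   success = rep(1, length(frame)),
                                   extra_header_space = TRUE) {
  sep <- if (extra_header_space) ", " else ","
  header <- paste(c("frame", "timestamp", "confidence", "success",
                    "AU06_r", "AU12_r", "AU25_c"), collapse = sep)
  rows <- sprintf("%d,%.10f,0.98,%d,%g,%g,%d",
                  frame, timestamp, success, au6, au12, as.integer(au25))
  writeLines(c(header, rows), file)
  file
}

# Independent brute-force oracle for episode segmentation: enumerate runs,
# then repeatedly merge the first adjacent pair whose gap is < standby.
oracle_segment <- function(smile, fps, standby) {
  runs <- NULL
  i <- 1L
  n <- length(smile)
  while (i <= n) {
    if (smile[i]) {
      j <- i
      while (j < n && smile[j + 1L]) j <- j + 1L
      runs <- rbind(runs, c(i, j))
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (is.null(runs)) {
    return(tibble::tibble(onset = integer(), offset = integer()))
  }
  repeat {
    merged <- FALSE
    if (nrow(runs) >= 2L) {
      for (k in seq_len(nrow(runs) - 1L)) {
        gap <- runs[k + 1L, 1L] - runs[k, 2L] - 1L
        if (gap / fps < standby) {
          runs[k, 2L] <- runs[k + 1L, 2L]
          runs <- runs[-(k + 1L), , drop = FALSE]
          merged <- TRUE
          break
        }
      }
    }
    if (!merged) break
  }
  tibble::tibble(onset = runs[, 1L] - 1L, offset = runs[, 2L] - 1L)
}

# A batch of separable synthetic sessions shared by calibration tests.
make_calibration_batch <- function(n_sessions = 6, seed_base = 100,
                                   noise_sd = 0.05, length_s = 60) {
  lapply(seq_len(n_sessions), function(i) {
    s <- simulate_session(synthetic_config(
      seed = seed_base + i, session_length = length_s, noise_sd = noise_sd))
    list(series = s$series, track = s$truth)
  })
}
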