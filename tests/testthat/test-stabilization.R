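make_series <- function(values, channel = "H") {
  df <- tibble::tibble(frame = seq_along(values),
                       t_s = seq_along(values) - 1)
  df[[channel]] <- values
  df
}

test_that("clean_series removes exactly the rows with any missing channel", {
  ts <- generate_color_kinetics(kinetics_config(noise_sd = 0), seed = 1)
  expect_identical(as.data.frame(clean_series(ts)), as.data.frame(ts))

  ts$H[c(10, 50, 100, 400, 599)] <- NA
  expect_equal(nrow(clean_series(ts)), 595)

  ## interleaved gaps across channels: removed iff any channel missing
  ts2 <- generate_color_kinetics(kinetics_config(noise_sd = 0), seed = 1)
  ts2$S[c(3, 7)] <- NA
  ts2$a[c(7, 11, 20)] <- NA
  ts2$Cr[500] <- NA
  bad <- sort(unique(c(3, 7, 11, 20, 500)))
  cleaned <- clean_series(ts2)
  expect_equal(nrow(cleaned), 600 - length(bad))
  ## brute-force row scan oracle
  keep_oracle <- vapply(seq_len(600), function(i) {
    !anyNA(unlist(ts2[i, chans12]))
  }, logical(1))
  expect_equal(cleaned$frame, which(keep_oracle))

  ts3 <- ts2[1:4, ]
  ts3$H[1:3] <- NA
  expect_error(clean_series(ts3), class = "halochrom_validation_error")
})

test_that("numerical gradient matches analytic derivatives", {
  expect_equal(numerical_gradient(rep(3.2, 50)), rep(0, 50))
  expect_equal(numerical_gradient(0.01 * (0:99)), rep(0.01, 100))
  expect_error(numerical_gradient(1), class = "halochrom_validation_error")

  t <- 0:599
  g <- numerical_gradient(sin(0.02 * t), t_s = t)
  expect_equal(g[2:599], 0.02 * cos(0.02 * t[2:599]), tolerance = 1e-3)
})

test_that("constant series stabilize immediately; persistent ramps never do", {
  const <- make_series(rep(0.4, 600))
  res <- detect_stabilization(const, "H")
  expect_true(res$stabilized)
  expect_equal(res$stabilization_frame, 1L)

  ramp <- make_series(0.01 * (0:599))
  res2 <- detect_stabilization(ramp, "H")
  expect_false(res2$stabilized)
  expect_true(is.na(res2$stabilization_frame))

  short <- make_series(rep(0.4, 30))
  expect_error(detect_stabilization(short, "H"),
               class = "halochrom_validation_error")
})

test_that("noiseless logistic stabilization matches the analytic slope oracle", {
  params <- stabilization_params()
  for (case in list(c(mid = 300, rate = 0.05), c(mid = 200, rate = 0.03),
                    c(mid = 150, rate = 0.1))) {
    cfg <- default_kinetics(8, noise_sd = 0,
                            transition_midpoint_s = case[["mid"]],
                            transition_rate = case[["rate"]])
    ts <- generate_color_kinetics(cfg, seed = 1)
    det <- detect_stabilization(ts, "H", params)
    amp <- cfg$plateau_features[["H"]] - cfg$baseline_features[["H"]]
    oracle <- logistic_settle_frame(amp, case[["rate"]], case[["mid"]],
                                    params$slope_threshold, 600)
    expect_true(det$stabilized)
    expect_lt(abs(det$stabilization_frame - oracle), params$ma_window + 1)
  }
})

test_that("low-noise kinetics recover the planted settling frame", {
  params <- stabilization_params()
  cfg <- default_kinetics(8, noise_sd = 5e-4, transition_midpoint_s = 300)
  amp <- cfg$plateau_features[["H"]] - cfg$baseline_features[["H"]]
  oracle <- logistic_settle_frame(amp, cfg$transition_rate, 300,
                                  params$slope_threshold, 600)
  for (seed in 1:5) {
    ts <- generate_color_kinetics(cfg, seed = seed)
    det <- detect_stabilization(ts, "H", params)
    expect_true(det$stabilized)
    expect_lt(abs(det$stabilization_frame - oracle), 31)
  }
})

test_that("detection is monotone in threshold and run length, shift-invariant", {
  ## single-peaked (noiseless) slope profile, where the ordering is exact
  cfg <- default_kinetics(8, noise_sd = 0, transition_midpoint_s = 250)
  ts <- generate_color_kinetics(cfg, seed = 4)

  frames <- vapply(c(5e-4, 1e-3, 2e-3, 5e-3), function(th) {
    r <- detect_stabilization(ts, "H", stabilization_params(slope_threshold = th))
    if (r$stabilized) r$stabilization_frame else NA_integer_
  }, integer(1))
  ok <- !is.na(frames)
  expect_true(all(diff(frames[ok]) <= 0)) # higher threshold: never later

  frames_k <- vapply(c(10, 30, 50, 100), function(k) {
    r <- detect_stabilization(ts, "H",
                              stabilization_params(consecutive_frames = k))
    if (r$stabilized) r$stabilization_frame else NA_integer_
  }, integer(1))
  ok <- !is.na(frames_k)
  expect_true(all(diff(frames_k[ok]) >= 0)) # longer run: never earlier

  shifted <- ts
  shifted$H <- shifted$H + 0.37
  expect_equal(detect_stabilization(shifted, "H"),
               detect_stabilization(ts, "H"))
})

test_that("response_time reports the primary channel and handles options", {
  ts <- generate_color_kinetics(default_kinetics(8, noise_sd = 0), seed = 1)
  y <- response_time(ts)
  expect_equal(y$channel, "H")
  expect_equal(y, detect_stabilization(ts, "H"))

  all3 <- response_time(ts, require_all = TRUE)
  expect_true(all3$stabilized)
  times <- vapply(c("H", "S", "a"), function(ch) {
    detect_stabilization(ts, ch)$stabilization_time_s
  }, numeric(1))
  expect_equal(all3$stabilization_time_s, max(times))

  no_h <- ts[, setdiff(names(ts), "H")]
  expect_error(response_time(no_h), "H",
               class = "halochrom_validation_error")
})
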