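#' Parameters of the stabilization (steady-state) detector
#'
#' @param slope_threshold Steady-state threshold on the moving-averaged
#'   absolute slope, in channel units per frame (default 0.001).
#' @param consecutive_frames Number of consecutive sub-threshold frames
#'   required to declare stabilization (default 50).
#' @param ma_window Moving-average window applied to the absolute gradient, in
#'   frames (default 10; centered, partial windows at the edges). The window
#'   length is not prescribed by the detection rule itself — 10 frames smooths
#'   frame-level noise without masking the 50-frame run criterion.
#' @export
stabilization_params <- function(slope_threshold = 0.001,
                                 consecutive_frames = 50,
                                 ma_window = 10) {
  check_number(slope_threshold, "slope_threshold", min = 0, strict_min = TRUE)
  check_number(consecutive_frames, "consecutive_frames", min = 1, integer = TRUE)
  check_number(ma_window, "ma_window", min = 1, integer = TRUE)
  structure(
    list(slope_threshold = slope_threshold,
         consecutive_frames = as.integer(consecutive_frames),
         ma_window = as.integer(ma_window)),
    class = "stabilization_params"
  )
}

#' Drop incomplete frames from a color time series
#'
#' Removes every row with a missing value in any channel column, preserving the
#' surviving timestamps.
#'
#' @param series A `color_ts` tibble (or any data frame with `t_s` and channel
#'   columns).
#' @return The cleaned series; errors if fewer than 2 complete rows remain.
#' @export
clean_series <- function(series) {
  chans <- intersect(CHANNELS, names(series))
  keep <- stats::complete.cases(series[, chans, drop = FALSE])
  out <- series[keep, , drop = FALSE]
  if (nrow(out) < 2L) {
    abort("fewer than 2 complete rows remain after cleaning",
          class = "halochrom_validation_error")
  }
  out
}

#' Numerical gradient of a sampled signal
#'
#' Central differences at interior points and one-sided differences at the
#' endpoints (the convention of the classic `gradient` routine). With the
#' default unit spacing, slopes are in channel units per frame.
#'
#' @param values Numeric vector, length >= 2.
#' @param t_s Optional timestamps; if supplied, slopes are per actual spacing
#'   (must be strictly increasing).
#' @return Numeric vector of per-frame slopes, same length as `values`.
#' @export
numerical_gradient <- function(values, t_s = NULL) {
  n <- length(values)
  if (n < 2L) {
    abort("need at least 2 frames to compute a gradient",
          class = "halochrom_validation_error")
  }
  if (is.null(t_s)) t_s <- seq_len(n)
  if (length(t_s) != n || any(diff(t_s) <= 0)) {
    abort("`t_s` must be strictly increasing and match `values`",
          class = "halochrom_validation_error")
  }
  g <- numeric(n)
  g[1] <- (values[2] - values[1]) / (t_s[2] - t_s[1])
  g[n] <- (values[n] - values[n - 1]) / (t_s[n] - t_s[n - 1])
  if (n > 2L) {
    i <- 2:(n - 1)
    g[i] <- (values[i + 1] - values[i - 1]) / (t_s[i + 1] - t_s[i - 1])
  }
  g
}

#' Detect the stabilization point of one color channel
#'
#' Implements the steady-state rule used to define the pH response time: the
#' absolute numerical gradient of the channel is smoothed with a moving
#' average, and the series is declared stabilized at the first frame starting a
#' run of at least `consecutive_frames` frames whose smoothed absolute slope
#' stays below `slope_threshold`. The reported time is the start of the
#' qualifying run — the moment the color transition is complete.
#'
#' Because a film that has not yet started its transition is also quiet, the
#' search is restricted to frames after the transition onset — the first frame
#' whose smoothed absolute slope reaches the threshold. A series that never
#' exceeds the threshold at all (a constant series, or a visually
#' imperceptible transition as in acidic buffer) is reported stabilized at the
#' first frame.
#'
#' @param series A cleaned `color_ts`.
#' @param channel Channel name (one of the 12 channel columns).
#' @param params A [stabilization_params()].
#' @return A one-row tibble: `channel`, `stabilized`, `stabilization_frame`,
#'   `stabilization_time_s` (frame/time are `NA` when not stabilized).
#' @export
detect_stabilization <- function(series, channel = "H",
                                 params = stabilization_params()) {
  if (!channel %in% names(series)) {
    abort(sprintf("channel `%s` not present in series", channel),
          class = "halochrom_validation_error")
  }
  v <- series[[channel]]
  n <- length(v)
  if (n < params$consecutive_frames) {
    abort("series shorter than the consecutive-frame criterion",
          class = "halochrom_validation_error")
  }
  ## Slopes per frame at unit spacing; non-uniform timestamps rescale slopes
  ## to per-second so a 1 s frame period gives identical numbers.
  t_s <- if ("t_s" %in% names(series)) series$t_s else NULL
  g <- numerical_gradient(v, t_s)
  sm <- movmean(abs(g), params$ma_window)
  below <- sm < params$slope_threshold
  onset <- which(!below)[1]
  if (is.na(onset)) {
    ## never exceeds the threshold: quiet throughout, stabilized immediately
    f <- 1L
  } else {
    below[seq_len(onset)] <- FALSE
    f <- first_run_start(below, params$consecutive_frames)
  }
  tibble(
    channel = channel,
    stabilized = !is.na(f),
    stabilization_frame = if (is.na(f)) NA_integer_ else as.integer(f),
    stabilization_time_s = if (is.na(f)) NA_real_ else {
      if (is.null(t_s)) as.numeric(f) else t_s[f]
    }
  )
}

#' pH response time of a film sample
#'
#' Applies [detect_stabilization()] to the primary transition channel (Hue by
#' default — the channel with the most distinct and reliable sigmoidal
#' transition) and reports its stabilization time as the response time `y`.
#' Optionally requires all three discriminative channels (H, S, a) to have
#' stabilized, in which case the response time is the latest of the three.
#'
#' @inheritParams detect_stabilization
#' @param channel Primary channel, default `"H"`.
#' @param require_all If `TRUE`, H, S and a must all stabilize; the reported
#'   time is the maximum of the three.
#' @return A one-row tibble as in [detect_stabilization()].
#' @export
response_time <- function(series, params = stabilization_params(),
                          channel = "H", require_all = FALSE) {
  needed <- if (require_all) c("H", "S", "a") else channel
  missing_ch <- setdiff(needed, names(series))
  if (length(missing_ch) > 0L) {
    abort(sprintf("channel `%s` not present in series", missing_ch[1]),
          class = "halochrom_validation_error")
  }
  if (!require_all) {
    return(detect_stabilization(series, channel, params))
  }
  res <- purrr::map_dfr(c("H", "S", "a"),
                        function(ch) detect_stabilization(series, ch, params))
  if (!all(res$stabilized)) {
    return(tibble(channel = "H+S+a", stabilized = FALSE,
                  stabilization_frame = NA_integer_,
                  stabilization_time_s = NA_real_))
  }
  i <- which.max(res$stabilization_time_s)
  tibble(channel = "H+S+a", stabilized = TRUE,
         stabilization_frame = res$stabilization_frame[i],
         stabilization_time_s = res$stabilization_time_s[i])
}
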