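#' Convert sRGB colors into the 12-channel colorimetric feature vector
#'
#' Expands unit-scaled sRGB triples into the feature vector used throughout the
#' package: the RGB components themselves, CIELAB (`L`, `a`, `b`; D65 reference
#' white, sRGB linearized before the XYZ transform), HSV (`H` stored as a
#' fraction of the hue circle in `[0, 1)`, achromatic hue defined as 0), and
#' analog BT.601 YCbCr scaled so `Y` lies in `[0, 1]` and `Cb`, `Cr` lie in
#' `[0, 1]` with the neutral axis at 0.5.
#'
#' @param rgb A numeric vector of length 3, or a matrix/data frame with three
#'   columns (R, G, B), all components in `[0, 1]`.
#' @return A tibble with one row per input color and columns
#'   `R, G, B, L, a, b, H, S, V, Y, Cb, Cr`.
#' @examples
#' convert_color_spaces(c(0.5, 0.5, 0.5))
#' convert_color_spaces(rbind(c(1, 0, 0), c(1, 1, 1)))
#' @export
convert_color_spaces <- function(rgb) {
  if (is.data.frame(rgb)) rgb <- as.matrix(rgb)
  if (is.null(dim(rgb))) {
    if (length(rgb) != 3L) {
      abort("`rgb` must have 3 components", class = "halochrom_validation_error")
    }
    rgb <- matrix(rgb, nrow = 1L)
  }
  if (ncol(rgb) != 3L || !is.numeric(rgb)) {
    abort("`rgb` must be numeric with 3 columns", class = "halochrom_validation_error")
  }
  if (anyNA(rgb) || any(rgb < 0) || any(rgb > 1)) {
    abort("`rgb` components must lie in [0, 1]",
          class = "halochrom_validation_error")
  }
  r <- rgb[, 1L]; g <- rgb[, 2L]; b <- rgb[, 3L]

  lab <- grDevices::convertColor(rgb, from = "sRGB", to = "Lab")

  hsv <- t(grDevices::rgb2hsv(t(rgb), maxColorValue = 1))

  ## BT.601 analog luma/chroma, unit-scaled with neutral chroma at 0.5.
  y <- 0.299 * r + 0.587 * g + 0.114 * b
  cb <- 0.5 + 0.5 * (b - y) / (1 - 0.114)
  cr <- 0.5 + 0.5 * (r - y) / (1 - 0.299)

  tibble(
    R = unname(r), G = unname(g), B = unname(b),
    L = unname(lab[, 1L]), a = unname(lab[, 2L]), b = unname(lab[, 3L]),
    H = unname(hsv[, 1L]), S = unname(hsv[, 2L]), V = unname(hsv[, 3L]),
    Y = unname(y), Cb = unname(cb), Cr = unname(cr)
  )
}

#' Mean foreground color features of a masked film image
#'
#' Averages the RGB values over the foreground (mask) pixels and converts the
#' mean color with [convert_color_spaces()]. Averaging is performed in sRGB
#' before any conversion, which sidesteps circular-mean issues for hue.
#'
#' @param image A `film_image` (see [generate_film_image()]) or any list with
#'   elements `pixels` (H x W x 3 array, values in `[0, 1]`) and `mask`
#'   (H x W logical or 0/1 matrix).
#' @return A one-row tibble of the 12 color channels.
#' @export
extract_masked_means <- function(image) {
  px <- image$pixels
  mask <- image$mask
  if (is.null(px) || is.null(mask) || length(dim(px)) != 3L ||
      !all(dim(px)[1:2] == dim(mask))) {
    abort("`image` must carry `pixels` (HxWx3) and a matching `mask`",
          class = "halochrom_validation_error")
  }
  keep <- as.logical(mask)
  if (!any(keep)) {
    abort("mask selects no foreground pixels: no region of interest",
          class = "halochrom_empty_mask_error")
  }
  mean_rgb <- vapply(1:3, function(ch) mean(px[, , ch][keep]), numeric(1))
  convert_color_spaces(mean_rgb)
}

#' Build a color time series from an ordered sequence of film images
#'
#' @param images List of `film_image` objects (all with identical dimensions),
#'   ordered by acquisition time; at least two frames.
#' @param frame_rate Frames per second (default 1, one frame per second).
#' @return A `color_ts` tibble with columns `frame`, `t_s` and the 12 channels;
#'   `t_s = (frame - 1) / frame_rate` so the series starts at 0 s.
#' @export
build_time_series <- function(images, frame_rate = 1) {
  check_number(frame_rate, "frame_rate", min = 0, strict_min = TRUE)
  if (!is.list(images) || length(images) < 2L) {
    abort("`images` must contain at least 2 frames",
          class = "halochrom_validation_error")
  }
  dims <- lapply(images, function(im) dim(im$pixels))
  if (length(unique(dims)) != 1L) {
    abort("all frames must share the same dimensions",
          class = "halochrom_validation_error")
  }
  feats <- purrr::map_dfr(images, extract_masked_means)
  n <- length(images)
  out <- dplyr::bind_cols(
    tibble(frame = seq_len(n), t_s = (seq_len(n) - 1) / frame_rate),
    feats
  )
  new_color_ts(out)
}

new_color_ts <- function(df, sample_id = NA_character_, peg_pct = NA_real_,
                         btb_pct = NA_real_, ph = NA_real_) {
  structure(
    df,
    sample_id = sample_id, peg_pct = peg_pct, btb_pct = btb_pct, ph = ph,
    class = c("color_ts", class(tibble()))
  )
}

#' @export
print.color_ts <- function(x, ...) {
  ph <- attr(x, "ph")
  cat(sprintf("<color_ts: %d frames%s>\n", nrow(x),
              if (is.na(ph)) "" else sprintf(", pH %g", ph)))
  NextMethod()
}
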