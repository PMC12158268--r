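#' Configuration for synthetic color-kinetics generation
#'
#' Describes one film sample's color transition as independent logistic
#' (sigmoidal) trajectories in each of the 12 color channels:
#' `v(t) = v0 + (vInf - v0) / (1 + exp(-rate * (t - midpoint)))`, plus optional
#' i.i.d. Gaussian noise, clipped to each channel's admissible range.
#'
#' @param baseline_features,plateau_features Named numeric vectors over the 12
#'   channels (`R,G,B,L,a,b,H,S,V,Y,Cb,Cr`) giving the initial (`v0`) and final
#'   (`vInf`) channel values. Defaults are derived from representative film
#'   colors via [convert_color_spaces()].
#' @param transition_midpoint_s Midpoint of the logistic transition, seconds;
#'   must satisfy `0 < transition_midpoint_s < duration_s`.
#' @param transition_rate Logistic rate, 1/s; must be positive.
#' @param noise_sd Gaussian noise standard deviation in channel units (applied
#'   to every channel); must be non-negative.
#' @param frame_rate Frames per second (default 1).
#' @param duration_s Total duration, seconds (default 600, i.e. a 10-minute
#'   acquisition at one frame per second). `duration_s * frame_rate` must be a
#'   positive integer.
#' @return A `kinetics_config` list.
#' @seealso [default_kinetics()] for the built-in per-pH presets.
#' @export
kinetics_config <- function(baseline_features = NULL,
                            plateau_features = NULL,
                            transition_midpoint_s = 150,
                            transition_rate = 0.05,
                            noise_sd = 5e-4,
                            frame_rate = 1,
                            duration_s = 600) {
  if (is.null(baseline_features)) {
    baseline_features <- feature_vec(convert_color_spaces(c(0.88, 0.84, 0.45)))
  }
  if (is.null(plateau_features)) {
    plateau_features <- feature_vec(convert_color_spaces(c(0.20, 0.45, 0.75)))
  }
  for (nm in c("baseline_features", "plateau_features")) {
    v <- get(nm)
    if (!is.numeric(v) || !all(CHANNELS %in% names(v))) {
      abort(sprintf("invalid value for field `%s`: must name all 12 channels", nm),
            class = "halochrom_validation_error")
    }
  }
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(transition_rate, "transition_rate", min = 0, strict_min = TRUE)
  check_number(duration_s, "duration_s", min = 0, strict_min = TRUE)
  check_number(transition_midpoint_s, "transition_midpoint_s",
               min = 0, max = duration_s, strict_min = TRUE, strict_max = TRUE)
  check_number(frame_rate, "frame_rate", min = 0, strict_min = TRUE)
  n_frames <- duration_s * frame_rate
  if (abs(n_frames - round(n_frames)) > 1e-9 || n_frames < 1) {
    abort("invalid value for field `duration_s`: duration_s * frame_rate must be a positive integer",
          class = "halochrom_validation_error")
  }
  structure(
    list(
      baseline_features = baseline_features[CHANNELS],
      plateau_features = plateau_features[CHANNELS],
      transition_midpoint_s = transition_midpoint_s,
      transition_rate = transition_rate,
      noise_sd = noise_sd,
      frame_rate = frame_rate,
      duration_s = duration_s
    ),
    class = "kinetics_config"
  )
}

feature_vec <- function(df) {
  v <- as.numeric(df[1, CHANNELS])
  names(v) <- CHANNELS
  v
}

## Representative plateau film colors by pH: yellow in acid (pH 6), green at
## neutrality (pH 7), blue in base with hue increasing from pH 8 to pH 10.
ph_plateau_rgb <- function(ph) {
  switch(as.character(ph),
    "6"  = c(0.90, 0.82, 0.20),
    "7"  = c(0.35, 0.70, 0.35),
    "8"  = c(0.20, 0.45, 0.75),
    "9"  = c(0.15, 0.35, 0.80),
    "10" = c(0.15, 0.25, 0.85),
    abort(sprintf("no default plateau color for pH %s", ph),
          class = "halochrom_validation_error")
  )
}

## Default transition midpoints (s) by pH: fastest in acid (pH 6), slowest at
## the buffering point (pH 7), fastest alkaline response at pH 8 with slower
## stabilization at pH 9-10.
ph_midpoint_s <- function(ph) {
  switch(as.character(ph),
    "6" = 90, "7" = 210, "8" = 120, "9" = 150, "10" = 165,
    abort(sprintf("no default transition midpoint for pH %s", ph),
          class = "halochrom_validation_error")
  )
}

#' Built-in kinetics presets by buffer pH
#'
#' Returns a [kinetics_config()] whose plateau color and transition midpoint
#' encode the qualitative behavior of the film across pH 6-10: a barely
#' perceptible yellow-to-yellow shift in acid, a yellow-to-green transition at
#' pH 7 (the slowest, reflecting buffering near neutrality), and
#' yellow-to-blue transitions in base, fastest at pH 8, with the plateau hue
#' increasing monotonically from pH 8 to pH 10.
#'
#' @param ph Buffer pH, one of 6, 7, 8, 9, 10.
#' @param ... Overrides passed on to [kinetics_config()].
#' @export
default_kinetics <- function(ph, ...) {
  args <- list(...)
  defaults <- list(
    plateau_features = feature_vec(convert_color_spaces(ph_plateau_rgb(ph))),
    transition_midpoint_s = ph_midpoint_s(ph)
  )
  do.call(kinetics_config, utils::modifyList(defaults, args))
}

#' Generate a synthetic color-kinetics time series
#'
#' Simulates the per-frame 12-channel color trajectory of one film sample: each
#' channel follows a logistic curve between its baseline and plateau value,
#' with additive Gaussian noise clipped to the channel's admissible range
#' after noise is applied. With `noise_sd = 0` the output equals the logistic
#' exactly at every frame.
#'
#' @param config A [kinetics_config()].
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @param ph,sample_id Optional metadata attached to the returned series.
#' @return A `color_ts` tibble (`frame`, `t_s`, 12 channel columns).
#' @examples
#' ts <- generate_color_kinetics(default_kinetics(8), seed = 1)
#' @export
generate_color_kinetics <- function(config, seed = 1L, ph = NA_real_,
                                    sample_id = NA_character_) {
  if (!inherits(config, "kinetics_config")) {
    abort("`config` must be a kinetics_config",
          class = "halochrom_validation_error")
  }
  n <- as.integer(round(config$duration_s * config$frame_rate))
  t_s <- (seq_len(n) - 1) / config$frame_rate
  set.seed(seed)
  sig <- 1 / (1 + exp(-config$transition_rate * (t_s - config$transition_midpoint_s)))
  vals <- lapply(CHANNELS, function(ch) {
    v0 <- config$baseline_features[[ch]]
    v1 <- config$plateau_features[[ch]]
    v <- v0 + (v1 - v0) * sig
    if (config$noise_sd > 0) {
      v <- v + rnorm(n, 0, config$noise_sd)
      rng <- CHANNEL_RANGES[[ch]]
      v <- pmin(pmax(v, rng[1]), rng[2])
    }
    v
  })
  names(vals) <- CHANNELS
  out <- dplyr::bind_cols(tibble(frame = seq_len(n), t_s = t_s), as_tibble(vals))
  new_color_ts(out, sample_id = sample_id, ph = ph)
}

#' Full-factorial design of the formulation experiment
#'
#' Defaults reproduce the experimental design: PEG at 6/8/10 % w/v crossed with
#' BTB at 0.01/0.03/0.05 % w/v (nine formulations), each tested at five buffer
#' pH levels (6-10) with four replicate films per pH — 20 films per formulation
#' and 180 records in total. Note the BTB scale: concentrations are on the
#' 0.01-0.05 % w/v scale used by the formulation table and the fitted response
#' surface (not the 1-5 % stock-solution scale).
#'
#' @param peg_levels,btb_levels,ph_levels Factor levels.
#' @param replicates_per_cell Replicate films per formulation x pH cell.
#' @export
design_spec <- function(peg_levels = c(6, 8, 10),
                        btb_levels = c(0.01, 0.03, 0.05),
                        ph_levels = 6:10,
                        replicates_per_cell = 4) {
  for (nm in c("peg_levels", "btb_levels", "ph_levels")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) == 0L || anyNA(v)) {
      abort(sprintf("invalid value for field `%s`", nm),
            class = "halochrom_validation_error")
    }
  }
  check_number(replicates_per_cell, "replicates_per_cell", min = 1, integer = TRUE)
  structure(
    list(peg_levels = peg_levels, btb_levels = btb_levels,
         ph_levels = ph_levels, replicates_per_cell = replicates_per_cell),
    class = "design_spec"
  )
}

#' Default additive pH effect on response time
#'
#' Offsets (seconds) added to the formulation response surface for each buffer
#' pH, encoding the observed ordering: fastest transition at pH 6, slowest at
#' pH 7, fastest alkaline transition at pH 8, slightly slower again at pH 9-10.
#'
#' @param ph Numeric vector of pH values (6-10).
#' @return Numeric vector of offsets in seconds.
#' @export
default_ph_effect <- function(ph) {
  offsets <- c("6" = -60, "7" = 80, "8" = -25, "9" = 15, "10" = 35)
  key <- as.character(ph)
  if (!all(key %in% names(offsets))) {
    abort("default pH effect defined for pH 6-10 only",
          class = "halochrom_validation_error")
  }
  unname(offsets[key])
}

#' Generate a synthetic formulation-response dataset
#'
#' Draws one response-time record per (formulation, pH, replicate):
#' `y = surface(x1, x2) + ph_effect(ph) + Normal(0, noise_sd^2)`, where `x1` is
#' the PEG concentration and `x2` the BTB concentration. With the default
#' design this yields the full 180-record dataset (9 formulations x 5 pH x 4
#' replicates) used for symbolic regression and ANOVA.
#'
#' @param design A [design_spec()].
#' @param surface Function of `(x1, x2)` returning the mean response time (s);
#'   default [fitness_eq2()], the published response surface. Must be defined
#'   (finite) at every design point.
#' @param ph_effect Function of pH returning an additive offset in seconds
#'   (default [default_ph_effect()]), or NULL for no pH effect.
#' @param noise_sd Replicate noise SD in seconds (default 100; combined with
#'   the default pH offsets this gives a within-cell SD of roughly 110 s,
#'   matching the scale of the published within-cell variability).
#' @param seed Integer seed.
#' @return A tibble with columns `peg_pct`, `btb_pct`, `ph`, `replicate`,
#'   `response_time_s`.
#' @export
generate_formulation_dataset <- function(design = design_spec(),
                                         surface = fitness_eq2,
                                         ph_effect = default_ph_effect,
                                         noise_sd = 100,
                                         seed = 1L) {
  if (!inherits(design, "design_spec")) {
    abort("`design` must be a design_spec", class = "halochrom_validation_error")
  }
  check_number(noise_sd, "noise_sd", min = 0)
  grid <- tidyr::expand_grid(
    peg_pct = design$peg_levels,
    btb_pct = design$btb_levels,
    ph = design$ph_levels,
    replicate = seq_len(design$replicates_per_cell)
  )
  mu <- tryCatch(
    suppressWarnings(surface(grid$peg_pct, grid$btb_pct)),
    error = function(e) {
      abort(sprintf("response surface undefined on a design point: %s",
                    conditionMessage(e)),
            class = "halochrom_domain_error")
    }
  )
  if (length(mu) == 1L) mu <- rep(mu, nrow(grid))
  if (anyNA(mu) || any(!is.finite(mu))) {
    abort("response surface undefined on a design point",
          class = "halochrom_domain_error")
  }
  off <- if (is.null(ph_effect)) 0 else ph_effect(grid$ph)
  set.seed(seed)
  eps <- if (noise_sd > 0) rnorm(nrow(grid), 0, noise_sd) else 0
  dplyr::mutate(grid, response_time_s = mu + off + eps)
}

#' Generate a synthetic film image with a rectangular foreground mask
#'
#' Produces an H x W x 3 sRGB raster with i.i.d. Gaussian pixel noise around a
#' mean color (clipped to `[0, 1]`) and a rectangular foreground mask covering
#' the central region (a margin of 1/8 of the shorter side is treated as
#' background, emulating a segmented film against its surround).
#'
#' @param mean_rgb Length-3 numeric in `[0, 1]`.
#' @param shape `c(height, width)` in pixels.
#' @param noise_sd Pixel noise SD in channel units.
#' @param seed Integer seed.
#' @return A `film_image` list with `pixels` (array) and `mask` (logical matrix).
#' @export
generate_film_image <- function(mean_rgb, shape = c(64, 64), noise_sd = 0,
                                seed = 1L) {
  if (!is.numeric(mean_rgb) || length(mean_rgb) != 3L || anyNA(mean_rgb) ||
      any(mean_rgb < 0) || any(mean_rgb > 1)) {
    abort("invalid value for field `mean_rgb`: must be 3 components in [0, 1]",
          class = "halochrom_validation_error")
  }
  if (length(shape) != 2L || any(shape < 1) || any(shape != round(shape))) {
    abort("invalid value for field `shape`", class = "halochrom_validation_error")
  }
  check_number(noise_sd, "noise_sd", min = 0)
  h <- shape[1]; w <- shape[2]
  set.seed(seed)
  px <- array(rep(mean_rgb, each = h * w), dim = c(h, w, 3))
  if (noise_sd > 0) {
    px <- px + array(rnorm(h * w * 3, 0, noise_sd), dim = c(h, w, 3))
    px <- pmin(pmax(px, 0), 1)
  }
  margin <- max(1L, floor(min(h, w) / 8))
  mask <- matrix(FALSE, h, w)
  rows <- (margin + 1L):(h - margin)
  cols <- (margin + 1L):(w - margin)
  mask[rows, cols] <- TRUE
  structure(list(pixels = px, mask = mask), class = "film_image")
}
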