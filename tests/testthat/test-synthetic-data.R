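test_that("noiseless kinetics equal the logistic exactly and are monotone", {
  cfg <- kinetics_config(noise_sd = 0, transition_midpoint_s = 200,
                         transition_rate = 0.04)
  ts <- generate_color_kinetics(cfg, seed = 7)
  expect_equal(nrow(ts), 600)
  sig <- 1 / (1 + exp(-0.04 * (ts$t_s - 200)))
  for (ch in chans12) {
    v0 <- cfg$baseline_features[[ch]]
    v1 <- cfg$plateau_features[[ch]]
    expect_equal(ts[[ch]], v0 + (v1 - v0) * sig, tolerance = 0)
    dv <- diff(ts[[ch]])
    expect_true(all(dv * sign(v1 - v0) >= 0))
    expect_true(all(ts[[ch]] >= min(v0, v1) - 1e-12 &
                      ts[[ch]] <= max(v0, v1) + 1e-12))
  }
})

test_that("identical baseline and plateau with no noise gives a constant series", {
  cfg <- kinetics_config(noise_sd = 0)
  cfg2 <- kinetics_config(baseline_features = cfg$baseline_features,
                          plateau_features = cfg$baseline_features,
                          noise_sd = 0)
  ts <- generate_color_kinetics(cfg2, seed = 1)
  for (ch in chans12) {
    expect_equal(diff(range(ts[[ch]])), 0)
  }
})

test_that("kinetics generation is seed-deterministic and respects frame count", {
  cfg <- kinetics_config(noise_sd = 0.01, duration_s = 120, frame_rate = 2,
                         transition_midpoint_s = 60)
  a <- generate_color_kinetics(cfg, seed = 42)
  b <- generate_color_kinetics(cfg, seed = 42)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_equal(nrow(a), 240)
  c2 <- generate_color_kinetics(cfg, seed = 43)
  expect_false(identical(a$H, c2$H))
})

test_that("invalid kinetics configs raise validation errors naming the field", {
  expect_error(kinetics_config(noise_sd = -1), "noise_sd",
               class = "halochrom_validation_error")
  expect_error(kinetics_config(transition_rate = 0), "transition_rate",
               class = "halochrom_validation_error")
  expect_error(kinetics_config(transition_midpoint_s = 700),
               "transition_midpoint_s", class = "halochrom_validation_error")
  expect_error(kinetics_config(duration_s = 10.7, frame_rate = 1,
                               transition_midpoint_s = 5),
               "duration_s", class = "halochrom_validation_error")
})

test_that("the full design yields 180 balanced records", {
  dat <- generate_formulation_dataset(seed = 1)
  expect_equal(nrow(dat), 180)
  counts <- dplyr::count(dat, peg_pct, btb_pct)
  expect_equal(nrow(counts), 9)
  expect_true(all(counts$n == 20))
  per_ph <- dplyr::count(dat, peg_pct, btb_pct, ph)
  expect_true(all(per_ph$n == 4))
})

test_that("noiseless dataset with no pH effect reproduces the surface exactly", {
  dat <- generate_formulation_dataset(noise_sd = 0, ph_effect = NULL, seed = 5)
  expect_equal(dat$response_time_s, fitness_eq2(dat$peg_pct, dat$btb_pct),
               tolerance = 0)
})

test_that("the design-grid minimizer of the published surface is (6, 0.03)", {
  ## direct arithmetic over the 9 design cells
  cells <- expand.grid(x1 = c(6, 8, 10), x2 = c(0.01, 0.03, 0.05))
  vals <- mapply(eq2_by_terms, cells$x1, cells$x2)
  best <- cells[which.min(vals), ]
  expect_equal(best$x1, 6)
  expect_equal(best$x2, 0.03)
  dat <- generate_formulation_dataset(noise_sd = 0, ph_effect = NULL)
  agg <- dplyr::summarise(dplyr::group_by(dat, peg_pct, btb_pct),
                          y = mean(response_time_s), .groups = "drop")
  expect_equal(unlist(agg[which.min(agg$y), c("peg_pct", "btb_pct")]),
               c(peg_pct = 6, btb_pct = 0.03))
})

test_that("a surface undefined at a design point raises a domain error", {
  bad <- function(x1, x2) log(x2 - 0.02) # negative at btb = 0.01
  expect_error(generate_formulation_dataset(surface = bad, noise_sd = 0),
               class = "halochrom_domain_error")
})

test_that("film images are exact at zero noise and recoverable under noise", {
  img <- generate_film_image(c(0.3, 0.6, 0.9), shape = c(32, 40), noise_sd = 0)
  expect_equal(dim(img$pixels), c(32, 40, 3))
  for (ch in 1:3) {
    expect_true(all(img$pixels[, , ch][img$mask] == c(0.3, 0.6, 0.9)[ch]))
  }
  fv <- extract_masked_means(img)
  expect_equal(unname(unlist(fv[, c("R", "G", "B")])), c(0.3, 0.6, 0.9))

  ## standard-error bound on the noisy foreground mean
  img2 <- generate_film_image(c(0.4, 0.5, 0.6), shape = c(64, 64),
                              noise_sd = 0.01, seed = 11)
  n_fg <- sum(img2$mask)
  fv2 <- extract_masked_means(img2)
  for (ch in 1:3) {
    expect_lt(abs(unlist(fv2[, ch]) - c(0.4, 0.5, 0.6)[ch]),
              4 * 0.01 / sqrt(n_fg))
  }
  expect_error(generate_film_image(c(1.2, 0, 0)), "mean_rgb",
               class = "halochrom_validation_error")
})

test_that("film image generation is seed-deterministic", {
  a <- generate_film_image(c(0.2, 0.4, 0.8), noise_sd = 0.05, seed = 3)
  b <- generate_film_image(c(0.2, 0.4, 0.8), noise_sd = 0.05, seed = 3)
  expect_identical(a, b)
})
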