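# Sprite, background, detection-stream and weather generators.

test_that("generate_sprites: construction, determinism, pose distinctness", {
  sp <- generate_sprites(seed = 1, n_poses = 1)
  expect_length(sp, 3)
  expect_setequal(vapply(sp, `[[`, character(1), "species"),
                  c("great_egret", "little_egret", "other"))
  for (s in sp) {
    a <- s$rgba[, , 4]
    expect_true(all(a %in% c(0, 255)))
    # tight box: first/last row and column contain opaque pixels
    expect_gt(sum(a[1, ]), 0); expect_gt(sum(a[nrow(a), ]), 0)
    expect_gt(sum(a[, 1]), 0); expect_gt(sum(a[, ncol(a)]), 0)
    expect_equal(s$box, c(0, 0, ncol(a), nrow(a)))
  }
  expect_identical(generate_sprites(5, 2), generate_sprites(5, 2))

  sp5 <- generate_sprites(seed = 2, n_poses = 5)
  species <- vapply(sp5, `[[`, character(1), "species")
  for (spc in unique(species)) {
    poses <- sp5[species == spc]
    for (i in seq_along(poses)) for (j in seq_len(i - 1)) {
      a <- poses[[i]]$rgba; b <- poses[[j]]$rgba
      differs <- !identical(dim(a), dim(b)) || sum(abs(a - b)) > 0
      expect_true(differs)
    }
  }
})

test_that("generate_background: size, determinism, seed sensitivity", {
  bg <- generate_background(256, 128, seed = 0)
  expect_equal(dim(bg), c(128, 256, 3))
  expect_identical(bg, generate_background(256, 128, seed = 0))
  expect_gt(sum(abs(bg - generate_background(256, 128, seed = 1))), 0)
  expect_error(generate_background(32, 256, seed = 0), "width")
})

test_that("simulate_detections plants a recoverable constant daily max", {
  cfg <- desk_config(n_days = 1, count_noise = "none",
                     base_count = c(great_egret = 3, little_egret = 0,
                                    other = 0),
                     multi_day_trend = FALSE,
                     trough_frac = 1)   # flat profile: always 3 birds
  sim <- simulate_detections(cfg)
  led <- sim$ledger$daily_max
  expect_equal(led$realized_max[led$species == "great_egret"], 3L)
  dc <- daily_count(sim$records, "great_egret")
  expect_equal(dc$count, 3L)
})

test_that("simulate_detections respects bands, frame bounds and window", {
  cfg <- desk_config(n_days = 2, count_noise = "poisson", seed = 3,
                     bands = list(great_egret = c(0.1, 0.7),
                                  little_egret = c(0.35, 0.65),
                                  other = c(0.05, 0.95)))
  sim <- simulate_detections(cfg)
  r <- sim$records
  H <- cfg$frame_height; W <- cfg$frame_width
  expect_true(all(r$x_min >= 0 & r$x_max <= W & r$y_min >= 0 & r$y_max <= H))
  sides <- c(r$x_max - r$x_min, r$y_max - r$y_min)
  expect_true(all(sides >= 42 - 1e-9 & sides <= 160 + 1e-9))
  mins <- as.numeric(r$timestamp - trunc(r$timestamp, "days"), units = "mins")
  expect_true(all(mins >= 240 & mins < 1200))
  yc <- (r$y_min + r$y_max) / 2
  for (sp in c("great_egret", "little_egret")) {
    b <- cfg$bands[[sp]]
    ycs <- yc[r$species == sp]
    expect_true(all(ycs >= b[1] * H - 1e-9 & ycs <= b[2] * H + 1e-9))
  }
  # determinism
  expect_identical(sim$records, simulate_detections(cfg)$records)
  # frame_interval exceeding the window is rejected
  bad <- desk_config(n_days = 1)
  bad$frame_interval <- 17 * 3600
  expect_error(simulate_detections(bad), "frame_interval")
})

test_that("simulate_weather: exact planted link at zero noise, shape, errors", {
  cfg62 <- sim_config(rng_seed = 4)
  sw <- simulate_weather(cfg62, noise_sd = 0)
  expect_equal(nrow(sw$weather), 62L)
  expect_true(all(weather_factor_names() %in% names(sw$weather)))
  # reconstruct ln(count) from the ledger: quadratic trend + beta . xdd
  n <- nrow(sw$weather)
  tt <- seq_len(n)
  xdd <- vapply(weather_factor_names(),
                function(f) detrend(sw$weather[[f]], tt)$residuals,
                numeric(n))
  tr <- sw$ledger$trend
  lny_hat <- tr[1] + tr[2] * tt + tr[3] * tt^2 +
    as.numeric(xdd %*% sw$ledger$beta)
  expect_equal(log(sw$weather$count_all), lny_hat, tolerance = 1e-10)
  # determinism
  expect_identical(sw$weather, simulate_weather(cfg62, noise_sd = 0)$weather)
  expect_error(simulate_weather(cfg62, coefficients = rep(NA_real_, 12)),
               "finite")
})

test_that("detection and weather CSV / ledger JSON round-trips", {
  cfg <- desk_config(n_days = 1, frame_interval = 1800)
  sim <- simulate_detections(cfg)
  p <- withr::local_tempfile(fileext = ".csv")
  write_detections_csv(sim$records, p)
  back <- read_detections_csv(p)
  expect_equal(back$timestamp, sim$records$timestamp)
  expect_equal(back$x_min, sim$records$x_min, tolerance = 1e-9)

  sw <- simulate_weather(desk_config(n_days = 6), seed = 5)
  pw <- withr::local_tempfile(fileext = ".csv")
  write_weather_csv(sw$weather, pw)
  backw <- read_weather_csv(pw)
  expect_equal(backw$date, sw$weather$date)
  expect_equal(backw$mean_temp_c, sw$weather$mean_temp_c, tolerance = 1e-9)

  pl <- withr::local_tempfile(fileext = ".json")
  write_ledger(sim$ledger, pl)
  led <- read_ledger(pl)
  expect_equal(led$daily_max$realized_max, sim$ledger$daily_max$realized_max)
})

test_that("simulate_feature_stack plants row-space signal, null-space noise", {
  fs <- simulate_feature_stack(seed = 9, h = 8, w = 8, d = 16, out_dim = 4)
  expect_equal(dim(fs$features), c(8, 8, 16))
  # projecting onto the row space must remove the noise: A x depends only
  # on the bump
  X <- matrix(aperm(fs$features, c(3, 1, 2)), nrow = 16)
  AX <- fs$A %*% X
  # each output coordinate proportional to the planted bump
  for (k in seq_len(nrow(AX))) {
    expect_equal(abs(stats::cor(AX[k, ], as.numeric(fs$signal))), 1,
                 tolerance = 1e-8)
  }
})
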