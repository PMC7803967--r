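# Synthetic monitoring-data generators.
#
# The simulator emulates what a trained detector would emit from a fixed
# camera watching a roost: per-frame detection records across a multi-day
# study period, with a diurnal occupancy profile (high before the morning
# departure, low over midday, high after the evening return), a multi-day
# rise-and-fall count trend with a migration surge, vertical stratification
# of the two egret species, and a weather table linked to log-counts
# through known coefficients. Every planted quantity is recorded in a
# ground-truth ledger so downstream estimators can be tested for recovery.

WEATHER_FACTORS <- c(
  "mean_pressure_hpa", "abs_max_temp_c", "mean_temp_c", "abs_min_temp_c",
  "mean_dew_point_c", "mean_rel_humidity_pct", "mean_cloud_pct",
  "total_rainfall_mm", "total_bright_sunshine_h", "mean_wind_speed_kmh",
  "wind_dir_ew_deg", "wind_dir_ns_deg")

#' Names of the twelve daily weather factors
#'
#' Order matches the regression report: mean pressure; absolute maximum,
#' mean and absolute minimum temperature; mean dew point; mean relative
#' humidity; mean cloud amount; total rainfall; total bright sunshine;
#' mean wind speed; prevailing wind direction east-west and north-south
#' components.
#' @return character vector of length 12.
#' @export
weather_factor_names <- function() WEATHER_FACTORS

#' Build a simulation configuration
#'
#' Defaults describe the emulated study: 2139 x 1281 px frames, recording
#' 04:00-20:00 each day, 62 consecutive days starting 2019-09-23, one
#' frame per minute, three species labels, a trapezoidal diurnal profile
#' peaking at the departure and return times, a rise-and-fall multi-day
#' trend with a late-October migration surge, and per-species vertical
#' occupancy bands (the great egret spans more of the tree height than the
#' little egret).
#'
#' @param frame_width,frame_height frame size in pixels.
#' @param day_span vector of `Date`s covered by the simulation.
#' @param recording_window `c("HH:MM", "HH:MM")` daily recording window.
#' @param frame_interval seconds between simulated frames (> 0).
#' @param base_count named per-species peak count on an average day.
#' @param trough_frac midday occupancy as a fraction of the peak.
#' @param departure_time,return_time clock times ("HH:MM") of the morning
#'   departure peak and the great egret's evening return peak.
#' @param return_offset_min minutes added to the little egret's return
#'   (positive = little egrets return later).
#' @param surge_center,surge_amplitude,surge_sd_days migration surge bump:
#'   date of the maximum, fractional amplitude, Gaussian width in days.
#' @param bands named list of `c(lo, hi)` vertical occupancy bands as
#'   fractions of frame height.
#' @param hotspot_centers,hotspot_sds,hotspot_weights horizontal hotspot
#'   mixture (fractions of frame width).
#' @param box_side_range bounding-box side range in pixels.
#' @param count_noise `"poisson"` for Poisson count noise, `"none"` for the
#'   deterministic rounded profile.
#' @param score_range detector confidence range for emitted records.
#' @param multi_day_trend apply the rise-and-fall trend and surge across
#'   days; `FALSE` keeps the per-species base counts constant over days.
#' @param rng_seed integer seed.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(frame_width = 2139L, frame_height = 1281L,
                       day_span = seq(as.Date("2019-09-23"),
                                      by = "day", length.out = 62L),
                       recording_window = c("04:00", "20:00"),
                       frame_interval = 60,
                       base_count = c(great_egret = 36, little_egret = 22,
                                      other = 3),
                       trough_frac = 0.12,
                       departure_time = "06:30",
                       return_time = "17:45",
                       return_offset_min = 45,
                       surge_center = as.Date("2019-10-29"),
                       surge_amplitude = 0.6,
                       surge_sd_days = 4,
                       bands = list(great_egret = c(0.10, 0.70),
                                    little_egret = c(0.35, 0.65),
                                    other = c(0.05, 0.95)),
                       hotspot_centers = c(0.62, 0.80),
                       hotspot_sds = c(0.05, 0.04),
                       hotspot_weights = c(0.6, 0.4),
                       box_side_range = c(42, 160),
                       count_noise = c("poisson", "none"),
                       score_range = c(0.55, 1.0),
                       multi_day_trend = TRUE,
                       rng_seed = 1L) {
  count_noise <- match.arg(count_noise)
  w0 <- hm_to_min(recording_window[1]); w1 <- hm_to_min(recording_window[2])
  assert_that(w0 < w1 && w1 <= 1440, "recording window must lie within one day")
  assert_that(frame_interval > 0, "frame_interval must be > 0")
  assert_that(all(base_count >= 0), "occupancy counts must be >= 0")
  assert_that(all(vapply(bands, function(b)
    b[1] >= 0 && b[2] <= 1 && b[1] < b[2], logical(1))),
    "vertical bands must be within [0, 1]")
  assert_that(all(SPECIES %in% names(base_count)) &&
                all(SPECIES %in% names(bands)),
              "base_count and bands must name all three species")
  structure(list(
    frame_width = as.integer(frame_width),
    frame_height = as.integer(frame_height),
    day_span = day_span,
    window_min = c(w0, w1),
    frame_interval = frame_interval,
    base_count = base_count,
    trough_frac = trough_frac,
    departure_min = hm_to_min(departure_time),
    return_min = hm_to_min(return_time),
    return_offset_min = return_offset_min,
    surge_center = surge_center,
    surge_amplitude = surge_amplitude,
    surge_sd_days = surge_sd_days,
    bands = bands,
    hotspot_centers = hotspot_centers,
    hotspot_sds = hotspot_sds,
    hotspot_weights = hotspot_weights,
    box_side_range = box_side_range,
    count_noise = count_noise,
    score_range = score_range,
    multi_day_trend = isTRUE(multi_day_trend),
    rng_seed = as.integer(rng_seed)
  ), class = "sim_config")
}

# Multi-day trend: triangular rise-and-fall within fixed sub-periods plus a
# Gaussian migration surge. Returns a positive multiplier per day.
day_trend <- function(config) {
  days <- config$day_span
  n <- length(days)
  if (!isTRUE(config$multi_day_trend)) return(rep(1, n))
  t01 <- if (n > 1) (seq_len(n) - 1) / (n - 1) else 0.5
  # five sub-periods of roughly equal length, peak mid-period
  k <- 5L
  phase <- (t01 * k) %% 1
  tri <- 1 - abs(2 * phase - 1)            # 0 at boundaries, 1 mid-period
  base <- 0.55 + 0.7 * tri
  dsurge <- as.numeric(days - config$surge_center)
  surge <- config$surge_amplitude * exp(-dsurge^2 / (2 * config$surge_sd_days^2))
  base + surge
}

# Species return minute, applying the little-egret offset.
species_return_min <- function(config, species) {
  config$return_min + if (species == "little_egret") config$return_offset_min else 0
}

# Diurnal shape in [0, 1] for minute-of-day m: linear rise into a one-hour
# plateau ending at the departure peak, fall to a midday trough, rise into
# a one-hour plateau ending at the return peak, then a slight decline as
# the returned birds settle into the canopy and become partly occluded.
# The backward 1-h moving average of this shape attains its morning
# maximum exactly at the departure minute and its evening maximum at the
# return minute (unique argmaxes).
diurnal_shape <- function(m, dep, ret, wend, ramp = 10) {
  s <- numeric(length(m))
  r0 <- dep - 60 - ramp
  sel <- m >= r0 & m < dep - 60
  s[sel] <- (m[sel] - r0) / ramp
  s[m >= dep - 60 & m <= dep] <- 1
  sel <- m > dep & m <= dep + 60
  s[sel] <- 1 - (m[sel] - dep) / 60
  r1 <- ret - 60 - ramp
  sel <- m >= r1 & m < ret - 60
  s[sel] <- pmax(s[sel], (m[sel] - r1) / ramp)
  s[m >= ret - 60 & m <= ret] <- 1
  late <- m > ret
  s[late] <- 1 - 0.15 * (m[late] - ret) / max(wend - ret, 1)
  s
}

#' Simulate a detection-record stream with a ground-truth ledger
#'
#' Emits one row per detected bird per frame across the configured study
#' period. Per-frame species counts follow the diurnal trapezoid profile
#' scaled by the multi-day trend (optionally Poisson-noised); bird centers
#' are drawn from the species' vertical band and a horizontal hotspot
#' mixture; box sides are uniform within the configured range and boxes
#' always lie inside the frame.
#'
#' @param config a [sim_config()].
#' @return list with elements
#'   \describe{
#'     \item{records}{data.frame with columns `timestamp` (POSIXct UTC),
#'       `species`, `x_min`, `y_min`, `x_max`, `y_max` (0-based half-open
#'       pixel boxes), `score`.}
#'     \item{ledger}{ground-truth ledger: `daily_max` (planted profile peak
#'       and realized per-day max per species), `schedule` (planted
#'       departure/return minute per species), and the occupancy
#'       parameters.}
#'   }
#' @export
simulate_detections <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  w0 <- config$window_min[1]; w1 <- config$window_min[2]
  assert_that(config$frame_interval <= (w1 - w0) * 60,
              "frame_interval larger than the recording window")
  # frames cover [start, end) of the recording window
  n_frames <- floor(((w1 - w0) * 60 - 1e-6) / config$frame_interval) + 1L
  frame_min <- (w0 * 60 + (seq_len(n_frames) - 1L) * config$frame_interval) / 60
  trend <- day_trend(config)
  W <- config$frame_width; H <- config$frame_height
  sides <- config$box_side_range

  with_seed(child_seed(config$rng_seed, "detections"), {
    recs <- vector("list", length(config$day_span) * length(SPECIES))
    daily_rows <- list()
    ri <- 0L
    for (di in seq_along(config$day_span)) {
      day <- config$day_span[di]
      day0 <- as.POSIXct(paste0(format(day), " 00:00:00"), tz = "UTC")
      for (species in SPECIES) {
        peak <- config$base_count[[species]] * trend[di]
        trough <- peak * config$trough_frac
        dep <- config$departure_min
        ret <- species_return_min(config, species)
        mu <- trough + (peak - trough) * diurnal_shape(frame_min, dep, ret, w1)
        counts <- if (config$count_noise == "poisson") rpois(length(mu), mu)
                  else as.integer(round(mu))
        total <- sum(counts)
        planted_peak <- if (config$count_noise == "poisson") max(round(mu))
                        else max(as.integer(round(mu)))
        daily_rows[[length(daily_rows) + 1L]] <- data.frame(
          date = day, species = species,
          planted_peak = planted_peak,
          realized_max = if (length(counts)) max(counts) else 0L)
        if (total == 0) next
        ts <- rep(day0 + frame_min * 60, counts)
        bw <- runif(total, sides[1], sides[2])
        bh <- runif(total, sides[1], sides[2])
        band <- config$bands[[species]]
        ycen <- clamp(runif(total, band[1], band[2]) * H, bh / 2, H - bh / 2)
        comp <- sample.int(length(config$hotspot_centers), total, replace = TRUE,
                           prob = config$hotspot_weights)
        xcen <- clamp(rnorm(total, config$hotspot_centers[comp] * W,
                            config$hotspot_sds[comp] * W), bw / 2, W - bw / 2)
        ri <- ri + 1L
        recs[[ri]] <- data.frame(
          timestamp = ts, species = species,
          x_min = xcen - bw / 2, y_min = ycen - bh / 2,
          x_max = xcen + bw / 2, y_max = ycen + bh / 2,
          score = runif(total, config$score_range[1], config$score_range[2]))
      }
    }
    records <- do.call(rbind, recs[seq_len(ri)])
    records <- records[order(records$timestamp), ]
    rownames(records) <- NULL
    ledger <- structure(list(
      daily_max = do.call(rbind, daily_rows),
      schedule = data.frame(
        species = SPECIES,
        departure_min = config$departure_min,
        return_min = vapply(SPECIES, function(s) species_return_min(config, s),
                            numeric(1))),
      occupancy = list(bands = config$bands,
                       hotspot_centers = config$hotspot_centers,
                       hotspot_sds = config$hotspot_sds,
                       hotspot_weights = config$hotspot_weights),
      frame = c(width = W, height = H),
      frame_interval = config$frame_interval
    ), class = "gt_ledger")
    list(records = records, ledger = ledger)
  })
}

#' Simulate a daily weather table linked to log bird counts
#'
#' Draws the twelve weather factors from independent, Hong-Kong-plausible
#' marginals, then sets
#' `ln(count) = a0 + a1 t + a2 t^2 + sum_i beta_i * xdd_ti + noise`,
#' where `xdd_ti` is factor i detrended by its own quadratic-in-time fit.
#' Because the planted link uses detrended factors, the detrend-then-
#' regress pipeline recovers `beta` exactly when `noise_sd = 0`.
#'
#' @param config a [sim_config()] (supplies the day span).
#' @param coefficients numeric vector of 12 planted regression
#'   coefficients, one per weather factor, in [weather_factor_names()]
#'   order. Defaults to plausible magnitudes for a roost-count link.
#' @param trend planted quadratic trend coefficients `c(a0, a1, a2)` for
#'   the log count over the day index `t = 1..n`.
#' @param noise_sd standard deviation of the Gaussian noise on the log
#'   count.
#' @param seed integer seed (defaults to the config seed).
#' @return list with `weather` (data.frame: `date`, the 12 factor columns,
#'   `count_all`) and `ledger` (planted `beta`, `trend`, `noise_sd`).
#' @export
simulate_weather <- function(config,
                             coefficients = c(-0.0098, 0.2460, -0.8448,
                                              0.0005, 0.7026, -0.1921,
                                              -0.0029, -0.0105, -0.1303,
                                              0.0109, 0.0070, 0.0019),
                             trend = c(3.8, 0.045, -0.00075),
                             noise_sd = 0.25,
                             seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  assert_that(length(coefficients) == 12 && all(is.finite(coefficients)),
              "coefficients must be 12 finite numbers")
  seed <- seed %||% config$rng_seed
  n <- length(config$day_span)
  with_seed(child_seed(seed, "weather"), {
    theta <- runif(n, 0, 360)
    wind <- wind_components(theta)
    fac <- data.frame(
      mean_pressure_hpa = rnorm(n, 1012, 3.5),
      abs_max_temp_c = rnorm(n, 29, 1.6),
      mean_temp_c = rnorm(n, 25.5, 1.3),
      abs_min_temp_c = rnorm(n, 22.5, 1.4),
      mean_dew_point_c = rnorm(n, 21, 1.5),
      mean_rel_humidity_pct = clamp(rnorm(n, 76, 6), 30, 100),
      mean_cloud_pct = runif(n, 10, 95),
      total_rainfall_mm = rbinom(n, 1, 0.4) * rexp(n, 1 / 6),
      total_bright_sunshine_h = runif(n, 0, 11),
      mean_wind_speed_kmh = pmax(rnorm(n, 20, 5), 0),
      wind_dir_ew_deg = wind[, "ew"],
      wind_dir_ns_deg = wind[, "ns"])
    tt <- seq_len(n)
    xdd <- vapply(fac, function(v) detrend(v, tt)$residuals, numeric(n))
    lny <- trend[1] + trend[2] * tt + trend[3] * tt^2 +
      as.numeric(xdd %*% coefficients) + rnorm(n, 0, noise_sd)
    weather <- cbind(data.frame(date = config$day_span), fac,
                     data.frame(count_all = exp(lny)))
    ledger <- structure(list(
      beta = stats::setNames(coefficients, WEATHER_FACTORS),
      trend = trend, noise_sd = noise_sd), class = "gt_ledger")
    list(weather = weather, ledger = ledger)
  })
}

#' Simulate a feature stack with planted row-space signal
#'
#' Builds an `h x w` grid of `d`-dimensional feature vectors consisting of
#' a smooth spatial bump carried by a row-space direction of the affine
#' operator `A`, plus noise confined to the null space of `A`. The
#' row/null-space split should therefore recover the bump and discard the
#' noise.
#'
#' @param seed integer seed.
#' @param h,w spatial grid size.
#' @param d feature dimension.
#' @param out_dim output dimension of the affine operator (< `d` so a
#'   nontrivial null space exists).
#' @param noise_sd standard deviation of the null-space noise.
#' @return list with `features` (array `[h, w, d]`), `A` (matrix
#'   `out_dim x d`), and `signal` (the planted `h x w` bump).
#' @export
simulate_feature_stack <- function(seed, h = 16L, w = 16L, d = 32L,
                                   out_dim = 8L, noise_sd = 1) {
  assert_that(out_dim < d, "out_dim must be smaller than d")
  with_seed(child_seed(seed, "featurestack"), {
    A <- matrix(rnorm(out_dim * d), out_dim, d)
    # signal direction in the row space, noise directions in the null space
    v_sig <- as.numeric(crossprod(A, rnorm(out_dim)))
    v_sig <- v_sig / sqrt(sum(v_sig^2))
    ns <- svd(A, nu = 0, nv = d)$v[, (out_dim + 1):d, drop = FALSE]
    cx <- runif(1, 0.3, 0.7) * w; cy <- runif(1, 0.3, 0.7) * h
    gx <- matrix(rep(seq_len(w) - 0.5, each = h), h, w)
    gy <- matrix(rep(seq_len(h) - 0.5, times = w), h, w)
    bump <- exp(-((gx - cx)^2 + (gy - cy)^2) / (2 * (0.15 * (h + w) / 2)^2))
    feats <- array(0, dim = c(h, w, d))
    noise_coef <- matrix(rnorm(h * w * ncol(ns), 0, noise_sd), h * w, ncol(ns))
    noise <- noise_coef %*% t(ns)
    for (k in seq_len(d)) {
      feats[, , k] <- bump * v_sig[k] + matrix(noise[, k], h, w)
    }
    list(features = feats, A = A, signal = bump)
  })
}
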