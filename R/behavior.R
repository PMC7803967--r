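# Behavioral analyses of detection streams: daily maximum counts,
# inter-species correlation, backward moving-average smoothing, and the
# daily departure/return schedule with its paired hypothesis tests.

#' Per-frame counts of a species
#'
#' @param records detection-record data.frame (see
#'   [simulate_detections()]).
#' @param species species label, or `"all"` to sum over the three labels
#'   before counting.
#' @param score_threshold minimum detector confidence for a record to
#'   count.
#' @return data.frame with `timestamp` (one row per frame that has any
#'   record at or above threshold) and `count`.
#' @export
frame_counts <- function(records, species = "all", score_threshold = 0.5) {
  keep <- records$score >= score_threshold
  if (species != "all") keep <- keep & records$species == species
  ts_all <- unique(records$timestamp)
  cnt <- table(factor(format(records$timestamp[keep], "%Y-%m-%d %H:%M:%S"),
                      levels = format(ts_all, "%Y-%m-%d %H:%M:%S")))
  out <- data.frame(timestamp = ts_all, count = as.integer(cnt))
  out[order(out$timestamp), , drop = FALSE]
}

#' Daily maximum count
#'
#' The site-occupancy proxy: for each calendar day, the maximum number of
#' birds of the species detected in any single frame. Days with no frames
#' are absent from the result (not zero).
#'
#' @inheritParams frame_counts
#' @return data.frame with `date` and `count`.
#' @export
daily_count <- function(records, species = "all", score_threshold = 0.5) {
  fc <- frame_counts(records, species, score_threshold)
  if (!nrow(fc)) return(data.frame(date = as.Date(character(0)),
                                   count = integer(0)))
  day <- as.Date(format(fc$timestamp, "%Y-%m-%d"))
  agg <- tapply(fc$count, day, max)
  data.frame(date = as.Date(names(agg)), count = as.integer(agg),
             row.names = NULL)
}

#' Pearson correlation between two aligned daily series
#'
#' @param a,b data.frames with `date` and `count` covering the same days.
#' @return the correlation coefficient, in `[-1, 1]`.
#' @export
pearson <- function(a, b) {
  assert_that(nrow(a) == nrow(b) && all(a$date == b$date),
              "series must be aligned on the same days")
  assert_that(nrow(a) >= 3, "need at least 3 paired days")
  assert_that(stats::var(a$count) > 0 && stats::var(b$count) > 0,
              "zero variance in a series")
  stats::cor(a$count, b$count, method = "pearson")
}

#' Backward moving average
#'
#' Value at time t is the mean of the samples with timestamps in
#' `(t - window, t]`; early points with a truncated window use the
#' available samples only.
#'
#' @param times POSIXct (or numeric seconds), strictly increasing.
#' @param values numeric, same length.
#' @param window window length in seconds (default one hour).
#' @return numeric vector of smoothed values.
#' @export
backward_moving_average <- function(times, values, window = 3600) {
  assert_that(window > 0, "window must be > 0")
  tnum <- as.numeric(times)
  n <- length(tnum)
  out <- numeric(n)
  lo <- 1L
  csum <- cumsum(values)
  for (i in seq_len(n)) {
    while (tnum[lo] <= tnum[i] - window) lo <- lo + 1L
    s <- csum[i] - if (lo > 1L) csum[lo - 1L] else 0
    out[i] <- s / (i - lo + 1L)
  }
  out
}

#' Departure and return time of one day
#'
#' Applies the backward moving average to the per-frame counts of the
#' species within one day; the departure time is the argmax of the
#' smoothed series within the morning window and the return time the
#' argmax within the evening window. Ties take the earliest time.
#'
#' @param records detection records of a single day.
#' @param species species label.
#' @param morning,evening `c("HH:MM", "HH:MM")` windows (morning end is
#'   the evening start by default; windows are half-open on the right).
#' @param window moving-average window in seconds.
#' @param score_threshold minimum confidence.
#' @return list with `departure` and `return` (POSIXct), plus
#'   `departure_min`/`return_min` (minutes since midnight).
#' @export
departure_return <- function(records, species,
                             morning = c("04:00", "12:00"),
                             evening = c("12:00", "20:00"),
                             window = 3600, score_threshold = 0.5) {
  fc <- frame_counts(records, species, score_threshold)
  assert_that(nrow(fc) > 0, "no frames in the day")
  sm <- backward_moving_average(fc$timestamp, fc$count, window)
  mins <- as.numeric(fc$timestamp - trunc(fc$timestamp, "days"),
                     units = "mins")
  pick <- function(w) {
    sel <- which(mins >= hm_to_min(w[1]) & mins < hm_to_min(w[2]))
    assert_that(length(sel) > 0, "empty schedule window")
    sel[which.max(sm[sel])]   # which.max returns the first (earliest) tie
  }
  i_dep <- pick(morning); i_ret <- pick(evening)
  list(departure = fc$timestamp[i_dep], return = fc$timestamp[i_ret],
       departure_min = mins[i_dep], return_min = mins[i_ret])
}

#' Daily schedule across a study period
#'
#' @param records multi-day detection records.
#' @param species species label.
#' @param ... passed to [departure_return()].
#' @return data.frame with `date`, `departure_min`, `return_min`.
#' @export
daily_schedule <- function(records, species, ...) {
  day <- as.Date(format(records$timestamp, "%Y-%m-%d"))
  days <- sort(unique(day))
  rows <- lapply(days, function(d) {
    dr <- departure_return(records[day == d, , drop = FALSE], species, ...)
    data.frame(date = d, departure_min = dr$departure_min,
               return_min = dr$return_min)
  })
  do.call(rbind, rows)
}

#' Paired schedule hypothesis tests
#'
#' HT1 (two-tailed paired t-test): the departure times of the two egret
#' species are the same. HT2 (one-tailed paired t-test): the return time
#' of the great egret is equal to or later than the little egret's; the
#' alternative is that the little egret returns later. Times are in
#' minutes since midnight, paired by day.
#'
#' @param departures_g,departures_l,returns_g,returns_l numeric vectors of
#'   daily times (minutes), paired by day.
#' @param alpha significance level for the decision flags.
#' @return list with `ht1` and `ht2`, each carrying `statistic`, `p_value`,
#'   `significant`, and a `degenerate` flag for zero-variance differences.
#' @export
schedule_tests <- function(departures_g, departures_l,
                           returns_g, returns_l, alpha = 0.05) {
  n <- length(departures_g)
  assert_that(length(departures_l) == n && length(returns_g) == n &&
                length(returns_l) == n, "samples must be paired by day")
  assert_that(n >= 3, "need at least 3 complete pairs")
  paired <- function(d, alternative) {
    if (stats::sd(d) == 0) {
      return(list(statistic = NA_real_, p_value = 1.0,
                  significant = FALSE, degenerate = TRUE,
                  mean_diff = mean(d), n = n))
    }
    tt <- stats::t.test(d, alternative = alternative)
    list(statistic = unname(tt$statistic), p_value = tt$p.value,
         significant = tt$p.value < alpha, degenerate = FALSE,
         mean_diff = mean(d), n = n)
  }
  list(ht1 = paired(departures_g - departures_l, "two.sided"),
       ht2 = paired(returns_g - returns_l, "less"),
       alpha = alpha)
}
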