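# Plain-text interchange: detection-record CSV, weather CSV, ledger JSON.

#' Write detection records to CSV
#'
#' Columns `timestamp_iso,species,x_min,y_min,x_max,y_max,score` with
#' 0-based half-open pixel boxes.
#'
#' @param records detection-record data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_detections_csv <- function(records, path) {
  out <- data.frame(timestamp_iso = iso_time(records$timestamp),
                    species = records$species,
                    x_min = records$x_min, y_min = records$y_min,
                    x_max = records$x_max, y_max = records$y_max,
                    score = records$score)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read detection records from CSV
#' @param path CSV written by [write_detections_csv()].
#' @return detection-record data.frame with POSIXct timestamps.
#' @export
read_detections_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  data.frame(timestamp = parse_iso_time(df$timestamp_iso),
             species = df$species,
             x_min = df$x_min, y_min = df$y_min,
             x_max = df$x_max, y_max = df$y_max, score = df$score)
}

#' Write a daily weather table to CSV
#' @param weather data.frame from [simulate_weather()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_weather_csv <- function(weather, path) {
  utils::write.csv(weather, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a daily weather table from CSV
#' @param path CSV path.
#' @return data.frame with `date` as `Date`.
#' @export
read_weather_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$date <- as.Date(df$date)
  df
}

#' Write a ground-truth ledger as JSON
#' @param ledger ledger object from a generator.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_ledger <- function(ledger, path) {
  jsonlite::write_json(unclass(ledger), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", Date = "ISO8601")
  invisible(path)
}

#' Read a ground-truth ledger from JSON
#' @param path ledger JSON path.
#' @return ledger list.
#' @export
read_ledger <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(x$daily_max)) x$daily_max$date <- as.Date(x$daily_max$date)
  structure(x, class = "gt_ledger")
}

#' Write a feature stack to a JSON container
#'
#' Text-based stand-in for an NPZ-style container: stores the array shape,
#' the flattened features and the affine operator.
#'
#' @param stack a [feature_stack()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_feature_stack <- function(stack, path) {
  jsonlite::write_json(
    list(shape = dim(stack$features),
         features = as.numeric(stack$features),
         a_dim = dim(stack$A), a = as.numeric(stack$A)),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read a feature stack from a JSON container
#' @param path JSON written by [write_feature_stack()].
#' @return a [feature_stack()].
#' @export
read_feature_stack <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  feature_stack(array(x$features, dim = x$shape),
                matrix(x$a, x$a_dim[1], x$a_dim[2]))
}
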