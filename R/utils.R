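# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
stop_ew <- function(...) stop(..., call. = FALSE)

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop_ew(msg)
  invisible(TRUE)
}

#' Derive a child RNG seed from a parent seed and a stream label.
#'
#' Keeps every generator independently reseedable from one user-facing seed
#' while staying below .Machine$integer.max.
#' @keywords internal
child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629L)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Parse "HH:MM" to minutes since midnight.
#' @keywords internal
hm_to_min <- function(x) {
  parts <- strsplit(x, ":", fixed = TRUE)[[1]]
  as.integer(parts[1]) * 60L + as.integer(parts[2])
}

min_to_hm <- function(m) sprintf("%02d:%02d", m %/% 60L, m %% 60L)

iso_time <- function(t) format(t, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

parse_iso_time <- function(x) as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")

SPECIES <- c("great_egret", "little_egret", "other")
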