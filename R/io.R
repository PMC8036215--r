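# On-disk formats: rate CSV (`time,rate`; seconds and events/s), dead-time
# JSON, interval-distribution CSV (`interval,probability,rate`). All times
# are in seconds; headers are mandatory; numbers are written with full
# round-trip precision (readr's shortest-exact representation).

#' Read and write rate series and interval distributions
#'
#' `read_rate_csv()` reads a CSV with header `time,rate` (right-edge bin
#' labels in seconds, rate in events/s) and returns the tibble with the
#' per-bin probability column added; if `grid` is supplied the times must
#' match it exactly. `write_rate_csv()` writes the `time` and `rate` columns
#' back (deriving `rate` from `p` if needed); read–write round trips are
#' exact. `write_distribution_csv()` writes an interval distribution as
#' `interval,probability,rate`. `read_deadtime_json()` /
#' `write_deadtime_json()` handle the dead-time spec, either
#' `{"type": "fixed_plus_geometric", "d_fixed": ..., "mu_rand": ...}` or
#' `{"type": "pmf", "durations": [...], "probs": [...]}` (seconds).
#'
#' @param path File path.
#' @param grid Optional [time_grid()] the series must match.
#' @param df Data frame with `time` and `rate` (or `p`).
#' @param dt Bin width in seconds for the dead-time distribution.
#' @param d_max Optional stored-support truncation, seconds.
#' @param dist A `deadtime_dist` or `interval_dist`.
#' @return `read_rate_csv()` a tibble `time, rate, p`;
#'   `read_deadtime_json()` a `deadtime_dist`; the writers return their
#'   input invisibly.
#' @name deadtime_io
NULL

#' @rdname deadtime_io
#' @export
read_rate_csv <- function(path, grid = NULL) {
  # read as text and convert with strtod for correctly rounded doubles
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!identical(names(raw), c("time", "rate"))) {
    abort(sprintf("%s: malformed header, expected `time,rate` got `%s`.",
                  path, paste(names(raw), collapse = ",")),
          class = "deadtime_format")
  }
  df <- suppressWarnings(tibble::tibble(time = as.numeric(raw$time),
                                        rate = as.numeric(raw$rate)))
  if (anyNA(df$time) || anyNA(df$rate)) {
    abort(sprintf("%s: non-numeric value at data line %d.", path,
                  which(is.na(df$time) | is.na(df$rate))[1]),
          class = "deadtime_format")
  }
  if (!is.null(grid)) check_grid_match(df, grid, what = path)
  rate_to_prob(df, grid = grid)
}

#' @rdname deadtime_io
#' @export
write_rate_csv <- function(df, path) {
  if (!"rate" %in% names(df)) df <- prob_to_rate(df)
  out <- data.frame(time = sprintf("%.17g", df$time),
                    rate = sprintf("%.17g", df$rate))
  readr::write_csv(out, path, progress = FALSE, quote = "none")
  invisible(df)
}

#' @rdname deadtime_io
#' @export
read_deadtime_json <- function(path, dt, d_max = NULL) {
  spec <- tryCatch(jsonlite::fromJSON(path),
                   error = function(e) {
                     abort(sprintf("%s: not valid JSON (%s).", path,
                                   conditionMessage(e)),
                           class = "deadtime_format")
                   })
  withCallingHandlers(
    switch(
      spec$type %||% "",
      fixed_plus_geometric =
        deadtime_fixed_geometric(spec$d_fixed, spec$mu_rand, dt,
                                 d_max = d_max),
      pmf = deadtime_pmf(spec$durations, spec$probs, dt),
      abort(sprintf("%s: unknown dead-time type `%s`.", path,
                    spec$type %||% "<missing>"),
            class = "deadtime_format")
    ),
    error = function(e) {
      if (inherits(e, "deadtime_argument") ||
          inherits(e, "deadtime_grid_mismatch")) {
        abort(sprintf("%s: %s", path, conditionMessage(e)),
              class = class(e)[1], parent = e)
      }
    }
  )
}

#' @rdname deadtime_io
#' @export
write_deadtime_json <- function(dist, path) {
  stopifnot(inherits(dist, "deadtime_dist"))
  spec <- if (dist$family == "fixed_plus_geometric") {
    list(type = "fixed_plus_geometric", d_fixed = dist$params$d_fixed,
         mu_rand = dist$params$mu_rand)
  } else {
    keep <- dist$pmf > 0
    list(type = "pmf", durations = dist$durations[keep],
         probs = dist$pmf[keep])
  }
  jsonlite::write_json(spec, path, auto_unbox = TRUE, digits = NA)
  invisible(dist)
}

#' @rdname deadtime_io
#' @export
write_distribution_csv <- function(dist, path) {
  df <- interval_rates(dist)
  out <- data.frame(interval = sprintf("%.17g", df$interval),
                    probability = sprintf("%.17g", df$probability),
                    rate = sprintf("%.17g", df$rate))
  readr::write_csv(out, path, progress = FALSE, quote = "none")
  invisible(dist)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
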