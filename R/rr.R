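#' Construct an RR-interval series
#'
#' An `rr_series` holds one patient's sequence of inter-beat (RR) intervals
#' in seconds, in recording order. The recording duration is the sum of the
#' intervals.
#'
#' @param intervals Numeric vector of RR intervals in seconds, all positive,
#'   at least two.
#' @return An object of class `rr_series`: the interval vector with a
#'   `duration` attribute (seconds).
#' @examples
#' rr <- rr_series(c(0.8, 0.82, 0.79, 0.81))
#' rr
#' @export
rr_series <- function(intervals) {
  intervals <- as.numeric(intervals)
  if (length(intervals) < 2)
    stop("an RR series needs at least 2 intervals")
  if (any(!is.finite(intervals)) || any(intervals <= 0))
    stop("all RR intervals must be finite and positive")
  structure(intervals, duration = sum(intervals), class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("RR series: %d intervals, %.1f s, mean RR %.3f s\n",
              length(x), attr(x, "duration"), mean(unclass(x))))
  invisible(x)
}

#' Artifact filter for RR series
#'
#' Removes physiologically implausible intervals and sudden jumps, a simple
#' stand-in for manual exclusion of ectopy and recording artifact. An
#' interval is dropped when it falls outside `[min_s, max_s]`, or when it
#' differs from the previously *retained* interval by more than
#' `max_rel_jump` as a fraction of that interval. The first in-range
#' interval anchors the jump rule.
#'
#' @param series An [rr_series()].
#' @param min_s,max_s Plausibility bounds in seconds (defaults 0.3 and 2.0,
#'   i.e. 30-200 beats/min).
#' @param max_rel_jump Maximum allowed relative change between consecutive
#'   retained intervals (default 0.2, i.e. 20%).
#' @return The filtered `rr_series`, with attributes `removed` (count) and
#'   `removed_fraction`.
#' @examples
#' filter_rr(rr_series(c(0.8, 3.0, 0.8)))
#' @export
filter_rr <- function(series, min_s = 0.3, max_s = 2.0, max_rel_jump = 0.2) {
  x <- unclass(series)
  keep <- logical(length(x))
  last <- NA_real_
  for (i in seq_along(x)) {
    if (x[i] < min_s || x[i] > max_s) next
    if (!is.na(last) && abs(x[i] / last - 1) > max_rel_jump) next
    keep[i] <- TRUE
    last <- x[i]
  }
  if (sum(keep) < 2)
    stop("unusable recording: fewer than 2 intervals survive artifact filtering")
  out <- rr_series(x[keep])
  attr(out, "removed") <- sum(!keep)
  attr(out, "removed_fraction") <- mean(!keep)
  out
}

#' Read RR-interval series from a text or CSV file
#'
#' Accepts either a plain file with one interval (seconds) per line, or a
#' long-format CSV with columns `patient_id,interval_s` holding several
#' patients.
#'
#' @param path File path.
#' @return A single `rr_series`, or a named list of them for long-format
#'   input.
#' @export
read_rr <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("patient_id", first, fixed = TRUE)) {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    lapply(split(d$interval_s, d$patient_id), rr_series)
  } else {
    rr_series(scan(path, what = numeric(), quiet = TRUE))
  }
}

#' Write RR-interval series to CSV
#'
#' Writes long-format `patient_id,interval_s` rows readable by [read_rr()].
#'
#' @param series A named list of [rr_series()] objects (names are patient
#'   ids), or a single series (written with id `"1"`).
#' @param path Output file path.
#' @export
write_rr <- function(series, path) {
  if (inherits(series, "rr_series")) series <- list(`1` = series)
  d <- data.frame(
    patient_id = rep(names(series), lengths(series)),
    interval_s = unlist(lapply(series, unclass), use.names = FALSE)
  )
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
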