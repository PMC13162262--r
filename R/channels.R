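#' A uniformly sampled sensor channel
#'
#' Container for one high-frequency sensor channel (a velocity component or
#' a scalar such as dissolved O2 or pH). Sampling is uniform: timestamps
#' are implied by `start_time` and `rate`. Invalid samples are carried as
#' `NA` in `values` and flagged in the `gaps` mask.
#'
#' @param values Numeric samples, in `units`.
#' @param rate Sampling rate, Hz.
#' @param start_time `POSIXct` time of the first sample (UTC).
#' @param units Unit string, e.g. `"m s-1"`, `"umol kg-1"`.
#' @param gaps Logical mask of invalid samples (defaults to `is.na(values)`).
#' @return An object of class `channel_series`.
#' @export
channel_series <- function(values, rate,
                           start_time = as.POSIXct("2020-09-18 00:00:00",
                                                   tz = "UTC"),
                           units = "", gaps = NULL) {
  values <- as.numeric(values)
  if (is.null(gaps)) gaps <- is.na(values)
  if (length(gaps) != length(values))
    stop("gap mask must have the same length as values")
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0)
    stop("rate must be a single positive number (Hz)")
  values[gaps] <- NA_real_
  structure(list(values = values, rate = rate,
                 start_time = as.POSIXct(start_time, tz = "UTC"),
                 units = units, gaps = gaps),
            class = "channel_series")
}

#' @export
print.channel_series <- function(x, ...) {
  cat(sprintf("<channel_series> %d samples @ %g Hz (%s), %d gaps\n",
              length(x$values), x$rate,
              if (nzchar(x$units)) x$units else "unitless", sum(x$gaps)))
  cat("  start:", format(x$start_time, "%Y-%m-%dT%H:%M:%OS6Z", tz = "UTC"),
      "\n")
  invisible(x)
}

#' @export
length.channel_series <- function(x) length(x$values)

#' Sample times of a channel
#'
#' @param x A `channel_series`.
#' @return `POSIXct` vector of sample times.
#' @export
channel_times <- function(x) {
  stopifnot(inherits(x, "channel_series"))
  x$start_time + (seq_along(x$values) - 1) / x$rate
}

#' Three-component velocity record
#'
#' Bundles the u, v, w velocity channels of an acoustic Doppler
#' velocimeter. All three must share start time, rate and length.
#' `heading` gives the compass direction (degrees clockwise from north) of
#' the instrument +u axis, used when reporting flow direction.
#'
#' @param u,v,w `channel_series` in m s^-1.
#' @param heading Instrument +u axis heading, degrees from north.
#' @return An object of class `velocity_record`.
#' @export
velocity_record <- function(u, v, w, heading = 90) {
  for (ch in list(u, v, w)) stopifnot(inherits(ch, "channel_series"))
  if (u$rate != v$rate || u$rate != w$rate)
    stop("velocity components must share a sampling rate")
  if (length(u) != length(v) || length(u) != length(w))
    stop("velocity components must share a length")
  if (u$start_time != v$start_time || u$start_time != w$start_time)
    stop("velocity components must share a start time")
  structure(list(u = u, v = v, w = w, heading = heading),
            class = "velocity_record")
}

#' @export
print.velocity_record <- function(x, ...) {
  cat(sprintf("<velocity_record> %d samples @ %g Hz, heading %g deg\n",
              length(x$u), x$u$rate, x$heading))
  invisible(x)
}
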