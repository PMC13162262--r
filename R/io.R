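## Delimited-text readers/writers and configuration serialization.
## Dialect: comma separator, "." decimal, ISO-8601 UTC timestamps,
## mandatory header row; NA written as "" and accepted as "NA" or "" on
## read.

ts_format <- function(t) format(t, "%Y-%m-%dT%H:%M:%OS6Z", tz = "UTC")

ts_parse <- function(s) {
  t <- as.POSIXct(sub("Z$", "", s), format = "%Y-%m-%dT%H:%M:%OS",
                  tz = "UTC")
  if (anyNA(t) && !anyNA(s))
    t <- as.POSIXct(s, tz = "UTC")
  t
}

#' Write a channel to CSV
#'
#' One row per sample: ISO-8601 UTC timestamp plus value; gaps are written
#' as empty fields.
#'
#' @param series A `channel_series`.
#' @param path Output file.
#' @param name Header name for the value column.
#' @return `path`, invisibly.
#' @export
write_channel_csv <- function(series, path, name = "value") {
  stopifnot(inherits(series, "channel_series"))
  df <- data.frame(timestamp = ts_format(channel_times(series)),
                   v = series$values)
  names(df)[2] <- name
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a channel from CSV
#'
#' Expects an ISO-8601 timestamp column followed by one or more value
#' columns. Timestamps must be strictly increasing and uniform; the rate
#' is inferred from the median spacing and checked against `rate` (within
#' 1%) when one is given.
#'
#' @param path Input file.
#' @param value_col Name or index of the value column (default: second
#'   column).
#' @param rate Expected rate in Hz, or `NULL` to accept the inferred one.
#' @param units Unit string attached to the result.
#' @return A `channel_series`.
#' @export
read_channel_csv <- function(path, value_col = 2, rate = NULL, units = "") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  if (nrow(df) < 2) stop("channel file ", path, " has fewer than 2 samples")
  tt <- ts_parse(df[[1]])
  if (anyNA(tt)) stop("unparseable timestamps in ", path)
  d <- diff(as.numeric(tt))
  if (any(d <= 0)) {
    bad <- which(d <= 0)[1]
    stop("non-monotone or duplicated timestamp in ", path, " at line ",
         bad + 2)  # +1 header, +1 diff offset
  }
  dt <- stats::median(d)
  if (max(abs(d - dt)) > 0.5 * dt)
    stop("non-uniform sampling in ", path)
  dt <- round(dt * 1e6) / 1e6        # timestamps carry microsecond precision
  inferred <- 1 / dt
  if (!is.null(rate) && abs(inferred - rate) > 0.01 * rate)
    stop("rate mismatch in ", path, ": inferred ", signif(inferred, 6),
         " Hz, expected ", rate)
  channel_series(df[[value_col]], inferred, tt[1], units)
}

#' Trim channels to their common time overlap
#'
#' @param channels Named list of `channel_series`.
#' @return The list with every channel trimmed to the latest start and
#'   earliest end across the set.
#' @export
align_channels <- function(channels) {
  starts <- vapply(channels, function(ch) as.numeric(ch$start_time),
                   numeric(1))
  ends <- vapply(channels, function(ch)
    as.numeric(ch$start_time) + length(ch) / ch$rate, numeric(1))
  t0 <- max(starts); t1 <- min(ends)
  if (t1 <= t0) stop("channels have no common time overlap")
  lapply(channels, function(ch) {
    i0 <- round((t0 - as.numeric(ch$start_time)) * ch$rate) + 1
    i1 <- min(length(ch), round((t1 - as.numeric(ch$start_time)) * ch$rate))
    channel_series(ch$values[i0:i1], ch$rate,
                   as.POSIXct(t0, origin = "1970-01-01", tz = "UTC"),
                   ch$units)
  })
}

#' Read the channel set of a deployment directory
#'
#' Expects the file layout written by the `simulate` subcommand:
#' `velocity.csv` (timestamp, u, v, w), `o2.csv`, `ph.csv` and optionally
#' `par.csv`. Channels are trimmed to their common overlap; the velocity
#' components keep their native rate.
#'
#' @param dir Deployment directory.
#' @param require_ph Error when the pH channel is missing (default
#'   `FALSE`: processing proceeds with O2 only).
#' @return List with `velocity` (`velocity_record`), `o2`, `ph`, `par`
#'   (`channel_series` or `NULL`).
#' @export
read_channels <- function(dir, require_ph = FALSE) {
  vf <- file.path(dir, "velocity.csv")
  if (!file.exists(vf)) stop("missing velocity.csv in ", dir)
  u <- read_channel_csv(vf, "u", units = "m s-1")
  v <- read_channel_csv(vf, "v", units = "m s-1")
  w <- read_channel_csv(vf, "w", units = "m s-1")
  out <- list(velocity = NULL, o2 = NULL, ph = NULL, par = NULL)
  o2f <- file.path(dir, "o2.csv")
  if (file.exists(o2f)) out$o2 <- read_channel_csv(o2f, 2, units = "umol kg-1")
  phf <- file.path(dir, "ph.csv")
  if (file.exists(phf)) out$ph <- read_channel_csv(phf, 2, units = "pH total")
  else if (require_ph) stop("missing ph.csv in ", dir)
  parf <- file.path(dir, "par.csv")
  if (file.exists(parf))
    out$par <- read_channel_csv(parf, 2, units = "umol photons m-2 s-1")
  chans <- Filter(Negate(is.null), c(list(u = u, v = v, w = w),
                                     out[c("o2", "ph")]))
  al <- align_channels(chans)
  out$velocity <- velocity_record(al$u, al$v, al$w)
  if (!is.null(out$o2)) out$o2 <- al$o2
  if (!is.null(out$ph)) out$ph <- al$ph
  out
}

#' Write a window table to CSV
#'
#' @param windows Data frame with `POSIXct` `start`/`end` columns.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_windows_csv <- function(windows, path) {
  df <- windows
  for (cn in intersect(c("start", "end"), names(df)))
    df[[cn]] <- ts_format(df[[cn]])
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a window table from CSV
#'
#' @param path Input file.
#' @return Data frame with parsed `start`/`end` columns.
#' @export
read_windows_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  for (cn in intersect(c("start", "end"), names(df)))
    df[[cn]] <- ts_parse(df[[cn]])
  df
}

#' Serialize an effective configuration next to outputs
#'
#' @param config Named list.
#' @param path Output YAML file.
#' @return The MD5 hash of the written file.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  unname(tools::md5sum(path))
}

#' Read a configuration file
#'
#' @param path YAML file.
#' @return Named list.
#' @export
read_config <- function(path) yaml::read_yaml(path)
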