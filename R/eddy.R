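## Turbulence flux-processing chain: downsampling, planar fit, Reynolds
## decomposition, lag alignment, windowed covariance fluxes, QC, cospectra.

#' Block-mean downsampling onto a lower-rate grid
#'
#' Resamples a channel onto the target grid (default 5 Hz, the optode
#' rate) by averaging all source samples whose times fall in each target
#' interval. Gaps propagate: a block keeps the mean of its valid samples
#' when at least half of them are valid, and becomes a gap otherwise.
#'
#' @param series A `channel_series`.
#' @param target_rate Target rate, Hz; must not exceed the input rate.
#' @return A `channel_series` at `target_rate`.
#' @export
downsample <- function(series, target_rate = 5) {
  stopifnot(inherits(series, "channel_series"))
  if (series$rate < target_rate)
    stop("input rate (", series$rate, " Hz) below target rate")
  n <- length(series$values)
  if (n == 0)
    return(channel_series(numeric(0), target_rate, series$start_time,
                          series$units))
  bin <- floor((seq_len(n) - 1) / series$rate * target_rate) + 1L
  nbins <- floor(n * target_rate / series$rate)
  keep <- bin <= nbins
  bin <- bin[keep]
  x <- series$values[keep]
  valid <- !is.na(x)
  tot <- tabulate(bin, nbins)
  nval <- tabulate(bin[valid], nbins)
  sums <- rep(0, nbins)
  s <- rowsum(x[valid], bin[valid])
  sums[as.integer(rownames(s))] <- s[, 1]
  out <- ifelse(nval >= tot / 2 & nval > 0, sums / pmax(nval, 1), NA_real_)
  channel_series(out, target_rate, series$start_time, series$units)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Planar-fit tilt rotation from window-mean velocities
#'
#' Least-squares fit of the plane `w = b0 + b1 u + b2 v` through
#' window-mean velocity vectors (Wilczak-style planar fit). The returned
#' rotation maps instrument coordinates into a frame whose vertical axis is
#' normal to the mean-flow plane, so the mean vertical velocity over the
#' fit set vanishes and instrument tilt no longer contaminates `w`.
#'
#' @param u_mean,v_mean,w_mean Numeric vectors of window-mean velocities
#'   (m s^-1); at least 6 windows spanning at least 2 flow directions.
#' @return An object of class `planar_fit`: `rotation` (orthonormal 3x3,
#'   rows are the new unit axes), `offset` (the fitted `b0`, subtracted
#'   from `w` before rotation), `coef`, and `tilt_deg` (angle between the
#'   fitted normal and the instrument vertical).
#' @export
planar_fit <- function(u_mean, v_mean, w_mean) {
  n <- length(u_mean)
  if (n < 6 || length(v_mean) != n || length(w_mean) != n)
    stop("planar fit needs >= 6 window-mean velocity vectors")
  X <- cbind(1, u_mean, v_mean)
  if (qr(X)$rank < 3)
    stop("degenerate geometry: mean flows are collinear, planar fit is rank-deficient")
  b <- qr.solve(X, w_mean)
  k <- c(-b[2], -b[3], 1)
  k <- k / sqrt(sum(k^2))
  j <- cross3(k, c(1, 0, 0))
  j <- j / sqrt(sum(j^2))
  i <- cross3(j, k)
  structure(list(rotation = rbind(i, j, k, deparse.level = 0),
                 offset = unname(b[1]), coef = unname(b),
                 tilt_deg = acos(min(1, k[3])) * 180 / pi),
            class = "planar_fit")
}

#' @export
print.planar_fit <- function(x, ...) {
  cat(sprintf("<planar_fit> tilt %.3f deg, w offset %.2e m/s\n",
              x$tilt_deg, x$offset))
  invisible(x)
}

#' Apply a planar-fit rotation to velocity components
#'
#' Subtracts the fitted `w` offset and rotates into the planar-fit frame.
#' The rotation object is meant to be applied exactly once to any given
#' record.
#'
#' @param fit A [planar_fit()] object.
#' @param u,v,w Numeric vectors (m s^-1) of equal length.
#' @return List with rotated `u`, `v`, `w`.
#' @export
apply_rotation <- function(fit, u, v, w) {
  stopifnot(inherits(fit, "planar_fit"))
  m <- fit$rotation %*% rbind(u, v, w - fit$offset)
  list(u = m[1, ], v = m[2, ], w = m[3, ])
}

#' Reynolds decomposition with a centred running mean
#'
#' Splits a series into a slowly varying mean and a turbulent fluctuation
#' using a centred running average (default 500 s, long enough to retain
#' low-frequency flux contributions). The averaging window shrinks
#' symmetrically at the record edges, which keeps it centred and makes the
#' fluctuation vanish identically for linear trends. Gaps are ignored in
#' the local mean and propagate to the fluctuation.
#'
#' @param values Numeric samples (may contain `NA`).
#' @param rate Sampling rate, Hz.
#' @param window_s Running-mean window, seconds.
#' @return List with `mean` and `fluctuation` vectors.
#' @export
reynolds_decompose <- function(values, rate, window_s = 500) {
  n <- length(values)
  if (n < window_s * rate)
    stop("series shorter than the running-mean window (", window_s, " s)")
  h <- round(window_s * rate / 2)
  valid <- !is.na(values)
  x0 <- ifelse(valid, values, 0)
  cs <- c(0, cumsum(x0))
  cv <- c(0, cumsum(valid))
  i <- seq_len(n)
  hw <- pmin(h, i - 1L, n - i)
  lo <- i - hw
  hi <- i + hw
  cnt <- cv[hi + 1] - cv[lo]
  mu <- (cs[hi + 1] - cs[lo]) / cnt
  mu[cnt == 0] <- NA_real_
  fl <- values - mu
  list(mean = mu, fluctuation = fl)
}

#' Align a scalar fluctuation to vertical velocity by cross-correlation
#'
#' Finds the lag (at sample resolution) within `max_lag_s` that maximises
#' the absolute cross-correlation between `w_prime` and `c_prime`, and
#' shifts the scalar by that lag. Positive lag means the scalar lags the
#' velocity (the usual case for a pumped or slow sensor). Ties are broken
#' toward the smaller absolute lag.
#'
#' @param w_prime,c_prime Equal-length fluctuation series at `rate`.
#' @param rate Sampling rate, Hz.
#' @param max_lag_s Search half-window, seconds (default 2).
#' @param min_abs_corr Below this peak |correlation| the window is flagged
#'   `low_correlation`.
#' @return List: `c_aligned` (shifted scalar, `NA`-padded), `lag_s`,
#'   `lag_samples`, `max_corr`, `low_correlation`, `undefined_correlation`.
#' @export
lag_align <- function(w_prime, c_prime, rate, max_lag_s = 2,
                      min_abs_corr = 0.1) {
  n <- length(w_prime)
  stopifnot(length(c_prime) == n)
  L <- round(max_lag_s * rate)
  lags <- -L:L
  rs <- vapply(lags, function(m) {
    if (m >= 0) {
      a <- w_prime[seq_len(n - m)]
      b <- c_prime[seq_len(n - m) + m]
    } else {
      a <- w_prime[seq_len(n + m) - m]
      b <- c_prime[seq_len(n + m)]
    }
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 10) return(NA_real_)
    sa <- stats::sd(a[ok]); sb <- stats::sd(b[ok])
    if (sa == 0 || sb == 0) return(NA_real_)
    stats::cor(a[ok], b[ok])
  }, numeric(1))
  if (all(is.na(rs))) {
    return(list(c_aligned = c_prime, lag_s = 0, lag_samples = 0L,
                max_corr = NA_real_, low_correlation = TRUE,
                undefined_correlation = TRUE))
  }
  ord <- order(-abs(rs), abs(lags), lags, na.last = TRUE)
  m <- lags[ord[1]]
  shifted <- rep(NA_real_, n)
  if (m >= 0) shifted[seq_len(n - m)] <- c_prime[seq_len(n - m) + m]
  else shifted[seq_len(n + m) - m] <- c_prime[seq_len(n + m)]
  list(c_aligned = shifted, lag_s = m / rate, lag_samples = as.integer(m),
       max_corr = rs[ord[1]],
       low_correlation = abs(rs[ord[1]]) < min_abs_corr,
       undefined_correlation = FALSE)
}

#' Eddy-covariance flux over one averaging window
#'
#' Arithmetic mean of `w' c'` over unmasked, valid samples, converted to a
#' daily areal flux through the seawater density. With the scalar in
#' umol kg^-1 the flux is in mmol m^-2 d^-1; with protons in nmol kg^-1 it
#' is in umol H+ m^-2 d^-1. Positive flux is an efflux from the bed to the
#' water column (`w` positive upward after rotation).
#'
#' @param w_prime,c_prime Aligned fluctuation series for one window.
#' @param density Seawater density, kg m^-3.
#' @param mask Logical; `TRUE` samples (e.g. pump flow reversals) are
#'   excluded from the covariance mean.
#' @param min_valid_frac Windows with a smaller usable fraction are
#'   invalidated (flux `NA`).
#' @return List: `flux`, `covariance` (m s^-1 x scalar units), `n_samples`,
#'   `n_used`, `valid_frac`, `qc_invalid`.
#' @export
compute_flux <- function(w_prime, c_prime, density = 1025, mask = NULL,
                         min_valid_frac = 0.5) {
  n <- length(w_prime)
  stopifnot(length(c_prime) == n)
  if (is.null(mask)) mask <- rep(FALSE, n)
  use <- !mask & !is.na(w_prime) & !is.na(c_prime)
  vf <- sum(use) / n
  if (vf < min_valid_frac || sum(use) == 0) {
    return(list(flux = NA_real_, covariance = NA_real_, n_samples = n,
                n_used = sum(use), valid_frac = vf, qc_invalid = TRUE))
  }
  cov <- mean(w_prime[use] * c_prime[use])
  list(flux = cov * density * 86400 / 1000, covariance = cov,
       n_samples = n, n_used = sum(use), valid_frac = vf,
       qc_invalid = FALSE)
}

#' Cumulative-flux linearity quality control
#'
#' The cumulative sum of `w' c'` over a stationary window grows linearly
#' in time; bursts or drifts concentrated in a few samples indicate
#' fouling, sensor impairment or water-mass changes. The window is flagged
#' nonlinear when the regression of the cumulative flux on time has
#' R^2 below `r2_threshold`, or when more than `burst_change` of the total
#' cumulative change occurs within `burst_span` of the samples. Windows
#' whose total covariance is indistinguishable from zero are flagged
#' `low_flux` instead of nonlinear.
#'
#' @param w_prime,c_prime One window's aligned fluctuation series.
#' @param r2_threshold Linearity threshold on R^2 (default 0.8).
#' @param burst_span Fraction of samples defining a burst interval.
#' @param burst_change Fraction of total change concentrated in a burst.
#' @return List: `linear`, `r2`, `low_flux`, `burst`.
#' @export
cumulative_flux_qc <- function(w_prime, c_prime, r2_threshold = 0.8,
                               burst_span = 0.05, burst_change = 0.5) {
  prod <- w_prime * c_prime
  prod[is.na(prod)] <- 0
  n <- length(prod)
  cum <- cumsum(prod)
  total <- cum[n]
  ## null scale for the cumulative sum: winsorize at 6 robust sigmas (a
  ## burst must not inflate its own threshold), then estimate the scatter
  ## from block sums, which respects the autocorrelation of band-limited
  ## turbulence
  m <- stats::mad(prod)
  clipped <- if (m > 0) pmin(pmax(prod, -6 * m), 6 * m) else prod
  nb <- 10L
  bs <- as.numeric(rowsum(clipped, rep(seq_len(nb), each = ceiling(n / nb),
                                       length.out = n)))
  se_total <- stats::sd(bs) * sqrt(nb)
  low_flux <- !is.finite(se_total) || se_total == 0 ||
    abs(total) < 3 * se_total
  r2 <- {
    r <- suppressWarnings(stats::cor(cum, seq_len(n)))
    if (is.na(r)) 0 else r^2
  }
  burst <- FALSE
  if (!low_flux) {
    k <- max(1L, ceiling(burst_span * n))
    d <- cum[(k + 1):n] - cum[seq_len(n - k)]
    burst <- max(abs(d)) > burst_change * abs(total)
  }
  nonlinear <- !low_flux && (r2 < r2_threshold || burst)
  list(linear = !nonlinear, r2 = r2, low_flux = low_flux, burst = burst)
}

#' Cospectrum of vertical velocity and a scalar
#'
#' Real part of the one-sided cross-spectral density of `w'` and `c'`,
#' whose integral over frequency equals the window covariance (Parseval),
#' plus the normalised ogive (cumulative flux fraction from the lowest
#' frequency). Gaps are linearly interpolated before the transform.
#'
#' @param w_prime,c_prime One window's aligned fluctuation series
#'   (>= 1024 samples).
#' @param rate Sampling rate, Hz.
#' @return An object of class `cospectrum`: `frequencies` (Hz),
#'   `co_density` (flux units per Hz), `ogive`, `covariance`.
#' @export
cospectrum <- function(w_prime, c_prime, rate) {
  n <- length(w_prime)
  if (n < 1024) stop("window too short for a cospectrum (< 1024 samples)")
  stopifnot(length(c_prime) == n)
  fill <- function(x) {
    if (anyNA(x)) {
      idx <- which(!is.na(x))
      if (length(idx) < 2) stop("cospectrum: too few valid samples")
      x <- stats::approx(idx, x[idx], xout = seq_len(n), rule = 2)$y
    }
    x - mean(x)
  }
  w <- fill(w_prime)
  cc <- fill(c_prime)
  cross <- Re(Conj(stats::fft(w)) * stats::fft(cc)) / n^2
  m <- floor(n / 2)
  df <- rate / n
  dens <- 2 * cross[2:(m + 1)] / df
  if (n %% 2 == 0) dens[m] <- dens[m] / 2   # Nyquist bin appears once
  total <- sum(dens) * df
  structure(list(frequencies = (1:m) * df, co_density = dens,
                 ogive = if (total != 0) cumsum(dens) * df / total
                         else rep(NA_real_, m),
                 covariance = total, rate = rate),
            class = "cospectrum")
}

#' @export
print.cospectrum <- function(x, ...) {
  cat(sprintf("<cospectrum> %d frequencies up to %.3g Hz, covariance %.4g\n",
              length(x$frequencies), max(x$frequencies), x$covariance))
  invisible(x)
}

#' High-frequency flux loss of a slow sensor relative to a reference
#'
#' Compares the cumulative (unnormalised) flux of a test cospectrum
#' (e.g. proton flux from a pumped pH sensor) against a reference from an
#' ideal sensor (e.g. O2) over the same window. Both cumulative curves are
#' first scaled to agree over the lowest-frequency quartile, where neither
#' sensor attenuates; the loss is one minus their ratio at the Nyquist
#' frequency. Negative loss (test richer in high frequencies) is allowed
#' and reported.
#'
#' @param cospectrum_test,cospectrum_reference `cospectrum` objects from
#'   the same window and rate.
#' @return List: `loss` (fraction in `[-0.5, 1]`, `NA` when the reference
#'   flux is ~0), `scale`, `flagged`.
#' @export
estimate_highfreq_loss <- function(cospectrum_test, cospectrum_reference) {
  te <- cospectrum_test; re <- cospectrum_reference
  stopifnot(inherits(te, "cospectrum"), inherits(re, "cospectrum"))
  if (length(te$frequencies) != length(re$frequencies))
    stop("cospectra must share a frequency grid")
  df <- te$frequencies[1]
  ## a coherent reference flux accumulates; near-total cancellation of the
  ## cospectral density means the reference flux is ~0 and the loss is
  ## undefined
  scale_ref <- sum(abs(re$co_density)) * df
  if (!is.finite(re$covariance) || scale_ref == 0 ||
      abs(re$covariance) < 0.05 * scale_ref) {
    return(list(loss = NA_real_, scale = NA_real_, flagged = TRUE))
  }
  ## scaling band: the lowest frequencies carrying the first quarter of the
  ## reference flux, where neither sensor attenuates
  q <- seq_len(max(1L, max(which(abs(re$ogive) <= 0.25), 1L)))
  num <- sum(te$co_density[q]) ; den <- sum(re$co_density[q])
  if (den == 0) return(list(loss = NA_real_, scale = NA_real_, flagged = TRUE))
  s <- num / den
  loss <- 1 - (te$covariance / s) / re$covariance
  list(loss = min(1, max(-0.5, loss)), scale = s, flagged = FALSE)
}

#' Storage flux of a solute layer below the measurement volume
#'
#' Rate of change of the solute inventory between the bed and the sensor
#' height, in the same units as the eddy flux. Rising concentration gives
#' a positive storage flux, which is subtracted from the measured
#' turbulent flux when inferring the benthic exchange.
#'
#' @param conc_start,conc_end Window-mean concentrations (umol kg^-1) at
#'   the window boundaries.
#' @param dt_s Time between the boundary means, seconds.
#' @param layer_height_m Height of the layer, m.
#' @param density Seawater density, kg m^-3.
#' @return Storage flux, mmol m^-2 d^-1.
#' @export
storage_flux <- function(conc_start, conc_end, dt_s, layer_height_m,
                         density = 1025) {
  (conc_end - conc_start) * density / 1000 * layer_height_m /
    (dt_s / 86400)
}

#' Convert a total-scale pH series to proton concentration
#'
#' `[H+] = 10^-pH`, elementwise, in nmol kg^-1. pH itself is not a
#' conservative quantity, so eddy fluxes are computed on the proton
#' concentration.
#'
#' @param ph Numeric pH values (total scale) in `[2, 12]`; `NA` passes
#'   through.
#' @return Proton concentration, nmol kg^-1.
#' @export
ph_to_proton <- function(ph) {
  bad <- !is.na(ph) & (ph < 2 | ph > 12)
  if (any(bad))
    stop("pH outside [2, 12]: first offending value ", ph[which(bad)[1]])
  10^(-ph) * 1e9
}

#' Single-point calibration of a raw ISFET millivolt record
#'
#' Converts an amplified ISFET signal to pH using the linear sensitivity
#' (default 590 mV per pH unit) anchored at a single in-situ reference pH:
#' `pH(t) = pH_ref + (mV(t) - mV(t_ref)) / gain`.
#'
#' @param mv_series `channel_series` of millivolt readings.
#' @param gain_mv_per_ph Sensitivity, mV per pH unit.
#' @param reference_time `POSIXct` time of the reference measurement; must
#'   lie within the record span.
#' @param reference_ph Reference pH (total scale).
#' @return A `channel_series` of pH.
#' @export
calibrate_isfet <- function(mv_series, gain_mv_per_ph = 590,
                            reference_time, reference_ph) {
  stopifnot(inherits(mv_series, "channel_series"))
  tt <- channel_times(mv_series)
  reference_time <- as.POSIXct(reference_time, tz = "UTC")
  if (reference_time < tt[1] || reference_time > tt[length(tt)])
    stop("calibration reference time outside the record span")
  ok <- !is.na(mv_series$values)
  mv_ref <- stats::approx(as.numeric(tt)[ok], mv_series$values[ok],
                          xout = as.numeric(reference_time), rule = 2)$y
  channel_series(reference_ph + (mv_series$values - mv_ref) / gain_mv_per_ph,
                 mv_series$rate, mv_series$start_time, units = "pH total")
}

#' Median-absolute-deviation despiking
#'
#' Flags samples deviating from a running median (default 10 s window) by
#' more than `n_mad` robust standard deviations and replaces them with
#' gaps. A conservative pre-filter for raw sensor channels; disable via
#' the processing configuration if the raw record is known clean.
#'
#' @param values Numeric samples.
#' @param rate Sampling rate, Hz.
#' @param n_mad Threshold in MAD-based sigmas (default 6).
#' @param window_s Running-median window, seconds (default 10).
#' @return List: `values` (spikes replaced by `NA`), `n_spikes`.
#' @export
despike_mad <- function(values, rate, n_mad = 6, window_s = 10) {
  n <- length(values)
  k <- round(window_s * rate)
  if (k %% 2 == 0) k <- k + 1
  if (k >= n) return(list(values = values, n_spikes = 0L))
  was_na <- is.na(values)
  x <- values
  if (any(was_na)) {
    idx <- which(!was_na)
    if (length(idx) < 2) return(list(values = values, n_spikes = 0L))
    x <- stats::approx(idx, values[idx], xout = seq_len(n), rule = 2)$y
  }
  med <- stats::runmed(x, k, endrule = "median")
  resid <- x - med
  sigma <- stats::mad(resid)
  if (sigma == 0) return(list(values = values, n_spikes = 0L))
  spikes <- abs(resid) > n_mad * sigma & !was_na
  out <- values
  out[spikes] <- NA_real_
  list(values = out, n_spikes = sum(spikes))
}

#' Flow direction as a compass bearing
#'
#' @param u,v Horizontal velocity components in instrument coordinates.
#' @param heading Compass heading of the instrument +u axis, degrees from
#'   north.
#' @return Direction toward which the flow moves, degrees clockwise from
#'   north.
#' @export
flow_direction <- function(u, v, heading = 90) {
  (heading - atan2(v, u) * 180 / pi) %% 360
}
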