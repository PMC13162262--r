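## Ground-truthed synthetic deployments: band-limited turbulence with
## prescribed scalar covariance, a diel metabolism/calcification forcing
## passed through the carbonate forward model, vent CO2 intrusions, and
## sensor artifacts (tilt, lag, response filtering, pump gaps, noise).

## Band-limited unit-variance noise: white Gaussian shaped in the
## frequency domain to a low-frequency plateau rolling off as f^(-5/3)
## (in power) above the knee f0 -- a simple inertial-range surrogate.
shaped_noise <- function(n, rate, f0 = 0.05) {
  x <- stats::rnorm(n)
  f <- (0:(n - 1)) * rate / n
  f <- pmin(f, rate - f)                      # two-sided frequency axis
  gain <- (1 + (f / f0)^2)^(-5 / 12)
  gain[1] <- 0                                # remove DC
  y <- Re(stats::fft(stats::fft(x) * gain, inverse = TRUE)) / n
  y / stats::sd(y)
}

#' Synthetic turbulent velocity/scalar pair with prescribed covariance
#'
#' Generates a vertical-velocity fluctuation series as band-limited
#' Gaussian noise and a scalar fluctuation `c' = alpha w' + noise`, with
#' `alpha` chosen so that the full-record covariance delivers the target
#' flux. Individual averaging windows then scatter around the target with
#' the natural sampling error of turbulent covariances.
#'
#' @param target_flux Target flux in mmol m^-2 d^-1 for a scalar in
#'   umol kg^-1 (or umol m^-2 d^-1 for nmol kg^-1).
#' @param duration_s Record length, seconds (>= 1800).
#' @param rate Sampling rate, Hz.
#' @param seed Integer seed; fixes the realization.
#' @param sigma_w Standard deviation of `w'`, m s^-1.
#' @param noise_sd Standard deviation of the scalar noise component,
#'   scalar units.
#' @param density Seawater density, kg m^-3.
#' @param f0 Spectral knee frequency, Hz.
#' @return List with `w` and `c` (`channel_series`), `alpha`, and
#'   `target_covariance`.
#' @export
simulate_turbulence <- function(target_flux, duration_s, rate = 5,
                                seed = 1, sigma_w = 0.006, noise_sd = 0.1,
                                density = 1025, f0 = 0.05) {
  if (duration_s < 1800) stop("duration must be at least 30 min")
  set.seed(seed)
  n <- round(duration_s * rate)
  w <- sigma_w * shaped_noise(n, rate, f0)
  target_cov <- target_flux / (density * 86.4)
  alpha <- target_cov / stats::var(w)
  cnoise <- noise_sd * shaped_noise(n, rate, f0)
  if (abs(alpha) * stats::sd(w) > 0 && noise_sd < 0) stop("negative noise sd")
  cc <- alpha * w + cnoise
  list(w = channel_series(w, rate, units = "m s-1"),
       c = channel_series(cc, rate, units = "scalar"),
       alpha = alpha, target_covariance = target_cov)
}

#' Apply sensor artifacts to a channel
#'
#' Applies, in order: a first-order low-pass response filter matched to a
#' stated 90% response time, a pure delay, additive white noise, and
#' Poisson-distributed spikes. A call with all defaults is the identity.
#'
#' @param series A `channel_series`.
#' @param lag_s Pure delay, seconds (rounded to whole samples).
#' @param t90_s 90% step-response time of a first-order filter, seconds
#'   (0 disables; the filter time constant is `t90 / ln 10`).
#' @param noise_sd Additive white-noise standard deviation.
#' @param spike_rate Expected spikes per hour (Poisson).
#' @param spike_amp Spike amplitude in units of the channel (default 10x
#'   the series standard deviation).
#' @return The perturbed `channel_series`; artifact parameters are stored
#'   in `attr(, "artifacts")`.
#' @export
inject_artifacts <- function(series, lag_s = 0, t90_s = 0, noise_sd = 0,
                             spike_rate = 0, spike_amp = NULL) {
  stopifnot(inherits(series, "channel_series"))
  x <- series$values
  n <- length(x)
  rate <- series$rate
  if (t90_s > 0) {
    tau <- t90_s / log(10)
    a <- exp(-1 / (rate * tau))
    x <- as.numeric(stats::filter(x * (1 - a), a, method = "recursive",
                                  init = x[1]))
  }
  shift <- round(lag_s * rate)
  if (shift > 0) x <- c(rep(x[1], shift), x[seq_len(n - shift)])
  if (noise_sd > 0) x <- x + stats::rnorm(n, 0, noise_sd)
  if (spike_rate > 0) {
    nspk <- stats::rpois(1, spike_rate * n / rate / 3600)
    if (nspk > 0) {
      if (is.null(spike_amp)) spike_amp <- 10 * stats::sd(x, na.rm = TRUE)
      at <- sample.int(n, min(nspk, n))
      x[at] <- x[at] + sample(c(-1, 1), length(at), TRUE) * spike_amp
    }
  }
  out <- channel_series(x, rate, series$start_time, series$units,
                        gaps = series$gaps)
  attr(out, "artifacts") <- list(lag_s = shift / rate, t90_s = t90_s,
                                 noise_sd = noise_sd,
                                 spike_rate = spike_rate)
  out
}

#' Default synthetic-deployment scenario
#'
#' The study conditions emulated by the generator: a 24 h deployment over
#' a seagrass meadow at 25 degC, salinity 38, alkalinity 2650 umol kg^-1
#' and background pH 8.04; 16 Hz velocities with 2-10 cm s^-1 mean flow
#' and ~0.6 cm s^-1 vertical turbulence; 5 Hz O2 and pH; net
#' photosynthesis +150 (light) / -60 (dark) mmol C m^-2 d^-1 with
#' Q = 1.09; net calcification +30 (light) / -15 (dark) mmol CaCO3
#' m^-2 d^-1; a 5 degree instrument pitch, a 1.4 s pH intake lag, a 1-min
#' pump flow reversal every 30 min, and sensor noise.
#'
#' @param ... Named overrides of any default.
#' @return A scenario list.
#' @export
default_scenario <- function(...) {
  sc <- list(
    start_time = as.POSIXct("2020-09-18 00:00:00", tz = "UTC"),
    duration_h = 24,
    vel_rate = 16, scalar_rate = 5,
    mean_speed_cm_s = 5, speed_amplitude_cm_s = 2,
    direction_deg = 45, direction_amplitude_deg = 60,
    direction_period_h = 6,
    tilt_deg = 5,
    ph_lag_s = 1.4, o2_lag_s = 0.4, ph_t90_s = 0,
    sigma_w = 0.006, f0 = 0.05,
    o2_noise_sd = 0.3, h_noise_sd = 0.05,
    o2_background = 220,
    sunrise_h = 6, sunset_h = 18, par_max = 1000,
    p_net_light = 150, p_net_dark = -60,
    g_net_light = 30, g_net_dark = -15,
    q = 1.09,
    alkalinity = 2650, salinity = 38, temperature = 25, ph_background = 8.04,
    vent_events = list(),
    pump_period_s = 1800, pump_duration_s = 60, pump_phase_s = 0,
    seed = 1
  )
  over <- list(...)
  if (length(over)) {
    unknown <- setdiff(names(over), names(sc))
    if (length(unknown)) stop("unknown scenario fields: ",
                              paste(unknown, collapse = ", "))
    sc[names(over)] <- over
  }
  sc
}

## Vent DIC enrichment (umol/kg) and spurious vent proton flux
## (mmol CO2-equivalents m^-2 d^-1) on a time grid (seconds from start).
vent_profiles <- function(t_s, events) {
  ddic <- numeric(length(t_s))
  vflux <- numeric(length(t_s))
  ramp_s <- 300
  for (ev in events) {
    t0 <- ev$start_h * 3600
    t1 <- t0 + ev$duration_h * 3600
    up <- pmin(1, pmax(0, (t_s - t0) / ramp_s))
    down <- pmin(1, pmax(0, (t1 - t_s) / ramp_s))
    shape <- pmin(up, down)
    ddic <- ddic + ev$ddic * shape
    fx <- if (is.null(ev$flux_co2eq)) 0 else ev$flux_co2eq
    vflux <- vflux + fx * shape
  }
  list(ddic = ddic, flux_co2eq = vflux)
}

#' Simulate a full ground-truthed deployment
#'
#' Realizes a scenario (see [default_scenario()]) as raw sensor channels
#' plus the generator's truth record. O2 and proton fluctuation channels
#' are built on the true 5 Hz vertical velocity with per-sample covariance
#' targets set by the diel net photosynthesis and calcification forcing
#' passed through the carbonate forward model; the pH channel is the
#' proton channel of the slowly varying background state (including any
#' vent DIC intrusions) plus those turbulent fluctuations. Instrument
#' tilt, sensor lags, optional response filtering, pump-reversal gaps and
#' noise are applied last.
#'
#' @param scenario A scenario list from [default_scenario()].
#' @return List: `velocity` (16 Hz `velocity_record`, instrument frame),
#'   `o2`, `ph` (5 Hz `channel_series`), `par` (1-min `channel_series`),
#'   `truth` (per 30-min window: prescribed and realized fluxes, light and
#'   vent labels), and the `scenario` (with all defaults resolved).
#' @export
simulate_deployment <- function(scenario = default_scenario()) {
  sc <- scenario
  if (is.character(sc$start_time))
    sc$start_time <- as.POSIXct(sub("Z$", "", sc$start_time),
                                format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
  set.seed(sc$seed)
  dur_s <- sc$duration_h * 3600
  n16 <- round(dur_s * sc$vel_rate)
  n5 <- round(dur_s * sc$scalar_rate)
  t5 <- (seq_len(n5) - 1) / sc$scalar_rate
  rho <- seawater_density(sc$temperature, sc$salinity)

  ## --- true velocity field (level frame) ---
  t16 <- (seq_len(n16) - 1) / sc$vel_rate
  speed <- (sc$mean_speed_cm_s +
              sc$speed_amplitude_cm_s * sin(2 * pi * t16 / 43200)) / 100
  dir_deg <- sc$direction_deg + sc$direction_amplitude_deg *
    sin(2 * pi * t16 / (sc$direction_period_h * 3600))
  dirrad <- (90 - dir_deg) * pi / 180           # +u axis points east
  w16 <- sc$sigma_w * shaped_noise(n16, sc$vel_rate, sc$f0)
  u16 <- speed * cos(dirrad) +
    2 * sc$sigma_w * shaped_noise(n16, sc$vel_rate, sc$f0)
  v16 <- speed * sin(dirrad) +
    1.5 * sc$sigma_w * shaped_noise(n16, sc$vel_rate, sc$f0)

  ## --- diel forcing and background carbonate state ---
  h0 <- as.numeric(format(sc$start_time, "%H", tz = "UTC")) +
    as.numeric(format(sc$start_time, "%M", tz = "UTC")) / 60
  hour <- (h0 + t5 / 3600) %% 24
  light <- hour >= sc$sunrise_h & hour < sc$sunset_h
  p_net <- ifelse(light, sc$p_net_light, sc$p_net_dark)
  g_net <- ifelse(light, sc$g_net_light, sc$g_net_dark)

  base <- solve_seawater(sc$alkalinity, ph = sc$ph_background,
                         temperature = sc$temperature,
                         salinity = sc$salinity)
  grid_s <- seq(0, dur_s, by = 300)
  vent_g <- vent_profiles(grid_s, sc$vent_events)
  ph_g <- numeric(length(grid_s))
  d1_g <- numeric(length(grid_s))
  d2_g <- numeric(length(grid_s))
  for (i in seq_along(grid_s)) {
    st <- if (vent_g$ddic[i] == 0) base else
      solve_seawater(sc$alkalinity, dic = base$dic + vent_g$ddic[i],
                     temperature = sc$temperature, salinity = sc$salinity)
    ph_g[i] <- st$ph
    d1_g[i] <- dh_ddic(st)
    d2_g[i] <- dh_ddic2alk(st)
  }
  ph_base <- stats::approx(grid_s, ph_g, xout = t5)$y
  d1 <- stats::approx(grid_s, d1_g, xout = t5)$y
  d2 <- stats::approx(grid_s, d2_g, xout = t5)$y
  vent5 <- vent_profiles(t5, sc$vent_events)

  ## --- per-sample flux targets ---
  flux_o2 <- p_net * sc$q                       # mmol O2 m-2 d-1
  flux_h_umol <- (-p_net * d1 + g_net * d2) * 1000 +
    vent5$flux_co2eq * d1 * 1000                # umol H+ m-2 d-1

  ## --- scalar fluctuations on the true 5 Hz vertical velocity ---
  w5 <- block_mean(w16, sc$vel_rate, sc$scalar_rate)
  var_w5 <- stats::var(w5)
  cov_o2 <- flux_o2 / (rho * 86.4)              # m/s umol/kg
  cov_h <- flux_h_umol / (rho * 86.4)           # m/s nmol/kg
  a_o2 <- cov_o2 / var_w5
  a_h <- cov_h / var_w5
  c_o2 <- a_o2 * w5
  c_h <- a_h * w5
  o2 <- sc$o2_background + c_o2 +
    sc$o2_noise_sd * shaped_noise(n5, sc$scalar_rate, sc$f0)
  h_nmol <- ph_to_proton(ph_base) + c_h +
    sc$h_noise_sd * shaped_noise(n5, sc$scalar_rate, sc$f0)

  ## --- truth per 30-min window (aligned with the processing grid) ---
  win <- floor(t5 / 1800) + 1L
  nwin <- max(win)
  win_mean <- function(x) vapply(seq_len(nwin),
                                 function(k) mean(x[win == k]), numeric(1))
  ## realized covariance of the correlated component within each window
  real_cov <- function(a) vapply(seq_len(nwin), function(k) {
    i <- win == k
    stats::cov(w5[i], a[i] * w5[i]) * (sum(i) - 1) / sum(i)
  }, numeric(1))
  truth <- data.frame(
    window = seq_len(nwin),
    start = sc$start_time + (seq_len(nwin) - 1) * 1800,
    light = win_mean(as.numeric(light)) > 0.5,
    p_net = win_mean(p_net),
    g_net = win_mean(g_net),
    flux_o2_target = win_mean(flux_o2),
    flux_h_target = win_mean(flux_h_umol),
    flux_o2_realized = real_cov(a_o2) * rho * 86.4,
    flux_h_realized = real_cov(a_h) * rho * 86.4,
    vent = win_mean(vent5$ddic) > 0.5 | win_mean(vent5$flux_co2eq) > 0.5
  )
  truth$applied_lag_s <- round(sc$ph_lag_s * sc$scalar_rate) / sc$scalar_rate
  truth$applied_tilt_deg <- sc$tilt_deg

  ## --- instrument artifacts ---
  th <- sc$tilt_deg * pi / 180                  # pitch about the v axis
  u_m <- u16 * cos(th) - w16 * sin(th)
  w_m <- u16 * sin(th) + w16 * cos(th)
  ph_meas <- -log10(pmax(h_nmol, 1e-3) * 1e-9)
  ph_ch <- channel_series(ph_meas, sc$scalar_rate, sc$start_time, "pH total")
  ph_ch <- inject_artifacts(ph_ch, lag_s = sc$ph_lag_s, t90_s = sc$ph_t90_s)
  o2_ch <- channel_series(o2, sc$scalar_rate, sc$start_time, "umol kg-1")
  o2_ch <- inject_artifacts(o2_ch, lag_s = sc$o2_lag_s)
  pump <- ((t5 - sc$pump_phase_s) %% sc$pump_period_s) < sc$pump_duration_s
  vals <- ph_ch$values
  vals[pump] <- NA_real_
  ph_ch <- channel_series(vals, sc$scalar_rate, sc$start_time, "pH total")

  par_t <- seq(0, dur_s - 60, by = 60)
  par_hour <- (h0 + par_t / 3600) %% 24
  par <- ifelse(par_hour >= sc$sunrise_h & par_hour < sc$sunset_h,
                sc$par_max * pmax(0, sin(pi * (par_hour - sc$sunrise_h) /
                                           (sc$sunset_h - sc$sunrise_h))),
                0)

  list(
    velocity = velocity_record(
      channel_series(u_m, sc$vel_rate, sc$start_time, "m s-1"),
      channel_series(v16, sc$vel_rate, sc$start_time, "m s-1"),
      channel_series(w_m, sc$vel_rate, sc$start_time, "m s-1"),
      heading = 90),
    o2 = o2_ch,
    ph = ph_ch,
    par = channel_series(par, 1 / 60, sc$start_time,
                         "umol photons m-2 s-1"),
    truth = truth,
    scenario = sc
  )
}

## Block means from a higher to a lower rate on bare numeric vectors.
block_mean <- function(x, rate_in, rate_out) {
  n <- length(x)
  bin <- floor((seq_len(n) - 1) / rate_in * rate_out) + 1L
  nbins <- floor(n * rate_out / rate_in)
  keep <- bin <= nbins
  as.numeric(rowsum(x[keep], bin[keep]) / tabulate(bin[keep], nbins))
}
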