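## Deployment-level processing driver: raw channels -> quality-controlled
## flux windows.

#' Processing configuration
#'
#' Defaults for the flux-processing chain. Every parameter that enters the
#' computation is present here, so the effective configuration serialized
#' next to the outputs is complete.
#'
#' @param ... Named overrides.
#' @return A named list of processing parameters.
#' @export
process_config <- function(...) {
  cfg <- list(
    target_rate = 5,          # Hz, scalar/processing rate
    window_s = 1800,          # flux window grid (incl. the pump minute)
    running_mean_s = 500,     # Reynolds decomposition window
    max_lag_s = 2,            # lag-alignment search half-window
    edge_exclude_s = 250,     # dropped at record edges (half running mean)
    min_valid_frac = 0.5,
    r2_threshold = 0.8,
    despike = TRUE, despike_mad = 6, despike_window_s = 10,
    pump_period_s = 1800, pump_duration_s = 60, pump_phase_s = 0,
    pump_applies_to = "ph",
    min_speed_cm_s = 0.5,
    par_light_threshold = 1,  # umol photons m-2 s-1
    light_hours = c(6, 18),   # fallback when no PAR channel is given
    temperature = 25, salinity = 38,
    min_abs_corr = 0.1
  )
  over <- list(...)
  if (length(over)) {
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown)) stop("unknown config keys: ",
                              paste(unknown, collapse = ", "))
    cfg[names(over)] <- over
  }
  cfg
}

#' Process a deployment into quality-controlled flux windows
#'
#' The full chain: optional despiking, downsampling of the velocity record
#' to the scalar rate, a whole-deployment planar-fit rotation from
#' window-mean velocities, Reynolds decomposition (running mean), and for
#' each window and scalar: pump-reversal masking, lag alignment,
#' covariance flux, cumulative-flux linearity QC and summary statistics.
#' pH channels are converted to proton concentration (nmol kg^-1) before
#' decomposition, so their flux column is in umol H+ m^-2 d^-1; scalar
#' channels in umol kg^-1 yield mmol m^-2 d^-1.
#'
#' @param velocity A `velocity_record` (any rate >= the scalar rate).
#' @param scalars Named list of `channel_series` at the scalar rate;
#'   a channel named `"ph"` is treated as total-scale pH.
#' @param par Optional `channel_series` of photosynthetically active
#'   radiation used to classify windows as light/dark.
#' @param config A [process_config()] list.
#' @return List of class `deployment_fluxes`: `windows` (one row per
#'   window: times, means, per-scalar fluxes `flux_<name>`, lags, QC
#'   flags), `rotation` (the `planar_fit`), `config`, and `qc_summary`
#'   (window counts by flag).
#' @export
process_deployment <- function(velocity, scalars, par = NULL,
                               config = process_config()) {
  stopifnot(inherits(velocity, "velocity_record"))
  if (!length(scalars)) stop("no scalar channels supplied")
  if (is.null(names(scalars)) || any(!nzchar(names(scalars))))
    stop("scalars must be a named list")
  cfg <- config
  rate <- cfg$target_rate

  despike_channel <- function(ch) {
    if (!cfg$despike) return(ch)
    d <- despike_mad(ch$values, ch$rate, cfg$despike_mad,
                     cfg$despike_window_s)
    channel_series(d$values, ch$rate, ch$start_time, ch$units)
  }

  u <- despike_channel(velocity$u); v <- despike_channel(velocity$v)
  w <- despike_channel(velocity$w)
  if (u$rate > rate) {
    u <- downsample(u, rate); v <- downsample(v, rate); w <- downsample(w, rate)
  } else if (u$rate != rate) stop("velocity rate below the processing rate")
  n <- length(u)
  for (nm in names(scalars)) {
    ch <- scalars[[nm]]
    stopifnot(inherits(ch, "channel_series"))
    if (abs(ch$rate - rate) > 0.01 * rate)
      stop("scalar '", nm, "' rate ", ch$rate, " != processing rate ", rate)
    if (abs(as.numeric(ch$start_time) - as.numeric(u$start_time)) > 1 / rate)
      stop("scalar '", nm, "' start time differs from the velocity record")
    scalars[[nm]] <- despike_channel(ch)
  }
  nw <- min(n, min(vapply(scalars, length, integer(1))))
  nwin <- floor(nw / (cfg$window_s * rate))
  if (nwin < 1) stop("record shorter than one flux window")

  ## whole-deployment planar fit from window-mean velocities
  wins_all <- rep(seq_len(nwin), each = cfg$window_s * rate)[seq_len(nw)]
  wmean <- function(x) as.numeric(tapply(x[seq_len(nw)], wins_all, mean,
                                         na.rm = TRUE))
  fit <- planar_fit(wmean(u$values), wmean(v$values), wmean(w$values))
  rot <- apply_rotation(fit, u$values[seq_len(nw)], v$values[seq_len(nw)],
                        w$values[seq_len(nw)])

  t_s <- (seq_len(nw) - 1) / rate
  edge <- t_s < cfg$edge_exclude_s | t_s >= (nw / rate - cfg$edge_exclude_s)
  pump <- ((t_s - cfg$pump_phase_s) %% cfg$pump_period_s) <
    cfg$pump_duration_s

  dec_w <- reynolds_decompose(rot$w, rate, cfg$running_mean_s)
  w_pr <- dec_w$fluctuation
  w_pr[edge] <- NA_real_

  scalar_pr <- list()
  scalar_raw <- list()
  for (nm in names(scalars)) {
    x <- scalars[[nm]]$values[seq_len(nw)]
    scalar_raw[[nm]] <- x
    xs <- if (identical(nm, "ph")) ph_to_proton(x) else x
    if (nm %in% cfg$pump_applies_to) xs[pump] <- NA_real_
    dec <- reynolds_decompose(xs, rate, cfg$running_mean_s)
    fl <- dec$fluctuation
    fl[edge] <- NA_real_
    scalar_pr[[nm]] <- fl
  }

  rho <- seawater_density(cfg$temperature, cfg$salinity)
  wl <- cfg$window_s * rate

  ## first pass: per-window lags; the deployment-median lag of confident
  ## windows serves as the fallback for low-correlation windows
  fallback_lag <- list()
  first_pass <- list()
  for (nm in names(scalars)) {
    first_pass[[nm]] <- lapply(seq_len(nwin), function(k) {
      i <- ((k - 1) * wl + 1):(k * wl)
      lag_align(w_pr[i], scalar_pr[[nm]][i], rate, cfg$max_lag_s,
                cfg$min_abs_corr)
    })
    good <- vapply(first_pass[[nm]], function(l)
      if (l$low_correlation) NA_real_ else l$lag_s, numeric(1))
    fallback_lag[[nm]] <- stats::median(good, na.rm = TRUE)
  }

  res <- vector("list", nwin)
  for (k in seq_len(nwin)) {
    i <- ((k - 1) * wl + 1):(k * wl)
    row <- list(
      window = k,
      start = u$start_time + (k - 1) * cfg$window_s,
      end = u$start_time + k * cfg$window_s,
      n_samples = wl,
      mean_speed = mean(sqrt(rot$u[i]^2 + rot$v[i]^2), na.rm = TRUE) * 100,
      mean_direction = flow_direction(mean(rot$u[i], na.rm = TRUE),
                                      mean(rot$v[i], na.rm = TRUE),
                                      velocity$heading)
    )
    row$qc_low_turbulence <- is.finite(row$mean_speed) &&
      row$mean_speed < cfg$min_speed_cm_s
    any_invalid <- FALSE
    for (nm in names(scalars)) {
      la <- lag_align(w_pr[i], scalar_pr[[nm]][i], rate, cfg$max_lag_s,
                      cfg$min_abs_corr)
      if (la$low_correlation && !is.na(fallback_lag[[nm]])) {
        ## weak peak correlation: searching for the maximum would inflate
        ## the covariance, so reuse the deployment-median lag of the
        ## confident windows
        m <- as.integer(round(fallback_lag[[nm]] * rate))
        shifted <- rep(NA_real_, length(i))
        cp <- scalar_pr[[nm]][i]
        if (m >= 0) shifted[seq_len(length(i) - m)] <-
            cp[seq_len(length(i) - m) + m]
        else shifted[seq_len(length(i) + m) - m] <- cp[seq_len(length(i) + m)]
        la$c_aligned <- shifted
        la$lag_s <- m / rate
      }
      fx <- compute_flux(w_pr[i], la$c_aligned, density = rho,
                         mask = pump[i] & (nm %in% cfg$pump_applies_to),
                         min_valid_frac = cfg$min_valid_frac)
      qc <- cumulative_flux_qc(w_pr[i], la$c_aligned, cfg$r2_threshold)
      ## the pH role carries a proton flux (umol H+ m-2 d-1)
      cn <- if (identical(nm, "ph")) "h" else nm
      row[[paste0("flux_", cn)]] <- fx$flux
      row[[paste0("lag_", cn)]] <- la$lag_s
      row[[paste0("corr_", cn)]] <- la$max_corr
      row[[paste0("qc_nonlinear_", cn)]] <- !qc$linear
      row[[paste0("qc_low_flux_", cn)]] <- qc$low_flux
      row[[paste0("qc_low_corr_", cn)]] <- la$low_correlation
      row[[paste0("mean_", nm)]] <- mean(scalar_raw[[nm]][i], na.rm = TRUE)
      any_invalid <- any_invalid || fx$qc_invalid
    }
    row$qc_invalid <- any_invalid
    res[[k]] <- row
  }
  windows <- do.call(rbind, lapply(res, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))

  ## light classification
  if (!is.null(par)) {
    pt <- as.numeric(channel_times(par) - u$start_time, units = "secs")
    windows$mean_par <- vapply(seq_len(nwin), function(k) {
      sel <- pt >= (k - 1) * cfg$window_s & pt < k * cfg$window_s
      if (!any(sel)) NA_real_ else mean(par$values[sel], na.rm = TRUE)
    }, numeric(1))
    windows$light <- !is.na(windows$mean_par) &
      windows$mean_par > cfg$par_light_threshold
  } else {
    mid <- windows$start + cfg$window_s / 2
    mid_h <- as.numeric(format(mid, "%H", tz = "UTC")) +
      as.numeric(format(mid, "%M", tz = "UTC")) / 60
    windows$light <- mid_h >= cfg$light_hours[1] & mid_h < cfg$light_hours[2]
  }
  windows$mean_temperature <- cfg$temperature

  qc_cols <- grep("^qc_", names(windows), value = TRUE)
  qc_summary <- vapply(qc_cols, function(cn) sum(windows[[cn]], na.rm = TRUE),
                       integer(1))
  structure(list(windows = windows, rotation = fit, config = cfg,
                 qc_summary = qc_summary),
            class = "deployment_fluxes")
}

#' @export
print.deployment_fluxes <- function(x, ...) {
  cat(sprintf("<deployment_fluxes> %d windows of %g min\n",
              nrow(x$windows), x$config$window_s / 60))
  cat(sprintf("  planar-fit tilt %.2f deg; QC flags: %s\n",
              x$rotation$tilt_deg,
              paste(names(x$qc_summary), x$qc_summary, sep = "=",
                    collapse = ", ")))
  invisible(x)
}
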