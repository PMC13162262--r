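## Net ecosystem calcification from paired proton and O2 fluxes, daily
## aggregation, O2-based metabolism, and the alkalinity-anomaly reference
## method.

#' Photosynthetic quotient from a C:N ratio
#'
#' `Q = (n + 2) / n`, where `n` is the molar C:N ratio of the organic
#' matter fixed and respired. The same quotient is used in the light
#' (moles O2 produced per mole CO2 fixed) and in the dark (as the inverse
#' respiratory quotient).
#'
#' @param n Molar C:N ratio, > 0.
#' @return The photosynthetic quotient.
#' @examples
#' photosynthetic_quotient(22.2)  # ~1.09
#' @export
photosynthetic_quotient <- function(n) {
  if (any(n <= 0)) stop("C:N ratio must be positive")
  (n + 2) / n
}

#' Metabolism-weighted community C:N ratio
#'
#' Weighted arithmetic mean of component C:N ratios, with weights equal to
#' each component's fraction of community metabolism. For a seagrass
#' meadow whose epiphytes contribute one third of photosynthesis, e.g.
#' `community_cn(data.frame(label = c("epiphytes", "seagrass"),
#' cn_ratio = c(13.7, 26.8), fraction = c(1/3, 2/3)))`.
#'
#' @param composition Data frame with columns `cn_ratio` (> 0) and
#'   `fraction` (in `[0, 1]`, summing to 1); an optional `label` column is
#'   carried for documentation.
#' @return The community C:N ratio.
#' @export
community_cn <- function(composition) {
  if (!is.data.frame(composition) || nrow(composition) == 0)
    stop("empty community composition")
  cn <- composition$cn_ratio
  f <- composition$fraction
  if (any(cn <= 0)) stop("C:N ratios must be positive")
  if (any(f < 0 | f > 1) || abs(sum(f) - 1) > 1e-9)
    stop("metabolism fractions must lie in [0, 1] and sum to 1")
  sum(cn * f)
}

#' Proton flux consumed by net photosynthesis
#'
#' The proton-flux contribution of net community photosynthesis inferred
#' from the O2 flux: `-(flux_o2 / Q) * dH+/dDIC`. Positive O2 flux (net
#' photosynthesis) gives a negative (downward) proton flux, because
#' photosynthetic DIC uptake removes protons at equilibrium.
#'
#' @param flux_o2 O2 eddy flux, mmol O2 m^-2 d^-1.
#' @param q Photosynthetic quotient, > 0.
#' @param state A solved [solve_seawater()] state.
#' @return Proton flux, mol H+ m^-2 d^-1.
#' @export
proton_flux_pnet <- function(flux_o2, q, state) {
  if (q <= 0) stop("photosynthetic quotient must be positive")
  -(flux_o2 / q) * dh_ddic(state) / 1000
}

#' Net ecosystem calcification from paired proton and O2 fluxes
#'
#' Inverts the proton budget: the measured ecosystem proton flux is the
#' sum of the (negative) photosynthetic contribution and the (positive)
#' calcification contribution, so
#' `gnet = (flux_h - proton_flux_pnet(flux_o2, q, state)) / dH+/d(DIC 2At)`
#' which equals `(flux_h + (flux_o2/q) dH+/dDIC) / dH+/d(DIC 2At)` with
#' the proton-yield ratio defined per unit DIC added. Positive values are
#' net calcification; negative values net CaCO3 dissolution.
#'
#' @param flux_h Measured ecosystem proton flux, mol H+ m^-2 d^-1
#'   (positive = efflux to the water column).
#' @param flux_o2 O2 eddy flux, mmol O2 m^-2 d^-1.
#' @param q Photosynthetic quotient.
#' @param state A solved `seawater_state` for the window.
#' @return Net calcification, mmol CaCO3 m^-2 d^-1.
#' @export
gnet <- function(flux_h, flux_o2, q, state) {
  d2 <- dh_ddic2alk(state)
  if (!is.finite(d2) || d2 == 0)
    stop("degenerate buffer: dH+/d(DIC 2At) is zero at this state")
  (flux_h - proton_flux_pnet(flux_o2, q, state)) / d2 * 1000
}

#' Daily net ecosystem calcification
#'
#' Hour-weighted combination of the light and dark mean calcification
#' rates: `NEC = G_light h_light/24 + G_dark h_dark/24`.
#'
#' @param gnet_light_mean,gnet_dark_mean Mean G_net in the light and dark,
#'   mmol CaCO3 m^-2 d^-1.
#' @param h_light,h_dark Light and dark hours; must sum to 24.
#' @return Daily NEC, mmol CaCO3 m^-2 d^-1.
#' @examples
#' daily_nec(28.9, 15.4, 12, 12)  # ~22.1
#' @export
daily_nec <- function(gnet_light_mean, gnet_dark_mean, h_light = 12,
                      h_dark = 12) {
  if (abs(h_light + h_dark - 24) > 1e-9)
    stop("light and dark hours must sum to 24")
  gnet_light_mean * h_light / 24 + gnet_dark_mean * h_dark / 24
}

#' Propagate light/dark standard errors to a daily value
#'
#' Quadrature sum `sqrt(se_light^2 + se_dark^2)` of the light and dark
#' standard errors.
#'
#' @param se_light,se_dark Standard errors, >= 0.
#' @return Daily standard error.
#' @examples
#' propagate_se(23.4, 12.9)  # ~26.7
#' @export
propagate_se <- function(se_light, se_dark) {
  if (any(c(se_light, se_dark) < 0)) stop("standard errors must be >= 0")
  sqrt(se_light^2 + se_dark^2)
}

#' Ecosystem metabolism from O2 flux windows
#'
#' Respiration `R` is the mean dark O2 flux taken as the around-the-clock
#' respiration rate; net ecosystem metabolism `NEM` is the hour-weighted
#' mean of light and dark fluxes; gross primary production is
#' `GPP = NEM - R`. Fluxes should be storage-corrected beforehand where
#' that correction is enabled.
#'
#' @param flux_o2 O2 fluxes per window, mmol O2 m^-2 d^-1.
#' @param light Logical, one per window.
#' @param h_light,h_dark Light and dark hours (sum 24).
#' @return List with `r`, `gpp`, `nem` (mmol O2 m^-2 d^-1) and their
#'   standard errors `r_se`, `gpp_se`, `nem_se`, plus `n_light`, `n_dark`.
#' @export
metabolism <- function(flux_o2, light, h_light = 12, h_dark = 12) {
  if (abs(h_light + h_dark - 24) > 1e-9)
    stop("light and dark hours must sum to 24")
  stopifnot(length(flux_o2) == length(light))
  ok <- !is.na(flux_o2)
  fl <- flux_o2[ok & light]
  fd <- flux_o2[ok & !light]
  if (length(fd) == 0) stop("no dark windows: respiration undefined")
  se <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
  r <- mean(fd); r_se <- se(fd)
  if (length(fl) == 0) {
    nem <- r; nem_se <- r_se
    gpp <- NA_real_; gpp_se <- NA_real_
  } else {
    ml <- mean(fl); ml_se <- se(fl)
    nem <- ml * h_light / 24 + r * h_dark / 24
    ## light/dark errors combine as plain quadrature sums
    nem_se <- propagate_se(ml_se, r_se)
    gpp <- nem - r
    gpp_se <- propagate_se(ml_se, r_se)
  }
  list(r = r, r_se = r_se, gpp = gpp, gpp_se = gpp_se,
       nem = nem, nem_se = nem_se,
       n_light = length(fl), n_dark = length(fd))
}

#' Net calcification by the alkalinity-anomaly technique
#'
#' The classical residence-time method: `G_net = dAt rho z / (2 tau)`,
#' with two moles of alkalinity consumed per mole of CaCO3 formed.
#' Provided as the reference technique against which the flux-based
#' estimate is discussed.
#'
#' @param delta_alk Alkalinity change of the water over the residence
#'   time, umol kg^-1 (negative when calcification consumes alkalinity).
#' @param density Seawater density, kg m^-3.
#' @param depth_m Mean water depth, m.
#' @param residence_time_d Residence time of water over the reef, days
#'   (> 0).
#' @return Net calcification, mmol CaCO3 m^-2 d^-1 (positive when
#'   alkalinity decreases).
#' @export
alkalinity_anomaly_gnet <- function(delta_alk, density, depth_m,
                                    residence_time_d) {
  if (residence_time_d <= 0) stop("residence time must be positive")
  -delta_alk * density / 1000 * depth_m / (2 * residence_time_d)
}

#' Flag vent-affected calcification windows
#'
#' Proton fluxes dominated by geologic CO2 enrichment dwarf the O2 fluxes
#' that metabolism could explain. A window is flagged when the magnitude
#' of its CO2-equivalent proton flux exceeds `magnitude_ratio_threshold`
#' times the larger of its O2-flux magnitude and `o2_floor`, or when its
#' mean flow direction falls in a configured exclusion sector. Flagged
#' windows are excluded from G_net aggregation but retained in output.
#'
#' @param windows Data frame with columns `flux_h_co2eq` (mmol
#'   CO2-equivalents m^-2 d^-1), `flux_o2` (mmol O2 m^-2 d^-1) and
#'   optionally `mean_direction` (degrees from north).
#' @param magnitude_ratio_threshold Ratio threshold (default 3;
#'   `Inf` disables the magnitude rule).
#' @param o2_floor Floor on the O2-flux magnitude, mmol m^-2 d^-1, so calm
#'   windows are not flagged on a near-zero denominator.
#' @param direction_sectors List of `c(from, to)` compass sectors
#'   (degrees, clockwise, `from` to `to`) to exclude; empty list disables.
#' @return Logical vector, `TRUE` for vent-affected windows.
#' @export
vent_flag <- function(windows, magnitude_ratio_threshold = 3,
                      o2_floor = 50, direction_sectors = list()) {
  mag <- abs(windows$flux_h_co2eq) >
    magnitude_ratio_threshold * pmax(abs(windows$flux_o2), o2_floor)
  mag[is.na(mag)] <- FALSE
  dirhit <- rep(FALSE, nrow(windows))
  if (length(direction_sectors) > 0 && !is.null(windows$mean_direction)) {
    d <- windows$mean_direction %% 360
    for (sec in direction_sectors) {
      a <- sec[1] %% 360; b <- sec[2] %% 360
      hit <- if (a <= b) d >= a & d <= b else d >= a | d <= b
      hit[is.na(hit)] <- FALSE
      dirhit <- dirhit | hit
    }
  }
  mag | dirhit
}

#' Per-window calcification from a processed flux-window table
#'
#' Takes the window table produced by [process_deployment()] (one row per
#' window with O2 and proton fluxes) and deployment chemistry, solves the
#' carbonate state for each window from its mean pH and temperature at the
#' fixed deployment alkalinity, converts the proton flux to CO2
#' equivalents, applies the vent rule, and inverts to G_net.
#'
#' @param windows Window table with columns `flux_o2`, `flux_h` (umol H+
#'   m^-2 d^-1, as produced from nmol kg^-1 proton fluctuations),
#'   `mean_ph`, `light`, and optionally `mean_temperature`,
#'   `mean_direction`.
#' @param alkalinity Deployment total alkalinity, umol kg^-1 (held
#'   constant across windows).
#' @param salinity,temperature Deployment salinity and fallback
#'   temperature for windows without a temperature mean.
#' @param q Photosynthetic quotient.
#' @param vent_ratio_threshold,vent_o2_floor,vent_sectors Passed to
#'   [vent_flag()].
#' @return The window table with added columns `flux_h_mol`,
#'   `flux_h_co2eq`, `dh_ddic`, `dh_ddic2alk`, `gnet`, `vent_affected`.
#' @export
calcify_windows <- function(windows, alkalinity = 2650, salinity = 38,
                            temperature = 25, q = 1.09,
                            vent_ratio_threshold = 3, vent_o2_floor = 50,
                            vent_sectors = list()) {
  stopifnot(is.data.frame(windows))
  n <- nrow(windows)
  out <- windows
  out$flux_h_mol <- windows$flux_h * 1e-6
  out$flux_h_co2eq <- NA_real_
  out$dh_ddic <- NA_real_
  out$dh_ddic2alk <- NA_real_
  out$gnet <- NA_real_
  for (i in seq_len(n)) {
    ph <- windows$mean_ph[i]
    if (is.na(ph) || is.na(out$flux_h_mol[i])) next
    tw <- if (!is.null(windows$mean_temperature) &&
              !is.na(windows$mean_temperature[i]))
      windows$mean_temperature[i] else temperature
    st <- solve_seawater(alkalinity, ph = ph, temperature = tw,
                         salinity = salinity)
    out$dh_ddic[i] <- dh_ddic(st)
    out$dh_ddic2alk[i] <- dh_ddic2alk(st)
    out$flux_h_co2eq[i] <- proton_flux_to_co2_equivalents(out$flux_h_mol[i],
                                                          st)
    fo2 <- if (!is.na(windows$flux_o2[i])) windows$flux_o2[i] else 0
    out$gnet[i] <- gnet(out$flux_h_mol[i], fo2, q, st)
  }
  out$vent_affected <- vent_flag(out, vent_ratio_threshold, vent_o2_floor,
                                 vent_sectors)
  ## fold cumulative-flux nonlinearity into the per-window invalid flag
  inval <- if (is.null(windows$qc_invalid)) rep(FALSE, n) else
    windows$qc_invalid
  for (cn in intersect(c("qc_nonlinear_h", "qc_nonlinear_o2"),
                       names(windows)))
    inval <- inval | (!is.na(windows[[cn]]) & windows[[cn]])
  out$qc_invalid <- inval
  out
}

#' Daily summary of calcification and metabolism
#'
#' Aggregates a calcified window table into daily net ecosystem
#' calcification with propagated standard errors, plus O2-based R, GPP and
#' NEM. Vent-affected and QC-invalidated windows are excluded from the
#' G_net means; metabolism uses all windows with a valid O2 flux.
#'
#' @param calc_windows Output of [calcify_windows()].
#' @param h_light,h_dark Light and dark hours (sum 24).
#' @return One-row data frame: `nec`, `nec_se`, `gnet_light`,
#'   `gnet_light_se`, `n_light`, `gnet_dark`, `gnet_dark_se`, `n_dark`,
#'   `r`, `gpp`, `nem` and their standard errors, `h_light`, `h_dark`,
#'   `n_vent_excluded`.
#' @export
daily_summary <- function(calc_windows, h_light = 12, h_dark = 12) {
  w <- calc_windows
  usable <- !w$vent_affected & !is.na(w$gnet)
  if (!is.null(w$qc_invalid)) usable <- usable & !w$qc_invalid
  gl <- w$gnet[usable & w$light]
  gd <- w$gnet[usable & !w$light]
  se <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
  gl_m <- if (length(gl)) mean(gl) else NA_real_
  gd_m <- if (length(gd)) mean(gd) else NA_real_
  nec <- if (!is.na(gl_m) && !is.na(gd_m))
    daily_nec(gl_m, gd_m, h_light, h_dark) else NA_real_
  ## daily se is the plain quadrature sum of the light and dark standard
  ## errors (no hour weighting)
  nec_se <- if (length(gl) > 1 && length(gd) > 1)
    propagate_se(se(gl), se(gd)) else NA_real_
  met <- metabolism(w$flux_o2, w$light, h_light, h_dark)
  data.frame(nec = nec, nec_se = nec_se,
             gnet_light = gl_m, gnet_light_se = se(gl), n_light = length(gl),
             gnet_dark = gd_m, gnet_dark_se = se(gd), n_dark = length(gd),
             r = met$r, r_se = met$r_se, gpp = met$gpp, gpp_se = met$gpp_se,
             nem = met$nem, nem_se = met$nem_se,
             h_light = h_light, h_dark = h_dark,
             n_vent_excluded = sum(w$vent_affected, na.rm = TRUE))
}
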