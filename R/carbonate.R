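#' Seawater density at atmospheric pressure
#'
#' One-atmosphere equation of state (EOS-80, Millero & Poisson 1980
#' coefficients). Deployments addressed by this package sit at 8.5-13 m,
#' where the pressure dependence of density is well below the accuracy
#' needed for unit conversion, so the surface value is used throughout.
#'
#' @param temperature In-situ temperature, degrees Celsius.
#' @param salinity Practical salinity.
#' @param pressure Pressure in dbar; accepted for bookkeeping, must lie in
#'   `[0, 20]` (surface value is returned).
#' @return Density in kg m^-3.
#' @examples
#' seawater_density(25, 38)
#' @export
seawater_density <- function(temperature, salinity, pressure = 0) {
  if (any(temperature < -2 | temperature > 40))
    stop("temperature out of range [-2, 40] degC for the equation of state")
  if (any(salinity < 0 | salinity > 42))
    stop("salinity out of range [0, 42] for the equation of state")
  if (any(pressure < 0 | pressure > 20))
    stop("pressure must be in [0, 20] dbar; density is evaluated at the surface")
  t <- temperature
  S <- salinity
  rho_w <- 999.842594 + 6.793952e-2 * t - 9.095290e-3 * t^2 +
    1.001685e-4 * t^3 - 1.120083e-6 * t^4 + 6.536332e-9 * t^5
  A <- 0.824493 - 4.0899e-3 * t + 7.6438e-5 * t^2 - 8.2467e-7 * t^3 +
    5.3875e-9 * t^4
  B <- -5.72466e-3 + 1.0227e-4 * t - 1.6546e-6 * t^2
  C <- 4.8314e-4
  rho_w + A * S + B * S^1.5 + C * S^2
}

#' Carbonate-system dissociation constants on the total pH scale
#'
#' Computes the constant set used throughout this package: `k1`/`k2` of
#' Lueker et al. (2000; the refit of Mehrbach), `kb` of Dickson (1990),
#' `kw` of Millero (1995; converted from the seawater to the total scale),
#' `kso4` of Dickson (1990), `kf` of Perez & Fraga (1987), and the
#' boron-to-salinity ratio of Lee et al. (2010). All equilibrium constants
#' are returned on the total pH scale except `kso4` (free scale, as
#' conventionally defined), in mol kg-sw^-1 units.
#'
#' @param temperature Temperature, degrees Celsius, in `[0, 40]`.
#' @param salinity Practical salinity in `[19, 43]` (validity range of the
#'   Lueker et al. refit).
#' @param pressure Pressure, dbar, in `[0, 20]`; constants are evaluated at
#'   the surface (corrections are negligible over that range).
#' @return An object of class `carb_constants`: a list with `k1`, `k2`,
#'   `kb`, `kw`, `kso4`, `kf` (mol kg^-1 scales as above) and the totals
#'   `total_boron`, `total_sulfate`, `total_fluoride` (mol kg^-1).
#' @examples
#' k <- carb_constants(25, 38)
#' k$k1 > k$k2
#' @export
carb_constants <- function(temperature, salinity, pressure = 0) {
  if (temperature < 0 || temperature > 40)
    stop("temperature ", temperature,
         " outside constant validity range [0, 40] degC")
  if (salinity < 19 || salinity > 43)
    stop("salinity ", salinity,
         " outside Lueker et al. validity range [19, 43]")
  if (pressure < 0 || pressure > 20)
    stop("pressure must be in [0, 20] dbar; constants are surface values")
  TK <- temperature + 273.15
  lnT <- log(TK)
  S <- salinity

  ## Lueker et al. (2000), total scale
  pk1 <- 3633.86 / TK - 61.2172 + 9.6777 * lnT - 0.011555 * S + 0.0001152 * S^2
  pk2 <- 471.78 / TK + 25.929 - 3.16967 * lnT - 0.01781 * S + 0.0001122 * S^2

  ## Dickson (1990b) boric acid, total scale
  lnkb <- (-8966.90 - 2890.53 * sqrt(S) - 77.942 * S + 1.728 * S^1.5 -
             0.0996 * S^2) / TK +
    148.0248 + 137.1942 * sqrt(S) + 1.62142 * S +
    (-24.4344 - 25.085 * sqrt(S) - 0.2474 * S) * lnT +
    0.053105 * sqrt(S) * TK

  ## Dickson (1990a) bisulfate, free scale, ionic-strength form
  is <- 19.924 * S / (1000 - 1.005 * S)
  lnkso4 <- -4276.1 / TK + 141.328 - 23.093 * lnT +
    (-13856 / TK + 324.57 - 47.986 * lnT) * sqrt(is) +
    (35474 / TK - 771.54 + 114.723 * lnT) * is -
    2698 / TK * is^1.5 + 1776 / TK * is^2 +
    log(1 - 0.001005 * S)

  ## Perez & Fraga (1987) hydrogen fluoride, total scale
  lnkf <- 874 / TK - 9.68 + 0.111 * sqrt(S)

  total_boron <- 0.0004326 * S / 35           # Lee et al. (2010)
  total_sulfate <- (0.14 / 96.062) * (S / 1.80655)
  total_fluoride <- (0.000067 / 18.998) * (S / 1.80655)

  kso4 <- exp(lnkso4)
  kf <- exp(lnkf)
  ## Millero (1995) water, seawater scale; convert to total
  lnkw <- 148.9802 - 13847.26 / TK - 23.6521 * lnT +
    (118.67 / TK - 5.977 + 1.0495 * lnT) * sqrt(S) - 0.01615 * S
  sws_to_tot <- (1 + total_sulfate / kso4) /
    (1 + total_sulfate / kso4 + total_fluoride / kf)
  structure(list(
    k1 = 10^-pk1, k2 = 10^-pk2, kb = exp(lnkb), kw = exp(lnkw) * sws_to_tot,
    kso4 = kso4, kf = kf,
    total_boron = total_boron, total_sulfate = total_sulfate,
    total_fluoride = total_fluoride,
    temperature = temperature, salinity = salinity, pressure = pressure
  ), class = "carb_constants")
}

## Total alkalinity (mol/kg) from total-scale [H+] and DIC (mol/kg).
## Nutrient (phosphate/silicate) alkalinity is excluded: nutrients are not
## part of the deployment metadata this package consumes; the borate, water,
## sulfate and fluoride terms are retained.
alkalinity_components <- function(h_total, dic, k) {
  h_free <- h_total / (1 + k$total_sulfate / k$kso4)
  den <- h_total^2 + k$k1 * h_total + k$k1 * k$k2
  hco3 <- dic * k$k1 * h_total / den
  co3 <- dic * k$k1 * k$k2 / den
  co2 <- dic * h_total^2 / den
  boh4 <- k$total_boron * k$kb / (k$kb + h_total)
  oh <- k$kw / h_total
  hso4 <- k$total_sulfate * h_free / (k$kso4 + h_free)
  hf <- k$total_fluoride * h_total / (k$kf + h_total)
  list(hco3 = hco3, co3 = co3, co2 = co2, boh4 = boh4, oh = oh,
       h_free = h_free, hso4 = hso4, hf = hf,
       alkalinity = hco3 + 2 * co3 + boh4 + oh - h_free - hso4 - hf)
}

dic_from_ph_alk <- function(ph, alk, k) {
  h <- 10^-ph
  h_free <- h / (1 + k$total_sulfate / k$kso4)
  boh4 <- k$total_boron * k$kb / (k$kb + h)
  oh <- k$kw / h
  hso4 <- k$total_sulfate * h_free / (k$kso4 + h_free)
  hf <- k$total_fluoride * h / (k$kf + h)
  ca <- alk - boh4 - oh + h_free + hso4 + hf
  ca * (h^2 + k$k1 * h + k$k1 * k$k2) / (k$k1 * h + 2 * k$k1 * k$k2)
}

ph_from_dic_alk <- function(dic, alk, k) {
  f <- function(ph) alkalinity_components(10^-ph, dic, k)$alkalinity - alk
  lo <- f(2); hi <- f(12)
  if (sign(lo) == sign(hi))
    stop("carbonate solver: no pH root bracketed in [2, 12]")
  stats::uniroot(f, c(2, 12), tol = 1e-10)$root
}

#' Solve the seawater CO2 system
#'
#' Given total alkalinity plus exactly one of pH (total scale) or DIC,
#' solves the full speciation and returns a `seawater_state`. pH-to-DIC is
#' closed form via the carbonate-alkalinity balance; DIC-to-pH is a
#' bracketed root find on pH in `[2, 12]` (tolerance 1e-10 pH units, which
#' is monotone in alkalinity and therefore guaranteed to converge).
#'
#' @param total_alkalinity Total alkalinity, umol kg^-1, in `(0, 10000]`.
#' @param ph pH on the total scale in `[2, 12]`, or `NULL`.
#' @param dic Dissolved inorganic carbon, umol kg^-1, or `NULL`.
#' @param temperature,salinity,pressure Passed to [carb_constants()] and
#'   [seawater_density()]. Salinity defaults to 38 (Tyrrhenian surface
#'   water) when a deployment does not report it.
#' @return A `seawater_state` list: the inputs, the solved `ph` and `dic`
#'   (umol kg^-1), `density` (kg m^-3), the `constants`, and `speciation`
#'   (umol kg^-1 concentrations of CO2*, HCO3-, CO3--, B(OH)4-, OH-, free
#'   and total H+, HSO4-, HF).
#' @examples
#' st <- solve_seawater(2650, ph = 8.04, temperature = 25, salinity = 38)
#' st$dic
#' @export
solve_seawater <- function(total_alkalinity, ph = NULL, dic = NULL,
                           temperature, salinity = 38, pressure = 0) {
  if (is.null(ph) == is.null(dic))
    stop("supply exactly one of `ph` or `dic`")
  if (total_alkalinity <= 0 || total_alkalinity > 10000)
    stop("total_alkalinity must be in (0, 10000] umol/kg")
  k <- carb_constants(temperature, salinity, pressure)
  alk <- total_alkalinity * 1e-6
  if (is.null(dic)) {
    if (ph < 2 || ph > 12) stop("ph must be in [2, 12] (total scale)")
    dic_mol <- dic_from_ph_alk(ph, alk, k)
  } else {
    dic_mol <- dic * 1e-6
    ph <- ph_from_dic_alk(dic_mol, alk, k)
  }
  sp <- alkalinity_components(10^-ph, dic_mol, k)
  if (any(unlist(sp[c("hco3", "co3", "co2", "boh4", "oh")]) < 0))
    stop("carbonate solver: negative species concentration (inconsistent inputs)")
  if (abs(sp$alkalinity - alk) * 1e6 > 1e-3)
    stop("carbonate solver: alkalinity closure failed")
  structure(list(
    temperature = temperature, salinity = salinity, pressure = pressure,
    total_alkalinity = total_alkalinity, ph = ph, dic = dic_mol * 1e6,
    density = seawater_density(temperature, salinity, pressure),
    constants = k,
    speciation = c(co2 = sp$co2, hco3 = sp$hco3, co3 = sp$co3,
                   boh4 = sp$boh4, oh = sp$oh, h_total = 10^-ph,
                   h_free = sp$h_free, hso4 = sp$hso4, hf = sp$hf) * 1e6
  ), class = "seawater_state")
}

#' @export
print.seawater_state <- function(x, ...) {
  cat("<seawater_state>\n")
  cat(sprintf("  T = %.2f degC, S = %.2f, P = %g dbar\n",
              x$temperature, x$salinity, x$pressure))
  cat(sprintf("  At = %.1f umol/kg, pH(total) = %.4f, DIC = %.1f umol/kg\n",
              x$total_alkalinity, x$ph, x$dic))
  cat(sprintf("  density = %.3f kg/m3\n", x$density))
  invisible(x)
}

#' Serialize a seawater state to a flat key-value record
#'
#' One `key: value` line per scalar field, suitable for embedding in
#' window-level output sidecars.
#'
#' @param state A `seawater_state`.
#' @return Character vector of lines.
#' @export
format_seawater_state <- function(state) {
  stopifnot(inherits(state, "seawater_state"))
  f <- c(temperature = state$temperature, salinity = state$salinity,
         pressure = state$pressure, total_alkalinity = state$total_alkalinity,
         ph = state$ph, dic = state$dic, density = state$density)
  sprintf("%s: %.10g", names(f), f)
}

## Re-solve pH at a perturbed (DIC, alkalinity) and return total [H+] mol/kg.
h_at_perturbation <- function(state, ddic, dalk) {
  k <- state$constants
  ph <- ph_from_dic_alk((state$dic + ddic) * 1e-6,
                        (state$total_alkalinity + dalk) * 1e-6, k)
  10^-ph
}

#' Equilibrium proton yield per unit DIC added at constant alkalinity
#'
#' Central finite difference of total `[H+]` with respect to DIC at fixed
#' total alkalinity, i.e. the proton production of the carbonate system per
#' umol kg^-1 of DIC added (a positive, dimensionless mol/mol ratio).
#'
#' @param state A solved [solve_seawater()] state.
#' @param step Perturbation step in umol kg^-1 (default 1, the unit
#'   perturbation; the ratio converges well below 1e-4 relative under step
#'   halving).
#' @return Dimensionless ratio, mol H+ per mol DIC.
#' @examples
#' st <- solve_seawater(2650, ph = 8.04, temperature = 25, salinity = 38)
#' dh_ddic(st)
#' @export
dh_ddic <- function(state, step = 1) {
  stopifnot(inherits(state, "seawater_state"))
  hp <- h_at_perturbation(state, +step, 0)
  hm <- h_at_perturbation(state, -step, 0)
  (hp - hm) / (2 * step * 1e-6)
}

#' Equilibrium proton yield per unit CaCO3 precipitated
#'
#' Central finite difference of total `[H+]` for the calcification
#' stoichiometry (1 umol kg^-1 DIC and 2 umol kg^-1 alkalinity removed per
#' umol kg^-1 CaCO3 formed). Positive: calcification produces protons.
#'
#' @inheritParams dh_ddic
#' @return Dimensionless ratio, mol H+ per mol CaCO3.
#' @export
dh_ddic2alk <- function(state, step = 1) {
  stopifnot(inherits(state, "seawater_state"))
  h_calc <- h_at_perturbation(state, -step, -2 * step)
  h_diss <- h_at_perturbation(state, +step, +2 * step)
  (h_calc - h_diss) / (2 * step * 1e-6)
}

#' Express a proton flux in CO2 equivalents
#'
#' Converts a proton flux to the DIC flux that would produce the same
#' proton flux through carbonate-system equilibration, i.e. multiplies by
#' dDIC/dH+ evaluated at the state.
#'
#' @param h_flux Proton flux, mol H+ m^-2 d^-1.
#' @param state A solved `seawater_state`.
#' @return Flux in mmol CO2-equivalents m^-2 d^-1.
#' @export
proton_flux_to_co2_equivalents <- function(h_flux, state) {
  r <- dh_ddic(state)
  if (!is.finite(r) || r == 0)
    stop("degenerate buffer: dH+/dDIC is zero at this state")
  h_flux / r * 1000
}

#' Convert a CO2-equivalent flux back to a proton flux
#'
#' Inverse of [proton_flux_to_co2_equivalents()].
#'
#' @param co2_flux Flux in mmol CO2-equivalents m^-2 d^-1.
#' @param state A solved `seawater_state`.
#' @return Proton flux, mol H+ m^-2 d^-1.
#' @export
co2_equivalents_to_proton_flux <- function(co2_flux, state) {
  co2_flux / 1000 * dh_ddic(state)
}
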