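## Error propagation: how measurement errors in pH, alkalinity and the
## photosynthetic quotient bias the inferred net calcification, as a
## function of the true G_net/P_net ratio.

#' Forward proton and O2 fluxes from prescribed metabolism and calcification
#'
#' The forward model of the proton budget: net photosynthesis `p_net`
#' consumes protons in proportion to `dH+/dDIC`, calcification `g_net`
#' produces them in proportion to `dH+/d(DIC 2At)`, and the O2 flux is
#' `p_net * q`.
#'
#' @param state A solved [solve_seawater()] state.
#' @param p_net Net community photosynthesis, mmol C m^-2 d^-1.
#' @param g_net Net calcification, mmol CaCO3 m^-2 d^-1.
#' @param q Photosynthetic quotient, > 0.
#' @return List with `flux_o2` (mmol O2 m^-2 d^-1) and `flux_h`
#'   (mol H+ m^-2 d^-1).
#' @export
forward_fluxes <- function(state, p_net, g_net, q) {
  if (q <= 0) stop("photosynthetic quotient must be positive")
  list(flux_o2 = p_net * q,
       flux_h = (-p_net * dh_ddic(state) + g_net * dh_ddic2alk(state)) / 1000)
}

#' Relative G_net error curve under a measurement-error perturbation
#'
#' For each true ratio `r = G_net/P_net` on the grid, generates exact
#' forward fluxes at the true state and quotient, re-inverts them as an
#' observer with a biased measurement would, and reports the relative
#' error of the recovered G_net.
#'
#' The perturbation pathways:
#' \describe{
#'   \item{`pH`}{A sensor bias of `magnitude` pH units scales the whole
#'     measured proton concentration series, and hence the measured proton
#'     flux, by `10^-magnitude`, and shifts the state at which the
#'     observer evaluates `dH+/dDIC` when predicting the photosynthetic
#'     proton sink. The CaCO3 stoichiometric ratio `dH+/d(DIC 2At)` is
#'     kept at its reference value: its own bias enters G_net as a
#'     ratio-independent scale factor, whereas this curve isolates the
#'     divergence of the error as `G_net/P_net` shrinks.}
#'   \item{`alkalinity`}{The observer assumes an alkalinity offset by
#'     `magnitude` umol kg^-1 and evaluates both proton-yield ratios at
#'     that state; the measured fluxes are unaffected.}
#'   \item{`Q`}{The observer inverts with the quotient multiplied by
#'     `(1 + magnitude)`; state and fluxes are unaffected.}
#' }
#'
#' @param parameter One of `"pH"`, `"alkalinity"`, `"Q"`.
#' @param magnitude Perturbation size: pH units, umol kg^-1, or relative
#'   fraction of Q, respectively.
#' @param state Baseline solved `seawater_state` (the true conditions).
#' @param q True photosynthetic quotient.
#' @param ratio_grid Positive `G_net/P_net` ratios; zeros are dropped with
#'   a warning (the relative error is undefined there).
#' @param p_net True net photosynthesis, mmol C m^-2 d^-1 (the errors are
#'   relative, so this only sets numerical scale).
#' @return Data frame of class `error_curve` with columns `ratio` and
#'   `relative_error` (fraction of true G_net, signed).
#' @examples
#' st <- solve_seawater(2650, ph = 8.04, temperature = 25, salinity = 38)
#' gnet_error_curve("Q", 0.10, st, q = 1.09, ratio_grid = 0.5)
#' @export
gnet_error_curve <- function(parameter = c("pH", "alkalinity", "Q"),
                             magnitude, state, q = 1.09,
                             ratio_grid = c(0.1, 0.2, 0.5, 1, 2),
                             p_net = 100) {
  parameter <- match.arg(parameter)
  stopifnot(inherits(state, "seawater_state"))
  if (any(ratio_grid == 0)) {
    warning("dropping ratio 0: relative G_net error is undefined there")
    ratio_grid <- ratio_grid[ratio_grid != 0]
  }
  if (any(ratio_grid < 0)) stop("ratio grid must be positive")
  d1_true <- dh_ddic(state)
  d2_true <- dh_ddic2alk(state)
  if (parameter == "pH") {
    pert <- solve_seawater(state$total_alkalinity, ph = state$ph + magnitude,
                           temperature = state$temperature,
                           salinity = state$salinity,
                           pressure = state$pressure)
    d1_obs <- dh_ddic(pert)
    d2_obs <- d2_true
    flux_scale <- 10^(-magnitude)
    q_obs <- q
  } else if (parameter == "alkalinity") {
    pert <- solve_seawater(state$total_alkalinity + magnitude, ph = state$ph,
                           temperature = state$temperature,
                           salinity = state$salinity,
                           pressure = state$pressure)
    d1_obs <- dh_ddic(pert)
    d2_obs <- dh_ddic2alk(pert)
    flux_scale <- 1
    q_obs <- q
  } else {
    d1_obs <- d1_true
    d2_obs <- d2_true
    flux_scale <- 1
    q_obs <- q * (1 + magnitude)
  }
  rel <- vapply(ratio_grid, function(r) {
    g_true <- r * p_net
    fw <- forward_fluxes(state, p_net, g_true, q)
    g_hat <- (fw$flux_h * flux_scale +
                (fw$flux_o2 / q_obs) * d1_obs / 1000) / d2_obs * 1000
    (g_hat - g_true) / g_true
  }, numeric(1))
  structure(data.frame(ratio = ratio_grid, relative_error = rel),
            class = c("error_curve", "data.frame"),
            parameter = parameter, magnitude = magnitude)
}
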