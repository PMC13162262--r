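## Shared fixtures for the test suite.

## Background study conditions used across tests.
baseline_state <- function(ph = 8.04, alkalinity = 2650, temperature = 25,
                           salinity = 38) {
  solve_seawater(alkalinity, ph = ph, temperature = temperature,
                 salinity = salinity)
}

## Reference grid computed with an independently transcribed CO2-system
## implementation (Python/scipy bracketed root find over the same constant
## set), frozen as a plain-text fixture.
carb_reference_grid <- function() {
  utils::read.csv(test_path("carb_reference_grid.csv"))
}

## Level mean-flow vectors spread over several directions, for planar-fit
## construction.
level_flows <- function(n = 12, speed = 0.05) {
  ang <- seq(0, 1.5 * pi, length.out = n)
  sp <- speed * (1 + 0.3 * sin(seq_len(n)))
  list(u = sp * cos(ang), v = sp * sin(ang), w = rep(0, n))
}

## Rotate level flows by a pitch angle about the v axis (instrument tilt).
pitch_flows <- function(flows, pitch_deg) {
  th <- pitch_deg * pi / 180
  list(u = flows$u * cos(th) - flows$w * sin(th),
       v = flows$v,
       w = flows$u * sin(th) + flows$w * cos(th))
}
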