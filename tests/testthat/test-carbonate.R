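test_that("dissociation constants are ordered, positive, continuous in salinity", {
  k <- carb_constants(25, 38)
  expect_true(k$k1 > k$k2)
  expect_true(all(unlist(k[c("k1", "k2", "kb", "kw", "kso4", "kf")]) > 0))
  expect_true(all(is.finite(unlist(k[1:9]))))

  k2 <- carb_constants(25, 38.0000001)
  for (nm in c("k1", "k2", "kb", "kw", "kso4", "kf"))
    expect_lt(abs(k2[[nm]] / k[[nm]] - 1), 1e-6)

  ## total boron scales linearly with salinity
  expect_equal(carb_constants(25, 38)$total_boron /
                 carb_constants(25, 19)$total_boron, 38 / 19)

  expect_error(carb_constants(-1, 38), "\\[0, 40\\]")
  expect_error(carb_constants(25, 10), "\\[19, 43\\]")
})

test_that("constants at 25 degC, S 35 match the independent reference to 5 digits", {
  k <- carb_constants(25, 35)
  ref <- c(k1 = 10^-5.84715, k2 = 10^-8.96595, kb = 2.5266e-09,
           kw = 6.0137e-14, kso4 = 1.0030e-01, kf = 2.2611e-03,
           total_boron = 4.326e-04)
  for (nm in names(ref))
    expect_equal(k[[nm]], unname(ref[nm]), tolerance = 1e-4)
})

test_that("carbonate solver: DIC, round trip, monotonicity, input validation", {
  st <- baseline_state()
  expect_equal(st$dic, 2294.275, tolerance = 2 / 2294)  # independent oracle

  rt <- solve_seawater(2650, dic = st$dic, temperature = 25, salinity = 38)
  expect_equal(rt$ph, 8.04, tolerance = 1e-6 / 8)

  lo <- solve_seawater(2650, ph = 7.94, temperature = 25, salinity = 38)
  expect_gt(lo$dic, st$dic)

  expect_error(solve_seawater(2650, temperature = 25), "exactly one")
  expect_error(solve_seawater(2650, ph = 8, dic = 2000, temperature = 25),
               "exactly one")
  expect_error(solve_seawater(-5, ph = 8, temperature = 25), "alkalinity")
  expect_error(solve_seawater(2650, ph = 13, temperature = 25), "\\[2, 12\\]")
})

test_that("alkalinity closure holds across the reference grid", {
  g <- carb_reference_grid()
  for (i in seq_len(nrow(g))) {
    st <- solve_seawater(g$alkalinity[i], ph = g$ph[i],
                         temperature = g$temperature[i],
                         salinity = g$salinity[i])
    sp <- st$speciation
    rebuilt <- sp[["hco3"]] + 2 * sp[["co3"]] + sp[["boh4"]] + sp[["oh"]] -
      sp[["h_free"]] - sp[["hso4"]] - sp[["hf"]]
    expect_lt(abs(rebuilt - st$total_alkalinity), 1e-3)
  }
})

test_that("solver and proton-yield ratios match the independent reference within 0.2%", {
  g <- carb_reference_grid()
  for (i in seq_len(nrow(g))) {
    st <- solve_seawater(g$alkalinity[i], ph = g$ph[i],
                         temperature = g$temperature[i],
                         salinity = g$salinity[i])
    expect_lt(abs(st$dic / g$dic[i] - 1), 0.002)
    expect_lt(abs(dh_ddic(st) / g$dh_ddic[i] - 1), 0.002)
    expect_lt(abs(dh_ddic2alk(st) / g$dh_ddic2alk[i] - 1), 0.002)
  }
})

test_that("dH+/dDIC: positive, converges under step halving, fine-step agreement", {
  st <- baseline_state()
  r1 <- dh_ddic(st)
  expect_gt(r1, 0)
  expect_lt(abs(dh_ddic(st, 0.5) / r1 - 1), 1e-4)     # Cauchy criterion
  expect_lt(abs(dh_ddic(st, 0.01) / r1 - 1), 0.001)   # fine-step oracle

  ## one-sided differences bracket the central value
  h0 <- 10^-st$ph
  fwd <- (eddycalc:::h_at_perturbation(st, 1, 0) - h0) / 1e-6
  bwd <- (h0 - eddycalc:::h_at_perturbation(st, -1, 0)) / 1e-6
  expect_true(min(fwd, bwd) <= r1 && r1 <= max(fwd, bwd))

  ## buffering weakens at lower pH
  expect_gt(dh_ddic(baseline_state(ph = 7.5)), r1)
})

test_that("dH+/d(DIC 2At): sign, local linearity, pH dominates over alkalinity", {
  st <- baseline_state()
  r2 <- dh_ddic2alk(st)
  expect_gt(r2, 0)
  expect_lt(abs(dh_ddic2alk(st, 0.5) / r2 - 1), 1e-4)
  expect_lt(abs(dh_ddic2alk(st, 0.01) / r2 - 1), 0.001)

  ## dissolution perturbation: equal magnitude, opposite sign within 1%
  h0 <- 10^-st$ph
  calc <- (eddycalc:::h_at_perturbation(st, -1, -2) - h0) / 1e-6
  diss <- (eddycalc:::h_at_perturbation(st, +1, +2) - h0) / 1e-6
  expect_lt(abs(calc / (-diss) - 1), 0.01)
  expect_lt(abs(calc / r2 - 1), 0.01)

  ## the ratio responds more to a 0.1 pH change than to +/-20 umol/kg At
  d_ph <- abs(dh_ddic2alk(baseline_state(ph = 7.94)) - r2)
  d_alk_up <- abs(dh_ddic2alk(baseline_state(alkalinity = 2670)) - r2)
  d_alk_dn <- abs(dh_ddic2alk(baseline_state(alkalinity = 2630)) - r2)
  expect_gt(d_ph, max(d_alk_up, d_alk_dn))
})

test_that("CO2-equivalent conversion is the exact inverse pair", {
  st <- baseline_state()
  expect_identical(proton_flux_to_co2_equivalents(0, st), 0)
  d <- dh_ddic(st)
  expect_equal(proton_flux_to_co2_equivalents(3e-3, st), 3e-3 / d * 1000)
  x <- 0.0123
  rt <- co2_equivalents_to_proton_flux(
    proton_flux_to_co2_equivalents(x, st), st)
  expect_lt(abs(rt / x - 1), 1e-12)
})

test_that("seawater density matches the published equation of state", {
  expect_equal(seawater_density(25, 35), 1023.343, tolerance = 0.01 / 1023)
  d38 <- seawater_density(25, 38)
  expect_gt(d38, 1024); expect_lt(d38, 1027)
  expect_lt(seawater_density(20, 0), seawater_density(20, 38))
  tt <- seq(15, 30, by = 0.5)
  expect_true(all(diff(seawater_density(tt, 38)) < 0))
})

test_that("seawater state serializes to a flat key-value record", {
  lines <- format_seawater_state(baseline_state())
  expect_true(any(grepl("^ph: 8.04", lines)))
  expect_true(any(grepl("^total_alkalinity: 2650", lines)))
  expect_length(lines, 7)
})
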