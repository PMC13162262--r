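test_that("photosynthetic quotient from C:N", {
  expect_equal(round(photosynthetic_quotient(22.2), 2), 1.09)
  expect_equal(photosynthetic_quotient(1e9), 1, tolerance = 1e-8)
  expect_equal(photosynthetic_quotient(2), 2)
  expect_error(photosynthetic_quotient(0), "positive")
})

test_that("community C:N is the metabolism-weighted arithmetic mean", {
  meadow <- data.frame(label = c("epiphytes", "seagrass"),
                       cn_ratio = c(13.7, 26.8),
                       fraction = c(1 / 3, 2 / 3))
  expect_equal(community_cn(meadow), 13.7 / 3 + 26.8 * 2 / 3)  # 22.433
  expect_equal(community_cn(data.frame(cn_ratio = 17, fraction = 1)), 17)
  expect_equal(community_cn(data.frame(cn_ratio = c(20, 20),
                                       fraction = c(0.4, 0.6))), 20)
  expect_error(community_cn(data.frame()), "empty")
  expect_error(community_cn(data.frame(cn_ratio = c(10, 20),
                                       fraction = c(0.5, 0.6))), "sum to 1")
})

test_that("photosynthetic proton flux: zero map, sign, linearity", {
  st <- baseline_state()
  expect_identical(proton_flux_pnet(0, 1.09, st), 0)
  f <- proton_flux_pnet(100, 1.09, st)
  expect_lt(f, 0)
  expect_equal(proton_flux_pnet(200, 1.09, st), 2 * f)
  expect_error(proton_flux_pnet(100, 0, st), "positive")
})

test_that("G_net inversion is the exact algebraic inverse of the forward model", {
  st <- baseline_state()
  q <- 1.09
  for (case in list(c(p = 100, g = 30), c(p = -60, g = -15),
                    c(p = 50, g = 0), c(p = 0, g = 12))) {
    fw <- forward_fluxes(st, case[["p"]], case[["g"]], q)
    ghat <- gnet(fw$flux_h, fw$flux_o2, q, st)
    expect_equal(ghat, case[["g"]], tolerance = 1e-10)
  }

  ## proton flux exactly cancelling the photosynthetic sink: G_net = 0
  fw <- forward_fluxes(st, 100, 0, q)
  expect_equal(gnet(fw$flux_h, fw$flux_o2, q, st), 0, tolerance = 1e-10)

  ## zero measured proton flux with net photosynthesis implies a proton
  ## source: net calcification
  expect_gt(gnet(0, 100, q, st), 0)
})

test_that("proton budget closes: flux_h_pnet + gnet * dh_ddic2alk rebuilds flux_h", {
  st <- baseline_state()
  q <- 1.09
  fw <- forward_fluxes(st, 80, 25, q)
  g <- gnet(fw$flux_h, fw$flux_o2, q, st)
  rebuilt <- proton_flux_pnet(fw$flux_o2, q, st) + g * dh_ddic2alk(st) / 1000
  expect_equal(rebuilt, fw$flux_h, tolerance = 1e-10)
})

test_that("daily NEC matches the worked field examples", {
  expect_equal(daily_nec(28.9, 15.4, 12, 12), 22.15)
  dark <- (-15.9 * 12 + -38.9 * 22) / 34
  expect_equal(daily_nec(25.4, dark, 12, 12), -2.69, tolerance = 0.005)
  expect_equal(daily_nec(5, 5, 7, 17), 5)
  expect_error(daily_nec(10, 10, 12, 13), "sum to 24")
  ## linear in each mean: a unit change scales by its hour fraction
  expect_equal(daily_nec(10 + 4, 6, 8, 16) - daily_nec(10, 6, 8, 16),
               4 * 8 / 24)
  expect_equal(daily_nec(10, 6 + 3, 8, 16) - daily_nec(10, 6, 8, 16),
               3 * 16 / 24)
})

test_that("standard errors combine in quadrature", {
  expect_equal(propagate_se(23.4, 12.9), sqrt(23.4^2 + 12.9^2))
  expect_gt(propagate_se(23.4, 12.9), 26.7)
  expect_lt(propagate_se(23.4, 12.9), 26.8)
  expect_equal(propagate_se(7, 0), 7)
  expect_equal(propagate_se(3, 4), propagate_se(4, 3))
  ## homogeneous of degree 1
  expect_equal(propagate_se(2 * 3, 2 * 4), 2 * propagate_se(3, 4))
  expect_error(propagate_se(-1, 2), ">= 0")
})

test_that("O2 metabolism: R, GPP, NEM", {
  m <- metabolism(c(-10, -10, -10, -10), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(m$nem, -10); expect_equal(m$r, -10); expect_equal(m$gpp, 0)

  m2 <- metabolism(c(100, 100, -60, -60), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(m2$nem, 20); expect_equal(m2$r, -60); expect_equal(m2$gpp, 80)

  expect_error(metabolism(c(1, 2), c(TRUE, TRUE)), "dark")
})

test_that("alkalinity-anomaly G_net", {
  expect_identical(alkalinity_anomaly_gnet(0, 1025, 2, 1), 0)
  expect_equal(alkalinity_anomaly_gnet(-10, 1025, 2, 1),
               10 * 1.025 * 2 / 2)
  expect_equal(alkalinity_anomaly_gnet(-10, 1025, 2, 2),
               alkalinity_anomaly_gnet(-10, 1025, 2, 1) / 2)
  expect_error(alkalinity_anomaly_gnet(-10, 1025, 2, 0), "positive")
})

test_that("vent flagging by magnitude ratio and direction sector", {
  w <- data.frame(flux_h_co2eq = c(2000, -120, 90, 400),
                  flux_o2 = c(100, 110, 80, 30),
                  mean_direction = c(270, 40, 300, 120))
  fl <- vent_flag(w, 3, o2_floor = 50)
  expect_identical(fl, c(TRUE, FALSE, FALSE, TRUE))

  ## balanced opposite-sign fluxes of similar magnitude are kept
  expect_false(vent_flag(data.frame(flux_h_co2eq = -120, flux_o2 = 110), 3,
                         50))
  ## disabled rule flags nothing
  expect_false(any(vent_flag(w, Inf, direction_sectors = list())))
  ## sector rule, including one wrapping through north
  fl2 <- vent_flag(w, Inf, direction_sectors = list(c(250, 290),
                                                    c(350, 10)))
  expect_identical(fl2, c(TRUE, FALSE, FALSE, FALSE))
})

test_that("window calcification and daily aggregation on a constructed table", {
  st <- baseline_state()
  q <- 1.09
  cases <- data.frame(p = c(100, 100, -60, -60), g = c(30, 32, -15, -13),
                      light = c(TRUE, TRUE, FALSE, FALSE))
  rows <- lapply(seq_len(nrow(cases)), function(i) {
    fw <- forward_fluxes(st, cases$p[i], cases$g[i], q)
    data.frame(flux_o2 = fw$flux_o2, flux_h = fw$flux_h * 1e6,
               mean_ph = st$ph, light = cases$light[i])
  })
  w <- do.call(rbind, rows)
  cw <- calcify_windows(w, alkalinity = 2650, salinity = 38,
                        temperature = 25, q = q)
  expect_equal(cw$gnet, cases$g, tolerance = 1e-8)
  expect_false(any(cw$vent_affected))
  ds <- daily_summary(cw)
  expect_equal(ds$gnet_light, 31, tolerance = 1e-8)
  expect_equal(ds$gnet_dark, -14, tolerance = 1e-8)
  expect_equal(ds$nec, daily_nec(31, -14), tolerance = 1e-8)
  expect_equal(ds$nec_se, propagate_se(1, 1), tolerance = 1e-6)
  expect_equal(ds$r, -60 * q)
})
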