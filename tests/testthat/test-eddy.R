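test_that("block-mean downsampling: constants, low-frequency fidelity, alias suppression", {
  const <- channel_series(rep(3.2, 160), 16)
  out <- downsample(const, 5)
  expect_equal(out$values, rep(3.2, 50))
  expect_equal(out$rate, 5)

  ## 0.01 Hz sine survives with < 0.1% amplitude loss
  t16 <- (0:(16 * 600 - 1)) / 16
  s <- channel_series(sin(2 * pi * 0.01 * t16), 16)
  out <- downsample(s, 5)
  t5 <- (seq_along(out$values) - 1) / 5
  fit <- stats::lm(out$values ~ sin(2 * pi * 0.01 * t5) +
                     cos(2 * pi * 0.01 * t5) - 1)
  amp <- sqrt(sum(stats::coef(fit)^2))
  expect_lt(abs(amp - 1), 0.001)

  ## 8 Hz alternation: block means leave sd sqrt(4/45) (4 of 5 blocks hold
  ## 3 samples at +/-1/3, one holds 4 at 0), vs sd 1 in the input
  alt <- channel_series(rep(c(1, -1), 800), 16)
  out <- downsample(alt, 5)
  expect_lt(abs(mean(out$values)), 1e-12)
  expect_equal(stats::sd(out$values), sqrt(4 / 45), tolerance = 0.01)

  ## gaps: a block over half invalid becomes a gap
  g <- channel_series(c(rep(1, 3), NA, rep(c(1, NA, NA, NA), 3), rep(1, 17)),
                      16)
  out <- downsample(g, 5)
  expect_equal(out$values[1], 1)      # 3/4 valid: mean of valid
  expect_true(is.na(out$values[2]))   # 1/4 valid: gap
  expect_error(downsample(channel_series(1:10, 2), 5), "below target")
  expect_length(downsample(channel_series(numeric(0), 16), 5)$values, 0)
})

test_that("planar fit recovers tilt and yields an orthonormal rotation", {
  fl <- level_flows()
  id <- planar_fit(fl$u, fl$v, fl$w)
  expect_lt(id$tilt_deg, 0.05)

  tilted <- pitch_flows(fl, 5)
  fit <- planar_fit(tilted$u, tilted$v, tilted$w)
  expect_equal(fit$tilt_deg, 5, tolerance = 0.1 / 5)

  R <- fit$rotation
  expect_equal(R %*% t(R), diag(3), tolerance = 1e-12)
  rot <- apply_rotation(fit, tilted$u, tilted$v, tilted$w)
  expect_lt(abs(mean(rot$w)), 1e-10 * mean(abs(fl$u)))
  ## speed preserved (offset is ~0 for an exact plane through the origin)
  expect_equal(sqrt(rot$u^2 + rot$v^2 + rot$w^2),
               sqrt(tilted$u^2 + tilted$v^2 + tilted$w^2),
               tolerance = 1e-10)

  ## collinear flows are rejected
  expect_error(planar_fit(rep(0.05, 8), rep(0, 8), rep(0.001, 8)),
               "collinear|rank")
  expect_error(planar_fit(1:3, 1:3, 1:3), ">= 6")
})

test_that("Reynolds decomposition: constants, trends, running-mean transfer", {
  rate <- 5
  dc <- reynolds_decompose(rep(7, 5000), rate)
  expect_true(all(abs(dc$fluctuation) < 1e-12))

  tr <- reynolds_decompose(seq(0, 10, length.out = 5000), rate)
  expect_true(all(abs(tr$fluctuation) < 1e-10))

  t_s <- (0:(5 * 3600 * rate - 1)) / rate
  fast <- sin(2 * pi * t_s / 50)
  df <- reynolds_decompose(fast, rate)
  core <- seq(500 * rate, length(t_s) - 500 * rate)
  expect_gt(stats::sd(df$fluctuation[core]) / stats::sd(fast[core]), 0.99)

  slow <- sin(2 * pi * t_s / 5000)
  ds <- reynolds_decompose(slow, rate)
  expect_lt(stats::sd(ds$fluctuation[core]) / stats::sd(slow[core]), 0.05)

  expect_error(reynolds_decompose(1:100, 5, 500), "shorter")
})

test_that("lag alignment recovers constructed delays to one sample", {
  set.seed(42)
  rate <- 5
  w <- as.numeric(stats::filter(rnorm(6000), rep(1 / 8, 8), sides = 2))
  w[is.na(w)] <- 0
  shift <- 7                      # 1.4 s at 5 Hz
  c_del <- c(rep(0, shift), w[1:(length(w) - shift)]) + 0.1 * rnorm(6000)
  la <- lag_align(w, c_del, rate)
  expect_equal(la$lag_s, 1.4, tolerance = 0.2 / 1.4 + 1e-9)
  expect_false(la$low_correlation)

  self <- lag_align(w, w, rate)
  expect_identical(self$lag_samples, 0L)

  noise <- lag_align(rnorm(6000), rnorm(6000), rate)
  expect_true(noise$low_correlation)
  expect_true(abs(noise$max_corr) < 0.1)

  z <- lag_align(rep(0, 1000), rep(0, 1000), rate)
  expect_true(z$undefined_correlation)
  expect_identical(z$lag_s, 0)
})

test_that("covariance flux: identical series, null distribution, masking", {
  set.seed(7)
  rho <- 1025
  x <- rnorm(8700)
  x <- x - mean(x)
  fx <- compute_flux(x, x, density = rho)
  expect_equal(fx$flux, mean(x * x) * rho * 86.4, tolerance = 1e-12)

  ## independent series: 20 windows scatter around zero
  fluxes <- replicate(20, {
    a <- rnorm(2000); b <- rnorm(2000)
    compute_flux(a - mean(a), b - mean(b), density = rho)$flux
  })
  expect_lt(abs(mean(fluxes)), 3 * stats::sd(fluxes) / sqrt(20))

  ## masking over half the window invalidates it
  m <- rep(c(TRUE, FALSE), c(5000, 3700))
  fx2 <- compute_flux(x, x, density = rho, mask = m)
  expect_true(fx2$qc_invalid)
  expect_true(is.na(fx2$flux))
})

test_that("cumulative-flux QC separates stationary, bursty and zero-flux windows", {
  set.seed(11)
  w <- rnorm(5000)
  c_ok <- w + 0.3 * rnorm(5000)
  qc <- cumulative_flux_qc(w, c_ok)
  expect_true(qc$linear)
  expect_gt(qc$r2, 0.9)
  expect_false(qc$low_flux)

  ## one spike carrying the whole covariance
  w_s <- rnorm(5000, sd = 0.01); c_s <- rnorm(5000, sd = 0.01)
  w_s[2500] <- 50; c_s[2500] <- 50
  qc2 <- cumulative_flux_qc(w_s, c_s)
  expect_false(qc2$linear)
  expect_true(qc2$burst)

  ## zero-flux noise: low-flux, not nonlinear
  qc3 <- cumulative_flux_qc(rnorm(5000), rnorm(5000))
  expect_true(qc3$low_flux)
  expect_true(qc3$linear)
})

test_that("cospectra close under Parseval and localize band-limited covariance", {
  set.seed(3)
  rate <- 5
  n <- 4096
  w <- rnorm(n)
  cs <- cospectrum(w, w, rate)
  expect_equal(cs$covariance, mean((w - mean(w))^2), tolerance = 0.01)
  expect_equal(cs$ogive[length(cs$ogive)], 1, tolerance = 1e-9)

  ## correlation confined below 0.1 Hz
  keep <- function(x, fc) {
    X <- stats::fft(x)
    f <- (0:(n - 1)) * rate / n
    f <- pmin(f, rate - f)
    Re(stats::fft(X * (f <= fc), inverse = TRUE)) / n
  }
  wl <- keep(w, 0.1)
  c_band <- wl + 0.1 * keep(rnorm(n), 2.4)
  cb <- cospectrum(w, c_band, rate)
  expect_gt(cb$ogive[max(which(cb$frequencies <= 0.1))], 0.95)

  mixed <- rnorm(2048)
  expect_equal(cospectrum(mixed, mixed, rate)$covariance,
               mean((mixed - mean(mixed))^2), tolerance = 0.01)
  expect_error(cospectrum(rnorm(500), rnorm(500), 5), "1024")
})

test_that("high-frequency loss estimate matches a direct attenuation calculation", {
  set.seed(9)
  rate <- 5
  n <- 18000
  ## red, boundary-layer-like spectra: flux carried below ~0.1 Hz
  redden <- function(x, f0 = 0.01) {
    X <- stats::fft(x)
    f <- (0:(n - 1)) * rate / n
    f <- pmin(f, rate - f)
    g <- (1 + (f / f0)^2)^(-5 / 12); g[1] <- 0
    y <- Re(stats::fft(X * g, inverse = TRUE)) / n
    y / stats::sd(y)
  }
  w <- redden(rnorm(n))
  cc <- w + 0.2 * redden(rnorm(n))
  ## identical sensors: no loss
  c0 <- cospectrum(w, cc, rate)
  expect_equal(estimate_highfreq_loss(c0, c0)$loss, 0, tolerance = 1e-9)

  ## first-order low-pass with t90 = 2.4 s on the test channel
  tau <- 2.4 / log(10)
  a <- exp(-1 / (rate * tau))
  c_slow <- as.numeric(stats::filter(cc * (1 - a), a, method = "recursive",
                                     init = cc[1]))
  ct <- cospectrum(w, c_slow, rate)
  est <- estimate_highfreq_loss(ct, c0)
  brute <- 1 - mean(w * c_slow) / mean(w * cc)   # attenuated-covariance oracle
  expect_gt(est$loss, 0)
  expect_equal(est$loss, brute, tolerance = 0.02 / max(brute, 0.02))

  ## swapped roles: negative loss is reported
  expect_lt(estimate_highfreq_loss(c0, ct)$loss, 0)

  ## near-zero reference flux is flagged
  z <- cospectrum(rnorm(n), rnorm(n), rate)
  expect_true(estimate_highfreq_loss(c0, z)$flagged)
})

test_that("storage flux arithmetic and sign convention", {
  expect_identical(storage_flux(220, 220, 3600, 1), 0)
  ## +10 umol/kg over 1 h in a 1 m layer at 1025 kg/m3
  expect_equal(storage_flux(220, 230, 3600, 1, 1025), 10 * 1.025 * 24)
  expect_gt(storage_flux(220, 221, 3600, 1), 0)
})

test_that("pH/proton conversion and ISFET calibration", {
  expect_equal(ph_to_proton(8), 10)
  expect_equal(ph_to_proton(7), 100)
  expect_true(all(diff(ph_to_proton(seq(7, 9, 0.1))) < 0))
  expect_error(ph_to_proton(c(8, 1.5)), "\\[2, 12\\]")

  t0 <- as.POSIXct("2020-09-18 12:00:00", tz = "UTC")
  mv <- channel_series(rep(100, 600), 5, t0)
  cal <- calibrate_isfet(mv, 590, t0 + 30, reference_ph = 8.04)
  expect_equal(cal$values, rep(8.04, 600))

  mv2 <- channel_series(c(rep(100, 300), rep(159, 300)), 5, t0)
  cal2 <- calibrate_isfet(mv2, 590, t0 + 10, reference_ph = 8)
  expect_equal(cal2$values[400], 8.1)

  ## affine consistency: any reference on a noiseless record gives the
  ## same calibrated series
  lin <- channel_series(seq(0, 59, length.out = 600), 5, t0)
  a <- calibrate_isfet(lin, 590, t0 + 10, 8)$values
  b <- calibrate_isfet(lin, 590, t0 + 100,
                       8 + (lin$values[501] - lin$values[51]) / 590)$values
  expect_equal(a, b, tolerance = 1e-12)
  expect_error(calibrate_isfet(mv, 590, t0 + 7200, 8), "outside")
})

test_that("MAD despiking removes planted spikes and passes clean records", {
  set.seed(5)
  x <- sin(2 * pi * (1:3000) / 500) + 0.05 * rnorm(3000)
  clean <- despike_mad(x, 5)
  expect_identical(clean$n_spikes, 0L)
  xs <- x
  hit <- c(400, 1500, 2600)
  xs[hit] <- xs[hit] + 1.5
  d <- despike_mad(xs, 5)
  expect_identical(d$n_spikes, 3L)
  expect_true(all(is.na(d$values[hit])))
})
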