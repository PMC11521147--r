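lam_fx <- seq(500, 700, length.out = 81)
tt_fx <- c(1, 2, 5, 10, 20, 50, 100, 200, 400, 800)
spec_fx <- 50 * exp(-((lam_fx - 600) / 80)^2)

test_that("Savitzky-Golay smoothing preserves low-order polynomials", {
  x <- 2 + 0.3 * lam_fx - 0.004 * lam_fx^2 + 1e-6 * lam_fx^3
  expect_lt(max(abs(smooth_spectrum(x) - x)), 1e-9)
  cst <- rep(3.7, 81)
  expect_equal(smooth_spectrum(cst), cst)
  set.seed(8)
  noisy <- spec_fx + rnorm(81)
  expect_lt(var(smooth_spectrum(noisy) - spec_fx), var(noisy - spec_fx))
  expect_error(smooth_spectrum(1:10), "window")
})

test_that("bias and slope recovered exactly from an exact linear series", {
  s <- synth_raw_series(lam_fx, tt_fx, 0, I_DC = 100, dark_slope = 2)
  cmp <- fit_bias_and_slope(s)
  expect_equal(cmp$I_DC, 100)
  expect_equal(unname(cmp$dark_ambient_slope), rep(2, 81), tolerance = 1e-12)
  # zero-slope series
  s0 <- synth_raw_series(lam_fx, tt_fx, 0, I_DC = 50, dark_slope = 0)
  cmp0 <- fit_bias_and_slope(s0)
  expect_equal(cmp0$I_DC, 50)
  expect_lt(max(abs(cmp0$dark_ambient_slope)), 1e-10)
  expect_error(fit_bias_and_slope(raw_series(lam_fx, c(1, 2),
                                             matrix(1, 81, 2), FALSE),
                                  linear_frac = 0.01), NA)
})

test_that("noisy bias is recovered within 3 SE over 20 seeds", {
  ests <- vapply(1:20, function(s) {
    ser <- synth_raw_series(lam_fx, tt_fx, 0, I_DC = 100, dark_slope = 2,
                            noise = 0.01, seed = s)
    fit_bias_and_slope(ser)$I_DC
  }, numeric(1))
  expect_lt(abs(mean(ests) - 100), 3 * sd(ests) / sqrt(20))
})

test_that("temporal nonlinearity ratio reproduces the injected saturation", {
  s <- synth_raw_series(lam_fx, tt_fx, 0, I_DC = 100, dark_slope = 2,
                        t0 = 1000)
  cmp <- fit_temporal_nonlinearity(s, fit_bias_and_slope(s))
  want <- 1 / (1 + tt_fx / 1000)
  # fit normalization shifts the curve slightly; shape within 2%
  expect_lt(max(abs(cmp$f_nl_time$ratio - want) / want), 0.02)
  expect_lt(abs(cmp$f_nl_time$ratio[1] - 1), 0.01)
  # perfectly linear series: ratio identically 1
  s2 <- synth_raw_series(lam_fx, tt_fx, 0, I_DC = 100, dark_slope = 2)
  cmp2 <- fit_temporal_nonlinearity(s2, fit_bias_and_slope(s2))
  expect_equal(cmp2$f_nl_time$ratio, rep(1, length(tt_fx)), tolerance = 1e-9)
})

test_that("intensity nonlinearity cubic is recovered from synthetic data", {
  cub <- c(1, -2e-6, 0, 0)
  on <- synth_raw_series(lam_fx, tt_fx, spec_fx, I_DC = 100, dark_slope = 2,
                         nl_cubic = cub)
  cmp <- fit_bias_and_slope(
    synth_raw_series(lam_fx, tt_fx, 0, I_DC = 100, dark_slope = 2))
  cmp <- fit_intensity_nonlinearity(on, cmp)
  x <- seq(1e3, 4e4, length.out = 50)
  fit <- cmp$f_nl_intensity
  want <- cub[1] + cub[2] * x
  got <- fit[1] + fit[2] * x + fit[3] * x^2 + fit[4] * x^3
  expect_lt(max(abs(got - want)), 0.02)
  # saturating data give a non-increasing fitted response
  expect_true(all(diff(got) <= 1e-9))
  # trivial ratios give a unit cubic
  on2 <- synth_raw_series(lam_fx, tt_fx, spec_fx, I_DC = 100, dark_slope = 2)
  cmp2 <- fit_intensity_nonlinearity(on2, fit_bias_and_slope(
    synth_raw_series(lam_fx, tt_fx, 0, I_DC = 100, dark_slope = 2)))
  xg <- seq(1e3, 4e4, length.out = 20)
  f2 <- cmp2$f_nl_intensity
  expect_lt(max(abs(f2[1] + f2[2] * xg + f2[3] * xg^2 + f2[4] * xg^3 - 1)),
            1e-6)
})

test_that("noisy cubic recovery is unbiased over 20 seeds", {
  cub <- c(1, -2e-6, 0, 0)
  x0 <- 2e4
  vals <- vapply(1:20, function(s) {
    on <- synth_raw_series(lam_fx, tt_fx, spec_fx, I_DC = 100,
                           dark_slope = 2, nl_cubic = cub,
                           noise = 0.005, seed = 300 + s)
    cmp <- fit_intensity_nonlinearity(on, fit_bias_and_slope(
      synth_raw_series(lam_fx, tt_fx, 0, I_DC = 100, dark_slope = 2)))
    f <- cmp$f_nl_intensity
    f[1] + f[2] * x0 + f[3] * x0^2 + f[4] * x0^3
  }, numeric(1))
  want <- cub[1] + cub[2] * x0
  expect_lt(abs(mean(vals) - want), 3 * sd(vals) / sqrt(20) + 1e-3)
})

test_that("signal model inverts algebraically and restores linearity", {
  cub <- c(1, -2e-6, 0, 0)
  comp <- calibration_components(120, rep(1.5, 81), lam_fx,
                                 data.frame(t = tt_fx,
                                            ratio = 1 / (1 + tt_fx / 2000)),
                                 cub)
  on <- synth_raw_series(lam_fx, tt_fx, spec_fx, I_DC = 120, dark_slope = 1.5,
                         t0 = 2000, nl_cubic = cub)
  rec <- correct_signal(on, comp, smooth = FALSE)
  expect_lt(max(abs(rec$I - spec_fx)), 1e-6)
  # corrected counts linear in t: R^2 > 0.999 per wavelength
  counts <- sweep(rec$I + 1.5, 2, tt_fx, `*`) # corrected total counts
  r2 <- vapply(seq(1, 81, by = 16), function(i) {
    suppressWarnings(summary(lm(counts[i, ] ~ tt_fx))$r.squared)
  }, numeric(1))
  expect_true(all(r2 > 0.999))
  # trivial components reduce to S / t
  triv <- calibration_components(0, 0, lam_fx)
  raw <- raw_series(lam_fx, tt_fx, outer(spec_fx, tt_fx))
  rec2 <- correct_signal(raw, triv, smooth = FALSE)
  expect_equal(rec2$I, outer(spec_fx, rep(1, length(tt_fx))),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("sphere ratio cancels every multiplicative system response", {
  set.seed(12)
  L <- runif(81, 0.3, 3) # arbitrary source x losses x spectrometer response
  robj <- 0.4 + 0.2 * sin(lam_fx / 40)
  expect_equal(experimental_reflectance(L * robj, L), robj)
  expect_equal(experimental_reflectance(rep(0, 81), L), rep(0, 81))
  expect_warning(out <- experimental_reflectance(c(1, 2), c(1, 0)),
                 "masked")
  expect_true(is.na(out[2]))
})

cal_fixture <- function() {
  fixture("cal", function() {
    pr <- radial_probe(c(0.1, 0.3, 0.6, 1.0), tilts = 0)
    g <- grid_spec(mus_p = c(0.45, 1.2, 2.0), gamma = seq(1.1, 1.9, by = 0.2),
                   mua = c(0, 0.05, 0.1, 0.15))
    lut <- build_lut(g, pr, n_photons = 1e5, seed = 9, oil_thickness = 0.05)
    rs <- phantom_rsim(lut, reference_phantoms())
    gstar <- c(2L, 4L, 1L)
    astar <- c(0.8, 1.1, 0.95, 1.3)
    r_exp <- sapply(seq_along(astar), function(cc) {
      sapply(1:3, function(p) rs$r_sim[p, gstar[p], cc] / astar[cc])
    })
    list(rs = rs, gstar = gstar, astar = astar, r_exp = r_exp)
  })
}

test_that("joint calibration is exact on noiseless synthetic phantoms", {
  fx <- cal_fixture()
  cal <- joint_calibrate(fx$r_exp, fx$rs$r_sim, fx$rs$gamma)
  expect_equal(cal$gamma_index, fx$gstar)
  expect_equal(cal$alpha, fx$astar, tolerance = 1e-12)
  expect_true(cal$converged)
  expect_lt(max(cal$misfit), 1e-12)
})

test_that("alpha scales exactly inversely with a rescaled combination", {
  fx <- cal_fixture()
  re2 <- fx$r_exp
  re2[, 2] <- re2[, 2] * 3
  cal <- joint_calibrate(re2, fx$rs$r_sim, fx$rs$gamma)
  expect_equal(cal$alpha[2], fx$astar[2] / 3, tolerance = 1e-12)
  expect_equal(cal$alpha[-2], fx$astar[-2], tolerance = 1e-12)
})

test_that("zero uncertainties get a floor with a message", {
  fx <- cal_fixture()
  w <- matrix(0.05, 3, 4)
  w[1, 1] <- 0
  expect_message(joint_calibrate(fx$r_exp, fx$rs$r_sim, fx$rs$gamma,
                                 w_tot = w), "floored")
})

test_that("raw series and calibration results round-trip through text files", {
  s <- synth_raw_series(lam_fx, tt_fx, spec_fx, I_DC = 100, dark_slope = 2)
  f <- tempfile(fileext = ".csv")
  write_raw_series(s, f)
  back <- read_raw_series(f, source_on = TRUE)
  expect_equal(back$lambda, s$lambda)
  expect_equal(back$t, s$t)
  expect_equal(back$counts, s$counts, ignore_attr = TRUE)
  fx <- cal_fixture()
  cal <- joint_calibrate(fx$r_exp, fx$rs$r_sim, fx$rs$gamma)
  f2 <- tempfile(fileext = ".yaml")
  write_calibration(cal, f2)
  y <- yaml::read_yaml(f2)
  expect_equal(y$alpha, fx$astar, tolerance = 1e-9)
  expect_equal(y$gamma, fx$rs$gamma[fx$gstar], tolerance = 1e-9)
})

test_that("reference phantom config carries the manufacturer IOPs", {
  ph <- reference_phantoms()
  expect_equal(ph$mua, c(0.0566, 0.0066, 0.115))
  expect_equal(ph$mus_p, c(1.17, 0.491, 1.98))
  expect_equal(ph$lambda_nm, c(560, 633, 560))
})
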