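test_that("same seed and config give a bit-identical path set", {
  med <- layered_medium(fx_props(1.5, 1.5), fx_props(1, 1.2), z_top = 0.4,
                        oil_thickness = 0.05)
  pr <- fx_probe3()
  a <- run_forward(med, pr, 2e4, seed = 9)
  b <- run_forward(med, pr, 2e4, seed = 9)
  expect_identical(a$records, b$records)
  expect_identical(a$counts, b$counts)
  c <- run_forward(med, pr, 2e4, seed = 10)
  expect_false(identical(a$records, c$records))
})

test_that("bilayer with identical layers degenerates to the homogeneous path", {
  props <- fx_props(1.2, 1.5)
  pr <- radial_probe(c(0.2, 0.6), tilts = 0)
  bi <- layered_medium(props, props, z_top = 0.3, oil_thickness = 0)
  ho <- homogeneous_medium(props, z_top = 0.8)
  a <- run_forward(bi, pr, 2e5, seed = 21, max_path = 60, max_lateral = 10)
  b <- run_forward(ho, pr, 2e5, seed = 22, max_path = 60, max_lateral = 10)
  expect_gt(nrow(a$records), 50)
  ks <- suppressWarnings(ks.test(a$records$l_top + a$records$l_deep,
                                 b$records$l_top + b$records$l_deep))
  expect_gt(ks$p.value, 0.01)
})

test_that("Beer-Lambert reweighting matches closed forms", {
  paths <- fx_default_paths()
  r0 <- apply_absorption(paths, 0, 0)
  # at zero absorption every weight is 1: R = n_col / N
  expect_equal(r0$R, r0$n_col / paths$n_photons)
  # single-photon closed form through the public chain
  one <- paths
  rec <- paths$records[1, ]
  rec$l_top <- 1; rec$l_deep <- 2
  one$records <- rec
  r1 <- apply_absorption(one, 0.1, 0.05)
  i <- which(r1$ill == rec$ill & r1$det == rec$det)
  expect_equal(r1$R[i], exp(-0.2) / paths$n_photons, tolerance = 1e-12)
  expect_error(apply_absorption(paths, -0.1, 0), "non-negative")
})

test_that("reflectance decreases monotonically in absorption (exact)", {
  paths <- fx_default_paths()
  mua <- seq(0, 0.3, by = 0.05)
  R <- sapply(mua, function(m) apply_absorption(paths, m, m)$R)
  occupied <- rowSums(R) > 0
  diffs <- t(apply(R[occupied, , drop = FALSE], 1, diff))
  expect_true(all(diffs < 0))
})

test_that("MC uncertainty implements the population-SD standard error", {
  expect_equal(mc_uncertainty(c(1, 1, 1)), 0)
  # hand evaluation: weights {1, 0}: S_abs = 0.5, mean = 0.5, n = 2
  expect_equal(mc_uncertainty(c(1, 0)), 0.5 / (0.5 * sqrt(2)))
  expect_error(mc_uncertainty(numeric(0)), "no collected photons")
})

test_that("relative uncertainty scales as 1/sqrt(N)", {
  med <- homogeneous_medium(fx_props(1.5, 1.5))
  pr <- radial_probe(c(0.1, 0.2), tilts = 0)
  ns <- c(3e4, 1.2e5, 4.8e5)
  wn <- vapply(seq_along(ns), function(i) {
    mean(vapply(1:2, function(s) {
      ps <- run_forward(med, pr, ns[i], seed = 30 + 10 * i + s,
                        max_path = 60, max_lateral = 10)
      mean(apply_absorption(ps, 0.05, 0.05)$w_num, na.rm = TRUE)
    }, numeric(1)))
  }, numeric(1))
  slope <- coef(lm(log(wn) ~ log(ns)))[2]
  expect_lt(abs(slope + 0.5), 0.1)
})

test_that("path-length histograms normalize to unit maximum", {
  paths <- fx_default_paths()
  combo <- paths$records[1, c("ill", "det")]
  h <- path_length_histogram(paths, c(combo$ill, combo$det), breaks = 10)
  expect_false(h$empty)
  expect_equal(max(h$normalized), 1)
  expect_equal(sum(h$counts > 0) >= 1, TRUE)
  # single photon lands in exactly one bin
  one <- paths
  one$records <- paths$records[1, ]
  h1 <- path_length_histogram(one, c(combo$ill, combo$det), breaks = 5)
  expect_equal(sum(h1$counts > 0), 1)
  # empty combination flagged
  h0 <- path_length_histogram(one, c(-1, -1))
  expect_true(h0$empty)
})

test_that("fiber diameter shifts counts but not the normalized distribution", {
  med <- homogeneous_medium(fx_props(1.5, 1.5))
  small <- radial_probe(0.4, tilts = 0, diameter_mm = 0.2)
  large <- radial_probe(0.4, tilts = 0, diameter_mm = 0.4)
  a <- run_forward(med, small, 3e5, seed = 41, max_path = 60, max_lateral = 10)
  b <- run_forward(med, large, 3e5, seed = 42, max_path = 60, max_lateral = 10)
  expect_gt(nrow(b$records), nrow(a$records)) # absolute counts increase
  ks <- suppressWarnings(ks.test(a$records$l_top + a$records$l_deep,
                                 b$records$l_top + b$records$l_deep))
  expect_gt(ks$p.value, 0.01) # shape unchanged within noise
})

test_that("sampled depth zv80 follows the weighted percentile rule", {
  paths <- fx_default_paths()
  one <- paths
  # all photons at the same depth
  one$records <- data.frame(ill = 1, det = 1, l_top = 1, l_deep = 0,
                            x = 0, y = 0, ux = 0, uy = 0, uz = -1,
                            max_depth = 0.42)[rep(1, 10), ]
  expect_equal(sampled_depth_zv80(one, c(1, 1)), 0.42)
  # boundary case: cumulative weight hits exactly 80% at the lower depth
  one$records <- data.frame(ill = 1, det = 1, l_top = 1, l_deep = 0,
                            x = 0, y = 0, ux = 0, uy = 0, uz = -1,
                            max_depth = c(rep(0.1, 80), rep(1.0, 20)))
  expect_equal(sampled_depth_zv80(one, c(1, 1)), 0.1)
  expect_error(sampled_depth_zv80(one, c(9, 9)), "empty")
})

test_that("higher detector tilt does not probe deeper at fixed SDS", {
  med <- homogeneous_medium(fx_props(1.5, 1.5))
  pr <- radial_probe(0.4, tilts = c(0, 30, 60))
  ps <- run_forward(med, pr, 4e5, seed = 50, max_path = 60, max_lateral = 10)
  z <- vapply(1:3, function(d) sampled_depth_zv80(ps, c(1, d)), numeric(1))
  expect_true(z[3] <= z[1] + 0.05) # 60 deg vs perpendicular, small slack
})
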