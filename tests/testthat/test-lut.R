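test_that("grid spec validates axes and enumerates nodes first-axis-fastest", {
  g <- grid_spec(mus_p = c(1, 2), gamma = c(1.2, 1.6), mua = c(0, 0.1, 0.2))
  expect_equal(g$kind, "monolayer")
  expect_error(grid_spec(mus_p = c(2, 1), gamma = 1.5, mua = 0), "increasing")
  expect_error(grid_spec(a = 1, b = 2), "axes must be")
  v1 <- subdrs:::node_values(g, 1)
  v2 <- subdrs:::node_values(g, 2)
  expect_equal(unname(v1), c(1, 1.2, 0))
  expect_equal(unname(v2), c(2, 1.2, 0)) # first axis varies fastest
  expect_equal(subdrs:::node_index(g, c(2, 1, 1)), 2L)
  expect_equal(subdrs:::node_index(g, c(1, 2, 3)), 1L + 2L + 2L * 2L * 2L)
})

test_that("build counts MC runs by the scattering sub-grid only", {
  g <- grid_spec(mus_p = c(1, 2), gamma = c(1.3, 1.7), mua = c(0, 0.1, 0.2))
  lut <- build_lut(g, fx_probe3(), n_photons = 5e3, seed = 1,
                   oil_thickness = 0)
  expect_equal(lut$provenance$n_mc_runs, 4) # 2 x 2 scattering nodes
  expect_equal(nrow(lut$table), 12)          # x 3 mua slices
  expect_equal(ncol(lut$table), 3)
  # absorption axis strictly decreasing wherever photons were collected
  for (j1 in 1:2) for (j2 in 1:2) for (cc in 1:3) {
    rows <- vapply(1:3, function(a) subdrs:::node_index(g, c(j1, j2, a)),
                   integer(1))
    r <- lut$table[rows, cc]
    if (r[1] > 0) expect_true(all(diff(r) < 0))
  }
})

test_that("infeasible grid gamma is rejected naming the node", {
  g <- grid_spec(mus_p = c(1, 2), gamma = c(1.3, 1.95), mua = 0.1)
  expect_error(build_lut(g, fx_probe3(), n_photons = 100, seed = 1),
               "infeasible grid point gamma = 1.95")
})

test_that("query snaps to the nearest node and round-trips", {
  lut <- fx_mono_lut()
  q <- lut_query(lut, c(mus_p = 2, gamma = 1.5, mua = 0.2))
  expect_equal(unname(q$node), c(2, 1.5, 0.2))
  expect_equal(unname(q$snap_distance), c(0, 0, 0))
  expect_equal(q$R, lut$table[q$index, ])
  # off-grid tuple snaps and reports the distance
  q2 <- lut_query(lut, c(mus_p = 2.2, gamma = 1.52, mua = 0.25))
  expect_equal(unname(q2$node), c(2, 1.5, 0.2))
  expect_equal(unname(q2$snap_distance), c(0.2, 0.02, 0.05))
  expect_error(lut_query(lut, c(mus_p = 5, gamma = 1.5, mua = 0.2)),
               "outside grid range")
  # mua = 0 node equals n_col / N of its path set by construction
  q0 <- lut_query(lut, c(mus_p = 2, gamma = 1.5, mua = 0))
  expect_true(all(q0$R * lut$provenance$per_fiber ==
                    round(q0$R * lut$provenance$per_fiber)))
})

test_that("LUT container round-trips and rejects foreign files", {
  lut <- fx_mono_lut()
  f <- tempfile(fileext = ".lut.rds")
  lut_write(lut, f)
  back <- lut_read(f)
  expect_equal(back$table, lut$table)
  expect_equal(back$wnum, lut$wnum)
  expect_equal(back$provenance, lut$provenance)
  expect_equal(back$grid, lut$grid)
  # truncated file
  raw <- readBin(f, "raw", file.size(f))
  f2 <- tempfile()
  writeBin(raw[1:20], f2)
  expect_error(lut_read(f2), "truncated|readable")
  # foreign RDS
  f3 <- tempfile()
  saveRDS(list(a = 1), f3)
  expect_error(lut_read(f3), "not a subdrs LUT")
})

test_that("inversion rejects measurements from a different probe", {
  lut <- fx_mono_lut()
  other <- radial_probe(c(0.2, 0.5, 0.9), tilts = 0)
  med <- homogeneous_medium(fx_props(2, 1.5))
  ps <- run_forward(med, other, 1e4, seed = 3, max_path = 40, max_lateral = 8)
  meas <- apply_absorption(ps, 0.2, 0.2)
  expect_error(cost_function(meas, lut), "probe geometry")
})

test_that("doubling photons shrinks the mean MC uncertainty by sqrt(2)", {
  g <- grid_spec(mus_p = 1.5, gamma = 1.5, mua = c(0, 0.05))
  pr <- radial_probe(c(0.1, 0.2), tilts = 0)
  w <- sapply(1:3, function(s) {
    l1 <- build_lut(g, pr, n_photons = 1e5, seed = 70 + s, oil_thickness = 0)
    l2 <- build_lut(g, pr, n_photons = 2e5, seed = 90 + s, oil_thickness = 0)
    c(mean(l1$wnum, na.rm = TRUE), mean(l2$wnum, na.rm = TRUE))
  })
  r <- mean(w[1, ]) / mean(w[2, ])
  expect_lt(abs(r - sqrt(2)), sqrt(2) * 0.10)
})

test_that("reweighted absorption axis is smooth despite scattering-axis noise", {
  lut <- fx_mono_lut()
  g <- lut$grid
  for (cc in seq_len(ncol(lut$table))) {
    rows <- vapply(seq_along(g$axes$mua), function(a) {
      subdrs:::node_index(g, c(2, 2, a))
    }, integer(1))
    r <- lut$table[rows, cc]
    if (r[1] <= 0) next
    # log-reflectance along mua is convex (divided differences of log R
    # non-decreasing) and decreasing: exact property of reweighting a fixed
    # path-length mixture, far smoother than the MC noise on scattering axes
    expect_true(all(diff(r) < 0))
    slopes <- diff(log(r)) / diff(g$axes$mua)
    expect_true(all(diff(slopes) > -1e-8))
  }
})
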