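test_that("cost formula matches hand evaluation", {
  lut <- fx_mono_lut()
  # measurement equal to a stored node: zero cost at that node
  q <- lut_reflectance(lut, c(mus_p = 2, gamma = 1.5, mua = 0.2))
  cs <- cost_function(q, lut)
  expect_equal(cs$F[attr(q, "index")], 0)
  expect_equal(cs$min_index, attr(q, "index"))
  # single-combination hand case: |1 - 0.9| / 1 = 0.1
  sub <- lut_subset(lut, 1)
  sub$table[, 1] <- 1
  m <- reflectance_set(ill = sub$combinations$ill,
                       det = sub$combinations$det, R = 0.9)
  expect_equal(cost_function(m, sub)$F, rep(0.1, nrow(sub$table)))
})

test_that("mean of single-fiber costs equals the all-fiber cost", {
  lut <- fx_mono_lut()
  q <- add_noise(lut_reflectance(lut, c(mus_p = 2, gamma = 1.5, mua = 0.2)),
                 0.1, seed = 5)
  all3 <- cost_function(q, lut)$F
  singles <- sapply(1:3, function(k) cost_function(q, lut_subset(lut, k))$F)
  ok <- apply(is.finite(singles), 1, all)
  expect_true(any(ok))
  expect_equal(all3[ok], rowMeans(singles)[ok], tolerance = 1e-12)
})

test_that("noiseless node data is recovered exactly at every node", {
  lut <- fx_mono_lut()
  for (idx in seq_len(nrow(lut$table))) {
    rm <- lut_reflectance(lut, idx)
    est <- grid_invert(rm, lut)
    expect_equal(est$index, idx)
    expect_equal(est$cost, 0)
    expect_equal(est$values, subdrs:::node_values(lut$grid, idx))
  }
})

test_that("exact ties break to the smallest node index and are counted", {
  lut <- fx_mono_lut()
  lut$table[5, ] <- lut$table[2, ] # duplicate a stored node
  rm <- lut_reflectance(lut, 2)
  est <- grid_invert(rm, lut)
  expect_equal(est$index, 2L)
  expect_equal(est$tie_count, 2L)
})

test_that("uncertainty bounds bracket the estimate and collapse at w = 0", {
  lut <- fx_mono_lut()
  rm <- lut_reflectance(lut, c(mus_p = 2, gamma = 1.5, mua = 0.2))
  pu <- propagate_uncertainty(rm, lut, w_tot = 0)
  expect_equal(pu$bounds_lo, pu$values)
  expect_equal(pu$bounds_hi, pu$values)
  pu2 <- propagate_uncertainty(rm, lut, w_tot = 0.3)
  expect_true(all(pu2$bounds_lo <= pu$values + 1e-12))
  expect_true(all(pu2$bounds_hi >= pu$values - 1e-12))
  expect_warning(propagate_uncertainty(rm, lut, w_tot = 1.2), "clipped")
})

test_that("bounds follow the scaling direction on a monotone toy table", {
  # strictly decreasing R(mua): scaling data down pushes mua up
  g <- grid_spec(mus_p = 1, gamma = 1.5, mua = seq(0, 0.5, by = 0.05))
  lut <- fx_mono_lut()
  toy <- lut
  toy$grid <- g
  toy$table <- matrix(exp(-5 * g$axes$mua), ncol = 1)
  toy$wnum <- toy$table * 0
  toy$combinations <- lut$combinations[1, ]
  toy$provenance$subset <- TRUE
  m <- reflectance_set(ill = toy$combinations$ill,
                       det = toy$combinations$det, R = exp(-5 * 0.2))
  pu <- propagate_uncertainty(m, toy, w_tot = 0.3)
  est_lo <- grid_invert(local({m$R <- m$R * 0.7; m}), toy)
  expect_equal(pu$bounds_hi[["mua"]], est_lo$values[["mua"]])
  expect_gte(pu$bounds_hi[["mua"]], pu$values[["mua"]])
  expect_lte(pu$bounds_lo[["mua"]], pu$values[["mua"]])
})

test_that("spectral inversion is independent per wavelength and stepwise", {
  lut <- fx_mono_lut()
  node <- c(mus_p = 2, gamma = 1.5, mua = 0.2)
  rm <- lut_reflectance(lut, node)
  lam <- c(500, 550, 600)
  spec <- do.call(rbind, lapply(lam, function(l) {
    data.frame(lambda = l, ill = rm$ill, det = rm$det, R = rm$R)
  }))
  out <- spectral_invert(spec, lut)
  expect_equal(nrow(out), 3)
  expect_true(all(out$mus_p == 2 & out$gamma == 1.5 & out$mua == 0.2))
  # estimates take only grid values
  expect_true(all(out$mua %in% lut$grid$axes$mua))
})

test_that("two distinct spectra stay distinguishable under 5% noise", {
  lut <- fx_mono_lut()
  na <- c(mus_p = 2, gamma = 1.5, mua = 0.2) # nevus-like
  nb <- c(mus_p = 3, gamma = 1.8, mua = 0.5) # melanoma-like
  lam <- seq(500, 600, by = 25)
  mk <- function(node, seed0) do.call(rbind, lapply(seq_along(lam), function(i) {
    rm <- add_noise(lut_reflectance(lut, node), 0.05, seed = seed0 + i)
    data.frame(lambda = lam[i], ill = rm$ill, det = rm$det, R = rm$R)
  }))
  ea <- spectral_invert(mk(na, 100), lut)
  eb <- spectral_invert(mk(nb, 200), lut)
  # distinguished at every wavelength in the majority of parameters
  sep <- (ea$mus_p != eb$mus_p) + (ea$gamma != eb$gamma) + (ea$mua != eb$mua)
  expect_true(all(sep >= 2))
})

test_that("landscape slices report the sub-10% region", {
  lut <- fx_mono_lut()
  rm <- lut_reflectance(lut, c(mus_p = 2, gamma = 1.5, mua = 0.2))
  cs <- cost_function(rm, lut)
  sl <- landscape_slices(cs, c("mus_p", "gamma"), fixed = list(mua = 0.2))
  expect_equal(dim(sl$F), c(3, 3))
  expect_true(sl$mask[2, 2]) # the generating node is inside the region
  expect_gte(sl$area, 1)
  expect_error(landscape_slices(cs, c("mus_p", "mus_p"),
                                fixed = list(mua = 0.2)), "differ")
  expect_error(landscape_slices(cs, c("mus_p", "gamma"),
                                fixed = list(mua = 0.21)), "not on the grid")
  # constant surface above threshold: empty region
  cs2 <- cs
  cs2$F[] <- 0.2
  sl2 <- landscape_slices(cs2, c("mus_p", "gamma"), fixed = list(mua = 0.2))
  expect_equal(sl2$area, 0)
})
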