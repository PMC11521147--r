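test_that("bevel formula matches direct evaluation and flags TIR", {
  expect_equal(effective_bevel_angle(0, 1.43), 0)
  expect_equal(effective_bevel_angle(30, 1.43), 15.643, tolerance = 1e-3)
  expect_equal(effective_bevel_angle(30, 1.30), 10.54, tolerance = 1e-2)
  expect_error(effective_bevel_angle(60, 1.43), "total internal reflection")
  # in oil contact the bevel contribution nearly cancels and 60 deg is fine
  expect_lt(abs(effective_bevel_angle(30, 1.43, n_ext = 1.45) + 0.45), 0.05)
  expect_no_error(effective_bevel_angle(60, 1.43, n_ext = 1.45))
})

test_that("default probe enumerates combinations and honors exclusions", {
  pr <- build_probe()
  expect_s3_class(pr, "probe_geometry")
  expect_equal(nrow(pr$combinations), 64)
  expect_equal(sum(pr$fibers$role == "illumination"), 8)
  # radii on the two design circles
  expect_setequal(unique(pr$fibers$radius_mm), c(0.8, 1.5))
  # SDS span from ~0.1 mm to the 3 mm tip maximum
  expect_lt(min(pr$combinations$sds), 0.11)
  expect_gt(max(pr$combinations$sds), 2.9)
  # damaged detection fiber excluded
  cfg <- default_probe_config()
  cfg$excluded <- "det:3"
  pr2 <- build_probe(cfg)
  expect_equal(nrow(pr2$combinations), 56)
  expect_false(3 %in% pr2$combinations$det)
})

test_that("geometry validation catches overlap and out-of-disc faces", {
  cfg <- default_probe_config()
  cfg$fibers[[2]]$azimuth_deg <- 0 # same center as illumination fiber 1
  expect_error(build_probe(cfg), "overlap")
  cfg2 <- default_probe_config()
  cfg2$fibers[[9]]$radius_mm <- 1.7
  expect_error(build_probe(cfg2), "tip disc")
})

test_that("probe config round-trips through YAML", {
  cfg <- default_probe_config()
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, f)
  pr1 <- build_probe(cfg)
  pr2 <- build_probe(f)
  expect_equal(pr1$fibers, pr2$fibers)
  expect_equal(pr1$combinations, pr2$combinations)
})

test_that("SDS table is a pure function of the geometry", {
  a <- build_probe()$combinations$sds
  b <- build_probe()$combinations$sds
  expect_identical(a, b)
  # hand check one inner-circle pair: chord of 7.5 deg on r = 0.8
  pr <- build_probe()
  i <- which(pr$combinations$ill == 1 & pr$combinations$det == 1)
  expect_equal(pr$combinations$sds[i], 2 * 0.8 * sin(7.5 / 2 * pi / 180),
               tolerance = 1e-12)
})

test_that("launch cone respects the in-medium NA limit", {
  pr <- build_probe()
  s <- sample_launch(pr, id = 1, n = 1e4, n_medium = 1.43, seed = 2)
  # perpendicular fiber: polar angle bounded by asin(NA / n)
  ang <- acos(pmin(1, s$direction[, "uz"]))
  expect_lte(max(ang), asin(0.22 / 1.43) + 1e-9)
  # mean launch position converges to the fiber center
  f <- pr$fibers[pr$fibers$role == "illumination" & pr$fibers$id == 1, ]
  se <- apply(s$position, 2, sd) / sqrt(nrow(s$position))
  expect_lt(abs(mean(s$position[, "x"]) - f$x), 3 * se[1])
  expect_lt(abs(mean(s$position[, "y"]) - f$y), 3 * se[2])
  # positions inside the elliptical footprint
  expect_true(all((s$position[, "x"] - f$x)^2 +
                    (s$position[, "y"] - f$y)^2 <= (0.05 + 1e-12)^2))
})

test_that("nearly-collapsed cone launches along the fiber axis", {
  cfg <- default_probe_config()
  cfg$fibers[[1]]$na <- 1e-6
  pr <- build_probe(cfg)
  s <- sample_launch(pr, id = 1, n = 100, seed = 1)
  expect_true(all(abs(s$direction[, "uz"] - 1) < 1e-9))
})

test_that("acceptance tests footprint and cone boundary exactly", {
  pr <- build_probe()
  f <- pr$fibers[pr$fibers$role == "detection" & pr$fibers$id == 1, ]
  up <- c(0, 0, -1) # straight up, along a perpendicular fiber's axis
  expect_true(accept(pr, 1, c(f$x, f$y), up))
  expect_false(accept(pr, 1, c(f$x + 1, f$y), up))
  # angle exactly at the cone edge accepted, epsilon beyond rejected
  th <- asin(0.22 / 1.43)
  at_edge <- c(sin(th), 0, -cos(th))
  beyond <- c(sin(th + 1e-6), 0, -cos(th + 1e-6))
  expect_true(accept(pr, 1, c(f$x, f$y), at_edge))
  expect_false(accept(pr, 1, c(f$x, f$y), beyond))
})

test_that("acceptance is invariant under probe+medium rotation", {
  pr <- build_probe()
  f <- pr$fibers[pr$fibers$role == "detection" & pr$fibers$id == 5, ]
  set.seed(4)
  for (i in 1:25) {
    pos <- c(f$x, f$y) + runif(2, -0.03, 0.03)
    d <- c(runif(2, -0.3, 0.3), -1)
    d <- d / sqrt(sum(d^2))
    a0 <- accept(pr, 5, pos, d)
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    cfg <- default_probe_config()
    for (k in seq_along(cfg$fibers)) {
      cfg$fibers[[k]]$azimuth_deg <- cfg$fibers[[k]]$azimuth_deg + th * 180 / pi
      cfg$fibers[[k]]$axis_azimuth_deg <-
        cfg$fibers[[k]]$axis_azimuth_deg + th * 180 / pi
    }
    prr <- build_probe(cfg)
    posr <- as.numeric(R %*% pos)
    dr <- c(as.numeric(R %*% d[1:2]), d[3])
    expect_equal(accept(prr, 5, posr, dr), a0)
  }
})
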