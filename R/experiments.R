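#' Add multiplicative white Gaussian noise to a reflectance set
#'
#' `R -> R (1 + level * eps)`, `eps ~ N(0, 1)` i.i.d. per combination, the
#' standard synthetic-noise model for reflectance data. Negative results are
#' clipped at zero and counted.
#'
#' @param rset a [reflectance_set()].
#' @param level relative noise level (e.g. 0.05 or 0.10).
#' @param seed RNG seed (same seed, same realization).
#' @return A noisy `reflectance_set`; `attr(, "n_clipped")` counts clipped
#'   values and `w_exp` is set to `level`.
#' @export
add_noise <- function(rset, level, seed = 1L) {
  stopifnot(level >= 0)
  out <- rset
  if (level > 0) {
    set.seed(seed)
    out$R <- rset$R * (1 + level * rnorm(length(rset$R)))
  }
  n_clip <- sum(out$R < 0)
  out$R[out$R < 0] <- 0
  out$w_exp <- level
  attr(out, "n_clipped") <- n_clip
  out
}

#' Reference tissue scenarios
#'
#' `scenario_case1()`: the homogeneous-tissue triplet used by the
#' fiber-placement and tilt-angle studies (mus' 2/mm, gamma 1.5,
#' mua 0.2/mm). `scenario_melanoma()`: the 540-nm melanoma-on-skin bilayer
#' case (top layer mus' 2.0, gamma 1.78, mua 0.16; deep layer 1.1, 1.55,
#' 0.06; thickness 0.7 mm).
#'
#' @return Named numeric vector of parameters (grid axis names).
#' @export
scenario_case1 <- function() c(mus_p = 2, gamma = 1.5, mua = 0.2)

#' @rdname scenario_case1
#' @export
scenario_melanoma <- function() {
  c(mus1 = 2.0, gamma1 = 1.78, mua1 = 0.16,
    mus2 = 1.1, gamma2 = 1.55, mua2 = 0.06, z = 0.7)
}

# relative recovery error per parameter; parameters whose true value is 0
# are normalized by the grid-axis range instead (flagged by name)
relative_errors <- function(est, truth, grid) {
  err <- numeric(length(truth))
  names(err) <- names(truth)
  for (nm in names(truth)) {
    tv <- truth[[nm]]
    if (abs(tv) > 0) {
      err[nm] <- abs(est[[nm]] - tv) / abs(tv)
    } else {
      rng <- diff(range(grid$axes[[nm]]))
      err[nm] <- abs(est[[nm]] - tv) / rng
    }
  }
  err
}

new_sweep_result <- function(df, ...) {
  extra <- list(...)
  for (nm in names(extra)) attr(df, nm) <- extra[[nm]]
  class(df) <- c("sweep_result", "data.frame")
  df
}

# one synthetic measurement per condition (either the LUT node itself, or a
# fresh off-LUT Monte Carlo run at the snapped truth), then n_trials noise
# realizations inverted against the LUT
sweep_base <- function(lut, truth, mode, probe, n_photons, seed) {
  base <- lut_reflectance(lut, truth)
  if (mode == "mc") {
    if (is.null(probe)) {
      stop('mode = "mc" needs the probe the LUT was built for', call. = FALSE)
    }
    tn <- attr(base, "node")
    pv <- lut$provenance
    if (lut$grid$kind == "bilayer") {
      top <- optical_properties(tn[["mus1"]], tn[["gamma1"]], 0, pv$n_tissue)
      deep <- optical_properties(tn[["mus2"]], tn[["gamma2"]], 0, pv$n_tissue)
      med <- layered_medium(top, deep, z_top = tn[["z"]],
                            oil_thickness = pv$oil_thickness,
                            oil_n = pv$oil_n, n_above = pv$n_above)
      mus_min <- min(tn[["mus1"]], tn[["mus2"]])
      mua <- c(tn[["mua1"]], tn[["mua2"]])
    } else {
      props <- optical_properties(tn[["mus_p"]], tn[["gamma"]], 0,
                                  pv$n_tissue)
      med <- layered_medium(props, props, z_top = 0.5,
                            oil_thickness = pv$oil_thickness,
                            oil_n = pv$oil_n, n_above = pv$n_above)
      mus_min <- tn[["mus_p"]]
      mua <- c(tn[["mua"]], tn[["mua"]])
    }
    cuts <- lut_cutoffs(mus_min)
    ps <- run_forward(med, probe, ceiling(n_photons / sum(
      probe$fibers$role == "illumination" &
        !(probe$fibers$key %in% probe$excluded))),
      seed = (seed * 31 + 17) %% 2147483629, g1 = pv$g1,
      max_path = cuts[["max_path"]], max_lateral = cuts[["max_lateral"]])
    out <- apply_absorption(ps, mua[1], mua[2])
    attr(out, "node") <- tn
    out
  } else {
    base
  }
}

sweep_trials <- function(lut, truth, level, n_trials, seed, params,
                         mode = "lut", probe = NULL, n_photons = NULL) {
  if (is.null(n_photons)) n_photons <- lut$provenance$n_photons_node
  base <- sweep_base(lut, truth, mode, probe, n_photons, seed)
  truth_node <- attr(base, "node")
  errs <- matrix(NA_real_, n_trials, length(params),
                 dimnames = list(NULL, params))
  for (tr in seq_len(n_trials)) {
    noisy <- add_noise(base, level, seed = seed + 7717L * tr)
    est <- suppressMessages(grid_invert(noisy, lut))
    errs[tr, ] <- relative_errors(est$values[params], truth_node[params],
                                  lut$grid)
  }
  errs
}

summarize_errs <- function(errs) {
  data.frame(param = colnames(errs),
             mean_rel_error_pct = 100 * colMeans(errs),
             se_pct = 100 * apply(errs, 2, sd) / sqrt(nrow(errs)),
             row.names = NULL)
}

#' Estimation error as a function of added noise
#'
#' Synthetic measurements are generated at the truth (snapped to the LUT
#' grid, solver-self-consistency mode), perturbed with multiplicative
#' Gaussian noise at each level and inverted; the mean relative estimation
#' error per parameter over `n_trials` repetitions is reported.
#'
#' @param truth named bilayer (or monolayer) parameter vector; snapped to
#'   the nearest grid node.
#' @param lut the look-up table.
#' @param levels noise levels (fractions, e.g. `seq(0, 0.10, 0.02)`).
#' @param n_trials noise realizations per level.
#' @param seed master seed (trial seeds derive from it).
#' @param mode `"lut"` draws the synthetic truth from the LUT node itself
#'   (solver self-consistency) and `"mc"` from a fresh off-LUT Monte Carlo
#'   run at the snapped truth (realism); every result labels which.
#' @param probe probe geometry, required for `mode = "mc"`.
#' @return A `sweep_result` data frame: `level`, `param`,
#'   `mean_rel_error_pct`, `se_pct`; attributes carry the snapped truth,
#'   trial count and seed.
#' @export
noise_sweep <- function(truth, lut, levels = seq(0, 0.10, by = 0.02),
                        n_trials = 20, seed = 1L, mode = c("lut", "mc"),
                        probe = NULL) {
  mode <- match.arg(mode)
  params <- names(lut$grid$axes)
  rows <- lapply(seq_along(levels), function(i) {
    errs <- sweep_trials(lut, truth, levels[i], n_trials,
                         seed + 104729L * i, params, mode, probe)
    cbind(level = levels[i], summarize_errs(errs))
  })
  new_sweep_result(do.call(rbind, rows),
                   truth = attr(lut_reflectance(lut, truth), "node"),
                   n_trials = n_trials, seed = seed,
                   mode = if (mode == "lut") "lut-node" else "fresh-mc")
}

#' Estimation error as a function of top-layer thickness
#'
#' The six layer properties are held at the truth while the interface depth
#' walks through `z_values`; at each depth noisy synthetic data are
#' inverted `n_trials` times. Expected shape: top-layer errors fall and
#' deep-layer errors rise with depth. With identical layers the interface
#' depth is unidentifiable: it is flagged and dropped from the error
#' report.
#'
#' @param truth named vector with the six layer parameters (`z` ignored).
#' @param lut bilayer LUT.
#' @param z_values interface depths to test (snapped to the grid).
#' @param noise noise level (default 10%).
#' @inheritParams noise_sweep
#' @return A `sweep_result` with columns `z`, `param`, errors.
#' @export
thickness_sweep <- function(truth, lut, z_values = lut$grid$axes$z,
                            noise = 0.10, n_trials = 20, seed = 1L,
                            mode = c("lut", "mc"), probe = NULL) {
  mode <- match.arg(mode)
  stopifnot(lut$grid$kind == "bilayer")
  identical_layers <-
    isTRUE(all.equal(unname(truth[c("mus1", "gamma1", "mua1")]),
                     unname(truth[c("mus2", "gamma2", "mua2")])))
  params <- names(lut$grid$axes)
  if (identical_layers) params <- setdiff(params, "z")
  rows <- lapply(seq_along(z_values), function(i) {
    tr <- truth
    tr["z"] <- z_values[i]
    errs <- sweep_trials(lut, tr, noise, n_trials, seed + 104729L * i,
                         params, mode, probe)
    cbind(z = z_values[i], summarize_errs(errs))
  })
  new_sweep_result(do.call(rbind, rows), n_trials = n_trials, seed = seed,
                   noise = noise, z_identifiable = !identical_layers,
                   mode = if (mode == "lut") "lut-node" else "fresh-mc")
}

#' Estimation error as a function of inter-layer contrast
#'
#' Both layers start at the smallest simulated values of the grid; the
#' three deep-layer properties are then increased together by a fraction of
#' their axis ranges (the contrast, reported in %). Because the base
#' absorption is zero, absorption errors are range-normalized.
#'
#' @param lut bilayer LUT.
#' @param contrasts fractions of the axis ranges added to the deep layer.
#' @param z interface depth used for all cases (default: middle grid
#'   value).
#' @inheritParams thickness_sweep
#' @return A `sweep_result` with columns `contrast_pct`, `param`, errors.
#' @export
contrast_sweep <- function(lut, contrasts = seq(0, 1, by = 0.2),
                           z = NULL, noise = 0.10, n_trials = 20, seed = 1L,
                           mode = c("lut", "mc"), probe = NULL) {
  mode <- match.arg(mode)
  stopifnot(lut$grid$kind == "bilayer")
  ax <- lut$grid$axes
  if (is.null(z)) z <- ax$z[ceiling(length(ax$z) / 2)]
  base <- c(mus1 = min(ax$mus1), gamma1 = min(ax$gamma1), mua1 = min(ax$mua1))
  params <- names(ax)
  rows <- lapply(seq_along(contrasts), function(i) {
    f <- contrasts[i]
    tr <- c(base,
            mus2 = min(ax$mus2) + f * diff(range(ax$mus2)),
            gamma2 = min(ax$gamma2) + f * diff(range(ax$gamma2)),
            mua2 = min(ax$mua2) + f * diff(range(ax$mua2)),
            z = z)
    # z stays in the report even at zero contrast: with identical layers it
    # is unidentifiable and its error measures the confusion baseline
    errs <- sweep_trials(lut, tr, noise, n_trials, seed + 104729L * i,
                         params, mode, probe)
    cbind(contrast_pct = 100 * f, summarize_errs(errs))
  })
  new_sweep_result(do.call(rbind, rows), n_trials = n_trials, seed = seed,
                   noise = noise, mode = if (mode == "lut") "lut-node" else "fresh-mc")
}

#' Radial study probes: one source, detectors fanned over SDS
#'
#' Geometry used by the measurement-count and landscape studies: a single
#' perpendicular illumination fiber at the probe center and detection
#' fibers at the requested source-detector separations. With
#' `tilts = 0` one perpendicular detector per SDS (azimuth 0); with
#' `tilts = c(0, 30, 60)` one detector per tilt per SDS, spread over
#' azimuths so faces never overlap and every tilt sees the same SDS.
#'
#' @param sds source-detector separations, mm.
#' @param tilts detector tilt set, degrees (tilted fibers lean toward the
#'   source).
#' @param diameter_mm fiber diameter(s): scalar, or `NULL` for the default
#'   rule 0.1 mm below 0.3 mm SDS (so close detectors fit) and 0.2 mm --
#'   the reference diameter of the diameter/NA study -- beyond.
#' @param na numerical aperture (0.4, the reference value of the
#'   diameter/NA study).
#' @return A `probe_geometry`. Face overlap is not enforced: a tilted
#'   detector at very short SDS is an idealized numerical-study layout.
#' @export
radial_probe <- function(sds, tilts = 0, diameter_mm = NULL, na = 0.4) {
  azs <- seq(0, 360, length.out = length(tilts) + 1)[seq_along(tilts)]
  dia <- if (is.null(diameter_mm)) ifelse(sds < 0.3, 0.1, 0.2)
         else rep_len(diameter_mm, length(sds))
  fibers <- list(list(id = 1L, role = "illumination", radius_mm = 0,
                      azimuth_deg = 0, tilt_deg = 0,
                      diameter_mm = 0.1, na = na, n_fiber = 1.43))
  k <- 1L
  for (i in seq_along(sds)) {
    for (j in seq_along(tilts)) {
      fibers[[length(fibers) + 1]] <- list(
        id = k, role = "detection", radius_mm = sds[i],
        azimuth_deg = azs[j], tilt_deg = tilts[j],
        axis_azimuth_deg = (azs[j] + 180) %% 360,
        diameter_mm = dia[i], na = na, n_fiber = 1.43)
      k <- k + 1L
    }
  }
  build_probe(list(tip_radius_mm = max(sds) + 0.5, excluded = character(),
                   fibers = fibers), check_overlap = FALSE)
}

#' Estimation error as a function of the number of detection fibers
#'
#' Detection fibers are evenly distributed over SDS between `sds_range`;
#' the error of the monolayer inversion with the first `n` detectors is
#' compared between a perpendicular-only probe and a probe carrying three
#' detectors (tilts 0, 30 and 60 degrees) at every SDS. One LUT is built
#' per probe variant; fiber subsets reuse it.
#'
#' @param truth monolayer truth triplet (snapped to the grid).
#' @param n_fibers numbers of SDS positions to use.
#' @param sds_range range of source-detector separations, mm.
#' @param tilt_set tilt angles of the mixed-tilt variant.
#' @param grid monolayer [grid_spec()] for the LUTs.
#' @param n_photons photons per LUT node.
#' @param noise noise level (default 10%).
#' @inheritParams noise_sweep
#' @return A `sweep_result` with columns `n_fibers`, `variant`
#'   (`"perpendicular"` / `"mixed_tilts"`), `param`, errors.
#' @export
fiber_count_convergence <- function(truth = scenario_case1(),
                                    n_fibers = c(1, 2, 4, 8),
                                    sds_range = c(0.1, 2.0),
                                    tilt_set = c(0, 30, 60),
                                    grid = desk_monolayer_grid(),
                                    n_photons = 2e5, noise = 0.10,
                                    n_trials = 20, seed = 1L) {
  n_max <- max(n_fibers)
  sds <- seq(sds_range[1], sds_range[2], length.out = n_max)
  probes <- list(perpendicular = radial_probe(sds, tilts = 0),
                 mixed_tilts = radial_probe(sds, tilts = tilt_set))
  luts <- lapply(seq_along(probes), function(i) {
    build_lut(grid, probes[[i]], n_photons = n_photons,
              seed = seed + 13L * i, oil_thickness = 0)
  })
  names(luts) <- names(probes)
  params <- names(grid$axes)
  rows <- list()
  for (v in names(probes)) {
    per_sds <- length(if (v == "perpendicular") 1 else tilt_set)
    combos <- luts[[v]]$combinations
    for (i in seq_along(n_fibers)) {
      n <- n_fibers[i]
      keep <- combos$sds <= sds[n] + 1e-9
      sub <- lut_subset(luts[[v]], keep)
      errs <- sweep_trials(sub, truth, noise, n_trials,
                           seed + 104729L * i, params)
      rows[[length(rows) + 1]] <-
        cbind(n_fibers = n * per_sds, variant = v, summarize_errs(errs))
    }
  }
  new_sweep_result(do.call(rbind, rows), n_trials = n_trials, seed = seed,
                   noise = noise, sds = sds, mode = "lut-node")
}

#' Bilayer recovery study (synthetic twin of the headline validation)
#'
#' Builds (or reuses) a desk-scale bilayer LUT for the default 16-fiber
#' probe, generates noisy synthetic measurements at a bilayer truth for a
#' set of top-layer thicknesses, inverts them, and reports the mean
#' relative estimation error of the six layer properties over `n_trials`
#' noise realizations per thickness.
#'
#' @param lut a bilayer LUT for the default probe, or `NULL` to build one
#'   on [desk_bilayer_grid()] with `n_photons` photons per node.
#' @param scenario bilayer truth (snapped to the grid); default the
#'   melanoma-on-skin case.
#' @param thicknesses top-layer thicknesses, mm.
#' @param noise multiplicative Gaussian noise level (default 5%, the level
#'   of the published bilayer demonstration).
#' @param n_trials noise realizations per thickness.
#' @param n_photons photons per node if the LUT is built here.
#' @param seed master seed.
#' @param probe probe used if the LUT is built here.
#' @return List with `per_thickness` (a `sweep_result` over `z`),
#'   `mean_error_pct` (grand mean over the six layer properties,
#'   thicknesses and trials), the snapped truth and the LUT provenance.
#' @export
bilayer_recovery_study <- function(lut = NULL, scenario = scenario_melanoma(),
                                   thicknesses = c(0.2, 0.4, 0.6, 0.8, 1.0),
                                   noise = 0.05, n_trials = 20,
                                   n_photons = 1e5, seed = 1L,
                                   probe = build_probe()) {
  if (is.null(lut)) {
    lut <- build_lut(desk_bilayer_grid(), probe, n_photons = n_photons,
                     seed = seed)
  }
  stopifnot(lut$grid$kind == "bilayer")
  iops <- c("mus1", "gamma1", "mua1", "mus2", "gamma2", "mua2")
  rows <- list()
  all_errs <- c()
  for (i in seq_along(thicknesses)) {
    tr <- scenario
    tr["z"] <- thicknesses[i]
    errs <- sweep_trials(lut, tr, noise, n_trials, seed + 104729L * i, iops)
    rows[[i]] <- cbind(z = thicknesses[i], summarize_errs(errs))
    all_errs <- c(all_errs, as.vector(errs))
  }
  truth_node <- attr(lut_reflectance(lut, scenario), "node")
  list(per_thickness = new_sweep_result(do.call(rbind, rows),
                                        n_trials = n_trials, seed = seed,
                                        noise = noise, mode = "lut-node"),
       mean_error_pct = 100 * mean(all_errs),
       truth = truth_node[iops],
       lut_provenance = lut$provenance)
}
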