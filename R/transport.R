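#' Optical properties of one layer
#'
#' @param mus_p reduced scattering coefficient, 1/mm (> 0).
#' @param gamma similarity parameter `(1 - g2)/(1 - g1)`; must be attainable
#'   by the phase-function family at the configured `g1` (see
#'   [gamma_range()]).
#' @param mua absorption coefficient, 1/mm (>= 0).
#' @param n refractive index.
#' @return Object of class `optical_properties`.
#' @export
optical_properties <- function(mus_p, gamma, mua = 0, n = 1.43) {
  stopifnot(mus_p > 0, mua >= 0, n > 0)
  structure(list(mus_p = mus_p, gamma = gamma, mua = mua, n = n),
            class = "optical_properties")
}

#' Layered medium: oil film over a finite top layer over a deep layer
#'
#' The geometry is a stack of analytic slabs: an optional scattering-free
#' immersion-oil film at the surface, a top layer of thickness `z_top` and a
#' deep layer, semi-infinite by default. A finite `deep_thickness` adds a
#' bottom boundary through which photons can escape (counted as transmitted),
#' which is what energy-conservation checks use.
#'
#' @param top,deep [optical_properties()] of the two tissue layers.
#' @param z_top top-layer thickness (interface depth), mm.
#' @param oil_thickness thickness of the scattering-free oil film, mm (0
#'   removes the film).
#' @param oil_n refractive index of the oil film.
#' @param n_above refractive index above the surface outside the fiber faces
#'   (air by default; the faces themselves present the fiber core index).
#' @param deep_thickness thickness of the deep layer, mm (`Inf` =
#'   semi-infinite).
#' @param n_below index below a finite deep layer (defaults to the deep-layer
#'   index, i.e. an index-matched open bottom).
#' @return Object of class `layered_medium`.
#' @examples
#' med <- layered_medium(optical_properties(2, 1.5, 0.16),
#'                       optical_properties(1.1, 1.45, 0.06),
#'                       z_top = 0.7, oil_thickness = 0.05)
#' @export
layered_medium <- function(top, deep, z_top, oil_thickness = 0.05,
                           oil_n = 1.45, n_above = 1.0,
                           deep_thickness = Inf, n_below = NULL) {
  stopifnot(inherits(top, "optical_properties"),
            inherits(deep, "optical_properties"),
            z_top > 0, oil_thickness >= 0, deep_thickness > 0)
  structure(list(top = top, deep = deep, z_top = z_top,
                 oil_thickness = oil_thickness, oil_n = oil_n,
                 n_above = n_above, deep_thickness = deep_thickness,
                 n_below = n_below %||% deep$n),
            class = "layered_medium")
}

#' Homogeneous half-space as a degenerate bilayer
#'
#' @param props [optical_properties()] of the medium.
#' @param ... passed to [layered_medium()] (e.g. `oil_thickness`).
#' @param z_top nominal interface depth; immaterial when both layers share
#'   `props`.
#' @return A `layered_medium` whose two layers are identical.
#' @export
homogeneous_medium <- function(props, z_top = 0.5, ...) {
  layered_medium(props, props, z_top = z_top, oil_thickness = 0, ...)
}

medium_contact_n <- function(medium) {
  if (medium$oil_thickness > 0) medium$oil_n else medium$top$n
}

med_for_engine <- function(medium, g1, analog) {
  ph_t <- solve_phase_params(g1, medium$top$gamma)
  ph_d <- solve_phase_params(g1, medium$deep$gamma)
  list(d_oil = medium$oil_thickness, n_oil = medium$oil_n,
       z_top = medium$z_top, d_deep = medium$deep_thickness,
       n_above = medium$n_above, n_below = medium$n_below,
       mus = c(medium$top$mus_p / (1 - g1), medium$deep$mus_p / (1 - g1)),
       g = c(ph_t$g_hg, ph_d$g_hg),
       beta = c(ph_t$beta_mix, ph_d$beta_mix),
       n = c(medium$top$n, medium$deep$n),
       mua = if (analog) c(medium$top$mua, medium$deep$mua) else c(0, 0))
}

#' Forward Monte Carlo run (white MC)
#'
#' Launches `n_photons` from every illumination fiber, propagates them with
#' exponential free paths at the scattering rate of each layer, scatters with
#' the modified-HG phase function matching each layer's `gamma` at the
#' configured `g1`, applies stochastic unpolarized Fresnel
#' reflection/refraction at the oil, interface, surface and (optional) bottom
#' boundaries, and records every photon collected by a detection fiber with
#' its per-layer partial path lengths. No absorption is applied during
#' transport (`analog = FALSE`), so a single run serves every absorption pair
#' through [apply_absorption()].
#'
#' @param medium a [layered_medium()]; its `mua` fields are ignored unless
#'   `analog = TRUE`.
#' @param probe a [build_probe()] geometry.
#' @param n_photons photons launched per illumination fiber.
#' @param seed integer seed; the run is bit-reproducible and each
#'   illumination fiber uses its own substream.
#' @param g1 first Legendre moment of the phase function in both layers
#'   (fixed configuration constant; `mus = mus_p / (1 - g1)`).
#' @param max_path photon termination: total path length cutoff, mm. The
#'   truncated weight is negligible against MC noise once `mua >=` about
#'   0.005/mm; at `mua = 0` the truncated fraction is reported in `counts`.
#' @param max_lateral photon termination: lateral distance cutoff, mm.
#' @param analog if `TRUE`, sample absorption events during transport using
#'   the medium's `mua` (the direct-simulation cross-check for the
#'   white-MC reweighting); collected weights are then all 1.
#' @return Object of class `path_set`: `records` (one row per collected
#'   photon: combination, per-layer path lengths, exit position/direction,
#'   maximum visited depth), `n_photons`, bookkeeping `counts`
#'   (top/bottom exits, truncated, absorbed), the probe, medium, seed.
#' @export
run_forward <- function(medium, probe, n_photons, seed = 1L, g1 = 0.9,
                        max_path = 200, max_lateral = 15, analog = FALSE) {
  stopifnot(inherits(medium, "layered_medium"),
            inherits(probe, "probe_geometry"))
  if (n_photons <= 0) stop("n_photons must be positive", call. = FALSE)
  n_contact <- medium_contact_n(medium)
  ill <- probe_fibers(probe, "illumination")
  det <- probe_fibers(probe, "detection")
  out <- cpp_run_forward(med_for_engine(medium, g1, analog),
                         face_matrix(ill, n_contact),
                         face_matrix(det, n_contact),
                         as.integer(n_photons), as.double(seed),
                         max_path, max_lateral, analog, TRUE)
  rec <- data.frame(
    ill = ill$id[out$ill], det = det$id[out$det],
    l_top = out$l_top, l_deep = out$l_deep,
    x = out$x, y = out$y, ux = out$ux, uy = out$uy, uz = out$uz,
    max_depth = out$max_depth)
  structure(list(
    records = rec,
    n_photons = n_photons,
    n_launched = out$n_launched,
    counts = c(top_exit = out$top_exit, bottom_exit = out$bottom_exit,
               truncated = out$truncated, absorbed = out$absorbed),
    combinations = probe$combinations,
    probe = probe, medium = medium, seed = seed, g1 = g1,
    analog = analog,
    engine = c(max_path = max_path, max_lateral = max_lateral)),
    class = "path_set")
}

#' @export
print.path_set <- function(x, ...) {
  cat(sprintf(
    "path_set: %d collected photons / %.3g launched (%d combinations, seed %s)\n",
    nrow(x$records), x$n_launched, nrow(x$combinations),
    format(x$seed)))
  invisible(x)
}

combo_index <- function(paths) {
  key <- paste(paths$records$ill, paths$records$det)
  ck <- paste(paths$combinations$ill, paths$combinations$det)
  match(key, ck)
}

#' Apply Beer-Lambert absorption to a white-MC path set
#'
#' Each collected photon gets weight
#' `exp(-mua_top * l_top - mua_deep * l_deep)`; the per-combination
#' reflectance is the summed weight divided by the photons launched from that
#' combination's illumination fiber, and the relative MC uncertainty comes
#' from [mc_uncertainty()].
#'
#' @param paths a [run_forward()] path set (white MC).
#' @param mua_top,mua_deep absorption coefficients, 1/mm.
#' @return Object of class `reflectance_set`: a data frame with one row per
#'   fiber combination (`ill`, `det`, `sds`, `R`, `w_num`, `n_col`) plus
#'   provenance attributes. `w_num` is `NA` for empty combinations.
#' @export
apply_absorption <- function(paths, mua_top, mua_deep) {
  stopifnot(inherits(paths, "path_set"))
  if (mua_top < 0 || mua_deep < 0) {
    stop("absorption coefficients must be non-negative", call. = FALSE)
  }
  if (isTRUE(paths$analog)) {
    stop("path set was run with analog absorption; reweighting needs a white-MC run",
         call. = FALSE)
  }
  nc <- nrow(paths$combinations)
  rw <- cpp_reweight(paths$records$l_top, paths$records$l_deep,
                     as.integer(combo_index(paths) - 1L), nc,
                     mua_top, mua_deep, paths$n_photons)
  out <- paths$combinations
  out$R <- as.numeric(rw$R[1, ])
  out$w_num <- as.numeric(rw$wnum[1, ])
  out$n_col <- as.numeric(rw$n_col)
  new_reflectance_set(out, n_photons = paths$n_photons,
                      mua = c(top = mua_top, deep = mua_deep),
                      seed = paths$seed,
                      probe_signature = probe_signature(paths$probe))
}

new_reflectance_set <- function(df, ...) {
  extra <- list(...)
  for (nm in names(extra)) attr(df, nm) <- extra[[nm]]
  class(df) <- c("reflectance_set", "data.frame")
  df
}

#' Assemble a reflectance set from per-combination values
#'
#' @param ill,det fiber ids per combination.
#' @param R reflectance per combination (detected weight fraction per
#'   launched photon).
#' @param sds optional source-detector separations, mm.
#' @param w_num,w_exp optional relative numerical / experimental
#'   uncertainties; `w_tot = w_num + w_exp` is used by weighted inversion.
#' @return A `reflectance_set`.
#' @export
reflectance_set <- function(ill, det, R, sds = NA_real_, w_num = NA_real_,
                            w_exp = NA_real_) {
  stopifnot(all(R >= 0, na.rm = TRUE))
  new_reflectance_set(data.frame(ill = ill, det = det, sds = sds, R = R,
                                 w_num = w_num, w_exp = w_exp))
}

w_tot_of <- function(rset) {
  wn <- if ("w_num" %in% names(rset)) rset$w_num else NA_real_
  we <- if ("w_exp" %in% names(rset)) rset$w_exp else NA_real_
  wn[is.na(wn)] <- 0
  we <- rep_len(we, length(wn))
  we[is.na(we)] <- 0
  wn + we
}

#' Relative Monte Carlo uncertainty of a collected-weight mean
#'
#' The population standard deviation of the collected weights,
#' `S = sqrt(mean((R_i - mean(R_i))^2))`, reported as a relative standard
#' error of the mean: `S / (mean(R_i) * sqrt(n_col))`.
#'
#' @param weights collected photon weights.
#' @param n_col number of collected photons (defaults to
#'   `length(weights)`).
#' @return Relative standard error (dimensionless).
#' @export
mc_uncertainty <- function(weights, n_col = length(weights)) {
  if (n_col < 1 || length(weights) < 1) {
    stop("undefined uncertainty: no collected photons", call. = FALSE)
  }
  m <- mean(weights)
  s_abs <- sqrt(mean((weights - m)^2))
  s_abs / (m * sqrt(n_col))
}

subset_combo <- function(paths, combination) {
  stopifnot(length(combination) == 2)
  r <- paths$records
  r[r$ill == combination[1] & r$det == combination[2], , drop = FALSE]
}

#' Path-length histogram of one fiber combination
#'
#' @param paths a [run_forward()] path set.
#' @param combination length-2 `c(ill, det)` fiber-id pair.
#' @param breaks passed to [graphics::hist()] semantics via [base::cut()]:
#'   either a number of bins or a vector of break points, over the total
#'   (top + deep) in-tissue path length.
#' @param mua_top,mua_deep optional absorption applied as Beer-Lambert
#'   weights before binning.
#' @return List with `breaks`, `mids`, weighted `counts` and a `normalized`
#'   histogram whose maximum bin is 1; `empty = TRUE` (with zero-length
#'   fields) when the combination collected nothing.
#' @export
path_length_histogram <- function(paths, combination, breaks = 30,
                                  mua_top = 0, mua_deep = 0) {
  r <- subset_combo(paths, combination)
  if (nrow(r) == 0) {
    return(list(breaks = numeric(), mids = numeric(), counts = numeric(),
                normalized = numeric(), empty = TRUE))
  }
  len <- r$l_top + r$l_deep
  w <- exp(-mua_top * r$l_top - mua_deep * r$l_deep)
  if (length(breaks) == 1) {
    breaks <- seq(0, max(len) * (1 + 1e-9), length.out = breaks + 1)
  }
  bin <- cut(len, breaks, include.lowest = TRUE, labels = FALSE)
  counts <- vapply(seq_len(length(breaks) - 1),
                   function(b) sum(w[bin == b]), numeric(1))
  list(breaks = breaks, mids = (breaks[-1] + breaks[-length(breaks)]) / 2,
       counts = counts, normalized = counts / max(counts), empty = FALSE)
}

#' Sampled depth zv80 of one fiber combination
#'
#' Weighted 80th percentile of the maximum depth visited by the collected
#' photons: the smallest recorded depth `d` such that at least 80% of the
#' collected weight comes from photons whose maximum depth is `<= d`
#' (weighted type-1 quantile; 80% of the detected visitation happens above
#' `zv80`).
#'
#' @inheritParams path_length_histogram
#' @param prob quantile level (0.8 for zv80).
#' @return Depth in mm.
#' @export
sampled_depth_zv80 <- function(paths, combination, prob = 0.8,
                               mua_top = 0, mua_deep = 0) {
  r <- subset_combo(paths, combination)
  if (nrow(r) == 0) {
    stop("empty combination: no collected photons", call. = FALSE)
  }
  w <- exp(-mua_top * r$l_top - mua_deep * r$l_deep)
  o <- order(r$max_depth)
  d <- r$max_depth[o]
  cw <- cumsum(w[o]) / sum(w)
  d[which(cw >= prob - 1e-12)[1]]
}
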