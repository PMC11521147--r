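#' Relative-difference cost surface over a look-up table
#'
#' For every grid node the cost is the mean over fiber combinations of the
#' weighted relative misfit
#' \deqn{F = \frac{1}{n_c}\sum_c \left|\frac{R_{sim,c} - R_{meas,c}}{R_{sim,c}}\right| \frac{1}{w_{tot,c}},}
#' with unit weights by default (the convention of the geometry-landscape
#' studies) or `1/w_tot` weights for calibrated data. Combinations whose
#' simulated reflectance is zero at a node (empty Monte Carlo bins) are
#' excluded from that node's mean; nodes with no usable combination get
#' `F = Inf`. Both exclusion counts are reported.
#'
#' @param r_meas a [reflectance_set()] covering the LUT's combinations.
#' @param lut a [build_lut()] table.
#' Empty Monte Carlo bins at a node (`R_sim = 0`, possible at small photon
#' budgets) are resolved by support: a combination where both the node and
#' the measurement are zero is uninformative and dropped from that node's
#' mean, while a node predicting zero where signal was measured cannot
#' explain the data and is excluded from the argmin (`F = Inf`), with the
#' count reported. If that strict rule would disqualify every node — as it
#' can for measurements from an independent sparse run — the cost falls
#' back to charging a unit relative misfit for such conflicts, with a
#' message.
#'
#' @param weights `NULL` for unit weights, `"inverse_wtot"` to use
#'   `1/(w_num + w_exp)` from `r_meas`, or a numeric vector (one weight per
#'   combination).
#' @return Object of class `cost_surface`: the grid, the per-node cost `F`,
#'   the minimizer index and value, the `F < 0.1` mask, and exclusion
#'   counts.
#' @export
cost_function <- function(r_meas, lut, weights = NULL) {
  stopifnot(inherits(lut, "reflectance_lut"))
  sig <- attr(r_meas, "probe_signature")
  lsig <- lut$provenance$probe_signature
  if (!is.null(sig) && !isTRUE(lut$provenance$subset) && !identical(sig, lsig)) {
    stop("probe geometry of the measurement does not match the LUT provenance",
         call. = FALSE)
  }
  m <- match(paste(lut$combinations$ill, lut$combinations$det),
             paste(r_meas$ill, r_meas$det))
  if (anyNA(m)) {
    stop("measurement does not cover every LUT combination", call. = FALSE)
  }
  r <- r_meas$R[m]
  nc <- length(r)
  w <- if (is.null(weights)) {
    rep(1, nc)
  } else if (identical(weights, "inverse_wtot")) {
    wt <- w_tot_of(r_meas)[m]
    if (any(wt <= 0)) {
      wt[wt <= 0] <- if (any(wt > 0)) min(wt[wt > 0]) else 1
    }
    1 / wt
  } else {
    stopifnot(is.numeric(weights), length(weights) == nc)
    weights
  }
  cc <- cpp_cost(lut$table, r, w, TRUE)
  if (!any(is.finite(cc$F))) {
    message("no node matches the measurement support; ",
            "falling back to lenient empty-bin handling")
    cc <- cpp_cost(lut$table, r, w, FALSE)
  }
  F <- cc$F
  fin <- is.finite(F)
  if (!any(fin)) stop("cost undefined at every node (empty LUT?)", call. = FALSE)
  imin <- which(fin)[which.min(F[fin])]
  structure(list(grid = lut$grid, F = F, min_index = imin,
                 min_value = F[imin], mask10 = is.finite(F) & F < 0.1,
                 n_partial_nodes = cc$n_partial, n_empty_nodes = cc$n_empty,
                 combinations = lut$combinations, weights = w),
            class = "cost_surface")
}

#' @export
print.cost_surface <- function(x, ...) {
  cat(sprintf(
    "cost surface: %d nodes, min F = %.4g at node %d; %d nodes in F<0.1 region\n",
    length(x$F), x$min_value, x$min_index, sum(x$mask10)))
  invisible(x)
}

#' Exhaustive grid inversion
#'
#' Argmin of [cost_function()] over all LUT nodes. Exact ties are broken
#' deterministically by the smallest linear node index (first axis fastest)
#' and the tie count is reported.
#'
#' @inheritParams cost_function
#' @return Object of class `drs_estimate`: named `values` (the recovered
#'   parameter tuple, always grid values), `cost` at the minimum,
#'   `tie_count`, `index` and the cost surface.
#' @export
grid_invert <- function(r_meas, lut, weights = NULL) {
  cs <- cost_function(r_meas, lut, weights)
  ties <- which(cs$F == cs$min_value)
  idx <- ties[1]
  structure(list(values = node_values(lut$grid, idx), cost = cs$min_value,
                 tie_count = length(ties), index = idx, surface = cs),
            class = "drs_estimate")
}

#' @export
print.drs_estimate <- function(x, ...) {
  cat("grid estimate (cost", format(x$cost, digits = 4))
  if (x$tie_count > 1) cat(",", x$tie_count, "tied nodes")
  cat("):\n")
  print(round(x$values, 6))
  invisible(x)
}

#' Uncertainty propagation through the inverse problem
#'
#' Re-solves the inversion with the measured reflectance scaled to
#' `(1 - w_tot) R` and `(1 + w_tot) R` and reports, per parameter, the
#' min/max envelope of the three solutions.
#'
#' @inheritParams cost_function
#' @param w_tot relative total uncertainty per combination; defaults to
#'   `w_num + w_exp` from `r_meas`. Values `>= 1` trigger a warning and the
#'   negative branch is clipped at zero reflectance.
#' @return List with `values` (central estimate), `bounds_lo`, `bounds_hi`
#'   and the three underlying estimates.
#' @export
propagate_uncertainty <- function(r_meas, lut, w_tot = NULL, weights = NULL) {
  if (is.null(w_tot)) w_tot <- w_tot_of(r_meas)
  w_tot <- rep_len(w_tot, nrow(r_meas))
  if (any(w_tot >= 1)) {
    warning("w_tot >= 1 for some combinations; negative reflectance branch clipped at 0")
  }
  scale_set <- function(s) {
    out <- r_meas
    out$R <- pmax(0, r_meas$R * s)
    out
  }
  e0 <- grid_invert(r_meas, lut, weights)
  elo <- grid_invert(scale_set(1 - w_tot), lut, weights)
  ehi <- grid_invert(scale_set(1 + w_tot), lut, weights)
  vals <- rbind(e0$values, elo$values, ehi$values)
  list(values = e0$values,
       bounds_lo = apply(vals, 2, min), bounds_hi = apply(vals, 2, max),
       estimates = list(central = e0, minus = elo, plus = ehi))
}

#' Per-wavelength spectral inversion
#'
#' Independent grid inversion at each wavelength (no spectral priors); with
#' nearest-node LUT semantics the recovered spectra are stepwise, taking
#' only grid values.
#'
#' @param spectra long-format data frame with columns `lambda`, `ill`,
#'   `det`, `R` and optionally `w_num` / `w_exp`.
#' @inheritParams cost_function
#' @return Data frame with one row per wavelength: `lambda`, the recovered
#'   parameters, `cost` and `tie_count`.
#' @export
spectral_invert <- function(spectra, lut, weights = NULL) {
  stopifnot(all(c("lambda", "ill", "det", "R") %in% names(spectra)))
  lam <- sort(unique(spectra$lambda))
  rows <- lapply(lam, function(l) {
    s <- spectra[spectra$lambda == l, , drop = FALSE]
    est <- tryCatch(grid_invert(new_reflectance_set(s), lut, weights),
                    error = function(e) {
                      stop(sprintf("wavelength %g: %s", l, conditionMessage(e)),
                           call. = FALSE)
                    })
    data.frame(lambda = l, as.list(est$values), cost = est$cost,
               tie_count = est$tie_count)
  })
  do.call(rbind, rows)
}

#' 2D slice of a cost surface with its sub-10% region
#'
#' Fixes all axes except the requested plane at given on-grid values and
#' returns the 2D cost map, the boolean region below the contour threshold
#' and its node-count area (the compactness metric of the fiber-placement
#' and tilt-angle studies).
#'
#' @param surface a [cost_function()] result.
#' @param plane character vector of two distinct axis names.
#' @param fixed named list of values for the remaining axes (snapped to the
#'   nearest node; must be on-grid within tolerance).
#' @param threshold contour level (default 0.1, i.e. 10% mean misfit).
#' @return List with the two axis value vectors, the cost matrix `F`
#'   (rows = first plane axis), the `mask`, the region `area` in nodes and
#'   the threshold.
#' @export
landscape_slices <- function(surface, plane, fixed = list(), threshold = 0.1) {
  stopifnot(inherits(surface, "cost_surface"), length(plane) == 2)
  if (plane[1] == plane[2]) stop("plane axes must differ", call. = FALSE)
  g <- surface$grid
  if (!all(plane %in% names(g$axes))) stop("unknown plane axes", call. = FALSE)
  rest <- setdiff(names(g$axes), plane)
  if (!all(rest %in% names(fixed))) {
    stop("fixed values required for axes: ", paste(rest, collapse = ", "),
         call. = FALSE)
  }
  n <- vapply(g$axes, length, integer(1))
  arr <- array(surface$F, dim = n, dimnames = NULL)
  sub <- as.list(rep(TRUE, length(n)))
  names(sub) <- names(g$axes)
  for (nm in rest) {
    ax <- g$axes[[nm]]
    k <- snap_axis(ax, fixed[[nm]])
    if (abs(ax[k] - fixed[[nm]]) > 1e-9 + 1e-6 * abs(fixed[[nm]])) {
      stop(sprintf("fixed %s = %g is not on the grid", nm, fixed[[nm]]),
           call. = FALSE)
    }
    sub[[nm]] <- k
  }
  sl <- do.call(`[`, c(list(arr), unname(sub), list(drop = FALSE)))
  perm <- match(c(plane, rest), names(g$axes))
  sl <- aperm(sl, perm)
  Fm <- matrix(sl, length(g$axes[[plane[1]]]), length(g$axes[[plane[2]]]))
  mask <- is.finite(Fm) & Fm < threshold
  list(x = g$axes[[plane[1]]], y = g$axes[[plane[2]]], plane = plane,
       F = Fm, mask = mask, area = sum(mask), threshold = threshold)
}
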