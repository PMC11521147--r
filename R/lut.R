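#' Grid specification for a reflectance look-up table
#'
#' Axes must be strictly increasing. A monolayer grid has axes
#' `mus_p, gamma, mua`; a bilayer grid has
#' `mus1, gamma1, mua1, mus2, gamma2, mua2, z` (top layer 1, deep layer 2,
#' interface depth `z` in mm). Nodes are enumerated with the first axis
#' varying fastest (column-major order over the axis list).
#'
#' @param ... named numeric axes, either the monolayer or the bilayer set.
#' @return Object of class `grid_spec` with fields `axes` and `kind`.
#' @examples
#' grid_spec(mus_p = c(0.5, 2), gamma = c(1.1, 1.5), mua = c(0, 0.1, 0.2))
#' @export
grid_spec <- function(...) {
  axes <- list(...)
  mono <- c("mus_p", "gamma", "mua")
  bi <- c("mus1", "gamma1", "mua1", "mus2", "gamma2", "mua2", "z")
  kind <- if (identical(sort(names(axes)), sort(mono))) "monolayer"
          else if (identical(sort(names(axes)), sort(bi))) "bilayer"
          else stop("axes must be {", paste(mono, collapse = ", "), "} or {",
                    paste(bi, collapse = ", "), "}", call. = FALSE)
  axes <- axes[if (kind == "monolayer") mono else bi]
  for (nm in names(axes)) {
    v <- as.numeric(axes[[nm]])
    if (length(v) < 1 || any(diff(v) <= 0)) {
      stop("axis ", nm, " must be strictly increasing", call. = FALSE)
    }
    axes[[nm]] <- v
  }
  structure(list(axes = axes, kind = kind), class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("%s grid, %d nodes:\n", x$kind, n_nodes(x)))
  for (nm in names(x$axes)) {
    v <- x$axes[[nm]]
    cat(sprintf("  %-6s %2d values in [%g, %g]\n", nm, length(v), min(v), max(v)))
  }
  invisible(x)
}

n_nodes <- function(grid) prod(vapply(grid$axes, length, integer(1)))

#' Desk-scale bilayer grid
#'
#' Reduced bilayer grid used by the packaged characterization studies:
#' 3 reduced-scattering and 3 gamma values per layer, 8 absorption values in
#' \[0, 0.2\]/mm per layer and 5 interface depths covering 0.2-1.0 mm. The
#' scattering/depth sub-grid implies `3*3*3*3*5 = 405` Monte Carlo runs; the
#' absorption axes are filled by reweighting.
#'
#' @return A bilayer [grid_spec()].
#' @export
desk_bilayer_grid <- function() {
  mus <- c(0.25, 1.0, 2.0)
  gam <- c(1.0, 1.45, 1.9)
  mua <- seq(0, 0.2, length.out = 8)
  grid_spec(mus1 = mus, gamma1 = gam, mua1 = mua,
            mus2 = mus, gamma2 = gam, mua2 = mua,
            z = c(0.2, 0.4, 0.6, 0.8, 1.0))
}

#' Desk-scale monolayer grid
#'
#' @param mus_p,gamma,mua axis values; defaults give a small grid containing
#'   the reference homogeneous-tissue triplet (2/mm, 1.5, 0.2/mm).
#' @return A monolayer [grid_spec()].
#' @export
desk_monolayer_grid <- function(mus_p = c(0.5, 1.25, 2.0, 2.75),
                                gamma = c(1.1, 1.3, 1.5, 1.7),
                                mua = c(0, 0.2, 0.4, 0.6, 0.8, 1.0)) {
  grid_spec(mus_p = mus_p, gamma = gamma, mua = mua)
}

#' Full-scale grids
#'
#' `fullscale_bilayer_grid()`: 10 reduced-scattering values in \[0.25, 3\]/mm,
#' 10 gamma values, 20 absorption values in \[0, 0.2\]/mm per layer and 15
#' interface depths in \[0.1, 1.5\] mm (about 150,000 Monte Carlo runs -- a
#' cluster-scale job). `fullscale_monolayer_grid()`: 40 points per axis over
#' \[0.5, 3\]/mm, \[1, 2\] and \[0, 1\]/mm. The gamma axes are clipped to 1.9,
#' the top of the feasible range of the modified-HG family at `g1 = 0.9`.
#'
#' @return A [grid_spec()].
#' @export
fullscale_bilayer_grid <- function() {
  mus <- seq(0.25, 3, length.out = 10)
  gam <- seq(1.0, 1.9, length.out = 10)
  mua <- seq(0, 0.2, length.out = 20)
  grid_spec(mus1 = mus, gamma1 = gam, mua1 = mua,
            mus2 = mus, gamma2 = gam, mua2 = mua,
            z = seq(0.1, 1.5, length.out = 15))
}

#' @rdname fullscale_bilayer_grid
#' @export
fullscale_monolayer_grid <- function() {
  grid_spec(mus_p = seq(0.5, 3, length.out = 40),
            gamma = seq(1.0, 1.9, length.out = 40),
            mua = seq(0, 1, length.out = 40))
}

# linear (1-based) node index from 1-based per-axis subscripts
node_index <- function(grid, sub) {
  n <- vapply(grid$axes, length, integer(1))
  stride <- cumprod(c(1, n[-length(n)]))
  as.integer(1 + sum((sub - 1) * stride))
}

# named node values at a 1-based linear index
node_values <- function(grid, idx) {
  n <- vapply(grid$axes, length, integer(1))
  i <- idx - 1L
  out <- numeric(length(n))
  for (k in seq_along(n)) {
    out[k] <- grid$axes[[k]][(i %% n[k]) + 1]
    i <- i %/% n[k]
  }
  names(out) <- names(grid$axes)
  out
}

snap_axis <- function(values, x) {
  d <- abs(values - x)
  which(d == min(d))[1] # ties -> lower value
}

# default engine cutoffs for LUT building: scaled with the transport mean
# free path of the least-scattering layer, clamped to the transport defaults
lut_cutoffs <- function(mus_min) {
  c(max_path = min(200, max(25, 25 / mus_min)),
    max_lateral = min(15, max(5, 12 / mus_min)))
}

#' Build a reflectance look-up table by white Monte Carlo
#'
#' One [run_forward()] per node of the scattering (x depth) sub-grid; the
#' absorption axes are filled by Beer-Lambert reweighting of the stored
#' per-layer path lengths ([apply_absorption()] semantics), never by fresh
#' simulation. A monolayer grid needs `n_mus * n_gamma` runs; a bilayer grid
#' `n_mus1 * n_gamma1 * n_mus2 * n_gamma2 * n_z`.
#'
#' @param grid a [grid_spec()].
#' @param probe a [build_probe()] geometry.
#' @param n_photons photons per node, split evenly across the probe's
#'   illumination fibers.
#' @param seed master seed; each node uses a derived sub-seed, so the table
#'   is reproducible node by node.
#' @param g1 phase-function first moment (configuration constant).
#' @param n_tissue refractive index used for both layers.
#' @param oil_thickness,oil_n scattering-free surface film (0 disables).
#' @param n_above index above the surface outside the fiber faces.
#' @param max_path,max_lateral engine cutoffs in mm; `NULL` (default) picks
#'   per-node values scaled with the transport mean free path (see the
#'   methods vignette), capped at the transport defaults 200 and 15 mm.
#' @param progress print one line per scattering node.
#' @return Object of class `reflectance_lut`: `grid`, `table` and `wnum`
#'   matrices (`n_nodes x n_combinations`), the probe `combinations`, and
#'   `provenance` (seed, photons per node, probe signature, engine settings,
#'   MC run count, schema version).
#' @export
build_lut <- function(grid, probe, n_photons = 1e5, seed = 1L, g1 = 0.9,
                      n_tissue = 1.43, oil_thickness = 0.05, oil_n = 1.45,
                      n_above = 1.0, max_path = NULL, max_lateral = NULL,
                      progress = FALSE) {
  stopifnot(inherits(grid, "grid_spec"), inherits(probe, "probe_geometry"))
  ax <- grid$axes
  gam_all <- if (grid$kind == "monolayer") ax$gamma else c(ax$gamma1, ax$gamma2)
  for (gm in gam_all) {
    ok <- tryCatch({ solve_phase_params(g1, gm); TRUE }, error = function(e) e)
    if (!isTRUE(ok)) {
      stop(sprintf("infeasible grid point gamma = %g at g1 = %g: %s",
                   gm, g1, conditionMessage(ok)), call. = FALSE)
    }
  }
  n_ill <- sum(probe$fibers$role == "illumination" &
                 !(probe$fibers$key %in% probe$excluded))
  per_fiber <- as.integer(ceiling(n_photons / n_ill))
  nc <- nrow(probe$combinations)
  nn <- n_nodes(grid)
  tab <- matrix(NA_real_, nn, nc)
  wnm <- matrix(NA_real_, nn, nc)

  node_seed <- function(i) (as.double(seed) * 1000003 + i * 7919) %% 2147483629

  run_node <- function(medium, mus_min, i_run) {
    cuts <- lut_cutoffs(mus_min)
    mp <- max_path %||% cuts[["max_path"]]
    ml <- max_lateral %||% cuts[["max_lateral"]]
    run_forward(medium, probe, per_fiber, seed = node_seed(i_run), g1 = g1,
                max_path = mp, max_lateral = ml)
  }

  i_run <- 0L
  if (grid$kind == "monolayer") {
    n1 <- length(ax$mus_p); n2 <- length(ax$gamma); na <- length(ax$mua)
    for (j2 in seq_len(n2)) for (j1 in seq_len(n1)) {
      i_run <- i_run + 1L
      props <- optical_properties(ax$mus_p[j1], ax$gamma[j2], 0, n_tissue)
      med <- layered_medium(props, props, z_top = 0.5,
                            oil_thickness = oil_thickness, oil_n = oil_n,
                            n_above = n_above)
      ps <- run_node(med, ax$mus_p[j1], i_run)
      rw <- cpp_reweight(ps$records$l_top + ps$records$l_deep,
                         numeric(nrow(ps$records)),
                         as.integer(combo_index(ps) - 1L), nc,
                         ax$mua, 0, ps$n_photons)
      rows <- (j1 - 1) + n1 * (j2 - 1) + n1 * n2 * (seq_len(na) - 1) + 1
      tab[rows, ] <- rw$R
      wnm[rows, ] <- rw$wnum
      if (progress) {
        message(sprintf("node %d/%d (mus_p=%g gamma=%g): %d collected",
                        i_run, n1 * n2, ax$mus_p[j1], ax$gamma[j2],
                        nrow(ps$records)))
      }
    }
  } else {
    n1 <- length(ax$mus1); n2 <- length(ax$gamma1); na1 <- length(ax$mua1)
    n4 <- length(ax$mus2); n5 <- length(ax$gamma2); na2 <- length(ax$mua2)
    nz <- length(ax$z)
    s3 <- n1 * n2                 # stride of mua1
    s6 <- n1 * n2 * na1 * n4 * n5 # stride of mua2
    n_scat <- n1 * n2 * n4 * n5 * nz
    for (jz in seq_len(nz)) for (j5 in seq_len(n5)) for (j4 in seq_len(n4))
      for (j2 in seq_len(n2)) for (j1 in seq_len(n1)) {
        i_run <- i_run + 1L
        top <- optical_properties(ax$mus1[j1], ax$gamma1[j2], 0, n_tissue)
        deep <- optical_properties(ax$mus2[j4], ax$gamma2[j5], 0, n_tissue)
        med <- layered_medium(top, deep, z_top = ax$z[jz],
                              oil_thickness = oil_thickness, oil_n = oil_n,
                              n_above = n_above)
        ps <- run_node(med, min(ax$mus1[j1], ax$mus2[j4]), i_run)
        rw <- cpp_reweight(ps$records$l_top, ps$records$l_deep,
                           as.integer(combo_index(ps) - 1L), nc,
                           ax$mua1, ax$mua2, ps$n_photons)
        base <- (j1 - 1) + n1 * (j2 - 1) + s3 * na1 * ((j4 - 1) + n4 * (j5 - 1)) +
          s6 * na2 * (jz - 1)
        rows <- base + as.vector(outer(s3 * (seq_len(na1) - 1),
                                       s6 * (seq_len(na2) - 1), "+")) + 1
        tab[rows, ] <- rw$R
        wnm[rows, ] <- rw$wnum
        if (progress && i_run %% 25 == 0) {
          message(sprintf("node %d/%d", i_run, n_scat))
        }
      }
  }

  structure(list(
    grid = grid, table = tab, wnum = wnm,
    combinations = probe$combinations,
    provenance = list(
      seed = seed, n_photons_node = n_photons, per_fiber = per_fiber,
      g1 = g1, n_tissue = n_tissue, oil_thickness = oil_thickness,
      oil_n = oil_n, n_above = n_above,
      probe_signature = probe_signature(probe),
      engine = list(max_path = max_path, max_lateral = max_lateral,
                    auto_cutoffs = is.null(max_path) || is.null(max_lateral)),
      n_mc_runs = i_run, version = 1L)),
    class = "reflectance_lut")
}

#' @export
print.reflectance_lut <- function(x, ...) {
  cat(sprintf(
    "reflectance LUT (%s): %d nodes x %d combinations, %d MC runs, %g photons/node\n",
    x$grid$kind, nrow(x$table), ncol(x$table), x$provenance$n_mc_runs,
    x$provenance$n_photons_node))
  invisible(x)
}

#' Query a look-up table at a parameter tuple
#'
#' Nearest-node semantics: each coordinate snaps to the closest axis value
#' (ties to the lower value); no interpolation, mirroring the stepwise
#' spectra that grid inversion produces. Out-of-range coordinates are an
#' error.
#'
#' @param lut a [build_lut()] table.
#' @param pars named vector/list of parameter values (the grid's axis names),
#'   or a single integer node index.
#' @return List with `R` (per-combination reflectance), `w_num`, the snapped
#'   `node` values, the linear `index`, and `snap_distance` per axis.
#' @export
lut_query <- function(lut, pars) {
  stopifnot(inherits(lut, "reflectance_lut"))
  g <- lut$grid
  if (is.numeric(pars) && length(pars) == 1 && is.null(names(pars))) {
    idx <- as.integer(pars)
    if (idx < 1 || idx > nrow(lut$table)) stop("node index out of range", call. = FALSE)
    nv <- node_values(g, idx)
    snap <- setNames(rep(0, length(nv)), names(nv))
  } else {
    pars <- unlist(pars)
    if (!all(names(g$axes) %in% names(pars))) {
      stop("pars must name every grid axis: ",
           paste(names(g$axes), collapse = ", "), call. = FALSE)
    }
    sub <- integer(length(g$axes))
    for (k in seq_along(g$axes)) {
      ax <- g$axes[[k]]
      x <- pars[[names(g$axes)[k]]]
      if (x < min(ax) - 1e-9 || x > max(ax) + 1e-9) {
        stop(sprintf("%s = %g outside grid range [%g, %g]",
                     names(g$axes)[k], x, min(ax), max(ax)), call. = FALSE)
      }
      sub[k] <- snap_axis(ax, x)
    }
    idx <- node_index(g, sub)
    nv <- node_values(g, idx)
    snap <- abs(nv - pars[names(nv)])
  }
  list(R = lut$table[idx, ], w_num = lut$wnum[idx, ], node = nv,
       index = idx, snap_distance = snap)
}

#' Reflectance set at a LUT node
#'
#' Convenience wrapper around [lut_query()] returning a
#' [reflectance_set()] (the synthetic-measurement generator in
#' solver-self-consistency mode).
#'
#' @inheritParams lut_query
#' @return A `reflectance_set` with the node's `R` and `w_num`.
#' @export
lut_reflectance <- function(lut, pars) {
  q <- lut_query(lut, pars)
  out <- lut$combinations
  out$R <- as.numeric(q$R)
  out$w_num <- as.numeric(q$w_num)
  new_reflectance_set(out, node = q$node, index = q$index, source = "lut",
                      probe_signature = lut$provenance$probe_signature)
}

#' Restrict a LUT to a subset of fiber combinations
#'
#' @param lut a `reflectance_lut`.
#' @param keep logical or integer index over the LUT's combination rows, or a
#'   data frame with `ill`/`det` columns.
#' @return A `reflectance_lut` with the selected combination columns; the
#'   probe signature is retained, with a subset marker.
#' @export
lut_subset <- function(lut, keep) {
  stopifnot(inherits(lut, "reflectance_lut"))
  if (is.data.frame(keep)) {
    keep <- match(paste(keep$ill, keep$det),
                  paste(lut$combinations$ill, lut$combinations$det))
    if (anyNA(keep)) stop("unknown combinations in subset", call. = FALSE)
  }
  lut$table <- lut$table[, keep, drop = FALSE]
  lut$wnum <- lut$wnum[, keep, drop = FALSE]
  lut$combinations <- lut$combinations[keep, , drop = FALSE]
  lut$provenance$subset <- TRUE
  lut
}

#' Write / read a look-up table
#'
#' The on-disk container is a versioned R serialization holding the grid,
#' the reflectance and uncertainty tables and the full provenance record;
#' reading validates the format tag and schema version and fails loudly on
#' truncated or foreign files.
#'
#' @param lut a `reflectance_lut`.
#' @param path file path (conventionally `.lut.rds`).
#' @return `lut_write` returns `path` invisibly; `lut_read` the
#'   `reflectance_lut`.
#' @export
lut_write <- function(lut, path) {
  stopifnot(inherits(lut, "reflectance_lut"))
  saveRDS(list(format = "subdrs_lut", version = 1L, payload = lut), path)
  invisible(path)
}

#' @rdname lut_write
#' @export
lut_read <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop("not a readable LUT container (truncated or foreign file): ",
         conditionMessage(e), call. = FALSE)
  })
  if (!is.list(obj) || !identical(obj$format, "subdrs_lut")) {
    stop("not a subdrs LUT container", call. = FALSE)
  }
  if (!identical(obj$version, 1L)) {
    stop("unsupported LUT schema version: ", obj$version, call. = FALSE)
  }
  obj$payload
}
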