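#' Added photon tilt from beveling a tilted fiber
#'
#' A fiber tilted by `beta` from the surface normal is beveled at the same
#' angle so its face sits flush with the probe tip. Refraction at the beveled
#' face increases the effective tilt of the launched (or accepted) photons by
#' \deqn{\gamma_B = \sin^{-1}(n_f \sin\beta / n_{ext}) - \beta,}
#' where `n_f` is the fiber core index and `n_ext` the index of the medium in
#' contact with the face (`n_ext = 1`, air, reproduces the textbook formula).
#' When the probe sits in optical contact with an immersion-oil film,
#' `n_ext` is the oil index and the bevel contribution nearly vanishes.
#'
#' @param tilt_deg fiber tilt angle `beta` from the surface normal, degrees.
#' @param n_fiber fiber core refractive index.
#' @param n_ext refractive index of the medium behind the beveled face.
#' @return Added angle `gamma_B` in degrees; the effective photon tilt is
#'   `tilt_deg + gamma_B`.
#' @examples
#' effective_bevel_angle(30, 1.43) # about 15.7 degrees into air
#' effective_bevel_angle(30, 1.43, n_ext = 1.45) # in oil contact: near zero
#' @export
effective_bevel_angle <- function(tilt_deg, n_fiber, n_ext = 1.0) {
  stopifnot(tilt_deg >= 0, tilt_deg < 90, n_fiber > 0, n_ext > 0)
  s <- n_fiber * sin(tilt_deg * pi / 180) / n_ext
  if (s > 1) {
    stop(sprintf(
      "total internal reflection: n_fiber sin(beta)/n_ext = %.4f > 1", s),
      call. = FALSE)
  }
  asin(s) * 180 / pi - tilt_deg
}

#' Default 16-fiber probe layout
#'
#' Eight illumination and eight detection fibers on circles of 0.8 and 1.5 mm
#' radius. Inner-circle fibers are perpendicular; outer-circle fibers are
#' tilted inward with tilts drawn from 30, 45 and 60 degrees, and every
#' tilted fiber is beveled at its tilt angle. One close illumination/detection
#' pair on the inner circle gives the shortest source-detector separation
#' (about 0.1 mm) and near-opposite outer fibers reach about 3 mm. Fibers are
#' 0.1 mm in diameter with NA 0.22 and core index 1.43. The exact azimuths are
#' a documented package choice satisfying these constraints; any alternative
#' layout can be supplied as a config list or YAML file to [build_probe()].
#'
#' @return A probe config list understood by [build_probe()].
#' @export
default_probe_config <- function() {
  fib <- function(id, role, r, az, tilt) {
    list(id = id, role = role, radius_mm = r, azimuth_deg = az,
         tilt_deg = tilt, axis_azimuth_deg = (az + 180) %% 360,
         diameter_mm = 0.1, na = 0.22, n_fiber = 1.43)
  }
  list(
    tip_radius_mm = 1.6,
    excluded = character(),
    fibers = list(
      # inner circle, perpendicular
      fib(1L, "illumination", 0.8, 0, 0),
      fib(2L, "illumination", 0.8, 90, 0),
      fib(3L, "illumination", 0.8, 180, 0),
      fib(4L, "illumination", 0.8, 270, 0),
      fib(1L, "detection", 0.8, 7.5, 0),
      fib(2L, "detection", 0.8, 120, 0),
      fib(3L, "detection", 0.8, 225, 0),
      fib(4L, "detection", 0.8, 315, 0),
      # outer circle, tilted inward
      fib(5L, "illumination", 1.5, 30, 30),
      fib(6L, "illumination", 1.5, 150, 45),
      fib(7L, "illumination", 1.5, 240, 60),
      fib(8L, "illumination", 1.5, 330, 30),
      fib(5L, "detection", 1.5, 60, 45),
      fib(6L, "detection", 1.5, 165, 60),
      fib(7L, "detection", 1.5, 255, 30),
      fib(8L, "detection", 1.5, 345, 60)
    )
  )
}

face_semiaxes <- function(diameter_mm, tilt_deg) {
  a <- diameter_mm / 2
  c(a = a, b = a / cos(tilt_deg * pi / 180))
}

#' Build a probe geometry from a config
#'
#' @param config a config list (see [default_probe_config()]) or the path to
#'   a YAML file with the same structure: `tip_radius_mm`, optional `excluded`
#'   (entries like `"det:3"` or `"ill:2"`), and `fibers`, each with `id`,
#'   `role` (`"illumination"`/`"detection"`, abbreviations allowed),
#'   `radius_mm`, `azimuth_deg`, `tilt_deg`, optional `axis_azimuth_deg`
#'   (defaults to pointing inward), `diameter_mm`, `na`, `n_fiber`.
#' @param check_overlap error when fiber faces overlap (bounding-ellipse
#'   test). Disable only for idealized numerical-study layouts where faces
#'   may touch or share space (physical probes need disjoint faces).
#' @return An object of class `probe_geometry`: a list with a `fibers` data
#'   frame (positions on the probe face in mm, z down into the medium), the
#'   enumerated illumination x detection `combinations` with their
#'   source-detector separations, the excluded fiber keys and the tip radius.
#' @examples
#' pr <- build_probe(default_probe_config())
#' nrow(pr$combinations) # 64
#' @export
build_probe <- function(config = default_probe_config(), check_overlap = TRUE) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config), !is.null(config$fibers))
  tip <- config$tip_radius_mm %||% 1.6
  excluded <- as.character(config$excluded %||% character())

  rows <- lapply(config$fibers, function(f) {
    role <- match.arg(f$role, c("illumination", "detection"))
    az <- f$azimuth_deg
    tilt <- f$tilt_deg %||% 0
    if (tilt < 0 || tilt >= 90) stop("tilt_deg must be in [0, 90)", call. = FALSE)
    d <- f$diameter_mm %||% 0.1
    if (d <= 0) stop("diameter_mm must be positive", call. = FALSE)
    na <- f$na %||% 0.22
    if (na <= 0 || na >= 1) stop("na must be in (0, 1)", call. = FALSE)
    data.frame(
      id = as.integer(f$id), role = role,
      radius_mm = f$radius_mm, azimuth_deg = az, tilt_deg = tilt,
      axis_azimuth_deg = f$axis_azimuth_deg %||% ((az + 180) %% 360),
      diameter_mm = d, na = na, n_fiber = f$n_fiber %||% 1.43,
      x = f$radius_mm * cos(az * pi / 180),
      y = f$radius_mm * sin(az * pi / 180)
    )
  })
  fibers <- do.call(rbind, rows)
  fibers$key <- paste0(substr(fibers$role, 1, 3), ":", fibers$id)
  if (anyDuplicated(fibers$key)) {
    stop("duplicated fiber (role, id) pairs in config", call. = FALSE)
  }

  # geometric validation: faces inside the tip disc and no face overlap
  semi <- t(vapply(seq_len(nrow(fibers)), function(i) {
    face_semiaxes(fibers$diameter_mm[i], fibers$tilt_deg[i])
  }, numeric(2)))
  reach <- sqrt(fibers$x^2 + fibers$y^2) + semi[, "b"]
  if (any(reach > tip + 1e-9)) {
    bad <- fibers$key[which.max(reach)]
    stop(sprintf("fiber face %s extends outside the %.2f mm tip disc",
                 bad, tip), call. = FALSE)
  }
  n <- nrow(fibers)
  if (check_overlap) for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dd <- sqrt((fibers$x[i] - fibers$x[j])^2 + (fibers$y[i] - fibers$y[j])^2)
      if (dd < semi[i, "b"] + semi[j, "b"] - 1e-9) {
        stop(sprintf("fiber faces %s and %s overlap", fibers$key[i],
                     fibers$key[j]), call. = FALSE)
      }
    }
  }

  keep <- !(fibers$key %in% excluded)
  ill <- fibers[fibers$role == "illumination" & keep, ]
  det <- fibers[fibers$role == "detection" & keep, ]
  if (nrow(ill) == 0 || nrow(det) == 0) {
    stop("probe needs at least one illumination and one detection fiber",
         call. = FALSE)
  }
  combos <- expand.grid(det = det$id, ill = ill$id, KEEP.OUT.ATTRS = FALSE)
  combos <- combos[, c("ill", "det")]
  ix <- match(combos$ill, ill$id)
  dx <- match(combos$det, det$id)
  combos$sds <- sqrt((ill$x[ix] - det$x[dx])^2 + (ill$y[ix] - det$y[dx])^2)
  rownames(combos) <- NULL

  structure(list(fibers = fibers, combinations = combos,
                 excluded = excluded, tip_radius_mm = tip),
            class = "probe_geometry")
}

#' @export
print.probe_geometry <- function(x, ...) {
  cat(sprintf(
    "probe: %d illumination + %d detection fibers, %d combinations (SDS %.2f-%.2f mm)\n",
    sum(x$fibers$role == "illumination"), sum(x$fibers$role == "detection"),
    nrow(x$combinations), min(x$combinations$sds), max(x$combinations$sds)))
  if (length(x$excluded)) cat("excluded:", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

probe_fibers <- function(probe, role) {
  probe$fibers[probe$fibers$role == role &
                 !(probe$fibers$key %in% probe$excluded), , drop = FALSE]
}

# Effective photon tilt (tilt + bevel refraction into the contact medium),
# radians. n_contact is the index of the layer touching the probe face.
effective_tilt_rad <- function(tilt_deg, n_fiber, n_contact) {
  gb <- effective_bevel_angle(tilt_deg, n_fiber, n_ext = n_contact)
  (tilt_deg + gb) * pi / 180
}

# One row per fiber for the transport engine:
# cx, cy, tx, ty, sin_beff, cos_beff, a, b, cos_cone, n_fiber
face_matrix <- function(fdf, n_contact) {
  m <- matrix(0, nrow(fdf), 10)
  for (i in seq_len(nrow(fdf))) {
    beff <- effective_tilt_rad(fdf$tilt_deg[i], fdf$n_fiber[i], n_contact)
    phi <- fdf$axis_azimuth_deg[i] * pi / 180
    sa <- face_semiaxes(fdf$diameter_mm[i], fdf$tilt_deg[i])
    cone <- asin(min(1, fdf$na[i] / n_contact))
    m[i, ] <- c(fdf$x[i], fdf$y[i], cos(phi), sin(phi), sin(beff), cos(beff),
                sa[["a"]], sa[["b"]], cos(cone), fdf$n_fiber[i])
  }
  colnames(m) <- c("cx", "cy", "tx", "ty", "sinb", "cosb", "a", "b",
                   "ccone", "nf")
  m
}

# compact geometry signature used as the LUT provenance guard
probe_signature <- function(probe) {
  f <- probe$fibers
  paste(c(sprintf("%.9g", c(f$x, f$y, f$tilt_deg, f$axis_azimuth_deg,
                            f$diameter_mm, f$na, f$n_fiber)),
          f$role, f$id, probe$excluded), collapse = "|")
}

#' Sample photon launches from an illumination fiber
#'
#' Positions are uniform over the beveled elliptical footprint; directions are
#' uniform in solid angle inside the in-medium acceptance cone (half-angle
#' `asin(NA / n_medium)`) around the effective (tilt + bevel) fiber axis.
#' This mirrors the source model used inside the transport engine.
#'
#' @param probe a `probe_geometry`.
#' @param id illumination fiber id.
#' @param n number of launches.
#' @param n_medium refractive index of the medium in contact with the face.
#' @param seed seed for the draw.
#' @return List with an `n x 2` `position` matrix (mm) and an `n x 3`
#'   `direction` matrix of unit vectors (z down into the medium).
#' @export
sample_launch <- function(probe, id, n, n_medium = 1.43, seed = 1L) {
  f <- probe_fibers(probe, "illumination")
  f <- f[f$id == id, , drop = FALSE]
  if (nrow(f) != 1) stop("unknown illumination fiber id", call. = FALSE)
  fm <- face_matrix(f, n_medium)[1, ]
  set.seed(seed)
  r <- sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  al <- fm[["b"]] * r * cos(th)
  ap <- fm[["a"]] * r * sin(th)
  pos <- cbind(x = fm[["cx"]] + al * fm[["tx"]] - ap * fm[["ty"]],
               y = fm[["cy"]] + al * fm[["ty"]] + ap * fm[["tx"]])
  axis <- c(fm[["sinb"]] * fm[["tx"]], fm[["sinb"]] * fm[["ty"]], fm[["cosb"]])
  if (fm[["sinb"]] < 1e-12) {
    e1 <- c(1, 0, 0); e2 <- c(0, 1, 0)
  } else {
    e1 <- c(axis[2], -axis[1], 0) / sqrt(sum(axis[1:2]^2))
    e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
            axis[3] * e1[1] - axis[1] * e1[3],
            axis[1] * e1[2] - axis[2] * e1[1])
  }
  cd <- 1 - stats::runif(n) * (1 - fm[["ccone"]])
  sdv <- sqrt(pmax(0, 1 - cd^2))
  psi <- stats::runif(n, 0, 2 * pi)
  dir <- cbind(cd * axis[1] + sdv * (cos(psi) * e1[1] + sin(psi) * e2[1]),
               cd * axis[2] + sdv * (cos(psi) * e1[2] + sin(psi) * e2[2]),
               cd * axis[3] + sdv * (cos(psi) * e1[3] + sin(psi) * e2[3]))
  colnames(dir) <- c("ux", "uy", "uz")
  list(position = pos, direction = dir)
}

#' Detection-fiber acceptance test
#'
#' A photon exiting the top surface is accepted when its exit point lies
#' inside the fiber-face footprint and the angle between its (in-medium) exit
#' direction and the fiber's effective acceptance axis is within the
#' acceptance cone `asin(NA / n_medium)`.
#'
#' @param probe a `probe_geometry`.
#' @param id detection fiber id.
#' @param exit_position length-2 (x, y) exit point on the surface, mm.
#' @param exit_direction length-3 unit direction of the exiting photon
#'   (z down, so an exiting photon has negative z-component).
#' @param n_medium refractive index of the medium at the surface.
#' @return `TRUE` if the photon is collected.
#' @export
accept <- function(probe, id, exit_position, exit_direction,
                   n_medium = 1.43) {
  f <- probe_fibers(probe, "detection")
  f <- f[f$id == id, , drop = FALSE]
  if (nrow(f) != 1) stop("unknown detection fiber id", call. = FALSE)
  fm <- face_matrix(f, n_medium)[1, ]
  dx <- exit_position[1] - fm[["cx"]]
  dy <- exit_position[2] - fm[["cy"]]
  al <- dx * fm[["tx"]] + dy * fm[["ty"]]
  ap <- -dx * fm[["ty"]] + dy * fm[["tx"]]
  inside <- (al / fm[["b"]])^2 + (ap / fm[["a"]])^2 <= 1 + 1e-12
  if (!inside) return(FALSE)
  axis <- c(fm[["sinb"]] * fm[["tx"]], fm[["sinb"]] * fm[["ty"]], fm[["cosb"]])
  dt <- -sum(exit_direction * axis)
  dt >= fm[["ccone"]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
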