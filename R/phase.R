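#' Two-parameter scattering phase function (modified Henyey-Greenstein)
#'
#' The package models single scattering with a mixture of a Henyey-Greenstein
#' (HG) term and a Rayleigh-like cos^2 term,
#' \deqn{p(\mu) = \beta\, p_{HG}(\mu; g) + (1-\beta)\, \tfrac{3}{2}\mu^2 / 2,}
#' normalised over \eqn{\mu = \cos\theta \in [-1, 1]}. Its first two Legendre
#' moments are closed-form, \eqn{g_1 = \beta g} and
#' \eqn{g_2 = \beta g^2 + (1-\beta)\,2/5}, so the sub-diffusive similarity
#' parameter \eqn{\gamma = (1-g_2)/(1-g_1)} can be dialled exactly. Any other
#' two-moment family could be substituted as long as it supplies moments and
#' an exact sampler.
#'
#' @param g_hg HG anisotropy, in (-1, 1).
#' @param beta_mix mixture weight of the HG component, in \[0, 1\].
#' @return An object of class `phase_params`.
#' @examples
#' p <- phase_params(0.9301, 0.9676)
#' mhg_moments(p)
#' @export
phase_params <- function(g_hg, beta_mix) {
  stopifnot(is.numeric(g_hg), length(g_hg) == 1L,
            is.numeric(beta_mix), length(beta_mix) == 1L)
  if (g_hg <= -1 || g_hg >= 1) {
    stop("g_hg must lie in (-1, 1)", call. = FALSE)
  }
  if (beta_mix < 0 || beta_mix > 1) {
    stop("beta_mix must lie in [0, 1]", call. = FALSE)
  }
  structure(list(g_hg = g_hg, beta_mix = beta_mix), class = "phase_params")
}

#' @export
print.phase_params <- function(x, ...) {
  m <- mhg_moments(x)
  cat(sprintf(
    "modified HG phase function: g = %.4f, beta = %.4f (g1 = %.4f, g2 = %.4f, gamma = %.4f)\n",
    x$g_hg, x$beta_mix, m[["g1"]], m[["g2"]], m[["gamma"]]))
  invisible(x)
}

#' Legendre moments and similarity parameter of a phase function
#'
#' @param params a [phase_params()] object.
#' @return Named numeric vector with `g1`, `g2` and `gamma`, where
#'   `gamma = (1 - g2) / (1 - g1)`.
#' @export
mhg_moments <- function(params) {
  stopifnot(inherits(params, "phase_params"))
  g <- params$g_hg
  b <- params$beta_mix
  g1 <- b * g
  g2 <- b * g^2 + (1 - b) * 2 / 5
  if (g1 >= 1 - 1e-12) {
    stop("degenerate forward scattering: g1 = 1", call. = FALSE)
  }
  c(g1 = g1, g2 = g2, gamma = (1 - g2) / (1 - g1))
}

#' Attainable gamma range of the mixture family at a given g1
#'
#' At fixed first moment `g1 > 0` the mixture weight can range over
#' `(g1, 1]` (the HG anisotropy `g = g1 / beta` must stay below 1), which maps
#' to `gamma` between 0.6 (exclusive) and `1 + g1`.
#'
#' @param g1 target first Legendre moment.
#' @return Numeric vector `c(lo, hi)` of attainable `gamma` values.
#' @export
gamma_range <- function(g1) {
  stopifnot(g1 > 0, g1 < 1)
  c(lo = 0.6, hi = 1 + g1)
}

#' Solve for mixture parameters that reproduce (g1, gamma)
#'
#' Inverts the closed-form moments: with `g2 = 1 - gamma (1 - g1)` the mixture
#' weight solves the quadratic `(2/5) beta^2 + (g2 - 2/5) beta - g1^2 = 0`
#' (positive root) and `g = g1 / beta`.
#'
#' @param g1_target first Legendre moment of the returned phase function.
#' @param gamma_target similarity parameter `(1 - g2)/(1 - g1)`.
#' @return A [phase_params()] object whose [mhg_moments()] reproduce the
#'   targets to better than 1e-10.
#' @examples
#' solve_phase_params(0.9, 1.5)
#' @export
solve_phase_params <- function(g1_target, gamma_target) {
  stopifnot(is.numeric(g1_target), is.numeric(gamma_target))
  if (g1_target <= -1 || g1_target >= 1) {
    stop("g1_target must lie in (-1, 1)", call. = FALSE)
  }
  g2 <- 1 - gamma_target * (1 - g1_target)
  if (abs(g1_target) < 1e-14) {
    # pure cos^2 component is the only member with g1 = 0 (gamma = 0.6)
    if (abs(g2 - 2 / 5) > 1e-10) {
      stop("infeasible (g1, gamma): at g1 = 0 only gamma = 0.6 is attainable",
           call. = FALSE)
    }
    return(phase_params(0, 0))
  }
  a <- 2 / 5
  bq <- g2 - 2 / 5
  cq <- -g1_target^2
  disc <- bq^2 - 4 * a * cq
  beta <- (-bq + sqrt(disc)) / (2 * a)
  g <- g1_target / beta
  rng <- gamma_range(abs(g1_target))
  if (beta <= 0 || beta > 1 + 1e-12 || abs(g) >= 1) {
    stop(sprintf(
      paste0("infeasible (g1 = %.4g, gamma = %.4g): the mixture family ",
             "attains gamma in (%.3g, %.3g] at this g1"),
      g1_target, gamma_target, rng[["lo"]], rng[["hi"]]), call. = FALSE)
  }
  phase_params(g, min(beta, 1))
}

#' Phase-function density over the scattering cosine
#'
#' @param mu cosine of the polar scattering angle, in \[-1, 1\].
#' @param params a [phase_params()] object.
#' @return Density values of `p(mu)`, normalised so that
#'   `integrate(mhg_pdf, -1, 1) == 1`.
#' @export
mhg_pdf <- function(mu, params) {
  stopifnot(inherits(params, "phase_params"))
  g <- params$g_hg
  b <- params$beta_mix
  hg <- 0.5 * (1 - g^2) / (1 + g^2 - 2 * g * mu)^1.5
  b * hg + (1 - b) * 1.5 * mu^2
}

#' Sample scattering-angle cosines
#'
#' Exact mixture sampling: with probability `beta_mix` an HG deviate through
#' the closed-form inverse CDF, otherwise a cos^2-law deviate
#' `mu = (2u - 1)^(1/3)` (signed cube root).
#'
#' @param params a [phase_params()] object.
#' @param n number of deviates.
#' @param seed integer seed for the internal deterministic stream.
#' @return Numeric vector of `n` cosines in \[-1, 1\].
#' @export
sample_scattering_cosine <- function(params, n, seed = 1L) {
  stopifnot(inherits(params, "phase_params"), n >= 1)
  cpp_sample_mhg(as.integer(n), params$g_hg, params$beta_mix, as.double(seed))
}
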