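#' Pulsatile flow waveform factor
#'
#' Dimensionless time factor `q(t) = 1 + (P/2) sin(2 pi t / period)` applied
#' to the axial velocity profile. Its time mean over one period is 1 and its
#' pulsatility `(q_max - q_min)/q_mean` equals `P`.
#'
#' @param t time (s), vectorised.
#' @param P pulsatility in `[0, 2)`; `P >= 2` would imply flow reversal.
#' @param period cardiac period (s).
#' @return Numeric vector of flow factors.
#' @examples
#' pulsatile_waveform(c(0, 0.25, 0.5), P = 0.4, period = 1)
#' @export
pulsatile_waveform <- function(t, P, period) {
  if (!is.numeric(P) || P < 0 || P >= 2) {
    abort("pulsatility P must lie in [0, 2): P >= 2 would yield negative flow")
  }
  1 + (P / 2) * sin(2 * pi * t / period)
}

#' Analytic duct velocity field
#'
#' Builds the divergence-free, time-periodic synthetic conduit flow: a
#' pulsatile axial cosine profile
#' \deqn{w(x, y, t) = w_0 \cos(\pi x / 2a) \cos(\pi y / 2a)\, q(t)}
#' (zero on the duct wall, peak `w0` on the axis) plus a blinking transverse
#' stirring field of amplitude `eps * w0` that alternates every `tau`
#' seconds between two patterns. Two stirring mechanisms are available:
#'
#' * `"vortex"` (default): the transverse velocity derives from a
#'   streamfunction that alternates between a single duct-filling
#'   recirculation cell,
#'   \eqn{\psi_A \propto \cos(\pi x/2a)\cos(\pi y/2a)}, and a pair of
#'   counter-rotating cells, \eqn{\psi_B \propto \sin(\pi x/a)\cos(\pi y/2a)}.
#'   Both streamfunctions vanish on the duct wall, so the transverse flow is
#'   everywhere tangent to the wall and particles are not expelled; the
#'   alternation of the two incompatible cell patterns is a classical
#'   blinking-vortex chaotic mixer.
#' * `"shear"`: a blinking pair of orthogonal sinusoidal shears,
#'   `u = eps * w0 * sin(pi y / a + phi)` (first half-blink) and
#'   `v = eps * w0 * sin(pi x / a + phi')` (second half-blink), with phases
#'   drawn once from the configuration seed. This variant is not tangent to
#'   the side walls, so strong stirring expels particles (terminated as
#'   out-of-domain); it is retained for benchmarking, but its long-time
#'   survivors sit on non-mixing islands, so it cannot reach the
#'   uniform-mixing regime.
#'
#' Both mechanisms are divergence-free by construction (the vortex one
#' because \eqn{u = \psi_y, v = -\psi_x}; the shear one because u depends
#' only on y and v only on x; w is z-independent in either case), and
#' `eps = 0` gives perfectly segregated parallel streams.
#'
#' @param config a [flow_config()].
#' @return An object of class `velocity_field`: a list with the vectorised
#'   evaluator `velocity(x, y, z, t)` (returning `list(u, v, w)`), the period,
#'   the domain (`a`, `L`) and the generating parameters.
#' @examples
#' fld <- make_duct_field(flow_config(seed = 1))
#' fld$velocity(0, 0, 1, 0)
#' @export
make_duct_field <- function(config) {
  stopifnot(inherits(config, "flow_config"))
  validate_flow_config(config)
  a <- config$a; w0 <- config$w0; P <- config$P
  period <- config$period; eps <- config$eps; tau <- config$tau
  stirring <- config$stirring
  phases <- with_seed(config$seed, runif(2, 0, 2 * pi))
  phi <- phases[1]; phi2 <- phases[2]
  C <- eps * w0 * 2 * a / pi  # streamfunction scale: max |u| = eps * w0

  B <- C * pi / (2 * a)  # transverse velocity scale, equals eps * w0

  velocity <- function(x, y, z, t) {
    n <- max(length(x), length(y), length(z), length(t))
    x <- rep_len(x, n); y <- rep_len(y, n)
    cx <- cospi(x / (2 * a)); cy <- cospi(y / (2 * a))
    q <- 1 + (P / 2) * sin(2 * pi * t / period)
    w <- w0 * cx * cy * if (length(q) == 1L) q else rep_len(q, n)
    if (eps == 0) {
      zero <- numeric(n)
      return(list(u = zero, v = zero, w = w))
    }
    first_half <- (t / tau) %% 2 < 1
    if (stirring == "vortex") {
      # u = d(psi)/dy, v = -d(psi)/dx for the active cell pattern; the
      # two-cell pattern reuses sin(pi x/a) = 2 sx cx, cos(pi x/a) = 2 cx^2 - 1
      sx <- sinpi(x / (2 * a)); sy <- sinpi(y / (2 * a))
      if (length(first_half) == 1L) {
        if (first_half) {
          u <- -B * cx * sy
          v <- B * sx * cy
        } else {
          u <- -B * (2 * sx * cx) * sy
          v <- -2 * B * (2 * cx * cx - 1) * cy
        }
      } else {
        fh <- rep_len(first_half, n)
        u <- ifelse(fh, -B * cx * sy, -B * (2 * sx * cx) * sy)
        v <- ifelse(fh, B * sx * cy, -2 * B * (2 * cx * cx - 1) * cy)
      }
    } else {
      if (length(first_half) == 1L) {
        if (first_half) {
          u <- eps * w0 * sin(pi * y / a + phi)
          v <- numeric(n)
        } else {
          u <- numeric(n)
          v <- eps * w0 * sin(pi * x / a + phi2)
        }
      } else {
        fh <- rep_len(first_half, n)
        u <- ifelse(fh, eps * w0 * sin(pi * y / a + phi), 0)
        v <- ifelse(fh, 0, eps * w0 * sin(pi * x / a + phi2))
      }
    }
    list(u = u, v = v, w = w)
  }

  structure(list(velocity = velocity, period = period, a = a, L = config$L,
                 w0 = w0, eps = eps, tau = tau, P = P, stirring = stirring,
                 phi = phi, phi2 = phi2, origin = "analytic"),
            class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  cat(sprintf("<velocity_field: %s> domain [-%.3g, %.3g]^2 x [0, %.3g] cm, period %.3g s\n",
              x$origin, x$a, x$a, x$L, x$period))
  if (x$origin == "analytic") {
    cat(sprintf("  w0 = %.3g cm/s, P = %.2f, eps = %.2f, tau = %.3g s\n",
                x$w0, x$P, x$eps, x$tau))
  }
  invisible(x)
}

#' Numerical divergence probe
#'
#' Estimates `max |div v| = |du/dx + dv/dy + dw/dz|` by central differences at
#' random interior points and times. For fields built by [make_duct_field()]
#' the construction is divergence-free, so the probe measures only rounding
#' error (well below `1e-6 * w0 / a`).
#'
#' @param field a `velocity_field`.
#' @param n number of probe points.
#' @param seed seed for the probe points.
#' @param h finite-difference step (default `1e-4 * a`).
#' @return Maximum absolute divergence over the probe points (per second).
#' @export
divergence_probe <- function(field, n = 1000, seed = 1L, h = NULL) {
  a <- field$a; L <- field$L
  if (is.null(h)) h <- 1e-4 * a
  pts <- with_seed(seed, tibble(
    x = runif(n, -a + 2 * h, a - 2 * h),
    y = runif(n, -a + 2 * h, a - 2 * h),
    z = runif(n, 2 * h, L - 2 * h),
    t = runif(n, 0, field$period)
  ))
  # central differences component-wise; time held fixed per point
  div <- numeric(n)
  for (i in seq_len(n)) {
    p <- pts[i, ]
    dux <- (field$velocity(p$x + h, p$y, p$z, p$t)$u -
              field$velocity(p$x - h, p$y, p$z, p$t)$u) / (2 * h)
    dvy <- (field$velocity(p$x, p$y + h, p$z, p$t)$v -
              field$velocity(p$x, p$y - h, p$z, p$t)$v) / (2 * h)
    dwz <- (field$velocity(p$x, p$y, p$z + h, p$t)$w -
              field$velocity(p$x, p$y, p$z - h, p$t)$w) / (2 * h)
    div[i] <- dux + dvy + dwz
  }
  max(abs(div))
}

# Fraction of the time-mean axial flux carried by {x > xs} for the cosine
# profile (y and t integrals factor out); computed by quadrature.
axial_flux_fraction <- function(field, xs) {
  a <- field$a
  num <- integrate(function(x) cospi(x / (2 * a)), xs, a,
                   rel.tol = 1e-12)$value
  den <- integrate(function(x) cospi(x / (2 * a)), -a, a,
                   rel.tol = 1e-12)$value
  num / den
}

#' Pulmonary split threshold
#'
#' Finds the in-plane threshold `x_split` such that the time-mean axial flux
#' through `{x > x_split}` equals `s` times the total flux, by bisection on
#' the flux integral (relative tolerance 1e-8). Particles leaving the duct
#' outlet with `x > x_split` are classified as reaching the LPA, the rest the
#' RPA, which reproduces a prescribed pulmonary flow split.
#'
#' @param field a `velocity_field` built by [make_duct_field()].
#' @param s LPA flux fraction in (0, 1).
#' @return The split threshold (same length units as `a`).
#' @examples
#' fld <- make_duct_field(flow_config(seed = 1))
#' solve_split_threshold(fld, 0.5)
#' @export
solve_split_threshold <- function(field, s) {
  if (!is.numeric(s) || s <= 0 || s >= 1) {
    abort("split fraction s must lie strictly between 0 and 1")
  }
  a <- field$a
  lo <- -a; hi <- a  # fraction decreases from 1 at -a to 0 at a
  repeat {
    mid <- (lo + hi) / 2
    f <- axial_flux_fraction(field, mid)
    if (abs(f - s) <= 1e-8 * s || (hi - lo) < 1e-13 * a) return(mid)
    if (f > s) lo <- mid else hi <- mid
  }
}
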