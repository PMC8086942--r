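#' Rectangular inlet sub-regions
#'
#' Inlet sub-regions are axis-aligned rectangles on the caudal release plane
#' of the duct, given as a tibble with one row per sub-region. The hepatic
#' veins (HV) are represented as one or more labelled sub-regions; the IVC as
#' a single region. Areas are used to apportion released particles.
#'
#' @param region character labels.
#' @param xmin,xmax,ymin,ymax rectangle bounds (same length units as the duct
#'   half-width `a`; x: right (-) to left (+), y: posterior (-) to
#'   anterior (+)).
#' @return A tibble with columns `region`, `xmin`, `xmax`, `ymin`, `ymax`,
#'   `area`.
#' @examples
#' inlet_regions("HV1", -0.5, 0, -0.6, -0.2)
#' @export
inlet_regions <- function(region, xmin, xmax, ymin, ymax) {
  out <- tibble(
    region = as.character(region),
    xmin = as.numeric(xmin), xmax = as.numeric(xmax),
    ymin = as.numeric(ymin), ymax = as.numeric(ymax)
  )
  out$area <- (out$xmax - out$xmin) * (out$ymax - out$ymin)
  if (any(!is.finite(out$area)) || any(out$area <= 0)) {
    abort("every inlet sub-region must have positive area (xmax > xmin, ymax > ymin)")
  }
  out
}

default_hv_regions <- function(a) {
  # two hepatic veins entering through a posterior band of the release plane
  inlet_regions(c("HV1", "HV2"),
                xmin = c(-0.8, 0) * a, xmax = c(0, 0.8) * a,
                ymin = c(-0.8, -0.8) * a, ymax = c(-0.3, -0.3) * a)
}

default_ivc_region <- function(a) {
  inlet_regions("IVC", xmin = -0.8 * a, xmax = 0.8 * a,
                ymin = -0.2 * a, ymax = 0.8 * a)
}

#' Virtual-patient flow configuration
#'
#' Describes one virtual Fontan patient: caval and hepatic flow rates, the
#' pulmonary flow split, the pulsatility of the conduit waveform, the duct
#' geometry of the synthetic conduit, and the transverse stirring parameters
#' of the synthetic velocity field.
#'
#' Units: lengths in cm, times in s, flows in l/min. The duct is a square
#' cross-section \eqn{[-a,a]^2} extruded from the caudal release plane
#' (z = 0) to the pulmonary outlet plane (z = L); x runs right (-) to
#' left (+) and y posterior (-) to anterior (+).
#'
#' @param Q_IVC,Q_HV inferior-vena-cava and total hepatic-venous flow (l/min);
#'   cohort means are 3.0 and 1.5 l/min. `Q_conduit = Q_IVC + Q_HV`.
#' @param s pulmonary split fraction in (0, 1): fraction of the outlet flux
#'   delivered to the left pulmonary artery (LPA, x above the split
#'   threshold).
#' @param P conduit waveform pulsatility, `(Q_max - Q_min)/Q_mean`, in
#'   `[0, 2)`.
#' @param eps dimensionless amplitude of the transverse blinking stirring
#'   field relative to `w0` (0 = perfectly segregated parallel streams).
#' @param stirring transverse stirring mechanism: `"vortex"` (wall-tangent
#'   blinking recirculation cells, the default) or `"shear"` (blinking
#'   sinusoidal shears); see [make_duct_field()].
#' @param tau blink half-period (s): the stirring field alternates between two
#'   orthogonal shear patterns every `tau` seconds.
#' @param a duct half-width (cm).
#' @param L duct length (cm).
#' @param period cardiac period T (s).
#' @param n_steps time steps per cardiac cycle.
#' @param z_c,z_cr axial positions of the caudal and cranial analysis
#'   cross-sections, `0 < z_c < z_cr < L`.
#' @param w0 peak axial velocity (cm/s); by default derived from `Q_conduit`
#'   and `a` so the cosine profile carries the prescribed time-mean flux.
#' @param hv_regions,ivc_region inlet sub-regions (see [inlet_regions()]).
#' @param seed optional integer seed controlling the stirring phases and all
#'   particle seeding derived from this configuration.
#' @return An object of class `flow_config` (a named list).
#' @examples
#' cfg <- flow_config()
#' cfg
#' @export
flow_config <- function(Q_IVC = 3.0, Q_HV = 1.5, s = 0.5, P = 0.6,
                        eps = 0.3, tau = 0.05, stirring = c("vortex", "shear"),
                        a = 0.8, L = 10, period = 1, n_steps = 100,
                        z_c = 0.1 * L, z_cr = 0.9 * L, w0 = NULL,
                        hv_regions = default_hv_regions(a),
                        ivc_region = default_ivc_region(a),
                        seed = NULL) {
  if (!is.numeric(a) || length(a) != 1 || !is.finite(a) || a <= 0) {
    abort("invalid flow configuration: duct half-width must be positive (a)")
  }
  stirring <- match.arg(stirring)
  cfg <- list(
    Q_IVC = Q_IVC, Q_HV = Q_HV, Q_conduit = Q_IVC + Q_HV,
    s = s, P = P, eps = eps, tau = tau, stirring = stirring,
    a = a, L = L, period = period, n_steps = as.integer(n_steps),
    z_c = z_c, z_cr = z_cr,
    w0 = if (is.null(w0)) peak_velocity_from_flow(Q_IVC + Q_HV, a) else w0,
    hv_regions = as_tibble(hv_regions), ivc_region = as_tibble(ivc_region),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  class(cfg) <- "flow_config"
  validate_flow_config(cfg)
}

# Peak velocity making the cosine-profile time-mean flux equal Q (l/min)
# through a square duct of half-width a (cm): flux = w0 * (4a/pi)^2.
peak_velocity_from_flow <- function(Q_lmin, a) {
  Q_cm3s <- Q_lmin * 1000 / 60
  Q_cm3s * pi^2 / (16 * a^2)
}

validate_flow_config <- function(cfg) {
  chk <- function(ok, field, msg) {
    if (!isTRUE(ok)) abort(sprintf("invalid flow configuration: %s (%s)", msg, field))
  }
  chk(is.numeric(cfg$Q_IVC) && cfg$Q_IVC > 0, "Q_IVC", "IVC flow must be positive")
  chk(is.numeric(cfg$Q_HV) && cfg$Q_HV > 0, "Q_HV", "hepatic-venous flow must be positive")
  chk(is.numeric(cfg$s) && cfg$s > 0 && cfg$s < 1, "s",
      "pulmonary split fraction must lie strictly between 0 and 1")
  chk(is.numeric(cfg$P) && cfg$P >= 0 && cfg$P < 2, "P",
      "pulsatility must lie in [0, 2); P >= 2 would imply reversed flow")
  chk(is.numeric(cfg$eps) && cfg$eps >= 0, "eps", "stirring amplitude must be >= 0")
  chk(is.numeric(cfg$tau) && cfg$tau > 0, "tau", "blink half-period must be positive")
  chk(cfg$a > 0, "a", "duct half-width must be positive")
  chk(cfg$L > 0, "L", "duct length must be positive")
  chk(cfg$period > 0, "period", "cardiac period must be positive")
  chk(cfg$w0 > 0, "w0", "peak axial velocity must be positive")
  chk(is.numeric(cfg$n_steps) && cfg$n_steps >= 2, "n_steps",
      "at least 2 time steps per cycle are required")
  chk(cfg$z_c > 0 && cfg$z_c < cfg$z_cr && cfg$z_cr < cfg$L, "z_c/z_cr",
      "analysis planes must satisfy 0 < z_c < z_cr < L")
  chk(nrow(cfg$hv_regions) >= 1 && all(cfg$hv_regions$area > 0), "hv_regions",
      "at least one hepatic-vein sub-region with positive area is required")
  chk(nrow(cfg$ivc_region) == 1 && all(cfg$ivc_region$area > 0), "ivc_region",
      "exactly one IVC region with positive area is required")
  within_duct <- function(r, a) {
    all(r$xmin >= -a & r$xmax <= a & r$ymin >= -a & r$ymax <= a)
  }
  chk(within_duct(cfg$hv_regions, cfg$a), "hv_regions",
      "hepatic-vein sub-regions must lie inside the duct cross-section")
  chk(within_duct(cfg$ivc_region, cfg$a), "ivc_region",
      "IVC region must lie inside the duct cross-section")
  cfg
}

#' @export
print.flow_config <- function(x, ...) {
  cat("<flow_config>\n")
  cat(sprintf("  flows     : Q_IVC %.2f + Q_HV %.2f = Q_conduit %.2f l/min (HV share %.0f%%)\n",
              x$Q_IVC, x$Q_HV, x$Q_conduit, 100 * x$Q_HV / x$Q_conduit))
  cat(sprintf("  outlet    : LPA split fraction s = %.2f\n", x$s))
  cat(sprintf("  waveform  : period %.3g s, %d steps/cycle, pulsatility P = %.2f\n",
              x$period, x$n_steps, x$P))
  cat(sprintf("  duct      : half-width a = %.3g cm, length L = %.3g cm, planes z_c = %.3g, z_cr = %.3g cm\n",
              x$a, x$L, x$z_c, x$z_cr))
  cat(sprintf("  stirring  : %s, eps = %.2f, blink half-period tau = %.3g s\n",
              x$stirring, x$eps, x$tau))
  cat(sprintf("  velocity  : peak w0 = %.3g cm/s\n", x$w0))
  cat(sprintf("  inlets    : %d HV sub-region(s), IVC region; seed %s\n",
              nrow(x$hv_regions), if (is.null(x$seed)) "unset" else x$seed))
  invisible(x)
}

#' Sample a cohort of virtual patients
#'
#' Draws `n_patients` flow configurations around the reported cohort
#' dispersion: `Q_IVC ~ N(3.0, 0.7)` and `Q_HV ~ N(1.5, 0.6)` l/min (both
#' truncated positive), pulmonary split `s ~ U(0.3, 0.7)` and stirring
#' amplitude `eps ~ U(0, eps_max)`. Deterministic given `seed`.
#'
#' @param n_patients number of virtual patients (>= 1).
#' @param seed integer seed.
#' @param eps_max upper bound of the stirring-amplitude draw.
#' @param ... further arguments passed to [flow_config()] (geometry etc.).
#' @return A list of `flow_config` objects; each carries its own derived seed.
#' @examples
#' cohort <- generate_cohort(3, seed = 1)
#' length(cohort)
#' @export
generate_cohort <- function(n_patients, seed = 1L, eps_max = 0.5, ...) {
  stopifnot(n_patients >= 1)
  with_seed(seed, {
    rtnorm <- function(n, mean, sd) {
      x <- rnorm(n, mean, sd)
      while (any(bad <- x <= 0)) x[bad] <- rnorm(sum(bad), mean, sd)
      x
    }
    q_ivc <- rtnorm(n_patients, 3.0, 0.7)
    q_hv <- rtnorm(n_patients, 1.5, 0.6)
    s <- runif(n_patients, 0.3, 0.7)
    eps <- runif(n_patients, 0, eps_max)
    seeds <- sample.int(.Machine$integer.max %/% 2, n_patients)
    purrr::pmap(list(q_ivc, q_hv, s, eps, seeds), function(qi, qh, si, ei, sdi) {
      flow_config(Q_IVC = qi, Q_HV = qh, s = si, eps = ei, seed = sdi, ...)
    })
  })
}

#' Designed demonstration configurations
#'
#' Frozen virtual-patient configurations used to demonstrate and test the
#' limiting regimes of the mixing and HFD machinery:
#'
#' * `"segregated"`: `eps = 0` with the hepatic-venous stream filling the
#'   left half of the duct and the IVC stream the right half. The streams
#'   are quadrant-aligned, so every subsection is pure and the mixing index
#'   is exactly 0 at every phase.
#' * `"strong_mixing"`: physiologic flows with fast, strong blinking-vortex
#'   stirring (`eps = 6`, `tau = 0.005` s, about 2.7 rad of transverse
#'   rotation per blink) and the caudal analysis plane at `z_c = 3` cm so
#'   that even the fastest core particles experience several blink
#'   alternations before reaching it. Drives both cross-sections into the
#'   uniform-mixing bin.
#' * `"poor_mixing"`: `eps = 0` with the hepatic-venous band shifted towards
#'   the left (LPA) side of the duct. Because there is no transverse mixing,
#'   the direct (HV-seeded) and conventional (conduit-seeded) HFD methods
#'   disagree strongly: the mechanism behind conventional-method inaccuracy
#'   under non-uniform hepatic flow.
#'
#' @param name preset name.
#' @param ... overrides passed on to [flow_config()] (e.g. `seed`).
#' @return A `flow_config`.
#' @examples
#' preset_config("poor_mixing", seed = 1)
#' @export
preset_config <- function(name = c("segregated", "strong_mixing", "poor_mixing"),
                          ...) {
  name <- match.arg(name)
  args <- switch(name,
    segregated = {
      a <- 0.8
      list(eps = 0,
           hv_regions = inlet_regions("HV", 0.05 * a, 0.9 * a,
                                      -0.85 * a, 0.85 * a),
           ivc_region = inlet_regions("IVC", -0.9 * a, -0.05 * a,
                                      -0.85 * a, 0.85 * a))
    },
    strong_mixing = list(eps = 6, tau = 0.005, z_c = 3),
    poor_mixing = {
      a <- 0.8
      list(eps = 0,
           hv_regions = inlet_regions(c("HV1", "HV2"),
                                      xmin = c(-0.2, 0.3) * a,
                                      xmax = c(0.3, 0.8) * a,
                                      ymin = c(-0.8, -0.8) * a,
                                      ymax = c(-0.3, -0.3) * a))
    })
  do.call(flow_config, utils::modifyList(args, list(...)))
}
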