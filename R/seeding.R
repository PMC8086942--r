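#' Largest-remainder apportionment
#'
#' Splits an integer total over categories proportionally to `weights`,
#' rounding with the largest-remainder rule so the parts sum exactly to `n`.
#'
#' @param n integer total (>= 0).
#' @param weights positive weights (e.g. sub-region areas).
#' @return Integer vector of the same length as `weights`, summing to `n`.
#' @examples
#' largest_remainder(7500, c(2, 1))
#' @export
largest_remainder <- function(n, weights) {
  stopifnot(n >= 0, all(weights >= 0))
  tot <- sum(weights)
  if (tot <= 0) abort("total weight must be positive")
  quota <- n * weights / tot
  base <- floor(quota)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

uniform_in_region <- function(region, n) {
  tibble(
    x = runif(n, region$xmin, region$xmax),
    y = runif(n, region$ymin, region$ymax)
  )
}

#' Labelled particle seed plan for one release event
#'
#' Places `n_hv` hepatic-vein particles on the caudal release plane, split
#' over the HV sub-regions proportionally to their cross-sectional areas
#' (largest-remainder rounding so counts sum exactly), plus
#' `round(n_hv * Q_IVC / Q_HV)` IVC particles in the IVC region. Positions
#' are uniform within each sub-region.
#'
#' @param config a [flow_config()].
#' @param n_hv number of HV particles for this release event (default 7500).
#' @param release_step 1-based global time-step index at which these seeds
#'   start moving.
#' @param include_ivc set `FALSE` for the direct hepatic-vein HFD seeding.
#' @param seed optional seed; by default the current RNG stream is used.
#' @return A tibble with columns `particle_id`, `label` (`"HV"`/`"IVC"`),
#'   `region`, `release_step`, `x`, `y`, `z`.
#' @examples
#' plan <- seed_plan(flow_config(seed = 1), n_hv = 30, seed = 1)
#' dplyr::count(plan, label)
#' @export
seed_plan <- function(config, n_hv = 7500, release_step = 1L,
                      include_ivc = TRUE, seed = NULL) {
  stopifnot(inherits(config, "flow_config"))
  if (config$Q_HV <= 0) abort("Q_HV must be positive to apportion seeds")
  hv <- config$hv_regions
  if (sum(hv$area) <= 0) abort("total hepatic-vein inlet area must be positive")
  counts <- largest_remainder(n_hv, hv$area)
  with_seed(seed, {
    hv_pts <- purrr::map2_dfr(seq_len(nrow(hv)), counts, function(i, k) {
      if (k == 0) return(NULL)
      mutate(uniform_in_region(hv[i, ], k), label = "HV", region = hv$region[i])
    })
    out <- hv_pts
    if (include_ivc) {
      n_ivc <- as.integer(round(n_hv * config$Q_IVC / config$Q_HV))
      ivc_pts <- mutate(uniform_in_region(config$ivc_region, n_ivc),
                        label = "IVC", region = config$ivc_region$region[1])
      out <- bind_rows(hv_pts, ivc_pts)
    }
    mutate(out,
           particle_id = seq_len(nrow(out)),
           release_step = as.integer(release_step),
           z = 0) %>%
      select("particle_id", "label", "region", "release_step", "x", "y", "z")
  })
}

#' Direct hepatic-vein seeding
#'
#' Seeds `n` particles from the hepatic veins only, divided over the HV
#' sub-regions by the ratio of their areas (the direct HFD method).
#'
#' @inheritParams seed_plan
#' @param n number of particles (default 7500).
#' @return A seed-plan tibble (see [seed_plan()]).
#' @export
seed_hv_direct <- function(config, n = 7500, release_step = 1L, seed = NULL) {
  seed_plan(config, n_hv = n, release_step = release_step,
            include_ivc = FALSE, seed = seed)
}

#' Uniform conduit seeding
#'
#' Seeds `n` source-unlabelled particles uniformly at random over the full
#' duct cross-section at the caudal or cranial analysis plane (the
#' conventional HFD method).
#'
#' @inheritParams seed_plan
#' @param plane `"caudal"` or `"cranial"`.
#' @param n number of particles (default 7500).
#' @return A seed-plan tibble with `label = "conduit"`.
#' @export
seed_conduit_uniform <- function(config, plane = c("caudal", "cranial"),
                                 n = 7500, release_step = 1L, seed = NULL) {
  plane <- match.arg(plane)
  a <- config$a
  z0 <- if (plane == "caudal") config$z_c else config$z_cr
  with_seed(seed, tibble(
    particle_id = seq_len(n),
    label = "conduit",
    region = plane,
    release_step = as.integer(release_step),
    x = runif(n, -a, a),
    y = runif(n, -a, a),
    z = z0
  ))
}

#' Release schedule for the mixing and HFD analyses
#'
#' Builds the full set of labelled seeds over the release window:
#'
#' * `mode = "mixing"`: one release event per time step for `cycles`
#'   (default 5) cardiac cycles, `n_hv` HV particles per event plus the
#'   flow-ratio IVC complement; plane transections are analysed in the final
#'   cycle.
#' * `mode = "hfd"`: `n_total` particles (default 7500) released over one
#'   cardiac cycle (`n_steps` events, largest-remainder split over the
#'   steps), tracked for 5 to 12 further cycles with early stop once >= 99%
#'   of particles have resolved.
#'
#' @param config a [flow_config()].
#' @param mode `"mixing"` or `"hfd"`.
#' @param n_hv HV particles per release event (mixing mode; default 7500).
#' @param n_total total particles over the release cycle (hfd mode;
#'   default 7500).
#' @param method seeding strategy for hfd mode: `"hv"` (direct),
#'   `"caudal_conduit"` or `"cranial_conduit"`.
#' @param cycles number of release cycles in mixing mode (default 5).
#' @param seed optional seed for the whole schedule.
#' @return A tibble of seeds with globally unique `particle_id`, carrying
#'   attributes `mode`, `n_release_events`, `analysis_cycle` (mixing) or
#'   `track_cycles`/`min_cycles`/`early_stop` (hfd).
#' @export
release_schedule <- function(config, mode = c("mixing", "hfd"),
                             n_hv = 7500, n_total = 7500,
                             method = c("hv", "caudal_conduit", "cranial_conduit"),
                             cycles = 5, seed = NULL) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  n_steps <- config$n_steps
  with_seed(seed, {
    if (mode == "mixing") {
      steps <- seq_len(cycles * n_steps)
      seeds <- purrr::map_dfr(steps, function(k) {
        seed_plan(config, n_hv = n_hv, release_step = k)
      })
      attrs <- list(mode = "mixing", n_release_events = length(steps),
                    analysis_cycle = cycles, cycles = cycles)
    } else {
      per_step <- largest_remainder(n_total, rep(1, n_steps))
      seeds <- purrr::map_dfr(seq_len(n_steps), function(k) {
        nk <- per_step[k]
        if (nk == 0) return(NULL)
        switch(method,
          hv = seed_hv_direct(config, n = nk, release_step = k),
          caudal_conduit = seed_conduit_uniform(config, "caudal", n = nk,
                                                release_step = k),
          cranial_conduit = seed_conduit_uniform(config, "cranial", n = nk,
                                                 release_step = k))
      })
      attrs <- list(mode = "hfd", n_release_events = n_steps, method = method,
                    track_cycles = 12L, min_cycles = 5L, early_stop = 0.99)
    }
    seeds$particle_id <- seq_len(nrow(seeds))
    for (nm in names(attrs)) attr(seeds, nm) <- attrs[[nm]]
    seeds
  })
}
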