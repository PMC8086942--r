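# One classical 4-stage explicit (RK4) position update for all particles at
# once; `vel` is the vectorised field evaluator, `t` the (scalar) substep
# start time, `h` the substep length.
rk4_positions <- function(vel, x, y, z, t, h) {
  k1 <- vel(x, y, z, t)
  k2 <- vel(x + h / 2 * k1$u, y + h / 2 * k1$v, z + h / 2 * k1$w, t + h / 2)
  k3 <- vel(x + h / 2 * k2$u, y + h / 2 * k2$v, z + h / 2 * k2$w, t + h / 2)
  k4 <- vel(x + h * k3$u, y + h * k3$v, z + h * k3$w, t + h)
  list(x = x + h / 6 * (k1$u + 2 * k2$u + 2 * k3$u + k4$u),
       y = y + h / 6 * (k1$v + 2 * k2$v + 2 * k3$v + k4$v),
       z = z + h / 6 * (k1$w + 2 * k2$w + 2 * k3$w + k4$w))
}

#' Trace particles through a time-periodic velocity field
#'
#' Advects a table of labelled seeds (see [seed_plan()], [release_schedule()])
#' through `field` with RK4 substepping, recording caudal-to-cranial (+z)
#' plane transections on the fly. A particle terminates when it reaches the
#' duct outlet (`z >= L`), when it leaves the cross-sectional domain (it is
#' clamped to the wall and flagged `out_of_domain`), or at the tracking
#' horizon.
#'
#' Each cardiac cycle is divided into `n_steps` time steps of length
#' `period / n_steps`, each integrated in `substeps` RK4 substeps; a
#' transection is assigned to the time step in which its trajectory segment
#' ends.
#'
#' @param field a `velocity_field`.
#' @param seeds seed tibble with columns `particle_id`, `label`, `region`,
#'   `release_step`, `x`, `y`, `z`.
#' @param n_steps time steps per cardiac cycle.
#' @param substeps RK4 substeps per time step (default 10).
#' @param max_cycles tracking horizon in cardiac cycles.
#' @param planes named numeric vector of transection plane z-positions,
#'   e.g. `c(caudal = z_c, cranial = z_cr)`; `NULL` records none.
#' @param min_cycles,early_stop optional early stopping: once all particles
#'   are released and at least `min_cycles` cycles have elapsed, stop at a
#'   cycle boundary when the resolved (non-active) fraction reaches
#'   `early_stop`.
#' @param record_path keep the full per-substep sample history (memory heavy;
#'   intended for small particle sets).
#' @return A list of class `fontan_trace` with elements `status` (one row per
#'   particle: terminal `status` of `"active"`, `"exited"` or
#'   `"out_of_domain"`, final `x`, `y`, `z`, `t_end`), `crossings` (one row
#'   per +z plane transection: `particle_id`, `label`, `plane`, `step`,
#'   `cycle`, `phase`, `x`, `y`) and, if requested, `samples`.
#' @export
trace_particles <- function(field, seeds, n_steps = 100, substeps = 10,
                            max_cycles = 12, planes = NULL,
                            min_cycles = NULL, early_stop = NULL,
                            record_path = FALSE) {
  stopifnot(inherits(field, "velocity_field"), nrow(seeds) >= 1)
  a <- field$a; L <- field$L
  dt <- field$period / n_steps
  h <- dt / substeps
  nan_is_oob <- isTRUE(field$nan_is_oob)
  if (is.null(min_cycles)) min_cycles <- max_cycles

  N <- nrow(seeds)
  X <- seeds$x; Y <- seeds$y; Z <- seeds$z
  rel <- seeds$release_step
  state <- integer(N)  # 0 pending, 1 active, 2 exited, 3 out of domain
  t_end <- rep(NA_real_, N)

  cross <- list(); n_cross <- 0L
  samp <- list(); n_samp <- 0L
  push_samples <- function(idx, t, x, y, z, step) {
    n_samp <<- n_samp + 1L
    samp[[n_samp]] <<- list(particle_id = seeds$particle_id[idx],
                            step = rep.int(step, length(idx)),
                            t = rep_len(t, length(idx)), x = x, y = y, z = z)
  }

  plane_z <- unname(planes)
  plane_id <- names(planes)
  total_steps <- max_cycles * n_steps

  for (g in seq_len(total_steps)) {
    newly <- which(state == 0L & rel == g)
    if (length(newly)) {
      state[newly] <- 1L
      if (record_path) push_samples(newly, (g - 1) * dt,
                                    X[newly], Y[newly], Z[newly], g)
    }
    act <- which(state == 1L)
    if (!length(act)) {
      if (!any(state == 0L)) break else next
    }
    t0 <- (g - 1) * dt
    x <- X[act]; y <- Y[act]; z <- Z[act]
    alive <- rep(TRUE, length(act))

    for (ss in seq_len(substeps)) {
      ia <- which(alive)
      if (!length(ia)) break
      t <- t0 + (ss - 1) * h
      xs <- x[ia]; ys <- y[ia]; zs <- z[ia]
      np <- rk4_positions(field$velocity, xs, ys, zs, t, h)
      bad <- !(is.finite(np$x) & is.finite(np$y) & is.finite(np$z))
      if (any(bad)) {
        if (nan_is_oob) {
          gi <- act[ia[bad]]
          state[gi] <- 3L; t_end[gi] <- t
          np$x[bad] <- xs[bad]; np$y[bad] <- ys[bad]; np$z[bad] <- zs[bad]
        } else {
          abort(sprintf(
            "non-finite velocity evaluation for particle %s at t = %.6g s",
            paste(seeds$particle_id[act[ia[bad]]], collapse = ", "), t))
        }
      }
      # +z plane transections on the segment (zs -> np$z)
      if (length(plane_z)) {
        for (p in seq_along(plane_z)) {
          zp <- plane_z[p]
          sel <- which(zs < zp & np$z >= zp)
          if (length(sel)) {
            frac <- (zp - zs[sel]) / (np$z[sel] - zs[sel])
            n_cross <- n_cross + 1L
            cross[[n_cross]] <- list(
              particle_id = seeds$particle_id[act[ia[sel]]],
              plane = rep.int(plane_id[p], length(sel)),
              step = rep.int(g, length(sel)),
              x = xs[sel] + frac * (np$x[sel] - xs[sel]),
              y = ys[sel] + frac * (np$y[sel] - ys[sel]))
          }
        }
      }
      # outlet exit (interpolate the crossing of z = L)
      ex <- which(np$z >= L & state[act[ia]] == 1L)
      if (length(ex)) {
        frac <- (L - zs[ex]) / (np$z[ex] - zs[ex])
        gi <- act[ia[ex]]
        state[gi] <- 2L
        X[gi] <- xs[ex] + frac * (np$x[ex] - xs[ex])
        Y[gi] <- ys[ex] + frac * (np$y[ex] - ys[ex])
        Z[gi] <- L
        t_end[gi] <- t + frac * h
        np$x[ex] <- X[gi]; np$y[ex] <- Y[gi]; np$z[ex] <- L
      }
      # side-wall escape: clamp to the wall and terminate
      oob <- which(state[act[ia]] == 1L & (abs(np$x) > a | abs(np$y) > a))
      if (length(oob)) {
        gi <- act[ia[oob]]
        state[gi] <- 3L
        X[gi] <- pmin(pmax(np$x[oob], -a), a)
        Y[gi] <- pmin(pmax(np$y[oob], -a), a)
        Z[gi] <- np$z[oob]
        t_end[gi] <- t + h
        np$x[oob] <- X[gi]; np$y[oob] <- Y[gi]
      }
      if (record_path) push_samples(act[ia], t + h, np$x, np$y, np$z, g)
      done <- state[act[ia]] != 1L
      alive[ia[done]] <- FALSE
      x[ia] <- np$x; y[ia] <- np$y; z[ia] <- np$z
    }
    keep <- which(alive)
    if (length(keep)) {
      gi <- act[keep]
      X[gi] <- x[keep]; Y[gi] <- y[keep]; Z[gi] <- z[keep]
    }
    if (!is.null(early_stop) && g %% n_steps == 0 &&
        g >= min_cycles * n_steps && !any(state == 0L)) {
      if (mean(state != 1L) >= early_stop) break
    }
  }

  status <- tibble(
    particle_id = seeds$particle_id,
    label = seeds$label,
    region = seeds$region,
    release_step = seeds$release_step,
    status = c("pending", "active", "exited", "out_of_domain")[state + 1L],
    x = X, y = Y, z = Z, t_end = t_end
  )
  # particles never released within the horizon count as active (unreleased)
  status$status[status$status == "pending"] <- "active"

  crossings <- if (n_cross > 0) {
    cr <- tibble(
      particle_id = unlist(lapply(cross, `[[`, "particle_id")),
      plane = unlist(lapply(cross, `[[`, "plane")),
      step = unlist(lapply(cross, `[[`, "step")),
      x = unlist(lapply(cross, `[[`, "x")),
      y = unlist(lapply(cross, `[[`, "y"))
    )
    cr$cycle <- (cr$step - 1L) %/% n_steps + 1L
    cr$phase <- (cr$step - 1L) %% n_steps + 1L
    cr$label <- seeds$label[match(cr$particle_id, seeds$particle_id)]
    cr <- cr[order(cr$step, cr$particle_id), ]
    select(cr, "particle_id", "label", "plane", "step", "cycle", "phase", "x", "y")
  } else {
    tibble(particle_id = integer(), label = character(), plane = character(),
           step = integer(), cycle = integer(), phase = integer(),
           x = numeric(), y = numeric())
  }

  out <- list(status = status, crossings = crossings,
              n_steps = n_steps, substeps = substeps, dt = dt)
  if (record_path) {
    out$samples <- tibble(
      particle_id = unlist(lapply(samp, `[[`, "particle_id")),
      step = unlist(lapply(samp, `[[`, "step")),
      t = unlist(lapply(samp, `[[`, "t")),
      x = unlist(lapply(samp, `[[`, "x")),
      y = unlist(lapply(samp, `[[`, "y")),
      z = unlist(lapply(samp, `[[`, "z"))
    ) %>% arrange(.data$particle_id, .data$t)
  }
  class(out) <- "fontan_trace"
  out
}

#' @export
print.fontan_trace <- function(x, ...) {
  tab <- table(x$status$status)
  cat(sprintf("<fontan_trace> %d particles (%s); %d plane transections\n",
              nrow(x$status),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
              nrow(x$crossings)))
  invisible(x)
}

#' Advect particles and keep their pathlines
#'
#' Convenience wrapper around [trace_particles()] that records the full
#' per-substep sample history (the pathlines). Intended for small particle
#' sets, visual checks and integrator verification; the pipeline itself uses
#' the history-free tracer.
#'
#' @inheritParams trace_particles
#' @param particles a seed tibble (see [seed_plan()]).
#' @return A `fontan_trace` with a `samples` tibble
#'   (`particle_id`, `step`, `t`, `x`, `y`, `z`).
#' @export
advect <- function(field, particles, n_steps = 100, substeps = 10,
                   max_cycles = 5, planes = NULL) {
  trace_particles(field, particles, n_steps = n_steps, substeps = substeps,
                  max_cycles = max_cycles, planes = planes, record_path = TRUE)
}

#' Detect plane transections along sampled pathlines
#'
#' Scans consecutive sample pairs of each pathline and records a transection
#' wherever a segment crosses the plane in the +z (caudal-to-cranial)
#' direction, with the in-plane position obtained by linear interpolation in
#' z. Retrograde (-z) crossings are ignored: the analysis counts flow
#' delivered cranially, and conduit flow is predominantly unidirectional. A
#' sample lying exactly on the plane is counted once, with the segment that
#' ends there.
#'
#' @param samples a data frame of pathline samples with columns `x`, `y`, `z`
#'   and optionally `particle_id`, `label` and `step` (as produced by
#'   [advect()]). Rows must be time-ordered within each particle.
#' @param plane_z z-position of the cross-section.
#' @param plane_id label for the plane (e.g. `"caudal"`).
#' @param n_steps if given (with `step` present), cycle and phase indices are
#'   derived from the step index.
#' @return A tibble of transections: `particle_id`, `label`, `plane`, `step`,
#'   `cycle`, `phase`, `x`, `y`.
#' @examples
#' path <- tibble::tibble(x = c(1, 2), y = c(0, 0), z = c(0.4, 0.6))
#' detect_crossings(path, plane_z = 0.5)
#' @export
detect_crossings <- function(samples, plane_z, plane_id = "plane",
                             n_steps = NULL) {
  samples <- as_tibble(samples)
  if (!all(c("x", "y", "z") %in% names(samples))) {
    abort("samples must have columns x, y, z")
  }
  if (!"particle_id" %in% names(samples)) samples$particle_id <- 1L
  if (!"step" %in% names(samples)) samples$step <- NA_integer_
  n <- nrow(samples)
  if (n < 2) return(empty_crossings())
  same <- samples$particle_id[-1] == samples$particle_id[-n]
  z1 <- samples$z[-n]; z2 <- samples$z[-1]
  sel <- which(same & z1 < plane_z & z2 >= plane_z)
  if (!length(sel)) return(empty_crossings())
  frac <- (plane_z - z1[sel]) / (z2[sel] - z1[sel])
  out <- tibble(
    particle_id = samples$particle_id[sel],
    label = if ("label" %in% names(samples)) samples$label[sel] else NA_character_,
    plane = plane_id,
    step = samples$step[sel + 1L],  # segment's end sample owns the crossing
    x = samples$x[sel] + frac * (samples$x[sel + 1L] - samples$x[sel]),
    y = samples$y[sel] + frac * (samples$y[sel + 1L] - samples$y[sel])
  )
  if (!is.null(n_steps)) {
    out$cycle <- (out$step - 1L) %/% n_steps + 1L
    out$phase <- (out$step - 1L) %% n_steps + 1L
  } else {
    out$cycle <- NA_integer_
    out$phase <- NA_integer_
  }
  select(out, "particle_id", "label", "plane", "step", "cycle", "phase", "x", "y")
}

empty_crossings <- function() {
  tibble(particle_id = integer(), label = character(), plane = character(),
         step = integer(), cycle = integer(), phase = integer(),
         x = numeric(), y = numeric())
}

#' Classify pulmonary outlet exits
#'
#' Assigns each traced particle to the left (`x > x_split`) or right
#' (`x < x_split`) pulmonary artery from its outlet-exit position; particles
#' still active at the horizon or terminated at the wall are `unresolved`.
#' An exact tie (`|x - x_split| < 1e-12 * a`) alternates deterministically by
#' particle-id parity.
#'
#' @param status a status tibble from [trace_particles()] (or the
#'   `fontan_trace` itself).
#' @param x_split split threshold from [solve_split_threshold()].
#' @param a duct half-width (sets the tie tolerance scale).
#' @return The status tibble with an `outlet` column
#'   (`"LPA"`, `"RPA"` or `"unresolved"`).
#' @export
classify_outlet <- function(status, x_split, a = 1) {
  if (inherits(status, "fontan_trace")) status <- status$status
  status <- as_tibble(status)
  ex <- status$status == "exited"
  tie <- ex & abs(status$x - x_split) < 1e-12 * a
  outlet <- rep("unresolved", nrow(status))
  outlet[ex & status$x > x_split] <- "LPA"
  outlet[ex & status$x < x_split] <- "RPA"
  outlet[tie] <- ifelse(status$particle_id[tie] %% 2 == 0, "LPA", "RPA")
  status$outlet <- outlet
  status
}
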