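#' Write a flow configuration to JSON
#'
#' @param config a [flow_config()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "flow_config"))
  x <- unclass(config)
  x$hv_regions <- as.data.frame(x$hv_regions)
  x$ivc_region <- as.data.frame(x$ivc_region)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load and validate a flow configuration from JSON
#'
#' Reads a virtual-patient configuration file, applies the documented
#' defaults for any omitted field (`n_steps = 100`, geometry, inlet regions,
#' ...) and validates it; schema violations raise an error naming the
#' offending field.
#'
#' The schema mirrors the arguments of [flow_config()]: scalar fields
#' `Q_IVC`, `Q_HV`, `s`, `P`, `eps`, `tau`, `a`, `L`, `period`, `n_steps`,
#' `z_c`, `z_cr`, `w0`, `seed`, plus `hv_regions` / `ivc_region` as arrays of
#' `{region, xmin, xmax, ymin, ymax}` records.
#'
#' @param path JSON file.
#' @return A validated `flow_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("configuration file not found: %s", path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("Q_IVC", "Q_HV", "s", "P", "eps", "tau", "stirring", "a", "L",
             "period", "n_steps", "z_c", "z_cr", "w0", "hv_regions",
             "ivc_region", "seed")
  unknown <- setdiff(names(raw), c(known, "Q_conduit"))
  if (length(unknown)) {
    abort(sprintf("unknown configuration field(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  args <- raw[intersect(names(raw), setdiff(known, c("hv_regions", "ivc_region")))]
  reg <- function(df) {
    if (!all(c("region", "xmin", "xmax", "ymin", "ymax") %in% names(df))) {
      abort("inlet regions need fields region, xmin, xmax, ymin, ymax")
    }
    inlet_regions(df$region, df$xmin, df$xmax, df$ymin, df$ymax)
  }
  if (!is.null(raw$hv_regions)) args$hv_regions <- reg(as.data.frame(raw$hv_regions))
  if (!is.null(raw$ivc_region)) args$ivc_region <- reg(as.data.frame(raw$ivc_region))
  do.call(flow_config, args)
}

#' Sample a velocity field onto legacy VTK structured-points files
#'
#' Writes one legacy ASCII VTK `STRUCTURED_POINTS` file per time snapshot,
#' with the velocity as a `VECTORS` point array, for visual inspection or for
#' round-trip ingestion via [read_velocity_vtk()].
#'
#' @param field a `velocity_field`.
#' @param dir output directory (created if needed).
#' @param dims grid dimensions `c(nx, ny, nz)`.
#' @param n_times number of snapshots, equally spaced over one period
#'   (snapshot k at `t = (k-1) * period / n_times`).
#' @return Tibble with columns `path` and `time`.
#' @export
write_velocity_vtk <- function(field, dir, dims = c(17, 17, 17), n_times = 4) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  a <- field$a; L <- field$L
  xs <- seq(-a, a, length.out = dims[1])
  ys <- seq(-a, a, length.out = dims[2])
  zs <- seq(0, L, length.out = dims[3])
  grid <- expand.grid(x = xs, y = ys, z = zs)  # x fastest: VTK point order
  times <- (seq_len(n_times) - 1) * field$period / n_times
  paths <- character(n_times)
  for (k in seq_len(n_times)) {
    v <- field$velocity(grid$x, grid$y, grid$z, times[k])
    path <- file.path(dir, sprintf("velocity_%03d.vtk", k))
    con <- file(path, "w")
    writeLines(c("# vtk DataFile Version 3.0",
                 sprintf("fontanmix velocity field t=%.6g", times[k]),
                 "ASCII",
                 "DATASET STRUCTURED_POINTS",
                 sprintf("DIMENSIONS %d %d %d", dims[1], dims[2], dims[3]),
                 sprintf("ORIGIN %.9g %.9g %.9g", -a, -a, 0),
                 sprintf("SPACING %.9g %.9g %.9g",
                         diff(xs[1:2]), diff(ys[1:2]), diff(zs[1:2])),
                 sprintf("POINT_DATA %d", nrow(grid)),
                 "VECTORS velocity float"), con)
    writeLines(sprintf("%.9g %.9g %.9g", v$u, v$v, v$w), con)
    close(con)
    paths[k] <- path
  }
  tibble(path = paths, time = times)
}

parse_vtk_structured_points <- function(path) {
  lines <- readLines(path, n = 50)
  need <- function(pat) {
    i <- grep(pat, lines)
    if (!length(i)) abort(sprintf("%s: missing '%s' in VTK header", path, pat))
    i[1]
  }
  if (!any(grepl("STRUCTURED_POINTS", lines))) {
    abort(sprintf("%s: only legacy ASCII STRUCTURED_POINTS files are supported", path))
  }
  dims <- as.integer(strsplit(trimws(sub("DIMENSIONS", "", lines[need("^DIMENSIONS")])), "\\s+")[[1]])
  origin <- as.numeric(strsplit(trimws(sub("ORIGIN", "", lines[need("^ORIGIN")])), "\\s+")[[1]])
  spacing <- as.numeric(strsplit(trimws(sub("SPACING", "", lines[need("^SPACING")])), "\\s+")[[1]])
  ivec <- need("^VECTORS")
  npts <- prod(dims)
  vals <- scan(path, what = numeric(), skip = ivec, n = 3 * npts, quiet = TRUE)
  if (length(vals) != 3 * npts) {
    abort(sprintf("%s: velocity array missing or truncated (expected %d values)",
                  path, 3 * npts))
  }
  m <- matrix(vals, ncol = 3, byrow = TRUE)
  list(dims = dims, origin = origin, spacing = spacing,
       u = array(m[, 1], dims), v = array(m[, 2], dims), w = array(m[, 3], dims))
}

# vectorised trilinear interpolation in one 3-d array
trilinear <- function(arr, dims, origin, spacing, x, y, z) {
  fx <- (x - origin[1]) / spacing[1]
  fy <- (y - origin[2]) / spacing[2]
  fz <- (z - origin[3]) / spacing[3]
  out <- rep(NA_real_, length(fx))
  ok <- fx >= 0 & fx <= dims[1] - 1 & fy >= 0 & fy <= dims[2] - 1 &
    fz >= 0 & fz <= dims[3] - 1
  if (!any(ok)) return(out)
  fx <- fx[ok]; fy <- fy[ok]; fz <- fz[ok]
  i0 <- pmin(floor(fx), dims[1] - 2); tx <- fx - i0
  j0 <- pmin(floor(fy), dims[2] - 2); ty <- fy - j0
  k0 <- pmin(floor(fz), dims[3] - 2); tz <- fz - k0
  idx <- function(i, j, k) 1 + i + dims[1] * (j + dims[2] * k)
  v000 <- arr[idx(i0, j0, k0)];     v100 <- arr[idx(i0 + 1, j0, k0)]
  v010 <- arr[idx(i0, j0 + 1, k0)]; v110 <- arr[idx(i0 + 1, j0 + 1, k0)]
  v001 <- arr[idx(i0, j0, k0 + 1)]; v101 <- arr[idx(i0 + 1, j0, k0 + 1)]
  v011 <- arr[idx(i0, j0 + 1, k0 + 1)]; v111 <- arr[idx(i0 + 1, j0 + 1, k0 + 1)]
  out[ok] <-
    (1 - tz) * ((1 - ty) * ((1 - tx) * v000 + tx * v100) +
                  ty * ((1 - tx) * v010 + tx * v110)) +
    tz * ((1 - ty) * ((1 - tx) * v001 + tx * v101) +
            ty * ((1 - tx) * v011 + tx * v111))
  out
}

#' Read a time series of VTK velocity snapshots as a velocity field
#'
#' Ingests externally produced (e.g. CFD) velocity data from legacy ASCII
#' VTK `STRUCTURED_POINTS` files sharing one grid, and returns a
#' `velocity_field` that interpolates trilinearly in space and
#' periodic-linearly in time. Queries outside the grid bounds return `NA`
#' velocities, which the tracer treats as an out-of-domain signal.
#'
#' @param paths VTK files, one per snapshot, covering one period.
#' @param times snapshot times (s), strictly increasing, within
#'   `[0, period)`.
#' @param period the cycle period (s).
#' @return A `velocity_field` whose cross-section half-width `a` and length
#'   `L` are taken from the grid bounds.
#' @export
read_velocity_vtk <- function(paths, times, period) {
  stopifnot(length(paths) == length(times), length(paths) >= 1)
  if (is.unsorted(times, strictly = length(times) > 1)) {
    abort("snapshot times must be strictly increasing")
  }
  snaps <- purrr::map(paths, parse_vtk_structured_points)
  ref <- snaps[[1]]
  for (s in snaps[-1]) {
    if (!identical(s$dims, ref$dims) || any(s$origin != ref$origin) ||
        any(s$spacing != ref$spacing)) {
      abort("all VTK snapshots must share the same grid")
    }
  }
  dims <- ref$dims; origin <- ref$origin; spacing <- ref$spacing
  nt <- length(snaps)
  eval_snap <- function(k, comp, x, y, z) {
    trilinear(snaps[[k]][[comp]], dims, origin, spacing, x, y, z)
  }
  velocity <- function(x, y, z, t) {
    n <- max(length(x), length(y), length(z), length(t))
    x <- rep_len(x, n); y <- rep_len(y, n); z <- rep_len(z, n)
    tm <- rep_len(t, n) %% period
    if (nt == 1) {
      return(list(u = eval_snap(1, "u", x, y, z),
                  v = eval_snap(1, "v", x, y, z),
                  w = eval_snap(1, "w", x, y, z)))
    }
    # periodic linear interpolation between bracketing snapshots
    k0 <- findInterval(tm, times)
    k0[k0 == 0] <- nt  # before the first snapshot: wrap from the last
    k1 <- k0 %% nt + 1
    t0 <- times[k0]
    span <- (times[k1] - t0) %% period
    span[span == 0] <- period
    wgt <- ((tm - t0) %% period) / span
    out <- list(u = numeric(n), v = numeric(n), w = numeric(n))
    for (k in unique(k0)) {
      sel <- which(k0 == k)
      for (comp in c("u", "v", "w")) {
        a0 <- eval_snap(k, comp, x[sel], y[sel], z[sel])
        a1 <- eval_snap(k %% nt + 1, comp, x[sel], y[sel], z[sel])
        out[[comp]][sel] <- (1 - wgt[sel]) * a0 + wgt[sel] * a1
      }
    }
    out
  }
  hi <- origin + (dims - 1) * spacing
  structure(list(velocity = velocity, period = period,
                 a = min(abs(c(origin[1:2], hi[1:2]))),
                 L = hi[3], w0 = NA_real_, eps = NA_real_, tau = NA_real_,
                 P = NA_real_, origin = "vtk", nan_is_oob = TRUE,
                 bounds = rbind(origin, hi)),
            class = "velocity_field")
}

#' Export pathlines as a legacy VTK polyline file
#'
#' @param trace a `fontan_trace` with recorded samples (see [advect()]).
#' @param path output `.vtk` file.
#' @return `path`, invisibly.
#' @export
write_pathlines_vtk <- function(trace, path) {
  if (is.null(trace$samples)) abort("trace has no recorded samples; use advect()")
  s <- trace$samples
  ids <- unique(s$particle_id)
  npts <- nrow(s)
  con <- file(path, "w")
  writeLines(c("# vtk DataFile Version 3.0", "fontanmix pathlines", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d float", npts)), con)
  writeLines(sprintf("%.9g %.9g %.9g", s$x, s$y, s$z), con)
  sizes <- tabulate(match(s$particle_id, ids))
  writeLines(sprintf("LINES %d %d", length(ids), length(ids) + npts), con)
  off <- 0
  for (i in seq_along(ids)) {
    writeLines(paste(c(sizes[i], seq.int(off, off + sizes[i] - 1)),
                     collapse = " "), con)
    off <- off + sizes[i]
  }
  close(con)
  invisible(path)
}
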