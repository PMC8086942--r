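QUADRANTS <- c("left-anterior", "left-posterior",
               "right-anterior", "right-posterior")
MIXING_LEVELS <- c("no mixing", "poor mixing", "mild mixing",
                   "moderate mixing", "good mixing", "uniform mixing")

#' Quadrant of an in-plane position
#'
#' The conduit cross-section is subdivided along the right-left (x) and
#' anterior-posterior (y) axes into four subsections. `x > 0` is left,
#' `y > 0` anterior; positions exactly on an axis are assigned to the
#' positive (left / anterior) side.
#'
#' @param x,y in-plane coordinates (vectorised).
#' @return Character vector of quadrant labels.
#' @examples
#' quadrant_of(c(0.4, -0.4, 0), c(0.4, -0.4, -0.4))
#' @export
quadrant_of <- function(x, y) {
  paste0(ifelse(x >= 0, "left", "right"), "-",
         ifelse(y >= 0, "anterior", "posterior"))
}

#' Transection count table
#'
#' Bins plane transections by plane, phase of the cardiac cycle, quadrant and
#' source label into HV/IVC counts, completing the grid with zeros.
#'
#' @param crossings a transection tibble (from [trace_particles()] or
#'   [detect_crossings()]) with columns `plane`, `phase`, `label`, `x`, `y`.
#' @param n_steps phases per cardiac cycle.
#' @return A tibble with columns `plane`, `phase`, `quadrant`, `n_hv`,
#'   `n_ivc` covering every plane x phase x quadrant combination.
#' @export
transection_table <- function(crossings, n_steps) {
  crossings <- as_tibble(crossings)
  if (!all(crossings$label %in% c("HV", "IVC"))) {
    abort("transection counting requires HV/IVC-labelled crossings")
  }
  planes <- unique(crossings$plane)
  if (!length(planes)) {
    return(tibble(plane = character(), phase = integer(),
                  quadrant = character(), n_hv = integer(),
                  n_ivc = integer()))
  }
  counts <- crossings %>%
    mutate(quadrant = quadrant_of(.data$x, .data$y)) %>%
    count(.data$plane, .data$phase, .data$quadrant, .data$label)
  grid <- tidyr::expand_grid(plane = planes,
                             phase = seq_len(n_steps),
                             quadrant = QUADRANTS,
                             label = c("HV", "IVC"))
  grid %>%
    left_join(counts, by = c("plane", "phase", "quadrant", "label")) %>%
    mutate(n = dplyr::coalesce(.data$n, 0L)) %>%
    tidyr::pivot_wider(names_from = "label", values_from = "n") %>%
    rename(n_hv = "HV", n_ivc = "IVC") %>%
    arrange(.data$plane, .data$phase, .data$quadrant)
}

#' Subsection mixing index
#'
#' Compares a subsection's HV:IVC transection ratio with the ratio over the
#' entire cross-section. With subsection HV fraction
#' `f_s = n_hv_s / (n_hv_s + n_ivc_s)` and cross-section fraction
#' `f_g = n_hv_g / (n_hv_g + n_ivc_g)`, the index is the tent ratio
#' \deqn{M = \min(f_s / f_g,\; (1 - f_s)/(1 - f_g)),}
#' which is 0 exactly when the subsection is pure (only HV or only IVC
#' transections present: no mixing) and 1 exactly when the subsection carries
#' the same HV:IVC ratio as the entire cross-section (perfect mixing). M is
#' undefined (`NA`) when the subsection is empty or when the cross-section
#' itself is pure (`f_g` of 0 or 1), since no ratio comparison is possible.
#'
#' @param n_hv_s,n_ivc_s subsection HV and IVC transection counts
#'   (vectorised).
#' @param n_hv_g,n_ivc_g cross-section (pooled over all four subsections)
#'   counts.
#' @return Mixing index in `[0, 1]`, or `NA` where undefined.
#' @examples
#' mixing_index(12, 0, 40, 60)   # pure subsection -> 0
#' mixing_index(5, 15, 25, 75)   # ratio-matching subsection -> 1
#' @export
mixing_index <- function(n_hv_s, n_ivc_s, n_hv_g, n_ivc_g) {
  counts <- cbind(n_hv_s, n_ivc_s, n_hv_g, n_ivc_g)
  if (any(counts < 0)) abort("transection counts must be non-negative")
  f_g <- n_hv_g / (n_hv_g + n_ivc_g)          # NaN when cross-section empty
  f_s <- n_hv_s / (n_hv_s + n_ivc_s)          # NaN when subsection empty
  m <- pmin(f_s / f_g, (1 - f_s) / (1 - f_g))
  m[!is.finite(f_s) | !is.finite(f_g) | f_g == 0 | f_g == 1] <- NA_real_
  unname(m)
}

#' Cross-section mixing at one phase
#'
#' Aggregates the four quadrant mixing indices of one phase into a single
#' cross-section value: by default the transection-count-weighted mean over
#' the quadrants where M is defined (robust when a quadrant receives few
#' transections); `weighted = FALSE` gives the plain mean.
#'
#' @param m quadrant mixing indices (length 4, `NA` = undefined).
#' @param counts total transections (HV + IVC) per quadrant.
#' @param weighted use count weighting (default `TRUE`).
#' @return The cross-section mixing index, or `NA` if all quadrants are
#'   undefined.
#' @examples
#' cross_section_mixing(c(0.4, 0.8), c(30, 10))
#' @export
cross_section_mixing <- function(m, counts = rep(1, length(m)),
                                 weighted = TRUE) {
  ok <- !is.na(m)
  if (!any(ok)) return(NA_real_)
  if (!weighted) return(mean(m[ok]))
  weighted.mean(m[ok], counts[ok])
}

#' Cycle-averaged mixing per subsection and cross-section
#'
#' Computes the per-phase mixing index for every quadrant and for the entire
#' cross-section, then averages over the phases of the analysis cycle where
#' the index is defined (`M_average`), attaching the clinical category label.
#'
#' @param table a transection count table from [transection_table()],
#'   restricted to the analysis cycle.
#' @param weighted count-weight the cross-section aggregate (see
#'   [cross_section_mixing()]).
#' @return An object of class `fontan_mixing`: a list with
#'   `phase` (tibble: `plane`, `quadrant` — the four subsections plus
#'   `"all"` —, `phase`, `n_hv`, `n_ivc`, `M`) and
#'   `summary` (tibble: `plane`, `quadrant`, `M_average`, `n_defined`,
#'   `n_undefined`, `category`).
#' @export
average_mixing <- function(table, weighted = TRUE) {
  table <- as_tibble(table)
  glob <- table %>%
    group_by(.data$plane, .data$phase) %>%
    summarise(g_hv = sum(.data$n_hv), g_ivc = sum(.data$n_ivc),
              .groups = "drop")
  quad <- table %>%
    left_join(glob, by = c("plane", "phase")) %>%
    mutate(M = mixing_index(.data$n_hv, .data$n_ivc, .data$g_hv, .data$g_ivc)) %>%
    select("plane", "quadrant", "phase", "n_hv", "n_ivc", "M")
  whole <- quad %>%
    group_by(.data$plane, .data$phase) %>%
    summarise(quadrant = "all",
              M = cross_section_mixing(.data$M, .data$n_hv + .data$n_ivc,
                                       weighted = weighted),
              n_hv = sum(.data$n_hv), n_ivc = sum(.data$n_ivc),
              .groups = "drop") %>%
    select("plane", "quadrant", "phase", "n_hv", "n_ivc", "M")
  phase <- bind_rows(quad, whole) %>%
    arrange(.data$plane, .data$quadrant, .data$phase)
  summary <- phase %>%
    group_by(.data$plane, .data$quadrant) %>%
    summarise(M_average = if (any(!is.na(.data$M))) mean(.data$M, na.rm = TRUE)
              else NA_real_,
              n_defined = sum(!is.na(.data$M)),
              n_undefined = sum(is.na(.data$M)),
              .groups = "drop") %>%
    mutate(category = as.character(categorize_mixing(.data$M_average)))
  if (any(summary$n_defined == 0)) {
    warn("M is undefined at every phase for at least one plane/quadrant")
  }
  structure(list(phase = phase, summary = summary),
            class = "fontan_mixing")
}

#' Clinical mixing category
#'
#' Bins a cycle-averaged mixing index into the clinical categories:
#' no mixing `[0, 0.1)`, poor `[0.1, 0.3)`, mild `[0.3, 0.5)`, moderate
#' `[0.5, 0.7)`, good `[0.7, 0.9)` and uniform mixing `[0.9, 1]`
#' (half-open on the left; the range endpoints overlap in prose, so a
#' convention is required).
#'
#' @param m mixing values in `[0, 1]` (vectorised).
#' @return Ordered factor of category labels.
#' @examples
#' categorize_mixing(c(0.05, 0.66, 0.79, 0.95))
#' @export
categorize_mixing <- function(m) {
  if (any(!is.na(m) & (!is.finite(m) | m < 0 | m > 1))) {
    abort("mixing values must lie in [0, 1]")
  }
  idx <- findInterval(m, c(0, 0.1, 0.3, 0.5, 0.7, 0.9), rightmost.closed = FALSE)
  factor(MIXING_LEVELS[idx], levels = MIXING_LEVELS, ordered = TRUE)
}

#' @export
print.fontan_mixing <- function(x, ...) {
  cat("<fontan_mixing>\n")
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}

#' @rdname average_mixing
#' @param x a `fontan_mixing` object.
#' @param ... unused.
#' @export
tidy.fontan_mixing <- function(x, ...) x$phase

#' @rdname average_mixing
#' @export
glance.fontan_mixing <- function(x, ...) {
  x$summary %>%
    filter(.data$quadrant == "all") %>%
    select("plane", "M_average") %>%
    tidyr::pivot_wider(names_from = "plane", values_from = "M_average",
                       names_prefix = "M_")
}

#' End-to-end mixing analysis of one virtual patient
#'
#' Releases HV/IVC-labelled particles from the caudal plane at every time
#' step for `cycles` cardiac cycles, traces them, records the transections at
#' the caudal and cranial cross-sections during the final cycle and computes
#' the mixing indices.
#'
#' @param field a `velocity_field`.
#' @param config the [flow_config()] that generated it.
#' @param n_hv HV particles per release event (default 7500, the study-scale
#'   count; reduce for quick exploration).
#' @param cycles release/analysis horizon in cardiac cycles (default 5;
#'   transections are analysed in the final cycle).
#' @param substeps RK4 substeps per time step.
#' @param seed optional seed for the release positions.
#' @param weighted count-weight the cross-section aggregate.
#' @return A `fontan_mixing` object (see [average_mixing()]) with the raw
#'   analysis-cycle crossings attached as attribute `crossings`.
#' @export
run_mixing <- function(field, config, n_hv = 7500, cycles = 5,
                       substeps = 10, seed = NULL, weighted = TRUE) {
  seeds <- release_schedule(config, "mixing", n_hv = n_hv, cycles = cycles,
                            seed = seed)
  tr <- trace_particles(field, seeds, n_steps = config$n_steps,
                        substeps = substeps, max_cycles = cycles,
                        planes = c(caudal = config$z_c, cranial = config$z_cr))
  cyc <- filter(tr$crossings, .data$cycle == cycles)
  res <- average_mixing(transection_table(cyc, config$n_steps),
                        weighted = weighted)
  attr(res, "crossings") <- cyc
  attr(res, "analysis_cycle") <- cycles
  res
}
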