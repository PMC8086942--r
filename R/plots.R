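#' Plot time-resolved mixing per subsection
#'
#' Mixing index against cardiac-cycle phase for each quadrant and for the
#' entire cross-section, one panel per analysis plane.
#'
#' @param object a `fontan_mixing` from [run_mixing()] / [average_mixing()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.fontan_mixing <- function(object, ...) {
  ggplot2::ggplot(object$phase,
                  ggplot2::aes(x = .data$phase, y = .data$M,
                               colour = .data$quadrant)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$plane)) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "phase of cardiac cycle", y = "mixing index M",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Bland-Altman panels for an HFD agreement report
#'
#' One Bland-Altman panel per method pair: per-subject difference against
#' pair mean, with the mean difference (solid) and limits of agreement
#' (dashed).
#'
#' @param object an `hfd_agreement` from [hfd_agreement()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.hfd_agreement <- function(object, ...) {
  wide <- attr(object, "wide")
  pts <- purrr::map_dfr(seq_len(nrow(object)), function(i) {
    pr <- strsplit(object$comparison[i], " vs ", fixed = TRUE)[[1]]
    tibble(comparison = object$comparison[i],
           mean = (wide[[pr[1]]] + wide[[pr[2]]]) / 2,
           diff = wide[[pr[1]]] - wide[[pr[2]]])
  })
  lines <- tidyr::pivot_longer(
    select(as_tibble(as.data.frame(object)),
           "comparison", "mean_diff", "loa_lower", "loa_upper"),
    -"comparison", names_to = "which", values_to = "y")
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(data = lines,
                        ggplot2::aes(yintercept = .data$y,
                                     linetype = .data$which == "mean_diff")) +
    ggplot2::facet_wrap(ggplot2::vars(.data$comparison)) +
    ggplot2::guides(linetype = "none") +
    ggplot2::labs(x = "pair mean HFD (%)", y = "difference (percentage points)") +
    ggplot2::theme_minimal()
}
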