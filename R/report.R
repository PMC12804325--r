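#' Plot fitted coverage curves for a sweep
#'
#' One sigmoid per sweep value over observed MAM from -5 to 10 mm, with the
#' target-probability line and the fitted A0 threshold marked per curve.
#'
#' @param sweeps a `sweep_result_list` from [run_sweep()]
#' @param file optional output path (png or svg); when `NULL` the ggplot
#'   object is returned without writing
#' @return the ggplot object, invisibly if written to file
#' @export
plot_coverage_curves <- function(sweeps, file = NULL) {
  if (length(sweeps) == 0) stop("no sweep results to plot", call. = FALSE)
  vary <- attr(sweeps, "vary")
  xs <- seq(-5, 10, by = 0.05)
  curves <- do.call(rbind, lapply(sweeps, function(s) {
    if (is.null(s$estimate)) {
      warning("sweep value ", s$value, " has no fit; curve omitted")
      return(NULL)
    }
    data.frame(x = xs,
               p = plogis(s$estimate$beta0 + s$estimate$beta1 * xs),
               value = factor(s$value),
               x_a0 = s$estimate$x_a0)
  }))
  marks <- unique(curves[, c("value", "x_a0")])
  p_target <- sweeps[[1]]$estimate$p_target
  gg <- ggplot2::ggplot(curves, ggplot2::aes(x = .data$x, y = .data$p,
                                             colour = .data$value)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = p_target, linetype = "dashed") +
    ggplot2::geom_vline(data = marks,
                        ggplot2::aes(xintercept = .data$x_a0,
                                     colour = .data$value),
                        linetype = "dotted", show.legend = FALSE) +
    ggplot2::labs(x = "Observed MAM (mm)",
                  y = "P(true complete coverage)",
                  colour = vary) +
    ggplot2::coord_cartesian(xlim = c(-5, 10), ylim = c(0, 1)) +
    ggplot2::theme_minimal()
  if (is.null(file)) return(gg)
  ggplot2::ggsave(file, gg, width = 7, height = 4.5, dpi = 150)
  invisible(gg)
}

#' Contour plot of the A0 threshold over segmentation x registration error
#'
#' Filled contours of the fitted A0 threshold with the 5-mm level drawn
#' explicitly: the region below that line is where the conventional 5-mm
#' margin rule remains reliable.
#'
#' @param grid_result an `a0_grid` from [run_grid()]
#' @param file optional output path (png or svg)
#' @return the ggplot object, invisibly if written to file
#' @export
plot_a0_contour <- function(grid_result, file = NULL) {
  tab <- grid_result$table
  if (length(unique(tab$segmentation_sd_mm)) < 2 ||
      length(unique(tab$registration_sd_mm)) < 2)
    stop("contour needs at least a 2 x 2 grid", call. = FALSE)
  if (anyNA(tab$x_a0)) {
    warning("NA cells in A0 grid are dropped from the contour")
    tab <- tab[!is.na(tab$x_a0), , drop = FALSE]
  }
  gg <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$registration_sd_mm,
                                          y = .data$segmentation_sd_mm,
                                          z = .data$x_a0)) +
    ggplot2::geom_contour_filled(bins = 8, alpha = 0.9) +
    ggplot2::geom_contour(breaks = 5, colour = "black", linewidth = 1) +
    ggplot2::labs(x = "Registration error SD (mm)",
                  y = "Segmentation error SD (mm)",
                  fill = "A0 (mm)") +
    ggplot2::theme_minimal()
  if (is.null(file)) return(gg)
  ggplot2::ggsave(file, gg, width = 6.5, height = 5, dpi = 150)
  invisible(gg)
}

#' Reliability verdict for the 5-mm margin rule
#'
#' A pure function of an [estimate_a0()] result: the 5-mm rule is deemed
#' reliable when the fitted A0 threshold does not exceed 5 mm (boundary
#' inclusive).
#'
#' @param estimate an `a0_estimate`
#' @return object of class `reliability_verdict`: `x_a0`,
#'   `five_mm_reliable`, `p_coverage_at_5mm`
#' @export
verdict <- function(estimate) {
  stopifnot(inherits(estimate, "a0_estimate"))
  structure(list(x_a0 = estimate$x_a0,
                 five_mm_reliable = estimate$x_a0 <= 5.0,
                 p_coverage_at_5mm = estimate$p_coverage_at_5mm),
            class = "reliability_verdict")
}

#' @export
print.reliability_verdict <- function(x, ...) {
  cat(sprintf(
    "<reliability_verdict> A0 = %.1f mm; 5-mm rule %s (P[coverage | obs >= 5 mm] = %.3f)\n",
    x$x_a0, if (x$five_mm_reliable) "RELIABLE" else "UNRELIABLE",
    x$p_coverage_at_5mm))
  invisible(x)
}
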