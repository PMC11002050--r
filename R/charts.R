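# Presentation layer: Shewhart Z-score charts and tolerance-band charts.
# All numbers come from the report objects; plotting adds nothing.

#' Shewhart control chart of prediction Z-scores
#'
#' Plots each sample's Z-score against its index with the
#' \eqn{\pm 1.96\,\mathrm{SD}(Z)} band (dashed) and the fixed \eqn{\pm 2}
#' and \eqn{\pm 3} \eqn{\sigma_{max}}-unit lines (dotted). Points outside
#' the 95% band are drawn filled.
#'
#' @param report a `zscore_report` from [compute_zscores()].
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, the data frame of plotted values.
#' @export
plot_zscore_chart <- function(report, ...) {
  stopifnot(inherits(report, "zscore_report"))
  z <- report$z
  n <- length(z)
  ylim <- range(c(z, 3.2, -3.2, 1.1 * report$limit_95,
                  -1.1 * report$limit_95))
  graphics::plot(seq_len(n), z, type = "n", xlab = "Sample index",
                 ylab = "Z-score", ylim = ylim,
                 main = sprintf("Z-score chart: %s (%s)", report$analyte,
                                report$mode), ...)
  graphics::abline(h = 0, col = "grey60")
  graphics::abline(h = c(-1, 1) * report$limit_95, lty = 2, col = "firebrick")
  graphics::abline(h = c(-2, 2), lty = 3, col = "grey40")
  graphics::abline(h = c(-3, 3), lty = 3, col = "grey40")
  graphics::points(seq_len(n), z, pch = ifelse(report$inside, 1, 16),
                   col = ifelse(report$inside, "steelblue4", "firebrick"))
  invisible(data.frame(index = seq_len(n), z = z, inside = report$inside))
}

#' Tolerance-band chart of predictions in ascending reference order
#'
#' Draws the acceptable band `[ALL(i), AUL(i)]` around the reference values
#' arranged in ascending order, with the predictions overlaid; predictions
#' outside their band are drawn filled.
#'
#' @param report a `tolerance_report` from [tolerance_bands()].
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, the data frame of plotted values (ascending order).
#' @export
plot_tolerance_chart <- function(report, ...) {
  stopifnot(inherits(report, "tolerance_report"))
  o <- report$order
  n <- length(o)
  idx <- seq_len(n)
  ylim <- range(c(report$all[o], report$aul[o], report$predicted[o]))
  graphics::plot(idx, report$actual[o], type = "n",
                 xlab = "Sample (ascending reference value)",
                 ylab = expression("Concentration (g kg"^-1 * ")"),
                 ylim = ylim,
                 main = sprintf("Tolerance intervals: %s (%.1f%% inside)",
                                report$analyte, report$percent_inside), ...)
  graphics::polygon(c(idx, rev(idx)), c(report$all[o], rev(report$aul[o])),
                    col = grDevices::adjustcolor("grey70", 0.5), border = NA)
  graphics::lines(idx, report$actual[o], col = "grey30")
  graphics::points(idx, report$predicted[o],
                   pch = ifelse(report$inside[o], 1, 16),
                   col = ifelse(report$inside[o], "steelblue4", "firebrick"))
  invisible(data.frame(index = idx, actual = report$actual[o],
                       predicted = report$predicted[o],
                       all = report$all[o], aul = report$aul[o],
                       inside = report$inside[o]))
}

#' Write assessment charts to files
#'
#' Renders a Shewhart chart for each `zscore_report` and a tolerance chart
#' for each `tolerance_report` as PNG files named after the analyte.
#'
#' @param reports non-empty list of `zscore_report` and/or
#'   `tolerance_report` objects.
#' @param dir output directory (created if missing).
#' @param width,height,res PNG device parameters.
#' @return Character vector of written file paths, invisibly.
#' @export
render_charts <- function(reports, dir, width = 900, height = 600, res = 110) {
  if (length(reports) == 0) stop_nutrispec("no reports to render")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (rep in reports) {
    if (inherits(rep, "zscore_report")) {
      path <- file.path(dir, sprintf("zscore_%s.png", gsub("[^A-Za-z0-9]", "_", rep$analyte)))
      grDevices::png(path, width = width, height = height, res = res)
      plot_zscore_chart(rep)
      grDevices::dev.off()
    } else if (inherits(rep, "tolerance_report")) {
      path <- file.path(dir, sprintf("tolerance_%s.png", gsub("[^A-Za-z0-9]", "_", rep$analyte)))
      grDevices::png(path, width = width, height = height, res = res)
      plot_tolerance_chart(rep)
      grDevices::dev.off()
    } else {
      stop_nutrispec("render_charts accepts zscore_report / tolerance_report objects")
    }
    paths <- c(paths, path)
  }
  invisible(paths)
}
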