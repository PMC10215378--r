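# Base-graphics plots in the style of published titration-panel figures:
# observed points, the fitted curve, and vertical guides at the derived
# doses (Rmax/Rmin for the linear-logistic fit, the breakpoint for the
# segmented fit).

#' Plot a linear-logistic fit
#'
#' Draws the data, the fitted rise-dip-rise curve, and dashed vertical
#' guides at Rmax (the dose maximizing the response) and Rmin (the local
#' minimum) when they exist.
#'
#' @param x A `linlog_fit`.
#' @param main Plot title.
#' @param ... Passed to [plot()].
#' @export
plot.linlog_fit <- function(x, main = "Linear-logistic fit", ...) {
  d <- x$data
  xx <- seq(min(d$dose), max(d$dose), length.out = 400)
  yy <- linlog_eval(x$params, xx)
  plot(d$dose, d$response, pch = 16, col = "grey30",
       xlab = "dose", ylab = "response", main = main,
       ylim = range(c(d$response, yy)), ...)
  graphics::lines(xx, yy, lwd = 2, col = "steelblue")
  st <- x$stationary
  if (st$regime == "two_points") {
    graphics::abline(v = c(st$rmax, st$rmin), lty = 2,
                     col = c("darkgreen", "firebrick"))
    graphics::mtext(sprintf("Rmax = %.4g", st$rmax), side = 3, adj = 0,
                    cex = 0.8, col = "darkgreen")
    graphics::mtext(sprintf("Rmin = %.4g", st$rmin), side = 3, adj = 1,
                    cex = 0.8, col = "firebrick")
  }
  invisible(x)
}

#' Plot a segmented (linear-plateau) fit
#'
#' @param x A `segmented_fit`.
#' @param main Plot title.
#' @param ... Passed to [plot()].
#' @export
plot.segmented_fit <- function(x, main = "Segmented (linear-plateau) fit",
                               ...) {
  d <- x$data
  xx <- seq(min(d$dose), max(d$dose), length.out = 400)
  yy <- stats::predict(x, xx)
  plot(d$dose, d$response, pch = 17, col = "grey30",
       xlab = "dose", ylab = "response", main = main,
       ylim = range(c(d$response, yy)), ...)
  graphics::lines(xx, yy, lwd = 2, lty = 5, col = "goldenrod3")
  graphics::abline(v = x$breakpoint, lty = 2, col = "firebrick")
  graphics::mtext(sprintf("breakpoint = %.4g", x$breakpoint), side = 3,
                  adj = 1, cex = 0.8, col = "firebrick")
  invisible(x)
}

#' Paired panel: primary curve with Rmax/Rmin plus companion breakpoint
#'
#' Two stacked panels sharing the dose axis: the primary (growth-type)
#' response with its linear-logistic fit and stationary-dose guides, and
#' the companion (physiological) response with its segmented fit and
#' breakpoint guide.
#'
#' @param x A `coincidence_report`.
#' @param ... Unused.
#' @export
plot.coincidence_report <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  plot(x$primary_fit, main = "Primary response (linear-logistic)")
  if (x$regime == "two_points")
    graphics::abline(v = x$breakpoint, lty = 3, col = "goldenrod3")
  plot(x$companion_fit, main = "Companion response (segmented)")
  invisible(x)
}

# write a plot to PNG; used by the CLI --plot flag
save_plot_png <- function(obj, path, width = 900, height = 700) {
  grDevices::png(path, width = width, height = height, res = 110)
  on.exit(grDevices::dev.off())
  plot(obj)
  invisible(path)
}
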