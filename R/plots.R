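#' Circular intensity profile diagram
#'
#' Plots the angular rim profile of each channel of one vesicle against the
#' bin angle (degrees), the standard companion diagram to an equatorial
#' section: segregating lectins show complementary arcs, co-localising
#' lectins parallel traces.
#'
#' @param profile a [extract_rim_profile()] result.
#' @param channels channels to draw (default: all).
#' @param col line colours, recycled.
#' @param ... passed to [graphics::matplot()].
#' @return The plotted matrix, invisibly.
#' @export
plot_rim_profile <- function(profile, channels = colnames(profile$values),
                             col = c("forestgreen", "darkorange", "blue"), ...) {
  stopifnot(inherits(profile, "guv_rim_profile"))
  v <- profile$values[, channels, drop = FALSE]
  graphics::matplot(profile$angles * 180 / pi, v, type = "l", lty = 1,
                    col = col, xlab = "angle (degrees)",
                    ylab = "rim intensity (a.u.)", ...)
  graphics::legend("topright", legend = channels, col = col[seq_along(channels)],
                   lty = 1, bty = "n")
  invisible(v)
}
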