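#' Extract the circular rim intensity profile of one vesicle
#'
#' For every angular bin (bin k covers `[(k-1), k) * 2*pi/n_bins`, sampled at
#' its centre angle) and every channel, the bin intensity is the maximum of
#' the interpolated image along the radial ray within
#' `[radius - band_halfwidth, radius + band_halfwidth]`. The radial maximum is
#' robust to sub-pixel errors in the detected centre for a thin rim.
#'
#' Besides the per-bin statistic the profile also records every raw pixel
#' inside the rim band together with its signed radial distance and angular
#' bin; [compute_binding_efficiency()] uses these to estimate the rim peak
#' without interpolation loss.
#'
#' @param image a [multichannel_image()] (2-D).
#' @param det one detection: a single-row `guv_detections` data.frame or a
#'   list with `x`, `y`, `radius` (and optional QC flags, which must be
#'   `FALSE`).
#' @param n_bins number of angular bins (default 360, i.e. 1 degree).
#' @param band_halfwidth radial half-width of the rim band, pixels.
#' @param radial_step radial sampling step along each ray, pixels.
#' @param interp interpolation used for ray sampling.
#' @param saturation_level intensities at or above this value anywhere in the
#'   band flag the vesicle as saturated (contrast is undefined under
#'   clipping); default `Inf` disables the check.
#' @return A `guv_rim_profile`: list with `values` (n_bins x channels matrix
#'   of bin intensities), `radial` (n_bins x radial samples x channels
#'   array), `band_pixels` (data.frame of raw band pixels), `angles`,
#'   `rim_band`, `center`, `radius`, `roles`, `saturated`.
#' @export
extract_rim_profile <- function(image, det, n_bins = 360L, band_halfwidth = 3,
                                radial_step = 0.5,
                                interp = c("bilinear", "cubic"),
                                saturation_level = Inf) {
  stopifnot(inherits(image, "guv_mcimage"))
  interp <- match.arg(interp)
  if (is.data.frame(det)) {
    stopifnot(nrow(det) == 1L)
    det <- as.list(det)
  }
  for (fl in c("border_touching", "overlapping", "too_small")) {
    if (isTRUE(det[[fl]])) stopf("detection is flagged '%s'; not quantifiable", fl)
  }
  x0 <- det$x; y0 <- det$y; r <- det$radius
  ch1 <- image$channels[[1]]
  h <- nrow(ch1); w <- ncol(ch1)
  if (x0 - (r + band_halfwidth) < 0 || x0 + (r + band_halfwidth) > w - 1 ||
      y0 - (r + band_halfwidth) < 0 || y0 + (r + band_halfwidth) > h - 1) {
    stopf("rim band extends outside the image")
  }
  if (r - band_halfwidth <= 0) stopf("band_halfwidth must be smaller than the radius")
  n_bins <- as.integer(n_bins)
  angles <- (seq_len(n_bins) - 0.5) * 2 * pi / n_bins
  rr <- seq(r - band_halfwidth, r + band_halfwidth, by = radial_step)
  px <- outer(cos(angles), rr, function(ct, d) x0 + ct * d)
  py <- outer(sin(angles), rr, function(st, d) y0 + st * d)
  chans <- names(image$channels)
  radial <- array(NA_real_, dim = c(n_bins, length(rr), length(chans)),
                  dimnames = list(NULL, NULL, chans))
  values <- matrix(NA_real_, n_bins, length(chans), dimnames = list(NULL, chans))
  for (ci in seq_along(chans)) {
    v <- sample_image(image$channels[[chans[ci]]], as.vector(px), as.vector(py),
                      method = interp)
    radial[, , ci] <- v
    values[, ci] <- apply(radial[, , ci, drop = FALSE], 1, max)
  }
  # raw pixels inside the band, with signed radial distance and angular bin
  x_lo <- max(0, floor(x0 - r - band_halfwidth)); x_hi <- min(w - 1, ceiling(x0 + r + band_halfwidth))
  y_lo <- max(0, floor(y0 - r - band_halfwidth)); y_hi <- min(h - 1, ceiling(y0 + r + band_halfwidth))
  xs <- x_lo:x_hi; ys <- y_lo:y_hi
  Xs <- matrix(rep(xs, each = length(ys)), nrow = length(ys))
  Ys <- matrix(rep(ys, times = length(xs)), nrow = length(ys))
  dd <- sqrt((Xs - x0)^2 + (Ys - y0)^2)
  sel <- abs(dd - r) <= band_halfwidth
  th <- wrap_angle(atan2(Ys[sel] - y0, Xs[sel] - x0))
  bin <- pmin(floor(th / (2 * pi / n_bins)) + 1L, n_bins)
  band_pixels <- data.frame(dr = dd[sel] - r, bin = as.integer(bin))
  saturated <- FALSE
  for (cn in chans) {
    chv <- image$channels[[cn]][cbind(Ys[sel] + 1L, Xs[sel] + 1L)]
    band_pixels[[cn]] <- chv
    if (any(chv >= saturation_level)) saturated <- TRUE
  }
  structure(list(values = values, radial = radial, band_pixels = band_pixels,
                 angles = angles, n_bins = n_bins,
                 rim_band = c(inner = r - band_halfwidth, outer = r + band_halfwidth),
                 center = c(x = x0, y = y0), radius = r,
                 roles = image$roles, saturated = saturated),
            class = "guv_rim_profile")
}

#' @export
print.guv_rim_profile <- function(x, ...) {
  cat(sprintf("<guv_rim_profile> r = %.2f px at (%.2f, %.2f), %d bins, band [%.2f, %.2f]\n",
              x$radius, x$center[1], x$center[2], x$n_bins,
              x$rim_band[1], x$rim_band[2]))
  invisible(x)
}

# Resolve a role or channel name against a profile.
profile_channel <- function(profile, channel) {
  nm <- if (channel %in% names(profile$roles)) profile$roles[[channel]] else channel
  if (!nm %in% colnames(profile$values)) stopf("profile has no channel '%s'", channel)
  nm
}
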