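#' Multi-channel fluorescence image
#'
#' Container for an equatorial confocal section (2-D) or a z-stack (3-D) with
#' a map from biological roles to channels. Pixel coordinates are 0-based with
#' the origin at the top-left corner, x increasing to the right (columns) and
#' y increasing downwards (rows); angles are measured from the +x axis towards
#' +y. All modules share this convention.
#'
#' @param channels named list of numeric matrices (2-D) or 3-D arrays, one per
#'   channel, all with identical dimensions and non-negative intensities.
#' @param roles named character vector mapping roles (`marker`, `lectin_1`,
#'   optionally `lectin_2`) to channel names. Exactly one `marker` entry is
#'   required for rim images.
#' @param pixel_size lateral pixel size in micrometres per pixel.
#' @return An object of class `guv_mcimage`.
#' @examples
#' ch <- list(bodipy = matrix(0, 32, 32), lecA = matrix(1, 32, 32))
#' img <- multichannel_image(ch, c(marker = "bodipy", lectin_1 = "lecA"))
#' @export
multichannel_image <- function(channels, roles, pixel_size = 0.1) {
  if (!is.list(channels) || is.null(names(channels)) || any(names(channels) == "")) {
    stopf("`channels` must be a named list of arrays")
  }
  dims <- lapply(channels, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L) {
    stopf("all channels must share the same dimensions")
  }
  for (nm in names(channels)) {
    if (!is.numeric(channels[[nm]])) stopf("channel '%s' is not numeric", nm)
    if (any(channels[[nm]] < 0, na.rm = TRUE)) {
      stopf("channel '%s' contains negative intensities", nm)
    }
  }
  roles <- unlist(roles)
  if (is.null(names(roles))) stopf("`roles` must be named by role")
  if (sum(names(roles) == "marker") > 1L) stopf("exactly one marker channel is allowed")
  missing <- setdiff(roles, names(channels))
  if (length(missing)) stopf("roles refer to unknown channels: %s", paste(missing, collapse = ", "))
  structure(
    list(channels = channels, roles = roles, pixel_size = pixel_size),
    class = "guv_mcimage"
  )
}

#' Extract one channel by role or name
#'
#' @param image a [multichannel_image()].
#' @param which a role (`"marker"`, `"lectin_1"`, ...) or a channel name.
#' @return The channel's numeric array.
#' @export
get_channel <- function(image, which) {
  stopifnot(inherits(image, "guv_mcimage"))
  nm <- if (which %in% names(image$roles)) image$roles[[which]] else which
  if (!nm %in% names(image$channels)) stopf("no channel for '%s'", which)
  image$channels[[nm]]
}

#' Roles of the lectin channels present in an image
#' @param image a [multichannel_image()].
#' @return Character vector of lectin roles, e.g. `c("lectin_1", "lectin_2")`.
#' @export
lectin_roles <- function(image) {
  stopifnot(inherits(image, "guv_mcimage"))
  sort(grep("^lectin", names(image$roles), value = TRUE))
}

#' Rotate a 2-D multi-channel image by multiples of 90 degrees
#'
#' Exact pixel permutation (no interpolation); used by the rotation-invariance
#' checks of the binding statistic.
#'
#' @param image a 2-D [multichannel_image()].
#' @param k number of counter-clockwise quarter turns (in matrix terms).
#' @return The rotated image.
#' @export
rotate_image <- function(image, k = 1L) {
  stopifnot(inherits(image, "guv_mcimage"))
  k <- ((k %% 4) + 4) %% 4
  rot1 <- function(m) t(m)[ncol(m):1, , drop = FALSE]
  chans <- image$channels
  for (i in seq_len(k)) chans <- lapply(chans, rot1)
  multichannel_image(chans, image$roles, image$pixel_size)
}

#' @export
print.guv_mcimage <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<guv_mcimage> %s px, %d channel(s), %.3g um/px\n",
              paste(d, collapse = " x "), length(x$channels), x$pixel_size))
  for (r in names(x$roles)) cat(sprintf("  %-9s -> %s\n", r, x$roles[[r]]))
  invisible(x)
}
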