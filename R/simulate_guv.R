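#' Specification of one synthetic GUV
#'
#' Describes a vesicle as it appears in an equatorial confocal section: a
#' circular rim whose radial profile is Gaussian with sigma `rim_width`
#' (mimicking a PSF-limited thin bilayer), carrying a membrane-marker signal
#' that is bright on liquid-disordered (ld) arcs and dim on liquid-ordered
#' (lo) arcs, and lectin signals whose rim peak is `(1 + contrast) * S` where
#' `S` is the free-lectin solution intensity.
#'
#' @param center numeric length 2, (x, y) centre in pixels (0-based).
#' @param radius rim radius in pixels; must exceed `rim_width`.
#' @param rim_width Gaussian radial sigma of the rim signal, pixels.
#' @param phase_arcs data.frame with columns `start`, `end` (radians) and
#'   `phase` (`"ld"`/`"lo"`); the arcs must partition `[0, 2*pi)` without
#'   overlap. Default: a single ld arc covering the full circle
#'   (non-phase-separated vesicle).
#' @param marker_rim_intensity named numeric `c(ld = , lo = )`, rim peak of the
#'   ld-marker channel in each phase (a.u.). The default 200 vs 50 reflects a
#'   marker that strongly partitions into the ld phase.
#' @param lectin_contrast named list, one element per lectin role
#'   (`lectin_1`, `lectin_2`), each either a single dimensionless contrast or
#'   a named vector `c(ld = , lo = )`. Contrasts must be >= -1 (a rim cannot
#'   be darker than empty).
#' @return A `guv_spec` list.
#' @export
guv_spec <- function(center, radius, rim_width = 1.5,
                     phase_arcs = NULL,
                     marker_rim_intensity = c(ld = 200, lo = 50),
                     lectin_contrast = list(lectin_1 = 1)) {
  stopifnot(length(center) == 2L, is.numeric(center))
  if (!(radius > rim_width && rim_width > 0)) {
    stopf("need radius > rim_width > 0 (got %g, %g)", radius, rim_width)
  }
  if (is.null(phase_arcs)) {
    phase_arcs <- data.frame(start = 0, end = 2 * pi, phase = "ld",
                             stringsAsFactors = FALSE)
  }
  phase_arcs <- phase_arcs[order(phase_arcs$start), , drop = FALSE]
  if (!all(phase_arcs$phase %in% c("ld", "lo"))) stopf("phase labels must be 'ld' or 'lo'")
  tol <- 1e-9
  if (abs(phase_arcs$start[1]) > tol ||
      abs(phase_arcs$end[nrow(phase_arcs)] - 2 * pi) > tol ||
      (nrow(phase_arcs) > 1 &&
       any(abs(phase_arcs$end[-nrow(phase_arcs)] - phase_arcs$start[-1]) > tol))) {
    stopf("phase_arcs must partition [0, 2*pi) contiguously")
  }
  if (any(phase_arcs$end <= phase_arcs$start)) stopf("arcs must have end > start")
  if (!all(c("ld", "lo") %in% names(marker_rim_intensity))) {
    stopf("marker_rim_intensity needs named 'ld' and 'lo' entries")
  }
  lectin_contrast <- lapply(lectin_contrast, function(ct) {
    if (length(ct) == 1L && is.null(names(ct))) ct <- c(ld = unname(ct), lo = unname(ct))
    if (!all(c("ld", "lo") %in% names(ct))) stopf("per-phase contrasts need 'ld' and 'lo' names")
    if (any(ct < -1)) stopf("lectin contrast must be >= -1")
    ct[c("ld", "lo")]
  })
  structure(list(center = as.numeric(center), radius = radius,
                 rim_width = rim_width, phase_arcs = phase_arcs,
                 marker_rim_intensity = marker_rim_intensity[c("ld", "lo")],
                 lectin_contrast = lectin_contrast),
            class = "guv_spec")
}

#' Specification of a synthetic GUV scene
#'
#' Generator configuration for one equatorial-section image: geometry and
#' optics plus the noise model. Intensities are in arbitrary units (a.u.);
#' `poisson_scale` converts a.u. to expected photons, so the rim
#' signal-to-noise ratio is roughly `sqrt(intensity * poisson_scale)`.
#'
#' The rim's Gaussian radial width already represents the PSF-limited image
#' of a thin bilayer, so the default `psf_sigma` is 0; setting it > 0 blurs
#' the whole field in addition (and then rim peaks no longer equal
#' `(1 + contrast) * S` exactly).
#'
#' @param image_shape integer length 2, (rows, cols) in pixels.
#' @param guvs list of [guv_spec()] objects.
#' @param solution_intensity named numeric, free-lectin exterior intensity per
#'   lectin role (a.u.); must be > 0 (the binding statistic divides by it).
#' @param background_offset intensity of lectin-free regions (GUV lumen), a.u.
#' @param psf_sigma extra Gaussian blur sigma in pixels (default 0, see above).
#' @param noise list with `gaussian_sigma` (additive read noise, a.u.) and
#'   `poisson_scale` (photons per a.u.; 0 disables shot noise).
#' @param pixel_size micrometres per pixel.
#' @param seed integer; fully determines the rendered image.
#' @return A `guv_scene_spec` list.
#' @export
scene_spec <- function(image_shape = c(128L, 128L), guvs = list(),
                       solution_intensity = c(lectin_1 = 100),
                       background_offset = 0, psf_sigma = 0,
                       noise = list(gaussian_sigma = 0, poisson_scale = 0),
                       pixel_size = 0.1, seed = 1L) {
  if (any(solution_intensity <= 0)) stopf("solution_intensity must be > 0")
  if (is.null(names(solution_intensity))) stopf("solution_intensity must be named by lectin role")
  noise <- utils::modifyList(list(gaussian_sigma = 0, poisson_scale = 0), as.list(noise))
  structure(list(image_shape = as.integer(image_shape), guvs = guvs,
                 solution_intensity = solution_intensity,
                 background_offset = background_offset, psf_sigma = psf_sigma,
                 noise = noise, pixel_size = pixel_size, seed = as.integer(seed)),
            class = "guv_scene_spec")
}

# Phase label at each angle for a guv_spec.
arc_phase_at <- function(guv, theta) {
  idx <- findInterval(wrap_angle(theta), guv$phase_arcs$start)
  guv$phase_arcs$phase[pmax(idx, 1L)]
}

#' Simulate a multi-channel GUV equatorial-section image
#'
#' Renders the marker channel (rim-localised, phase-dependent, zero in
#' solution and lumen) and each lectin channel: exterior at the solution
#' intensity `S`, lumen at the background offset (lectin is applied outside
#' intact vesicles), rim peak at `(1 + contrast) * S` before any blur/noise.
#' The lumen-to-solution transition is rendered as a Gaussian rolloff of the
#' same width as the rim that reaches `S` exactly at the rim circle, keeping
#' the field continuous there as a diffraction-limited image would be.
#' Optional PSF blur, Poisson shot noise and Gaussian read noise follow; a
#' single seed makes the output bit-reproducible.
#'
#' Scenes in which the rim band of one vesicle intersects another vesicle are
#' rejected: the ground truth of such a scene is ill-posed.
#'
#' @param scene a [scene_spec()].
#' @return List with `image` (a [multichannel_image()]) and `truth` (a
#'   JSON-serialisable ground-truth record holding every generative value).
#' @export
simulate_guv_image <- function(scene) {
  stopifnot(inherits(scene, "guv_scene_spec"))
  h <- scene$image_shape[1]; w <- scene$image_shape[2]
  lectins <- names(scene$solution_intensity)
  band <- function(g) 4 * g$rim_width
  ng <- length(scene$guvs)
  if (ng >= 2L) {
    for (i in seq_len(ng - 1L)) for (j in seq(i + 1L, ng)) {
      gi <- scene$guvs[[i]]; gj <- scene$guvs[[j]]
      d <- sqrt(sum((gi$center - gj$center)^2))
      if (d < gi$radius + gj$radius + band(gi) + band(gj)) {
        stopf("GUVs %d and %d overlap (rim bands intersect); scene rejected", i, j)
      }
    }
  }
  X <- matrix(rep(seq_len(w) - 1, each = h), nrow = h)
  Y <- matrix(rep(seq_len(h) - 1, times = w), nrow = h)
  chans <- c(list(marker = matrix(0, h, w)),
             stats::setNames(lapply(lectins, function(l) {
               matrix(scene$solution_intensity[[l]], h, w)
             }), lectins))
  truth_guvs <- vector("list", ng)
  for (i in seq_len(ng)) {
    g <- scene$guvs[[i]]
    dx <- X - g$center[1]; dy <- Y - g$center[2]
    d <- sqrt(dx^2 + dy^2)
    inside <- d < g$radius
    near <- abs(d - g$radius) <= band(g)
    theta <- wrap_angle(atan2(dy, dx))
    phase <- matrix("", h, w)
    phase[near] <- arc_phase_at(g, theta[near])
    gauss <- matrix(0, h, w)
    gauss[near] <- exp(-(d[near] - g$radius)^2 / (2 * g$rim_width^2))
    amp <- matrix(0, h, w)
    amp[near] <- unname(g$marker_rim_intensity[phase[near]])
    chans$marker <- chans$marker + amp * gauss
    for (l in lectins) {
      # lumen is lectin-free (background offset); the lumen-to-solution edge
      # is a Gaussian rolloff of the same width as the rim, reaching the
      # solution level exactly at the rim circle, so the field is continuous
      # and the rim centreline equals (1 + contrast) * S before noise
      S <- scene$solution_intensity[[l]]
      b <- scene$background_offset
      chans[[l]][inside] <- b + (S - b) * gauss[inside]
      ampl <- matrix(0, h, w)
      ct <- g$lectin_contrast[[l]]
      if (is.null(ct)) ct <- c(ld = 0, lo = 0)
      ampl[near] <- unname(ct[phase[near]]) * S
      chans[[l]] <- chans[[l]] + ampl * gauss
    }
    border <- g$center[1] - (g$radius + band(g)) < 0 ||
      g$center[1] + (g$radius + band(g)) > w - 1 ||
      g$center[2] - (g$radius + band(g)) < 0 ||
      g$center[2] + (g$radius + band(g)) > h - 1
    truth_guvs[[i]] <- list(
      id = i, center = g$center, radius = g$radius, rim_width = g$rim_width,
      border_touching = border,
      phase_arcs = lapply(seq_len(nrow(g$phase_arcs)), function(k) {
        as.list(g$phase_arcs[k, c("start", "end", "phase")])
      }),
      marker_rim_intensity = as.list(g$marker_rim_intensity),
      lectin_contrast = lapply(g$lectin_contrast, as.list)
    )
  }
  if (scene$psf_sigma > 0) chans <- lapply(chans, blur_gaussian, sigma = scene$psf_sigma)
  chans <- with_seed(scene$seed, {
    lapply(chans, function(m) {
      v <- m
      if (scene$noise$poisson_scale > 0) {
        v <- stats::rpois(length(v), pmax(v, 0) * scene$noise$poisson_scale) /
          scene$noise$poisson_scale
        v <- matrix(v, nrow(m), ncol(m))
      }
      if (scene$noise$gaussian_sigma > 0) {
        v <- v + matrix(stats::rnorm(length(v), 0, scene$noise$gaussian_sigma),
                        nrow(m), ncol(m))
      }
      pmax(v, 0)
    })
  })
  roles <- stats::setNames(names(chans), names(chans))
  img <- multichannel_image(chans, roles, scene$pixel_size)
  truth <- list(kind = "guv_scene", image_shape = scene$image_shape,
                pixel_size = scene$pixel_size,
                solution_intensity = as.list(scene$solution_intensity),
                background_offset = scene$background_offset,
                psf_sigma = scene$psf_sigma, noise = scene$noise,
                seed = scene$seed, guvs = truth_guvs)
  list(image = img, truth = truth)
}
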