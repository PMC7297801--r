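#' Detection configuration
#'
#' Parameters of the circular Hough transform run on the gradient of the
#' membrane-marker channel, plus QC settings used downstream.
#'
#' @param radius_range numeric length 2, candidate rim radii in pixels.
#' @param radius_step accumulator radius step, pixels.
#' @param edge_quantile gradient-magnitude quantile above which pixels vote.
#' @param score_threshold minimum normalised accumulator score (votes per
#'   pixel of circumference) for a detection; chosen so that a rim that is
#'   bright on only half of the circle (a phase-separated vesicle with a dim
#'   lo arc) is still found, while blank noise images yield nothing.
#' @param min_radius detections below this radius are flagged `too_small`
#'   (default: lower end of `radius_range`).
#' @param band_halfwidth rim band half-width used for the overlap/border QC
#'   flags and as the default profiling band, pixels.
#' @param solution_margin extra dilation (pixels) beyond the rim band when
#'   masking vesicles out of the free-solution estimate.
#' @param refine logical; refine centre/radius by a sub-pixel circle fit to
#'   per-angle radial rim peaks.
#' @return A `guv_detection_config` list.
#' @export
detection_config <- function(radius_range = c(10, 50), radius_step = 1,
                             edge_quantile = 0.95, score_threshold = 0.35,
                             min_radius = NULL, band_halfwidth = 3,
                             solution_margin = 6, refine = TRUE) {
  stopifnot(length(radius_range) == 2L, radius_range[1] > 0,
            radius_range[2] >= radius_range[1])
  structure(list(radius_range = radius_range, radius_step = radius_step,
                 edge_quantile = edge_quantile, score_threshold = score_threshold,
                 min_radius = min_radius %||% radius_range[1],
                 band_halfwidth = band_halfwidth,
                 solution_margin = solution_margin, refine = refine),
            class = "guv_detection_config")
}

#' Detect GUVs in the membrane-marker channel
#'
#' Circular Hough transform on the gradient of the marker channel: pixels
#' with strong gradients vote for circle centres one radius away along the
#' gradient direction (both senses, so the inner and outer slope of the rim
#' both contribute). Accumulator peaks above the score threshold become
#' detections; non-maximum suppression removes any candidate whose centre
#' lies within the smaller of the two radii of a better-scoring one, ties
#' broken in favour of the larger radius. Centres and radii are then refined
#' to sub-pixel accuracy by an algebraic circle fit to per-angle radial peaks
#' of the marker rim.
#'
#' QC flags: `border_touching` (rim band leaves the image), `overlapping`
#' (rim bands of two detections intersect) and `too_small`; flagged vesicles
#' are excluded from quantification downstream.
#'
#' @param image a [multichannel_image()] with a marker channel.
#' @param cfg a [detection_config()].
#' @return A data.frame of class `guv_detections`: `id`, `x`, `y`, `radius`,
#'   `score`, `border_touching`, `overlapping`, `too_small`.
#' @export
detect_guvs <- function(image, cfg = detection_config()) {
  stopifnot(inherits(image, "guv_mcimage"))
  m <- get_channel(image, "marker")
  if (!is.matrix(m)) stopf("detection needs a 2-D image")
  h <- nrow(m); w <- ncol(m)
  rmin <- cfg$radius_range[1]
  if (min(h, w) < 2 * rmin + 3) {
    stopf("image (%d x %d) smaller than the minimum detectable radius window", h, w)
  }
  gx <- matrix(0, h, w); gy <- matrix(0, h, w)
  gx[, 2:(w - 1)] <- (m[, 3:w] - m[, 1:(w - 2)]) / 2
  gy[2:(h - 1), ] <- (m[3:h, ] - m[1:(h - 2), ]) / 2
  gmag <- sqrt(gx^2 + gy^2)
  thr <- stats::quantile(gmag, cfg$edge_quantile)
  edge <- which(gmag > thr & gmag > 1e-12)
  if (!length(edge)) return(empty_detections())
  ey <- (edge - 1) %% h           # 0-based row (y)
  ex <- (edge - 1) %/% h          # 0-based col (x)
  ux <- gx[edge] / gmag[edge]
  uy <- gy[edge] / gmag[edge]
  radii <- seq(cfg$radius_range[1], cfg$radius_range[2], by = cfg$radius_step)
  cand <- list()
  for (r in radii) {
    cx <- round(c(ex + r * ux, ex - r * ux))
    cy <- round(c(ey + r * uy, ey - r * uy))
    ok <- cx >= 0 & cx < w & cy >= 0 & cy < h
    if (!any(ok)) next
    tab <- tabulate(cy[ok] * w + cx[ok] + 1L, nbins = h * w)
    acc <- t(matrix(tab, nrow = w))  # row-major votes -> acc[y+1, x+1]
    acc_s <- box3(acc)
    score <- acc_s / (2 * pi * r)
    peaks <- which(score > cfg$score_threshold & acc_s >= box3_max_neighbors(acc_s))
    if (length(peaks)) {
      py <- (peaks - 1) %% h
      px <- (peaks - 1) %/% h
      cand[[length(cand) + 1L]] <- data.frame(x = px, y = py, radius = r,
                                              score = score[peaks])
    }
  }
  if (!length(cand)) return(empty_detections())
  cand <- do.call(rbind, cand)
  # non-maximum suppression: best score first, larger radius breaks ties
  cand <- cand[order(-cand$score, -cand$radius), , drop = FALSE]
  keep <- integer(0)
  for (i in seq_len(nrow(cand))) {
    ok <- TRUE
    for (k in keep) {
      dmin <- min(cand$radius[i], cand$radius[k])
      if ((cand$x[i] - cand$x[k])^2 + (cand$y[i] - cand$y[k])^2 < dmin^2) {
        ok <- FALSE; break
      }
    }
    if (ok) keep <- c(keep, i)
  }
  det <- cand[keep, , drop = FALSE]
  if (cfg$refine) {
    for (i in seq_len(nrow(det))) {
      ref <- refine_circle(m, det$x[i], det$y[i], det$radius[i])
      det$x[i] <- ref$x; det$y[i] <- ref$y; det$radius[i] <- ref$radius
    }
  }
  bw <- cfg$band_halfwidth
  det$border_touching <- det$x - (det$radius + bw) < 0 |
    det$x + (det$radius + bw) > w - 1 |
    det$y - (det$radius + bw) < 0 |
    det$y + (det$radius + bw) > h - 1
  det$too_small <- det$radius < cfg$min_radius
  det$overlapping <- FALSE
  n <- nrow(det)
  if (n >= 2L) for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    d <- sqrt((det$x[i] - det$x[j])^2 + (det$y[i] - det$y[j])^2)
    if (d < det$radius[i] + det$radius[j] + 2 * bw) {
      det$overlapping[i] <- TRUE; det$overlapping[j] <- TRUE
    }
  }
  det <- det[order(-det$score), , drop = FALSE]
  det$id <- seq_len(nrow(det))
  rownames(det) <- NULL
  det <- det[, c("id", "x", "y", "radius", "score",
                 "border_touching", "overlapping", "too_small")]
  class(det) <- c("guv_detections", "data.frame")
  det
}

empty_detections <- function() {
  det <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                    radius = numeric(0), score = numeric(0),
                    border_touching = logical(0), overlapping = logical(0),
                    too_small = logical(0))
  class(det) <- c("guv_detections", "data.frame")
  det
}

# 3x3 box sum with zero padding.
box3 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  p <- matrix(0, h + 2, w + 2)
  p[2:(h + 1), 2:(w + 1)] <- m
  out <- matrix(0, h, w)
  for (dy in 0:2) for (dx in 0:2) {
    out <- out + p[(1 + dy):(h + dy), (1 + dx):(w + dx)]
  }
  out
}

# For local-maximum detection: max over the 8 neighbours (zero padded).
box3_max_neighbors <- function(m) {
  h <- nrow(m); w <- ncol(m)
  p <- matrix(-Inf, h + 2, w + 2)
  p[2:(h + 1), 2:(w + 1)] <- m
  out <- matrix(-Inf, h, w)
  for (dy in 0:2) for (dx in 0:2) {
    if (dy == 1 && dx == 1) next
    out <- pmax(out, p[(1 + dy):(h + dy), (1 + dx):(w + dx)])
  }
  out
}

# Sub-pixel refinement: locate the radial peak of the marker rim on a fan of
# rays, then fit a circle (Kasa algebraic fit) through the peak points.
# Iterated twice so the ray geometry uses the improved centre.
refine_circle <- function(m, x0, y0, r0, n_rays = 72L, search = 4, step = 0.25) {
  h <- nrow(m); w <- ncol(m)
  x <- x0; y <- y0; r <- r0
  for (pass in 1:2) {
    theta <- (seq_len(n_rays) - 0.5) * 2 * pi / n_rays
    rr <- seq(max(r - search, 1), r + search, by = step)
    px <- outer(cos(theta), rr, function(ct, d) x + ct * d)
    py <- outer(sin(theta), rr, function(st, d) y + st * d)
    inb <- px >= 0 & px <= w - 1 & py >= 0 & py <= h - 1
    vals <- matrix(NA_real_, n_rays, length(rr))
    vals[inb] <- sample_image(m, px[inb], py[inb], method = "bilinear")
    pts <- matrix(NA_real_, n_rays, 2)
    peak_val <- rep(NA_real_, n_rays)
    for (i in seq_len(n_rays)) {
      v <- vals[i, ]
      if (all(is.na(v))) next
      k <- which.max(v)
      d <- rr[k]
      if (k > 1 && k < length(rr) && !any(is.na(v[(k - 1):(k + 1)]))) {
        den <- v[k - 1] - 2 * v[k] + v[k + 1]
        if (den < 0) d <- d + step * 0.5 * (v[k - 1] - v[k + 1]) / den
      }
      pts[i, ] <- c(x + cos(theta[i]) * d, y + sin(theta[i]) * d)
      peak_val[i] <- v[k]
    }
    ok <- !is.na(peak_val)
    # drop rays without a real rim (dim arcs still carry a ridge; require
    # a peak above 10% of the brightest rays to reject pure background rays)
    if (any(ok)) ok <- ok & peak_val > 0.1 * stats::quantile(peak_val[ok], 0.9)
    if (sum(ok) < 8L) return(list(x = x, y = y, radius = r))
    fit <- kasa_circle(pts[ok, 1], pts[ok, 2])
    if (is.null(fit)) return(list(x = x, y = y, radius = r))
    x <- fit$x; y <- fit$y; r <- fit$r
  }
  list(x = x, y = y, radius = r)
}

# Algebraic least-squares circle fit (Kasa).
kasa_circle <- function(px, py) {
  A <- cbind(2 * px, 2 * py, 1)
  b <- px^2 + py^2
  fit <- tryCatch(qr.solve(A, b), error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  r2 <- fit[3] + fit[1]^2 + fit[2]^2
  if (r2 <= 0) return(NULL)
  list(x = fit[1], y = fit[2], r = sqrt(r2))
}

#' Estimate the free-lectin solution intensity
#'
#' The binding statistic references the lectin signal in free solution. This
#' is estimated as the median intensity over all pixels outside every
#' detected vesicle disk dilated by the rim band plus a safety margin; the
#' median resists bright debris that escaped detection.
#'
#' @param image a [multichannel_image()].
#' @param detections a `guv_detections` data.frame (all detections are masked,
#'   including flagged ones).
#' @param channel channel role or name.
#' @param band_halfwidth,margin dilation of each vesicle disk in pixels.
#' @return Median exterior intensity (a.u.).
#' @export
estimate_solution_intensity <- function(image, detections, channel = "lectin_1",
                                        band_halfwidth = 3, margin = 6) {
  ch <- get_channel(image, channel)
  h <- nrow(ch); w <- ncol(ch)
  keep <- matrix(TRUE, h, w)
  if (nrow(detections)) {
    X <- matrix(rep(seq_len(w) - 1, each = h), nrow = h)
    Y <- matrix(rep(seq_len(h) - 1, times = w), nrow = h)
    for (i in seq_len(nrow(detections))) {
      d2 <- (X - detections$x[i])^2 + (Y - detections$y[i])^2
      keep <- keep & d2 > (detections$radius[i] + band_halfwidth + margin)^2
    }
  }
  if (!any(keep)) {
    stopf("no exterior pixels left after masking detected vesicles; image unquantifiable")
  }
  stats::median(ch[keep])
}
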