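# Scene builders shared across the test files. All fixtures are generated in
# code; nothing is read from disk.

# One vesicle, optionally phase-separated, in a 128 x 128 field.
single_guv_scene <- function(contrast = 1, radius = 25, center = c(64, 64),
                             arcs = NULL, solution = 100, noise = FALSE,
                             background = 0, seed = 1, lectin2 = NULL,
                             marker = c(ld = 200, lo = 50)) {
  lc <- list(lectin_1 = contrast)
  sol <- c(lectin_1 = solution)
  if (!is.null(lectin2)) {
    lc$lectin_2 <- lectin2
    sol <- c(sol, lectin_2 = solution)
  }
  g <- guv_spec(center = center, radius = radius, phase_arcs = arcs,
                marker_rim_intensity = marker, lectin_contrast = lc)
  scene_spec(image_shape = c(128L, 128L), guvs = list(g),
             solution_intensity = sol, background_offset = background,
             noise = if (noise) list(gaussian_sigma = 2, poisson_scale = 1)
                     else list(gaussian_sigma = 0, poisson_scale = 0),
             seed = seed)
}

# Half/half ld-lo arc table.
half_arcs <- function() {
  data.frame(start = c(0, pi), end = c(pi, 2 * pi), phase = c("ld", "lo"),
             stringsAsFactors = FALSE)
}

# Detect + solution + profile + overall binding efficiency for a lectin.
quantify_single <- function(image, channel = "lectin_1",
                            radius_range = c(15, 35), ...) {
  det <- detect_guvs(image, detection_config(radius_range = radius_range))
  stopifnot(nrow(det) >= 1)
  sol <- estimate_solution_intensity(image, det, channel)
  prof <- extract_rim_profile(image, det[1, ], ...)
  list(det = det, sol = sol, prof = prof,
       be = compute_binding_efficiency(prof, sol, channel))
}

# Minimal hand-built rim profile (for unit tests of profile consumers).
fake_profile <- function(marker, lectin_1 = NULL, lectin_2 = NULL) {
  vals <- cbind(marker = marker)
  roles <- c(marker = "marker")
  if (!is.null(lectin_1)) {
    vals <- cbind(vals, lectin_1 = lectin_1)
    roles <- c(roles, lectin_1 = "lectin_1")
  }
  if (!is.null(lectin_2)) {
    vals <- cbind(vals, lectin_2 = lectin_2)
    roles <- c(roles, lectin_2 = "lectin_2")
  }
  n <- nrow(vals)
  structure(list(values = vals, angles = (seq_len(n) - 0.5) * 2 * pi / n,
                 n_bins = n, roles = roles,
                 rim_band = c(inner = 22, outer = 28),
                 center = c(x = 64, y = 64), radius = 25, saturated = FALSE),
            class = "guv_rim_profile")
}

# Exhaustive two-sided Mann-Whitney p-value for small tie-free samples:
# enumerate every assignment of the pooled ranks to group A.
mw_exact_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(nx + ny, nx)
  us <- apply(combs, 2, function(idx) sum(seq_len(nx + ny)[idx]) - nx * (nx + 1) / 2)
  mu <- nx * ny / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}
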