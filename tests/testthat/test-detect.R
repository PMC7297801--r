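test_that("a blank noise image yields no detections", {
  set.seed(5)
  noise <- matrix(pmax(stats::rnorm(96 * 96, 10, 2), 0), 96, 96)
  img <- multichannel_image(list(marker = noise, lectin_1 = noise),
                            c(marker = "marker", lectin_1 = "lectin_1"))
  det <- detect_guvs(img, detection_config(radius_range = c(10, 30)))
  expect_equal(nrow(det), 0L)
})

test_that("single vesicles are located within a pixel in centre and radius", {
  cases <- list(list(center = c(64, 64), radius = 20),
                list(center = c(50.5, 70.3), radius = 25),
                list(center = c(70, 40), radius = 17))
  for (cs in cases) {
    sim <- simulate_guv_image(single_guv_scene(center = cs$center,
                                               radius = cs$radius))
    det <- detect_guvs(sim$image, detection_config(radius_range = c(12, 32)))
    expect_equal(nrow(det), 1L)
    expect_lt(abs(det$x - cs$center[1]), 1)
    expect_lt(abs(det$y - cs$center[2]), 1)
    expect_lt(abs(det$radius - cs$radius), 1)
  }
  # refinement reaches well below a pixel on clean data
  sim <- simulate_guv_image(single_guv_scene(center = c(64.4, 63.6), radius = 24))
  det <- detect_guvs(sim$image, detection_config(radius_range = c(15, 35)))
  expect_lt(abs(det$x - 64.4), 0.1)
  expect_lt(abs(det$y - 63.6), 0.1)
  expect_lt(abs(det$radius - 24), 0.1)
})

test_that("detection still works under realistic noise", {
  for (seed in 1:5) {
    sim <- simulate_guv_image(single_guv_scene(radius = 22, noise = TRUE,
                                               seed = seed))
    det <- detect_guvs(sim$image, detection_config(radius_range = c(15, 35)))
    expect_equal(nrow(det), 1L)
    expect_lt(abs(det$x - 64), 1)
    expect_lt(abs(det$radius - 22), 1)
  }
})

test_that("vesicles cut by the border are flagged and phase-separated rims found", {
  sim <- simulate_guv_image(single_guv_scene(center = c(12, 64), radius = 22))
  det <- detect_guvs(sim$image, detection_config(radius_range = c(15, 35)))
  expect_gte(nrow(det), 1L)
  expect_true(det$border_touching[1])
  # a rim whose lo half carries only a quarter of the marker signal
  sim2 <- simulate_guv_image(single_guv_scene(arcs = half_arcs()))
  det2 <- detect_guvs(sim2$image, detection_config(radius_range = c(15, 35)))
  expect_equal(nrow(det2), 1L)
  expect_lt(abs(det2$radius - 25), 1)
})

test_that("images smaller than the radius window are rejected", {
  tiny <- multichannel_image(list(marker = matrix(1, 16, 16)),
                             c(marker = "marker"))
  expect_error(detect_guvs(tiny, detection_config(radius_range = c(10, 30))),
               "smaller than the minimum")
})

test_that("detection agrees with an exhaustive search on small images", {
  g <- guv_spec(center = c(32, 30), radius = 14)
  sc <- scene_spec(image_shape = c(64L, 64L), guvs = list(g), seed = 1)
  sim <- simulate_guv_image(sc)
  m <- get_channel(sim$image, "marker")
  # brute force: best integer centre/radius by mean marker intensity on the circle
  best <- c(score = -Inf, x = NA, y = NA, r = NA)
  tt <- seq(0, 2 * pi, length.out = 64)[-64]
  for (cx in 20:44) for (cy in 20:44) for (r in 10:18) {
    px <- round(cx + r * cos(tt)); py <- round(cy + r * sin(tt))
    ok <- px >= 0 & px < 64 & py >= 0 & py < 64
    if (mean(ok) < 1) next
    s <- mean(m[cbind(py + 1, px + 1)])
    if (s > best["score"]) best <- c(score = s, x = cx, y = cy, r = r)
  }
  det <- detect_guvs(sim$image, detection_config(radius_range = c(10, 18)))
  expect_equal(nrow(det), 1L)
  expect_lt(abs(det$x - best[["x"]]), 1)
  expect_lt(abs(det$y - best[["y"]]), 1)
  expect_lt(abs(det$radius - best[["r"]]), 1)
})

test_that("solution intensity is the exterior median", {
  sim <- simulate_guv_image(single_guv_scene(contrast = 3))
  det <- detect_guvs(sim$image, detection_config(radius_range = c(15, 35)))
  expect_equal(estimate_solution_intensity(sim$image, det, "lectin_1"), 100)
})

test_that("noisy solution estimates match a brute-force median over the same mask", {
  sim <- simulate_guv_image(single_guv_scene(contrast = 3, noise = TRUE, seed = 21))
  det <- detect_guvs(sim$image, detection_config(radius_range = c(15, 35)))
  est <- estimate_solution_intensity(sim$image, det, "lectin_1",
                                     band_halfwidth = 3, margin = 6)
  lec <- get_channel(sim$image, "lectin_1")
  vals <- c()
  for (yy in 0:127) for (xx in 0:127) {
    outside <- TRUE
    for (i in seq_len(nrow(det))) {
      if (sqrt((xx - det$x[i])^2 + (yy - det$y[i])^2) <= det$radius[i] + 9) {
        outside <- FALSE
      }
    }
    if (outside) vals <- c(vals, lec[yy + 1, xx + 1])
  }
  expect_lt(abs(est - stats::median(vals)), 1)
  expect_lt(abs(est - 100), 1)
})

test_that("an image fully covered by vesicles cannot provide a solution estimate", {
  sim <- simulate_guv_image(single_guv_scene())
  det <- detect_guvs(sim$image, detection_config(radius_range = c(15, 35)))
  expect_error(estimate_solution_intensity(sim$image, det, "lectin_1",
                                           margin = 200),
               "unquantifiable")
})
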