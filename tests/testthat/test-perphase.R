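quantify_phases <- function(sim, boundary_exclude = 1L) {
  det <- detect_guvs(sim$image, detection_config(radius_range = c(15, 35)))
  prof <- extract_rim_profile(sim$image, det[1, ])
  lab <- segment_phases(prof)
  lectins <- sort(grep("^lectin", names(prof$roles), value = TRUE))
  sol <- vapply(lectins, function(l) {
    estimate_solution_intensity(sim$image, det, l)
  }, numeric(1))
  list(prof = prof, lab = lab,
       bind = per_phase_binding(prof, lab, sol, boundary_exclude = boundary_exclude))
}

test_that("phase-resolved contrasts {ld: 0, lo: 7} are recovered", {
  sim <- simulate_guv_image(single_guv_scene(arcs = half_arcs(),
                                             contrast = c(ld = 0, lo = 7)))
  q <- quantify_phases(sim)
  expect_equal(q$lab$mode, "phase_separated")
  b <- q$bind[q$bind$channel == "lectin_1", ]
  expect_lt(abs(b$ld), 0.05)
  expect_lt(abs(b$lo - 7) / 7, 0.1)
  expect_gt(b$n_bins_ld, 100)
  expect_gt(b$n_bins_lo, 100)
})

test_that("mirrored phase preferences mirror the per-phase values", {
  sim <- simulate_guv_image(single_guv_scene(arcs = half_arcs(),
                                             contrast = c(ld = 7, lo = 0)))
  b <- quantify_phases(sim)$bind
  expect_lt(abs(b$lo), 0.05)
  expect_lt(abs(b$ld - 7) / 7, 0.1)
})

test_that("two lectins with swapped preferences swap their per-phase values", {
  sim <- simulate_guv_image(single_guv_scene(arcs = half_arcs(),
                                             contrast = c(ld = 0, lo = 5),
                                             lectin2 = c(ld = 5, lo = 0)))
  b <- quantify_phases(sim)$bind
  b1 <- b[b$channel == "lectin_1", ]; b2 <- b[b$channel == "lectin_2", ]
  expect_lt(abs(b1$ld), 0.05)
  expect_lt(abs(b2$lo), 0.05)
  expect_lt(abs(b1$lo - 5) / 5, 0.1)
  expect_lt(abs(b2$ld - 5) / 5, 0.1)
  expect_equal(b1$lo, b2$ld, tolerance = 0.02)
})

test_that("uniform vesicles only populate the present phase", {
  sim <- simulate_guv_image(single_guv_scene(contrast = 2))
  q <- quantify_phases(sim)
  expect_equal(q$lab$mode, "uniform")
  b <- q$bind[q$bind$channel == "lectin_1", ]
  expect_false(is.na(b$ld))
  expect_true(is.na(b$lo))
  expect_equal(b$n_bins_lo, 0L)
  expect_lt(abs(b$ld - 2) / 2, 0.05)
  expect_lt(abs(b$overall - 2) / 2, 0.05)
})

test_that("identical profiles correlate perfectly and complements anti-correlate", {
  a <- 100 + 50 * sin(seq(0, 2 * pi, length.out = 120))
  prof <- fake_profile(marker = rep(100, 120), lectin_1 = a, lectin_2 = a)
  expect_equal(segregation_profile(prof)$correlation, 1)
  prof2 <- fake_profile(marker = rep(100, 120), lectin_1 = a, lectin_2 = 300 - a)
  expect_equal(segregation_profile(prof2)$correlation, -1)
})

test_that("zero-variance profiles are flagged rather than correlated", {
  prof <- fake_profile(marker = rep(100, 60), lectin_1 = rep(5, 60),
                       lectin_2 = 1:60)
  seg <- segregation_profile(prof)
  expect_true(seg$flagged)
  expect_true(is.na(seg$correlation))
  expect_equal(nrow(seg$table), 60L)
})

test_that("lectins on opposite phases anti-correlate on simulated vesicles", {
  sim <- simulate_guv_image(single_guv_scene(arcs = half_arcs(),
                                             contrast = c(ld = 4, lo = 0),
                                             lectin2 = c(ld = 0, lo = 4)))
  det <- detect_guvs(sim$image, detection_config(radius_range = c(15, 35)))
  prof <- extract_rim_profile(sim$image, det[1, ])
  seg <- segregation_profile(prof, "lectin_1", "lectin_2")
  expect_lt(seg$correlation, -0.5)
})
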