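test_that("zero contrast makes exterior rim pixels equal the solution level", {
  sim <- simulate_guv_image(single_guv_scene(contrast = 0))
  lec <- get_channel(sim$image, "lectin_1")
  h <- nrow(lec); w <- ncol(lec)
  X <- matrix(rep(seq_len(w) - 1, each = h), h)
  Y <- matrix(rep(seq_len(h) - 1, times = w), h)
  d <- sqrt((X - 64)^2 + (Y - 64)^2)
  outer_band <- d >= 25 & d <= 28
  expect_true(all(lec[outer_band] == 100))
  # with the lumen equilibrated to the solution level the whole channel is flat
  sim2 <- simulate_guv_image(single_guv_scene(contrast = 0, background = 100))
  expect_true(all(get_channel(sim2$image, "lectin_1") == 100))
})

test_that("rim centreline intensity is (1 + contrast) * solution", {
  sim <- simulate_guv_image(single_guv_scene(contrast = 1))
  lec <- get_channel(sim$image, "lectin_1")
  # pixel exactly one radius to the right of the centre lies on the rim
  expect_equal(lec[64 + 1, 64 + 25 + 1], 200)
  sim7 <- simulate_guv_image(single_guv_scene(contrast = 7))
  expect_equal(get_channel(sim7$image, "lectin_1")[64 + 1, 64 + 25 + 1], 800)
})

test_that("a fixed seed reproduces the noisy image bit for bit", {
  sc <- single_guv_scene(contrast = 2, noise = TRUE, seed = 42)
  a <- simulate_guv_image(sc)
  b <- simulate_guv_image(sc)
  expect_identical(a$image$channels, b$image$channels)
  # a different seed changes the realisation
  sc2 <- single_guv_scene(contrast = 2, noise = TRUE, seed = 43)
  expect_false(identical(simulate_guv_image(sc2)$image$channels,
                         a$image$channels))
})

test_that("the simulator does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(simulate_guv_image(single_guv_scene(noise = TRUE)))
  expect_identical(runif(1), before)
})

test_that("scenes with intersecting rim bands are rejected", {
  g1 <- guv_spec(center = c(40, 64), radius = 20)
  g2 <- guv_spec(center = c(80, 64), radius = 20)  # centres 40 px apart, r+r=40
  sc <- scene_spec(image_shape = c(128L, 128L), guvs = list(g1, g2))
  expect_error(simulate_guv_image(sc), "overlap")
  # well separated vesicles are fine
  g3 <- guv_spec(center = c(32, 32), radius = 14)
  g4 <- guv_spec(center = c(96, 96), radius = 14)
  expect_silent(simulate_guv_image(scene_spec(image_shape = c(128L, 128L),
                                              guvs = list(g3, g4))))
})

test_that("vesicles cut by the image border are flagged in the ground truth", {
  sc <- single_guv_scene(center = c(10, 64), radius = 25)
  sim <- simulate_guv_image(sc)
  expect_true(sim$truth$guvs[[1]]$border_touching)
  expect_false(simulate_guv_image(single_guv_scene())$truth$guvs[[1]]$border_touching)
})

test_that("marker signal away from rim bands is indistinguishable from background", {
  sc <- single_guv_scene(noise = TRUE, seed = 9)
  sim <- simulate_guv_image(sc)
  m <- get_channel(sim$image, "marker")
  h <- nrow(m); w <- ncol(m)
  X <- matrix(rep(seq_len(w) - 1, each = h), h)
  Y <- matrix(rep(seq_len(h) - 1, times = w), h)
  d <- sqrt((X - 64)^2 + (Y - 64)^2)
  outside <- m[abs(d - 25) > 4 * 1.5 + 2]
  # reference: a pure-background marker field under the same noise model
  blank <- simulate_guv_image(scene_spec(image_shape = c(64L, 64L), guvs = list(),
                                         noise = list(gaussian_sigma = 2,
                                                      poisson_scale = 1),
                                         seed = 10))
  ref <- as.vector(get_channel(blank$image, "marker"))
  ks <- suppressWarnings(stats::ks.test(outside, ref))
  expect_gt(ks$p.value, 0.01)
})

test_that("phase arcs must partition the circle and contrasts stay above -1", {
  bad_arcs <- data.frame(start = c(0, pi / 2), end = c(pi / 2, pi),
                         phase = c("ld", "lo"))
  expect_error(guv_spec(c(64, 64), 25, phase_arcs = bad_arcs), "partition")
  expect_error(guv_spec(c(64, 64), 25, lectin_contrast = list(lectin_1 = -1.5)),
               ">= -1")
  expect_error(guv_spec(c(64, 64), radius = 1, rim_width = 1.5), "radius > rim_width")
})

test_that("cell stacks honour configured membrane intensities", {
  sc_eq <- cell_scene_spec(grid = c(3L, 3L), n_cells = 9L,
                           ap_intensity = c(lectin_1 = 50),
                           bl_intensity = c(lectin_1 = 50),
                           labeled_fraction = 1, seed = 2)
  sim <- simulate_cell_stack(sc_eq)
  rec <- measure_simulated_cells(sim, "lectin_1")
  expect_equal(rec$ap_intensity, rec$bl_intensity)
  expect_equal(rec$ap_intensity / rec$bl_intensity, rep(1, nrow(rec)))

  sc7 <- cell_scene_spec(grid = c(3L, 3L), n_cells = 9L,
                         ap_intensity = c(lectin_1 = 70),
                         bl_intensity = c(lectin_1 = 10),
                         labeled_fraction = 1, seed = 2)
  rec7 <- measure_simulated_cells(simulate_cell_stack(sc7), "lectin_1")
  expect_equal(unique(rec7$ap_intensity), 70)
  expect_equal(unique(rec7$bl_intensity), 10)
  expect_equal(rec7$ap_intensity / rec7$bl_intensity, rep(7, nrow(rec7)))
})

test_that("the labelling draw is reproducible from the seed alone", {
  sc <- cell_scene_spec(grid = c(10L, 10L), n_cells = 100L,
                        labeled_fraction = 0.1, seed = 77)
  sim <- simulate_cell_stack(sc)
  expected <- guvquant:::with_seed(77, stats::runif(100) < 0.1)
  expect_identical(sim$truth$cells$labeled, expected)
  expect_identical(sim$truth$n_labeled, sum(expected))
})

test_that("cell scenes that do not fit the grid are rejected", {
  expect_error(cell_scene_spec(grid = c(2L, 2L), n_cells = 5L), "packable grid")
  expect_error(cell_scene_spec(labeled_fraction = 0), "labeled_fraction")
})
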