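make_stack <- function(value = 50) {
  a <- array(value, c(8, 8, 4))
  multichannel_image(list(lectin_1 = a), c(lectin_1 = "lectin_1"),
                     pixel_size = 0.2)
}

test_that("a constant stack measures identical apical and basolateral means", {
  st <- make_stack(50)
  rec <- measure_cell(st, mask_ap = 1:10, mask_bl = 11:30, cell_id = 1)
  expect_equal(rec$ap_intensity, 50)
  expect_equal(rec$bl_intensity, 50)
})

test_that("simulated membranes are measured exactly without noise", {
  sc <- cell_scene_spec(grid = c(3L, 3L), n_cells = 9L,
                        ap_intensity = c(lectin_1 = 70),
                        bl_intensity = c(lectin_1 = 10),
                        labeled_fraction = 1, seed = 4)
  sim <- simulate_cell_stack(sc)
  rec <- measure_cell(sim$image, sim$masks[[1]]$ap, sim$masks[[1]]$bl,
                      cell_id = 1)
  expect_identical(rec$ap_intensity, 70)
  expect_identical(rec$bl_intensity, 10)
})

test_that("overlapping or empty masks are rejected", {
  st <- make_stack()
  expect_error(measure_cell(st, 1:10, 5:20), "overlap")
  expect_error(measure_cell(st, integer(0), 1:5), "empty")
  expect_error(measure_cell(st, 1:5, integer(0)), "empty")
  expect_error(measure_cell(st, 1:5, 10^6), "out of range")
})

test_that("the population ratio is the ratio of means over isolated cells", {
  rec <- data.frame(cell_id = 1:2, ap_intensity = c(60, 80),
                    bl_intensity = c(10, 10), isolated = TRUE)
  expect_equal(ap_bl_ratio(rec), 7)
  # non-isolated cells never influence the ratio
  rec2 <- rbind(rec, data.frame(cell_id = 3, ap_intensity = 1000,
                                bl_intensity = 1, isolated = FALSE))
  expect_equal(ap_bl_ratio(rec2), ap_bl_ratio(rec))
  expect_error(ap_bl_ratio(rec2[rec2$isolated == FALSE, ]), "no isolated")
  rec3 <- data.frame(cell_id = 1, ap_intensity = 5, bl_intensity = 0,
                     isolated = TRUE)
  expect_error(ap_bl_ratio(rec3), "undefined")
})

test_that("paired t-test matches the closed-form computation on differences", {
  a <- c(7, 8, 6); b <- c(2.7, 3.2, 2.2)
  res <- paired_ratio_test(a, b)
  d <- a - b
  t_hand <- mean(d) / (stats::sd(d) / sqrt(length(d)))
  p_hand <- 2 * stats::pt(-abs(t_hand), df = length(d) - 1)
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$p, p_hand, tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_false(res$degenerate)
})

test_that("degenerate paired comparisons are handled explicitly", {
  res <- paired_ratio_test(c(3, 4, 5), c(3, 4, 5))
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  res2 <- paired_ratio_test(c(5, 6), c(3, 4))  # constant non-zero differences
  expect_true(res2$degenerate)
  expect_true(is.na(res2$t))
  expect_error(paired_ratio_test(1:3, 1:2), "equal length")
  expect_error(paired_ratio_test(1, 2), "at least 2")
})

test_that("experiment summaries flag low cell counts", {
  s <- experiment_summary(c(7.1, 6.8, 7.3), c(60L, 72L, 55L), "StxB apical")
  expect_false(s$low_n)
  expect_equal(s$mean_ratio, mean(c(7.1, 6.8, 7.3)))
  expect_equal(s$sem, stats::sd(c(7.1, 6.8, 7.3)) / sqrt(3))
  expect_true(experiment_summary(c(7, 7), c(60L, 40L))$low_n)
})

test_that("isolation flags react to labeled neighbours", {
  # force all cells labeled: every cell has an adjacent labeled neighbour
  sc <- cell_scene_spec(grid = c(3L, 3L), n_cells = 9L, labeled_fraction = 1,
                        ap_intensity = c(lectin_1 = 70),
                        bl_intensity = c(lectin_1 = 10), seed = 1)
  sim <- simulate_cell_stack(sc)
  expect_true(all(!sim$truth$cells$isolated))
  rec <- measure_simulated_cells(sim, "lectin_1")
  expect_error(ap_bl_ratio(rec), "no isolated")
})
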