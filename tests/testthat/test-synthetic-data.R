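test_that("mucus_model validates its parameters", {
  expect_s3_class(mucus_model(80, 0.5), "mucus_model")
  expect_error(mucus_model(-1, 0.5), class = "mucometry_config_error")
  expect_error(mucus_model(80, 1.2), class = "mucometry_config_error")
  expect_error(mucus_model(80, 0.5, surface_jitter = -1), class = "mucometry_config_error")
  expect_error(mucus_model(80, 0.5, depth_law = "exponential"),
               class = "mucometry_config_error")
  expect_error(mucus_model(80, 0.5, depth_law = "exponential", depth_scale = 0),
               class = "mucometry_config_error")
})

test_that("tissue surface generator honours amplitude, bounds and seed", {
  flat <- simulate_tissue_surface(16, 12, mean_z = 50, amplitude = 0, seed = 3)
  expect_true(all(flat$z == 50))
  expect_equal(dim(flat$z), c(12, 16))

  s1 <- simulate_tissue_surface(32, 32, mean_z = 50, amplitude = 5,
                                correlation_length = 10, seed = 7)
  s2 <- simulate_tissue_surface(32, 32, mean_z = 50, amplitude = 5,
                                correlation_length = 10, seed = 7)
  expect_identical(s1$z, s2$z)
  # amplitude is the max deviation, comfortably inside mean_z +/- 3*amplitude
  expect_true(all(s1$z >= 35 & s1$z <= 65))
  expect_equal(max(abs(s1$z - mean(s1$z))), 5, tolerance = 0.05)

  expect_error(simulate_tissue_surface(0, 4), class = "mucometry_config_error")
  expect_error(simulate_tissue_surface(8, 8, mean_z = 4, amplitude = 5),
               class = "mucometry_config_error")
})

test_that("bilinear surface interpolation is exact on a planar surface", {
  s <- simulate_tissue_surface(10, 10, pixel_size = 2, mean_z = 50,
                               amplitude = 0, seed = 1)
  s$z <- outer(seq_len(10), seq_len(10), function(iy, ix) 10 + 2 * ix + 3 * iy)
  at <- mucometry:::surface_height_at(s, x_um = c(3, 7.4), y_um = c(3, 11))
  # cell centres sit at (ix - 0.5) * 2, heights linear in the indices
  expect_equal(at[1], 10 + 2 * 2 + 3 * 2)            # exactly on a centre
  expect_equal(at[2], 10 + 2 * (7.4 / 2 + 0.5) + 3 * (11 / 2 + 0.5))
})

test_that("bead population reflects the configured mixture with ground truth", {
  surf <- simulate_tissue_surface(16, 16, mean_z = 20, amplitude = 0)

  b0 <- simulate_beads(surf, mucus_model(80, 0), 200, seed = 1)
  expect_true(all(b0$depth_um == 0))
  expect_true(all(b0$label == "surface"))
  expect_true(all(b0$z_um == 100))

  b1 <- simulate_beads(surf, mucus_model(80, 1), 1e5, seed = 2)
  se <- 80 / sqrt(12) / sqrt(1e5)
  expect_lt(abs(mean(b1$depth_um) - 40), 3 * se)

  b5 <- simulate_beads(surf, mucus_model(80, 0.5), 1e4, seed = 3)
  frac <- mean(b5$label == "penetrant")
  ci <- qnorm(0.995) * sqrt(0.25 / 1e4)
  expect_lt(abs(frac - 0.5), ci)

  expect_identical(simulate_beads(surf, mucus_model(80, 0.5), 50, seed = 9),
                   simulate_beads(surf, mucus_model(80, 0.5), 50, seed = 9))
})

test_that("empirical depth distributions match the configured law (KS)", {
  surf <- simulate_tissue_surface(8, 8, mean_z = 20, amplitude = 0)
  bu <- simulate_beads(surf, mucus_model(60, 1), 1e4, seed = 11)
  expect_gt(stats::ks.test(bu$depth_um, "punif", 0, 60)$p.value, 0.01)

  be <- simulate_beads(surf, mucus_model(60, 1, depth_law = "exponential",
                                         depth_scale = 15), 1e4, seed = 12)
  ptrunc <- function(q) pexp(pmin(q, 60), rate = 1 / 15) / pexp(60, rate = 1 / 15)
  expect_gt(stats::ks.test(be$depth_um, ptrunc)$p.value, 0.01)
})

test_that("thickness series generator is linear, noisy and deterministic", {
  s0 <- simulate_thickness_series(350, 0, noise_sigma = 0)
  expect_equal(nrow(s0), 20)
  expect_true(all(s0$thickness_um == 350))

  s1 <- simulate_thickness_series(400, 2, noise_sigma = 0)
  expect_equal(sort(unique(s1$thickness_um)), c(400, 430, 460, 490))
  expect_true(all(s1$thickness_um == 400 + 2 * s1$time_min))

  a <- simulate_thickness_series(400, 1.5, noise_sigma = 5, seed = 4)
  b <- simulate_thickness_series(400, 1.5, noise_sigma = 5, seed = 4)
  expect_identical(a, b)
})

test_that("cohort generator echoes its design", {
  cfg <- cohort_config_obob(n_per_group = 5)
  coh <- simulate_cohort(cfg, seed = 1)
  expect_equal(nrow(coh$cohort), 10)
  expect_equal(as.integer(table(coh$cohort$group)), c(5L, 5L))
  # separated scenario: true penetration fractions differ by the configured 0.6
  ptrue <- tapply(coh$cohort$penetration_true, coh$cohort$group, unique)
  expect_equal(unname(abs(diff(ptrue))), 0.6)
  # homa_ir column is consistent with the formula
  expect_equal(coh$cohort$homa_ir,
               homa_ir(coh$cohort$fasting_glucose_mM, coh$cohort$fasting_insulin_uU_ml))

  co <- simulate_cohort(cohort_config_obob(housing = "cohoused"), seed = 1)
  expect_equal(length(unique(co$cohort$penetration_true)), 1L)
  expect_equal(length(unique(co$cohort$thickness_true_um)), 1L)

  expect_identical(simulate_cohort(cfg, seed = 5)$bead_distances,
                   simulate_cohort(cfg, seed = 5)$bead_distances)
  expect_error(
    cohort_group("g", 1, mucus_model(80, 0.1), c(30, 3), c(8, 1), c(15, 5),
                 c(2, 0.3), c(450, 30)),
    class = "mucometry_config_error"
  )
})
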