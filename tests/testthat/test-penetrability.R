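test_that("distance binning follows the left-closed uniform-bin convention", {
  h <- bin_distances(c(10, 10, 10), bin_width = 5)
  expect_equal(h$count, c(0, 0, 3))
  expect_equal(h$lower_um, c(0, 5, 10))
  expect_equal(h$upper_um, c(5, 10, 15))

  h2 <- bin_distances(c(2, 7, 12), bin_width = 5)
  expect_equal(h2$count, c(1, 1, 1))
  expect_equal(h2$center_um, c(2.5, 7.5, 12.5))

  # below-tissue distances are clamped into the first bin and reported
  h3 <- bin_distances(c(-3, 2, 12), bin_width = 5)
  expect_equal(h3$count, c(2, 0, 1))
  expect_equal(attr(h3, "n_below_tissue"), 1L)
  expect_equal(sum(h3$count), 3)

  expect_error(bin_distances(numeric(0)), class = "mucometry_data_error")
  expect_error(bin_distances(10, bin_width = 0), class = "mucometry_config_error")
})

test_that("large uniform samples fill bins within multinomial bounds", {
  set.seed(101)
  d <- runif(1e4, 0, 50)
  h <- bin_distances(d, 5)
  expect_equal(length(h$count), 10)
  ci <- qnorm(0.995) * sqrt(1e4 * 0.1 * 0.9)
  expect_true(all(abs(h$count - 1000) < ci))
})

test_that("normalize_align applies max-normalisation, alignment and cropping", {
  mk <- function(counts) {
    n <- length(counts)
    h <- tibble::tibble(
      lower_um = (seq_len(n) - 1) * 5, upper_um = seq_len(n) * 5,
      center_um = (seq_len(n) - 0.5) * 5, count = counts
    )
    attr(h, "bin_width") <- 5
    h
  }

  nd <- normalize_align(mk(c(0, 0, 5)))
  expect_equal(attr(nd, "surface_bin_distance"), 12.5)
  expect_equal(nd$x_um, 0)
  expect_equal(nd$f, 1)
  expect_equal(attr(nd, "n_cropped_above"), 0)

  nd2 <- normalize_align(mk(c(10, 1, 100, 7)))
  expect_equal(attr(nd2, "surface_bin_distance"), 12.5)
  expect_equal(nd2$x_um, c(0, 5, 10))
  expect_equal(nd2$f, c(1, 0.01, 0.1))
  expect_equal(attr(nd2, "n_cropped_above"), 7)

  # exact scale invariance in the bead count
  nd3 <- normalize_align(mk(3 * c(10, 1, 100, 7)))
  expect_identical(nd3$f, nd2$f)
  expect_identical(nd3$x_um, nd2$x_um)

  # modal tie broken towards the outermost bin
  nd4 <- normalize_align(mk(c(5, 5, 2)))
  expect_equal(attr(nd4, "surface_bin_distance"), 7.5)

  expect_error(normalize_align(mk(c(0, 0, 0))), class = "mucometry_data_error")
})

test_that("penetrability AUC integrates the normalized curve", {
  one <- normalize_align(bin_distances(rep(12, 5), 5))
  expect_equal(penetrability_auc(one), 0)

  flat <- structure(
    tibble::tibble(x_um = seq(0, 45, by = 5), f = rep(1, 10), count = rep(1, 10)),
    class = c("normalized_distribution", class(tibble::tibble()))
  )
  expect_equal(penetrability_auc(flat), 45)

  curve <- structure(
    tibble::tibble(x_um = seq(0, 20, 5), f = c(1, 0.1, 0.1, 0.1, 0.1),
                   count = c(10, 1, 1, 1, 1)),
    class = c("normalized_distribution", class(tibble::tibble()))
  )
  expect_equal(penetrability_auc(curve), 4.25)
})

test_that("bead-count and surface-offset invariances hold exactly", {
  set.seed(7)
  d <- runif(400, 0, 60)
  base <- normalize_align(bin_distances(d, 5))

  # replicating every bead k times leaves the curve and AUC exactly unchanged
  for (k in c(2L, 5L)) {
    rep_nd <- normalize_align(bin_distances(rep(d, k), 5))
    expect_identical(rep_nd$f, base$f)
    expect_identical(rep_nd$x_um, base$x_um)
    expect_identical(penetrability_auc(rep_nd), penetrability_auc(base))
  }

  # shifting all distances by multiples of the bin width (thicker overlying
  # buffer) is absorbed by the surface anchor
  for (shift in c(5, 20)) {
    sh <- normalize_align(bin_distances(d + shift, 5))
    expect_equal(sh$f, base$f)
    expect_equal(sh$x_um, base$x_um)
    expect_equal(penetrability_auc(sh), penetrability_auc(base))
  }
})

test_that("bead counts are conserved through normalize and crop", {
  set.seed(8)
  for (p in c(0.2, 0.9)) {
    d <- sample_distances(mucus_model(50, p), 2000)
    h <- bin_distances(d, 5)
    nd <- normalize_align(h)
    expect_equal(sum(h$count), 2000)
    expect_equal(sum(nd$count) + attr(nd, "n_cropped_above"), 2000)
  }
})

test_that("thickness_from_beads is the mean distance", {
  expect_equal(thickness_from_beads(c(30, 30, 30)), 30)
  expect_equal(thickness_from_beads(c(10, 20, 30, 40)), 25)
  expect_error(thickness_from_beads(numeric(0)), class = "mucometry_data_error")
})

test_that("impenetrable phantom recovers the layer thickness end to end", {
  d <- sample_distances(mucus_model(80, 0), 500)
  expect_equal(thickness_from_beads(d), 80)
  expect_equal(penetrability_auc(normalize_align(bin_distances(d, 5))), 0)
})

test_that("penetrability() summarises per stack and per mouse", {
  set.seed(21)
  tbl <- dplyr::bind_rows(lapply(1:3, function(s) {
    tibble::tibble(mouse = "m1", stack = s,
                   d_um = sample_distances(mucus_model(50, 0.4), 300))
  }))
  ps <- penetrability(tbl, bin_width = 5)
  expect_equal(nrow(ps), 3)
  expect_true(all(ps$n_beads == 300))

  pm <- penetrability_by_mouse(ps)
  expect_equal(nrow(pm), 1)
  expect_equal(pm$auc_um, median(ps$auc_um))
  expect_equal(pm$n_beads, 900)

  # one stack: mouse value equals the stack value; three: the median
  one <- penetrability_by_mouse(ps[1, ])
  expect_equal(one$auc_um, ps$auc_um[1])
  fake <- tibble::tibble(mouse = "x", auc_um = c(2, 9, 4),
                         thickness_um = 1, n_beads = 1)
  expect_equal(penetrability_by_mouse(fake)$auc_um, 4)
})

test_that("median display curve equals brute-force padding and median", {
  curves_list <- list(
    data.frame(x_um = c(0, 5, 10), f = c(1, 0.5, 0.2)),
    data.frame(x_um = c(0, 5), f = c(1, 0.3)),
    data.frame(x_um = c(0, 5, 10, 15), f = c(1, 0.6, 0.4, 0.1))
  )
  tidy <- dplyr::bind_rows(lapply(seq_along(curves_list), function(i) {
    tibble::tibble(mouse = "m", stack = i,
                   x_um = curves_list[[i]]$x_um, f = curves_list[[i]]$f)
  }))
  got <- median_curve(tidy)
  want <- median_curve_bruteforce(curves_list)
  expect_equal(got$x_um, want$x_um)
  expect_equal(got$f_median, want$f_median)
})

test_that("pipeline AUC agrees with the closed form on large samples", {
  set.seed(33)
  m <- mucus_model(50, 0.5)
  d <- sample_distances(m, 1e6)
  auc <- penetrability_auc(normalize_align(bin_distances(d, 5)))
  expect_equal(auc, expected_penetrability(m, 5), tolerance = 0.01)
})
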