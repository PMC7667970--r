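flat_stack <- function(mean_z = 49, nx = 24, ny = 24, z_step = 2,
                       beads = NULL, noise = 0, seed = NULL, nz = NULL) {
  surf <- simulate_tissue_surface(nx, ny, pixel_size = 1.25, mean_z = mean_z,
                                  amplitude = 0)
  if (is.null(beads)) {
    beads <- tibble::tibble(x_um = numeric(0), y_um = numeric(0), z_um = numeric(0))
  }
  render_stack(surf, beads, z_step = z_step, nz = nz, noise_sigma = noise,
               seed = seed)
}

test_that("tissue surface extraction recovers a flat phantom within dz", {
  st <- flat_stack(mean_z = 50, z_step = 2, nz = 40)
  es <- extract_tissue_surface(st)
  expect_true(all(es$valid))
  # topmost filled voxel centre: 49 for a surface at 50 with dz = 2
  expect_true(all(abs(es$z - 50) <= 2))
  expect_equal(length(unique(as.vector(es$z))), 1L)
})

test_that("an all-background tissue channel yields an empty mask, not a failure", {
  st <- flat_stack(nz = 10)
  st$tissue[] <- 0
  expect_warning(es <- extract_tissue_surface(st), "no signal")
  expect_false(any(es$valid))
  expect_error(bead_distances(tibble::tibble(x_um = 1, y_um = 1, z_um = 5), es),
               class = "mucometry_data_error")
})

test_that("an undulating surface is recovered within one z-step per column", {
  surf <- simulate_tissue_surface(32, 32, pixel_size = 1.25, mean_z = 40,
                                  amplitude = 8, correlation_length = 10,
                                  seed = 13)
  st <- render_stack(surf, tibble::tibble(x_um = numeric(0), y_um = numeric(0),
                                          z_um = numeric(0)),
                     z_step = 2, nz = 40)
  es <- extract_tissue_surface(st)
  expect_true(all(abs(es$z - surf$z) <= 2))
})

test_that("bead detection finds exactly the rendered beads", {
  surf <- simulate_tissue_surface(48, 48, pixel_size = 1.25, mean_z = 20,
                                  amplitude = 0)
  beads <- simulate_beads(surf, mucus_model(40, 0.5), 25, seed = 17,
                          min_spacing = 8)
  st <- render_stack(surf, beads, z_step = 2)
  det <- detect_beads(st)
  expect_equal(nrow(det), 25)
  # each centroid within one voxel diagonal of its ground-truth bead
  diag_um <- sqrt(sum(st$voxel_size^2))
  nn <- vapply(seq_len(nrow(det)), function(i) {
    min(sqrt((beads$x_um - det$x_um[i])^2 + (beads$y_um - det$y_um[i])^2 +
               (beads$z_um - det$z_um[i])^2))
  }, numeric(1))
  expect_true(all(nn <= diag_um))
})

test_that("a noise-only bead channel yields zero beads", {
  st <- flat_stack(nz = 12)
  set.seed(3)
  st$beads <- array(abs(rnorm(length(st$beads), 0, 1e-3)), dim = dim(st$beads))
  det <- detect_beads(st, min_voxels = 2)
  expect_equal(nrow(det), 0)

  st$beads[] <- 0
  expect_equal(nrow(detect_beads(st)), 0)
})

test_that("re-rendering a bead onto itself still yields one component", {
  surf <- simulate_tissue_surface(16, 16, pixel_size = 1.25, mean_z = 10,
                                  amplitude = 0)
  one <- tibble::tibble(x_um = 10, y_um = 10, z_um = 20)
  st1 <- render_stack(surf, one, z_step = 2, nz = 15)
  st2 <- render_stack(surf, dplyr::bind_rows(one, one), z_step = 2, nz = 15)
  expect_identical(st1$beads, st2$beads)  # max-compositing of identical blobs
  expect_equal(nrow(detect_beads(st2)), 1)
})

test_that("single noise-free bead peaks at its own voxel", {
  surf <- simulate_tissue_surface(16, 16, pixel_size = 1.25, mean_z = 5,
                                  amplitude = 0)
  st <- render_stack(surf, tibble::tibble(x_um = 10.1, y_um = 7.2, z_um = 21),
                     z_step = 2, nz = 15)
  idx <- arrayInd(which.max(st$beads), dim(st$beads))
  expect_equal(idx[1, 1], floor(7.2 / 1.25) + 1)   # y voxel
  expect_equal(idx[1, 2], floor(10.1 / 1.25) + 1)  # x voxel
  expect_equal(idx[1, 3], floor(21 / 2) + 1)       # z voxel
})

test_that("out-of-volume beads are reported as clipped, not dropped silently", {
  surf <- simulate_tissue_surface(8, 8, pixel_size = 1.25, mean_z = 5,
                                  amplitude = 0)
  st <- render_stack(surf, tibble::tibble(x_um = c(5, 500), y_um = c(5, 5),
                                          z_um = c(10, 10)),
                     z_step = 2, nz = 10)
  expect_equal(st$clipped, 2L)
})

test_that("bead distances do the arithmetic and exclusion accounting", {
  surf <- simulate_tissue_surface(8, 8, pixel_size = 2, mean_z = 50, amplitude = 0)
  beads <- tibble::tibble(bead = 1:2, x_um = c(5, 9), y_um = c(5, 9),
                          z_um = c(80, 50))
  d <- bead_distances(beads, surf)
  expect_equal(d$d_um, c(30, 0))
  expect_equal(attr(d, "n_excluded"), 0L)

  surf$valid[] <- FALSE
  surf$valid[1, 1] <- TRUE
  d2 <- bead_distances(beads, surf)
  expect_equal(nrow(d2), 0)
  expect_equal(attr(d2, "n_excluded"), 2L)
})

test_that("shifting both channels by k z-planes shifts z and preserves d", {
  surf <- simulate_tissue_surface(24, 24, pixel_size = 1.25, mean_z = 20,
                                  amplitude = 3, correlation_length = 10, seed = 5)
  beads <- simulate_beads(surf, mucus_model(30, 0.4), 12, seed = 6,
                          min_spacing = 8)
  st <- render_stack(surf, beads, z_step = 2, nz = 40)
  k <- 4L
  shift <- function(a, k) {
    out <- array(0, dim = dim(a))
    out[, , (k + 1):dim(a)[3]] <- a[, , 1:(dim(a)[3] - k)]
    out
  }
  st2 <- st
  st2$tissue <- shift(st$tissue, k)
  st2$beads <- shift(st$beads, k)

  s1 <- extract_tissue_surface(st);  s2 <- extract_tissue_surface(st2)
  expect_equal(s2$z, s1$z + k * 2)
  b1 <- detect_beads(st);  b2 <- detect_beads(st2)
  expect_equal(nrow(b1), nrow(b2))
  expect_equal(sort(b2$z_um), sort(b1$z_um) + k * 2, tolerance = 1e-10)
  d1 <- bead_distances(b1, s1);  d2 <- bead_distances(b2, s2)
  expect_equal(sort(d2$d_um), sort(d1$d_um), tolerance = 1e-10)
})

test_that("render -> extract -> distances recovers generator distances (RMS <= dz)", {
  surf <- simulate_tissue_surface(48, 48, pixel_size = 1.25, mean_z = 20,
                                  amplitude = 2, correlation_length = 15, seed = 23)
  beads <- simulate_beads(surf, mucus_model(40, 0.5), 30, seed = 24,
                          min_spacing = 8)
  st <- render_stack(surf, beads, z_step = 2)
  es <- extract_tissue_surface(st)
  det <- detect_beads(st)
  expect_equal(nrow(det), 30)
  d <- bead_distances(det, es)
  # match detections to ground truth by nearest centroid
  truth <- vapply(seq_len(nrow(d)), function(i) {
    j <- which.min((beads$x_um - d$x_um[i])^2 + (beads$y_um - d$y_um[i])^2 +
                     (beads$z_um - d$z_um[i])^2)
    beads$d_true_um[j]
  }, numeric(1))
  rms <- sqrt(mean((d$d_um - truth)^2))
  expect_lte(rms, 2)
})
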