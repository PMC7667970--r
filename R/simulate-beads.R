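#' Simulate a sedimented microbead population over a tissue surface
#'
#' Places `n_beads` beads uniformly over the lateral field. Each bead either
#' rests on the mucus surface (depth 0 plus optional jitter) or penetrates to
#' a depth drawn from the model's depth law, so its axial position is
#' `surface_z(x, y) + thickness - depth`. The returned table carries the
#' ground-truth depth and a surface/penetrant label for every bead, which is
#' what downstream recovery tests are scored against.
#'
#' @param surface A `tissue_surface` (see [simulate_tissue_surface()]).
#' @param model A [mucus_model()].
#' @param n_beads Number of beads (>= 1).
#' @param seed Integer seed.
#' @param min_spacing Optional minimum pairwise 3D distance in micrometres,
#'   enforced by rejection sampling. Use when the beads will be rendered into
#'   an image stack, so that connected-component detection counts are
#'   well defined. `NULL` (default) places beads independently.
#'
#' @return A tibble with one row per bead: `bead`, `x_um`, `y_um`, `z_um`,
#'   `depth_um` (true depth below the mucus surface), `label`
#'   (`"surface"`/`"penetrant"`), and `d_true_um`, the true tissue-to-bead
#'   z distance `z_um - surface_z(x, y)`.
#' @examples
#' surf <- simulate_tissue_surface(16, 16, mean_z = 20, amplitude = 0)
#' beads <- simulate_beads(surf, mucus_model(80, 0.5), 100, seed = 1)
#' table(beads$label)
#' @export
simulate_beads <- function(surface, model, n_beads, seed = NULL,
                           min_spacing = NULL) {
  stopifnot(inherits(surface, "tissue_surface"), inherits(model, "mucus_model"))
  n_beads <- check_count(n_beads, "n_beads", min = 1L)
  if (!is.null(min_spacing)) {
    check_number(min_spacing, "min_spacing", lower = 0, strict_lower = TRUE)
  }

  px <- surface$pixel_size
  lx <- ncol(surface$z) * px
  ly <- nrow(surface$z) * px

  with_seed(seed, {
    if (is.null(min_spacing)) {
      x <- stats::runif(n_beads, 0, lx)
      y <- stats::runif(n_beads, 0, ly)
      dd <- draw_depths(model, n_beads)
      depth <- dd$depth
      label <- dd$label
    } else {
      # rejection sampling for non-overlapping beads
      x <- y <- depth <- numeric(0)
      label <- character(0)
      tries <- 0L
      while (length(x) < n_beads) {
        tries <- tries + 1L
        if (tries > 1000L * n_beads) {
          abort_config("could not place non-overlapping beads: `min_spacing` too large for the field")
        }
        cx <- stats::runif(1, 0, lx)
        cy <- stats::runif(1, 0, ly)
        dd <- draw_depths(model, 1L)
        sz <- surface_height_at(surface, cx, cy)
        cz <- sz + model$thickness - dd$depth
        if (length(x) > 0) {
          zs <- surface_height_at(surface, x, y) + model$thickness - depth
          if (min((cx - x)^2 + (cy - y)^2 + (cz - zs)^2) < min_spacing^2) next
        }
        x <- c(x, cx); y <- c(y, cy)
        depth <- c(depth, dd$depth); label <- c(label, dd$label)
      }
    }
    surf_z <- surface_height_at(surface, x, y)
    tibble::tibble(
      bead = seq_len(n_beads),
      x_um = x,
      y_um = y,
      z_um = surf_z + model$thickness - depth,
      depth_um = depth,
      label = label,
      d_true_um = model$thickness - depth
    )
  })
}

#' Simulate repeated ex vivo mucus thickness measurements
#'
#' Emulates micromanipulator thickness measurements on mounted explant
#' tissue: the mucus surface position is probed at several locations every
#' 15 minutes, and the layer grows linearly while the tissue is maintained.
#' Thickness at time `t` is `t0 + rate * t` plus Gaussian measurement noise.
#'
#' @param t0 Initial mucus thickness, micrometres (> 0).
#' @param rate Mucus growth rate, micrometres per minute.
#' @param noise_sigma Measurement noise SD, micrometres (>= 0).
#' @param times Measurement times in minutes (default every 15 min up to 45).
#' @param n_locations Number of probed locations per time point (default 5).
#' @param seed Integer seed.
#' @param mouse Optional mouse id stored in the output.
#'
#' @return A tibble with columns `mouse` (if given), `location`, `time_min`,
#'   `thickness_um`.
#' @examples
#' simulate_thickness_series(400, 2, noise_sigma = 0)
#' @export
simulate_thickness_series <- function(t0, rate, noise_sigma = 10,
                                      times = c(0, 15, 30, 45),
                                      n_locations = 5, seed = NULL,
                                      mouse = NULL) {
  check_number(t0, "t0", lower = 0, strict_lower = TRUE)
  check_number(rate, "rate")
  check_number(noise_sigma, "noise_sigma", lower = 0)
  n_locations <- check_count(n_locations, "n_locations", min = 1L)
  if (length(times) < 1) abort_config("`times` must contain at least one time point")

  grid <- tidyr::expand_grid(location = seq_len(n_locations), time_min = sort(times))
  thick <- with_seed(seed, {
    t0 + rate * grid$time_min +
      if (noise_sigma > 0) stats::rnorm(nrow(grid), 0, noise_sigma) else 0
  })
  out <- tibble::tibble(
    location = grid$location,
    time_min = grid$time_min,
    thickness_um = thick
  )
  if (!is.null(mouse)) out <- tibble::add_column(out, mouse = mouse, .before = 1)
  out
}
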