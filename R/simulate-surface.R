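#' Simulate a smooth epithelial tissue surface
#'
#' Generates a gently undulating tissue surface height map on a regular
#' (x, y) grid, used as the floor of the simulated imaging chamber. Heights
#' are a smoothed Gaussian random field rescaled so that the largest
#' deviation from `mean_z` equals `amplitude` exactly; the surface is
#' therefore guaranteed to stay within `mean_z +/- amplitude` micrometres.
#'
#' @param nx,ny Grid size in cells (x and y).
#' @param pixel_size Lateral cell size in micrometres.
#' @param mean_z Mean surface height above the stack origin, micrometres.
#' @param amplitude Maximum absolute deviation from `mean_z`, micrometres
#'   (>= 0; 0 gives a perfectly flat surface). Must satisfy
#'   `mean_z - amplitude > 0` so the surface never leaves the volume.
#' @param correlation_length Lateral smoothing length of the undulations,
#'   micrometres.
#' @param seed Integer seed; the same seed reproduces the same surface.
#'
#' @return A `tissue_surface` object: height matrix (rows = y, cols = x) with
#'   pixel size and validity mask. Use [as_tibble()][tibble::as_tibble] for a
#'   tidy (x, y, z) view.
#' @examples
#' surf <- simulate_tissue_surface(32, 32, pixel_size = 2, mean_z = 50,
#'                                 amplitude = 5, seed = 1)
#' range(surf$z)
#' @export
simulate_tissue_surface <- function(nx, ny, pixel_size = 1.25, mean_z = 20,
                                    amplitude = 3, correlation_length = 20,
                                    seed = NULL) {
  nx <- check_count(nx, "nx", min = 1L)
  ny <- check_count(ny, "ny", min = 1L)
  check_number(pixel_size, "pixel_size", lower = 0, strict_lower = TRUE)
  check_number(mean_z, "mean_z", lower = 0, strict_lower = TRUE)
  check_number(amplitude, "amplitude", lower = 0)
  check_number(correlation_length, "correlation_length", lower = 0, strict_lower = TRUE)
  if (mean_z - amplitude <= 0) {
    abort_config("`mean_z - amplitude` must be positive: the tissue must stay inside the volume")
  }

  if (amplitude == 0) {
    z <- matrix(mean_z, nrow = ny, ncol = nx)
  } else {
    z <- with_seed(seed, {
      field <- matrix(stats::rnorm(ny * nx), nrow = ny, ncol = nx)
      field <- smooth_field(field, sigma_px = correlation_length / pixel_size)
      dev <- field - mean(field)
      mx <- max(abs(dev))
      mean_z + if (mx == 0) 0 * dev else amplitude * dev / mx
    })
  }

  new_tissue_surface(z, pixel_size = pixel_size,
                     valid = matrix(TRUE, nrow = ny, ncol = nx))
}

new_tissue_surface <- function(z, pixel_size, valid) {
  structure(
    list(z = z, pixel_size = pixel_size, valid = valid),
    class = "tissue_surface"
  )
}

#' @export
print.tissue_surface <- function(x, ...) {
  cat(sprintf(
    "<tissue_surface> %d x %d cells at %g um/px; z in [%g, %g] um; %d invalid cells\n",
    ncol(x$z), nrow(x$z), x$pixel_size,
    suppressWarnings(min(x$z[x$valid])), suppressWarnings(max(x$z[x$valid])),
    sum(!x$valid)
  ))
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.tissue_surface <- function(x, ...) {
  ny <- nrow(x$z); nx <- ncol(x$z)
  tibble::tibble(
    x_um = rep((seq_len(nx) - 0.5) * x$pixel_size, each = ny),
    y_um = rep((seq_len(ny) - 0.5) * x$pixel_size, times = nx),
    z_um = as.vector(ifelse(x$valid, x$z, NA_real_)),
    valid = as.vector(x$valid)
  )
}

# separable circular Gaussian smoothing of a matrix; the kernel is truncated
# to the grid size so small fields still smooth rather than error
smooth_field <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  sm_cols <- function(mat) {
    half <- min(max(1L, ceiling(3 * sigma_px)), (nrow(mat) - 1L) %/% 2L)
    if (half < 1L) return(mat)
    k <- stats::dnorm(seq(-half, half), sd = sigma_px)
    k <- k / sum(k)
    apply(mat, 2, function(col) {
      as.numeric(stats::filter(col, k, method = "convolution",
                               sides = 2, circular = TRUE))
    })
  }
  t(sm_cols(t(sm_cols(m))))
}

# surface height (um) at arbitrary physical (x, y), bilinear between cell
# centres; returns NA where any contributing cell is invalid
surface_height_at <- function(surface, x_um, y_um) {
  z <- surface$z
  valid <- surface$valid
  px <- surface$pixel_size
  ny <- nrow(z); nx <- ncol(z)

  # fractional cell-centre coordinates, clamped to the grid interior
  gx <- pmin(pmax(x_um / px - 0.5, 0), nx - 1)
  gy <- pmin(pmax(y_um / px - 0.5, 0), ny - 1)
  ix0 <- pmin(floor(gx), nx - 2); ix0 <- pmax(ix0, 0)
  iy0 <- pmin(floor(gy), ny - 2); iy0 <- pmax(iy0, 0)
  if (nx == 1) ix0 <- rep(0, length(gx))
  if (ny == 1) iy0 <- rep(0, length(gy))
  fx <- gx - ix0
  fy <- gy - iy0

  idx <- function(iy, ix) iy + 1L + ny * ix  # matrix linear index
  i00 <- idx(iy0, ix0)
  i01 <- idx(iy0, pmin(ix0 + 1, nx - 1))
  i10 <- idx(pmin(iy0 + 1, ny - 1), ix0)
  i11 <- idx(pmin(iy0 + 1, ny - 1), pmin(ix0 + 1, nx - 1))

  ok <- valid[i00] & valid[i01] & valid[i10] & valid[i11]
  out <- (1 - fx) * (1 - fy) * z[i00] + fx * (1 - fy) * z[i01] +
    (1 - fx) * fy * z[i10] + fx * fy * z[i11]
  out[!ok] <- NA_real_
  out
}
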