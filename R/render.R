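#' Render a two-channel confocal z-stack from a surface and a bead set
#'
#' Builds the synthetic voxel volume that the image-analysis stage consumes:
#' channel 1 ("tissue") holds constant signal in every voxel whose centre
#' lies at or below the tissue surface, channel 2 ("beads") holds one
#' Gaussian-profile blob per bead. Beads smaller than a voxel are rendered
#' with a footprint of about one voxel FWHM (per axis
#' `sigma = max(bead_diameter / 2.355, voxel size)`), the minimal footprint
#' from which a sub-voxel centroid can be recovered; this mimics the finite
#' sampling of a diffraction-limited spot without modelling a PSF. Gaussian
#' background noise is added to both channels when `noise_sigma > 0`.
#'
#' Beads whose centre falls outside the rendered volume are reported in the
#' `clipped` attribute of the result, never silently dropped.
#'
#' @param surface A `tissue_surface`.
#' @param beads A bead tibble from [simulate_beads()] (columns `x_um`,
#'   `y_um`, `z_um`).
#' @param z_step Axial voxel size, µm (default 2).
#' @param nz Number of z planes; default covers the highest bead plus margin.
#' @param bead_diameter Physical bead diameter, µm (default 1).
#' @param tissue_intensity,bead_intensity Signal amplitudes in `[0, 1]`.
#' @param noise_sigma Background noise SD (same units; must be smaller than
#'   both intensities).
#' @param seed Integer seed for the noise.
#' @return A `voxel_stack`: arrays `tissue` and `beads` with dimensions
#'   (y, x, z), voxel sizes in µm, and a `clipped` report.
#' @export
render_stack <- function(surface, beads, z_step = 2, nz = NULL,
                         bead_diameter = 1, tissue_intensity = 0.8,
                         bead_intensity = 0.9, noise_sigma = 0, seed = NULL) {
  stopifnot(inherits(surface, "tissue_surface"))
  check_number(z_step, "z_step", lower = 0, strict_lower = TRUE)
  check_number(bead_diameter, "bead_diameter", lower = 0, strict_lower = TRUE)
  check_number(tissue_intensity, "tissue_intensity", lower = 0, upper = 1, strict_lower = TRUE)
  check_number(bead_intensity, "bead_intensity", lower = 0, upper = 1, strict_lower = TRUE)
  check_number(noise_sigma, "noise_sigma", lower = 0)
  if (noise_sigma >= min(tissue_intensity, bead_intensity)) {
    abort_config("`noise_sigma` must be smaller than the signal intensities")
  }

  ny <- nrow(surface$z); nx <- ncol(surface$z)
  dx <- dy <- surface$pixel_size
  sigma <- c(z = max(bead_diameter / 2.355, z_step),
             y = max(bead_diameter / 2.355, dy),
             x = max(bead_diameter / 2.355, dx))
  if (is.null(nz)) {
    top <- max(max(surface$z), if (nrow(beads)) max(beads$z_um) else 0)
    nz <- ceiling((top + 3 * sigma[["z"]]) / z_step) + 1L
  }
  nz <- check_count(nz, "nz", min = 1L)

  zc <- (seq_len(nz) - 0.5) * z_step
  tissue <- array(0, dim = c(ny, nx, nz))
  for (iz in seq_len(nz)) {
    tissue[, , iz] <- tissue_intensity * (surface$z >= zc[iz])
  }

  bead_ch <- array(0, dim = c(ny, nx, nz))
  clipped <- integer(0)
  lx <- nx * dx; ly <- ny * dy; lz <- nz * z_step
  for (i in seq_len(nrow(beads))) {
    bx <- beads$x_um[i]; by <- beads$y_um[i]; bz <- beads$z_um[i]
    if (bx < 0 || bx > lx || by < 0 || by > ly || bz < 0 || bz > lz) {
      clipped <- c(clipped, i)
    }
    # 3-sigma voxel window around the bead centre
    rng <- function(c_um, step, nmax, s) {
      lo <- max(1L, floor((c_um - 3 * s) / step - 0.5) + 1L)
      hi <- min(nmax, ceiling((c_um + 3 * s) / step + 0.5))
      if (lo > hi) integer(0) else lo:hi
    }
    ixs <- rng(bx, dx, nx, sigma[["x"]])
    iys <- rng(by, dy, ny, sigma[["y"]])
    izs <- rng(bz, z_step, nz, sigma[["z"]])
    if (!length(ixs) || !length(iys) || !length(izs)) next
    gx <- exp(-0.5 * (((ixs - 0.5) * dx - bx) / sigma[["x"]])^2)
    gy <- exp(-0.5 * (((iys - 0.5) * dy - by) / sigma[["y"]])^2)
    gz <- exp(-0.5 * (((izs - 0.5) * z_step - bz) / sigma[["z"]])^2)
    blob <- bead_intensity * outer(outer(gy, gx), gz)
    bead_ch[iys, ixs, izs] <- pmax(bead_ch[iys, ixs, izs], blob)
  }

  if (noise_sigma > 0) {
    noise <- with_seed(seed, {
      list(t = stats::rnorm(length(tissue), 0, noise_sigma),
           b = stats::rnorm(length(bead_ch), 0, noise_sigma))
    })
    tissue <- tissue + noise$t
    bead_ch <- bead_ch + noise$b
  }

  structure(
    list(
      tissue = tissue, beads = bead_ch,
      voxel_size = c(dz = z_step, dy = dy, dx = dx),
      clipped = clipped
    ),
    class = "voxel_stack"
  )
}

#' @export
print.voxel_stack <- function(x, ...) {
  d <- dim(x$tissue)
  cat(sprintf(
    "<voxel_stack> 2 channels x %d z x %d y x %d x voxels, voxel %g x %g x %g um (z,y,x); %d clipped beads\n",
    d[3], d[1], d[2], x$voxel_size[["dz"]], x$voxel_size[["dy"]],
    x$voxel_size[["dx"]], length(x$clipped)
  ))
  invisible(x)
}

#' Write / read a voxel stack as a multi-page TIFF with a YAML sidecar
#'
#' The stack is stored as 32-bit float pages ordered channel-major (all
#' tissue planes bottom-to-top, then all bead planes); voxel sizes, grid
#' dimensions and channel roles go into `<path>.yaml`. Intensities are
#' clamped to `[0, 1]` on write, the float range of the TIFF encoding used.
#'
#' @param stack A `voxel_stack`.
#' @param path Output TIFF path.
#' @return `write_stack_tiff()` returns `path` invisibly; `read_stack_tiff()`
#'   returns a `voxel_stack`.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "voxel_stack"))
  d <- dim(stack$tissue)
  clamp <- function(a) pmin(pmax(a, 0), 1)
  pages <- c(
    lapply(seq_len(d[3]), function(iz) clamp(stack$tissue[, , iz])),
    lapply(seq_len(d[3]), function(iz) clamp(stack$beads[, , iz]))
  )
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(
    ny = d[1], nx = d[2], nz = d[3],
    voxel_size_um = as.list(stack$voxel_size),
    channels = c("tissue", "beads"),
    page_order = "channel_major_z_ascending"
  )
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  pages <- tiff::readTIFF(path, all = TRUE)
  nz <- meta$nz
  if (length(pages) != 2 * nz) abort_data("TIFF page count does not match sidecar metadata")
  to_array <- function(ps) {
    a <- array(0, dim = c(meta$ny, meta$nx, nz))
    for (iz in seq_len(nz)) a[, , iz] <- ps[[iz]]
    a
  }
  structure(
    list(
      tissue = to_array(pages[seq_len(nz)]),
      beads = to_array(pages[nz + seq_len(nz)]),
      voxel_size = c(dz = meta$voxel_size_um$dz, dy = meta$voxel_size_um$dy,
                     dx = meta$voxel_size_um$dx),
      clipped = integer(0)
    ),
    class = "voxel_stack"
  )
}
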