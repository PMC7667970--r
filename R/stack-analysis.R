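#' Extract the tissue surface from the tissue channel of a voxel stack
#'
#' For every (x, y) column the surface height is the physical z of the
#' topmost voxel whose tissue intensity exceeds `threshold_fraction` of the
#' channel maximum (voxel centre convention: plane `i` sits at
#' `(i - 1/2) * dz`). Columns with no supra-threshold voxel are masked
#' invalid; an all-background channel yields an empty mask with a warning,
#' not a failure.
#'
#' @param stack A `voxel_stack`.
#' @param threshold_fraction Threshold as a fraction of the channel maximum,
#'   in (0, 1). Default 0.5.
#' @return A `tissue_surface` with per-cell heights (µm) and validity mask.
#' @export
extract_tissue_surface <- function(stack, threshold_fraction = 0.5) {
  stopifnot(inherits(stack, "voxel_stack"))
  check_number(threshold_fraction, "threshold_fraction",
               lower = 0, upper = 1, strict_lower = TRUE, strict_upper = TRUE)
  ch <- stack$tissue
  d <- dim(ch)
  dz <- stack$voxel_size[["dz"]]
  mx <- max(ch)
  surf <- matrix(NA_real_, nrow = d[1], ncol = d[2])
  if (mx <= 0) {
    warning("tissue channel contains no signal: all surface cells are invalid")
  } else {
    thr <- threshold_fraction * mx
    for (iz in seq_len(d[3])) {
      above <- ch[, , iz] > thr
      surf[above] <- (iz - 0.5) * dz  # later (higher) planes overwrite
    }
    if (all(is.na(surf))) {
      warning("no supra-threshold tissue voxels: all surface cells are invalid")
    }
  }
  valid <- !is.na(surf)
  surf[!valid] <- NA_real_
  new_tissue_surface(surf, pixel_size = stack$voxel_size[["dx"]], valid = valid)
}

#' Detect bead centroids in the bead channel of a voxel stack
#'
#' Thresholds the bead channel at `threshold_fraction` of its maximum (or at
#' the background noise floor, median + 5 MAD, if that is higher — so pure
#' noise yields zero detections), labels 3D connected components under
#' 26-connectivity, discards components
#' smaller than `min_voxels` (single-voxel noise), and returns the
#' intensity-weighted centroid of each remaining component in physical
#' micrometres. Zero beads is a valid result.
#'
#' @param stack A `voxel_stack`.
#' @param threshold_fraction Threshold as a fraction of the channel maximum.
#' @param min_voxels Minimum component size in voxels (default 2).
#' @return A tibble: `bead`, `x_um`, `y_um`, `z_um`, `voxel_count`,
#'   `peak_intensity`.
#' @export
detect_beads <- function(stack, threshold_fraction = 0.5, min_voxels = 2) {
  stopifnot(inherits(stack, "voxel_stack"))
  check_number(threshold_fraction, "threshold_fraction",
               lower = 0, upper = 1, strict_lower = TRUE, strict_upper = TRUE)
  min_voxels <- check_count(min_voxels, "min_voxels", min = 1L)
  ch <- stack$beads
  d <- dim(ch)
  empty <- tibble::tibble(
    bead = integer(0), x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
    voxel_count = integer(0), peak_intensity = numeric(0)
  )
  mx <- max(ch)
  if (mx <= 0) return(empty)
  # beads must both exceed the relative threshold and stand out from the
  # background by at least 5 robust SDs, so a noise-only channel (or relative
  # thresholding inside pure noise) yields zero beads rather than speckle
  noise_floor <- stats::median(ch) + 5 * stats::mad(ch)
  thr <- max(threshold_fraction * mx, noise_floor)
  vox <- which(ch > thr)
  if (length(vox) == 0) return(empty)

  labels <- label_components_3d(vox, dims = d)
  iy <- ((vox - 1L) %% d[1]) + 1L
  ix <- (((vox - 1L) %/% d[1]) %% d[2]) + 1L
  iz <- ((vox - 1L) %/% (d[1] * d[2])) + 1L
  w <- ch[vox]
  vs <- stack$voxel_size

  comp <- tibble::tibble(lab = labels, iy = iy, ix = ix, iz = iz, w = w) |>
    dplyr::group_by(.data$lab) |>
    dplyr::summarise(
      voxel_count = dplyr::n(),
      x_um = sum((.data$ix - 0.5) * vs[["dx"]] * .data$w) / sum(.data$w),
      y_um = sum((.data$iy - 0.5) * vs[["dy"]] * .data$w) / sum(.data$w),
      z_um = sum((.data$iz - 0.5) * vs[["dz"]] * .data$w) / sum(.data$w),
      peak_intensity = max(.data$w),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$voxel_count >= min_voxels) |>
    dplyr::arrange(.data$z_um, .data$y_um, .data$x_um)

  tibble::tibble(
    bead = seq_len(nrow(comp)),
    x_um = comp$x_um, y_um = comp$y_um, z_um = comp$z_um,
    voxel_count = as.integer(comp$voxel_count),
    peak_intensity = comp$peak_intensity
  )
}

# 26-connectivity connected-component labelling of a sparse voxel set,
# union-find with path halving; `vox` holds linear indices into an array of
# dimension `dims` (y, x, z)
label_components_3d <- function(vox, dims) {
  n <- length(vox)
  ny <- dims[1]; nx <- dims[2]; nz <- dims[3]
  iy <- ((vox - 1L) %% ny)
  ix <- (((vox - 1L) %/% ny) %% nx)
  iz <- ((vox - 1L) %/% (ny * nx))

  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }

  # half the 26-neighbourhood: offsets lexicographically positive
  offs <- expand.grid(dy = -1:1, dx = -1:1, dz = -1:1)
  offs <- offs[offs$dz > 0 | (offs$dz == 0 & offs$dx > 0) |
                 (offs$dz == 0 & offs$dx == 0 & offs$dy > 0), ]

  key <- iy + ny * (ix + nx * iz)
  ord <- order(key)
  sorted_key <- key[ord]
  for (k in seq_len(nrow(offs))) {
    ny2 <- iy + offs$dy[k]; nx2 <- ix + offs$dx[k]; nz2 <- iz + offs$dz[k]
    inb <- ny2 >= 0 & ny2 < ny & nx2 >= 0 & nx2 < nx & nz2 >= 0 & nz2 < nz
    if (!any(inb)) next
    nkey <- ny2[inb] + ny * (nx2[inb] + nx * nz2[inb])
    pos <- match(nkey, sorted_key)
    hit <- !is.na(pos)
    if (!any(hit)) next
    ia <- which(inb)[hit]
    ib <- ord[pos[hit]]
    for (j in seq_along(ia)) {
      ra <- find(ia[j]); rb <- find(ib[j])
      if (ra != rb) parent[rb] <- ra
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Tissue-to-bead z distances
#'
#' For each detected bead, the z distance to the tissue surface beneath it:
#' `d = bead_z - surface_z(x, y)`, with the surface height bilinearly
#' interpolated between valid cells. Positive distances are above the
#' tissue. Beads over invalid surface cells are excluded from the result and
#' counted in the `n_excluded` attribute.
#'
#' @param beads A bead centroid tibble (columns `x_um`, `y_um`, `z_um`),
#'   e.g. from [detect_beads()].
#' @param surface A `tissue_surface`, e.g. from [extract_tissue_surface()].
#' @return A tibble `bead`, `x_um`, `y_um`, `z_um`, `d_um`; attribute
#'   `n_excluded` counts beads dropped over invalid surface.
#' @export
bead_distances <- function(beads, surface) {
  stopifnot(inherits(surface, "tissue_surface"))
  if (!any(surface$valid)) abort_data("all surface cells are invalid: cannot compute distances")
  if (nrow(beads) == 0) {
    out <- tibble::tibble(bead = integer(0), x_um = numeric(0), y_um = numeric(0),
                          z_um = numeric(0), d_um = numeric(0))
    attr(out, "n_excluded") <- 0L
    return(out)
  }
  sz <- surface_height_at(surface, beads$x_um, beads$y_um)
  keep <- is.finite(sz)
  out <- tibble::tibble(
    bead = beads$bead %||% seq_len(nrow(beads)),
    x_um = beads$x_um, y_um = beads$y_um, z_um = beads$z_um,
    d_um = beads$z_um - sz
  )[keep, ]
  attr(out, "n_excluded") <- sum(!keep)
  out
}
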