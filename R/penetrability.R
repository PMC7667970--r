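#' Bin tissue-to-bead z distances into a frequency distribution
#'
#' Builds the uniform-width histogram of tissue-to-bead z-axis distances that
#' underlies the normalized-penetrability statistic. Bins are left-closed
#' intervals `[(j-1)b, jb)` starting at the tissue (distance 0) and extending
#' far enough to contain the largest distance. Distances below the tissue
#' surface (`d < 0`, possible when a noisy surface estimate overshoots) are
#' clamped into the first bin and counted in the `n_below_tissue` attribute,
#' never silently dropped.
#'
#' @param d_um Numeric vector of tissue-to-bead z distances, micrometres.
#' @param bin_width Bin width `b` in micrometres (default 5).
#'
#' @return A tibble with columns `lower_um`, `upper_um`, `center_um`, `count`,
#'   and attributes `bin_width` and `n_below_tissue`. Counts sum to
#'   `length(d_um)`.
#' @examples
#' bin_distances(c(2, 7, 12), bin_width = 5)
#' @export
bin_distances <- function(d_um, bin_width = 5) {
  check_number(bin_width, "bin_width", lower = 0, strict_lower = TRUE)
  if (length(d_um) == 0) abort_data("no beads detected: cannot bin an empty distance set")
  if (any(!is.finite(d_um))) abort_data("distances must be finite")

  n_below <- sum(d_um < 0)
  d <- pmax(d_um, 0)
  n_bins <- floor(max(d) / bin_width) + 1L
  idx <- pmin(floor(d / bin_width) + 1L, n_bins)
  counts <- tabulate(idx, nbins = n_bins)

  out <- tibble::tibble(
    lower_um = (seq_len(n_bins) - 1) * bin_width,
    upper_um = seq_len(n_bins) * bin_width,
    center_um = (seq_len(n_bins) - 0.5) * bin_width,
    count = counts
  )
  attr(out, "bin_width") <- bin_width
  attr(out, "n_below_tissue") <- n_below
  out
}

#' Normalize and surface-align a bead distance distribution
#'
#' Applies the three normalisation rules of the penetrability statistic:
#' frequencies are divided by the maximum bin count (so curves from stacks
#' with different bead numbers are comparable), the depth axis is re-anchored
#' at the mucus surface — the bin with the maximum bead frequency, ties
#' broken towards the outermost (largest-distance) bin since the mucus
#' surface is the outermost bead accumulation — and bins above the surface
#' are cropped, with their bead count recorded. The curve ends at the deepest
#' occupied bin; interior empty bins are kept at zero frequency.
#'
#' @param dist A binned distance distribution from [bin_distances()].
#'
#' @return A `normalized_distribution`: a tibble with `x_um` (depth below the
#'   mucus surface, 0 at the surface, increasing towards the tissue), `f`
#'   (normalized frequency, max exactly 1 at `x_um = 0`) and `count`, plus
#'   attributes `surface_bin_distance` (distance of the surface bin centre
#'   from the tissue, micrometres), `n_cropped_above`, `bin_width` and
#'   `n_below_tissue`.
#' @examples
#' h <- bin_distances(c(2, 7, 7, 12), bin_width = 5)
#' normalize_align(h)
#' @export
normalize_align <- function(dist) {
  counts <- dist$count
  if (length(counts) == 0 || all(counts == 0)) {
    abort_data("empty distance distribution: nothing to normalize")
  }
  mx <- max(counts)
  modal <- max(which(counts == mx))  # outermost bin among ties
  s <- dist$center_um[modal]
  x <- s - dist$center_um
  keep <- x >= 0
  out <- tibble::tibble(
    x_um = x[keep],
    f = counts[keep] / mx,
    count = counts[keep]
  )
  out <- out[order(out$x_um), ]
  # the curve ends at the deepest occupied bin: trailing empty bins on the
  # tissue side carry no frequency information and are trimmed (interior
  # empty bins are kept at f = 0)
  last_occ <- max(which(out$count > 0))
  out <- out[seq_len(last_occ), ]
  out <- structure(out, class = c("normalized_distribution", class(tibble::tibble())))
  attr(out, "surface_bin_distance") <- s
  attr(out, "n_cropped_above") <- sum(counts[!keep])
  attr(out, "bin_width") <- attr(dist, "bin_width")
  attr(out, "n_below_tissue") <- attr(dist, "n_below_tissue") %||% 0L
  out
}

#' Area under a normalized bead distribution: the penetrability statistic
#'
#' Trapezoidal integral of the normalized frequency over depth below the
#' mucus surface, in micrometres. An impenetrable layer concentrates all
#' beads in the surface bin, giving a single-point curve and an AUC of 0;
#' deeper bead penetration raises the curve at positive depths and with it
#' the AUC.
#'
#' @param nd A `normalized_distribution` from [normalize_align()].
#' @return The normalized penetrability in micrometres (>= 0).
#' @examples
#' h <- bin_distances(rep(c(2, 12), c(3, 9)), bin_width = 5)
#' penetrability_auc(normalize_align(h))
#' @export
penetrability_auc <- function(nd) {
  if (nrow(nd) < 2) return(0)
  pracma::trapz(nd$x_um, nd$f)
}

#' Bead-derived mucus thickness
#'
#' The mucus layer thickness implied by a bead distance set: the arithmetic
#' mean tissue-to-bead z distance over all beads.
#'
#' @param d_um Numeric vector of tissue-to-bead z distances, micrometres.
#' @return Mean distance in micrometres.
#' @examples
#' thickness_from_beads(c(10, 20, 30, 40))
#' @export
thickness_from_beads <- function(d_um) {
  if (length(d_um) == 0) abort_data("no beads: cannot estimate thickness")
  mean(d_um)
}

#' Per-stack penetrability and thickness from a bead distance table
#'
#' The main tabular verb of the penetrability pipeline. Takes a table of
#' tissue-to-bead z distances with grouping columns (typically `mouse` and
#' `stack`), runs histogram, normalisation/alignment and AUC per stack and
#' returns one row per stack.
#'
#' @param data A data frame with a distance column (default `d_um`) and any
#'   of the id columns `mouse`, `stack` present.
#' @param bin_width Histogram bin width in micrometres (default 5).
#' @param distance Name of the distance column (default `"d_um"`).
#'
#' @return A tibble with one row per (`mouse`, `stack`) group: `auc_um`
#'   (normalized penetrability), `thickness_um` (mean bead distance),
#'   `n_beads`, `n_cropped_above`, `n_below_tissue`,
#'   `surface_bin_distance_um`.
#' @examples
#' surf <- simulate_tissue_surface(8, 8, mean_z = 20, amplitude = 0)
#' beads <- simulate_beads(surf, mucus_model(50, 0.3), 500, seed = 1)
#' penetrability(data.frame(mouse = "m1", stack = 1, d_um = beads$d_true_um))
#' @export
penetrability <- function(data, bin_width = 5, distance = "d_um") {
  if (!distance %in% names(data)) {
    abort_data(sprintf("column `%s` not found in `data`", distance))
  }
  ids <- intersect(c("mouse", "stack"), names(data))
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(ids))) |>
    dplyr::summarise(
      {
        d <- .data[[distance]]
        h <- bin_distances(d, bin_width = bin_width)
        nd <- normalize_align(h)
        tibble::tibble(
          auc_um = penetrability_auc(nd),
          thickness_um = thickness_from_beads(d),
          n_beads = length(d),
          n_cropped_above = attr(nd, "n_cropped_above"),
          n_below_tissue = attr(nd, "n_below_tissue"),
          surface_bin_distance_um = attr(nd, "surface_bin_distance")
        )
      },
      .groups = "drop"
    )
}

#' Normalized distribution curves per stack
#'
#' Tidy companion to [penetrability()]: returns the normalized,
#' surface-aligned curve of every stack for plotting or per-mouse curve
#' aggregation.
#'
#' @inheritParams penetrability
#' @return A tibble with the id columns plus `x_um`, `f`.
#' @export
penetrability_curves <- function(data, bin_width = 5, distance = "d_um") {
  if (!distance %in% names(data)) {
    abort_data(sprintf("column `%s` not found in `data`", distance))
  }
  ids <- intersect(c("mouse", "stack"), names(data))
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(ids))) |>
    dplyr::reframe(
      {
        nd <- normalize_align(bin_distances(.data[[distance]], bin_width = bin_width))
        tibble::tibble(x_um = nd$x_um, f = nd$f)
      }
    )
}

#' Aggregate per-stack penetrability to one value per mouse
#'
#' Each mouse contributes several z-stacks; the per-mouse summary is the
#' median of the per-stack AUCs (and of the other per-stack quantities),
#' matching the convention of displaying the median bead frequency
#' distribution per mouse.
#'
#' @param per_stack Output of [penetrability()] (must contain a `mouse`
#'   column).
#' @return A tibble with one row per mouse: `auc_um`, `thickness_um`
#'   (medians across stacks), `n_stacks`, `n_beads` (total).
#' @export
penetrability_by_mouse <- function(per_stack) {
  if (!"mouse" %in% names(per_stack)) {
    abort_data("`per_stack` must contain a `mouse` column")
  }
  per_stack |>
    dplyr::group_by(.data$mouse) |>
    dplyr::summarise(
      auc_um = stats::median(.data$auc_um),
      thickness_um = stats::median(.data$thickness_um),
      n_stacks = dplyr::n(),
      n_beads = sum(.data$n_beads),
      .groups = "drop"
    )
}

#' Pointwise-median display curve per mouse
#'
#' Combines the normalized curves of a mouse's stacks into a single display
#' curve: curves are placed on the union depth grid (regular with the common
#' bin width), each curve is zero beyond its own extent, and the median
#' frequency is taken at every grid point.
#'
#' @param curves Output of [penetrability_curves()] with columns `mouse`,
#'   `stack`, `x_um`, `f`.
#' @return A tibble with `mouse`, `x_um`, `f_median`.
#' @export
median_curve <- function(curves) {
  need <- c("mouse", "stack", "x_um", "f")
  if (!all(need %in% names(curves))) {
    abort_data("`curves` must have columns mouse, stack, x_um, f")
  }
  curves |>
    dplyr::group_by(.data$mouse) |>
    dplyr::group_modify(function(g, key) {
      grid <- sort(unique(g$x_um))
      per_stack <- lapply(split(g, g$stack), function(s) {
        m <- match(grid, s$x_um)
        ifelse(is.na(m), 0, s$f[m])  # zero beyond a curve's extent
      })
      f_mat <- do.call(cbind, per_stack)
      tibble::tibble(x_um = grid, f_median = apply(f_mat, 1, stats::median))
    }) |>
    dplyr::ungroup()
}
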