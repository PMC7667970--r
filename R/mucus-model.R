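#' Parametric model of a mucus layer probed by sedimenting microbeads
#'
#' The generative model behind all synthetic bead data. A mucus layer of
#' thickness `thickness` (micrometres) overlies the tissue surface. Beads
#' sediment onto the mucus surface; a fraction `penetration` of them enter the
#' layer and come to rest at a depth drawn from `depth_law`, while the
#' remainder stay at the surface (depth 0, optionally jittered by
#' `surface_jitter` to mimic surface roughness and detection noise). The
#' penetration fraction is the ground-truth quantity that the normalized
#' penetrability statistic (see [penetrability()]) is designed to track.
#'
#' @param thickness Mucus layer thickness in micrometres (> 0).
#' @param penetration Fraction of beads that penetrate the layer, in `[0, 1]`.
#' @param surface_jitter Standard deviation (micrometres, >= 0) of Gaussian
#'   jitter applied to the depth of surface-resting beads. Default 0: surface
#'   beads sit exactly at the mucus surface.
#' @param depth_law Resting-depth law for penetrant beads, either `"uniform"`
#'   (uniform over the layer) or `"exponential"` (exponential with mean
#'   `depth_scale`, truncated to the layer). The uniform law is the default
#'   because it is the least-informative choice over a layer of known
#'   thickness; the exponential law models beads that preferentially stall in
#'   the outer mucus.
#' @param depth_scale Mean (micrometres, > 0) of the exponential depth law
#'   before truncation. Ignored for the uniform law.
#'
#' @return An object of class `mucus_model`.
#' @examples
#' mucus_model(thickness = 80, penetration = 0.1)
#' @export
mucus_model <- function(thickness,
                        penetration,
                        surface_jitter = 0,
                        depth_law = c("uniform", "exponential"),
                        depth_scale = NULL) {
  depth_law <- match.arg(depth_law)
  check_number(thickness, "thickness", lower = 0, strict_lower = TRUE)
  check_number(penetration, "penetration", lower = 0, upper = 1)
  check_number(surface_jitter, "surface_jitter", lower = 0)
  if (depth_law == "exponential") {
    if (is.null(depth_scale)) {
      abort_config("`depth_scale` must be given for the exponential depth law")
    }
    check_number(depth_scale, "depth_scale", lower = 0, strict_lower = TRUE)
  }
  structure(
    list(
      thickness = thickness,
      penetration = penetration,
      surface_jitter = surface_jitter,
      depth_law = depth_law,
      depth_scale = depth_scale
    ),
    class = "mucus_model"
  )
}

#' @export
print.mucus_model <- function(x, ...) {
  law <- if (x$depth_law == "exponential") {
    sprintf("exponential(scale = %g um)", x$depth_scale)
  } else {
    "uniform"
  }
  cat(sprintf(
    "<mucus_model> thickness %g um, penetration %.3g, depth law %s, surface jitter %g um\n",
    x$thickness, x$penetration, law, x$surface_jitter
  ))
  invisible(x)
}

# draw resting depths (um below the mucus surface) for n beads
draw_depths <- function(model, n) {
  penetrant <- stats::runif(n) < model$penetration
  depth <- numeric(n)
  if (model$surface_jitter > 0) {
    depth[!penetrant] <- stats::rnorm(sum(!penetrant), 0, model$surface_jitter)
  }
  np <- sum(penetrant)
  if (np > 0) {
    depth[penetrant] <- switch(
      model$depth_law,
      uniform = stats::runif(np, 0, model$thickness),
      exponential = {
        # inverse-CDF sampling of the exponential truncated to [0, thickness]
        u <- stats::runif(np)
        pmax_cdf <- stats::pexp(model$thickness, rate = 1 / model$depth_scale)
        stats::qexp(u * pmax_cdf, rate = 1 / model$depth_scale)
      }
    )
  }
  list(depth = depth, label = ifelse(penetrant, "penetrant", "surface"))
}
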