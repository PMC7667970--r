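#' Fit the ex vivo mucus growth rate from repeated thickness measurements
#'
#' Ordinary least squares of mucus thickness on time, pooling all probed
#' locations (measurements at up to five locations every 15 minutes). The
#' slope is the mucus growth rate in micrometres per minute. Initial
#' thickness is taken as the mean measured thickness at `t = 0` when that
#' time point is present; otherwise the regression intercept is used and the
#' result is flagged (`initial_from_intercept`).
#'
#' @param data A data frame with columns `time_min` and `thickness_um`
#'   (extra columns such as `location` are allowed and ignored by the fit).
#' @return A `growth_fit` object. Use [generics::tidy()] / [generics::glance()]
#'   or the `$` accessors (`rate`, `rate_se`, `initial_thickness`,
#'   `r_squared`).
#' @examples
#' s <- simulate_thickness_series(400, 2, noise_sigma = 0)
#' fit_growth_rate(s)
#' @export
fit_growth_rate <- function(data) {
  need <- c("time_min", "thickness_um")
  if (!all(need %in% names(data))) {
    abort_data("`data` must have columns time_min and thickness_um")
  }
  if (length(unique(data$time_min)) < 2) {
    abort_data("at least two distinct time points are required to fit a growth rate")
  }
  fit <- stats::lm(thickness_um ~ time_min, data = data)
  # noise-free phantoms fit exactly; the perfect-fit chatter from summary()
  # is not informative here
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  has_t0 <- any(data$time_min == 0)
  initial <- if (has_t0) {
    mean(data$thickness_um[data$time_min == 0])
  } else {
    unname(co["(Intercept)", "Estimate"])
  }
  if (!has_t0) {
    warning("no t = 0 measurement: initial thickness taken from the regression intercept")
  }
  structure(
    list(
      rate = unname(co["time_min", "Estimate"]),
      rate_se = unname(co["time_min", "Std. Error"]),
      initial_thickness = initial,
      initial_from_intercept = !has_t0,
      r_squared = sm$r.squared,
      n_obs = nrow(data),
      lm = fit
    ),
    class = "growth_fit"
  )
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf(
    "<growth_fit> rate %.3f +/- %.3f um/min, initial thickness %.1f um%s, r^2 = %.3f (n = %d)\n",
    x$rate, x$rate_se, x$initial_thickness,
    if (x$initial_from_intercept) " (intercept)" else "",
    x$r_squared, x$n_obs
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.growth_fit <- function(x, ...) {
  tibble::tibble(
    term = c("initial_thickness_um", "rate_um_per_min"),
    estimate = c(x$initial_thickness, x$rate),
    std.error = c(NA_real_, x$rate_se)
  )
}

#' @export
glance.growth_fit <- function(x, ...) {
  tibble::tibble(
    rate_um_per_min = x$rate,
    rate_se = x$rate_se,
    initial_thickness_um = x$initial_thickness,
    initial_from_intercept = x$initial_from_intercept,
    r_squared = x$r_squared,
    n_obs = x$n_obs
  )
}

#' Growth rates for many mice at once
#'
#' Applies [fit_growth_rate()] per mouse and returns one row per mouse.
#'
#' @param data A data frame with columns `mouse`, `time_min`, `thickness_um`.
#' @return A tibble with `mouse`, `rate_um_per_min`, `rate_se`,
#'   `initial_thickness_um`, `r_squared`, `n_obs`.
#' @export
fit_growth_rates <- function(data) {
  if (!"mouse" %in% names(data)) abort_data("`data` must contain a `mouse` column")
  data |>
    dplyr::group_by(.data$mouse) |>
    dplyr::group_modify(function(g, key) {
      glance(fit_growth_rate(g))[, c(
        "rate_um_per_min", "rate_se", "initial_thickness_um", "r_squared", "n_obs"
      )]
    }) |>
    dplyr::ungroup()
}
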