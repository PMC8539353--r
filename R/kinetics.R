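#' Interpolating cubic spline of a normalized mass trajectory
#'
#' Fits an exact interpolating cubic spline through the `(time, m)` pairs of
#' one seed. End conditions follow Forsythe-Malcolm-Moler (an exact cubic
#' through the four points at each end), which makes the interpolant reproduce
#' polynomials up to degree 3 exactly; the first and second derivatives are
#' continuous at the interior knots, so velocity and acceleration curves are
#' smooth.
#'
#' @param times Strictly increasing recording times in hours, starting at 0.
#' @param m Normalized masses (dimensionless), same length as `times`.
#' @return An object of class `mass_spline` carrying the piecewise cubic
#'   coefficients and the domain `[0, tau]`.
#' @examples
#' sp <- fit_spline(0:6, 1 + 0.05 * (0:6))
#' velocity(sp, 2.5) # 0.05: the spline reproduces the line
#' @export
fit_spline <- function(times, m) {
  if (length(times) != length(m)) {
    abort("times and m must have the same length", class = "seedkin_domain_error")
  }
  if (length(unique(times)) < 4) {
    abort("cubic spline interpolation needs at least 4 distinct knots",
          class = "seedkin_degenerate_input")
  }
  if (is.unsorted(times, strictly = TRUE)) {
    abort("times must be strictly increasing", class = "seedkin_domain_error")
  }
  f <- stats::splinefun(times, m, method = "fmm")
  z <- environment(f)$z
  structure(
    list(fun = f, knots = as.numeric(z$x), y = as.numeric(z$y),
         b = as.numeric(z$b), c = as.numeric(z$c), d = as.numeric(z$d),
         domain = range(times)),
    class = "mass_spline"
  )
}

check_domain <- function(model, t) {
  lo <- model$domain[1]; hi <- model$domain[2]
  eps <- 1e-9 * max(1, abs(hi))
  if (any(t < lo - eps | t > hi + eps)) {
    abort(sprintf("t outside the interpolation domain [%g, %g]; the spline is not extrapolated",
                  lo, hi),
          class = "seedkin_domain_error")
  }
}

#' @export
predict.mass_spline <- function(object, t, deriv = 0, ...) {
  check_domain(object, t)
  object$fun(t, deriv = deriv)
}

#' Water-uptake velocity: first derivative of normalized mass
#'
#' @param model A `mass_spline` from [fit_spline()].
#' @param t Times in hours, inside the fitted domain (no extrapolation).
#' @return Velocity in g H2O per hour per unit initial mass.
#' @export
velocity <- function(model, t) predict(model, t, deriv = 1)

#' Water-uptake acceleration: second derivative of normalized mass
#'
#' @inheritParams velocity
#' @return Acceleration in g H2O per hour squared per unit initial mass.
#' @export
acceleration <- function(model, t) predict(model, t, deriv = 2)

# Exact integral of the deriv-th derivative of the piecewise cubic on
# [0, tau]. On knot interval i the interpolant is
#   s(u) = y_i + b_i u + c_i u^2 + d_i u^3,  u = t - x_i,
# so derivatives and antiderivatives are evaluated in closed form; no grid
# quadrature is involved.
integrate_spline <- function(model, tau, deriv = 0) {
  x <- model$knots
  if (tau < x[1] - 1e-12 || tau > x[length(x)] + 1e-9) {
    abort("tau outside the spline domain", class = "seedkin_domain_error")
  }
  total <- 0
  for (i in seq_len(length(x) - 1)) {
    if (x[i] >= tau) break
    h <- min(tau, x[i + 1]) - x[i]
    co <- c(model$y[i], model$b[i], model$c[i], model$d[i]) # value poly
    for (k in seq_len(deriv)) co <- deriv_poly(co)
    total <- total + poly_integral(co, h)
  }
  total
}

# d/du of polynomial with ascending coefficients
deriv_poly <- function(co) {
  if (length(co) <= 1) return(0)
  co[-1] * seq_len(length(co) - 1)
}

# integral over u in [0, h]
poly_integral <- function(co, h) {
  k <- seq_along(co)
  sum(co * h^k / k)
}

#' Time average of the spline or one of its derivatives
#'
#' The time average of a curve f over the germination window is
#' `(1/tau) * integral of f from 0 to tau`, computed by exact integration of
#' the piecewise cubic polynomial. `deriv = 1` gives the mean velocity and
#' `deriv = 2` the mean acceleration.
#'
#' @param model A `mass_spline`.
#' @param deriv Order of derivative to average (0, 1 or 2).
#' @param tau Upper integration limit in hours; defaults to the last knot.
#' @return The time-averaged value (scalar).
#' @export
time_average <- function(model, deriv = 1, tau = NULL) {
  tau <- tau %||% model$domain[2]
  if (tau <= 0) {
    abort("tau must be positive", class = "seedkin_domain_error")
  }
  integrate_spline(model, tau, deriv = deriv) / tau
}

#' Per-seed kinetic summaries: mean velocity and mean acceleration
#'
#' For each seed, interpolates the normalized mass with [fit_spline()] and
#' computes the time-averaged velocity `v_m` and acceleration `a_m` over
#' `[0, tau]`, where `tau` is that seed's last recording time. Because the
#' averages are exact integrals of the interpolant, `v_m` equals
#' `(m(tau) - m(0)) / tau` and `a_m` equals `(v(tau) - v(0)) / tau` up to
#' floating-point error.
#'
#' @param data Trajectory tibble; if it has no `m` column it is normalized
#'   with [normalize_mass()] first. A `sample_id` column, if present, is
#'   carried through.
#' @return A tibble with one row per seed: `seed_id`, (`sample_id`,)
#'   `n_obs`, `tau`, `v_m`, `a_m`.
#' @export
seed_kinetics <- function(data) {
  if (nrow(data) == 0) {
    abort("empty trajectory collection", class = "seedkin_domain_error")
  }
  if (!"m" %in% names(data)) data <- normalize_mass(data)
  keys <- intersect(c("seed_id", "sample_id"), names(data))
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(function(d, key) {
      d <- dplyr::arrange(d, .data$time_h)
      sp <- fit_spline(d$time_h, d$m)
      tau <- max(d$time_h)
      tibble::tibble(
        n_obs = nrow(d),
        tau = tau,
        v_m = time_average(sp, deriv = 1, tau = tau),
        a_m = time_average(sp, deriv = 2, tau = tau)
      )
    }) |>
    dplyr::ungroup()
}

#' Sample-level kinetics with bootstrap confidence intervals
#'
#' Aggregates per-seed `v_m` and `a_m` (each seed integrated over its own
#' `tau`, so censored seeds are never extrapolated) to sample means, with
#' percentile-bootstrap confidence intervals over seeds.
#'
#' @param data Trajectory tibble (long, possibly several samples via a
#'   `sample_id` column).
#' @param B Number of bootstrap resamples (default 1000).
#' @param alpha Significance level of the interval (default 0.05).
#' @param seed Optional RNG seed for reproducible intervals.
#' @return A tibble with one row per sample and statistic: `sample_id`,
#'   `statistic` (`"v_m"` or `"a_m"`), `n_seeds`, `point`, `lower`, `upper`,
#'   `B`.
#' @export
sample_kinetics <- function(data, B = 1000L, alpha = 0.05, seed = NULL) {
  per_seed <- seed_kinetics(data)
  if (!"sample_id" %in% names(per_seed)) per_seed$sample_id <- "sample"
  with_optional_seed(seed, {
    per_seed |>
      tidyr::pivot_longer(c("v_m", "a_m"), names_to = "statistic") |>
      dplyr::group_by(.data$sample_id, .data$statistic) |>
      dplyr::group_modify(function(d, key) {
        ci <- bootstrap_mean(d$value, B = B, alpha = alpha,
                             label = key$statistic)
        tibble::tibble(n_seeds = length(d$value), point = ci$point,
                       lower = ci$lower, upper = ci$upper, B = ci$B)
      }) |>
      dplyr::ungroup()
  })
}
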