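#' Percentile-bootstrap confidence interval for a sample mean
#'
#' Resamples the per-seed statistics with replacement `B` times, recomputes
#' the mean of each resample, and reports the empirical `alpha/2` and
#' `1 - alpha/2` quantiles of the bootstrap distribution. With a fixed seed
#' the interval is fully reproducible.
#'
#' @param values Numeric vector of per-seed statistics (length >= 2).
#' @param B Number of resamples (default 1000, the point where interval
#'   endpoints have converged for lots of this size; see
#'   [convergence_check()]).
#' @param alpha Significance level (default 0.05 for a 95% interval).
#' @param seed Optional RNG seed.
#' @param label Name of the statistic, carried into reports.
#' @return An object of class `boot_ci` with fields `statistic`, `point`
#'   (the observed mean), `lower`, `upper`, `B`, `alpha`, `n`, `seed`.
#' @export
bootstrap_mean <- function(values, B = 1000L, alpha = 0.05, seed = NULL,
                           label = "mean") {
  if (length(values) == 0) {
    abort("empty input", class = "seedkin_domain_error")
  }
  if (length(values) < 2) {
    abort("bootstrap needs at least 2 values", class = "seedkin_domain_error")
  }
  B <- as.integer(B)
  if (B < 1) abort("B must be >= 1", class = "seedkin_domain_error")
  n <- length(values)
  means <- with_optional_seed(seed, {
    idx <- sample.int(n, n * B, replace = TRUE)
    colMeans(matrix(values[idx], nrow = n, ncol = B))
  })
  qs <- quantile(means, c(alpha / 2, 1 - alpha / 2), names = FALSE, type = 7)
  structure(
    list(statistic = label, point = mean(values), lower = qs[1],
         upper = qs[2], B = B, alpha = alpha, n = n, seed = seed),
    class = "boot_ci"
  )
}

#' @export
print.boot_ci <- function(x, ...) {
  cat(sprintf("%s = %.6g, %g%% percentile bootstrap CI (%.6g, %.6g), B = %d, n = %d\n",
              x$statistic, x$point, 100 * (1 - x$alpha), x$lower, x$upper,
              x$B, x$n))
  invisible(x)
}

#' @rdname bootstrap_mean
#' @param x A `boot_ci` object.
#' @param ... Unused.
#' @export
tidy.boot_ci <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, point = x$point, lower = x$lower,
    upper = x$upper, B = x$B, alpha = x$alpha, n = x$n
  )
}

#' Smallest resample count with stable interval endpoints
#'
#' Computes the bootstrap interval at each value of `B_grid` and returns the
#' smallest B whose endpoints change by less than `rel_tol` (relative) against
#' the next grid point — the convergence check used to justify a resample
#' count.
#'
#' @inheritParams bootstrap_mean
#' @param B_grid Increasing integer vector of candidate resample counts.
#' @param rel_tol Relative endpoint-change threshold (default 0.01).
#' @return The selected B (integer). If no grid point is stable, the largest
#'   is returned with a warning.
#' @export
convergence_check <- function(values, B_grid = c(250L, 500L, 1000L, 2000L),
                              alpha = 0.05, seed = NULL, rel_tol = 0.01) {
  B_grid <- sort(unique(as.integer(B_grid)))
  if (length(B_grid) == 1) return(B_grid)
  cis <- lapply(seq_along(B_grid), function(i) {
    s <- if (is.null(seed)) NULL else seed + i
    bootstrap_mean(values, B = B_grid[i], alpha = alpha, seed = s)
  })
  scale <- max(abs(c(vapply(cis, `[[`, numeric(1), "lower"),
                     vapply(cis, `[[`, numeric(1), "upper"))),
               .Machine$double.eps)
  for (i in seq_len(length(B_grid) - 1)) {
    dl <- abs(cis[[i + 1]]$lower - cis[[i]]$lower) / scale
    du <- abs(cis[[i + 1]]$upper - cis[[i]]$upper) / scale
    if (dl < rel_tol && du < rel_tol) return(B_grid[i])
  }
  warn("bootstrap interval endpoints never stabilized over B_grid; returning the largest B")
  B_grid[length(B_grid)]
}

#' Do two confidence intervals overlap?
#'
#' Overlapping intervals are reported as non-significant differences between
#' sample means.
#'
#' @param a,b `boot_ci` objects or numeric `c(lower, upper)` pairs.
#' @return `TRUE` if the intervals intersect.
#' @export
ci_overlap <- function(a, b) {
  bounds <- function(x) {
    if (inherits(x, "boot_ci")) c(x$lower, x$upper) else sort(as.numeric(x)[1:2])
  }
  a <- bounds(a); b <- bounds(b)
  a[1] <= b[2] && b[1] <= a[2]
}
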