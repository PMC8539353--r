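#' Remove sample-level means before correlating
#'
#' Centers every numeric column within sample, leaving the within-sample
#' deviations. Correlations computed on these residuals measure the
#' association between characteristics net of the sample effect, instead of
#' being driven by between-sample mean differences. Samples with fewer than
#' two observations carry no within-sample information and are dropped with
#' a warning.
#'
#' @param data A tibble of per-seed (or per-replicate) measurements.
#' @param sample Unquoted name of the column holding the sample labels.
#' @return The input tibble with numeric columns centered within sample.
#' @export
residualize <- function(data, sample) {
  sample <- rlang::enquo(sample)
  sample_name <- rlang::as_name(sample)
  sizes <- dplyr::count(data, !!sample)
  small <- sizes[[sample_name]][sizes$n < 2]
  if (length(small) > 0) {
    warn(paste0("dropping sample(s) with a single observation: ",
                paste(small, collapse = ", ")))
    data <- dplyr::filter(data, !(!!sample %in% small))
  }
  if (dplyr::n_distinct(data[[sample_name]]) < 1) {
    abort("no samples with >= 2 observations", class = "seedkin_domain_error")
  }
  data |>
    dplyr::group_by(!!sample) |>
    dplyr::mutate(dplyr::across(dplyr::where(is.numeric),
                                ~ .x - mean(.x, na.rm = TRUE))) |>
    dplyr::ungroup()
}

#' Pearson correlation with Student t significance test
#'
#' Computes the Pearson coefficient, its t statistic
#' `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees of freedom, the
#' two-sided p value, a significance flag at `alpha`, and a magnitude label
#' (see [classify_magnitude()]).
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @param alpha Significance level (default 0.01).
#' @return A one-row tibble: `r`, `t`, `p`, `n`, `significant`, `magnitude`.
#' @export
pearson_with_test <- function(x, y, alpha = 0.01) {
  if (length(x) != length(y) || length(x) < 3) {
    abort("x and y must have equal length >= 3", class = "seedkin_domain_error")
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) {
    abort("fewer than 3 complete observations", class = "seedkin_domain_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("correlation undefined: zero variance",
          class = "seedkin_undefined_correlation")
  }
  n <- length(x)
  r <- cor(x, y)
  r <- max(-1, min(1, r))
  # exact collinearity leaves |r| a few ulp short of 1; snap so perfect
  # correlations are detected as such
  if (1 - abs(r) < 1e-12) r <- sign(r)
  t_stat <- if (abs(r) == 1) sign(r) * Inf else r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * pt(-abs(t_stat), df = n - 2)
  tibble::tibble(
    r = r, t = t_stat, p = p, n = n,
    significant = p <= alpha,
    magnitude = classify_magnitude(r)
  )
}

#' Magnitude label of a correlation coefficient
#'
#' Adjective bands on `|r|`: negligible, low, moderate, substantial, very
#' high, and perfect at exactly 1. The published band edges (0.09/0.10,
#' 0.29/0.30, ...) leave gaps between printed two-decimal limits; the
#' classifier uses the midpoints (0.095, 0.295, 0.495, 0.695) as half-open
#' boundaries so that every value in `[-1, 1]` receives exactly one label.
#'
#' @param r Correlation coefficient(s) in `[-1, 1]`.
#' @return An ordered factor of labels.
#' @examples
#' classify_magnitude(c(0.05, 0.2, 0.5, -0.8, 1))
#' @export
classify_magnitude <- function(r) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) {
    abort("|r| must not exceed 1", class = "seedkin_domain_error")
  }
  a <- pmin(abs(r), 1)
  label <- dplyr::case_when(
    a == 1 ~ "perfect",
    a < 0.095 ~ "negligible",
    a < 0.295 ~ "low",
    a < 0.495 ~ "moderate",
    a < 0.695 ~ "substantial",
    .default = "very high"
  )
  factor(label, levels = c("negligible", "low", "moderate", "substantial",
                           "very high", "perfect"), ordered = TRUE)
}

#' Pairwise correlation screening across characteristics
#'
#' Correlates every pair of numeric columns, optionally after removing
#' sample means with [residualize()]. Pairs are tested at `alpha` (default
#' 0.01); only significant pairs are flagged for display, mirroring heatmaps
#' that show only characteristics with established associations.
#'
#' @param data Tibble of measurements; non-numeric columns other than the
#'   sample column are ignored.
#' @param sample Optional unquoted column of sample labels; when supplied the
#'   correlations are computed on within-sample residuals.
#' @param alpha Significance level (default 0.01).
#' @return A tibble of class `correlation_report` with one row per unordered
#'   pair: `var1`, `var2`, `r`, `t`, `p`, `n`, `significant`, `magnitude`.
#' @seealso [cor_report_matrix()] for the symmetric matrix form,
#'   [autoplot.correlation_report()] for a heatmap.
#' @export
correlation_matrix <- function(data, sample = NULL, alpha = 0.01) {
  sample <- rlang::enquo(sample)
  if (!rlang::quo_is_null(sample)) {
    data <- residualize(data, !!sample)
    data <- dplyr::select(data, -!!sample)
  }
  num <- dplyr::select(data, dplyr::where(is.numeric))
  vars <- names(num)
  if (length(vars) < 2) {
    abort("need at least two numeric characteristics",
          class = "seedkin_domain_error")
  }
  pairs <- utils::combn(vars, 2)
  out <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    v1 <- pairs[1, j]; v2 <- pairs[2, j]
    ok <- is.finite(num[[v1]]) & is.finite(num[[v2]])
    if (sum(ok) < 3) {
      abort(sprintf("pair (%s, %s) has fewer than 3 common observations",
                    v1, v2),
            class = "seedkin_domain_error")
    }
    dplyr::bind_cols(tibble::tibble(var1 = v1, var2 = v2),
                     pearson_with_test(num[[v1]][ok], num[[v2]][ok],
                                       alpha = alpha))
  })
  class(out) <- c("correlation_report", class(out))
  attr(out, "alpha") <- alpha
  out
}

#' Symmetric correlation matrix from a pairwise report
#'
#' @param report A `correlation_report` from [correlation_matrix()].
#' @return A symmetric numeric matrix of r values with a unit diagonal.
#' @export
cor_report_matrix <- function(report) {
  vars <- unique(c(report$var1, report$var2))
  m <- diag(length(vars))
  dimnames(m) <- list(vars, vars)
  for (i in seq_len(nrow(report))) {
    m[report$var1[i], report$var2[i]] <- report$r[i]
    m[report$var2[i], report$var1[i]] <- report$r[i]
  }
  m
}

#' Heatmap of a pairwise correlation report
#'
#' Tiles are colored by r; non-significant pairs are shown hollow.
#'
#' @param object A `correlation_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.correlation_report <- function(object, ...) {
  m <- cor_report_matrix(object)
  long <- tibble::as_tibble(as.data.frame.table(m, responseName = "r",
                                                stringsAsFactors = FALSE))
  names(long)[1:2] <- c("var1", "var2")
  sig <- dplyr::bind_rows(
    dplyr::select(object, "var1", "var2", "significant"),
    dplyr::select(object, var1 = "var2", var2 = "var1", "significant"),
    tibble::tibble(var1 = rownames(m), var2 = rownames(m), significant = TRUE)
  )
  long <- dplyr::left_join(long, sig, by = c("var1", "var2"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$var1, y = .data$var2,
                                     fill = .data$r)) +
    ggplot2::geom_tile(ggplot2::aes(alpha = .data$significant)) +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac", limits = c(-1, 1)) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.25),
                                guide = "none") +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
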