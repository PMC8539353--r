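#' Lot specification presets for the three quality bands
#'
#' Builds a `lot_spec`: the ground-truth parameters of a synthetic seed lot.
#' Presets encode the published behavior of low-, intermediate- and
#' high-quality soybean lots — assay probabilities matching the reported
#' percentages and kinetic ground truth (initial diffusion coefficient, mean
#' velocity slope, mean acceleration curvature) matching the reported kinetic
#' values, so recovery tests can use them as injected truth.
#'
#' @param label `"low"`, `"intermediate"` or `"high"`.
#' @param ... Named overrides of any spec field (e.g. `noise_sd = 0`,
#'   `n_seeds = 10`, `mode = "linear"`).
#' @return A `lot_spec` list. Fields: quality `label`; sizes `n_seeds`
#'   (kinetics, 50), `n_assay` and `n_ageing` (200); outcome probabilities
#'   `G`, `V`, `NS`, `AS`, `DS`, `AA` (proportions, `G <= V`); kinetic truth
#'   `D_over_rho2` (1/h), `uptake_frac` (saturation uptake as a fraction of
#'   initial mass), `slope` and `curvature` (used by the `"linear"` /
#'   `"quadratic"` trajectory modes); metabolic surge `surge_amplitude`,
#'   `surge_offset_h`, `surge_scale_h`; measurement `noise_sd`
#'   (multiplicative lognormal), `m0_mean`, `m0_sd` (g), `diameter_mean`,
#'   `diameter_sd` (mm); design `protrusion_mean_h`, `protrusion_sd_h`,
#'   `horizon_h`; trajectory `mode` (`"fick"`, `"linear"`, `"quadratic"`).
#' @export
lot_preset <- function(label = c("low", "intermediate", "high"), ...) {
  label <- match.arg(label)
  base <- list(
    label = label, n_seeds = 50L, n_assay = 200L, n_ageing = 200L,
    mode = "fick",
    uptake_frac = 1.0, surge_amplitude = 0.10, surge_offset_h = 1,
    surge_scale_h = 1, noise_sd = 0.01,
    m0_mean = 0.15, m0_sd = 0.01, diameter_mean = 6.9, diameter_sd = 0.3,
    horizon_h = 14
  )
  by_quality <- switch(label,
    low = list(G = 0.28, V = 0.48, NS = 0.24, AS = 0.25, DS = 0.51,
               AA = 0.16, D_over_rho2 = 0.0014, slope = 0.055,
               curvature = -0.0184, protrusion_mean_h = 12,
               protrusion_sd_h = 2),
    intermediate = list(G = 0.54, V = 0.62, NS = 0.48, AS = 0.27, DS = 0.23,
                        AA = 0.34, D_over_rho2 = 0.0018, slope = 0.058,
                        curvature = -0.0182, protrusion_mean_h = 10,
                        protrusion_sd_h = 1.5),
    high = list(G = 0.98, V = 0.98, NS = 0.98, AS = 0.01, DS = 0.01,
                AA = 0.94, D_over_rho2 = 0.0016, slope = 0.055,
                curvature = -0.0164, protrusion_mean_h = 8,
                protrusion_sd_h = 1)
  )
  spec <- utils::modifyList(c(base, by_quality), list(...))
  validate_lot_spec(spec)
  structure(spec, class = "lot_spec")
}

validate_lot_spec <- function(spec) {
  probs <- unlist(spec[c("G", "V", "NS", "AS", "DS", "AA")])
  if (any(probs < 0 | probs > 1)) {
    abort("outcome probabilities must be in [0, 1]",
          class = "seedkin_domain_error")
  }
  if (spec$G > spec$V) {
    abort("G must not exceed V: a germinated seed is viable",
          class = "seedkin_domain_error")
  }
  if (spec$D_over_rho2 <= 0 || spec$noise_sd < 0 || spec$n_seeds < 1) {
    abort("invalid lot spec", class = "seedkin_domain_error")
  }
  invisible(spec)
}

#' Simulate hourly mass recordings for a lot of seeds
#'
#' Emulates the measurement design of the water-dynamics assay: `n_seeds`
#' seeds weighed every hour, each germinating seed until 2 h after its embryo
#' protrusion, non-germinating seeds until the observation horizon. The
#' default (`mode = "fick"`) mass model is
#' `M(t) = M0 * (1 + U * fick_ratio(t; D/rho^2) + L(t))` where `L` is a
#' logistic metabolic surge that turns on shortly before protrusion (zero for
#' non-germinating seeds and at `t = 0`), with multiplicative lognormal
#' measurement noise. `mode = "linear"` (`M0 * (1 + slope * t)`) and
#' `mode = "quadratic"` (`M0 * (1 + slope * t + curvature/2 * t^2)`) generate
#' trajectories whose mean velocity / acceleration are known exactly, for
#' round-trip checks.
#'
#' @param spec A [lot_preset()] specification.
#' @param seed Optional RNG seed; a fixed seed gives an identical table on
#'   rerun.
#' @return A long tibble: `seed_id`, `sample_id`, `time_h`, `mass_g`,
#'   `protrusion_h` (`NA` for non-germinating seeds), `diameter_mm`.
#' @export
simulate_trajectories <- function(spec, seed = NULL) {
  validate_lot_spec(spec)
  with_optional_seed(seed, {
    purrr::map_dfr(seq_len(spec$n_seeds), function(i) {
      m0 <- max(rnorm(1, spec$m0_mean, spec$m0_sd), 0.01)
      diam <- rnorm(1, spec$diameter_mean, spec$diameter_sd)
      germinates <- rbinom(1, 1, spec$G) == 1
      protrusion <- if (germinates) {
        max(rnorm(1, spec$protrusion_mean_h, spec$protrusion_sd_h), 2)
      } else NA_real_
      t_max <- if (germinates) ceiling(protrusion + 2) else spec$horizon_h
      t <- 0:t_max
      base <- switch(spec$mode,
        fick = {
          up <- spec$uptake_frac * fick_ratio(t, spec$D_over_rho2, 50L)
          surge <- if (germinates && spec$surge_amplitude > 0) {
            onset <- protrusion - spec$surge_offset_h
            raw <- stats::plogis((t - onset) / spec$surge_scale_h)
            spec$surge_amplitude * (raw - stats::plogis(-onset / spec$surge_scale_h))
          } else 0
          1 + up + surge
        },
        linear = 1 + spec$slope * t,
        quadratic = 1 + spec$slope * t + spec$curvature / 2 * t^2,
        abort("unknown trajectory mode", class = "seedkin_domain_error")
      )
      noise <- if (spec$noise_sd > 0) {
        c(1, rlnorm(length(t) - 1, 0, spec$noise_sd)) # t = 0 is the reference
      } else 1
      tibble::tibble(
        seed_id = sprintf("%s_%02d", spec$label, i),
        sample_id = spec$label,
        time_h = t,
        mass_g = m0 * base * noise,
        protrusion_h = protrusion,
        diameter_mm = diam
      )
    })
  })
}

#' Simulate a germination/seedling assay for a lot
#'
#' Draws coupled binomial outcomes: viable seeds first, germinated among the
#' viable (so every germinated seed is viable), normal seedlings among the
#' germinated, abnormal as the remainder of germinated, dead as the
#' non-viable. Normal seedlings after accelerated ageing are drawn over the
#' aged subsample. Hard (physically dormant) seeds are 0, as observed for
#' soybean.
#'
#' @inheritParams simulate_trajectories
#' @return A one-row assay tibble compatible with [summarize_assay()].
#' @export
simulate_assay <- function(spec, seed = NULL) {
  validate_lot_spec(spec)
  with_optional_seed(seed, {
    n <- spec$n_assay
    viable <- rbinom(1, n, spec$V)
    p_g <- if (spec$V > 0) min(spec$G / spec$V, 1) else 0
    germinated <- rbinom(1, viable, p_g)
    p_ns <- if (spec$G > 0) min(spec$NS / spec$G, 1) else 0
    normal <- rbinom(1, germinated, p_ns)
    tibble::tibble(
      sample_id = spec$label, n_seeds = n,
      germinated = germinated, viable = viable, normal = normal,
      abnormal = germinated - normal, dead = n - viable, hard = 0L,
      normal_after_ageing = rbinom(1, spec$n_ageing, spec$AA),
      n_ageing = spec$n_ageing
    )
  })
}

#' Simulate a complete lot: trajectories, assay and ground truth
#'
#' @inheritParams simulate_trajectories
#' @return A list with `trajectories`, `assays` and `truth` (the injected
#'   parameters, for recovery tests and the run manifest).
#' @export
simulate_lot <- function(spec, seed = NULL) {
  with_optional_seed(seed, {
    list(
      trajectories = simulate_trajectories(spec),
      assays = simulate_assay(spec),
      truth = unclass(spec)
    )
  })
}

#' Plot simulated or measured trajectories
#'
#' @param data Long trajectory tibble.
#' @param normalized Plot normalized mass `m` instead of raw grams.
#' @return A ggplot object: one line per seed, colored by sample.
#' @export
plot_trajectories <- function(data, normalized = TRUE) {
  if (normalized && !"m" %in% names(data)) data <- normalize_mass(data)
  if (!"sample_id" %in% names(data)) data$sample_id <- "sample"
  yvar <- if (normalized) "m" else "mass_g"
  ylab <- if (normalized) "normalized mass m" else "mass (g)"
  ggplot2::ggplot(data, ggplot2::aes(x = .data$time_h, y = .data[[yvar]],
                                     group = .data$seed_id,
                                     colour = .data$sample_id)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "time (h)", y = ylab, colour = "sample") +
    ggplot2::theme_minimal()
}
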