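# build a long trajectory tibble from a normalized-mass function of time
make_traj <- function(f, times = 0:10, m0 = 0.15, seed_id = "s1",
                      sample_id = NULL) {
  out <- tibble::tibble(seed_id = seed_id, time_h = times,
                        mass_g = m0 * f(times))
  if (!is.null(sample_id)) out$sample_id <- sample_id
  out
}

linear_traj <- function(slope, times = 0:10, m0 = 0.15, ...) {
  make_traj(function(t) 1 + slope * t, times = times, m0 = m0, ...)
}

quadratic_traj <- function(slope, curvature, times = 0:10, m0 = 0.15, ...) {
  make_traj(function(t) 1 + slope * t + curvature / 2 * t^2,
            times = times, m0 = m0, ...)
}
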