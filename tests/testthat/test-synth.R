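test_that("presets honor the quality bands and injected kinetic truth", {
  high <- lot_preset("high")
  expect_gt(high$G, 0.90)
  expect_gt(high$V, 0.90)
  low <- lot_preset("low")
  expect_lte(low$G, 0.50)
  expect_lte(low$V, 0.60)
  expect_equal(lot_preset("intermediate")$D_over_rho2, 0.0018)
  expect_equal(lot_preset("high")$curvature, -0.0164)
  expect_equal(lot_preset("intermediate")$slope, 0.058)
  for (q in c("low", "intermediate", "high")) {
    expect_lte(lot_preset(q)$G, lot_preset(q)$V)
  }
})

test_that("invalid specs are rejected", {
  expect_error(lot_preset("high", G = 1.5), class = "seedkin_domain_error")
  expect_error(lot_preset("high", G = 0.9, V = 0.5),
               class = "seedkin_domain_error")
  expect_error(lot_preset("high", noise_sd = -1),
               class = "seedkin_domain_error")
})

test_that("noise-free fick-mode lots are recovered exactly by the fitter", {
  sp <- lot_preset("intermediate", noise_sd = 0, surge_amplitude = 0, G = 0)
  traj <- simulate_trajectories(sp, seed = 7)
  fit <- fit_fick(traj, t_cut = 3)
  expect_equal(fit$D_over_rho2, 0.0018, tolerance = 1e-6)
})

test_that("linear-mode lots give the injected slope as v_m exactly", {
  sp <- lot_preset("high", mode = "linear", noise_sd = 0, n_seeds = 5L)
  traj <- simulate_trajectories(sp, seed = 3)
  k <- seed_kinetics(traj)
  expect_equal(k$v_m, rep(sp$slope, 5), tolerance = 1e-10)
  spq <- lot_preset("high", mode = "quadratic", noise_sd = 0, n_seeds = 3L)
  kq <- seed_kinetics(simulate_trajectories(spq, seed = 3))
  expect_equal(kq$a_m, rep(spq$curvature, 3), tolerance = 1e-10)
})

test_that("a fixed seed reproduces the lot byte for byte", {
  sp <- lot_preset("low")
  t1 <- simulate_trajectories(sp, seed = 99)
  t2 <- simulate_trajectories(sp, seed = 99)
  expect_identical(t1, t2)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_trajectories(t1, f1)
  write_trajectories(t2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(simulate_assay(sp, seed = 99), simulate_assay(sp, seed = 99))
})

test_that("trajectories respect the measurement design", {
  sp <- lot_preset("high", n_seeds = 30L)
  traj <- simulate_trajectories(sp, seed = 15)
  expect_equal(dplyr::n_distinct(traj$seed_id), 30)
  per_seed <- traj |>
    dplyr::group_by(seed_id) |>
    dplyr::summarise(
      hourly = all(diff(time_h) == 1),
      starts_zero = time_h[1] == 0,
      protrusion = protrusion_h[1],
      t_max = max(time_h)
    )
  expect_true(all(per_seed$hourly))
  expect_true(all(per_seed$starts_zero))
  germ <- per_seed[!is.na(per_seed$protrusion), ]
  # recording stops at the first full hour at least 2 h past protrusion
  expect_true(all(germ$t_max == ceiling(germ$protrusion + 2)))
  expect_true(all(validate_trajectories(traj)$mass_g > 0))
})

test_that("assay draws respect coupling and hit their probabilities at large n", {
  sp <- lot_preset("high", n_assay = 10000L, n_ageing = 10000L)
  counts <- simulate_assay(sp, seed = 123)
  expect_lte(counts$germinated, counts$viable)
  expect_equal(counts$normal + counts$abnormal, counts$germinated)
  s <- summarize_assay(counts)
  expect_equal(s$G, 98, tolerance = 0.02)
  expect_equal(s$V, 98, tolerance = 0.02)
  expect_equal(s$NS, 98, tolerance = 0.02)
  expect_equal(s$AA, 94, tolerance = 0.02)

  none <- simulate_assay(lot_preset("low", G = 0, n_assay = 500L), seed = 4)
  expect_equal(none$germinated, 0)
  expect_equal(none$dead + none$hard + none$viable, 500)
})

test_that("the full pipeline on a noisy lot recovers injected parameters", {
  sp <- lot_preset("high")
  lot <- simulate_lot(sp, seed = 2718)
  k <- seed_kinetics(lot$trajectories)
  # early-phase velocity is dominated by imbibition; v_m positive for all seeds
  expect_true(all(k$v_m > 0))
  # with 4 hourly points and 1% noise the pooled (D, M_inf) fit is weakly
  # identified; recovery is to the right order of magnitude, and tightens
  # to exactness as the noise vanishes (tested separately)
  fit <- fit_fick(lot$trajectories, t_cut = 3, loss = "relative")
  expect_gt(fit$D_over_rho2, sp$D_over_rho2 / 3)
  expect_lt(fit$D_over_rho2, sp$D_over_rho2 * 3)
  s <- summarize_assay(lot$assays)
  expect_equal(s$G, 100 * sp$G, tolerance = 0.05)
  expect_equal(as.character(s$quality), "high")
})
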