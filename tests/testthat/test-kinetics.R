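test_that("the interpolant reproduces polynomials through degree 3", {
  t <- 0:6
  tt <- seq(0, 6, by = 0.13)
  lin <- fit_spline(t, 1 + 0.05 * t)
  expect_equal(predict(lin, tt), 1 + 0.05 * tt, tolerance = 1e-12)
  expect_equal(velocity(lin, tt), rep(0.05, length(tt)), tolerance = 1e-12)
  expect_equal(acceleration(lin, tt), rep(0, length(tt)), tolerance = 1e-12)

  quad <- fit_spline(t, 1 + 0.05 * t - 0.002 * t^2)
  expect_equal(acceleration(quad, tt), rep(-0.004, length(tt)),
               tolerance = 1e-10)
  expect_equal(velocity(fit_spline(0:10, 1 + 0.05 * (0:10) - 0.002 * (0:10)^2), 10),
               0.05 - 0.004 * 10, tolerance = 1e-10)

  cub <- fit_spline(t, 1 + t^3 / 6000)
  expect_equal(acceleration(cub, 6), 6 * 6 / 6000, tolerance = 1e-10)
})

test_that("the spline interpolates every knot to machine precision", {
  withr::with_seed(42, {
    t <- sort(c(0, runif(8, 0.1, 9.9), 10))
    m <- 1 + cumsum(abs(rnorm(10, 0.05, 0.02)))
    sp <- fit_spline(t, m)
    expect_equal(predict(sp, t), m, tolerance = 1e-14)
  })
})

test_that("degenerate and out-of-domain inputs are rejected", {
  expect_error(fit_spline(0:2, c(1, 1.1, 1.2)),
               class = "seedkin_degenerate_input")
  sp <- fit_spline(0:5, 1 + 0.05 * (0:5))
  expect_error(velocity(sp, 5.5), class = "seedkin_domain_error")
  expect_error(velocity(sp, -0.5), class = "seedkin_domain_error")
})

test_that("time averages use exact closed forms", {
  # constant velocity: average equals the constant
  sp <- fit_spline(0:8, 1 + 0.03 * (0:8))
  expect_equal(time_average(sp, deriv = 1), 0.03, tolerance = 1e-12)
  # linear velocity a + b t over [0, tau]: average a + b tau / 2
  spq <- fit_spline(0:8, 1 + 0.05 * (0:8) - 0.002 * (0:8)^2)
  expect_equal(time_average(spq, deriv = 1), 0.05 - 0.004 * 8 / 2,
               tolerance = 1e-12)
  expect_error(time_average(sp, tau = 0), class = "seedkin_domain_error")
})

test_that("fundamental-theorem identities hold on random splines", {
  withr::with_seed(7, {
    for (i in 1:100) {
      n <- sample(5:15, 1)
      tau <- runif(1, 4, 14)
      t <- sort(c(0, runif(n - 2, 0, tau), tau))
      m <- 1 + cumsum(abs(rnorm(n, 0.05, 0.03)))
      sp <- fit_spline(t, m)
      v_m <- time_average(sp, deriv = 1, tau = tau)
      a_m <- time_average(sp, deriv = 2, tau = tau)
      expect_equal(v_m, (predict(sp, tau) - predict(sp, 0)) / tau,
                   tolerance = 1e-8)
      expect_equal(a_m, (velocity(sp, tau) - velocity(sp, 0)) / tau,
                   tolerance = 1e-8)
    }
  })
})

test_that("time_average is linear in the curve", {
  t <- 0:9
  f <- fit_spline(t, 1 + 0.04 * t - 0.001 * t^2)
  g <- fit_spline(t, 1 + 0.01 * t + 0.0005 * t^2)
  h <- fit_spline(t, (1 + 0.04 * t - 0.001 * t^2) * 2 +
                     (1 + 0.01 * t + 0.0005 * t^2) * 3)
  for (d in 1:2) {
    expect_equal(time_average(h, deriv = d),
                 2 * time_average(f, deriv = d) + 3 * time_average(g, deriv = d),
                 tolerance = 1e-10)
  }
})

test_that("per-seed kinetics recover injected slope and curvature", {
  one <- seed_kinetics(linear_traj(0.058))
  expect_equal(one$v_m, 0.058, tolerance = 1e-10)
  expect_equal(one$tau, 10)

  quad <- seed_kinetics(quadratic_traj(0.05, -0.0164))
  expect_equal(quad$a_m, -0.0164, tolerance = 1e-10)

  two <- seed_kinetics(dplyr::bind_rows(linear_traj(0.04, seed_id = "a"),
                                        linear_traj(0.06, seed_id = "b")))
  expect_equal(mean(two$v_m), 0.05, tolerance = 1e-12)
})

test_that("kinetics of normalized mass are scale invariant", {
  traj <- quadratic_traj(0.05, -0.012)
  k1 <- seed_kinetics(traj)
  k2 <- seed_kinetics(dplyr::mutate(traj, mass_g = mass_g * 2.5))
  expect_equal(k1$v_m, k2$v_m, tolerance = 1e-12)
  expect_equal(k1$a_m, k2$a_m, tolerance = 1e-12)
})

test_that("seeds of unequal length each use their own tau", {
  traj <- dplyr::bind_rows(
    linear_traj(0.05, times = 0:6, seed_id = "short"),
    linear_traj(0.05, times = 0:12, seed_id = "long")
  )
  k <- seed_kinetics(traj)
  expect_equal(sort(k$tau), c(6, 12))
  expect_equal(k$v_m, c(0.05, 0.05), tolerance = 1e-10)
})

test_that("sample_kinetics brackets the mean with a bootstrap interval", {
  sp <- lot_preset("intermediate", mode = "linear", noise_sd = 0.005)
  traj <- simulate_trajectories(sp, seed = 5)
  res <- sample_kinetics(traj, B = 200, seed = 9)
  expect_setequal(res$statistic, c("v_m", "a_m"))
  expect_true(all(res$lower <= res$point & res$point <= res$upper))
  again <- sample_kinetics(traj, B = 200, seed = 9)
  expect_equal(res, again)
})
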