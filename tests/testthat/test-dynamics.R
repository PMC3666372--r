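test_that("RK4 reproduces the exponential test problem at fourth order", {
  rhs <- function(t, y) -y
  sol1 <- integrate_rk4(rhs, 1, 0, 2, dt = 0.1)
  err1 <- max(abs(sol1$y[, 1] - exp(-sol1$t)))
  expect_lt(err1, 1e-6)
  sol2 <- integrate_rk4(rhs, 1, 0, 2, dt = 0.05)
  err2 <- max(abs(sol2$y[, 1] - exp(-sol2$t)))
  ratio <- err1 / err2
  expect_gt(ratio, 2^3.8)   # empirical order within [3.8, 4.2]
  expect_lt(ratio, 2^4.2)
})

test_that("RK4 agrees with an established solver on the lesion system", {
  groups <- groups_default
  f_fn <- stress_function()
  F_fn <- forcing_function()
  rhs <- lesion_rhs(groups, f_fn, F_fn)
  sol <- integrate_rk4(rhs, c(1, 0), 0, 5, dt = 1e-3)
  ref <- deSolve::ode(c(y0 = 1, y1 = 0), times = seq(0, 5, by = 1e-3),
                      func = function(t, y, p) list(rhs(t, y)),
                      parms = NULL, method = "rk4")
  expect_equal(sol$y[, 1], unname(ref[, 2]), tolerance = 1e-10)
})

test_that("the nondimensional right-hand side matches an independent transcription", {
  groups <- groups_default
  f_fn <- stress_function()
  F0 <- groups$F_bar
  rhs <- lesion_rhs(groups, f_fn, function(tau) F0)
  # independent term-by-term transcription of the momentum balance
  oracle <- function(y0, y1) {
    f <- (-(-22.5e5) * 1e-3 / 1.26 + (-7.8e5) * 1e-3 +
            (-(-22.5e5) * 1e-3 / (2 * 1.26^2) +
               3 * (-22.5e5) * 1e-3 / (2 * 1.26) -
               2 * (-7.8e5) * 1e-3) * (y0^2 - 1)) / ((-22.5e5) * 1e-3)
    num <- F0 - 3 * groups$b * y1^2 / 2 - 4 * groups$m_f * y1 / y0 -
      2 * f / y0 - 4 * groups$m * groups$d * y1 / y0^4
    num / (groups$b * y0 + y0^-2)
  }
  for (y0 in c(0.7, 1, 1.34, 1.8)) for (y1 in c(-0.5, 0, 0.3)) {
    got <- rhs(0, c(y0, y1))
    expect_equal(got[1], y1)
    expect_equal(got[2], oracle(y0, y1), tolerance = 1e-12)
  }
  # fixed point: both derivatives vanish at the equilibrium
  co <- derived_coefficients(mat_default, F0)
  lam_eq <- equilibrium_stretch(co)$physical
  expect_equal(rhs(0, c(lam_eq, 0)), c(0, 0), tolerance = 1e-9)
  # algebraic cancellation: b = m_f = m = 0 and F = 2f/y0 zeroes dy1
  g0 <- groups; g0$b <- 1e-300; g0$m_f <- 0; g0$m <- 0
  y0 <- 1.2
  rhs0 <- lesion_rhs(g0, f_fn, function(tau) 2 * f_fn(y0) / y0)
  expect_equal(rhs0(0, c(y0, 0.0))[2], 0, tolerance = 1e-9)
})

test_that("forcing behaves as the nondimensionalization dictates", {
  F_fn0 <- forcing_function(quiet_breathing())
  expect_lt(F_fn0(3), 0)
  expect_equal(F_fn0(0), groups_default$F_bar, tolerance = 1e-12)
  # doubling |c1| halves |F|
  mat2 <- material_parameters(c1 = 2 * mat_default$c1)
  g2 <- nondimensional_groups(mat = mat2)
  F_fn2 <- forcing_function(quiet_breathing(), g2, mat = mat2)
  expect_equal(F_fn2(0), F_fn0(0) / 2, tolerance = 1e-12)
  # time-average over the common breathing period equals F_bar
  F_fn <- forcing_function()
  tc <- groups_default$time_scale
  tau_period <- 12.8 / tc
  taus <- (seq_len(4096) - 1) * tau_period / 4096
  expect_equal(mean(F_fn(taus)), groups_default$F_bar, tolerance = 1e-9)
})

test_that("default parameters give bounded oscillation about the equilibrium", {
  traj <- simulate_lesion(tau_end = 100, dt = 1e-3, record_every = 5L)
  expect_false(attr(traj, "nonphysical"))
  expect_gt(min(traj$y0), 0.9)
  expect_lt(max(traj$y0), 1.9)
  expect_equal(mean(traj$y0), 1.3, tolerance = 0.05)
})

test_that("minor perturbations of the initial state stay on nearby bounded orbits", {
  lo <- simulate_lesion(ic = c(0.95, 0), tau_end = 150, dt = 2e-3,
                        record_every = 5L)
  hi <- simulate_lesion(ic = c(1.05, 0), tau_end = 150, dt = 2e-3,
                        record_every = 5L)
  for (traj in list(lo, hi)) {
    expect_false(attr(traj, "nonphysical"))
    expect_gt(min(traj$y0), 0.75)
    expect_lt(max(traj$y0), 2.0)
    expect_equal(mean(traj$y0), 1.34, tolerance = 0.05)
  }
})

test_that("oscillation metrics recover a synthetic sinusoid", {
  tau <- seq(0, 100, by = 0.01)
  traj <- data.frame(tau = tau, y0 = 1 + 0.1 * sin(2 * pi * 0.3 * tau),
                     y1 = 0)
  met <- oscillation_metrics(traj)
  expect_equal(met$amplitude, 0.1, tolerance = 1e-3)
  expect_equal(met$frequency, 0.3, tolerance = 1e-3)
  flat <- data.frame(tau = tau, y0 = rep(1, length(tau)), y1 = 0)
  met0 <- oscillation_metrics(flat)
  expect_identical(met0$amplitude, 0)
  expect_true(is.na(met0$frequency))
})

test_that("force decomposition satisfies the momentum-balance identity", {
  groups <- groups_default
  f_fn <- stress_function()
  F_fn <- forcing_function()
  traj <- simulate_lesion(tau_end = 10, dt = 1e-3)
  fp <- force_proportions(traj, groups, f_fn, F_fn)
  rhs <- lesion_rhs(groups, f_fn, F_fn)
  dy1 <- vapply(seq_len(nrow(traj)), function(i)
    rhs(traj$tau[i], c(traj$y0[i], traj$y1[i]))[2], numeric(1))
  lhs <- fp$pressure - fp$fluid_structure - fp$radial_stress -
    fp$internal_membrane - fp$viscoelastic
  denom <- groups$b * traj$y0 + traj$y0^-2
  expect_equal(lhs, dy1 * denom, tolerance = 1e-10)
  # pressure and internal membrane stress dominate the other three terms
  mm <- attr(fp, "mean_magnitude")
  others <- max(mm[c("fluid_structure", "radial_stress", "viscoelastic")])
  expect_gt(mm[["pressure"]], others)
  expect_gt(mm[["internal_membrane"]], others)
  # a zero-rate trajectory has identically zero rate-dependent terms
  static <- data.frame(tau = 0:5, y0 = rep(1.3, 6), y1 = rep(0, 6))
  fp0 <- force_proportions(static, groups, f_fn, F_fn)
  expect_equal(fp0$fluid_structure, rep(0, 6))
  expect_equal(fp0$radial_stress, rep(0, 6))
  expect_equal(fp0$viscoelastic, rep(0, 6))
})

test_that("rupture occurs for the unstable point with the limiter but not for defaults", {
  phi <- default_energy_limit()
  # stable defaults survive 50 characteristic times with a large cap
  calm <- simulate_lesion(stress = "limited", phi = 1e12, tau_end = 50,
                          dt = 1e-3, record_every = 5L)
  expect_false(attr(calm, "ruptured"))
  expect_false(attr(calm, "nonphysical"))
  # the strain-hardening unstable point, started from the normal-tissue
  # equilibrium, ruptures in finite time
  burst <- simulate_lesion(mat_hardening, ic = c(1.3405, 0),
                           stress = "limited", phi = phi, tau_end = 50,
                           dt = 1e-3)
  expect_true(attr(burst, "ruptured"))
  expect_true(is.finite(attr(burst, "rupture_tau")))
  # post-hoc detector agrees with the online flag
  det <- detect_rupture(burst, mat_hardening, phi = phi)
  expect_true(det$ruptured)
  expect_equal(det$rupture_tau, attr(burst, "rupture_tau"), tolerance = 0.1)
})

test_that("shrinking the energy cap lowers the softening stretch and keeps rupture finite", {
  phi0 <- default_energy_limit()
  scales <- c(1, 0.6, 0.36)
  stars <- vapply(scales, function(s)
    rupture_stretch(mat_hardening, phi = s * phi0), numeric(1))
  expect_true(all(diff(stars) < 0))   # smaller cap, earlier softening onset
  taus <- vapply(scales, function(s) {
    tr <- simulate_lesion(mat_hardening, ic = c(1.3405, 0),
                          stress = "limited", phi = s * phi0, tau_end = 50,
                          dt = 1e-3)
    attr(tr, "rupture_tau")
  }, numeric(1))
  expect_true(all(is.finite(taus)))
  # while the softening onset lies above the starting stretch, an earlier
  # onset is reached sooner (rupture time can jump once the onset drops
  # below the starting stretch, because the detector also requires an
  # expanding wall)
  above <- stars > 1.3405
  expect_true(all(diff(taus[above]) <= 1e-9))
})

test_that("SI and nondimensional integrations agree through the scalings", {
  tc <- groups_default$time_scale
  nd <- simulate_lesion(tau_end = 20, dt = 1e-3)
  si <- simulate_lesion_si(t_end = 20 * tc, dt_s = 1e-3 * tc)
  n <- min(nrow(nd), nrow(si))
  expect_lt(max(abs(nd$y0[1:n] - si$lambda[1:n]) / nd$y0[1:n]), 1e-6)
  expect_lt(max(abs(nd$y1[1:n] - si$lambda_dot[1:n] * tc)), 1e-6)
})
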