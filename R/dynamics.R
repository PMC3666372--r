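#' Nondimensional forcing function
#'
#' Builds `F(tau) = (P_inner(t(tau)) - p_inf) * R / (c1 * H)` with
#' `t = tau * time_scale` and the inner pressure converted from mmHg to Pa.
#' With a zero-amplitude breathing model the result is the constant
#' `F_bar < 0` of [nondimensional_groups()].
#'
#' @param bm A [breathing_model()], or `NULL` for the constant (autonomous)
#'   forcing at the baseline pressure.
#' @param groups A [nondimensional_groups()].
#' @param geom A [lesion_geometry()].
#' @param mat A [material_parameters()].
#' @param fluid A [fluid_properties()].
#' @return A function of nondimensional time `tau` returning dimensionless
#'   forcing (vectorized).
#' @export
forcing_function <- function(bm = breathing_model(),
                             groups = nondimensional_groups(),
                             geom = lesion_geometry(),
                             mat = material_parameters(),
                             fluid = fluid_properties()) {
  scale <- geom$R / (mat$c1 * geom$H)
  tc <- groups$time_scale
  p_inf <- fluid$p_inf
  if (is.null(bm)) {
    F0 <- (mmHg_to_Pa(760) - p_inf) * scale
    return(function(tau) rep_len(F0, length(tau)))
  }
  A <- bm$components$A; w <- 2 * pi * bm$components$f
  ph <- bm$components$phi
  base <- bm$baseline; Rb <- bm$R_b
  mmhg <- 101325 / 760
  function(tau) {
    t <- tau * tc
    q <- if (length(t) == 1L) sum(A * cos(w * t + ph)) else
      colSums(A * cos(outer(w, t) + ph))
    ((base + Rb * q) * mmhg - p_inf) * scale
  }
}

#' Nondimensional elastic stress function
#'
#' Returns `f(y0) = T_elastic(y0) / (c1 * H)`, the membrane-stress term of
#' the nondimensional momentum balance.  The viscous part of the stress
#' resultant is carried separately by the `4*m*d*y1/y0^4` term of the
#' system, so `f` contains the elastic part only.
#'
#' @param mat A [material_parameters()].
#' @param geom A [lesion_geometry()].
#' @param stress `"taylor"` for the hyperelastic Taylor stress or
#'   `"limited"` for the energy-limited stress.
#' @param phi Failure-energy density (J m^-3); required when
#'   `stress = "limited"`.
#' @return A vectorized function of the stretch ratio `y0`.
#' @export
stress_function <- function(mat = material_parameters(),
                            geom = lesion_geometry(),
                            stress = c("taylor", "limited"), phi = NULL) {
  stress <- match.arg(stress)
  co <- taylor_energy_coefficients(mat, geom)
  c1H <- mat$c1 * geom$H
  if (stress == "taylor") {
    function(y0) (co$a1 + co$a2 * (y0^2 - 1)) / c1H
  } else {
    stopifnot(is.numeric(phi), phi > 0)
    cap <- geom$H * phi
    function(y0) {
      E11 <- (y0^2 - 1) / 2
      w <- co$a1 * E11 + co$a2 * E11^2
      (co$a1 + 2 * co$a2 * E11) * exp(-w / cap) / c1H
    }
  }
}

#' Right-hand side of the nondimensional lesion system
#'
#' `dy0/dtau = y1`;
#' `dy1/dtau = (F(tau) - 3*b*y1^2/2 - 4*m_f*y1/y0 - 2*f(y0)/y0 -
#' 4*m*d*y1/y0^4) / (b*y0 + y0^-2)`.
#'
#' @param groups A [nondimensional_groups()].
#' @param f_fn Stress function from [stress_function()].
#' @param F_fn Forcing function from [forcing_function()].
#' @return A function `rhs(tau, y)` with `y = c(y0, y1)` returning the two
#'   derivatives, suitable for [integrate_rk4()].
#' @export
lesion_rhs <- function(groups, f_fn, F_fn) {
  b <- groups$b; m_f <- groups$m_f; md4 <- 4 * groups$m * groups$d
  function(tau, y) {
    y0 <- y[1L]; y1 <- y[2L]
    num <- F_fn(tau) - 1.5 * b * y1 * y1 - 4 * m_f * y1 / y0 -
      2 * f_fn(y0) / y0 - md4 * y1 / y0^4
    c(y1, num / (b * y0 + 1 / (y0 * y0)))
  }
}

#' Classical fixed-step fourth-order Runge-Kutta integrator
#'
#' Integrates `dy/dt = rhs(t, y)` with the classical RK4 scheme on a fixed
#' step.  Integration halts early when `stop_fn` (if given) returns a
#' non-`NULL` label for the proposed state, or when the state becomes
#' non-finite.
#'
#' @param rhs Function `rhs(t, y)` returning `dy/dt`.
#' @param y Initial state vector.
#' @param t0 Initial time.
#' @param t_end Final time (greater than `t0`).
#' @param dt Step size (positive).
#' @param stop_fn Optional function `stop_fn(t, y)` returning `NULL` to
#'   continue or a character label describing why integration must stop.
#' @param record_every Record every `record_every`-th step (the initial and
#'   final states are always recorded).
#' @return A list with `t` (times), `y` (matrix, one row per record),
#'   `stopped` (`NULL` or the stop label) and `t_stop`.
#' @export
integrate_rk4 <- function(rhs, y, t0 = 0, t_end, dt, stop_fn = NULL,
                          record_every = 1L) {
  stopifnot(dt > 0, t_end > t0)
  n_steps <- ceiling((t_end - t0) / dt - 1e-9)
  n_rec <- n_steps %/% record_every + 2L
  ts <- numeric(n_rec)
  ys <- matrix(NA_real_, n_rec, length(y))
  ts[1L] <- t0; ys[1L, ] <- y
  rec <- 1L
  t <- t0
  stopped <- NULL; t_stop <- NA_real_
  for (i in seq_len(n_steps)) {
    h <- min(dt, t_end - t)
    k1 <- rhs(t, y)
    k2 <- rhs(t + h / 2, y + (h / 2) * k1)
    k3 <- rhs(t + h / 2, y + (h / 2) * k2)
    k4 <- rhs(t + h, y + h * k3)
    y_new <- y + (h / 6) * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + h
    if (!all(is.finite(y_new))) {
      stopped <- "nonfinite"; t_stop <- t
      break
    }
    y <- y_new
    if (!is.null(stop_fn)) {
      label <- stop_fn(t, y)
      if (!is.null(label)) {
        stopped <- label; t_stop <- t
        rec <- rec + 1L; ts[rec] <- t; ys[rec, ] <- y
        break
      }
    }
    if (i %% record_every == 0L || i == n_steps) {
      rec <- rec + 1L
      ts[rec] <- t; ys[rec, ] <- y
    }
  }
  list(t = ts[seq_len(rec)], y = ys[seq_len(rec), , drop = FALSE],
       stopped = stopped, t_stop = t_stop)
}

#' Simulate the nondimensional lesion system
#'
#' Integrates the coupled air-tissue-pleural fluid system with fixed-step
#' RK4 from an initial stretch/stretch-rate state.  With
#' `stress = "limited"` the run halts at rupture (softening onset crossed
#' while expanding, or, with `rupture_rule = "energy"`, stored energy
#' reaching 99% of the cap).  Nonphysical collapse (`y0` below
#' `collapse_at`) also halts the run.
#'
#' @param mat,geom,mem,fluid Model parameter blocks (see [material_parameters()],
#'   [lesion_geometry()], [membrane_properties()], [fluid_properties()]).
#' @param bm A [breathing_model()] or `NULL` for constant forcing.
#' @param ic Initial `c(y0, y1)`: stretch ratio and nondimensional stretch
#'   rate. Defaults to the undeformed state at rest.
#' @param tau_end Final nondimensional time.
#' @param dt Nondimensional step size.
#' @param stress `"taylor"` or `"limited"`.
#' @param phi Failure-energy density (J m^-3) for `stress = "limited"`;
#'   defaults to [default_energy_limit()].
#' @param rupture_rule `"softening"` (first crossing of the stress maximum
#'   while expanding) or `"energy"` (stored energy at 99% of the cap).
#' @param record_every Record every n-th step.
#' @param collapse_at Stretch below which the run is flagged as nonphysical
#'   collapse.
#' @return A `lesion_trajectory`: data frame with columns `tau`, `y0`, `y1`
#'   and attributes `ruptured`, `rupture_tau`, `nonphysical`, `groups`.
#' @export
simulate_lesion <- function(mat = material_parameters(),
                            geom = lesion_geometry(),
                            mem = membrane_properties(),
                            fluid = fluid_properties(),
                            bm = breathing_model(),
                            ic = c(1, 0), tau_end = 50, dt = 1e-3,
                            stress = c("taylor", "limited"), phi = NULL,
                            rupture_rule = c("softening", "energy"),
                            record_every = 1L, collapse_at = 0.05) {
  stress <- match.arg(stress)
  rupture_rule <- match.arg(rupture_rule)
  stopifnot(length(ic) == 2L, ic[1] > 0)
  groups <- nondimensional_groups(geom, mem, fluid, mat)
  if (stress == "limited" && is.null(phi)) phi <- default_energy_limit(mat, geom)
  f_fn <- stress_function(mat, geom, stress, phi)
  F_fn <- forcing_function(bm, groups, geom, mat, fluid)
  rhs <- lesion_rhs(groups, f_fn, F_fn)

  stop_fn <- NULL
  if (stress == "limited") {
    if (rupture_rule == "softening") {
      lam_star <- rupture_stretch(mat, geom, phi)
      if (!is.na(lam_star)) {
        stop_fn <- function(t, y) {
          if (y[1] < collapse_at) return("collapse")
          if (y[1] > lam_star && y[2] > 0) return("rupture")
          NULL
        }
      }
    } else {
      co <- taylor_energy_coefficients(mat, geom)
      cap <- geom$H * phi
      stop_fn <- function(t, y) {
        if (y[1] < collapse_at) return("collapse")
        E11 <- (y[1]^2 - 1) / 2
        w <- co$a1 * E11 + co$a2 * E11^2
        if (w > 0 && cap * (1 - exp(-w / cap)) >= 0.99 * cap) return("rupture")
        NULL
      }
    }
  }
  if (is.null(stop_fn))
    stop_fn <- function(t, y) if (y[1] < collapse_at) "collapse" else NULL

  sol <- integrate_rk4(rhs, ic, 0, tau_end, dt, stop_fn = stop_fn,
                       record_every = record_every)
  traj <- data.frame(tau = sol$t, y0 = sol$y[, 1], y1 = sol$y[, 2])
  class(traj) <- c("lesion_trajectory", "data.frame")
  attr(traj, "ruptured") <- identical(sol$stopped, "rupture")
  attr(traj, "rupture_tau") <- if (identical(sol$stopped, "rupture")) sol$t_stop else NA_real_
  attr(traj, "nonphysical") <- identical(sol$stopped, "collapse") ||
    identical(sol$stopped, "nonfinite")
  attr(traj, "groups") <- groups
  traj
}

#' Simulate the lesion system in SI units
#'
#' Integrates the dimensional momentum balance directly (time in seconds,
#' stretch rate in s^-1):
#' `(rho_f*R^2*lam + rho_m*H*R/lam^2) * lam_dd =
#'  -(P_inner(t) - p_inf) - (3/2)*rho_f*R^2*lam_d^2 - 4*mu_f*lam_d/lam
#'  + 2*T_el(lam)/(lam*R) - 4*mu_m*H*lam_d/(R*lam^4)`.
#' This is the exact redimensionalization of the nondimensional system and
#' is used to certify the reconstructed scalings: mapping its output
#' through the nondimensional groups must reproduce the nondimensional
#' trajectory.
#'
#' @inheritParams simulate_lesion
#' @param t_end Final time, seconds.
#' @param dt_s Step size, seconds.
#' @return A data frame with columns `t`, `lambda`, `lambda_dot`.
#' @export
simulate_lesion_si <- function(mat = material_parameters(),
                               geom = lesion_geometry(),
                               mem = membrane_properties(),
                               fluid = fluid_properties(),
                               bm = breathing_model(),
                               ic = c(1, 0), t_end, dt_s,
                               record_every = 1L) {
  H <- geom$H; R <- geom$R
  rho_f <- fluid$rho_f; mu_f <- fluid$mu_f; p_inf <- fluid$p_inf
  rho_m <- mem$rho_m; mu_m <- mem$mu_m
  co <- taylor_energy_coefficients(mat, geom)
  P_fn <- if (is.null(bm)) function(t) mmHg_to_Pa(760) else
    function(t) mmHg_to_Pa(inner_pressure(t, bm))
  rhs <- function(t, y) {
    lam <- y[1L]; ld <- y[2L]
    Tel <- co$a1 + co$a2 * (lam^2 - 1)
    num <- -(P_fn(t) - p_inf) - 1.5 * rho_f * R^2 * ld^2 - 4 * mu_f * ld / lam +
      2 * Tel / (lam * R) - 4 * mu_m * H * ld / (R * lam^4)
    c(ld, num / (rho_f * R^2 * lam + rho_m * H * R / lam^2))
  }
  sol <- integrate_rk4(rhs, ic, 0, t_end, dt_s, record_every = record_every)
  data.frame(t = sol$t, lambda = sol$y[, 1], lambda_dot = sol$y[, 2])
}

#' Amplitude and dominant frequency of a trajectory
#'
#' Discards the leading `transient_fraction` of the record, then measures
#' the oscillation amplitude as half the peak-to-trough range of the
#' stretch ratio and the dominant frequency as the location of the largest
#' spectral peak of the mean-removed, Hann-windowed series (with parabolic
#' interpolation between frequency bins; ties break to the lowest
#' frequency).
#'
#' @param traj A `lesion_trajectory` (or any data frame with `tau`, `y0`).
#' @param transient_fraction Fraction of the record to discard, in [0, 1).
#' @param min_amplitude Amplitude below which the trajectory is reported as
#'   non-oscillatory (`amplitude = 0`, `frequency = NA`).
#' @return A list with `amplitude` (stretch units) and `frequency`
#'   (cycles per unit nondimensional time).
#' @export
oscillation_metrics <- function(traj, transient_fraction = 0.2,
                                min_amplitude = 1e-8) {
  stopifnot(transient_fraction >= 0, transient_fraction < 1)
  n <- nrow(traj)
  keep <- seq.int(floor(n * transient_fraction) + 1L, n)
  y <- traj$y0[keep]
  tau <- traj$tau[keep]
  amplitude <- (max(y) - min(y)) / 2
  if (amplitude < min_amplitude)
    return(list(amplitude = 0, frequency = NA_real_))
  m <- length(y)
  dt <- (tau[m] - tau[1]) / (m - 1)
  win <- 0.5 * (1 - cos(2 * pi * seq(0, m - 1) / (m - 1)))  # Hann
  z <- (y - mean(y)) * win
  sp <- Mod(stats::fft(z))[seq_len(m %/% 2)]
  sp[1] <- 0                       # remove residual DC
  k <- which.max(sp)               # which.max ties break to lowest bin
  # parabolic interpolation around the peak bin
  if (k > 1L && k < length(sp)) {
    s1 <- sp[k - 1]; s2 <- sp[k]; s3 <- sp[k + 1]
    denom <- s1 - 2 * s2 + s3
    delta <- if (abs(denom) > 0) 0.5 * (s1 - s3) / denom else 0
  } else delta <- 0
  freq <- (k - 1 + delta) / (m * dt)
  list(amplitude = amplitude, frequency = freq)
}

#' Decompose the nondimensional forces along a trajectory
#'
#' Evaluates the five named force terms of the momentum balance along a
#' trajectory: pressure `F(tau)`, fluid-structure `3*b*y1^2/2`, radial
#' stress `4*m_f*y1/y0`, internal membrane `2*f(y0)/y0` and viscoelastic
#' `4*m*d*y1/y0^4`.  Their signed combination equals `dy1/dtau` times the
#' inertial factor `b*y0 + y0^-2` at every sample.
#'
#' @param traj A `lesion_trajectory`.
#' @param groups A [nondimensional_groups()].
#' @param f_fn Stress function from [stress_function()].
#' @param F_fn Forcing function from [forcing_function()].
#' @return A data frame with `tau` and one column per term, with attribute
#'   `mean_magnitude` (time-averaged absolute value of each term).
#' @export
force_proportions <- function(traj, groups, f_fn, F_fn) {
  y0 <- traj$y0; y1 <- traj$y1
  out <- data.frame(
    tau = traj$tau,
    pressure = F_fn(traj$tau),
    fluid_structure = 1.5 * groups$b * y1^2,
    radial_stress = 4 * groups$m_f * y1 / y0,
    internal_membrane = 2 * f_fn(y0) / y0,
    viscoelastic = 4 * groups$m * groups$d * y1 / y0^4
  )
  mm <- colMeans(abs(out[, -1, drop = FALSE]))
  attr(out, "mean_magnitude") <- mm
  out
}

#' Detect rupture along an energy-limited trajectory
#'
#' Declares rupture at the first time the stretch exceeds the
#' softening-onset stretch of the energy-limited wall (see
#' [rupture_stretch()]) while still expanding (`y1 > 0`).
#'
#' @param traj A `lesion_trajectory`.
#' @param mat A [material_parameters()].
#' @param geom A [lesion_geometry()].
#' @param phi Failure-energy density, J m^-3.
#' @return A list with `ruptured` (logical) and `rupture_tau`
#'   (`NA` if no rupture).
#' @export
detect_rupture <- function(traj, mat = material_parameters(),
                           geom = lesion_geometry(), phi) {
  lam_star <- rupture_stretch(mat, geom, phi)
  if (is.na(lam_star))
    return(list(ruptured = FALSE, rupture_tau = NA_real_))
  hit <- which(traj$y0 > lam_star & traj$y1 > 0)
  if (length(hit) == 0L)
    return(list(ruptured = FALSE, rupture_tau = NA_real_))
  list(ruptured = TRUE, rupture_tau = traj$tau[hit[1L]])
}

#' Sweep the stiffness constant and measure the oscillations
#'
#' Re-simulates the system for each value of `c2` and reports the
#' steady-state oscillation amplitude and dominant frequency.
#'
#' @param c2_values Vector of stiffness constants to sweep.
#' @param mat Base [material_parameters()] supplying `c1` and `c3`.
#' @param geom,mem,fluid,bm Remaining parameter blocks.
#' @param ic,tau_end,dt,record_every Passed to [simulate_lesion()].
#' @param transient_fraction Passed to [oscillation_metrics()].
#' @return A data frame with columns `c2`, `amplitude`, `frequency`.
#' @export
sweep_stiffness <- function(c2_values = seq(0.5, 1.6, by = 0.02),
                            mat = material_parameters(),
                            geom = lesion_geometry(),
                            mem = membrane_properties(),
                            fluid = fluid_properties(),
                            bm = breathing_model(),
                            ic = c(1, 0), tau_end = 500, dt = 5e-3,
                            record_every = 2L, transient_fraction = 0.2) {
  res <- lapply(c2_values, function(c2) {
    m <- material_parameters(mat$c1, c2, mat$c3)
    traj <- simulate_lesion(m, geom, mem, fluid, bm, ic = ic,
                            tau_end = tau_end, dt = dt,
                            record_every = record_every)
    met <- oscillation_metrics(traj, transient_fraction)
    data.frame(c2 = c2, amplitude = met$amplitude, frequency = met$frequency)
  })
  do.call(rbind, res)
}

#' @export
print.lesion_trajectory <- function(x, ...) {
  cat(sprintf("Lesion trajectory: %d samples, tau in [%.3g, %.3g]\n",
              nrow(x), x$tau[1], x$tau[nrow(x)]))
  cat(sprintf("  stretch range [%.4g, %.4g]; ruptured: %s; nonphysical: %s\n",
              min(x$y0), max(x$y0), attr(x, "ruptured"),
              attr(x, "nonphysical")))
  invisible(x)
}
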