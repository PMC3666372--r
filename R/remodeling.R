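#' Remodelling drive signal
#'
#' The magnitude `|w' - Psi'|` of the gap between the combined
#' collagen-elastin strain energy (quadratic form) and its energy-limited
#' counterpart, in J m^-2.  Far from rupture `w' << H*phi` and the gap is
#' tiny (second order in `w'/(H*phi)`); approaching rupture it grows
#' towards the energy cap, so it is the natural stimulus for
#' stress-driven collagen deposition and elastolysis.
#'
#' @param lam Stretch ratio(s).
#' @param mat A [material_parameters()].
#' @param geom A [lesion_geometry()].
#' @param elastin_b Elastin stiffness, N m^-2.
#' @param Ac,Ae Active collagen and elastin numbers.
#' @param phi Failure-energy density, J m^-3.
#' @return Signal value(s), J m^-2 (non-negative).
#' @export
remodeling_signal <- function(lam, mat = material_parameters(),
                              geom = lesion_geometry(), elastin_b,
                              Ac, Ae, phi) {
  w <- combined_energy(lam, mat, geom, elastin_b, Ac, Ae, form = "quadratic")
  abs(w - limited_energy(w, geom, phi))
}

#' Collagen and elastin turnover rates
#'
#' First-order kinetics driven by the remodelling signal: collagen is
#' deposited (`dAc/dt = k1*Ac*s^n >= 0`) and elastin degraded
#' (`dAe/dt = -k2*Ae*s^n <= 0`), with `s` the signal normalized by
#' `signal_ref` so that the rate constants have units of s^-1.
#'
#' @param Ac,Ae Active protein numbers (non-negative).
#' @param k1,k2 Rate constants, s^-1 (non-negative).
#' @param n_exp Signal exponent (positive).
#' @param signal Remodelling signal, J m^-2 (from [remodeling_signal()]).
#' @param signal_ref Normalizing signal scale, J m^-2 (typically the areal
#'   energy cap `H*phi`).
#' @return A list with `dAc_dt` and `dAe_dt`, s^-1.
#' @export
protein_rates <- function(Ac, Ae, k1, k2, n_exp = 1, signal, signal_ref) {
  stopifnot(Ac >= 0, Ae >= 0, k1 >= 0, k2 >= 0, n_exp > 0, signal_ref > 0)
  s <- (signal / signal_ref)^n_exp
  list(dAc_dt = k1 * Ac * s, dAe_dt = -k2 * Ae * s)
}

#' Right-hand side of the extended (mechanics + protein) system
#'
#' Builds the 4-state derivative function for
#' `y = (y0, y1, Ac, Ae)` in nondimensional time.  The mechanical part is
#' the lesion momentum balance with the protein-weighted, energy-limited
#' combined stress and an additional mass-flux term `-m_p*y1/y0^2`, where
#' `m_p = (t_c/rho_m)*(rho_c*dAc/dt + rho_e*dAe/dt)` accounts for momentum
#' carried by the changing protein mass (`t_c` the characteristic time).
#' The protein part applies [protein_rates()] converted to nondimensional
#' time.
#'
#' @param groups A [nondimensional_groups()].
#' @param mat,geom Parameter blocks.
#' @param elastin_b Elastin stiffness, N m^-2.
#' @param phi Failure-energy density, J m^-3.
#' @param k1,k2,n_exp Kinetic constants (see [protein_rates()]).
#' @param rho_c,rho_e Protein densities, kg m^-3.
#' @param rho_m Membrane density, kg m^-3.
#' @param F_fn Forcing function from [forcing_function()].
#' @param signal_ref Signal normalization, J m^-2; defaults to `H*phi`.
#' @return A function `rhs(tau, y)` returning the 4 derivatives.
#' @export
remodeling_rhs <- function(groups, mat = material_parameters(),
                           geom = lesion_geometry(), elastin_b, phi,
                           k1, k2, n_exp = 1, rho_c = 5.10, rho_e = 5.10,
                           rho_m = 1050, F_fn, signal_ref = geom$H * phi) {
  b <- groups$b; m_f <- groups$m_f; md4 <- 4 * groups$m * groups$d
  tc <- groups$time_scale
  co <- taylor_energy_coefficients(mat, geom)
  c1H <- mat$c1 * geom$H
  cap <- geom$H * phi
  ebH2 <- elastin_b * geom$H / 2
  function(tau, y) {
    y0 <- y[1L]; y1 <- y[2L]; Ac <- max(y[3L], 0); Ae <- max(y[4L], 0)
    E11 <- (y0^2 - 1) / 2
    A1 <- Ac * co$a1
    B2 <- Ae * ebH2 + Ac * co$a2
    w <- A1 * E11 + B2 * E11^2
    f <- (A1 + 2 * B2 * E11) * exp(-w / cap) / c1H
    sig <- abs(w - cap * -expm1(-w / cap))
    s <- (sig / signal_ref)^n_exp
    dAc <- tc * k1 * Ac * s
    dAe <- -tc * k2 * Ae * s
    # per-tau protein rates over rho_m: equals (t_c/rho_m) * d(C + E)/dt
    m_p <- (rho_c * dAc + rho_e * dAe) / rho_m
    num <- F_fn(tau) - 1.5 * b * y1 * y1 - 4 * m_f * y1 / y0 -
      2 * f / y0 - md4 * y1 / y0^4 - m_p * y1 / (y0 * y0)
    c(y1, num / (b * y0 + 1 / (y0 * y0)), dAc, dAe)
  }
}

#' Simulate lesion dynamics with collagen-elastin remodelling
#'
#' Integrates the 4-ODE extended system (stretch, stretch rate, collagen
#' number, elastin number) with fixed-step RK4.  With `k1 = k2 = 0` the
#' protein channels are frozen and the mechanical trajectory coincides
#' with the base (non-remodelling) system under the same combined stress.
#' Integration halts on energy rupture (stored energy at 99% of the cap),
#' nonphysical collapse, or when the stretch exceeds `expand_stop`.
#'
#' @param mat,geom,mem,fluid,bm Parameter blocks as in [simulate_lesion()].
#' @param elastin_b Elastin stiffness, N m^-2.
#' @param Ac0,Ae0 Initial active protein numbers.
#' @param k1,k2 Rate constants, s^-1.
#' @param n_exp Signal exponent.
#' @param phi Failure-energy density, J m^-3; defaults to a cap of three
#'   times the combined energy at `lambda = 2` with the initial protein
#'   numbers.
#' @param rho_c,rho_e Protein densities, kg m^-3 (default 5.10).
#' @param ic Initial `c(y0, y1)`.
#' @param tau_end,dt,record_every Integration controls.
#' @param collapse_at,expand_stop Stretch bounds that halt the run.
#' @return A `remodeling_trajectory`: data frame with columns `tau`, `y0`,
#'   `y1`, `Ac`, `Ae` and attributes `ruptured`, `rupture_tau`,
#'   `nonphysical`, `stopped`, `phi`, `groups`.
#' @export
simulate_remodeling <- function(mat = material_parameters(),
                                geom = lesion_geometry(),
                                mem = membrane_properties(),
                                fluid = fluid_properties(),
                                bm = breathing_model(),
                                elastin_b = 7.8e5,
                                Ac0 = 100, Ae0 = 50,
                                k1 = 1e7, k2 = 1e3, n_exp = 1,
                                phi = NULL, rho_c = 5.10, rho_e = 5.10,
                                ic = c(1, 0), tau_end = 50, dt = 1e-3,
                                record_every = 1L,
                                collapse_at = 0.05, expand_stop = 25) {
  stopifnot(Ac0 >= 0, Ae0 >= 0, k1 >= 0, k2 >= 0, n_exp > 0)
  groups <- nondimensional_groups(geom, mem, fluid, mat)
  if (is.null(phi))
    phi <- 3 * combined_energy(2, mat, geom, elastin_b, Ac0, Ae0,
                               form = "quadratic") / geom$H
  stopifnot(phi > 0)
  F_fn <- forcing_function(bm, groups, geom, mat, fluid)
  rhs <- remodeling_rhs(groups, mat, geom, elastin_b, phi,
                        k1, k2, n_exp, rho_c, rho_e, mem$rho_m, F_fn)
  co <- taylor_energy_coefficients(mat, geom)
  cap <- geom$H * phi
  ebH2 <- elastin_b * geom$H / 2
  stop_fn <- function(t, y) {
    if (y[1] < collapse_at) return("collapse")
    if (y[1] > expand_stop) return("expansion")
    E11 <- (y[1]^2 - 1) / 2
    w <- y[3] * co$a1 * E11 + (y[4] * ebH2 + y[3] * co$a2) * E11^2
    if (w > 0 && (1 - exp(-w / cap)) >= 0.99) return("rupture")
    NULL
  }
  sol <- integrate_rk4(rhs, c(ic, Ac0, Ae0), 0, tau_end, dt,
                       stop_fn = stop_fn, record_every = record_every)
  traj <- data.frame(tau = sol$t, y0 = sol$y[, 1], y1 = sol$y[, 2],
                     Ac = sol$y[, 3], Ae = sol$y[, 4])
  class(traj) <- c("remodeling_trajectory", "data.frame")
  attr(traj, "ruptured") <- identical(sol$stopped, "rupture")
  attr(traj, "rupture_tau") <- if (identical(sol$stopped, "rupture")) sol$t_stop else NA_real_
  attr(traj, "nonphysical") <- identical(sol$stopped, "collapse") ||
    identical(sol$stopped, "nonfinite")
  attr(traj, "stopped") <- sol$stopped
  attr(traj, "phi") <- phi
  attr(traj, "groups") <- groups
  traj
}

#' Detect escape from the stable orbit
#'
#' Compares a remodelling trajectory against the orbit envelope of its
#' non-remodelling base case.  Escape is declared when the stretch leaves
#' the envelope `[(1 - margin)*min, (1 + margin)*max]` of the base orbit
#' for at least `sustain` units of nondimensional time, or when the
#' remodelling run terminates early in rupture, collapse or runaway
#' expansion (departures the base case does not exhibit).
#'
#' @param traj A `remodeling_trajectory`.
#' @param base_traj The corresponding `k1 = k2 = 0` trajectory.
#' @param margin Relative envelope margin (default 0.5).
#' @param sustain Minimum sustained excursion, in nondimensional time.
#' @return A list with `escaped` (logical) and `escape_tau`.
#' @export
remodeling_escape <- function(traj, base_traj, margin = 0.5, sustain = 1) {
  hi <- (1 + margin) * max(base_traj$y0)
  lo <- (1 - margin) * min(base_traj$y0)
  out <- traj$y0 > hi | traj$y0 < lo
  if (any(out)) {
    r <- rle(out)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      t0 <- traj$tau[starts[i]]; t1 <- traj$tau[ends[i]]
      last <- ends[i] == length(out)
      if (t1 - t0 >= sustain || (last && !is.null(attr(traj, "stopped"))))
        return(list(escaped = TRUE, escape_tau = t0))
    }
  }
  stopped <- attr(traj, "stopped")
  if (!is.null(stopped) && stopped %in% c("rupture", "collapse", "expansion",
                                          "nonfinite"))
    return(list(escaped = TRUE,
                escape_tau = traj$tau[nrow(traj)]))
  list(escaped = FALSE, escape_tau = NA_real_)
}
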