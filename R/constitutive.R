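#' Green-Lagrange strain from the stretch ratio
#'
#' `E11 = (lambda^2 - 1)/2` for the equibiaxial spherical deformation.
#'
#' @param lam Stretch ratio (deformed over undeformed radius), positive.
#' @return Green-Lagrange strain, dimensionless.
#' @export
green_strain <- function(lam) {
  stopifnot(all(lam > 0))
  (lam^2 - 1) / 2
}

#' Hyperelastic strain energy of the lesion wall (full form)
#'
#' Energy per unit reference area of the collagen pseudostrain-energy
#' function multiplied by the deformed thickness `H/lambda^2`:
#' `w = (H/lam^2) * (c1*log(1 - (exp(E11)-1)/c2) + c3*E11)`.
#' The logarithm restricts validity to `exp(E11) - 1 < c2`.
#'
#' @param lam Stretch ratio(s), positive.
#' @param mat A [material_parameters()].
#' @param geom A [lesion_geometry()].
#' @return Strain energy per reference area, J m^-2.
#' @export
strain_energy_full <- function(lam, mat = material_parameters(),
                               geom = lesion_geometry()) {
  E11 <- green_strain(lam)
  arg <- 1 - (exp(E11) - 1) / mat$c2
  if (any(arg <= 0))
    stop("strain_energy_full: state beyond constitutive validity (log argument <= 0)")
  (geom$H / lam^2) * (mat$c1 * log(arg) + mat$c3 * E11)
}

# Coefficients of the second-order Taylor expansion of the wall energy
# about E11 = 0: w ~ a1*E11 + a2*E11^2 (both include the thickness H).
taylor_energy_coefficients <- function(mat, geom) {
  H <- geom$H; c1 <- mat$c1; c2 <- mat$c2; c3 <- mat$c3
  list(a1 = -c1 * H / c2 + c3 * H,
       a2 = -c1 * H / (2 * c2^2) + 3 * c1 * H / (2 * c2) - 2 * c3 * H)
}

#' Hyperelastic strain energy, second-order Taylor form
#'
#' Taylor expansion of [strain_energy_full()] about the undeformed state:
#' `w = (-c1*H/c2 + c3*H)*E11 + (-c1*H/(2*c2^2) + 3*c1*H/(2*c2) - 2*c3*H)*E11^2`.
#'
#' @inheritParams strain_energy_full
#' @return Strain energy per reference area, J m^-2.
#' @export
strain_energy_taylor <- function(lam, mat = material_parameters(),
                                 geom = lesion_geometry()) {
  E11 <- green_strain(lam)
  co <- taylor_energy_coefficients(mat, geom)
  co$a1 * E11 + co$a2 * E11^2
}

#' Isotropic stress resultant of the wall
#'
#' Membrane tension (force per unit length) from the Taylor strain energy
#' plus the viscous rate term:
#' `T = a1 + 2*a2*E11 + 2*mu_m*H*lam_dot/lam^3`, with `a1`, `a2` the Taylor
#' energy coefficients.  The elastic part equals `dw/dE11` of the Taylor
#' energy.
#'
#' @param lam Stretch ratio(s), positive.
#' @param lam_dot Stretch rate(s), s^-1.
#' @param mat A [material_parameters()].
#' @param geom A [lesion_geometry()].
#' @param mem A [membrane_properties()].
#' @return Stress resultant, N m^-1.
#' @export
stress_resultant <- function(lam, lam_dot = 0, mat = material_parameters(),
                             geom = lesion_geometry(),
                             mem = membrane_properties()) {
  stopifnot(all(lam > 0))
  co <- taylor_energy_coefficients(mat, geom)
  co$a1 + co$a2 * (lam^2 - 1) + 2 * mem$mu_m * geom$H * lam_dot / lam^3
}

#' Default failure-energy density for rupture studies
#'
#' The failure-energy density `phi` (J m^-3) is not a measured tissue
#' constant; any rupture study must choose it.  The packaged default sets
#' the areal energy cap `H*phi` to three times the Taylor strain energy at
#' `lambda = 2` for the supplied materials, which places rupture
#' mid-expansion rather than immediately or never.
#'
#' @param mat A [material_parameters()].
#' @param geom A [lesion_geometry()].
#' @return Failure-energy density `phi`, J m^-3.
#' @export
default_energy_limit <- function(mat = material_parameters(),
                                 geom = lesion_geometry()) {
  3 * strain_energy_taylor(2, mat, geom) / geom$H
}

#' Energy-limited strain energy
#'
#' Caps the storable strain energy: `Psi = H*phi*(1 - exp(-w/(H*phi)))`.
#' `Psi` increases with `w`, tends to the finite value `H*phi` as
#' `w -> Inf`, and `Psi ~ w` when `w << H*phi`.
#'
#' @param w Unlimited strain energy per reference area, J m^-2.
#' @param geom A [lesion_geometry()].
#' @param phi Failure-energy density, J m^-3 (positive).
#' @return Limited strain energy, J m^-2.
#' @export
limited_energy <- function(w, geom = lesion_geometry(), phi) {
  stopifnot(is.numeric(phi), length(phi) == 1L, phi > 0)
  cap <- geom$H * phi
  cap * -expm1(-w / cap)   # expm1 keeps precision when w << cap
}

#' Energy-limited isotropic stress resultant
#'
#' The elastic part of [stress_resultant()] attenuated by the factor
#' `exp(-w_taylor/(H*phi))` implied by differentiating the limited energy,
#' plus the unchanged viscous term `2*mu_m*H*lam_dot/lam^3`.  The elastic
#' part attains an interior maximum in `lambda` (the softening onset) for
#' strain-hardening materials with a finite energy limit.
#'
#' @inheritParams stress_resultant
#' @param phi Failure-energy density, J m^-3.
#' @return Stress resultant, N m^-1.
#' @export
stress_resultant_limited <- function(lam, lam_dot = 0,
                                     mat = material_parameters(),
                                     geom = lesion_geometry(),
                                     mem = membrane_properties(), phi) {
  stopifnot(all(lam > 0), phi > 0)
  co <- taylor_energy_coefficients(mat, geom)
  E11 <- green_strain(lam)
  w <- co$a1 * E11 + co$a2 * E11^2
  elastic <- (co$a1 + 2 * co$a2 * E11) * exp(-w / (geom$H * phi))
  elastic + 2 * mem$mu_m * geom$H * lam_dot / lam^3
}

#' Softening-onset stretch of the energy-limited wall
#'
#' Locates the interior maximum of the elastic part of
#' [stress_resultant_limited()] over a stretch grid.  Crossing this stretch
#' while expanding defines the rupture point: beyond it the wall softens
#' and can no longer sustain additional load.  Returns `NA` when the
#' elastic stress has no interior maximum above `lambda = 1` (for example
#' for strain-softening parameter sets, which fail by other routes).
#'
#' @param mat A [material_parameters()].
#' @param geom A [lesion_geometry()].
#' @param phi Failure-energy density, J m^-3.
#' @param lam_max Upper end of the search grid.
#' @param n_grid Number of grid points.
#' @return Softening-onset stretch, or `NA_real_` if none exists.
#' @export
rupture_stretch <- function(mat = material_parameters(),
                            geom = lesion_geometry(), phi,
                            lam_max = 6, n_grid = 4001L) {
  lam <- seq(1, lam_max, length.out = n_grid)
  Tel <- stress_resultant_limited(lam, 0, mat, geom,
                                  membrane_properties(mu_m = 0), phi)
  i <- which.max(Tel)
  if (i == 1L || i == n_grid) return(NA_real_)
  lam[i]
}

#' Combined collagen-elastin strain energy
#'
#' Linear combination of the collagen-only wall energy and an elastin-only
#' neo-Hookean-like term, weighted by the active protein numbers:
#' `w' = Ac*w_collagen(lam) + Ae*(elastin_b*H/lam^2)*(lam - log(lam) - 1)`.
#' `form = "quadratic"` returns the second-order expansion about the
#' undeformed state used by the remodelling dynamics:
#' `w' ~ Ac*a1*E11 + (Ae*elastin_b*H/2 + Ac*a2)*E11^2`.
#'
#' Note that the elastin stiffness `elastin_b` (N m^-2) is unrelated to the
#' inertia ratio `b` of [nondimensional_groups()]; the two only share a
#' symbol in the underlying theory.
#'
#' @param lam Stretch ratio(s), positive.
#' @param mat A [material_parameters()].
#' @param geom A [lesion_geometry()].
#' @param elastin_b Elastin stiffness, N m^-2 (positive).
#' @param Ac Active collagen number (dimensionless, >= 0).
#' @param Ae Active elastin number (dimensionless, >= 0).
#' @param form `"full"` (exact, collagen log form) or `"quadratic"`.
#' @return Strain energy per reference area, J m^-2.
#' @export
combined_energy <- function(lam, mat = material_parameters(),
                            geom = lesion_geometry(), elastin_b,
                            Ac = 1, Ae = 0,
                            form = c("full", "quadratic")) {
  form <- match.arg(form)
  stopifnot(all(Ac >= 0), all(Ae >= 0), elastin_b > 0 || all(Ae == 0))
  if (form == "full") {
    collagen <- strain_energy_full(lam, mat, geom)
    elastin <- (elastin_b * geom$H / lam^2) * (lam - log(lam) - 1)
    Ac * collagen + Ae * elastin
  } else {
    E11 <- green_strain(lam)
    co <- taylor_energy_coefficients(mat, geom)
    Ac * co$a1 * E11 + (Ae * elastin_b * geom$H / 2 + Ac * co$a2) * E11^2
  }
}
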