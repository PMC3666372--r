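#' Material parameters of the lesion wall
#'
#' Constructor for the three constants of the isotropic collagen
#' pseudostrain-energy function used for the parenchymal wall.  For
#' physically relevant lung tissue `c1 < 0`, `c2 > 0` and `c3 < 0`; the
#' constructor enforces these sign constraints.
#'
#' @param c1 Stress-like constant, N m^-2. Must be negative.
#' @param c2 Dimensionless stiffness constant. Must be positive.
#' @param c3 Stress-like constant, N m^-2. Must be negative.
#' @return An object of class `material_parameters`.
#' @examples
#' material_parameters() # normal lung parenchymal tissue values
#' @export
material_parameters <- function(c1 = -22.5e5, c2 = 1.26, c3 = -7.8e5) {
  stopifnot(is.numeric(c1), is.numeric(c2), is.numeric(c3),
            length(c1) == 1L, length(c2) == 1L, length(c3) == 1L,
            is.finite(c1), is.finite(c2), is.finite(c3))
  if (c1 >= 0) stop("non-physical material parameters: c1 must be negative")
  if (c2 <= 0) stop("non-physical material parameters: c2 must be positive")
  if (c3 >= 0) stop("non-physical material parameters: c3 must be negative")
  structure(list(c1 = c1, c2 = c2, c3 = c3), class = "material_parameters")
}

#' Undeformed lesion geometry
#'
#' @param H Undeformed wall thickness, m.
#' @param R Undeformed lesion radius, m. The membrane assumption requires
#'   `H` to be much smaller than `R`; this is advisory and not enforced.
#' @return An object of class `lesion_geometry`.
#' @export
lesion_geometry <- function(H = 1e-3, R = 1e-2) {
  stopifnot(is.numeric(H), is.numeric(R), length(H) == 1L, length(R) == 1L,
            is.finite(H), is.finite(R))
  if (H <= 0 || R <= 0) stop("geometry: H and R must be positive")
  structure(list(H = H, R = R), class = "lesion_geometry")
}

#' Membrane (wall) material properties
#'
#' @param rho_m Membrane density, kg m^-3.
#' @param mu_m Membrane dynamic viscosity, Pa s.
#' @return An object of class `membrane_properties`.
#' @export
membrane_properties <- function(rho_m = 1050, mu_m = 7e-2) {
  stopifnot(is.finite(rho_m), is.finite(mu_m))
  if (rho_m <= 0) stop("membrane: rho_m must be positive")
  if (mu_m < 0) stop("membrane: mu_m must be non-negative")
  structure(list(rho_m = rho_m, mu_m = mu_m), class = "membrane_properties")
}

#' Pleural fluid properties
#'
#' The default viscosity is the midpoint of the reported physiological
#' range 1.39--1.57e-3 Pa s for pleural fluid.
#'
#' @param rho_f Pleural fluid density, kg m^-3.
#' @param mu_f Pleural fluid dynamic viscosity, Pa s.
#' @param p_inf Far-field pleural pressure, Pa.
#' @return An object of class `fluid_properties`.
#' @export
fluid_properties <- function(rho_f = 980.3, mu_f = 1.48e-3, p_inf = 0) {
  stopifnot(is.finite(rho_f), is.finite(mu_f), is.finite(p_inf))
  if (rho_f <= 0) stop("fluid: rho_f must be positive")
  if (mu_f < 0) stop("fluid: mu_f must be non-negative")
  structure(list(rho_f = rho_f, mu_f = mu_f, p_inf = p_inf),
            class = "fluid_properties")
}

#' Convert a pressure from mmHg to pascal
#'
#' Uses the exact definition 760 mmHg = 101325 Pa.
#'
#' @param value Pressure in mmHg.
#' @return Pressure in Pa.
#' @examples
#' mmHg_to_Pa(760) # 101325
#' @export
mmHg_to_Pa <- function(value) {
  stopifnot(is.numeric(value), all(is.finite(value)))
  value * 101325 / 760
}

#' Characteristic time scale of the membrane
#'
#' The nondimensional time is `tau = t / time_scale`, with
#' `time_scale = R * sqrt(rho_m / |c1|)`.  This scale makes the inertial
#' coefficient of the nondimensional momentum balance equal to
#' `b*y0 + y0^-2` exactly.
#'
#' @param geom A [lesion_geometry()].
#' @param mem A [membrane_properties()].
#' @param mat A [material_parameters()].
#' @return Time scale in seconds.
#' @export
time_scale <- function(geom = lesion_geometry(), mem = membrane_properties(),
                       mat = material_parameters()) {
  geom$R * sqrt(mem$rho_m / abs(mat$c1))
}

#' Equilibrium-quadratic coefficients
#'
#' Coefficients of the quadratic `gamma*lambda^2 + alpha*lambda + beta = 0`
#' whose positive root is the equilibrium stretch of the autonomous system:
#' `alpha = c1*c2^2*F`, `beta = -c1 + 5*c1*c2 - 6*c2^2*c3` and
#' `gamma = c1 - 3*c1*c2 + 4*c2^2*c3`.  For physical material parameters
#' `alpha > 0` and `beta`, `gamma` are never simultaneously positive.
#'
#' @param mat A [material_parameters()].
#' @param F_bar Constant nondimensional transmural forcing (negative for
#'   physical inputs).
#' @return An object of class `derived_coefficients` with fields
#'   `alpha`, `beta`, `gamma`.
#' @export
derived_coefficients <- function(mat, F_bar) {
  if (!inherits(mat, "material_parameters"))
    mat <- do.call(material_parameters, as.list(mat)[c("c1", "c2", "c3")])
  stopifnot(is.numeric(F_bar), length(F_bar) == 1L, is.finite(F_bar))
  c1 <- mat$c1; c2 <- mat$c2; c3 <- mat$c3
  structure(list(
    alpha = c1 * c2^2 * F_bar,
    beta  = -c1 + 5 * c1 * c2 - 6 * c2^2 * c3,
    gamma = c1 - 3 * c1 * c2 + 4 * c2^2 * c3
  ), class = "derived_coefficients")
}

#' Nondimensional groups of the air-tissue-pleural fluid system
#'
#' Computes the dimensionless numbers parameterizing the reduced system:
#' inertia ratio `b = rho_f*R/(rho_m*H)`, thickness ratio `d = H/R`,
#' viscosity numbers `m_f = mu_f/(H*sqrt(rho_m*|c1|))` and
#' `m = mu_m/(H*sqrt(rho_m*|c1|))`, and the constant forcing
#' `F_bar = P_transmural*R/(c1*H)` (negative for positive transmural
#' pressure, since `c1 < 0`).
#'
#' @param geom A [lesion_geometry()].
#' @param mem A [membrane_properties()].
#' @param fluid A [fluid_properties()].
#' @param mat A [material_parameters()].
#' @param P_transmural Mean transmural pressure (inner minus far-field), Pa.
#'   The default is one standard atmosphere, the baseline inner pressure
#'   with `p_inf = 0`.
#' @return An object of class `nondimensional_groups` with fields `b`, `d`,
#'   `m_f`, `m`, `F_bar` and the characteristic `time_scale` (s).
#' @export
nondimensional_groups <- function(geom = lesion_geometry(),
                                  mem = membrane_properties(),
                                  fluid = fluid_properties(),
                                  mat = material_parameters(),
                                  P_transmural = mmHg_to_Pa(760)) {
  stopifnot(inherits(geom, "lesion_geometry"),
            inherits(mem, "membrane_properties"),
            inherits(fluid, "fluid_properties"),
            inherits(mat, "material_parameters"),
            is.finite(P_transmural))
  if (geom$H == 0 || geom$R == 0 || mat$c1 == 0)
    stop("nondimensional_groups: H, R and c1 must be nonzero")
  visc_scale <- geom$H * sqrt(mem$rho_m * abs(mat$c1))
  structure(list(
    b = fluid$rho_f * geom$R / (mem$rho_m * geom$H),
    d = geom$H / geom$R,
    m_f = fluid$mu_f / visc_scale,
    m = mem$mu_m / visc_scale,
    F_bar = P_transmural * geom$R / (mat$c1 * geom$H),
    time_scale = time_scale(geom, mem, mat)
  ), class = "nondimensional_groups")
}

#' Recover dimensional quantities from nondimensional groups
#'
#' Inverse of [nondimensional_groups()] given the geometry and the
#' membrane density: returns the fluid density, the two viscosities and the
#' transmural pressure implied by the groups.  Used to check that
#' nondimensionalization is lossless.
#'
#' @param groups A [nondimensional_groups()].
#' @param geom A [lesion_geometry()].
#' @param mem A [membrane_properties()].
#' @param mat A [material_parameters()].
#' @return A list with `rho_f`, `mu_f`, `mu_m`, `P_transmural`, `R_over_H`.
#' @export
redimensionalize <- function(groups, geom, mem, mat) {
  visc_scale <- geom$H * sqrt(mem$rho_m * abs(mat$c1))
  list(
    rho_f = groups$b * mem$rho_m * geom$H / geom$R,
    mu_f = groups$m_f * visc_scale,
    mu_m = groups$m * visc_scale,
    P_transmural = groups$F_bar * mat$c1 * geom$H / geom$R,
    R_over_H = 1 / groups$d
  )
}

#' @export
print.material_parameters <- function(x, ...) {
  cat(sprintf("Lesion wall material parameters: c1 = %.4g N/m^2, c2 = %.4g, c3 = %.4g N/m^2\n",
              x$c1, x$c2, x$c3))
  invisible(x)
}

#' @export
print.nondimensional_groups <- function(x, ...) {
  cat(sprintf("Nondimensional groups: b = %.4g, d = %.4g, m_f = %.4g, m = %.4g, F_bar = %.4g\n",
              x$b, x$d, x$m_f, x$m, x$F_bar))
  cat(sprintf("Characteristic time scale: %.4g s\n", x$time_scale))
  invisible(x)
}
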