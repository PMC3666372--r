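#' Closed-form equilibrium stretch ratios
#'
#' Roots of the equilibrium quadratic `gamma*lam^2 + alpha*lam + beta = 0`
#' of the autonomous system: `lam = (-alpha +/- sqrt(alpha^2 -
#' 4*beta*gamma)) / (2*gamma)`.  The positive root is the physically
#' meaningful equilibrium; which branch is positive depends on the signs of
#' `beta` and `gamma`.  The `+` branch (`root_plus`) is the one about which
#' the closed-form Jacobian criteria are formulated.
#'
#' @param coeffs A [derived_coefficients()].
#' @return A list with `root_plus`, `root_minus` (the two quadratic roots),
#'   and `physical` (the positive root).
#' @export
equilibrium_stretch <- function(coeffs) {
  a <- coeffs$alpha; b <- coeffs$beta; g <- coeffs$gamma
  if (g == 0) stop("equilibrium_stretch: gamma = 0, quadratic degenerates")
  disc <- a^2 - 4 * b * g
  if (disc < 0) stop("equilibrium_stretch: no real equilibrium (alpha^2 < 4*beta*gamma)")
  rp <- (-a + sqrt(disc)) / (2 * g)
  rm <- (-a - sqrt(disc)) / (2 * g)
  pos <- c(rp, rm)[c(rp, rm) > 0]
  list(root_plus = rp, root_minus = rm,
       physical = if (length(pos)) max(pos) else NA_real_)
}

#' Jacobian of the reduced system at an equilibrium
#'
#' The 2x2 Jacobian of the autonomous nondimensional system evaluated at
#' `(lam, 0)`.  Row one is `(0, 1)`.  With `N(y0) = F_bar - 2*f(y0)/y0 =
#' F_bar*Q(y0)/(alpha*y0)` (where `Q` is the equilibrium quadratic) and
#' `D(y0) = b*y0 + y0^-2`, the second row at a root of `Q` is
#' `J21 = F_bar*Q'(lam)/(alpha*lam*D)` and
#' `J22 = -(4*m_f/lam + 4*m*d/lam^4)/D`.
#'
#' By default the Jacobian is evaluated at the `+` quadratic branch
#' (`root_plus`), the branch about which the closed-form instability
#' criteria are stated; `branch = "physical"` uses the positive root
#' instead.
#'
#' @param coeffs A [derived_coefficients()].
#' @param groups A [nondimensional_groups()].
#' @param branch `"analysis"` (the `+` branch) or `"physical"` (the
#'   positive root).
#' @return A 2x2 numeric matrix.
#' @export
jacobian_at_equilibrium <- function(coeffs, groups,
                                    branch = c("analysis", "physical")) {
  branch <- match.arg(branch)
  eq <- equilibrium_stretch(coeffs)
  lam <- if (branch == "analysis") eq$root_plus else eq$physical
  if (is.na(lam)) stop("jacobian_at_equilibrium: no equilibrium on requested branch")
  a <- coeffs$alpha; g <- coeffs$gamma
  D <- groups$b * lam + 1 / lam^2
  Qp <- 2 * g * lam + a
  J21 <- groups$F_bar * Qp / (a * lam * D)
  J22 <- -(4 * groups$m_f / lam + 4 * groups$m * groups$d / lam^4) / D
  matrix(c(0, J21, 1, J22), 2, 2)
}

#' Determinant-based instability test
#'
#' The system is unstable with `det J < 0` whenever `gamma < 0`,
#' `beta > 0` and `gamma < b^(1/3)*alpha - b^(2/3)*beta`.
#'
#' @param coeffs A [derived_coefficients()].
#' @param groups A [nondimensional_groups()].
#' @return Logical flag.
#' @export
unstable_by_determinant <- function(coeffs, groups) {
  a <- coeffs$alpha; be <- coeffs$beta; g <- coeffs$gamma
  b <- groups$b
  isTRUE(g < 0 && be > 0 && g < b^(1 / 3) * a - b^(2 / 3) * be)
}

#' Trace-based instability test
#'
#' The system is unstable with `tr J > 0` whenever `gamma < 0`, `beta > 0`,
#' `gamma > b^(1/3)*alpha - b^(2/3)*beta` and a fourth inequality involving
#' the dissipation numbers holds.  With `k = (d*m/m_f)^(1/3)`, the default
#' (`form = "derived"`) fourth inequality is
#' `beta < alpha*k - gamma*k^2`, obtained by carrying the trace-sign
#' algebra through from the Jacobian entries; it is exactly equivalent to
#' the dissipation part of `tr J` changing sign at the analysis branch.
#' `form = "printed"` evaluates the typeset variant
#' `beta > alpha*gamma^2*k + gamma*k^2`, which is dimensionally
#' inhomogeneous and retained only for comparison; see
#' [trace_criterion_forms_agree()].
#'
#' @inheritParams unstable_by_determinant
#' @param form `"derived"` (default) or `"printed"`.
#' @return Logical flag.
#' @export
unstable_by_trace <- function(coeffs, groups, form = c("derived", "printed")) {
  form <- match.arg(form)
  a <- coeffs$alpha; be <- coeffs$beta; g <- coeffs$gamma
  b <- groups$b
  if (groups$m_f == 0) stop("unstable_by_trace: m_f = 0, dissipation ratio undefined")
  k <- (groups$d * groups$m / groups$m_f)^(1 / 3)
  fourth <- if (form == "derived") be < a * k - g * k^2 else
    be > a * g^2 * k + g * k^2
  isTRUE(g < 0 && be > 0 && g > b^(1 / 3) * a - b^(2 / 3) * be && fourth)
}

#' Compare the two forms of the trace criterion
#'
#' Evaluates [unstable_by_trace()] under both the derived and the printed
#' fourth inequality and reports whether they agree, together with the
#' numeric sign of `tr J` at the analysis branch.  Disagreements indicate
#' parameter regions where the printed variant contradicts the actual
#' trace sign.
#'
#' @inheritParams unstable_by_determinant
#' @return A list with `derived`, `printed`, `agree`, `tr_J`.
#' @export
trace_criterion_forms_agree <- function(coeffs, groups) {
  d <- unstable_by_trace(coeffs, groups, "derived")
  p <- unstable_by_trace(coeffs, groups, "printed")
  J <- jacobian_at_equilibrium(coeffs, groups, "analysis")
  list(derived = d, printed = p, agree = identical(d, p),
       tr_J = J[1, 1] + J[2, 2])
}

#' Classify a lesion as stable or unstable
#'
#' Computes the nondimensional groups, the equilibrium-quadratic
#' coefficients and the equilibrium stretch, then applies the
#' determinant and trace instability criteria.  The signs of `det J` and
#' `tr J` are always recomputed numerically from the 2x2 Jacobian at the
#' analysis branch as a cross-check.
#'
#' @param mat A [material_parameters()].
#' @param geom A [lesion_geometry()].
#' @param mem A [membrane_properties()].
#' @param fluid A [fluid_properties()].
#' @param P_transmural Mean transmural pressure, Pa.
#' @param trace_form Passed to [unstable_by_trace()].
#' @return An object of class `stability_verdict`: a list with
#'   `lambda_eq` (positive equilibrium stretch), `is_unstable`, `criterion`
#'   (`"determinant"`, `"trace"`, `"none"` or `"no_equilibrium"`),
#'   `det_sign`, `tr_sign` (numeric signs of det/tr J), `coeffs`, `groups`.
#' @examples
#' classify_lesion() # normal tissue defaults: stable, lambda_eq ~ 1.34
#' @export
classify_lesion <- function(mat = material_parameters(),
                            geom = lesion_geometry(),
                            mem = membrane_properties(),
                            fluid = fluid_properties(),
                            P_transmural = mmHg_to_Pa(760),
                            trace_form = c("derived", "printed")) {
  trace_form <- match.arg(trace_form)
  groups <- nondimensional_groups(geom, mem, fluid, mat, P_transmural)
  coeffs <- derived_coefficients(mat, groups$F_bar)
  eq <- tryCatch(equilibrium_stretch(coeffs), error = function(e) NULL)
  if (is.null(eq) || is.na(eq$physical)) {
    out <- list(lambda_eq = NA_real_, is_unstable = NA,
                criterion = "no_equilibrium", det_sign = NA_real_,
                tr_sign = NA_real_, coeffs = coeffs, groups = groups)
    class(out) <- "stability_verdict"
    return(out)
  }
  det_fires <- unstable_by_determinant(coeffs, groups)
  tr_fires <- unstable_by_trace(coeffs, groups, trace_form)
  J <- jacobian_at_equilibrium(coeffs, groups, "analysis")
  out <- list(
    lambda_eq = eq$physical,
    is_unstable = det_fires || tr_fires,
    criterion = if (det_fires) "determinant" else if (tr_fires) "trace" else "none",
    det_sign = sign(J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]),
    tr_sign = sign(J[1, 1] + J[2, 2]),
    coeffs = coeffs, groups = groups
  )
  class(out) <- "stability_verdict"
  out
}

#' Scan a material-parameter plane for instability regions
#'
#' Evaluates [classify_lesion()] on a grid over two of the three material
#' parameters, holding the third at its value in `mat`.
#'
#' @param x_param,y_param Parameter names, two of `"c1"`, `"c2"`, `"c3"`.
#' @param x_values,y_values Grid values for the two axes.
#' @param mat Base [material_parameters()] supplying the fixed parameter.
#' @param geom,mem,fluid,P_transmural As in [classify_lesion()].
#' @return A data frame with columns `x`, `y`, `unstable`, `criterion`,
#'   `lambda_eq` and attribute `axes = c(x_param, y_param)`.  Grid points
#'   with non-physical parameter signs are marked `criterion =
#'   "non_physical"`.
#' @export
region_scan <- function(x_param, y_param, x_values, y_values,
                        mat = material_parameters(),
                        geom = lesion_geometry(),
                        mem = membrane_properties(),
                        fluid = fluid_properties(),
                        P_transmural = mmHg_to_Pa(760)) {
  stopifnot(x_param %in% c("c1", "c2", "c3"), y_param %in% c("c1", "c2", "c3"),
            x_param != y_param)
  grid <- expand.grid(x = x_values, y = y_values)
  base <- list(c1 = mat$c1, c2 = mat$c2, c3 = mat$c3)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    p <- base
    p[[x_param]] <- grid$x[i]
    p[[y_param]] <- grid$y[i]
    m <- tryCatch(material_parameters(p$c1, p$c2, p$c3), error = function(e) NULL)
    if (is.null(m))
      return(data.frame(unstable = NA, criterion = "non_physical",
                        lambda_eq = NA_real_))
    v <- classify_lesion(m, geom, mem, fluid, P_transmural)
    data.frame(unstable = v$is_unstable, criterion = v$criterion,
               lambda_eq = v$lambda_eq)
  })
  out <- cbind(grid, do.call(rbind, res))
  attr(out, "axes") <- c(x_param, y_param)
  out
}

#' @export
print.stability_verdict <- function(x, ...) {
  if (identical(x$criterion, "no_equilibrium")) {
    cat("Stability verdict: no real equilibrium for these parameters\n")
    return(invisible(x))
  }
  cat(sprintf("Stability verdict: %s (criterion: %s)\n",
              if (isTRUE(x$is_unstable)) "UNSTABLE" else "stable", x$criterion))
  cat(sprintf("  lambda_eq+ = %.4f; sign(det J) = %+d, sign(tr J) = %+d\n",
              x$lambda_eq, x$det_sign, x$tr_sign))
  invisible(x)
}
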