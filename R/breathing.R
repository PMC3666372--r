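#' Seven-component Fourier table for tidal breathing
#'
#' The packaged default flow decomposition: amplitudes `A` (L s^-1),
#' frequencies `f` (Hz) and phases `phi` (rad) of the seven cosine
#' components of the driven air flow.  All frequencies are integer
#' multiples of 0.078125 Hz, so the series has a common period of 12.8 s.
#'
#' @return A data frame with columns `A`, `f`, `phi`.
#' @export
breathing_table <- function() {
  data.frame(
    A   = c(1, 0.3, 0.25, 0.25, 0.175, 0.175, 0.125),
    f   = c(0.156250, 0.390625, 0.859375, 1.484375, 2.421875, 4.609375,
            8.046875),
    phi = c(4.95, 3.82, 4.37, 3.67, 4.05, 4.13, 4.02)
  )
}

#' Breathing forcing model
#'
#' Bundles the Fourier flow components with the respiratory resistance of
#' the bronchiole network and the baseline (atmospheric) pressure.  The
#' pulsatile inner pressure is `baseline + R_b * Q(t)` in mmHg.
#'
#' @param components Data frame with columns `A` (L s^-1, >= 0),
#'   `f` (Hz, > 0) and `phi` (rad); defaults to [breathing_table()].
#' @param R_b Respiratory resistance, mmHg s L^-1 (positive).
#' @param baseline Baseline inner pressure, mmHg.
#' @return An object of class `breathing_model`.
#' @export
breathing_model <- function(components = breathing_table(), R_b = 1,
                            baseline = 760) {
  stopifnot(is.data.frame(components),
            all(c("A", "f", "phi") %in% names(components)),
            all(components$A >= 0), all(components$f > 0),
            is.finite(R_b), R_b > 0, is.finite(baseline))
  structure(list(components = components, R_b = R_b, baseline = baseline),
            class = "breathing_model")
}

#' Read a breathing Fourier table from CSV
#'
#' Expects columns `A`, `f`, `phi` as in [breathing_table()].
#'
#' @param path Path to a CSV file.
#' @param ... Passed on to [breathing_model()].
#' @return A `breathing_model`.
#' @export
read_breathing_csv <- function(path, ...) {
  breathing_model(utils::read.csv(path), ...)
}

#' Driven air flow
#'
#' `Q(t) = sum_i A_i * cos(2*pi*f_i*t + phi_i)`, in L s^-1.
#'
#' @param t Time(s), seconds.
#' @param bm A [breathing_model()].
#' @return Flow, L s^-1 (vectorized over `t`).
#' @export
driven_flow <- function(t, bm = breathing_model()) {
  stopifnot(all(is.finite(t)))
  comp <- bm$components
  vapply(t, function(ti) sum(comp$A * cos(2 * pi * comp$f * ti + comp$phi)),
         numeric(1))
}

#' Pulsatile inner pressure
#'
#' `P_inner(t) = baseline + R_b * Q(t)`, in mmHg.  Averaged over the common
#' period of the flow components the cosines cancel and the mean equals the
#' baseline.
#'
#' @inheritParams driven_flow
#' @return Inner pressure, mmHg (vectorized over `t`).
#' @export
inner_pressure <- function(t, bm = breathing_model()) {
  bm$baseline + bm$R_b * driven_flow(t, bm)
}

#' Common period of the breathing components
#'
#' Least `T` such that `f_i * T` is an integer for every component, found by
#' rationalizing the frequencies with a continued-fraction expansion.  For
#' the packaged table the result is 12.8 s.  Errors if the frequencies are
#' incommensurate within the tolerance (no common period below the
#' denominator bound).
#'
#' @param bm A [breathing_model()].
#' @param max_denominator Largest denominator considered when rationalizing
#'   frequency ratios.
#' @param tol Relative tolerance for the rational approximation.
#' @return Common period, seconds.
#' @export
common_period <- function(bm = breathing_model(), max_denominator = 1e6,
                          tol = 1e-9) {
  f <- bm$components$f
  # rationalize each f_i / f_1, then T = lcm(denominators) / (f_1 / gcd(numerators))
  rats <- lapply(f / f[1], .as_rational, max_denominator = max_denominator,
                 tol = tol)
  if (any(vapply(rats, is.null, logical(1))))
    stop("common_period: frequencies are incommensurate (no common period found)")
  den <- vapply(rats, `[[`, numeric(1), "q")
  num <- vapply(rats, `[[`, numeric(1), "p")
  L <- Reduce(.lcm, den)
  # f_i * T = (p_i * L / q_i) * (f_1 * T / L); choose T = L * g / f_1 minimal:
  k <- num * (L / den)           # f_i = k_i * f_1 / L, k_i integers
  g <- Reduce(.gcd, k)
  Tc <- L / (g * f[1])
  if (!all(abs(f * Tc - round(f * Tc)) < 1e-6))
    stop("common_period: frequencies are incommensurate (no common period found)")
  Tc
}

# continued-fraction rational approximation of x as p/q, or NULL
.as_rational <- function(x, max_denominator, tol) {
  p0 <- 1; q0 <- 0; p1 <- floor(x); q1 <- 1; r <- x - p1
  while (abs(p1 / q1 - x) > tol * max(1, abs(x))) {
    if (r < .Machine$double.eps || q1 > max_denominator) break
    a <- floor(1 / r); r <- 1 / r - a
    tmp_p <- a * p1 + p0; tmp_q <- a * q1 + q0
    p0 <- p1; q0 <- q1; p1 <- tmp_p; q1 <- tmp_q
  }
  if (q1 > max_denominator || abs(p1 / q1 - x) > tol * max(1, abs(x)))
    return(NULL)
  list(p = p1, q = q1)
}

.gcd <- function(a, b) {
  a <- round(a); b <- round(b)
  while (b != 0) { t <- b; b <- a %% b; a <- t }
  a
}

.lcm <- function(a, b) a / .gcd(a, b) * b
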