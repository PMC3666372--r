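# 3x3 convolution evaluated at interior pixels (border left at zero).
conv3x3 <- function(M, K) {
  n <- nrow(M); m <- ncol(M)
  acc <- matrix(0, n - 2L, m - 2L)
  for (i in 1:3) for (j in 1:3) {
    if (K[i, j] != 0)
      acc <- acc + K[i, j] * M[i:(n - 3L + i), j:(m - 3L + j)]
  }
  out <- matrix(0, n, m)
  out[2:(n - 1L), 2:(m - 1L)] <- acc
  out
}

# separable Gaussian smoothing with replicate padding
gaussian_blur <- function(M, sigma = 1) {
  if (sigma <= 0) return(M)
  r <- ceiling(3 * sigma)
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  n <- nrow(M); m <- ncol(M)
  idx <- c(rep(1L, r), seq_len(n), rep(n, r))
  Mp <- M[idx, , drop = FALSE]
  out <- matrix(0, n, m)
  for (i in seq_along(k)) out <- out + k[i] * Mp[i:(i + n - 1L), , drop = FALSE]
  idx <- c(rep(1L, r), seq_len(m), rep(m, r))
  Mp <- out[, idx, drop = FALSE]
  out <- matrix(0, n, m)
  for (i in seq_along(k)) out <- out + k[i] * Mp[, i:(i + m - 1L), drop = FALSE]
  out
}

#' Preprocess a frame for edge detection
#'
#' Converts to grayscale if needed, compresses the contrast by 50% towards
#' mid-gray (`0.5 + 0.5*(x - 0.5)`, halving the intensity range) and
#' applies Gaussian softening.
#'
#' @param frame Numeric matrix in `[0, 1]`, or an array whose channels are
#'   averaged to grayscale.
#' @param sigma Gaussian softening scale, pixels.
#' @return A numeric matrix of the same size.
#' @export
preprocess_frame <- function(frame, sigma = 1) {
  if (length(dim(frame)) == 3L) frame <- apply(frame, c(1, 2), mean)
  stopifnot(is.matrix(frame))
  gaussian_blur(0.5 + 0.5 * (frame - 0.5), sigma)
}

#' Sobel edge detection
#'
#' Applies the 3x3 horizontal and vertical Sobel masks at the interior
#' pixels, forms the gradient magnitude `G = |Gx| + |Gy|`, and keeps the
#' pixels with `G >= threshold_fraction * max(G)`.  Coordinates are
#' returned in a centered system with the image center as the origin,
#' x to the right (columns) and y up (rows decreasing).
#'
#' @param frame Numeric matrix (at least 3x3).
#' @param threshold_fraction Fraction of the maximum gradient magnitude
#'   used as the edge threshold, in (0, 1).
#' @return An `edge_set`: data frame with columns `row`, `col` (1-based
#'   pixel indices), `x`, `y` (centered coordinates) and `g` (gradient
#'   magnitude); attribute `frame_dim` holds the frame size.  A uniform frame
#'   yields an empty set.
#' @export
sobel_edges <- function(frame, threshold_fraction = 0.25) {
  stopifnot(is.matrix(frame), nrow(frame) >= 3, ncol(frame) >= 3,
            threshold_fraction > 0, threshold_fraction < 1)
  Kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  Ky <- t(Kx)
  G <- abs(conv3x3(frame, Kx)) + abs(conv3x3(frame, Ky))
  gmax <- max(G)
  sel <- which(G >= threshold_fraction * gmax & G > 0, arr.ind = TRUE)
  cx <- (ncol(frame) + 1) / 2
  cy <- (nrow(frame) + 1) / 2
  out <- data.frame(row = sel[, 1], col = sel[, 2],
                    x = sel[, 2] - cx, y = cy - sel[, 1],
                    g = G[sel])
  attr(out, "frame_dim") <- dim(frame)
  class(out) <- c("edge_set", "data.frame")
  out
}

#' Bin edge pixels into angular sectors
#'
#' Assigns each edge pixel to one of `n_sectors` equal half-open angular
#' bins `[lo, hi)` measured counterclockwise from the positive x axis
#' about the image center.  The bins partition `[0, 2*pi)`.
#'
#' @param edges An `edge_set`.
#' @param n_sectors Number of sectors (>= 4).
#' @return The edge set with an added integer `sector` column; attributes
#'   `n_sectors` and `empty_sectors` (indices with no pixels).
#' @export
sectorize <- function(edges, n_sectors = 36) {
  stopifnot(n_sectors >= 4)
  width <- 2 * pi / n_sectors
  theta <- atan2(edges$y, edges$x) %% (2 * pi)
  sec <- pmin(floor(theta / width) + 1L, n_sectors)
  edges$sector <- as.integer(sec)
  attr(edges, "n_sectors") <- as.integer(n_sectors)
  attr(edges, "empty_sectors") <- setdiff(seq_len(n_sectors), unique(sec))
  edges
}

#' Angular bounds of the sectors
#'
#' @param n_sectors Number of sectors.
#' @return Data frame with `sector`, `theta_lo`, `theta_hi` (radians).
#' @export
sector_bounds <- function(n_sectors) {
  width <- 2 * pi / n_sectors
  data.frame(sector = seq_len(n_sectors),
             theta_lo = (seq_len(n_sectors) - 1) * width,
             theta_hi = seq_len(n_sectors) * width)
}

#' Per-sector boundary kinematics
#'
#' For each sector and frame, the mean radial distance of the sector's
#' edge pixels (weighted by gradient magnitude, which localizes the
#' boundary at sub-pixel accuracy, and converted to metres) gives the
#' boundary radius; from it the
#' stretch factor (radius over first-frame radius), the radial velocity
#' (centered finite differences over the frame interval; one-sided at the
#' ends) and the kinetic energy per unit area `0.5*rho_m*v^2*H`.
#' Sectors empty in any frame are flagged incomplete and excluded from
#' fitting.
#'
#' @param edge_frames List of sectorized `edge_set`s, one per frame (all
#'   with the same `n_sectors`).
#' @param pixel_size Metres per pixel.
#' @param frame_interval Seconds between frames.
#' @param mem A [membrane_properties()] (for `rho_m`).
#' @param geom A [lesion_geometry()] (for `H`).
#' @return A list of `sector_series` objects: each a list with `sector`,
#'   `theta_lo`, `theta_hi`, `complete` and `data` (data frame with `t`,
#'   `mean_radius`, `stretch`, `radial_velocity`, `ke_per_area`).
#' @export
sector_kinematics <- function(edge_frames, pixel_size, frame_interval,
                              mem = membrane_properties(),
                              geom = lesion_geometry()) {
  n_sectors <- attr(edge_frames[[1]], "n_sectors")
  stopifnot(!is.null(n_sectors))
  n_frames <- length(edge_frames)
  bounds <- sector_bounds(n_sectors)
  t <- (seq_len(n_frames) - 1) * frame_interval
  lapply(seq_len(n_sectors), function(s) {
    radii <- vapply(edge_frames, function(ef) {
      sel <- ef$sector == s
      if (!any(sel)) return(NA_real_)
      w <- ef$g[sel]
      sum(w * sqrt(ef$x[sel]^2 + ef$y[sel]^2)) / sum(w) * pixel_size
    }, numeric(1))
    complete <- !anyNA(radii)
    if (complete) {
      stretch <- radii / radii[1]
      v <- numeric(n_frames)
      v[1] <- (radii[2] - radii[1]) / frame_interval
      v[n_frames] <- (radii[n_frames] - radii[n_frames - 1]) / frame_interval
      if (n_frames > 2) {
        k <- 2:(n_frames - 1)
        v[k] <- (radii[k + 1] - radii[k - 1]) / (2 * frame_interval)
      }
      ke <- 0.5 * mem$rho_m * v^2 * geom$H
    } else {
      stretch <- v <- ke <- rep(NA_real_, n_frames)
    }
    structure(list(sector = s, theta_lo = bounds$theta_lo[s],
                   theta_hi = bounds$theta_hi[s], complete = complete,
                   data = data.frame(t = t, mean_radius = radii,
                                     stretch = stretch,
                                     radial_velocity = v,
                                     ke_per_area = ke)),
              class = "sector_series")
  })
}

#' Fit wall material parameters to a sector's kinematics
#'
#' Damped (Levenberg-Marquardt) least squares of the momentum-balance
#' residual along the observed boundary kinematics.  The observed stretch
#' series (radius over first-frame radius) is smoothed and differentiated
#' with Savitzky-Golay filters; the residual at each retained frame is the
#' difference between the membrane-stress side `2*T_el(lambda)/(lambda*R)`
#' (Taylor stress, parameters `c1`, `c2`, `c3`) and the remaining terms of
#' the balance (inertia, fluid and wall damping, transmural pressure)
#' evaluated from the data.  Sign constraints (`c1 < 0 < c2`, `c3 < 0`)
#' are enforced by a log parameterization.  The optimizer is started from
#' `start` and from the 8 corners of a log-spaced cube around it; the
#' lowest residual wins, with ties broken by log-distance to `start`.
#'
#' Only two combinations of (`c1`, `c2`, `c3`) enter the Taylor stress, so
#' a single trajectory determines the fit up to a one-parameter ridge; the
#' multi-start policy resolves the ridge towards `start`.  The stability
#' verdict is invariant along the ridge, so classification does not depend
#' on this choice.
#'
#' @param series A `sector_series` from [sector_kinematics()].
#' @param geom A [lesion_geometry()]; its `H` is used, while the
#'   undeformed radius is taken from the first observed frame.
#' @param mem A [membrane_properties()].
#' @param fluid A [fluid_properties()].
#' @param bm A [breathing_model()] (or `NULL` for constant baseline
#'   pressure) describing the transmural forcing during acquisition.
#' @param start Starting [material_parameters()] for the optimizer.
#' @param start_spread Multiplicative half-width of the log-spaced start
#'   cube.
#' @param sg_order,sg_window Savitzky-Golay polynomial order and window
#'   (window reduced to fit short series).
#' @param min_frames Minimum usable frames.
#' @return A `sector_fit`: list with `c1`, `c2`, `c3`, `r_squared`, `ssr`,
#'   `status` (`"ok"`, `"degenerate"`, `"incomplete"` or `"failed"`),
#'   `sector`, and `verdict` (`NULL` until classified).
#' @export
fit_material_parameters <- function(series, geom = lesion_geometry(),
                                    mem = membrane_properties(),
                                    fluid = fluid_properties(),
                                    bm = breathing_model(),
                                    start = material_parameters(),
                                    start_spread = 1.5,
                                    sg_order = 3, sg_window = 11,
                                    min_frames = 10) {
  empty <- function(status)
    structure(list(c1 = NA_real_, c2 = NA_real_, c3 = NA_real_,
                   r_squared = NA_real_, ssr = NA_real_, status = status,
                   sector = series$sector, verdict = NULL),
              class = "sector_fit")
  if (!isTRUE(series$complete)) return(empty("incomplete"))
  d <- series$data
  n <- nrow(d)
  if (n < min_frames) return(empty("incomplete"))
  R0 <- d$mean_radius[1]
  lam_raw <- d$mean_radius / R0
  if (stats::sd(lam_raw) < 1e-4) return(empty("degenerate"))

  dt <- d$t[2] - d$t[1]
  w <- min(sg_window, if (n %% 2 == 1) n else n - 1)
  if (w %% 2 == 0) w <- w - 1
  p <- min(sg_order, w - 2)
  lam <- signal::sgolayfilt(lam_raw, p = p, n = w, m = 0)
  lam_d <- signal::sgolayfilt(lam_raw, p = p, n = w, m = 1, ts = dt)
  lam_dd <- signal::sgolayfilt(lam_raw, p = p, n = w, m = 2, ts = dt)
  h <- (w - 1) / 2
  keep <- (h + 1):(n - h)
  lam <- lam[keep]; lam_d <- lam_d[keep]; lam_dd <- lam_dd[keep]
  t_keep <- d$t[keep]

  H <- geom$H; R <- R0
  P <- if (is.null(bm)) rep(mmHg_to_Pa(760), length(t_keep)) else
    mmHg_to_Pa(inner_pressure(t_keep, bm))
  y_obs <- (fluid$rho_f * R^2 * lam + mem$rho_m * H * R / lam^2) * lam_dd +
    1.5 * fluid$rho_f * R^2 * lam_d^2 + 4 * fluid$mu_f * lam_d / lam +
    4 * mem$mu_m * H * lam_d / (R * lam^4) + (P - fluid$p_inf)
  lam2m1 <- lam^2 - 1

  model_fn <- function(par) {
    c1 <- -exp(par[1]); c2 <- exp(par[2]); c3 <- -exp(par[3])
    a1 <- -c1 * H / c2 + c3 * H
    a2 <- -c1 * H / (2 * c2^2) + 3 * c1 * H / (2 * c2) - 2 * c3 * H
    2 * (a1 + a2 * lam2m1) / (lam * R)
  }
  resid_fn <- function(par) model_fn(par) - y_obs

  center <- c(log(-start$c1), log(start$c2), log(-start$c3))
  corners <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))) *
    log(start_spread)
  starts <- rbind(center, sweep(corners, 2, center, `+`))

  fits <- apply(starts, 1, function(p0) {
    f <- tryCatch(minpack.lm::nls.lm(par = p0, fn = resid_fn,
                                     control = minpack.lm::nls.lm.control(
                                       maxiter = 200)),
                  error = function(e) NULL)
    if (is.null(f)) return(NULL)
    list(par = f$par, ssr = sum(f$fvec^2), info = f$info)
  })
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0L) return(empty("failed"))
  ssrs <- vapply(fits, `[[`, numeric(1), "ssr")
  best_ssr <- min(ssrs)
  cand <- which(ssrs <= best_ssr * (1 + 1e-6) + 1e-300)
  if (length(cand) > 1L) {
    dist <- vapply(cand, function(i) sum((fits[[i]]$par - center)^2),
                   numeric(1))
    cand <- cand[which.min(dist)]
  }
  f <- fits[[cand[1]]]
  sst <- sum((y_obs - mean(y_obs))^2)
  structure(list(c1 = -exp(f$par[1]), c2 = exp(f$par[2]),
                 c3 = -exp(f$par[3]),
                 r_squared = 1 - f$ssr / sst, ssr = f$ssr, status = "ok",
                 sector = series$sector, verdict = NULL),
            class = "sector_fit")
}

#' Attach stability verdicts to sector fits
#'
#' Passes each successful fit through [classify_lesion()]; failed,
#' degenerate or incomplete fits are labelled `"indeterminate"`.
#'
#' @param fits List of `sector_fit` objects.
#' @param geom,mem,fluid As in [classify_lesion()].
#' @param P_transmural Mean transmural pressure, Pa.
#' @return The list of fits with `verdict` set to `"stable"`,
#'   `"unstable"` or `"indeterminate"`, and `lambda_eq`/`criterion` fields
#'   added where available.
#' @export
classify_sectors <- function(fits, geom = lesion_geometry(),
                             mem = membrane_properties(),
                             fluid = fluid_properties(),
                             P_transmural = mmHg_to_Pa(760)) {
  lapply(fits, function(f) {
    if (!identical(f$status, "ok")) {
      f$verdict <- "indeterminate"
      return(f)
    }
    v <- tryCatch(
      classify_lesion(material_parameters(f$c1, f$c2, f$c3), geom, mem,
                      fluid, P_transmural),
      error = function(e) NULL)
    if (is.null(v) || identical(v$criterion, "no_equilibrium")) {
      f$verdict <- "indeterminate"
    } else {
      f$verdict <- if (isTRUE(v$is_unstable)) "unstable" else "stable"
      f$lambda_eq <- v$lambda_eq
      f$criterion <- v$criterion
    }
    f
  })
}

#' Summary table of sector fits and verdicts
#'
#' @param fits List of (classified) `sector_fit` objects.
#' @return Data frame with one row per sector.
#' @export
sector_verdict_table <- function(fits) {
  do.call(rbind, lapply(fits, function(f)
    data.frame(sector = f$sector, c1 = f$c1, c2 = f$c2, c3 = f$c3,
               r_squared = f$r_squared, status = f$status,
               verdict = if (is.null(f$verdict)) NA_character_ else f$verdict)))
}

#' Recolor boundary pixels by sector verdict
#'
#' Returns an RGB array equal to the grayscale frame with the edge pixels
#' recolored: green for stable sectors, red for unstable, yellow for
#' indeterminate.  Only edge pixels are modified.
#'
#' @param frame Grayscale frame matrix.
#' @param edges A sectorized `edge_set` for that frame.
#' @param verdicts Character vector of per-sector verdicts (length
#'   `n_sectors`), or a list of classified `sector_fit`s.
#' @return An `nrow x ncol x 3` array in `[0, 1]`, with attribute `legend`.
#' @export
render_overlay <- function(frame, edges, verdicts) {
  if (is.list(verdicts) && !is.character(verdicts))
    verdicts <- vapply(verdicts, `[[`, character(1), "verdict")
  n_sectors <- attr(edges, "n_sectors")
  stopifnot(length(verdicts) == n_sectors)
  cols <- list(stable = c(0, 0.8, 0), unstable = c(0.9, 0, 0),
               indeterminate = c(0.9, 0.9, 0))
  out <- array(rep(frame, 3), c(dim(frame), 3))
  for (i in seq_len(nrow(edges))) {
    v <- verdicts[edges$sector[i]]
    rgb <- cols[[v]]
    if (is.null(rgb)) rgb <- cols$indeterminate
    out[edges$row[i], edges$col[i], ] <- rgb
  }
  attr(out, "legend") <- list(stable = "green", unstable = "red",
                              indeterminate = "yellow")
  out
}

#' Run the full boundary-stability pipeline on an image stack
#'
#' Preprocesses every frame, detects the boundary with the Sobel operator,
#' bins edge pixels into angular sectors, measures per-sector kinematics,
#' fits the wall material parameters per sector and classifies each sector
#' as stable or unstable.
#'
#' @param stack An `image_stack`.
#' @param n_sectors Number of angular sectors.
#' @param threshold_fraction Sobel threshold fraction.
#' @param sigma Preprocessing softening scale, pixels.
#' @param geom,mem,fluid Model parameter blocks.
#' @param bm A [breathing_model()] for the acquisition-time forcing.
#' @param P_transmural Mean transmural pressure for classification, Pa.
#' @param ... Passed to [fit_material_parameters()].
#' @return A list with `edges` (per-frame sectorized edge sets),
#'   `kinematics` (per-sector series), `fits` (classified),
#'   `table` (summary data frame) and `overlay` (RGB array for the first
#'   frame).
#' @export
analyze_stack <- function(stack, n_sectors = 36, threshold_fraction = 0.25,
                          sigma = 1,
                          geom = lesion_geometry(),
                          mem = membrane_properties(),
                          fluid = fluid_properties(),
                          bm = breathing_model(),
                          P_transmural = mmHg_to_Pa(760), ...) {
  edges <- lapply(stack$frames, function(fr)
    sectorize(sobel_edges(preprocess_frame(fr, sigma), threshold_fraction),
              n_sectors))
  kin <- sector_kinematics(edges, stack$pixel_size, stack$frame_interval,
                           mem, geom)
  fits <- lapply(kin, fit_material_parameters, geom = geom, mem = mem,
                 fluid = fluid, bm = bm, ...)
  fits <- classify_sectors(fits, geom, mem, fluid, P_transmural)
  verdicts <- vapply(fits, `[[`, character(1), "verdict")
  list(edges = edges, kinematics = kin, fits = fits,
       table = sector_verdict_table(fits),
       overlay = render_overlay(stack$frames[[1]], edges[[1]], verdicts))
}
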