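#' Generate a synthetic image stack of a deforming lesion boundary
#'
#' Renders grayscale frames of a bright quasi-circular lesion interior on a
#' dark background, with the boundary radius driven by the forward lesion
#' model: each angular region follows `R * lambda(t)` for its own material
#' parameters.  This is a synthetic stand-in for transient CT frames of a
#' deforming tissue boundary; it emulates the geometry and contrast of
#' such data, not its acquisition physics.  Gaussian pixel noise is added
#' in units of 8-bit gray levels.
#'
#' @param mat Default [material_parameters()] for the whole boundary.
#' @param geom A [lesion_geometry()].
#' @param mem,fluid,bm Remaining forward-model blocks.
#' @param n_frames Number of frames (>= 2).
#' @param frame_interval Time between frames, s.  The default resolves the
#'   membrane's natural oscillation (period of a few milliseconds for the
#'   default parameters).
#' @param pixel_size Physical size of a pixel, m.
#' @param n_px Frame side length, pixels (square frames).
#' @param noise_sd Gaussian pixel noise standard deviation, in 8-bit gray
#'   levels (1 gray level = 1/255 of full scale).
#' @param seed Integer seed fixing all randomness of the stack.
#' @param sector_overrides Optional list of `list(theta_lo, theta_hi, mat)`
#'   entries assigning different material parameters to angular ranges
#'   (radians in `[0, 2*pi)`, half-open `[lo, hi)`).
#' @param ic Initial `c(y0, y1)` for the forward trajectories.
#' @param interior,exterior Interior and exterior intensities in `[0, 1]`.
#' @param edge_softness Width of the rendered boundary transition, pixels.
#' @return An object of class `image_stack`: list with `frames` (list of
#'   `n_px` x `n_px` matrices in `[0, 1]`), `pixel_size`, `frame_interval`,
#'   and a `meta` list recording the generating trajectories and angular
#'   material map.
#' @export
generate_fixture_frames <- function(mat = material_parameters(),
                                    geom = lesion_geometry(),
                                    mem = membrane_properties(),
                                    fluid = fluid_properties(),
                                    bm = breathing_model(),
                                    n_frames = 64, frame_interval = 2e-5,
                                    pixel_size = 1e-4, n_px = 384,
                                    noise_sd = 0, seed = 1,
                                    sector_overrides = NULL,
                                    ic = c(1, 0),
                                    interior = 0.9, exterior = 0.1,
                                    edge_softness = 1) {
  stopifnot(n_frames >= 2, frame_interval > 0, pixel_size > 0, n_px >= 32,
            noise_sd >= 0)
  set.seed(as.integer(seed))
  tc <- time_scale(geom, mem, mat)
  t_frames <- (seq_len(n_frames) - 1) * frame_interval

  # forward trajectories, one per distinct material group
  mats <- list(mat)
  if (!is.null(sector_overrides)) {
    for (ov in sector_overrides) {
      stopifnot(is.numeric(ov$theta_lo), is.numeric(ov$theta_hi),
                inherits(ov$mat, "material_parameters"))
      mats <- c(mats, list(ov$mat))
    }
  }
  lam_of_t <- lapply(mats, function(m) {
    tci <- time_scale(geom, mem, m)
    tau_end <- max(t_frames) / tci * 1.001 + 1e-9
    traj <- simulate_lesion(m, geom, mem, fluid, bm, ic = ic,
                            tau_end = tau_end, dt = 1e-3)
    if (attr(traj, "nonphysical") || nrow(traj) < 2)
      stop("generate_fixture_frames: forward trajectory left the physical range within the imaging window; shorten the stack")
    stats::approx(traj$tau * tci, traj$y0, xout = t_frames)$y
  })
  if (anyNA(unlist(lam_of_t)))
    stop("generate_fixture_frames: forward trajectory shorter than the imaging window")

  # angular material map: group 1 everywhere, overridden on given ranges
  cx <- (n_px + 1) / 2
  xs <- matrix(rep(seq_len(n_px) - cx, each = n_px), n_px)      # x right
  ys <- matrix(rep(cx - seq_len(n_px), times = n_px), n_px)     # y up
  rho <- sqrt(xs^2 + ys^2)
  theta <- atan2(ys, xs) %% (2 * pi)
  group <- matrix(1L, n_px, n_px)
  if (!is.null(sector_overrides)) {
    for (i in seq_along(sector_overrides)) {
      ov <- sector_overrides[[i]]
      sel <- theta >= ov$theta_lo & theta < ov$theta_hi
      group[sel] <- i + 1L
    }
  }

  R_px <- geom$R / pixel_size
  frames <- vector("list", n_frames)
  for (k in seq_len(n_frames)) {
    r_b <- matrix(R_px * vapply(seq_along(mats),
                                function(g) lam_of_t[[g]][k], numeric(1))[group],
                  n_px, n_px)
    if (max(r_b) > n_px / 2 - 2)
      stop("generate_fixture_frames: boundary radius exceeds the frame")
    img <- exterior + (interior - exterior) /
      (1 + exp(-(r_b - rho) / edge_softness))
    if (noise_sd > 0)
      img <- img + matrix(stats::rnorm(n_px * n_px, 0, noise_sd / 255), n_px)
    frames[[k]] <- pmin(pmax(img, 0), 1)
  }

  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_interval = frame_interval,
                 meta = list(lambda = lam_of_t, t = t_frames, group = mats,
                             sector_overrides = sector_overrides,
                             breathing = bm, geom = geom, mem = mem,
                             fluid = fluid, ic = ic, seed = seed)),
            class = "image_stack")
}

#' Write an image stack to PNG frames with a JSON sidecar
#'
#' Frames are written as `frame_%03d.png` plus `stack.json` holding
#' `pixel_size_m` and `frame_interval_s`.  Requires the `png` package.
#'
#' @param stack An `image_stack`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
write_image_stack <- function(stack, dir) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("write_image_stack requires the 'png' package")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_along(stack$frames))
    png::writePNG(stack$frames[[k]],
                  file.path(dir, sprintf("frame_%03d.png", k)))
  jsonlite::write_json(list(pixel_size_m = stack$pixel_size,
                            frame_interval_s = stack$frame_interval),
                       file.path(dir, "stack.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read an image stack from a directory of PNG frames
#'
#' Expects the layout written by [write_image_stack()]: ordered PNG frames
#' and a `stack.json` sidecar with `pixel_size_m` and `frame_interval_s`.
#'
#' @param dir Directory containing the frames.
#' @return An `image_stack`.
#' @export
read_image_stack <- function(dir) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("read_image_stack requires the 'png' package")
  meta <- jsonlite::read_json(file.path(dir, "stack.json"))
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) < 2) stop("read_image_stack: need at least 2 frames")
  frames <- lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3L) img <- img[, , 1]  # grayscale channel
    img
  })
  structure(list(frames = frames, pixel_size = meta$pixel_size_m,
                 frame_interval = meta$frame_interval_s, meta = list()),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("Image stack: %d frames of %dx%d px, pixel %.3g m, interval %.3g s\n",
              length(x$frames), d[1], d[2], x$pixel_size, x$frame_interval))
  invisible(x)
}
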