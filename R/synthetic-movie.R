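#' Configuration for the synthetic wound-healing movie generator
#'
#' Produces a textured monolayer advected toward a cell-free wound by a
#' known velocity field `v(d) = v0 * exp(-d / lambda)`, where `d` is the
#' distance (um) from the current wound edge into the monolayer.
#' `lambda_um = Inf` gives a uniform field of speed `v0_umh`. The wound
#' occupies the top `wound_fraction` of the image and is flat (low texture
#' variance) apart from the additive per-frame noise; the monolayer carries
#' a smooth random texture of spatial scale `texture_grain_px`.
#'
#' @param height_px,width_px frame size in pixels.
#' @param pixel_um microns per pixel.
#' @param n_frames number of frames.
#' @param dt_min minutes per frame.
#' @param v0_umh edge speed of the ground-truth field, um/h.
#' @param lambda_um decay length of the field, um (Inf = uniform).
#' @param texture_grain_px Gaussian smoothing scale of the monolayer texture.
#' @param noise_sd additive intensity noise SD (intensities are in [0, 1]).
#' @param wound_fraction fraction of the image height that is cell-free.
#' @param seed integer seed.
#' @return an object of class `movie_sim_config`.
#' @export
movie_sim_config <- function(height_px = 256, width_px = 128,
                             pixel_um = 0.7422, n_frames = 10, dt_min = 10,
                             v0_umh = 20, lambda_um = 50,
                             texture_grain_px = 2, noise_sd = 0.02,
                             wound_fraction = 0.3, seed = 1L) {
  if (wound_fraction < 0 || wound_fraction >= 1)
    stop("wound_fraction must be in [0, 1)", call. = FALSE)
  if (lambda_um <= 0) stop("lambda_um must be positive (Inf allowed)", call. = FALSE)
  structure(list(height_px = as.integer(height_px),
                 width_px = as.integer(width_px), pixel_um = pixel_um,
                 n_frames = as.integer(n_frames), dt_min = dt_min,
                 v0_umh = v0_umh, lambda_um = lambda_um,
                 texture_grain_px = texture_grain_px, noise_sd = noise_sd,
                 wound_fraction = wound_fraction, seed = as.integer(seed)),
            class = "movie_sim_config")
}

# separable Gaussian smoothing of a matrix (reflective boundary)
gauss_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma); k <- k / sum(k)
  pad_apply <- function(x) {  # smooth each column of x with kernel k
    n <- nrow(x)
    xp <- rbind(x[r:1, , drop = FALSE], x, x[n:(n - r + 1), , drop = FALSE])
    out <- matrix(0, n, ncol(x))
    for (i in seq_along(k))
      out <- out + k[i] * xp[i:(i + n - 1), , drop = FALSE]
    out
  }
  t(pad_apply(t(pad_apply(m))))
}

# ground-truth speed (px/frame) at signed distance d_um from the wound edge
field_speed_px <- function(cfg, d_um) {
  v_umh <- if (is.finite(cfg$lambda_um))
    cfg$v0_umh * exp(-pmax(d_um, 0) / cfg$lambda_um) else cfg$v0_umh
  v_umh / cfg$pixel_um * cfg$dt_min / 60
}

#' Generate a synthetic wound-healing movie with known velocity field
#'
#' Frame `k + 1` is frame `k` backward-warped by the ground-truth
#' displacement field (bilinear interpolation, motion toward the wound at
#' the top of the image), plus freshly drawn additive noise; the wound edge
#' advances each frame at the edge-adjacent speed `v(0) = v0`. The returned
#' ground truth carries the per-frame edge row and a displacement lookup.
#'
#' @param cfg a [movie_sim_config()].
#' @return list with `stack` (list of height x width matrices, values in
#'   [0, 1]), and `truth`: `edge_row_px` (wound/monolayer boundary row per
#'   frame, 0 = image top), `v_px` function(frame, y_px) giving the signed
#'   y-displacement (px/frame, negative = toward the wound), and the config.
#' @export
gen_movie <- function(cfg) {
  stopifnot(inherits(cfg, "movie_sim_config"))
  set.seed(cfg$seed)
  H <- cfg$height_px; Wd <- cfg$width_px
  if (field_speed_px(cfg, 0) > 16)
    warning("per-frame displacement exceeds 16 px; PIV at 32-px windows will alias")
  edge0 <- cfg$wound_fraction * H  # boundary row (px from top, 0-based)
  tex <- gauss_smooth(matrix(stats::rnorm(H * Wd), H, Wd), cfg$texture_grain_px)
  tex <- 0.5 + 0.35 * tex / max(stats::sd(tex), 1e-12)
  tex <- pmin(pmax(tex, 0), 1)
  clean <- tex
  if (edge0 >= 1) clean[1:floor(edge0), ] <- 0.5
  edge <- numeric(cfg$n_frames); edge[1] <- edge0
  stack <- vector("list", cfg$n_frames)
  add_noise <- function(m) {
    if (cfg$noise_sd > 0)
      m <- m + matrix(stats::rnorm(length(m), 0, cfg$noise_sd), nrow(m))
    pmin(pmax(m, 0), 1)
  }
  stack[[1]] <- add_noise(clean)
  ys <- seq_len(H)
  for (k in seq_len(cfg$n_frames - 1)) {
    d_um <- (ys - 1 - edge[k]) * cfg$pixel_um
    s <- field_speed_px(cfg, d_um)       # px/frame, applied as motion in -y
    src <- pmin(pmax(ys + s, 1), H)      # backward warp, clamped at borders
    lo <- floor(src); hi <- pmin(lo + 1, H); w <- src - lo
    clean <- clean[lo, , drop = FALSE] * (1 - w) +
      clean[hi, , drop = FALSE] * w
    edge[k + 1] <- edge[k] - field_speed_px(cfg, 0)
    stack[[k + 1]] <- add_noise(clean)
  }
  truth <- list(edge_row_px = edge,
                v0_umh = cfg$v0_umh, lambda_um = cfg$lambda_um,
                edge_speed_px_frame = field_speed_px(cfg, 0),
                v_px = function(frame, y_px) {
                  d_um <- (y_px - edge[frame]) * cfg$pixel_um
                  -field_speed_px(cfg, d_um)
                },
                cfg = cfg)
  list(stack = stack, truth = truth)
}

#' Write an image stack as a multi-page 16-bit grayscale TIFF
#'
#' @param stack list of numeric matrices with values in [0, 1].
#' @param path output file.
#' @export
write_movie_tiff <- function(stack, path) {
  tiff::writeTIFF(stack, path, bits.per.sample = 16)
  invisible(path)
}

#' Read a multi-page grayscale TIFF as a list of matrices
#'
#' @param path TIFF file.
#' @return list of numeric matrices, values in [0, 1].
#' @export
read_movie_tiff <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE)
  lapply(frames, function(f) if (length(dim(f)) == 3) f[, , 1] else f)
}
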