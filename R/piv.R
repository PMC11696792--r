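#' PIV configuration
#'
#' Settings for windowed cross-correlation between consecutive frames:
#' 32-px interrogation windows with 0.75 overlap (grid step 8 px), global
#' amplitude filtering at mean +/- 3 SD, and a 4-frame trailing temporal
#' average -- the standard wound-healing monolayer settings.
#'
#' @param window_px interrogation window edge in pixels (power of two
#'   preferred for the FFT).
#' @param overlap window overlap fraction in `[0, 1)`.
#' @param pixel_um microns per pixel.
#' @param dt_min minutes per frame.
#' @param time_avg_frames length of the trailing temporal averaging window.
#' @param outlier_k SD multiplier for the amplitude filter.
#' @param search_px correlation-peak search radius in px; defaults to
#'   `window_px / 4` (the one-quarter rule: displacements beyond a quarter
#'   window are unreliable at a fixed single-pass window).
#' @return an object of class `piv_config`.
#' @export
piv_config <- function(window_px = 32, overlap = 0.75, pixel_um = 0.7422,
                       dt_min = 10, time_avg_frames = 4, outlier_k = 3,
                       search_px = NULL) {
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)", call. = FALSE)
  step <- window_px * (1 - overlap)
  if (step < 1) stop("grid step window*(1-overlap) must be >= 1 px", call. = FALSE)
  if (is.null(search_px)) search_px <- window_px %/% 4
  if (search_px < 1 || search_px > window_px %/% 2)
    stop("search_px must be in [1, window_px/2]", call. = FALSE)
  structure(list(window_px = as.integer(window_px), overlap = overlap,
                 pixel_um = pixel_um, dt_min = dt_min,
                 time_avg_frames = as.integer(time_avg_frames),
                 outlier_k = outlier_k, step_px = as.integer(round(step)),
                 search_px = as.integer(search_px)),
            class = "piv_config")
}

# wrap FFT correlation-plane index (1-based, length n) to a signed shift
wrap_shift <- function(idx, n) ifelse(idx - 1 > n / 2, idx - 1 - n, idx - 1)

# linear (zero-padded) cross-covariance of two equal W x W windows,
# normalized by the per-shift overlap count so the estimator carries no
# loss-of-pairs pull toward zero; returned restricted to |shift| <= h
xcorr_plane <- function(a, b, h) {
  W <- nrow(a)
  a <- a - mean(a); b <- b - mean(b)
  n2 <- 2L * W
  ap <- bp <- matrix(0, n2, n2)
  ap[1:W, 1:W] <- a; bp[1:W, 1:W] <- b
  cc <- Re(stats::fft(Conj(stats::fft(ap)) * stats::fft(bp),
                      inverse = TRUE)) / (n2 * n2)
  sh <- -h:h
  idx <- ((sh %% n2) + 1L)            # wrap signed shift to plane index
  plane <- cc[idx, idx]
  ov <- W - abs(sh)                   # overlap count per axis
  list(plane = plane / outer(ov, ov), shifts = sh)
}

# subpixel offset from three points around a 1-D correlation peak:
# Gaussian estimator, falling back to parabolic when a value is <= 0
subpixel_offset <- function(rm, r0, rp) {
  if (rm > 0 && r0 > 0 && rp > 0) {
    den <- 2 * log(rm) - 4 * log(r0) + 2 * log(rp)
    if (abs(den) > 1e-12) return((log(rm) - log(rp)) / den)
  }
  den <- 2 * (rm - 2 * r0 + rp)
  if (abs(den) > 1e-12) (rm - rp) / den else 0
}

#' Displacement field between one frame pair by FFT cross-correlation
#'
#' Tiles both frames with `window_px` windows on a regular grid (step
#' `window_px * (1 - overlap)`), mean-subtracts each window and locates the
#' cross-correlation peak, refined to subpixel precision by a 3-point
#' Gaussian fit in x and y. Windows overhanging the frame are dropped.
#' `peak_quality` is the ratio of the highest to the second-highest
#' correlation peak (the 3x3 neighbourhood of the main peak excluded).
#' Flat (zero-variance) windows are flagged invalid rather than propagating
#' NaN. Coordinates are image coordinates: origin top-left, x along
#' columns, y along rows increasing downward; displacements are px/frame of
#' pattern motion from `frame_a` to `frame_b`.
#'
#' @param frame_a,frame_b equal-sized numeric matrices (rows = y).
#' @param cfg a [piv_config()].
#' @return a `vector_field`: list with `grid_x`, `grid_y` (window centres,
#'   px), matrices `u`, `v` (px/frame), `peak_q`, `valid`, plus the config.
#' @export
piv_pair <- function(frame_a, frame_b, cfg) {
  stopifnot(is.matrix(frame_a), is.matrix(frame_b),
            all(dim(frame_a) == dim(frame_b)))
  W <- cfg$window_px
  if (any(dim(frame_a) < W)) stop("frame smaller than window", call. = FALSE)
  step <- cfg$step_px
  ny_px <- nrow(frame_a); nx_px <- ncol(frame_a)
  x0 <- seq(1, nx_px - W + 1, by = step)
  y0 <- seq(1, ny_px - W + 1, by = step)
  u <- v <- pq <- matrix(NA_real_, length(y0), length(x0))
  valid <- matrix(FALSE, length(y0), length(x0))
  half <- W / 2
  for (iy in seq_along(y0)) {
    ys <- y0[iy]:(y0[iy] + W - 1)
    for (ix in seq_along(x0)) {
      xs <- x0[ix]:(x0[ix] + W - 1)
      wa <- frame_a[ys, xs]; wb <- frame_b[ys, xs]
      if (stats::var(as.vector(wa)) == 0 || stats::var(as.vector(wb)) == 0) next
      xc <- xcorr_plane(wa, wb, cfg$search_px)
      cc <- xc$plane; sh <- xc$shifts; np <- length(sh)
      pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
      py <- pk[1]; px <- pk[2]
      # second peak outside the 3x3 neighbourhood of the main peak
      nb_y <- intersect(1:np, (py - 1):(py + 1))
      nb_x <- intersect(1:np, (px - 1):(px + 1))
      cc2 <- cc; cc2[nb_y, nb_x] <- -Inf
      second <- max(cc2)
      pq[iy, ix] <- if (second > 0) max(cc) / second else Inf
      # subpixel refinement; peaks at the search border get no refinement
      ofy <- if (py > 1 && py < np)
        subpixel_offset(cc[py - 1, px], cc[py, px], cc[py + 1, px]) else 0
      ofx <- if (px > 1 && px < np)
        subpixel_offset(cc[py, px - 1], cc[py, px], cc[py, px + 1]) else 0
      dy <- sh[py] + ofy
      dx <- sh[px] + ofx
      u[iy, ix] <- dx; v[iy, ix] <- dy
      valid[iy, ix] <- abs(dx) <= half && abs(dy) <= half &&
        py > 1 && py < np && px > 1 && px < np
    }
  }
  structure(list(grid_x = x0 + (W - 1) / 2, grid_y = y0 + (W - 1) / 2,
                 u = u, v = v, peak_q = pq, valid = valid,
                 window_px = W, pixel_um = cfg$pixel_um, dt_min = cfg$dt_min),
            class = "vector_field")
}

# distance-weighted mean of valid 8-neighbours, iterated until all invalid
# vectors are filled (or no progress is possible)
fill_invalid <- function(u, v, valid) {
  ny <- nrow(u); nx <- ncol(u)
  offs <- expand.grid(dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dy == 0 & offs$dx == 0), ]
  wts <- 1 / sqrt(offs$dy^2 + offs$dx^2)
  repeat {
    todo <- which(!valid, arr.ind = TRUE)
    if (nrow(todo) == 0) break
    progress <- FALSE
    u_new <- u; v_new <- v; valid_new <- valid
    for (r in seq_len(nrow(todo))) {
      iy <- todo[r, 1]; ix <- todo[r, 2]
      sw <- su <- sv <- 0
      for (k in seq_len(nrow(offs))) {
        jy <- iy + offs$dy[k]; jx <- ix + offs$dx[k]
        if (jy >= 1 && jy <= ny && jx >= 1 && jx <= nx && valid[jy, jx]) {
          sw <- sw + wts[k]
          su <- su + wts[k] * u[jy, jx]
          sv <- sv + wts[k] * v[jy, jx]
        }
      }
      if (sw > 0) {
        u_new[iy, ix] <- su / sw; v_new[iy, ix] <- sv / sw
        valid_new[iy, ix] <- TRUE
        progress <- TRUE
      }
    }
    u <- u_new; v <- v_new; valid <- valid_new
    if (!progress) break
  }
  list(u = u, v = v, valid = valid)
}

#' Filter spurious vectors on amplitude and fill by neighbour interpolation
#'
#' Vectors whose magnitude falls outside mean +/- `outlier_k` SD of the
#' field's valid magnitudes are marked spurious; spurious and otherwise
#' invalid vectors are replaced by the distance-weighted mean of their valid
#' 8-neighbourhood, iterating outward until the field is filled. Vectors
#' that pass the filter are never modified.
#'
#' @param field a `vector_field` from [piv_pair()].
#' @param cfg a [piv_config()].
#' @return the filtered and filled `vector_field`; `filled` marks replaced
#'   vectors.
#' @export
validate_and_fill <- function(field, cfg) {
  mag <- sqrt(field$u^2 + field$v^2)
  m <- mean(mag[field$valid]); s <- stats::sd(mag[field$valid])
  keep <- field$valid
  if (is.finite(s) && s > 0)
    keep <- keep & (mag >= m - cfg$outlier_k * s) & (mag <= m + cfg$outlier_k * s)
  if (mean(keep) < 0.5) stop("field unusable: >50% invalid vectors", call. = FALSE)
  fl <- fill_invalid(field$u, field$v, keep)
  out <- field
  out$u <- fl$u; out$v <- fl$v; out$valid <- fl$valid
  out$filled <- fl$valid & !keep
  out
}

#' Trailing temporal average of a sequence of vector fields
#'
#' Output field `t` is the arithmetic mean of input fields
#' `t .. t + time_avg_frames - 1` on their common grid (the sequence
#' shortens by `time_avg_frames - 1`). A window's output vector is valid
#' only where all contributors are valid; remaining holes are refilled by
#' neighbour interpolation.
#'
#' @param fields list of `vector_field` objects on one grid, in time order.
#' @param cfg a [piv_config()].
#' @return list of averaged `vector_field` objects.
#' @export
smooth_time <- function(fields, cfg) {
  w <- cfg$time_avg_frames
  if (length(fields) < w) stop("need at least time_avg_frames fields", call. = FALSE)
  g <- fields[[1]]
  for (f in fields)
    if (!identical(f$grid_x, g$grid_x) || !identical(f$grid_y, g$grid_y))
      stop("grid mismatch between fields", call. = FALSE)
  out <- vector("list", length(fields) - w + 1)
  for (t in seq_along(out)) {
    us <- lapply(fields[t:(t + w - 1)], `[[`, "u")
    vs <- lapply(fields[t:(t + w - 1)], `[[`, "v")
    vals <- lapply(fields[t:(t + w - 1)], `[[`, "valid")
    fo <- fields[[t]]
    fo$u <- Reduce(`+`, us) / w
    fo$v <- Reduce(`+`, vs) / w
    fo$valid <- Reduce(`&`, vals)
    if (any(!fo$valid)) {
      fl <- fill_invalid(fo$u, fo$v, fo$valid)
      fo$u <- fl$u; fo$v <- fl$v; fo$valid <- fl$valid
    }
    fo$peak_q <- NULL
    out[[t]] <- fo
  }
  out
}

#' Convert a displacement field to velocities in um/h
#'
#' @param field a `vector_field` with `u`, `v` in px/frame.
#' @param cfg a [piv_config()] supplying `pixel_um` and `dt_min`.
#' @return the field with `u_umh`, `v_umh`, `speed_umh` added.
#' @export
to_velocity <- function(field, cfg) {
  k <- cfg$pixel_um * 60 / cfg$dt_min
  field$u_umh <- field$u * k
  field$v_umh <- field$v * k
  field$speed_umh <- sqrt(field$u_umh^2 + field$v_umh^2)
  field
}

#' Run the full PIV chain on an image stack
#'
#' [piv_pair()] on consecutive pairs, [validate_and_fill()], then
#' [smooth_time()] and [to_velocity()].
#'
#' @param stack list of frames (numeric matrices) in time order.
#' @param cfg a [piv_config()].
#' @return list of validated, time-averaged velocity fields.
#' @export
piv_movie <- function(stack, cfg) {
  fields <- vector("list", length(stack) - 1)
  for (t in seq_along(fields)) {
    f <- piv_pair(stack[[t]], stack[[t + 1]], cfg)
    fields[[t]] <- validate_and_fill(f, cfg)
  }
  sm <- smooth_time(fields, cfg)
  lapply(sm, to_velocity, cfg = cfg)
}
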