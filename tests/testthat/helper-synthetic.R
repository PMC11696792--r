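# shared fixtures built in code

# smooth random texture (rows = y); grain ~ Gaussian sigma in px
mk_texture <- function(h, w, grain = 2, seed = 2) {
  set.seed(seed)
  m <- matrix(rnorm(h * w), h, w)
  r <- max(1L, ceiling(3 * grain))
  k <- dnorm(-r:r, sd = grain); k <- k / sum(k)
  smooth1 <- function(x) {
    n <- nrow(x)
    xp <- rbind(x[r:1, , drop = FALSE], x, x[n:(n - r + 1), , drop = FALSE])
    out <- matrix(0, n, ncol(x))
    for (i in seq_along(k)) out <- out + k[i] * xp[i:(i + n - 1), , drop = FALSE]
    out
  }
  t(smooth1(t(smooth1(m))))
}

# exact subpixel translation by Fourier phase shift (periodic)
fourier_shift <- function(m, dx, dy) {
  h <- nrow(m); w <- ncol(m)
  kx <- c(0:(w / 2), (-w / 2 + 1):-1)
  ky <- c(0:(h / 2), (-h / 2 + 1):-1)
  ph <- exp(-2i * pi * (outer(ky * dy / h, rep(1, w)) +
                          outer(rep(1, h), kx * dx / w)))
  Re(fft(fft(m) * ph, inverse = TRUE)) / length(m)
}

# track object from a coordinate matrix (t in minutes)
mk_track <- function(xy, dt_min = 10, cell_id = 1) {
  n <- nrow(xy)
  list(cell_id = cell_id, dt_min = dt_min,
       points = cbind(t_min = seq(0, by = dt_min, length.out = n),
                      x_um = xy[, 1], y_um = xy[, 2]))
}

# uniform vector field on a small grid
mk_field <- function(u, v, nx = 6, ny = 6, valid = TRUE) {
  structure(list(grid_x = seq(16, by = 8, length.out = nx),
                 grid_y = seq(16, by = 8, length.out = ny),
                 u = matrix(u, ny, nx), v = matrix(v, ny, nx),
                 peak_q = matrix(2, ny, nx),
                 valid = matrix(valid, ny, nx),
                 window_px = 32L, pixel_um = 1, dt_min = 10),
            class = "vector_field")
}
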