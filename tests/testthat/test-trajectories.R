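test_that("track CSV round-trips and malformed input is reported", {
  cfg <- track_sim_config(n_cells = 2, duration_min = 30, dt_min = 10, seed = 1)
  sim <- gen_tracks(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracks(sim$tracks, path)
  trks <- read_tracks(path)
  expect_length(trks, 2)
  expect_equal(nrow(trks[[1]]$points), 4)
  # empty file with header
  writeLines("cell_id,frame,t_min,x_um,y_um", path)
  expect_length(read_tracks(path), 0)
  # duplicated (cell, frame)
  writeLines(c("cell_id,frame,t_min,x_um,y_um",
               "1,0,0,0,0", "1,0,0,1,1"), path)
  expect_error(read_tracks(path), "duplicated")
  # non-uniform dt
  writeLines(c("cell_id,frame,t_min,x_um,y_um",
               "7,0,0,0,0", "7,1,10,1,1", "7,2,25,2,2"), path)
  expect_error(read_tracks(path), "cell 7")
})

test_that("cell speed is the mean step displacement over dt", {
  expect_equal(cell_speed(mk_track(rbind(c(0, 0), c(10, 0)))), 1)
  expect_equal(cell_speed(mk_track(rbind(c(5, 5), c(5, 5), c(5, 5)))), 0)
  xy <- rbind(c(0, 0), c(3, 0), c(7, 0), c(12, 0))  # steps 3, 4, 5 um
  expect_equal(cell_speed(mk_track(xy)), 0.4)
  expect_error(cell_speed(mk_track(rbind(c(0, 0)))), "2 points")
})

test_that("direction autocorrelation matches enumerated cosines", {
  straight <- mk_track(cbind(0:10 * 2, 0))
  cv <- direction_autocorrelation(straight)
  expect_equal(cv$values, rep(1, length(cv$values)))
  expect_equal(cv$values[1], 1)  # lag 0
  # steps E, N, E, N
  zig <- mk_track(rbind(c(0, 0), c(1, 0), c(1, 1), c(2, 1), c(2, 2)))
  cz <- direction_autocorrelation(zig, max_lag_steps = 2)
  expect_equal(cz$values, c(1, 0, 1))
  expect_equal(cz$n_pairs, c(4L, 3L, 2L))
  # single reversal
  rev2 <- mk_track(rbind(c(0, 0), c(1, 0), c(0, 0), c(1, 0)))
  expect_equal(direction_autocorrelation(rev2, max_lag_steps = 1)$values[2], -1)
  # degenerate
  still <- mk_track(rbind(c(0, 0), c(0, 0), c(0, 0), c(0, 0)))
  expect_error(direction_autocorrelation(still), "degenerate")
})

test_that("zero-length steps are dropped from cosine pairs, not zero-angled", {
  xy <- rbind(c(0, 0), c(1, 0), c(1, 0), c(2, 0), c(3, 0))  # step 2 is null
  cv <- direction_autocorrelation(mk_track(xy), max_lag_steps = 1)
  expect_equal(cv$n_pairs[1], 3L)   # lag 0: three nonzero steps
  expect_equal(cv$n_pairs[2], 1L)   # lag 1: only steps (3,4) both nonzero
  expect_equal(cv$values[2], 1)
})

test_that("autocorrelation is invariant under rotation and translation", {
  cfg <- track_sim_config(n_cells = 1, duration_min = 200, seed = 9)
  tr <- split_tracks(gen_tracks(cfg)$tracks)[[1]]
  base <- direction_autocorrelation(tr)
  set.seed(31)
  for (i in 1:5) {
    th <- runif(1, 0, 2 * pi); sh <- runif(2, -50, 50)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    xy <- t(R %*% t(tr$points[, c("x_um", "y_um")])) +
      matrix(sh, nrow(tr$points), 2, byrow = TRUE)
    rot <- direction_autocorrelation(mk_track(xy, dt_min = tr$dt_min))
    expect_equal(rot$values, base$values, tolerance = 1e-9)
  }
})

test_that("noiseless model curves are recovered to 1e-6 relative", {
  t <- seq(0, 180, 10)
  for (pars in list(c(50, 0.4), c(20, 0), c(120, -0.3))) {
    y <- (1 - pars[2]) * exp(-t / pars[1]) + pars[2]
    f <- fit_persistence(list(lags_min = t, values = y))
    expect_true(f$converged)
    expect_lt(abs(f$a - pars[1]) / pars[1], 1e-6)
    expect_lt(abs(f$b - pars[2]), 1e-6 * max(abs(pars[2]), 1))
  }
})

test_that("constant curve at 1 is reported as the plateau-only limit", {
  f <- fit_persistence(list(lags_min = seq(0, 100, 10), values = rep(1, 11)))
  expect_true(f$converged)
  expect_equal(f$b, 1)
  expect_identical(f$a, Inf)
})

test_that("grid-search oracle agrees with the nonlinear fitter", {
  t <- seq(0, 190, 10)
  set.seed(12)
  for (i in 1:10) {
    a_true <- runif(1, 20, 150); b_true <- runif(1, -0.5, 0.8)
    y <- (1 - b_true) * exp(-t / a_true) + b_true
    f <- fit_persistence(list(lags_min = t, values = y))
    g <- persistence_grid_fit(list(lags_min = t, values = y),
                              a_range = a_true * c(0.95, 1.05),
                              b_range = pmax(pmin(b_true + c(-0.05, 0.05), 1), -1),
                              n_a = 101, n_b = 101)
    expect_lt(abs(f$a - g$a), g$a_step + 1e-9)
    expect_lt(abs(f$b - g$b), g$b_step + 1e-9)
  }
})

test_that("median fitted decay constant recovers tau on simulated cohorts", {
  cfg <- track_sim_config(n_cells = 60, duration_min = 390, dt_min = 10,
                          tau_min = 60, bias = 0, seed = 21)
  trks <- split_tracks(gen_tracks(cfg)$tracks)
  fits <- fit_cohort(trks)
  expect_lt(abs(median(fits$a_min) - 60) / 60, 0.30)  # single noisy cohort
  coh <- fit_cohort(trks, method = "mean_curve")
  expect_lt(abs(coh$a_min - 60) / 60, 0.25)
  expect_lt(abs(coh$b), 0.1)
})

test_that("identical groups compare as null; labels swap symmetrically", {
  cfg <- track_sim_config(n_cells = 12, duration_min = 390, seed = 33)
  fits <- fit_cohort(split_tracks(gen_tracks(cfg)$tracks))
  same <- compare_persistence(fits, fits, n_boot = 500, seed = 7)
  expect_equal(same$effect_b, 0)
  expect_equal(same$p_b, 1)
  cfg2 <- track_sim_config(n_cells = 12, duration_min = 390, bias = 0.5,
                           seed = 34)
  fits2 <- fit_cohort(split_tracks(gen_tracks(cfg2)$tracks))
  ab <- compare_persistence(fits, fits2, n_boot = 2000, seed = 7)
  ba <- compare_persistence(fits2, fits, n_boot = 2000, seed = 7)
  expect_equal(ab$p_b, ba$p_b)
  expect_equal(ab$effect_b, -ba$effect_b)
})

test_that("bias 0 vs 0.5 cohorts separate at alpha = 0.05", {
  # plateau difference is large (~0.4); modest repetition count keeps the
  # suite fast while still checking power
  n_sig <- 0
  for (r in 1:5) {
    f0 <- fit_cohort(split_tracks(gen_tracks(
      track_sim_config(n_cells = 30, duration_min = 390, bias = 0,
                       seed = 100 + r))$tracks))
    f5 <- fit_cohort(split_tracks(gen_tracks(
      track_sim_config(n_cells = 30, duration_min = 390, bias = 0.5,
                       seed = 200 + r))$tracks))
    cmp <- compare_persistence(f0, f5, n_boot = 2000, seed = r)
    if (cmp$p_b < 0.05) n_sig <- n_sig + 1
  }
  expect_equal(n_sig, 5)
})
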