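test_that("wound segmentation recovers the cell-free fraction", {
  cfg <- movie_sim_config(height_px = 200, width_px = 100, pixel_um = 1,
                          n_frames = 2, v0_umh = 0, lambda_um = Inf,
                          noise_sd = 0.01, wound_fraction = 0.4, seed = 8)
  mv <- gen_movie(cfg)
  mask <- segment_wound(mv$stack[[1]], "top")
  expect_lt(abs(sum(mask) / length(mask) - 0.4), 0.04)
})

test_that("fully textured frames raise a wound-not-found error", {
  A <- mk_texture(96, 96, seed = 9)
  expect_error(segment_wound(A, "top"), "wound not found")
})

test_that("a noiseless half-blank frame segments along the boundary", {
  A <- mk_texture(120, 60, seed = 10)
  A[1:60, ] <- 0.5
  mask <- segment_wound(A, "top", disk_radius_px = 8)
  # exact away from the disk-radius mixing zone around the boundary
  expect_true(all(mask[1:52, ]))
  expect_true(all(!mask[69:120, ]))
})

test_that("edge progression tracks planted edge motion", {
  # static wound
  m0 <- matrix(FALSE, 50, 30); m0[1:20, ] <- TRUE
  geom0 <- wound_geometry(list(m0, m0, m0), "top", pixel_um = 1)
  expect_equal(edge_progression(geom0, 10)$progression_um, c(0, 0, 0))
  # edge advancing 2 px/frame at pixel 1 um
  masks <- lapply(0:3, function(k) {
    m <- matrix(FALSE, 50, 30); if (20 - 2 * k >= 1) m[1:(20 - 2 * k), ] <- TRUE
    m
  })
  pr <- edge_progression(wound_geometry(masks, "top", pixel_um = 1), 10)
  expect_equal(pr$progression_um, c(0, 2, 4, 6))
  expect_equal(unname(coef(lm(progression_um ~ t_min, pr))[2] * 10), 2)
  # ragged edge: columns at 10 and 20 px average to 15
  mr <- matrix(FALSE, 50, 2); mr[1:10, 1] <- TRUE; mr[1:20, 2] <- TRUE
  expect_equal(wound_geometry(list(mr), "top")$edge_px, 15)
})

test_that("order parameter has the analytic values and flips with side", {
  geom_top <- structure(list(wound_side = "top", pixel_um = 1),
                        class = "wound_geometry")
  geom_bot <- structure(list(wound_side = "bottom", pixel_um = 1),
                        class = "wound_geometry")
  toward <- mk_field(0, -2)      # straight toward a top wound
  along <- mk_field(2, 0)        # parallel to the wound edge
  expect_true(all(order_parameter(toward, geom_top) == 1))
  expect_true(all(order_parameter(along, geom_top) == 0))
  expect_true(all(order_parameter(toward, geom_bot) == -1))
  still <- mk_field(0, 0)
  expect_true(all(is.na(order_parameter(still, geom_top))))
  expect_error(order_parameter(toward, NULL), "geometry")
})

test_that("isotropic directions give near-zero mean order parameter", {
  n <- 10000
  set.seed(13)
  th <- runif(n, 0, 2 * pi)
  f <- mk_field(0, 0, nx = 100, ny = 100)
  f$u <- matrix(cos(th), 100); f$v <- matrix(sin(th), 100)
  geom <- structure(list(wound_side = "top", pixel_um = 1),
                    class = "wound_geometry")
  expect_lt(abs(mean(order_parameter(f, geom))), 3 / sqrt(2 * n))
})

test_that("heat map cells average uniform fields exactly and conserve counts", {
  cfg <- piv_config(pixel_um = 1, dt_min = 10)
  mkv <- function(s) {
    f <- to_velocity(mk_field(0, -s / 6, nx = 6, ny = 10), cfg)
    list(f, f, f)
  }
  geom <- structure(list(wound_side = "top", pixel_um = 1,
                         edge_px = c(0, 0, 0)), class = "wound_geometry")
  hm <- build_heatmap(list(mkv(6)), list(geom), scalar = "speed",
                      band_um = 8, dt_min = 10)
  expect_true(all(abs(hm$values - 6) < 1e-9, na.rm = TRUE))
  # conservation: every valid vector lands in exactly one cell
  expect_equal(sum(hm$n), 3 * 6 * 10)
  # two movies at speeds s and 3s average to 2s
  hm2 <- build_heatmap(list(mkv(6), mkv(18)), list(geom, geom),
                       scalar = "speed", band_um = 8, dt_min = 10)
  expect_true(all(abs(hm2$values - 12) < 1e-9, na.rm = TRUE))
})

test_that("time profiles index the nearest column", {
  map <- structure(list(values = matrix(rep(1:5, each = 3), 3),
                        n = matrix(1, 3, 5), dist_um = c(4, 12, 20),
                        t_min = seq(0, 40, 10), scalar = "speed",
                        band_um = 8), class = "spacetime_map")
  expect_equal(profile_at_time(map, 20)$value, rep(3, 3))
  expect_equal(profile_at_time(map, 24)$value, rep(3, 3))
  expect_error(profile_at_time(map, 100), "outside")
  # constant-in-time map: any column equals any other
  mapc <- map; mapc$values <- matrix(7, 3, 5)
  expect_equal(profile_at_time(mapc, 0)$value, profile_at_time(mapc, 40)$value)
})

test_that("full chain recovers the planted exponential velocity profile", {
  mcfg <- movie_sim_config(height_px = 320, width_px = 160, pixel_um = 0.7422,
                           n_frames = 10, dt_min = 10, v0_umh = 20,
                           lambda_um = 50, noise_sd = 0.02,
                           wound_fraction = 0.25, seed = 5)
  mv <- gen_movie(mcfg)
  masks <- lapply(mv$stack, segment_wound, wound_side = "top")
  geom <- wound_geometry(masks, "top", pixel_um = 0.7422)
  pr <- edge_progression(geom, 10)
  slope_umh <- unname(coef(lm(progression_um ~ t_min, pr))[2]) * 60
  expect_lt(abs(slope_umh - 20) / 20, 0.05)
  cfg <- piv_config(pixel_um = 0.7422, dt_min = 10)
  fields <- piv_movie(mv$stack, cfg)
  hm <- build_heatmap(list(fields), list(geom), scalar = "speed", dt_min = 10)
  est <- rowMeans(hm$values, na.rm = TRUE)[2:6]
  truth <- 20 * exp(-hm$dist_um[2:6] / 50)
  expect_true(all(abs(est - truth) / truth < 0.1))
  hmo <- build_heatmap(list(fields), list(geom), scalar = "order", dt_min = 10)
  expect_true(all(rowMeans(hmo$values, na.rm = TRUE)[2:6] > 0.95))
})
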