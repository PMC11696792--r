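#' Read tracked cell trajectories from CSV
#'
#' Expects the column layout `cell_id, frame, t_min, x_um, y_um` (header
#' required). Rows are grouped by `cell_id` and sorted by time. Malformed
#' rows (missing coordinates, non-numeric time) are reported with their line
#' numbers; duplicated (cell, frame) pairs and non-uniform frame intervals
#' within a cell are errors.
#'
#' @param path CSV file path.
#' @return a named list of track objects (see [split_tracks()]).
#' @export
read_tracks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "frame", "t_min", "x_um", "y_um")
  if (!all(need %in% names(df)))
    stop("track CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0) return(list())
  bad <- which(!stats::complete.cases(df[, need]) |
                 !is.finite(df$x_um) | !is.finite(df$y_um))
  if (length(bad))
    stop("malformed rows at lines (1-based, incl. header): ",
         paste(bad + 1L, collapse = ", "), call. = FALSE)
  dup <- duplicated(df[, c("cell_id", "frame")])
  if (any(dup))
    stop("duplicated (cell_id, frame) rows at lines: ",
         paste(which(dup) + 1L, collapse = ", "), call. = FALSE)
  split_tracks(df)
}

#' Group a long-format trajectory table into per-cell tracks
#'
#' @param df data.frame with columns `cell_id, frame, t_min, x_um, y_um`.
#' @param dt_min expected frame interval; inferred from the data when `NULL`.
#' @return named list of tracks; each track is a list with `cell_id`,
#'   `dt_min` and a `points` matrix (columns `t_min, x_um, y_um`, sorted by
#'   time).
#' @export
split_tracks <- function(df, dt_min = NULL) {
  lapply(split(df, df$cell_id), function(d) {
    d <- d[order(d$t_min), ]
    dts <- diff(d$t_min)
    if (length(dts)) {
      if (any(abs(dts - dts[1]) > 1e-9 * max(dts[1], 1)))
        stop("non-uniform frame interval in cell ", d$cell_id[1],
             call. = FALSE)
      if (!is.null(dt_min) && abs(dts[1] - dt_min) > 1e-9)
        stop("cell ", d$cell_id[1], " has dt ", dts[1],
             " but expected ", dt_min, call. = FALSE)
    }
    list(cell_id = d$cell_id[1],
         dt_min = if (length(dts)) dts[1] else NA_real_,
         points = cbind(t_min = d$t_min, x_um = d$x_um, y_um = d$y_um))
  })
}

track_steps <- function(track) {
  p <- track$points
  cbind(dx = diff(p[, "x_um"]), dy = diff(p[, "y_um"]))
}

#' Mean instantaneous speed of one track
#'
#' Mean over steps of step length divided by the frame interval.
#'
#' @param track a track from [split_tracks()].
#' @return speed in um/min.
#' @export
cell_speed <- function(track) {
  p <- track$points
  if (nrow(p) < 2) stop("need at least 2 points for speed", call. = FALSE)
  st <- track_steps(track)
  mean(sqrt(st[, 1]^2 + st[, 2]^2)) / track$dt_min
}

#' Direction autocorrelation of a track
#'
#' For each lag `k` (in frames) computes the mean cosine of the angle
#' between step vectors `i` and `i + k`. Pairs involving a zero-length step
#' are dropped (direction undefined). Lag 0 equals 1 by construction for any
#' track with at least one nonzero step.
#'
#' @param track a track from [split_tracks()].
#' @param max_lag_steps largest lag in frames; defaults to half the number
#'   of steps (standard practice, limits noisy tails).
#' @return an `autocorr_curve`: list with `lags_min`, `values`, `n_pairs`.
#' @export
direction_autocorrelation <- function(track, max_lag_steps = NULL) {
  st <- track_steps(track)
  n <- nrow(st)
  if (is.null(max_lag_steps)) max_lag_steps <- floor(n / 2)
  if (n < max_lag_steps + 1)
    stop("track too short for max_lag_steps = ", max_lag_steps, call. = FALSE)
  len <- sqrt(st[, 1]^2 + st[, 2]^2)
  ok <- len > 0
  if (!any(ok)) stop("degenerate track: all steps zero-length", call. = FALSE)
  ux <- st[, 1] / len; uy <- st[, 2] / len  # NaN where len == 0, masked below
  lags <- 0:max_lag_steps
  vals <- numeric(length(lags)); npairs <- integer(length(lags))
  for (j in seq_along(lags)) {
    k <- lags[j]
    i1 <- seq_len(n - k); i2 <- i1 + k
    use <- ok[i1] & ok[i2]
    npairs[j] <- sum(use)
    vals[j] <- if (npairs[j]) mean(ux[i1][use] * ux[i2][use] +
                                     uy[i1][use] * uy[i2][use]) else NA_real_
  }
  structure(list(lags_min = lags * track$dt_min, values = vals,
                 n_pairs = npairs),
            class = "autocorr_curve")
}

#' Pointwise mean and SEM of a set of autocorrelation curves
#'
#' @param curves list of `autocorr_curve` objects on a common lag grid.
#' @return data.frame with `lags_min, mean, sem, n`.
#' @export
mean_autocorr <- function(curves) {
  lags <- curves[[1]]$lags_min
  for (cv in curves)
    if (!identical(length(cv$lags_min), length(lags)) ||
        any(cv$lags_min != lags))
      stop("curves must share a lag grid", call. = FALSE)
  m <- vapply(curves, function(cv) cv$values, numeric(length(lags)))
  m <- matrix(m, nrow = length(lags))
  data.frame(lags_min = lags,
             mean = rowMeans(m, na.rm = TRUE),
             sem = apply(m, 1, function(r) {
               r <- r[!is.na(r)]
               if (length(r) > 1) stats::sd(r) / sqrt(length(r)) else NA_real_
             }),
             n = apply(m, 1, function(r) sum(!is.na(r))))
}

persistence_model <- function(t, a, b) (1 - b) * exp(-t / a) + b

#' Fit the exponential-decay-with-plateau persistence model
#'
#' Least-squares fit of `y(t) = (1 - b) * exp(-t / a) + b` to a direction
#' autocorrelation curve, where `a > 0` is the decay constant (minutes) and
#' `b` in `[-1, 1]` the plateau. Lag 0 is included (anchoring `y(0) = 1`)
#' and points are unweighted. Initialisation: `a` = total lag span / 4,
#' `b` = mean of the last quartile of lags; up to 20 jittered restarts on
#' failure. A curve whose values all sit within `1e-6` of 1 is the
#' identifiable plateau-only limit and is reported as `b = 1, a = Inf`.
#'
#' @param curve an `autocorr_curve` (or list with `lags_min` and `values`).
#' @param max_restarts bounded number of jittered restarts.
#' @return a `persistence_fit`: list with `a`, `b`, `rss`, `converged`.
#' @export
fit_persistence <- function(curve, max_restarts = 20) {
  t <- curve$lags_min; y <- curve$values
  keep <- !is.na(y)
  t <- t[keep]; y <- y[keep]
  if (length(unique(t)) < 4)
    stop("need at least 4 distinct lags to fit", call. = FALSE)
  if (all(abs(y - 1) < 1e-6))
    return(structure(list(a = Inf, b = 1, rss = sum((y - 1)^2),
                          converged = TRUE), class = "persistence_fit"))
  q4 <- t >= stats::quantile(t, 0.75)
  a0 <- max(diff(range(t)) / 4, min(t[t > 0]))
  b0 <- min(max(mean(y[q4]), -0.99), 0.99)
  best <- NULL
  # deterministic restart schedule (no RNG use): spread a multiplicatively,
  # sweep b against it
  a_mult <- exp(seq(-1.5, 1.5, length.out = max(max_restarts, 1)))
  b_alt <- seq(0.9, -0.9, length.out = max(max_restarts, 1))
  for (r in 0:max_restarts) {
    a_start <- if (r == 0) a0 else a0 * a_mult[r]
    b_start <- if (r == 0) b0 else b_alt[r]
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ (1 - b) * exp(-t / a) + b,
                        start = list(a = a_start, b = b_start),
                        lower = c(a = 1e-6, b = -1), upper = c(a = 1e8, b = 1),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss - 1e-12) {
        cf <- stats::coef(fit)
        best <- list(a = unname(cf["a"]), b = unname(cf["b"]), rss = rss,
                     converged = TRUE)
      }
      if (r >= 2 && !is.null(best)) break
    }
  }
  if (is.null(best)) {
    # bounded restarts exhausted: report best-so-far grid point, unconverged
    gs <- persistence_grid_fit(list(lags_min = t, values = y),
                               a_range = c(min(t[t > 0]), 10 * max(t)),
                               b_range = c(-1, 1), n_a = 60, n_b = 41)
    best <- list(a = gs$a, b = gs$b, rss = gs$rss, converged = FALSE)
  }
  structure(best, class = "persistence_fit")
}

#' Brute-force grid search for the persistence model
#'
#' Dense evaluation of the residual sum of squares of
#' `y(t) = (1 - b) exp(-t/a) + b` over an (a, b) grid. Independent oracle
#' for [fit_persistence()]; also the fallback when the nonlinear fitter
#' fails to converge.
#'
#' @param curve list with `lags_min`, `values`.
#' @param a_range,b_range grid limits.
#' @param n_a,n_b grid sizes.
#' @return list with the best `a`, `b`, `rss` and the grid steps.
#' @export
persistence_grid_fit <- function(curve, a_range, b_range = c(-1, 1),
                                 n_a = 201, n_b = 201) {
  t <- curve$lags_min; y <- curve$values
  keep <- !is.na(y); t <- t[keep]; y <- y[keep]
  a_grid <- seq(a_range[1], a_range[2], length.out = n_a)
  b_grid <- seq(b_range[1], b_range[2], length.out = n_b)
  E <- exp(-outer(t, a_grid, function(tt, aa) tt / aa))  # |t| x n_a
  best <- list(rss = Inf)
  for (j in seq_along(b_grid)) {
    b <- b_grid[j]
    R <- (1 - b) * E + b - y            # residuals, |t| x n_a
    rss <- colSums(R * R)
    i <- which.min(rss)
    if (rss[i] < best$rss)
      best <- list(a = a_grid[i], b = b, rss = rss[i])
  }
  best$a_step <- diff(a_grid[1:2]); best$b_step <- diff(b_grid[1:2])
  best
}

#' Fit persistence for every track in a cohort
#'
#' With `method = "per_cell"` (the default, matching per-cell readouts) each
#' track's autocorrelation curve is fitted separately; note that at usual
#' track lengths (about 40 frames) the per-cell plateau estimate carries a
#' small negative skew because negative tail noise can only be absorbed by
#' `b`, while positive tail noise can also be absorbed by a larger `a`.
#' `method = "mean_curve"` fits the cohort's pointwise mean curve instead,
#' which is nearly unbiased for both parameters.
#'
#' @param tracks list of tracks (from [split_tracks()]).
#' @param max_lag_frac fraction of track length used as maximum lag.
#' @param method `"per_cell"` or `"mean_curve"`.
#' @return for `"per_cell"`, a data.frame with
#'   `cell_id, a_min, b, rss, converged`; for `"mean_curve"`, a single-row
#'   data.frame (cell_id `"cohort"`).
#' @export
fit_cohort <- function(tracks, max_lag_frac = 0.5,
                       method = c("per_cell", "mean_curve")) {
  method <- match.arg(method)
  curves <- lapply(tracks, function(tr) {
    n_steps <- nrow(tr$points) - 1
    direction_autocorrelation(tr,
                              max_lag_steps = floor(n_steps * max_lag_frac))
  })
  if (method == "mean_curve") {
    m <- mean_autocorr(curves)
    f <- fit_persistence(list(lags_min = m$lags_min, values = m$mean))
    return(data.frame(cell_id = "cohort", a_min = f$a, b = f$b, rss = f$rss,
                      converged = f$converged))
  }
  rows <- Map(function(tr, cv) {
    f <- fit_persistence(cv)
    data.frame(cell_id = tr$cell_id, a_min = f$a, b = f$b, rss = f$rss,
               converged = f$converged)
  }, tracks, curves)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Compare migration persistence between two groups of cells
#'
#' Per-cell persistence fits are compared by a two-sided bootstrap of the
#' difference in group means of the fitted plateau `b` (primary readout) and
#' of the decay constant `a` (secondary). The bootstrap resamples cells with
#' replacement within each group; the p-value is the fraction of resampled,
#' null-centred differences at least as extreme as the observed one.
#'
#' @param fits_a,fits_b data.frames from [fit_cohort()] (>= 2 cells each).
#' @param n_boot number of bootstrap resamples.
#' @param seed integer seed for the resampling.
#' @return list with `effect_b` (mean b difference, A - B), `p_b`,
#'   `effect_a`, `p_a`, and per-group summaries.
#' @export
compare_persistence <- function(fits_a, fits_b, n_boot = 10000, seed = 1L) {
  for (f in list(fits_a, fits_b)) {
    if (nrow(f) < 2) stop("need >= 2 cells per group", call. = FALSE)
    if (all(!f$converged)) stop("group with all-degenerate fits", call. = FALSE)
  }
  # each group's resampling stream is seeded from its own (sorted) values, so
  # the result is exactly invariant under a swap of group labels
  boot_means <- function(x) {
    gseed <- (abs(seed) * 7919 +
                sum(as.numeric(abs(round(sort(x) * 1e6)) %% 9973)) * 131) %%
      2147483647
    set.seed(as.integer(gseed))
    n <- length(x)
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
    rowMeans(matrix(x[idx], nrow = n_boot))
  }
  boot_diff <- function(xa, xb) {
    obs <- mean(xa) - mean(xb)
    d <- boot_means(xa) - boot_means(xb)
    # null-centred bootstrap: shift resampled differences to mean 0
    p <- (sum(abs(d - mean(d)) >= abs(obs)) + 1) / (n_boot + 1)
    list(effect = obs, p = p)
  }
  # a can be Inf for plateau-only cells; compare on finite fits only
  fa <- fits_a$a_min[is.finite(fits_a$a_min)]
  fb <- fits_b$a_min[is.finite(fits_b$a_min)]
  rb <- boot_diff(fits_a$b, fits_b$b)
  ra <- boot_diff(fa, fb)
  list(effect_b = rb$effect, p_b = rb$p, effect_a = ra$effect, p_a = ra$p,
       group_a = c(mean_b = mean(fits_a$b), mean_a = mean(fa)),
       group_b = c(mean_b = mean(fits_b$b), mean_a = mean(fb)))
}
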