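#' Configuration for the synthetic fluorescence line-profile generator
#'
#' One-dimensional intensity profiles: a constant background plus a Gaussian
#' peak at a landmark position plus i.i.d. noise, emulating line scans
#' across a cell edge or cell-cell junction.
#'
#' @param length_um profile length (must be an integral multiple of
#'   `step_um`).
#' @param step_um sample spacing.
#' @param peak_pos_um,peak_sigma_um,peak_amp Gaussian peak parameters.
#' @param background constant background level.
#' @param noise_sd additive noise SD.
#' @param seed integer seed.
#' @return an object of class `profile_sim_config`.
#' @export
profile_sim_config <- function(length_um = 10, step_um = 0.1,
                               peak_pos_um = 5, peak_sigma_um = 0.5,
                               peak_amp = 100, background = 100,
                               noise_sd = 5, seed = 1L) {
  n <- length_um / step_um
  if (abs(n - round(n)) > 1e-9)
    stop("length_um must be an integral multiple of step_um", call. = FALSE)
  if (peak_amp < 0) stop("peak_amp must be >= 0", call. = FALSE)
  structure(list(length_um = length_um, step_um = step_um,
                 peak_pos_um = peak_pos_um, peak_sigma_um = peak_sigma_um,
                 peak_amp = peak_amp, background = background,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "profile_sim_config")
}

#' Generate synthetic line profiles with a Gaussian landmark peak
#'
#' @param cfg a [profile_sim_config()].
#' @param n number of profiles.
#' @return list with `profiles` (list of `line_profile` objects: lists with
#'   `distance_um` and an `intensity` matrix, one column per channel) and
#'   `truth` (the generating parameters).
#' @export
gen_profiles <- function(cfg, n = 1) {
  stopifnot(inherits(cfg, "profile_sim_config"))
  set.seed(cfg$seed)
  x <- seq(0, cfg$length_um, by = cfg$step_um)
  base <- cfg$background +
    cfg$peak_amp * exp(-(x - cfg$peak_pos_um)^2 / (2 * cfg$peak_sigma_um^2))
  profs <- lapply(seq_len(n), function(i) {
    y <- base
    if (cfg$noise_sd > 0) y <- y + stats::rnorm(length(x), 0, cfg$noise_sd)
    structure(list(distance_um = x,
                   intensity = matrix(y, ncol = 1,
                                      dimnames = list(NULL, "ch1")),
                   source = paste0("sim_", i)),
              class = "line_profile")
  })
  list(profiles = profs,
       truth = list(peak_pos_um = cfg$peak_pos_um, noiseless = base,
                    grid_um = x))
}

# bilinear interpolation of image values at fractional (x, y) positions;
# image is a matrix with rows = y, columns = x (1-based pixel centres)
bilinear_at <- function(img, x, y) {
  x0 <- floor(x); y0 <- floor(y)
  x1 <- pmin(x0 + 1, ncol(img)); y1 <- pmin(y0 + 1, nrow(img))
  fx <- x - x0; fy <- y - y0
  img[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
    img[cbind(y0, x1)] * fx * (1 - fy) +
    img[cbind(y1, x0)] * (1 - fx) * fy +
    img[cbind(y1, x1)] * fx * fy
}

#' Extract an intensity profile along a user-drawn line
#'
#' Samples the image every pixel along the segment from `(x0, y0)` to
#' `(x1, y1)` (pixel coordinates, origin top-left); at each sample the
#' intensity is the mean over `width_px` bilinearly interpolated points
#' spread perpendicular to the line.
#'
#' @param image numeric matrix or list of matrices (one per channel).
#' @param line numeric vector `c(x0, y0, x1, y1)`.
#' @param width_px averaging width perpendicular to the line (>= 1).
#' @param pixel_um microns per pixel (distance axis scaling).
#' @return a `line_profile`: list with `distance_um` and `intensity`
#'   (matrix, one column per channel).
#' @export
extract_profile <- function(image, line, width_px = 1, pixel_um = 1) {
  if (is.matrix(image)) image <- list(ch1 = image)
  if (width_px < 1) stop("width_px must be >= 1", call. = FALSE)
  x0 <- line[1]; y0 <- line[2]; x1 <- line[3]; y1 <- line[4]
  len_px <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
  n <- floor(len_px) + 1L
  tt <- seq(0, len_px, length.out = n)
  ex <- (x1 - x0) / len_px; ey <- (y1 - y0) / len_px   # along-line unit
  px <- -ey; py <- ex                                  # perpendicular unit
  woff <- seq(-(width_px - 1) / 2, (width_px - 1) / 2, length.out = width_px)
  h <- nrow(image[[1]]); w <- ncol(image[[1]])
  xs <- outer(x0 + tt * ex, woff * px, `+`)
  ys <- outer(y0 + tt * ey, woff * py, `+`)
  if (any(xs < 1 | xs > w | ys < 1 | ys > h))
    stop("line (or its width) exits the image", call. = FALSE)
  intens <- vapply(image, function(ch) {
    rowMeans(matrix(bilinear_at(ch, as.vector(xs), as.vector(ys)), nrow = n))
  }, numeric(n))
  intens <- matrix(intens, nrow = n,
                   dimnames = list(NULL, names(image)))
  structure(list(distance_um = tt * pixel_um, intensity = intens,
                 source = "line"),
            class = "line_profile")
}

#' Register line profiles to a common landmark
#'
#' In `"edge"` mode each profile is shifted so the maximum of the reference
#' channel sits at distance 0; in `"junction"` mode the profile's own zero
#' (a user-annotated landmark) is kept. Profiles are then resampled by
#' linear interpolation onto a common grid spanning `window_um`. Profiles
#' whose reference maximum lies at either scan end, or whose reference
#' channel is flat, are rejected.
#'
#' @param profiles list of `line_profile` objects.
#' @param reference_channel channel name or index used as landmark.
#' @param mode `"edge"` (align to reference max) or `"junction"`.
#' @param window_um `c(min, max)` of the common registered grid.
#' @param step_um grid step; default: the first profile's step.
#' @return list with `registered` (profiles on the common grid),
#'   `rejected` (count) and `reasons` (character).
#' @export
register_profiles <- function(profiles, reference_channel = 1,
                              mode = c("edge", "junction"),
                              window_um = c(-2.5, 2.5), step_um = NULL) {
  mode <- match.arg(mode)
  if (!length(profiles)) stop("no profiles", call. = FALSE)
  if (is.null(step_um))
    step_um <- diff(profiles[[1]]$distance_um[1:2])
  grid <- seq(window_um[1], window_um[2], by = step_um)
  kept <- list(); reasons <- character()
  for (p in profiles) {
    ref <- p$intensity[, reference_channel]
    if (mode == "edge") {
      if (diff(range(ref)) < 1e-12) {
        reasons <- c(reasons, "flat reference channel"); next
      }
      i_max <- which.max(ref)
      if (i_max == 1 || i_max == length(ref)) {
        reasons <- c(reasons, "reference maximum at scan end"); next
      }
      shift <- p$distance_um[i_max]
    } else shift <- 0
    d <- p$distance_um - shift
    res <- apply(p$intensity, 2, function(ch)
      stats::approx(d, ch, xout = grid, rule = 1)$y)
    res <- matrix(res, nrow = length(grid),
                  dimnames = list(NULL, colnames(p$intensity)))
    kept[[length(kept) + 1]] <- structure(
      list(distance_um = grid, intensity = res, source = p$source),
      class = "line_profile")
  }
  list(registered = kept, rejected = length(reasons), reasons = reasons)
}

#' Average registered profiles per channel
#'
#' Optionally rescales each profile so its per-channel maximum is 100
#' ("percent of max"), then computes the pointwise mean and SEM.
#'
#' @param registered list of `line_profile` objects on one grid.
#' @param normalize `"percent_max"`, `"percent_sum"` or `"none"`.
#' @return long-format data.frame: `distance_um, channel, mean, sem, n`.
#' @export
average_profiles <- function(registered,
                             normalize = c("percent_max", "percent_sum", "none")) {
  normalize <- match.arg(normalize)
  if (length(registered) < 2) stop("need >= 2 profiles", call. = FALSE)
  grid <- registered[[1]]$distance_um
  for (p in registered)
    if (length(p$distance_um) != length(grid) || any(p$distance_um != grid))
      stop("grid mismatch between registered profiles", call. = FALSE)
  channels <- colnames(registered[[1]]$intensity)
  out <- list()
  for (ch in channels) {
    m <- vapply(registered, function(p) {
      y <- p$intensity[, ch]
      switch(normalize,
             percent_max = 100 * y / max(y, na.rm = TRUE),
             percent_sum = 100 * y / sum(y, na.rm = TRUE),
             none = y)
    }, numeric(length(grid)))
    n <- rowSums(!is.na(m))
    out[[ch]] <- data.frame(
      distance_um = grid, channel = ch,
      mean = rowMeans(m, na.rm = TRUE),
      sem = apply(m, 1, function(r) {
        r <- r[!is.na(r)]
        if (length(r) > 1) stats::sd(r) / sqrt(length(r)) else NA_real_
      }),
      n = n)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Edge-enrichment fold ratio between two regions of interest
#'
#' Ratio of the mean intensity in an edge band (e.g. the lamellipodial tip)
#' to the mean in a similar band just beneath it. ROIs are logical masks of
#' the image; they must not overlap and must have similar area (within
#' `area_tol`). An optional constant background is subtracted from both
#' means first.
#'
#' @param image numeric matrix.
#' @param edge_band,inner_band logical masks, same size as `image`.
#' @param background constant background level to subtract (default 0).
#' @param area_tol maximum relative area difference between the ROIs.
#' @return the fold ratio (scalar).
#' @export
edge_enrichment <- function(image, edge_band, inner_band, background = 0,
                            area_tol = 0.1) {
  stopifnot(all(dim(edge_band) == dim(image)),
            all(dim(inner_band) == dim(image)))
  if (any(edge_band & inner_band)) stop("ROIs overlap", call. = FALSE)
  a1 <- sum(edge_band); a2 <- sum(inner_band)
  if (a1 == 0 || a2 == 0) stop("empty ROI", call. = FALSE)
  if (abs(a1 - a2) / max(a1, a2) > area_tol)
    stop("ROI areas differ by more than ", 100 * area_tol, "%", call. = FALSE)
  inner <- mean(image[inner_band]) - background
  if (inner <= 0) stop("inner-band mean <= 0 after background subtraction",
                       call. = FALSE)
  (mean(image[edge_band]) - background) / inner
}
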