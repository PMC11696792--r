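#' Segment the cell-free wound region of a monolayer frame
#'
#' The wound is detected as low-texture area: the local intensity standard
#' deviation (disk neighbourhood) is thresholded with Otsu's method, and the
#' largest connected low-texture component touching `wound_side` is
#' returned. The candidate must be clearly smoother than the rest of the
#' frame (mean local SD below half the outside value), otherwise the frame
#' is declared wound-free.
#'
#' @param frame numeric matrix (rows = y, origin top-left).
#' @param wound_side which image border the wound touches:
#'   `"top"`, `"bottom"`, `"left"` or `"right"`.
#' @param disk_radius_px radius of the local-SD neighbourhood.
#' @return logical matrix, `TRUE` inside the wound.
#' @export
segment_wound <- function(frame, wound_side = "top", disk_radius_px = 8) {
  wound_side <- match.arg(wound_side, c("top", "bottom", "left", "right"))
  k <- EBImage::makeBrush(2 * disk_radius_px + 1, shape = "disc")
  k <- k / sum(k)
  mu <- EBImage::filter2(frame, k, boundary = "replicate")
  mu2 <- EBImage::filter2(frame^2, k, boundary = "replicate")
  lsd <- sqrt(pmax(mu2 - mu^2, 0))
  rng <- range(lsd)
  if (diff(rng) < 1e-12) stop("wound not found: uniform texture", call. = FALSE)
  lsd01 <- (lsd - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(lsd01), range = c(0, 1))
  low <- lsd01 < thr
  lab <- EBImage::bwlabel(EBImage::Image(low))
  lab <- EBImage::imageData(lab)
  border <- switch(wound_side,
                   top = lab[1, ], bottom = lab[nrow(lab), ],
                   left = lab[, 1], right = lab[, ncol(lab)])
  ids <- setdiff(unique(border), 0)
  if (!length(ids)) stop("wound not found: no low-texture region on wound side",
                         call. = FALSE)
  areas <- vapply(ids, function(i) sum(lab == i), numeric(1))
  mask <- lab == ids[which.max(areas)]
  if (sum(mask) < 0.01 * length(mask) ||
      mean(lsd[mask]) >= 0.5 * mean(lsd[!mask]))
    stop("wound not found: candidate region not clearly cell-free",
         call. = FALSE)
  mask
}

#' Wound geometry from per-frame masks
#'
#' Computes, per frame, the wound/monolayer boundary coordinate per column
#' (for a top/bottom wound; per row for left/right) as the run of wound
#' pixels from the wound-side border, and its mean across columns.
#'
#' @param masks list of logical wound masks, one per frame.
#' @param wound_side image border the wound touches.
#' @param pixel_um microns per pixel.
#' @return an object of class `wound_geometry` with `wound_side`,
#'   `pixel_um`, `edge_px` (mean boundary depth per frame, px from the
#'   wound-side border) and `edge_per_column` (list of per-column depths).
#' @export
wound_geometry <- function(masks, wound_side = "top", pixel_um = 1) {
  wound_side <- match.arg(wound_side, c("top", "bottom", "left", "right"))
  depth_runs <- function(mask) {
    m <- switch(wound_side,
                top = mask, bottom = mask[nrow(mask):1, , drop = FALSE],
                left = t(mask), right = t(mask[, ncol(mask):1, drop = FALSE]))
    # per column: wound depth = number of wound pixels (equals the boundary
    # coordinate for a wound contiguous from the border)
    colSums(m)
  }
  per_col <- lapply(masks, depth_runs)
  edge <- vapply(per_col, mean, numeric(1))
  structure(list(wound_side = wound_side, pixel_um = pixel_um,
                 edge_px = edge, edge_per_column = per_col),
            class = "wound_geometry")
}

#' Leading-edge progression over time
#'
#' Signed displacement of the mean leading-edge position toward the wound
#' since the first frame, in microns. Frames whose mask shows no boundary
#' (all or no wound pixels in every column) are returned as `NA`.
#'
#' @param geometry a [wound_geometry()].
#' @param dt_min minutes per frame.
#' @return data.frame with `t_min` and `progression_um`.
#' @export
edge_progression <- function(geometry, dt_min = 10) {
  e <- geometry$edge_px
  data.frame(t_min = (seq_along(e) - 1) * dt_min,
             progression_um = (e[1] - e) * geometry$pixel_um)
}

# unit vector pointing toward the wound, in image coordinates (x right,
# y down); for a top wound this is (0, -1)
woundward_unit <- function(wound_side) {
  switch(wound_side,
         top = c(0, -1), bottom = c(0, 1), left = c(-1, 0), right = c(1, 0))
}

#' Local order parameter of a displacement field
#'
#' Per vector, the cosine of the angle between the displacement and the
#' unit vector pointing perpendicular to the wound axis, toward the wound
#' (1 = coordinated advance into the wound). Zero-magnitude vectors are
#' undefined and returned as `NA`.
#'
#' @param field a `vector_field`.
#' @param geometry a [wound_geometry()] (supplies the wound side).
#' @return matrix of order-parameter values on the field grid.
#' @export
order_parameter <- function(field, geometry) {
  if (missing(geometry) || is.null(geometry))
    stop("wound geometry required", call. = FALSE)
  n <- woundward_unit(geometry$wound_side)
  mag <- sqrt(field$u^2 + field$v^2)
  op <- (field$u * n[1] + field$v * n[2]) / mag
  op[mag == 0] <- NA_real_
  op
}

#' Space-time map of speed or order parameter across the monolayer
#'
#' Bins every valid vector of every (validated, time-averaged) field by its
#' distance from the instantaneous front edge along the wound normal (rows,
#' band width `band_um`, front edge first) and by time (columns). Within a
#' movie, values are averaged per cell; across movies, per-movie cell means
#' are averaged. Vectors on the wound side of the edge are not assigned.
#'
#' @param fields_by_movie list (one element per movie) of lists of velocity
#'   fields (from [piv_movie()]).
#' @param geometries list of [wound_geometry()] objects, one per movie; the
#'   per-frame edge is matched to each field's time index.
#' @param scalar `"speed"` (um/h, requires [to_velocity()]) or `"order"`.
#' @param band_um distance band width; defaults to the PIV grid step in um.
#' @param dt_min minutes per frame (time-axis labels, window start frame).
#' @param n_bands number of distance bands to keep.
#' @return a `spacetime_map`: list with `values` (bands x times), `n`
#'   (contributing vectors per cell), `dist_um` (band centres), `t_min`.
#' @export
build_heatmap <- function(fields_by_movie, geometries, scalar = c("speed", "order"),
                          band_um = NULL, dt_min = 10, n_bands = NULL) {
  scalar <- match.arg(scalar)
  if (!length(fields_by_movie)) stop("no fields", call. = FALSE)
  f1 <- fields_by_movie[[1]][[1]]
  px_um <- geometries[[1]]$pixel_um
  if (is.null(band_um))
    band_um <- (f1$grid_y[2] - f1$grid_y[1]) * px_um
  n_times <- min(vapply(fields_by_movie, length, integer(1)))
  if (is.null(n_bands)) {
    span_px <- max(f1$grid_y) - min(geometries[[1]]$edge_px)
    n_bands <- max(1L, floor(span_px * px_um / band_um) + 1L)
  }
  acc_sum <- acc_cnt <- array(0, c(n_bands, n_times, length(fields_by_movie)))
  for (m in seq_along(fields_by_movie)) {
    geom <- geometries[[m]]
    if (geom$wound_side != "top")
      stop("heat maps currently require a top-side wound", call. = FALSE)
    for (t in seq_len(n_times)) {
      f <- fields_by_movie[[m]][[t]]
      edge <- geom$edge_px[min(t, length(geom$edge_px))]
      val <- switch(scalar,
                    speed = {
                      if (is.null(f$speed_umh))
                        stop("speed map needs velocity fields (to_velocity)",
                             call. = FALSE)
                      f$speed_umh
                    },
                    order = order_parameter(f, geom))
      d_um <- outer(f$grid_y - edge, rep(1, length(f$grid_x))) * geom$pixel_um
      band <- floor(d_um / band_um) + 1L
      use <- f$valid & !is.na(val) & band >= 1L & band <= n_bands
      for (i in which(use)) {
        acc_sum[band[i], t, m] <- acc_sum[band[i], t, m] + val[i]
        acc_cnt[band[i], t, m] <- acc_cnt[band[i], t, m] + 1L
      }
    }
  }
  per_movie <- acc_sum / ifelse(acc_cnt > 0, acc_cnt, NA)
  values <- apply(per_movie, c(1, 2), mean, na.rm = TRUE)
  values[is.nan(values)] <- NA_real_
  structure(list(values = values, n = apply(acc_cnt, c(1, 2), sum),
                 dist_um = (seq_len(n_bands) - 0.5) * band_um,
                 t_min = (seq_len(n_times) - 1) * dt_min,
                 scalar = scalar, band_um = band_um),
            class = "spacetime_map")
}

#' Distance profile of a space-time map at a given time
#'
#' Returns the map column nearest to `t_min` as a distance-profile table
#' (trailing-averaged series are labelled by their window's first frame).
#'
#' @param map a `spacetime_map`.
#' @param t_min time in minutes; must fall within the map's time range.
#' @return data.frame with `dist_um`, `value`, `n`.
#' @export
profile_at_time <- function(map, t_min) {
  if (t_min < min(map$t_min) || t_min > max(map$t_min))
    stop("t_min outside map time range", call. = FALSE)
  j <- which.min(abs(map$t_min - t_min))
  data.frame(dist_um = map$dist_um, value = map$values[, j], n = map$n[, j])
}

#' Write a space-time map as a CSV matrix with labelled axes
#'
#' @param map a `spacetime_map`.
#' @param path output CSV.
#' @export
write_heatmap_csv <- function(map, path) {
  df <- as.data.frame(map$values)
  names(df) <- paste0("t", map$t_min, "min")
  df <- cbind(dist_um = map$dist_um, df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
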