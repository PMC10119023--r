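# Polar image projection of organ cross-sections.
#
# Coordinate conventions (fixed once, used everywhere):
#   * image pixels: origin at the top-left, x rightward (columns), y downward
#     (rows), 0-based; a pixel centre (x, y) maps to matrix entry
#     [y + 1, x + 1];
#   * ray angles: measured in degrees counter-clockwise (as displayed) from
#     the vertical (upward) axis, i.e. angle 0 points up along the rotated
#     primary-xylem axis; the unit ray for angle a is
#     (dx, dy) = (-sin a, -cos a);
#   * bilinear interpolation for all resampling; samples falling outside the
#     image are masked (NA), never extrapolated.

# vectorised bilinear sampling; x, y are 0-based pixel coordinates
bilinear_sample <- function(img, x, y) {
  h <- nrow(img); w <- ncol(img)
  x <- as.vector(x); y <- as.vector(y)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  ok <- x >= 0 & x <= w - 1 & y >= 0 & y <= h - 1
  # clamp neighbour indices so border pixels interpolate against themselves
  x0c <- pmin(pmax(x0, 0), w - 1); x1c <- pmin(x0c + 1, w - 1)
  y0c <- pmin(pmax(y0, 0), h - 1); y1c <- pmin(y0c + 1, h - 1)
  idx <- function(yy, xx) img[cbind(yy + 1, xx + 1)]
  v <- (1 - fx) * (1 - fy) * idx(y0c, x0c) + fx * (1 - fy) * idx(y0c, x1c) +
       (1 - fx) * fy * idx(y1c, x0c) + fx * fy * idx(y1c, x1c)
  v[!ok] <- NA_real_
  v
}

ray_direction <- function(angle_deg) {
  a <- angle_deg * pi / 180
  cbind(dx = -sin(a), dy = -cos(a))
}

#' Rotate a section so the primary xylem axis is vertical
#'
#' The image is resampled (bilinear) around the annotated centre by the
#' rotation that brings the annotated xylem-axis angle to 90 degrees
#' (vertical); the centre is unchanged and the landmark polyline's angular
#' coordinates are shifted by the same rotation.
#'
#' @param section A `radial_section` (see [render_section()] /
#'   [read_section()]).
#' @param fill Value for pixels rotated in from outside the image frame
#'   (default `NA`, i.e. masked).
#' @return The rotated `radial_section` with `xylem_axis_angle = 90`.
#' @export
rotate_section <- function(section, fill = NA_real_) {
  stopifnot(inherits(section, "radial_section"))
  assert_that(!is.null(section$xylem_axis_angle) && !is.na(section$xylem_axis_angle),
              "section has no xylem-axis annotation")
  delta <- 90 - section$xylem_axis_angle # CCW rotation applied to the image
  if (delta %% 360 == 0) {
    section$xylem_axis_angle <- 90
    return(section)
  }
  h <- dim(section$image)[1]; w <- dim(section$image)[2]
  cx <- section$centre[["x"]]; cy <- section$centre[["y"]]
  # inverse mapping: source = centre + R(-delta) (target - centre),
  # with R(d) the visually counter-clockwise rotation in y-down coordinates:
  # (x, y) -> (x cos d + y sin d, -x sin d + y cos d)
  d <- -delta * pi / 180
  tx <- rep(0:(w - 1), each = h) - cx
  ty <- rep(0:(h - 1), times = w) - cy
  sx <- cx + tx * cos(d) + ty * sin(d)
  sy <- cy - tx * sin(d) + ty * cos(d)
  out <- section$image
  for (ch in seq_len(dim(section$image)[3])) {
    v <- bilinear_sample(section$image[, , ch], sx, sy)
    v[is.na(v)] <- fill
    out[, , ch] <- matrix(v, nrow = h, ncol = w)
  }
  section$image <- out
  section$xylem_axis_angle <- 90
  if (!is.null(section$landmark_polyline)) {
    section$landmark_polyline$angle_deg <-
      (section$landmark_polyline$angle_deg + delta) %% 360
    section$landmark_polyline <-
      section$landmark_polyline[order(section$landmark_polyline$angle_deg), ]
  }
  section
}

#' Unwrap a section into an angle-by-radius polar map
#'
#' Intensities are sampled (bilinear) along rays from the annotated centre to
#' the image edge. Grid cell (i, j) holds the intensity at angle
#' `(i - 1) * 360 / n_angle_bins` (counter-clockwise from vertical) and
#' radius `(j - 1) * radial_step` pixels; radius bin 1 is the centre. Rays
#' are truncated (masked `NA`) at the image border.
#'
#' @param section A `radial_section`.
#' @param n_angle_bins Number of angular bins (>= 8; default 360).
#' @param radial_step Radial sampling step in pixels (default 1).
#' @return Object of class `polar_map`: list with `grid`
#'   (`n_angle_bins x n_radius x n_channel` array), `angles`, `radial_step`,
#'   `channels`, `centre`, `pixel_size`.
#' @export
unwrap <- function(section, n_angle_bins = 360L, radial_step = 1) {
  stopifnot(inherits(section, "radial_section"))
  assert_that(n_angle_bins >= 8, "need at least 8 angular bins")
  h <- dim(section$image)[1]; w <- dim(section$image)[2]
  cx <- section$centre[["x"]]; cy <- section$centre[["y"]]
  assert_that(cx >= 0 && cx <= w - 1 && cy >= 0 && cy <= h - 1,
              "centre (%g, %g) lies outside the image", cx, cy)
  max_radius <- sqrt(max((c(0, w - 1) - cx)^2) + max((c(0, h - 1) - cy)^2))
  radii <- seq(0, max_radius, by = radial_step)
  angles <- (seq_len(n_angle_bins) - 1) * 360 / n_angle_bins
  dir <- ray_direction(angles)
  sx <- outer(dir[, "dx"], radii) + cx # n_angle x n_radius
  sy <- outer(dir[, "dy"], radii) + cy
  n_ch <- dim(section$image)[3]
  grid <- array(NA_real_, dim = c(n_angle_bins, length(radii), n_ch),
                dimnames = list(NULL, NULL, section$channels))
  for (ch in seq_len(n_ch)) {
    grid[, , ch] <- matrix(bilinear_sample(section$image[, , ch], sx, sy),
                           nrow = n_angle_bins)
  }
  structure(list(grid = grid, angles = angles, radial_step = radial_step,
                 channels = section$channels, centre = section$centre,
                 pixel_size = section$pixel_size),
            class = "polar_map")
}

# landmark radius per angular bin, linearly interpolated across annotation
# gaps with wrap-around at 360 degrees
interpolate_polyline <- function(polyline, angles) {
  stopifnot(is.data.frame(polyline), all(c("angle_deg", "radius_px") %in% names(polyline)))
  a <- polyline$angle_deg %% 360
  o <- order(a)
  a <- a[o]; r <- polyline$radius_px[o]
  if (length(a) == 1L) return(rep(r, length(angles)))
  stats::approx(x = c(a[length(a)] - 360, a, a[1] + 360),
                y = c(r[length(r)], r, r[1]),
                xout = angles %% 360)$y
}

#' Align every angular column of a polar map to the cambial landmark
#'
#' Each column is shifted by an integer number of radial bins so that the
#' landmark (most recent division wall) sits at a common reference row; no
#' sub-bin resampling is applied, so raw intensities are preserved. Cells
#' shifted in from beyond the data are masked (`NA`). Columns whose landmark
#' radius is missing, non-positive, or beyond the ray length are fully masked
#' with a warning, never dropped silently.
#'
#' @param pmap A [unwrap()] result.
#' @param landmark_polyline data.frame with `angle_deg`, `radius_px`;
#'   interpolated (with wrap) to the map's bin angles.
#' @param reference_row Row index at which the landmark is fixed; default is
#'   the rounded median landmark bin. Use a common value when aligning maps
#'   that will be aggregated together.
#' @return Object of class `aligned_polar_map`: the shifted `grid` plus
#'   `reference_row`, `shifts`, `landmark_bins`, `masked_columns` and
#'   `masked_fraction` (fraction of grid cells masked by the alignment).
#' @export
align_to_landmark <- function(pmap, landmark_polyline, reference_row = NULL) {
  stopifnot(inherits(pmap, "polar_map"))
  n_angle <- dim(pmap$grid)[1]; n_radius <- dim(pmap$grid)[2]
  lr <- interpolate_polyline(landmark_polyline, pmap$angles)
  bins <- as.integer(round(lr / pmap$radial_step)) + 1L
  bad <- is.na(bins) | bins < 1L | bins > n_radius
  if (any(bad)) {
    warning(sum(bad), " column(s) have landmark radius outside the ray; masked")
  }
  reference_row <- as.integer(reference_row %||% round(stats::median(bins[!bad])))
  shifts <- reference_row - bins
  grid <- array(NA_real_, dim = dim(pmap$grid), dimnames = dimnames(pmap$grid))
  for (i in seq_len(n_angle)) {
    if (bad[i]) next
    s <- shifts[i]
    src <- seq_len(n_radius) - s
    valid <- src >= 1L & src <= n_radius
    grid[i, which(valid), ] <- pmap$grid[i, src[valid], ]
  }
  pre_masked <- sum(is.na(pmap$grid))
  structure(list(grid = grid, angles = pmap$angles,
                 radial_step = pmap$radial_step, channels = pmap$channels,
                 reference_row = reference_row, shifts = shifts,
                 landmark_bins = bins, masked_columns = which(bad),
                 masked_fraction = (sum(is.na(grid)) - pre_masked) /
                   length(grid)),
            class = "aligned_polar_map")
}

# order-independent sums: values in each row of `m` are sorted before
# summation so aggregation is bit-identical under permutation of the inputs
.sorted_rows <- function(m) {
  key <- m
  key[is.na(key)] <- Inf # keep masked entries at the row end, per row
  matrix(m[order(row(m), key)], nrow = nrow(m), byrow = TRUE)
}

#' Aggregate aligned polar maps into a per-cell mean/sd/n stack
#'
#' All maps must share bin geometry and reference row. Statistics are
#' computed over unmasked values per grid cell and are bit-identical for any
#' ordering of the input list. Cells with no observations are masked; the sd
#' is 0 wherever n = 1.
#'
#' @param maps List of [align_to_landmark()] results.
#' @param treatment Optional treatment label.
#' @return Object of class `projection_stack`: arrays `mean`, `sd`, `n`
#'   (each `n_angle x n_radius x n_channel`), plus geometry metadata.
#' @export
aggregate_maps <- function(maps, treatment = NA_character_) {
  assert_that(length(maps) >= 1, "need at least one map")
  stopifnot(all(vapply(maps, inherits, logical(1), "aligned_polar_map")))
  ref <- maps[[1]]
  for (m in maps[-1]) {
    assert_that(identical(dim(m$grid), dim(ref$grid)) &&
                  identical(m$radial_step, ref$radial_step) &&
                  identical(m$reference_row, ref$reference_row),
                "maps have mixed bin geometries or reference rows")
  }
  dd <- dim(ref$grid)
  vals <- .sorted_rows(vapply(maps, function(m) as.vector(m$grid),
                              numeric(prod(dd))))
  n <- rowSums(!is.na(vals))
  mean_v <- rowSums(vals, na.rm = TRUE) / n
  sd_v <- sqrt(rowSums((vals - mean_v)^2, na.rm = TRUE) / pmax(n - 1, 1))
  sd_v[n == 1] <- 0
  # identical observations have sd exactly 0 (values are sorted: compare ends)
  all_equal <- vals[, 1] == vals[cbind(seq_len(nrow(vals)), pmax(n, 1))]
  sd_v[!is.na(all_equal) & all_equal] <- 0
  mean_v[n == 0] <- NA_real_
  sd_v[n == 0] <- NA_real_
  shape <- function(v) array(v, dim = dd, dimnames = dimnames(ref$grid))
  structure(list(mean = shape(mean_v), sd = shape(sd_v), n = shape(n),
                 angles = ref$angles, radial_step = ref$radial_step,
                 channels = ref$channels, reference_row = ref$reference_row,
                 n_maps = length(maps), treatment = treatment),
            class = "projection_stack")
}

#' Per-row radial profile of an aligned map or stack
#'
#' Collapses the angular dimension: mean and sd per aligned-radius row and
#' channel, with the row index also given relative to the reference row
#' (0 = landmark).
#'
#' @param x An `aligned_polar_map` or `projection_stack`.
#' @return data.frame with `row`, `rel_row`, `channel`, `mean`, `sd`, `n`.
#' @export
aligned_profile <- function(x) {
  grid <- if (inherits(x, "projection_stack")) x$mean else x$grid
  stopifnot(!is.null(x$reference_row))
  out <- do.call(rbind, lapply(seq_along(x$channels), function(ch) {
    g <- grid[, , ch, drop = FALSE][, , 1]
    data.frame(row = seq_len(ncol(g)),
               rel_row = seq_len(ncol(g)) - x$reference_row,
               channel = x$channels[ch],
               mean = colMeans(g, na.rm = TRUE),
               sd = apply(g, 2, stats::sd, na.rm = TRUE),
               n = colSums(!is.na(g)),
               stringsAsFactors = FALSE)
  }))
  out$mean[out$n == 0] <- NA_real_
  rownames(out) <- NULL
  out
}
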