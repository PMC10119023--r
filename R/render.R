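# Raster rendering of synthetic cross-sections.
#
# Cells are drawn as annular sectors on a concentric wedge lattice: each cell
# file occupies one angular wedge and each cell one radial ring. This is all
# the geometry the polar projection pipeline relies on; no growth mechanics
# or optics are modelled. Channels:
#   wall — bright lines on every ring and wedge boundary;
#   DR5, ANT (and any other marker column) — flat per-cell intensities taken
#   from the cell files;
#   EdU — a small bright nucleus at the centre of each EdU-positive cell.

#' Geometry of a rendered section
#'
#' @param n_cells Cells per file (rings).
#' @param inner_radius Radius of the innermost cell boundary, pixels.
#' @param cell_width Radial width of one cell, pixels.
#' @param pixel_size Physical pixel size, micrometres per pixel.
#' @param margin Blank margin outside the outermost ring, pixels.
#' @return List with `radii` (the `n_cells + 1` increasing ring boundaries),
#'   `pixel_size` and `margin`.
#' @export
section_geometry <- function(n_cells, inner_radius = 20, cell_width = 8,
                             pixel_size = 1, margin = 6) {
  radii <- inner_radius + cell_width * (0:n_cells)
  list(radii = radii, pixel_size = pixel_size, margin = margin)
}

#' Render cell files into a multichannel section image
#'
#' @param files List of [cell_file()] objects (>= 8, one per angular wedge);
#'   all files must have the same cell count and channels.
#' @param geometry A [section_geometry()]; its `radii` must be strictly
#'   increasing with `length(radii) == n_cells + 1`.
#' @param noise_sd Gaussian intensity noise added to every channel
#'   (default 0).
#' @param rng_seed Optional integer seed for the noise.
#' @return Object of class `radial_section`: list with `image`
#'   (`h x w x n_channel` array, channels `wall`, markers..., `edu`),
#'   `channels`, `centre` (x, y, 0-based pixels), `xylem_axis_angle` (90 by
#'   construction: wedge angles are laid out relative to the vertical axis),
#'   `landmark_polyline` (per-degree landmark radius), `pixel_size`, `files`
#'   (the ground truth).
#' @export
#' @examples
#' files <- make_cell_files(load_preset("col0_mock"), 8, rng_seed = 1)
#' sec <- render_section(files, rng_seed = 1)
render_section <- function(files, geometry = NULL, noise_sd = 0,
                           rng_seed = NULL) {
  assert_that(length(files) >= 8, "need at least 8 cell files (angular wedges)")
  stopifnot(all(vapply(files, inherits, logical(1), "cell_file")))
  n_cells <- unique(vapply(files, function(f) nrow(f$cells), integer(1)))
  assert_that(length(n_cells) == 1, "all files must have the same cell count")
  geometry <- geometry %||% section_geometry(n_cells)
  radii <- geometry$radii
  assert_that(length(radii) == n_cells + 1, "geometry needs n_cells + 1 radii")
  assert_that(all(diff(radii) > 0), "radii must be strictly increasing")

  n_wedge <- length(files)
  wedge_breaks <- seq(0, 360, length.out = n_wedge + 1)
  markers <- files[[1]]$channels
  channels <- c("wall", markers, "edu")

  r_max <- max(radii) + geometry$margin
  half <- ceiling(r_max)
  wh <- 2L * half + 1L
  cx <- half; cy <- half # 0-based centre

  # coordinate fields as wh x wh matrices [row (y), col (x)]
  xs <- matrix(rep(0:(wh - 1), each = wh), nrow = wh) # col index per entry
  ys <- matrix(rep(0:(wh - 1), times = wh), nrow = wh)
  ddx <- xs - cx
  ddy <- ys - cy
  r <- sqrt(ddx^2 + ddy^2)
  phi <- (atan2(-ddx, -ddy) * 180 / pi) %% 360 # CCW from vertical

  wedge <- pmin(findInterval(phi, wedge_breaks), n_wedge)
  ring <- findInterval(r, radii) # 0 = inside innermost boundary
  inside <- ring >= 1 & ring <= n_cells & r >= radii[1]

  # distance to the nearest ring boundary
  lo <- pmax(pmin(findInterval(r, radii), length(radii) - 1L), 1L)
  d_ring <- pmin(abs(r - radii[lo]), abs(r - radii[lo + 1L]))
  # arc distance to the nearest wedge boundary
  d_phi <- pmin(abs(phi - wedge_breaks[wedge]), abs(wedge_breaks[wedge + 1L] - phi))
  d_spoke <- d_phi * pi / 180 * r
  in_annulus <- r >= radii[1] - 0.75 & r <= max(radii) + 0.75
  wall <- matrix(0, wh, wh)
  wall[in_annulus & (d_ring <= 0.75 | (d_spoke <= 0.75 & inside))] <- WALL_LEVEL

  cell_lookup <- function(values_by_file) {
    # values_by_file: n_cells x n_wedge matrix -> paint per pixel
    img <- matrix(0, wh, wh)
    sel <- which(inside)
    img[sel] <- values_by_file[cbind(ring[sel], wedge[sel])]
    img
  }

  img <- array(0, dim = c(wh, wh, length(channels)),
               dimnames = list(NULL, NULL, channels))
  img[, , "wall"] <- wall
  for (mk in markers) {
    vals <- vapply(files, function(f) f$cells[[mk]], numeric(n_cells))
    img[, , mk] <- cell_lookup(vals)
  }
  # EdU nuclei: bright discs at the cell centres of EdU-positive cells
  edu <- matrix(0, wh, wh)
  mid_r <- (radii[-1] + radii[-length(radii)]) / 2
  mid_phi <- (wedge_breaks[-1] + wedge_breaks[-(n_wedge + 1)]) / 2
  for (wdg in seq_len(n_wedge)) {
    idx <- which(files[[wdg]]$cells$edu)
    for (ci in idx) {
      dir <- ray_direction(mid_phi[wdg])
      px <- cx + dir[, "dx"] * mid_r[ci]
      py <- cy + dir[, "dy"] * mid_r[ci]
      edu[(xs - px)^2 + (ys - py)^2 <= (0.3 * diff(radii)[ci])^2] <- MARKER_ON
    }
  }
  img[, , "edu"] <- edu

  if (noise_sd > 0) {
    img <- with_opt_seed(rng_seed,
      array(pmax(0, img + stats::rnorm(length(img), 0, noise_sd)),
            dim = dim(img), dimnames = dimnames(img)))
  }

  # per-degree landmark polyline, piecewise constant across each wedge
  ang <- 0:359 + 0.5
  wdg_of_ang <- pmin(findInterval(ang, wedge_breaks), n_wedge)
  lm_radius <- vapply(files, function(f) radii[f$landmark_index + 1L], numeric(1))
  polyline <- data.frame(angle_deg = ang, radius_px = lm_radius[wdg_of_ang])

  structure(list(image = img, channels = channels,
                 centre = c(x = cx, y = cy), xylem_axis_angle = 90,
                 landmark_polyline = polyline,
                 pixel_size = geometry$pixel_size,
                 wedge_breaks = wedge_breaks, radii = radii, files = files),
            class = "radial_section")
}

#' @export
print.radial_section <- function(x, ...) {
  cat(sprintf("<radial_section> %d x %d px, channels: %s, centre (%g, %g)\n",
              dim(x$image)[1], dim(x$image)[2],
              paste(x$channels, collapse = ", "),
              x$centre[["x"]], x$centre[["y"]]))
  invisible(x)
}
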