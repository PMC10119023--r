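# shared fixtures, all built in code

# a loaded preset with selected distributions overridden
preset_with <- function(base = "col0_mock", end = NULL, spread = NULL,
                        edu = NULL, noise_sd = NULL) {
  p <- load_preset(base)
  if (!is.null(end)) {
    probs <- stats::setNames(rep(0, 5), c("le_m3", "m2", "m1", "p1", "ge_p2"))
    probs[names(end)] <- end
    p$end_position_probs <- probs / sum(probs)
  }
  if (!is.null(spread)) p$spread_probs <- spread / sum(spread)
  if (!is.null(edu)) p$edu_probs <- edu / sum(edu)
  if (!is.null(noise_sd)) p$noise_sd <- noise_sd
  p
}

# hand-built cell file from an identity vector and per-cell intensities
toy_file <- function(identity, landmark_index, DR5 = NULL, ANT = NULL,
                     edu = NULL, apl = NULL) {
  n <- length(identity)
  cells <- data.frame(
    identity = identity,
    edu = edu %||% rep(FALSE, n),
    apl = apl %||% (identity == "sieve_element"),
    DR5 = DR5 %||% rep(50, n),
    ANT = ANT %||% rep(50, n),
    stringsAsFactors = FALSE
  )
  cell_file(cells, landmark_index = landmark_index, channels = c("DR5", "ANT"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# single-channel section holding an arbitrary image matrix (0-based centre)
matrix_section <- function(img, cx, cy, axis_angle = 90,
                           landmark_radius = 50) {
  structure(list(
    image = array(img, c(nrow(img), ncol(img), 1),
                  dimnames = list(NULL, NULL, "m")),
    channels = "m", centre = c(x = cx, y = cy),
    xylem_axis_angle = axis_angle,
    landmark_polyline = data.frame(angle_deg = 0:359,
                                   radius_px = landmark_radius),
    pixel_size = 1), class = "radial_section")
}

# smooth off-centre Gaussian blob on a flat background
blob_image <- function(h = 201, x0 = 130, y0 = 80, amp = 500, sigma = 40) {
  xs <- matrix(rep(0:(h - 1), each = h), nrow = h)
  ys <- matrix(rep(0:(h - 1), times = h), nrow = h)
  amp * exp(-((xs - x0)^2 + (ys - y0)^2) / (2 * sigma^2)) + 100
}

# brute-force nearest-neighbour polar sampler (independent oracle for unwrap)
nn_unwrap <- function(sec, n_angle_bins, radial_step = 1) {
  img <- sec$image[, , 1]
  h <- nrow(img); w <- ncol(img)
  cx <- sec$centre[["x"]]; cy <- sec$centre[["y"]]
  max_radius <- sqrt(max((c(0, w - 1) - cx)^2) + max((c(0, h - 1) - cy)^2))
  radii <- seq(0, max_radius, by = radial_step)
  out <- matrix(NA_real_, n_angle_bins, length(radii))
  for (i in seq_len(n_angle_bins)) {
    a <- (i - 1) * 360 / n_angle_bins * pi / 180
    for (j in seq_along(radii)) {
      x <- round(cx - radii[j] * sin(a)); y <- round(cy - radii[j] * cos(a))
      if (x >= 0 && x <= w - 1 && y >= 0 && y <= h - 1) out[i, j] <- img[y + 1, x + 1]
    }
  }
  out
}

# brute-force recount oracle for cell-type counting: walk the file cell by
# cell and tally with explicit position logic
recount_oracle <- function(file) {
  n <- nrow(file$cells); L <- file$landmark_index
  vessels <- parenchyma <- xylem <- phloem <- sieve <- apl <- 0L
  for (i in seq_len(n)) {
    id <- file$cells$identity[i]
    if (i <= L) {
      xylem <- xylem + 1L
      if (id == "vessel") vessels <- vessels + 1L else parenchyma <- parenchyma + 1L
    } else if (id != "periderm") {
      phloem <- phloem + 1L
      if (id == "sieve_element") sieve <- sieve + 1L
      if (isTRUE(file$cells$apl[i])) apl <- apl + 1L
    }
  }
  list(vessels = vessels, xylem_parenchyma = parenchyma, xylem_total = xylem,
       phloem_total = phloem, sieve_elements = sieve, apl_positive = apl)
}

random_count_table <- function(nr, nc) {
  matrix(stats::rpois(nr * nc, lambda = 20) + 1, nr, nc)
}
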