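test_that("unwrapping a constant image gives a constant grid", {
  sec <- matrix_section(matrix(7, 101, 101), 50, 50)
  pm <- unwrap(sec, n_angle_bins = 36, radial_step = 2)
  vals <- pm$grid[, , 1]
  expect_true(all(abs(vals[!is.na(vals)] - 7) < 1e-9))
  # truncation: corners of the square image are masked, never extrapolated
  expect_true(any(is.na(vals)))
})

test_that("a bright annulus unwraps to a constant argmax radius", {
  h <- 151; cx <- cy <- 75; r0 <- 40
  xs <- matrix(rep(0:(h - 1), each = h), nrow = h)
  ys <- matrix(rep(0:(h - 1), times = h), nrow = h)
  img <- exp(-((sqrt((xs - cx)^2 + (ys - cy)^2) - r0)^2) / 4) * 100
  pm <- unwrap(matrix_section(img, cx, cy), n_angle_bins = 90, radial_step = 1)
  argmax <- apply(pm$grid[, , 1], 1, which.max) - 1
  expect_true(all(abs(argmax - r0) <= 1))
})

test_that("unwrap agrees with a brute-force nearest-neighbour sampler on a smooth image", {
  sec <- matrix_section(blob_image(), 100, 100)
  pm <- unwrap(sec, n_angle_bins = 90, radial_step = 2)
  nn <- nn_unwrap(sec, 90, radial_step = 2)
  ok <- !is.na(nn) & !is.na(pm$grid[, , 1])
  mad <- mean(abs(pm$grid[, , 1][ok] - nn[ok]))
  expect_lt(mad / mean(nn[ok]), 0.02)
})

test_that("unwrap validates its inputs", {
  sec <- matrix_section(matrix(1, 50, 50), 200, 10)
  expect_error(unwrap(sec), "outside the image")
  sec2 <- matrix_section(matrix(1, 50, 50), 25, 25)
  expect_error(unwrap(sec2, n_angle_bins = 4), "8 angular bins")
})

test_that("polar-map mean weighted by annulus area matches the image mean in the disc", {
  sec <- matrix_section(blob_image(), 100, 100)
  pm <- unwrap(sec, n_angle_bins = 180, radial_step = 1)
  R <- 90
  radii <- (seq_len(dim(pm$grid)[2]) - 1) * pm$radial_step
  keep <- radii <= R & radii > 0
  w <- radii[keep]
  polar_mean <- sum(t(pm$grid[, keep, 1]) * w) / (sum(w) * length(pm$angles))
  h <- nrow(sec$image)
  xs <- matrix(rep(0:(h - 1), each = h), nrow = h)
  ys <- matrix(rep(0:(h - 1), times = h), nrow = h)
  disc <- (xs - 100)^2 + (ys - 100)^2 <= R^2
  img_mean <- mean(sec$image[, , 1][disc])
  expect_lt(abs(polar_mean - img_mean) / img_mean, 0.03)
})

test_that("rotation is the identity for a vertical axis and consistent for 90 degrees", {
  sec <- matrix_section(blob_image(), 100, 100, axis_angle = 90)
  expect_identical(rotate_section(sec)$image, sec$image)
  # axis at 0 degrees: the image is rotated by +90, a landmark point at
  # angle theta maps to theta + 90
  sec0 <- matrix_section(blob_image(), 100, 100, axis_angle = 0)
  rot <- rotate_section(sec0, fill = 0)
  expect_equal(rot$xylem_axis_angle, 90)
  expect_equal(sort(unique((sec0$landmark_polyline$angle_deg + 90) %% 360)),
               sort(unique(rot$landmark_polyline$angle_deg)))
  expect_error(rotate_section(matrix_section(blob_image(), 100, 100,
                                             axis_angle = NA)),
               "axis")
})

test_that("rotating by an angle and back reconstructs the section", {
  files <- make_cell_files(load_preset("col0_mock"), 10, rng_seed = 4)
  sec <- render_section(files)
  sec$xylem_axis_angle <- 35
  rot <- rotate_section(sec, fill = 0)
  rot$xylem_axis_angle <- 90 + 55 # undo: rotate back by -55
  back <- rotate_section(rot, fill = 0)
  h <- dim(sec$image)[1]
  xs <- matrix(rep(0:(h - 1), each = h), nrow = h)
  ys <- matrix(rep(0:(h - 1), times = h), nrow = h)
  disc <- (xs - sec$centre[["x"]])^2 + (ys - sec$centre[["y"]])^2 <=
    max(sec$radii)^2
  for (ch in c("DR5", "ANT")) {
    expect_gt(stats::cor(back$image[, , ch][disc], sec$image[, , ch][disc]),
              0.99)
  }
})

test_that("alignment pins the landmark to the reference row", {
  # synthetic polar map with a bright line following a sawtooth landmark
  n_angle <- 48; n_radius <- 60
  bins <- 20 + (seq_len(n_angle) %% 7)
  grid <- array(0, c(n_angle, n_radius, 1), dimnames = list(NULL, NULL, "m"))
  grid[cbind(seq_len(n_angle), bins, 1)] <- 100
  pmap <- structure(list(grid = grid, angles = (0:(n_angle - 1)) * 360 / n_angle,
                         radial_step = 1, channels = "m",
                         centre = c(x = 0, y = 0), pixel_size = 1),
                    class = "polar_map")
  poly <- data.frame(angle_deg = pmap$angles, radius_px = bins - 1)
  am <- align_to_landmark(pmap, poly, reference_row = 30)
  expect_true(all(am$grid[, 30, 1] == 100))
  expect_equal(stats::var(am$landmark_bins + am$shifts), 0)
  expect_equal(sum(am$grid[, -30, 1] == 100, na.rm = TRUE), 0)
  # constant polyline: all shifts equal, reference row is row r of the input
  flat <- data.frame(angle_deg = pmap$angles, radius_px = 24)
  am2 <- align_to_landmark(pmap, flat, reference_row = 40)
  expect_equal(unique(am2$shifts), 40 - 25)
  expect_identical(am2$grid[, 40, 1], pmap$grid[, 25, 1])
  # idempotence: aligning an aligned map with its landmark at the reference
  # row changes nothing
  pm3 <- structure(list(grid = am2$grid, angles = pmap$angles, radial_step = 1,
                        channels = "m", centre = c(x = 0, y = 0),
                        pixel_size = 1), class = "polar_map")
  am3 <- align_to_landmark(pm3, data.frame(angle_deg = pmap$angles,
                                           radius_px = 39),
                           reference_row = 40)
  expect_identical(am3$grid, am2$grid)
  # out-of-range landmark radii mask the column with a warning
  badpoly <- data.frame(angle_deg = pmap$angles,
                        radius_px = c(rep(24, n_angle - 1), 500))
  expect_warning(amb <- align_to_landmark(pmap, badpoly, reference_row = 40),
                 "masked")
  expect_true(all(is.na(amb$grid[n_angle, , 1])))
  expect_gt(amb$masked_fraction, 0)
})

test_that("the aligned marker profile peaks on the side the preset prescribes", {
  # all gradient ends deep in the xylem -> supra-threshold marker mass must
  # sit on the xylem side of the reference row
  p <- preset_with(end = c(m2 = 1), noise_sd = 0)
  files <- make_cell_files(p, 10, rng_seed = 6)
  sec <- render_section(files)
  am <- align_to_landmark(unwrap(sec, n_angle_bins = 120),
                          sec$landmark_polyline)
  prof <- aligned_profile(am)
  dr5 <- prof[prof$channel == "DR5" & prof$n > 0, ]
  expect_gt(max(dr5$mean[dr5$rel_row < 0]), max(dr5$mean[dr5$rel_row > 0]))
})

test_that("aggregation is exact for identical maps and order-invariant", {
  files <- make_cell_files(load_preset("col0_mock"), 10, rng_seed = 8)
  sec <- render_section(files, noise_sd = 10, rng_seed = 1)
  am <- align_to_landmark(unwrap(sec, n_angle_bins = 60), sec$landmark_polyline)
  st <- aggregate_maps(list(am, am, am))
  unmasked <- !is.na(am$grid)
  expect_equal(st$mean[unmasked], am$grid[unmasked])
  expect_true(all(st$sd[unmasked] == 0))
  expect_true(all(st$n[unmasked] == 3))
  expect_true(all(st$n[!unmasked] == 0))
  # permutation invariance, bit-identical
  sec2 <- render_section(files, noise_sd = 10, rng_seed = 2)
  am2 <- align_to_landmark(unwrap(sec2, n_angle_bins = 60),
                           sec2$landmark_polyline)
  s_a <- aggregate_maps(list(am, am2))
  s_b <- aggregate_maps(list(am2, am))
  expect_identical(s_a$mean, s_b$mean)
  expect_identical(s_a$sd, s_b$sd)
  expect_identical(s_a$n, s_b$n)
  # mixed geometries are rejected
  am3 <- align_to_landmark(unwrap(sec, n_angle_bins = 30), sec$landmark_polyline)
  expect_error(aggregate_maps(list(am, am3)), "mixed")
})
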