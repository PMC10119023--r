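test_that("fate parameters validate and the presets satisfy their constraints", {
  expect_error(fate_params(0.5, 0.4, 0.2), "sum to 1")
  expect_error(fate_params(-0.1, 1.1, 0), "0, 1")
  mock <- load_preset("fate_mock")$fate
  expect_equal(mock$q_x, mock$q_p)
  expect_equal(mock$q_d, 0)
  low <- load_preset("fate_lowGA")$fate
  expect_gt(low$q_p, low$q_x)
  hi <- load_preset("fate_highGA")$fate
  expect_gt(hi$q_x, hi$q_p)
  expect_gt(hi$q_d, 0)
})

test_that("degenerate parameters produce the forced outcome streams", {
  all_x <- fate_params(1, 0, 0)
  st <- new_file_state(origin = "ant_stem_cell")
  n0 <- length(st$identity)
  for (k in 1:6) st <- fate_step(st, all_x)
  expect_equal(length(st$identity), n0 + 6) # one new cell per cycle
  expect_equal(sum(st$identity == "stem"), 1)
  expect_equal(sum(st$identity == "xylem"), 3 + 6)
  expect_equal(sum(st$identity == "phloem"), 3)
  all_p <- fate_params(0, 1, 0)
  st <- new_file_state(origin = "ant_stem_cell")
  for (k in 1:6) st <- fate_step(st, all_p)
  expect_equal(sum(st$identity == "phloem"), 3 + 6)
  # the stem remains the innermost non-xylem cell
  expect_equal(st$stem, max(which(st$identity == "xylem")) + 1)
})

test_that("double-xylem respecifies the adjacent phloem cell and can exhaust the file", {
  par <- fate_params(0, 0, 1)
  st <- new_file_state(n_xylem = 2, n_phloem = 2, origin = "ant_stem_cell")
  st <- fate_step(st, par)
  # both daughters xylem, former adjacent phloem cell is now the stem
  expect_equal(sum(st$identity == "xylem"), 4)
  expect_equal(sum(st$identity == "stem"), 1)
  expect_equal(sum(st$identity == "phloem"), 1)
  expect_false(st$terminated)
  st <- fate_step(st, par)
  expect_false(st$terminated)
  st <- fate_step(st, par) # no phloem cell left to respecify
  expect_true(st$terminated)
  expect_error(fate_step(st, par), "terminated")
})

test_that("exactly one stem cell exists after every completed cycle", {
  params <- load_preset("fate_highGA")$fate
  withr::with_seed(23, {
    for (k in 1:50) {
      st <- new_file_state(origin = "ant_stem_cell")
      for (j in 1:5) {
        st <- fate_step(st, params)
        if (st$terminated) break
        expect_equal(sum(st$identity == "stem"), 1)
      }
    }
  })
})

test_that("event-log outcome frequencies recover the parameters within 3 sigma", {
  params <- load_preset("fate_highGA")$fate
  cohort <- simulate_cohort("ant_stem_cell", params, 600, rng_seed = 19)
  counts <- cohort$outcome_counts
  n <- sum(counts)
  probs <- c(params$q_x, params$q_p, params$q_d)
  for (i in 1:3) {
    expect_lt(abs(counts[[i]] / n - probs[i]),
              3 * sqrt(probs[i] * (1 - probs[i]) / n))
  }
})

test_that("symmetric parameters give symmetric sector extents", {
  cohort <- simulate_cohort("ant_stem_cell", load_preset("fate_mock")$fate,
                            500, rng_seed = 29)
  diffs <- vapply(cohort$sectors, function(s) s$n_xylem - s$n_phloem, numeric(1))
  expect_lt(abs(mean(diffs)), 3 * stats::sd(diffs) / sqrt(length(diffs)))
})

test_that("a phloem-origin clone can never regain stem identity without double events", {
  # without double events the labelled phloem cell never proliferates, so
  # the extent summary is flagged undefined as well
  expect_warning(
    cohort <- simulate_cohort("pear1_phloem", load_preset("fate_mock")$fate,
                              300, rng_seed = 37),
    "min_size")
  cls <- vapply(cohort$sectors, classify_sector, character(1))
  expect_equal(sum(cls == "stem_regain"), 0)
})

test_that("enumeration matches simulation and carries the calibrated class rates", {
  params <- load_preset("fate_highGA")$fate
  for (origin in c("ant_stem_cell", "pear1_phloem")) {
    probs <- enumerate_sector_classes(origin, params)
    expect_equal(sum(probs), 1, tolerance = 1e-9)
    cohort <- simulate_cohort(origin, params, 800, rng_seed = 41)
    cls <- vapply(cohort$sectors, classify_sector, character(1))
    for (cl in names(probs)) {
      se3 <- 3 * sqrt(probs[[cl]] * (1 - probs[[cl]]) / 800)
      expect_lt(abs(mean(cls == cl) - probs[[cl]]), se3 + 1e-12)
    }
  }
  # the calibration reproduces both printed sector-class frequencies closely
  expect_lt(abs(enumerate_sector_classes("ant_stem_cell", params)[["xylem_only"]]
                - 0.21), 0.02)
  expect_lt(abs(enumerate_sector_classes("pear1_phloem", params)[["stem_regain"]]
                - 0.21), 0.025)
})

test_that("cohorts are reproducible for a fixed seed", {
  a <- simulate_cohort("ant_stem_cell", load_preset("fate_highGA")$fate, 25,
                       rng_seed = 43)
  b <- simulate_cohort("ant_stem_cell", load_preset("fate_highGA")$fate, 25,
                       rng_seed = 43)
  expect_identical(a$sectors, b$sectors)
  one <- suppressWarnings(simulate_cohort("random_cambium",
                                          load_preset("fate_mock")$fate, 1,
                                          rng_seed = 44))
  expect_false(one$summary$sd_defined)
})
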