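test_that("position indexing skips 0 and negates under file reversal", {
  expect_identical(index_positions(6, landmark_index = 2),
                   c(-2L, -1L, 1L, 2L, 3L, 4L))
  expect_identical(index_positions(2, landmark_index = 1), c(-1L, 1L))
  withr::with_seed(1, {
    for (k in 1:50) {
      n <- sample(4:12, 1)
      L <- sample(seq_len(n - 1), 1)
      pos <- index_positions(n, landmark_index = L)
      expect_false(any(pos == 0))
      expect_identical(diff(pos[pos < 0]), rep(1L, sum(pos < 0) - 1))
      # reversing the file mirrors the landmark and negates positions
      expect_identical(rev(-pos), index_positions(n, landmark_index = n - L))
    }
  })
  expect_error(index_positions(5, landmark_index = NA), "landmark")
  expect_error(index_positions(5, landmark_index = 5), "out of range")
})

test_that("gradient_end follows the contiguous run holding the maximum", {
  f <- toy_file(c("vessel", "xylem_parenchyma", "stem_daughter",
                  "stem_daughter", "phloem"), 3,
                DR5 = c(1000, 1000, 1000, 50, 50))
  expect_identical(gradient_end(f, "DR5", 0.25), -1L)
  sat <- toy_file(rep(c("xylem_parenchyma", "phloem"), each = 2), 2,
                  DR5 = rep(1000, 4))
  expect_identical(gradient_end(sat, "DR5", 0.25), 2L)
  # discontinuous expression: contiguous mode stops at the main run,
  # anywhere mode reports the outermost supra-threshold cell
  disc <- toy_file(c("vessel", "xylem_parenchyma", "stem_daughter",
                     "stem_daughter", "phloem", "phloem"), 3,
                   DR5 = c(1000, 900, 50, 50, 800, 50))
  expect_identical(gradient_end(disc, "DR5", 0.25), -2L)
  expect_identical(gradient_end(disc, "DR5", 0.25, mode = "anywhere"), 2L)
  # results are insensitive to the threshold over a broad range
  for (tf in c(0.1, 0.25, 0.4, 0.6)) {
    expect_identical(gradient_end(f, "DR5", tf), -1L)
  }
})

test_that("files with no supra-threshold cell yield the sentinel, tallied apart", {
  f <- toy_file(c("xylem_parenchyma", "stem_daughter", "stem_daughter",
                  "phloem"), 2, DR5 = c(0, 0, 0, 0))
  expect_true(is.na(gradient_end(f, "DR5", 0.25)))
  d <- position_distribution(c(-1L, 1L, NA, -2L, NA))
  expect_equal(d$n, 3)
  expect_equal(d$n_no_expression, 2)
})

test_that("fraction_reaching sums exact counts and grows with the target set", {
  d <- position_distribution(c(rep(-2L, 5), rep(-1L, 3), rep(1L, 2)))
  expect_equal(fraction_reaching(d, c(-1, 1)), 0.5)
  expect_equal(fraction_reaching(d, c(-3, -2, -1, 1, 2)), 1.0)
  expect_error(fraction_reaching(position_distribution(integer(0)), c(-1, 1)),
               "empty")
  withr::with_seed(2, {
    ends <- sample(c(-4:-1, 1:3), 200, replace = TRUE)
    d <- position_distribution(ends)
    sets <- list(c(-1), c(-1, 1), c(-2, -1, 1), c(-3, -2, -1, 1, 2))
    fr <- vapply(sets, fraction_reaching, numeric(1), dist = d)
    expect_true(all(diff(fr) >= 0))
  })
})

test_that("spread classification matches its definition", {
  both <- toy_file(c("xylem_parenchyma", "stem_daughter", "stem_daughter",
                     "phloem"), 2, ANT = c(50, 1000, 1000, 50))
  expect_identical(classify_spread(both), "both_daughters")
  ponly <- toy_file(c("xylem_parenchyma", "stem_daughter", "stem_daughter",
                      "phloem"), 2, ANT = c(50, 50, 1000, 1000))
  expect_identical(classify_spread(ponly), "phloem_only")
  xonly <- toy_file(c("xylem_parenchyma", "stem_daughter", "stem_daughter",
                      "phloem"), 2, ANT = c(50, 1000, 50, 50))
  expect_identical(classify_spread(xonly), "other")
})

test_that("EdU classification partitions nuclei around the marker domain", {
  f <- toy_file(c("xylem_parenchyma", "stem_daughter", "stem_daughter",
                  "phloem"), 2, ANT = c(50, 1000, 1000, 50),
                edu = c(FALSE, TRUE, FALSE, FALSE))
  expect_identical(classify_edu(f)$classes, "overlap_ant")
  g <- toy_file(c("xylem_parenchyma", "stem_daughter", "stem_daughter",
                  "phloem"), 2, ANT = c(50, 50, 1000, 50),
                edu = c(TRUE, FALSE, FALSE, FALSE))
  expect_identical(classify_edu(g)$classes, "xylem_side")
  # phloem-ward nuclei are excluded from the two-class tally, not dropped
  h <- toy_file(c("xylem_parenchyma", "stem_daughter", "stem_daughter",
                  "phloem"), 2, ANT = c(50, 1000, 1000, 50),
                edu = c(FALSE, FALSE, FALSE, TRUE))
  res <- classify_edu(h)
  expect_length(res$classes, 0)
  expect_equal(res$n_excluded, 1)
  none <- toy_file(c("xylem_parenchyma", "stem_daughter", "stem_daughter",
                     "phloem"), 2, ANT = c(50, 1000, 1000, 50))
  expect_true(classify_edu(none)$empty)
})

test_that("cell-type counts match a hand count and the brute-force recount", {
  f <- toy_file(c("vessel", "xylem_parenchyma", "stem_daughter",
                  "stem_daughter", "phloem", "sieve_element", "periderm"), 3)
  ct <- count_cell_types(f)
  expect_equal(ct$vessels, 1)
  expect_equal(ct$xylem_total, 3)
  expect_equal(ct$phloem_total, 3)
  expect_equal(ct$sieve_elements, 1)
  expect_equal(ct$xylem_total, ct$vessels + ct$xylem_parenchyma)
  allx <- toy_file(c("vessel", "xylem_parenchyma", "xylem_parenchyma",
                     "stem_daughter"), 3)
  expect_equal(count_cell_types(allx)$phloem_total, 1)
  files <- unlist(lapply(c("col0_mock", "edu_ga"), function(nm)
    make_cell_files(load_preset(nm), 100, rng_seed = 13)), recursive = FALSE)
  for (f in files) {
    ct <- count_cell_types(f)
    oracle <- recount_oracle(f)
    expect_equal(unclass(ct)[names(oracle)], oracle)
    expect_lte(ct$sieve_elements, ct$phloem_total)
    expect_lte(ct$apl_positive, ct$phloem_total)
  }
})

test_that("apl_ratio divides labelled by total phloem and flags empty phloem", {
  f <- toy_file(c("stem_daughter", "stem_daughter", rep("phloem", 3),
                  "sieve_element"), 1)
  expect_equal(apl_ratio(count_cell_types(f)), 0.2)
  f$cells$apl <- FALSE
  expect_equal(apl_ratio(count_cell_types(f)), 0)
  allx <- toy_file(c("vessel", "stem_daughter", "periderm"), 2)
  expect_warning(r <- apl_ratio(count_cell_types(allx)), "undefined")
  expect_true(is.na(r))
})

test_that("control normalisation gives the control group mean exactly 1", {
  vals <- c(2, 2, 3, 1)
  grp <- c("wt", "wt", "tr", "tr")
  norm <- normalize_by_control(vals, grp, "wt")
  expect_equal(norm, c(1, 1, 1.5, 0.5))
  expect_equal(mean(norm[grp == "wt"]), 1)
  withr::with_seed(8, {
    batch <- rep(paste0("b", 1:4), each = 6)
    grp <- rep(c("wt", "wt", "wt", "tr", "tr", "tr"), 4)
    vals <- stats::runif(24, 1, 5)
    norm <- normalize_by_control(vals, grp, "wt", batch = batch)
    for (b in unique(batch)) {
      sel <- batch == b
      expect_equal(norm[sel], vals[sel] / mean(vals[sel & grp == "wt"]))
      expect_equal(mean(norm[sel & grp == "wt"]), 1)
    }
  })
  expect_error(normalize_by_control(c(0, 0, 1), c("wt", "wt", "tr"), "wt"),
               "zero")
})

test_that("the chi-square statistic matches hand values and stats::chisq.test", {
  hom <- chi_square_test(rbind(c(10, 10), c(10, 10)))
  expect_equal(hom$statistic, 0)
  expect_equal(hom$p.value, 1)
  diag <- chi_square_test(rbind(c(20, 0), c(0, 20)))
  expect_equal(diag$statistic, 40)
  expect_equal(diag$df, 1)
  withr::with_seed(99, {
    for (k in 1:100) {
      x <- random_count_table(sample(2:4, 1), sample(2:5, 1))
      ours <- chi_square_test(x)
      ref <- suppressWarnings(stats::chisq.test(x, correct = FALSE))
      expect_lt(abs(ours$statistic - unname(ref$statistic)), 1e-10)
      expect_lt(abs(ours$p.value - ref$p.value), 1e-10)
      expect_equal(ours$df, unname(ref$parameter))
    }
    x <- random_count_table(2, 2)
    yates <- chi_square_test(x, correct = TRUE)
    ref <- suppressWarnings(stats::chisq.test(x, correct = TRUE))
    expect_lt(abs(yates$statistic - unname(ref$statistic)), 1e-10)
  })
  expect_error(chi_square_test(rbind(c(0, 0), c(3, 4))), "merge")
})

test_that("score_files reports exclusions instead of dropping files", {
  files <- make_cell_files(load_preset("col0_mock"), 10, rng_seed = 21)
  files[[3]]$landmark_index <- NA_integer_
  res <- score_files(files)
  expect_equal(nrow(res$scores), 9)
  expect_equal(res$exclusions$file_id, "file_3")
  expect_equal(res$exclusions$reason, "no_landmark")
})
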