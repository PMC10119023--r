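# Positional quantification rules for radial cell files: signed position
# indexing around the landmark wall, marker gradient reach, stem-cell marker
# spread classes, EdU overlap classes, cell-type counts, ratios, control
# normalisation, and the chi-square comparison of categorical position
# tables.

#' Signed cell positions relative to the landmark wall
#'
#' The cell just inward of the landmark wall is position -1, the cell just
#' outward is 1; positions run ..., -2, -1, 1, 2, ... with no position 0
#' (negative towards the xylem, positive towards the phloem).
#'
#' @param file A [cell_file()], or an integer cell count combined with
#'   `landmark_index`.
#' @param landmark_index Overrides the file's landmark (required when `file`
#'   is a count).
#' @return Integer vector of positions, one per cell, innermost first.
#' @export
#' @examples
#' index_positions(6, landmark_index = 2) # -2 -1 1 2 3 4
index_positions <- function(file, landmark_index = NULL) {
  if (inherits(file, "cell_file")) {
    n <- nrow(file$cells)
    landmark_index <- landmark_index %||% file$landmark_index
  } else {
    n <- as.integer(file)
  }
  assert_that(!is.null(landmark_index) && !is.na(landmark_index),
              "landmark_index is missing; files without a recognizable landmark cannot be scored")
  L <- as.integer(landmark_index)
  assert_that(L >= 1 && L <= n - 1, "landmark_index out of range")
  i <- seq_len(n)
  ifelse(i <= L, i - L - 1L, i - L)
}

# per-file intensity threshold: fraction of the file's maximum in a channel
channel_threshold <- function(file, channel, threshold_fraction) {
  assert_that(channel %in% file$channels, "unknown channel '%s'", channel)
  threshold_fraction * max(file$cells[[channel]])
}

#' Position at which a marker gradient ends ("reach")
#'
#' A cell expresses the marker when its intensity exceeds
#' `threshold_fraction` times the file's maximum for that channel. In the
#' default `"contiguous"` mode the reach is the most phloem-ward position of
#' the contiguous supra-threshold run containing the brightest cell; mode
#' `"anywhere"` returns the most phloem-ward supra-threshold position
#' regardless of contiguity (for markers with discontinuous expression).
#'
#' @param file A [cell_file()].
#' @param channel Channel name (e.g. `"DR5"`).
#' @param threshold_fraction Fraction of the per-file maximum (default 0.25).
#' @param mode `"contiguous"` (default) or `"anywhere"`.
#' @return The signed end position, or `NA` (sentinel for "no expression",
#'   to be tallied separately, never dropped silently).
#' @export
#' @examples
#' cf <- make_cell_file(load_preset("col0_mock"), rng_seed = 1)
#' gradient_end(cf, "DR5")
gradient_end <- function(file, channel, threshold_fraction = 0.25,
                         mode = c("contiguous", "anywhere")) {
  mode <- match.arg(mode)
  stopifnot(inherits(file, "cell_file"))
  pos <- index_positions(file)
  x <- file$cells[[channel]]
  on <- x > channel_threshold(file, channel, threshold_fraction)
  if (!any(on)) return(NA_integer_)
  if (mode == "anywhere") return(pos[max(which(on))])
  runs <- rle(on)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  imax <- which.max(x)
  k <- which(starts <= imax & imax <= ends & runs$values)
  pos[ends[k]]
}

#' Tabulate gradient end positions into a categorical distribution
#'
#' Counts end positions into the bins `<=-3, -2, -1, 1, >=2`; files whose
#' marker never exceeded threshold (`NA` reach) are tallied separately in
#' `n_no_expression` and excluded from `n`.
#'
#' @param ends Integer vector of end positions (may contain `NA`).
#' @param condition Optional condition label.
#' @return Object of class `position_distribution` with elements `counts`
#'   (named integer vector over the bins), `n`, `n_no_expression`,
#'   `condition`.
#' @export
position_distribution <- function(ends, condition = NA_character_) {
  scored <- ends[!is.na(ends)]
  assert_that(!any(scored == 0), "position 0 does not exist")
  bins <- cut(scored, breaks = c(-Inf, -2.5, -1.5, 0, 1.5, Inf),
              labels = POSITION_BINS)
  structure(list(counts = stats::setNames(as.integer(table(bins)), POSITION_BINS),
                 n = length(scored),
                 n_no_expression = sum(is.na(ends)),
                 condition = condition),
            class = "position_distribution")
}

#' @export
print.position_distribution <- function(x, ...) {
  cat("<position_distribution>",
      if (!is.na(x$condition)) x$condition else "", "n =", x$n, "\n")
  lab <- c("<=-3", "-2", "-1", "1", ">=2")
  cat(" ", paste(sprintf("%s:%d", lab, x$counts), collapse = "  "),
      sprintf(" (no expression: %d)\n", x$n_no_expression))
  invisible(x)
}

# map integer target positions onto distribution bins
positions_to_bins <- function(targets) {
  assert_that(!any(targets == 0), "position 0 does not exist")
  unique(ifelse(targets <= -3, "le_m3",
         ifelse(targets == -2, "m2",
         ifelse(targets == -1, "m1",
         ifelse(targets == 1, "p1", "ge_p2")))))
}

#' Fraction of files whose gradient end falls in a target set of positions
#'
#' Counts are summed exactly (integer arithmetic) before the single final
#' division by `n`. Target positions `<= -3` or `>= 2` address the
#' corresponding tail bins.
#'
#' @param dist A [position_distribution()].
#' @param target_positions Integer positions, e.g. `c(-1, 1)`.
#' @return Fraction in `[0, 1]`.
#' @export
#' @examples
#' d <- position_distribution(c(-2, -2, -2, -2, -2, -1, -1, -1, 1, 1))
#' fraction_reaching(d, c(-1, 1)) # 0.5
fraction_reaching <- function(dist, target_positions) {
  stopifnot(inherits(dist, "position_distribution"))
  assert_that(dist$n > 0, "empty position distribution")
  sum(dist$counts[positions_to_bins(target_positions)]) / dist$n
}

#' Spread class of a stem-cell domain marker over the two daughters
#'
#' `both_daughters` when positions -1 and 1 are both supra-threshold,
#' `phloem_only` when only position 1 is, `other` otherwise.
#'
#' @inheritParams gradient_end
#' @return One of `"both_daughters"`, `"phloem_only"`, `"other"`.
#' @export
classify_spread <- function(file, channel = "ANT", threshold_fraction = 0.25) {
  stopifnot(inherits(file, "cell_file"))
  pos <- index_positions(file)
  on <- file$cells[[channel]] > channel_threshold(file, channel, threshold_fraction)
  m1 <- on[pos == -1L]; p1 <- on[pos == 1L]
  if (m1 && p1) "both_daughters" else if (p1 && !m1) "phloem_only" else "other"
}

#' Classify EdU-positive nuclei relative to the stem-cell marker domain
#'
#' Each EdU-positive cell is `overlap_ant` when it lies within the
#' supra-threshold marker domain (the contiguous run containing the brightest
#' cell) and `xylem_side` when it lies inward of it. Cells phloem-ward of the
#' domain are excluded from the two-class tally (`n_excluded` reports them).
#'
#' @inheritParams gradient_end
#' @param ant_channel Stem-cell marker channel (default `"ANT"`).
#' @return List with `classes` (character vector, one entry per classified
#'   EdU cell), `n_excluded`, and `empty` (TRUE when the file has no
#'   EdU-positive cell, flagged rather than dropped).
#' @export
classify_edu <- function(file, ant_channel = "ANT", threshold_fraction = 0.25) {
  stopifnot(inherits(file, "cell_file"))
  pos <- index_positions(file)
  edu_pos <- pos[file$cells$edu]
  if (!length(edu_pos)) {
    return(list(classes = character(0), n_excluded = 0L, empty = TRUE))
  }
  x <- file$cells[[ant_channel]]
  on <- x > channel_threshold(file, ant_channel, threshold_fraction)
  assert_that(any(on), "no supra-threshold %s domain", ant_channel)
  runs <- rle(on); ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
  imax <- which.max(x)
  k <- which(starts <= imax & imax <= ends & runs$values)
  domain <- pos[starts[k]:ends[k]]
  cls <- ifelse(edu_pos %in% domain, "overlap_ant",
         ifelse(edu_pos < min(domain), "xylem_side", NA_character_))
  list(classes = cls[!is.na(cls)], n_excluded = sum(is.na(cls)), empty = FALSE)
}

#' Count cell types in a cell file
#'
#' Xylem cells are all cells inward of the landmark wall (including the
#' xylem-side stem-cell daughter); cells that are not vessels count as xylem
#' parenchyma. Phloem cells are all cells outward of the wall up to (and
#' excluding) the periderm border. Sieve elements and APL-positive cells come
#' from the per-cell labels.
#'
#' @param file A [cell_file()].
#' @return Object of class `cell_type_counts`: list with `vessels`,
#'   `xylem_parenchyma`, `xylem_total`, `phloem_total`, `sieve_elements`,
#'   `apl_positive`, and `periderm_found` (when no periderm label exists the
#'   phloem extends to the file end and the flag is FALSE).
#' @export
count_cell_types <- function(file) {
  stopifnot(inherits(file, "cell_file"))
  pos <- index_positions(file)
  id <- file$cells$identity
  xyl <- pos < 0
  peri <- id == "periderm"
  periderm_found <- any(peri)
  phl <- pos > 0 & !peri
  out <- list(
    vessels = sum(xyl & id == "vessel"),
    xylem_parenchyma = sum(xyl & id != "vessel"),
    xylem_total = sum(xyl),
    phloem_total = sum(phl),
    sieve_elements = sum(phl & id == "sieve_element"),
    apl_positive = sum(phl & (file$cells$apl %||% FALSE)),
    periderm_found = periderm_found
  )
  class(out) <- "cell_type_counts"
  out
}

#' Ratio of APL-positive cells to all phloem cells
#'
#' @param counts A [count_cell_types()] result.
#' @return `apl_positive / phloem_total`, or `NA` with a warning when the
#'   file has no phloem cells.
#' @export
apl_ratio <- function(counts) {
  stopifnot(inherits(counts, "cell_type_counts"))
  if (counts$phloem_total == 0) {
    warning("phloem_total is 0; APL ratio undefined")
    return(NA_real_)
  }
  counts$apl_positive / counts$phloem_total
}

#' Normalise measurements to a control group
#'
#' Every value is divided by the mean of the control group, per batch, so the
#' control group's mean becomes exactly 1 in each batch.
#'
#' @param values Numeric vector.
#' @param group Group label per value.
#' @param control_group Label of the control group.
#' @param batch Optional batch label per value; normalisation is applied
#'   within each batch.
#' @return Numeric vector of normalised values.
#' @export
#' @examples
#' normalize_by_control(c(2, 2, 3, 1), c("wt", "wt", "tr", "tr"), "wt")
normalize_by_control <- function(values, group, control_group, batch = NULL) {
  assert_that(length(values) == length(group), "values and group lengths differ")
  batch <- batch %||% rep("all", length(values))
  out <- numeric(length(values))
  for (b in unique(batch)) {
    sel <- batch == b
    ctrl <- values[sel & group == control_group]
    assert_that(length(ctrl) > 0, "batch '%s' has no control values", b)
    m <- mean(ctrl)
    assert_that(is.finite(m) && m != 0, "control mean is zero in batch '%s'", b)
    out[sel] <- values[sel] / m
  }
  out
}

#' Pearson chi-square test for a contingency table of counts
#'
#' Computes the Pearson statistic `X^2 = sum((O - E)^2 / E)` with expected
#' counts from the row/column margins, `df = (r - 1)(c - 1)`, and the upper
#' tail probability of the chi-square distribution. No continuity correction
#' by default; `correct = TRUE` applies the Yates correction to 2x2 tables.
#'
#' @param table Numeric matrix of counts (r x c, r, c >= 2).
#' @param correct Apply the Yates continuity correction (2x2 tables only).
#' @return List with `statistic`, `df`, `p.value`, `expected`.
#' @export
#' @examples
#' chi_square_test(rbind(c(20, 10), c(5, 15)))
chi_square_test <- function(table, correct = FALSE) {
  x <- as.matrix(table)
  assert_that(nrow(x) >= 2 && ncol(x) >= 2, "need an r x c table with r, c >= 2")
  assert_that(all(x >= 0) && all(is.finite(x)), "counts must be finite and non-negative")
  E <- outer(rowSums(x), colSums(x)) / sum(x)
  if (any(E <= 0)) {
    stop("expected count of zero (empty row or column margin); ",
         "merge sparse bins before testing", call. = FALSE)
  }
  dev <- abs(x - E)
  if (correct) {
    assert_that(all(dim(x) == 2L), "Yates correction applies to 2x2 tables only")
    dev <- pmax(0, dev - 0.5)
  }
  stat <- sum(dev^2 / E)
  df <- (nrow(x) - 1L) * (ncol(x) - 1L)
  list(statistic = stat, df = df,
       p.value = stats::pchisq(stat, df, lower.tail = FALSE), expected = E)
}

#' Score a batch of cell files
#'
#' Applies [gradient_end()], [classify_spread()] and [classify_edu()] to
#' every file and returns a tidy per-file table, alongside an exclusions
#' report: files without a recognizable landmark are excluded (with a reason
#' code), never silently dropped.
#'
#' @param files List of [cell_file()] objects.
#' @param channel Gradient channel for [gradient_end()].
#' @param ant_channel Stem-cell marker channel.
#' @param threshold_fraction Threshold fraction for all classifiers.
#' @param condition Optional condition label.
#' @return List with `scores` (data.frame: `file_id`, `end_position`,
#'   `spread_class`, `edu_class` (first classified EdU cell or `NA`),
#'   `condition`) and `exclusions` (data.frame: `file_id`, `reason`).
#' @export
score_files <- function(files, channel = "DR5", ant_channel = "ANT",
                        threshold_fraction = 0.25, condition = NA_character_) {
  keep <- vapply(files, function(f) !is.na(f$landmark_index), logical(1))
  excl <- data.frame(
    file_id = vapply(files[!keep], function(f) f$id %||% NA_character_, character(1)),
    reason = rep("no_landmark", sum(!keep)),
    stringsAsFactors = FALSE
  )
  rows <- lapply(files[keep], function(f) {
    edu <- classify_edu(f, ant_channel, threshold_fraction)
    data.frame(
      file_id = f$id %||% NA_character_,
      end_position = gradient_end(f, channel, threshold_fraction),
      spread_class = classify_spread(f, ant_channel, threshold_fraction),
      edu_class = if (length(edu$classes)) edu$classes[1] else NA_character_,
      condition = condition,
      stringsAsFactors = FALSE
    )
  })
  list(scores = do.call(rbind, rows), exclusions = excl)
}
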