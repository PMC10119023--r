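# Synthetic radial cell files.
#
# A cell file is an ordered run of cells from the organ centre outward. The
# landmark index marks the most recent periclinal division: the wall between
# cells landmark_index and landmark_index + 1, separating the xylem-side
# stem-cell daughter (position -1) from the phloem-side daughter (position 1).
# Two marker channels are generated per file:
#   DR5 — a gradient marker, "on" from the innermost cell up to a drawn end
#         position and at background beyond it;
#   ANT — a stem-cell domain marker, "on" in both daughters or only in the
#         phloem-side daughter, per the drawn spread class.
# One EdU-positive nucleus is placed relative to the ANT domain per the drawn
# EdU class. All draws are recorded as ground truth so downstream quantifiers
# can be validated by round trip.

CELL_IDENTITIES <- c("vessel", "xylem_parenchyma", "stem_daughter", "phloem",
                     "sieve_element", "periderm")

#' Construct a cell file
#'
#' @param cells data.frame with one row per cell (innermost first) and columns
#'   `identity` (one of vessel, xylem_parenchyma, stem_daughter, phloem,
#'   sieve_element, periderm), `edu` (logical), `apl` (logical), plus one
#'   numeric intensity column per marker channel.
#' @param landmark_index Index of the cell just inward of the landmark wall;
#'   must satisfy `1 <= landmark_index <= nrow(cells) - 1`.
#' @param channels Character vector naming the intensity columns.
#' @param ground_truth Optional list of generator draws
#'   (`end_position`, `end_bin`, `spread`, `edu_class`).
#' @param id Optional file identifier.
#' @return Object of class `cell_file`.
#' @export
cell_file <- function(cells, landmark_index, channels,
                      ground_truth = NULL, id = NA_character_) {
  cf <- structure(list(cells = cells, landmark_index = as.integer(landmark_index),
                       channels = channels, ground_truth = ground_truth, id = id),
                  class = "cell_file")
  validate_cell_file(cf)
  cf
}

validate_cell_file <- function(cf) {
  stopifnot(inherits(cf, "cell_file"), is.data.frame(cf$cells))
  n <- nrow(cf$cells)
  assert_that(n >= 2, "a cell file needs at least 2 cells")
  # NA marks a file whose landmark wall was not recognizable; such files are
  # excluded (and tallied) by scoring functions rather than silently dropped
  assert_that(is.na(cf$landmark_index) ||
                (cf$landmark_index >= 1 && cf$landmark_index <= n - 1),
              "landmark_index must lie strictly between two cells (1..n-1)")
  assert_that(all(cf$cells$identity %in% CELL_IDENTITIES),
              "unknown cell identity")
  assert_that(all(cf$channels %in% names(cf$cells)),
              "every channel needs an intensity column")
  peri <- which(cf$cells$identity == "periderm")
  if (length(peri)) {
    assert_that(min(peri) > max(which(cf$cells$identity != "periderm"), 0),
                "periderm cells must be outermost")
  }
  invisible(cf)
}

#' @export
print.cell_file <- function(x, ...) {
  cat(sprintf("<cell_file> %d cells, landmark wall between cells %d|%d, channels: %s\n",
              nrow(x$cells), x$landmark_index, x$landmark_index + 1L,
              paste(x$channels, collapse = ", ")))
  invisible(x)
}

#' Vectorised ground-truth draws for a preset
#'
#' Draws the categorical ground truth (gradient end bin, spread class, EdU
#' class) for `n` files from the preset's distributions, using the current
#' RNG stream. Used by [make_cell_files()]; exposed so the generator's
#' distributions can be checked directly at large n.
#'
#' @param preset A [load_preset()] object.
#' @param n Number of files.
#' @return data.frame with columns `end_bin`, `spread`, `edu_class`.
#' @export
draw_ground_truth <- function(preset, n) {
  stopifnot(inherits(preset, "generator_preset"))
  data.frame(
    end_bin = sample(POSITION_BINS, n, replace = TRUE,
                     prob = preset$end_position_probs),
    spread = sample(SPREAD_CLASSES, n, replace = TRUE,
                    prob = preset$spread_probs),
    edu_class = sample(EDU_CLASSES, n, replace = TRUE,
                       prob = preset$edu_probs),
    stringsAsFactors = FALSE
  )
}

# map a drawn end bin to a concrete position within the file bounds;
# tail bins resolve uniformly over the positions they cover
resolve_end_bin <- function(end_bin, n_xylem, n_phloem) {
  switch(end_bin,
    m1 = -1L,
    p1 = 1L,
    m2 = -2L,
    le_m3 = {
      assert_that(n_xylem >= 3, "end bin <=-3 needs n_xylem >= 3")
      lo <- -n_xylem
      if (lo == -3L) -3L else sample(seq(-3L, lo), 1L)
    },
    ge_p2 = {
      # periderm (outermost cell) never expresses the gradient marker
      hi <- n_phloem - 1L
      assert_that(hi >= 2, "end bin >=2 needs n_phloem >= 3")
      if (hi == 2L) 2L else sample(seq(2L, hi), 1L)
    }
  )
}

#' Generate one synthetic cell file
#'
#' Identities follow the radial anatomy of a young secondary root: a vessel
#' and xylem parenchyma inward, the two stem-cell daughters flanking the
#' landmark wall, then phloem, a sieve element, and a periderm cell
#' outermost. Marker intensities are set to the preset's "on" level (default
#' 1000 a.u.) within the drawn expression domain and to background (50 a.u.)
#' outside it, with Gaussian noise of sd `preset$noise_sd` added and negative
#' values clamped at zero.
#'
#' @param preset A [load_preset()] object.
#' @param n_xylem Cells inward of the landmark wall (>= 2; >= 3 when the
#'   preset puts mass on the `<=-3` bin).
#' @param n_phloem Cells outward of the landmark wall, incl. periderm (>= 2).
#' @param rng_seed Optional integer seed.
#' @param draws Optional single-row data.frame of pre-drawn ground truth
#'   (from [draw_ground_truth()]).
#' @return A [cell_file()] with channels `DR5` and `ANT`, an EdU flag, and
#'   `ground_truth` recording every draw.
#' @export
#' @examples
#' cf <- make_cell_file(load_preset("col0_mock"), rng_seed = 1)
#' cf$ground_truth$end_position
make_cell_file <- function(preset, n_xylem = 5L, n_phloem = 5L,
                           rng_seed = NULL, draws = NULL) {
  stopifnot(inherits(preset, "generator_preset"))
  assert_that(n_xylem >= 2 && n_phloem >= 2,
              "degenerate file: need n_xylem >= 2 and n_phloem >= 2")
  with_opt_seed(rng_seed, {
    if (is.null(draws)) draws <- draw_ground_truth(preset, 1L)
    end_pos <- resolve_end_bin(draws$end_bin, n_xylem, n_phloem)
    n <- n_xylem + n_phloem
    positions <- c(seq(-n_xylem, -1L), seq(1L, n_phloem))

    identity <- character(n)
    identity[positions <= -2L] <- "xylem_parenchyma"
    identity[positions == -n_xylem] <- "vessel"
    identity[abs(positions) == 1L] <- "stem_daughter"
    identity[positions >= 2L] <- "phloem"
    identity[positions == n_phloem] <- "periderm"
    if (n_phloem >= 3) identity[positions == n_phloem - 1L] <- "sieve_element"

    # gradient marker: on from the innermost cell through the drawn end
    dr5_on <- positions <= end_pos
    # stem-cell domain marker
    ant_on <- if (draws$spread == "both_daughters") abs(positions) == 1L
              else positions == 1L
    # EdU nucleus relative to the ANT domain
    ant_pos <- positions[ant_on]
    edu_pos <- if (draws$edu_class == "overlap_ant") {
      if (length(ant_pos) == 1L) ant_pos else sample(ant_pos, 1L)
    } else {
      min(ant_pos) - if (min(ant_pos) == 1L) 2L else 1L # next cell inward
    }

    paint <- function(on) {
      pmax(0, ifelse(on, preset$on_level, preset$off_level) +
             stats::rnorm(n, 0, preset$noise_sd))
    }
    cells <- data.frame(
      identity = identity,
      edu = positions == edu_pos,
      apl = identity == "sieve_element",
      DR5 = paint(dr5_on),
      ANT = paint(ant_on),
      stringsAsFactors = FALSE
    )
    cell_file(cells, landmark_index = n_xylem, channels = c("DR5", "ANT"),
              ground_truth = list(end_position = end_pos,
                                  end_bin = draws$end_bin,
                                  spread = draws$spread,
                                  edu_class = draws$edu_class))
  })
}

#' Generate a batch of synthetic cell files
#'
#' @inheritParams make_cell_file
#' @param n Number of files.
#' @param rng_seed Integer seed; for a fixed seed the batch is bit-identical
#'   across runs.
#' @return List of [cell_file()] objects with ids `file_1`, `file_2`, ...
#' @export
#' @examples
#' files <- make_cell_files(load_preset("col0_mock"), 10, rng_seed = 1)
make_cell_files <- function(preset, n, n_xylem = 5L, n_phloem = 5L,
                            rng_seed = NULL) {
  with_opt_seed(rng_seed, {
    draws <- draw_ground_truth(preset, n)
    lapply(seq_len(n), function(i) {
      cf <- make_cell_file(preset, n_xylem = n_xylem, n_phloem = n_phloem,
                           draws = draws[i, , drop = FALSE])
      cf$id <- paste0("file_", i)
      cf
    })
  })
}
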