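# Clonal lineage sectors: contiguous radial runs of clonally marked cells,
# described by their cell extents on either side of the most recent division
# wall (the landmark) and classified by where they sit relative to it.

SECTOR_CLASSES <- c("bifacial", "xylem_only", "phloem_only", "stem_regain")
SECTOR_ORIGINS <- c("random_cambium", "ant_stem_cell", "pear1_phloem")

#' Construct a lineage sector
#'
#' @param origin Tracing origin, one of `"random_cambium"`,
#'   `"ant_stem_cell"`, `"pear1_phloem"`.
#' @param n_xylem Number of clone cells inward of the landmark wall.
#' @param n_phloem Number of clone cells outward of the landmark wall.
#' @param landmark_within Logical: is the landmark wall inside the clone span
#'   or at one of its boundaries?
#' @param truncated_on_vessel Logical: did the clone end on a differentiated
#'   vessel (its xylem extent is then a lower bound)?
#' @param treatment Optional treatment label.
#' @return Object of class `sector`.
#' @export
#' @examples
#' sector("ant_stem_cell", n_xylem = 4, n_phloem = 3, landmark_within = TRUE)
sector <- function(origin, n_xylem, n_phloem, landmark_within,
                   truncated_on_vessel = FALSE, treatment = NA_character_) {
  origin <- match.arg(origin, SECTOR_ORIGINS)
  assert_that(n_xylem >= 0 && n_phloem >= 0 && n_xylem + n_phloem >= 1,
              "a sector must contain at least one cell")
  structure(list(origin = origin, n_xylem = as.integer(n_xylem),
                 n_phloem = as.integer(n_phloem),
                 landmark_within = isTRUE(landmark_within),
                 truncated_on_vessel = isTRUE(truncated_on_vessel),
                 treatment = treatment),
            class = "sector")
}

#' @export
print.sector <- function(x, ...) {
  cat(sprintf("<sector> origin=%s extents=(%d xylem, %d phloem) class=%s\n",
              x$origin, x$n_xylem, x$n_phloem, classify_sector(x)))
  invisible(x)
}

#' Split a clone at the landmark into xylem- and phloem-side extents
#'
#' @param clone_cells Integer indices (in file order, innermost first) of the
#'   cells belonging to one clone; must form a contiguous run.
#' @param landmark_index Index of the cell just inward of the landmark wall
#'   (the wall lies between `landmark_index` and `landmark_index + 1`).
#' @return List with `n_xylem`, `n_phloem` and `landmark_within`.
#' @export
#' @examples
#' sector_extents(3:8, landmark_index = 6) # 4 xylem-side, 2 phloem-side cells
sector_extents <- function(clone_cells, landmark_index) {
  clone_cells <- sort(as.integer(clone_cells))
  assert_that(length(clone_cells) >= 1, "clone is empty")
  assert_that(all(diff(clone_cells) == 1L),
              "clone cells must form a contiguous radial run")
  assert_that(is.numeric(landmark_index) && length(landmark_index) == 1L,
              "landmark_index must be a single index")
  list(n_xylem = sum(clone_cells <= landmark_index),
       n_phloem = sum(clone_cells > landmark_index),
       landmark_within = (min(clone_cells) - 1L) <= landmark_index &&
         landmark_index <= max(clone_cells))
}

#' Classify a lineage sector
#'
#' Classes: `bifacial` (cells on both sides of the landmark, landmark within
#' or adjacent to the clone — the clone retained stem-cell activity),
#' `xylem_only` (no phloem-side cells and the landmark outside the clone —
#' the clone was pushed into the xylem, losing stem identity),
#' `stem_regain` (a phloem-origin clone with cells on both sides — its
#' progenitor respecified as a stem cell), and `phloem_only` otherwise.
#'
#' @param sec A [sector()].
#' @return One of `"bifacial"`, `"xylem_only"`, `"phloem_only"`,
#'   `"stem_regain"`.
#' @export
classify_sector <- function(sec) {
  stopifnot(inherits(sec, "sector"))
  both <- sec$n_xylem > 0 && sec$n_phloem > 0
  if (sec$origin == "pear1_phloem" && both) return("stem_regain")
  if (both && sec$landmark_within) return("bifacial")
  if (sec$n_phloem == 0 && !sec$landmark_within) return("xylem_only")
  "phloem_only"
}

#' Landmark-aligned bar-plot table for a set of sectors
#'
#' One row per sector with start/end coordinates in landmark-relative cell
#' units (a sector with extents (2, 3) spans -2 .. 3), its class and a colour
#' key, sorted by treatment and then total extent; ready for bar plotting
#' with the landmark drawn as a vertical line at 0.
#'
#' @param sectors List of [sector()] objects.
#' @return A data.frame with columns `sector_id`, `origin`, `treatment`,
#'   `start`, `end`, `n_xylem`, `n_phloem`, `class`, `colour`,
#'   `truncated_on_vessel`.
#' @export
sector_plot_table <- function(sectors) {
  assert_that(length(sectors) >= 1, "need at least one sector")
  stopifnot(all(vapply(sectors, inherits, logical(1), "sector")))
  colour_key <- c(bifacial = "grey35", xylem_only = "lightblue",
                  phloem_only = "grey65", stem_regain = "lightblue")
  tab <- data.frame(
    sector_id = seq_along(sectors),
    origin = vapply(sectors, `[[`, character(1), "origin"),
    treatment = vapply(sectors, function(s) as.character(s$treatment), character(1)),
    start = -vapply(sectors, `[[`, integer(1), "n_xylem"),
    end = vapply(sectors, `[[`, integer(1), "n_phloem"),
    n_xylem = vapply(sectors, `[[`, integer(1), "n_xylem"),
    n_phloem = vapply(sectors, `[[`, integer(1), "n_phloem"),
    class = vapply(sectors, classify_sector, character(1)),
    truncated_on_vessel = vapply(sectors, `[[`, logical(1), "truncated_on_vessel"),
    stringsAsFactors = FALSE
  )
  tab$colour <- unname(colour_key[tab$class])
  tab[order(tab$treatment, tab$end - tab$start, tab$sector_id), ]
}

#' Summary statistics for a sector cohort
#'
#' Mean and standard deviation of the xylem- and phloem-side extents
#' (restricted to sectors that proliferated, i.e. reached `min_size` cells)
#' and the sector-class fractions (over all sectors; they sum to 1).
#' Truncated-on-vessel sectors are tallied: their xylem extents are lower
#' bounds.
#'
#' @param sectors List of [sector()] objects. With fewer than two
#'   proliferating sectors the standard deviations are undefined and flagged
#'   via `sd_defined = FALSE`.
#' @param min_size Minimum clone size for a sector to enter the extent
#'   summaries (default 3).
#' @return List with `n`, `n_proliferating`, `mean_xylem`, `sd_xylem`,
#'   `mean_phloem`, `sd_phloem`, `class_fractions`, `n_truncated_on_vessel`,
#'   `sd_defined`.
#' @export
cohort_summary <- function(sectors, min_size = 3L) {
  assert_that(length(sectors) >= 1, "cohort summaries need at least 1 sector")
  stopifnot(all(vapply(sectors, inherits, logical(1), "sector")))
  nx <- vapply(sectors, `[[`, integer(1), "n_xylem")
  np <- vapply(sectors, `[[`, integer(1), "n_phloem")
  keep <- (nx + np) >= min_size
  cls <- factor(vapply(sectors, classify_sector, character(1)),
                levels = SECTOR_CLASSES)
  sd_defined <- sum(keep) >= 2
  if (sum(keep) < 1) warning("no sector reaches min_size; extent summaries undefined")
  list(
    n = length(sectors),
    n_proliferating = sum(keep),
    mean_xylem = if (any(keep)) mean(nx[keep]) else NA_real_,
    sd_xylem = if (sd_defined) stats::sd(nx[keep]) else NA_real_,
    mean_phloem = if (any(keep)) mean(np[keep]) else NA_real_,
    sd_phloem = if (sd_defined) stats::sd(np[keep]) else NA_real_,
    class_fractions = prop.table(table(cls)),
    n_truncated_on_vessel = sum(vapply(sectors, `[[`, logical(1), "truncated_on_vessel")),
    sd_defined = sd_defined
  )
}
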