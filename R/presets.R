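# Generator presets: the study conditions for the synthetic cell-file and
# fate simulators. Each preset carries
#   * end_position_probs  — categorical distribution of the position at which
#     a gradient marker (auxin-response type) stops, over the bins
#     {<=-3, -2, -1, 1, >=2} (negative = xylem side, positive = phloem side,
#     no position 0; the landmark wall separates -1 from 1);
#   * spread_probs        — stem-cell marker domain over the two daughters:
#     both_daughters vs phloem_only;
#   * edu_probs           — placement of an S-phase (EdU) nucleus relative to
#     the stem-cell marker domain: overlap_ant vs xylem_side;
#   * fate                — per-division outcome probabilities (see
#     [fate_params()]);
#   * noise_sd, on/off levels and the number of files rendered per section.
#
# Only the aggregate frequencies printed for each condition constrain these
# distributions (fraction of gradient ends in {-1, 1}; spread and EdU class
# fractions; sector-class fractions); the split of the remaining mass across
# bins is a documented package choice (see the methods vignette).

POSITION_BINS <- c("le_m3", "m2", "m1", "p1", "ge_p2")
SPREAD_CLASSES <- c("both_daughters", "phloem_only")
EDU_CLASSES <- c("overlap_ant", "xylem_side")

# synthetic intensity scale (arbitrary fluorescence units)
MARKER_ON <- 1000
MARKER_OFF <- 50
WALL_LEVEL <- 1500
DEFAULT_NOISE_SD <- 20

end_probs <- function(le_m3 = 0, m2 = 0, m1 = 0, p1 = 0, ge_p2 = 0) {
  stats::setNames(c(le_m3, m2, m1, p1, ge_p2), POSITION_BINS)
}

# Mock conditions spread the mass not in {-1, 1} uniformly over the deeper
# xylem bins {<=-3, -2}; GA-treated conditions over {-2} and {>=2} (after GA
# the gradient occasionally overshoots into the phloem). Within {-1, 1} the
# mock conditions put ~5:1 weight on -1 (the gradient rarely reaches the
# phloem-side daughter without GA) and GA conditions ~2:1.
.preset_table <- function() {
  list(
    col0_mock   = list(end = end_probs(le_m3 = 0.26, m2 = 0.26, m1 = 0.40, p1 = 0.08)),
    ga1_mock    = list(end = end_probs(le_m3 = 0.355, m2 = 0.355, m1 = 0.25, p1 = 0.04)),
    col0_ga48h  = list(end = end_probs(m2 = 0.085, m1 = 0.55, p1 = 0.28, ge_p2 = 0.085)),
    ga1_ga48h   = list(end = end_probs(m2 = 0.215, m1 = 0.40, p1 = 0.17, ge_p2 = 0.215)),
    ant_mock    = list(spread = c(both_daughters = 0.68, phloem_only = 0.32)),
    ant_ga      = list(spread = c(both_daughters = 0.57, phloem_only = 0.43)),
    edu_mock    = list(spread = c(both_daughters = 0.68, phloem_only = 0.32),
                       edu = c(overlap_ant = 0.80, xylem_side = 0.20)),
    edu_ga      = list(spread = c(both_daughters = 0.57, phloem_only = 0.43),
                       edu = c(overlap_ant = 0.64, xylem_side = 0.36)),
    fate_mock   = list(fate = "mock"),
    fate_highGA = list(fate = "highGA"),
    fate_lowGA  = list(fate = "lowGA")
  )
}

#' List the available generator presets
#'
#' @return Character vector of preset names accepted by [load_preset()].
#' @export
preset_names <- function() names(.preset_table())

#' Load a named generator preset
#'
#' A preset bundles every distribution the synthetic generator draws from:
#' the gradient end-position distribution, the stem-cell marker spread
#' distribution, the EdU placement distribution and the division-fate
#' parameters, together with image-noise settings. Presets are parameterised
#' with the aggregate frequencies reported for the corresponding experimental
#' condition, so recovering those frequencies from generated data is the
#' package's main self-check.
#'
#' @param name One of [preset_names()].
#' @return Object of class `generator_preset`: a list with elements `name`,
#'   `end_position_probs`, `spread_probs`, `edu_probs`, `fate` (a
#'   [fate_params()] object), `noise_sd`, `on_level`, `off_level`,
#'   `n_files_per_section`.
#' @export
#' @examples
#' p <- load_preset("col0_mock")
#' sum(p$end_position_probs[c("m1", "p1")])  # fraction of ends in {-1, 1}
load_preset <- function(name) {
  tab <- .preset_table()
  if (!is.character(name) || length(name) != 1L || !name %in% names(tab)) {
    stop("unknown preset '", paste(name, collapse = ","),
         "'; available presets: ", paste(names(tab), collapse = ", "),
         call. = FALSE)
  }
  entry <- tab[[name]]
  fate <- switch(entry$fate %||% "mock",
    mock   = fate_params(0.5, 0.5, 0),
    lowGA  = fate_params(0.33, 0.67, 0),
    highGA = high_ga_fate_params()
  )
  preset <- structure(list(
    name = name,
    end_position_probs = normalize_probs(entry$end %||% end_probs(le_m3 = 0.26, m2 = 0.26, m1 = 0.40, p1 = 0.08)),
    spread_probs = normalize_probs(entry$spread %||% c(both_daughters = 0.68, phloem_only = 0.32)),
    edu_probs = normalize_probs(entry$edu %||% c(overlap_ant = 0.80, xylem_side = 0.20)),
    fate = fate,
    noise_sd = DEFAULT_NOISE_SD,
    on_level = MARKER_ON,
    off_level = MARKER_OFF,
    n_files_per_section = 16L
  ), class = "generator_preset")
  validate_preset(preset)
  preset
}

normalize_probs <- function(p) {
  assert_that(all(p >= 0) && sum(p) > 0, "probabilities must be non-negative and not all zero")
  p / sum(p)
}

validate_preset <- function(p) {
  for (field in c("end_position_probs", "spread_probs", "edu_probs")) {
    assert_that(abs(sum(p[[field]]) - 1) < 1e-9, "%s must sum to 1", field)
  }
  assert_that(identical(names(p$end_position_probs), POSITION_BINS),
              "end_position_probs must be over bins %s", paste(POSITION_BINS, collapse = ","))
  stopifnot(inherits(p$fate, "fate_params"))
  invisible(p)
}

#' @export
print.generator_preset <- function(x, ...) {
  cat("<generator_preset>", x$name, "\n")
  cat("  end position bins {<=-3,-2,-1,1,>=2}:",
      paste(sprintf("%.3f", x$end_position_probs), collapse = " "), "\n")
  cat("  spread {both,phloem_only}:",
      paste(sprintf("%.2f", x$spread_probs), collapse = " "),
      "| EdU {overlap,xylem_side}:",
      paste(sprintf("%.2f", x$edu_probs), collapse = " "), "\n")
  cat(sprintf("  fate: q_x=%.3f q_p=%.3f q_d=%.3f n_cycles=%d | noise_sd=%g\n",
              x$fate$q_x, x$fate$q_p, x$fate$q_d, x$fate$n_cycles, x$noise_sd))
  invisible(x)
}
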