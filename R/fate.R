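# Stochastic model of bifacial cambial stem-cell fate decisions.
#
# A radial cell file holds, at every cycle boundary, exactly one stem cell
# between a xylem stack (inward) and a phloem stack (outward). Each cycle the
# stem cell divides periclinally into a xylem-side daughter (-1) and a
# phloem-side daughter (1); the new wall between them is the current
# landmark ("thinnest wall"). The division then resolves into one of three
# outcomes, with probabilities set by the gibberellin regime:
#
#   xylem_gain   (q_x): the -1 daughter differentiates to xylem, the 1
#                       daughter remains the stem cell;
#   phloem_gain  (q_p): the 1 daughter differentiates to phloem, the -1
#                       daughter remains the stem cell;
#   double_xylem (q_d): both daughters differentiate to xylem and the
#                       phloem-identity cell adjacent to the cambium
#                       respecifies as the new stem cell.
#
# Lineage labels are inherited by daughters; a respecified cell keeps its own
# label. Running the model from a labelled progenitor and extracting the
# labelled clone yields lineage sectors comparable to clonal (GUS) sectors.

FATE_OUTCOMES <- c("xylem_gain", "phloem_gain", "double_xylem")

#' Division-outcome probabilities for the fate simulator
#'
#' @param q_x Probability of a xylem-gain resolution.
#' @param q_p Probability of a phloem-gain resolution.
#' @param q_d Probability of a double-xylem resolution with stem-cell
#'   respecification from the adjacent phloem cell.
#' @param n_cycles Number of division cycles per tracing window (default 5).
#' @return Object of class `fate_params`.
#' @seealso [high_ga_fate_params()] for the calibrated high-GA regime.
#' @export
#' @examples
#' fate_params(0.5, 0.5, 0)
fate_params <- function(q_x, q_p, q_d, n_cycles = 5L) {
  q <- c(q_x, q_p, q_d)
  assert_that(all(q >= 0 & q <= 1), "probabilities must lie in [0, 1]")
  assert_that(abs(sum(q) - 1) < 1e-9, "q_x + q_p + q_d must sum to 1 (got %g)", sum(q))
  assert_that(n_cycles >= 1, "n_cycles must be >= 1")
  structure(list(q_x = q_x, q_p = q_p, q_d = q_d, n_cycles = as.integer(n_cycles)),
            class = "fate_params")
}

#' @export
print.fate_params <- function(x, ...) {
  cat(sprintf("<fate_params> q_x=%.4f q_p=%.4f q_d=%.4f n_cycles=%d\n",
              x$q_x, x$q_p, x$q_d, x$n_cycles))
  invisible(x)
}

#' Initialise a radial file for the fate simulator
#'
#' The file starts with `n_xylem` xylem cells, one stem cell, and `n_phloem`
#' phloem cells (innermost first). The clone label is seeded according to the
#' tracing origin: `ant_stem_cell` labels the stem cell, `pear1_phloem` the
#' phloem cell adjacent to the cambium; `random_cambium` labels one of the
#' first division's daughters with equal probability (applied by
#' [simulate_sector()] after the first cycle).
#'
#' @param n_xylem,n_phloem Initial stack sizes (each >= 1).
#' @param origin One of `"ant_stem_cell"`, `"pear1_phloem"`,
#'   `"random_cambium"`, or `NULL` for no label.
#' @return Object of class `file_state`: identity and clone-label vectors,
#'   stem index, landmark index (wall between `landmark` and `landmark + 1`,
#'   `NA` before the first division), an event log, and a `terminated` flag.
#' @export
new_file_state <- function(n_xylem = 3L, n_phloem = 3L, origin = NULL) {
  assert_that(n_xylem >= 1 && n_phloem >= 1, "need at least one xylem and one phloem cell")
  identity <- c(rep("xylem", n_xylem), "stem", rep("phloem", n_phloem))
  clone <- rep(FALSE, length(identity))
  stem <- n_xylem + 1L
  if (!is.null(origin)) {
    origin <- match.arg(origin, c("ant_stem_cell", "pear1_phloem", "random_cambium"))
    if (origin == "ant_stem_cell") clone[stem] <- TRUE
    if (origin == "pear1_phloem") clone[stem + 1L] <- TRUE
    # random_cambium is labelled after the first division by simulate_sector()
  }
  structure(list(identity = identity, clone = clone, stem = stem,
                 landmark = NA_integer_, origin = origin,
                 log = data.frame(cycle = integer(), outcome = character(),
                                  stem_index = integer()),
                 terminated = FALSE),
            class = "file_state")
}

#' Advance the fate simulation by one stem-cell division
#'
#' The stem cell divides (cell count grows by exactly one) and the outcome is
#' drawn from `(q_x, q_p, q_d)` unless forced via `outcome`. If a double-xylem
#' outcome finds no phloem cell outward of the daughters the file is flagged
#' `terminated` and left otherwise unchanged past the division.
#'
#' @param state A `file_state`.
#' @param params A [fate_params()] object.
#' @param outcome Optional forced outcome (one of
#'   `"xylem_gain"`, `"phloem_gain"`, `"double_xylem"`), used for exact
#'   enumeration; by default drawn from the current RNG stream.
#' @return The updated `file_state`.
#' @export
fate_step <- function(state, params, outcome = NULL) {
  stopifnot(inherits(state, "file_state"), inherits(params, "fate_params"))
  if (state$terminated) stop("cannot step a terminated file", call. = FALSE)
  if (is.null(outcome)) {
    outcome <- sample(FATE_OUTCOMES, 1L,
                      prob = c(params$q_x, params$q_p, params$q_d))
  } else {
    outcome <- match.arg(outcome, FATE_OUTCOMES)
  }
  s <- state$stem
  # division: the stem is replaced by two daughters at s (-1 side) and s + 1
  id <- append(state$identity, state$identity[s], after = s)
  cl <- append(state$clone, state$clone[s], after = s)
  if (outcome == "xylem_gain") {
    id[s] <- "xylem"; id[s + 1L] <- "stem"
    state$stem <- s + 1L
  } else if (outcome == "phloem_gain") {
    id[s + 1L] <- "phloem"; id[s] <- "stem"
    state$stem <- s
  } else { # double_xylem
    id[s] <- "xylem"; id[s + 1L] <- "xylem"
    j <- s + 2L
    if (j > length(id) || id[j] != "phloem") {
      state$identity <- id; state$clone <- cl; state$landmark <- s
      state$terminated <- TRUE
      state$log <- rbind(state$log,
                         data.frame(cycle = nrow(state$log) + 1L,
                                    outcome = outcome, stem_index = NA_integer_))
      return(state)
    }
    id[j] <- "stem"
    state$stem <- j
  }
  state$identity <- id; state$clone <- cl; state$landmark <- s
  state$log <- rbind(state$log,
                     data.frame(cycle = nrow(state$log) + 1L, outcome = outcome,
                                stem_index = state$stem))
  state
}

# extract the labelled clone of a finished file as a sector
state_to_sector <- function(state, treatment = NA_character_) {
  ci <- which(state$clone)
  assert_that(length(ci) >= 1, "file carries no clone label")
  assert_that(all(diff(ci) == 1L), "clone is not contiguous")
  L <- state$landmark
  sector(origin = state$origin %||% "random_cambium",
         n_xylem = sum(ci <= L), n_phloem = sum(ci > L),
         landmark_within = (min(ci) - 1L) <= L && L <= max(ci),
         truncated_on_vessel = FALSE,
         treatment = treatment)
}

#' Simulate one lineage-tracing sector
#'
#' Runs `n_cycles` division cycles from a labelled progenitor and extracts the
#' labelled clone as a [sector()] with xylem/phloem extents relative to the
#' final landmark wall.
#'
#' @param origin Tracing origin: `"ant_stem_cell"` (label the stem cell),
#'   `"pear1_phloem"` (label the phloem cell adjacent to the cambium) or
#'   `"random_cambium"` (label either first-division daughter with equal
#'   probability).
#' @param params A [fate_params()] object.
#' @param n_cycles Number of division cycles (defaults to `params$n_cycles`).
#' @param rng_seed Optional integer seed.
#' @param treatment Optional treatment label attached to the sector.
#' @param outcomes Optional character vector of forced outcomes (length
#'   `n_cycles`), for exact enumeration.
#' @return A [sector()] object; its `terminated` attribute flags files that
#'   ran out of phloem cells during a double-xylem event.
#' @export
#' @examples
#' simulate_sector("ant_stem_cell", fate_params(0.5, 0.5, 0), rng_seed = 1)
simulate_sector <- function(origin, params, n_cycles = params$n_cycles,
                            rng_seed = NULL, treatment = NA_character_,
                            outcomes = NULL) {
  origin <- match.arg(origin, c("ant_stem_cell", "pear1_phloem", "random_cambium"))
  with_opt_seed(rng_seed, {
    st <- new_file_state(origin = origin)
    for (k in seq_len(n_cycles)) {
      st <- fate_step(st, params, outcome = outcomes[k])
      if (k == 1L && origin == "random_cambium") {
        # the first division's daughters sit at landmark and landmark + 1
        st$clone[st$landmark + sample(0:1, 1L)] <- TRUE
      }
      if (st$terminated) break
    }
    sec <- state_to_sector(st, treatment = treatment)
    attr(sec, "terminated") <- st$terminated
    attr(sec, "event_log") <- st$log
    sec
  })
}

#' Simulate a cohort of lineage sectors
#'
#' @inheritParams simulate_sector
#' @param n_sectors Number of sectors (>= 1).
#' @param rng_seed Integer seed; the cohort is reproducible for a fixed seed.
#' @return List with `sectors` (list of [sector()]), `outcome_counts` (tally
#'   of logged division outcomes across the cohort), and `summary`
#'   (via [cohort_summary()], `NULL` when `n_sectors < 2`).
#' @export
simulate_cohort <- function(origin, params, n_sectors, rng_seed = NULL,
                            n_cycles = params$n_cycles, treatment = NA_character_) {
  assert_that(n_sectors >= 1, "n_sectors must be >= 1")
  with_opt_seed(rng_seed, {
    sectors <- lapply(seq_len(n_sectors), function(i) {
      simulate_sector(origin, params, n_cycles = n_cycles, treatment = treatment)
    })
    logs <- lapply(sectors, attr, "event_log")
    outcome_counts <- table(factor(unlist(lapply(logs, `[[`, "outcome")),
                                   levels = FATE_OUTCOMES))
    list(sectors = sectors,
         outcome_counts = outcome_counts,
         summary = cohort_summary(sectors))
  })
}

#' Exact sector-class probabilities by enumeration
#'
#' Enumerates every outcome sequence of length `n_cycles` (there are
#' `3^n_cycles`), runs the deterministic division mechanics on each, and sums
#' sequence probabilities per sector class. This is the closed-form companion
#' of [simulate_cohort()]: simulation results converge to these values.
#'
#' @inheritParams simulate_sector
#' @return Named numeric vector of class probabilities (sums to 1).
#' @export
#' @examples
#' enumerate_sector_classes("ant_stem_cell", fate_params(0.5, 0.5, 0))
enumerate_sector_classes <- function(origin, params, n_cycles = params$n_cycles) {
  origin <- match.arg(origin, c("ant_stem_cell", "pear1_phloem"))
  tab <- .sector_class_table(origin, n_cycles)
  q <- c(params$q_x, params$q_p, params$q_d)
  pr <- q[1]^tab$counts[, 1] * q[2]^tab$counts[, 2] * q[3]^tab$counts[, 3]
  out <- tapply(pr, tab$class, sum)
  res <- stats::setNames(numeric(length(SECTOR_CLASSES)), SECTOR_CLASSES)
  res[names(out)] <- out
  res
}

# class of every outcome sequence; depends only on (origin, n_cycles), cached
.fate_cache <- new.env(parent = emptyenv())
.sector_class_table <- function(origin, n_cycles) {
  key <- paste(origin, n_cycles)
  if (!is.null(.fate_cache[[key]])) return(.fate_cache[[key]])
  seqs <- as.matrix(expand.grid(rep(list(1:3), n_cycles)))
  dummy <- fate_params(1, 0, 0, n_cycles = n_cycles) # probabilities unused below
  cls <- apply(seqs, 1L, function(r) {
    sec <- simulate_sector(origin, dummy, n_cycles = n_cycles,
                           outcomes = FATE_OUTCOMES[r])
    classify_sector(sec)
  })
  counts <- cbind(rowSums(seqs == 1L), rowSums(seqs == 2L), rowSums(seqs == 3L))
  .fate_cache[[key]] <- list(class = cls, counts = counts)
  .fate_cache[[key]]
}

#' Calibrate the double-xylem rate against printed sector-class frequencies
#'
#' With the phloem-gain probability fixed, the double-xylem rate `q_d` is the
#' only free fate parameter. It is chosen by exact enumeration
#' ([enumerate_sector_classes()]) to reproduce, in the least-squares sense,
#' the target sector-class frequencies: the fraction of stem-cell-origin
#' sectors classified `xylem_only` and the fraction of phloem-origin sectors
#' classified `stem_regain` after the tracing window.
#'
#' @param q_p Phloem-gain probability (held fixed).
#' @param n_cycles Divisions per tracing window.
#' @param target_xylem_only Target `xylem_only` fraction for
#'   `ant_stem_cell`-origin sectors.
#' @param target_stem_regain Target `stem_regain` fraction for
#'   `pear1_phloem`-origin sectors.
#' @return The calibrated `q_d`.
#' @export
calibrate_double_rate <- function(q_p = 0.33, n_cycles = 5L,
                                  target_xylem_only = 0.21,
                                  target_stem_regain = 0.21) {
  obj <- function(q_d) {
    par <- fate_params(1 - q_p - q_d, q_p, q_d, n_cycles = n_cycles)
    pa <- enumerate_sector_classes("ant_stem_cell", par)[["xylem_only"]]
    pp <- enumerate_sector_classes("pear1_phloem", par)[["stem_regain"]]
    (pa - target_xylem_only)^2 + (pp - target_stem_regain)^2
  }
  stats::optimize(obj, c(1e-6, 1 - q_p - 1e-6))$minimum
}

#' Fate parameters for the high-GA regime
#'
#' `q_p` is fixed at 0.33 (the fraction of divisions that still resolve to
#' phloem under high GA); `q_d` is calibrated with [calibrate_double_rate()]
#' against the two printed 21% sector-class frequencies; `q_x` takes the
#' remainder.
#'
#' @param n_cycles Divisions per tracing window (default 5).
#' @return A [fate_params()] object.
#' @export
high_ga_fate_params <- function(n_cycles = 5L) {
  key <- paste("highGA", n_cycles)
  if (is.null(.fate_cache[[key]])) {
    q_d <- calibrate_double_rate(q_p = 0.33, n_cycles = n_cycles)
    .fate_cache[[key]] <- fate_params(1 - 0.33 - q_d, 0.33, q_d, n_cycles = n_cycles)
  }
  .fate_cache[[key]]
}
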