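# Readers, writers and the umbrella pipeline driver.
#
# On-disk formats:
#   * sections: multipage TIFF (one 16-bit page per channel, intensities
#     divided by an `intensity_scale` recorded in the sidecar) + JSON
#     annotation {channels, centre (0-based x, y), axis_angle_deg,
#     pixel_size_um, intensity_scale, landmark_polyline {angle_deg,
#     radius_px}};
#   * cell files: CSV, one row per cell;
#   * sectors: CSV, one row per sector;
#   * configs: YAML with strict key validation.

#' Write a section as multipage TIFF plus JSON annotation
#'
#' @param section A `radial_section`.
#' @param tiff_path Output TIFF path; the annotation is written next to it
#'   (same name, `.json`) unless `json_path` is given.
#' @param json_path Optional annotation path.
#' @return Invisibly, the two paths.
#' @export
write_section <- function(section, tiff_path, json_path = NULL) {
  stopifnot(inherits(section, "radial_section"))
  json_path <- json_path %||% sub("\\.tiff?$", ".json", tiff_path)
  # reuse the scale a section was read with, so write -> read -> write is
  # byte-stable; fresh scales are rounded so they survive JSON serialisation
  scale <- section$intensity_scale %||%
    signif(max(section$image, 1, na.rm = TRUE) * 1.000001, 6)
  pages <- lapply(seq_along(section$channels), function(ch) {
    m <- section$image[, , ch]
    m[is.na(m)] <- 0
    # snap to the 16-bit grid with a half-step offset: the TIFF writer
    # truncates, so this makes quantisation deterministic and write -> read
    # -> write byte-stable
    k <- round(pmin(pmax(m / scale, 0), 1) * 65535)
    pmin((k + 0.5) / 65535, 1)
  })
  tiff::writeTIFF(pages, tiff_path, bits.per.sample = 16L)
  ann <- list(
    channels = section$channels,
    centre = list(x = section$centre[["x"]], y = section$centre[["y"]]),
    axis_angle_deg = section$xylem_axis_angle,
    pixel_size_um = section$pixel_size,
    intensity_scale = scale,
    coordinate_convention = "origin top-left, x rightward, y downward, 0-based; angles deg CCW from vertical",
    landmark_polyline = list(angle_deg = section$landmark_polyline$angle_deg,
                             radius_px = section$landmark_polyline$radius_px)
  )
  jsonlite::write_json(ann, json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(tiff = tiff_path, json = json_path))
}

#' Read a section from a TIFF + JSON annotation pair
#'
#' @param tiff_path Multipage TIFF (one page per channel).
#' @param annotation_path JSON annotation; defaults to the TIFF path with a
#'   `.json` extension.
#' @return A validated `radial_section`.
#' @export
read_section <- function(tiff_path, annotation_path = NULL) {
  annotation_path <- annotation_path %||% sub("\\.tiff?$", ".json", tiff_path)
  assert_that(file.exists(tiff_path), "no such TIFF: %s", tiff_path)
  assert_that(file.exists(annotation_path), "no such annotation: %s", annotation_path)
  ann <- jsonlite::read_json(annotation_path, simplifyVector = TRUE)
  for (key in c("channels", "centre", "axis_angle_deg", "pixel_size_um",
                "intensity_scale", "landmark_polyline")) {
    assert_that(key %in% names(ann), "annotation is missing key '%s'", key)
  }
  pages <- tiff::readTIFF(tiff_path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  assert_that(length(pages) == length(ann$channels),
              "TIFF has %d page(s) but annotation lists %d channel(s)",
              length(pages), length(ann$channels))
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  img <- array(0, dim = c(h, w, length(pages)),
               dimnames = list(NULL, NULL, ann$channels))
  for (ch in seq_along(pages)) img[, , ch] <- pages[[ch]] * ann$intensity_scale
  centre <- c(x = ann$centre$x, y = ann$centre$y)
  assert_that(centre[["x"]] >= 0 && centre[["x"]] <= w - 1 &&
                centre[["y"]] >= 0 && centre[["y"]] <= h - 1,
              "annotated centre lies outside the image")
  poly <- data.frame(angle_deg = ann$landmark_polyline$angle_deg,
                     radius_px = ann$landmark_polyline$radius_px)
  assert_that(all(poly$radius_px > 0) &&
                all(poly$radius_px < max(h, w) / 2 + 1),
              "landmark radius must be positive and within the image half-extent")
  structure(list(image = img, channels = ann$channels, centre = centre,
                 xylem_axis_angle = ann$axis_angle_deg,
                 landmark_polyline = poly, pixel_size = ann$pixel_size_um,
                 intensity_scale = ann$intensity_scale, files = NULL),
            class = "radial_section")
}

#' Write cell files as a tidy CSV (one row per cell)
#'
#' @param files List of [cell_file()] objects.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_cell_files <- function(files, path) {
  rows <- lapply(seq_along(files), function(i) {
    f <- files[[i]]
    gt <- f$ground_truth %||% list()
    data.frame(
      file_id = f$id %||% paste0("file_", i),
      cell_index = seq_len(nrow(f$cells)),
      identity = f$cells$identity,
      f$cells[f$channels],
      edu = f$cells$edu,
      apl = f$cells$apl,
      is_landmark_inner = seq_len(nrow(f$cells)) == f$landmark_index,
      gt_end_position = gt$end_position %||% NA_integer_,
      gt_end_bin = gt$end_bin %||% NA_character_,
      gt_spread = gt$spread %||% NA_character_,
      gt_edu_class = gt$edu_class %||% NA_character_,
      stringsAsFactors = FALSE
    )
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read cell files from CSV
#'
#' @param path CSV written by [write_cell_files()].
#' @param channels Marker channel columns (default `c("DR5", "ANT")`).
#' @return List of [cell_file()] objects.
#' @export
read_cell_files <- function(path, channels = c("DR5", "ANT")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("file_id", "cell_index", "identity", channels, "edu", "apl",
            "is_landmark_inner")
  assert_that(all(need %in% names(tab)), "CSV is missing columns: %s",
              paste(setdiff(need, names(tab)), collapse = ", "))
  lapply(split(tab, factor(tab$file_id, levels = unique(tab$file_id))), function(d) {
    d <- d[order(d$cell_index), ]
    lm <- which(d$is_landmark_inner)
    gt <- if (!is.na(d$gt_end_bin[1] %||% NA)) {
      list(end_position = d$gt_end_position[1], end_bin = d$gt_end_bin[1],
           spread = d$gt_spread[1], edu_class = d$gt_edu_class[1])
    }
    cell_file(
      cells = data.frame(identity = d$identity, edu = d$edu, apl = d$apl,
                         d[channels], stringsAsFactors = FALSE),
      landmark_index = if (length(lm) == 1) lm else NA_integer_,
      channels = channels, ground_truth = gt, id = d$file_id[1]
    )
  })
}

#' Write sectors as CSV
#'
#' @param sectors List of [sector()] objects.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_sectors <- function(sectors, path) {
  tab <- sector_plot_table(sectors)
  utils::write.csv(tab[order(tab$sector_id), ], path, row.names = FALSE)
  invisible(path)
}

#' Read sectors from CSV
#'
#' @param path CSV with columns `origin`, `n_xylem`, `n_phloem` and
#'   optionally `treatment`, `truncated_on_vessel`, `landmark_within`.
#' @return List of [sector()] objects. When `landmark_within` is absent it is
#'   inferred: TRUE iff both extents are positive.
#' @export
read_sectors <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("origin", "n_xylem", "n_phloem")
  assert_that(all(need %in% names(tab)), "CSV is missing columns: %s",
              paste(setdiff(need, names(tab)), collapse = ", "))
  lapply(seq_len(nrow(tab)), function(i) {
    sector(origin = tab$origin[i], n_xylem = tab$n_xylem[i],
           n_phloem = tab$n_phloem[i],
           landmark_within = if ("landmark_within" %in% names(tab))
             tab$landmark_within[i] else tab$n_xylem[i] > 0 && tab$n_phloem[i] > 0,
           truncated_on_vessel = if ("truncated_on_vessel" %in% names(tab))
             tab$truncated_on_vessel[i] else FALSE,
           treatment = if ("treatment" %in% names(tab)) tab$treatment[i]
           else NA_character_)
  })
}

#' Default pipeline configuration
#'
#' @return Named list of configuration values understood by
#'   [run_pipeline()]: presets to compare, batch sizes, projection and
#'   quantification parameters.
#' @export
default_config <- function() {
  list(
    preset_a = "col0_mock",
    preset_b = "ga1_mock",
    n_files = 200L,
    n_files_per_section = 12L,
    n_angle_bins = 120L,
    radial_step = 1,
    channel = "DR5",
    threshold_fraction = 0.25,
    fate_preset = "fate_highGA",
    fate_origin = "ant_stem_cell",
    n_sectors = 100L
  )
}

validate_config <- function(config) {
  known <- names(default_config())
  unknown <- setdiff(names(config), known)
  assert_that(length(unknown) == 0, "unknown config key(s): %s",
              paste(unknown, collapse = ", "))
  utils::modifyList(default_config(), config)
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys fall back to [default_config()].
#'
#' @param path YAML file.
#' @return Validated configuration list.
#' @export
read_config <- function(path) validate_config(yaml::read_yaml(path))

#' Run the full synthetic pipeline
#'
#' Executes simulate -> render -> unwrap -> align -> aggregate -> quantify ->
#' fate/sectors -> chi-square on two generator presets and writes every
#' artefact (CSV/TIFF/JSON) plus a provenance record and an exclusions report
#' into `out_dir`. Byte-identical outputs for identical config and seed.
#'
#' @param config Configuration list (see [default_config()]) or a YAML path.
#' @param seed Integer root seed; every stage seed derives from it.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the artefact paths and the stage summaries.
#' @export
run_pipeline <- function(config = default_config(), seed = 1L,
                         out_dir = tempfile("cambiokit_run_")) {
  if (is.character(config)) config <- read_config(config)
  config <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(seed, 6)
  paths <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  # simulate
  files_a <- stage("simulate", make_cell_files(load_preset(config$preset_a),
                                               config$n_files, rng_seed = seeds[1]))
  files_b <- stage("simulate", make_cell_files(load_preset(config$preset_b),
                                               config$n_files, rng_seed = seeds[2]))
  paths$files_a <- file.path(out_dir, "files_a.csv")
  paths$files_b <- file.path(out_dir, "files_b.csv")
  write_cell_files(files_a, paths$files_a)
  write_cell_files(files_b, paths$files_b)

  # render + project one section per condition
  proj <- stage("project", {
    lapply(list(a = files_a, b = files_b), function(fl) {
      sec <- render_section(fl[seq_len(config$n_files_per_section)],
                            noise_sd = load_preset(config$preset_a)$noise_sd,
                            rng_seed = seeds[3])
      pm <- unwrap(rotate_section(sec, fill = 0),
                   n_angle_bins = config$n_angle_bins,
                   radial_step = config$radial_step)
      align_to_landmark(pm, sec$landmark_polyline)
    })
  })
  paths$section_a <- file.path(out_dir, "section_a.tif")
  write_section(render_section(files_a[seq_len(config$n_files_per_section)],
                               rng_seed = seeds[3]), paths$section_a)
  stack <- aggregate_maps(list(proj$a), treatment = config$preset_a)
  paths$profile <- file.path(out_dir, "aligned_profile.csv")
  utils::write.csv(aligned_profile(stack), paths$profile, row.names = FALSE)

  # quantify
  quant <- stage("quantify", {
    lapply(list(a = files_a, b = files_b), function(fl) {
      score_files(fl, channel = config$channel,
                  threshold_fraction = config$threshold_fraction)
    })
  })
  dist_a <- position_distribution(quant$a$scores$end_position, config$preset_a)
  dist_b <- position_distribution(quant$b$scores$end_position, config$preset_b)
  dist_tab <- data.frame(
    condition = rep(c(config$preset_a, config$preset_b), each = length(POSITION_BINS)),
    position = rep(c("<=-3", "-2", "-1", "1", ">=2"), 2),
    count = c(dist_a$counts, dist_b$counts)
  )
  paths$distributions <- file.path(out_dir, "position_distributions.csv")
  utils::write.csv(dist_tab, paths$distributions, row.names = FALSE)
  exclusions <- rbind(quant$a$exclusions, quant$b$exclusions)
  paths$exclusions <- file.path(out_dir, "exclusions.csv")
  utils::write.csv(exclusions, paths$exclusions, row.names = FALSE)

  # stats: chi-square comparison of the two position tables
  counts <- rbind(dist_a$counts, dist_b$counts)
  keep <- colSums(counts) > 0
  chisq <- stage("stats", chi_square_test(counts[, keep, drop = FALSE]))

  # fate + sectors
  cohort <- stage("fate", simulate_cohort(config$fate_origin,
                                          load_preset(config$fate_preset)$fate,
                                          config$n_sectors, rng_seed = seeds[4]))
  paths$sectors <- file.path(out_dir, "sectors.csv")
  write_sectors(cohort$sectors, paths$sectors)

  summary <- list(
    config = config, seed = seed,
    package_version = as.character(utils::packageVersion("cambiokit")),
    n_files = config$n_files,
    n_excluded = nrow(exclusions),
    fraction_daughters_a = fraction_reaching(dist_a, c(-1, 1)),
    fraction_daughters_b = fraction_reaching(dist_b, c(-1, 1)),
    chi_square = chisq[c("statistic", "df", "p.value")],
    sector_class_fractions = as.list(cohort$summary$class_fractions)
  )
  paths$summary <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(list(paths = paths, summary = summary, out_dir = out_dir))
}
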