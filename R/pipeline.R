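#' Pipeline configuration
#'
#' Assembles and validates the configuration tree for a full quantification
#' run. Unknown keys anywhere in the tree are rejected before any stage
#' runs, so a typo cannot silently fall back to a default.
#'
#' @param ... named overrides for the top-level sections `seed`, `detection`,
#'   `profiling`, `phases`, `stats` (each a list of the corresponding
#'   function's parameters, see [detection_config()], [extract_rim_profile()],
#'   [phase_config()], [pairwise_significance()]).
#' @return A validated `guv_pipeline_config` list.
#' @examples
#' cfg <- pipeline_config(detection = list(radius_range = c(15, 35)))
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    detection = list(radius_range = c(10, 50), radius_step = 1,
                     edge_quantile = 0.95, score_threshold = 0.35,
                     min_radius = NULL, band_halfwidth = 3,
                     solution_margin = 6, refine = TRUE),
    profiling = list(n_bins = 360L, band_halfwidth = 3, radial_step = 0.5,
                     interp = "bilinear", saturation_level = Inf,
                     statistic = "pooled_peak"),
    phases = list(min_contrast_ratio = 2, min_arc_fraction = 0.05,
                  smooth_bins = 5L, marker_phase = "ld", boundary_exclude = 1L),
    stats = list(method = "wilcoxon", p_adjust = "holm")
  )
  overrides <- list(...)
  if (length(overrides) == 1L && is.null(names(overrides)) && is.list(overrides[[1]])) {
    overrides <- overrides[[1]]
  }
  cfg <- merge_validated(defaults, overrides, path = "config")
  class(cfg) <- "guv_pipeline_config"
  cfg
}

# Recursive merge of overrides into defaults, rejecting unknown keys.
merge_validated <- function(defaults, overrides, path) {
  if (is.null(overrides)) return(defaults)
  if (!is.list(overrides)) {
    stopf("`%s` must be a named list", path, class = "guvquant_config_error")
  }
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad)) {
    stopf("unknown configuration key%s under %s: %s",
          if (length(bad) > 1) "s" else "", path, paste(bad, collapse = ", "),
          class = "guvquant_config_error")
  }
  for (nm in names(overrides)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- merge_validated(defaults[[nm]], overrides[[nm]],
                                        paste(path, nm, sep = "$"))
    } else {
      defaults[[nm]] <- overrides[[nm]]
    }
  }
  defaults
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys follow [pipeline_config()].
#' @return A validated `guv_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  pipeline_config(yaml::read_yaml(path))
}

#' Run the full GUV quantification pipeline on one image
#'
#' Detection on the marker channel, free-solution estimation per lectin
#' channel, rim profiling, phase segmentation, overall and per-phase binding
#' efficiencies, and (when two lectin channels are present) the rim
#' segregation correlation. Vesicles flagged at detection (border-touching,
#' overlapping, too small) or saturated in the rim band are excluded from
#' quantification but reported with their flags. The run is deterministic
#' given the configuration; the configuration hash is attached to the result
#' and written into every output file.
#'
#' @param image a 2-D [multichannel_image()] (or use `tiff` to load one).
#' @param config a [pipeline_config()].
#' @param tiff optional path to a TIFF written by [write_scene()]; used when
#'   `image` is `NULL`.
#' @return A `guv_pipeline_result`: list with `results` (one row per
#'   detected vesicle), `profiles` (long per-bin table), `segregation`,
#'   `detections`, `solution`, `log` (per-stage counts) and `config_hash`.
#' @export
run_pipeline <- function(image = NULL, config = pipeline_config(), tiff = NULL) {
  if (!inherits(config, "guv_pipeline_config")) config <- pipeline_config(config)
  if (is.null(image)) {
    if (is.null(tiff)) stopf("provide `image` or `tiff`")
    image <- read_scene(tiff)
  }
  det_cfg <- do.call(detection_config, config$detection)
  det <- detect_guvs(image, det_cfg)
  lectins <- lectin_roles(image)
  solution <- vapply(lectins, function(l) {
    estimate_solution_intensity(image, det, l,
                                band_halfwidth = det_cfg$band_halfwidth,
                                margin = det_cfg$solution_margin)
  }, numeric(1))
  ph_cfg <- do.call(phase_config, config$phases[setdiff(names(config$phases),
                                                        "boundary_exclude")])
  prof_args <- config$profiling
  statistic <- prof_args$statistic
  prof_args <- prof_args[setdiff(names(prof_args), "statistic")]
  results <- list(); profiles <- list(); segregation <- list()
  n_excluded <- 0L; n_phase_sep <- 0L
  for (i in seq_len(nrow(det))) {
    row <- det[i, ]
    base <- data.frame(guv_id = row$id, x = row$x, y = row$y,
                       radius = row$radius, score = row$score,
                       border_touching = row$border_touching,
                       overlapping = row$overlapping, too_small = row$too_small,
                       saturated = FALSE, excluded = FALSE,
                       phase_mode = NA_character_, stringsAsFactors = FALSE)
    if (row$border_touching || row$overlapping || row$too_small) {
      base$excluded <- TRUE
      n_excluded <- n_excluded + 1L
      results[[i]] <- fill_binding_cols(base, lectins)
      next
    }
    prof <- tryCatch(
      do.call(extract_rim_profile, c(list(image = image, det = row), prof_args)),
      error = function(e) e)
    if (inherits(prof, "error")) {
      stopf("quantification failed for GUV %d at (%.1f, %.1f): %s",
            row$id, row$x, row$y, conditionMessage(prof),
            class = "guvquant_quantification_error")
    }
    if (prof$saturated) {
      base$saturated <- TRUE
      base$excluded <- TRUE
      n_excluded <- n_excluded + 1L
      results[[i]] <- fill_binding_cols(base, lectins)
      next
    }
    lab <- segment_phases(prof, ph_cfg)
    base$phase_mode <- lab$mode
    if (lab$mode == "phase_separated") n_phase_sep <- n_phase_sep + 1L
    bind <- per_phase_binding(prof, lab, solution, channels = lectins,
                              boundary_exclude = config$phases$boundary_exclude,
                              statistic = statistic)
    res <- base
    for (l in lectins) {
      b <- bind[bind$channel == l, ]
      res[[paste0("be_overall_", l)]] <- b$overall
      res[[paste0("be_ld_", l)]] <- b$ld
      res[[paste0("be_lo_", l)]] <- b$lo
      res[[paste0("solution_", l)]] <- b$solution
    }
    results[[i]] <- res
    prof_df <- data.frame(guv_id = row$id, bin = seq_len(prof$n_bins),
                          angle = prof$angles, phase = lab$labels)
    for (cn in colnames(prof$values)) prof_df[[cn]] <- prof$values[, cn]
    profiles[[i]] <- prof_df
    if (length(lectins) >= 2L) {
      seg <- segregation_profile(prof, lectins[1], lectins[2])
      segregation[[i]] <- data.frame(guv_id = row$id,
                                     correlation = seg$correlation,
                                     flagged = seg$flagged)
    }
  }
  hash <- digest::digest(unclass(config), algo = "sha1")
  log <- list(n_detected = nrow(det), n_excluded = n_excluded,
              n_quantified = nrow(det) - n_excluded,
              n_phase_separated = n_phase_sep)
  message(sprintf("guvquant: %d GUV(s) detected, %d excluded, %d phase-separated",
                  log$n_detected, log$n_excluded, log$n_phase_separated))
  structure(list(results = rbind_fill(results), profiles = rbind_fill(profiles),
                 segregation = rbind_fill(segregation), detections = det,
                 solution = solution, log = log, config = config,
                 config_hash = hash),
            class = "guv_pipeline_result")
}

fill_binding_cols <- function(base, lectins) {
  for (l in lectins) {
    base[[paste0("be_overall_", l)]] <- NA_real_
    base[[paste0("be_ld_", l)]] <- NA_real_
    base[[paste0("be_lo_", l)]] <- NA_real_
    base[[paste0("solution_", l)]] <- NA_real_
  }
  base
}

rbind_fill <- function(rows) {
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(NULL)
  cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (cn in setdiff(cols, names(r))) r[[cn]] <- NA
    r[, cols, drop = FALSE]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write pipeline results to CSV files
#'
#' Writes `results.csv`, `profiles.csv` and (two-lectin runs)
#' `segregation.csv`, each starting with a comment line carrying the
#' configuration hash, plus a QC overlay PNG of the detections. Outputs are
#' byte-identical across runs with the same configuration and inputs.
#'
#' @param res a [run_pipeline()] result.
#' @param dir output directory.
#' @param image optional image for the QC overlay.
#' @return The directory, invisibly.
#' @export
write_results <- function(res, dir, image = NULL) {
  stopifnot(inherits(res, "guv_pipeline_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    if (is.null(df)) return(invisible(NULL))
    path <- file.path(dir, name)
    con <- file(path, "w")
    writeLines(sprintf("# guvquant config_hash %s", res$config_hash), con)
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
  }
  wr(res$results, "results.csv")
  wr(res$profiles, "profiles.csv")
  wr(res$segregation, "segregation.csv")
  if (!is.null(image)) {
    qc_overlay(image, res$detections, file.path(dir, "overlay.png"))
  }
  invisible(dir)
}

#' QC overlay of detections on the marker channel
#'
#' @param image a 2-D [multichannel_image()].
#' @param detections a `guv_detections` data.frame.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
qc_overlay <- function(image, detections, path) {
  m <- get_channel(image, "marker")
  grDevices::png(path, width = 640, height = 640)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(2, 2, 2, 1))
  graphics::image(x = seq_len(ncol(m)) - 1, y = seq_len(nrow(m)) - 1,
                  z = t(m)[, nrow(m):1],
                  col = grDevices::gray.colors(256, start = 0, end = 1),
                  useRaster = TRUE, asp = 1, xlab = "", ylab = "",
                  main = "marker channel + detections")
  h <- nrow(m)
  tt <- seq(0, 2 * pi, length.out = 120)
  for (i in seq_len(nrow(detections))) {
    flagged <- detections$border_touching[i] || detections$overlapping[i] ||
      detections$too_small[i]
    graphics::lines(detections$x[i] + detections$radius[i] * cos(tt),
                    (h - 1) - (detections$y[i] + detections$radius[i] * sin(tt)),
                    col = if (flagged) "red" else "green", lwd = 2)
  }
  invisible(path)
}
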