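#' Phase-segmentation configuration
#'
#' @param min_contrast_ratio minimum ratio between the mean marker intensity
#'   of the bright and the dim class for the vesicle to count as
#'   phase-separated (default 2; below it the marker is considered uniform).
#' @param min_arc_fraction minimum fraction of bins either phase must cover.
#' @param smooth_bins window (odd) of the circular majority filter applied to
#'   the labels.
#' @param marker_phase which phase the marker lipid highlights; the bright
#'   class gets this label. The default `"ld"` matches an ld-partitioning
#'   marker such as a BODIPY-labelled phosphatidylcholine; markers that
#'   enrich in the ordered phase would use `"lo"`.
#' @return A `guv_phase_config` list.
#' @export
phase_config <- function(min_contrast_ratio = 2, min_arc_fraction = 0.05,
                         smooth_bins = 5L, marker_phase = c("ld", "lo")) {
  marker_phase <- match.arg(marker_phase)
  if (smooth_bins %% 2L == 0L) stopf("smooth_bins must be odd")
  structure(list(min_contrast_ratio = min_contrast_ratio,
                 min_arc_fraction = min_arc_fraction,
                 smooth_bins = as.integer(smooth_bins),
                 marker_phase = marker_phase),
            class = "guv_phase_config")
}

#' Segment the rim into liquid-disordered and liquid-ordered arcs
#'
#' Classifies every angular bin from the membrane-marker profile by a
#' deterministic two-cluster 1-D k-means (centres initialised at the 25th and
#' 75th percentiles, so no random initialisation is involved). The brighter
#' class is labelled with the marker's preferred phase (ld for an
#' ld-partitioning marker), the dimmer with the other. The vesicle is called
#' `uniform` - all bins share one label and the missing phase has no
#' statistics - when the bright/dim mean ratio stays below
#' `min_contrast_ratio` or either class covers less than `min_arc_fraction`
#' of the bins after smoothing by a circular majority filter.
#'
#' @param profile a [extract_rim_profile()] result with a marker channel.
#' @param cfg a [phase_config()].
#' @return A `guv_phase_labeling`: list with `labels` (per-bin `"ld"`/`"lo"`),
#'   `mode` (`"phase_separated"` or `"uniform"`), `arcs` (data.frame
#'   `start_bin`, `end_bin`, `label`; circular arcs, `end_bin` inclusive),
#'   `bright_dim_ratio` and `n_bins`.
#' @export
segment_phases <- function(profile, cfg = phase_config()) {
  stopifnot(inherits(profile, "guv_rim_profile"))
  if (profile$n_bins < 12L) stopf("need at least 12 angular bins to segment phases")
  nm <- profile_channel(profile, "marker")
  x <- profile$values[, nm]
  n <- length(x)
  other <- if (cfg$marker_phase == "ld") "lo" else "ld"
  uniform <- function(ratio) {
    structure(list(labels = rep(cfg$marker_phase, n), mode = "uniform",
                   arcs = data.frame(start_bin = 1L, end_bin = n,
                                     label = cfg$marker_phase,
                                     stringsAsFactors = FALSE),
                   bright_dim_ratio = ratio, n_bins = n),
              class = "guv_phase_labeling")
  }
  km <- kmeans_1d_two(x)
  if (is.null(km)) return(uniform(1))
  bright <- km$assign == which.max(km$centers)
  mean_bright <- mean(x[bright]); mean_dim <- mean(x[!bright])
  ratio <- if (mean_dim <= 0) Inf else mean_bright / mean_dim
  if (ratio < cfg$min_contrast_ratio) return(uniform(ratio))
  lab01 <- circular_majority(as.integer(bright), cfg$smooth_bins)
  frac <- mean(lab01 == 1L)
  if (min(frac, 1 - frac) < cfg$min_arc_fraction) return(uniform(ratio))
  labels <- ifelse(lab01 == 1L, cfg$marker_phase, other)
  structure(list(labels = labels, mode = "phase_separated",
                 arcs = label_runs(labels), bright_dim_ratio = ratio,
                 n_bins = n),
            class = "guv_phase_labeling")
}

# Deterministic 2-class 1-D k-means (Lloyd, percentile init). Returns NULL
# when the data have no spread.
kmeans_1d_two <- function(x, max_iter = 100L) {
  c1 <- stats::quantile(x, 0.25, names = FALSE)
  c2 <- stats::quantile(x, 0.75, names = FALSE)
  if (!is.finite(c1) || !is.finite(c2) || c2 - c1 < .Machine$double.eps * max(1, abs(c2))) {
    return(NULL)
  }
  centers <- c(c1, c2)
  assign <- integer(length(x))
  for (it in seq_len(max_iter)) {
    new_assign <- ifelse(abs(x - centers[1]) <= abs(x - centers[2]), 1L, 2L)
    if (length(unique(new_assign)) < 2L) return(NULL)
    new_centers <- c(mean(x[new_assign == 1L]), mean(x[new_assign == 2L]))
    if (identical(new_assign, assign)) break
    assign <- new_assign
    centers <- new_centers
  }
  list(centers = centers, assign = assign)
}

# Circular run-length arcs of a label vector; end_bin inclusive. The run
# containing bin 1 may wrap: it is reported with start_bin > end_bin.
label_runs <- function(labels) {
  n <- length(labels)
  changes <- which(labels != labels[c(n, seq_len(n - 1L))])
  if (!length(changes)) {
    return(data.frame(start_bin = 1L, end_bin = n, label = labels[1],
                      stringsAsFactors = FALSE))
  }
  starts <- sort(changes)
  ends <- c(starts[-1L] - 1L, starts[1L] - 1L)
  ends[ends == 0L] <- n
  data.frame(start_bin = starts, end_bin = ends, label = labels[starts],
             stringsAsFactors = FALSE)
}

#' @export
print.guv_phase_labeling <- function(x, ...) {
  cat(sprintf("<guv_phase_labeling> %s, %d bins, bright/dim ratio %.2f\n",
              x$mode, x$n_bins, x$bright_dim_ratio))
  print(x$arcs)
  invisible(x)
}
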