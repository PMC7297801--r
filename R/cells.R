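#' Measure apical and basolateral intensities of a single cell
#'
#' Mean lectin intensity over the apical and the basolateral membrane voxel
#' sets of one cell. Masks are an input contract (from the simulator's
#' ground truth or user-supplied label images); automated segmentation of
#' real monolayers is out of scope.
#'
#' @param stack a 3-D [multichannel_image()].
#' @param mask_ap,mask_bl apical/basolateral membrane voxels: integer linear
#'   indices into a channel array, or logical arrays of the stack's shape.
#'   Must be non-empty and disjoint.
#' @param channel lectin role or channel name.
#' @param cell_id identifier stored in the record.
#' @param isolated whether this cell has no labeled neighbour within the
#'   isolation margin; only isolated cells enter population ratios.
#' @return One-row data.frame: `cell_id`, `ap_intensity`, `bl_intensity`,
#'   `isolated`, `n_ap`, `n_bl`.
#' @export
measure_cell <- function(stack, mask_ap, mask_bl, channel = "lectin_1",
                         cell_id = NA_integer_, isolated = TRUE) {
  ch <- get_channel(stack, channel)
  as_idx <- function(mask) {
    if (is.logical(mask)) {
      if (!identical(dim(mask), dim(ch))) stopf("logical mask shape differs from the stack")
      which(mask)
    } else {
      idx <- as.integer(mask)
      if (any(idx < 1L | idx > length(ch))) stopf("mask indices out of range")
      idx
    }
  }
  ia <- as_idx(mask_ap); ib <- as_idx(mask_bl)
  if (!length(ia) || !length(ib)) stopf("empty membrane mask")
  if (length(intersect(ia, ib))) stopf("apical and basolateral masks overlap")
  data.frame(cell_id = cell_id, ap_intensity = mean(ch[ia]),
             bl_intensity = mean(ch[ib]), isolated = isolated,
             n_ap = length(ia), n_bl = length(ib))
}

#' Measure all labeled cells of a simulated stack
#'
#' Convenience wrapper running [measure_cell()] over every labeled cell of a
#' [simulate_cell_stack()] result.
#'
#' @param sim result of [simulate_cell_stack()].
#' @param channel lectin role.
#' @return Data.frame of per-cell polarity records.
#' @export
measure_simulated_cells <- function(sim, channel = "lectin_1") {
  cells <- sim$truth$cells
  rows <- lapply(which(cells$labeled), function(i) {
    measure_cell(sim$image, sim$masks[[i]]$ap, sim$masks[[i]]$bl,
                 channel = channel, cell_id = cells$cell_id[i],
                 isolated = cells$isolated[i])
  })
  if (!length(rows)) stopf("no labeled cells in this simulation")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Apical-to-basolateral intensity ratio of one experiment
#'
#' Ratio of means across cells (not mean of per-cell ratios): the apical
#' signal averaged over isolated cells divided by the basolateral signal
#' averaged over the same cells. Non-isolated records never contribute.
#'
#' @param records data.frame of [measure_cell()] rows.
#' @return Dimensionless AP/BL ratio.
#' @export
ap_bl_ratio <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("ap_intensity", "bl_intensity", "isolated") %in% names(records)))
  rec <- records[records$isolated, , drop = FALSE]
  if (!nrow(rec)) stopf("no isolated cells to average")
  mbl <- mean(rec$bl_intensity)
  if (mbl <= 0) stopf("mean basolateral intensity is zero; ratio undefined")
  mean(rec$ap_intensity) / mbl
}

#' Summarise AP/BL ratios across experiments for one condition
#'
#' @param ratios numeric vector of per-experiment AP/BL ratios.
#' @param n_cells integer vector, cells measured per experiment.
#' @param condition label.
#' @return One-row data.frame with mean ratio, SEM, experiment count and a
#'   `low_n` flag set when any experiment used 50 cells or fewer (population
#'   ratios are conventionally based on > 50 cells per condition).
#' @export
experiment_summary <- function(ratios, n_cells, condition = "condition") {
  stopifnot(length(ratios) == length(n_cells), length(ratios) >= 1L)
  data.frame(condition = condition, n_experiments = length(ratios),
             mean_ratio = mean(ratios),
             sem = if (length(ratios) > 1L) stats::sd(ratios) / sqrt(length(ratios)) else NA_real_,
             low_n = any(n_cells <= 50L))
}

#' Paired two-tailed t-test on per-experiment ratios
#'
#' Compares two conditions measured in the same experiments (pairs are
#' matched by position). Zero-variance differences are degenerate: all-zero
#' differences give t = 0, p = 1; constant non-zero differences have an
#' undefined t and are flagged.
#'
#' @param cond_a,cond_b numeric vectors of per-experiment ratios, equal
#'   length >= 2.
#' @return List with `t`, `p`, `df`, `mean_diff`, `degenerate`.
#' @export
paired_ratio_test <- function(cond_a, cond_b) {
  if (length(cond_a) != length(cond_b)) stopf("conditions must have equal length")
  if (length(cond_a) < 2L) stopf("need at least 2 paired experiments")
  d <- cond_a - cond_b
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      return(list(t = 0, p = 1, df = length(d) - 1L, mean_diff = 0, degenerate = TRUE))
    }
    return(list(t = NA_real_, p = NA_real_, df = length(d) - 1L,
                mean_diff = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(cond_a, cond_b, paired = TRUE, alternative = "two.sided")
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter),
       mean_diff = unname(tt$estimate), degenerate = FALSE)
}
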