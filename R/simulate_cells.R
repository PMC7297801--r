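#' Specification of a synthetic polarized-monolayer stack
#'
#' Emulates a confluent epithelial monolayer in which only a fraction of the
#' cells express the lectin receptor (receptor-positive cells mixed 1:10 with
#' wild-type cells by default, so single labeled cells can be measured
#' without labeled neighbours). Cells are rectangular prisms on a grid with a
#' one-voxel gap; labeled cells carry lectin signal on their apical membrane
#' (top face) at `ap_intensity` and on their basolateral membrane (bottom
#' face plus lateral walls) at `bl_intensity`.
#'
#' @param grid integer length 2, cells per (row, col) of the monolayer.
#' @param cell_size lateral cell footprint in pixels (square).
#' @param n_z number of z-slices of the stack (cell height).
#' @param n_cells number of cells to place (row-major); must fit the grid.
#' @param ap_intensity,bl_intensity named numeric per lectin role (a.u.);
#'   defaults follow the apical-to-basolateral contrast reported for the two
#'   lectins on polarized epithelia (about 2.7:1 and 7:1).
#' @param labeled_fraction fraction of receptor-positive cells, in (0, 1].
#' @param noise list with `gaussian_sigma` and `poisson_scale` as in
#'   [scene_spec()]; the default photon scale keeps the basolateral membrane
#'   at a signal-to-noise ratio of about 10.
#' @param pixel_size micrometres per voxel (lateral).
#' @param isolation_margin_um labeled cells with another labeled cell's mask
#'   within this lateral distance are flagged non-isolated.
#' @param seed integer; fully determines the stack.
#' @return A `cell_scene_spec` list.
#' @export
cell_scene_spec <- function(grid = c(4L, 4L), cell_size = 10L, n_z = 10L,
                            n_cells = prod(grid),
                            ap_intensity = c(lectin_1 = 27, lectin_2 = 70),
                            bl_intensity = c(lectin_1 = 10, lectin_2 = 10),
                            labeled_fraction = 0.1,
                            noise = list(gaussian_sigma = 0, poisson_scale = 0),
                            pixel_size = 0.2, isolation_margin_um = 2,
                            seed = 1L) {
  if (any(ap_intensity < 0) || any(bl_intensity < 0)) {
    stopf("membrane intensities must be >= 0")
  }
  if (!(labeled_fraction > 0 && labeled_fraction <= 1)) {
    stopf("labeled_fraction must be in (0, 1]")
  }
  if (n_cells > prod(grid)) {
    stopf("n_cells = %d exceeds the packable grid (%d x %d)", n_cells, grid[1], grid[2])
  }
  if (is.null(names(ap_intensity)) || is.null(names(bl_intensity)) ||
      !setequal(names(ap_intensity), names(bl_intensity))) {
    stopf("ap_intensity and bl_intensity must be named by the same lectin roles")
  }
  noise <- utils::modifyList(list(gaussian_sigma = 0, poisson_scale = 0), as.list(noise))
  structure(list(grid = as.integer(grid), cell_size = as.integer(cell_size),
                 n_z = as.integer(n_z), n_cells = as.integer(n_cells),
                 ap_intensity = ap_intensity,
                 bl_intensity = bl_intensity[names(ap_intensity)],
                 labeled_fraction = labeled_fraction, noise = noise,
                 pixel_size = pixel_size,
                 isolation_margin_um = isolation_margin_um, seed = as.integer(seed)),
            class = "cell_scene_spec")
}

#' Simulate a polarized-cell z-stack with per-cell ground truth
#'
#' The first random draw consumed from the seed is the labelling draw
#' `runif(n_cells) < labeled_fraction` (in cell order), so the set of
#' labeled cells can be reproduced independently from the seed. Apical and
#' basolateral membrane masks for every cell are returned as voxel index
#' vectors; the JSON-serialisable ground truth records the per-cell true
#' intensities and flags.
#'
#' @param scene a [cell_scene_spec()].
#' @return List with `image` (3-D [multichannel_image()]), `truth`
#'   (serialisable record) and `masks` (per cell: `ap` and `bl` linear voxel
#'   indices).
#' @export
simulate_cell_stack <- function(scene) {
  stopifnot(inherits(scene, "cell_scene_spec"))
  gap <- 1L
  pitch <- scene$cell_size + gap
  ny <- scene$grid[1] * pitch + gap
  nx <- scene$grid[2] * pitch + gap
  nz <- scene$n_z
  lectins <- names(scene$ap_intensity)
  dims <- c(ny, nx, nz)
  labeled <- with_seed(scene$seed, {
    lab <- stats::runif(scene$n_cells) < scene$labeled_fraction
    # keep noise reproducible given the seed: draw it inside the same block
    chans <- stats::setNames(lapply(lectins, function(l) array(0, dims)), lectins)
    masks <- vector("list", scene$n_cells)
    cells <- data.frame(cell_id = seq_len(scene$n_cells),
                        row = (seq_len(scene$n_cells) - 1L) %/% scene$grid[2] + 1L,
                        col = (seq_len(scene$n_cells) - 1L) %% scene$grid[2] + 1L,
                        labeled = lab)
    for (i in seq_len(scene$n_cells)) {
      y0 <- gap + (cells$row[i] - 1L) * pitch + 1L
      x0 <- gap + (cells$col[i] - 1L) * pitch + 1L
      ys <- y0:(y0 + scene$cell_size - 1L)
      xs <- x0:(x0 + scene$cell_size - 1L)
      foot <- as.matrix(expand.grid(y = ys, x = xs))
      ap <- cbind(foot, z = nz)
      bl_bottom <- cbind(foot, z = 1L)
      per <- foot[foot[, "y"] %in% range(ys) | foot[, "x"] %in% range(xs), , drop = FALSE]
      bl_side <- do.call(rbind, lapply(seq(2L, nz - 1L), function(z) cbind(per, z = z)))
      to_idx <- function(vox) {
        (vox[, "z"] - 1L) * ny * nx + (vox[, "x"] - 1L) * ny + vox[, "y"]
      }
      masks[[i]] <- list(ap = as.integer(to_idx(ap)),
                         bl = as.integer(to_idx(rbind(bl_bottom, bl_side))))
      if (lab[i]) {
        for (l in lectins) {
          chans[[l]][masks[[i]]$ap] <- scene$ap_intensity[[l]]
          chans[[l]][masks[[i]]$bl] <- scene$bl_intensity[[l]]
        }
      }
    }
    chans <- lapply(chans, function(a) {
      v <- a
      if (scene$noise$poisson_scale > 0) {
        v <- array(stats::rpois(length(v), pmax(v, 0) * scene$noise$poisson_scale) /
                     scene$noise$poisson_scale, dims)
      }
      if (scene$noise$gaussian_sigma > 0) {
        v <- v + array(stats::rnorm(length(v), 0, scene$noise$gaussian_sigma), dims)
      }
      pmax(v, 0)
    })
    list(lab = lab, chans = chans, masks = masks, cells = cells)
  })
  cells <- labeled$cells
  # isolation: no other labeled cell footprint within the lateral margin
  margin_px <- scene$isolation_margin_um / scene$pixel_size
  cells$isolated <- vapply(seq_len(nrow(cells)), function(i) {
    if (!cells$labeled[i]) return(FALSE)
    others <- which(cells$labeled & cells$cell_id != cells$cell_id[i])
    if (!length(others)) return(TRUE)
    # edge-to-edge distance between the two cells' footprint rectangles
    dy <- pmax(0, abs(cells$row[others] - cells$row[i]) * pitch - scene$cell_size)
    dx <- pmax(0, abs(cells$col[others] - cells$col[i]) * pitch - scene$cell_size)
    all(sqrt(dy^2 + dx^2) > margin_px)
  }, logical(1))
  for (l in lectins) {
    cells[[paste0("ap_true_", l)]] <- ifelse(cells$labeled, scene$ap_intensity[[l]], 0)
    cells[[paste0("bl_true_", l)]] <- ifelse(cells$labeled, scene$bl_intensity[[l]], 0)
  }
  roles <- stats::setNames(lectins, lectins)
  img <- multichannel_image(labeled$chans, roles, scene$pixel_size)
  truth <- list(kind = "cell_scene", stack_shape = dims,
                pixel_size = scene$pixel_size,
                ap_intensity = as.list(scene$ap_intensity),
                bl_intensity = as.list(scene$bl_intensity),
                labeled_fraction = scene$labeled_fraction,
                n_labeled = sum(cells$labeled), noise = scene$noise,
                seed = scene$seed, cells = cells)
  list(image = img, truth = truth, masks = labeled$masks)
}

#' Write a simulated cell scene to disk
#'
#' One multi-page TIFF per lectin channel (one page per z-slice), apical and
#' basolateral label TIFFs (voxel value = cell id), the ground truth as JSON
#' and a YAML sidecar describing the layout.
#'
#' @param sim result of [simulate_cell_stack()].
#' @param dir output directory.
#' @return Named vector of written paths, invisibly.
#' @export
write_cell_scene <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dims <- dim(sim$image$channels[[1]])
  nz <- dims[3]
  paths <- c()
  slices <- function(a) lapply(seq_len(nz), function(z) a[, , z])
  for (cn in names(sim$image$channels)) {
    p <- file.path(dir, sprintf("cells_%s.tif", cn))
    write_tiff(slices(sim$image$channels[[cn]]), p)
    paths[cn] <- p
  }
  lab_ap <- array(0, dims); lab_bl <- array(0, dims)
  for (i in seq_along(sim$masks)) {
    lab_ap[sim$masks[[i]]$ap] <- i
    lab_bl[sim$masks[[i]]$bl] <- i
  }
  write_tiff(slices(lab_ap), file.path(dir, "cells_ap_labels.tif"))
  write_tiff(slices(lab_bl), file.path(dir, "cells_bl_labels.tif"))
  yaml::write_yaml(list(channels = as.list(names(sim$image$channels)),
                        roles = as.list(stats::setNames(unname(sim$image$roles),
                                                        names(sim$image$roles))),
                        n_z = nz, stack_shape = as.integer(dims),
                        pixel_size = sim$image$pixel_size),
                   file.path(dir, "cells.channels.yaml"))
  truth <- sim$truth
  truth$cells <- lapply(seq_len(nrow(truth$cells)), function(i) as.list(truth$cells[i, ]))
  jsonlite::write_json(truth, file.path(dir, "cells.truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a cell scene written by [write_cell_scene()]
#'
#' @param dir scene directory.
#' @return List with `image`, `truth` and `masks` as in
#'   [simulate_cell_stack()].
#' @export
read_cell_scene <- function(dir) {
  cfg <- yaml::read_yaml(file.path(dir, "cells.channels.yaml"))
  dims <- as.integer(unlist(cfg$stack_shape))
  restack <- function(path) {
    pages <- read_tiff(path)
    a <- array(0, dims)
    for (z in seq_along(pages)) a[, , z] <- pages[[z]]
    a
  }
  chans <- stats::setNames(lapply(unlist(cfg$channels), function(cn) {
    restack(file.path(dir, sprintf("cells_%s.tif", cn)))
  }), unlist(cfg$channels))
  lab_ap <- restack(file.path(dir, "cells_ap_labels.tif"))
  lab_bl <- restack(file.path(dir, "cells_bl_labels.tif"))
  truth <- jsonlite::read_json(file.path(dir, "cells.truth.json"),
                               simplifyVector = TRUE)
  n_cells <- nrow(truth$cells)
  masks <- lapply(seq_len(n_cells), function(i) {
    list(ap = which(abs(lab_ap - i) < 0.5), bl = which(abs(lab_bl - i) < 0.5))
  })
  img <- multichannel_image(chans, unlist(cfg$roles), cfg$pixel_size %||% 0.2)
  list(image = img, truth = truth, masks = masks)
}
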