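# Minimal baseline TIFF I/O.
#
# No TIFF package is available in this R installation, so the subset of the
# format the pipeline needs is implemented directly: multi-page greyscale,
# uncompressed, little- or big-endian on read (uint8/uint16/uint32/float32),
# little-endian float32 on write. One page per channel; channel roles travel
# in a YAML sidecar (see write_scene()).

TIFF_TAGS <- c(width = 256L, length = 257L, bits = 258L, compression = 259L,
               photometric = 262L, strip_offsets = 273L, spp = 277L,
               rows_per_strip = 278L, strip_bytes = 279L, sample_format = 339L)

#' Write matrices to a multi-page greyscale TIFF
#'
#' Each matrix becomes one uncompressed 32-bit float page (little-endian,
#' single strip). Page order follows the list order.
#'
#' @param channels named list of numeric matrices.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(channels, path) {
  if (is.matrix(channels)) channels <- list(channels)
  stopifnot(length(channels) >= 1L, all(vapply(channels, is.matrix, TRUE)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  # first IFD offset written after we lay out the pages
  n <- length(channels)
  header_size <- 8L
  entry_count <- length(TIFF_TAGS)
  ifd_size <- 2L + entry_count * 12L + 4L
  # layout: header | page1 data | ... | pagen data | IFD1 | ... | IFDn
  sizes <- vapply(channels, function(m) 4L * length(m), integer(1))
  data_offsets <- header_size + cumsum(c(0L, sizes[-n]))
  ifd_offsets <- header_size + sum(sizes) + (seq_len(n) - 1L) * ifd_size
  writeBin(as.integer(ifd_offsets[1]), con, size = 4, endian = "little")
  for (m in channels) {
    # TIFF is row-major: write rows in order
    writeBin(as.numeric(t(m)), con, size = 4, endian = "little")
  }
  write_entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3L) { # SHORT packed left-justified
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  for (i in seq_len(n)) {
    m <- channels[[i]]
    writeBin(as.integer(entry_count), con, size = 2, endian = "little")
    write_entry(256L, 3L, 1L, ncol(m))
    write_entry(257L, 3L, 1L, nrow(m))
    write_entry(258L, 3L, 1L, 32L)
    write_entry(259L, 3L, 1L, 1L)   # no compression
    write_entry(262L, 3L, 1L, 1L)   # black is zero
    write_entry(273L, 4L, 1L, data_offsets[i])
    write_entry(277L, 3L, 1L, 1L)
    write_entry(278L, 3L, 1L, nrow(m))
    write_entry(279L, 4L, 1L, sizes[i])
    write_entry(339L, 3L, 1L, 3L)   # IEEE float
    next_off <- if (i < n) ifd_offsets[i + 1] else 0L
    writeBin(as.integer(next_off), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a multi-page greyscale TIFF
#'
#' Supports the uncompressed baseline subset: single sample per pixel,
#' uint8/uint16/uint32 or float32, one or more strips, either byte order.
#'
#' @param path TIFF file path.
#' @return Named list of numeric matrices (`page1`, `page2`, ... unless the
#'   caller renames them).
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8) stopf("'%s' is not a TIFF", path)
  order_tag <- rawToChar(raw[1:2])
  endian <- switch(order_tag, II = "little", MM = "big",
                   stopf("'%s' is not a TIFF", path))
  rd_int <- function(off, size, n = 1L) {
    readBin(raw[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = endian, signed = size == 4)
  }
  if (rd_int(2, 2) != 42L) stopf("'%s' is not a TIFF", path)
  ifd_off <- rd_int(4, 4)
  pages <- list()
  while (ifd_off != 0L) {
    n_entries <- rd_int(ifd_off, 2)
    tags <- list()
    for (e in seq_len(n_entries)) {
      base <- ifd_off + 2L + (e - 1L) * 12L
      tag <- rd_int(base, 2)
      type <- rd_int(base + 2, 2)
      count <- rd_int(base + 4, 4)
      tsize <- switch(as.character(type), `1` = 1L, `3` = 2L, `4` = 4L, NA_integer_)
      if (is.na(tsize)) next
      nbytes <- tsize * count
      voff <- if (nbytes <= 4L) base + 8L else rd_int(base + 8, 4)
      tags[[as.character(tag)]] <- rd_int(voff, tsize, count)
    }
    need <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) {
        if (is.null(default)) stopf("TIFF page missing tag %d", tag)
        default
      } else v
    }
    if (need(259L, 1L)[1] != 1L) stopf("compressed TIFF is not supported")
    w <- need(256L); h <- need(257L)
    bits <- need(258L, 1L)[1]
    fmt <- need(339L, 1L)[1]
    offs <- need(273L)
    counts <- need(279L, (bits / 8) * w * h)
    payload <- raw(0)
    for (s in seq_along(offs)) {
      payload <- c(payload, raw[(offs[s] + 1):(offs[s] + counts[s])])
    }
    npx <- as.integer(w) * as.integer(h)
    vals <- if (fmt == 3L) {
      readBin(payload, "double", n = npx, size = bits / 8, endian = endian)
    } else if (bits == 32L) {
      readBin(payload, "integer", n = npx, size = 4, endian = endian)
    } else if (bits %in% c(8L, 16L)) {
      readBin(payload, "integer", n = npx, size = bits / 8, endian = endian,
              signed = FALSE)
    } else {
      stopf("unsupported TIFF bit depth %d", bits)
    }
    pages[[length(pages) + 1L]] <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
    ifd_off <- rd_int(ifd_off + 2L + n_entries * 12L, 4)
  }
  names(pages) <- paste0("page", seq_along(pages))
  pages
}

#' Write a simulated scene to disk
#'
#' Writes the multi-channel TIFF (one page per channel), a YAML sidecar with
#' channel names, roles and pixel size, and the ground truth as JSON.
#'
#' @param sim result of [simulate_guv_image()] (or any list with `image` and
#'   `truth` elements whose image channels are 2-D).
#' @param dir output directory (created if needed).
#' @param name basename for the three files.
#' @return Named character vector of the paths written, invisibly.
#' @export
write_scene <- function(sim, dir, name = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img <- sim$image
  tif <- file.path(dir, paste0(name, ".tif"))
  write_tiff(img$channels, tif)
  cfg <- list(channels = as.list(names(img$channels)),
              roles = as.list(stats::setNames(unname(img$roles), names(img$roles))),
              pixel_size = img$pixel_size)
  yml <- file.path(dir, paste0(name, ".channels.yaml"))
  yaml::write_yaml(cfg, yml)
  js <- file.path(dir, paste0(name, ".truth.json"))
  jsonlite::write_json(sim$truth, js, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(tiff = tif, channels = yml, truth = js))
}

#' Read a scene written by [write_scene()]
#'
#' @param tif path to the TIFF; the `.channels.yaml` sidecar is looked up next
#'   to it (or passed explicitly).
#' @param channels_yaml optional explicit sidecar path.
#' @return A [multichannel_image()].
#' @export
read_scene <- function(tif, channels_yaml = NULL) {
  channels_yaml <- channels_yaml %||% sub("\\.tiff?$", ".channels.yaml", tif)
  if (!file.exists(channels_yaml)) stopf("channel sidecar '%s' not found", channels_yaml)
  cfg <- yaml::read_yaml(channels_yaml)
  pages <- read_tiff(tif)
  if (length(pages) != length(cfg$channels)) {
    stopf("TIFF has %d pages but sidecar lists %d channels",
          length(pages), length(cfg$channels))
  }
  names(pages) <- unlist(cfg$channels)
  multichannel_image(pages, unlist(cfg$roles), cfg$pixel_size %||% 0.1)
}
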