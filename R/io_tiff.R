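# Minimal baseline TIFF support (little-endian, uncompressed, grayscale,
# one strip per page): enough for the package's external interfaces —
# unsigned 8-bit label/mask stacks and 32-bit float volumes. No pre-installed
# R package reads TIFF, so this is implemented here and round-trip tested.

#' Write a 3D volume as an uncompressed multipage TIFF
#'
#' Pages are z slices (first array index); rows are y, columns x.
#'
#' @param vol 3D numeric/integer/logical array, dim (z, y, x).
#' @param path Output file.
#' @param type "uint8" (labels/masks, values 0..255) or "float32".
#' @return `path`, invisibly.
#' @export
write_tiff_volume <- function(vol, path, type = c("uint8", "float32")) {
  type <- match.arg(type)
  stopifnot(length(dim(vol)) == 3L)
  d <- dim(vol)
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  bps <- if (type == "uint8") 1L else 4L
  sfmt <- if (type == "uint8") 1L else 3L
  strip_bytes <- nx * ny * bps

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  # layout: header(8) then per page [pixel data][IFD]; IFD has 8 entries
  n_entries <- 8L
  ifd_size <- 2L + n_entries * 12L + 4L
  offset <- 8L
  write_entry <- function(tag, typ, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(typ), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (typ == 3L) {  # SHORT: left-justified in the 4-byte value field
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  ifd_first <- offset + strip_bytes
  writeBin(as.integer(ifd_first), con, size = 4, endian = "little")
  for (z in seq_len(nz)) {
    page_off <- 8L + (z - 1L) * (strip_bytes + ifd_size)
    sl <- t(vol[z, , ])  # write row-major: rows y, columns x
    if (type == "uint8") {
      writeBin(as.raw(pmin(pmax(as.integer(sl), 0L), 255L)), con)
    } else {
      writeBin(as.numeric(sl), con, size = 4, endian = "little")
    }
    # IFD
    writeBin(n_entries, con, size = 2, endian = "little")
    write_entry(256L, 3L, 1L, nx)            # ImageWidth
    write_entry(257L, 3L, 1L, ny)            # ImageLength
    write_entry(258L, 3L, 1L, 8L * bps)      # BitsPerSample
    write_entry(259L, 3L, 1L, 1L)            # Compression = none
    write_entry(262L, 3L, 1L, 1L)            # Photometric = BlackIsZero
    write_entry(273L, 4L, 1L, page_off)      # StripOffsets
    write_entry(279L, 4L, 1L, strip_bytes)   # StripByteCounts
    write_entry(339L, 3L, 1L, sfmt)          # SampleFormat
    nxt <- if (z < nz) page_off + strip_bytes + ifd_size + strip_bytes else 0L
    writeBin(as.integer(nxt), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a multipage TIFF written by [write_tiff_volume()]
#'
#' Supports little-endian uncompressed grayscale TIFFs with one strip per
#' page, 8-bit unsigned or 32-bit float samples.
#'
#' @param path TIFF file.
#' @return 3D array, dim (z, y, x); integer for uint8, numeric for float32.
#' @export
read_tiff_volume <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  u16 <- function(off) as.integer(raw[off + 1]) + 256L * as.integer(raw[off + 2])
  u32 <- function(off) as.integer(raw[off + 1]) + 256 * as.integer(raw[off + 2]) +
    65536 * as.integer(raw[off + 3]) + 16777216 * as.integer(raw[off + 4])
  if (rawToChar(raw[1:2]) != "II" || u16(2) != 42L)
    stopf("read_tiff_volume: not a little-endian TIFF")
  ifd <- u32(4)
  pages <- list()
  while (ifd != 0) {
    n <- u16(ifd)
    tags <- list()
    for (i in seq_len(n)) {
      e <- ifd + 2L + (i - 1L) * 12L
      tag <- u16(e); typ <- u16(e + 2L)
      val <- if (typ == 3L) u16(e + 8L) else u32(e + 8L)
      tags[[as.character(tag)]] <- val
    }
    if (!is.null(tags[["259"]]) && tags[["259"]] != 1L)
      stopf("read_tiff_volume: compressed TIFF not supported")
    nx <- tags[["256"]]; ny <- tags[["257"]]
    bits <- if (is.null(tags[["258"]])) 8L else tags[["258"]]
    sfmt <- if (is.null(tags[["339"]])) 1L else tags[["339"]]
    off <- tags[["273"]]; nbytes <- tags[["279"]]
    if (bits == 8L && sfmt == 1L) {
      px <- as.integer(raw[(off + 1):(off + nbytes)])
    } else if (bits == 32L && sfmt == 3L) {
      px <- readBin(raw[(off + 1):(off + nbytes)], "numeric", n = nbytes / 4,
                    size = 4, endian = "little")
    } else stopf("read_tiff_volume: unsupported sample format (%d bit, fmt %d)",
                 bits, sfmt)
    m <- matrix(px, nrow = nx, ncol = ny)  # stored row-major
    pages[[length(pages) + 1L]] <- t(m)
    ifd <- u32(ifd + 2L + n * 12L)
  }
  nz <- length(pages)
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  out <- array(if (is.integer(pages[[1]][1])) 0L else 0, dim = c(nz, ny, nx))
  for (z in seq_len(nz)) out[z, , ] <- pages[[z]]
  out
}

#' Write a labelled phantom to disk
#'
#' Labels as an unsigned 8-bit multipage TIFF plus a JSON sidecar holding the
#' spec, the canal registry and the voxel size.
#'
#' @param phantom A `labelled_phantom`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "labelled_phantom"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tiff_volume(phantom$labels, file.path(dir, "labels.tif"), "uint8")
  side <- list(voxel_size_um = phantom$voxel_size_um,
               spec = unclass(phantom$spec),
               registry = phantom$registry,
               n_lacunae = phantom$n_lacunae)
  jsonlite::write_json(side, file.path(dir, "phantom.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a labelled phantom written by [write_phantom()]
#' @param dir Directory containing `labels.tif` and `phantom.json`.
#' @return A `labelled_phantom`.
#' @export
read_phantom <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "phantom.json"), simplifyVector = TRUE)
  labels <- read_tiff_volume(file.path(dir, "labels.tif"))
  spec <- side$spec
  spec$grid_shape <- as.integer(spec$grid_shape)
  class(spec) <- "phantom_spec"
  reg <- as.data.frame(side$registry, stringsAsFactors = FALSE)
  structure(list(labels = labels, voxel_size_um = side$voxel_size_um,
                 spec = spec, registry = reg,
                 n_lacunae = as.integer(side$n_lacunae)),
            class = "labelled_phantom")
}

#' Write a reconstruction (or material map) as float TIFF + JSON sidecar
#' @param recon A `recon_volume`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_recon <- function(recon, dir) {
  stopifnot(inherits(recon, "recon_volume"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tiff_volume(recon$values, file.path(dir, "recon.tif"), "float32")
  jsonlite::write_json(list(voxel_size_um = recon$voxel_size_um,
                            beam = unclass(recon$provenance)),
                       file.path(dir, "recon.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a reconstruction written by [write_recon()]
#' @param dir Directory containing `recon.tif` and `recon.json`.
#' @return A `recon_volume` (values in float32 precision).
#' @export
read_recon <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "recon.json"), simplifyVector = TRUE)
  beam <- side$beam
  class(beam) <- "beam_config"
  structure(list(values = read_tiff_volume(file.path(dir, "recon.tif")),
                 voxel_size_um = side$voxel_size_um, provenance = beam),
            class = "recon_volume")
}

#' Write a sinogram as float TIFF (pages = angles) + JSON sidecar
#' @param sino A `sinogram`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_sinogram <- function(sino, dir) {
  stopifnot(inherits(sino, "sinogram"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vol <- aperm(sino$intensities, c(3, 1, 2))  # (angle, row, column) on disk
  write_tiff_volume(vol, file.path(dir, "sinogram.tif"), "float32")
  jsonlite::write_json(list(angles = sino$angles, beam = unclass(sino$beam)),
                       file.path(dir, "sinogram.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a sinogram written by [write_sinogram()]
#' @param dir Directory containing `sinogram.tif` and `sinogram.json`.
#' @return A `sinogram`.
#' @export
read_sinogram <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "sinogram.json"), simplifyVector = TRUE)
  vol <- read_tiff_volume(file.path(dir, "sinogram.tif"))
  beam <- side$beam
  class(beam) <- "beam_config"
  structure(list(intensities = aperm(vol, c(2, 3, 1)),
                 angles = as.numeric(side$angles), beam = beam),
            class = "sinogram")
}
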