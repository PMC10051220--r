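# Readers/writers for the on-disk formats: 32-bit float TIFF image stacks,
# PNG boolean masks, CSV tables and JSON sidecars, plus the directory bundle
# holding a ptychography dataset.

#' Read and write image stacks as 32-bit float TIFF
#'
#' Single images are stored as one page; stacks (lists or 3D arrays with the
#' page index last) as multipage TIFF.  Round trips are lossless at float32
#' precision.
#'
#' @param path TIFF file path.
#' @param stack matrix, 3D array, or list of matrices.
#' @return `read_image_stack`: a matrix (single page) or list of matrices.
#' @export
read_image_stack <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = FALSE),
                    error = function(e) stop("unreadable TIFF '", path, "': ",
                                             conditionMessage(e)))
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]   # collapse accidental channels
    p
  })
  if (length(pages) == 1L) pages[[1]] else pages
}

#' @rdname read_image_stack
#' @export
write_image_stack <- function(stack, path) {
  if (is.array(stack) && length(dim(stack)) == 3L)
    stack <- lapply(seq_len(dim(stack)[3]), function(k) stack[, , k])
  if (is.matrix(stack)) stack <- list(stack)
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  write_float_tiff(stack, path)
  invisible(path)
}

# Minimal uncompressed 32-bit IEEE-float TIFF writer (little-endian, one
# strip per page, chained IFDs).  Needed because the available TIFF binding
# only writes integer sample formats; libtiff reads these pages natively.
write_float_tiff <- function(pages, path) {
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeChar("II", con, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  # data blocks first; IFDs follow all pixel data
  sizes <- vapply(pages, function(m) 4L * length(m), integer(1))
  data_off <- 8L + c(0L, cumsum(sizes))[seq_along(pages)]
  ifd_size <- 2L + 10L * 12L + 4L
  ifd_off <- 8L + sum(sizes) + (seq_along(pages) - 1L) * ifd_size
  writeBin(as.integer(ifd_off[1]), con, size = 4, endian = "little")
  for (m in pages)
    writeBin(as.numeric(t(m)), con, size = 4, endian = "little")
  entry <- function(tag, type, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(1L, con, size = 4, endian = "little")
    if (type == 3L) {  # SHORT padded to 4 bytes
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  for (k in seq_along(pages)) {
    m <- pages[[k]]
    writeBin(10L, con, size = 2, endian = "little")
    entry(256, 4, ncol(m))            # ImageWidth
    entry(257, 4, nrow(m))            # ImageLength
    entry(258, 3, 32)                 # BitsPerSample
    entry(259, 3, 1)                  # Compression: none
    entry(262, 3, 1)                  # Photometric: BlackIsZero
    entry(273, 4, data_off[k])        # StripOffsets
    entry(277, 3, 1)                  # SamplesPerPixel
    entry(278, 4, nrow(m))            # RowsPerStrip
    entry(279, 4, sizes[k])           # StripByteCounts
    entry(339, 3, 3)                  # SampleFormat: IEEE float
    nxt <- if (k < length(pages)) ifd_off[k + 1] else 0L
    writeBin(as.integer(nxt), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read and write sampling masks as PNG
#'
#' Masks are stored as 0/1 8-bit PNG and read back as a [make_mask]-style
#' `sampling_mask` (scheme tagged `"file"`).
#'
#' @param path PNG file path; `mask` a `sampling_mask` or logical matrix.
#' @param mask mask to write.
#' @return `read_mask`: a `sampling_mask`.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  keep <- m > 0.5
  structure(list(keep = keep, fraction = mean(keep), scheme = "file"),
            class = "sampling_mask")
}

#' @rdname read_mask
#' @export
write_mask <- function(mask, path) {
  keep <- mask_values(mask)
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  png::writePNG(keep * 1, path)
  invisible(path)
}

#' Ptychography dataset bundle
#'
#' On-disk container for a [ptycho_dataset]: a directory holding
#' `data.tif` (multipage 32-bit float intensity stack), `positions.csv`
#' (columns `rx`, `ry` in object pixels) and `meta.json` (keys `energy_ev`,
#' `distance_m`, `pixel_size_m`, `regime`).  Round trips preserve data,
#' positions and attributes exactly at float32/CSV precision.
#'
#' @param dataset a [ptycho_dataset]; `dir` the bundle directory.
#' @param dir bundle directory path.
#' @return `read_ptycho_bundle`: a [ptycho_dataset].
#' @export
write_ptycho_bundle <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_image_stack(dataset$intensities, file.path(dir, "data.tif"))
  utils::write.csv(data.frame(rx = dataset$positions[, 1],
                              ry = dataset$positions[, 2]),
                   file.path(dir, "positions.csv"), row.names = FALSE)
  jsonlite::write_json(list(energy_ev = dataset$spec$energy_ev,
                            distance_m = dataset$spec$distance_m,
                            pixel_size_m = dataset$spec$pixel_size_m,
                            regime = dataset$spec$regime),
                       file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_ptycho_bundle
#' @export
read_ptycho_bundle <- function(dir) {
  files <- c(data = "data.tif", positions = "positions.csv", meta = "meta.json")
  missing <- files[!file.exists(file.path(dir, files))]
  if (length(missing))
    stop("ptycho bundle schema error; missing: ", paste(missing, collapse = ", "))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  need <- c("energy_ev", "distance_m", "pixel_size_m", "regime")
  absent <- setdiff(need, names(meta))
  if (length(absent))
    stop("ptycho bundle schema error; missing attributes: ",
         paste(absent, collapse = ", "))
  pos <- utils::read.csv(file.path(dir, "positions.csv"))
  ints <- read_image_stack(file.path(dir, "data.tif"))
  if (is.matrix(ints)) ints <- list(ints)
  spec <- propagation_spec(distance_m = meta$distance_m,
                           pixel_size_m = meta$pixel_size_m,
                           energy_ev = meta$energy_ev,
                           regime = meta$regime)
  ptycho_dataset(ints, cbind(pos$rx, pos$ry), spec)
}

write_sidecar <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
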