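# Volume input/output. OPT cameras and reconstruction pipelines exchange
# image stacks as multi-page TIFF; 32-bit IEEE float pages are written by a
# small built-in writer (the CRAN tiff package reads float TIFFs but only
# writes integer sample formats) and read back through tiff::readTIFF.

write_float_tiff <- function(slices, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  wb <- function(x, size) writeBin(x, con, size = size, endian = "little")
  wb(charToRaw("II"), 1L) # little-endian byte order mark
  wb(42L, 2L)
  wb(8L, 4L) # offset of the first IFD, directly after this 8-byte header
  # strips follow each IFD
  n_entries <- 10L
  ifd_size <- 2L + 12L * n_entries + 4L
  pos <- 8L
  for (s in seq_along(slices)) {
    x <- slices[[s]]
    H <- nrow(x); W <- ncol(x)
    strip_at <- pos + ifd_size
    nbytes <- H * W * 4L
    entry <- function(tag, type, count, value) {
      wb(as.integer(tag), 2L); wb(as.integer(type), 2L)
      wb(as.integer(count), 4L)
      if (type == 3L) { wb(as.integer(value), 2L); wb(0L, 2L) }
      else wb(as.integer(value), 4L)
    }
    wb(n_entries, 2L)
    entry(256L, 4L, 1L, W)           # ImageWidth
    entry(257L, 4L, 1L, H)           # ImageLength
    entry(258L, 3L, 1L, 32L)         # BitsPerSample
    entry(259L, 3L, 1L, 1L)          # Compression: none
    entry(262L, 3L, 1L, 1L)          # Photometric: BlackIsZero
    entry(273L, 4L, 1L, strip_at)    # StripOffsets
    entry(277L, 3L, 1L, 1L)          # SamplesPerPixel
    entry(278L, 4L, 1L, H)           # RowsPerStrip
    entry(279L, 4L, 1L, nbytes)      # StripByteCounts
    entry(339L, 3L, 1L, 3L)          # SampleFormat: IEEE float
    next_ifd <- if (s < length(slices)) strip_at + nbytes else 0L
    wb(next_ifd, 4L)
    wb(as.numeric(t(x)), 4L)         # scanlines are rows
    pos <- strip_at + nbytes
  }
  invisible(path)
}

#' Write a slice stack to disk
#'
#' Multi-page TIFF (32-bit IEEE float, one page per slice, page order = slice
#' order) for `.tif`/`.tiff` paths, or R's native array container for `.rds`
#' paths. A structured-text sidecar `<path>.yml` records dimensions and any
#' generation parameters.
#'
#' @param slices List of numeric matrices, or a 3-d array (slices along the
#'   third dimension).
#' @param path Output path (`.tif`, `.tiff` or `.rds`).
#' @param metadata Named list echoed into the sidecar file.
#' @return `path`, invisibly.
#' @export
write_volume <- function(slices, path, metadata = list()) {
  if (is.array(slices) && length(dim(slices)) == 3L)
    slices <- lapply(seq_len(dim(slices)[3]), function(k) slices[, , k])
  stopifnot(is.list(slices), length(slices) >= 1L,
            all(vapply(slices, is.matrix, logical(1))))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) write_float_tiff(slices, path)
  else if (ext == "rds") saveRDS(simplify2array(slices), path)
  else stop("unsupported volume format: .", ext, call. = FALSE)
  meta <- c(list(n_slices = length(slices),
                 height = nrow(slices[[1]]), width = ncol(slices[[1]]),
                 format = if (ext == "rds") "rds" else "tiff-float32"),
            metadata)
  yaml::write_yaml(meta, paste0(path, ".yml"))
  invisible(path)
}

#' Read a slice stack from disk
#'
#' Reads multi-page TIFF (float or integer sample formats; integer pixel
#' values are preserved exactly as numeric) or `.rds` array containers
#' written by [write_volume()].
#'
#' @param path Input path.
#' @return List of numeric matrices, in page order.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "rds") {
    a <- readRDS(path)
    if (is.matrix(a)) return(list(a))
    stopifnot(length(dim(a)) == 3L)
    return(lapply(seq_len(dim(a)[3]), function(k) a[, , k]))
  }
  # as.is = TRUE preserves raw integer pixel values but is rejected for
  # floating-point sample formats, which are already returned verbatim
  pages <- tryCatch(
    tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
             error = function(e) {
               if (grepl("floating point", conditionMessage(e)))
                 tiff::readTIFF(path, all = TRUE)
               else stop(e)
             }),
    error = function(e)
      stop("not a readable TIFF: ", path, " (", conditionMessage(e), ")",
           call. = FALSE))
  lapply(seq_along(pages), function(k) {
    pg <- pages[[k]]
    if (!is.numeric(pg) || length(dim(pg)) > 2L)
      stop(sprintf("page %d of %s is not a single-channel image", k, path),
           call. = FALSE)
    storage.mode(pg) <- "double"
    as.matrix(pg)
  })
}
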