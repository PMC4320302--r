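#' In-memory MSI dataset
#'
#' Container for a mass spectrometry image: a shared m/z axis, integer pixel
#' grid coordinates, and one intensity vector per pixel. Pixels are stored in
#' ascending `(y, x)` order (1-based, imzML convention); every accessor and
#' every streaming reader in the package visits pixels in that order, which
#' makes seeded downstream steps deterministic.
#'
#' @param coords integer matrix or data frame with columns `x`, `y`
#'   (1-based grid positions, one row per pixel, no duplicates).
#' @param mz numeric vector of m strictly increasing m/z values (Daltons).
#' @param intensities numeric matrix, m channels x n pixels, column j holding
#'   the spectrum of pixel j. Negative entries are clamped to 0 with a
#'   warning.
#'
#' @return An object of class `msi_dataset`, which also implements the
#'   streaming reader interface ([n_pixels()], [n_channels()], [mz_axis()],
#'   [pixel_coords()], [read_spectra()]).
#' @export
msi_dataset <- function(coords, mz, intensities) {
  coords <- as.matrix(as.data.frame(coords)[, c("x", "y")])
  storage.mode(coords) <- "integer"
  mz <- as.numeric(mz)
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"

  m <- length(mz)
  n <- nrow(coords)
  if (n < 1L) domain_error("an MSI dataset must contain at least one pixel")
  if (m < 1L) domain_error("an MSI dataset must contain at least one m/z channel")
  if (any(is.na(coords))) domain_error("pixel coordinates must not be missing")
  if (anyDuplicated(coords)) domain_error("pixel coordinates must be unique")
  if (any(diff(mz) <= 0)) domain_error("mz axis must be strictly increasing")
  if (nrow(intensities) != m || ncol(intensities) != n) {
    domain_error(sprintf(
      "intensities must be %d channels x %d pixels, got %d x %d",
      m, n, nrow(intensities), ncol(intensities)))
  }
  if (anyNA(intensities)) domain_error("intensities must not contain NA")
  if (any(intensities < 0)) {
    warning("negative intensities clamped to 0", call. = FALSE)
    intensities[intensities < 0] <- 0
  }

  ord <- order(coords[, "y"], coords[, "x"])
  structure(
    list(coords = coords[ord, , drop = FALSE],
         mz = mz,
         intensities = intensities[, ord, drop = FALSE]),
    class = "msi_dataset")
}

# ---- streaming reader interface ---------------------------------------------
# A "reader" is anything that can report its geometry and serve spectra by
# pixel index in the canonical (y, x)-ascending order. msi_dataset serves from
# memory; imzml_reader (see imzml.R) serves from disk one spectrum at a time.

#' Number of pixels of an MSI reader
#' @param x an MSI reader (`msi_dataset` or `imzml_reader`).
#' @return integer pixel count n.
#' @export
n_pixels <- function(x) UseMethod("n_pixels")

#' Number of m/z channels of an MSI reader
#' @inheritParams n_pixels
#' @return integer channel count m.
#' @export
n_channels <- function(x) UseMethod("n_channels")

#' Shared m/z axis of an MSI reader
#' @inheritParams n_pixels
#' @return numeric vector of m strictly increasing m/z values.
#' @export
mz_axis <- function(x) UseMethod("mz_axis")

#' Pixel coordinates of an MSI reader
#' @inheritParams n_pixels
#' @return integer matrix (n x 2, columns `x`, `y`) in iteration order.
#' @export
pixel_coords <- function(x) UseMethod("pixel_coords")

#' Read spectra by pixel index
#'
#' @inheritParams n_pixels
#' @param idx integer vector of pixel indices (1..n, iteration order).
#' @return numeric matrix m x `length(idx)`; column j is the spectrum of
#'   pixel `idx[j]`.
#' @export
read_spectra <- function(x, idx) UseMethod("read_spectra")

#' @export
n_pixels.msi_dataset <- function(x) nrow(x$coords)
#' @export
n_channels.msi_dataset <- function(x) length(x$mz)
#' @export
mz_axis.msi_dataset <- function(x) x$mz
#' @export
pixel_coords.msi_dataset <- function(x) x$coords
#' @export
read_spectra.msi_dataset <- function(x, idx) {
  check_pixel_idx(idx, n_pixels(x))
  x$intensities[, idx, drop = FALSE]
}

#' @export
print.msi_dataset <- function(x, ...) {
  cat(sprintf("<msi_dataset> %d pixels x %d m/z channels, m/z [%.4g, %.4g]\n",
              n_pixels(x), n_channels(x), min(x$mz), max(x$mz)))
  invisible(x)
}

check_pixel_idx <- function(idx, n) {
  if (length(idx) < 1L || anyNA(idx) || any(idx < 1L) || any(idx > n)) {
    domain_error(sprintf("pixel indices must lie in 1..%d", n))
  }
}

#' Stream over a reader in fixed-size chunks
#'
#' Applies `fun(idx, spectra)` to consecutive chunks of pixels in iteration
#' order; `spectra` is the m x length(idx) block. Memory use is bounded by one
#' chunk regardless of n. Used by every full-data pass in the package.
#'
#' @param reader an MSI reader.
#' @param fun function of `(idx, spectra)` called once per chunk, in order.
#' @param chunk_size pixels per chunk (default 64).
#' @return invisibly, `NULL`.
#' @export
stream_spectra <- function(reader, fun, chunk_size = 64L) {
  n <- n_pixels(reader)
  chunk_size <- max(1L, as.integer(chunk_size))
  start <- 1L
  while (start <= n) {
    idx <- start:min(n, start + chunk_size - 1L)
    fun(idx, read_spectra(reader, idx))
    start <- start + chunk_size
  }
  invisible(NULL)
}

#' Materialize a reader as an in-memory dataset
#' @param reader an MSI reader.
#' @return an [msi_dataset()].
#' @export
collect_dataset <- function(reader) {
  if (inherits(reader, "msi_dataset")) return(reader)
  msi_dataset(pixel_coords(reader), mz_axis(reader),
              read_spectra(reader, seq_len(n_pixels(reader))))
}
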