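# imzML 1.1 I/O: an XML index (.imzML) plus a binary companion (.ibd) holding
# the arrays. Continuous mode stores one shared m/z axis and a dense intensity
# vector per pixel; processed mode stores a (mz, intensity) peak list per
# pixel, which this package resamples onto a fixed-width-bin axis at read
# time. Only uncompressed 32/64-bit float arrays are supported, which covers
# files produced by the common converters.

CV_MZ_ARRAY <- "MS:1000514"
CV_INT_ARRAY <- "MS:1000515"
CV_FLOAT64 <- "MS:1000523"
CV_FLOAT32 <- "MS:1000521"
CV_CONTINUOUS <- "IMS:1000030"
CV_PROCESSED <- "IMS:1000031"
CV_UUID <- "IMS:1000080"
CV_POS_X <- "IMS:1000050"
CV_POS_Y <- "IMS:1000051"
CV_EXT_OFFSET <- "IMS:1000102"
CV_EXT_ARRLEN <- "IMS:1000103"
CV_EXT_ENCLEN <- "IMS:1000104"

ibd_path_for <- function(path) {
  cand <- sub("\\.[iI][mM][zZ][mM][lL]$", ".ibd", path)
  if (identical(cand, path)) cand <- paste0(path, ".ibd")
  cand
}

# Deterministic 16-byte identifier derived from the dataset content (FNV-1a
# over the byte stream of a content digest vector, four offset basins). A
# content hash rather than a random UUID keeps whole-pipeline outputs
# byte-identical across reruns with the same seeds.
content_uuid <- function(mz, digest_values) {
  bytes <- writeBin(c(as.numeric(length(mz)), range(mz), digest_values),
                    raw(), size = 8)
  out <- raw(16)
  for (block in 0:3) {
    h <- 2166136261 + block * 16777619
    for (b in as.integer(bytes)) {
      h <- bitwXor(as.integer(h %% 2147483647), b)
      h <- (as.numeric(h) * 16777619) %% 4294967296
    }
    out[(block * 4 + 1):(block * 4 + 4)] <-
      writeBin(as.integer(h %% 2147483648), raw(), size = 4)
  }
  out
}

format_uuid <- function(bytes) {
  hex <- paste(format(bytes), collapse = "")
  sprintf("{%s-%s-%s-%s-%s}", substr(hex, 1, 8), substr(hex, 9, 12),
          substr(hex, 13, 16), substr(hex, 17, 20), substr(hex, 21, 32))
}

#' Write an MSI dataset as a continuous-mode imzML/ibd pair
#'
#' Streams the reader one chunk at a time, so datasets larger than memory can
#' be re-exported. The shared m/z axis is stored once; intensities are stored
#' as uncompressed 64-bit floats, so a write/read round trip is bit-exact.
#'
#' @param dataset an MSI reader ([msi_dataset()] or [read_imzml()] handle).
#' @param path output path ending in `.imzML`; the `.ibd` companion is
#'   written alongside.
#' @return invisibly, a character vector with the two paths written.
#' @export
write_imzml <- function(dataset, path) {
  if (!(inherits(dataset, "msi_dataset") || inherits(dataset, "imzml_reader"))) {
    domain_error("`dataset` must be an msi_dataset or imzml_reader")
  }
  n <- n_pixels(dataset)
  m <- n_channels(dataset)
  if (n < 1L) domain_error("cannot write an empty dataset (0 pixels)")
  mz <- mz_axis(dataset)
  coords <- pixel_coords(dataset)
  ibd <- ibd_path_for(path)

  con <- tryCatch(file(ibd, open = "wb"),
                  error = function(e) io_error(paste0("cannot write ibd file: ", ibd)))
  ok <- FALSE
  on.exit({
    close(con)
    if (!ok) unlink(c(ibd, path))
  })

  # digest for the content uuid: cheap moments over the streamed data
  total <- 0; sqtotal <- 0
  uuid_placeholder <- raw(16)
  writeBin(uuid_placeholder, con)
  writeBin(as.numeric(mz), con, size = 8, endian = "little")
  stream_spectra(dataset, function(idx, spectra) {
    total <<- total + sum(spectra)
    sqtotal <<- sqtotal + sum(spectra^2)
    writeBin(as.numeric(spectra), con, size = 8, endian = "little")
  })
  uuid <- content_uuid(mz, c(n, total, sqtotal))
  seek(con, 0, origin = "start", rw = "write")
  writeBin(uuid, con)
  flush(con)

  mz_offset <- 16
  int_offsets <- 16 + 8 * m + (seq_len(n) - 1) * 8 * m

  spectrum_xml <- sprintf(paste0(
    '    <spectrum index="%d" id="spectrum=%d" defaultArrayLength="%d">\n',
    '     <scanList count="1">\n      <scan>\n',
    '       <cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/>\n',
    '       <cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%d"/>\n',
    '      </scan>\n     </scanList>\n',
    '     <binaryDataArrayList count="2">\n',
    '      <binaryDataArray encodedLength="0">\n',
    '       <referenceableParamGroupRef ref="mzArray"/>\n',
    '       <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%.0f"/>\n',
    '       <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>\n',
    '       <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%.0f"/>\n',
    '       <binary/>\n      </binaryDataArray>\n',
    '      <binaryDataArray encodedLength="0">\n',
    '       <referenceableParamGroupRef ref="intensityArray"/>\n',
    '       <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%.0f"/>\n',
    '       <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>\n',
    '       <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%.0f"/>\n',
    '       <binary/>\n      </binaryDataArray>\n',
    '     </binaryDataArrayList>\n    </spectrum>'),
    seq_len(n) - 1L, seq_len(n), m, coords[, "x"], coords[, "y"],
    mz_offset, m, 8 * m, int_offsets, m, 8 * m)

  header <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">',
    ' <cvList count="2">',
    '  <cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="http://psidev.info/ms/mzML/psi-ms.obo"/>',
    '  <cv id="IMS" fullName="Imaging MS Ontology" URI="http://www.maldi-msi.org/download/imzml/imagingMS.obo"/>',
    ' </cvList>',
    ' <fileDescription>',
    '  <fileContent>',
    '   <cvParam cvRef="IMS" accession="IMS:1000030" name="continuous"/>',
    sprintf('   <cvParam cvRef="IMS" accession="IMS:1000080" name="universally unique identifier" value="%s"/>',
            format_uuid(uuid)),
    '  </fileContent>',
    ' </fileDescription>',
    ' <referenceableParamGroupList count="2">',
    '  <referenceableParamGroup id="mzArray">',
    '   <cvParam cvRef="MS" accession="MS:1000514" name="m/z array" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>',
    '   <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
    '   <cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>',
    '   <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>',
    '  </referenceableParamGroup>',
    '  <referenceableParamGroup id="intensityArray">',
    '   <cvParam cvRef="MS" accession="MS:1000515" name="intensity array" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>',
    '   <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
    '   <cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>',
    '   <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>',
    '  </referenceableParamGroup>',
    ' </referenceableParamGroupList>',
    sprintf(' <scanSettingsList count="1">\n  <scanSettings id="scansettings1">\n   <cvParam cvRef="IMS" accession="IMS:1000042" name="max count of pixels x" value="%d"/>\n   <cvParam cvRef="IMS" accession="IMS:1000043" name="max count of pixels y" value="%d"/>\n  </scanSettings>\n </scanSettingsList>',
            max(coords[, "x"]), max(coords[, "y"])),
    ' <run id="run1">',
    sprintf('  <spectrumList count="%d">', n))
  footer <- c('  </spectrumList>', ' </run>', '</mzML>')

  xcon <- tryCatch(file(path, open = "wb"),
                   error = function(e) io_error(paste0("cannot write imzML file: ", path)))
  writeLines(c(header, spectrum_xml, footer), xcon)
  close(xcon)
  ok <- TRUE
  invisible(c(path, ibd))
}

# ---- reading -----------------------------------------------------------------

parse_param_groups <- function(doc) {
  groups <- xml2::xml_find_all(doc, "//referenceableParamGroup")
  out <- list()
  for (g in groups) {
    acc <- xml2::xml_attr(xml2::xml_find_all(g, "cvParam"), "accession")
    out[[xml2::xml_attr(g, "id")]] <- acc
  }
  out
}

array_kind <- function(accessions, what) {
  is_mz <- CV_MZ_ARRAY %in% accessions
  is_int <- CV_INT_ARRAY %in% accessions
  size <- if (CV_FLOAT64 %in% accessions) 8L
          else if (CV_FLOAT32 %in% accessions) 4L
          else io_error(paste0("unsupported binary data type in ", what,
                               " (only 32/64-bit float arrays are supported)"))
  list(is_mz = is_mz, is_int = is_int, size = size)
}

#' Open an imzML file as a streaming MSI reader
#'
#' Parses the XML index up front (coordinates, array offsets, data types) but
#' reads intensity data lazily from the `.ibd` companion, one spectrum (or
#' chunk) at a time, so the full m x n matrix is never held in memory.
#' Pixels are iterated in ascending `(y, x)` order regardless of file order.
#'
#' Processed-mode files (per-pixel peak lists) are resampled onto a common
#' axis by summing peak intensities into fixed-width bins spanning the global
#' m/z range; `bin_width` is required for such files and ignored for
#' continuous ones. Negative intensities are clamped to 0 with a warning.
#'
#' @param path path to the `.imzML` file; the `.ibd` companion must sit
#'   alongside it.
#' @param bin_width bin width in Daltons used to resample processed-mode
#'   spectra onto a common axis. No default: a processed-mode file without a
#'   configured bin width is a configuration error.
#' @return an object of class `imzml_reader` implementing the streaming
#'   reader interface (see [msi_dataset()]).
#' @export
read_imzml <- function(path, bin_width = NULL) {
  if (!file.exists(path)) io_error(paste0("imzML file not found: ", path))
  ibd <- ibd_path_for(path)
  if (!file.exists(ibd)) io_error(paste0("missing ibd companion file: ", ibd))

  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) io_error(paste0("corrupt imzML XML: ", path)))
  xml2::xml_ns_strip(doc)

  fc_acc <- xml2::xml_attr(
    xml2::xml_find_all(doc, "//fileDescription/fileContent/cvParam"), "accession")
  mode <- if (CV_PROCESSED %in% fc_acc) "processed"
          else if (CV_CONTINUOUS %in% fc_acc) "continuous"
          else io_error(paste0("imzML file declares neither continuous nor processed mode: ", path))

  spectra <- xml2::xml_find_all(doc, "//spectrum")
  n <- length(spectra)
  if (n < 1L) io_error(paste0("imzML file contains no spectra: ", path))

  xs <- as.integer(xml2::xml_attr(
    xml2::xml_find_all(doc, sprintf("//spectrum//cvParam[@accession='%s']", CV_POS_X)), "value"))
  ys <- as.integer(xml2::xml_attr(
    xml2::xml_find_all(doc, sprintf("//spectrum//cvParam[@accession='%s']", CV_POS_Y)), "value"))
  if (length(xs) != n || length(ys) != n || anyNA(xs) || anyNA(ys)) {
    io_error(paste0("every spectrum needs exactly one x and y position: ", path))
  }

  arr_counts <- as.integer(xml2::xml_attr(
    xml2::xml_find_all(doc, "//spectrum/binaryDataArrayList"), "count"))
  arrays <- xml2::xml_find_all(doc, "//spectrum//binaryDataArray")
  if (length(arr_counts) != n || sum(arr_counts) != length(arrays)) {
    io_error(paste0("malformed binaryDataArrayList structure: ", path))
  }

  groups <- parse_param_groups(doc)
  offs <- as.numeric(xml2::xml_attr(xml2::xml_find_all(
    arrays, sprintf("cvParam[@accession='%s']", CV_EXT_OFFSET)), "value"))
  lens <- as.numeric(xml2::xml_attr(xml2::xml_find_all(
    arrays, sprintf("cvParam[@accession='%s']", CV_EXT_ARRLEN)), "value"))
  if (length(offs) != length(arrays) || length(lens) != length(arrays)) {
    io_error(paste0("binary data arrays missing external offset/length: ", path))
  }

  refs <- xml2::xml_find_first(arrays, "referenceableParamGroupRef")
  ref_ids <- xml2::xml_attr(refs, "ref")
  kinds <- vector("list", length(arrays))
  for (i in seq_along(arrays)) {
    acc <- if (!is.na(ref_ids[i])) groups[[ref_ids[i]]] else character()
    acc <- c(acc, xml2::xml_attr(xml2::xml_find_all(arrays[[i]], "cvParam"), "accession"))
    kinds[[i]] <- array_kind(acc, path)
  }
  is_mz <- vapply(kinds, `[[`, logical(1), "is_mz")
  is_int <- vapply(kinds, `[[`, logical(1), "is_int")
  sizes <- vapply(kinds, `[[`, integer(1), "size")

  spec_of_array <- rep(seq_len(n), arr_counts)
  tab <- data.frame(mz_offset = NA_real_, mz_len = NA_real_, mz_size = NA_integer_,
                    int_offset = NA_real_, int_len = NA_real_, int_size = NA_integer_)[rep(1, n), ]
  rownames(tab) <- NULL
  for (j in seq_along(arrays)) {
    s <- spec_of_array[j]
    if (is_mz[j]) {
      tab$mz_offset[s] <- offs[j]; tab$mz_len[s] <- lens[j]; tab$mz_size[s] <- sizes[j]
    } else if (is_int[j]) {
      tab$int_offset[s] <- offs[j]; tab$int_len[s] <- lens[j]; tab$int_size[s] <- sizes[j]
    }
  }
  if (anyNA(tab)) io_error(paste0("each spectrum needs one m/z and one intensity array: ", path))

  ibd_size <- file.info(ibd)$size
  if (any(tab$int_offset + tab$int_len * tab$int_size > ibd_size) ||
      any(tab$mz_offset + tab$mz_len * tab$mz_size > ibd_size)) {
    io_error(paste0("ibd file is truncated or corrupt: ", ibd))
  }

  ord <- order(ys, xs)
  coords <- cbind(x = xs, y = ys)[ord, , drop = FALSE]
  if (anyDuplicated(coords)) domain_error(paste0("duplicate pixel coordinates in ", path))
  tab <- tab[ord, ]

  reader <- structure(
    list(path = path, ibd_path = ibd, mode = mode, coords = coords,
         tab = tab, bin_width = bin_width),
    class = "imzml_reader")

  if (mode == "continuous") {
    mz <- with_ibd_con(reader, function(con) {
      read_ibd_array(con, ibd, tab$mz_offset[1], tab$mz_len[1], tab$mz_size[1])
    })
    if (any(diff(mz) <= 0)) io_error(paste0("m/z axis not strictly increasing in ", path))
    if (any(tab$int_len != length(mz))) {
      io_error(paste0("continuous-mode spectra disagree on channel count: ", path))
    }
    reader$mz <- mz
  } else {
    if (is.null(bin_width)) {
      config_error("processed-mode imzML requires a configured `bin_width` (Daltons)")
    }
    if (!is.numeric(bin_width) || bin_width <= 0) {
      config_error("`bin_width` must be a positive number of Daltons")
    }
    rng <- with_ibd_con(reader, function(con) {
      out <- c(Inf, -Inf)
      for (i in seq_len(n)) {
        mzv <- read_ibd_array(con, ibd, tab$mz_offset[i], tab$mz_len[i], tab$mz_size[i])
        out <- c(min(out[1], mzv[1]), max(out[2], mzv[length(mzv)]))
      }
      out
    })
    nb <- as.integer(floor((rng[2] - rng[1]) / bin_width)) + 1L
    reader$mz <- rng[1] + (seq_len(nb) - 0.5) * bin_width
    reader$mz_min <- rng[1]
    reader$n_bins <- nb
  }
  reader
}

# Connections are scoped to one call (opened per chunk read, closed on exit)
# so readers never hold OS resources between uses.
with_ibd_con <- function(reader, fun) {
  con <- tryCatch(file(reader$ibd_path, open = "rb"),
                  error = function(e) io_error(paste0("cannot open ibd file: ",
                                                      reader$ibd_path)))
  on.exit(close(con))
  fun(con)
}

read_ibd_array <- function(con, ibd_path, offset, len, size) {
  seek(con, where = offset, origin = "start", rw = "read")
  v <- readBin(con, "double", n = len, size = size, endian = "little")
  if (length(v) != len) io_error(paste0("ibd file is truncated or corrupt: ", ibd_path))
  v
}

#' @export
n_pixels.imzml_reader <- function(x) nrow(x$coords)
#' @export
n_channels.imzml_reader <- function(x) length(x$mz)
#' @export
mz_axis.imzml_reader <- function(x) x$mz
#' @export
pixel_coords.imzml_reader <- function(x) x$coords

#' @export
read_spectra.imzml_reader <- function(x, idx) {
  check_pixel_idx(idx, n_pixels(x))
  m <- n_channels(x)
  out <- matrix(0, m, length(idx))
  clamped <- FALSE
  with_ibd_con(x, function(con) {
    for (j in seq_along(idx)) {
      i <- idx[j]
      v <- read_ibd_array(con, x$ibd_path, x$tab$int_offset[i],
                          x$tab$int_len[i], x$tab$int_size[i])
      if (x$mode == "processed") {
        mzv <- read_ibd_array(con, x$ibd_path, x$tab$mz_offset[i],
                              x$tab$mz_len[i], x$tab$mz_size[i])
        bins <- pmin(pmax(floor((mzv - x$mz_min) / x$bin_width) + 1, 1), x$n_bins)
        acc <- rowsum(v, bins)
        w <- numeric(m)
        w[as.integer(rownames(acc))] <- acc
        v <- w
      }
      if (any(v < 0)) { clamped <<- TRUE; v[v < 0] <- 0 }
      out[, j] <<- v
    }
  })
  if (clamped) warning("negative intensities clamped to 0", call. = FALSE)
  out
}

#' @export
print.imzml_reader <- function(x, ...) {
  cat(sprintf("<imzml_reader> %s: %d pixels x %d channels (%s mode)\n",
              basename(x$path), n_pixels(x), n_channels(x), x$mode))
  invisible(x)
}
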