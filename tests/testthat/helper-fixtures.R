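# Shared fixtures, all built in code at test time.

# The full liver-like phantom (4096 px x 4000 channels) takes a few seconds to
# generate; cache it per test process.
.fixture_cache <- new.env(parent = emptyenv())

default_phantom_cached <- function() {
  if (is.null(.fixture_cache$ph)) {
    .fixture_cache$ph <- generate_phantom(default_liver_like_spec())
  }
  .fixture_cache$ph
}

# 3-region 24x24 phantom, cheap enough for per-test generation
small_phantom_spec <- function(seed = 11L, noise = c(3, 0.05),
                               grid = c(24L, 24L), n_channels = 800L) {
  phantom_spec(
    grid = grid,
    regions = list(
      list(mask = list(shape = "stripe", axis = "x", from = 1, to = 6),
           profile = data.frame(mz = c(620, 700, 780),
                                amplitude = c(60, 40, 50), width = 0.8)),
      list(mask = list(shape = "blob", center = c(16, 12), radius = 6),
           profile = data.frame(mz = c(650, 730, 880),
                                amplitude = c(50, 70, 40), width = 0.8)),
      list(mask = list(shape = "rest"), profile = NULL)),
    shared_peaks = data.frame(mz = c(900, 930), amplitude = c(30, 25), width = 0.8),
    noise = noise, mz_range = c(600, 950), n_channels = n_channels, seed = seed)
}

small_phantom_cached <- function() {
  if (is.null(.fixture_cache$small)) {
    .fixture_cache$small <- generate_phantom(small_phantom_spec())
  }
  .fixture_cache$small
}

# dense random dataset on a full grid
random_dataset <- function(width, height, m, seed = 1L) {
  set.seed(seed)
  coords <- cbind(x = rep(seq_len(width), times = height),
                  y = rep(seq_len(height), each = width))
  msi_dataset(coords, seq(100, 200, length.out = m),
              matrix(runif(m * width * height), m))
}

# Independent power-iteration oracle for the top singular value of A
power_iteration_s1 <- function(A, iters = 5000, tol = 1e-14) {
  G <- if (ncol(A) <= nrow(A)) crossprod(A) else tcrossprod(A)
  v <- rep(1 / sqrt(ncol(G)), ncol(G))
  lambda <- 0
  for (i in seq_len(iters)) {
    w <- G %*% v
    lambda_new <- sqrt(sum(w^2))
    v <- as.numeric(w / lambda_new)
    if (abs(lambda_new - lambda) < tol * lambda_new) break
    lambda <- lambda_new
  }
  sqrt(lambda_new)
}

# Independent brute-force (pair-counting) Rand index oracle
rand_index_bruteforce <- function(a, b, adjusted = TRUE) {
  n <- length(a)
  s_ab <- 0; s_a <- 0; s_b <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ca <- a[i] == a[j]; cb <- b[i] == b[j]
      s_ab <- s_ab + (ca && cb)
      s_a <- s_a + ca; s_b <- s_b + cb
    }
  }
  nn <- choose(n, 2)
  if (!adjusted) return((s_ab + (nn - s_a - s_b + s_ab)) / nn)
  expected <- s_a * s_b / nn
  maxi <- (s_a + s_b) / 2
  if (maxi == expected) return(1)
  (s_ab - expected) / (maxi - expected)
}

# Builds a decay_fit with exact parameters by fitting noise-free model data
# (fit_exponential recovers them to ~1e-9 relative; see test-selection.R).
exact_fit <- function(a, b, c) {
  x <- seq(0.5, 12 / max(b, 1e-3), length.out = 60)
  fit_exponential(list(subset_sizes = x, values = a * exp(-b * x) + c))
}

# Hand-rolled processed-mode imzML writer, independent of the package writer:
# spectra is a list of list(mz = ..., intensity = ...) aligned with coords.
write_processed_fixture <- function(path, coords, spectra) {
  ibd <- sub("\\.imzML$", ".ibd", path)
  con <- file(ibd, "wb")
  writeBin(as.raw(1:16), con)
  offsets <- list()
  pos <- 16
  for (i in seq_along(spectra)) {
    mzv <- as.numeric(spectra[[i]]$mz)
    iv <- as.numeric(spectra[[i]]$intensity)
    offsets[[i]] <- c(mz_off = pos, mz_len = length(mzv),
                      int_off = pos + 8 * length(mzv), int_len = length(iv))
    writeBin(mzv, con, size = 8, endian = "little")
    writeBin(iv, con, size = 8, endian = "little")
    pos <- pos + 8 * (length(mzv) + length(iv))
  }
  close(con)

  spec_xml <- vapply(seq_along(spectra), function(i) {
    o <- offsets[[i]]
    sprintf(paste0(
      '<spectrum index="%d" id="spectrum=%d" defaultArrayLength="%d">',
      '<scanList count="1"><scan>',
      '<cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%d"/>',
      '</scan></scanList><binaryDataArrayList count="2">',
      '<binaryDataArray encodedLength="0"><referenceableParamGroupRef ref="mzArray"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%d"/>',
      '<binary/></binaryDataArray>',
      '<binaryDataArray encodedLength="0"><referenceableParamGroupRef ref="intensityArray"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%d"/>',
      '<binary/></binaryDataArray></binaryDataArrayList></spectrum>'),
      i - 1L, i, o["int_len"], coords[i, 1], coords[i, 2],
      o["mz_off"], o["mz_len"], 8 * o["mz_len"],
      o["int_off"], o["int_len"], 8 * o["int_len"])
  }, character(1))

  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">',
    '<fileDescription><fileContent>',
    '<cvParam cvRef="IMS" accession="IMS:1000031" name="processed"/>',
    '</fileContent></fileDescription>',
    '<referenceableParamGroupList count="2">',
    '<referenceableParamGroup id="mzArray">',
    '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array"/>',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
    '</referenceableParamGroup>',
    '<referenceableParamGroup id="intensityArray">',
    '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array"/>',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
    '</referenceableParamGroup>',
    '</referenceableParamGroupList>',
    sprintf('<run id="run1"><spectrumList count="%d">', length(spectra)),
    spec_xml,
    '</spectrumList></run></mzML>'), path)
  invisible(path)
}
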