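#' Gaussian random projection basis
#'
#' Builds the k x m projection matrix Q whose entries are i.i.d. draws from a
#' standard normal distribution N(0, 1). Each row of Q is a random direction
#' in spectral space; projecting a spectrum onto all k rows gives its score
#' vector. No scaling is applied to Q: scores are the raw products Q x, and
#' any Johnson-Lindenstrauss 1/sqrt(k) distance factor is applied externally
#' by consumers that need it.
#'
#' Rows are generated on independent, deterministically derived RNG
#' sub-streams: row r uses seed `derive(seed, r)` under Mersenne-Twister with
#' inversion sampling (recorded in `generator_id`). Consequences: the same
#' `(k, m, seed)` always reproduces the matrix bit-exactly, and a basis with
#' more rows is a bit-exact *extension* of the smaller one — the first k rows
#' of `make_basis(k + j, m, seed)` equal `make_basis(k, m, seed)`. This
#' prefix property is what makes the incremental elbow workflow (project a
#' batch, fit the decay curve, add rows only if the elbow is not reached)
#' possible without re-projecting anything.
#'
#' @param k number of projections (rows), >= 1.
#' @param m number of spectral channels (columns), >= 1.
#' @param seed integer RNG seed recorded in the basis.
#' @return An object of class `projection_basis`: list with `matrix` (k x m),
#'   `k`, `m`, `seed`, `generator_id`.
#' @export
make_basis <- function(k, m, seed) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1) {
    domain_error("`k` must be a positive integer")
  }
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m < 1) {
    domain_error("`m` must be a positive integer")
  }
  k <- as.integer(k); m <- as.integer(m)
  Q <- matrix(0, k, m)
  for (r in seq_len(k)) {
    Q[r, ] <- with_seed(derive_seed(seed, r), stats::rnorm(m))
  }
  structure(list(matrix = Q, k = k, m = m, seed = as.integer(seed),
                 generator_id = "mt19937-inversion-rowchain-v1"),
            class = "projection_basis")
}

#' Extend a projection basis by fresh rows
#'
#' Appends `k_extra` new standard-normal rows. Because every row has its own
#' derived seed (a pure function of the basis seed and the row index), the
#' first k rows of the result are bit-identical to the input and extending is
#' associative: extending twice by 5 equals extending once by 10, and both
#' equal `make_basis(k + 10, m, seed)`.
#'
#' @param basis a [make_basis()] object.
#' @param k_extra number of rows to append, >= 1.
#' @return a `projection_basis` with `k + k_extra` rows.
#' @export
extend_basis <- function(basis, k_extra) {
  stopifnot(inherits(basis, "projection_basis"))
  if (!is.numeric(k_extra) || length(k_extra) != 1L || is.na(k_extra) || k_extra < 1) {
    domain_error("`k_extra` must be a positive integer")
  }
  k_extra <- as.integer(k_extra)
  extra <- matrix(0, k_extra, basis$m)
  for (j in seq_len(k_extra)) {
    extra[j, ] <- with_seed(derive_seed(basis$seed, basis$k + j), stats::rnorm(basis$m))
  }
  structure(list(matrix = rbind(basis$matrix, extra), k = basis$k + k_extra,
                 m = basis$m, seed = basis$seed, generator_id = basis$generator_id),
            class = "projection_basis")
}

#' @export
print.projection_basis <- function(x, ...) {
  cat(sprintf("<projection_basis> %d x %d, seed %d (%s)\n",
              x$k, x$m, x$seed, x$generator_id))
  invisible(x)
}

#' Project a single spectrum
#'
#' Score element i is the dot product of basis row i with the spectrum:
#' the column of A = QX belonging to this pixel.
#'
#' @param basis a [make_basis()] object (k x m).
#' @param x numeric intensity vector of length m.
#' @return numeric score vector of length k.
#' @export
project_spectrum <- function(basis, x) {
  stopifnot(inherits(basis, "projection_basis"))
  if (length(x) != basis$m) {
    domain_error(sprintf("spectrum has %d channels but basis expects %d",
                         length(x), basis$m))
  }
  drop(basis$matrix %*% as.numeric(x))
}

#' Project a whole dataset, streaming
#'
#' Computes the score matrix A = QX by streaming the reader in small pixel
#' chunks: peak memory is one chunk of spectra plus the basis plus the
#' accumulating k x n scores — the m x n data matrix is never materialized.
#' Column j of the result is `project_spectrum` of pixel j, in the reader's
#' canonical (y, x)-ascending order.
#'
#' @param reader an MSI reader.
#' @param basis a [make_basis()] object with `m == n_channels(reader)`.
#' @param chunk_size pixels per streamed chunk (memory/speed trade-off only;
#'   the result is independent of it).
#' @return An object of class `score_matrix`: list with `scores` (k x n,
#'   doubles), `k`, `basis_ref` (seed, generator_id, k, m), `pixel_coords`
#'   (the pixel order used), `method = "rp"`.
#' @export
project_dataset <- function(reader, basis, chunk_size = 64L) {
  stopifnot(inherits(basis, "projection_basis"))
  m <- n_channels(reader)
  if (m != basis$m) {
    domain_error(sprintf("reader has %d channels but basis expects %d", m, basis$m))
  }
  n <- n_pixels(reader)
  scores <- matrix(0, basis$k, n)
  stream_spectra(reader, function(idx, spectra) {
    scores[, idx] <<- basis$matrix %*% spectra
  }, chunk_size = chunk_size)
  new_score_matrix(scores, basis_ref = basis_ref(basis),
                   pixel_coords = pixel_coords(reader), method = "rp")
}

basis_ref <- function(basis) {
  list(seed = basis$seed, generator_id = basis$generator_id,
       k = basis$k, m = basis$m)
}

new_score_matrix <- function(scores, basis_ref, pixel_coords, method) {
  structure(list(scores = scores, k = nrow(scores), basis_ref = basis_ref,
                 pixel_coords = pixel_coords, method = method),
            class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("<score_matrix> %d projections x %d pixels (%s)\n",
              nrow(x$scores), ncol(x$scores), x$method))
  invisible(x)
}

as_score_matrix <- function(x) {
  if (inherits(x, "score_matrix")) return(x)
  if (is.matrix(x)) {
    return(new_score_matrix(x, basis_ref = NULL, pixel_coords = NULL,
                            method = "matrix"))
  }
  domain_error("expected a score_matrix or a numeric matrix")
}

#' Write scores as delimited text with a metadata sidecar
#'
#' Layout: a TSV with one row per pixel (`x`, `y`, `p1`..`pk`) plus a JSON
#' sidecar `<path>.meta.json` recording k, the basis seed and generator, the
#' method (rp/pca) and the pixel order, sufficient to reproduce the matrix.
#'
#' @param scores a `score_matrix`.
#' @param path output TSV path.
#' @return invisibly, the paths written.
#' @export
write_scores <- function(scores, path) {
  scores <- as_score_matrix(scores)
  tab <- as.data.frame(t(scores$scores))
  names(tab) <- paste0("p", seq_len(scores$k))
  if (!is.null(scores$pixel_coords)) {
    tab <- cbind(as.data.frame(scores$pixel_coords), tab)
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(k = scores$k, n = ncol(scores$scores), method = scores$method,
               basis = scores$basis_ref, pixel_order = "ascending (y, x)")
  meta_path <- paste0(path, ".meta.json")
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  invisible(c(path, meta_path))
}
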