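# Reproducibility of the segmentation across repeated random bases and
# projection counts, a PCA baseline computed with the same streaming
# constraints, and a maximum-window peak-picking diagnostic for the mean
# spectrum. "Correlation between maps" is made label-permutation-invariant by
# correlating co-assignment indicators over pixel pairs; the adjusted Rand
# index is reported alongside.

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected, label-permutation-invariant partition agreement.
#'
#' @param a,b integer label vectors of equal length.
#' @return a scalar, 1 for identical partitions, ~0 for independent ones.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) domain_error("labelings must have equal length")
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  nn <- choose(length(a), 2)
  expected <- ai * bj / nn
  maxi <- (ai + bj) / 2
  if (maxi == expected) return(1)     # both partitions trivial (single class)
  (nij - expected) / (maxi - expected)
}

#' Agreement between two segmentation maps
#'
#' Pearson correlation between the co-assignment indicator vectors of the two
#' maps over pixel pairs: pair (i, j) contributes (1 if i,j share a cluster in
#' map A, else 0) against the same indicator for map B. Invariant to label
#' permutations. All pairs are used when n <= 2000; otherwise `n_pairs`
#' seeded random pairs keep the cost O(1) in n. If either indicator is
#' constant on the sampled pairs the correlation is undefined; the function
#' then returns 1 if the indicators are identical and 0 otherwise.
#'
#' @param map_a,map_b [kmeans_segment()] results (or integer label vectors)
#'   over the same pixels in the same order.
#' @param n_pairs pairs to subsample for large n (default 1e6).
#' @param seed seed for the pair subsample.
#' @return agreement in \[-1, 1\], with attributes `ari` (adjusted Rand index)
#'   and `n_pairs` (pairs actually used).
#' @export
segmentation_agreement <- function(map_a, map_b, n_pairs = 1e6, seed = 1L) {
  la <- if (inherits(map_a, "segmentation_map")) map_a$labels else as.integer(map_a)
  lb <- if (inherits(map_b, "segmentation_map")) map_b$labels else as.integer(map_b)
  n <- length(la)
  if (length(lb) != n) {
    domain_error(sprintf("maps cover different pixel counts (%d vs %d)",
                         n, length(lb)))
  }
  if (n < 2L) domain_error("need at least two pixels to compare maps")

  if (n <= 2000L) {
    pr <- utils::combn(n, 2L)
    i <- pr[1, ]; j <- pr[2, ]
  } else {
    pairs <- with_seed(derive_seed(seed, 17L), {
      i <- sample.int(n, n_pairs, replace = TRUE)
      j <- sample.int(n - 1L, n_pairs, replace = TRUE)
      j <- j + (j >= i)                 # uniform over ordered pairs, i != j
      cbind(i, j)
    })
    i <- pairs[, 1]; j <- pairs[, 2]
  }
  ca <- as.numeric(la[i] == la[j])
  cb <- as.numeric(lb[i] == lb[j])
  agreement <- if (stats::sd(ca) == 0 || stats::sd(cb) == 0) {
    if (all(ca == cb)) 1 else 0
  } else {
    stats::cor(ca, cb)
  }
  structure(agreement, ari = adjusted_rand_index(la, lb), n_pairs = length(i))
}

#' Segmentation stability across repeated random bases
#'
#' For each projection count, draws `repeats` independent Gaussian bases
#' (seeds derived from `seed`, the count, and the repeat index), projects the
#' dataset, segments each score matrix with k-means, and computes all
#' pairwise [segmentation_agreement()] values. Low counts give unstable,
#' basis-dependent maps; past roughly a hundred projections the maps
#' stabilize.
#'
#' @param reader an MSI reader.
#' @param projection_counts integer vector of projection counts to test.
#' @param repeats independent bases per count (>= 2).
#' @param n_clusters clusters for the segmentation.
#' @param seed master seed; everything is derived from it.
#' @param n_restarts k-means restarts per segmentation.
#' @return An object of class `stability_table`: data frame with columns
#'   `n_projections`, `i`, `j`, `agreement`, `ari`, plus attribute `summary`
#'   (data frame of per-count mean and SD of agreement).
#' @export
stability_experiment <- function(reader, projection_counts, repeats,
                                 n_clusters, seed = 1L, n_restarts = 10L) {
  if (!is.numeric(repeats) || repeats < 2L) {
    domain_error("`repeats` must be at least 2")
  }
  repeats <- as.integer(repeats)
  m <- n_channels(reader)
  rows <- list()
  for (ci in seq_along(projection_counts)) {
    k <- as.integer(projection_counts[ci])
    maps <- vector("list", repeats)
    for (r in seq_len(repeats)) {
      bseed <- derive_seed(seed, ci * 10000L + r)
      basis <- make_basis(k, m, bseed)
      sc <- project_dataset(reader, basis)
      maps[[r]] <- kmeans_segment(sc, n_clusters,
                                  seed = derive_seed(seed, ci * 10000L + 5000L + r),
                                  n_restarts = n_restarts)
    }
    for (i in seq_len(repeats - 1L)) {
      for (j in (i + 1L):repeats) {
        ag <- segmentation_agreement(maps[[i]], maps[[j]],
                                     seed = derive_seed(seed, 999L))
        rows[[length(rows) + 1L]] <- data.frame(
          n_projections = k, i = i, j = j,
          agreement = as.numeric(ag), ari = attr(ag, "ari"))
      }
    }
  }
  tab <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(tab, tab$n_projections), function(d) {
    data.frame(n_projections = d$n_projections[1],
               mean_agreement = mean(d$agreement),
               sd_agreement = stats::sd(d$agreement),
               mean_ari = mean(d$ari))
  }))
  rownames(summ) <- NULL
  structure(tab, summary = summ[order(summ$n_projections), ],
            class = c("stability_table", "data.frame"))
}

#' Streaming PCA scores (baseline for random projection)
#'
#' Principal-component scores of the pixels on the top components of the
#' mean-centered (unscaled) data, computed under the same streaming contract
#' as [project_dataset()]: pass 1 accumulates the mean spectrum, pass 2
#' accumulates the m x m scatter matrix chunk-wise, pass 3 streams the
#' centered spectra through the eigenvectors. The top eigenvectors are
#' extracted by a seeded randomized subspace iteration (Gaussian sketch,
#' oversampling `oversample`, `power_iter` power iterations), which is exact
#' whenever `n_components + oversample >= m` and otherwise accurate for the
#' leading, well-separated components that drive segmentation.
#'
#' @param reader an MSI reader.
#' @param n_components number of components r, <= min(m, n).
#' @param chunk_size streaming chunk size.
#' @param seed seed for the sketch.
#' @param oversample extra sketch columns (default 10).
#' @param power_iter power iterations on the scatter (default 3).
#' @return a `score_matrix` (r x n) with `method = "pca"`; attribute
#'   `sdev` holds the component standard deviations and `rotation` the m x r
#'   eigenvector matrix.
#' @export
pca_scores <- function(reader, n_components, chunk_size = 64L, seed = 1L,
                       oversample = 10L, power_iter = 3L) {
  n <- n_pixels(reader)
  m <- n_channels(reader)
  r <- as.integer(n_components)
  if (r < 1L || r > min(m, n)) {
    domain_error(sprintf("n_components must lie in 1..min(m, n) = %d", min(m, n)))
  }

  mu <- numeric(m)
  stream_spectra(reader, function(idx, spectra) {
    mu <<- mu + rowSums(spectra)
  }, chunk_size = chunk_size)
  mu <- mu / n

  S <- matrix(0, m, m)
  stream_spectra(reader, function(idx, spectra) {
    S <<- S + tcrossprod(spectra - mu)
  }, chunk_size = chunk_size)

  l <- min(m, r + as.integer(oversample))
  sketch <- with_seed(derive_seed(seed, 29L), matrix(stats::rnorm(m * l), m, l))
  Y <- S %*% sketch
  for (q in seq_len(power_iter)) {
    Y <- qr.Q(qr(Y))
    Y <- S %*% Y
  }
  Qb <- qr.Q(qr(Y))
  B <- crossprod(Qb, S %*% Qb)
  B <- (B + t(B)) / 2
  eb <- eigen(B, symmetric = TRUE)
  V <- Qb %*% eb$vectors[, seq_len(r), drop = FALSE]
  eigvals <- pmax(eb$values[seq_len(r)], 0)

  scores <- matrix(0, r, n)
  stream_spectra(reader, function(idx, spectra) {
    scores[, idx] <<- crossprod(V, spectra - mu)
  }, chunk_size = chunk_size)

  out <- new_score_matrix(scores,
                          basis_ref = list(seed = as.integer(seed),
                                           generator_id = "pca-randomized-subspace-v1",
                                           k = r, m = m),
                          pixel_coords = pixel_coords(reader), method = "pca")
  attr(out, "sdev") <- sqrt(eigvals / max(n - 1L, 1L))
  attr(out, "rotation") <- V
  out
}

#' Maximum-window peak detection
#'
#' Channel i is a peak apex iff its intensity is the strict maximum over the
#' `window` channels centered on i (truncated at the spectrum edges) and is at
#' least `min_intensity`. The reported centroid is the intensity-weighted
#' mean m/z over the window, giving sub-channel accuracy.
#'
#' @param spectrum numeric intensity vector (length m).
#' @param mz numeric m/z axis (length m, strictly increasing).
#' @param window odd integer >= 1, full window width in channels.
#' @param min_intensity apex intensity threshold (default 0).
#' @return An object of class `peak_list`: data frame with columns
#'   `centroid_mz`, `apex_intensity`, `apex_channel`; attribute `half_width`
#'   is the window half-width in channels.
#' @export
peak_pick_max_window <- function(spectrum, mz, window, min_intensity = 0) {
  m <- length(spectrum)
  if (length(mz) != m) domain_error("spectrum and mz axis differ in length")
  if (!is.numeric(window) || length(window) != 1L || is.na(window) ||
      window < 1 || window %% 2 == 0) {
    domain_error("`window` must be a positive odd integer (channels)")
  }
  hw <- (as.integer(window) - 1L) %/% 2L
  apex <- logical(m)
  for (i in seq_len(m)) {
    if (spectrum[i] < min_intensity) next
    lo <- max(1L, i - hw); hi <- min(m, i + hw)
    nb <- spectrum[lo:hi][-(i - lo + 1L)]
    apex[i] <- length(nb) == 0L || spectrum[i] > max(nb)
  }
  idx <- which(apex)
  centroids <- vapply(idx, function(i) {
    lo <- max(1L, i - hw); hi <- min(m, i + hw)
    wts <- spectrum[lo:hi]
    if (sum(wts) <= 0) mz[i] else sum(wts * mz[lo:hi]) / sum(wts)
  }, numeric(1))
  ord <- order(centroids)
  structure(data.frame(centroid_mz = centroids[ord],
                       apex_intensity = spectrum[idx][ord],
                       apex_channel = idx[ord]),
            half_width = hw, class = c("peak_list", "data.frame"))
}

#' Mean spectrum of a dataset (streaming)
#' @param reader an MSI reader.
#' @param chunk_size streaming chunk size.
#' @return numeric vector of length m.
#' @export
mean_spectrum <- function(reader, chunk_size = 64L) {
  m <- n_channels(reader)
  mu <- numeric(m)
  stream_spectra(reader, function(idx, spectra) mu <<- mu + rowSums(spectra),
                 chunk_size = chunk_size)
  mu / n_pixels(reader)
}
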