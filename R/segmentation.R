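# k-means segmentation of pixels in projection-score space. Lloyd's
# algorithm is implemented directly so that the policies the results depend
# on are explicit and testable: seeded D^2-weighted choice of data columns as
# initial centroids (k-means++ seeding; plain uniform choice reliably misses
# small tissue classes), best-of-n restarts by inertia, empty clusters
# re-seeded to the point currently farthest from its centroid, convergence on
# unchanged labels or relative inertia change < tol.

#' k-means segmentation of projected pixels
#'
#' Clusters the n score columns in k-dimensional projection space with
#' Lloyd's algorithm under the Euclidean distance, keeping the best of
#' `n_restarts` seeded runs by total within-cluster squared distance
#' (inertia). Restarts are initialized with D^2-weighted sampling of data
#' columns (k-means++ seeding), which reliably places a starting centroid in
#' small, well-separated tissue classes. Deterministic given `seed`.
#'
#' @param scores a `score_matrix` (or k x n numeric matrix).
#' @param n_clusters number of clusters C, 1 <= C <= n.
#' @param seed integer seed controlling all restarts.
#' @param n_restarts independent initializations (default 10).
#' @param max_iter Lloyd iteration cap per restart (default 300).
#' @param tol relative inertia change declaring convergence (default 1e-6).
#' @return An object of class `segmentation_map`: `labels` (integer 1..C per
#'   pixel), `n_clusters`, `centroids` (C x k), `inertia`, `inertia_trace`
#'   (per accepted iteration of the winning restart), `n_reseeds`, `seed`,
#'   `grid_shape` (width, height), `pixel_coords`.
#' @export
kmeans_segment <- function(scores, n_clusters, seed = 1L, n_restarts = 10L,
                           max_iter = 300L, tol = 1e-6) {
  sm <- as_score_matrix(scores)
  P <- t(sm$scores)                       # n points x k dims
  n <- nrow(P)
  if (!is.numeric(n_clusters) || length(n_clusters) != 1L || is.na(n_clusters) ||
      n_clusters < 1) {
    domain_error("`n_clusters` must be a positive integer")
  }
  n_clusters <- as.integer(n_clusters)
  if (n_clusters > n) {
    domain_error(sprintf("n_clusters (%d) exceeds the number of pixels (%d)",
                         n_clusters, n))
  }

  pp <- rowSums(P^2)
  run_lloyd <- function(init_rows) {
    cen <- P[init_rows, , drop = FALSE]
    labels_old <- integer(n)
    inertia <- Inf
    trace <- numeric(0)
    n_reseeds <- 0L
    for (it in seq_len(max_iter)) {
      d2 <- pp - 2 * P %*% t(cen) +
        matrix(rowSums(cen^2), n, n_clusters, byrow = TRUE)
      labels <- max.col(-d2, ties.method = "first")
      # empty clusters: re-seed to the point farthest from its centroid
      empty <- setdiff(seq_len(n_clusters), unique(labels))
      for (e in empty) {
        far <- which.max(d2[cbind(seq_len(n), labels)])
        cen[e, ] <- P[far, ]
        d2[, e] <- pp - 2 * P %*% cen[e, ] + sum(cen[e, ]^2)
        labels <- max.col(-d2, ties.method = "first")
        n_reseeds <- n_reseeds + 1L
      }
      inertia_new <- sum(pmax(d2[cbind(seq_len(n), labels)], 0))
      trace <- c(trace, inertia_new)
      done <- identical(labels, labels_old) ||
        (is.finite(inertia) && abs(inertia - inertia_new) <= tol * inertia)
      labels_old <- labels
      inertia <- inertia_new
      cnt <- tabulate(labels, n_clusters)
      cen <- rowsum(P, labels, reorder = TRUE) / cnt
      if (done) break
    }
    list(labels = labels_old, centroids = cen, inertia = inertia,
         trace = trace, n_reseeds = n_reseeds)
  }

  # k-means++ seeding: first centroid uniform, then D^2-weighted
  init_pp <- function() {
    rows <- integer(n_clusters)
    rows[1] <- sample.int(n, 1L)
    if (n_clusters > 1L) {
      d2min <- pp - 2 * drop(P %*% P[rows[1], ]) + pp[rows[1]]
      for (cl in 2L:n_clusters) {
        w <- pmax(d2min, 0)
        rows[cl] <- if (sum(w) > 0) sample.int(n, 1L, prob = w)
                    else sample.int(n, 1L)
        d2min <- pmin(d2min, pp - 2 * drop(P %*% P[rows[cl], ]) + pp[rows[cl]])
      }
    }
    rows
  }

  best <- NULL
  for (r in seq_len(n_restarts)) {
    init_rows <- with_seed(derive_seed(seed, r), init_pp())
    res <- run_lloyd(init_rows)
    if (is.null(best) || res$inertia < best$inertia) best <- res
  }

  coords <- sm$pixel_coords
  grid_shape <- if (!is.null(coords)) {
    c(width = max(coords[, "x"]), height = max(coords[, "y"]))
  } else NULL
  structure(list(labels = as.integer(best$labels), n_clusters = n_clusters,
                 centroids = unname(best$centroids), inertia = best$inertia,
                 inertia_trace = best$trace, n_reseeds = best$n_reseeds,
                 seed = as.integer(seed), grid_shape = grid_shape,
                 pixel_coords = coords),
            class = "segmentation_map")
}

#' @export
print.segmentation_map <- function(x, ...) {
  cat(sprintf("<segmentation_map> %d pixels in %d clusters, inertia %.6g\n",
              length(x$labels), x$n_clusters, x$inertia))
  invisible(x)
}

#' Render a segmentation as a label image
#'
#' Places each pixel's label on its (x, y) grid position. Grid cells not
#' covered by the acquisition are NA (rendered as background). The attached
#' palette is deterministic, one color per label.
#'
#' @param map a [kmeans_segment()] result with pixel coordinates.
#' @return integer matrix (height x width; row y, column x) of labels with an
#'   attribute `palette`, classed `msi_label_image`.
#' @export
render_map <- function(map) {
  stopifnot(inherits(map, "segmentation_map"))
  coords <- map$pixel_coords
  if (is.null(coords)) domain_error("segmentation map carries no pixel coordinates")
  w <- map$grid_shape[["width"]]; h <- map$grid_shape[["height"]]
  if (any(coords[, "x"] < 1L) || any(coords[, "y"] < 1L) ||
      any(coords[, "x"] > w) || any(coords[, "y"] > h)) {
    domain_error("pixel coordinate outside the rendering grid")
  }
  img <- matrix(NA_integer_, nrow = h, ncol = w)
  img[cbind(coords[, "y"], coords[, "x"])] <- map$labels
  palette <- grDevices::hcl.colors(max(map$n_clusters, 2L), "Dark 3")[seq_len(map$n_clusters)]
  structure(img, palette = palette, class = c("msi_label_image", "matrix", "array"))
}

#' Euclidean distances between cluster centroids
#'
#' Computed in projection-score space; since projections approximately
#' preserve Euclidean distance, this measures spectral similarity between
#' clusters (small = similar tissue profiles).
#'
#' @param map a [kmeans_segment()] result.
#' @return symmetric C x C matrix with zero diagonal.
#' @export
centroid_distance_matrix <- function(map) {
  stopifnot(inherits(map, "segmentation_map"))
  as.matrix(stats::dist(map$centroids, method = "euclidean"))
}

#' Per-cluster mean spectra from the original data
#'
#' Molecular profile of each cluster: the arithmetic mean of its member
#' pixels' raw spectra, accumulated in a single streaming pass over the
#' reader (memory bounded by C spectra), not from the projected scores.
#'
#' @param reader an MSI reader whose pixel order matches the segmentation.
#' @param map a [kmeans_segment()] result with `length(labels) == n_pixels(reader)`.
#' @param chunk_size streaming chunk size.
#' @return An object of class `cluster_profiles`: `mean_spectrum` (m x C
#'   matrix), `member_count` (length C), `mz`.
#' @export
cluster_mean_spectra <- function(reader, map, chunk_size = 64L) {
  stopifnot(inherits(map, "segmentation_map"))
  n <- n_pixels(reader)
  if (length(map$labels) != n) {
    domain_error(sprintf("segmentation has %d labels but reader has %d pixels",
                         length(map$labels), n))
  }
  m <- n_channels(reader)
  C <- map$n_clusters
  sums <- matrix(0, m, C)
  counts <- integer(C)
  stream_spectra(reader, function(idx, spectra) {
    lab <- map$labels[idx]
    agg <- rowsum(t(spectra), lab)       # clusters-in-chunk x m
    cl <- as.integer(rownames(agg))
    sums[, cl] <<- sums[, cl] + t(agg)
    counts[cl] <<- counts[cl] + tabulate(lab, C)[cl]
  }, chunk_size = chunk_size)
  if (any(counts == 0L)) domain_error("segmentation contains an empty cluster label")
  structure(list(mean_spectrum = sweep(sums, 2, counts, "/"),
                 member_count = counts, mz = mz_axis(reader)),
            class = "cluster_profiles")
}
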