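make_two_clouds <- function(n_per = 30, k = 3, sep = 100, seed = 4) {
  set.seed(seed)
  P <- rbind(matrix(rnorm(n_per * k), ncol = k),
             matrix(rnorm(n_per * k) + sep, ncol = k))
  t(P)   # scores layout: k x n
}

test_that("one cluster collapses to the global mean", {
  A <- make_two_clouds()
  mp <- kmeans_segment(A, 1, seed = 1)
  expect_true(all(mp$labels == 1L))
  expect_equal(drop(mp$centroids), rowMeans(A))
  expect_equal(mp$inertia, sum((A - rowMeans(A))^2), tolerance = 1e-10)
})

test_that("well-separated clouds are recovered exactly and deterministically", {
  A <- make_two_clouds(sep = 100)
  mp <- kmeans_segment(A, 2, seed = 7)
  truth <- rep(1:2, each = 30)
  expect_equal(adjusted_rand_index(mp$labels, truth), 1)
  expect_identical(kmeans_segment(A, 2, seed = 7)$labels, mp$labels)
  expect_error(kmeans_segment(A, 61, seed = 1), class = "msi_domain_error")
  expect_error(kmeans_segment(A, 0, seed = 1), class = "msi_domain_error")
})

test_that("inertia is non-increasing across Lloyd iterations", {
  d <- small_phantom_cached()$dataset
  sc <- project_dataset(d, make_basis(30, n_channels(d), seed = 2))
  mp <- kmeans_segment(sc, 4, seed = 3, n_restarts = 3)
  expect_equal(mp$n_reseeds, 0L)
  expect_true(all(diff(mp$inertia_trace) <= 1e-9 * mp$inertia_trace[-length(mp$inertia_trace)]))
  # centroids are the member means at convergence
  P <- t(sc$scores)
  for (cl in seq_len(mp$n_clusters)) {
    expect_equal(mp$centroids[cl, ], colMeans(P[mp$labels == cl, , drop = FALSE]),
                 tolerance = 1e-10)
  }
})

test_that("segmentation is invariant to permuting the projection rows", {
  d <- small_phantom_cached()$dataset
  sc <- project_dataset(d, make_basis(25, n_channels(d), seed = 9))
  set.seed(1)
  perm <- sample(25)
  sc_perm <- sc
  sc_perm$scores <- sc$scores[perm, , drop = FALSE]
  expect_identical(kmeans_segment(sc, 4, seed = 5)$labels,
                   kmeans_segment(sc_perm, 4, seed = 5)$labels)
})

test_that("render_map places labels on the grid with a stable palette", {
  coords <- cbind(x = c(1L, 2L, 1L, 2L), y = c(1L, 1L, 2L, 2L))
  mp <- structure(list(labels = c(1L, 1L, 2L, 2L), n_clusters = 2L,
                       centroids = matrix(0, 2, 3), inertia = 0,
                       seed = 1L, grid_shape = c(width = 2L, height = 2L),
                       pixel_coords = coords),
                  class = "segmentation_map")
  img <- render_map(mp)
  expect_equal(unclass(img)[1, ], c(1L, 1L), ignore_attr = TRUE)
  expect_equal(unclass(img)[2, ], c(2L, 2L), ignore_attr = TRUE)
  expect_length(attr(img, "palette"), 2)
  # relabeling permutes colors, not shapes
  mp2 <- mp; mp2$labels <- 3L - mp$labels
  img2 <- render_map(mp2)
  expect_equal(unclass(img2), 3L - unclass(img), ignore_attr = TRUE)
  # coordinate outside grid
  mp3 <- mp; mp3$grid_shape <- c(width = 1L, height = 2L)
  expect_error(render_map(mp3), class = "msi_domain_error")
})

test_that("phantom segmentation map matches ground-truth region shapes", {
  ph <- small_phantom_cached()
  d <- ph$dataset
  sc <- project_dataset(d, make_basis(60, n_channels(d), seed = 4))
  mp <- kmeans_segment(sc, 3, seed = 6)
  expect_gte(adjusted_rand_index(mp$labels, ph$labels), 0.9)
  img <- render_map(mp)
  # correctly clustered pixels form the same boundaries as the truth image:
  # the rendered map must be a pure relabeling on agreeing pixels
  tab <- table(ph$labels, mp$labels)
  best <- apply(tab, 1, which.max)
  agree <- mp$labels == best[ph$labels]
  coords <- pixel_coords(d)
  expect_equal(unclass(img)[cbind(coords[agree, "y"], coords[agree, "x"])],
               unname(best[ph$labels[agree]]), ignore_attr = TRUE)
})

test_that("centroid distances match a brute-force oracle and metric axioms", {
  d <- small_phantom_cached()$dataset
  sc <- project_dataset(d, make_basis(12, n_channels(d), seed = 8))
  mp <- kmeans_segment(sc, 3, seed = 2)
  D <- centroid_distance_matrix(mp)
  C <- mp$n_clusters
  for (i in seq_len(C)) {
    for (j in seq_len(C)) {
      expect_equal(D[i, j], sqrt(sum((mp$centroids[i, ] - mp$centroids[j, ])^2)),
                   tolerance = 1e-12)
    }
  }
  expect_equal(D, t(D))
  expect_equal(diag(D), rep(0, C), ignore_attr = TRUE)
  for (i in 1:C) for (j in 1:C) for (l in 1:C) {
    expect_lte(D[i, j], D[i, l] + D[l, j] + 1e-12)
  }
  # identical centroids -> all-zero matrix
  mp0 <- mp; mp0$centroids <- mp$centroids[c(1, 1, 1), ]
  expect_true(all(centroid_distance_matrix(mp0) == 0))
})

test_that("cluster mean spectra stream equals a batch group-by mean", {
  ph <- small_phantom_cached()
  d <- ph$dataset
  sc <- project_dataset(d, make_basis(20, n_channels(d), seed = 1))
  mp <- kmeans_segment(sc, 3, seed = 4)
  pr <- cluster_mean_spectra(d, mp, chunk_size = 17)
  X <- read_spectra(d, seq_len(n_pixels(d)))
  for (cl in 1:3) {
    expect_equal(pr$mean_spectrum[, cl], rowMeans(X[, mp$labels == cl, drop = FALSE]),
                 tolerance = 1e-12)
  }
  expect_equal(sum(pr$member_count), n_pixels(d))
  # single-pixel cluster profile equals that pixel's spectrum
  mp1 <- mp
  mp1$labels <- rep(1L, n_pixels(d)); mp1$labels[5] <- 2L; mp1$n_clusters <- 2L
  pr1 <- cluster_mean_spectra(d, mp1)
  expect_equal(pr1$mean_spectrum[, 2], X[, 5])
  # all pixels in one cluster -> dataset mean spectrum
  mp_all <- mp; mp_all$labels <- rep(1L, n_pixels(d)); mp_all$n_clusters <- 1L
  expect_equal(cluster_mean_spectra(d, mp_all)$mean_spectrum[, 1], rowMeans(X))
  # label/pixel mismatch
  mp_bad <- mp; mp_bad$labels <- mp$labels[-1]
  expect_error(cluster_mean_spectra(d, mp_bad), class = "msi_domain_error")
})

test_that("the most similar ground-truth regions have the closest centroids", {
  ph <- default_phantom_cached()
  d <- ph$dataset
  tdist <- as.matrix(dist(t(ph$templates)))
  mp <- kmeans_segment(project_dataset(d, make_basis(150, n_channels(d), seed = 1)),
                       4, seed = 7)
  expect_gte(adjusted_rand_index(mp$labels, ph$labels), 0.9)
  # map clusters onto regions by majority vote, reorder the centroid matrix
  maj <- vapply(1:4, function(cl) {
    as.integer(names(which.max(table(ph$labels[mp$labels == cl]))))
  }, integer(1))
  expect_setequal(maj, 1:4)
  cdist <- centroid_distance_matrix(mp)[order(maj), order(maj)]
  amin <- function(M) { diag(M) <- Inf; which(M == min(M), arr.ind = TRUE)[1, ] }
  expect_equal(sort(amin(cdist)), sort(amin(tdist)))
})
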