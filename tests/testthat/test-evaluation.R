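test_that("adjusted Rand index matches a brute-force pair-counting oracle", {
  set.seed(3)
  for (rep in 1:5) {
    a <- sample(1:3, 25, replace = TRUE)
    b <- sample(1:4, 25, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), rand_index_bruteforce(a, b),
                 tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:10, 1:10), 1)
  expect_error(adjusted_rand_index(1:5, 1:6), class = "msi_domain_error")
})

test_that("agreement is 1 for identical and label-permuted maps", {
  set.seed(8)
  lab <- sample(1:4, 500, replace = TRUE)
  ag <- segmentation_agreement(lab, lab)
  expect_equal(as.numeric(ag), 1)
  expect_equal(attr(ag, "ari"), 1)
  perm <- c(3L, 1L, 4L, 2L)
  expect_equal(as.numeric(segmentation_agreement(lab, perm[lab])), 1)
  expect_error(segmentation_agreement(lab, lab[-1]), class = "msi_domain_error")
})

test_that("independent random maps score near zero agreement", {
  for (s in 1:20) {
    set.seed(1000 + s)
    a <- sample(1:4, 1000, replace = TRUE)
    b <- sample(1:4, 1000, replace = TRUE)
    expect_lt(abs(as.numeric(segmentation_agreement(a, b))), 0.05)
  }
})

test_that("pair subsampling is seeded and stays in bounds", {
  set.seed(2)
  a <- sample(1:3, 5000, replace = TRUE)
  b <- ifelse(a == 1, 1L, sample(2:3, 5000, replace = TRUE))
  ag1 <- segmentation_agreement(a, b, n_pairs = 5e4, seed = 1)
  ag2 <- segmentation_agreement(a, b, n_pairs = 5e4, seed = 1)
  expect_identical(as.numeric(ag1), as.numeric(ag2))
  expect_equal(attr(ag1, "n_pairs"), 5e4)
  expect_true(as.numeric(ag1) >= -1 && as.numeric(ag1) <= 1)
})

test_that("stability experiment counts pairs and reproduces bit-exactly", {
  d <- generate_phantom(small_phantom_spec(grid = c(10L, 10L), n_channels = 300L))$dataset
  st <- stability_experiment(d, c(3L, 8L), repeats = 2, n_clusters = 3, seed = 5)
  expect_equal(nrow(st), 2L)                      # one pair per count
  expect_equal(st$n_projections, c(3L, 8L))
  st2 <- stability_experiment(d, c(3L, 8L), repeats = 2, n_clusters = 3, seed = 5)
  expect_identical(as.data.frame(st), as.data.frame(st2))
  summ <- attr(st, "summary")
  expect_equal(summ$n_projections, c(3L, 8L))
  expect_error(stability_experiment(d, 5L, repeats = 1, n_clusters = 3),
               class = "msi_domain_error")
})

test_that("pca_scores matches a full-SVD oracle on a small fixture", {
  set.seed(12)
  # 30 channels x 20 pixels with strong planted structure
  basis_dirs <- qr.Q(qr(matrix(rnorm(30 * 3), 30)))
  X <- basis_dirs %*% diag(c(50, 20, 8)) %*% matrix(rnorm(3 * 20), 3) +
    matrix(rnorm(30 * 20, sd = 0.1), 30)
  d <- msi_dataset(cbind(x = 1:20, y = rep(1L, 20)), 1:30, abs(X))
  Xc <- read_spectra(d, 1:20) - rowMeans(read_spectra(d, 1:20))
  sv <- svd(Xc)

  r <- 3
  pc <- pca_scores(d, r, chunk_size = 7)
  # same subspace: scores agree up to per-component sign
  oracle_scores <- diag(sv$d[1:r]) %*% t(sv$v[, 1:r])
  for (i in 1:r) {
    expect_equal(abs(cor(pc$scores[i, ], oracle_scores[i, ])), 1, tolerance = 1e-6)
    expect_equal(sd(pc$scores[i, ]), sd(oracle_scores[i, ]), tolerance = 1e-6)
  }
  # reconstruction error from top-r components equals tail singular energy
  V <- attr(pc, "rotation")
  resid <- Xc - V %*% crossprod(V, Xc)
  expect_equal(sum(resid^2), sum(sv$d[-(1:r)]^2), tolerance = 1e-6)

  # lossless at full rank
  pc_full <- pca_scores(d, 20)
  Vf <- attr(pc_full, "rotation")
  expect_lt(sum((Xc - Vf %*% crossprod(Vf, Xc))^2), 1e-8 * sum(Xc^2))
  expect_error(pca_scores(d, 21), class = "msi_domain_error")
})

test_that("pca provenance is flagged and deterministic", {
  d <- small_phantom_cached()$dataset
  p1 <- pca_scores(d, 5, seed = 3)
  p2 <- pca_scores(d, 5, seed = 3)
  expect_equal(p1$method, "pca")
  expect_identical(p1$scores, p2$scores)
})

test_that("maximum-window peak picking finds isolated Gaussians", {
  mz <- seq(600, 700, length.out = 1000)
  g <- function(c, a, w) a * exp(-(mz - c)^2 / (2 * w^2))
  # apex deliberately off-grid (an on-grid-midpoint peak would tie two
  # channels exactly and strict-max correctly rejects exact ties)
  one <- g(650.03, 100, 0.5)
  pk <- peak_pick_max_window(one, mz, window = 7, min_intensity = 5)
  expect_equal(nrow(pk), 1)
  expect_lt(abs(pk$centroid_mz - 650.03), diff(mz)[1])
  two <- g(630, 80, 0.4) + g(670, 120, 0.4)
  pk2 <- peak_pick_max_window(two, mz, window = 7, min_intensity = 5)
  expect_equal(nrow(pk2), 2)
  expect_true(all(diff(pk2$centroid_mz) > 0))
  # flat spectrum below threshold -> nothing
  expect_equal(nrow(peak_pick_max_window(rep(1, 1000), mz, 7, min_intensity = 5)), 0)
  # a two-channel plateau is not a strict maximum
  plat <- rep(0, 100); plat[50:51] <- 10
  expect_equal(nrow(peak_pick_max_window(plat, seq_len(100), 5, 1)), 0)
  expect_error(peak_pick_max_window(one, mz, window = 6), class = "msi_domain_error")
  expect_error(peak_pick_max_window(one, mz[-1], window = 7), class = "msi_domain_error")
})

test_that("mean_spectrum streams to the exact dataset mean", {
  d <- random_dataset(5, 4, 120, seed = 3)
  X <- read_spectra(d, 1:20)
  expect_equal(mean_spectrum(d, chunk_size = 3), rowMeans(X), tolerance = 1e-12)
})
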