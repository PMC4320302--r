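test_that("normalized_first_sv matches closed forms and a power-iteration oracle", {
  # rank-1: single row -> Euclidean norm / 1
  v <- c(3, 4, 12)
  expect_equal(normalized_first_sv(matrix(v, 1)), 13)
  # diagonal matrix: singular values are the diagonal
  expect_equal(normalized_first_sv(diag(c(3, 2, 1))), 1)
  expect_equal(normalized_first_sv(diag(c(3, 2, 1)), norm = "s1sq_over_k"), 3)
  set.seed(5)
  A <- matrix(rnorm(20 * 50), 20)
  expect_equal(normalized_first_sv(A), power_iteration_s1(A) / 20,
               tolerance = 1e-8)
  expect_error(normalized_first_sv(matrix(numeric(0), 0, 0)),
               class = "msi_domain_error")
})

test_that("decay_curve evaluates prefix subsets consistently", {
  d <- small_phantom_cached()$dataset
  m <- n_channels(d)
  sc150 <- project_dataset(d, make_basis(150, m, seed = 3))
  sc10 <- project_dataset(d, make_basis(10, m, seed = 3))
  # single size = full matrix
  cv <- decay_curve(sc10, 10L)
  expect_equal(cv$values, normalized_first_sv(sc10))
  # nested-prefix consistency across basis extension
  cv_a <- decay_curve(sc10, c(5L, 10L))
  cv_b <- decay_curve(sc150, c(5L, 10L))
  expect_equal(cv_a$values, cv_b$values)
  expect_error(decay_curve(sc10, c(5L, 11L)), class = "msi_domain_error")
  expect_error(decay_curve(sc10, c(5L, 5L)), class = "msi_domain_error")
})

test_that("phantom decay curves are decreasing beyond small-k noise", {
  d <- small_phantom_cached()$dataset
  sizes <- c(2L, 4L, 8L, 16L, 32L, 64L)
  for (s in 1:10) {
    sc <- project_dataset(d, make_basis(64, n_channels(d), seed = s))
    cv <- decay_curve(sc, sizes)
    expect_lt(cor(sizes, cv$values, method = "spearman"), 0)
  }
})

test_that("random subset policy averages seeded draws deterministically", {
  d <- small_phantom_cached()$dataset
  sc <- project_dataset(d, make_basis(40, n_channels(d), seed = 3))
  cv1 <- decay_curve(sc, c(5L, 10L, 20L), policy = "random", seed = 2)
  cv2 <- decay_curve(sc, c(5L, 10L, 20L), policy = "random", seed = 2)
  expect_identical(cv1$values, cv2$values)
})

test_that("fit_exponential recovers noise-free parameters to 1e-6 relative", {
  x <- seq(5, 200, by = 5)
  fit <- fit_exponential(list(subset_sizes = x, values = 2 * exp(-0.05 * x) + 1))
  expect_true(fit$converged)
  expect_equal(fit$a, 2, tolerance = 1e-6)
  expect_equal(fit$b, 0.05, tolerance = 1e-6)
  expect_equal(fit$c, 1, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-12)
})

test_that("fit_exponential recovers b within 10% under noise", {
  x <- seq(5, 200, by = 5)
  y0 <- 2 * exp(-0.05 * x) + 1
  for (s in 1:20) {
    set.seed(s)
    fit <- fit_exponential(list(subset_sizes = x, values = y0 + rnorm(length(x), sd = 0.01)))
    expect_true(fit$converged)
    expect_lt(abs(fit$b - 0.05) / 0.05, 0.10)
  }
})

test_that("degenerate and invalid curves are handled explicitly", {
  x <- seq(5, 50, by = 5)
  flat <- fit_exponential(list(subset_sizes = x, values = rep(3, length(x))))
  expect_true(flat$converged)
  expect_true(flat$degenerate)
  expect_equal(flat$a, 0)
  expect_equal(flat$c, 3)
  expect_error(fit_exponential(list(subset_sizes = 1:3, values = 1:3)),
               class = "msi_domain_error")
})

test_that("fit is scale-equivariant: a, c scale with the data, b does not", {
  x <- seq(4, 120, by = 4)
  y <- 1.5 * exp(-0.08 * x) + 0.4
  set.seed(1)
  y <- y + rnorm(length(y), sd = 1e-4)
  f1 <- fit_exponential(list(subset_sizes = x, values = y))
  f2 <- fit_exponential(list(subset_sizes = x, values = 100 * y))
  expect_equal(f2$a / f1$a, 100, tolerance = 1e-3)
  expect_equal(f2$c / f1$c, 100, tolerance = 1e-3)
  expect_equal(f2$b, f1$b, tolerance = 1e-6)
})

test_that("curvature matches the closed form and a finite-difference oracle", {
  fit <- exact_fit(1, 1, 0)
  expect_equal(curvature(fit, 0), 1 / 2^1.5, tolerance = 1e-6)
  # finite-difference curvature of y(x) itself
  yfun <- function(x) fit$a * exp(-fit$b * x) + fit$c
  h <- 1e-5
  for (x0 in c(0.2, 1, 3)) {
    d1 <- (yfun(x0 + h) - yfun(x0 - h)) / (2 * h)
    d2 <- (yfun(x0 + h) - 2 * yfun(x0) + yfun(x0 - h)) / h^2
    expect_equal(curvature(fit, x0), abs(d2) / (1 + d1^2)^1.5, tolerance = 1e-5)
  }
  # vertical shift leaves curvature unchanged
  expect_equal(curvature(exact_fit(1, 1, 7), c(0, 0.5, 2)),
               curvature(fit, c(0, 0.5, 2)), tolerance = 1e-6)
  # flat line has zero curvature
  flat <- fit_exponential(list(subset_sizes = seq(2, 20, 2), values = rep(2, 10)))
  expect_equal(curvature(flat, c(0, 5, 50)), rep(0, 3))
  # non-converged fit is refused
  bad <- fit; bad$converged <- FALSE
  expect_error(curvature(bad, 1), class = "msi_domain_error")
})

grid_max_curvature <- function(fit, x_hi) {
  xs <- seq(0, x_hi, length.out = 20001)
  ks <- curvature(fit, xs)
  i <- which.max(ks)
  if (i == 1) return(0)
  opt <- optimize(function(x) -curvature(fit, x),
                  c(xs[max(1, i - 1)], xs[min(length(xs), i + 1)]), tol = 1e-12)
  opt$minimum
}

test_that("closed-form elbow equals dense-grid maximization over the sweep", {
  for (a in c(0.5, 1, 5)) {
    for (b in c(0.01, 0.1, 1)) {
      fit <- exact_fit(a, b, 0.3)
      xstar <- max_curvature_point(fit)
      xgrid <- grid_max_curvature(fit, x_hi = 30 / b)
      expect_equal(xstar, xgrid, tolerance = 1e-6,
                   label = sprintf("a=%g b=%g closed form", a, b))
      # interior iff a*b >= 1/sqrt(2)
      if (a * b < 1 / sqrt(2)) expect_equal(xstar, 0)
      else expect_gt(xstar, 0)
    }
  }
  # x* independent of c
  expect_equal(max_curvature_point(exact_fit(5, 1, 0)),
               max_curvature_point(exact_fit(5, 1, 12)), tolerance = 1e-6)
  flat <- fit_exponential(list(subset_sizes = seq(2, 20, 2), values = rep(2, 10)))
  expect_error(max_curvature_point(flat), class = "msi_domain_error")
})

test_that("select_projection_count matches a grid root-finding oracle", {
  grid_select <- function(fit, fraction) {
    xstar <- max_curvature_point(fit)
    target <- fraction * curvature(fit, xstar)
    xs <- seq(xstar, xstar + 200 / fit$b, length.out = 200001)
    i <- which(curvature(fit, xs) <= target)[1]
    root <- uniroot(function(x) curvature(fit, x) - target,
                    c(xs[i - 1], xs[i]), tol = 1e-12)$root
    as.integer(ceiling(root))
  }
  for (a in c(1, 5)) {
    for (b in c(0.05, 0.5, 1)) {
      fit <- exact_fit(a, b, 0.2)
      k_est <- select_projection_count(fit)
      expect_equal(k_est, grid_select(fit, 2 / 3),
                   label = sprintf("a=%g b=%g k_est", a, b))
      expect_gt(k_est, max_curvature_point(fit))
    }
  }
})

test_that("smaller curvature fractions select more projections", {
  fit <- exact_fit(2, 0.05, 1)
  ks <- vapply(c(0.5, 2 / 3, 0.9), function(f) select_projection_count(fit, f),
               integer(1))
  expect_true(all(diff(ks) < 0))
  # fraction -> 1 approaches the elbow from above
  expect_equal(select_projection_count(exact_fit(1, 1, 0), 0.999),
               as.integer(ceiling(max_curvature_point(exact_fit(1, 1, 0)) + 1e-6)))
  expect_error(select_projection_count(fit, 0), class = "msi_domain_error")
  expect_error(select_projection_count(fit, 1), class = "msi_domain_error")
})

test_that("elbow_reached compares k_est to the measured range", {
  fit <- exact_fit(2, 0.05, 1)
  k_est <- select_projection_count(fit)
  expect_gt(k_est, 1L)
  long <- list(subset_sizes = seq(5, 200, 5), values = rep(1, 40))
  short <- list(subset_sizes = seq_len(k_est - 1L), values = rep(1, k_est - 1L))
  exact <- list(subset_sizes = c(5, k_est), values = c(1, 1))
  expect_true(elbow_reached(long, fit))
  expect_false(elbow_reached(short, fit))
  expect_true(elbow_reached(exact, fit))  # boundary is inclusive
})

test_that("k_est is stable across seeds when the curve is truly exponential", {
  # score matrices constructed so the prefix-s1 curve follows a known
  # exponential: diagonal rows with s1(prefix k') = k' * (a e^{-b k'} + c)
  a <- 2; b <- 0.05; cc <- 1
  k <- 200; n <- 250
  f <- function(kk) kk * (a * exp(-b * kk) + cc)
  kests <- vapply(1:10, function(s) {
    A <- matrix(0, k, n)
    A[cbind(1:k, 1:k)] <- f(1:k)
    set.seed(s)
    A <- A + matrix(rnorm(k * n, sd = 0.05), k, n)
    cv <- decay_curve(A, as.integer(seq(5, 200, by = 5)))
    select_projection_count(fit_exponential(cv))
  }, integer(1))
  expect_true(all(abs(kests - median(kests)) / median(kests) <= 0.10))
})
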