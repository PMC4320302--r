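# Automatic choice of the number of projections. As projections accumulate,
# the largest singular value of the score matrix, normalized to the number of
# projections ("variance captured per projection"), decays roughly
# exponentially and plateaus once additional projections add little. The
# workflow: measure that decay over nested row subsets, fit
# y(x) = a exp(-b x) + c, locate the elbow analytically as the point of
# maximum curvature, and declare the elbow passed where the curvature has
# dropped to a fraction (default two-thirds) of its maximum.

#' Normalized first singular value of a score matrix
#'
#' Returns s1 / k' (default) where s1 is the largest singular value of the
#' k' x n score matrix. The alternative normalization s1^2 / k' (energy per
#' projection) is available via `norm = "s1sq_over_k"`.
#'
#' @param scores a `score_matrix` or numeric matrix with k' rows.
#' @param norm `"s1_over_k"` (default) or `"s1sq_over_k"`.
#' @return a non-negative scalar.
#' @export
normalized_first_sv <- function(scores, norm = c("s1_over_k", "s1sq_over_k")) {
  norm <- match.arg(norm)
  A <- as_score_matrix(scores)$scores
  if (length(A) == 0L || nrow(A) < 1L || ncol(A) < 1L) {
    domain_error("score matrix must be non-empty")
  }
  # s1 via the smaller Gram matrix; k' is small by construction
  G <- if (nrow(A) <= ncol(A)) tcrossprod(A) else crossprod(A)
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values[1]
  s1 <- sqrt(max(ev, 0))
  kk <- nrow(A)
  if (norm == "s1_over_k") s1 / kk else s1^2 / kk
}

#' Decay curve of the normalized first singular value
#'
#' Evaluates [normalized_first_sv()] on row subsets of the score matrix. The
#' default `"prefix"` policy takes the first k' rows (nested subsets in basis
#' order), which makes the curve a deterministic function of one basis and
#' consistent under [extend_basis()]. The `"random"` policy averages over
#' `n_draws` seeded random row subsets per size.
#'
#' @param scores a `score_matrix` or numeric matrix (k rows).
#' @param subset_sizes strictly increasing integers, all <= k.
#' @param policy `"prefix"` (default) or `"random"`.
#' @param n_draws random subsets averaged per size (`"random"` policy only).
#' @param seed seed for the `"random"` policy.
#' @inheritParams normalized_first_sv
#' @return An object of class `decay_curve`: list with `subset_sizes`,
#'   `values`, `policy`, `norm`.
#' @export
decay_curve <- function(scores, subset_sizes, policy = c("prefix", "random"),
                        n_draws = 5L, seed = 1L,
                        norm = c("s1_over_k", "s1sq_over_k")) {
  policy <- match.arg(policy)
  norm <- match.arg(norm)
  A <- as_score_matrix(scores)$scores
  subset_sizes <- as.integer(subset_sizes)
  if (length(subset_sizes) < 1L || anyNA(subset_sizes)) {
    domain_error("`subset_sizes` must be non-empty integers")
  }
  if (any(diff(subset_sizes) <= 0)) {
    domain_error("`subset_sizes` must be strictly increasing")
  }
  if (subset_sizes[1] < 1L || max(subset_sizes) > nrow(A)) {
    domain_error(sprintf("subset sizes must lie in 1..%d", nrow(A)))
  }
  values <- vapply(seq_along(subset_sizes), function(i) {
    kk <- subset_sizes[i]
    if (policy == "prefix") {
      normalized_first_sv(A[seq_len(kk), , drop = FALSE], norm = norm)
    } else {
      draws <- vapply(seq_len(n_draws), function(d) {
        rows <- with_seed(derive_seed(seed, i * 1000L + d),
                          sample.int(nrow(A), kk))
        normalized_first_sv(A[rows, , drop = FALSE], norm = norm)
      }, numeric(1))
      mean(draws)
    }
  }, numeric(1))
  structure(list(subset_sizes = subset_sizes, values = values,
                 subset_policy = policy, norm = norm),
            class = "decay_curve")
}

#' Fit a three-parameter exponential to a decay curve
#'
#' Least-squares fit of y(x) = a exp(-b x) + c. The asymptote c captures the
#' plateau the curve reaches once enough projections are included. Fitting is
#' deterministic: initialization by variable projection (profile the linear
#' parameters a, c over a fixed log-spaced grid of decay rates b, refine the
#' best b by golden-section search), then full Levenberg-Marquardt with an
#' analytic Jacobian. A curve with (numerically) zero variance is returned as
#' a degenerate flat fit (a = 0) rather than an error.
#'
#' @param curve a [decay_curve()], or anything with `$subset_sizes` and
#'   `$values` (>= 4 distinct sizes required).
#' @return An object of class `decay_fit`: list with `a`, `b`, `c`, `rss`,
#'   `converged`, `degenerate`, `niter`.
#' @export
fit_exponential <- function(curve) {
  x <- as.numeric(curve$subset_sizes)
  y <- as.numeric(curve$values)
  if (length(x) != length(y) || length(unique(x)) < 4L) {
    domain_error("exponential fit requires at least 4 distinct subset sizes")
  }
  if (anyNA(x) || anyNA(y)) domain_error("decay curve contains missing values")

  yscale <- max(abs(y), 1e-300)
  if (stats::sd(y) < 1e-12 * yscale) {
    return(new_decay_fit(a = 0, b = 1, c = mean(y), rss = sum((y - mean(y))^2),
                         converged = TRUE, degenerate = TRUE, niter = 0L))
  }

  # variable projection: for fixed b, (a, c) solve linearly
  prof <- function(b) {
    e <- exp(-b * x)
    fit <- stats::lm.fit(cbind(e, 1), y)
    list(a = fit$coefficients[1], c = fit$coefficients[2],
         rss = sum(fit$residuals^2))
  }
  xspan <- max(x) - min(x)
  b_grid <- 10^seq(log10(1e-4 / xspan), log10(50 / xspan), length.out = 120)
  rss_grid <- vapply(b_grid, function(b) prof(b)$rss, numeric(1))
  i0 <- which.min(rss_grid)
  lo <- b_grid[max(1L, i0 - 1L)]
  hi <- b_grid[min(length(b_grid), i0 + 1L)]
  b0 <- stats::optimize(function(b) prof(b)$rss, c(lo, hi),
                        tol = .Machine$double.eps^0.5)$minimum
  p0 <- prof(b0)
  theta <- c(a = unname(p0$a), b = b0, c = unname(p0$c))

  # Levenberg-Marquardt on r(theta) = a exp(-b x) + c - y
  resid <- function(th) th[1] * exp(-th[2] * x) + th[3] - y
  jac <- function(th) {
    e <- exp(-th[2] * x)
    cbind(e, -th[1] * x * e, 1)
  }
  rss <- sum(resid(theta)^2)
  lambda <- 1e-3
  niter <- 0L
  converged <- FALSE
  for (it in seq_len(500L)) {
    niter <- it
    r <- resid(theta)
    J <- jac(theta)
    g <- crossprod(J, r)
    H <- crossprod(J)
    step_ok <- FALSE
    for (try_i in 1:30) {
      Haug <- H + lambda * diag(pmax(diag(H), 1e-12))
      delta <- tryCatch(solve(Haug, -g), error = function(e) NULL)
      if (is.null(delta)) { lambda <- lambda * 10; next }
      cand <- theta + drop(delta)
      rss_cand <- sum(resid(cand)^2)
      if (is.finite(rss_cand) && rss_cand <= rss) {
        improve <- rss - rss_cand
        theta <- cand; rss <- rss_cand
        lambda <- max(lambda * 0.3, 1e-12)
        step_ok <- TRUE
        if (improve < 1e-15 * (rss + 1e-15)) converged <- TRUE
        break
      }
      lambda <- lambda * 10
    }
    if (!step_ok) { converged <- TRUE; break }  # stuck at a (local) minimum
    if (converged) break
  }
  new_decay_fit(a = unname(theta[1]), b = unname(theta[2]), c = unname(theta[3]),
                rss = rss, converged = converged && is.finite(rss),
                degenerate = abs(theta[1]) < 1e-10 * yscale, niter = niter)
}

new_decay_fit <- function(a, b, c, rss, converged, degenerate, niter) {
  structure(list(a = a, b = b, c = c, rss = rss, converged = converged,
                 degenerate = degenerate, niter = niter),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "<decay_fit> y = %.6g * exp(-%.6g x) + %.6g  (rss %.3g, %s%s)\n",
    x$a, x$b, x$c, x$rss, if (x$converged) "converged" else "NOT converged",
    if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

check_fit <- function(fit) {
  stopifnot(inherits(fit, "decay_fit"))
  if (!isTRUE(fit$converged)) {
    domain_error("decay fit did not converge; refusing to analyze curvature")
  }
}

#' Curvature of a fitted decay curve
#'
#' kappa(x) = |y''(x)| / (1 + y'(x)^2)^(3/2) for y = a exp(-b x) + c.
#' Independent of the vertical shift c.
#'
#' @param fit a converged [fit_exponential()] result.
#' @param x evaluation points, >= 0 (vectorized).
#' @return non-negative curvature values.
#' @export
curvature <- function(fit, x) {
  check_fit(fit)
  u <- abs(fit$a) * fit$b * exp(-fit$b * x)   # |y'(x)|
  (fit$b * u) / (1 + u^2)^1.5
}

#' Point of maximum curvature (the elbow)
#'
#' With u(x) = a b exp(-b x) = |y'(x)|, kappa = b u / (1 + u^2)^(3/2) is
#' maximized at u = 1/sqrt(2), giving the interior solution
#' x* = ln(sqrt(2) a b) / b whenever a b >= 1/sqrt(2); otherwise kappa is
#' decreasing on x >= 0 and the maximum sits on the boundary x* = 0.
#'
#' @param fit a converged [fit_exponential()] result with a > 0, b > 0.
#' @return the location x* >= 0 of maximum curvature.
#' @export
max_curvature_point <- function(fit) {
  check_fit(fit)
  if (!is.finite(fit$a) || !is.finite(fit$b) || fit$a <= 0 || fit$b <= 0) {
    domain_error("maximum curvature requires a decreasing fit with a > 0 and b > 0")
  }
  ab <- fit$a * fit$b
  if (ab >= 1 / sqrt(2)) log(sqrt(2) * ab) / fit$b else 0
}

#' Select the number of projections from a fitted decay curve
#'
#' Finds the smallest x beyond the elbow x* where the curvature has fallen to
#' `fraction` of its maximum (the curvature is strictly decreasing on that
#' branch, so the root is unique) and rounds up to an integer. Rounding up is
#' conservative: extra projections cost time, not correctness.
#'
#' @inheritParams max_curvature_point
#' @param fraction curvature fraction in (0, 1); default 2/3.
#' @return integer k_est, always > x*.
#' @export
select_projection_count <- function(fit, fraction = 2 / 3) {
  check_fit(fit)
  if (!is.numeric(fraction) || length(fraction) != 1L || is.na(fraction) ||
      fraction <= 0 || fraction >= 1) {
    domain_error("`fraction` must lie strictly between 0 and 1")
  }
  xstar <- max_curvature_point(fit)
  target <- fraction * curvature(fit, xstar)
  width <- 20 / fit$b
  hi <- xstar + width
  tries <- 0L
  while (curvature(fit, hi) > target) {
    width <- width * 2
    hi <- xstar + width
    tries <- tries + 1L
    if (tries > 60L) numerical_error("could not bracket the curvature target")
  }
  root <- stats::uniroot(function(x) curvature(fit, x) - target,
                         lower = xstar, upper = hi,
                         tol = 1e-10 * max(1, xstar))$root
  k_est <- as.integer(ceiling(root))
  if (k_est <= xstar) k_est <- as.integer(floor(xstar)) + 1L
  max(k_est, 1L)
}

#' Has the measured curve reached the elbow?
#'
#' TRUE iff the selected projection count falls within the measured range of
#' the curve; FALSE signals that more projections should be appended (see
#' [extend_basis()]) and the curve extended until the elbow is seen.
#'
#' @param curve the measured [decay_curve()].
#' @param fit the converged fit of that curve.
#' @param fraction passed to [select_projection_count()].
#' @return logical.
#' @export
elbow_reached <- function(curve, fit, fraction = 2 / 3) {
  select_projection_count(fit, fraction) <= max(curve$subset_sizes)
}
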