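test_that("sample covariance matches the direct (n-1) formula", {
  x <- matrix(c(1.2, -0.5, 2.2, 0.7, 1.9,
                0.3, 1.1, -0.4, 0.8, 0.2,
                5.0, 4.1, 6.2, 5.5, 4.8), 5)
  co <- toy_cohort(x)
  xc <- sweep(x, 2, colMeans(x))
  expect_equal(sample_covariance(co), crossprod(xc) / 4,
               ignore_attr = TRUE)
  # standardized input -> correlation matrix with unit diagonal
  sz <- sample_covariance(standardize(co))
  expect_lt(max(abs(diag(sz) - 1)), 1e-10)
  # perfect correlation / orthogonality
  co2 <- standardize(toy_cohort(cbind(a = c(1, 2, 3), b = c(2, 4, 6))))
  expect_equal(sample_covariance(co2)[1, 2], 1)
  co3 <- toy_cohort(cbind(a = c(1, -1, 1, -1), b = c(1, 1, -1, -1)))
  expect_equal(sample_covariance(co3)[1, 2], 0)
  expect_error(sample_covariance(toy_cohort(matrix(1:2, 1))), "at least 2")
})

test_that("lambda grid is log-spaced and handles degenerate input", {
  S <- diag(2)
  S[1, 2] <- S[2, 1] <- 0.8
  expect_equal(lambda_grid(S, 3, 0.01), c(0.8, 0.08, 0.008))
  expect_equal(lambda_grid(S, 2, 0.05), c(0.8, 0.04))
  expect_warning(g <- lambda_grid(diag(3)), "degenerate")
  expect_equal(g, 0)
})

test_that("graphical lasso solves trivial and invertible cases exactly", {
  # independence fixed point
  f <- graphical_lasso(diag(3), 0.1)
  expect_equal(f$precision, diag(3), ignore_attr = TRUE)
  expect_equal(f$edge_count, 0)
  # full-sparsity threshold: lam >= max |S_ij| kills every edge exactly
  S <- diag(3)
  S[1, 2] <- S[2, 1] <- 0.4
  S[1, 3] <- S[3, 1] <- -0.25
  f2 <- graphical_lasso(S, 0.5)
  expect_true(all(f2$precision[upper.tri(S)] == 0))
  # lam = 0 equals direct inversion
  S3 <- matrix(c(1, 0.5, 0.5, 1), 2)
  f3 <- graphical_lasso(S3, 0, tol = 1e-10)
  expect_lt(max(abs(f3$precision - solve(S3))), 1e-6)
  expect_equal(f3$pcor[1, 2], 0.5, tolerance = 1e-6)
  expect_error(graphical_lasso(matrix(c(1, 2, 3, 4), 2), 0.1), "symmetric")
})

test_that("partial correlations are bounded, symmetric, zero-diagonal", {
  set.seed(11)
  for (rep in 1:5) {
    x <- matrix(rnorm(50 * 5), 50)
    f <- ggm(toy_cohort(x), n_lambda = 20)
    expect_equal(f$pcor, t(f$pcor))
    expect_true(all(diag(f$pcor) == 0))
    expect_true(all(abs(f$pcor) < 1))
    expect_true(all(eigen(f$precision, only.values = TRUE)$values > 0))
  }
})

test_that("relabeling variables permutes the fitted network consistently", {
  set.seed(21)
  x <- mvn_from_theta(120, theta_with_edges(4, list(c(1, 2), c(3, 4))))
  f1 <- ggm(toy_cohort(x), n_lambda = 25)
  perm <- c(3, 1, 4, 2)
  f2 <- ggm(toy_cohort(x[, perm]), n_lambda = 25)
  expect_equal(f2$pcor, f1$pcor[perm, perm], tolerance = 1e-8)
})

test_that("IC selection recovers independence and a planted edge", {
  # independent variables -> empty selected network
  set.seed(31)
  x <- matrix(rnorm(200 * 5), 200)
  f <- ggm(toy_cohort(x))
  expect_equal(f$edge_count, 0)
  # single planted edge (partial correlation 0.6) is found and strong
  th <- theta_with_edges(5, list(c(1, 2)), rho = 0.6)
  y <- mvn_from_theta(200, th, seed = 32)
  f2 <- ggm(toy_cohort(y))
  expect_gt(abs(f2$pcor[1, 2]), 0.3)
  # grid of length 1 -> that fit is selected
  f3 <- ggm(toy_cohort(y), lambda = 0.2)
  expect_equal(f3$lam, 0.2)
  expect_equal(f3$path$selected_index, 1)
})

test_that("IC value follows the penalized-likelihood formula", {
  set.seed(41)
  x <- matrix(rnorm(80 * 4), 80)
  co <- standardize(toy_cohort(x))
  f <- ggm(co, n_lambda = 10, keep_path = TRUE)
  S <- sample_covariance(co)
  n <- 80
  p <- 4
  for (fit in f$path$fits[c(1, 5, 10)]) {
    E <- sum(fit$precision[upper.tri(S)] != 0)
    ll <- (n / 2) * (determinant(fit$precision)$modulus[1] -
                       sum(S * fit$precision)) - (n * p / 2) * log(2 * pi)
    expect_equal(fit$ic_value, -2 * ll + E * log(n), tolerance = 1e-8)
  }
  # selected index minimizes the IC over the path
  expect_equal(f$path$selected_index, which.min(f$path$ic))
})

test_that("edge count shrinks as the penalty grows on a data fixture", {
  set.seed(51)
  x <- mvn_from_theta(150, theta_with_edges(5, list(c(1, 2), c(2, 3),
                                                    c(4, 5))))
  f <- ggm(toy_cohort(x), n_lambda = 30, keep_path = TRUE)
  ec <- f$path$edge_count  # grid is descending: counts should not increase
  expect_true(all(diff(rev(ec)) <= 0))
})

test_that("bootstrap connection-difference test separates unequal edges", {
  # B too small is refused
  expect_error(bootstrap_edge_difference(toy_cohort(diag(3)), B = 50),
               ">= 100")
  th <- theta_with_edges(4, list(c(1, 2)), rho = 0.6)
  x <- mvn_from_theta(300, th, seed = 61)
  res <- bootstrap_edge_difference(toy_cohort(x), B = 200, seed = 62,
                                   n_lambda = 25)
  d <- res$differences
  # an edge against itself: degenerate [0, 0] interval, never significant
  self <- d[d$edge1 == d$edge2, ]
  expect_true(all(self$lo == 0 & self$hi == 0))
  expect_false(any(self$significant))
  # the planted v1--v2 edge differs from any weak edge it is paired with
  strong <- "v1--v2"
  if (any(d$edge1 == strong & d$edge2 != strong)) {
    others <- d[d$edge1 == strong & d$edge2 != strong, ]
    expect_true(any(others$significant))
  }
  # determinism under the same seed
  res2 <- bootstrap_edge_difference(toy_cohort(x), B = 200, seed = 62,
                                    n_lambda = 25)
  expect_identical(res$boot, res2$boot)
})

test_that("edges of equal planted strength are rarely declared different", {
  th <- theta_with_edges(5, list(c(1, 2), c(3, 4)), rho = 0.5)
  hits <- vapply(1:40, function(s) {
    x <- mvn_from_theta(300, th, seed = 70 + s)
    res <- bootstrap_edge_difference(toy_cohort(x), B = 200,
                                     seed = 700 + s, n_lambda = 30)
    d <- res$differences
    row <- d$edge1 == "v1--v2" & d$edge2 == "v3--v4"
    if (!any(row)) return(FALSE)
    d$significant[row]
  }, logical(1))
  expect_lte(mean(hits), 0.1)
})
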