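#' Sample covariance matrix of a cohort table
#'
#' Uses the n - 1 denominator; on standardized input this is the sample
#' correlation matrix (unit diagonal).
#'
#' @param table A `tn_cohort` with at least two rows.
#' @return A symmetric p x p matrix with the variable names as dimnames.
#' @export
sample_covariance <- function(table) {
  stopifnot(inherits(table, "tn_cohort"))
  n <- nrow(table$values)
  if (n < 2) stop("need at least 2 rows to form a covariance matrix")
  x <- scale(table$values, center = TRUE, scale = FALSE)
  s <- crossprod(x) / (n - 1)
  (s + t(s)) / 2
}

#' Penalty grid for the graphical lasso
#'
#' Log-spaced descending grid from `lambda_max = max |S_ij|` (i != j),
#' the smallest penalty at which the estimated network is empty, down to
#' `lambda_max * min_ratio`.
#'
#' @param S Symmetric covariance/correlation matrix.
#' @param n_points Number of grid points (>= 2).
#' @param min_ratio Ratio of the smallest to the largest penalty, in (0,1).
#' @return Strictly decreasing numeric vector.
#' @export
lambda_grid <- function(S, n_points = 100, min_ratio = 0.01) {
  stopifnot(n_points >= 2, min_ratio > 0, min_ratio < 1)
  off <- abs(S[upper.tri(S)])
  lam_max <- if (length(off)) max(off) else 0
  if (lam_max == 0) {
    warning("all off-diagonal entries are zero; degenerate single-point grid")
    return(0)
  }
  exp(seq(log(lam_max), log(lam_max * min_ratio), length.out = n_points))
}

# Build a fitted-GGM object from a precision matrix. Entries below the
# structural-zero threshold are treated as absent edges.
new_ggm_fit <- function(theta, lam, n = NA_real_, gamma = 0,
                        variables = NULL, zero_tol = 1e-10) {
  S <- attr(theta, "S")
  attr(theta, "S") <- NULL
  theta[abs(theta) < zero_tol & row(theta) != col(theta)] <- 0
  d <- sqrt(diag(theta))
  pcor <- -theta / tcrossprod(d)
  diag(pcor) <- 0
  ic <- NA_real_
  if (is.finite(n)) {
    ic <- ggm_ic(theta, S = S, n = n, gamma = gamma)
  }
  structure(list(lam = lam, precision = theta, pcor = pcor,
                 ic_value = ic, n = n, gamma = gamma,
                 edge_count = sum(theta[upper.tri(theta)] != 0),
                 variables = variables),
            class = "tn_ggm")
}

# -2 * loglik + E log n + 4 gamma E log p, with the Gaussian profile
# log-likelihood l = (n/2)(log det Theta - tr(S Theta)) - (n p / 2) log(2 pi).
# S enters through the fitted Theta at the optimum; for selection we need S
# explicitly, so callers that know S pass it via attr.
ggm_ic <- function(theta, S = attr(theta, "S"), n, gamma = 0) {
  p <- nrow(theta)
  E <- sum(theta[upper.tri(theta)] != 0)
  if (is.null(S)) stop("internal: S required for the information criterion")
  ld <- determinant(theta, logarithm = TRUE)
  if (ld$sign <= 0) return(Inf)
  ll <- (n / 2) * (as.numeric(ld$modulus) - sum(S * theta)) -
    (n * p / 2) * log(2 * pi)
  -2 * ll + E * log(n) + 4 * gamma * E * log(p)
}

#' Graphical lasso at a single penalty
#'
#' Maximizes `log det(Theta) - tr(S Theta) - lam * sum_(i != j) |Theta_ij|`
#' by block coordinate descent.  The diagonal is unpenalized by default
#' (set `penalize_diagonal = TRUE` to add `lam` to the working covariance
#' diagonal).  Exact zeros in the solution are recorded as absent edges.
#'
#' @param S Symmetric matrix with positive diagonal.
#' @param lam Penalty, >= 0.
#' @param tol Convergence tolerance on the successive change of the working
#'   covariance, relative to the mean absolute off-diagonal of `S`.
#' @param max_iter Maximum outer sweeps.
#' @param penalize_diagonal Penalize the diagonal as well?
#' @param n,gamma Optional sample size and EBIC weight used to attach an
#'   information-criterion value to the fit.
#' @return A `tn_ggm` fit: penalty, precision matrix, regularized
#'   partial-correlation matrix (zero diagonal), edge count and IC value.
#' @examples
#' S <- matrix(c(1, .5, .5, 1), 2)
#' fit <- graphical_lasso(S, lam = 0)
#' fit$pcor[1, 2]  # 0.5
#' @export
graphical_lasso <- function(S, lam, tol = 1e-4, max_iter = 200,
                            penalize_diagonal = FALSE, n = NA_real_,
                            gamma = 0) {
  S <- as.matrix(S)
  if (nrow(S) != ncol(S) || max(abs(S - t(S))) > 1e-8) {
    stop("S must be symmetric")
  }
  if (any(diag(S) <= 0)) stop("S must have a positive diagonal")
  if (lam < 0) stop("lam must be >= 0")
  res <- glasso_cpp(S, lam, tol, as.integer(max_iter), penalize_diagonal)
  if (res$status == 2) {
    stop("graphical lasso failed (singular or non-positive-definite ",
         "working estimate); try lam > 0")
  }
  if (res$status == 1) {
    stop("graphical lasso did not converge in ", max_iter,
         " sweeps (last change ", signif(res$gap, 3), ")")
  }
  theta <- res$theta
  dimnames(theta) <- dimnames(S)
  attr(theta, "S") <- S
  fit <- new_ggm_fit(theta, lam, n = n, gamma = gamma)
  fit
}

#' Fit a Gaussian graphical model with IC-selected penalty
#'
#' Fits the graphical lasso along a descending log-spaced penalty grid and
#' selects the penalty minimizing the (extended) Bayesian information
#' criterion `-2 loglik + E log n + 4 gamma E log p`, where `E` is the
#' number of edges.  `gamma = 0` (the default) is the plain BIC; ties are
#' broken toward the sparser fit (larger penalty).  The input is
#' standardized first if it is not already.
#'
#' @param table A `tn_cohort`.
#' @param gamma EBIC sparsity weight, >= 0; 0 gives plain BIC.
#' @param n_lambda,lambda_min_ratio Grid size and ratio for [lambda_grid()].
#' @param lambda Optional explicit descending penalty grid.
#' @param tol,max_iter,penalize_diagonal Passed to the solver.
#' @param keep_path Keep the full list of per-penalty fits?
#' @return A `tn_ggm` fit for the selected penalty, with the search path
#'   recorded in `$path` (grid, IC values, edge counts, selected index).
#' @seealso [graphical_lasso()], [strong_edges_ggm()],
#'   [bootstrap_edge_difference()]
#' @export
ggm <- function(table, gamma = 0, n_lambda = 100, lambda_min_ratio = 0.01,
                lambda = NULL, tol = 1e-4, max_iter = 200,
                penalize_diagonal = FALSE, keep_path = FALSE) {
  stopifnot(inherits(table, "tn_cohort"), gamma >= 0)
  table <- ensure_standardized(table)
  n <- nrow(table$values)
  S <- sample_covariance(table)
  grid <- if (is.null(lambda)) {
    lambda_grid(S, n_lambda, lambda_min_ratio)
  } else {
    sort(as.numeric(lambda), decreasing = TRUE)
  }
  res <- glasso_path_cpp(S, grid, tol, as.integer(max_iter),
                         penalize_diagonal)
  p <- ncol(S)
  ok <- res$status == 0
  if (!any(ok)) stop("graphical lasso failed at every grid penalty")
  if (!all(ok)) {
    warning(sum(!ok), " penalty value(s) dropped (solver failure)")
  }
  ics <- rep(Inf, length(grid))
  edges <- rep(NA_integer_, length(grid))
  for (k in which(ok)) {
    th <- res$thetas[[k]]
    th[abs(th) < 1e-10 & row(th) != col(th)] <- 0
    attr(th, "S") <- S
    ics[k] <- ggm_ic(th, n = n, gamma = gamma)
    edges[k] <- sum(th[upper.tri(th)] != 0)
  }
  sel <- which.min(ics)  # first minimum = largest lambda on ties
  theta <- res$thetas[[sel]]
  dimnames(theta) <- dimnames(S)
  attr(theta, "S") <- S
  fit <- new_ggm_fit(theta, grid[sel], n = n, gamma = gamma,
                     variables = table$variables)
  fit$path <- list(grid = grid, ic = ics, edge_count = edges,
                   selected_index = sel, status = res$status)
  if (keep_path) {
    fit$path$fits <- lapply(which(ok), function(k) {
      th <- res$thetas[[k]]
      dimnames(th) <- dimnames(S)
      attr(th, "S") <- S
      f <- new_ggm_fit(th, grid[k], n = n, gamma = gamma,
                       variables = table$variables)
      f
    })
  }
  fit
}

ensure_standardized <- function(table) {
  v <- table$values
  m <- colMeans(v)
  s <- apply(v, 2, stats::sd)
  if (max(abs(m)) > 1e-8 || max(abs(s - 1)) > 1e-8) standardize(table)
  else table
}

#' @export
print.tn_ggm <- function(x, ...) {
  cat("Gaussian graphical model (graphical lasso)\n")
  cat(sprintf("  p = %d variables, n = %s, lambda = %.4g (gamma = %g)\n",
              ncol(x$pcor), ifelse(is.finite(x$n), x$n, "?"), x$lam,
              x$gamma))
  cat(sprintf("  edges: %d nonzero partial correlations (IC = %.2f)\n",
              x$edge_count, x$ic_value))
  invisible(x)
}

#' @export
summary.tn_ggm <- function(object, ...) {
  el <- pcor_edge_list(object$pcor)
  el <- el[order(-abs(el$weight)), , drop = FALSE]
  rownames(el) <- NULL
  structure(list(fit = object, edges = el), class = "summary.tn_ggm")
}

#' @export
print.summary.tn_ggm <- function(x, ...) {
  print(x$fit)
  if (nrow(x$edges)) {
    cat("Edges (by |partial correlation|):\n")
    print(head(x$edges, 25), digits = 3)
  } else cat("No edges.\n")
  invisible(x)
}

#' @export
coef.tn_ggm <- function(object, ...) object$pcor

#' @export
plot.tn_ggm <- function(x, threshold = 0, ...) {
  el <- pcor_edge_list(x$pcor)
  el <- el[abs(el$weight) >= threshold, , drop = FALSE]
  g <- igraph::graph_from_data_frame(el, directed = FALSE,
                                     vertices = colnames(x$pcor))
  igraph::plot.igraph(
    g,
    edge.width = 1 + 4 * abs(el$weight),
    edge.color = ifelse(el$weight >= 0, "steelblue", "firebrick"), ...)
  invisible(g)
}

#' Simulate from a fitted Gaussian graphical model
#'
#' Draws standardized multivariate-normal rows with covariance equal to
#' the inverse of the fitted precision matrix.
#'
#' @param object A `tn_ggm`.
#' @param nsim Number of rows.
#' @param seed Optional RNG seed.
#' @param ... Unused.
#' @return Numeric matrix `nsim x p`.
#' @export
simulate.tn_ggm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sigma <- solve(object$precision)
  r <- chol((sigma + t(sigma)) / 2)
  z <- matrix(stats::rnorm(nsim * nrow(sigma)), nsim)
  x <- z %*% r
  colnames(x) <- colnames(object$pcor)
  x
}

pcor_edge_list <- function(pcor) {
  idx <- which(upper.tri(pcor) & pcor != 0, arr.ind = TRUE)
  data.frame(var_a = colnames(pcor)[idx[, 1]],
             var_b = colnames(pcor)[idx[, 2]],
             weight = pcor[idx],
             stringsAsFactors = FALSE)
}

#' Bootstrap connection-difference test for GGM edges
#'
#' Assesses whether pairs of edge weights in the IC-selected network
#' differ: over `B` nonparametric row-resamples the model is refitted
#' (penalty re-selected each time) and, for every ordered pair of edges of
#' the original fit, the bootstrap distribution of the difference of their
#' partial correlations is summarized by a percentile interval; a pair
#' differs significantly when the `1 - alpha` interval excludes zero.
#'
#' @param table A `tn_cohort`.
#' @param B Number of bootstrap resamples, >= 100.
#' @param alpha Significance level for the percentile interval.
#' @param seed RNG seed governing the whole resample sequence.
#' @param gamma,n_lambda,lambda_min_ratio Passed to [ggm()].
#' @return A list with the original fit, the `B x E` matrix of bootstrap
#'   edge weights, and `$differences`: a data.frame with one row per edge
#'   pair (`edge1`, `edge2`, `lo`, `hi`, `significant`).
#' @export
bootstrap_edge_difference <- function(table, B = 1000, alpha = 0.05,
                                      seed = NULL, gamma = 0,
                                      n_lambda = 100,
                                      lambda_min_ratio = 0.01) {
  if (B < 100) stop("B must be >= 100 for stable bootstrap quantiles")
  stopifnot(inherits(table, "tn_cohort"))
  if (!is.null(seed)) set.seed(seed)
  table <- ensure_standardized(table)
  fit <- ggm(table, gamma = gamma, n_lambda = n_lambda,
             lambda_min_ratio = lambda_min_ratio)
  el <- pcor_edge_list(fit$pcor)
  if (nrow(el) == 0) {
    return(list(fit = fit, boot = matrix(0, B, 0),
                differences = data.frame()))
  }
  keys <- paste(el$var_a, el$var_b, sep = "--")
  n <- nrow(table$values)
  boot <- matrix(NA_real_, B, length(keys),
                 dimnames = list(NULL, keys))
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    tb <- table
    tb$values <- table$values[idx, , drop = FALSE]
    tb$subject_id <- paste0("b", seq_len(n))
    tb <- standardize(tb)
    fb <- ggm(tb, gamma = gamma, n_lambda = n_lambda,
              lambda_min_ratio = lambda_min_ratio)
    boot[b, ] <- fb$pcor[cbind(match(el$var_a, colnames(fb$pcor)),
                               match(el$var_b, colnames(fb$pcor)))]
  }
  pairs <- expand.grid(e1 = seq_along(keys), e2 = seq_along(keys))
  qs <- t(apply(pairs, 1, function(pr) {
    d <- boot[, pr[1]] - boot[, pr[2]]
    stats::quantile(d, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  }))
  diffs <- data.frame(edge1 = keys[pairs$e1], edge2 = keys[pairs$e2],
                      lo = qs[, 1], hi = qs[, 2],
                      significant = qs[, 1] > 0 | qs[, 2] < 0,
                      stringsAsFactors = FALSE)
  list(fit = fit, boot = boot, differences = diffs)
}
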