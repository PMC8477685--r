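# Shared fixtures and independent oracles for the test suite.

# Small cohort table straight from a numeric matrix.
toy_cohort <- function(x, roles = NULL, sex = NULL, timepoint = NULL) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("v", seq_len(ncol(x)))
  if (is.null(roles)) roles <- rep("metabolite", ncol(x))
  if (is.null(sex)) sex <- rep("male", nrow(x))
  if (is.null(timepoint)) timepoint <- rep("baseline", nrow(x))
  cohort_table(x, paste0("s", seq_len(nrow(x))), sex, timepoint,
               variable_spec(colnames(x), roles))
}

# Gaussian sample with a planted precision matrix.
mvn_from_theta <- function(n, theta, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sigma <- solve(theta)
  z <- matrix(rnorm(n * nrow(theta)), n) %*% chol((sigma + t(sigma)) / 2)
  colnames(z) <- colnames(theta)
  z
}

# Precision matrix with unit diagonal and -rho on the listed index pairs.
theta_with_edges <- function(p, pairs, rho = 0.5, names = NULL) {
  th <- diag(p)
  for (pr in pairs) th[pr[1], pr[2]] <- th[pr[2], pr[1]] <- -rho
  if (is.null(names)) names <- paste0("v", seq_len(p))
  dimnames(th) <- list(names, names)
  stopifnot(min(eigen(th, only.values = TRUE)$values) > 0)
  th
}

# ---- independent DAG enumeration oracle ------------------------------------

# All DAGs on p labelled nodes, as two-column arc matrices. Enumerates every
# subset of the p(p-1) ordered pairs and keeps the acyclic ones (25 DAGs for
# p = 3, 543 for p = 4).
enumerate_all_dags <- function(nodes) {
  p <- length(nodes)
  ord_pairs <- which(!diag(p) > 0, arr.ind = TRUE)
  m <- nrow(ord_pairs)
  out <- list()
  for (mask in 0:(2^m - 1)) {
    sel <- bitwAnd(mask, 2^(seq_len(m) - 1)) > 0
    arcs <- ord_pairs[sel, , drop = FALSE]
    if (oracle_is_acyclic(p, arcs)) {
      a <- matrix(nodes[arcs], ncol = 2)
      colnames(a) <- c("from", "to")
      out[[length(out) + 1]] <- a
    }
  }
  out
}

oracle_is_acyclic <- function(p, arcs) {
  if (nrow(arcs) == 0) return(TRUE)
  adj <- matrix(FALSE, p, p)
  adj[arcs] <- TRUE
  if (any(diag(adj))) return(FALSE)
  # repeated elimination of sinks; a stuck nonempty remainder is a cycle
  alive <- rep(TRUE, p)
  repeat {
    idx <- which(alive)
    if (!length(idx)) return(TRUE)
    sub <- adj[idx, idx, drop = FALSE]
    sinks <- idx[rowSums(sub) == 0]
    if (!length(sinks)) return(FALSE)
    alive[sinks] <- FALSE
  }
}

# Independent network BIC via lm-style regressions (ML variance), matching
# the documented score convention: loglik - (|parents| + 2)/2 log n.
oracle_bn_score <- function(x, arcs) {
  n <- nrow(x)
  tot <- 0
  for (y in colnames(x)) {
    pa <- arcs[arcs[, 2] == y, 1]
    r <- if (length(pa)) {
      stats::lm.fit(cbind(1, x[, pa, drop = FALSE]), x[, y])$residuals
    } else {
      x[, y] - mean(x[, y])
    }
    s2 <- mean(r^2)
    tot <- tot + sum(stats::dnorm(r, 0, sqrt(s2), log = TRUE)) -
      (length(pa) + 2) / 2 * log(n)
  }
  tot
}

# Data generated from a random DAG with strong linear coefficients.
simulate_dag_data <- function(nodes, arcs, n, coef = 0.8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- length(nodes)
  x <- matrix(0, n, p, dimnames = list(NULL, nodes))
  remaining <- nodes
  done <- character(0)
  while (length(remaining)) {
    for (v in remaining) {
      pa <- arcs[arcs[, 2] == v, 1]
      if (all(pa %in% done)) {
        mu <- if (length(pa)) {
          rowSums(x[, pa, drop = FALSE]) * coef
        } else 0
        x[, v] <- mu + rnorm(n)
        done <- c(done, v)
      }
    }
    remaining <- setdiff(nodes, done)
  }
  x
}

# Random tree-structured DAG (each node has at most one parent). Plain
# greedy hill climbing is expected to attain the global score optimum on
# data from such truths; dense random truths create genuine single-move
# local optima (covered by a separate local-optimality test).
random_forest_dag <- function(nodes, arc_prob = 0.75) {
  ord <- sample(nodes)
  arcs <- matrix(character(), 0, 2)
  for (i in seq_along(ord)[-1]) {
    if (runif(1) < arc_prob) {
      arcs <- rbind(arcs, c(sample(ord[seq_len(i - 1)], 1), ord[i]))
    }
  }
  colnames(arcs) <- c("from", "to")
  arcs
}

random_edge_set <- function(nodes, n_edges) {
  all_pairs <- t(combn(nodes, 2))
  idx <- sample(nrow(all_pairs), min(n_edges, nrow(all_pairs)))
  edge_set(all_pairs[idx, , drop = FALSE], nodes = nodes)
}
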