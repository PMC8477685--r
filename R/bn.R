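# Linear-Gaussian Bayesian networks: BIC scoring, greedy hill climbing,
# bootstrap model averaging. All scoring works off the maximum-likelihood
# covariance of the (centered) data, so a hill climb costs small linear
# solves rather than repeated regressions.

# ---- DAG helpers -----------------------------------------------------------

as_arc_matrix <- function(arcs) {
  if (is.null(arcs) || (is.matrix(arcs) && nrow(arcs) == 0) ||
      (is.data.frame(arcs) && nrow(arcs) == 0)) {
    return(matrix(character(), 0, 2,
                  dimnames = list(NULL, c("from", "to"))))
  }
  arcs <- as.matrix(arcs)
  stopifnot(ncol(arcs) == 2)
  colnames(arcs) <- c("from", "to")
  arcs
}

validate_dag <- function(nodes, arcs) {
  arcs <- as_arc_matrix(arcs)
  unknown <- setdiff(c(arcs), nodes)
  if (length(unknown)) {
    stop("arc references unknown node(s): ", paste(unknown, collapse = ", "))
  }
  if (any(arcs[, 1] == arcs[, 2])) stop("self-arcs are not allowed")
  if (anyDuplicated(paste(arcs[, 1], arcs[, 2]))) {
    stop("duplicated arcs")
  }
  if (is.na(topological_order(nodes, arcs)[1]) && nrow(arcs) > 0) {
    stop("arcs contain a directed cycle")
  }
  arcs
}

# Kahn's algorithm; returns NA if cyclic.
topological_order <- function(nodes, arcs) {
  p <- length(nodes)
  if (nrow(arcs) == 0) return(nodes)
  indeg <- setNames(integer(p), nodes)
  tab <- table(arcs[, 2])
  indeg[names(tab)] <- as.integer(tab)
  out <- character(0)
  avail <- nodes[indeg == 0]
  arcs_left <- arcs
  while (length(avail)) {
    v <- avail[1]
    avail <- avail[-1]
    out <- c(out, v)
    hit <- arcs_left[, 1] == v
    for (w in arcs_left[hit, 2]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) avail <- c(avail, w)
    }
    arcs_left <- arcs_left[!hit, , drop = FALSE]
  }
  if (length(out) < p) NA_character_ else out
}

# ---- scoring ---------------------------------------------------------------

# Per-node BIC contribution: Gaussian log-likelihood of the node's linear
# regression on its parents (ML variance) minus (|parents| + 2)/2 * log n.
# The intercept and the residual variance are both counted as parameters;
# centering absorbs the ML intercept so only the covariance is needed.
node_bic <- function(C, n, y, parents, cache = NULL) {
  key <- NULL
  if (!is.null(cache)) {
    key <- paste0(y, "|", paste(sort(parents), collapse = ","))
    v <- cache[[key]]
    if (!is.null(v)) return(v)
  }
  k <- length(parents)
  if (k >= n) stop("rank deficiency: node '", colnames(C)[y], "' has ", k,
                   " parents with only n = ", n, " observations")
  if (k == 0) {
    s2 <- C[y, y]
  } else {
    b <- solve(C[parents, parents, drop = FALSE], C[parents, y])
    s2 <- C[y, y] - sum(C[y, parents] * b)
  }
  s2 <- max(s2, 1e-12)
  v <- -(n / 2) * (log(2 * pi * s2) + 1) - (k + 2) / 2 * log(n)
  if (!is.null(cache)) cache[[key]] <- v
  v
}

ml_covariance <- function(values) {
  x <- scale(values, center = TRUE, scale = FALSE)
  crossprod(x) / nrow(x)
}

#' BIC score of a linear-Gaussian network
#'
#' The network score is the sum over nodes of the Gaussian log-likelihood
#' of each node's linear regression on its parents (maximum-likelihood
#' variance) minus a BIC penalty of `(|parents| + 2)/2 * log(n)` per node
#' (coefficients, intercept and residual variance all count as
#' parameters).  Higher is better.  The score is likelihood-equivalent:
#' Markov-equivalent DAGs receive the same score.
#'
#' @param table A `tn_cohort` (standardized internally if needed).
#' @param arcs Two-column matrix or data.frame of directed arcs
#'   (parent, child); `NULL` for the empty graph.
#' @return A list with `score` (total) and `by_node` (named vector of
#'   per-node contributions).
#' @export
bic_score <- function(table, arcs = NULL) {
  stopifnot(inherits(table, "tn_cohort"))
  table <- ensure_standardized(table)
  nodes <- colnames(table$values)
  arcs <- validate_dag(nodes, arcs)
  n <- nrow(table$values)
  C <- ml_covariance(table$values)
  by_node <- vapply(seq_along(nodes), function(y) {
    parents <- match(arcs[arcs[, 2] == nodes[y], 1], nodes)
    node_bic(C, n, y, parents)
  }, numeric(1))
  names(by_node) <- nodes
  list(score = sum(by_node), by_node = by_node)
}

# ---- hill climbing ---------------------------------------------------------

# Reachability matrix (TRUE where a directed path of length >= 1 exists).
reach_matrix <- function(adj) {
  r <- adj
  p <- nrow(adj)
  repeat {
    r2 <- r | (r %*% adj > 0)
    if (identical(r2, r)) break
    r <- r2
  }
  r
}

# Core greedy search over integer-indexed DAGs given the ML covariance.
hc_core <- function(C, n, nodes, start_adj = NULL, cache = NULL,
                    eps = 1e-10) {
  p <- length(nodes)
  if (is.null(cache)) cache <- new.env(hash = TRUE, parent = emptyenv())
  adj <- if (is.null(start_adj)) matrix(FALSE, p, p) else start_adj
  parents <- lapply(seq_len(p), function(j) which(adj[, j]))
  score_y <- vapply(seq_len(p),
                    function(y) node_bic(C, n, y, parents[[y]], cache),
                    numeric(1))
  reach <- reach_matrix(adj)
  trace <- sum(score_y)
  repeat {
    best <- NULL
    best_delta <- eps
    # additions
    for (x in seq_len(p)) for (y in seq_len(p)) {
      if (x == y || adj[x, y] || adj[y, x] || reach[y, x]) next
      d <- node_bic(C, n, y, sort(c(parents[[y]], x)), cache) - score_y[y]
      cand <- list(op = "add", x = x, y = y, delta = d)
      if (better_move(d, best_delta, cand, best, nodes)) {
        best <- cand; best_delta <- d
      }
    }
    # deletions
    arc_idx <- which(adj, arr.ind = TRUE)
    for (k in seq_len(nrow(arc_idx))) {
      x <- arc_idx[k, 1]; y <- arc_idx[k, 2]
      d <- node_bic(C, n, y, setdiff(parents[[y]], x), cache) - score_y[y]
      cand <- list(op = "delete", x = x, y = y, delta = d)
      if (better_move(d, best_delta, cand, best, nodes)) {
        best <- cand; best_delta <- d
      }
    }
    # reversals
    for (k in seq_len(nrow(arc_idx))) {
      x <- arc_idx[k, 1]; y <- arc_idx[k, 2]
      adj2 <- adj
      adj2[x, y] <- FALSE
      if (reach_matrix(adj2)[x, y]) next  # alternative x -> y path: cycle
      d <- (node_bic(C, n, x, sort(c(parents[[x]], y)), cache) -
              score_y[x]) +
        (node_bic(C, n, y, setdiff(parents[[y]], x), cache) - score_y[y])
      cand <- list(op = "reverse", x = x, y = y, delta = d)
      if (better_move(d, best_delta, cand, best, nodes)) {
        best <- cand; best_delta <- d
      }
    }
    if (is.null(best)) break
    x <- best$x; y <- best$y
    if (best$op == "add") {
      adj[x, y] <- TRUE
      parents[[y]] <- sort(c(parents[[y]], x))
    } else if (best$op == "delete") {
      adj[x, y] <- FALSE
      parents[[y]] <- setdiff(parents[[y]], x)
    } else {
      adj[x, y] <- FALSE
      adj[y, x] <- TRUE
      parents[[y]] <- setdiff(parents[[y]], x)
      parents[[x]] <- sort(c(parents[[x]], y))
      score_y[x] <- node_bic(C, n, x, parents[[x]], cache)
    }
    score_y[y] <- node_bic(C, n, y, parents[[y]], cache)
    reach <- reach_matrix(adj)
    stopifnot(!any(diag(reach)))  # acyclicity preserved by every move
    trace <- c(trace, sum(score_y))
  }
  list(adj = adj, score = sum(score_y), by_node = score_y, trace = trace)
}

# Deterministic preference: strictly larger delta wins; ties (within 1e-9)
# resolve lexicographically on (operation, parent name, child name).
better_move <- function(d, best_delta, cand, best, nodes) {
  if (d < best_delta - 1e-9) return(FALSE)
  if (is.null(best) || d > best_delta + 1e-9) return(d >= best_delta)
  key_new <- c(cand$op, nodes[cand$x], nodes[cand$y])
  key_old <- c(best$op, nodes[best$x], nodes[best$y])
  for (i in 1:3) {
    if (key_new[i] < key_old[i]) return(TRUE)
    if (key_new[i] > key_old[i]) return(FALSE)
  }
  FALSE
}

#' Learn a Bayesian network by BIC hill climbing
#'
#' Greedy score-based structure search: starting from the empty graph the
#' single arc addition, deletion or reversal with the greatest BIC
#' improvement is applied until no move improves the score.  Tie-breaks
#' are deterministic (lexicographic on operation, parent, child), so runs
#' are exactly reproducible.  Optional seeded random restarts from random
#' DAGs keep the best local optimum.
#'
#' @param table A `tn_cohort` (standardized internally if needed).
#' @param restarts Number of additional random-start searches (default 0,
#'   plain hill climbing).
#' @param seed RNG seed, used only when `restarts > 0`.
#' @return A `tn_bn`: node names, learned `arcs`, the total and per-node
#'   `score`, and the score trace across accepted moves.
#' @examples
#' co <- simulate_cohort(make_truth(p = 4, n_stable = 1, n_unstable = 0,
#'                                  seed = 1), 30, 30, seed = 2)
#' fit <- bn_hillclimb(stratify(co, "male", "baseline",
#'                              include_covariates = FALSE))
#' @export
bn_hillclimb <- function(table, restarts = 0, seed = NULL) {
  stopifnot(inherits(table, "tn_cohort"))
  table <- ensure_standardized(table)
  n <- nrow(table$values)
  nodes <- colnames(table$values)
  p <- length(nodes)
  if (n <= p) {
    warning("n (", n, ") <= p (", p, "): structure learning is unreliable")
  }
  C <- ml_covariance(table$values)
  cache <- new.env(hash = TRUE, parent = emptyenv())
  best <- hc_core(C, n, nodes, cache = cache)
  if (restarts > 0) {
    if (!is.null(seed)) set.seed(seed)
    for (r in seq_len(restarts)) {
      ord <- sample.int(p)
      adj0 <- matrix(FALSE, p, p)
      for (i in seq_len(p - 1)) for (j in (i + 1):p) {
        if (stats::runif(1) < 0.2) adj0[ord[i], ord[j]] <- TRUE
      }
      cand <- hc_core(C, n, nodes, start_adj = adj0, cache = cache)
      if (cand$score > best$score + 1e-9) best <- cand
    }
  }
  idx <- which(best$adj, arr.ind = TRUE)
  arcs <- matrix(nodes[idx], ncol = 2,
                 dimnames = list(NULL, c("from", "to")))
  ord <- order(arcs[, 1], arcs[, 2])
  structure(list(nodes = nodes, arcs = arcs[ord, , drop = FALSE],
                 score = best$score, by_node = setNames(best$by_node, nodes),
                 score_trace = best$trace, n = n),
            class = "tn_bn")
}

#' @export
print.tn_bn <- function(x, ...) {
  cat("Bayesian network (BIC hill climbing)\n")
  cat(sprintf("  %d nodes, %d arcs, n = %d, score = %.2f\n",
              length(x$nodes), nrow(x$arcs), x$n, x$score))
  if (nrow(x$arcs)) {
    cat(paste0("  ", x$arcs[, 1], " -> ", x$arcs[, 2], collapse = "\n"),
        "\n")
  }
  invisible(x)
}

#' @export
summary.tn_bn <- function(object, ...) {
  cat("Score decomposition by node:\n")
  print(round(object$by_node, 2))
  invisible(object)
}

#' @export
plot.tn_bn <- function(x, ...) {
  g <- igraph::graph_from_data_frame(as.data.frame(x$arcs),
                                     directed = TRUE, vertices = x$nodes)
  igraph::plot.igraph(g, ...)
  invisible(g)
}

#' Bootstrap arc strengths by model averaging
#'
#' Learns a network on each of `B` row-resamples (with replacement, at the
#' original sample size) and records, for every unordered variable pair,
#' the fraction of resamples whose learned structure connects the pair in
#' either direction.  Direction frequencies are recorded alongside but the
#' downstream consensus logic uses only the undirected strengths.
#'
#' @param table A `tn_cohort`.
#' @param B Number of bootstrap resamples (study default 1000).
#' @param seed RNG seed governing the whole resample sequence.
#' @param restarts Passed to [bn_hillclimb()].
#' @return A `tn_bn_strength`: data.frame `var_a`, `var_b` (canonical
#'   order), `strength` in `[0, 1]` (a multiple of `1/B`) and
#'   `direction_frac` (fraction of resamples with the `var_a -> var_b`
#'   orientation among all B), plus attributes `B` and `nodes`.
#' @export
bootstrap_strengths <- function(table, B = 1000, seed = NULL,
                                restarts = 0) {
  stopifnot(inherits(table, "tn_cohort"), B >= 1)
  if (!is.null(seed)) set.seed(seed)
  table <- ensure_standardized(table)
  n <- nrow(table$values)
  nodes <- colnames(table$values)
  p <- length(nodes)
  count_adj <- matrix(0L, p, p, dimnames = list(nodes, nodes))
  count_dir <- matrix(0L, p, p, dimnames = list(nodes, nodes))
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    tb <- table
    tb$values <- table$values[idx, , drop = FALSE]
    tb$subject_id <- paste0("b", seq_len(n))
    sds <- apply(tb$values, 2, stats::sd)
    if (any(sds == 0)) next  # degenerate resample; contributes no arcs
    tb <- standardize(tb)
    fit <- bn_hillclimb(tb, restarts = restarts)
    if (nrow(fit$arcs)) {
      fr <- match(fit$arcs[, 1], nodes)
      to <- match(fit$arcs[, 2], nodes)
      count_dir[cbind(fr, to)] <- count_dir[cbind(fr, to)] + 1L
      lo <- pmin(fr, to); hi <- pmax(fr, to)
      count_adj[cbind(lo, hi)] <- count_adj[cbind(lo, hi)] + 1L
    }
  }
  ut <- which(upper.tri(count_adj), arr.ind = TRUE)
  df <- data.frame(var_a = nodes[ut[, 1]], var_b = nodes[ut[, 2]],
                   strength = count_adj[ut] / B,
                   direction_frac = count_dir[ut] / B,
                   dir_rev = count_dir[ut[, c(2, 1), drop = FALSE]] / B,
                   stringsAsFactors = FALSE)
  # canonical lexicographic pair order; direction_frac follows var_a -> var_b
  swap <- df$var_a > df$var_b
  if (any(swap)) {
    tmp <- df$var_a[swap]
    df$var_a[swap] <- df$var_b[swap]
    df$var_b[swap] <- tmp
    df$direction_frac[swap] <- df$dir_rev[swap]
  }
  df$dir_rev <- NULL
  df <- df[order(df$var_a, df$var_b), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("tn_bn_strength", "data.frame"),
            B = B, nodes = nodes)
}

#' @export
print.tn_bn_strength <- function(x, ...) {
  cat("Bootstrap arc strengths (B =", attr(x, "B"), "resamples)\n")
  top <- x[order(-x$strength), , drop = FALSE]
  print.data.frame(head(top[top$strength > 0, ], 20), row.names = FALSE)
  invisible(x)
}

#' Undirected skeleton of a learned network
#'
#' @param x A `tn_bn` fit or a two-column arc matrix.
#' @param nodes Node vocabulary (required when `x` is a bare arc matrix).
#' @return A presence-only [edge_set()].
#' @export
to_undirected <- function(x, nodes = NULL) {
  if (inherits(x, "tn_bn")) {
    arcs <- x$arcs
    nodes <- x$nodes
  } else {
    arcs <- as_arc_matrix(x)
    if (is.null(nodes)) nodes <- sort(unique(c(arcs)))
  }
  edge_set(arcs, nodes = nodes, method = "bn")
}
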