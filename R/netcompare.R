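# Between-group network comparison.

#' Permutation network structure invariance test
#'
#' Tests whether two groups (e.g. the sexes) share the same regularized
#' partial-correlation network.  The statistic is the maximum absolute
#' edge-weight difference `M = max |pcor_A - pcor_B|` between the two
#' IC-selected graphical-lasso networks.  Group labels are permuted over
#' the pooled rows (preserving group sizes) and the full fitting procedure
#' (re-standardization and penalty selection included) is re-run per
#' permuted group; the p-value uses the add-one correction
#' `p = (1 + #\{M_perm >= M_obs\}) / (1 + n_perm)`.
#'
#' @param tableA,tableB `tn_cohort`s over the same variables.  A warning
#'   is issued when the group sizes differ by more than a factor of two
#'   (the test assumes comparable sizes).
#' @param n_perm Number of permutations (default 1000).
#' @param seed RNG seed.
#' @param gamma,n_lambda,lambda_min_ratio Passed to [ggm()].
#' @return A `tn_nct`: `m_stat`, `p_value`, `n_perm`, `per_edge_diffs`
#'   (matrix of observed differences) and `seed`.
#' @export
invariance_test <- function(tableA, tableB, n_perm = 1000, seed = NULL,
                            gamma = 0, n_lambda = 100,
                            lambda_min_ratio = 0.01) {
  stopifnot(inherits(tableA, "tn_cohort"), inherits(tableB, "tn_cohort"))
  if (!identical(colnames(tableA$values), colnames(tableB$values))) {
    stop("variable mismatch between the two groups")
  }
  nA <- nrow(tableA$values)
  nB <- nrow(tableB$values)
  if (nA == 0 || nB == 0) stop("empty group")
  if (max(nA, nB) / min(nA, nB) > 2) {
    warning("group sizes differ by more than a factor of 2; ",
            "the invariance test assumes comparable sizes")
  }
  if (!is.null(seed)) set.seed(seed)
  fit_pcor <- function(values) {
    tb <- cohort_table(values, paste0("s", seq_len(nrow(values))),
                       rep("male", nrow(values)),
                       rep("baseline", nrow(values)),
                       tableA$variables)
    ggm(standardize(tb), gamma = gamma, n_lambda = n_lambda,
        lambda_min_ratio = lambda_min_ratio)$pcor
  }
  pA <- fit_pcor(tableA$values)
  pB <- fit_pcor(tableB$values)
  diffs <- pA - pB
  m_obs <- max(abs(diffs[upper.tri(diffs)]))
  pooled <- rbind(tableA$values, tableB$values)
  n <- nA + nB
  exceed <- 0L
  for (k in seq_len(n_perm)) {
    idx <- sample.int(n)
    mA <- fit_pcor(pooled[idx[seq_len(nA)], , drop = FALSE])
    mB <- fit_pcor(pooled[idx[(nA + 1):n], , drop = FALSE])
    d <- mA - mB
    if (max(abs(d[upper.tri(d)])) >= m_obs) exceed <- exceed + 1L
  }
  structure(list(m_stat = m_obs,
                 p_value = (1 + exceed) / (1 + n_perm),
                 n_perm = n_perm, per_edge_diffs = diffs,
                 seed = seed),
            class = "tn_nct")
}

#' @export
print.tn_nct <- function(x, ...) {
  cat("Network structure invariance test (permutation)\n")
  cat(sprintf("  M = %.4f (max |edge difference|), p = %.4g (%d permutations)\n",
              x$m_stat, x$p_value, x$n_perm))
  invisible(x)
}
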