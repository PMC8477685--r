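# Synthetic cohort generator: planted sparse dependence structure on the
# scale and design of the study cohort (two sexes, two timepoints,
# right-skewed metabolite concentrations, correlated covariate pairs), so
# that every pipeline stage is testable without the original data.

#' Construct a planted ground truth
#'
#' Builds, per timepoint, a sparse symmetric positive-definite precision
#' matrix over `p` metabolite nodes.  `n_stable` planted edges are shared
#' by both timepoints; `n_unstable` additional edges are specific to each
#' timepoint (strong at exactly one).  Planted edges target a partial
#' correlation of `target_pcor` (edges are placed node-disjoint where
#' possible; the planted-partial-correlation invariant
#' `|pcor| >= 0.4` is verified by direct computation and violation is an
#' error).  Both sexes share the same truth.
#'
#' @param p Number of metabolite nodes (>= 3).
#' @param n_stable Edges strong at both timepoints.
#' @param n_unstable Timepoint-specific edges (this many per timepoint).
#' @param seed RNG seed.
#' @param target_pcor Planted partial-correlation magnitude (default 0.5).
#' @param nodes Node names; defaults to the first `p` metabolite codes.
#' @return A `tn_truth` with per-sex, per-timepoint precision matrices,
#'   the planted stable/unstable pair lists, covariate correlation targets
#'   and log-normal marginal parameters.
#' @export
make_truth <- function(p = 19, n_stable = 2, n_unstable = 1, seed = NULL,
                       target_pcor = 0.5, nodes = NULL) {
  stopifnot(p >= 3, n_stable >= 0, n_unstable >= 0)
  n_pairs <- p * (p - 1) / 2
  if (n_stable + 2 * n_unstable > n_pairs) {
    stop("infeasible edge budget: ", n_stable, " stable + 2 x ",
         n_unstable, " unstable exceeds ", n_pairs, " pairs")
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(nodes)) {
    metab <- trp_variables("metabolite")$name
    nodes <- if (p <= length(metab)) metab[seq_len(p)] else
      sprintf("m%02d", seq_len(p))
  }
  stopifnot(length(nodes) == p)

  n_edges <- n_stable + 2 * n_unstable
  pairs <- pick_planted_pairs(nodes, n_edges)
  stable <- pairs[seq_len(n_stable), , drop = FALSE]
  unstable_base <- pairs[n_stable + seq_len(n_unstable), , drop = FALSE]
  unstable_follow <- pairs[n_stable + n_unstable + seq_len(n_unstable), ,
                           drop = FALSE]

  build_theta <- function(planted) {
    theta <- diag(p)
    dimnames(theta) <- list(nodes, nodes)
    for (k in seq_len(nrow(planted))) {
      i <- match(planted[k, 1], nodes)
      j <- match(planted[k, 2], nodes)
      theta[i, j] <- theta[j, i] <- -target_pcor
    }
    ev <- min(eigen(theta, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < 0.05) theta <- theta + (0.05 - ev) * diag(p)
    # verify the planted-partial-correlation invariant directly
    d <- sqrt(diag(theta))
    pc <- -theta / tcrossprod(d)
    for (k in seq_len(nrow(planted))) {
      i <- match(planted[k, 1], nodes)
      j <- match(planted[k, 2], nodes)
      if (abs(pc[i, j]) < 0.4) {
        stop("planted edge ", planted[k, 1], "--", planted[k, 2],
             " has |partial correlation| ", signif(abs(pc[i, j]), 3),
             " < 0.4; lower the edge budget or raise target_pcor")
      }
    }
    theta
  }
  theta_base <- build_theta(rbind(stable, unstable_base))
  theta_follow <- build_theta(rbind(stable, unstable_follow))

  ms <- trp_marginal_specs()
  marg <- if (all(nodes %in% ms$name)) {
    ms[match(nodes, ms$name), , drop = FALSE]
  } else {
    data.frame(name = nodes, meanlog = 0, sdlog = 0.5,
               stringsAsFactors = FALSE)
  }
  rownames(marg) <- NULL
  structure(list(
    nodes = nodes, p = p,
    theta = list(
      male = list(baseline = theta_base, followup = theta_follow),
      female = list(baseline = theta_base, followup = theta_follow)),
    stable_edges = canonical_pairs(stable),
    unstable_edges = list(baseline = canonical_pairs(unstable_base),
                          followup = canonical_pairs(unstable_follow)),
    covariate_structure = c(bw_bl = 0.7, energy_protein = 0.8),
    marginal_specs = marg,
    target_pcor = target_pcor, seed = seed),
    class = "tn_truth")
}

canonical_pairs <- function(m) {
  if (nrow(m) == 0) {
    return(matrix(character(), 0, 2,
                  dimnames = list(NULL, c("var_a", "var_b"))))
  }
  out <- cbind(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
  colnames(out) <- c("var_a", "var_b")
  out
}

# Sample planted pairs, exhausting node-disjoint pairs first so the planted
# precision stays block-structured (partial correlations hit the target
# exactly) whenever the budget allows.
pick_planted_pairs <- function(nodes, n_edges) {
  p <- length(nodes)
  out <- matrix(character(), 0, 2)
  shuffled <- sample(nodes)
  n_disjoint <- min(n_edges, floor(p / 2))
  for (k in seq_len(n_disjoint)) {
    out <- rbind(out, shuffled[c(2 * k - 1, 2 * k)])
  }
  if (n_edges > n_disjoint) {
    all_pairs <- t(utils::combn(nodes, 2))
    used <- paste(pmin(out[, 1], out[, 2]), pmax(out[, 1], out[, 2]))
    keys <- paste(pmin(all_pairs[, 1], all_pairs[, 2]),
                  pmax(all_pairs[, 1], all_pairs[, 2]))
    avail <- which(!keys %in% used)
    extra <- sample(avail, n_edges - n_disjoint)
    out <- rbind(out, all_pairs[extra, , drop = FALSE])
  }
  out
}

#' @export
print.tn_truth <- function(x, ...) {
  cat("Planted network truth:", x$p, "metabolite nodes\n")
  cat("  stable edges:",
      paste(x$stable_edges[, 1], x$stable_edges[, 2], sep = "--",
            collapse = ", "), "\n")
  for (tp in c("baseline", "followup")) {
    u <- x$unstable_edges[[tp]]
    if (nrow(u)) {
      cat("  ", tp, "-only edges: ",
          paste(u[, 1], u[, 2], sep = "--", collapse = ", "), "\n",
          sep = "")
    }
  }
  invisible(x)
}

#' Simulate a two-timepoint, two-sex cohort from a planted truth
#'
#' Per sex and timepoint, draws multivariate-normal metabolite vectors
#' with covariance equal to the inverse of the planted precision matrix.
#' In `"realistic"` mode the Gaussian columns are mapped through
#' log-normal marginals on the concentration scales of the study cohort
#' (micromolar medians/quartiles); `"gaussian"` mode (default) skips the
#' transform, since the analysis standardizes anyway.  Five covariates
#' are appended: birth weight and length (constant per subject across
#' timepoints, correlated at the target in `covariate_structure`), BMI,
#' and energy and protein intake (per timepoint, energy-protein
#' correlated).  Covariates are independent of the metabolites.
#' Timepoints are drawn independently given the truth.
#'
#' @param truth A `tn_truth`.
#' @param n_male,n_female Subjects per sex (study design: 64 and 68).
#' @param seed RNG seed; the same seed reproduces the table bit-for-bit.
#' @param mode `"gaussian"` or `"realistic"`.
#' @return A `tn_cohort` with `2 * (n_male + n_female)` rows.
#' @export
simulate_cohort <- function(truth, n_male = 64, n_female = 68, seed = NULL,
                            mode = c("gaussian", "realistic")) {
  stopifnot(inherits(truth, "tn_truth"), n_male >= 10, n_female >= 10)
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  covs <- trp_variables("covariate")
  vars <- rbind(
    data.frame(name = truth$nodes, role = "metabolite", unit = "uM",
               stringsAsFactors = FALSE),
    covs[, c("name", "role", "unit")])
  rows <- list()
  ids <- list()
  sexes <- list()
  tps <- list()
  for (sex in c("male", "female")) {
    n <- if (sex == "male") n_male else n_female
    id <- sprintf("%s%03d", substr(sex, 1, 1), seq_len(n))
    # birth size: constant within subject across timepoints
    r_bwbl <- truth$covariate_structure[["bw_bl"]]
    z1 <- stats::rnorm(n)
    bw <- z1
    bl <- r_bwbl * z1 + sqrt(1 - r_bwbl^2) * stats::rnorm(n)
    for (tp in c("baseline", "followup")) {
      sigma <- solve(truth$theta[[sex]][[tp]])
      sigma <- (sigma + t(sigma)) / 2
      z <- matrix(stats::rnorm(n * truth$p), n) %*% chol(sigma)
      colnames(z) <- truth$nodes
      if (mode == "realistic") {
        for (k in seq_len(truth$p)) {
          sdk <- sqrt(sigma[k, k])
          z[, k] <- stats::qlnorm(stats::pnorm(z[, k] / sdk),
                                  truth$marginal_specs$meanlog[k],
                                  truth$marginal_specs$sdlog[k])
        }
      }
      r_ep <- truth$covariate_structure[["energy_protein"]]
      z2 <- stats::rnorm(n)
      energy <- z2
      protein <- r_ep * z2 + sqrt(1 - r_ep^2) * stats::rnorm(n)
      bmi <- stats::rnorm(n)
      cv <- cbind(bw = bw, bl = bl, bmi = bmi, energy = energy,
                  protein = protein)
      if (mode == "realistic") {
        scale_cov <- rbind(bw = c(3500, 400), bl = c(51.5, 2.2),
                           bmi = c(21.3, 2.4), energy = c(2130, 550),
                           protein = c(74, 22))
        for (k in rownames(scale_cov)) {
          cv[, k] <- scale_cov[k, 1] + scale_cov[k, 2] * cv[, k]
        }
      }
      rows[[length(rows) + 1]] <- cbind(z, cv)
      ids[[length(ids) + 1]] <- id
      sexes[[length(sexes) + 1]] <- rep(sex, n)
      tps[[length(tps) + 1]] <- rep(tp, n)
    }
  }
  cohort_table(do.call(rbind, rows), unlist(ids), unlist(sexes),
               unlist(tps), vars)
}

#' Recovery experiment: does the pipeline find the planted edges?
#'
#' Runs the full dual-method consensus pipeline on `n_seeds` independent
#' cohorts simulated from `truth`, and scores the resulting consensus
#' edge sets (union over sexes) against the planted structure: stable
#' edges should be recovered, timepoint-specific (unstable) edges should
#' not survive the temporal intersection.
#'
#' @param truth A `tn_truth`.
#' @param config Pipeline configuration overrides (see [run_pipeline()]);
#'   the fast profile is used by default.
#' @param n_seeds Number of simulated cohorts.
#' @param seed Base seed; cohort `s` uses `seed + s`.
#' @param n_male,n_female Cohort sizes per sex.
#' @param mode Passed to [simulate_cohort()].
#' @return A list: `stable_recovery` (per-edge recovery fraction),
#'   `both_stable_rate` (fraction of seeds recovering every stable edge),
#'   `unstable_rate` (per-edge fraction of seeds where an unstable edge
#'   appears in the consensus), `mean_consensus_size`, and the per-seed
#'   consensus edge keys.
#' @export
recovery_experiment <- function(truth, config = list(), n_seeds = 20,
                                seed = 1, n_male = 64, n_female = 68,
                                mode = "gaussian") {
  stopifnot(inherits(truth, "tn_truth"))
  base_cfg <- modifyList(pipeline_defaults(fast = TRUE),
                         config, keep.null = TRUE)
  base_cfg$run_invariance <- FALSE
  base_cfg$output_dir <- NULL
  stable_keys <- apply(truth$stable_edges, 1, paste, collapse = "--")
  unstable_keys <- unique(c(
    apply(truth$unstable_edges$baseline, 1, paste, collapse = "--"),
    apply(truth$unstable_edges$followup, 1, paste, collapse = "--")))
  per_seed <- vector("list", n_seeds)
  for (s in seq_len(n_seeds)) {
    co <- simulate_cohort(truth, n_male, n_female, seed = seed + s,
                          mode = mode)
    cfg <- base_cfg
    cfg$seed <- seed + 100000 + s
    rep <- run_pipeline(cfg, cohort = co)
    per_seed[[s]] <- unique(paste(rep$consensus_edges$var_a,
                                  rep$consensus_edges$var_b, sep = "--"))
  }
  hit <- function(keys) {
    vapply(keys, function(k) {
      mean(vapply(per_seed, function(cs) k %in% cs, logical(1)))
    }, numeric(1))
  }
  stable_recovery <- hit(stable_keys)
  unstable_rate <- hit(unstable_keys)
  both_rate <- mean(vapply(per_seed, function(cs) {
    all(stable_keys %in% cs)
  }, logical(1)))
  list(stable_recovery = stable_recovery,
       both_stable_rate = both_rate,
       unstable_rate = unstable_rate,
       mean_consensus_size = mean(lengths(per_seed)),
       consensus_per_seed = per_seed)
}
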