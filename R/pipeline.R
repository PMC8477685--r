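# End-to-end orchestration: config, stage sequencing, artifacts, replay.

#' Default pipeline configuration
#'
#' Canonical defaults mirror the study: strong-edge cutoffs 0.3 (GGM
#' partial correlation) and 0.85 (BN bootstrap strength), 1000 BN
#' bootstrap resamples, 1000 permutations for the invariance test and
#' 1000 GGM bootstrap resamples.  The fast profile (`fast = TRUE`;
#' B = 100, n_perm = 200, 30-point penalty grid) is intended for
#' continuous-integration runs and simulation studies, and is
#' non-canonical.
#'
#' @param fast Use the reduced-cost profile?
#' @return A nested configuration list.
#' @export
pipeline_defaults <- function(fast = FALSE) {
  cfg <- list(
    input = NULL,
    id_col = "id", sex_col = "sex", timepoint_col = "timepoint",
    seed = 1,
    output_dir = NULL,
    standardization = "stratum",  # or "pooled"
    ggm = list(n_lambda = 100, lambda_min_ratio = 0.01, gamma = 0,
               threshold = 0.3, bootstrap_B = 1000, alpha = 0.05),
    bn = list(B = 1000, threshold = 0.85, restarts = 0),
    compare = list(n_perm = 1000),
    run_invariance = TRUE,
    fast = fast)
  if (fast) {
    cfg$ggm$n_lambda <- 30
    cfg$ggm$bootstrap_B <- 100
    cfg$bn$B <- 100
    cfg$compare$n_perm <- 200
  }
  cfg
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Values present in the file override the defaults of
#' [pipeline_defaults()].
#'
#' @param path File path ending in `.yaml`/`.yml` or `.json`.
#' @return A configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  fast <- isTRUE(raw$fast)
  modifyList(pipeline_defaults(fast = fast), raw, keep.null = TRUE)
}

#' Write a pipeline configuration
#'
#' @param config Configuration list.
#' @param path Output path (`.yaml`/`.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(config, path)
  } else {
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  }
  invisible(path)
}

validate_config <- function(cfg) {
  stopifnot(cfg$ggm$threshold > 0, cfg$bn$threshold > 0,
            cfg$bn$threshold <= 1, cfg$ggm$gamma >= 0, cfg$bn$B >= 1)
  if (is.null(cfg$seed)) stop("config must set a seed")
  cfg
}

#' Run the full dual-method network analysis
#'
#' Per sex: fits the unadjusted baseline GGM and BN (19 metabolites
#' only), the covariate-adjusted baseline and follow-up GGM and BN
#' (covariates as ordinary network nodes), extracts strong edges,
#' intersects them across timepoints per method, and intersects the
#' reproducible sets across methods into the consensus.  Between sexes,
#' the permutation structure-invariance test and the Hamming distance
#' between the strong baseline BN skeletons are computed on the
#' unadjusted baseline networks.  All stochastic stages are seeded from
#' `config$seed`; the same config and seed give byte-identical artifacts.
#'
#' @param config A configuration list (see [pipeline_defaults()]) or a
#'   path to a YAML/JSON config file.
#' @param cohort Optional in-memory `tn_cohort`; otherwise
#'   `config$input` is read with [read_cohort()].
#' @return A `tn_report` (see [consensus_report()]) with additional
#'   components: `$fits` (per sex/adjustment/timepoint GGM fits and BN
#'   strength tables), `$unadjusted` summary statistics, `$invariance`,
#'   `$hamming_bn_baseline`, and `$config`.  When `config$output_dir` is
#'   set, writes edge CSVs, GraphML files, `consensus_report.json`,
#'   `consensus_edges.csv` and `run.log` there.
#' @export
run_pipeline <- function(config = pipeline_defaults(), cohort = NULL) {
  if (is.character(config)) config <- read_config(config)
  config <- validate_config(
    modifyList(pipeline_defaults(fast = isTRUE(config$fast)), config,
               keep.null = TRUE))
  if (is.null(cohort)) {
    if (is.null(config$input)) stop("config$input or cohort required")
    cohort <- read_cohort(config$input,
                          schema = if (is.null(config$schema))
                            trp_variables() else config$schema,
                          id_col = config$id_col, sex_col = config$sex_col,
                          timepoint_col = config$timepoint_col)
  }
  pooled <- identical(config$standardization, "pooled")
  if (pooled) cohort <- standardize(cohort)
  set.seed(config$seed)
  stage_seed <- sample.int(.Machine$integer.max - 1, 24)
  si <- 0L
  next_seed <- function() {
    si <<- si + 1L
    stage_seed[si]
  }
  n_metab <- sum(cohort$variables$role == "metabolite")

  fits <- list()
  sex_sets <- list()
  unadj <- list()
  for (sex in c("male", "female")) {
    strat <- function(tp, adj) {
      stratify(cohort, sex, tp, include_covariates = adj,
               restandardize = !pooled)
    }
    f <- list()
    # unadjusted baseline networks (metabolites only)
    tb <- strat("baseline", FALSE)
    f$ggm_unadj_baseline <- ggm(tb, gamma = config$ggm$gamma,
                                n_lambda = config$ggm$n_lambda,
                                lambda_min_ratio = config$ggm$lambda_min_ratio)
    f$bn_unadj_baseline <- bootstrap_strengths(tb, B = config$bn$B,
                                               seed = next_seed(),
                                               restarts = config$bn$restarts)
    # covariate-adjusted baseline and follow-up
    for (tp in c("baseline", "followup")) {
      ta <- strat(tp, TRUE)
      f[[paste0("ggm_adj_", tp)]] <-
        ggm(ta, gamma = config$ggm$gamma, n_lambda = config$ggm$n_lambda,
            lambda_min_ratio = config$ggm$lambda_min_ratio)
      f[[paste0("bn_adj_", tp)]] <-
        bootstrap_strengths(ta, B = config$bn$B, seed = next_seed(),
                            restarts = config$bn$restarts)
    }
    fits[[sex]] <- f
    vars <- cohort$variables
    sex_sets[[sex]] <- list(
      ggm_baseline = strong_edges_ggm(f$ggm_adj_baseline,
                                      config$ggm$threshold, vars,
                                      sex = sex, timepoint = "baseline",
                                      adjusted = TRUE),
      ggm_followup = strong_edges_ggm(f$ggm_adj_followup,
                                      config$ggm$threshold, vars,
                                      sex = sex, timepoint = "followup",
                                      adjusted = TRUE),
      bn_baseline = strong_edges_bn(f$bn_adj_baseline, config$bn$threshold,
                                    vars, sex = sex,
                                    timepoint = "baseline",
                                    adjusted = TRUE),
      bn_followup = strong_edges_bn(f$bn_adj_followup, config$bn$threshold,
                                    vars, sex = sex,
                                    timepoint = "followup",
                                    adjusted = TRUE))
    unadj[[sex]] <- list(
      nonzero = f$ggm_unadj_baseline$edge_count,
      strong = nrow(strong_edges_ggm(f$ggm_unadj_baseline,
                                     config$ggm$threshold, vars)))
  }

  report <- consensus_report(
    male = sex_sets$male, female = sex_sets$female,
    n_metabolites = n_metab,
    unadjusted_strong = c(male = unadj$male$strong,
                          female = unadj$female$strong),
    unadjusted_nonzero = c(male = unadj$male$nonzero,
                           female = unadj$female$nonzero))
  report$fits <- fits
  report$config <- config

  bn_skel <- lapply(c(male = "male", female = "female"), function(sex) {
    es <- strong_edges_bn(fits[[sex]]$bn_unadj_baseline,
                          config$bn$threshold, cohort$variables,
                          sex = sex, timepoint = "baseline",
                          adjusted = FALSE)
    attr(es, "nodes") <- sort(attr(fits[[sex]]$bn_unadj_baseline, "nodes"))
    es
  })
  report$hamming_bn_baseline <- hamming_distance(bn_skel$male,
                                                 bn_skel$female)
  if (isTRUE(config$run_invariance)) {
    report$invariance <- invariance_test(
      stratify(cohort, "male", "baseline", include_covariates = FALSE,
               restandardize = !pooled),
      stratify(cohort, "female", "baseline", include_covariates = FALSE,
               restandardize = !pooled),
      n_perm = config$compare$n_perm, seed = next_seed(),
      gamma = config$ggm$gamma, n_lambda = config$ggm$n_lambda,
      lambda_min_ratio = config$ggm$lambda_min_ratio)
  }
  if (!is.null(config$output_dir)) {
    write_artifacts(report, config$output_dir)
  }
  report
}

write_artifacts <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- report$config
  for (sex in c("male", "female")) {
    f <- report$fits[[sex]]
    combos <- list(c("unadj", "baseline"), c("adj", "baseline"),
                   c("adj", "followup"))
    for (cb in combos) {
      tag <- paste0(sex, "_", cb[1], "_", cb[2])
      gfit <- f[[paste0("ggm_", cb[1], "_", cb[2])]]
      el <- pcor_edge_list(gfit$pcor)
      names(el)[3] <- "pcor"
      utils::write.csv(el, file.path(dir, paste0("edges_ggm_", tag,
                                                 ".csv")),
                       row.names = FALSE)
      export_graphml_ggm(gfit, file.path(dir, paste0("network_ggm_", tag,
                                                     ".graphml")))
      st <- f[[paste0("bn_", cb[1], "_", cb[2])]]
      utils::write.csv(as.data.frame(st),
                       file.path(dir, paste0("edges_bn_", tag, ".csv")),
                       row.names = FALSE)
    }
  }
  utils::write.csv(report$consensus_edges,
                   file.path(dir, "consensus_edges.csv"),
                   row.names = FALSE)
  json <- list(
    config = cfg[setdiff(names(cfg), "schema")],
    counts = report$counts,
    metabolite_panel = report$metabolite_panel,
    consensus_edges = report$consensus_edges,
    hamming_bn_baseline = report$hamming_bn_baseline,
    invariance = if (!is.null(report$invariance)) {
      report$invariance[c("m_stat", "p_value", "n_perm")]
    })
  jsonlite::write_json(json, file.path(dir, "consensus_report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  log <- c(
    paste("run at:", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste("seed:", cfg$seed),
    paste("ggm threshold:", cfg$ggm$threshold,
          "gamma:", cfg$ggm$gamma, "n_lambda:", cfg$ggm$n_lambda),
    paste("bn B:", cfg$bn$B, "threshold:", cfg$bn$threshold),
    paste("n_perm:", cfg$compare$n_perm),
    paste("fast profile:", isTRUE(cfg$fast)))
  writeLines(log, file.path(dir, "run.log"))
  invisible(dir)
}

#' Verify that a recorded run is reproducible
#'
#' Re-runs the pipeline with the configuration and seed recorded in a
#' `consensus_report.json` and checks that (a) the recomputed consensus
#' edge set matches the recorded one and (b) the `consensus_edges.csv`
#' artifact on disk matches the recorded edges.
#'
#' @param report_path Path to a `consensus_report.json` written by
#'   [run_pipeline()].
#' @param cohort Optional in-memory cohort (otherwise the recorded
#'   `input` path is read).
#' @return A list with `status` (`"pass"`/`"fail"`) and `differences`
#'   (character vector of differing edge keys, with a reason).
#' @export
replay <- function(report_path, cohort = NULL) {
  if (!file.exists(report_path)) stop("report not found: ", report_path)
  rec <- jsonlite::read_json(report_path, simplifyVector = TRUE)
  recorded <- rec$consensus_edges
  rec_keys <- if (NROW(recorded)) {
    sort(paste(recorded$sex, recorded$var_a, recorded$var_b, sep = ":"))
  } else character(0)
  differences <- character(0)
  csv_path <- file.path(dirname(report_path), "consensus_edges.csv")
  if (file.exists(csv_path)) {
    on_disk <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
    disk_keys <- if (NROW(on_disk)) {
      sort(paste(on_disk$sex, on_disk$var_a, on_disk$var_b, sep = ":"))
    } else character(0)
    bad <- c(setdiff(rec_keys, disk_keys), setdiff(disk_keys, rec_keys))
    if (length(bad)) {
      differences <- c(differences,
                       paste0("artifact consensus_edges.csv differs: ",
                              bad))
    }
  }
  cfg <- modifyList(pipeline_defaults(fast = isTRUE(rec$config$fast)),
                    rec$config, keep.null = TRUE)
  cfg$output_dir <- NULL
  rerun <- run_pipeline(cfg, cohort = cohort)
  new_keys <- if (nrow(rerun$consensus_edges)) {
    sort(paste(rerun$consensus_edges$sex, rerun$consensus_edges$var_a,
               rerun$consensus_edges$var_b, sep = ":"))
  } else character(0)
  bad <- c(setdiff(rec_keys, new_keys), setdiff(new_keys, rec_keys))
  if (length(bad)) {
    differences <- c(differences,
                     paste0("re-run consensus differs (recorded seed ",
                            cfg$seed, "): ", bad))
  }
  list(status = if (length(differences)) "fail" else "pass",
       differences = differences)
}

#' Export a fitted GGM as GraphML
#'
#' Writes the nonzero partial-correlation network with `pcor` as the
#' edge weight attribute.
#'
#' @param fit A `tn_ggm`.
#' @param path Output `.graphml` path.
#' @return `path`, invisibly.
#' @export
export_graphml_ggm <- function(fit, path) {
  el <- pcor_edge_list(fit$pcor)
  g <- igraph::graph_from_data_frame(el, directed = FALSE,
                                     vertices = colnames(fit$pcor))
  if (nrow(el)) igraph::E(g)$pcor <- el$weight
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Export a learned Bayesian network as GraphML
#'
#' Directed arcs with a `direction` attribute recording the learned
#' orientation.
#'
#' @param fit A `tn_bn`.
#' @param path Output `.graphml` path.
#' @return `path`, invisibly.
#' @export
export_graphml_bn <- function(fit, path) {
  g <- igraph::graph_from_data_frame(as.data.frame(fit$arcs),
                                     directed = TRUE, vertices = fit$nodes)
  if (nrow(fit$arcs)) {
    igraph::E(g)$direction <- paste(fit$arcs[, 1], "->", fit$arcs[, 2])
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
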