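# Consensus report: the headline statistics of the dual-method analysis.

#' Round half away from zero
#'
#' Report percentages use one-decimal half-up rounding (so 7/82 of
#' possible pairs prints as 8.5, 7/171 as 4.1, 4/171 as 2.3), unlike
#' [round()]'s round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal digits.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

pct_1dp <- function(k, total) {
  if (total == 0) return(0)
  round_half_up(100 * k / total, 1)
}

#' Summarize the dual-method consensus analysis
#'
#' Combines, per sex, the strong-edge sets of the covariate-adjusted
#' baseline and follow-up GGM and BN networks into temporal-reproducibility
#' intersections ([reproducible_edges()]), the cross-method consensus
#' ([cross_method_consensus()]), and report statistics: the number of
#' possible metabolite pairs `p (p - 1) / 2`, strong-edge counts with
#' percentages (one-decimal, half-up) of possible pairs and optionally of
#' nonzero network edges, per-sex and overall consensus counts, the
#' distinct-metabolite panel spanned by the consensus, and GGM sign flips
#' between timepoints.
#'
#' @param male,female Named lists with `tn_edge_set` entries
#'   `ggm_baseline`, `ggm_followup`, `bn_baseline`, `bn_followup`
#'   (covariate-adjusted strong-edge sets).
#' @param n_metabolites Number of metabolite variables (default 19).
#' @param unadjusted_strong,unadjusted_nonzero Optional named vectors
#'   (`c(male = ..., female = ...)`) of strong and nonzero edge counts of
#'   the unadjusted baseline GGMs, used for the "percent of possible
#'   pairs" and "percent of nonzero correlations" report statistics.
#' @return A `tn_report`.
#' @export
consensus_report <- function(male, female, n_metabolites = 19,
                             unadjusted_strong = NULL,
                             unadjusted_nonzero = NULL) {
  possible <- n_metabolites * (n_metabolites - 1) / 2
  per_sex <- lapply(list(male = male, female = female), function(s) {
    ggm_rep <- reproducible_edges(s$ggm_baseline, s$ggm_followup)
    bn_rep <- reproducible_edges(s$bn_baseline, s$bn_followup)
    cons <- cross_method_consensus(ggm_rep, bn_rep)
    list(ggm_reproducible = ggm_rep, bn_reproducible = bn_rep,
         consensus = cons,
         strong_ggm_baseline = nrow(s$ggm_baseline),
         strong_ggm_followup = nrow(s$ggm_followup),
         strong_bn_baseline = nrow(s$bn_baseline),
         strong_bn_followup = nrow(s$bn_followup),
         sign_flips = ggm_rep[ggm_rep$sign_flip, c("var_a", "var_b"),
                              drop = FALSE])
  })
  tag_sex <- function(sex, es) {
    data.frame(sex = rep(sex, nrow(es)),
               as.data.frame(es)[, c("var_a", "var_b", "weight")],
               stringsAsFactors = FALSE)
  }
  cons_all <- rbind(tag_sex("male", per_sex$male$consensus),
                    tag_sex("female", per_sex$female$consensus))
  panel <- sort(unique(c(cons_all$var_a, cons_all$var_b)))
  counts <- list(
    possible_pairs = possible,
    strong_pct_of_possible = lapply(per_sex, function(s) {
      c(ggm_baseline = pct_1dp(s$strong_ggm_baseline, possible),
        ggm_followup = pct_1dp(s$strong_ggm_followup, possible))
    }),
    consensus = c(male = nrow(per_sex$male$consensus),
                  female = nrow(per_sex$female$consensus),
                  overall = nrow(cons_all)))
  if (!is.null(unadjusted_strong)) {
    counts$unadjusted_strong <- unadjusted_strong
    counts$unadjusted_pct_of_possible <- c(
      male = pct_1dp(unadjusted_strong[["male"]], possible),
      female = pct_1dp(unadjusted_strong[["female"]], possible))
    if (!is.null(unadjusted_nonzero)) {
      counts$unadjusted_nonzero <- unadjusted_nonzero
      counts$strong_pct_of_nonzero <- c(
        male = pct_1dp(unadjusted_strong[["male"]],
                       unadjusted_nonzero[["male"]]),
        female = pct_1dp(unadjusted_strong[["female"]],
                         unadjusted_nonzero[["female"]]))
    }
  }
  structure(list(per_sex = per_sex, consensus_edges = cons_all,
                 metabolite_panel = panel, counts = counts,
                 n_metabolites = n_metabolites),
            class = "tn_report")
}

#' @export
print.tn_report <- function(x, ...) {
  cat("Consensus of strong, temporally reproducible metabolite",
      "associations\n")
  cat(sprintf("  %d metabolites -> %d possible pairs\n", x$n_metabolites,
              x$counts$possible_pairs))
  for (s in c("male", "female")) {
    ps <- x$per_sex[[s]]
    cat(sprintf(
      "  %s: GGM-reproducible %d, BN-reproducible %d, consensus %d\n",
      s, nrow(ps$ggm_reproducible), nrow(ps$bn_reproducible),
      nrow(ps$consensus)))
  }
  cat(sprintf("  overall consensus: %d association(s) spanning %d metabolites\n",
              x$counts$consensus[["overall"]],
              length(x$metabolite_panel)))
  if (nrow(x$consensus_edges)) {
    apply(x$consensus_edges, 1, function(r) {
      cat(sprintf("    [%s] %s -- %s\n", r[["sex"]], r[["var_a"]],
                  r[["var_b"]]))
    })
  }
  invisible(x)
}

#' @export
summary.tn_report <- function(object, ...) {
  print(object)
  cat("Metabolite panel:", paste(object$metabolite_panel, collapse = ", "),
      "\n")
  if (!is.null(object$counts$strong_pct_of_nonzero)) {
    cat("Strong edges as % of nonzero baseline GGM edges:",
        paste(names(object$counts$strong_pct_of_nonzero),
              object$counts$strong_pct_of_nonzero, sep = "=",
              collapse = " "), "\n")
  }
  invisible(object)
}
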