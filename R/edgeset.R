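# Edge sets: unordered variable pairs with optional weights and provenance.
# The unit of all temporal-reproducibility and cross-method consensus logic.

#' Construct an edge set
#'
#' An edge set is a collection of unordered variable-name pairs, stored in
#' canonical (lexicographic) order with optional weights (signed partial
#' correlations for GGM edges, bootstrap strengths in `[0, 1]` for BN
#' edges) and provenance labels (method, sex, timepoint, adjusted).
#'
#' @param pairs Two-column matrix/data.frame of variable names, or a
#'   zero-row object for the empty set.
#' @param weight Optional numeric weight per pair.
#' @param nodes Node vocabulary the pairs live over (defaults to the names
#'   occurring in `pairs`).
#' @param method,sex,timepoint,adjusted Provenance labels.
#' @return A `tn_edge_set` (a data.frame with columns `var_a`, `var_b`,
#'   `weight` and provenance attributes).
#' @export
edge_set <- function(pairs, weight = NULL, nodes = NULL, method = NA,
                     sex = NA, timepoint = NA, adjusted = NA) {
  if (is.null(pairs) || NROW(pairs) == 0) {
    df <- data.frame(var_a = character(), var_b = character(),
                     weight = numeric(), stringsAsFactors = FALSE)
  } else {
    pairs <- as.matrix(pairs)
    stopifnot(ncol(pairs) == 2)
    if (any(pairs[, 1] == pairs[, 2])) stop("self-pairs are not allowed")
    a <- pmin(pairs[, 1], pairs[, 2])
    b <- pmax(pairs[, 1], pairs[, 2])
    w <- if (is.null(weight)) rep(NA_real_, length(a)) else as.numeric(weight)
    df <- data.frame(var_a = a, var_b = b, weight = w,
                     stringsAsFactors = FALSE)
    if (anyDuplicated(paste(df$var_a, df$var_b))) {
      stop("duplicated pairs in edge set")
    }
    df <- df[order(df$var_a, df$var_b), , drop = FALSE]
    rownames(df) <- NULL
  }
  if (is.null(nodes)) nodes <- sort(unique(c(df$var_a, df$var_b)))
  structure(df, class = c("tn_edge_set", "data.frame"),
            nodes = sort(nodes), method = method, sex = sex,
            timepoint = timepoint, adjusted = adjusted)
}

es_keys <- function(es) paste(es$var_a, es$var_b, sep = "--")

#' @export
print.tn_edge_set <- function(x, ...) {
  prov <- c(method = attr(x, "method"), sex = attr(x, "sex"),
            timepoint = attr(x, "timepoint"))
  prov <- prov[!is.na(prov)]
  cat("Edge set (", nrow(x), " edges",
      if (length(prov)) paste0("; ", paste(names(prov), prov, sep = "=",
                                           collapse = " ")), ")\n",
      sep = "")
  if (nrow(x)) print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Strong edges of a fitted GGM
#'
#' Retains edges whose absolute regularized partial correlation is at or
#' above the cutoff (inclusive; the study default is 0.3, and a negative
#' edge of -0.31 counts as strong).  When covariates are present as
#' network nodes, only metabolite-metabolite pairs are retained (covariate
#' edges are reported separately by the pipeline).
#'
#' @param fit A `tn_ggm`, or a data.frame `var_a`, `var_b`, `weight`.
#' @param threshold Positive cutoff on `|pcor|` (default 0.3).
#' @param variables Variable specification used to identify metabolites
#'   when `fit` is a plain edge list; defaults to [trp_variables()].
#' @param sex,timepoint,adjusted Provenance labels attached to the result.
#' @return A weighted `tn_edge_set` with `method = "ggm"`.
#' @export
strong_edges_ggm <- function(fit, threshold = 0.3, variables = NULL,
                             sex = NA, timepoint = NA, adjusted = NA) {
  stopifnot(threshold > 0)
  if (inherits(fit, "tn_ggm")) {
    el <- pcor_edge_list(fit$pcor)
    if (is.null(variables)) variables <- fit$variables
    nodes <- colnames(fit$pcor)
  } else {
    el <- as.data.frame(fit)
    names(el)[1:3] <- c("var_a", "var_b", "weight")
    nodes <- sort(unique(c(el$var_a, el$var_b)))
  }
  if (is.null(variables)) variables <- trp_variables()
  el <- el[abs(el$weight) >= threshold, , drop = FALSE]
  metab <- variables$name[variables$role == "metabolite"]
  if (any(!nodes %in% metab)) {
    keep_nodes <- intersect(nodes, metab)
    el <- el[el$var_a %in% keep_nodes & el$var_b %in% keep_nodes, ,
             drop = FALSE]
    nodes <- keep_nodes
  }
  edge_set(el[, c("var_a", "var_b")], weight = el$weight, nodes = nodes,
           method = "ggm", sex = sex, timepoint = timepoint,
           adjusted = adjusted)
}

#' Strong edges of a bootstrap strength table
#'
#' Retains pairs whose bootstrap adjacency frequency is at or above the
#' cutoff (inclusive: "appears in at least 85% of resamples" for the
#' study default of 0.85).  Metabolite-metabolite pairs only when
#' covariates are present.
#'
#' @param strengths A `tn_bn_strength` table (or data.frame `var_a`,
#'   `var_b`, `strength`).
#' @param threshold Cutoff in (0, 1] (default 0.85).
#' @param variables,sex,timepoint,adjusted As in [strong_edges_ggm()].
#' @return A `tn_edge_set` with `method = "bn"` and strengths as weights.
#' @export
strong_edges_bn <- function(strengths, threshold = 0.85, variables = NULL,
                            sex = NA, timepoint = NA, adjusted = NA) {
  stopifnot(threshold > 0, threshold <= 1)
  df <- as.data.frame(strengths)
  nodes <- attr(strengths, "nodes")
  if (is.null(nodes)) nodes <- sort(unique(c(df$var_a, df$var_b)))
  if (is.null(variables)) variables <- trp_variables()
  df <- df[df$strength >= threshold, , drop = FALSE]
  metab <- variables$name[variables$role == "metabolite"]
  if (any(!nodes %in% metab)) {
    keep_nodes <- intersect(nodes, metab)
    df <- df[df$var_a %in% keep_nodes & df$var_b %in% keep_nodes, ,
             drop = FALSE]
    nodes <- keep_nodes
  }
  edge_set(df[, c("var_a", "var_b")], weight = df$strength, nodes = nodes,
           method = "bn", sex = sex, timepoint = timepoint,
           adjusted = adjusted)
}

#' Temporally reproducible edges
#'
#' Intersects the strong-edge sets of the baseline and follow-up networks
#' of the same method and sex.  Identity is existence of the unordered
#' pair; the sign of a GGM edge need not match across timepoints, but
#' sign flips are flagged.
#'
#' @param baseline,followup `tn_edge_set`s with matching method and sex
#'   provenance.
#' @return A `tn_edge_set` with columns `weight_baseline`,
#'   `weight_followup` and `sign_flip`; `weight` holds the baseline value.
#' @export
reproducible_edges <- function(baseline, followup) {
  stopifnot(inherits(baseline, "tn_edge_set"),
            inherits(followup, "tn_edge_set"))
  for (f in c("method", "sex")) {
    a <- attr(baseline, f); b <- attr(followup, f)
    if (!identical(a, b) && !(is.na(a) && is.na(b))) {
      stop("provenance mismatch: baseline ", f, "='", a,
           "' vs followup '", b, "'")
    }
  }
  keys_b <- es_keys(baseline)
  keys_f <- es_keys(followup)
  common <- intersect(keys_b, keys_f)
  ib <- match(common, keys_b)
  jf <- match(common, keys_f)
  out <- edge_set(cbind(baseline$var_a[ib], baseline$var_b[ib]),
                  weight = baseline$weight[ib],
                  nodes = union(attr(baseline, "nodes"),
                                attr(followup, "nodes")),
                  method = attr(baseline, "method"),
                  sex = attr(baseline, "sex"),
                  timepoint = "both", adjusted = attr(baseline, "adjusted"))
  ord <- match(es_keys(out), common)
  out$weight_baseline <- baseline$weight[ib][ord]
  out$weight_followup <- followup$weight[jf][ord]
  out$sign_flip <- !is.na(out$weight_baseline) &
    !is.na(out$weight_followup) &
    sign(out$weight_baseline) * sign(out$weight_followup) < 0
  out
}

#' Cross-method consensus edges
#'
#' Intersects the temporally reproducible GGM and BN edge sets of the same
#' sex: the resulting edges are strong and temporally reproducible under
#' both network approaches.
#'
#' @param ggm_rep,bn_rep `tn_edge_set`s from [reproducible_edges()] with
#'   matching sex provenance.
#' @return A `tn_edge_set` with `method = "consensus"`; GGM weights are
#'   retained.
#' @export
cross_method_consensus <- function(ggm_rep, bn_rep) {
  stopifnot(inherits(ggm_rep, "tn_edge_set"),
            inherits(bn_rep, "tn_edge_set"))
  a <- attr(ggm_rep, "sex"); b <- attr(bn_rep, "sex")
  if (!identical(a, b) && !(is.na(a) && is.na(b))) {
    stop("sex provenance mismatch: '", a, "' vs '", b, "'")
  }
  common <- intersect(es_keys(ggm_rep), es_keys(bn_rep))
  i <- match(common, es_keys(ggm_rep))
  edge_set(cbind(ggm_rep$var_a[i], ggm_rep$var_b[i]),
           weight = ggm_rep$weight[i],
           nodes = union(attr(ggm_rep, "nodes"), attr(bn_rep, "nodes")),
           method = "consensus", sex = a, timepoint = "both",
           adjusted = attr(ggm_rep, "adjusted"))
}

#' Hamming distance between network skeletons
#'
#' Number of unordered pairs present in exactly one of the two edge sets
#' (the size of the symmetric difference); a metric on skeletons over a
#' shared node vocabulary.
#'
#' @param a,b `tn_edge_set`s over the same node vocabulary.
#' @return Integer distance.
#' @export
hamming_distance <- function(a, b) {
  stopifnot(inherits(a, "tn_edge_set"), inherits(b, "tn_edge_set"))
  if (!identical(attr(a, "nodes"), attr(b, "nodes"))) {
    stop("node vocabulary mismatch between edge sets")
  }
  ka <- es_keys(a)
  kb <- es_keys(b)
  length(setdiff(ka, kb)) + length(setdiff(kb, ka))
}
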