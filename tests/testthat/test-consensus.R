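# Consensus logic exercised on the published reference edge lists of the
# two-timepoint adolescent cohort analysis, plus generic set-logic checks.

ref <- reference_networks()

test_that("edge sets canonicalize pairs and refuse degenerate input", {
  es <- edge_set(rbind(c("kyn", "trp"), c("xa", "kyna")),
                 weight = c(0.42, 0.4))
  expect_equal(es$var_a, c("kyn", "kyna"))
  expect_equal(es$var_b, c("trp", "xa"))
  expect_error(edge_set(rbind(c("a", "a"))), "self-pairs")
  expect_error(edge_set(rbind(c("a", "b"), c("b", "a"))), "duplicated")
  expect_equal(nrow(edge_set(NULL)), 0)
})

test_that("GGM strong-edge extraction keeps the inclusive 0.3 cutoff and signs", {
  # covariate-adjusted baseline male list: 6 strong edges incl. one negative
  base_m <- ref$ggm$male$baseline
  expect_equal(nrow(base_m), 6)
  expect_true(any(base_m$weight < 0))  # picolinic--anthranilic, -0.31
  raw <- as.data.frame(base_m)[, c("var_a", "var_b", "weight")]
  extra <- rbind(raw, data.frame(var_a = "ser", var_b = "trp",
                                 weight = 0.29))
  sel <- strong_edges_ggm(extra, threshold = 0.3)
  expect_equal(nrow(sel), 6)  # 0.29 dropped, -0.31 kept
  # an edge at exactly 0.30 is retained (follow-up female has one)
  f_fu <- ref$ggm$female$followup
  expect_true("0.3" %in% as.character(f_fu$weight) ||
                any(abs(f_fu$weight - 0.3) < 1e-12))
  expect_equal(nrow(strong_edges_ggm(f_fu, threshold = 0.3)), nrow(f_fu))
  # all-zero network -> empty set
  none <- strong_edges_ggm(data.frame(var_a = character(),
                                      var_b = character(),
                                      weight = numeric()))
  expect_equal(nrow(none), 0)
})

test_that("GGM strong edges are restricted to metabolite pairs", {
  el <- data.frame(var_a = c("trp", "bw", "bw"),
                   var_b = c("kyn", "bl", "trp"),
                   weight = c(0.5, 0.9, 0.6))
  sel <- strong_edges_ggm(el, threshold = 0.3)
  expect_equal(nrow(sel), 1)
  expect_equal(sel$var_a, "kyn")
})

test_that("BN strong-edge extraction uses the inclusive 0.85 cutoff", {
  st <- data.frame(var_a = c("aa", "haa", "iaa"),
                   var_b = c("trp", "kyn", "kyna"),
                   strength = c(1.0, 0.85, 0.84))
  sel <- strong_edges_bn(st, threshold = 0.85)
  expect_equal(nrow(sel), 2)
  expect_false("iaa" %in% sel$var_a)
  expect_equal(nrow(strong_edges_bn(st, threshold = 1.0)), 1)
  st$strength <- 0
  expect_equal(nrow(strong_edges_bn(st)), 0)
})

test_that("temporal intersection reproduces the published GGM overlaps", {
  m <- reproducible_edges(ref$ggm$male$baseline, ref$ggm$male$followup)
  expect_equal(nrow(m), 3)
  expect_setequal(paste(m$var_a, m$var_b, sep = "--"),
                  c("iaa--iam", "kyn--trp", "kyna--xa"))
  f <- reproducible_edges(ref$ggm$female$baseline, ref$ggm$female$followup)
  expect_equal(nrow(f), 3)
  expect_setequal(paste(f$var_a, f$var_b, sep = "--"),
                  c("iaa--kyna", "hk--kyn", "haa--hk"))
  # weights carried as (baseline, followup) pairs
  expect_equal(m$weight_baseline[m$var_a == "kyna"], 0.40)
  expect_equal(m$weight_followup[m$var_a == "kyna"], 0.45)
  expect_false(any(m$sign_flip))
  # disjoint sets intersect to nothing
  expect_equal(nrow(reproducible_edges(
    edge_set(rbind(c("a", "b")), method = "ggm", sex = "male"),
    edge_set(rbind(c("c", "d")), method = "ggm", sex = "male"))), 0)
  # provenance guard
  expect_error(reproducible_edges(ref$ggm$male$baseline,
                                  ref$ggm$female$followup), "provenance")
  expect_error(reproducible_edges(ref$ggm$male$baseline,
                                  ref$bn$male$followup), "provenance")
})

test_that("temporal intersection reproduces the published BN overlaps", {
  m <- reproducible_edges(ref$bn$male$baseline, ref$bn$male$followup)
  expect_equal(nrow(m), 2)
  expect_setequal(paste(m$var_a, m$var_b, sep = "--"),
                  c("kyn--trp", "kyna--xa"))
  f <- reproducible_edges(ref$bn$female$baseline, ref$bn$female$followup)
  expect_equal(nrow(f), 7)
  expect_setequal(paste(f$var_a, f$var_b, sep = "--"),
                  c("iaa--iam", "icho--ipa", "iaa--kyna", "kyna--qa",
                    "hk--kyn", "haa--hk", "kyn--trp"))
})

test_that("cross-method consensus matches the published per-sex overlap", {
  ggm_m <- reproducible_edges(ref$ggm$male$baseline, ref$ggm$male$followup)
  bn_m <- reproducible_edges(ref$bn$male$baseline, ref$bn$male$followup)
  cons_m <- cross_method_consensus(ggm_m, bn_m)
  expect_setequal(paste(cons_m$var_a, cons_m$var_b, sep = "--"),
                  c("kyn--trp", "kyna--xa"))
  ggm_f <- reproducible_edges(ref$ggm$female$baseline,
                              ref$ggm$female$followup)
  bn_f <- reproducible_edges(ref$bn$female$baseline,
                             ref$bn$female$followup)
  cons_f <- cross_method_consensus(ggm_f, bn_f)
  expect_setequal(paste(cons_f$var_a, cons_f$var_b, sep = "--"),
                  c("iaa--kyna", "hk--kyn", "haa--hk"))
  # intersections are subsets of every input
  for (pair in list(list(cons_m, ggm_m), list(cons_m, bn_m),
                    list(cons_f, ggm_f), list(cons_f, bn_f))) {
    keys_sub <- paste(pair[[1]]$var_a, pair[[1]]$var_b)
    keys_sup <- paste(pair[[2]]$var_a, pair[[2]]$var_b)
    expect_true(all(keys_sub %in% keys_sup))
  }
  expect_equal(nrow(cross_method_consensus(ggm_m,
                                           edge_set(NULL, method = "bn",
                                                    sex = "male"))), 0)
  expect_error(cross_method_consensus(ggm_m, bn_f), "sex")
})

test_that("report arithmetic: possible pairs, percentages, panel", {
  rep <- consensus_report(
    male = list(ggm_baseline = ref$ggm$male$baseline,
                ggm_followup = ref$ggm$male$followup,
                bn_baseline = ref$bn$male$baseline,
                bn_followup = ref$bn$male$followup),
    female = list(ggm_baseline = ref$ggm$female$baseline,
                  ggm_followup = ref$ggm$female$followup,
                  bn_baseline = ref$bn$female$baseline,
                  bn_followup = ref$bn$female$followup),
    n_metabolites = 19,
    unadjusted_strong = ref$unadjusted$strong,
    unadjusted_nonzero = ref$unadjusted$nonzero)
  expect_equal(rep$counts$possible_pairs, 171)
  expect_equal(unname(rep$counts$consensus),
               c(2, 3, 5))
  expect_length(rep$metabolite_panel, 7)
  expect_setequal(rep$metabolite_panel,
                  c("trp", "kyn", "kyna", "hk", "haa", "xa", "iaa"))
  expect_equal(unname(rep$counts$unadjusted_pct_of_possible),
               c(4.1, 2.3))
  expect_equal(unname(rep$counts$strong_pct_of_nonzero[["male"]]), 8.5)
})

test_that("percentage rounding is half-up at one decimal", {
  expect_equal(round_half_up(100 * 7 / 82, 1), 8.5)
  expect_equal(round_half_up(100 * 7 / 171, 1), 4.1)
  expect_equal(round_half_up(100 * 4 / 171, 1), 2.3)
  expect_equal(round_half_up(2.35, 1), 2.4)  # plain round() would give 2.4/2.3
  expect_equal(round_half_up(-2.35, 1), -2.4)
  expect_equal(round_half_up(0, 1), 0)
})
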