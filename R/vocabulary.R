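#' Variable vocabulary: tryptophan metabolites and cohort covariates
#'
#' The default analysis vocabulary covers urinary tryptophan and 18 of its
#' downstream metabolites (kynurenine, serotonin and indole pathways), all
#' quantified in micromolar units, plus five non-metabolite covariates
#' (birth weight, birth length, BMI, and daily energy and protein intake).
#'
#' @param role Optional filter, `"metabolite"` or `"covariate"`.
#' @return A data.frame with columns `name` (short identifier used as the
#'   column name in cohort tables), `label` (full display name), `role`,
#'   `unit` and `pathway` (kynurenine / serotonin / indole / precursor for
#'   metabolites, `NA` for covariates).
#' @examples
#' nrow(trp_variables("metabolite"))  # 19
#' @export
trp_variables <- function(role = NULL) {
  v <- rbind(
    data.frame(
      name = c("trp", "pic", "qa", "kyna", "kyn", "xa", "aa", "haa",
               "hk", "ser", "hiaa", "htp", "iam", "iaa", "ila", "ipa",
               "icho", "ica", "trm"),
      label = c("tryptophan", "picolinic acid", "quinolinic acid",
                "kynurenic acid", "kynurenine", "xanthurenic acid",
                "anthranilic acid", "3-hydroxyanthranilic acid",
                "3-hydroxykynurenine", "serotonin",
                "5-hydroxyindole-3-acetic acid", "5-hydroxy-tryptophan",
                "indole-3-acetamide", "indole-3-acetic acid",
                "indole-3-lactic acid", "indole-3-propionic acid",
                "indole-3-carboxaldehyde", "indole-3-carboxylic acid",
                "tryptamine"),
      role = "metabolite",
      unit = "uM",
      pathway = c("precursor", "kynurenine", "kynurenine", "kynurenine",
                  "kynurenine", "kynurenine", "kynurenine", "kynurenine",
                  "kynurenine", "serotonin", "serotonin", "serotonin",
                  "indole", "indole", "indole", "indole", "indole",
                  "indole", "indole"),
      stringsAsFactors = FALSE
    ),
    data.frame(
      name = c("bw", "bl", "bmi", "energy", "protein"),
      label = c("birth weight", "birth length", "body mass index",
                "energy intake", "protein intake"),
      role = "covariate",
      unit = c("g", "cm", "kg/m2", "kcal/day", "g/day"),
      pathway = NA_character_,
      stringsAsFactors = FALSE
    )
  )
  if (!is.null(role)) {
    role <- match.arg(role, c("metabolite", "covariate"))
    v <- v[v$role == role, , drop = FALSE]
    rownames(v) <- NULL
  }
  v
}

#' Construct a variable specification table
#'
#' @param name Character vector of unique variable identifiers.
#' @param role `"metabolite"` or `"covariate"`, recycled.
#' @param unit Display unit, recycled.
#' @return A data.frame usable as the `variables` slot of a cohort table.
#' @export
variable_spec <- function(name, role = "metabolite", unit = NA_character_) {
  stopifnot(is.character(name), length(name) >= 1)
  if (anyDuplicated(name)) {
    stop("variable names must be unique: ",
         paste(unique(name[duplicated(name)]), collapse = ", "))
  }
  role <- rep_len(as.character(role), length(name))
  bad <- setdiff(unique(role), c("metabolite", "covariate"))
  if (length(bad)) stop("unknown role(s): ", paste(bad, collapse = ", "))
  data.frame(name = name, role = role,
             unit = rep_len(as.character(unit), length(name)),
             stringsAsFactors = FALSE)
}

# Study-scale log-normal marginal parameters for the 19 metabolites, derived
# from published medians and quartiles of 24-h urine concentrations (uM):
# meanlog = log(median), sdlog = (log q75 - log q25) / (2 * 0.6745).
trp_marginal_specs <- function() {
  med <- c(trp = 55.29, pic = 1.43, qa = 40.08, kyna = 20.1, kyn = 3.55,
           xa = 6.38, aa = 0.4, haa = 0.43, hk = 0.34, ser = 0.45,
           hiaa = 18.47, htp = 0.1, iam = 0.26, iaa = 30.72, ila = 1.29,
           ipa = 0.05, icho = 0.13, ica = 0.09, trm = 0.42)
  q25 <- c(trp = 37.23, pic = 1.23, qa = 27.44, kyna = 13.96, kyn = 1.92,
           xa = 3.92, aa = 0.27, haa = 0.25, hk = 0.05, ser = 0.32,
           hiaa = 13.85, htp = 0.07, iam = 0.18, iaa = 19.4, ila = 0.72,
           ipa = 0.04, icho = 0.08, ica = 0.07, trm = 0.29)
  q75 <- c(trp = 92.33, pic = 1.59, qa = 49.58, kyna = 28.73, kyn = 6.13,
           xa = 9.04, aa = 0.59, haa = 0.71, hk = 0.59, ser = 0.66,
           hiaa = 29.56, htp = 0.14, iam = 0.43, iaa = 42.67, ila = 2.02,
           ipa = 0.07, icho = 0.19, ica = 0.13, trm = 0.61)
  data.frame(name = names(med), meanlog = log(med),
             sdlog = (log(q75) - log(q25)) / (2 * 0.6745),
             stringsAsFactors = FALSE, row.names = NULL)
}
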