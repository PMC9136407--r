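## Seeded synthetic longitudinal cohorts with planted, optionally confounded,
## effects: the package's self-contained test bed. Structure mirrors a
## 160-infant, 6-visit case/control cohort with binary probiotic use
## correlated with disease, 3-level diet, delivery mode and visit age.

#' Configuration of a synthetic cohort
#'
#' Defaults encode the emulated study conditions: 160 subjects sampled at 6
#' visits, 50 compositional features, disease prevalence 0.5, and probiotic
#' use confounded with disease (P(probiotic | disease) = 0.6 vs 0.1 in
#' healthy subjects). Effects are planted on the arcsine-square-root (AST)
#' scale so fitted coefficients are directly comparable to the truth;
#' per-feature baseline AST values are drawn from \code{baseline_range},
#' chosen so the expected raw composition sums to about 1 and the final
#' renormalisation perturbs planted effects only at second order.
#'
#' @param n_subjects number of subjects.
#' @param visits_per_subject longitudinal visits per subject (visits are two
#'   months apart; age at visit v is 2v months plus jitter).
#' @param n_features number of compositional features.
#' @param disease_prevalence P(disease) per subject.
#' @param probiotic_given_disease,probiotic_given_healthy conditional
#'   probabilities of probiotic use; unequal values create confounding.
#' @param effects data.frame(feature, variable, level, beta): planted
#'   AST-scale effects. \code{level} is the affected level for categorical
#'   variables, \code{""} for continuous (beta is then a slope per unit).
#' @param subject_sd standard deviation of per-subject random intercepts
#'   (AST scale).
#' @param noise_sd residual standard deviation (AST scale).
#' @param baseline_range range of per-feature baseline AST values.
#' @param missing_probiotic fraction of subjects whose reported probiotic
#'   status is missing (the planted effect still uses the true status).
#' @param seed RNG seed; identical seeds give bit-identical cohorts.
#' @return a list of class \code{cohort_config}.
#' @export
cohort_config <- function(n_subjects = 160L, visits_per_subject = 6L,
                          n_features = 50L, disease_prevalence = 0.5,
                          probiotic_given_disease = 0.6,
                          probiotic_given_healthy = 0.1,
                          effects = default_effects(),
                          subject_sd = 0.06, noise_sd = 0.05,
                          baseline_range = c(0.08, 0.155),
                          missing_probiotic = 0.02, seed = 1L) {
  probs <- c(disease_prevalence, probiotic_given_disease,
             probiotic_given_healthy, missing_probiotic)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (subject_sd < 0 || noise_sd < 0) stop("standard deviations must be >= 0")
  if (!is.null(effects) && nrow(effects) &&
      !all(is.finite(effects$beta))) stop("effect coefficients must be finite")
  structure(list(n_subjects = as.integer(n_subjects),
                 visits_per_subject = as.integer(visits_per_subject),
                 n_features = as.integer(n_features),
                 disease_prevalence = disease_prevalence,
                 probiotic_given_disease = probiotic_given_disease,
                 probiotic_given_healthy = probiotic_given_healthy,
                 effects = effects,
                 subject_sd = subject_sd, noise_sd = noise_sd,
                 baseline_range = baseline_range,
                 missing_probiotic = missing_probiotic,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Default planted effects
#'
#' Three planted associations of realistic size on the AST scale: a disease
#' effect, an age slope, and a diet effect.
#'
#' @return data.frame(feature, variable, level, beta).
#' @export
default_effects <- function() {
  data.frame(feature = c("feature_01", "feature_02", "feature_03"),
             variable = c("disease", "age", "diet"),
             level = c("case", "", "formula"),
             beta = c(0.10, 0.008, 0.08),
             stringsAsFactors = FALSE)
}

cohort_variables <- c("disease", "probiotics", "delivery", "diet", "age")

#' Generate a synthetic longitudinal cohort
#'
#' Per subject, disease is drawn by prevalence, probiotic use conditional on
#' disease (the confounding channel), delivery mode and diet independently,
#' and a per-feature random intercept. Per sample, latent AST-scale
#' abundances are baseline + planted effects + subject intercept + Gaussian
#' noise, clamped to \eqn{[0, \pi/2]}, back-transformed by \eqn{\sin^2} to
#' relative abundances and renormalised to sum to 1. The same seed gives a
#' bit-identical table.
#'
#' @param config a \code{\link{cohort_config}}.
#' @return list with \code{table} (a \code{\link{sample_table}} whose schema
#'   declares subject as the random variable), \code{truth} (planted effects
#'   and variance components) and \code{config}.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  eff <- config$effects
  if (!is.null(eff) && nrow(eff)) {
    bad <- setdiff(unique(eff$variable), cohort_variables)
    if (length(bad))
      stop("effect map references unknown variables: ",
           paste(bad, collapse = ", "))
  }
  set.seed(config$seed)
  ns <- config$n_subjects; nv <- config$visits_per_subject
  nf <- config$n_features
  subjects <- sprintf("S%03d", seq_len(ns))
  disease <- ifelse(stats::runif(ns) < config$disease_prevalence,
                    "case", "control")
  p_pro <- ifelse(disease == "case", config$probiotic_given_disease,
                  config$probiotic_given_healthy)
  probiotics_true <- ifelse(stats::runif(ns) < p_pro, "yes", "no")
  delivery <- c("C-section", "vaginal")[1L +
    (stats::runif(ns) < 0.7)]                      # ~70% vaginal
  diet <- c("breastfed", "formula", "mixed")[
    1L + findInterval(stats::runif(ns), c(1 / 3, 2 / 3))]
  pro_missing <- stats::runif(ns) < config$missing_probiotic
  probiotics <- probiotics_true
  probiotics[pro_missing] <- NA_character_
  feats <- sprintf("feature_%02d", seq_len(nf))
  baseline <- stats::runif(nf, config$baseline_range[1L],
                           config$baseline_range[2L])
  u <- matrix(stats::rnorm(ns * nf, 0, config$subject_sd), ns, nf)
  n_samples <- ns * nv
  subj_idx <- rep(seq_len(ns), each = nv)
  visit <- rep(seq_len(nv), times = ns)
  age <- 2 * visit + stats::runif(n_samples, -0.5, 0.5)
  lat <- matrix(rep(baseline, each = n_samples), n_samples, nf) +
    u[subj_idx, , drop = FALSE] +
    matrix(stats::rnorm(n_samples * nf, 0, config$noise_sd), n_samples, nf)
  if (!is.null(eff) && nrow(eff)) {
    meta_true <- list(disease = disease[subj_idx],
                      probiotics = probiotics_true[subj_idx],
                      delivery = delivery[subj_idx],
                      diet = diet[subj_idx], age = age)
    for (k in seq_len(nrow(eff))) {
      j <- match(eff$feature[k], feats)
      if (is.na(j)) stop("effect map references unknown feature: ",
                         eff$feature[k])
      v <- meta_true[[eff$variable[k]]]
      lat[, j] <- lat[, j] + if (nzchar(eff$level[k])) {
        eff$beta[k] * (v == eff$level[k])
      } else {
        eff$beta[k] * as.numeric(v)
      }
    }
  }
  lat <- pmin(pmax(lat, 0), pi / 2)
  abund <- sin(lat)^2
  totals <- rowSums(abund)
  if (any(totals == 0)) abund[totals == 0, 1L] <- 1e-12   # degenerate guard
  abund <- abund / rowSums(abund)
  colnames(abund) <- feats
  ids <- sprintf("%s_V%d", subjects[subj_idx], visit)
  metadata <- data.frame(subject = subjects[subj_idx],
                         disease = disease[subj_idx],
                         probiotics = probiotics[subj_idx],
                         delivery = delivery[subj_idx],
                         diet = diet[subj_idx],
                         age = age, stringsAsFactors = FALSE)
  schema <- variable_schema(
    sample_id = "sample",
    random = "subject",
    fixed = c(disease = "categorical", probiotics = "categorical",
              delivery = "categorical", diet = "categorical",
              age = "continuous"))
  table <- sample_table(ids, metadata, abund, schema)
  list(table = table,
       truth = list(effects = eff, subject_sd = config$subject_sd,
                    noise_sd = config$noise_sd, baseline = stats::setNames(
                      baseline, feats)),
       config = config)
}

#' Generate the confounded probiotic/disease scenario
#'
#' One feature carries a planted probiotic effect (default +0.3 AST units on
#' \code{feature_01}) while probiotic use is correlated with disease through
#' the conditional probabilities of the config. The machine-readable
#' expectation states the confounder shift: a model without probiotics should
#' flag the feature on disease (q < 0.2), and a model including probiotics
#' should flag it on probiotics while the disease q-value inflates relative
#' to the first model.
#'
#' @param config a \code{\link{cohort_config}}; its effect map is replaced by
#'   the single probiotic effect unless it already plants one on probiotics.
#' @param probiotic_beta planted probiotic effect (AST scale) used when the
#'   config does not plant one.
#' @return list with \code{table}, \code{truth}, \code{models} (two
#'   \code{\link{model_spec}}s: \code{basic} and \code{with_probiotics}),
#'   \code{expectation} and \code{config}.
#' @export
confounder_scenario <- function(config = cohort_config(),
                                probiotic_beta = 0.3) {
  stopifnot(inherits(config, "cohort_config"))
  eff <- config$effects
  if (is.null(eff) || !nrow(eff) || !any(eff$variable == "probiotics")) {
    config$effects <- data.frame(feature = "feature_01",
                                 variable = "probiotics", level = "yes",
                                 beta = probiotic_beta,
                                 stringsAsFactors = FALSE)
  }
  coh <- generate_cohort(config)
  planted <- config$effects$feature[config$effects$variable == "probiotics"][1L]
  models <- list(
    basic = model_spec("basic", fixed = c("disease", "delivery", "age"),
                       random = "subject",
                       reference = list(disease = "control")),
    with_probiotics = model_spec("with_probiotics",
                                 fixed = c("disease", "delivery", "age",
                                           "probiotics"),
                                 random = "subject",
                                 reference = list(disease = "control")))
  expectation <- list(
    feature = planted,
    without_probiotics = "disease q < 0.2 (confounded attribution)",
    with_probiotics = paste("probiotics q < 0.2; disease q larger than in",
                            "the model without probiotics"))
  c(coh, list(models = models, expectation = expectation))
}

#' Write a generated cohort and its ground truth to TSV
#'
#' @param cohort output of \code{\link{generate_cohort}}.
#' @param table_path path for the merged sample table TSV.
#' @param truth_path optional path for the planted-effect table TSV.
#' @return \code{table_path}, invisibly.
#' @export
write_cohort <- function(cohort, table_path, truth_path = NULL) {
  write_sample_table(cohort$table, table_path, id_name = "sample")
  if (!is.null(truth_path)) {
    eff <- cohort$truth$effects
    if (is.null(eff)) eff <- data.frame(feature = character(),
                                        variable = character(),
                                        level = character(), beta = numeric())
    write_tsv(eff, truth_path)
  }
  invisible(table_path)
}
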