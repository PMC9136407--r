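# Independent oracles and small fixture builders used across tests.

# Brute-force step-up BH: for each observed p, minimise m*t/#{p <= t} over all
# observed thresholds t >= p. Independent of the package's adjustment path.
bh_brute <- function(p) {
  keep <- !is.na(p)
  obs <- p[keep]
  m <- length(obs)
  out <- rep(NA_real_, length(p))
  if (!m) return(out)
  cnt <- vapply(obs, function(t) sum(obs <= t), numeric(1))
  val <- m * obs / cnt
  out[keep] <- vapply(obs, function(pk) min(1, min(val[obs >= pk])),
                      numeric(1))
  out
}

# closed-form pooled (equal-variance) two-sample t-test p-value
pooled_t_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  2 * pt(-abs(tt), n1 + n2 - 2)
}

# closed-form Welch (unequal-variance) two-sample t-test p-value
welch_oracle_p <- function(a, b) {
  sa <- var(a) / length(a); sb <- var(b) / length(b)
  tt <- (mean(a) - mean(b)) / sqrt(sa + sb)
  df <- (sa + sb)^2 / (sa^2 / (length(a) - 1) + sb^2 / (length(b) - 1))
  2 * pt(-abs(tt), df)
}

# write a small merged table to a temp file and return the path
write_fixture_table <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

mini_schema <- function() {
  variable_schema(sample_id = "sid", random = character(),
                  fixed = c(group = "categorical", age = "continuous"))
}

# a small but non-trivial cohort for plumbing tests (defaults stay untouched)
small_cohort <- function(seed = 1L, ...) {
  generate_cohort(cohort_config(n_subjects = 24L, visits_per_subject = 3L,
                                n_features = 10L, seed = seed, ...))
}

# fabricate a minimal mbassoc_fit for comparison-module boundary tests
fake_fit <- function(name, results, sample_ids = c("s1", "s2")) {
  terms <- unique(results[c("variable", "level")])
  terms$term <- paste0(terms$variable, terms$level)
  structure(list(results = results,
                 spec = model_spec(name, fixed = unique(results$variable)),
                 terms = terms[c("term", "variable", "level")],
                 sample_ids = sample_ids),
            class = "mbassoc_fit")
}

fake_results <- function(feature, variable, level, q) {
  data.frame(feature = feature, variable = variable, level = level,
             reference = "", coefficient = 0, stderr = 1, p = q, q = q,
             n_used = 2L, status = "ok", stringsAsFactors = FALSE)
}
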