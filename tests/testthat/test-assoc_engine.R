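# helper: a design over explicit metadata, no preprocessing involved
design_for <- function(meta, fixed, random = character(),
                       reference = list(), kinds = NULL) {
  if (is.null(kinds))
    kinds <- vapply(meta[fixed], function(x)
      if (is.numeric(x)) "continuous" else "categorical", character(1))
  sch <- mbassoc:::resolve_schema(
    variable_schema("sid", random = random,
                    fixed = setNames(kinds, fixed)), meta)
  spec <- model_spec("t", fixed = fixed, random = random,
                     reference = reference)
  build_design(meta, spec, sch)
}

test_that("treatment coding: one indicator per non-reference level plus continuous columns", {
  meta <- data.frame(disease = c("case", "control", "case", "control"),
                     age = c(1, 2, 3, 4), stringsAsFactors = FALSE)
  d <- design_for(meta, c("disease", "age"),
                  reference = list(disease = "control"))
  expect_equal(d$terms$term, c("diseasecase", "age"))
  expect_equal(d$terms$reference, c("control", ""))

  meta2 <- data.frame(diet = rep(c("breastfed", "formula", "mixed"), 3),
                      stringsAsFactors = FALSE)
  d2 <- design_for(meta2, "diet")
  expect_equal(d2$terms$level, c("formula", "mixed"))  # ref = breastfed
  expect_equal(d2$terms$reference, c("breastfed", "breastfed"))
})

test_that("perfectly aliased variables are reported as a rank-deficiency error", {
  meta <- data.frame(a = rep(c("x", "y"), 5), b = rep(c("x", "y"), 5),
                     stringsAsFactors = FALSE)
  expect_error(design_for(meta, c("a", "b")), "aliased")
})

test_that("two-group OLS: coefficient is the group-mean difference, p the pooled t-test p", {
  meta <- data.frame(g = c("A", "A", "B", "B"), stringsAsFactors = FALSE)
  d <- design_for(meta, "g")
  y <- c(0.10, 0.20, 0.40, 0.50)
  r <- fit_feature(y, d)
  expect_equal(r$coefficient, 0.30, tolerance = 1e-12)
  expect_equal(r$p, pooled_t_p(y[3:4], y[1:2]), tolerance = 1e-10)

  # property: random two-group data agrees with the closed form to 1e-10
  set.seed(21)
  for (i in 1:25) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    meta_i <- data.frame(g = rep(c("A", "B"), c(n1, n2)),
                         stringsAsFactors = FALSE)
    y_i <- rnorm(n1 + n2)
    r_i <- fit_feature(y_i, design_for(meta_i, "g"))
    expect_equal(r_i$p, pooled_t_p(y_i[seq_len(n1)], y_i[-seq_len(n1)]),
                 tolerance = 1e-10)
  }
})

test_that("degenerate responses are flagged, not fatal", {
  meta <- data.frame(g = c("A", "A", "B", "B"), stringsAsFactors = FALSE)
  d <- design_for(meta, "g")
  expect_equal(fit_feature(rep(0.2, 4), d)$status, "skipped_constant")
  # saturated design: 3 rows, 3 fixed columns -> no residual df
  meta2 <- data.frame(g = c("A", "B", "A"), x = c(1.0, 2.0, 3.5),
                      stringsAsFactors = FALSE)
  d2 <- design_for(meta2, c("g", "x"))
  expect_equal(unique(fit_feature(c(0.1, 0.3, 0.2), d2)$status), "fit_failed")
})

test_that("with zero between-subject variance the mixed fit matches OLS within 1e-3", {
  set.seed(33)
  n_subj <- 40; per <- 4
  meta <- data.frame(subject = rep(sprintf("u%02d", 1:n_subj), each = per),
                     g = rep(sample(c("A", "B"), n_subj, replace = TRUE),
                             each = per),
                     x = rnorm(n_subj * per), stringsAsFactors = FALSE)
  y <- 0.5 + 0.3 * (meta$g == "B") + 0.2 * meta$x + rnorm(nrow(meta), 0, 0.1)
  sch <- mbassoc:::resolve_schema(
    variable_schema("sid", random = "subject",
                    fixed = c(g = "categorical", x = "continuous")), meta)
  d_mix <- build_design(meta, model_spec("m", fixed = c("g", "x"),
                                         random = "subject"), sch)
  d_ols <- build_design(meta, model_spec("o", fixed = c("g", "x")), sch)
  r_mix <- fit_feature(y, d_mix)
  r_ols <- fit_feature(y, d_ols)
  expect_equal(r_mix$status, c("ok", "ok"))
  expect_equal(r_mix$coefficient, r_ols$coefficient, tolerance = 1e-3)
})

test_that("BH adjustment matches the hand-enumerated example and passes NAs through", {
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03, 0.005)),
               c(0.02, 0.04, 0.04, 0.02))
  expect_equal(bh_adjust(0.5), 0.5)
  expect_equal(bh_adjust(rep(0.3, 7)), rep(0.3, 7))
  got <- bh_adjust(c(0.01, NA, 0.04))
  expect_true(is.na(got[2]))
  expect_equal(got[c(1, 3)], c(0.02, 0.04))  # family size 2, not 3
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH agrees with a brute-force step-up oracle on random vectors (property)", {
  set.seed(42)
  for (i in 1:300) {
    m <- sample(1:60, 1)
    p <- round(runif(m), sample(c(1, 2, 6), 1))  # rounding induces ties
    expect_equal(bh_adjust(p), bh_brute(p), tolerance = 1e-12)
  }
})

test_that("run_model tests every feature x term and pools one BH family", {
  coh <- small_cohort(seed = 3)
  spec <- model_spec("m", fixed = c("disease", "delivery", "age"))
  fit <- run_model(coh$table, spec)
  r <- fit$results
  # 10 features x terms [disease=control?, delivery=vaginal, age] -> 3 each
  expect_equal(nrow(r), ncol(fit$feature_matrix) * 3)
  ok <- r$status == "ok"
  expect_equal(r$q[ok], bh_brute(r$p)[ok], tolerance = 1e-12)
  expect_true(all(r$q[ok] >= r$p[ok] - 1e-12))
  expect_true(!is.unsorted(r$q[ok]))
})

test_that("a feature that is constant after preprocessing is skipped, not fatal", {
  meta <- data.frame(group = c("a", "a", "b", "b", "a", "b"),
                     stringsAsFactors = FALSE)
  # f1 is a constant 25% of every sample's total
  tot <- c(4, 8, 4, 8, 4, 8)
  f1 <- 0.25 * tot
  f2 <- c(1, 2, 1.5, 3, 0.5, 2.5)
  f3 <- tot - f1 - f2
  sch <- variable_schema("sid", fixed = c(group = "categorical"))
  tab <- sample_table(paste0("s", 1:6), meta,
                      cbind(f1 = f1, f2 = f2, f3 = f3), sch)
  fit <- run_model(tab, model_spec("m", fixed = "group"))
  r <- fit$results
  expect_equal(r$status[r$feature == "f1"], "skipped_constant")
  expect_true(is.na(r$p[r$feature == "f1"]))
  expect_true(all(r$status[r$feature != "f1"] == "ok"))
})

test_that("q-values do not depend on the order features are processed in", {
  coh <- small_cohort(seed = 8)
  spec <- model_spec("m", fixed = c("disease", "age"))
  f1 <- run_model(coh$table, spec)
  tab2 <- coh$table
  perm <- rev(seq_len(ncol(tab2$features)))
  tab2$features <- tab2$features[, perm]
  f2 <- run_model(tab2, spec)
  key <- function(r) paste(r$feature, r$variable, r$level)
  r1 <- f1$results; r2 <- f2$results
  expect_equal(r1$q[order(key(r1))], r2$q[order(key(r2))], tolerance = 1e-12)
})

test_that("fit accessors expose coefficients and results coherently", {
  coh <- small_cohort(seed = 5)
  fit <- run_model(coh$table, model_spec("m", fixed = c("disease", "age")))
  cm <- coef(fit)
  expect_equal(dim(cm), c(ncol(fit$feature_matrix), 2))
  r <- as.data.frame(fit)
  i <- which(r$feature == rownames(cm)[1] & r$variable == "age")
  expect_equal(unname(cm[1, "age"]), r$coefficient[i])
  expect_output(print(fit), "mbassoc_fit")
  expect_output(print(summary(fit)), "associations")
})
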