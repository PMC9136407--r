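# build a categorical detail record set directly (bypassing a model fit)
make_records <- function(y, x, extra = NULL) {
  lev <- c(sort(setdiff(unique(x), "NA")), if ("NA" %in% x) "NA")
  ref <- lev[1]
  rec <- data.frame(sample_id = paste0("s", seq_along(y)), y = y,
                    stringsAsFactors = FALSE)
  if (!is.null(extra)) rec <- cbind(rec, extra, stringsAsFactors = FALSE)
  rec$x <- factor(x, levels = lev)
  structure(rec, class = c("assoc_detail", "data.frame"),
            brackets = data.frame(level = setdiff(lev, c(ref, "NA")),
                                  reference = ref, coefficient = NA_real_,
                                  q = NA_real_, stringsAsFactors = FALSE),
            kind = "categorical", feature = "f", variable = "v", model = "m",
            levels = lev, reference = ref, ast = TRUE)
}

test_that("detail records keep NA-metadata samples as an explicit group outside the fit", {
  coh <- small_cohort(seed = 2, missing_probiotic = 0.3)
  fit <- run_model(coh$table,
                   model_spec("m", fixed = c("disease", "probiotics", "age")))
  rec <- association_detail(fit, "feature_04", "probiotics")
  expect_s3_class(rec, "assoc_detail")
  expect_equal(nrow(rec), fit$n_samples)            # every sample plotted
  expect_gt(fit$n_samples, fit$n_used)              # but not every sample fitted
  expect_true("NA" %in% levels(rec$x))
  expect_equal(sum(rec$x == "NA"), sum(is.na(fit$metadata$probiotics)))
  # y is the same transformed abundance the model saw
  expect_equal(rec$y, unname(fit$feature_matrix[, "feature_04"]))
  # brackets carry the run's q-values, significant or not
  br <- attr(rec, "brackets")
  r <- fit$results
  expect_equal(br$q, r$q[r$feature == "feature_04" & r$variable == "probiotics"])
})

test_that("continuous detail yields scatter-ready pairs without level brackets", {
  coh <- small_cohort(seed = 2)
  fit <- run_model(coh$table, model_spec("m", fixed = c("disease", "age")))
  rec <- association_detail(fit, "feature_05", "age")
  expect_equal(attr(rec, "kind"), "continuous")
  expect_true(is.numeric(rec$x))
  expect_equal(attr(rec, "brackets")$level, "")
  expect_error(association_detail(fit, "no_such_feature", "age"), "unknown feature")
  expect_error(association_detail(fit, "feature_05", "diet"), "not tested")
})

test_that("facet t-tests are Welch two-sided and match the closed form", {
  rec <- make_records(y = c(1, 2, 3, 4, 5, 6),
                      x = rep(c("A", "B"), each = 3),
                      extra = data.frame(fv = rep("one", 6)))
  out <- facet_ttest(rec, "fv")
  expect_equal(out$p, welch_oracle_p(c(1, 2, 3), c(4, 5, 6)), tolerance = 1e-10)
  expect_equal(out$status, "ok")

  # identical groups: zero mean difference, p = 1
  rec2 <- make_records(y = c(1, 2, 3, 1, 2, 3),
                       x = rep(c("A", "B"), each = 3),
                       extra = data.frame(fv = rep("one", 6)))
  expect_equal(facet_ttest(rec2, "fv")$p, 1, tolerance = 1e-12)

  # random small groups (property)
  set.seed(77)
  for (i in 1:30) {
    n1 <- sample(3:9, 1); n2 <- sample(3:9, 1)
    y <- rnorm(n1 + n2)
    rec_i <- make_records(y, rep(c("A", "B"), c(n1, n2)),
                          extra = data.frame(fv = rep("z", n1 + n2)))
    expect_equal(facet_ttest(rec_i, "fv")$p,
                 welch_oracle_p(y[seq_len(n1)], y[-seq_len(n1)]),
                 tolerance = 1e-10)
  }
})

test_that("a single-level facet variable reproduces the unfaceted pairwise tests", {
  set.seed(5)
  y <- rnorm(18)
  x <- rep(c("ctrl", "hi", "lo"), each = 6)
  rec <- make_records(y, x, extra = data.frame(fv = rep("all", 18)))
  out <- facet_ttest(rec, "fv")
  expect_equal(out$level, c("hi", "lo"))
  expect_equal(out$p[1], welch_oracle_p(y[x == "ctrl"], y[x == "hi"]),
               tolerance = 1e-12)
  expect_equal(out$p[2], welch_oracle_p(y[x == "ctrl"], y[x == "lo"]),
               tolerance = 1e-12)
})

test_that("the NA group never enters a statistic; tiny groups are untestable", {
  y <- c(1, 2, 3, 10, 11, 12, 100, 200, 300)
  x <- c("A", "A", "A", "B", "B", "B", "NA", "NA", "NA")
  rec <- make_records(y, x, extra = data.frame(fv = rep("one", 9)))
  out <- facet_ttest(rec, "fv")
  expect_equal(nrow(out), 1L)                       # only A vs B, never NA
  expect_equal(out$p, welch_oracle_p(y[1:3], y[4:6]), tolerance = 1e-12)

  rec2 <- make_records(c(1, 2, 3, 9), c("A", "A", "A", "B"),
                       extra = data.frame(fv = rep("one", 4)))
  out2 <- facet_ttest(rec2, "fv")
  expect_equal(out2$status, "untestable")
  expect_true(is.na(out2$p))

  # facet panels ordered with the NA panel last
  rec3 <- make_records(rnorm(12), rep(c("A", "B"), 6),
                       extra = data.frame(fv = rep(c("x", "NA", "w"), each = 4)))
  expect_equal(unique(facet_ttest(rec3, "fv")$facet), c("w", "x", "NA"))
})

test_that("detail rendering writes box/scatter figures and returns the stats shown", {
  coh <- small_cohort(seed = 4, missing_probiotic = 0.2)
  fit <- run_model(coh$table,
                   model_spec("m", fixed = c("disease", "diet", "age")))
  rec <- association_detail(fit, "feature_03", "diet")
  pdf_path <- tempfile(fileext = ".pdf")
  shown <- render_detail(rec, file = pdf_path)
  expect_true(file.exists(pdf_path) && file.size(pdf_path) > 0)
  expect_equal(shown$q,
               attr(rec, "brackets")$q)            # unfaceted: model q-values
  png_path <- tempfile(fileext = ".png")
  shown_f <- render_detail(rec, file = png_path, facet = "probiotics",
                           color = "disease", label = "subject")
  expect_true(file.exists(png_path) && file.size(png_path) > 0)
  expect_true("p" %in% names(shown_f))             # faceted: Welch t-test p
  expect_false("q" %in% names(shown_f))
  cont <- association_detail(fit, "feature_02", "age")
  pdf2 <- tempfile(fileext = ".pdf")
  render_detail(cont, file = pdf2, color = "diet")
  expect_true(file.exists(pdf2) && file.size(pdf2) > 0)
})
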