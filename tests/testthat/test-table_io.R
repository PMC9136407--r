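test_that("minimal TSV parses with typed columns, and CSV gives the identical parse", {
  tsv <- write_fixture_table(c("sid\tgroup\tfA", "s1\tcase\t0.4", "s2\tctrl\t0.6"))
  raw <- read_merged_table(tsv)
  expect_s3_class(raw, "mb_raw_table")
  expect_equal(raw$sample_ids, c("s1", "s2"))
  expect_type(raw$columns$group, "character")
  expect_type(raw$columns$fA, "double")

  csv <- write_fixture_table(c("sid,group,fA", "s1,case,0.4", "s2,ctrl,0.6"),
                             ext = ".csv")
  raw2 <- read_merged_table(csv)
  expect_equal(raw2$sample_ids, raw$sample_ids)
  expect_equal(raw2$columns, raw$columns)
})

test_that("delimiter is sniffed from the header when the extension is uninformative", {
  txt <- write_fixture_table(c("sid\tgroup\tfA", "s1\tcase\t0.4",
                               "s2\tctrl\t0.6"), ext = ".txt")
  expect_equal(read_merged_table(txt)$sample_ids, c("s1", "s2"))
  amb <- write_fixture_table(c("sid,a\tb,c\td", "x,1\t2,3\t4", "y,5\t6,7\t8"),
                             ext = ".txt")
  expect_error(read_merged_table(amb), "delimiter")
})

test_that("missing-value tokens are read as NA in both string and numeric columns", {
  tsv <- write_fixture_table(c("sid\tgroup\tfA\tfB",
                               "s1\tNA\t0.4\t1",
                               "s2\tctrl\tNaN\t2",
                               "s3\tna\t0.1\t3"))
  raw <- read_merged_table(tsv)
  expect_true(is.na(raw$columns$group[1]))
  expect_true(is.na(raw$columns$group[3]))
  expect_true(is.na(raw$columns$fA[2]))
})

test_that("a column mixing numbers and strings errors, naming column and row", {
  tsv <- write_fixture_table(c("sid\tv\tfA", "s1\t1\t0.1", "s2\t2\t0.2",
                               "s3\tx\t0.3"))
  expect_error(read_merged_table(tsv), "column 'v'.*row 3")
})

test_that("malformed inputs are rejected: duplicate IDs, too few rows/columns", {
  dup <- write_fixture_table(c("sid\tg\tf", "s1\ta\t1", "s1\tb\t2"))
  expect_error(read_merged_table(dup), "duplicate sample IDs")
  short <- write_fixture_table(c("sid\tg\tf", "s1\ta\t1"))
  expect_error(read_merged_table(short), "2 data rows")
  narrow <- write_fixture_table(c("sid\tf", "s1\t1", "s2\t2"))
  expect_error(read_merged_table(narrow), "3 columns")
})

test_that("partition assigns schema columns to metadata and the rest to features", {
  n <- 6
  lines <- c(paste(c("sid", "group", "age", paste0("f", 1:4)), collapse = "\t"),
             vapply(1:n, function(i) paste(c(paste0("s", i),
                                             c("a", "b")[1 + i %% 2], i * 10,
                                             round(runif(4), 3)),
                                           collapse = "\t"), character(1)))
  raw <- read_merged_table(write_fixture_table(lines))
  tab <- partition_columns(raw, mini_schema())
  expect_s3_class(tab, "sample_table")
  expect_equal(ncol(tab$features), 4)
  expect_setequal(names(tab$metadata), c("group", "age"))
  expect_equal(tab$n_samples, n)
})

test_that("degenerate partitions error: no features, string feature, missing schema column", {
  lines <- c("sid\tgroup\tage", "s1\ta\t1", "s2\tb\t2")
  raw <- read_merged_table(write_fixture_table(lines))
  expect_error(partition_columns(raw, mini_schema()), "no feature columns")

  lines2 <- c("sid\tgroup\tage\tnote", "s1\ta\t1\thigh", "s2\tb\t2\tlow")
  raw2 <- read_merged_table(write_fixture_table(lines2))
  expect_error(partition_columns(raw2, mini_schema()), "note")

  lines3 <- c("sid\tgroup\tf1", "s1\ta\t1", "s2\tb\t2")
  raw3 <- read_merged_table(write_fixture_table(lines3))
  sch <- variable_schema("sid", fixed = c(group = "categorical",
                                          weight = "continuous"))
  expect_error(partition_columns(raw3, sch), "weight")
})

test_that("write + re-read round-trips a sample table (property, several seeds)", {
  for (seed in 1:4) {
    set.seed(seed)
    n <- 5 + seed
    meta <- data.frame(group = sample(c("a", "b", "c"), n, replace = TRUE),
                       age = round(runif(n, 1, 12), 4),
                       stringsAsFactors = FALSE)
    feats <- matrix(round(runif(n * 3), 6), n,
                    dimnames = list(NULL, c("f1", "f2", "f3")))
    sch <- variable_schema("sid", fixed = c(group = "categorical",
                                            age = "continuous"))
    tab <- sample_table(paste0("s", 1:n), meta, feats, sch)
    path <- tempfile(fileext = ".tsv")
    write_sample_table(tab, path, id_name = "sid")
    tab2 <- partition_columns(read_merged_table(path), sch)
    expect_equal(tab2$sample_ids, tab$sample_ids)
    expect_equal(tab2$metadata$group, tab$metadata$group)
    expect_equal(tab2$metadata$age, tab$metadata$age, tolerance = 1e-12)
    expect_equal(unname(tab2$features), unname(tab$features), tolerance = 1e-12)
  }
})
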