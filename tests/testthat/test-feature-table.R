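test_that("construction validates shape, IDs and labels", {
  v <- matrix(1:6, 3, 2, dimnames = list(c("a", "b", "c"), c("x", "y")))
  v[] <- as.numeric(v)
  tab <- feature_table(v, c("Case", "Control", "Case"))
  expect_s3_class(tab, "feature_table")
  expect_equal(dim(tab), c(3L, 2L))
  expect_false(any(tab$synthetic))

  expect_error(feature_table(v, c("Case", "Control")), "one entry per sample")
  expect_error(feature_table(v, c("Case", "Control", "case")), "case")
  v_na <- v; v_na[2, 1] <- NA
  expect_error(feature_table(v_na, c("Case", "Control", "Case")), "missing")
  v_dup <- v; rownames(v_dup) <- c("a", "a", "c")
  expect_error(feature_table(v_dup, c("Case", "Control", "Case")),
               "duplicate sample IDs")
})

test_that("write then read is the identity on values, IDs and labels", {
  tab <- tiny_table(5, 3)
  tab$values[1, 1] <- 1 / 3   # exercise full-precision printing
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tab, path)
  back <- read_feature_table(path)
  expect_identical(back$values, tab$values)
  expect_identical(back$labels, tab$labels)
  expect_identical(rownames(back$values), rownames(tab$values))
})

test_that("synthetic flags survive a round trip when present", {
  tab <- tiny_table(4, 3)
  tab$synthetic <- c(FALSE, FALSE, TRUE, FALSE)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tab, path)
  expect_identical(read_feature_table(path)$synthetic, tab$synthetic)
})

test_that("reader rejects non-numeric cells naming the position", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,M1,M2,label",
               "s1,1.5,2.0,Case",
               "s2,NA,3.0,Control"), path)
  expect_error(read_feature_table(path), "sample 's2', feature 'M1'")
})

test_that("reader maps labels explicitly and transposes on request", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,M1,M2,label",
               "s1,1,2,bacterial",
               "s2,3,4,healthy"), path)
  tab <- read_feature_table(path, label_map = c(bacterial = "Case",
                                                healthy = "Control"))
  expect_equal(as.character(tab$labels), c("Case", "Control"))
  expect_error(read_feature_table(path, label_map = c(bacterial = "Case")),
               "healthy")

  # samples in columns: features down the first column
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("feature,s1,s2", "M1,1,3", "M2,2,4", "label,Case,Control"), path2)
  tab2 <- read_feature_table(path2, orientation = "samples_in_columns")
  expect_equal(unname(tab2$values), matrix(c(1, 3, 2, 4), 2, 2))
  expect_equal(as.character(tab2$labels), c("Case", "Control"))
})

test_that("writing an empty table is refused", {
  tab <- tiny_table(3, 2)
  empty <- tab[integer(0), ]
  expect_error(write_feature_table(empty, tempfile()), "empty")
})

test_that("report serialization is deterministic and round-trips, NaN -> null", {
  rep1 <- list(auc = 0.9, counts = list(tp = 3L, fn = 1L),
               rate_undefined = NaN, label = "none")
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_report(rep1, p1)
  write_report(rep1, p2)
  expect_identical(readLines(p1), readLines(p2))
  back <- read_report(p1)
  expect_equal(back$auc, 0.9)
  expect_equal(back$counts$tp, 3L)
  expect_null(back$rate_undefined)
})
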