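test_that("TSV round trip is identity and row-sum detection tags the space", {
  ft <- fx_small_ft()
  expect_identical(space_tag(ft), "relative")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(ft, path)
  back <- read_feature_table(path)
  expect_identical(space_tag(back), "relative")
  expect_equal(unclass(back), unclass(ft), tolerance = 1e-12)
  expect_identical(colnames(back), colnames(ft))

  # counts detection
  cm <- unclass(ft) * c(100, 200, 50)
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(feature_table(cm, "counts"), path2)
  expect_identical(space_tag(read_feature_table(path2)), "counts")
})

test_that("transposed dialect reads to the identical table", {
  ft <- fx_small_ft()
  df <- data.frame(taxon = colnames(ft), t(unclass(ft)), check.names = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  data.table::fwrite(df, path, sep = "\t")
  back <- read_feature_table(path, dialect = "tsv_taxa_by_samples")
  expect_equal(unclass(back), unclass(ft), tolerance = 1e-12)
})

test_that("BIOM-JSON dialect reads through biomformat", {
  skip_if_not_installed("biomformat")
  ft <- fx_small_ft()
  cm <- round(unclass(ft) * 1000)
  b <- biomformat::make_biom(t(cm))  # biom stores taxa x samples
  path <- withr::local_tempfile(fileext = ".biom")
  biomformat::write_biom(b, path)
  back <- read_feature_table(path, dialect = "biom_json")
  expect_equal(unclass(back)[rownames(cm), colnames(cm)], cm, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("duplicate ids and negative values are hard errors naming offenders", {
  m <- matrix(1, 2, 2, dimnames = list(c("a", "a"), c("k__X", "k__Y")))
  expect_error(feature_table(m, "counts"), "a")
  m2 <- matrix(c(-1, 1, 1, 1), 2, 2,
               dimnames = list(c("a", "b"), c("k__X", "k__Y")))
  expect_error(feature_table(m2, "counts"), "negative")
})

test_that("align_union pads zeros, sorts the union axis, and is idempotent", {
  m1 <- matrix(c(0.6, 0.4), 1, 2, dimnames = list("s1", c("k__A", "k__B")))
  m2 <- matrix(c(0.7, 0.3), 1, 2, dimnames = list("s2", c("k__B", "k__C")))
  out <- align_union(list(feature_table(m1, "relative"), feature_table(m2, "relative")))
  expect_identical(colnames(out[[1]]), c("k__A", "k__B", "k__C"))
  expect_identical(colnames(out[[2]]), colnames(out[[1]]))
  expect_equal(unname(unclass(out[[2]])[, "k__A"]), 0)
  expect_equal(rowSums(out[[1]]), c(s1 = 1))  # zero padding keeps closure
  # idempotent
  again <- align_union(out)
  expect_equal(again, out)
  # single table unchanged
  one <- align_union(list(feature_table(m1, "relative")))
  expect_equal(unclass(one[[1]]), m1, ignore_attr = TRUE)
  # order-insensitive up to the deterministic axis
  swapped <- align_union(list(feature_table(m2, "relative"), feature_table(m1, "relative")))
  expect_equal(unclass(swapped[[2]]), unclass(out[[1]]))
  # conflicting spaces refuse
  expect_error(align_union(list(feature_table(m1, "relative"),
                                feature_table(m2 * 10, "counts"))), "space tags")
})

test_that("write_results round-trips JSON records and writes keyed TSV", {
  rec <- list(model = "rf", scc = 0.6543, folds = c(1, 2, 3))
  path <- withr::local_tempfile(fileext = ".json")
  write_results(rec, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$scc, rec$scc)
  expect_equal(back$folds, rec$folds)

  df <- data.frame(sample_id = c("d1", "d2"), prediction = c(4.2, 3.9))
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_results(df, path2)
  back2 <- data.table::fread(path2, data.table = FALSE)
  expect_equal(back2, df)
})

test_that("metadata validation enforces the donor/recipient contract", {
  md <- data.frame(sample_id = c("d1", "r1"), subject_id = c("D1", "R1"),
                   role = c("donor", "recipient"), donor_id = c(NA, "D1"),
                   cohort_id = "c1", days_post_fmt = c(NA, 7))
  expect_silent(validate_sample_metadata(md))
  bad <- md; bad$donor_id[2] <- NA
  expect_error(validate_sample_metadata(bad), "donor_id")
  bad2 <- md; bad2$days_post_fmt[1] <- 3
  expect_error(validate_sample_metadata(bad2), "donor rows")
})
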