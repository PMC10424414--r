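test_that("merge_to_level follows sum and mean semantics", {
  m <- matrix(c(0.5, 0.3, 0.2), 1, 3, dimnames = list("s1", fx_taxa3()))
  ft <- feature_table(m, "relative")
  s <- merge_to_level(ft, "order", "sum")
  o1 <- "k__B;p__P1;c__C;o__O"
  expect_equal(unclass(s)[1, o1], 0.8, tolerance = 1e-12)
  mn <- merge_to_level(ft, "order", "mean")
  expect_equal(unclass(mn)[1, o1], 0.4, tolerance = 1e-12)
})

test_that("merge conserves totals (sum) and mean = sum / member count", {
  taxa <- fx_random_taxa(25, seed = 4)
  m <- with_seed(9, matrix(rexp(5 * 25), 5, 25,
                           dimnames = list(paste0("s", 1:5), taxa)))
  ft <- feature_table(m, "counts")
  s <- merge_to_level(ft, "order", "sum")
  expect_equal(rowSums(s), rowSums(ft), tolerance = 1e-10)
  mn <- merge_to_level(ft, "order", "mean")
  # oracle: group sizes by truncating strings independently
  key <- vapply(strsplit(taxa, ";", fixed = TRUE),
                function(l) paste(l[1:4], collapse = ";"), character(1))
  sizes <- table(key)[colnames(s)]
  expect_equal(unclass(mn), sweep(unclass(s), 2, as.numeric(sizes), "/"),
               tolerance = 1e-12)
})

test_that("normalization matches the closed forms and refuses double transforms", {
  m <- matrix(c(2, 2), 1, 2, dimnames = list("s1", c("k__A", "k__B")))
  ft <- feature_table(m, "counts")
  out <- normalize_table(ft, prep_recipe(log_epsilon = 1e-4))
  expect_equal(unclass(out)[1, ], rep(log10(0.5001), 2), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_identical(space_tag(out), "log_normalized")
  expect_error(normalize_table(out), "already log-normalized")

  # zero cell maps to log10(epsilon)
  m2 <- matrix(c(1, 0), 1, 2, dimnames = list("s1", c("k__A", "k__B")))
  out2 <- normalize_table(feature_table(m2, "counts"))
  expect_equal(unclass(out2)[1, "k__B"], -4, tolerance = 1e-9)

  # all-zero row names the sample
  m3 <- rbind(m2, bad = c(0, 0)); rownames(m3)[1] <- "ok"
  expect_error(normalize_table(feature_table(m3, "counts")), "bad")
})

test_that("z-scored columns standardize on request and freeze stats", {
  taxa <- fx_random_taxa(10, seed = 2)
  m <- with_seed(3, matrix(rexp(80), 8, 10, dimnames = list(paste0("s", 1:8), taxa)))
  rec <- prep_recipe(zscore = TRUE)
  out <- normalize_table(feature_table(m, "counts"), rec)
  expect_equal(unname(colMeans(out)), rep(0, 10), tolerance = 1e-9)
  expect_equal(unname(apply(out, 2, sd)), rep(1, 10), tolerance = 1e-9)
  # frozen stats reapply unchanged to new data
  st <- attr(out, "norm_stats")
  out2 <- normalize_table(feature_table(m[1:3, ], "counts"), rec, stats = st)
  expect_equal(unclass(out2), unclass(out)[1:3, ], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("normalization is monotone per row", {
  m <- matrix(c(5, 1, 3, 0.5), 1, 4,
              dimnames = list("s", paste0("k__T", 1:4)))
  out <- normalize_table(feature_table(m, "counts"))
  expect_identical(order(unclass(out)[1, ]), order(m[1, ]))
})

test_that("shannon diversity matches closed forms and invariances", {
  expect_equal(shannon_diversity(rep(1, 10)), log(10), tolerance = 1e-12)
  expect_equal(shannon_diversity(c(0.5, 0.5)), log(2), tolerance = 1e-12)
  expect_equal(shannon_diversity(c(0, 1, 0)), 0)
  expect_error(shannon_diversity(c(0, 0)), "all-zero")
  p <- with_seed(5, runif(12))
  expect_equal(shannon_diversity(p), shannon_diversity(rev(p)), tolerance = 1e-12)
  expect_equal(shannon_diversity(p), shannon_diversity(p * 17), tolerance = 1e-12)
  expect_equal(shannon_diversity(rep(1, 8), base = 2), 3, tolerance = 1e-12)
})

test_that("covariate assembly imputes medians and flags imputation", {
  md <- data.frame(sample_id = paste0("d", 1:3), subject_id = paste0("D", 1:3),
                   role = "donor", donor_id = NA, cohort_id = "c1",
                   days_post_fmt = NA, age = c(30, 40, NA))
  cv <- assemble_covariates(md, md$sample_id, impute_policy = "cohort_median")
  expect_true(cv$imputed[3, "age"])
  # imputed value is the cohort median (35), checked on the destandardized scale
  raw <- cv$x[, "age"] * cv$stats$scale["age"] + cv$stats$center["age"]
  expect_equal(unname(raw[3]), 35)
  expect_equal(mean(cv$x[, "age"]), 0, tolerance = 1e-9)
  expect_error(assemble_covariates(md, md$sample_id, impute_policy = "drop"),
               "age")
  # complete data under drop passes through (standardized)
  md2 <- md; md2$age[3] <- 50
  cv2 <- assemble_covariates(md2, md2$sample_id, impute_policy = "drop")
  expect_false(any(cv2$imputed))
})
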