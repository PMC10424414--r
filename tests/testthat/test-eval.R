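test_that("grouped folds partition recipients without splitting subjects", {
  b <- fx_cohort("timepoints", n_taxa = 30, n_orders = 4, n_donors = 10,
                 recipients_per_donor = 2, timepoints = c(7, 14, 30), seed = 8)
  plan <- grouped_kfold(b, k = 10, seed = 4)
  subs <- unique(pairing_subjects(b))  # 20 recipients -> folds of 2
  expect_setequal(names(plan$fold), subs)
  expect_true(all(table(plan$fold) == 2))
  # a recipient with several timepoints keeps all samples in one fold
  pairs <- fmtforge:::.task_labels(prediction_task("shannon"), b)
  f <- plan$fold[pairs$subject]
  expect_true(all(tapply(f, pairs$subject, function(v) length(unique(v))) == 1))
  # deterministic per seed, different across seeds
  expect_identical(plan$fold, grouped_kfold(b, k = 10, seed = 4)$fold)
  expect_false(identical(plan$fold, grouped_kfold(b, k = 10, seed = 5)$fold))
  expect_error(grouped_kfold(b, k = 25, seed = 1), "fewer recipients")
})

test_that("cross-validation scores held-out samples only and reports fold SE", {
  b <- fx_cohort("model_cohort")
  plan <- grouped_kfold(b, k = 5, seed = 2)
  cv <- cross_validate(prediction_task("shannon", horizon = 7), b, "ridge",
                       plan = plan, seed = 2)
  expect_identical(nrow(cv$per_fold), 5L)
  expect_true(is.finite(cv$scc["mean"]) && is.finite(cv$scc["se"]))
  # every sample scored exactly once, and never with its own training fold
  expect_identical(sort(cv$predictions$recipient_sample),
                   sort(b$pairing$recipient_sample))
  f <- plan$fold[pairing_subjects(b)]
  scored_fold <- cv$predictions$fold[match(b$pairing$recipient_sample,
                                           cv$predictions$recipient_sample)]
  expect_identical(as.integer(scored_fold), as.integer(unname(f)))
})

test_that("label permutation drives held-out R2 to zero or below", {
  b <- fx_cohort("model_cohort")
  # shuffle outcomes by permuting the pairing's recipient labels
  perm <- b
  with_seed(99, {
    idx <- sample(nrow(perm$recipients))
  })
  shuf <- unclass(perm$recipients)[idx, , drop = FALSE]
  rownames(shuf) <- rownames(perm$recipients)
  perm$recipients <- feature_table(shuf, "relative")
  cv <- cross_validate(prediction_task("shannon", horizon = 7), perm, "ridge",
                       plan = grouped_kfold(perm, k = 5, seed = 3), seed = 3)
  expect_lt(cv$r2["mean"], 0.1)
  expect_lt(abs(cv$scc["mean"]), 0.25)
})

test_that("LODO trains strictly outside the held-out cohort", {
  b1 <- generate_cohort(synth_config(n_taxa = 30, n_orders = 4, n_donors = 15,
                                     recipients_per_donor = 2, seed = 61,
                                     cohort_id = "cohA"))
  b2 <- generate_cohort(synth_config(n_taxa = 30, n_orders = 4, n_donors = 15,
                                     recipients_per_donor = 2, seed = 62,
                                     cohort_id = "cohB"))
  # merge the two cohorts into one bundle (shared generator => shared taxa)
  don <- rbind(unclass(b1$donors), unclass(b2$donors))
  rownames(don) <- c(paste0("A_", rownames(b1$donors)), paste0("B_", rownames(b2$donors)))
  rec <- rbind(unclass(b1$recipients), unclass(b2$recipients))
  rownames(rec) <- c(paste0("A_", rownames(b1$recipients)), paste0("B_", rownames(b2$recipients)))
  fixmd <- function(md, tag) {
    md$sample_id <- paste0(tag, md$sample_id)
    md$subject_id <- paste0(tag, md$subject_id)
    md$donor_id <- ifelse(is.na(md$donor_id), NA, paste0(tag, md$donor_id))
    md
  }
  md <- rbind(fixmd(b1$metadata, "A_"), fixmd(b2$metadata, "B_"))
  bb <- cohort_bundle(feature_table(don, "relative"), feature_table(rec, "relative"), md)
  res <- lodo_evaluate(prediction_task("shannon", horizon = 7), bb, "cohB",
                       model_kind = "ridge", seed = 1)
  # all scored samples come from the held-out cohort
  scored <- res$predictions$recipient_sample
  expect_true(all(bb$metadata$cohort_id[match(scored, bb$metadata$sample_id)] == "cohB"))
  expect_error(lodo_evaluate(prediction_task("shannon"), bb, "nope"), "unknown cohort")
})

test_that("model comparison runs ANOVA then one-sided tests against the best", {
  mk <- function(v) {
    structure(list(per_fold = data.frame(fold = seq_along(v), n = 10,
                                         skipped = FALSE, r2 = NA, scc = v,
                                         auc = NA)), class = "eval_metrics")
  }
  # clearly separated models
  sep <- list(good = mk(c(0.8, 0.82, 0.79, 0.81, 0.80)),
              bad = mk(c(0.40, 0.42, 0.39, 0.41, 0.40)),
              mid = mk(c(0.60, 0.62, 0.59, 0.61, 0.60)))
  rep1 <- compare_models(sep)
  expect_lt(rep1$anova_p, 0.05)
  expect_identical(rep1$best_model, "good")
  expect_true(all(rep1$pairwise$p_one_sided < 0.05))
  # near-identical metric vectors: no pairwise tests
  same <- list(a = mk(c(0.5, 0.6, 0.55, 0.52, 0.58)),
               b = mk(c(0.5, 0.6, 0.55, 0.52, 0.58) + 1e-6))
  rep2 <- compare_models(same)
  expect_gt(rep2$anova_p, 0.9)
  expect_null(rep2$pairwise)
  # fold-order invariance
  swapped <- list(good = mk(rev(c(0.8, 0.82, 0.79, 0.81, 0.80))),
                  bad = mk(rev(c(0.40, 0.42, 0.39, 0.41, 0.40))),
                  mid = mk(rev(c(0.60, 0.62, 0.59, 0.61, 0.60))))
  rep3 <- compare_models(swapped)
  expect_equal(rep3$anova_f, rep1$anova_f, tolerance = 1e-12)
  expect_error(compare_models(list(a = mk(1:3 / 10), b = mk(1:4 / 10))),
               "unequal")
})

test_that("time-stratified SCC tracks the generator's decay", {
  task <- prediction_task("shannon")
  # no decay: per-bin SCCs similar
  b0 <- fx_cohort("timepoints")
  cv0 <- cross_validate(task, b0, "rf", plan = grouped_kfold(b0, 4, 1), seed = 1)
  tab0 <- scc_by_time(task, b0, cv = cv0)
  expect_identical(nrow(tab0), 3L)
  expect_lt(diff(range(tab0$scc)), 0.45)
  # strong decay: accuracy falls with time
  bd <- fx_cohort("decay", n_taxa = 30, n_orders = 4, n_donors = 40,
                  recipients_per_donor = 3, timepoints = c(7, 60),
                  delta = 0.8, rho = 0.05, tau = 0.05, seed = 9)
  cvd <- cross_validate(task, bd, "rf", plan = grouped_kfold(bd, 4, 1), seed = 1)
  tabd <- scc_by_time(task, bd, cv = cvd)
  expect_gt(tabd$scc[1], tabd$scc[2])
})

test_that("metric identities hold: AUC flip, SCC monotone invariance", {
  set.seed(7)
  y <- rbinom(40, 1, 0.5)
  s <- runif(40) + 0.3 * y
  expect_equal(metric_auc(y, s) , 1 - metric_auc(1 - y, s), tolerance = 1e-12)
  x <- rnorm(30); z <- rnorm(30)
  expect_equal(metric_scc(x, z), metric_scc(x, exp(z)), tolerance = 1e-12)
  expect_equal(metric_scc(x, x^3), 1, tolerance = 1e-12)
  # R2 of the mean predictor is 0
  expect_equal(metric_r2(x, rep(mean(x), 30)), 0, tolerance = 1e-12)
})
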