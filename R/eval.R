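#' Recipient-grouped k-fold plan
#'
#' Partitions recipient subjects into `k` near-equal folds so that all samples
#' of one recipient stay in one fold, preventing leakage between training and
#' held-out data.
#'
#' @param bundle A [cohort_bundle()].
#' @param k Number of folds (default 10).
#' @param seed Integer seed; the plan is deterministic per seed.
#' @return A `fold_plan`: list with `fold` (named integer vector, one entry
#'   per recipient subject), `k`, `seed`.
#' @export
grouped_kfold <- function(bundle, k = 10, seed = 1) {
  subjects <- unique(pairing_subjects(bundle))
  if (length(subjects) < k)
    stop("fewer recipients (", length(subjects), ") than folds (", k, ")", call. = FALSE)
  shuffled <- with_seed(seed, sample(subjects))
  fold <- stats::setNames(rep_len(seq_len(k), length(shuffled)), shuffled)
  structure(list(fold = fold, k = k, seed = seed), class = "fold_plan")
}

.fold_masks <- function(plan, pairs) {
  f <- plan$fold[pairs$subject]
  lapply(seq_len(plan$k), function(i) which(f == i))
}

.subset_bundle <- function(bundle, recipient_samples) {
  b <- bundle
  b$pairing <- bundle$pairing[bundle$pairing$recipient_sample %in% recipient_samples, ,
                              drop = FALSE]
  b
}

.fold_metrics <- function(truth, pred, binary) {
  if (binary) {
    list(auc = metric_auc(truth, pred), r2 = NA_real_,
         scc = suppressWarnings(metric_scc(truth, pred)))
  } else {
    list(auc = NA_real_, r2 = metric_r2(truth, pred), scc = metric_scc(truth, pred))
  }
}

.summarize_folds <- function(per_fold, plan_info) {
  agg <- function(v) {
    v <- v[is.finite(v)]
    if (!length(v)) return(c(mean = NA_real_, se = NA_real_))
    c(mean = mean(v), se = stats::sd(v) / sqrt(length(v)))
  }
  structure(list(per_fold = per_fold,
                 r2 = agg(per_fold$r2), scc = agg(per_fold$scc),
                 auc = agg(per_fold$auc), plan = plan_info),
            class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat("<eval_metrics>\n")
  for (m in c("r2", "scc", "auc")) {
    if (is.finite(x[[m]]["mean"]))
      cat(sprintf("  %s = %.3f +/- %.3f (SE over %d folds)\n",
                  toupper(m), x[[m]]["mean"], x[[m]]["se"], nrow(x$per_fold)))
  }
  invisible(x)
}

#' Recipient-grouped cross-validation of a predictor
#'
#' Fits the model on each training fold and scores held-out pairs only,
#' reporting R2, Spearman correlation and (for binary tasks) AUC per fold with
#' mean and standard error over folds. Folds whose held-out labels are
#' constant are skipped with a warning and recorded.
#'
#' @param task A [prediction_task()].
#' @param bundle A [cohort_bundle()].
#' @param model_kind Model kind, see [fit_predictor()].
#' @param plan A [grouped_kfold()] plan (default: 10 folds from `seed`).
#' @param seed Integer seed (fold plan and model fits).
#' @param ... Passed to [fit_predictor()].
#' @return An `eval_metrics` with `$per_fold` (data frame incl. fold sizes and
#'   skip flags) and `$predictions` (held-out predictions across folds).
#' @export
cross_validate <- function(task, bundle, model_kind = "imic_cnn", plan = NULL,
                           seed = 1, ...) {
  if (is.null(plan)) plan <- grouped_kfold(bundle, k = 10, seed = seed)
  pairs <- .task_labels(task, bundle)
  masks <- .fold_masks(plan, pairs)
  binary <- identical(task$task_type, "binary")
  rows <- list(); preds <- list()
  for (i in seq_len(plan$k)) {
    test_idx <- masks[[i]]
    if (!length(test_idx)) next
    train_pairs <- pairs[-test_idx, , drop = FALSE]
    test_pairs <- pairs[test_idx, , drop = FALSE]
    stopifnot(length(intersect(train_pairs$recipient_sample,
                               test_pairs$recipient_sample)) == 0L)
    if (length(unique(test_pairs$y)) < 2L) {
      warning("fold ", i, " has constant held-out labels; skipped")
      rows[[i]] <- data.frame(fold = i, n = length(test_idx), skipped = TRUE,
                              r2 = NA_real_, scc = NA_real_, auc = NA_real_)
      next
    }
    fit <- fit_predictor(task, .subset_bundle(bundle, train_pairs$recipient_sample),
                         model_kind = model_kind, seed = seed + i, ...)
    ph <- .predict_pairs(fit, bundle, test_pairs)
    m <- .fold_metrics(test_pairs$y, ph, binary)
    rows[[i]] <- data.frame(fold = i, n = length(test_idx), skipped = FALSE,
                            r2 = m$r2, scc = m$scc, auc = m$auc)
    preds[[i]] <- data.frame(recipient_sample = test_pairs$recipient_sample,
                             days_post_fmt = test_pairs$days_post_fmt,
                             fold = i, truth = test_pairs$y, pred = ph)
  }
  out <- .summarize_folds(do.call(rbind, rows), list(k = plan$k, seed = plan$seed))
  out$predictions <- do.call(rbind, preds)
  out
}

# held-out predictions for specific pairs (uses each pair's own horizon);
# each distinct donor is predicted once per timepoint
.predict_pairs <- function(fit, bundle, pairs) {
  preds <- numeric(nrow(pairs))
  for (d in unique(pairs$days_post_fmt)) {
    sel <- which(pairs$days_post_fmt == d)
    dsamp <- unique(pairs$donor_sample[sel])
    p <- predict(fit, .subset_ft(bundle$donors, i = dsamp),
                 metadata = bundle$metadata, days_post_fmt = d)
    preds[sel] <- p[pairs$donor_sample[sel]]
  }
  preds
}

#' Leave-one-dataset-out evaluation
#'
#' Trains on all cohorts except the held-out one and scores the held-out
#' cohort, measuring cross-cohort generalization.
#'
#' @param task A [prediction_task()].
#' @param bundle A multi-cohort [cohort_bundle()].
#' @param holdout_cohort Cohort id to hold out.
#' @param model_kind,seed,... As in [cross_validate()].
#' @return An `eval_metrics` with a single evaluation row.
#' @export
lodo_evaluate <- function(task, bundle, holdout_cohort, model_kind = "imic_cnn",
                          seed = 1, ...) {
  cohorts <- unique(bundle$pairing$cohort_id)
  if (length(cohorts) < 2L) stop("LODO needs at least 2 cohorts", call. = FALSE)
  if (!holdout_cohort %in% cohorts)
    stop("unknown cohort id: ", holdout_cohort, call. = FALSE)
  pairs <- .task_labels(task, bundle)
  test_pairs <- pairs[pairs$cohort_id == holdout_cohort, , drop = FALSE]
  train_pairs <- pairs[pairs$cohort_id != holdout_cohort, , drop = FALSE]
  if (!nrow(test_pairs)) stop("holdout cohort has no labelled pairs", call. = FALSE)
  fit <- fit_predictor(task, .subset_bundle(bundle, train_pairs$recipient_sample),
                       model_kind = model_kind, seed = seed, ...)
  ph <- .predict_pairs(fit, bundle, test_pairs)
  binary <- identical(task$task_type, "binary")
  m <- .fold_metrics(test_pairs$y, ph, binary)
  per_fold <- data.frame(fold = 1L, n = nrow(test_pairs), skipped = FALSE,
                         r2 = m$r2, scc = m$scc, auc = m$auc)
  out <- .summarize_folds(per_fold, list(holdout = holdout_cohort, seed = seed))
  out$predictions <- data.frame(recipient_sample = test_pairs$recipient_sample,
                                days_post_fmt = test_pairs$days_post_fmt,
                                fold = 1L, truth = test_pairs$y, pred = ph)
  out
}

#' Compare models on per-fold metrics
#'
#' One-way ANOVA across models on the per-fold metric; when significant at
#' 0.05, one-sided pairwise t-tests of the best model against each other
#' model.
#'
#' @param metrics_by_model Named list of `eval_metrics` (same fold count).
#' @param metric `"scc"`, `"r2"` or `"auc"`.
#' @return List with `anova_f`, `anova_p`, `best_model`, and `pairwise`
#'   (data frame of one-sided p-values, or `NULL` when the ANOVA is not
#'   significant).
#' @export
compare_models <- function(metrics_by_model, metric = "scc") {
  stopifnot(length(metrics_by_model) >= 2L)
  vals <- lapply(metrics_by_model, function(m) {
    v <- m$per_fold[[metric]]
    v[is.finite(v)]
  })
  nf <- vapply(vals, length, integer(1))
  if (length(unique(nf)) != 1L)
    stop("models have unequal usable fold counts: ",
         paste(nf, collapse = ", "), call. = FALSE)
  df <- data.frame(value = unlist(vals),
                   model = factor(rep(names(vals), nf)))
  fit <- stats::aov(value ~ model, data = df)
  s <- summary(fit)[[1]]
  f <- s[["F value"]][1]; p <- s[["Pr(>F)"]][1]
  means <- vapply(vals, mean, numeric(1))
  best <- names(which.max(means))
  pairwise <- NULL
  if (is.finite(p) && p < 0.05) {
    others <- setdiff(names(vals), best)
    pw <- vapply(others, function(o) {
      stats::t.test(vals[[best]], vals[[o]], alternative = "greater")$p.value
    }, numeric(1))
    pairwise <- data.frame(model = others, p_one_sided = unname(pw),
                           stars = star_code(unname(pw)))
  }
  list(anova_f = unname(f), anova_p = unname(p), best_model = best,
       means = means, pairwise = pairwise)
}

#' Held-out accuracy stratified by time post-FMT
#'
#' Runs grouped cross-validation, then computes the Spearman correlation
#' between held-out predictions and truth within bins of days post-FMT,
#' testing whether accuracy persists long after the transplant.
#'
#' @param task,bundle,model_kind,seed,... As in [cross_validate()].
#' @param bins Numeric break points (passed to [cut()]); default one bin per
#'   distinct timepoint.
#' @param cv An existing [cross_validate()] result to reuse (optional).
#' @return Data frame with one row per bin: bin label, n, SCC (`NA` when a bin
#'   is empty or too small).
#' @export
scc_by_time <- function(task, bundle, model_kind = "imic_cnn", bins = NULL,
                        seed = 1, cv = NULL, ...) {
  if (is.null(cv)) cv <- cross_validate(task, bundle, model_kind, seed = seed, ...)
  pd <- cv$predictions
  grp <- if (is.null(bins)) factor(pd$days_post_fmt)
         else cut(pd$days_post_fmt, breaks = bins, include.lowest = TRUE)
  out <- lapply(levels(grp), function(g) {
    sel <- grp == g
    scc <- if (sum(sel) >= 3L) metric_scc(pd$truth[sel], pd$pred[sel]) else NA_real_
    data.frame(bin = g, n = sum(sel), scc = scc)
  })
  do.call(rbind, out)
}
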