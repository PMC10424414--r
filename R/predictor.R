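#' Define a prediction task
#'
#' One fitted model targets one recipient property: post-FMT Shannon
#' diversity, the relative abundance or presence of a single taxon at a chosen
#' rank, or the binary clinical outcome. A separate model is fitted per taxon.
#'
#' @param target `"shannon"`, `"taxon_abundance"`, `"taxon_presence"`, or
#'   `"clinical_outcome"`.
#' @param taxon Taxonomy string of the target taxon (abundance/presence tasks).
#' @param level Rank at which the target taxon lives (default `"order"`).
#' @param horizon Days post-FMT the label is taken at; `NULL` uses all post-FMT
#'   samples with days as a model covariate.
#' @return A `prediction_task`.
#' @export
prediction_task <- function(target = c("shannon", "taxon_abundance",
                                       "taxon_presence", "clinical_outcome"),
                            taxon = NULL, level = "order", horizon = NULL) {
  target <- match.arg(target)
  if (target %in% c("taxon_abundance", "taxon_presence") && is.null(taxon))
    stop("taxon tasks need a target taxon", call. = FALSE)
  structure(list(target = target, taxon = taxon, level = level, horizon = horizon,
                 task_type = if (target %in% c("taxon_presence", "clinical_outcome"))
                   "binary" else "regression"),
            class = "prediction_task")
}

# labels per pairing row; returns pairing subset with y column
.task_labels <- function(task, bundle) {
  pr <- bundle$pairing
  if (!is.null(task$horizon)) pr <- pr[pr$days_post_fmt == task$horizon, , drop = FALSE]
  if (!nrow(pr)) stop("no pairs at the requested horizon", call. = FALSE)
  rec <- bundle$recipients
  if (task$target == "shannon") {
    pr$y <- as.numeric(shannon_diversity(unclass(rec)[pr$recipient_sample, , drop = FALSE]))
  } else if (task$target %in% c("taxon_abundance", "taxon_presence")) {
    merged <- merge_to_level(rec, task$level, "sum")
    if (!task$taxon %in% colnames(merged))
      stop("target taxon not found at level '", task$level, "': ", task$taxon,
           call. = FALSE)
    v <- unclass(merged)[pr$recipient_sample, task$taxon]
    pr$y <- if (task$target == "taxon_presence") as.numeric(v > 0) else as.numeric(v)
  } else {
    md <- bundle$metadata
    out <- md$outcome[match(pr$recipient_sample, md$sample_id)]
    if (all(is.na(out))) stop("clinical outcome labels unavailable", call. = FALSE)
    pr$y <- as.numeric(out)
    pr <- pr[!is.na(pr$y), , drop = FALSE]
  }
  pr$subject <- bundle$metadata$subject_id[match(pr$recipient_sample,
                                                 bundle$metadata$sample_id)]
  pr
}

# shared design construction: preprocessed donor features + covariates
.build_design <- function(bundle, pairs, recipe, covariate_policy,
                          use_donor_covariates, frozen = NULL) {
  merged <- merge_to_level(bundle$donors, recipe$merge_level, recipe$merge_method)
  # normalization statistics come from the training donors only
  merged <- .subset_ft(merged, i = unique(pairs$donor_sample))
  prep <- normalize_table(merged, recipe, stats = frozen$norm_stats)
  axis <- colnames(prep)
  feat <- unclass(prep)[pairs$donor_sample, , drop = FALSE]
  day <- pairs$days_post_fmt
  if (is.null(frozen)) {
    dmu <- mean(day); dsd <- stats::sd(day)
    if (!is.finite(dsd) || dsd < 1e-12) dsd <- 1
  } else {
    dmu <- frozen$day_center; dsd <- frozen$day_scale
  }
  cov <- matrix((day - dmu) / dsd, ncol = 1L, dimnames = list(NULL, "days_post_fmt"))
  cov_stats <- frozen$cov_stats
  if (use_donor_covariates) {
    cv <- assemble_covariates(bundle$metadata, pairs$donor_sample,
                              impute_policy = covariate_policy,
                              stats = frozen$cov_stats)
    if (ncol(cv$x)) cov <- cbind(cov, cv$x)
    cov_stats <- cv$stats
  }
  list(features = feat, covariates = cov, axis = axis,
       norm_stats = attr(prep, "norm_stats"),
       day_center = dmu, day_scale = dsd, cov_stats = cov_stats)
}

.model_kinds <- c("imic_cnn", "ridge", "knn", "svr", "rf", "gboost", "dense_nn")

#' Fit a donor-only outcome predictor
#'
#' Trains one model for one [prediction_task()] from a paired cohort: donor
#' compositions are MIPMLP-preprocessed (taxonomic merge, closure, log), the
#' days-post-FMT of each label and any donor covariates (age, sex, weight) are
#' standardized on the training data and concatenated to the features, and the
#' chosen model is fitted. `"imic_cnn"` renders each donor as a
#' taxonomy-structured image and trains the small convolutional network with
#' early stopping on an internal validation split that keeps all samples of a
#' recipient on one side. All other kinds consume the flat feature vector, so
#' model comparisons share one design-matrix contract.
#'
#' @param task A [prediction_task()].
#' @param bundle A [cohort_bundle()] (training data only).
#' @param model_kind One of `"imic_cnn"`, `"ridge"`, `"knn"`, `"svr"`, `"rf"`,
#'   `"gboost"`, `"dense_nn"`.
#' @param recipe A [prep_recipe()].
#' @param hyperparams Named list overriding model defaults (for `imic_cnn`:
#'   any [cnn_config] field).
#' @param use_donor_covariates Include donor age/sex/weight when present.
#' @param covariate_policy Imputation policy, see [assemble_covariates()].
#' @param val_fraction Fraction of recipients held out internally for early
#'   stopping (CNN, gradient boosting).
#' @param seed Integer seed; fits are deterministic given the seed.
#' @return A `trained_predictor`.
#' @export
fit_predictor <- function(task, bundle, model_kind = "imic_cnn",
                          recipe = prep_recipe(), hyperparams = list(),
                          use_donor_covariates = TRUE,
                          covariate_policy = "cohort_median",
                          val_fraction = 0.15, seed = 1) {
  model_kind <- match.arg(model_kind, .model_kinds)
  pairs <- .task_labels(task, bundle)
  if (nrow(pairs) < 20L) stop("need at least 20 training pairs", call. = FALSE)
  if (length(unique(pairs$y)) < 2L) stop("degenerate constant labels", call. = FALSE)
  des <- .build_design(bundle, pairs, recipe, covariate_policy, use_donor_covariates)
  X <- cbind(des$features, des$covariates)
  y <- pairs$y
  binary <- identical(task$task_type, "binary")

  # internal grouped validation split for early-stopping models
  subjects <- unique(pairs$subject)
  val_idx <- NULL
  if (val_fraction > 0 && length(subjects) >= 10L) {
    val_sub <- with_seed(seed + 17L,
                         sample(subjects, max(1L, round(val_fraction * length(subjects)))))
    val_idx <- which(pairs$subject %in% val_sub)
    if (!length(val_idx) || length(val_idx) == nrow(pairs)) val_idx <- NULL
  }

  fitobj <- NULL; imap <- NULL; cnn <- NULL
  if (identical(model_kind, "imic_cnn")) {
    hp <- utils::modifyList(cnn_config(loss = if (binary) "bce" else "mse"), hyperparams)
    imap <- taxonomy_image_map(des$axis, colMeans(des$features))
    Ximg <- apply_image_map(imap, des$features)
    geom <- cnn_geometry(imap$depth, imap$width, hp)
    cnn <- cnn_train(Ximg, des$covariates, y, geom, hp, seed = seed, val = val_idx)
  } else if (identical(model_kind, "ridge")) {
    fam <- if (binary) "binomial" else "gaussian"
    cvfit <- with_seed(seed, glmnet::cv.glmnet(X, y, alpha = 0, family = fam, nfolds = 5))
    fitobj <- list(fit = cvfit$glmnet.fit, lambda = cvfit$lambda.min)
  } else if (identical(model_kind, "knn")) {
    k <- if (!is.null(hyperparams$k)) hyperparams$k else 5L
    fitobj <- if (binary) caret::knn3(X, factor(y, levels = c(0, 1)), k = k)
              else caret::knnreg(X, y, k = k)
  } else if (identical(model_kind, "svr")) {
    fitobj <- with_seed(seed, {
      if (binary) e1071::svm(X, factor(y, levels = c(0, 1)), probability = TRUE,
                             scale = FALSE)
      else e1071::svm(X, y, scale = FALSE)
    })
  } else if (identical(model_kind, "rf")) {
    df <- data.frame(X, check.names = FALSE)
    fitobj <- ranger::ranger(
      x = df, y = if (binary) factor(y, levels = c(0, 1)) else y,
      num.trees = 500, probability = binary, seed = seed, num.threads = 1)
  } else if (identical(model_kind, "gboost")) {
    fitobj <- with_seed(seed, xgboost::xgboost(
      x = X, y = if (binary) factor(y, levels = c(0, 1)) else y,
      nrounds = 200, learning_rate = 0.05, max_depth = 3,
      subsample = 0.8, verbosity = 0, nthreads = 1,
      seed = seed %% .Machine$integer.max))
  } else if (identical(model_kind, "dense_nn")) {
    fitobj <- with_seed(seed, nnet::nnet(
      x = X, y = y, size = 32, linout = !binary, entropy = binary,
      decay = 1e-3, maxit = 200, MaxNWts = 1e6, trace = FALSE))
  }

  model <- structure(list(
    task = task, recipe = recipe, model_kind = model_kind,
    taxon_axis = des$axis,
    norm_stats = des$norm_stats, day_center = des$day_center,
    day_scale = des$day_scale, cov_stats = des$cov_stats,
    cov_names = colnames(des$covariates),
    use_donor_covariates = use_donor_covariates,
    imap = imap, cnn = cnn, fit = fitobj, seed = seed), class = "trained_predictor")
  model$fitted <- .predict_design(model, des$features, des$covariates)
  names(model$fitted) <- pairs$recipient_sample
  model
}

#' @export
print.trained_predictor <- function(x, ...) {
  cat(sprintf("<trained_predictor> task=%s model=%s taxa=%d\n",
              x$task$target, x$model_kind, length(x$taxon_axis)))
  invisible(x)
}

.predict_design <- function(model, features, covariates) {
  X <- cbind(features, covariates)
  binary <- identical(model$task$task_type, "binary")
  out <- switch(model$model_kind,
    imic_cnn = cnn_predict_raw(model$cnn, apply_image_map(model$imap, features),
                               covariates),
    ridge = as.numeric(stats::predict(model$fit$fit, newx = X, s = model$fit$lambda,
                                      type = if (binary) "response" else "link")),
    knn = if (binary) stats::predict(model$fit, X, type = "prob")[, "1"]
          else as.numeric(stats::predict(model$fit, X)),
    svr = if (binary) {
      p <- stats::predict(model$fit, X, probability = TRUE)
      attr(p, "probabilities")[, "1"]
    } else as.numeric(stats::predict(model$fit, X)),
    rf = if (binary) stats::predict(model$fit, data.frame(X, check.names = FALSE),
                                    num.threads = 1)$predictions[, "1"]
         else stats::predict(model$fit, data.frame(X, check.names = FALSE),
                             num.threads = 1)$predictions,
    gboost = as.numeric(stats::predict(model$fit, X)),
    dense_nn = as.numeric(stats::predict(model$fit, X)))
  as.numeric(out)
}

# align arbitrary donor input onto the trained taxon axis; returns the
# preprocessed (log-space) feature matrix
.align_donor_features <- function(model, donors) {
  if (identical(colnames(donors), model$taxon_axis) &&
      !identical(space_tag(donors), "log_normalized")) {
    prep <- normalize_table(donors, model$recipe, stats = model$norm_stats)
    return(unclass(prep))
  }
  merged <- merge_to_level(donors, model$recipe$merge_level, model$recipe$merge_method)
  extra <- setdiff(colnames(merged), model$taxon_axis)
  if (length(extra)) {
    nz <- colSums(unclass(merged)[, extra, drop = FALSE]) > 0
    if (any(nz))
      stop("taxon-axis mismatch: donor taxa absent from the training axis: ",
           paste(utils::head(extra[nz], 5), collapse = ", "), call. = FALSE)
    merged <- .subset_ft(merged, j = setdiff(colnames(merged), extra))
  }
  m <- matrix(0, nrow(merged), length(model$taxon_axis),
              dimnames = list(rownames(merged), model$taxon_axis))
  m[, colnames(merged)] <- unclass(merged)
  padded <- structure(m, space_tag = space_tag(merged),
                      class = c("feature_table", "matrix", "array"))
  unclass(normalize_table(padded, model$recipe, stats = model$norm_stats))
}

#' Predict recipient outcomes for donor samples
#'
#' @param object A `trained_predictor`.
#' @param donors A `feature_table` of donor compositions. Tables already on
#'   the trained (merged) taxon axis are used directly; otherwise they are
#'   merged and zero-padded onto it (unseen non-zero taxa are an error).
#' @param metadata Optional metadata for donor covariates; when absent, donor
#'   covariates are imputed at the training mean.
#' @param days_post_fmt Horizon of the prediction; defaults to the task
#'   horizon, or 7 days.
#' @param ... Unused.
#' @return Named numeric vector: regression value or probability per donor.
#' @export
predict.trained_predictor <- function(object, donors, metadata = NULL,
                                      days_post_fmt = NULL, ...) {
  feat <- .align_donor_features(object, donors)
  n <- nrow(feat)
  if (is.null(days_post_fmt))
    days_post_fmt <- if (!is.null(object$task$horizon)) object$task$horizon else 7
  day <- rep_len(days_post_fmt, n)
  cov <- matrix((day - object$day_center) / object$day_scale, ncol = 1L,
                dimnames = list(NULL, "days_post_fmt"))
  extra <- setdiff(object$cov_names, "days_post_fmt")
  if (length(extra)) {
    if (!is.null(metadata)) {
      cv <- assemble_covariates(metadata, rownames(feat),
                                impute_policy = "global_median",
                                stats = object$cov_stats)
      cov <- cbind(cov, cv$x[, extra, drop = FALSE])
    } else {
      cov <- cbind(cov, matrix(0, n, length(extra), dimnames = list(NULL, extra)))
    }
  }
  out <- .predict_design(object, feat, cov)
  stats::setNames(out, rownames(feat))
}

#' Univariate donor-recipient Spearman baseline
#'
#' Correlates a property of each donor sample with the same property of its
#' paired recipient post-FMT, the raw association that multivariate predictors
#' are compared against.
#'
#' @param bundle A [cohort_bundle()].
#' @param property `"shannon"` or a taxonomy string (order-level relative
#'   abundance).
#' @param level Rank for taxon properties.
#' @return Spearman correlation across pairs.
#' @export
raw_donor_recipient_scc <- function(bundle, property = "shannon", level = "order") {
  pr <- bundle$pairing
  if (nrow(pr) < 3L) stop("need at least 3 donor-recipient pairs", call. = FALSE)
  if (identical(property, "shannon")) {
    dv <- shannon_diversity(unclass(bundle$donors)[pr$donor_sample, , drop = FALSE])
    rv <- shannon_diversity(unclass(bundle$recipients)[pr$recipient_sample, , drop = FALSE])
  } else {
    dm <- merge_to_level(bundle$donors, level, "sum")
    rm_ <- merge_to_level(bundle$recipients, level, "sum")
    if (!property %in% colnames(dm) || !property %in% colnames(rm_))
      stop("taxon not found at level '", level, "': ", property, call. = FALSE)
    dv <- unclass(dm)[pr$donor_sample, property]
    rv <- unclass(rm_)[pr$recipient_sample, property]
  }
  metric_scc(as.numeric(dv), as.numeric(rv))
}
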