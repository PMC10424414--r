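#' Preprocessing recipe
#'
#' Captures the MIPMLP-style preprocessing applied before modelling: taxonomic
#' merge to a chosen rank with `"mean"` or `"sum"` aggregation, closure to
#' relative abundance, optional log transform `x -> log10(x + log_epsilon)`,
#' and optional per-taxon z-scoring (whose statistics are learned on training
#' data only and frozen into the fitted predictor).
#'
#' @param merge_level Rank to merge to (`"species"` default, `"order"` for the
#'   similarity analyses).
#' @param merge_method `"mean"` (default, used when feeding the predictor) or
#'   `"sum"` (keeps relative abundances interpretable).
#' @param normalization `"relative_then_log"` (default) or `"relative_only"`.
#' @param log_epsilon Pseudo-abundance added before the log; default `1e-4`
#'   keeps zero cells well below any observed abundance while avoiding `-Inf`.
#' @param zscore Per-taxon z-scoring across samples (default `FALSE`).
#' @return A `prep_recipe` object (a validated list).
#' @export
prep_recipe <- function(merge_level = "species",
                        merge_method = c("mean", "sum"),
                        normalization = c("relative_then_log", "relative_only"),
                        log_epsilon = 1e-4,
                        zscore = FALSE) {
  merge_method <- match.arg(merge_method)
  normalization <- match.arg(normalization)
  .rank_index(merge_level)
  stopifnot(is.numeric(log_epsilon), log_epsilon > 0)
  structure(list(merge_level = merge_level, merge_method = merge_method,
                 normalization = normalization, log_epsilon = log_epsilon,
                 zscore = isTRUE(zscore)),
            class = "prep_recipe")
}

#' Merge a feature table to a taxonomic level
#'
#' Columns are grouped by their taxonomy path truncated at `level` (missing
#' ranks completed with `"<parent>__unclassified"` placeholders first, so every
#' output taxon is a full path to `level`). `method = "sum"` adds member leaf
#' values per sample and conserves row totals; `method = "mean"` averages them.
#'
#' @param ft A `feature_table`.
#' @param level Target rank, at or above species.
#' @param method `"mean"` or `"sum"`.
#' @return A `feature_table` on the truncated taxon axis (taxa sorted
#'   lexicographically), same `space_tag` for `"sum"`; `"mean"` output of a
#'   relative table is tagged `counts` because rows no longer close to 1.
#' @export
#' @examples
#' m <- matrix(c(0.5, 0.3, 0.2), 1, 3,
#'             dimnames = list("s1", c("k__B;p__P;c__C;o__O;f__F;g__G;s__a",
#'                                     "k__B;p__P;c__C;o__O;f__F;g__G;s__b",
#'                                     "k__B;p__P;c__C;o__O2;f__F2;g__G2;s__c")))
#' merge_to_level(feature_table(m, "relative"), "order", "sum")
merge_to_level <- function(ft, level, method = c("mean", "sum")) {
  method <- match.arg(method)
  if (identical(space_tag(ft), "log_normalized"))
    stop("merge taxa before log-normalization, not after", call. = FALSE)
  d <- .rank_index(level)
  mat <- parse_taxonomy(colnames(ft))
  depths <- apply(mat, 1L, function(r) max(which(!is.na(r)), 0L))
  if (all(depths < d))
    stop("no taxon resolved to rank '", level, "' or deeper", call. = FALSE)
  full <- parse_taxonomy(complete_taxonomy(colnames(ft), depth = level))
  key <- format_taxonomy(full[, seq_len(d), drop = FALSE])
  groups <- sort(unique(key))
  agg <- t(rowsum(t(unclass(ft)), group = key))  # samples x groups, summed
  agg <- agg[, groups, drop = FALSE]
  if (identical(method, "mean")) {
    n_members <- as.vector(table(key)[groups])
    agg <- sweep(agg, 2L, n_members, "/")
  }
  tag <- space_tag(ft)
  if (identical(method, "mean") && identical(tag, "relative")) tag <- "counts"
  structure(agg, space_tag = tag, class = c("feature_table", "matrix", "array"))
}

#' Apply closure and log-normalization to a feature table
#'
#' Closes each row to relative abundance, then (for
#' `normalization = "relative_then_log"`) maps `x -> log10(x + log_epsilon)`,
#' and optionally z-scores each taxon across samples. Re-running on a
#' log-normalized table is an error (no double transform).
#'
#' @param ft A `feature_table` in counts or relative space.
#' @param recipe A [prep_recipe()].
#' @param stats Optional frozen normalization statistics (from a previous call
#'   on training data) with elements `center` and `scale`; when supplied the
#'   z-score reuses them instead of recomputing, preventing train/test leakage.
#' @return A `feature_table` with `space_tag = "log_normalized"` (or
#'   `"relative"` for `relative_only` without z-scoring) carrying the applied
#'   statistics in `attr(, "norm_stats")`.
#' @export
normalize_table <- function(ft, recipe = prep_recipe(), stats = NULL) {
  if (identical(space_tag(ft), "log_normalized"))
    stop("table is already log-normalized; refusing to transform twice", call. = FALSE)
  rel <- as_relative(ft)
  m <- unclass(rel)
  tag <- "relative"
  if (identical(recipe$normalization, "relative_then_log")) {
    m <- log10(m + recipe$log_epsilon)
    tag <- "log_normalized"
  }
  norm_stats <- NULL
  if (recipe$zscore) {
    if (is.null(stats)) {
      center <- colMeans(m)
      scale <- apply(m, 2L, stats::sd)
      scale[!is.finite(scale) | scale < 1e-12] <- 1
      norm_stats <- list(center = center, scale = scale)
    } else {
      norm_stats <- stats
    }
    m <- sweep(sweep(m, 2L, norm_stats$center, "-"), 2L, norm_stats$scale, "/")
    tag <- "log_normalized"
  }
  structure(m, space_tag = tag, norm_stats = norm_stats,
            class = c("feature_table", "matrix", "array"))
}

#' Shannon diversity of a relative-abundance vector
#'
#' `H = -sum(p_i log p_i)` over the non-zero entries, computed in nats by
#' default. Vectors not on the simplex are closed first, so the statistic is
#' scale-invariant.
#'
#' @param p Non-negative numeric vector (or matrix with samples in rows, in
#'   which case one value per row is returned).
#' @param base Logarithm base; default `exp(1)` (nats).
#' @return Shannon diversity value(s), in `[0, log_base(K)]`.
#' @export
#' @examples
#' shannon_diversity(rep(1, 10))  # log(10)
shannon_diversity <- function(p, base = exp(1)) {
  if (is.matrix(p)) return(apply(p, 1L, shannon_diversity, base = base))
  if (any(p < 0)) stop("negative abundances", call. = FALSE)
  s <- sum(p)
  if (s <= 0) stop("all-zero abundance vector", call. = FALSE)
  p <- p[p > 0] / s
  -sum(p * log(p, base = base))
}

#' Assemble donor covariates for modelling
#'
#' Builds the numeric covariate matrix (age, sex, weight) for a set of donor
#' samples, imputing missing values per policy and recording imputation flags.
#' Standardization statistics are learned on the training rows only (or reused
#' from `stats`) and returned for freezing into the fitted predictor.
#'
#' @param metadata Metadata data frame (donor rows are used).
#' @param sample_ids Donor sample ids, in output row order.
#' @param impute_policy `"cohort_median"`, `"global_median"`, or `"drop"`
#'   (`"drop"` requires complete data and errors otherwise).
#' @param stats Optional frozen list with `center`/`scale` per covariate.
#' @return List with `x` (numeric matrix, one row per sample id; columns
#'   `age`, `sex`, `weight` where available), `imputed` (logical matrix of the
#'   same shape) and `stats`.
#' @export
assemble_covariates <- function(metadata, sample_ids,
                                impute_policy = c("cohort_median", "global_median", "drop"),
                                stats = NULL) {
  impute_policy <- match.arg(impute_policy)
  md <- metadata[match(sample_ids, metadata$sample_id), , drop = FALSE]
  cols <- intersect(c("age", "sex", "weight"), names(metadata))
  cols <- cols[vapply(cols, function(cl) !all(is.na(metadata[[cl]])), logical(1))]
  if (!length(cols)) {
    return(list(x = matrix(0, length(sample_ids), 0,
                           dimnames = list(sample_ids, NULL)),
                imputed = matrix(FALSE, length(sample_ids), 0), stats = list()))
  }
  x <- matrix(NA_real_, length(sample_ids), length(cols),
              dimnames = list(sample_ids, cols))
  for (cl in cols) {
    v <- md[[cl]]
    if (identical(cl, "sex") && !is.numeric(v)) {
      lv <- sort(unique(stats::na.omit(as.character(metadata[[cl]]))))
      v <- as.numeric(match(as.character(v), lv) - 1L)
    }
    x[, cl] <- as.numeric(v)
  }
  imputed <- is.na(x)
  if (any(imputed)) {
    if (identical(impute_policy, "drop"))
      stop("missing covariate value(s) under policy 'drop': ",
           paste(cols[colSums(imputed) > 0], collapse = ", "), call. = FALSE)
    for (cl in cols) {
      nas <- which(is.na(x[, cl]))
      if (!length(nas)) next
      if (identical(impute_policy, "cohort_median")) {
        med <- tapply(x[, cl], md$cohort_id, stats::median, na.rm = TRUE)
        fill <- med[as.character(md$cohort_id[nas])]
        fill[is.na(fill)] <- stats::median(x[, cl], na.rm = TRUE)
      } else {
        fill <- rep(stats::median(x[, cl], na.rm = TRUE), length(nas))
      }
      if (any(is.na(fill)))
        stop("covariate '", cl, "' has no observed values to impute from", call. = FALSE)
      x[nas, cl] <- fill
    }
  }
  if (is.null(stats)) {
    center <- colMeans(x)
    scale <- apply(x, 2L, stats::sd)
    scale[!is.finite(scale) | scale < 1e-12] <- 1
    stats <- list(center = center, scale = scale)
  }
  x <- sweep(sweep(x, 2L, stats$center, "-"), 2L, stats$scale, "/")
  list(x = x, imputed = imputed, stats = stats)
}
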