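#' Rank candidate donors by predicted recipient outcome
#'
#' Predicts the expected post-FMT outcome of a transplant from each candidate
#' donor sample with a trained predictor and ranks donors in descending order
#' of the prediction, ties broken by donor id (lexicographic).
#'
#' @param model A `trained_predictor`.
#' @param candidate_donors A `feature_table` of donor compositions.
#' @param metadata Optional donor metadata (covariates, strata).
#' @param days_post_fmt Prediction horizon (default: task horizon, or 7).
#' @return A `donor_ranking` data frame: `donor_sample`, `prediction`, `rank`,
#'   `group` (all `"excluded"` until [split_donor_groups()]).
#' @export
rank_donors <- function(model, candidate_donors, metadata = NULL,
                        days_post_fmt = NULL) {
  p <- predict(model, candidate_donors, metadata = metadata,
               days_post_fmt = days_post_fmt)
  ord <- order(-p, names(p))
  out <- data.frame(donor_sample = names(p)[ord], prediction = unname(p)[ord],
                    rank = seq_along(p), group = "excluded",
                    stringsAsFactors = FALSE)
  class(out) <- c("donor_ranking", "data.frame")
  out
}

#' Split a ranking into predicted-high and predicted-low groups
#'
#' Assigns the top `n_high` donors to `predicted_high` and the bottom `n_low`
#' to `predicted_low` (e.g., 8 optimal and 16 sub-optimal donors). With
#' `stratify_by`, an additional covariate-matched low group of size `n_high`
#' is drawn from the lowest-ranked donors that share the high group's dominant
#' stratum, mirroring an age-matched control arm.
#'
#' @param ranking A [rank_donors()] result.
#' @param n_high,n_low Group sizes; `n_high + n_low` must not exceed the
#'   number of donors.
#' @param stratify_by Optional metadata column name.
#' @param metadata Metadata with `sample_id` and the stratification column
#'   (required with `stratify_by`).
#' @return The ranking with `group` filled in (`predicted_low_matched` for the
#'   stratified arm) and an attribute `stratum` naming the matched stratum.
#' @export
split_donor_groups <- function(ranking, n_high, n_low, stratify_by = NULL,
                               metadata = NULL) {
  n <- nrow(ranking)
  if (n_high + n_low > n)
    stop("requested groups overlap: ", n_high, " + ", n_low, " > ", n, call. = FALSE)
  ranking$group <- "excluded"
  ranking$group[seq_len(n_high)] <- "predicted_high"
  ranking$group[(n - n_low + 1L):n] <- "predicted_low"
  stratum <- NULL
  if (!is.null(stratify_by)) {
    if (is.null(metadata) || !stratify_by %in% names(metadata))
      stop("stratify_by needs metadata with column '", stratify_by, "'", call. = FALSE)
    strat <- metadata[[stratify_by]][match(ranking$donor_sample, metadata$sample_id)]
    high_strat <- strat[ranking$group == "predicted_high"]
    stratum <- names(sort(table(high_strat), decreasing = TRUE))[1]
    pool <- which(ranking$group == "excluded" & strat == stratum)
    take <- utils::tail(pool, n_high)
    if (length(take) < n_high)
      warning("only ", length(take), " matched donors available in stratum ", stratum)
    ranking$group[take] <- "predicted_low_matched"
  }
  attr(ranking, "stratum") <- stratum
  ranking
}

#' Per-donor transplant success fractions
#'
#' For each donor with outcome-labelled recipients, the fraction of successful
#' transplants among all transplants from that donor. Donors with a single
#' labelled recipient are reported separately (their fraction is degenerate).
#'
#' @param bundle A [cohort_bundle()] with outcome labels.
#' @return List with `fractions` (data frame: donor subject, n transplants,
#'   successes, fraction; donors with >= 2 recipients) and `singletons` (same
#'   columns, single-recipient donors).
#' @export
success_fraction_per_donor <- function(bundle) {
  md <- bundle$metadata
  pr <- bundle$pairing
  out <- md$outcome[match(pr$recipient_sample, md$sample_id)]
  sub <- md$subject_id[match(pr$recipient_sample, md$sample_id)]
  donor <- md$subject_id[match(pr$donor_sample, md$sample_id)]
  keep <- !is.na(out)
  if (!any(keep)) stop("no outcome labels present", call. = FALSE)
  df <- unique(data.frame(donor = donor[keep], subject = sub[keep],
                          outcome = out[keep]))
  agg <- stats::aggregate(outcome ~ donor, data = df,
                          FUN = function(v) c(n = length(v), s = sum(v)))
  res <- data.frame(donor = agg$donor, n = agg$outcome[, "n"],
                    successes = agg$outcome[, "s"],
                    fraction = agg$outcome[, "s"] / agg$outcome[, "n"])
  list(fractions = res[res$n >= 2L, , drop = FALSE],
       singletons = res[res$n < 2L, , drop = FALSE])
}

#' Predicted richness of clinical successes vs failures
#'
#' Predicts the post-FMT Shannon diversity from each labelled recipient's
#' donor with a trained Shannon model, splits predictions by clinical
#' success/failure, and compares the groups with a two-sided Welch t-test.
#'
#' @param model A `trained_predictor` for the Shannon task.
#' @param bundle A [cohort_bundle()] with outcome labels.
#' @return List: `mean_success`, `mean_failure`, `t`, `p`, `n_success`,
#'   `n_failure`, and the per-recipient `predictions` data frame.
#' @export
success_vs_failure_richness <- function(model, bundle) {
  md <- bundle$metadata
  pr <- bundle$pairing
  out <- md$outcome[match(pr$recipient_sample, md$sample_id)]
  keep <- which(!is.na(out))
  if (!length(keep)) stop("no outcome labels present", call. = FALSE)
  pr <- pr[keep, , drop = FALSE]; out <- out[keep]
  preds <- .predict_pairs(model, bundle, pr)
  if (sum(out == 1) < 2L || sum(out == 0) < 2L)
    stop("need at least 2 successes and 2 failures", call. = FALSE)
  if (stats::sd(preds) < 1e-12) {
    tt <- list(statistic = c(t = 0), p.value = 1)
  } else {
    tt <- stats::t.test(preds[out == 1], preds[out == 0], alternative = "two.sided")
  }
  list(mean_success = mean(preds[out == 1]), mean_failure = mean(preds[out == 0]),
       t = unname(tt$statistic), p = tt$p.value,
       n_success = sum(out == 1), n_failure = sum(out == 0),
       predictions = data.frame(recipient_sample = pr$recipient_sample,
                                outcome = out, predicted_shannon = preds))
}
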