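#' Donor-vs-background distance groups
#'
#' Computes the three groups of between-recipient distances that separate the
#' donor effect from the recipient background:
#' \describe{
#'   \item{SDSR}{samples of the same recipient at different timepoints
#'     (temporal variation; post-FMT only)}
#'   \item{SDDR}{different recipients of the same donor at the same timepoint
#'     (recipient-background effect)}
#'   \item{DDDR}{recipients of different donors at the same timepoint
#'     (background plus donor effect)}
#' }
#' Distances are Euclidean between order-level relative-abundance vectors
#' (`metric = "euclidean_order_vectors"`) or absolute differences of Shannon
#' diversity (`metric = "abs_shannon_difference"`). The pre-FMT phase uses
#' samples at `days_post_fmt <= 0` (and defines no SDSR group).
#'
#' @param bundle A [cohort_bundle()] whose recipients carry `donor_id` and
#'   `days_post_fmt`.
#' @param metric Distance metric (see above).
#' @param phase `"post_fmt"` (default) or `"pre_fmt"`.
#' @param time_tolerance Maximal difference in `days_post_fmt` for two samples
#'   to count as "same timepoint" (default 0 = exact).
#' @return List of `distance_group` results keyed SDSR/SDDR/DDDR, each with
#'   `distances`, `n_pairs`, `metric`, `phase`, and `empty` flag.
#' @export
pairwise_distance_groups <- function(bundle,
                                     metric = c("euclidean_order_vectors",
                                                "abs_shannon_difference"),
                                     phase = c("post_fmt", "pre_fmt"),
                                     time_tolerance = 0) {
  metric <- match.arg(metric)
  phase <- match.arg(phase)
  md <- bundle$metadata
  md <- md[md$role == "recipient" & md$sample_id %in% rownames(bundle$recipients), ,
           drop = FALSE]
  md <- if (identical(phase, "post_fmt")) md[md$days_post_fmt > 0, , drop = FALSE]
        else md[md$days_post_fmt <= 0, , drop = FALSE]
  if (nrow(md) < 2L) stop("fewer than 2 recipient samples in phase ", phase, call. = FALSE)

  if (identical(metric, "euclidean_order_vectors")) {
    ord <- merge_to_level(.subset_ft(bundle$recipients, i = md$sample_id),
                          "order", "sum")
    m <- unclass(ord)
    dfun <- function(i, j) sqrt(sum((m[i, ] - m[j, ])^2))
  } else {
    h <- shannon_diversity(unclass(bundle$recipients)[md$sample_id, , drop = FALSE])
    dfun <- function(i, j) abs(h[i] - h[j])
  }

  n <- nrow(md)
  same_time <- function(i, j) abs(md$days_post_fmt[i] - md$days_post_fmt[j]) <= time_tolerance
  groups <- list(SDSR = numeric(0), SDDR = numeric(0), DDDR = numeric(0))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (md$subject_id[i] == md$subject_id[j]) {
      if (identical(phase, "post_fmt") &&
          md$days_post_fmt[i] != md$days_post_fmt[j] &&
          md$donor_id[i] == md$donor_id[j]) {
        groups$SDSR <- c(groups$SDSR, dfun(i, j))
      }
    } else if (same_time(i, j)) {
      if (md$donor_id[i] == md$donor_id[j]) {
        groups$SDDR <- c(groups$SDDR, dfun(i, j))
      } else {
        groups$DDDR <- c(groups$DDDR, dfun(i, j))
      }
    }
  }
  lapply(stats::setNames(names(groups), names(groups)), function(g) {
    d <- groups[[g]]
    structure(list(group = g, distances = d, n_pairs = length(d),
                   metric = metric, phase = phase, empty = length(d) < 2L),
              class = "distance_group")
  })
}

#' Test the hierarchy of distance groups
#'
#' One-sided Welch t-tests of the expected ordering
#' SDSR < SDDR < DDDR (and SDSR < DDDR): distances within the same donor
#' should be smaller than across donors if the donor drives the post-FMT
#' microbiome. Empty groups are skipped with a note.
#'
#' @param groups Result of [pairwise_distance_groups()].
#' @return Data frame with one row per comparison: group means, t, one-sided
#'   p, significance stars (`*` < 0.05, `**` < 0.01, `***` < 0.001), and a
#'   `skipped` flag for comparisons lacking a group.
#' @export
hierarchy_test <- function(groups) {
  comparisons <- list(c("SDSR", "SDDR"), c("SDDR", "DDDR"), c("SDSR", "DDDR"))
  rows <- lapply(comparisons, function(cp) {
    a <- groups[[cp[1]]]; b <- groups[[cp[2]]]
    if (is.null(a) || is.null(b) || a$empty || b$empty) {
      return(data.frame(lower = cp[1], higher = cp[2], mean_lower = NA_real_,
                        mean_higher = NA_real_, t = NA_real_, p = NA_real_,
                        stars = NA_character_, skipped = TRUE))
    }
    tt <- stats::t.test(a$distances, b$distances, alternative = "less")
    data.frame(lower = cp[1], higher = cp[2],
               mean_lower = mean(a$distances), mean_higher = mean(b$distances),
               t = unname(tt$statistic), p = tt$p.value,
               stars = star_code(tt$p.value), skipped = FALSE)
  })
  out <- do.call(rbind, rows)
  if (all(out$skipped)) stop("need at least 2 non-empty distance groups", call. = FALSE)
  out
}
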