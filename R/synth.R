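#' Configuration for the synthetic FMT cohort generator
#'
#' Defines a paired donor-to-recipient cohort with a known transfer model. The
#' recipient composition at `t` days post-FMT is
#' `close(delta * exp(-tau * t) * (engraftability * donor) + rho * background_i
#'  + (1 - delta - rho) * noise)`, with per-taxon multiplicative lognormal
#' jitter of standard deviation `noise_sd` applied before closure. `delta`
#' sets the donor effect, `rho` the recipient-background effect (0 is a
#' germ-free recipient, high values an untreated human), `tau` the decay of
#' the donor effect with time. Clinical outcomes are Bernoulli with success
#' probability `plogis(alpha * H_recipient + beta)` on the realized recipient
#' Shannon diversity `H`.
#'
#' @param n_taxa,n_orders Number of species-level taxa and of orders they are
#'   (power-law skewed) distributed over.
#' @param n_donors,recipients_per_donor Cohort shape; each donor sample is
#'   transplanted into this many distinct recipients.
#' @param timepoints Days post-FMT at which recipients are sampled.
#' @param delta,rho Donor-effect and recipient-background weights,
#'   `delta + rho <= 1`.
#' @param tau Time-decay rate of the donor effect (per day), `>= 0`.
#' @param engraftability Optional per-taxon engraftment propensity in `[0, 1]`;
#'   by default drawn from the seed as `Bernoulli(0.6) * Unif(0.05, 1)` — a
#'   substantial minority of taxa never engraft, the rest engraft with
#'   variable propensity, which makes the donor's own property an imperfect
#'   univariate predictor of the recipient's.
#' @param outcome_link Numeric `c(alpha, beta)` of the outcome logit.
#' @param noise_sd Lognormal jitter SD (natural-log scale).
#' @param pre_fmt If `TRUE`, also emit one pre-FMT sample per recipient
#'   (`days_post_fmt = 0`), drawn from the recipient background alone.
#' @param cohort_id Cohort label stamped on all samples.
#' @param seed Integer seed; generation is bit-reproducible per seed.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_taxa = 100, n_orders = 8, n_donors = 100,
                         recipients_per_donor = 4, timepoints = 7,
                         delta = 0.7, rho = 0.1, tau = 0,
                         engraftability = NULL,
                         outcome_link = c(alpha = 3, beta = -10.5),
                         noise_sd = 0.3, pre_fmt = FALSE,
                         cohort_id = "synth1", seed = 1) {
  stopifnot(delta >= 0, rho >= 0, delta + rho <= 1, tau >= 0, noise_sd >= 0,
            n_taxa >= n_orders, n_orders >= 1)
  structure(list(n_taxa = n_taxa, n_orders = n_orders, n_donors = n_donors,
                 recipients_per_donor = recipients_per_donor,
                 timepoints = timepoints, delta = delta, rho = rho, tau = tau,
                 engraftability = engraftability,
                 outcome_link = outcome_link, noise_sd = noise_sd,
                 pre_fmt = isTRUE(pre_fmt), cohort_id = cohort_id, seed = seed),
            class = "synth_config")
}

#' Generate a synthetic species-level taxonomy
#'
#' Full seven-rank paths; species are assigned to orders following a skewed
#' (power-law-like) size distribution, as observed in gut communities where a
#' few orders carry most species.
#'
#' @param n_taxa Number of species.
#' @param n_orders Number of orders.
#' @param seed Integer seed.
#' @return Character vector of `n_taxa` taxonomy strings.
#' @export
generate_taxonomy <- function(n_taxa, n_orders, seed = 1) {
  stopifnot(n_taxa >= n_orders, n_orders >= 1)
  with_seed(seed, {
    w <- (1 / seq_len(n_orders))^1.5
    sizes <- as.vector(stats::rmultinom(1, n_taxa - n_orders, w / sum(w))) + 1L
    order_of <- rep(seq_len(n_orders), sizes)
    n_phyla <- max(1L, ceiling(n_orders / 3))
    phylum_of_order <- sample(rep_len(seq_len(n_phyla), n_orders))
    sprintf("k__Bacteria;p__Phy%02d;c__Cls%02d;o__Ord%02d;f__Fam%03d;g__Gen%03d;s__Sp%03d",
            phylum_of_order[order_of], order_of, order_of,
            seq_len(n_taxa), seq_len(n_taxa), seq_len(n_taxa))
  })
}

.rand_composition <- function(n, n_taxa, base_log_mean, sd_log = 1.2,
                              keep_prob = NULL) {
  m <- exp(matrix(stats::rnorm(n * n_taxa, 0, sd_log), n, n_taxa,
                  byrow = FALSE) + rep(base_log_mean, each = n))
  if (!is.null(keep_prob)) {
    keep <- matrix(stats::runif(n * n_taxa) < rep(keep_prob, each = n), n, n_taxa)
    m <- m * keep
    zero <- rowSums(m) <= 0
    if (any(zero)) m[zero, which.max(keep_prob)] <- 1
  }
  m / rowSums(m)
}

#' Simulate post-FMT recipients for given donor profiles
#'
#' Applies the generator's transfer model to arbitrary donor composition rows,
#' returning realized recipient compositions. Used both inside
#' [generate_cohort()] and to emulate a transplant experiment on ranked donor
#' groups without animals.
#'
#' @param donor_rows Numeric matrix of donor relative abundances (rows on the
#'   simplex, columns on the generator's taxon axis).
#' @param config A [synth_config()] (its `engraftability` must be resolved; use
#'   the `truth$config` stored on a generated bundle to reuse a cohort's).
#' @param t Days post-FMT.
#' @param backgrounds Optional matrix of per-recipient background compositions;
#'   default freshly drawn.
#' @param seed Integer seed.
#' @return Matrix of recipient relative abundances, same shape as `donor_rows`.
#' @export
simulate_recipients <- function(donor_rows, config, t = 7, backgrounds = NULL,
                                seed = 1) {
  n <- nrow(donor_rows)
  k <- ncol(donor_rows)
  e <- config$engraftability
  if (is.null(e)) stop("config must carry a resolved engraftability vector", call. = FALSE)
  with_seed(seed, {
    if (is.null(backgrounds)) {
      base <- stats::rnorm(k, 0, 1.2)
      backgrounds <- .rand_composition(n, k, base, sd_log = 1.2)
    }
    noise <- .rand_composition(n, k, rep(0, k), sd_log = 1.2)
    donor_part <- sweep(donor_rows, 2L, e, "*")
    ds <- rowSums(donor_part)
    ds[ds <= 0] <- 1
    donor_part <- donor_part / ds
    w_d <- config$delta * exp(-config$tau * t)
    mix <- w_d * donor_part + config$rho * backgrounds +
      (1 - config$delta - config$rho) * noise
    if (config$noise_sd > 0) {
      mix <- mix * exp(matrix(stats::rnorm(n * k, 0, config$noise_sd), n, k))
    }
    mix / rowSums(mix)
  })
}

#' Generate a synthetic paired FMT cohort
#'
#' Donors are lognormal-then-closed sparse compositions; recipients follow the
#' transfer model described in [synth_config()]. The returned bundle carries a
#' `truth` attribute with the resolved configuration (including the realized
#' engraftability vector), per-recipient backgrounds, and realized recipient
#' Shannon diversities, for use as ground truth in validation.
#'
#' @param config A [synth_config()].
#' @return A [cohort_bundle()] with `attr(, "truth")`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  k <- config$n_taxa
  taxa <- generate_taxonomy(k, config$n_orders, seed = config$seed)
  with_seed(config$seed + 1L, {
    base <- stats::rnorm(k, 0, 1.5)          # shared taxon abundance scale
    prev <- stats::runif(k, 0.3, 1)          # per-taxon donor prevalence
    if (is.null(config$engraftability)) {
      # taxon-specific engraftment: a substantial minority of taxa never
      # engraft, the rest with variable propensity
      config$engraftability <- stats::rbinom(k, 1, 0.6) * stats::runif(k, 0.05, 1)
    }
    donor_m <- .rand_composition(config$n_donors, k, base, sd_log = 1.2,
                                 keep_prob = prev)
    n_rec <- config$n_donors * config$recipients_per_donor
    bg_base <- stats::rnorm(k, 0, 1.2)
    backgrounds <- .rand_composition(n_rec, k, bg_base, sd_log = 1.2)
  })
  donor_ids <- sprintf("D%03d", seq_len(config$n_donors))
  rec_subjects <- sprintf("R%04d", seq_len(config$n_donors * config$recipients_per_donor))
  rec_donor <- rep(donor_ids, each = config$recipients_per_donor)

  rows <- list(); meta <- list()
  donor_rows_per_rec <- donor_m[rep(seq_len(config$n_donors),
                                    each = config$recipients_per_donor), , drop = FALSE]
  for (ti in seq_along(config$timepoints)) {
    t <- config$timepoints[[ti]]
    rec_m <- simulate_recipients(donor_rows_per_rec, config, t = t,
                                 backgrounds = backgrounds,
                                 seed = config$seed + 100L + ti)
    rownames(rec_m) <- sprintf("%s_d%03d", rec_subjects, t)
    rows[[ti]] <- rec_m
    meta[[ti]] <- data.frame(sample_id = rownames(rec_m), subject_id = rec_subjects,
                             role = "recipient", donor_id = rec_donor,
                             cohort_id = config$cohort_id, days_post_fmt = t,
                             stringsAsFactors = FALSE)
  }
  if (config$pre_fmt) {
    with_seed(config$seed + 999L, {
      pre_m <- backgrounds * exp(matrix(stats::rnorm(length(backgrounds), 0,
                                                     max(config$noise_sd, 0.05)),
                                        nrow(backgrounds), ncol(backgrounds)))
      pre_m <- pre_m / rowSums(pre_m)
    })
    rownames(pre_m) <- sprintf("%s_d000", rec_subjects)
    rows <- c(rows, list(pre_m))
    meta <- c(meta, list(data.frame(sample_id = rownames(pre_m),
                                    subject_id = rec_subjects, role = "recipient",
                                    donor_id = rec_donor, cohort_id = config$cohort_id,
                                    days_post_fmt = 0, stringsAsFactors = FALSE)))
  }
  rec_all <- do.call(rbind, rows)
  colnames(rec_all) <- taxa
  colnames(donor_m) <- taxa
  rownames(donor_m) <- sprintf("%s_s", donor_ids)

  md_r <- do.call(rbind, meta)
  md_d <- data.frame(sample_id = rownames(donor_m), subject_id = donor_ids,
                     role = "donor", donor_id = NA_character_,
                     cohort_id = config$cohort_id, days_post_fmt = NA_real_,
                     stringsAsFactors = FALSE)
  with_seed(config$seed + 2L, {
    md_d$age <- round(stats::runif(nrow(md_d), 5, 70))
    md_d$sex <- sample(c("F", "M"), nrow(md_d), replace = TRUE)
    md_d$weight <- round(stats::rnorm(nrow(md_d), 70, 12), 1)
  })
  md_r$age <- NA_real_; md_r$sex <- NA_character_; md_r$weight <- NA_real_

  # clinical outcome per recipient subject, linked to realized day-1 horizon H
  h_first <- shannon_diversity(rows[[1L]])
  alpha <- config$outcome_link[[1]]; beta <- config$outcome_link[[2]]
  with_seed(config$seed + 3L, {
    succ <- stats::rbinom(length(rec_subjects), 1, stats::plogis(alpha * h_first + beta))
  })
  outcome_of <- stats::setNames(succ, rec_subjects)
  md_r$outcome <- as.integer(outcome_of[md_r$subject_id])
  md_d$outcome <- NA_integer_

  bundle <- cohort_bundle(feature_table(donor_m, "relative"),
                          feature_table(rec_all, "relative"),
                          rbind(md_d, md_r))
  # pre-FMT samples are background draws, not transplant outcomes
  bundle$pairing <- bundle$pairing[bundle$pairing$days_post_fmt > 0, , drop = FALSE]
  attr(bundle, "truth") <- list(config = config,
                                backgrounds = backgrounds,
                                donor_matrix = donor_m,
                                recipient_shannon = shannon_diversity(rec_all),
                                success = outcome_of)
  bundle
}

#' Recipient-background regime presets
#'
#' Four regimes of increasing recipient-background strength, emulating
#' germ-free mice, antibiotic-treated mice, antibiotic-treated humans and
#' untreated humans. `rho` rises across the regimes and the donor effect
#' `delta = 0.9 - rho` falls correspondingly, holding the residual noise
#' weight constant.
#'
#' @return Named list of parameter deltas (`rho`, `delta`) to splice into a
#'   [synth_config()], ordered by increasing `rho`.
#' @export
regime_presets <- function() {
  rho <- c(germ_free = 0, abx_mouse = 0.1, abx_human = 0.25, untreated_human = 0.45)
  lapply(rho, function(r) list(rho = unname(r), delta = 0.9 - unname(r)))
}
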