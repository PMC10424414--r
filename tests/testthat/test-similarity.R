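# hand-built two-donor bundle for exact distance arithmetic
fx_sim_bundle <- function() {
  taxa <- c("k__B;p__P;c__C;o__O1;f__F;g__G;s__a",
            "k__B;p__P;c__C;o__O2;f__F2;g__G2;s__b")
  don <- matrix(c(0.6, 0.4, 0.5, 0.5), 2, 2, byrow = TRUE,
                dimnames = list(c("d1", "d2"), taxa))
  rec <- matrix(c(0.5, 0.5,   # r1 day 7 (donor D1)
                  0.3, 0.7,   # r2 day 7 (donor D1)
                  0.9, 0.1,   # r3 day 7 (donor D2)
                  0.4, 0.6),  # r1 day 14
                4, 2, byrow = TRUE,
                dimnames = list(c("r1_7", "r2_7", "r3_7", "r1_14"), taxa))
  md <- data.frame(
    sample_id = c("d1", "d2", "r1_7", "r2_7", "r3_7", "r1_14"),
    subject_id = c("D1", "D2", "R1", "R2", "R3", "R1"),
    role = c("donor", "donor", rep("recipient", 4)),
    donor_id = c(NA, NA, "D1", "D1", "D2", "D1"),
    cohort_id = "c1",
    days_post_fmt = c(NA, NA, 7, 7, 7, 14))
  cohort_bundle(feature_table(don, "relative"), feature_table(rec, "relative"), md)
}

test_that("distance groups are assigned exhaustively with exact arithmetic", {
  b <- fx_sim_bundle()
  gr <- pairwise_distance_groups(b, "euclidean_order_vectors")
  # SDDR: r1_7 vs r2_7 (same donor, same day): sqrt(0.04 + 0.04)
  expect_equal(gr$SDDR$distances, sqrt(0.08), tolerance = 1e-12)
  # DDDR: r1_7 vs r3_7 and r2_7 vs r3_7
  expect_equal(sort(gr$DDDR$distances),
               sort(c(sqrt(2 * 0.4^2), sqrt(2 * 0.6^2))), tolerance = 1e-12)
  # SDSR: r1 across days
  expect_equal(gr$SDSR$distances, sqrt(2 * 0.1^2), tolerance = 1e-12)
  # groups exhaust the eligible pairs exactly once
  expect_identical(gr$SDDR$n_pairs + gr$DDDR$n_pairs + gr$SDSR$n_pairs, 4L)
})

test_that("identical vectors give zero distance; Shannon metric is |dH|", {
  b <- fx_sim_bundle()
  rec <- unclass(b$recipients)
  rec["r2_7", ] <- rec["r1_7", ]
  b$recipients <- feature_table(rec, "relative")
  gr <- pairwise_distance_groups(b, "euclidean_order_vectors")
  expect_equal(gr$SDDR$distances, 0)
  grs <- pairwise_distance_groups(b, "abs_shannon_difference")
  h <- shannon_diversity(rec)
  expect_equal(grs$DDDR$distances[1], abs(h["r1_7"] - h["r3_7"]),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("the donor-effect hierarchy is significant post-FMT, absent pre-FMT", {
  b <- generate_cohort(synth_config(n_taxa = 60, n_orders = 6, n_donors = 20,
                                    recipients_per_donor = 3,
                                    timepoints = c(7, 14), delta = 0.7,
                                    rho = 0.1, pre_fmt = TRUE, seed = 77))
  post <- pairwise_distance_groups(b, "euclidean_order_vectors", "post_fmt")
  rep_post <- hierarchy_test(post)
  sddr_dddr <- rep_post[rep_post$lower == "SDDR" & rep_post$higher == "DDDR", ]
  expect_lt(sddr_dddr$p, 0.05)
  expect_lt(sddr_dddr$mean_lower, sddr_dddr$mean_higher)
  pre <- pairwise_distance_groups(b, "euclidean_order_vectors", "pre_fmt")
  rep_pre <- hierarchy_test(pre)
  pre_cmp <- rep_pre[rep_pre$lower == "SDDR" & rep_pre$higher == "DDDR", ]
  expect_gt(pre_cmp$p, 0.05)
})

test_that("identical group distributions give a one-sided p near 0.5", {
  d <- list(SDDR = structure(list(group = "SDDR", distances = c(1, 2, 3, 4),
                                  n_pairs = 4L, metric = "euclidean_order_vectors",
                                  phase = "post_fmt", empty = FALSE),
                             class = "distance_group"),
            DDDR = structure(list(group = "DDDR", distances = c(1, 2, 3, 4),
                                  n_pairs = 4L, metric = "euclidean_order_vectors",
                                  phase = "post_fmt", empty = FALSE),
                             class = "distance_group"))
  rep <- hierarchy_test(d)
  row <- rep[rep$lower == "SDDR" & rep$higher == "DDDR", ]
  expect_equal(row$p, 0.5, tolerance = 1e-12)
  expect_identical(row$stars, "ns")
})

test_that("the SDDR/DDDR gap grows with the donor-effect parameter", {
  gap <- vapply(c(0.1, 0.45, 0.8), function(d) {
    b <- generate_cohort(synth_config(n_taxa = 40, n_orders = 5, n_donors = 15,
                                      recipients_per_donor = 3, delta = d,
                                      rho = 0.1, seed = 301))
    gr <- pairwise_distance_groups(b, "euclidean_order_vectors")
    mean(gr$DDDR$distances) - mean(gr$SDDR$distances)
  }, numeric(1))
  expect_true(all(diff(gap) > 0))
})
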