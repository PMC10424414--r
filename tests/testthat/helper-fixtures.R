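# Shared fixtures, built once per test run.

.fx <- new.env(parent = emptyenv())

fx_taxa3 <- function() {
  c("k__B;p__P1;c__C;o__O;f__F;g__G;s__a",
    "k__B;p__P1;c__C;o__O;f__F;g__G;s__b",
    "k__B;p__P2;c__C2;o__O2;f__F2;g__G2;s__c")
}

# small table: 3 samples x 3 taxa, relative
fx_small_ft <- function() {
  m <- rbind(s1 = c(0.5, 0.3, 0.2),
             s2 = c(0.1, 0.4, 0.5),
             s3 = c(0.25, 0.25, 0.5))
  colnames(m) <- fx_taxa3()
  feature_table(m, "relative")
}

# random full-depth taxonomy of n leaves (unbalanced)
fx_random_taxa <- function(n, seed) {
  generate_taxonomy(n, max(2L, n %/% 5L), seed = seed)
}

# small synthetic cohort, cached by key
fx_cohort <- function(key = "default", ...) {
  if (is.null(.fx[[key]])) {
    .fx[[key]] <- generate_cohort(synth_config(...))
  }
  .fx[[key]]
}

# a small but real trained predictor (rf for speed), cached
fx_rf_model <- function() {
  if (is.null(.fx$rf_model)) {
    b <- fx_cohort("model_cohort", n_taxa = 40, n_orders = 5, n_donors = 30,
                   recipients_per_donor = 3, seed = 21)
    .fx$rf_model <- fit_predictor(prediction_task("shannon", horizon = 7), b,
                                  "rf", seed = 5)
    .fx$rf_bundle <- b
  }
  .fx$rf_model
}

fx_rf_bundle <- function() {
  fx_rf_model()
  .fx$rf_bundle
}

# full-size cohort (100 donors x 4 recipients) + rf model, for analyses that
# need realistic power (donor ranking, clinical contrasts)
fx_big_rf <- function() {
  if (is.null(.fx$big_rf)) {
    .fx$big_bundle <- generate_cohort(synth_config(seed = 21))
    .fx$big_rf <- fit_predictor(prediction_task("shannon", horizon = 7),
                                .fx$big_bundle, "rf", seed = 5)
  }
  .fx$big_rf
}

fx_big_bundle <- function() {
  fx_big_rf()
  .fx$big_bundle
}

# independent bottom-up recomputation of ancestor values by string bookkeeping
# (oracle for the image builder; shares no code with build_taxonomy_tree)
oracle_node_value <- function(taxa, values, prefix_key, depth) {
  labs <- strsplit(taxa, ";", fixed = TRUE)
  recurse <- function(key, d) {
    mine <- vapply(labs, function(l) paste(l[seq_len(d)], collapse = ";") == key,
                   logical(1))
    if (d == length(labs[[1L]])) return(values[which(mine)[1L]])
    kids <- unique(vapply(labs[mine], function(l)
      paste(l[seq_len(d + 1L)], collapse = ";"), character(1)))
    mean(vapply(kids, recurse, numeric(1), d = d + 1L))
  }
  recurse(prefix_key, depth)
}

oracle_image <- function(taxa, values, leaf_order) {
  labs <- strsplit(taxa, ";", fixed = TRUE)
  d <- length(labs[[1L]])
  pos <- match(leaf_order, taxa)
  img <- matrix(NA_real_, d, length(taxa))
  for (c in seq_along(pos)) {
    for (r in seq_len(d)) {
      key <- paste(labs[[pos[c]]][seq_len(r)], collapse = ";")
      img[r, c] <- oracle_node_value(taxa, values, key, r)
    }
  }
  img
}
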