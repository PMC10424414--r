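#' Genetic-algorithm configuration
#'
#' Parameters of the generative GA that searches donor-profile space for
#' transplants optimizing a predicted recipient outcome under a sparsity
#' penalty. Defaults follow the published protocol: population 100, 30 elites
#' selected per generation, mutation and recombination probabilities 0.3,
#' prediction horizon 7 days, 25 generations.
#'
#' @param population_size,n_select Population and elite-set sizes
#'   (`n_select < population_size`).
#' @param p_mutation,p_recombination Per-offspring operator probabilities.
#' @param gamma Sparsity weight `>= 0` multiplying the non-zero taxon count in
#'   the fitness.
#' @param mode `"maximize"` or `"minimize"` the predicted outcome.
#' @param horizon_days Days post-FMT at which the outcome is predicted.
#' @param max_generations Generation budget.
#' @param plateau_patience Optional early stop: end once the best fitness has
#'   not improved by more than 1e-6 for this many generations.
#' @param mutation_lambda Poisson rate of the number of taxa toggled per
#'   applied mutation (`k ~ Poisson(lambda) + 1`).
#' @param seed Integer seed; the full run is deterministic per seed.
#' @return A `ga_config`.
#' @export
ga_config <- function(population_size = 100, n_select = 30, p_mutation = 0.3,
                      p_recombination = 0.3, gamma = 0,
                      mode = c("maximize", "minimize"), horizon_days = 7,
                      max_generations = 25, plateau_patience = NULL,
                      mutation_lambda = 3, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(n_select < population_size, p_mutation >= 0, p_mutation <= 1,
            p_recombination >= 0, p_recombination <= 1, gamma >= 0,
            max_generations >= 1)
  structure(list(population_size = as.integer(population_size),
                 n_select = as.integer(n_select), p_mutation = p_mutation,
                 p_recombination = p_recombination, gamma = gamma, mode = mode,
                 horizon_days = horizon_days,
                 max_generations = as.integer(max_generations),
                 plateau_patience = plateau_patience,
                 mutation_lambda = mutation_lambda, seed = seed),
            class = "ga_config")
}

#' Sparsity-penalized GA fitness
#'
#' `fitness = s - nnz(b) * gamma` when maximizing; when minimizing the target,
#' minus the predicted property enters the same form:
#' `fitness = -s - nnz(b) * gamma`. `b` is the binary support mask of the
#' candidate (1 where abundance > 0), so zero-abundance taxa never affect
#' fitness.
#'
#' @param s Predicted outcome(s), finite.
#' @param b Binary mask vector, or matrix with one candidate per row.
#' @param gamma Sparsity weight `>= 0`.
#' @param mode `"maximize"` or `"minimize"`.
#' @return Numeric fitness value(s).
#' @export
#' @examples
#' ga_fitness(4.2, rep(1, 100), gamma = 0.01)  # 3.2
ga_fitness <- function(s, b, gamma = 0, mode = c("maximize", "minimize")) {
  mode <- match.arg(mode)
  if (gamma < 0) stop("gamma must be non-negative", call. = FALSE)
  if (!all(is.finite(s))) stop("non-finite predicted outcome", call. = FALSE)
  nnz <- if (is.matrix(b)) rowSums(b != 0) else sum(b != 0)
  base <- if (identical(mode, "maximize")) s else -s
  base - nnz * gamma
}

#' Expand a donor pool with simulated profiles
#'
#' Grows a small real donor cohort into a large candidate pool by
#' support-respecting convex mixtures of random donor pairs with per-taxon
#' lognormal jitter: taxa present in both parents are mixed `w*a + (1-w)*b`;
#' taxa exclusive to one parent are inherited with probability equal to that
#' parent's weight, preserving per-taxon prevalence in expectation. Profiles
#' are re-closed to the simplex. With `jitter_sd = 0` and `w = 1` the operator
#' degenerates to copying a parent.
#'
#' @param real_donors A `feature_table` of relative donor compositions.
#' @param n_total Total pool size (original donors are kept; must be
#'   `>= nrow(real_donors)`).
#' @param seed Integer seed.
#' @param jitter_sd Lognormal jitter SD on the natural-log scale.
#' @return A `feature_table` of `n_total` relative profiles (originals first).
#' @export
expand_donor_pool <- function(real_donors, n_total, seed = 1, jitter_sd = 0.3) {
  n0 <- nrow(real_donors)
  if (n0 < 2L) stop("need at least 2 real donors", call. = FALSE)
  if (n_total < n0) stop("n_total smaller than the real pool", call. = FALSE)
  m <- unclass(as_relative(real_donors))
  k <- ncol(m)
  n_new <- n_total - n0
  if (n_new == 0L) return(as_relative(real_donors))
  out <- with_seed(seed, {
    res <- matrix(0, n_new, k)
    for (i in seq_len(n_new)) {
      pick <- sample.int(n0, 2L)
      a <- m[pick[1L], ]; b <- m[pick[2L], ]
      w <- stats::runif(1)
      both <- a > 0 & b > 0
      only_a <- a > 0 & b == 0
      only_b <- b > 0 & a == 0
      x <- numeric(k)
      x[both] <- w * a[both] + (1 - w) * b[both]
      keep_a <- only_a & (stats::runif(k) < w)
      keep_b <- only_b & (stats::runif(k) < 1 - w)
      x[keep_a] <- a[keep_a]
      x[keep_b] <- b[keep_b]
      if (jitter_sd > 0) {
        nz <- x > 0
        x[nz] <- x[nz] * exp(stats::rnorm(sum(nz), 0, jitter_sd))
      }
      if (sum(x) <= 0) x <- a  # degenerate draw: fall back to parent
      res[i, ] <- x / sum(x)
    }
    res
  })
  colnames(out) <- colnames(m)
  rownames(out) <- sprintf("sim%04d", seq_len(n_new))
  feature_table(rbind(m, out), "relative")
}

#' Merged donor pool on a trained predictor's taxon axis
#'
#' Convenience: merges a bundle's donors with the model's recipe and closes
#' rows to relative abundance, yielding the `a_i` vectors the GA operates on.
#'
#' @param bundle A [cohort_bundle()].
#' @param model A `trained_predictor`.
#' @return A relative `feature_table` on `model$taxon_axis`.
#' @export
ga_donor_pool <- function(bundle, model) {
  merged <- merge_to_level(bundle$donors, model$recipe$merge_level,
                           model$recipe$merge_method)
  pool <- as_relative(merged)
  if (!identical(colnames(pool), model$taxon_axis))
    stop("donor pool axis does not match the trained taxon axis", call. = FALSE)
  pool
}

# --- internal operators (RNG comes from the caller's stream) ---

.ga_recombine <- function(a, b, p_recombination) {
  if (stats::runif(1) >= p_recombination) {
    return(if (stats::runif(1) < 0.5) a else b)
  }
  from_a <- stats::runif(length(a)) < 0.5
  x <- ifelse(from_a, a, b)
  if (sum(x) <= 0) x <- a
  x / sum(x)
}

.ga_mutate <- function(x, p_mutation, lambda, taxon_values) {
  if (stats::runif(1) >= p_mutation) return(x)
  k <- stats::rpois(1, lambda) + 1L
  idx <- sample.int(length(x), min(k, length(x)))
  for (j in idx) {
    if (x[j] > 0) {
      x[j] <- 0
    } else {
      vals <- taxon_values[[j]]
      if (length(vals)) x[j] <- vals[sample.int(length(vals), 1L)]
    }
  }
  if (sum(x) <= 0) return(x * 0 + 1 / length(x))  # degenerate: uniform fallback
  x / sum(x)
}

.ga_select_idx <- function(fitness, nnz, n_select) {
  ord <- order(-fitness, nnz, seq_along(fitness))
  ord[seq_len(n_select)]
}

#' Uniform crossover of two candidate donors
#'
#' With probability `p_recombination` the offspring takes each taxon's
#' abundance from either parent with equal probability and is re-closed to the
#' simplex; otherwise it is a clone of a random parent. Offspring support is a
#' subset of the union of the parents' supports.
#'
#' @param a,b Parent abundance vectors on one taxon axis.
#' @param p_recombination Probability of performing the crossover.
#' @param seed Integer seed.
#' @return Offspring abundance vector on the simplex.
#' @export
ga_recombine <- function(a, b, p_recombination = 0.3, seed = 1) {
  if (length(a) != length(b)) stop("parents on different taxon axes", call. = FALSE)
  with_seed(seed, .ga_recombine(a, b, p_recombination))
}

#' Mutate a candidate donor
#'
#' With probability `p_mutation`, toggles `Poisson(lambda) + 1` randomly
#' chosen taxa: a non-zero taxon is zeroed; a zero taxon switched on draws its
#' abundance from the pool's empirical non-zero distribution for that taxon.
#' The vector is re-closed and the support mask re-derived.
#'
#' @param x Candidate abundance vector on the simplex.
#' @param pool Matrix of pool profiles supplying the empirical per-taxon
#'   abundance distributions.
#' @param p_mutation Probability of applying the mutation.
#' @param lambda Poisson rate of the toggle count.
#' @param seed Integer seed.
#' @return Mutated abundance vector on the simplex.
#' @export
ga_mutate <- function(x, pool, p_mutation = 0.3, lambda = 3, seed = 1) {
  taxon_values <- lapply(seq_len(ncol(pool)), function(j) {
    v <- pool[, j]; v[v > 0]
  })
  with_seed(seed, .ga_mutate(x, p_mutation, lambda, taxon_values))
}

#' Select elite candidates
#'
#' Top `n_select` candidates by fitness; ties broken by fewer non-zero taxa,
#' then by position (stable).
#'
#' @param population Matrix of candidate profiles (rows on the simplex).
#' @param fitness Numeric fitness per row.
#' @param n_select Number of elites.
#' @return Integer row indices of the elites, fitness-ordered.
#' @export
ga_select <- function(population, fitness, n_select) {
  if (nrow(population) < n_select)
    stop("population smaller than n_select", call. = FALSE)
  .ga_select_idx(fitness, rowSums(population > 0), n_select)
}

# candidate's own value of the target property (for the triviality check)
.own_property <- function(task, pop) {
  if (identical(task$target, "shannon")) {
    as.numeric(shannon_diversity(pop))
  } else if (task$target %in% c("taxon_abundance", "taxon_presence")) {
    key <- format_taxonomy(parse_taxonomy(
      complete_taxonomy(colnames(pop), depth = task$level))[, seq_len(.rank_index(task$level)),
                                                            drop = FALSE])
    sel <- key == task$taxon
    if (!any(sel)) return(rep(NA_real_, nrow(pop)))
    rowSums(pop[, sel, drop = FALSE])
  } else {
    rep(NA_real_, nrow(pop))
  }
}

#' Run the generative genetic algorithm
#'
#' Evolves a population of candidate donor profiles against a trained
#' predictor: each generation, the predicted outcome at `horizon_days` is
#' computed for every candidate, converted to the sparsity-penalized fitness,
#' the `n_select` best candidates are kept unchanged as elites, and the
#' population is refilled with offspring bred from elite pairs by uniform
#' recombination (probability `p_recombination`) followed by mutation
#' (probability `p_mutation`; `Poisson(lambda)+1` taxa toggled, switched-on
#' taxa drawing abundance from the pool's empirical non-zero distribution).
#' Because elites persist, the best fitness is non-decreasing.
#'
#' @param config A [ga_config()].
#' @param model A `trained_predictor` for `config`'s target task.
#' @param donor_pool A relative `feature_table` on `model$taxon_axis`
#'   (see [ga_donor_pool()], [expand_donor_pool()]).
#' @return A `ga_result`: `best_fitness` and `mean_elite_nnz` trajectories,
#'   `generations` actually run, final `elites` (profiles), `elite_fitness`,
#'   `elite_predictions`, `triviality_scc` (Spearman between each final
#'   elite's own target property and its predicted recipient property), and
#'   `dominant_orders`.
#' @export
run_ga <- function(config, model, donor_pool) {
  stopifnot(inherits(config, "ga_config"), inherits(model, "trained_predictor"))
  pool <- unclass(as_relative(donor_pool))
  if (!identical(colnames(pool), model$taxon_axis))
    stop("donor pool is not on the model's taxon axis", call. = FALSE)
  if (nrow(pool) < config$population_size)
    stop("pool smaller than population_size; expand it first ",
         "(see expand_donor_pool)", call. = FALSE)
  k <- ncol(pool)
  taxon_values <- lapply(seq_len(k), function(j) {
    v <- pool[, j]; v[v > 0]
  })
  evaluate <- function(pop, tag) {
    rownames(pop) <- sprintf("%s_%03d", tag, seq_len(nrow(pop)))
    ft <- feature_table(pop, "relative")
    s <- unname(predict(model, ft, days_post_fmt = config$horizon_days))
    fit <- ga_fitness(s, pop > 0, config$gamma, config$mode)
    list(s = s, fitness = fit)
  }
  with_seed(config$seed, {
    pop <- pool[sample.int(nrow(pool), config$population_size), , drop = FALSE]
    best_traj <- numeric(0)
    nnz_traj <- numeric(0)
    ev <- NULL; elite_idx <- NULL
    for (gen in seq_len(config$max_generations)) {
      ev <- evaluate(pop, sprintf("g%02d", gen))
      elite_idx <- .ga_select_idx(ev$fitness, rowSums(pop > 0), config$n_select)
      best_traj[gen] <- max(ev$fitness)
      nnz_traj[gen] <- mean(rowSums(pop[elite_idx, , drop = FALSE] > 0))
      if (!is.null(config$plateau_patience) && gen > config$plateau_patience) {
        recent <- best_traj[(gen - config$plateau_patience):gen]
        if (max(recent) - min(recent) <= 1e-6) break
      }
      if (gen == config$max_generations) break
      elites <- pop[elite_idx, , drop = FALSE]
      n_off <- config$population_size - config$n_select
      offspring <- matrix(0, n_off, k)
      for (i in seq_len(n_off)) {
        pr <- sample.int(nrow(elites), 2L)
        child <- .ga_recombine(elites[pr[1L], ], elites[pr[2L], ],
                               config$p_recombination)
        offspring[i, ] <- .ga_mutate(child, config$p_mutation,
                                     config$mutation_lambda, taxon_values)
      }
      pop <- rbind(elites, offspring)
    }
    elites <- pop[elite_idx, , drop = FALSE]
    rownames(elites) <- sprintf("elite_%02d", seq_len(nrow(elites)))
    own <- .own_property(model$task, elites)
    preds <- ev$s[elite_idx]
    triv <- if (all(is.finite(own)) && stats::sd(own) > 0 && stats::sd(preds) > 0)
      metric_scc(own, preds) else NA_real_
    structure(list(config = config,
                   best_fitness = best_traj, mean_elite_nnz = nnz_traj,
                   generations = length(best_traj),
                   elites = elites, elite_fitness = ev$fitness[elite_idx],
                   elite_predictions = preds, triviality_scc = triv,
                   dominant_orders = dominant_orders_matrix(elites)),
              class = "ga_result")
  })
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("<ga_result> %d generations, best fitness %.4f, mean elite nnz %.1f\n",
              x$generations, x$best_fitness[x$generations],
              x$mean_elite_nnz[x$generations]))
  invisible(x)
}

dominant_orders_matrix <- function(profiles) {
  key <- format_taxonomy(parse_taxonomy(
    complete_taxonomy(colnames(profiles), depth = "order"))[, 1:4, drop = FALSE])
  agg <- t(rowsum(t(profiles), group = key))
  colMeans(agg)[order(-colMeans(agg))]
}

#' Dominant orders among elite profiles
#'
#' Mean relative contribution of each bacterial order across the final elite
#' donors, the community-composition summary of the designed transplants.
#'
#' @param result A `ga_result`.
#' @param top_k Number of orders to report.
#' @return Data frame `order`, `mean_fraction`, sorted decreasing; fractions
#'   over all orders sum to 1 (<= 1 for the reported subset).
#' @export
dominant_orders <- function(result, top_k = 10) {
  fr <- result$dominant_orders
  data.frame(order = names(fr), mean_fraction = unname(fr))[
    seq_len(min(top_k, length(fr))), , drop = FALSE]
}

#' First generation at which a fitness trajectory plateaus
#'
#' The first generation from which no later generation improves the best
#' fitness by more than `rel_tol` of the then-current best — i.e., the point
#' where meaningful per-generation improvements stop. This per-step reading
#' is invariant to how long the run is observed: an elitist GA on a
#' continuous search space accumulates vanishing improvements indefinitely,
#' so a cumulative remaining-gap criterion would grow with the observation
#' window rather than measure the algorithm.
#'
#' @param best_fitness Non-decreasing numeric trajectory.
#' @param rel_tol Relative per-generation improvement threshold (default 1%).
#' @return Integer generation index (1 if no improvement ever exceeds the
#'   threshold).
#' @export
ga_convergence_generation <- function(best_fitness, rel_tol = 0.01) {
  n <- length(best_fitness)
  if (n < 2L) return(1L)
  inc <- diff(best_fitness)
  thr <- rel_tol * pmax(abs(best_fitness[-n]), 1e-12)
  big <- which(inc > thr)
  if (!length(big)) 1L else as.integer(max(big) + 1L)
}
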