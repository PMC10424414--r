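#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the given seed, evaluates `expr`, and restores the caller's RNG state,
#' so library functions are reproducible per seed without clobbering the
#' session stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Spearman correlation coefficient
#' @param x,y Numeric vectors.
#' @return Spearman's rho.
#' @export
metric_scc <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  suppressWarnings(stats::cor(x, y, method = "spearman"))
}

#' Held-out coefficient of determination
#'
#' `R2 = 1 - SS_res / SS_tot` with the total sum of squares taken around the
#' held-out mean; can be negative when predictions are worse than the mean.
#'
#' @param truth,pred Numeric vectors.
#' @return R-squared.
#' @export
metric_r2 <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  ss_tot <- sum((truth - mean(truth))^2)
  if (ss_tot <= 0) return(NA_real_)
  1 - sum((truth - pred)^2) / ss_tot
}

#' Area under the ROC curve
#'
#' Probability that a random positive scores above a random negative (ties
#' counted half), computed with `pROC`.
#'
#' @param labels Binary 0/1 vector.
#' @param scores Numeric scores.
#' @return AUC in `[0, 1]`, or `NA` if a class is absent.
#' @export
metric_auc <- function(labels, scores) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) return(NA_real_)
  r <- pROC::roc(response = labels, predictor = scores, levels = c(0, 1),
                 direction = "<", quiet = TRUE)
  as.numeric(pROC::auc(r))
}

star_code <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}
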