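# The three group mean comparison approaches: sum scores + Welch's t-test,
# multigroup IRT model + likelihood ratio test, and EAP scores + Welch's
# t-test.

#' Sum scores with listwise deletion
#'
#' Adds up the numeric responses over `item_subset`; any person with a
#' missing response on the subset is excluded (scored `NA`).
#'
#' @param responses persons x items integer response matrix.
#' @param item_subset column indices to score (default all).
#' @return Numeric vector, one entry per person, `NA` for excluded persons.
#' @export
sum_scores <- function(responses, item_subset = seq_len(ncol(responses))) {
  if (length(item_subset) == 0L) stop("`item_subset` must be non-empty")
  rowSums(responses[, item_subset, drop = FALSE])  # NA propagates
}

#' Welch's two-sample t-test
#'
#' Two-sided independent-samples t-test without assuming equal variances
#' (Welch-Satterthwaite degrees of freedom). If both groups have zero
#' variance, the p-value is 1 when the means agree and 0 otherwise.
#'
#' @param x,y numeric score vectors (each of length >= 2).
#' @return List with `statistic`, `df`, `p_value`.
#' @export
welch_t_test <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L) stop("each group needs at least 2 scores")
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx + vy == 0) {
    eq <- isTRUE(all.equal(mean(x), mean(y)))
    return(list(statistic = if (eq) 0 else sign(mean(x) - mean(y)) * Inf,
                df = nx + ny - 2, p_value = if (eq) 1 else 0))
  }
  se2 <- vx / nx + vy / ny
  stat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(statistic = stat, df = df,
       p_value = 2 * stats::pt(abs(stat), df, lower.tail = FALSE))
}

#' Pooled-SD standardized mean difference
#'
#' `(mean_focal - mean_reference)` divided by the pooled standard deviation
#' with `(n - 1)` weights (the classical Cohen's d pooling).
#'
#' @param mean_f,sd_f,n_f focal group mean, SD, and size.
#' @param mean_r,sd_r,n_r reference group mean, SD, and size.
#' @return Standardized effect size.
#' @export
pooled_effect_size <- function(mean_f, sd_f, n_f, mean_r, sd_r, n_r) {
  if (sd_f < 0 || sd_r < 0) stop("SDs must be non-negative")
  pooled <- sqrt(((n_f - 1) * sd_f^2 + (n_r - 1) * sd_r^2) / (n_f + n_r - 2))
  if (pooled == 0) stop("pooled SD is zero; effect size undefined")
  (mean_f - mean_r) / pooled
}

.method_result <- function(method, prescreened, p_value, effect_size,
                           diagnostics = list()) {
  structure(list(method = method, prescreened = prescreened,
                 reject = is.finite(p_value) && p_value < 0.05,
                 p_value = p_value, effect_size = effect_size,
                 diagnostics = diagnostics),
            class = "method_result")
}

#' @export
print.method_result <- function(x, ...) {
  cat(sprintf("%s (%s): p = %.4g, %s, effect size = %.3f\n", x$method,
              if (x$prescreened) "prescreened" else "non-prescreened",
              x$p_value, if (x$reject) "reject" else "retain",
              x$effect_size))
  invisible(x)
}

#' Sum-score group comparison
#'
#' Sum scores (listwise deletion) per group, Welch's t-test at alpha 0.05
#' (two-sided), and the pooled-SD standardized mean difference.
#'
#' @param dataset a [simulate_dataset()] result.
#' @param item_subset items to score (default all).
#' @param prescreened flag recorded in the result.
#' @return A `method_result`.
#' @export
run_sum_score <- function(dataset, item_subset = NULL, prescreened = FALSE) {
  if (is.null(item_subset)) item_subset <- seq_along(dataset$items_ref)
  sr <- sum_scores(dataset$resp_ref, item_subset)
  sf <- sum_scores(dataset$resp_foc, item_subset)
  n_excl <- sum(is.na(sr)) + sum(is.na(sf))
  sr <- sr[!is.na(sr)]; sf <- sf[!is.na(sf)]
  if (length(sr) < 2L || length(sf) < 2L)
    stop("listwise deletion left a degenerate group")
  tt <- welch_t_test(sf, sr)
  es <- pooled_effect_size(mean(sf), stats::sd(sf), length(sf),
                           mean(sr), stats::sd(sr), length(sr))
  .method_result("sum_score", prescreened, tt$p_value, es,
                 list(n_excluded = n_excl, statistic = tt$statistic))
}

#' Calibrated item set with small calibration error
#'
#' Emulates an item bank pre-calibrated in a large sample: every parameter
#' of the reference items is perturbed by an independent U(-jiggle, jiggle)
#' draw. If a perturbed item's thresholds become non-monotone, that item's
#' perturbation is redrawn.
#'
#' @param items list of [grm_item()] (true reference parameters).
#' @param jiggle half-width of the perturbation (default 0.2).
#' @return List of [grm_item()] with every parameter within `jiggle` of its
#'   generating value.
#' @export
calibrate_items <- function(items, jiggle = 0.2) {
  lapply(items, function(it) {
    repeat {
      a <- it$a + stats::runif(1, -jiggle, jiggle)
      b <- it$b + stats::runif(length(it$b), -jiggle, jiggle)
      if (a > 0 && (length(b) == 1L || all(diff(b) > 0)))
        return(grm_item(a, b))
    }
  })
}

#' EAP-score group comparison
#'
#' EAP trait scores per person under pre-calibrated reference-group item
#' parameters and a standard normal prior, followed by Welch's t-test and
#' the pooled-SD effect size. Missing responses are simply omitted from the
#' posterior (no listwise deletion); a person with no observed responses on
#' the subset contributes the prior mean 0.
#'
#' @param dataset a [simulate_dataset()] result.
#' @param calibrated list of [grm_item()] from [calibrate_items()] (full
#'   item set, aligned with the dataset's items).
#' @param item_subset items used for scoring (default all).
#' @param prescreened flag recorded in the result.
#' @param grid quadrature grid carrying the N(0,1) prior.
#' @return A `method_result`.
#' @export
run_irt_eap <- function(dataset, calibrated, item_subset = NULL,
                        prescreened = FALSE, grid = latent_grid()) {
  if (is.null(item_subset)) item_subset <- seq_along(calibrated)
  items <- calibrated[item_subset]
  er <- eap_scores(dataset$resp_ref[, item_subset, drop = FALSE], items, grid)
  ef <- eap_scores(dataset$resp_foc[, item_subset, drop = FALSE], items, grid)
  tt <- welch_t_test(ef$mean, er$mean)
  es <- pooled_effect_size(mean(ef$mean), stats::sd(ef$mean), nrow(ef),
                           mean(er$mean), stats::sd(er$mean), nrow(er))
  .method_result("irt_eap", prescreened, tt$p_value, es,
                 list(statistic = tt$statistic))
}

#' IRT-model group comparison via the likelihood ratio test
#'
#' Fits the general multigroup GRM (focal mean and variance free) and the
#' restricted model (focal mean fixed at 0) under the same item constraint
#' plan, and tests the equal-means constraint with a 1-df likelihood ratio
#' test. The effect size is the estimated focal mean divided by the pooled
#' latent SD (reference SD 1, focal SD from the estimated variance, pooled
#' with group-size weights).
#'
#' @param dataset a [simulate_dataset()] result.
#' @param constraint_plan logical per item: `TRUE` = invariant across
#'   groups. Default all invariant (full measurement invariance). With DIF
#'   prescreening, flagged items stay in the model with group-specific
#'   (free) parameters.
#' @param prescreened flag recorded in the result.
#' @param grid quadrature grid.
#' @param control EM control list, see [fit_grm_multigroup()].
#' @param start optional warm-start `grm_fit` for the general model.
#' @return A `method_result` with convergence diagnostics.
#' @export
run_irt_model <- function(dataset, constraint_plan = NULL,
                          prescreened = FALSE, grid = latent_grid(),
                          control = list(), start = NULL) {
  J <- length(dataset$items_ref)
  if (is.null(constraint_plan)) constraint_plan <- rep(TRUE, J)
  n_cat <- dataset$condition$n_categories
  general <- fit_grm_multigroup(dataset$resp_ref, dataset$resp_foc,
                                constraint_plan = constraint_plan,
                                n_cat = n_cat, grid = grid,
                                control = control, start = start)
  restricted <- fit_grm_multigroup(dataset$resp_ref, dataset$resp_foc,
                                   constraint_plan = constraint_plan,
                                   mean_constraint = TRUE, n_cat = n_cat,
                                   grid = grid, control = control,
                                   start = general)
  lrt <- likelihood_ratio_test(general, restricted)
  n_r <- nrow(dataset$resp_ref); n_f <- nrow(dataset$resp_foc)
  pooled_sd <- sqrt(((n_r - 1) * 1 +
                     (n_f - 1) * general$groups$focal_variance) /
                    (n_r + n_f - 2))
  es <- general$groups$focal_mean / pooled_sd
  .method_result("irt_model", prescreened, lrt$p_value, es,
                 list(statistic = lrt$statistic, df = lrt$df,
                      converged = general$converged && restricted$converged,
                      lrt_flagged = lrt$flagged,
                      focal_mean = general$groups$focal_mean,
                      focal_variance = general$groups$focal_variance))
}
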