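# DIF prescreening: all-others-as-anchors (AOAA) likelihood-ratio scan,
# rank-based anchor selection, and anchored retest.

#' All-others-as-anchors DIF scan
#'
#' Each item is tested for DIF in turn: the constrained model holds every
#' item invariant across groups (focal moments free); the general model
#' frees the tested item's parameters in both groups. The likelihood ratio
#' statistic has degrees of freedom equal to the tested item's parameter
#' count.
#'
#' @param dataset a [simulate_dataset()] result.
#' @param grid quadrature grid.
#' @param control EM control list, see [fit_grm_multigroup()].
#' @return List: `table` (data.frame with per-item `statistic`, `df`,
#'   `p_value`, `a_constrained`, `converged`) and `base_fit` (the
#'   all-invariant fit, reusable as a warm start).
#' @export
aoaa_scan <- function(dataset, grid = latent_grid(), control = list()) {
  J <- length(dataset$items_ref)
  n_cat <- dataset$condition$n_categories
  base <- fit_grm_multigroup(dataset$resp_ref, dataset$resp_foc,
                             constraint_plan = rep(TRUE, J), n_cat = n_cat,
                             grid = grid, control = control)
  stat <- df <- pval <- numeric(J)
  conv <- logical(J)
  for (j in seq_len(J)) {
    plan <- rep(TRUE, J)
    plan[j] <- FALSE
    fit_j <- fit_grm_multigroup(dataset$resp_ref, dataset$resp_foc,
                                constraint_plan = plan, n_cat = n_cat,
                                grid = grid, control = control, start = base)
    lrt <- likelihood_ratio_test(fit_j, base)
    stat[j] <- lrt$statistic
    df[j] <- lrt$df
    pval[j] <- lrt$p_value
    conv[j] <- fit_j$converged
  }
  list(table = data.frame(
         item = seq_len(J), statistic = stat, df = df, p_value = pval,
         a_constrained = vapply(base$items_ref, `[[`, numeric(1), "a"),
         converged = conv & base$converged),
       base_fit = base)
}

#' Rank-based anchor selection
#'
#' Selects `k` presumed-invariant anchor items from an AOAA scan: if at
#' least `k` items are non-significant at alpha 0.05, the `k` of those with
#' the largest constrained-fit discriminations; otherwise the `k` items
#' with the smallest scan statistics. Ties break by item id.
#'
#' @param scan scan table from [aoaa_scan()].
#' @param k number of anchors, default `round(0.2 * J)` with a floor of 1.
#' @return Integer vector of anchor item indices (sorted).
#' @export
select_anchors <- function(scan, k = NULL) {
  J <- nrow(scan)
  if (is.null(k)) k <- max(1L, round(0.2 * J))
  stopifnot(k >= 1L, k <= J)
  nonsig <- scan$item[scan$p_value >= 0.05]
  if (length(nonsig) >= k) {
    ord <- order(-scan$a_constrained[nonsig], scan$item[nonsig])
    anchors <- nonsig[ord][seq_len(k)]
  } else {
    ord <- order(scan$statistic, scan$item)
    anchors <- scan$item[ord][seq_len(k)]
  }
  sort(anchors)
}

#' Anchored DIF retest
#'
#' Retests every non-anchor for DIF against the metric fixed by the
#' anchors. The general model holds only the anchors invariant (all
#' non-anchors group-specific); for each non-anchor j, the restricted model
#' additionally constrains item j invariant, isolating a per-item test with
#' df equal to the item's parameter count.
#'
#' @param dataset a [simulate_dataset()] result.
#' @param anchors anchor item indices.
#' @inheritParams aoaa_scan
#' @return data.frame with one row per non-anchor: `item`, `statistic`,
#'   `df`, `p_value`, `dif_flag` (p < 0.05), `converged`.
#' @export
retest_with_anchors <- function(dataset, anchors, grid = latent_grid(),
                                control = list()) {
  J <- length(dataset$items_ref)
  n_cat <- dataset$condition$n_categories
  non_anchors <- setdiff(seq_len(J), anchors)
  plan_gen <- seq_len(J) %in% anchors
  general <- fit_grm_multigroup(dataset$resp_ref, dataset$resp_foc,
                                constraint_plan = plan_gen, n_cat = n_cat,
                                grid = grid, control = control)
  out <- data.frame(item = non_anchors, statistic = NA_real_, df = NA_real_,
                    p_value = NA_real_, dif_flag = FALSE, converged = NA)
  for (i in seq_along(non_anchors)) {
    j <- non_anchors[i]
    plan <- plan_gen
    plan[j] <- TRUE
    fit_j <- fit_grm_multigroup(dataset$resp_ref, dataset$resp_foc,
                                constraint_plan = plan, n_cat = n_cat,
                                grid = grid, control = control,
                                start = general)
    lrt <- likelihood_ratio_test(general, fit_j)
    out$statistic[i] <- lrt$statistic
    out$df[i] <- lrt$df
    out$p_value[i] <- lrt$p_value
    out$dif_flag[i] <- lrt$p_value < 0.05
    out$converged[i] <- fit_j$converged && general$converged
  }
  out
}

#' DIF prescreening pipeline
#'
#' Composes [aoaa_scan()], [select_anchors()], and [retest_with_anchors()].
#' The clean item set (anchors plus retest-nonsignificant items) feeds the
#' sum-score and EAP approaches; the flagged items stay in the IRT-model
#' approach with group-specific parameters.
#'
#' @inheritParams aoaa_scan
#' @return A `prescreen_outcome`: `anchors`, `clean_items`, `dif_items`
#'   (integer index vectors partitioning the item set), `constraint_plan`
#'   (logical, `TRUE` = invariant, for [run_irt_model()]), plus the scan and
#'   retest tables.
#' @export
prescreen <- function(dataset, grid = latent_grid(), control = list()) {
  J <- length(dataset$items_ref)
  scan <- aoaa_scan(dataset, grid, control)
  anchors <- select_anchors(scan$table)
  retest <- retest_with_anchors(dataset, anchors, grid, control)
  dif_items <- sort(retest$item[retest$dif_flag])
  clean <- sort(union(anchors, setdiff(retest$item, dif_items)))
  structure(list(
    anchors = anchors,
    clean_items = clean,
    dif_items = dif_items,
    constraint_plan = !(seq_len(J) %in% dif_items),
    scan = scan$table,
    retest = retest
  ), class = "prescreen_outcome")
}

#' @export
print.prescreen_outcome <- function(x, ...) {
  cat(sprintf("DIF prescreening: anchors {%s}; clean items {%s}; DIF items {%s}\n",
              paste(x$anchors, collapse = ","),
              paste(x$clean_items, collapse = ","),
              if (length(x$dif_items)) paste(x$dif_items, collapse = ",")
              else "none"))
  invisible(x)
}
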