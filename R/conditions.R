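# The simulation design: seven two-level data-generation features crossed
# with two true focal means.

#' Specify one simulation condition
#'
#' @param n_per_group subjects per group, 100 or 400.
#' @param n_items number of items, 5 or 20.
#' @param discrimination `"high"` or `"low"` item discriminations.
#' @param n_categories 2 (dichotomous) or 5 (polytomous).
#' @param thresholds_mode `"homogeneous"` or `"diverse"`.
#' @param dif `"present"` or `"absent"`.
#' @param missing `"present"` or `"absent"` (30% of subjects missing 20% of
#'   items, missing at random).
#' @param true_focal_mean 0 (Type I error arm) or 0.5 (power arm), z-metric.
#' @return A `condition_spec` object.
#' @export
condition_spec <- function(n_per_group, n_items, discrimination,
                           n_categories, thresholds_mode, dif, missing,
                           true_focal_mean) {
  spec <- list(
    n_per_group = as.integer(n_per_group),
    n_items = as.integer(n_items),
    discrimination = match.arg(discrimination, c("high", "low")),
    n_categories = as.integer(n_categories),
    thresholds_mode = match.arg(thresholds_mode,
                                c("homogeneous", "diverse")),
    dif = match.arg(dif, c("present", "absent")),
    missing = match.arg(missing, c("present", "absent")),
    true_focal_mean = as.numeric(true_focal_mean)
  )
  stopifnot(spec$n_per_group %in% c(100L, 400L),
            spec$n_items %in% c(5L, 20L),
            spec$n_categories %in% c(2L, 5L),
            spec$true_focal_mean %in% c(0, 0.5))
  structure(spec, class = "condition_spec")
}

#' Full crossing of the simulation design
#'
#' All 2^7 combinations of the seven two-level data-generation features,
#' crossed with the two true focal means: 256 cells.
#'
#' @return data.frame with one row per condition and a `condition_id`
#'   column.
#' @export
build_condition_grid <- function() {
  g <- expand.grid(
    n_per_group = c(100L, 400L),
    n_items = c(5L, 20L),
    discrimination = c("high", "low"),
    n_categories = c(2L, 5L),
    thresholds_mode = c("homogeneous", "diverse"),
    dif = c("present", "absent"),
    missing = c("present", "absent"),
    true_focal_mean = c(0, 0.5),
    stringsAsFactors = FALSE,
    KEEP.OUT.ATTRS = FALSE
  )
  cbind(condition_id = seq_len(nrow(g)), g)
}

#' Turn a condition-grid row into a `condition_spec`
#'
#' @param row one-row data.frame (or list) with the condition fields.
#' @return A [condition_spec()].
#' @export
as_condition_spec <- function(row) {
  condition_spec(row$n_per_group, row$n_items, row$discrimination,
                 row$n_categories, row$thresholds_mode, row$dif,
                 row$missing, row$true_focal_mean)
}
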