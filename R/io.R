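# Plain-text interfaces: item parameter tables, wide/long response tables,
# results and summary CSVs, and JSON provenance sidecars.

#' Item lists and item parameter tables
#'
#' `items_to_df` serializes a list of [grm_item()] to the item parameter
#' table layout (`item_id`, `V`, `a`, `b1`..`b4`, trailing `NA` for
#' dichotomous items); `df_to_items` inverts it. `write_item_table` /
#' `read_item_table` do the same through a CSV file, and also round-trip
#' item banks.
#'
#' @param items list of [grm_item()].
#' @param item_ids optional ids (default sequential).
#' @return `items_to_df`: a data.frame; `df_to_items`: a list of
#'   [grm_item()].
#' @export
items_to_df <- function(items, item_ids = seq_along(items)) {
  b <- t(vapply(items, function(it) {
    out <- rep(NA_real_, 4L)
    out[seq_along(it$b)] <- it$b
    out
  }, numeric(4)))
  data.frame(item_id = item_ids,
             V = vapply(items, n_categories, integer(1)),
             a = vapply(items, `[[`, numeric(1), "a"),
             b1 = b[, 1], b2 = b[, 2], b3 = b[, 3], b4 = b[, 4])
}

#' @rdname items_to_df
#' @param df data.frame in the item table layout.
#' @export
df_to_items <- function(df) {
  items <- lapply(seq_len(nrow(df)), function(i) {
    b <- as.numeric(df[i, c("b1", "b2", "b3", "b4")])
    grm_item(df$a[i], b[seq_len(df$V[i] - 1L)])
  })
  attr(items, "item_ids") <- df$item_id
  items
}

#' @rdname items_to_df
#' @param path file path.
#' @export
write_item_table <- function(items, path, item_ids = seq_along(items)) {
  df <- if (is.data.frame(items)) items else items_to_df(items, item_ids)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname items_to_df
#' @export
read_item_table <- function(path) {
  df <- utils::read.csv(path)
  df_to_items(df)
}

#' Response tables in wide and long format
#'
#' Wide: `person_id`, `group`, `item_1`..`item_J` (empty cell = missing).
#' Long: `person_id`, `group`, `item_id`, `response` (`NA` = missing).
#'
#' @param dataset a [simulate_dataset()] result (or any list with
#'   `resp_ref` / `resp_foc` matrices).
#' @return data.frame in the requested format.
#' @export
dataset_to_wide <- function(dataset) {
  J <- ncol(dataset$resp_ref)
  resp <- rbind(dataset$resp_ref, dataset$resp_foc)
  colnames(resp) <- paste0("item_", seq_len(J))
  data.frame(person_id = seq_len(nrow(resp)),
             group = rep(c("reference", "focal"),
                         c(nrow(dataset$resp_ref), nrow(dataset$resp_foc))),
             resp)
}

#' @rdname dataset_to_wide
#' @export
dataset_to_long <- function(dataset) {
  wide <- dataset_to_wide(dataset)
  J <- ncol(wide) - 2L
  long <- stats::reshape(wide, direction = "long",
                         varying = paste0("item_", seq_len(J)),
                         v.names = "response", timevar = "item_id",
                         idvar = "person_id")
  long <- long[order(long$person_id, long$item_id),
               c("person_id", "group", "item_id", "response")]
  rownames(long) <- NULL
  long
}

#' @rdname dataset_to_wide
#' @param path file path.
#' @param format `"wide"` or `"long"`.
#' @export
write_response_table <- function(dataset, path,
                                 format = c("wide", "long")) {
  format <- match.arg(format)
  df <- if (format == "wide") dataset_to_wide(dataset)
        else dataset_to_long(dataset)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write study outputs
#'
#' `write_results_csv` writes the long results table; `write_summary_csv`
#' writes the three summary tables (`type1`, `power`, `mae`) as separate
#' CSVs with a common prefix.
#'
#' @param study a `grm_study` or its long results data.frame.
#' @param path output CSV path.
#' @export
write_results_csv <- function(study, path) {
  df <- if (inherits(study, "grm_study")) study$results else study
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_results_csv
#' @param summaries a [summarize_study()] result.
#' @param prefix path prefix; files are `<prefix>_type1.csv` etc.
#' @export
write_summary_csv <- function(summaries, prefix) {
  paths <- character(0)
  for (nm in names(summaries)) {
    if (is.null(summaries[[nm]])) next
    p <- paste0(prefix, "_", nm, ".csv")
    utils::write.csv(summaries[[nm]], p, row.names = FALSE, na = "")
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' JSON provenance sidecar for a replication
#'
#' Records the seed, condition, drawn bank item ids, DIF draws, and the
#' prescreening outcome for audit.
#'
#' @param record a [run_replication()] result.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @export
replication_sidecar <- function(record, path = NULL) {
  ps <- record$prescreen
  x <- list(
    seed = record$seed,
    condition = unclass(record$condition),
    item_ids = record$item_ids,
    dtf = record$dtf,
    prescreen = list(anchors = ps$anchors, clean_items = ps$clean_items,
                     dif_items = ps$dif_items,
                     scan_statistics = ps$scan$statistic,
                     scan_p = ps$scan$p_value),
    methods = lapply(record$results, function(r)
      list(method = r$method, prescreened = r$prescreened,
           reject = r$reject, p_value = r$p_value,
           effect_size = r$effect_size))
  )
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
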