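# Study runner: seeded replications over the condition grid and the
# Type I error / power / effect-size-MAE summary tables.

#' Derive a per-replication seed from a master seed
#'
#' Two multiplicative-congruential scrambles keep every intermediate value
#' below 2^31 while spreading (condition, replication) pairs across the seed
#' space, so each replication is independently reproducible regardless of
#' execution order.
#'
#' @param master_seed integer master seed.
#' @param condition_id condition index.
#' @param rep replication index.
#' @return Integer seed in `[1, 2147483646]`.
#' @export
derive_seed <- function(master_seed, condition_id, rep) {
  m <- 2147483647
  s <- (abs(as.numeric(master_seed)) %% m)
  s <- (s * 48271) %% m
  s <- (s + condition_id * 100003 + rep * 7919) %% m
  s <- (s * 48271) %% m
  as.integer(s %% (m - 1)) + 1L
}

#' Build the four generating item banks
#'
#' One bank per item type x discrimination level, generated from the
#' current RNG state.
#'
#' @param size items per bank (default 10000).
#' @return Named list of [build_item_bank()] results, keyed
#'   `"<item_type>.<level>"`.
#' @export
build_bank_set <- function(size = 10000L) {
  out <- list()
  for (it in c("dichotomous", "polytomous"))
    for (lev in c("high", "low"))
      out[[paste(it, lev, sep = ".")]] <- build_item_bank(it, lev, size)
  out
}

.bank_for <- function(banks, condition) {
  key <- paste(if (condition$n_categories == 2L) "dichotomous"
               else "polytomous", condition$discrimination, sep = ".")
  banks[[key]]
}

#' Run one replication of the study
#'
#' Generates one data set, runs DIF prescreening once, and applies all six
#' method x prescreening analyses to the same data (paired contrasts). The
#' non-prescreened arms use all items (full invariance for the IRT model,
#' the full calibrated set for EAP); the prescreened arms use the clean
#' item set and, for the IRT model, free parameters on flagged items.
#'
#' @param condition a [condition_spec()].
#' @param seed replication seed (see [derive_seed()]).
#' @param banks a [build_bank_set()] result.
#' @param grid quadrature grid.
#' @param control EM control list.
#' @return A `replication_record`: the six `method_result`s, the DTF effect
#'   size (DIF conditions only), prescreening outcome, seed, and condition.
#' @export
run_replication <- function(condition, seed, banks, grid = latent_grid(),
                            control = list()) {
  set.seed(seed)
  dataset <- simulate_dataset(condition, .bank_for(banks, condition))
  calibrated <- calibrate_items(dataset$items_ref)
  ps <- prescreen(dataset, grid, control)

  safely <- function(method, prescreened, expr) {
    tryCatch(expr, error = function(e)
      .method_result(method, prescreened, NA_real_, NA_real_,
                     list(error = conditionMessage(e))))
  }
  results <- list(
    safely("sum_score", FALSE, run_sum_score(dataset)),
    safely("sum_score", TRUE,
           run_sum_score(dataset, ps$clean_items, prescreened = TRUE)),
    safely("irt_eap", FALSE, run_irt_eap(dataset, calibrated, grid = grid)),
    safely("irt_eap", TRUE,
           run_irt_eap(dataset, calibrated, ps$clean_items,
                       prescreened = TRUE, grid = grid)),
    safely("irt_model", FALSE,
           run_irt_model(dataset, grid = grid, control = control)),
    safely("irt_model", TRUE,
           run_irt_model(dataset, ps$constraint_plan, prescreened = TRUE,
                         grid = grid, control = control))
  )
  dtf <- if (condition$dif == "present")
    dtf_effect_size(dataset$items_ref, dataset$items_foc,
                    dataset$theta_foc)$effect_size
  else NA_real_

  structure(list(condition = condition, seed = seed, results = results,
                 dtf = dtf, prescreen = ps,
                 item_ids = dataset$item_ids),
            class = "replication_record")
}

# One replication record -> six long-format rows
.record_rows <- function(record, condition_id = NA_integer_,
                         rep = NA_integer_) {
  cond <- record$condition
  do.call(rbind, lapply(record$results, function(r) {
    data.frame(
      condition_id = condition_id, rep = rep, seed = record$seed,
      n_per_group = cond$n_per_group, n_items = cond$n_items,
      discrimination = cond$discrimination,
      n_categories = cond$n_categories,
      thresholds_mode = cond$thresholds_mode,
      dif = cond$dif, missing = cond$missing,
      true_focal_mean = cond$true_focal_mean,
      method = r$method,
      prescreened = r$prescreened,
      reject = if (is.na(r$p_value)) NA else r$reject,
      p_value = r$p_value,
      effect_size = r$effect_size,
      dtf = record$dtf,
      error = if (is.null(r$diagnostics$error)) NA_character_
              else r$diagnostics$error,
      stringsAsFactors = FALSE
    )
  }))
}

#' Run the simulation study
#'
#' Executes `n_reps` seeded replications for every row of a condition grid.
#' Per-replication seeds derive from `(master_seed, condition_id, rep)`, so
#' results do not depend on execution order. A replication whose data
#' generation fails (e.g. an infeasible homogeneous item draw) is redrawn
#' with a derived retry seed and counted.
#'
#' @param grid data.frame of conditions (see [build_condition_grid()]; any
#'   subset of its rows).
#' @param n_reps replications per condition (the full study used 450;
#'   reduced runs are labeled in the output).
#' @param master_seed integer master seed; also seeds the item banks.
#' @param banks optional pre-built [build_bank_set()]; by default banks are
#'   generated from `derive_seed(master_seed, 0, 0)`.
#' @param quad_grid quadrature grid.
#' @param control EM control list.
#' @param progress print a line per condition.
#' @return A `grm_study`: `results` (long data.frame, six rows per
#'   replication), `records` (list of `replication_record`), `n_reps`,
#'   `master_seed`, and a `diagnostics` list (retry and error counts).
#' @export
run_study <- function(grid, n_reps = 450L, master_seed = 1L, banks = NULL,
                      quad_grid = latent_grid(), control = list(),
                      progress = FALSE) {
  if (is.null(banks)) {
    set.seed(derive_seed(master_seed, 0L, 0L))
    banks <- build_bank_set()
  }
  records <- list()
  rows <- vector("list", nrow(grid) * n_reps)
  retries <- 0L
  k <- 0L
  for (ci in seq_len(nrow(grid))) {
    cond <- as_condition_spec(grid[ci, ])
    cid <- if ("condition_id" %in% names(grid)) grid$condition_id[ci] else ci
    if (progress)
      message(sprintf("condition %d/%d (id %d)", ci, nrow(grid), cid))
    for (r in seq_len(n_reps)) {
      seed <- derive_seed(master_seed, cid, r)
      rec <- NULL
      for (attempt in 0:25) {
        rec <- tryCatch(
          run_replication(cond, seed, banks, quad_grid, control),
          error = function(e) NULL)
        if (!is.null(rec)) break
        retries <- retries + 1L
        seed <- derive_seed(seed, cid, 1000L + attempt)
      }
      if (is.null(rec))
        stop("replication failed repeatedly for condition ", cid)
      k <- k + 1L
      records[[k]] <- rec
      rows[[k]] <- .record_rows(rec, cid, r)
    }
  }
  results <- do.call(rbind, rows[seq_len(k)])
  structure(list(results = results, records = records, n_reps = n_reps,
                 master_seed = master_seed,
                 diagnostics = list(
                   retries = retries,
                   n_errors = sum(!is.na(results$error)))),
            class = "grm_study")
}

#' Summarize a study into Type I error, power, and MAE tables
#'
#' Type I error rows come from cells with true focal mean 0, power rows
#' from cells with true focal mean 0.5, and the MAE table covers all cells
#' using `|estimated - true|` averaged over replications. Each table is
#' expanded by method and prescreening status (six rows per design cell).
#'
#' @param results long results data.frame (from [run_study()]`$results`) or
#'   a `grm_study`.
#' @return List of data.frames `type1`, `power`, `mae`, each with the seven
#'   design features, `method`, `prescreened`, the outcome column
#'   (`rate` or `mae`), and `n_reps`.
#' @export
summarize_study <- function(results) {
  if (inherits(results, "grm_study")) results <- results$results
  keys <- c("n_per_group", "n_items", "discrimination", "n_categories",
            "thresholds_mode", "dif", "missing", "true_focal_mean",
            "method", "prescreened")
  agg <- function(df, value, fun, out_name) {
    if (nrow(df) == 0L) return(NULL)
    res <- stats::aggregate(df[[value]], df[keys],
                            function(z) fun(z[!is.na(z)]))
    cnt <- stats::aggregate(df[[value]], df[keys],
                            function(z) sum(!is.na(z)))
    names(res)[ncol(res)] <- out_name
    res$n_reps <- cnt$x
    res[do.call(order, unname(res[keys])), , drop = FALSE]
  }
  results$abs_err <- abs(results$effect_size - results$true_focal_mean)
  list(
    type1 = agg(results[results$true_focal_mean == 0, ], "reject", mean,
                "rate"),
    power = agg(results[results$true_focal_mean == 0.5, ], "reject", mean,
                "rate"),
    mae = agg(results, "abs_err", mean, "mae")
  )
}
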