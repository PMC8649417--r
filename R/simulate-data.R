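# Data-generating phase: true scores, DIF injection, GRM response
# simulation, MAR missingness, and the differential-test-functioning (DTF)
# effect size.

#' Draw true latent trait scores
#'
#' Reference group traits are N(0,1); focal group traits are N(mean, 1),
#' with the focal mean doubling as the true effect size (z-metric).
#'
#' @param n number of subjects.
#' @param mean latent mean (0 or 0.5 in the study design).
#' @return Numeric vector of traits.
#' @export
draw_true_scores <- function(n, mean = 0) {
  stats::rnorm(n, mean, 1)
}

#' Inject directional DIF into an item set
#'
#' Flags `round(prop * J)` randomly chosen items and disadvantages the
#' focal group on them: focal discrimination is lowered by a U(0, 0.3) draw
#' and all of the item's thresholds are raised by one shared U(0.5, 0.7)
#' draw (one magnitude per item, keeping category ordering intact).
#' Reference parameters are returned untouched.
#'
#' @param items list of [grm_item()] (reference parameters).
#' @param prop proportion of items receiving DIF (default 0.4).
#' @return List: `items_focal`, logical `dif_flags`, and per-item `a_shift`
#'   / `b_shift` audit vectors (`NA` for unflagged items).
#' @export
apply_dif <- function(items, prop = 0.4) {
  J <- length(items)
  k <- round(prop * J)
  flags <- rep(FALSE, J)
  a_shift <- b_shift <- rep(NA_real_, J)
  if (k > 0L) {
    flagged <- sample.int(J, k)
    flags[flagged] <- TRUE
    a_shift[flagged] <- stats::runif(k, 0, 0.3)
    b_shift[flagged] <- stats::runif(k, 0.5, 0.7)
  }
  focal <- items
  for (j in which(flags))
    focal[[j]] <- grm_item(items[[j]]$a - a_shift[j],
                           items[[j]]$b + b_shift[j])
  list(items_focal = focal, dif_flags = flags,
       a_shift = a_shift, b_shift = b_shift)
}

#' Simulate GRM item responses
#'
#' Each cell is an independent draw from the categorical distribution given
#' by [category_prob()] at the subject's trait value.
#'
#' @param traits vector of latent trait values.
#' @param items list of [grm_item()].
#' @return Integer matrix (subjects x items) with categories `0..V-1`.
#' @export
simulate_responses <- function(traits, items) {
  stopifnot(all(is.finite(traits)))
  n <- length(traits)
  J <- length(items)
  out <- matrix(NA_integer_, n, J)
  for (j in seq_len(J)) {
    p <- category_prob(items[[j]], traits)
    if (is.null(dim(p))) p <- matrix(p, nrow = 1L)
    V <- ncol(p)
    cum <- p %*% upper.tri(diag(V), diag = TRUE)  # cum[, v] = P(u < v)
    out[, j] <- as.integer(rowSums(stats::runif(n) >= cum[, seq_len(V - 1L),
                                                         drop = FALSE]))
  }
  out
}

#' Impose missing-at-random responses
#'
#' Selects `round(0.2 * J)` items as missingness-eligible and deletes their
#' responses for `round(prop_subjects * N)` subjects. Subjects are sampled
#' without replacement with probability increasing in their mean observed
#' response on the non-eligible items (a logistic transform of the
#' standardized mean), so the mechanism is missing at random: selection
#' depends only on responses that remain observed.
#'
#' @param responses subjects x items integer response matrix (complete).
#' @param prop_items proportion of items eligible for missingness
#'   (default 0.2).
#' @param prop_subjects proportion of subjects receiving missing responses
#'   (default 0.3).
#' @return List: `responses` (with `NA`s), logical `mask` of deleted cells,
#'   `eligible_items`, `subjects`.
#' @export
impose_mar_missingness <- function(responses, prop_items = 0.2,
                                   prop_subjects = 0.3) {
  n <- nrow(responses)
  J <- ncol(responses)
  n_elig <- round(prop_items * J)
  n_subj <- round(prop_subjects * n)
  eligible <- sort(sample.int(J, n_elig))
  keep <- setdiff(seq_len(J), eligible)
  score <- rowMeans(responses[, keep, drop = FALSE])
  z <- if (stats::sd(score) > 0) (score - mean(score)) / stats::sd(score)
       else rep(0, n)
  w <- stats::plogis(z)
  subjects <- sort(sample.int(n, n_subj, prob = w))
  mask <- matrix(FALSE, n, J)
  mask[subjects, eligible] <- TRUE
  responses[mask] <- NA_integer_
  list(responses = responses, mask = mask, eligible_items = eligible,
       subjects = subjects)
}

#' Expected test score under known parameters
#'
#' `E[sum_j u_j | theta]` evaluated at each trait value.
#'
#' @param items list of [grm_item()].
#' @param traits vector of trait values.
#' @return Numeric vector of expected test scores.
#' @export
expected_test_score <- function(items, traits) {
  out <- numeric(length(traits))
  for (it in items) {
    p <- category_prob(it, traits)
    if (is.null(dim(p))) p <- matrix(p, nrow = 1L)
    out <- out + as.vector(p %*% (seq_len(ncol(p)) - 1L))
  }
  out
}

#' Differential test functioning effect size
#'
#' Standardized expected-test-score difference over the focal sample: the
#' mean, across focal-group trait draws, of the expected test score under
#' the focal parameters minus that under the reference parameters, divided
#' by the standard deviation of the reference-parameter expected test
#' scores in that same sample. Negative values indicate a disadvantaged
#' focal group; the value is exactly 0 when the two parameter sets agree.
#'
#' @param items_ref,items_focal aligned lists of [grm_item()].
#' @param focal_traits focal-group trait draws.
#' @return List with `effect_size`, the unstandardized `numerator` (signed
#'   expected-score difference) and the `sd` used as denominator.
#' @export
dtf_effect_size <- function(items_ref, items_focal, focal_traits) {
  stopifnot(length(items_ref) == length(items_focal))
  ets_ref <- expected_test_score(items_ref, focal_traits)
  ets_foc <- expected_test_score(items_focal, focal_traits)
  numer <- mean(ets_foc - ets_ref)
  sd_ts <- stats::sd(ets_ref)
  list(effect_size = if (numer == 0) 0 else numer / sd_ts,
       numerator = numer, sd = sd_ts)
}

#' Generate one simulated two-group data set
#'
#' Composes the data-generating phase for one condition: item draw from the
#' bank, true score draws, DIF injection (when present), GRM response
#' simulation per group, and MAR missingness (when present).
#'
#' @param condition a [condition_spec()].
#' @param bank a [build_item_bank()] result matching the condition's item
#'   type and discrimination level.
#' @return A `grm_dataset`: response matrices `resp_ref` / `resp_foc`,
#'   trait vectors, reference and focal item lists, `dif_flags`,
#'   missingness info, and the condition.
#' @export
simulate_dataset <- function(condition, bank) {
  stopifnot(inherits(condition, "condition_spec"),
            inherits(bank, "grm_item_bank"))
  want_type <- if (condition$n_categories == 2L) "dichotomous" else "polytomous"
  if (!identical(attr(bank, "item_type"), want_type) ||
      !identical(attr(bank, "discrimination_level"), condition$discrimination))
    stop("bank does not match the condition (item type / discrimination)")

  items <- draw_items(bank, condition$n_items, condition$thresholds_mode)
  n <- condition$n_per_group
  theta_ref <- draw_true_scores(n, 0)
  theta_foc <- draw_true_scores(n, condition$true_focal_mean)

  if (condition$dif == "present") {
    dif <- apply_dif(items)
  } else {
    dif <- list(items_focal = items, dif_flags = rep(FALSE, length(items)),
                a_shift = rep(NA_real_, length(items)),
                b_shift = rep(NA_real_, length(items)))
  }

  resp_ref <- simulate_responses(theta_ref, items)
  resp_foc <- simulate_responses(theta_foc, dif$items_focal)

  miss <- NULL
  if (condition$missing == "present") {
    pooled <- rbind(resp_ref, resp_foc)
    miss <- impose_mar_missingness(pooled)
    resp_ref <- miss$responses[seq_len(n), , drop = FALSE]
    resp_foc <- miss$responses[n + seq_len(n), , drop = FALSE]
  }

  structure(list(
    resp_ref = resp_ref, resp_foc = resp_foc,
    theta_ref = theta_ref, theta_foc = theta_foc,
    items_ref = items, items_foc = dif$items_focal,
    dif_flags = dif$dif_flags,
    dif_a_shift = dif$a_shift, dif_b_shift = dif$b_shift,
    item_ids = attr(items, "item_ids"),
    missing = miss,
    condition = condition
  ), class = "grm_dataset")
}
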