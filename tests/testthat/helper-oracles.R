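# Independent brute-force oracles, written against the model formulas in
# plain base R. They deliberately avoid the package's own probability /
# likelihood code paths.

# cumulative category response function, direct logistic evaluation
oracle_cum <- function(a, b_v, theta) 1 / (1 + exp(-a * (theta - b_v)))

# category probabilities as differences of consecutive cumulative curves
oracle_cat <- function(a, b, theta) {
  cum <- c(1, vapply(b, function(bv) oracle_cum(a, bv, theta), numeric(1)), 0)
  cum[-length(cum)] - cum[-1]
}

# log pattern likelihood at a fixed theta (missing entries skipped)
oracle_pattern_ll <- function(pattern, a, b_list, theta) {
  ll <- 0
  for (j in seq_along(pattern)) {
    u <- pattern[j]
    if (is.na(u)) next
    ll <- ll + log(oracle_cat(a[j], b_list[[j]], theta)[u + 1])
  }
  ll
}

# dense-grid marginal log-likelihood for a one-group response matrix
# integrated against N(mean, sd) on a 2001-node grid
oracle_marginal_ll <- function(resp, a, b_list, mean = 0, sd = 1,
                               n_nodes = 2001) {
  nodes <- seq(-6, 6, length.out = n_nodes)
  w <- dnorm(nodes, mean, sd)
  w <- w / sum(w)
  total <- 0
  for (i in seq_len(nrow(resp))) {
    lik <- vapply(nodes, function(th)
      exp(oracle_pattern_ll(resp[i, ], a, b_list, th)), numeric(1))
    total <- total + log(sum(lik * w))
  }
  total
}

# dense-grid EAP moments under a standard normal prior
oracle_eap <- function(pattern, a, b_list, n_nodes = 2001) {
  nodes <- seq(-6, 6, length.out = n_nodes)
  w <- dnorm(nodes)
  w <- w / sum(w)
  lik <- vapply(nodes, function(th)
    exp(oracle_pattern_ll(pattern, a, b_list, th)), numeric(1))
  post <- lik * w
  post <- post / sum(post)
  m <- sum(post * nodes)
  list(mean = m, sd = sqrt(sum(post * nodes^2) - m^2))
}

# brute-force single best SSE split of a table over categorical predictors:
# enumerates every predictor and every binary partition of its levels
oracle_best_split <- function(X, y, minbucket = 1) {
  sse <- function(z) sum((z - mean(z))^2)
  best <- NULL
  for (f in names(X)) {
    lev <- unique(as.character(X[[f]]))
    if (length(lev) < 2) next
    # canonical subsets: contain the first level, never all levels
    for (code in 0:(2^(length(lev) - 1) - 2)) {
      inc <- c(TRUE, as.logical(bitwAnd(code, 2^(seq_along(lev)[-1] - 2))))
      subset <- lev[inc]
      left <- as.character(X[[f]]) %in% subset
      if (sum(left) < minbucket || sum(!left) < minbucket) next
      red <- sse(y) - sse(y[left]) - sse(y[!left])
      if (is.null(best) || red > best$reduction + 1e-12)
        best <- list(feature = f, reduction = red, subset = subset)
    }
  }
  best
}

# small deterministic fixtures ------------------------------------------

toy_items_poly <- function(J = 3, seed = 101) {
  set.seed(seed)
  lapply(seq_len(J), function(j)
    grm_item(runif(1, 0.8, 2.5), sort(runif(2, -1.5, 1.5))))
}

toy_items_dich <- function(J = 5, seed = 202) {
  set.seed(seed)
  lapply(seq_len(J), function(j)
    grm_item(runif(1, 0.8, 2.5), runif(1, -1.5, 1.5)))
}

# small two-group dataset without going through the study machinery
toy_dataset <- function(items, n = 30, focal_mean = 0.3, seed = 7,
                        condition = NULL) {
  set.seed(seed)
  if (is.null(condition))
    condition <- condition_spec(100, 5, "high",
                                if (n_categories(items[[1]]) == 2L) 2L else 5L,
                                "diverse", "absent", "absent", 0.5)
  structure(list(
    resp_ref = simulate_responses(rnorm(n), items),
    resp_foc = simulate_responses(rnorm(n, focal_mean), items),
    theta_ref = NULL, theta_foc = NULL,
    items_ref = items, items_foc = items,
    dif_flags = rep(FALSE, length(items)),
    missing = NULL, condition = condition
  ), class = "grm_dataset")
}

test_banks <- function(size = 2000, seed = 500) {
  set.seed(seed)
  out <- list()
  for (it in c("dichotomous", "polytomous"))
    for (lev in c("high", "low"))
      out[[paste(it, lev, sep = ".")]] <- build_item_bank(it, lev, size)
  out
}
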