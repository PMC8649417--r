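# Marginal likelihood, multigroup EM estimation, and the LRT.

test_that("marginal_loglik matches the dense-grid oracle on a toy set", {
  items <- toy_items_poly(3)
  set.seed(31)
  resp_ref <- simulate_responses(rnorm(10), items)
  resp_foc <- simulate_responses(rnorm(10, 0.3), items)
  a <- vapply(items, `[[`, numeric(1), "a")
  b <- lapply(items, `[[`, "b")
  got <- marginal_loglik(list(ref = resp_ref, foc = resp_foc),
                         list(ref = items, foc = items),
                         group_structure(0.3, 1.2))
  want <- oracle_marginal_ll(resp_ref, a, b, 0, 1) +
    oracle_marginal_ll(resp_foc, a, b, 0.3, sqrt(1.2))
  expect_equal(got, want, tolerance = 1e-6)
})

test_that("marginal_loglik obeys independence and missing-pattern rules", {
  items <- toy_items_poly(3)
  set.seed(32)
  resp <- simulate_responses(rnorm(8), items)
  g <- group_structure(0, 1)
  prm <- list(ref = items, foc = items)
  ll1 <- marginal_loglik(list(ref = resp, foc = NULL), prm, g)
  ll2 <- marginal_loglik(list(ref = rbind(resp, resp), foc = NULL), prm, g)
  expect_equal(ll2, 2 * ll1, tolerance = 1e-10)
  allmiss <- matrix(NA_integer_, 1, 3)
  ll3 <- marginal_loglik(list(ref = rbind(resp, allmiss), foc = NULL), prm, g)
  expect_equal(ll3, ll1, tolerance = 1e-10)
  expect_error(group_structure(0, -1), "positive")
})

test_that("EM fit maximizes the quadrature marginal likelihood it reports", {
  items <- toy_items_dich(5)
  set.seed(33)
  resp_ref <- simulate_responses(rnorm(150), items)
  resp_foc <- simulate_responses(rnorm(150, 0.4), items)
  fit <- fit_grm_multigroup(resp_ref, resp_foc, n_cat = 2)
  # reported loglik equals a direct quadrature evaluation at the estimates
  ll <- marginal_loglik(list(ref = resp_ref, foc = resp_foc),
                        list(ref = fit$items_ref, foc = fit$items_foc),
                        fit$groups)
  expect_equal(fit$log_likelihood, ll, tolerance = 1e-8)
  # and beats the generating parameters (it is the MLE on this grid)
  ll_true <- marginal_loglik(list(ref = resp_ref, foc = resp_foc),
                             list(ref = items, foc = items),
                             group_structure(0.4, 1))
  expect_gte(fit$log_likelihood, ll_true - 1e-6)
})

test_that("nesting: general fits dominate restricted fits", {
  items <- toy_items_dich(5)
  set.seed(34)
  resp_ref <- simulate_responses(rnorm(120), items)
  resp_foc <- simulate_responses(rnorm(120), items)
  full <- fit_grm_multigroup(resp_ref, resp_foc, n_cat = 2)
  restr <- fit_grm_multigroup(resp_ref, resp_foc, n_cat = 2,
                              mean_constraint = TRUE, start = full)
  expect_gte(full$log_likelihood, restr$log_likelihood - 1e-4)
  expect_identical(full$n_free_parameters - restr$n_free_parameters, 1L)
  free <- fit_grm_multigroup(resp_ref, resp_foc, n_cat = 2,
                             constraint_plan = rep(FALSE, 5), start = full)
  expect_gte(free$log_likelihood, full$log_likelihood - 1e-4)
  # true focal mean is 0, so the constraint should cost little
  lrt <- likelihood_ratio_test(full, restr)
  expect_lt(lrt$statistic, qchisq(0.999, 1))
  # invariant plan: per-group estimates coincide
  expect_equal(full$items_ref, full$items_foc)
})

test_that("SQUAREM-accelerated and plain EM agree", {
  items <- toy_items_dich(4)
  set.seed(35)
  resp_ref <- simulate_responses(rnorm(100), items)
  resp_foc <- simulate_responses(rnorm(100, 0.3), items)
  fa <- fit_grm_multigroup(resp_ref, resp_foc, n_cat = 2)
  fp <- fit_grm_multigroup(resp_ref, resp_foc, n_cat = 2,
                           control = list(accelerate = FALSE,
                                          max_iter = 3000L))
  expect_equal(fa$log_likelihood, fp$log_likelihood, tolerance = 1e-3)
  expect_equal(fa$groups$focal_mean, fp$groups$focal_mean, tolerance = 0.02)
})

test_that("likelihood_ratio_test follows the chi-square difference rules", {
  items <- toy_items_dich(3)
  set.seed(36)
  resp_ref <- simulate_responses(rnorm(60), items)
  resp_foc <- simulate_responses(rnorm(60), items)
  fit <- fit_grm_multigroup(resp_ref, resp_foc, n_cat = 2)
  # identical fits: statistic 0, p = 1 (self-comparison via fabricated df)
  same <- fit
  same$n_free_parameters <- fit$n_free_parameters - 1L
  lrt0 <- likelihood_ratio_test(fit, same)
  expect_identical(lrt0$statistic, 0)
  expect_identical(lrt0$p_value, 1)
  # arithmetic: lnL_G = -1000, lnL_S = -1002, df 1 -> statistic 4
  g <- fit; g$log_likelihood <- -1000
  s <- fit; s$log_likelihood <- -1002
  s$n_free_parameters <- fit$n_free_parameters - 1L
  lrt <- likelihood_ratio_test(g, s)
  expect_equal(lrt$statistic, 4)
  expect_equal(lrt$p_value, pchisq(4, 1, lower.tail = FALSE))
  # non-nested usage error and negative-statistic flagging
  expect_error(likelihood_ratio_test(s, g), "not nested")
  s2 <- fit; s2$log_likelihood <- fit$log_likelihood + 1
  s2$n_free_parameters <- fit$n_free_parameters - 1L
  lrt2 <- likelihood_ratio_test(fit, s2)
  expect_identical(lrt2$statistic, 0)
  expect_true(lrt2$flagged)
})

test_that("empty observed categories are merged for the fit and logged", {
  set.seed(37)
  items <- lapply(1:3, function(j)
    grm_item(runif(1, 1.5, 2.5), sort(rnorm(4, 0.3, 0.8))))
  resp_ref <- simulate_responses(rnorm(40), items)
  resp_foc <- simulate_responses(rnorm(40), items)
  # guarantee items 2 and 3 show all five categories...
  resp_ref[1:5, 2] <- 0:4
  resp_ref[1:5, 3] <- 0:4
  # ...and force category 3 of item 1 to be unobserved in both groups
  resp_ref[resp_ref[, 1] == 3L, 1] <- 4L
  resp_foc[resp_foc[, 1] == 3L, 1] <- 4L
  fit <- fit_grm_multigroup(resp_ref, resp_foc, n_cat = 5)
  expect_identical(fit$collapsed_items, 1L)
  expect_identical(fit$n_cat_used, c(4L, 5L, 5L))
  expect_length(fit$items_ref[[1]]$b, 3L)
  expect_true(is.finite(fit$log_likelihood))
})

test_that("fits are deterministic given data", {
  items <- toy_items_dich(4)
  set.seed(38)
  resp_ref <- simulate_responses(rnorm(80), items)
  resp_foc <- simulate_responses(rnorm(80), items)
  f1 <- fit_grm_multigroup(resp_ref, resp_foc, n_cat = 2)
  f2 <- fit_grm_multigroup(resp_ref, resp_foc, n_cat = 2)
  expect_identical(f1$log_likelihood, f2$log_likelihood)
  expect_identical(f1$items_ref, f2$items_ref)
})
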