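# Sum-score, Welch, pooled effect size, and the three method runners.

test_that("sum_scores adds responses and listwise-deletes", {
  resp <- rbind(c(1L, 0L, 1L, 1L, 0L),
                c(1L, NA, 1L, 0L, 0L),
                c(2L, 2L, 2L, 2L, 2L))
  s <- sum_scores(resp)
  expect_identical(s[1], 3)
  expect_true(is.na(s[2]))
  # excluding the missing item retains the person
  expect_identical(sum_scores(resp, c(1, 3, 4, 5))[2], 2)
  expect_error(sum_scores(resp, integer(0)), "non-empty")
})

test_that("welch_t_test matches stats::t.test and its conventions", {
  set.seed(3001)
  x <- rnorm(40); y <- rnorm(35, 0.3, 1.4)
  got <- welch_t_test(x, y)
  want <- t.test(x, y)
  expect_equal(got$statistic, unname(want$statistic), tolerance = 1e-12)
  expect_equal(got$df, unname(want$parameter), tolerance = 1e-9)
  expect_equal(got$p_value, want$p.value, tolerance = 1e-12)
  # symmetry and the degenerate conventions
  rev <- welch_t_test(y, x)
  expect_equal(rev$statistic, -got$statistic)
  expect_equal(rev$p_value, got$p_value)
  same <- welch_t_test(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_identical(welch_t_test(rep(1, 5), rep(1, 7))$p_value, 1)
  expect_identical(welch_t_test(rep(2, 5), rep(1, 7))$p_value, 0)
  expect_error(welch_t_test(1, y), "at least 2")
})

test_that("welch_t_test holds its nominal level under the null", {
  set.seed(3002)
  rej <- 0
  for (k in 1:5000)
    rej <- rej + (welch_t_test(rnorm(100), rnorm(100))$p_value < 0.05)
  rate <- rej / 5000
  envelope <- 1.96 * sqrt(0.05 * 0.95 / 5000)
  expect_lt(abs(rate - 0.05), envelope + 1e-12)
})

test_that("pooled_effect_size is the (n-1)-weighted Cohen's d", {
  expect_identical(pooled_effect_size(1, 1, 10, 1, 1, 10), 0)
  expect_equal(pooled_effect_size(0.5, 1, 50, 0, 1, 50), 0.5)
  e1 <- pooled_effect_size(0.7, 1.1, 30, 0.2, 0.9, 40)
  e2 <- pooled_effect_size(7, 11, 30, 2, 9, 40)  # common rescaling
  expect_equal(e1, e2, tolerance = 1e-12)
  expect_error(pooled_effect_size(1, 0, 5, 1, 0, 5), "zero")
})

test_that("calibrate_items jiggles within +/-0.2 and keeps order", {
  items <- toy_items_poly(20, seed = 303)
  set.seed(3003)
  cal <- calibrate_items(items)
  for (j in seq_along(items)) {
    expect_lte(abs(cal[[j]]$a - items[[j]]$a), 0.2)
    expect_true(all(abs(cal[[j]]$b - items[[j]]$b) <= 0.2))
    expect_true(all(diff(cal[[j]]$b) > 0))
  }
})

test_that("run_sum_score composes scoring, Welch test, and effect size", {
  items <- toy_items_dich(5)
  ds <- toy_dataset(items, n = 80, focal_mean = 0.8, seed = 304)
  r <- run_sum_score(ds)
  expect_s3_class(r, "method_result")
  expect_identical(r$reject, r$p_value < 0.05)
  sr <- sum_scores(ds$resp_ref); sf <- sum_scores(ds$resp_foc)
  expect_equal(r$effect_size,
               pooled_effect_size(mean(sf), sd(sf), 80, mean(sr), sd(sr), 80),
               tolerance = 1e-12)
})

test_that("run_irt_eap handles missing persons and item order", {
  items <- toy_items_poly(5, seed = 305)
  ds <- toy_dataset(items, n = 60, focal_mean = 0.5, seed = 306)
  ds$resp_foc[1, ] <- NA_integer_  # all-missing person stays in
  set.seed(307)
  cal <- calibrate_items(items)
  r1 <- run_irt_eap(ds, cal)
  expect_true(is.finite(r1$p_value))
  ef <- eap_scores(ds$resp_foc, cal)
  expect_equal(ef$mean[1], 0, tolerance = 1e-8)
  # order invariance of the subset
  r2 <- run_irt_eap(ds, cal, item_subset = c(4, 2, 5, 1, 3))
  r3 <- run_irt_eap(ds, cal, item_subset = 1:5)
  expect_equal(r2$p_value, r3$p_value, tolerance = 1e-12)
  expect_equal(r2$effect_size, r3$effect_size, tolerance = 1e-12)
})

test_that("EAP group means track the true means in large samples", {
  items <- lapply(1:20, function(j)
    grm_item(runif(1, 1.7, 3.5), sort(rnorm(4, 0.5, 0.8))))
  set.seed(3004)
  ds <- toy_dataset(items, n = 4000, focal_mean = 0.5, seed = 308,
                    condition = condition_spec(400, 20, "high", 5,
                                               "diverse", "absent",
                                               "absent", 0.5))
  cal <- calibrate_items(items)
  er <- eap_scores(ds$resp_ref, cal)
  ef <- eap_scores(ds$resp_foc, cal)
  expect_gt(mean(ef$mean) - mean(er$mean), 0.3)
})

test_that("run_irt_model tests the focal mean with df 1", {
  items <- toy_items_dich(5)
  ds <- toy_dataset(items, n = 200, focal_mean = 0, seed = 309)
  r <- run_irt_model(ds)
  expect_identical(r$diagnostics$df, 1L)
  expect_identical(r$reject, r$p_value < 0.05)
  es_expected <- r$diagnostics$focal_mean /
    sqrt((199 * 1 + 199 * r$diagnostics$focal_variance) / 398)
  expect_equal(r$effect_size, es_expected, tolerance = 1e-12)
})

test_that("run_irt_model rejects with high probability under favorable
           power conditions", {
  items <- lapply(1:20, function(j)
    grm_item(runif(1, 1.7, 3.5), sort(rnorm(4, 0.5, 0.8))))
  ds <- toy_dataset(items, n = 400, focal_mean = 0.5, seed = 310,
                    condition = condition_spec(400, 20, "high", 5,
                                               "diverse", "absent",
                                               "absent", 0.5))
  r <- run_irt_model(ds)
  expect_true(r$reject)
  expect_equal(r$effect_size, 0.5, tolerance = 0.15)
})
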