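# True scores, DIF injection, response simulation, MAR missingness, DTF.

test_that("draw_true_scores are unit-SD normals with the requested mean", {
  set.seed(2001)
  x <- draw_true_scores(1e6, 0)
  expect_lt(abs(mean(x)), 0.01)
  expect_equal(sd(x), 1, tolerance = 0.01)
  set.seed(123); a <- draw_true_scores(50, 0.5)
  set.seed(123); b <- draw_true_scores(50, 0.5)
  expect_identical(a, b)
  expect_equal(mean(draw_true_scores(1e5, 0.5)), 0.5, tolerance = 0.02)
})

test_that("apply_dif flags 40% of items and disadvantages the focal group", {
  set.seed(2002)
  items5 <- toy_items_poly(5)
  d5 <- apply_dif(items5)
  expect_identical(sum(d5$dif_flags), 2L)
  items20 <- lapply(1:20, function(j) grm_item(runif(1, 1.7, 3.5),
                                               sort(rnorm(4, 0.5, 0.8))))
  d20 <- apply_dif(items20)
  expect_identical(sum(d20$dif_flags), 8L)
  for (j in which(d20$dif_flags)) {
    expect_lt(d20$items_focal[[j]]$a, items20[[j]]$a)
    expect_gte(items20[[j]]$a - d20$items_focal[[j]]$a, 0)
    expect_lte(items20[[j]]$a - d20$items_focal[[j]]$a, 0.3)
    shift <- d20$items_focal[[j]]$b - items20[[j]]$b
    expect_true(all(shift >= 0.5 & shift <= 0.7))
    expect_equal(max(shift) - min(shift), 0)  # one shared draw per item
  }
  for (j in which(!d20$dif_flags))
    expect_identical(d20$items_focal[[j]], items20[[j]])
  # zero proportion: identity map
  d0 <- apply_dif(items5, prop = 0)
  expect_identical(d0$items_focal, items5)
  expect_false(any(d0$dif_flags))
})

test_that("simulate_responses reproduces the category distribution", {
  it <- grm_item(1.6, c(-0.8, 0.1, 0.9, 1.7))
  set.seed(2003)
  resp <- simulate_responses(rep(0, 1e5), list(it))
  freq <- tabulate(resp + 1L, 5) / 1e5
  expect_equal(freq, category_prob(it, 0), tolerance = 0.01)
  # near-deterministic limit: huge a, theta far above all thresholds
  strong <- grm_item(50, c(-1, -0.5, 0, 0.5))
  top <- simulate_responses(rep(3, 2000), list(strong))
  expect_gt(mean(top == 4L), 0.999)
  set.seed(9); r1 <- simulate_responses(rnorm(20), list(it))
  set.seed(9); r2 <- simulate_responses(rnorm(20), list(it))
  expect_identical(r1, r2)
})

test_that("MAR missingness hits the stated quotas and columns", {
  items <- lapply(1:20, function(j) grm_item(runif(1, 1.7, 3.5),
                                             sort(rnorm(4, 0.5, 0.8))))
  set.seed(2004)
  resp <- simulate_responses(rnorm(800), items)
  m <- impose_mar_missingness(resp)
  expect_length(m$eligible_items, 4L)
  expect_length(m$subjects, 240L)
  expect_identical(sum(is.na(m$responses)), 4L * 240L)
  na_cols <- which(colSums(is.na(m$responses)) > 0)
  expect_identical(na_cols, m$eligible_items)
  na_rows <- which(rowSums(is.na(m$responses)) > 0)
  expect_identical(na_rows, m$subjects)
})

test_that("missingness is MAR: selection ignores the deleted values given
           the observed ones", {
  items <- lapply(1:10, function(j) grm_item(1.2, sort(rnorm(4, 0.5, 0.8))))
  set.seed(2005)
  theta <- rnorm(20000)
  resp <- simulate_responses(theta, items)
  m <- impose_mar_missingness(resp)
  selected <- seq_len(nrow(resp)) %in% m$subjects
  obs_mean <- rowMeans(resp[, -m$eligible_items, drop = FALSE])
  elig_sum <- rowSums(resp[, m$eligible_items, drop = FALSE])
  fit <- glm(selected ~ obs_mean + elig_sum, family = binomial)
  z <- summary(fit)$coefficients
  expect_gt(z["obs_mean", "z value"], 3)          # depends on observed data
  expect_lt(abs(z["elig_sum", "z value"]), 3.5)   # not on the deleted values
})

test_that("DTF effect size has the stated fixed points and sign behavior", {
  items <- toy_items_poly(5)
  theta <- rnorm(500, 0.2)
  expect_identical(dtf_effect_size(items, items, theta)$effect_size, 0)
  set.seed(2006)
  neg <- 0
  for (k in 1:50) {
    d <- apply_dif(items)
    neg <- neg + (dtf_effect_size(items, d$items_focal, theta)$effect_size < 0)
  }
  expect_gt(neg / 50, 0.9)  # disadvantaging DIF is negative almost always
  # doubling every item leaves the standardized sign (and value) unchanged
  d <- apply_dif(items)
  e1 <- dtf_effect_size(items, d$items_focal, theta)$effect_size
  e2 <- dtf_effect_size(c(items, items),
                        c(d$items_focal, d$items_focal), theta)$effect_size
  expect_identical(sign(e1), sign(e2))
})

test_that("simulate_dataset enforces the condition invariants exactly", {
  banks <- test_banks()
  cond <- condition_spec(100, 20, "high", 5, "diverse", "present",
                         "present", 0.5)
  set.seed(2007)
  ds <- simulate_dataset(cond, banks[["polytomous.high"]])
  expect_identical(sum(ds$dif_flags), 8L)
  expect_identical(dim(ds$resp_ref), c(100L, 20L))
  expect_identical(length(ds$missing$eligible_items), 4L)
  expect_identical(length(ds$missing$subjects), 60L)  # 30% of 200 pooled
  expect_identical(sum(is.na(rbind(ds$resp_ref, ds$resp_foc))), 240L)

  cond0 <- condition_spec(100, 5, "low", 2, "homogeneous", "absent",
                          "absent", 0)
  ds0 <- simulate_dataset(cond0, banks[["dichotomous.low"]])
  expect_false(any(ds0$dif_flags))
  expect_null(ds0$missing)
  expect_identical(ds0$items_ref, ds0$items_foc)
  expect_false(anyNA(ds0$resp_ref))
  # mismatched bank is rejected
  expect_error(simulate_dataset(cond0, banks[["polytomous.high"]]),
               "does not match")
})
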