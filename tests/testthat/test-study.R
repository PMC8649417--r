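# Condition grid, replication determinism, and the summary tables.

test_that("the condition grid is the full 2^7 x 2 crossing", {
  grid <- build_condition_grid()
  expect_identical(nrow(grid), 256L)
  expect_identical(anyDuplicated(grid[, -1]), 0L)
  expect_identical(nrow(grid[grid$dif == "absent", ]), 128L)
  expect_setequal(grid$n_per_group, c(100L, 400L))
  spec <- as_condition_spec(grid[17, ])
  expect_s3_class(spec, "condition_spec")
  expect_error(condition_spec(250, 5, "high", 2, "diverse", "absent",
                              "absent", 0))
})

test_that("derived seeds are reproducible, distinct, and in range", {
  s1 <- derive_seed(1, 10, 3)
  expect_identical(s1, derive_seed(1, 10, 3))
  seeds <- outer(1:50, 1:20, function(c, r) derive_seed(7, c, r))
  expect_identical(anyDuplicated(as.vector(seeds)), 0L)
  expect_true(all(seeds >= 1 & seeds <= 2147483646))
  expect_false(derive_seed(2, 10, 3) == s1)
})

test_that("run_replication is deterministic and complete", {
  banks <- test_banks()
  cond <- condition_spec(100, 5, "high", 2, "diverse", "present",
                         "present", 0.5)
  r1 <- run_replication(cond, 12345L, banks)
  r2 <- run_replication(cond, 12345L, banks)
  expect_identical(vapply(r1$results, `[[`, numeric(1), "p_value"),
                   vapply(r2$results, `[[`, numeric(1), "p_value"))
  expect_identical(r1$dtf, r2$dtf)
  expect_length(r1$results, 6L)
  expect_setequal(vapply(r1$results, `[[`, character(1), "method"),
                  c("sum_score", "irt_eap", "irt_model"))
  expect_identical(vapply(r1$results, `[[`, logical(1), "prescreened"),
                   rep(c(FALSE, TRUE), 3))
  expect_true(is.finite(r1$dtf))
  # DIF-free condition: no DTF value
  cond0 <- condition_spec(100, 5, "high", 2, "diverse", "absent",
                          "absent", 0)
  r0 <- run_replication(cond0, 99L, banks)
  expect_true(is.na(r0$dtf))
})

test_that("run_study assembles the long table and summaries compute the
           stated definitions", {
  banks <- test_banks()
  grid <- build_condition_grid()
  grid <- grid[grid$n_per_group == 100 & grid$n_items == 5 &
                 grid$n_categories == 2 & grid$discrimination == "high" &
                 grid$thresholds_mode == "diverse" & grid$dif == "absent" &
                 grid$missing == "absent", ]
  expect_identical(nrow(grid), 2L)  # the two true means
  study <- run_study(grid, n_reps = 3, master_seed = 5, banks = banks)
  expect_identical(nrow(study$results), 2L * 3L * 6L)
  s <- summarize_study(study)
  expect_identical(nrow(s$type1), 6L)
  expect_identical(nrow(s$power), 6L)
  expect_identical(nrow(s$mae), 12L)
  expect_true(all(s$type1$rate >= 0 & s$type1$rate <= 1))
  expect_true(all(s$mae$mae >= 0))
  expect_true(all(s$type1$n_reps == 3L))
  # rates recompute from the long table
  sub <- study$results[study$results$true_focal_mean == 0 &
                         study$results$method == "sum_score" &
                         !study$results$prescreened, ]
  expect_equal(s$type1$rate[s$type1$method == "sum_score" &
                              !s$type1$prescreened], mean(sub$reject))
})

test_that("summarize_study computes known rates on a synthetic table", {
  rows <- expand.grid(n_per_group = 100L, n_items = 5L,
                      discrimination = "high", n_categories = 2L,
                      thresholds_mode = "diverse", dif = "absent",
                      missing = "absent", true_focal_mean = c(0, 0.5),
                      method = "sum_score", prescreened = FALSE,
                      rep = 1:10, stringsAsFactors = FALSE)
  rows$reject <- rows$rep <= 5  # half the reps reject in each mean arm
  rows$effect_size <- rows$true_focal_mean + 0.1
  s <- summarize_study(rows)
  expect_equal(s$type1$rate, 0.5)
  expect_equal(s$power$rate, 0.5)
  expect_equal(s$mae$mae, c(0.1, 0.1), tolerance = 1e-12)
})

test_that("power does not decrease from n=100 to n=400 in a favorable
           DIF-free cell", {
  banks <- test_banks()
  grid <- build_condition_grid()
  grid <- grid[grid$n_items == 5 & grid$n_categories == 2 &
                 grid$discrimination == "high" &
                 grid$thresholds_mode == "diverse" & grid$dif == "absent" &
                 grid$missing == "absent" & grid$true_focal_mean == 0.5, ]
  expect_identical(nrow(grid), 2L)
  # scaled down (20 reps) from the spec's 100-rep property for budget
  study <- run_study(grid, n_reps = 20, master_seed = 11, banks = banks)
  s <- summarize_study(study)$power
  for (m in unique(s$method))
    for (p in c(TRUE, FALSE)) {
      r <- s[s$method == m & s$prescreened == p, ]
      expect_gte(r$rate[r$n_per_group == 400], r$rate[r$n_per_group == 100])
    }
})
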