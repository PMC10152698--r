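test_that("standardized regression: null, exact, and singular cases", {
  tab <- make_balanced_table(n_per_cell = 1250, seed = 11)  # n = 1e4 noise
  co <- standardized_regression(tab, lambda = "none")
  expect_lt(abs(co["sex"]), 0.05)
  expect_lt(abs(co["age"]), 0.05)

  tab2 <- make_balanced_table(n_per_cell = 50, seed = 12)
  tab2$value <- tab2$age                      # perfect age dependence
  co2 <- standardized_regression(tab2, lambda = "none")
  expect_equal(unname(co2["age"]), 1, tolerance = 1e-8)
  expect_equal(unname(co2["sex"]), 0, tolerance = 1e-8)

  single <- tab[tab$sex == "F", ]
  expect_error(standardized_regression(single), "single sex")
})

test_that("variance components: null data gives near-zero group SDs", {
  tab <- make_balanced_table(n_per_cell = 1250, seed = 13)
  pa <- variance_components(tab, lambda = "none")
  expect_lt(pa$sd_sex, 0.05 * pa$sd_residual)
  expect_lt(pa$sd_age, 0.05 * pa$sd_residual)
  expect_false(pa$partition_by_sex)
  expect_false(pa$partition_by_age)
})

test_that("variance components recover an injected sex shift", {
  # shift equal to the residual SD => between-sex (population) SD = shift/2,
  # so the expected SDR is 0.5
  tab <- make_balanced_table(n_per_cell = 1250, seed = 14, sex_shift = 1, sd = 1)
  pa <- variance_components(tab, lambda = "none")
  expect_gt(pa$sdr_sex, 0.35)
  expect_lt(pa$sdr_sex, 0.65)
  expect_true(pa$partition_by_sex)
})

test_that("degenerate designs error out", {
  tab <- make_balanced_table(n_per_cell = 20, seed = 15)
  tab$value <- 5 + (tab$sex == "M")           # zero residual noise
  expect_error(variance_components(tab, lambda = "none"), "zero residual")
  gap <- tab[!(tab$sex == "M" & tab$age >= 50), ]
  expect_error(variance_components(gap, lambda = "none"), "empty cell")
})

test_that("partition_decision is strict", {
  expect_true(partition_decision(0.727, 0.4))
  expect_false(partition_decision(0.4, 0.4))
  expect_false(partition_decision(0, 0.4))
  expect_error(partition_decision(-0.1, 0.4))
})

test_that("SDR is invariant to rescaling the values", {
  tab <- make_balanced_table(n_per_cell = 100, seed = 16, sex_shift = 0.8)
  pa1 <- variance_components(tab, lambda = "none")
  tab$value <- tab$value * 7.3
  pa2 <- variance_components(tab, lambda = "none")
  expect_equal(pa1$sdr_sex, pa2$sdr_sex, tolerance = 1e-9)
  expect_equal(pa1$sdr_age, pa2$sdr_age, tolerance = 1e-9)
})

test_that("expected SDR_sex is monotone in the generated sex shift", {
  shifts <- c(0, 0.4, 0.8, 1.6)
  mean_sdr <- vapply(seq_along(shifts), function(i) {
    reps <- vapply(1:20, function(r) {
      tab <- make_balanced_table(n_per_cell = 125, seed = 1000 * i + r,
                                 sex_shift = shifts[i])
      variance_components(tab, lambda = "none")$sdr_sex
    }, 0)
    mean(reps)
  }, 0)
  expect_true(all(diff(mean_sdr) > 0))
})
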