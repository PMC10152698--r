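test_that("generate_cohort honours the contract", {
  spec <- cohort_spec("X", list(component_spec(1, 0, 0, 1)), n = 500)
  t1 <- generate_cohort(spec, seed = 11)
  t2 <- generate_cohort(spec, seed = 11)
  expect_identical(t1, t2)                      # determinism
  expect_equal(nrow(t1), 500L)
  expect_true(all(t1$value > 0))
  expect_true(all(t1$age >= 18 & t1$age <= 59))
  expect_true(all(t1$truth_label == "healthy"))
  t3 <- generate_cohort(spec, seed = 12)
  expect_false(identical(t1$value, t3$value))   # seed actually matters
})

test_that("degenerate variance yields the back-transformed means", {
  spec <- cohort_spec("X", list(
    component_spec(0.8, 0.5, 2, 0, "healthy"),
    component_spec(0.2, 0.5, 4, 0, "patho_high")), n = 200)
  tab <- generate_cohort(spec, seed = 3)
  expect_setequal(round(unique(tab$value), 10),
                  round(inverse_boxcox(c(2, 4), 0.5), 10))
})

test_that("lognormal cohort matches analytic quantiles at n = 1e5", {
  spec <- cohort_spec("LN", list(component_spec(1, 0, 0, 1)), n = 1e5)
  tab <- generate_cohort(spec, seed = 21)
  q <- quantile(tab$value, c(0.025, 0.975), type = 7, names = FALSE)
  target <- qlnorm(c(0.025, 0.975))             # analytic oracle
  expect_lt(abs(q[1] / target[1] - 1), 0.02)
  expect_lt(abs(q[2] / target[2] - 1), 0.02)
})

test_that("empirical healthy quantiles converge to the closed-form truth", {
  spec <- thyroid_panel_spec(1e5)$TSH
  tab <- generate_cohort(spec, seed = 33)
  h <- tab$value[tab$truth_label == "healthy"]
  q <- quantile(h, pnorm(c(-1.96, 1.96)), type = 7, names = FALSE)
  tr <- true_ri(spec)
  expect_lt(abs(q[1] / tr[1] - 1), 0.02)
  expect_lt(abs(q[2] / tr[2] - 1), 0.02)
})

test_that("true_ri reduces to the closed form without covariate effects", {
  spec <- cohort_spec("X", list(component_spec(1, 0.4, 1.2, 0.3)), n = 10)
  expect_equal(true_ri(spec),
               inverse_boxcox(1.2 + c(-1.96, 1.96) * 0.3, 0.4),
               tolerance = 1e-7)
})

test_that("thyroid panel specs satisfy their stated shape", {
  specs <- thyroid_panel_spec(1000)
  expect_named(specs, c("TSH", "FT3", "FT4", "TT3", "TT4"))
  for (s in specs) {
    w <- vapply(s$components, `[[`, 0, "weight")
    expect_equal(sum(w), 1, tolerance = 1e-12)
    lab <- vapply(s$components, `[[`, "", "label")
    expect_gte(w[lab == "healthy"], max(w))
  }
  h_tsh <- specs$TSH$components[[1]]
  expect_lt(abs(h_tsh$lambda), 0.1)            # log-normal-like core
  expect_gte(h_tsh$weight, 0.90)
  expect_true(specs$FT4$sex_shift != 0)        # sex-partitioned analyte
  expect_true(specs$FT3$sex_shift != 0)
})

test_that("spec invariants are enforced", {
  expect_error(cohort_spec("X", list(component_spec(0.5, 0, 0, 1))), "sum to 1")
  expect_error(cohort_spec("X", list(
    component_spec(0.4, 0, 0, 1, "healthy"),
    component_spec(0.6, 0, 3, 1, "patho_high"))), "largest")
  expect_error(component_spec(1.2, 0, 0, 1))
  expect_error(cohort_spec("X", list(component_spec(1, 0, 0, 1)),
                           age_range = c(18, 65)))
})

test_that("infeasible inverse-transform domains trigger the rejection guard", {
  # lambda = 1 with mu = -5: almost every draw has y + 1 <= 0
  spec <- cohort_spec("X", list(component_spec(1, 1, -5, 0.5)), n = 100)
  expect_error(generate_cohort(spec, seed = 5), "rejection rate")
})
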