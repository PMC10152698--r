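test_that("log-variant equals the closed form exactly", {
  set.seed(21)
  x <- exp(rnorm(500, 0.2, 0.5))
  ri <- transformed_parametric_ri(x, lambda = 0)
  m <- mean(log(x)); s <- sd(log(x))
  expect_equal(c(ri$ll, ri$ul), exp(m + c(-1.96, 1.96) * s), tolerance = 1e-12)
})

test_that("analytic limits are recovered on large samples", {
  set.seed(22)
  ln <- exp(rnorm(1e5))
  ri <- transformed_parametric_ri(ln, lambda = 0)
  expect_lt(abs(ri$ll / qlnorm(pnorm(-1.96)) - 1), 0.02)
  expect_lt(abs(ri$ul / qlnorm(pnorm(1.96)) - 1), 0.02)
  g <- rnorm(1e5, 10, 1)
  rig <- transformed_parametric_ri(g, lambda = "auto")
  expect_lt(abs(rig$ll / (10 - 1.96) - 1), 0.02)
  expect_lt(abs(rig$ul / (10 + 1.96) - 1), 0.02)
})

test_that("scaling equivariance holds for the log variant", {
  set.seed(23)
  x <- exp(rnorm(2000, 0, 0.4))
  r1 <- transformed_parametric_ri(x, lambda = 0)
  r2 <- transformed_parametric_ri(5 * x, lambda = 0)
  expect_equal(c(r2$ll, r2$ul), 5 * c(r1$ll, r1$ul), tolerance = 1e-9)
})

test_that("degenerate and undersized inputs error", {
  expect_error(transformed_parametric_ri(rep(2, 500)), "degenerate")
  expect_error(transformed_parametric_ri(rexp(50) + 1), "below minimum")
})

test_that("bootstrap CIs are deterministic, contain the estimate, and are
           degenerate for a constant estimator", {
  set.seed(24)
  x <- exp(rnorm(1000))
  est <- function(v) transformed_parametric_ri(v, lambda = 0)
  b1 <- bootstrap_ci(x, est, B = 50, seed = 99)
  b2 <- bootstrap_ci(x, est, B = 50, seed = 99)
  expect_identical(b1, b2)
  ri <- b1$ri
  expect_true(ri$ci_ll[1] <= ri$ll && ri$ll <= ri$ci_ll[2])
  expect_true(ri$ci_ul[1] <= ri$ul && ri$ul <= ri$ci_ul[2])
  const <- function(v) c(1, 3)
  bc <- bootstrap_ci(x, const, B = 20, seed = 1)
  expect_equal(bc$ci_ll, c(1, 1))
  expect_equal(bc$ci_ul, c(3, 3))
})

test_that("unstable estimators are reported", {
  set.seed(25)
  x <- exp(rnorm(300))
  # succeeds on the original sample (all values distinct) but fails on every
  # bootstrap resample (ties are certain), so >20% of replicates fail
  flaky <- function(v) {
    if (anyDuplicated(v)) stop("resample rejected")
    range(v)
  }
  expect_error(bootstrap_ci(x, flaky, B = 10, seed = 2), "failed on")
})

test_that("ci_width_ok implements the strict 0.2-width rule", {
  ri <- reference_interval(0.801, 4.221, ci_ll = c(0.7722, 0.8305),
                           ci_ul = c(4.0900, 4.3570))
  expect_true(ci_width_ok(ri))                # published-style TSH row
  zero <- reference_interval(1, 2, ci_ll = c(1, 1), ci_ul = c(2, 2))
  expect_true(ci_width_ok(zero))
  # CI width exactly 0.2 * (ul - ll) fails the strict rule
  edge <- reference_interval(0, 10, ci_ll = c(-1, 1), ci_ul = c(9, 11))
  expect_false(ci_width_ok(edge))
})
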