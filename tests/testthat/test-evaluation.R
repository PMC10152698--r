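test_that("bias_ratio reproduces the worked desk examples", {
  # standard (0.801, 4.221) vs EM (0.970, 4.276): SD_RI = 3.42/3.92
  br <- bias_ratio(c(0.970, 4.276), c(0.801, 4.221))
  expect_equal(br$sd_ri, (4.221 - 0.801) / 3.92, tolerance = 1e-12)
  expect_equal(round(br$br_ul, 3), 0.063)
  expect_false(br$flag_ul)
  # standard vs Hoffmann (0.709, 4.976)
  br2 <- bias_ratio(c(0.709, 4.976), c(0.801, 4.221))
  expect_equal(round(br2$br_ll, 3), 0.105)
  expect_equal(round(br2$br_ul, 3), 0.865)
  expect_false(br2$flag_ll)
  expect_true(br2$flag_ul)
})

test_that("bias_ratio identity, symmetry, and scale invariance", {
  std <- c(2, 8)
  id <- bias_ratio(std, std)
  expect_equal(c(id$br_ll, id$br_ul), c(0, 0))
  expect_false(id$flag_ll || id$flag_ul)
  # mirrored deviations give the same BR
  up <- bias_ratio(std + c(0.3, 0.4), std)
  dn <- bias_ratio(std - c(0.3, 0.4), std)
  expect_equal(c(up$br_ll, up$br_ul), c(dn$br_ll, dn$br_ul))
  # common rescaling leaves BR unchanged
  c_ <- 7.7
  sc <- bias_ratio(c_ * (std + c(0.3, 0.4)), c_ * std)
  expect_equal(c(sc$br_ll, sc$br_ul), c(up$br_ll, up$br_ul), tolerance = 1e-12)
  expect_error(bias_ratio(c(1, 2), c(5, 5)), "invalid reference")
})

test_that("bias_ratio accepts reference_interval objects and rounding", {
  t_ri <- reference_interval(0.9701, 4.2762, method = "em")
  s_ri <- reference_interval(0.8014, 4.2205)
  raw <- bias_ratio(t_ri, s_ri)
  rounded <- bias_ratio(t_ri, s_ri, digits = 3)
  expect_false(isTRUE(all.equal(raw$br_ul, rounded$br_ul)))
  expect_equal(rounded$sd_ri, (4.221 - 0.801) / 3.92, tolerance = 1e-12)
})

test_that("br_matrix shape, order invariance, and missing-standard error", {
  est <- data.frame(
    method = c("em", "hoffmann", "em"),
    analyte = c("TSH", "TSH", "FT4"),
    subgroup = "T",
    ll = c(0.970, 0.709, 1.02), ul = c(4.276, 4.976, 1.44),
    stringsAsFactors = FALSE)
  std <- data.frame(analyte = c("TSH", "FT4"), subgroup = "T",
                    ll = c(0.801, 0.98), ul = c(4.221, 1.53),
                    stringsAsFactors = FALSE)
  m1 <- br_matrix(est, std)
  expect_equal(nrow(m1), 3L)
  expect_true(all(is.finite(m1$br_ll)) && all(is.finite(m1$br_ul)))
  m2 <- br_matrix(est[c(3, 1, 2), ], std[c(2, 1), ])
  expect_equal(as.data.frame(m1), as.data.frame(m2))
  expect_error(br_matrix(est, std[1, ]), "no standard for analyte FT4")
})

test_that("identity estimates give an all-zero matrix row", {
  est <- data.frame(method = "mock", analyte = "A", subgroup = "T",
                    ll = 1.5, ul = 6.5, stringsAsFactors = FALSE)
  std <- data.frame(analyte = "A", subgroup = "T", ll = 1.5, ul = 6.5,
                    stringsAsFactors = FALSE)
  m <- br_matrix(est, std)
  expect_equal(c(m$br_ll, m$br_ul), c(0, 0))
})
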