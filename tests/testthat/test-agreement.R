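test_that("regression recovers exact linear relations", {
  # identity data: unit slope, zero intercept, perfect fit
  rec <- area_records(1:5, 0.2, a_ire_mm2 = c(1, 2, 3, 4, 5),
                      a_he_mm2 = c(1, 2, 3, 4, 5))
  fr <- fit_regression(rec)
  expect_equal(fr$slope, 1, tolerance = 1e-12)
  expect_equal(fr$intercept, 0, tolerance = 1e-12)
  expect_equal(fr$r_squared, 1, tolerance = 1e-12)

  # exact doubling with the reference as predictor
  rec2 <- area_records(1:3, 0.2, a_ire_mm2 = c(2, 4, 6), a_he_mm2 = c(1, 2, 3))
  fr2 <- fit_regression(rec2)
  expect_equal(fr2$slope, 2, tolerance = 1e-12)
  expect_equal(fr2$r_squared, 1, tolerance = 1e-12)

  # collinear data is significant regardless of scale
  rec3 <- area_records(1:4, 0.1, a_ire_mm2 = 1e-3 * c(1, 2, 3, 4),
                       a_he_mm2 = 1e-3 * c(2, 4, 6, 8) + 5)
  fr3 <- fit_regression(rec3)
  expect_equal(fr3$r_squared, 1, tolerance = 1e-10)
  expect_lt(fr3$p_value, 1e-6)

  # swapped predictor role
  fr_sw <- fit_regression(rec2, predictor = "a_ire")
  expect_equal(fr_sw$slope, 0.5, tolerance = 1e-12)

  # through-origin variant
  fr_o <- fit_regression(rec2, intercept = FALSE)
  expect_equal(fr_o$slope, 2, tolerance = 1e-12)
  expect_equal(fr_o$intercept, 0)

  expect_error(fit_regression(rec2[1:2, ]), "at least 3")
  bad <- area_records(1:3, 0.2, a_ire_mm2 = c(1, 2, 3), a_he_mm2 = c(2, 2, 2))
  expect_error(fit_regression(bad), "zero variance")
})

test_that("regression matches the closed-form normal equations to 1e-10", {
  set.seed(17)
  a_he <- seq(1, 5, length.out = 9)
  a_ire <- 0.9 * a_he + 0.3 + rnorm(9, sd = 0.1)
  rec <- area_records(1:9, 0.2, a_ire_mm2 = a_ire, a_he_mm2 = a_he)
  fr <- fit_regression(rec)
  or <- oracle_ols(a_he, a_ire)
  expect_equal(fr$slope, or$slope, tolerance = 1e-10)
  expect_equal(fr$intercept, or$intercept, tolerance = 1e-10)
  expect_equal(fr$r_squared, or$r_squared, tolerance = 1e-10)
  expect_equal(fr$p_value, or$p_value, tolerance = 1e-10)
})

test_that("Bland-Altman handles offsets, degeneracy, and matches the oracle", {
  # constant offset: zero-width limits of agreement
  rec <- area_records(1:3, 0.2, a_ire_mm2 = c(1, 2, 3), a_he_mm2 = c(1.2, 2.2, 3.2))
  ba <- bland_altman(rec)
  expect_equal(ba$mean_diff, -0.2, tolerance = 1e-12)
  expect_equal(ba$sd_diff, 0)
  expect_equal(ba$loa_low, -0.2, tolerance = 1e-12)
  expect_equal(ba$loa_high, -0.2, tolerance = 1e-12)
  expect_false(ba$correlation_defined)

  # identical methods: all zero, correlation flagged not computable
  rec0 <- area_records(1:3, 0.2, a_ire_mm2 = c(1, 2, 3), a_he_mm2 = c(1, 2, 3))
  ba0 <- bland_altman(rec0)
  expect_equal(ba0$mean_diff, 0)
  expect_equal(c(ba0$loa_low, ba0$loa_high), c(0, 0))
  expect_false(ba0$correlation_defined)
  expect_true(is.na(ba0$r_diff_vs_mean))

  # random table vs direct-formula oracle
  set.seed(23)
  a <- runif(9, 1, 6); b <- a + rnorm(9, 0.1, 0.3)
  rec9 <- area_records(1:9, 0.3, a_ire_mm2 = a, a_he_mm2 = b)
  ba9 <- bland_altman(rec9)
  or <- oracle_bland_altman(a, b)
  expect_equal(ba9$mean_diff, or$mean_diff, tolerance = 1e-10)
  expect_equal(ba9$sd_diff, or$sd_diff, tolerance = 1e-10)
  expect_equal(ba9$loa_low, or$loa_low, tolerance = 1e-10)
  expect_equal(ba9$loa_high, or$loa_high, tolerance = 1e-10)
  expect_equal(ba9$r_diff_vs_mean, or$r, tolerance = 1e-10)
  expect_equal(ba9$p_diff_vs_mean, or$p, tolerance = 1e-10)
  expect_true(ba9$correlation_defined)

  # limits symmetric about the mean difference, by construction
  expect_equal(ba9$loa_high - ba9$mean_diff, ba9$mean_diff - ba9$loa_low,
               tolerance = 1e-12)

  expect_error(bland_altman(rec9[1:2, ]), "at least 3")
})

test_that("best-level selection maximizes R^2 with the stated tie-break", {
  one <- data.frame(p_level = 0.2, r_squared = 0.8, mean_diff = 0.3)
  expect_equal(select_best_level(one)$p_level, 0.2)

  multi <- data.frame(p_level = c(0.1, 0.2, 0.3),
                      r_squared = c(0.85, 0.93, 0.90),
                      mean_diff = c(0.5, 0.06, -0.4))
  expect_equal(select_best_level(multi)$p_level, 0.2)

  # exact R^2 tie: smaller |mean difference| wins
  tie <- data.frame(p_level = c(0.1, 0.3),
                    r_squared = c(0.9, 0.9),
                    mean_diff = c(-0.5, 0.2))
  expect_equal(select_best_level(tie)$p_level, 0.3)

  expect_error(select_best_level(data.frame()), "at least one")
})

test_that("agreement outputs are invariant to record order", {
  set.seed(31)
  a <- runif(9, 1, 6); b <- a + rnorm(9, 0, 0.2)
  rec <- area_records(1:9, 0.2, a_ire_mm2 = a, a_he_mm2 = b)
  perm <- rec[sample(9), ]
  fr1 <- fit_regression(rec); fr2 <- fit_regression(perm)
  expect_equal(fr1$slope, fr2$slope, tolerance = 1e-12)
  expect_equal(fr1$r_squared, fr2$r_squared, tolerance = 1e-12)
  ba1 <- bland_altman(rec); ba2 <- bland_altman(perm)
  expect_equal(ba1$mean_diff, ba2$mean_diff, tolerance = 1e-12)
  expect_equal(ba1$loa_low, ba2$loa_low, tolerance = 1e-12)
  expect_equal(ba1$r_diff_vs_mean, ba2$r_diff_vs_mean, tolerance = 1e-12)
})

test_that("level statistics split records by level and mix both analyses", {
  set.seed(37)
  a_he <- runif(9, 1, 6)
  rec <- do.call(rbind, lapply(c(0.1, 0.2, 0.3), function(p)
    area_records(1:9, p, a_ire_mm2 = p * 5 * a_he + rnorm(9, 0, 0.1),
                 a_he_mm2 = a_he)))
  ls <- level_statistics(rec)
  expect_equal(ls$p_level, c(0.1, 0.2, 0.3))
  expect_equal(ls$n, rep(9L, 3))
  for (k in 1:3) {
    sub <- rec[rec$p == ls$p_level[k], ]
    expect_equal(ls$slope[k], fit_regression(sub)$slope, tolerance = 1e-12)
    expect_equal(ls$mean_diff[k], bland_altman(sub)$mean_diff, tolerance = 1e-12)
  }
  # records mixing levels are refused by the single-level analyses
  expect_error(fit_regression(rec), "multiple probability levels")
})
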