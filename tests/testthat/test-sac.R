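test_that("stretch_ratio computes the length ratio and validates input", {
  expect_identical(stretch_ratio(0.97, 0.97), 1)
  expect_equal(stretch_ratio(1.164, 0.97), 1.2)
  expect_equal(stretch_ratio(1.164), 1.2)  # default half_sl0 = 0.97
  expect_error(stretch_ratio(0, 0.97), "positive")
  expect_error(stretch_ratio(0.97, -1), "positive")
})

test_that("compute_isac matches closed-form hand evaluations", {
  p <- sac_params()
  expect_equal(p$g_sac, 0.025)
  expect_equal(p$v_rev, -20)
  expect_equal(p$k, 1)
  expect_equal(p$alpha, 3)
  expect_equal(p$half_sl0, 0.97)
  # reversal potential: zero current for any stretch
  expect_equal(compute_isac(-20, 1.0, p), 0)
  expect_equal(compute_isac(-20, 1.3, p), 0)
  # no conductance: zero everywhere
  p0 <- sac_params(g_sac = 0)
  expect_equal(compute_isac(-80, 1.2, p0), 0)
  # hand evaluations
  expect_equal(compute_isac(-80, 1.0, p), 0.025 * (-60) / 2)
  expect_equal(compute_isac(-80, 1.2, p),
               0.025 * (-60) / (1 + exp(-0.6)),
               tolerance = 1e-12)
})

test_that("effective conductance is monotone in stretch and saturates", {
  p <- sac_params()
  lams <- seq(0.8, 3, by = 0.05)
  g <- vapply(lams, function(l) sac_conductance(l, p), numeric(1))
  expect_true(all(diff(g) > 0))
  expect_equal(sac_conductance(1, p), p$g_sac / 2)
  expect_lt(abs(sac_conductance(50, p) - p$g_sac), 1e-12)
})

test_that("current is linear in the driving voltage at fixed stretch", {
  p <- sac_params()
  vs <- c(-90, -60, -20, 0, 30)
  i <- vapply(vs, function(v) compute_isac(v, 1.15, p), numeric(1))
  g <- sac_conductance(1.15, p)
  expect_equal(i, g * (vs - p$v_rev), tolerance = 1e-12)
})

test_that("parameter validation rejects bad values", {
  expect_error(sac_params(g_sac = -1), "g_sac")
  expect_error(sac_params(k = -0.1))
  expect_error(sac_params(half_sl0 = 0))
  expect_error(compute_isac(NaN, 1, sac_params()))
})
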