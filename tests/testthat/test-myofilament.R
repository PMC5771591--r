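test_that("clamped-calcium steady state matches the algebraic fixed point", {
  for (ca_uM in c(0.1, 0.5, 1.0, 3.0)) {
    ss <- nl_steady_state(cai = ca_uM / 1000)
    sim <- twitch_from_calcium(
      data.frame(time = seq(0, 20000, 0.5), cai = ca_uM / 1000))
    expect_equal(sim$force[nrow(sim)], ss$force, tolerance = 1e-6,
                 label = sprintf("Cai = %.1f uM", ca_uM))
  }
})

test_that("zero calcium relaxes force to rest", {
  rel <- twitch_from_calcium(data.frame(time = seq(0, 2000, 0.5), cai = 0))
  # after 2 s at diastolic calcium the force is below 1% of a twitch peak
  tr <- run_paced_cell(duration = 600, prepace = 2)
  tw <- twitch_from_calcium(tr)
  expect_lt(rel$force[nrow(rel)], 0.01 * max(tw$force))
})

test_that("a real calcium transient produces a physiological twitch", {
  tr <- run_paced_cell(duration = 1000, prepace = 2)
  tw <- twitch_from_calcium(tr)
  peak_t <- tw$time[which.max(tw$force)]
  expect_gt(max(tw$force), 0.05)
  expect_gt(peak_t, 30)        # force peaks well after the calcium upstroke
  expect_lt(peak_t, 300)
  expect_lt(tw$force[nrow(tw)], 0.05 * max(tw$force))  # relaxed by 1 s
})

test_that("steady force increases with half-sarcomere length below optimum", {
  f <- vapply(c(0.7, 0.85, 0.97, 1.05), function(L) {
    sim <- twitch_from_calcium(data.frame(time = seq(0, 10000, 1), cai = 1e-3),
                               half_sl = L)
    sim$force[nrow(sim)]
  }, numeric(1))
  expect_true(all(diff(f) > 0))
})

test_that("sub-stepping does not change the twitch materially", {
  tr <- run_paced_cell(duration = 600, prepace = 2)
  tw1 <- twitch_from_calcium(tr, substeps = 5)
  tw2 <- twitch_from_calcium(tr, substeps = 25)
  expect_lt(max(abs(tw1$force - tw2$force)), 1e-3 * max(tw2$force))
})

test_that("prescribed-length mode follows the supplied trajectory", {
  tt <- seq(0, 500, 0.5)
  len <- 0.97 * (1 + 0.1 * sin(2 * pi * tt / 500))
  tw <- twitch_from_calcium(data.frame(time = tt, cai = 5e-4, half_sl = len),
                            mode = "prescribed")
  expect_equal(tw$half_sl, len, tolerance = 1e-12)
})

test_that("input validation", {
  expect_error(twitch_from_calcium(data.frame(time = 1, cai = 1)),
               "two")
  expect_error(
    twitch_from_calcium(data.frame(time = c(0, 1, 3), cai = c(0, 0, 0))),
    "uniform")
  expect_error(
    twitch_from_calcium(data.frame(time = 0:10, cai = 0), mode = "prescribed"),
    "half_sl")
  expect_error(nl_step(sarcomere_state(), cai = -1), "cai")
  expect_error(nl_step(sarcomere_state(), cai = 1e-4, dt = 0), "dt")
  expect_error(sarcomere_params(tt = 0))
  expect_error(sarcomere_params(l_a = 1.2, l_opt = 1.1))
})
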