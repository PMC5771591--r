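test_that("activation time of a linear ramp is exact", {
  tr <- tibble::tibble(time = 0:20, vm = -80 + 2 * time)
  expect_equal(detect_at(tr), 10)
  # never crosses
  low <- tibble::tibble(time = 0:20, vm = rep(-80, 21))
  expect_true(is.na(detect_at(low)))
  expect_error(detect_at(tibble::tibble(time = numeric(0), vm = numeric(0))),
               "empty")
})

test_that("recovery time of a triangular AP is exact", {
  # up in 1 ms, plateau, linear fall crossing -60 mV at exactly t = 350
  tr <- tibble::tibble(
    time = seq(0, 400, 0.5),
    vm = approx(c(0, 1, 300, 350, 400), c(-80, 20, 20, -60, -68),
                xout = seq(0, 400, 0.5))$y
  )
  at <- detect_at(tr)
  expect_equal(detect_rt(tr, after = at), 350, tolerance = 1e-9)
})

test_that("apd is the difference and validates ordering", {
  expect_equal(apd(4.4, 353.3), 348.9)
  expect_error(apd(10, 5), "after")
  expect_true(is.na(apd(NA, 350)))
})

test_that("markers recovered from synthetic fixtures match ground truth", {
  for (at_true in c(5, 12.5)) {
    for (rt_true in c(305, 361.2)) {
      tr <- synthetic_ap_trace(at = at_true, rt = rt_true, dt = 0.5)
      at <- detect_at(tr)
      rt <- detect_rt(tr, after = at)
      expect_equal(at, at_true, tolerance = 1e-6)
      expect_equal(rt, rt_true, tolerance = 1e-6)
      expect_equal(apd(at, rt), rt_true - at_true, tolerance = 1e-6)
    }
  }
  # non-repolarizing fixture -> failure flag
  bad <- synthetic_ap_trace(at = 5, rt = NA)
  at <- detect_at(bad)
  expect_false(is.na(at))
  expect_true(is.na(detect_rt(bad, after = at)))
})

test_that("marker extraction is robust to sampling stride", {
  base <- synthetic_ap_trace(at = 7, rt = 312, dt = 0.1)
  coarse <- base[seq(1, nrow(base), by = 10), ]  # 1 ms stride
  expect_lt(abs(detect_at(base) - detect_at(coarse)), 0.5)
  rt_f <- detect_rt(base, after = detect_at(base))
  rt_c <- detect_rt(coarse, after = detect_at(coarse))
  expect_lt(abs(rt_f - rt_c), 0.5)
})

test_that("per-fiber extraction and summaries handle failures", {
  good <- synthetic_ap_trace(at = 5, rt = 300)
  fail <- synthetic_ap_trace(at = 6, rt = NA)
  quiet <- tibble::tibble(time = good$time, vm = -80)
  long <- dplyr::bind_rows(
    dplyr::mutate(good, fiber = 1), dplyr::mutate(fail, fiber = 2),
    dplyr::mutate(quiet, fiber = 3))
  mk <- extract_markers(long)
  expect_equal(nrow(mk), 3)
  expect_equal(mk$repolarization_failed, c(FALSE, TRUE, FALSE))
  expect_true(is.na(mk$at[3]))
  sm <- summarize_markers(mk)
  expect_equal(sm$n_fibers, 3)
  expect_equal(sm$n_activated, 2)
  expect_equal(sm$n_failed, 1)
  expect_equal(sm$min_apd, sm$max_apd)   # single fiber with a defined APD
  # all failed -> NA summary
  allf <- extract_markers(dplyr::mutate(fail, fiber = 1))
  smf <- summarize_markers(allf)
  expect_equal(smf$n_failed, 1)
  expect_true(is.na(smf$min_apd) && is.na(smf$first_rt))
  # single-fiber plain trace without id column
  one <- extract_markers(good)
  expect_equal(nrow(one), 1)
})
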