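# Single run shared by several expensive expectations
paced <- run_paced_cell(duration = 1000, prepace = 2, full_states = TRUE)

test_that("current assembly: additivity and the all-off case", {
  st <- cell_state()
  cur <- compute_ionic_currents(st, cell_params())
  comps <- cur[setdiff(names(cur), "i_total")]
  expect_equal(sum(unlist(comps)), cur$i_total, tolerance = 1e-12)
  # all conductance/pump/exchanger scales zero -> zero total
  p0 <- cell_params(g_na = 0, g_k1 = 0, g_to = 0, g_kr = 0, g_ks = 0,
                    g_cal = 0, g_bna = 0, g_bca = 0, g_pk = 0, g_pca = 0,
                    k_nak = 0, k_naca = 0)
  cur0 <- compute_ionic_currents(st, p0)
  expect_equal(cur0$i_total, 0)
  # additivity over assorted states along a real trajectory
  states <- attr(paced, "final_state")
  cur2 <- compute_ionic_currents(states, cell_params(), i_sac = -0.3)
  comps2 <- cur2[setdiff(names(cur2), "i_total")]
  expect_equal(sum(unlist(comps2)), cur2$i_total, tolerance = 1e-10)
  expect_equal(cur2$i_sac, -0.3)
})

test_that("ionic currents match the pure-R reference implementation", {
  p <- cell_params()
  for (st in list(cell_state(), attr(paced, "final_state"))) {
    ours <- compute_ionic_currents(st, p)
    ref <- ref_currents(unclass(st), p)
    for (nm in names(ref)) {
      expect_equal(ours[[nm]], ref[[nm]], tolerance = 1e-10, label = nm)
    }
  }
})

test_that("one integration step matches the pure-R reference step", {
  p <- cell_params()
  s <- unclass(cell_state())
  r <- s
  for (i in 1:50) {
    istim <- if (i <= 50) 52 else 0   # depolarize to exercise all branches
    step <- euler_step(s, p, istim = istim, dt = 0.02)
    s <- unclass(step)
    r <- ref_step(r, p, istim = istim, dt = 0.02)
  }
  # arithmetic-ordering roundoff is amplified by the steep upstroke, so the
  # two implementations agree only to ~1e-7 relative after 50 steps
  expect_equal(as.numeric(s), as.numeric(r[names(s)]), tolerance = 1e-6)
})

test_that("a full reference beat agrees with the compiled core", {
  st <- equilibrate_cell(duration = 2000)
  tr <- run_paced_cell(cell_params(), sac = sac_disabled(), duration = 400,
                       prepace = 0, init = st, stride = 0.5)
  ref <- ref_run(st, cell_params(), duration = 400, stride = 0.5)
  expect_equal(nrow(ref), nrow(tr))
  # roundoff accumulates into a sub-millisecond phase shift that is
  # amplified on the steep repolarization slope, so compare the plateau
  # pointwise and the phase timings via the markers
  plateau <- tr$time >= 50 & tr$time <= 250
  expect_lt(max(abs(tr$vm[plateau] - ref$vm[plateau])), 0.5)
  a_c <- detect_at(tr); a_r <- detect_at(ref)
  expect_lt(abs(a_c - a_r), 0.1)
  expect_lt(abs(detect_rt(tr, after = a_c) - detect_rt(ref, after = a_r)), 0.5)
})

test_that("voltage update convention: Iion = 0, Istim = 52 gives +1.04 mV", {
  st <- cell_state()
  new <- euler_step(st, cell_params(), istim = 52, dt = 0.02,
                    iion_override = 0)
  expect_equal(new[["vm"]] - st[["vm"]], 0.02 * 52, tolerance = 1e-12)
})

test_that("resting state is a fixed point and stays quiet for 5 s", {
  st <- equilibrate_cell(duration = 10000)
  cur <- compute_ionic_currents(st, cell_params())
  expect_lt(abs(cur$i_total), 0.01)
  one <- euler_step(st, cell_params(), istim = 0, dt = 0.02)
  expect_lt(abs(one[["vm"]] - st[["vm"]]), 1e-4)
  tr <- run_paced_cell(cell_params(), stimulus_spec(amplitude = 0),
                       duration = 5000, prepace = 0, init = st, stride = 5)
  expect_lt(max(abs(tr$vm - tr$vm[1])), 0.1)
})

test_that("gate bounds and concentration positivity hold over pacing", {
  gates <- paced[, c("m", "h", "j", "xr1", "xr2", "xs", "r", "s", "d", "f",
                     "g")]
  expect_true(all(gates >= 0 & gates <= 1))
  # fCa's steady state exceeds 1 at low calcium by construction (max
  # 1.53/1.46); it must stay within that bound
  expect_true(all(paced$fca >= 0 & paced$fca <= 1.53 / 1.46))
  conc <- paced[, c("cai", "ca_sr", "nai", "ki")]
  expect_true(all(conc > 0))
})

test_that("APD80 converges when dt is halved", {
  apd_at <- function(dt) {
    tr <- run_paced_cell(duration = 600, dt = dt, prepace = 2)
    a <- detect_at(tr)
    detect_rt(tr, after = a) - a
  }
  a02 <- apd_at(0.02)
  a01 <- apd_at(0.01)
  expect_lt(abs(a02 - a01), 1)
})

test_that("heart-failure remodeling touches exactly the six named scales", {
  p <- cell_params()
  expect_identical(apply_hf(p, hf_modifiers(1, 1, 1, 1, 1, 1)), p)
  m <- hf_modifiers()
  hf <- apply_hf(p, m)
  expect_equal(hf$g_to / p$g_to, m$f_to)
  expect_equal(hf$g_ks / p$g_ks, m$f_ks)
  expect_equal(hf$g_k1 / p$g_k1, m$f_k1)
  expect_equal(hf$g_na / p$g_na, m$f_na)
  expect_equal(hf$g_cal / p$g_cal, m$f_cal)
  expect_equal(hf$k_naca / p$k_naca, m$f_naca)
  same <- c("g_kr", "g_bna", "g_bca", "g_pk", "g_pca", "k_nak", "cm")
  for (nm in same) expect_identical(hf[[nm]], p[[nm]])
  expect_error(hf_modifiers(f_to = 0), "positive")
  expect_error(apply_hf(p, list(f_to = 0.5)), "hf_modifiers")
})

test_that("instability reporting names dt and time", {
  st <- cell_state()
  expect_error(
    run_paced_cell(cell_params(), stimulus_spec(amplitude = 1e5),
                   duration = 10, dt = 5, prepace = 0, init = st),
    "dt"
  )
})
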