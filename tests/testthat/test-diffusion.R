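test_that("uniform field and zero diffusivity are fixed points", {
  geo <- ventricle_geometry(n_rings = 4, nodes_per_ring = 8)
  nn <- geo$n_rings * geo$nodes_per_ring
  u <- rep(-80, nn)
  out <- diffusion_step(u, geo, d_coeff = 1.4, dt = 0.02)
  expect_equal(out, u)
  v <- rnorm(nn, -80, 5)
  out0 <- diffusion_step(v, geo, d_coeff = 0, dt = 0.02)
  expect_equal(out0, v)
})

test_that("node sum is conserved to machine precision on a closed ring", {
  geo <- ventricle_geometry(n_rings = 1, nodes_per_ring = 64)
  v <- rnorm(64, -70, 10)
  out <- diffusion_step(v, geo, d_coeff = 1.4, dt = 0.02, nsteps = 200)
  expect_equal(sum(out), sum(v), tolerance = 1e-12)
})

test_that("a Gaussian bump spreads with variance 2 D t on a fine ring", {
  n <- 512
  geo <- ventricle_geometry(n_rings = 1, nodes_per_ring = n)
  dx <- (geo$circ0[1] / 1000) / n         # node spacing (mm)
  xs <- (seq_len(n) - 1) * dx
  x0 <- xs[n / 2]
  sigma0 <- 20 * dx
  v <- exp(-(xs - x0)^2 / (2 * sigma0^2))
  d_coeff <- 0.3   # keeps D / dx^2 below the near-apex coupling cap
  t_end <- 40
  dt <- 0.01                              # keep the explicit update stable
  out <- diffusion_step(v, geo, d_coeff = d_coeff, dt = dt,
                        nsteps = round(t_end / dt))
  w <- out / sum(out)
  var_out <- sum(w * (xs - x0)^2)
  expect_equal(var_out, sigma0^2 + 2 * d_coeff * t_end, tolerance = 0.02)
})

test_that("a stability violation reports the admissible step", {
  geo <- ventricle_geometry(n_rings = 1, nodes_per_ring = 512)
  v <- rnorm(512)
  expect_error(diffusion_step(v, geo, d_coeff = 50, dt = 1), "dt")
})
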