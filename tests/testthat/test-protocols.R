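# Small geometry keeps the tissue protocol runs affordable here; the
# acceptance checks use the full-resolution defaults.
small_geo <- ventricle_geometry(n_rings = 8, nodes_per_ring = 8)

test_that("single-cell stretch protocol: shape, shared grid, determinism", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  res <- run_single_cell_stretch(lambdas = c(1.0, 1.2), duration = 500,
                                 prepace = 1, out_dir = d1)
  expect_named(res, c("traces", "markers"))
  expect_setequal(unique(res$traces$lambda), c(1.0, 1.2))
  expect_true(all(c("time", "vm", "cai") %in% names(res$traces)))
  # identical time grids across stretch ratios
  grids <- split(res$traces$time, res$traces$lambda)
  expect_identical(grids[[1]], grids[[2]])
  expect_equal(nrow(res$markers), 2)
  expect_true(all(c("lambda", "at", "rt", "apd", "repolarization_failed")
                  %in% names(res$markers)))
  # byte-identical rerun
  res2 <- run_single_cell_stretch(lambdas = c(1.0, 1.2), duration = 500,
                                  prepace = 1, out_dir = d2)
  expect_identical(res$traces$vm, res2$traces$vm)
  for (f in c("single_cell_traces.csv", "single_cell_markers.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # provenance header present
  head1 <- readLines(file.path(d1, "single_cell_markers.csv"), n = 1)
  expect_match(head1, "^#")
  expect_error(run_single_cell_stretch(lambdas = numeric(0)), "non-empty")
})

test_that("preload protocol emits the comparison-table schema", {
  out <- withr::local_tempdir()
  tab <- run_ventricle_preload(preloads = c(0, 20),
                               conditions = c("control", "hf"),
                               geometry = small_geo, duration = 500,
                               out_dir = out)
  expect_identical(names(tab),
                   c("stretch_ratio", "min_apd_control", "min_apd_hf",
                     "max_apd_control", "max_apd_hf"))
  expect_equal(tab$stretch_ratio, c(1.0, 1.2))
  expect_true(all(is.finite(tab$min_apd_control)))
  expect_true(all(tab$max_apd_control >= tab$min_apd_control, na.rm = TRUE))
  sm <- attr(tab, "summaries")
  expect_setequal(unique(sm$condition), c("control", "hf"))
  expect_equal(nrow(sm), 4)
  expect_true(file.exists(file.path(out, "preload_apd_table.csv")))
  # a control-only run leaves the hf columns NA
  tab1 <- run_ventricle_preload(preloads = 0, conditions = "control",
                                geometry = small_geo, duration = 500)
  expect_true(is.na(tab1$min_apd_hf) && is.na(tab1$max_apd_hf))
  expect_true(is.finite(tab1$min_apd_control))
  expect_error(run_ventricle_preload(preloads = numeric(0)), "non-empty")
})

test_that("configuration round-trips through YAML and rejects unknowns", {
  cfg <- default_config()
  cfg$sac$g_sac <- 0.05
  cfg$numerics$duration_tissue <- 350
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, path)
  back <- read_config(path)
  expect_equal(back, cfg)
  obj <- config_objects(back)
  expect_equal(obj$sac$g_sac, 0.05)
  expect_s3_class(obj$cell, "cardio_cell_params")
  expect_s3_class(obj$geometry, "cardio_geometry")
  # a partial file keeps defaults for omitted keys
  writeLines("sac:\n  g_sac: 0.01\n", path)
  part <- read_config(path)
  expect_equal(part$sac$g_sac, 0.01)
  expect_equal(part$sac$v_rev, default_config()$sac$v_rev)
  expect_equal(part$cell, default_config()$cell)
  # unknown section / key
  writeLines("bogus:\n  a: 1\n", path)
  expect_error(read_config(path), "unknown configuration section")
  writeLines("sac:\n  g_wrong: 1\n", path)
  expect_error(read_config(path), "unknown key")
})
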