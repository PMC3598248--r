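test_that("the same seed reproduces a curve bit for bit", {
  a <- clean_curve(E = 6, noise = 2e-3, seed = 123)$curve
  b <- clean_curve(E = 6, noise = 2e-3, seed = 123)$curve
  expect_identical(a$deflection, b$deflection)
  c2 <- clean_curve(E = 6, noise = 2e-3, seed = 124)$curve
  expect_false(identical(a$deflection, c2$deflection))
})

test_that("generator inputs are validated", {
  expect_error(clean_curve(E = -1), "positive")
  expect_error(clean_curve(offset = 5), "inside the ramp")
  expect_error(clean_curve(n = 10), "at least 64")
  expect_error(simulate_raw_curve(5, noise_sd = -1), "non-negative")
})

test_that("deflection approaches piezo travel in the rigid limit", {
  # the implicit contact solution obeys d/s = 1 - sqrt(K / (C s)) + O(K/Cs):
  # the approach to the rigid asymptote is monotone in E and reaches 1%
  # only at very large moduli
  p <- default_params()
  rel_gap <- vapply(c(1e2, 1e4, 1e6, 1e8), function(E) {
    sim <- simulate_raw_curve(E, p, contact_offset = 0.5, n_samples = 256L)
    s <- sim$curve$z - 0.5
    i <- which.max(s)
    1 - sim$curve$deflection[i] / s[i]
  }, numeric(1))
  expect_true(all(diff(rel_gap) < 0))
  expect_lt(rel_gap[4], 0.01)
})

test_that("the implicit deflection solve satisfies the force balance", {
  p <- default_params()
  sim <- clean_curve(E = 7, offset = 0.5, slope = 0, n = 256L)
  crv <- sim$curve
  post <- crv$z > 0.5
  d <- crv$deflection[post]
  delta <- (crv$z[post] - 0.5) - d
  lhs <- 1000 * p$spring_constant * d
  rhs <- sneddon_force(7, delta, p)
  expect_lt(max(abs(lhs - rhs)), 1e-10)
})

test_that("an experiment writes the expected dataset layout", {
  groups <- data.frame(condition = c("control", "hypothyroid"),
                       cell_type = "PC", age = "P0",
                       true_modulus = c(3, 5))
  design <- experiment_design(groups, n_cells = 10L, curves_per_cell = 3L,
                              cell_sd = 0, noise_sd = 0, n_samples = 64L,
                              seed = 5)
  td <- withr::local_tempdir()
  sim <- simulate_experiment(design, default_params(), dir = td)
  expect_length(sim$curves, 60)
  expect_length(sim$manifest, 60)
  expect_length(list.files(td, pattern = "\\.csv$"), 60)
  expect_true(file.exists(file.path(td, "dataset.json")))
  # regeneration from the same design is bit-identical
  sim2 <- simulate_experiment(design, default_params())
  expect_identical(sim$curves[[17]]$deflection, sim2$curves[[17]]$deflection)
  # manifest carries enough truth to re-derive each curve
  m <- sim$manifest[[1]]
  redo <- simulate_raw_curve(m$cell_modulus, default_params(),
                             contact_offset = m$contact_offset,
                             baseline_slope = m$baseline_slope,
                             noise_sd = m$noise_sd, n_samples = 64L,
                             seed = m$seed)
  expect_identical(redo$curve$deflection, sim$curves[[1]]$deflection)
})

test_that("gel profiles integrate to their specified analytic areas", {
  prof <- simulate_gel_profile(list(ref = c(150, 12, 1000)),
                               background = c(0, 0))
  expect_equal(band_area(prof$positions, prof$intensity,
                         prof$band_windows$ref),
               1000, tolerance = 1e-3)
  # zero-area bands leave only the background
  flat <- simulate_gel_profile(list(a = c(150, 12, 0)), background = c(7, 0))
  expect_true(all(abs(flat$intensity - 7) < 1e-12))
  # same seed reproducibility under noise
  n1 <- simulate_gel_profile(list(a = c(150, 12, 500)), background = c(10, 0),
                             noise_sd = 2, seed = 3)
  n2 <- simulate_gel_profile(list(a = c(150, 12, 500)), background = c(10, 0),
                             noise_sd = 2, seed = 3)
  expect_identical(n1$intensity, n2$intensity)
  expect_error(simulate_gel_profile(list(a = c(150, -1, 10))), "positive")
})

test_that("line-scan patches place 2-um windows inside constant regions", {
  patch <- simulate_line_scan_patch(c(PC = 987, OHC = 300))
  expect_equal(line_scan_intensity(patch$image, patch$windows$PC,
                                   patch$pixel_size), 987)
  expect_equal(line_scan_intensity(patch$image, patch$windows$OHC,
                                   patch$pixel_size), 300)
  expect_error(simulate_line_scan_patch(c(a = 1), region_width = 1.5),
               "at least 2")
  # noisy window means concentrate around truth (CLT bound)
  means <- vapply(1:20, function(s) {
    p <- simulate_line_scan_patch(c(PC = 500), noise_sd = 5, seed = s)
    line_scan_intensity(p$image, p$windows$PC, p$pixel_size)
  }, numeric(1))
  n_px <- 40 * 20   # 2 x 4 um window at 0.1 um pixels
  expect_true(all(abs(means - 500) < 3 * 5 / sqrt(n_px)))
})

test_that("Ct tables encode fold changes exactly and without bias", {
  fc <- data.frame(gene = "Fgfr1", condition = "hypothyroid", fold = 6)
  tb <- simulate_ct_table(fc, noise_sd = 0)
  expect_equal(ddct_fold_change(tb, "Fgfr1", "hypothyroid", "control"), 6,
               tolerance = 1e-12)
  tb1 <- simulate_ct_table(data.frame(gene = "g", condition = "hypothyroid",
                                      fold = 1))
  expect_equal(ddct_fold_change(tb1, "g", "hypothyroid", "control"), 1)
  expect_error(simulate_ct_table(data.frame(gene = "g",
                                            condition = "hypothyroid",
                                            fold = 0)), "positive")
  # Monte-Carlo: recovered folds unbiased on the log2 scale
  lf <- vapply(1:50, function(s) {
    tbs <- simulate_ct_table(fc, noise_sd = 0.1, seed = s)
    log2(ddct_fold_change(tbs, "Fgfr1", "hypothyroid", "control"))
  }, numeric(1))
  expect_lt(abs(mean(lf) - log2(6)), 0.05)
})
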