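test_that("forward Sneddon force matches hand arithmetic and scalings", {
  p <- cantilever_params()   # alpha 18 deg, nu 0.5
  # (2/pi) tan(18 deg) / (1 - 0.25) at E = 1 kPa, delta = 1 um
  expect_equal(sneddon_force(1, 1, p), 0.2758004, tolerance = 1e-6)
  expect_equal(sneddon_force(3, 0, p), 0)
  expect_equal(sneddon_force(2, 1, p), 2 * sneddon_force(1, 1, p))
  expect_equal(sneddon_force(1, 2, p), 4 * sneddon_force(1, 1, p))
  expect_error(sneddon_force(1, -0.1, p), "non-negative")
  expect_error(sneddon_force(-1, 0.1, p), "positive")
})

test_that("both prefactor conventions are available and differ by tan^2", {
  p <- cantilever_params()
  a <- p$tip_half_angle * pi / 180
  f_tan <- sneddon_force(1, 1, p, form = "tan")
  f_inv <- sneddon_force(1, 1, p, form = "inv-tan")
  expect_equal(f_tan / f_inv, tan(a)^2, tolerance = 1e-12)
})

test_that("fitting a noiseless forward curve returns the exact modulus", {
  p <- cantilever_params()
  for (E in c(0.5, 5, 50)) {
    fit <- fit_modulus(ideal_indentation(E), p)
    expect_rel(fit$modulus, E, 1e-9)
    expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  }
  # round trip holds in the alternative prefactor convention too
  delta <- seq(0, 1.5, length.out = 40)
  crv <- indentation_curve(delta, sneddon_force(7, delta, p, form = "inv-tan"),
                           0, 0)
  expect_rel(fit_modulus(crv, p, form = "inv-tan")$modulus, 7, 1e-9)
})

test_that("the estimator is linear: scaling forces scales the modulus", {
  p <- cantilever_params()
  crv <- ideal_indentation(4)
  crv2 <- indentation_curve(crv$delta, 2.5 * crv$force, 0, 0)
  expect_rel(fit_modulus(crv2, p)$modulus, 2.5 * fit_modulus(crv, p)$modulus,
             1e-12)
})

test_that("closed-form fit agrees with a brute-force SSE minimizer", {
  p <- cantilever_params()
  set.seed(3)
  for (i in 1:5) {
    E_true <- runif(1, 1, 30)
    delta <- seq(0, 1.5, length.out = 120)
    force <- sneddon_force(E_true, delta, p) + rnorm(120, 0, 0.05)
    crv <- indentation_curve(delta, pmax(force, min(force)), 0, 0)
    E_hat <- fit_modulus(crv, p)$modulus
    sse <- function(E) sum((force - sneddon_force(E, delta, p))^2)
    E_brute <- stats::optimize(sse, c(0.01, 100), tol = 1e-12)$minimum
    expect_rel(E_hat, E_brute, 1e-6)
  }
})

test_that("the tip half-angle cancels in generation-fit round trips", {
  for (alpha in c(10, 18, 35)) {
    p <- cantilever_params(tip_half_angle = alpha)
    expect_rel(fit_modulus(ideal_indentation(6, params = p), p)$modulus, 6,
               1e-9)
  }
})

test_that("degenerate indentation inputs are rejected", {
  p <- cantilever_params()
  crv <- indentation_curve(rep(0.5, 10), rep(1, 10), 0, 0)
  expect_error(fit_modulus(crv, p), "degenerate")
  neg <- indentation_curve(seq(0, 1, length.out = 10),
                           -seq(0, 1, length.out = 10), 0, 0)
  expect_error(fit_modulus(neg, p), "non-physical")
  short <- ideal_indentation(5, n = 5)
  expect_error(fit_modulus(short, p), "at least 8 points")
})

test_that("sneddon_fit behaves like a fitted model object", {
  p <- cantilever_params()
  fit <- fit_modulus(ideal_indentation(5, meta = make_meta()), p)
  expect_named(coef(fit), "modulus_kPa")
  expect_equal(unname(predict(fit, 1)), sneddon_force(fit$modulus, 1, p))
  expect_length(residuals(fit), fit$n_points)
  expect_output(print(fit), "Young's modulus")
  expect_output(print(summary(fit)), "RMSE")
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "indentation_curve")
})

test_that("cell aggregation averages its curve fits", {
  p <- cantilever_params()
  fits <- lapply(c(4, 5, 6), function(E) {
    fit_modulus(ideal_indentation(E, meta = make_meta("cellZ")), p)
  })
  rec <- aggregate_cell(fits)
  expect_equal(rec$cell_modulus_kPa, 5, tolerance = 1e-9)
  expect_equal(rec$n_curves, 3L)
  expect_warning(aggregate_cell(fits[1]), "only one surviving")
  bad <- c(fits[1], list(fit_modulus(
    ideal_indentation(5, meta = make_meta("other")), p)))
  expect_error(aggregate_cell(bad), "different cells")
  expect_error(aggregate_cell(list()), "no fits")
})

test_that("group aggregation reports mean and s.e.m. over cells", {
  p <- cantilever_params()
  mk_cell <- function(id, E) {
    suppressWarnings(aggregate_cell(list(
      fit_modulus(ideal_indentation(E, meta = make_meta(id)), p))))
  }
  cells10 <- lapply(1:10, function(i) mk_cell(paste0("c", i), 6.06))
  g <- aggregate_group(cells10)
  expect_equal(g$mean_kPa, 6.06, tolerance = 1e-9)
  expect_equal(g$sem_kPa, 0, tolerance = 1e-12)
  expect_equal(g$n_cells, 10L)
  cells3 <- lapply(1:3, function(i) mk_cell(paste0("d", i), i))
  g3 <- aggregate_group(cells3)
  expect_equal(g3$mean_kPa, 2, tolerance = 1e-9)
  expect_equal(g3$sem_kPa, 1 / sqrt(3), tolerance = 1e-9)
  expect_error(aggregate_group(cells3[1]), "at least 2 cells")
  mixed <- c(cells3, list(suppressWarnings(aggregate_cell(list(fit_modulus(
    ideal_indentation(5, meta = make_meta("e1", cell_type = "PC")), p))))))
  expect_error(aggregate_group(mixed), "heterogeneous")
})
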