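# shared fixture builders (all data generated in code)

default_params <- function() cantilever_params()

make_meta <- function(cell_id = "cellA", ...) curve_meta(cell_id, ...)

# noiseless synthetic approach curve with known truth
clean_curve <- function(E = 6, offset = 0.5, slope = 0.005, n = 1024L,
                        ramp = 3, noise = 0, seed = 1L, ...) {
  simulate_raw_curve(E, default_params(), contact_offset = offset,
                     baseline_slope = slope, noise_sd = noise,
                     n_samples = n, ramp = ramp, seed = seed, ...)
}

# indentation curve synthesized directly from the forward model
ideal_indentation <- function(E = 5, n = 50L, delta_max = 1.5,
                              params = default_params(),
                              meta = NULL) {
  delta <- seq(0, delta_max, length.out = n)
  indentation_curve(delta, sneddon_force(E, delta, params), 0, 0, meta = meta)
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
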