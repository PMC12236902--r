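# Shared fixtures: small, fast parameter sets for module tests. The
# acceptance tests use the full default study conditions instead.

small_params <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(duration_s = 1200, n_voids = 3, n_nvcs = 2, fs_pressure = 20,
         fs_photometry = 50, seed = seed),
    list(...))
  do.call(sim_params, args)
}

small_opto_params <- function(seed = 1L, n_stim_trials = 10, ...) {
  args <- utils::modifyList(
    list(n_stim_trials = n_stim_trials, stim_duration_s = 5, stim_gap_s = 10,
         fs_emg = 500, fs_pressure = 20, seed = seed),
    list(...))
  p <- do.call(sim_params, args)
  d <- p$stim_duration_s
  p$duration_s <- p$n_stim_trials * (3 * d + p$stim_gap_s) + 3 * d + 10
  p
}

# flat trace with known injected transients, for recovery tests
flat_dff <- function(values, fs = 10) {
  structure(list(values = values, fs = fs, t0 = 0, corrected = TRUE,
                 baseline_model = list(family = "test")),
            class = "lut_dff")
}

expect_rel_equal <- function(x, y, tol) {
  expect_true(all(abs(x - y) <= tol * pmax(abs(y), 1e-12)),
              label = sprintf("max rel err %.3g <= %g",
                              max(abs(x - y) / pmax(abs(y), 1e-12)), tol))
}
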