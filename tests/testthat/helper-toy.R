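# Shared fixtures, built once per test run and memoised.
#
# Heavier DE/property tests run at a reduced horizon (800 min instead of
# the 2000 min default) and small populations to stay inside the test
# budget; the phenotype constraint and the predictions are always
# evaluated at the same horizon, so the runs are internally consistent.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, .fixtures)) assign(name, build(), .fixtures)
  get(name, .fixtures)
}

toy_fixture <- function() fixture("toy", function() make_toy_model())

small_panel <- function() {
  fixture("panel", function()
    make_strain_panel(c("ks_a", "ks_a2", "ki_ae", "ks_rS1"),
                      max_order = 2))
}

small_ensemble <- function() {
  fixture("ensemble", function() {
    toy <- toy_fixture()
    make_reference_ensemble(toy$model, toy$pv, n = 12, seed = 42)
  })
}

# A hand-built trajectory object for exercising the classification rules
# without simulation.
fake_traj <- function(div_size, max_size, blowup = FALSE, n_time = 11) {
  structure(list(time = seq(0, length.out = n_time, by = 0.05), dt = 0.05,
                 horizon = 0.05 * (n_time - 1), species = "V",
                 div_time = seq_along(div_size) * 1.0, div_size = div_size,
                 max_size = max_size, means = c(V = max_size),
                 final_state = c(V = max_size),
                 post_last_div = c(V = max_size), blowup = blowup,
                 blowup_time = if (blowup) 0.5 else NA_real_),
            class = "pde_trajectory")
}
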