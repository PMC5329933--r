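test_that("wild-type simulation cycles and records division events", {
  toy <- toy_fixture()
  tr <- simulate_strain(toy$model, toy$pv)
  expect_gte(length(tr$div_time), 3)
  expect_true(all(diff(tr$div_time) > 0))
  expect_equal(nrow(tr$states), length(tr$time))
  # division map conservation: stored grid state at an event row holds
  # f * (size at division), within one Euler step
  f <- toy$pv[["f"]]
  k <- round(tr$div_time / tr$dt) + 1
  expect_equal(unname(tr$states[k, "V"]), f * tr$div_size, tolerance = 1e-9)
})

test_that("degenerate horizons and absent growth behave as documented", {
  toy <- toy_fixture()
  tr0 <- simulate_strain(toy$model, toy$pv, horizon = 0)
  expect_length(tr0$div_time, 0)
  expect_lte(length(tr0$time), 1)

  # no growth from a sub-ignition state: size constant, no divisions
  quiet <- c(V = 0.3, A = 0.2, B = 0.02, E = 0.01, Z = 0.2,
             rS1 = 0.2, rM1 = 0.2, rX1 = 0.2)
  trg <- simulate_strain(toy$model, toy$pv,
                         strain_spec(1L, "no-growth", c(mu = 0)),
                         horizon = 500, init = quiet, keep_states = FALSE)
  expect_length(trg$div_time, 0)
  expect_equal(unname(trg$final_state["V"]), 0.3, tolerance = 1e-12)
})

test_that("wt_final_state returns the post-division state and errors when acyclic", {
  toy <- toy_fixture()
  tr <- simulate_strain(toy$model, toy$pv, keep_states = FALSE)
  expect_equal(wt_final_state(toy$model, toy$pv), tr$post_last_div)
  # an acyclic parameterisation cannot seed mutants
  pv0 <- toy$pv
  pv0["ks_e"] <- 0
  expect_error(wt_final_state(toy$model, pv0), "acyclic")
})

test_that("phenotype rules implement the cap, band and oscillation cases", {
  # size cap dominates everything
  expect_equal(classify_phenotype(fake_traj(c(10, 10, 10), 30))$code, 2L)
  # balanced divisions within the band are viable
  expect_equal(classify_phenotype(fake_traj(c(10, 10, 10), 12))$code, 1L)
  # band is checked against BOTH previous divisions
  expect_equal(classify_phenotype(fake_traj(c(8, 12, 8, 12), 13))$code, 0L)
  expect_equal(classify_phenotype(fake_traj(c(10, 9.8, 10.0), 12))$code, 1L)
  expect_equal(classify_phenotype(fake_traj(c(9.2, 10, 10), 12))$code, 0L)
  # fewer than three divisions is an arrest
  ph <- classify_phenotype(fake_traj(c(10, 10), 12))
  expect_equal(ph$code, 2L)
  expect_match(ph$reason, "arrest")
  # numerical blow-up is inviable regardless of the recorded sizes
  expect_equal(classify_phenotype(fake_traj(c(10, 10, 10), 12,
                                            blowup = TRUE))$code, 2L)
  # boundary: exactly 5 percent off the last division size stays viable
  expect_equal(classify_phenotype(fake_traj(c(9.5, 9.5, 10), 12),
                                  band = 0.05)$code, 1L)
})

test_that("phenotype classification ignores data appended past the horizon", {
  tr <- fake_traj(c(10, 10, 10), 12)
  code0 <- classify_phenotype(tr)$code
  tr$time <- c(tr$time, max(tr$time) + 0.05)
  expect_equal(classify_phenotype(tr)$code, code0)
})

test_that("time averages equal an independent re-summation of the grid", {
  toy <- toy_fixture()
  tr <- simulate_strain(toy$model, toy$pv, horizon = 200)
  expect_equal(time_average_abundances(tr), colMeans(tr$states),
               tolerance = 1e-12)
  # constant and linear species sanity
  expect_equal(unname(time_average_abundances(
    fake_traj(c(1, 1, 1), 3))["V"]), 3)
})

test_that("native integrator matches the generic R reference path", {
  toy <- toy_fixture()
  generic <- toy$model
  generic$native <- NULL
  tr_c <- simulate_strain(toy$model, toy$pv, horizon = 150)
  tr_r <- simulate_strain(generic, toy$pv, horizon = 150)
  expect_equal(tr_r$states, tr_c$states, tolerance = 1e-9)
  expect_equal(tr_r$div_time, tr_c$div_time)
  expect_equal(tr_r$div_size, tr_c$div_size, tolerance = 1e-9)
  expect_equal(tr_r$max_size, tr_c$max_size, tolerance = 1e-9)
})

test_that("simulation is deterministic and strains apply overrides", {
  toy <- toy_fixture()
  a <- simulate_strain(toy$model, toy$pv, horizon = 300)
  b <- simulate_strain(toy$model, toy$pv, horizon = 300)
  expect_identical(a$states, b$states)
  s <- strain_spec(5L, "ks_a-del", c(ks_a = 0))
  tr <- simulate_strain(toy$model, toy$pv, s, horizon = 100)
  expect_false(identical(tr$states, a$states[seq_len(nrow(tr$states)), ]))
  expect_error(simulate_strain(toy$model, toy$pv,
                               strain_spec(6L, "bad", c(nope = 0))),
               "unknown parameters")
})

test_that("trajectories export as delimited tables", {
  toy <- toy_fixture()
  tr <- simulate_strain(toy$model, toy$pv, horizon = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory(tr, path)
  df <- read.delim(path)
  expect_equal(nrow(df), length(tr$time))
  expect_equal(names(df), c("time", toy$model$species))
})
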