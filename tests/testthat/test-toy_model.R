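test_that("the reference toy model satisfies the fixture contract", {
  toy <- toy_fixture()
  tr <- simulate_strain(toy$model, truncate32(toy$pv), keep_states = FALSE)
  expect_equal(classify_phenotype(tr)$code, 1L)
  init_wt <- tr$post_last_div
  codes <- vapply(toy_eliminable_rates(), function(r)
    phenoDE:::strain_phenotype(toy$model, toy$pv,
                               strain_spec(1L, r, setNames(0, r)),
                               init = init_wt), integer(1))
  expect_true(any(codes == 2L))  # at least one lethal single knockout
  expect_true(any(codes == 1L))  # at least one benign single knockout
  # every species is annotated; V stays unannotated
  expect_equal(unname(toy$model$modules["V"]), "--")
  expect_setequal(setdiff(unique(toy$model$modules), "--"),
                  c("START", "S/G2/M", "EXIT"))
})

test_that("an unviable configuration is rejected by the constructor", {
  expect_error(make_toy_model(toy_config(growth_rate = 0)),
               "reference vector not viable")
})

test_that("strain panel combinatorics match binomial sums", {
  p9 <- make_strain_panel(paste0("ks_", letters[1:9]), max_order = 3)
  expect_length(p9$strains, 129)  # 9 + 36 + 84
  orders <- vapply(p9$strains, function(s) length(s$overrides), integer(1))
  expect_equal(as.vector(table(orders)), c(9, 36, 84))
  expect_equal(vapply(p9$strains, `[[`, integer(1), "id"), 1:129)

  expect_length(make_strain_panel("ks_x", max_order = 1)$strains, 1)
  expect_length(make_strain_panel(paste0("k", 1:4), max_order = 3)$strains,
                14)  # 4 + 6 + 4
  for (r in c(2, 5, 12)) {
    got <- length(make_strain_panel(paste0("k", seq_len(r)),
                                    max_order = 3)$strains)
    expect_equal(got, sum(choose(r, 1:3)))
  }
  expect_error(make_strain_panel(c("a", "a"), 2), "duplicate")
})

test_that("all panel overrides set the chosen rates to zero", {
  p <- make_strain_panel(c("ks_a", "ks_a2", "ki_ae"), max_order = 2)
  for (s in p$strains) expect_true(all(s$overrides == 0))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_strain_panel(p, path)
  df <- read.delim(path)
  expect_equal(nrow(df), 6)
  expect_equal(df$id, 1:6)
})

test_that("reference ensembles are feasible, deterministic and jitter-sensitive", {
  toy <- toy_fixture()
  # zero jitter reproduces the reference vector n times
  e0 <- make_reference_ensemble(toy$model, toy$pv, n = 3, jitter = 0,
                                seed = 1)
  expect_equal(nrow(e0), 3)
  expect_equal(e0[1, ], truncate32(toy$pv))
  expect_equal(e0[1, ], e0[3, ])

  ens <- small_ensemble()
  ens2 <- make_reference_ensemble(toy$model, toy$pv, n = 12, seed = 42)
  expect_identical(unclass(ens)[, ], unclass(ens2)[, ])
  # every member passes FC1 when re-evaluated (idempotence)
  for (i in seq_len(nrow(ens)))
    expect_true(check_fc1(ens[i, ], toy$model, toy_training_constraint()))
})

test_that("feasible fraction decreases as the jitter grows", {
  toy <- toy_fixture()
  frac <- vapply(c(0.005, 0.08), function(j) {
    e <- make_reference_ensemble(toy$model, toy$pv, n = 10, jitter = j,
                                 seed = 7, max_batches = 8)
    nrow(e) / attr(e, "n_tried")
  }, numeric(1))
  expect_gt(frac[1], frac[2])
})

test_that("module-structured features are deterministic and label-shifted", {
  f1 <- make_module_structured_features(400, effect_size = 2, seed = 5)
  f2 <- make_module_structured_features(400, effect_size = 2, seed = 5)
  expect_identical(f1, f2)
  expect_setequal(unique(f1$label), c("START", "S/G2/M", "EXIT"))
  # the shift direction separates the class means
  m_start <- mean(f1$mean[f1$label == "START"])
  m_exit <- mean(f1$mean[f1$label == "EXIT"])
  expect_gt(m_start, m_exit)
  # effect 0 removes the separation (labels exchangeable)
  f0 <- make_module_structured_features(2000, effect_size = 0, seed = 5)
  grand <- abs(mean(f0$mean[f0$label == "START"]) -
               mean(f0$mean[f0$label == "EXIT"]))
  expect_lt(grand, 0.2)
})
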