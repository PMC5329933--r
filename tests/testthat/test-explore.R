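test_that("truncate32 rounds to single precision and is idempotent", {
  expect_identical(truncate32(c(a = 1)), c(a = 1))
  # independent bit-level oracle via a 4-byte round trip
  x <- c(pi, 1/3, 1e-7, 123456.789, 0.1)
  oracle <- readBin(writeBin(x, raw(), size = 4L), "numeric", size = 4L,
                    n = length(x))
  expect_identical(truncate32(x), oracle)
  expect_identical(truncate32(truncate32(x)), truncate32(x))
  expect_error(truncate32(1e300), "overflow")
})

test_that("FC1 matches required phenotypes and is vacuous on NULL", {
  toy <- toy_fixture()
  constraint <- toy_training_constraint()
  expect_true(check_fc1(toy$pv, toy$model, constraint))
  pv0 <- toy$pv
  pv0["mu"] <- 0
  expect_false(check_fc1(pv0, toy$model, constraint))
  expect_true(check_fc1(pv0, toy$model, NULL))
})

test_that("Latin hypercube samples stratify every axis exactly", {
  b <- rbind(min = c(x = 0, y = -1), max = c(x = 1, y = -1))
  s <- lhs_sample(b, 2, seed = 3)
  expect_equal(dim(s), c(2, 2))
  expect_equal(sum(s[, "x"] < 0.5), 1)  # one sample per stratum
  expect_true(all(s[, "y"] == -1))      # degenerate axis collapses

  n <- 1000
  b2 <- rbind(min = c(p = 2), max = c(p = 6))
  s2 <- lhs_sample(b2, n, seed = 9)
  strata <- findInterval(s2[, 1], seq(2, 6, length.out = n + 1),
                         rightmost.closed = TRUE)
  expect_equal(sort(strata), 1:n)  # exactly one sample in each stratum
  expect_identical(s2, lhs_sample(b2, n, seed = 9))
})

test_that("DE mutation follows the difference-vector rule", {
  pop <- rbind(c(1, 1), c(2, 0), c(0, 0))
  colnames(pop) <- c("a", "b")
  expect_equal(de_mutate(pop, 1, F = 0.1, partners = c(2, 3)),
               c(a = 1.2, b = 1))
  # forced identical partners collapse the perturbation
  expect_equal(de_mutate(pop, 1, F = 0.5, partners = c(2, 2)),
               c(a = 1, b = 1))
  expect_equal(de_mutate(pop, 1, F = 1e-12, partners = c(2, 3)),
               c(a = 1, b = 1), tolerance = 1e-9)
  # random partners never include the focal parent
  for (i in 1:20) {
    v <- de_mutate(pop, 2, F = 0.1)
    expect_false(isTRUE(all.equal(v, pop[2, ] + 0)))  # i' != i'' != i
  }
})

test_that("DE crossover mixes coordinates by the uniform draws", {
  parent <- c(a = 1, b = 2)
  mutant <- c(a = 10, b = 20)
  expect_equal(de_crossover(parent, mutant, C = 1), mutant)
  expect_equal(de_crossover(parent, mutant, C = 0,
                            u = c(0.5, 0.9)), parent)
  expect_equal(de_crossover(parent, mutant, C = 0.5, u = c(0.3, 0.7)),
               c(a = 10, b = 2))
  expect_named(de_crossover(parent, mutant, C = 0.5), c("a", "b"))
})

test_that("selection records FC1 passes and applies FC2/FC3 gates", {
  toy <- toy_fixture()
  ens <- small_ensemble()
  state <- list(model = toy$model, constraint = toy_training_constraint(),
                cfg = de_config(N = 4, criteria = c("FC1", "FC2")),
                dt = 0.05, horizon = 2000,
                volume_axes = c("ks_a", "kd_a"),
                parents = ens[1:4, ], pred_keys = character(0))
  # infeasible trial: nothing recorded
  bad <- ens[1, ]; bad["mu"] <- 0
  sel <- de_select(1, bad, state)
  expect_false(sel$recorded)
  expect_false(sel$accept)
  # a feasible trial inside the parents' bounding box fails FC2 but is
  # recorded; the volume oracle is the bounding-box product itself
  inside <- ens[1, ]
  inside[c("ks_a", "kd_a")] <-
    colMeans(ens[2:4, c("ks_a", "kd_a")])
  inside <- truncate32(inside)
  sel2 <- de_select(1, inside, state)
  expect_true(sel2$recorded)
  expect_false(sel2$accept)
  # FC1-only: the same trial is accepted
  state$cfg <- de_config(N = 4, criteria = "FC1")
  expect_true(de_select(1, inside, state)$accept)
})

test_that("run_de is reproducible, records feasible trials and honours t_max", {
  toy <- toy_fixture()
  ens <- small_ensemble()
  cfg0 <- de_config(N = 4, t_max = 0, seed = 1)
  r0 <- run_de(toy$model, toy_training_constraint(), ens[1:4, ], cfg0)
  expect_equal(nrow(r0$recorded), 4)  # initial population only
  expect_equal(nrow(r0$acceptance_log), 0)

  cfg <- de_config(N = 4, t_max = 4, seed = 11)
  r1 <- run_de(toy$model, toy_training_constraint(), ens[1:4, ], cfg,
               dt = 0.05, horizon = 800)
  r2 <- run_de(toy$model, toy_training_constraint(), ens[1:4, ], cfg,
               dt = 0.05, horizon = 800)
  expect_identical(r1$recorded, r2$recorded)
  expect_identical(r1$acceptance_log, r2$acceptance_log)
  expect_equal(nrow(r1$acceptance_log), 16)
  # every recorded vector re-passes FC1 (idempotence of feasibility)
  for (i in seq_len(nrow(r1$recorded)))
    expect_true(check_fc1(r1$recorded[i, ], toy$model,
                          toy_training_constraint(), horizon = 800))
  # an infeasible starting member is rejected up front
  bad <- ens[1:4, ]
  bad[2, "mu"] <- 0
  expect_error(run_de(toy$model, toy_training_constraint(), bad, cfg),
               "not FC1-feasible")
})

test_that("initial-population selection implements its three modes", {
  # synthetic 2-axis ensemble whose bounding box is spanned by 4 corners
  corners <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  interior <- matrix(runif(12, 0.3, 0.7), ncol = 2)
  ens <- rbind(corners, interior)
  colnames(ens) <- c("a", "b")
  sel <- select_initial_population(ens, 4, mode = "Vmax",
                                   axes = c("a", "b"))
  expect_equal(sel[order(sel[, 1], sel[, 2]), ],
               corners[order(corners[, 1], corners[, 2]), ],
               ignore_attr = TRUE)

  r1 <- select_initial_population(ens, 5, mode = "random", seed = 4)
  r2 <- select_initial_population(ens, 5, mode = "random", seed = 4)
  expect_identical(r1, r2)
  expect_error(select_initial_population(ens, 99, mode = "random"),
               "exceeds ensemble size")

  # SmaxVmax: with N = #unique prediction vectors, selected vectors have
  # pairwise distinct predictions
  P <- matrix(c(1, 1, 1, 1,
                1, 1, 1, 1,
                2, 2, 2, 2,
                0, 1, 0, 1,
                2, 2, 2, 2,
                1, 1, 1, 1,
                0, 1, 0, 1,
                1, 2, 1, 2), ncol = 4, byrow = TRUE)
  ens8 <- ens[1:8, ]
  sel8 <- select_initial_population(ens8, 4, mode = "SmaxVmax", P = P)
  keys <- apply(sel8, 1, function(v) {
    i <- which(apply(ens8, 1, function(e) all(e == v)))[1]
    paste(P[i, ], collapse = "")
  })
  expect_equal(length(unique(keys)), 4)
})

test_that("FC3 grows the unique prediction set by one per acceptance", {
  toy <- toy_fixture()
  ens <- small_ensemble()
  panel <- small_panel()
  cfg <- de_config(N = 4, t_max = 5, criteria = c("FC1", "FC3"), seed = 2)
  init_keys <- unique(apply(ens[1:4, ], 1, function(v)
    paste(phenoDE:::prediction_vector(toy$model, v, panel$strains,
                                      horizon = 800), collapse = "")))
  r <- run_de(toy$model, toy_training_constraint(), ens[1:4, ], cfg,
              prediction_strains = panel$strains, horizon = 800)
  expect_equal(length(r$pred_keys),
               length(init_keys) + sum(r$acceptance_log$accepted))
  expect_false(any(duplicated(r$pred_keys)))
})
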