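make_records <- function(mutant, num, den, cv, mean = 1, sd = cv * mean) {
  df <- data.frame(mutant = as.integer(mutant), num = num, den = den,
                   mean = mean, sd = sd, cv = cv,
                   stringsAsFactors = FALSE)
  class(df) <- c("pde_abundance_records", "data.frame")
  df
}

test_that("consistently viable mutants require code 1 everywhere", {
  P1 <- matrix(c(1, 1, 1, 1, 2, 1), nrow = 2,
               dimnames = list(NULL, c("1", "2", "3")))
  P2 <- matrix(1L, nrow = 3, ncol = 3,
               dimnames = list(NULL, c("1", "2", "3")))
  expect_equal(consistently_viable_mutants(list(P1, P2)), c(1L, 2L))
  expect_equal(consistently_viable_mutants(list(P2)), 1:3)
  P3 <- P2
  colnames(P3) <- c("1", "2", "9")
  expect_error(consistently_viable_mutants(list(P1, P3)), "share")

  # column-scan oracle on a toy prediction matrix
  toy <- toy_fixture()
  P <- prediction_matrix(small_ensemble()[1:3, ], toy$model,
                         small_panel(), horizon = 800)
  oracle <- as.integer(colnames(P))[apply(unclass(P), 2,
                                          function(x) all(x == 1))]
  expect_equal(consistently_viable_mutants(list(P)), oracle)
})

test_that("abundance records carry sample statistics of the stored ratios", {
  toy <- toy_fixture()
  ens <- small_ensemble()[1:3, ]
  strains <- list(strain_spec(4L, "rM-del", c(ks_rM1 = 0)))
  rec <- relative_abundance_table(ens, toy$model, strains, horizon = 800,
                                  keep_values = TRUE)
  expect_true(all(is.finite(rec$cv)))
  expect_setequal(unique(rec$mutant), c(0L, 4L))
  n_sp <- length(toy$model$species)
  expect_lte(nrow(rec), 2 * n_sp * (n_sp - 1))
  # oracle: recompute mean/sd/cv from the stored per-vector ratios
  for (i in seq_len(nrow(rec))) {
    v <- rec$values[[i]]
    expect_equal(rec$mean[i], mean(v))
    expect_equal(rec$sd[i], sd(v))
    expect_equal(rec$cv[i], sd(v) / mean(v))
  }

  # identical vectors give zero CV everywhere
  rec0 <- relative_abundance_table(rbind(ens[1, ], ens[1, ]), toy$model,
                                   strains, horizon = 800)
  expect_true(all(abs(rec0$cv) < 1e-12))
})

test_that("mutant variability sums finite CVs and ranks descending", {
  rec <- make_records(c(1, 1, 2, 2, 2), "A", "B", c(0.1, 0.2, 0.3, 0.1, 0))
  mv <- mutant_variability(rec)
  expect_equal(mv$mutant, c(2L, 1L))
  expect_equal(mv$score, c(0.4, 0.3))
  expect_equal(mv$rank, 1:2)
  # zero-CV records tie all mutants at zero
  mv0 <- mutant_variability(make_records(c(1, 2), "A", "B", c(0, 0)))
  expect_true(all(mv0$score == 0))
})

test_that("protein scores, percentiles and categories follow the ranking rules", {
  rec <- make_records(1, c("P1", "P1", "P2"), c("P2", "P3", "P1"),
                      c(2, 3, 1))
  rep_num <- protein_variability_scores(rec, "numerator")
  expect_equal(rep_num$protein, c("P1", "P2"))
  expect_equal(rep_num$score, c(5, 1))
  expect_equal(rep_num$percentile, c(100, 0))
  expect_equal(rep_num$category, c("high", "low"))

  rep_den <- protein_variability_scores(rec, "denominator")
  # each CV is counted exactly once under either orientation
  expect_equal(sum(rep_num$score), sum(rep_den$score))

  # ties break deterministically by species name
  tied <- make_records(1, c("B", "A"), c("A", "B"), c(1, 1))
  rt <- protein_variability_scores(tied, "numerator")
  expect_equal(rt$protein, c("A", "B"))
  expect_equal(rt$rank, 1:2)
})

test_that("orientation correlation compares the two rank vectors", {
  r1 <- data.frame(protein = c("A", "B", "C"), rank = 1:3)
  r2 <- data.frame(protein = c("A", "B", "C"), rank = 1:3)
  expect_equal(ranking_orientation_correlation(r1, r2), 1)
  r3 <- data.frame(protein = c("A", "B", "C"), rank = 3:1)
  expect_equal(ranking_orientation_correlation(r1, r3), -1)
  # textbook-formula oracle on a scrambled ranking
  r4 <- data.frame(protein = c("C", "A", "B"), rank = c(1L, 3L, 2L))
  x <- r1$rank[order(r1$protein)]
  y <- r4$rank[order(r4$protein)]
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(ranking_orientation_correlation(r1, r4), oracle)
})

test_that("process aggregation averages member scores", {
  rep <- protein_variability_scores(
    make_records(1, c("A", "B", "C"), c("B", "C", "A"), c(107.48, 100, 200)))
  ann <- list(A = "exit from mitosis", B = "cell size control",
              C = "cell size control")
  pv <- process_variability(rep, ann)
  scoreA <- rep$score[rep$protein == "A"]
  row_exit <- pv[pv$process == "exit from mitosis", ]
  expect_equal(row_exit$mean, scoreA)
  expect_equal(row_exit$sd, 0)  # singleton process prints +/- 0.00
  row_size <- pv[pv$process == "cell size control", ]
  expect_equal(row_size$n, 2)
  sBC <- rep$score[rep$protein %in% c("B", "C")]
  expect_equal(row_size$mean, mean(sBC))
  expect_equal(row_size$sd, sd(sBC))
  # two members {100, 200} -> 150 +/- 70.71
  expect_equal(sd(c(100, 200)), 70.71068, tolerance = 1e-6)
  expect_equal(nrow(process_variability(rep, list())), 0)
  expect_error(process_variability(rep, list(Z = "p")), "absent")
})
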