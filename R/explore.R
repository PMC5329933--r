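#' Training constraint: the phenotypes a feasible vector must capture
#'
#' @param strains list of [strain_spec()] objects.
#' @param codes integer vector of required phenotype codes (0, 1 or 2),
#'   one per strain.
#' @return object of class `pde_constraint`.
#' @export
training_constraint <- function(strains, codes) {
  stopifnot(length(strains) == length(codes), length(strains) > 0,
            all(codes %in% 0:2))
  structure(list(strains = strains, codes = as.integer(codes)),
            class = "pde_constraint")
}

# Phenotype code of one strain under one parameter vector, without storing
# the state matrix.  `init` seeds the initial conditions (WT-derived for
# mutants); when NULL the vector's own initial conditions are used.
strain_phenotype <- function(model, pv, strain = NULL, init = NULL,
                             dt = 0.05, horizon = 2000, size_cap = 25,
                             band = 0.05) {
  traj <- simulate_strain(model, pv, strain, dt = dt, horizon = horizon,
                          init = init, keep_states = FALSE)
  classify_phenotype(traj, size_cap = size_cap, band = band)$code
}

#' First feasibility criterion: phenotype capture
#'
#' A parameter vector satisfies FC1 when the simulated phenotype of every
#' constrained strain equals its required code.  Feasibility is evaluated
#' on the 32-bit truncated copy of the vector.  The wild type is simulated
#' first; its post-last-division state seeds the initial conditions of all
#' mutant simulations.  Evaluation short-circuits on the first miss; a
#' wild type without divisions fails any constraint containing a mutant
#' strain (mutants cannot be seeded) unless the WT itself is required
#' inviable.
#'
#' @param pv full parameter vector.
#' @param model a [model_spec()].
#' @param constraint a [training_constraint()]; an empty set of strains is
#'   not representable, but passing `NULL` returns `TRUE` (vacuous).
#' @param dt,horizon,size_cap,band simulation and classification settings.
#' @return logical.
#' @export
check_fc1 <- function(pv, model, constraint, dt = 0.05, horizon = 2000,
                      size_cap = 25, band = 0.05) {
  if (is.null(constraint)) return(TRUE)
  pv <- truncate32(pv)
  wt_traj <- simulate_strain(model, pv, NULL, dt = dt, horizon = horizon,
                             keep_states = FALSE)
  wt_code <- classify_phenotype(wt_traj, size_cap, band)$code
  init_wt <- wt_traj$post_last_div
  for (i in seq_along(constraint$strains)) {
    s <- constraint$strains[[i]]
    if (length(s$overrides) == 0) {
      code <- wt_code
    } else {
      if (length(wt_traj$div_time) == 0) return(FALSE)  # cannot seed
      code <- strain_phenotype(model, pv, s, init = init_wt, dt = dt,
                               horizon = horizon, size_cap = size_cap,
                               band = band)
    }
    if (code != constraint$codes[i]) return(FALSE)
  }
  TRUE
}

# Integer prediction vector over a strain panel for one parameter vector.
# WT-seeded initial conditions; unseedable mutants get code 2.
prediction_vector <- function(model, pv, strains, dt = 0.05,
                              horizon = 2000, size_cap = 25, band = 0.05) {
  pv <- truncate32(pv)
  wt_traj <- simulate_strain(model, pv, NULL, dt = dt, horizon = horizon,
                             keep_states = FALSE)
  init_wt <- wt_traj$post_last_div
  seedable <- length(wt_traj$div_time) > 0
  vapply(strains, function(s) {
    if (length(s$overrides) == 0)
      return(classify_phenotype(wt_traj, size_cap, band)$code)
    if (!seedable) return(2L)
    strain_phenotype(model, pv, s, init = init_wt, dt = dt,
                     horizon = horizon, size_cap = size_cap, band = band)
  }, integer(1))
}

#' Latin hypercube sample of the parameter space
#'
#' One-sample-per-stratum Latin hypercube in every axis: for each
#' parameter the range is split into `n` equal strata, one uniform draw is
#' taken per stratum, and the strata are randomly permuted independently
#' per axis.
#'
#' @param bounds 2-row matrix (`min`, `max`) with one column per
#'   parameter; column names carry the parameter names.
#' @param n number of samples.
#' @param seed RNG seed.
#' @return `n` x D matrix with the bounds' column names.
#' @export
lhs_sample <- function(bounds, n, seed = 1L) {
  stopifnot(is.matrix(bounds), nrow(bounds) == 2, n >= 1)
  if (any(bounds[2, ] < bounds[1, ])) stop("bounds must satisfy min <= max")
  D <- ncol(bounds)
  withr::with_seed(seed, {
    out <- vapply(seq_len(D), function(j) {
      u <- (sample.int(n) - 1 + runif(n)) / n
      bounds[1, j] + u * (bounds[2, j] - bounds[1, j])
    }, numeric(n))
  })
  out <- matrix(out, nrow = n, ncol = D)
  colnames(out) <- colnames(bounds)
  out
}

#' Per-parameter bounds of an ensemble
#'
#' @param ensemble ensemble matrix (rows = vectors).
#' @return 2-row matrix of per-column min and max.
#' @export
ensemble_bounds <- function(ensemble) {
  rbind(min = apply(ensemble, 2, min), max = apply(ensemble, 2, max))
}

#' Differential evolution settings
#'
#' @param N population size (at least 4: mutation needs three distinct
#'   additional parents).  The reference study used 19.
#' @param F scale factor of the mutation step, in (0, 1); default 0.1.
#' @param C crossover probability in `[0, 1]`; default 0.5 so neither
#'   parental nor mutant values are favoured.
#' @param t_max number of generations.
#' @param criteria subset of `c("FC1", "FC2", "FC3")`; FC1 is always
#'   enforced and is added if absent.
#' @param volume_axes parameter names spanning the volume estimate used by
#'   FC2 and the dynamic-volume trace; `NULL` means all kinetic axes.
#' @param seed RNG seed of the run.
#' @return list of class `pde_de_config`.
#' @export
de_config <- function(N = 19L, F = 0.1, C = 0.5, t_max = 100L,
                      criteria = "FC1", volume_axes = NULL, seed = 1L) {
  stopifnot(F > 0, F < 1, C >= 0, C <= 1, N >= 4,
            all(criteria %in% c("FC1", "FC2", "FC3")))
  criteria <- union("FC1", criteria)
  structure(list(N = as.integer(N), F = F, C = C, t_max = as.integer(t_max),
                 criteria = criteria, volume_axes = volume_axes,
                 seed = as.integer(seed)),
            class = "pde_de_config")
}

#' DE mutation step
#'
#' Builds the mutant vector `v = x_i + F * (x_i' - x_i'')` from a parental
#' vector and the difference of two additional parents drawn at random,
#' distinct from each other and from `i`.
#'
#' @param population matrix of parent vectors (rows).
#' @param i index of the parent being perturbed.
#' @param F scale factor.
#' @param partners optional integer pair overriding the random draw of
#'   `(i', i'')` (test hook; the two indices may then coincide).
#' @return mutant parameter vector.
#' @export
de_mutate <- function(population, i, F, partners = NULL) {
  N <- nrow(population)
  stopifnot(N >= 3)
  if (is.null(partners)) {
    partners <- sample(setdiff(seq_len(N), i), 2L)
  }
  population[i, ] + F * (population[partners[1], ] - population[partners[2], ])
}

#' DE crossover step
#'
#' Coordinate `j` of the trial vector takes the mutant value when
#' `U_j <= C` and the parental value otherwise, with `U_j` iid
#' uniform(0, 1).
#'
#' @param parent,mutant vectors of equal length.
#' @param C crossover probability.
#' @param u optional vector of uniforms overriding the random draws
#'   (test hook).
#' @return trial parameter vector.
#' @export
de_crossover <- function(parent, mutant, C, u = NULL) {
  stopifnot(length(parent) == length(mutant))
  if (is.null(u)) u <- runif(length(parent))
  trial <- ifelse(u <= C, mutant, parent)
  names(trial) <- names(parent)
  trial
}

#' DE selection step under the active feasibility criteria
#'
#' The trial replaces the parent iff all active criteria pass: FC1
#' (phenotype capture, always enforced), FC2 (replacing the parent by the
#' trial strictly expands the parent population's estimated log-volume),
#' and FC3 (the trial's prediction vector over the prediction panel has
#' not been generated by any parent or accepted trial so far in this
#' run).  Any FC1-passing trial is recorded regardless of acceptance.
#'
#' @param parent_idx index of the parent within `state$parents`.
#' @param trial trial vector (already 32-bit truncated).
#' @param state run state: list with `parents` (matrix), `pred_keys`
#'   (character set of prediction-vector keys), plus the model/constraint
#'   settings (see [run_de()]).
#' @return list with `accept` (logical), `recorded` (logical: FC1 pass),
#'   `pred_key` (prediction key or `NA`).
#' @export
de_select <- function(parent_idx, trial, state) {
  cfg <- state$cfg
  fc1 <- check_fc1(trial, state$model, state$constraint, dt = state$dt,
                   horizon = state$horizon)
  if (!fc1) return(list(accept = FALSE, recorded = FALSE, pred_key = NA))

  accept <- TRUE
  if ("FC2" %in% cfg$criteria) {
    parents <- state$parents
    v1 <- estimated_log_volume(parents, state$volume_axes)
    swapped <- parents
    swapped[parent_idx, ] <- trial
    v2 <- estimated_log_volume(swapped, state$volume_axes)
    accept <- v2 > v1
  }
  pred_key <- NA_character_
  if (accept && "FC3" %in% cfg$criteria) {
    pv <- prediction_vector(state$model, trial, state$prediction_strains,
                            dt = state$dt, horizon = state$horizon)
    pred_key <- paste(pv, collapse = "")
    accept <- !(pred_key %in% state$pred_keys)
  }
  list(accept = accept, recorded = TRUE, pred_key = pred_key)
}

#' Kinetic axes with a non-degenerate range within an ensemble
#'
#' @param ensemble ensemble matrix.
#' @param model optional [model_spec()]; restricts the result to kinetic
#'   parameters (initial conditions excluded).
#' @return character vector of axis names.
#' @export
variable_axes <- function(ensemble, model = NULL) {
  axes <- colnames(ensemble)
  if (!is.null(model)) axes <- intersect(model$params, axes)
  rng <- apply(ensemble[, axes, drop = FALSE], 2, function(x)
    max(x) - min(x))
  axes[rng > 0]
}

#' Run differential evolution under feasibility criteria
#'
#' Runs `t_max` generations of mutate / crossover / select for each of the
#' `N` parents.  Trial vectors are truncated to 32-bit precision before
#' feasibility evaluation.  Every FC1-passing trial (accepted or not) is
#' recorded; the dynamic estimated log-volume of the parent population is
#' appended to the trace once per generation.  Deterministic in
#' `cfg$seed`: a single seeded generator drives, per trial, first the two
#' partner indices, then the D crossover uniforms.
#'
#' @param model a [model_spec()].
#' @param constraint a [training_constraint()].
#' @param initial_population matrix of FC1-feasible starting vectors
#'   (`cfg$N` rows); an infeasible member is an error.
#' @param cfg a [de_config()].
#' @param prediction_strains list of [strain_spec()] (required when FC3 is
#'   active; also used to seed the novelty set from the initial parents).
#' @param dt,horizon integration settings.
#' @return object of class `pde_de_result`: `recorded` matrix of all
#'   FC1-feasible vectors (generation-0 rows are the initial population),
#'   `recorded_meta`, `acceptance_log` (one row per trial), `parents`
#'   (final population), `volume_trace`, `pred_keys` (the running unique
#'   prediction-vector set; empty when FC3 inactive), and `cfg`.
#' @export
run_de <- function(model, constraint, initial_population, cfg,
                   prediction_strains = NULL, dt = 0.05, horizon = 2000) {
  stopifnot(inherits(cfg, "pde_de_config"),
            nrow(initial_population) == cfg$N)
  if ("FC3" %in% cfg$criteria && is.null(prediction_strains))
    stop("FC3 requires prediction_strains")

  parents <- t(apply(initial_population, 1, truncate32))
  colnames(parents) <- colnames(initial_population)
  for (i in seq_len(nrow(parents))) {
    if (!check_fc1(parents[i, ], model, constraint, dt = dt,
                   horizon = horizon))
      stop("initial population member ", i, " is not FC1-feasible")
  }

  # default volume axes: kinetic parameters with a non-degenerate range in
  # the initial population (fixed constants contribute no volume and would
  # pin the bounding-box estimate at -Inf)
  volume_axes <- cfg$volume_axes %||% variable_axes(parents, model)
  state <- list(model = model, constraint = constraint, cfg = cfg,
                dt = dt, horizon = horizon, volume_axes = volume_axes,
                prediction_strains = prediction_strains,
                parents = parents, pred_keys = character(0))

  init_keys <- rep(NA_character_, cfg$N)
  if ("FC3" %in% cfg$criteria) {
    init_keys <- apply(parents, 1, function(v)
      paste(prediction_vector(model, v, prediction_strains, dt = dt,
                              horizon = horizon), collapse = ""))
    state$pred_keys <- unique(init_keys)
  }

  recorded <- lapply(seq_len(cfg$N), function(i) parents[i, ])
  rec_gen <- rep(0L, cfg$N); rec_par <- seq_len(cfg$N)
  rec_acc <- rep(NA, cfg$N); rec_key <- init_keys
  n_trials <- cfg$t_max * cfg$N
  log_gen <- integer(n_trials); log_par <- integer(n_trials)
  log_fc1 <- logical(n_trials); log_acc <- logical(n_trials)
  vol <- numeric(cfg$t_max + 1)
  vol[1] <- estimated_log_volume(parents, volume_axes)
  trial_no <- 0L

  withr::with_seed(cfg$seed, {
    for (t in seq_len(cfg$t_max)) {
      for (i in seq_len(cfg$N)) {
        mutant <- de_mutate(state$parents, i, cfg$F)
        trial <- de_crossover(state$parents[i, ], mutant, cfg$C)
        trial <- truncate32(trial)
        sel <- de_select(i, trial, state)
        trial_no <- trial_no + 1L
        log_gen[trial_no] <- t; log_par[trial_no] <- i
        log_fc1[trial_no] <- sel$recorded; log_acc[trial_no] <- sel$accept
        if (sel$recorded) {
          recorded[[length(recorded) + 1L]] <- trial
          rec_gen <- c(rec_gen, t); rec_par <- c(rec_par, i)
          rec_acc <- c(rec_acc, sel$accept)
          rec_key <- c(rec_key, as.character(sel$pred_key))
        }
        if (sel$accept) {
          state$parents[i, ] <- trial
          if ("FC3" %in% cfg$criteria)
            state$pred_keys <- c(state$pred_keys, sel$pred_key)
        }
      }
      vol[t + 1] <- estimated_log_volume(state$parents, volume_axes)
    }
  })

  rec <- do.call(rbind, recorded)
  colnames(rec) <- colnames(parents)
  structure(list(
    recorded = rec,
    recorded_meta = data.frame(generation = rec_gen, parent = rec_par,
                               accepted = rec_acc,
                               pred_key = rec_key,
                               stringsAsFactors = FALSE),
    acceptance_log = data.frame(generation = log_gen, parent = log_par,
                                fc1 = log_fc1, accepted = log_acc),
    parents = state$parents,
    volume_trace = data.frame(generation = 0:cfg$t_max, log_volume = vol),
    pred_keys = state$pred_keys, cfg = cfg),
    class = "pde_de_result")
}

#' @export
print.pde_de_result <- function(x, ...) {
  acc <- sum(x$acceptance_log$accepted)
  cat("<pde_de_result>", nrow(x$recorded), "recorded vectors,",
      nrow(x$acceptance_log), "trials,", acc, "acceptances\n")
  invisible(x)
}

#' Biased selection of the initial DE population
#'
#' `random` draws a uniform subset.  `Vmax` greedily maximises the
#' estimated log-volume over the given axes: the selection is seeded with
#' the vectors attaining each axis minimum and maximum, filled greedily by
#' the candidate giving the largest volume, then refined by improving
#' single swaps.  `SmaxVmax` first buckets the ensemble by prediction
#' vector and picks at most one volume-greedy representative per bucket
#' (prioritising distinct prediction vectors up to `N`), then fills any
#' shortfall volume-greedily.
#'
#' @param ensemble ensemble matrix.
#' @param N population size to select.
#' @param mode one of `"random"`, `"Vmax"`, `"SmaxVmax"`.
#' @param axes volume axes for the greedy modes (default: all columns).
#' @param model,prediction_strains needed by `SmaxVmax` to compute
#'   prediction vectors (ignored if `P` is supplied).
#' @param P optional precomputed prediction matrix of the ensemble.
#' @param seed RNG seed (used by `random` and to break ties).
#' @param dt,horizon integration settings for `SmaxVmax`.
#' @return matrix of `N` selected rows.
#' @export
select_initial_population <- function(ensemble, N,
                                      mode = c("random", "Vmax", "SmaxVmax"),
                                      axes = NULL, model = NULL,
                                      prediction_strains = NULL, P = NULL,
                                      seed = 1L, dt = 0.05, horizon = 2000) {
  mode <- match.arg(mode)
  m <- nrow(ensemble)
  if (N > m) stop("N exceeds ensemble size")
  axes <- axes %||% colnames(ensemble)

  if (mode == "random") {
    idx <- withr::with_seed(seed, sample.int(m, N))
    return(ensemble[idx, , drop = FALSE])
  }

  logvol <- function(idx) {
    if (length(idx) < 2) return(-Inf)
    estimated_log_volume(ensemble[idx, , drop = FALSE], axes)
  }

  greedy_fill <- function(sel, budget, pool) {
    while (length(sel) < budget) {
      cand <- setdiff(pool, sel)
      if (length(cand) == 0) break
      gains <- vapply(cand, function(c) logvol(c(sel, c)), numeric(1))
      sel <- c(sel, cand[which.max(gains)])
    }
    sel
  }

  if (mode == "Vmax") {
    seedv <- unique(c(apply(ensemble[, axes, drop = FALSE], 2, which.min),
                      apply(ensemble[, axes, drop = FALSE], 2, which.max)))
    sel <- if (length(seedv) > N) seedv[seq_len(N)] else
      greedy_fill(seedv, N, seq_len(m))
    # improving single swaps until no improvement
    repeat {
      improved <- FALSE
      for (s in seq_along(sel)) {
        for (c in setdiff(seq_len(m), sel)) {
          alt <- sel; alt[s] <- c
          if (logvol(alt) > logvol(sel) + 1e-12) {
            sel <- alt; improved <- TRUE
          }
        }
      }
      if (!improved) break
    }
    return(ensemble[sel, , drop = FALSE])
  }

  # SmaxVmax
  if (is.null(P)) {
    if (is.null(model) || is.null(prediction_strains))
      stop("SmaxVmax needs either P or (model, prediction_strains)")
    P <- prediction_matrix(ensemble, model, prediction_strains, dt = dt,
                           horizon = horizon)
  }
  keys <- apply(P, 1, paste, collapse = "")
  buckets <- split(seq_len(m), keys)
  sel <- integer(0)
  # one volume-greedy representative per bucket, until N buckets are used
  for (b in buckets[order(-lengths(buckets))]) {
    if (length(sel) >= N) break
    gains <- vapply(b, function(c) logvol(c(sel, c)), numeric(1))
    sel <- c(sel, b[which.max(gains)])
  }
  sel <- greedy_fill(sel, N, seq_len(m))
  ensemble[sel, , drop = FALSE]
}
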