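# Core parameter order expected by the compiled toy integrator.
.toy_core_order <- c("mu", "ks_a", "ks_a2", "kd_a", "ki_ae", "ki_az",
                     "ks_b", "kd_b", "Ka", "ks_e", "kd_e", "Kb",
                     "ks_z", "kd_z", "h", "theta_hi", "theta_lo", "f")

#' Configuration of the synthetic growth-division toy model
#'
#' The toy model is a size-gated relaxation oscillator spanning three
#' network modules.  Cell size `V` grows exponentially and drives a START
#' activator `A` (two redundant synthesis routes, `ks_a` and `ks_a2`); `A`
#' switches on an S/G2/M activity `B` through a Hill function; `B` switches
#' on an EXIT effector `E`, which both accumulates a clearance factor `Z`
#' and (together with `Z`) clears `A`, shutting the cascade down.  Division
#' is triggered by the downward crossing of `E` through `theta_lo` after it
#' has exceeded `theta_hi`; at division the followed daughter cell retains
#' the fraction `f < 0.5` of the size at division (the daughter is the
#' smaller cell of the asymmetric division).  Each module additionally
#' carries pure reporter species (first-order readouts of `A`, `B`, `E`)
#' whose rates can be knocked out without touching viability.
#'
#' @param n_reporters integer vector of reporter counts per module, named
#'   `START`, `S/G2/M`, `EXIT`.
#' @param growth_rate exponential growth rate of `V` (1/min).  The default
#'   0.007 gives a mass doubling time of ~99 min.
#' @param division_threshold_hi,division_threshold_lo arming/firing
#'   thresholds of the division trigger on `E`.
#' @param daughter_fraction size fraction `f` retained by the followed
#'   daughter cell.
#' @param params optional named overrides of reference kinetic parameters.
#' @param init optional named overrides of reference initial conditions.
#' @param seed seed recorded in the config (the model itself is
#'   deterministic).
#' @return a list of class `pde_toy_config`.
#' @export
toy_config <- function(n_reporters = c(START = 1, `S/G2/M` = 1, EXIT = 1),
                       growth_rate = 0.007,
                       division_threshold_hi = 0.3,
                       division_threshold_lo = 0.08,
                       daughter_fraction = 0.45,
                       params = numeric(0), init = numeric(0),
                       seed = 1L) {
  stopifnot(daughter_fraction > 0, daughter_fraction < 1,
            division_threshold_lo < division_threshold_hi)
  structure(list(n_reporters = n_reporters, growth_rate = growth_rate,
                 theta_hi = division_threshold_hi,
                 theta_lo = division_threshold_lo,
                 f = daughter_fraction, params = params, init = init,
                 seed = as.integer(seed)),
            class = "pde_toy_config")
}

toy_reference_params <- function(cfg) {
  p <- c(mu = cfg$growth_rate,
         ks_a = 0.108, ks_a2 = 0.012, kd_a = 0.1,
         ki_ae = 0.25, ki_az = 1.5,
         ks_b = 1, kd_b = 0.2, Ka = 1,
         ks_e = 1, kd_e = 0.2, Kb = 1,
         ks_z = 0.4, kd_z = 0.1,
         h = 4, theta_hi = cfg$theta_hi, theta_lo = cfg$theta_lo,
         f = cfg$f)
  rep_names <- toy_reporter_names(cfg)
  for (nm in rep_names) {
    p[paste0("ks_", nm)] <- 0.5
    p[paste0("kd_", nm)] <- 0.25
  }
  if (length(cfg$params) > 0) p[names(cfg$params)] <- cfg$params
  p
}

toy_reporter_names <- function(cfg) {
  nr <- cfg$n_reporters
  mk <- function(prefix, n) if (n > 0) paste0(prefix, seq_len(n)) else character(0)
  c(mk("rS", nr[["START"]]), mk("rM", nr[["S/G2/M"]]), mk("rX", nr[["EXIT"]]))
}

toy_reference_init <- function(cfg) {
  x0 <- c(V = 1.2, A = 0.5, B = 0.1, E = 0.1, Z = 0.1)
  for (nm in toy_reporter_names(cfg)) x0[nm] <- 0.5
  if (length(cfg$init) > 0) x0[names(cfg$init)] <- cfg$init
  x0
}

#' Build the synthetic toy model and its reference parameter vector
#'
#' Deterministic in the config.  The emitted model has exponential size
#' growth, a cyclic activator cascade spanning the three modules, division
#' triggered by a downward threshold crossing of the EXIT effector, and
#' size reset by the daughter fraction `f`; every species is annotated
#' with its module.  The constructor validates the fixture's contract:
#' the reference vector yields a viable wild type (on its 32-bit truncated
#' copy), and among the eliminable rates at least one single knockout is
#' inviable and at least one is viable.
#'
#' @param cfg a [toy_config()].
#' @param validate verify the viability contract (default `TRUE`).
#' @return list with elements `model` (a [model_spec()]), `pv` (reference
#'   parameter vector) and `config`.
#' @export
make_toy_model <- function(cfg = toy_config(), validate = TRUE) {
  rep_names <- toy_reporter_names(cfg)
  species <- c("V", "A", "B", "E", "Z", rep_names)
  nr <- cfg$n_reporters
  modules <- c(V = "--", A = "START", B = "S/G2/M", E = "EXIT", Z = "EXIT",
               setNames(rep("START", nr[["START"]]),
                        grep("^rS", rep_names, value = TRUE)),
               setNames(rep("S/G2/M", nr[["S/G2/M"]]),
                        grep("^rM", rep_names, value = TRUE)),
               setNames(rep("EXIT", nr[["EXIT"]]),
                        grep("^rX", rep_names, value = TRUE)))
  par_ref <- toy_reference_params(cfg)
  driver_idx <- c(rS = 1L, rM = 2L, rX = 3L)  # state indices of A, B, E

  assemble <- function(par) {
    rk <- as.numeric(par[paste0("ks_", rep_names)])
    rd <- as.numeric(par[paste0("kd_", rep_names)])
    drv <- driver_idx[substr(rep_names, 1, 2)]
    list(core = as.numeric(par[.toy_core_order]),
         rep_ks = rk, rep_kd = rd, rep_driver = as.integer(drv))
  }

  # R closures mirroring the compiled dynamics; used by the generic
  # integrator as an independent cross-check of the native path.
  deriv <- function(state, par) {
    hillf <- function(x, K, h) if (x <= 0) 0 else x^h / (K^h + x^h)
    dx <- numeric(length(state))
    dx[1] <- par[["mu"]] * state[["V"]]
    dx[2] <- (par[["ks_a"]] + par[["ks_a2"]]) * state[["V"]] -
      par[["kd_a"]] * state[["A"]] -
      (par[["ki_ae"]] * state[["E"]] + par[["ki_az"]] * state[["Z"]]) *
        state[["A"]]
    dx[3] <- par[["ks_b"]] * hillf(state[["A"]], par[["Ka"]], par[["h"]]) -
      par[["kd_b"]] * state[["B"]]
    dx[4] <- par[["ks_e"]] * hillf(state[["B"]], par[["Kb"]], par[["h"]]) -
      par[["kd_e"]] * state[["E"]]
    dx[5] <- par[["ks_z"]] * state[["E"]] - par[["kd_z"]] * state[["Z"]]
    if (length(rep_names) > 0) {
      drv <- c(rS = "A", rM = "B", rX = "E")[substr(rep_names, 1, 2)]
      for (i in seq_along(rep_names)) {
        dx[5 + i] <- par[[paste0("ks_", rep_names[i])]] * state[[drv[i]]] -
          par[[paste0("kd_", rep_names[i])]] * state[[rep_names[i]]]
      }
    }
    dx
  }
  trigger <- function(state, armed, par) {
    if (!armed && state[["E"]] >= par[["theta_hi"]]) armed <- TRUE
    list(armed = armed, fire = armed && state[["E"]] < par[["theta_lo"]])
  }
  divide <- function(state, par) {
    state[["V"]] <- state[["V"]] * par[["f"]]
    state
  }

  model <- model_spec(
    name = "toy3", species = species, modules = modules,
    params = names(par_ref), native = "toy", assemble = assemble,
    deriv = deriv, trigger = trigger, divide = divide)

  x0 <- toy_reference_init(cfg)
  pv <- parameter_vector(model, par_ref, x0)

  if (validate) {
    tr <- simulate_strain(model, truncate32(pv), keep_states = FALSE)
    ph <- classify_phenotype(tr)
    if (ph$code != 1L)
      stop("reference vector not viable: WT phenotype ", ph$code,
           " (", ph$reason, ")")
    init_wt <- tr$post_last_div
    codes <- vapply(toy_eliminable_rates(cfg), function(r) {
      strain_phenotype(model, pv, strain_spec(1L, r, setNames(0, r)),
                       init = init_wt)
    }, integer(1))
    if (!any(codes == 2L) || !any(codes == 1L))
      stop("reference vector not viable: single knockouts do not span ",
           "viable and inviable phenotypes")
  }

  list(model = model, pv = pv, config = cfg)
}

#' Default eliminable rates of the toy model
#'
#' Nine rate constants whose elimination (alone and in combination) builds
#' the prediction panel: the two redundant START activation routes, the
#' two redundant EXIT clearance routes, the EXIT effector and
#' clearance-factor synthesis rates, and three reporter rates.  Mirrors a
#' panel built from nine synthetically lethal
#' phosphorylation/dephosphorylation rates.
#'
#' @param cfg a [toy_config()].
#' @return character vector of parameter names.
#' @export
toy_eliminable_rates <- function(cfg = toy_config()) {
  rep_names <- toy_reporter_names(cfg)
  reps <- head(c(rbind(paste0("ks_", rep_names), paste0("kd_", rep_names))), 3)
  c("ks_a", "ks_a2", "ki_ae", "ki_az", "ks_e", "ks_z", reps)
}

#' Default training constraint of the toy fixture
#'
#' The "must-capture" phenotypes screened by the first feasibility
#' criterion: a viable wild type, a viable reporter knockout, and an
#' inviable growth-rate knockout.
#'
#' @param cfg a [toy_config()].
#' @return a [training_constraint()].
#' @export
toy_training_constraint <- function(cfg = toy_config()) {
  rep1 <- toy_reporter_names(cfg)[1]
  training_constraint(
    strains = list(
      wt_strain(),
      strain_spec(1L, paste0(rep1, "-synth-del"),
                  setNames(0, paste0("ks_", rep1))),
      strain_spec(2L, "growth-del", c(mu = 0))),
    codes = c(1L, 1L, 2L))
}

#' Build a mutant strain panel from eliminable rates
#'
#' The prediction panel consists of all single, pair, and (up to
#' `max_order`) triple eliminations of the given rates, each override
#' setting the chosen rates to zero.  The wild type is excluded.  Panel
#' size is `choose(r,1) + ... + choose(r,max_order)`; ids are dense
#' from 1 in order of increasing mutation order.
#'
#' @param eliminable_rates character vector of distinct parameter names.
#' @param max_order highest mutation order, 1 to 3.
#' @return list of class `pde_strain_panel`: `strains` (list of
#'   [strain_spec()]), `eliminable_rates`, `max_order`.
#' @export
make_strain_panel <- function(eliminable_rates, max_order = 3) {
  if (anyDuplicated(eliminable_rates)) stop("duplicate rate names")
  stopifnot(max_order %in% 1:3)
  r <- length(eliminable_rates)
  strains <- list()
  id <- 0L
  for (ord in seq_len(max_order)) {
    if (ord > r) break
    sets <- combn(eliminable_rates, ord, simplify = FALSE)
    for (s in sets) {
      id <- id + 1L
      strains[[id]] <- strain_spec(id, paste(s, collapse = " "),
                                   setNames(rep(0, length(s)), s))
    }
  }
  structure(list(strains = strains, eliminable_rates = eliminable_rates,
                 max_order = max_order),
            class = "pde_strain_panel")
}

#' @export
print.pde_strain_panel <- function(x, ...) {
  cat("<pde_strain_panel>", length(x$strains), "strains from",
      length(x$eliminable_rates), "eliminable rates, max order",
      x$max_order, "\n")
  invisible(x)
}

#' Write a strain panel as a delimited table
#' @param panel a [make_strain_panel()] panel.
#' @param path output file path.
#' @export
write_strain_panel <- function(panel, path) {
  df <- data.frame(
    id = vapply(panel$strains, `[[`, integer(1), "id"),
    label = vapply(panel$strains, `[[`, character(1), "label"),
    overrides = vapply(panel$strains, function(s)
      paste(names(s$overrides), s$overrides, sep = "=", collapse = ";"),
      character(1)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Jittered feasible ensemble around the reference vector
#'
#' Draws candidate vectors by multiplicative log-normal jitter around the
#' reference parameter vector (the daughter fraction `f`, Hill exponent
#' `h` and trigger thresholds are held fixed so the division map stays
#' valid), keeps the candidates whose 32-bit truncation passes the first
#' feasibility criterion, and returns the first `n` feasible vectors.
#' Stands in for an externally supplied ensemble of optimally performing
#' vectors.
#'
#' @param model,pv from [make_toy_model()].
#' @param n number of feasible vectors requested.
#' @param jitter log-normal sigma of the multiplicative jitter
#'   (`jitter = 0` returns `n` copies of the reference).
#' @param seed RNG seed (deterministic in the seed).
#' @param constraint a [training_constraint()]; defaults to the toy
#'   fixture's constraint.
#' @param max_batches retry budget: at most `max_batches * n` candidates
#'   are drawn before giving up with diagnostics.
#' @param dt,horizon integration settings.
#' @return ensemble matrix (`n` rows, one column per parameter).
#' @export
make_reference_ensemble <- function(model, pv, n = 50, jitter = 0.02,
                                    seed = 1L,
                                    constraint = toy_training_constraint(),
                                    max_batches = 20L, dt = 0.05,
                                    horizon = 2000) {
  stopifnot(n >= 2)
  fixed <- c("f", "h", "theta_hi", "theta_lo", paste0("ic_", model$species))
  jitter_names <- setdiff(names(pv), fixed)
  kept <- list()
  tried <- 0L
  withr::with_seed(seed, {
    for (b in seq_len(max_batches)) {
      for (i in seq_len(n)) {
        cand <- pv
        if (jitter > 0) {
          cand[jitter_names] <- cand[jitter_names] *
            exp(rnorm(length(jitter_names), 0, jitter))
        }
        tried <- tried + 1L
        if (check_fc1(cand, model, constraint, dt = dt, horizon = horizon))
          kept[[length(kept) + 1L]] <- truncate32(cand)
        if (length(kept) >= n) break
      }
      if (length(kept) >= n) break
    }
  })
  if (length(kept) == 0)
    stop("no feasible vectors found in ", tried, " candidates ",
         "(jitter = ", jitter, "); reduce jitter or relax the constraint")
  ens <- do.call(rbind, kept)
  colnames(ens) <- names(pv)
  attr(ens, "n_tried") <- tried
  ens
}

#' Synthetic module-structured abundance-statistic features
#'
#' Generates a feature table emulating relative-abundance statistics with
#' module-specific structure: for each record a module label is drawn
#' uniformly from the three network modules and the `(mean, std, CV)`
#' features receive Gaussian shifts along a module-specific direction
#' scaled by `effect_size` (plus unit Gaussian noise).  The mutant id is a
#' label-free numeric feature.  `effect_size = 0` makes the labels
#' exchangeable.
#'
#' @param n_records number of feature rows.
#' @param effect_size magnitude of the module-specific shift, in noise
#'   standard deviations.
#' @param seed RNG seed.
#' @param n_mutants number of distinct mutant ids to draw from.
#' @return data.frame of class `pde_feature_table` with columns `mean`,
#'   `std`, `cv`, `mutant`, `label`.
#' @export
make_module_structured_features <- function(n_records = 3000,
                                            effect_size = 1.5, seed = 1L,
                                            n_mutants = 30L) {
  stopifnot(effect_size >= 0, n_records >= 1)
  shifts <- rbind(START = c(1, 0.5, 0),
                  `S/G2/M` = c(0, 1, 0.5),
                  EXIT = c(0.5, 0, 1))
  withr::with_seed(seed, {
    lab <- sample(rownames(shifts), n_records, replace = TRUE)
    noise <- matrix(rnorm(3 * n_records), n_records, 3)
    feats <- shifts[lab, , drop = FALSE] * effect_size + noise
    df <- data.frame(mean = feats[, 1], std = feats[, 2], cv = feats[, 3],
                     mutant = sample.int(n_mutants, n_records,
                                         replace = TRUE),
                     label = lab, stringsAsFactors = FALSE)
  })
  class(df) <- c("pde_feature_table", "data.frame")
  df
}
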