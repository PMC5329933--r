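#' Growth-division model specification
#'
#' A model couples a set of chemical species to a distinguished cell-size
#' variable `V`.  Dynamics are given by a deterministic state-derivative
#' rule integrated with fixed-step explicit Euler; a division trigger
#' predicate fires division events, and the division map multiplies the
#' size of the followed daughter cell by the fraction `f` (strictly
#' reducing `V`).
#'
#' Two kinds of models are supported.  Generic models carry R closures
#' (`deriv`, `trigger`, `divide`) and are integrated in R.  The built-in
#' toy model (see [make_toy_model()]) sets `native = "toy"` and is
#' integrated by compiled code; `assemble` maps a named parameter vector to
#' the compiled integrator's inputs.
#'
#' @param name model name.
#' @param species character vector of species names; must contain `"V"`.
#' @param modules named character vector mapping each species to its
#'   network module (`"START"`, `"S/G2/M"`, `"EXIT"`) or `"--"` for
#'   unannotated species such as `V`.
#' @param params character vector of kinetic parameter names.
#' @param native `NULL` for generic models, `"toy"` for the compiled toy
#'   integrator.
#' @param deriv,trigger,divide R closures for generic models:
#'   `deriv(state, par)` returns the state derivative; `trigger(state,
#'   armed, par)` returns `list(armed=, fire=)` implementing a (possibly
#'   hysteretic) division predicate; `divide(state, par)` returns the
#'   post-division state of the followed cell.
#' @param assemble for native models, `assemble(par)` returning the
#'   compiled integrator's parameter blocks.
#' @param f_param name of the parameter holding the daughter size fraction.
#' @return an object of class `pde_model`.
#' @export
model_spec <- function(name, species, modules, params, native = NULL,
                       deriv = NULL, trigger = NULL, divide = NULL,
                       assemble = NULL, f_param = "f") {
  stopifnot(is.character(species), is.character(params))
  if (anyDuplicated(species)) stop("species names must be unique")
  if (anyDuplicated(params)) stop("parameter names must be unique")
  if (!"V" %in% species) stop("model must contain the size variable 'V'")
  if (!setequal(names(modules), species))
    stop("modules must annotate exactly the model species")
  m <- structure(
    list(name = name, species = species, modules = modules[species],
         params = params, native = native, deriv = deriv,
         trigger = trigger, divide = divide, assemble = assemble,
         f_param = f_param),
    class = "pde_model")
  m
}

#' @export
print.pde_model <- function(x, ...) {
  cat("<pde_model>", x$name, "\n")
  cat("  species:", length(x$species), " parameters:", length(x$params),
      if (!is.null(x$native)) paste0(" [native: ", x$native, "]"), "\n")
  invisible(x)
}

#' Build a full parameter vector (kinetic constants + initial conditions)
#'
#' Parameter vectors concatenate the model's kinetic parameters with one
#' initial condition per species (named `ic_<species>`), mirroring the
#' convention that the search space covers both rate constants and initial
#' conditions.
#'
#' @param model a [model_spec()].
#' @param params named numeric of kinetic parameter values.
#' @param init named numeric of initial conditions (one per species).
#' @return named numeric vector of length `D = #params + #species`.
#' @export
parameter_vector <- function(model, params, init) {
  stopifnot(setequal(names(params), model$params),
            setequal(names(init), model$species))
  pv <- c(params[model$params],
          setNames(as.numeric(init[model$species]),
                   paste0("ic_", model$species)))
  if (!all(is.finite(pv))) stop("parameter vector must be finite")
  pv
}

pv_params <- function(model, pv) pv[model$params]
pv_init <- function(model, pv) {
  setNames(as.numeric(pv[paste0("ic_", model$species)]), model$species)
}

#' Round a parameter vector to 32-bit single precision
#'
#' Feasibility is always judged on the single-precision truncated copy of a
#' parameter vector, so that feasible vectors are not artifacts of extra
#' double-precision digits.  Each value is rounded to the nearest
#' single-precision representable number and returned at working (double)
#' precision; the operation is idempotent.
#'
#' @param pv numeric vector.
#' @return numeric vector of the same length and names.
#' @export
truncate32 <- function(pv) cpp_truncate32(pv)

#' Mutant strain specification
#'
#' A mutant is a set of parameter overrides (typically a rate constant set
#' to zero) applied on top of a background parameter vector.
#'
#' @param id integer strain id (unique within a panel; 0 is reserved for WT).
#' @param label human-readable strain label.
#' @param overrides named numeric of parameter replacements; may be empty
#'   (the wild type).
#' @return an object of class `pde_strain`.
#' @export
strain_spec <- function(id, label, overrides = numeric(0)) {
  stopifnot(length(id) == 1, is.numeric(overrides))
  structure(list(id = as.integer(id), label = label, overrides = overrides),
            class = "pde_strain")
}

#' @export
print.pde_strain <- function(x, ...) {
  ov <- if (length(x$overrides) == 0) "none"
        else paste(names(x$overrides), "=", x$overrides, collapse = ", ")
  cat("<pde_strain>", x$id, x$label, "| overrides:", ov, "\n")
  invisible(x)
}

#' The wild-type strain (no overrides)
#' @export
wt_strain <- function() strain_spec(0L, "WT")

apply_strain <- function(model, pv, strain) {
  if (is.null(strain) || length(strain$overrides) == 0) return(pv)
  bad <- setdiff(names(strain$overrides), model$params)
  if (length(bad) > 0)
    stop("strain overrides unknown parameters: ", paste(bad, collapse = ", "))
  pv[names(strain$overrides)] <- strain$overrides
  pv
}

#' Simulate one strain with fixed-step Euler integration
#'
#' Applies the strain's overrides to the parameter vector, then integrates
#' the model with explicit Euler at step `dt` over `horizon` minutes.
#' Division events are recorded whenever the division trigger fires; at a
#' division the followed cell's size becomes `f` times the size at
#' division, applied at the firing grid point before the next Euler step.
#' Non-finite state (numerical blow-up) aborts the integration; the
#' trajectory up to the failure point is returned with `blowup = TRUE` and
#' is treated downstream as exceeding any viability cap.
#'
#' @param model a [model_spec()].
#' @param pv full parameter vector (see [parameter_vector()]).
#' @param strain a [strain_spec()] or `NULL` for the wild type.
#' @param dt Euler step in minutes (default 0.05).
#' @param horizon total simulated time in minutes (default 2000).
#' @param init optional named state vector overriding the initial
#'   conditions stored in `pv` (used to seed mutants from the WT state).
#' @param keep_states keep the full state matrix (default `TRUE`).  The
#'   summary statistics (division events, size maximum, time averages) are
#'   always computed.
#' @return an object of class `pde_trajectory`.
#' @export
simulate_strain <- function(model, pv, strain = NULL, dt = 0.05,
                            horizon = 2000, init = NULL,
                            keep_states = TRUE) {
  stopifnot(dt > 0, horizon >= 0)
  if (is.null(names(pv))) stop("parameter vector must be named")
  pv <- apply_strain(model, pv, strain)
  x0 <- if (is.null(init)) pv_init(model, pv)
        else setNames(as.numeric(init[model$species]), model$species)
  nsteps <- as.integer(round(horizon / dt))

  if (identical(model$native, "toy")) {
    blocks <- model$assemble(pv_params(model, pv))
    raw <- cpp_toy_simulate(as.numeric(x0), blocks$core, blocks$rep_ks,
                            blocks$rep_kd, blocks$rep_driver, dt, nsteps,
                            keep_states)
  } else {
    raw <- simulate_generic(model, pv_params(model, pv), x0, dt, nsteps,
                            keep_states)
  }

  traj <- list(
    time = seq(0, by = dt, length.out = raw$n_grid),
    dt = dt, horizon = horizon, species = model$species,
    div_time = raw$div_time, div_size = raw$div_size,
    max_size = raw$max_size,
    means = setNames(as.numeric(raw$means), model$species),
    final_state = setNames(as.numeric(raw$final_state), model$species),
    post_last_div = setNames(as.numeric(raw$post_last_div), model$species),
    blowup = raw$blowup, blowup_time = raw$blowup_time)
  if (keep_states) {
    states <- raw$states
    colnames(states) <- model$species
    traj$states <- states
  }
  structure(traj, class = "pde_trajectory")
}

# Reference R implementation of the Euler/event loop for generic models.
# Slow; used for small horizons and as an independent cross-check of the
# compiled toy integrator.
simulate_generic <- function(model, par, x0, dt, nsteps, keep_states) {
  S <- length(x0)
  x <- as.numeric(x0)
  states <- if (keep_states) matrix(NA_real_, nsteps + 1, S) else NULL
  sums <- numeric(S)
  div_time <- div_size <- numeric(0)
  post_last <- rep(NA_real_, S)
  max_size <- x[1]
  armed <- FALSE
  blowup <- FALSE; blowup_time <- NA_real_
  n_grid <- 0L
  iV <- match("V", model$species)

  for (k in 0:nsteps) {
    if (x[iV] > max_size) max_size <- x[iV]
    st <- setNames(x, model$species)
    tr <- model$trigger(st, armed, par)
    armed <- tr$armed
    if (isTRUE(tr$fire) && k > 0) {
      div_time <- c(div_time, k * dt)
      div_size <- c(div_size, unname(st[[iV]]))
      st <- model$divide(st, par)
      x <- as.numeric(st)
      post_last <- x
      armed <- FALSE
    }
    if (keep_states) states[k + 1, ] <- x
    sums <- sums + x
    n_grid <- n_grid + 1L
    if (k == nsteps) break
    dx <- model$deriv(setNames(x, model$species), par)
    x <- x + dt * as.numeric(dx)
    if (!all(is.finite(x)) || any(abs(x) > 1e12)) {
      blowup <- TRUE; blowup_time <- (k + 1) * dt
      break
    }
  }
  list(div_time = div_time, div_size = div_size, max_size = max_size,
       means = sums / n_grid, final_state = x, post_last_div = post_last,
       n_grid = n_grid, blowup = blowup, blowup_time = blowup_time,
       states = if (keep_states) states[seq_len(n_grid), , drop = FALSE])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pde_trajectory <- function(x, ...) {
  cat("<pde_trajectory>", length(x$time), "grid points,",
      length(x$div_time), "divisions, max size",
      format(x$max_size, digits = 4),
      if (x$blowup) "[blow-up]", "\n")
  invisible(x)
}

#' Post-division state after the last wild-type division
#'
#' Simulates the wild type and returns the cell state right after its last
#' division; this state seeds the initial conditions of all mutant
#' simulations.
#'
#' @inheritParams simulate_strain
#' @return named state vector.
#' @export
wt_final_state <- function(model, pv, dt = 0.05, horizon = 2000) {
  traj <- simulate_strain(model, pv, NULL, dt = dt, horizon = horizon,
                          keep_states = FALSE)
  if (length(traj$div_time) == 0)
    stop("WT acyclic; cannot seed mutants")
  traj$post_last_div
}

#' Classify the phenotype of a trajectory
#'
#' Code 2 (inviable) if cell size exceeds `size_cap` at any grid point or
#' the integration blew up; else code 1 (viable) if the trajectory has at
#' least three divisions and the size at the last division is within
#' `band` of the sizes at the two previous divisions (relative to the last
#' division size); else code 0 (multiply periodic) if there are at least
#' three divisions; otherwise code 2 with reason `"arrest"`: a cell that
#' stops dividing is not viable.
#'
#' @param traj a [simulate_strain()] trajectory.
#' @param size_cap inviability size cap in the model's size units
#'   (default 25).
#' @param band relative tolerance on division-size balance (default 0.05).
#' @return object of class `pde_phenotype`: list with integer `code` in
#'   `{0, 1, 2}` and a `reason` string.
#' @export
classify_phenotype <- function(traj, size_cap = 25, band = 0.05) {
  if (isTRUE(traj$blowup))
    return(phenotype(2L, "numerical blow-up"))
  if (traj$max_size > size_cap)
    return(phenotype(2L, sprintf("size exceeded cap %g", size_cap)))
  nd <- length(traj$div_size)
  if (nd < 3)
    return(phenotype(2L, "arrest"))
  s <- traj$div_size
  last <- s[nd]
  ok <- abs(last - s[nd - 1]) / last <= band &&
        abs(last - s[nd - 2]) / last <= band
  if (ok) phenotype(1L, "balanced divisions")
  else phenotype(0L, "division sizes oscillate beyond band")
}

phenotype <- function(code, reason) {
  structure(list(code = code, reason = reason), class = "pde_phenotype")
}

#' @export
print.pde_phenotype <- function(x, ...) {
  lab <- c("multiply periodic", "viable", "inviable")[x$code + 1L]
  cat("<pde_phenotype>", x$code, paste0("(", lab, "):"), x$reason, "\n")
  invisible(x)
}

#' Time-averaged species abundances of a trajectory
#'
#' Arithmetic mean over all grid points of the full horizon, per species
#' (including the size variable `V`).  The time average of a protein
#' concentration is the model's prediction for that protein's abundance in
#' an asynchronous population.
#'
#' @param traj a [simulate_strain()] trajectory.
#' @return named numeric vector of species means.
#' @export
time_average_abundances <- function(traj) {
  if (length(traj$time) == 0) stop("empty trajectory")
  traj$means
}

#' Write a trajectory as a delimited table
#'
#' Tab-separated table with a time column and one column per species.
#' Requires the trajectory to have been simulated with
#' `keep_states = TRUE`.
#'
#' @param traj a [simulate_strain()] trajectory.
#' @param path output file path.
#' @export
write_trajectory <- function(traj, path) {
  if (is.null(traj$states)) stop("trajectory was simulated without states")
  df <- data.frame(time = traj$time, traj$states, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
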