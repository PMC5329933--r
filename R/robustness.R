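#' The nine-level perturbation grid
#'
#' Multiplicative factors 1 +/- 0.2, 1 +/- 0.4, 1 +/- 0.6, 1 +/- 0.8
#' (eight levels) plus an absolute zero (ninth level), applied to one
#' parameter at a time.  Factors stay positive, so negative parameter
#' values cannot arise; setting to zero is the only hard zero.
#'
#' @return numeric vector of length 9; the ninth entry (`0`) is the
#'   absolute "set to zero" level, the rest are factors.
#' @export
perturbation_levels <- function() {
  c(1 - c(0.2, 0.4, 0.6, 0.8), 1 + c(0.2, 0.4, 0.6, 0.8), 0)
}

perturb_pv <- function(pv, param, level_idx) {
  lv <- perturbation_levels()[level_idx]
  pv[param] <- if (level_idx == 9L) 0 else pv[param] * lv
  pv
}

#' Robustness indicator tensor over a perturbation grid
#'
#' For each ensemble vector i, critical parameter j, fragile strain k and
#' perturbation level l: perturb parameter j of vector i by level l,
#' simulate strain k with WT-seeded initial conditions, and set
#' `R[i,j,k,l] = 1` iff the strain's phenotype equals its pre-perturbation
#' phenotype under the same (unperturbed) vector, simulated once and
#' cached.  Simulation blow-ups count as phenotype lost.
#'
#' @param ensemble matrix of FC1-feasible parameter vectors.
#' @param model a [model_spec()].
#' @param critical_params character vector of parameter names to perturb.
#' @param fragile_strains list of [strain_spec()]; the phenotype to
#'   maintain per strain is the pre-perturbation phenotype.
#' @param dt,horizon,size_cap,band simulation and classification settings.
#' @return 4-d 0/1 array of class `pde_robustness_tensor` with dimensions
#'   (vector, parameter, strain, level).
#' @export
robustness_tensor <- function(ensemble, model, critical_params,
                              fragile_strains, dt = 0.05, horizon = 2000,
                              size_cap = 25, band = 0.05) {
  stopifnot(all(critical_params %in% colnames(ensemble)))
  fragile_strains <- as_strain_list(fragile_strains)
  m <- nrow(ensemble)
  np <- length(critical_params)
  ns <- length(fragile_strains)
  R <- array(0L, dim = c(m, np, ns, 9L),
             dimnames = list(NULL, critical_params,
                             vapply(fragile_strains, `[[`, character(1),
                                    "label"),
                             NULL))
  one <- function(pv, strain) {
    # WT-seeded phenotype; unseedable or blown-up WT counts as code 2
    wt <- simulate_strain(model, pv, NULL, dt = dt, horizon = horizon,
                          keep_states = FALSE)
    if (length(strain$overrides) == 0)
      return(classify_phenotype(wt, size_cap, band)$code)
    if (length(wt$div_time) == 0) return(2L)
    strain_phenotype(model, pv, strain, init = wt$post_last_div, dt = dt,
                     horizon = horizon, size_cap = size_cap, band = band)
  }
  for (i in seq_len(m)) {
    pv0 <- ensemble[i, ]
    baseline <- vapply(fragile_strains, function(s) one(pv0, s), integer(1))
    for (j in seq_len(np)) {
      for (l in 1:9) {
        pvp <- perturb_pv(pv0, critical_params[j], l)
        for (k in seq_len(ns)) {
          code <- one(pvp, fragile_strains[[k]])
          R[i, j, k, l] <- as.integer(code == baseline[k])
        }
      }
    }
  }
  class(R) <- c("pde_robustness_tensor", class(R))
  R
}

#' Robustness aggregates
#'
#' `r_hat(R, i)` is the robustness score of the i-th parameter vector (sum
#' of the indicator over parameters, strains and levels; at most
#' `9 * #params * #strains`, i.e. 900 for the 10 x 10 reference grid).
#' `r_breve(R)` is the highest score within the ensemble.
#' `r_tilde(R, i, j, k)` sums the nine levels of one (vector, parameter,
#' strain) cell, and `r_bar(R, j, k)` is the maximum of that cell score
#' over the ensemble.
#'
#' @param R a [robustness_tensor()].
#' @param i,j,k vector / parameter / strain indices.
#' @return integer score.
#' @export
r_hat <- function(R, i) sum(R[i, , , ])

#' @rdname r_hat
#' @export
r_breve <- function(R) max(vapply(seq_len(dim(R)[1]),
                                  function(i) r_hat(R, i), numeric(1)))

#' @rdname r_hat
#' @export
r_tilde <- function(R, i, j, k) sum(R[i, j, k, ])

#' @rdname r_hat
#' @export
r_bar <- function(R, j, k) {
  max(vapply(seq_len(dim(R)[1]), function(i) r_tilde(R, i, j, k),
             numeric(1)))
}

#' Relative robustness of ensemble b with respect to ensemble a
#'
#' For every (parameter, strain) pair, the sign of
#' `r_bar_b(j, k) - r_bar_a(j, k)`: +1 where b is more robust, -1 where
#' less, 0 on ties.
#'
#' @param tensor_a,tensor_b robustness tensors over the same
#'   (parameter, strain) grid.
#' @return integer matrix (parameters x strains) with entries in
#'   `{-1, 0, 1}`.
#' @export
relative_robustness <- function(tensor_a, tensor_b) {
  stopifnot(identical(dim(tensor_a)[2:4], dim(tensor_b)[2:4]))
  np <- dim(tensor_a)[2]; ns <- dim(tensor_a)[3]
  out <- matrix(0L, np, ns,
                dimnames = dimnames(tensor_a)[2:3])
  for (j in seq_len(np)) {
    for (k in seq_len(ns)) {
      out[j, k] <- sign(r_bar(tensor_b, j, k) - r_bar(tensor_a, j, k))
    }
  }
  out
}

#' Export a robustness tensor as a long-format table
#' @param R a [robustness_tensor()].
#' @param path output file path.
#' @export
write_robustness_tensor <- function(R, path) {
  d <- dim(R)
  grid <- expand.grid(vector_id = seq_len(d[1]),
                      param = dimnames(R)[[2]],
                      strain = dimnames(R)[[3]],
                      level = seq_len(d[4]))
  grid$maintained <- as.vector(R)  # expand.grid varies the first index fastest
  write.table(grid, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
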