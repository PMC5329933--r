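#' Prediction matrix of an ensemble over a strain panel
#'
#' Entry (i, j) is the phenotype code of strain j simulated under
#' parameter vector i, with initial conditions seeded from that vector's
#' own wild-type simulation.  Simulation failures propagate as code 2.
#'
#' @param ensemble ensemble matrix (rows = parameter vectors).
#' @param model a [model_spec()].
#' @param strains list of [strain_spec()] or a `pde_strain_panel`.
#' @param dt,horizon,size_cap,band simulation and classification settings.
#' @return integer matrix, one column per strain (strain ids as column
#'   names), of class `pde_prediction_matrix`.
#' @export
prediction_matrix <- function(ensemble, model, strains, dt = 0.05,
                              horizon = 2000, size_cap = 25, band = 0.05) {
  strains <- as_strain_list(strains)
  P <- t(apply(ensemble, 1, function(v)
    prediction_vector(model, v, strains, dt = dt, horizon = horizon,
                      size_cap = size_cap, band = band)))
  P <- matrix(as.integer(P), nrow = nrow(ensemble))
  colnames(P) <- vapply(strains, `[[`, integer(1), "id")
  class(P) <- c("pde_prediction_matrix", class(P))
  P
}

as_strain_list <- function(strains) {
  if (inherits(strains, "pde_strain_panel")) strains$strains else strains
}

#' Range of predictions: number of unique prediction vectors
#'
#' The range S(P) of a prediction matrix is the number of distinct rows.
#' Invariant under row permutation; bounded by `min(m, 3^l)`.
#'
#' @param P prediction matrix.
#' @return integer count.
#' @export
prediction_range <- function(P) {
  if (is.null(dim(P)) || nrow(P) == 0) stop("P must be a non-empty matrix")
  length(unique(apply(P, 1, paste, collapse = ",")))
}

#' Sampling efficiency e_S = S / n_tot
#'
#' Unique prediction vectors found per sample taken from the parameter
#' space.
#'
#' @param S prediction range.
#' @param n_tot total number of parameter-space samples.
#' @return fraction in `[0, 1]`.
#' @export
sampling_efficiency <- function(S, n_tot) {
  if (n_tot <= 0) stop("n_tot must be positive")
  S / n_tot
}

#' Feasibility efficiency e_FC1 = n_FC1 / n_tot
#'
#' @param n_fc1 number of FC1-feasible vectors found.
#' @param n_tot total number of parameter-space samples.
#' @return fraction in `[0, 1]`.
#' @export
feasibility_efficiency <- function(n_fc1, n_tot) {
  if (n_tot <= 0) stop("n_tot must be positive")
  n_fc1 / n_tot
}

#' Estimated log-volume spanned by an ensemble
#'
#' Axis-aligned bounding-box estimate: the sum over the chosen axes of
#' `log(max - min)` across ensemble members.  Returns `-Inf` when any
#' axis is degenerate.  All volume comparisons (the second feasibility
#' criterion, the dynamic-volume trace) are made on this log scale; the
#' estimator is deliberately simple and monotone (adding a vector never
#' decreases it).
#'
#' @param ensemble ensemble matrix with at least 2 rows.
#' @param axes parameter names (default: all columns).
#' @return extended real.
#' @export
estimated_log_volume <- function(ensemble, axes = NULL) {
  if (nrow(ensemble) < 2) stop("volume needs at least 2 vectors")
  axes <- axes %||% colnames(ensemble)
  sub <- ensemble[, axes, drop = FALSE]
  rng <- apply(sub, 2, max) - apply(sub, 2, min)
  if (any(rng <= 0)) return(-Inf)
  sum(log(rng))
}

#' Per-parameter max/min range ratios of an ensemble
#'
#' Diagnoses the shrinkage of parameter ranges over a population: for each
#' parameter the maximum divided by the minimum across ensemble members.
#' Axes with non-positive values are excluded with a warning.
#'
#' @param ensemble ensemble matrix.
#' @return named numeric vector of ratios (each >= 1).
#' @export
parameter_range_ratios <- function(ensemble) {
  lo <- apply(ensemble, 2, min)
  bad <- lo <= 0
  if (any(bad)) {
    warning("excluding non-positive axes: ",
            paste(colnames(ensemble)[bad], collapse = ", "))
  }
  hi <- apply(ensemble, 2, max)
  (hi / lo)[!bad]
}

#' Write a prediction matrix as a delimited integer table
#' @param P prediction matrix.
#' @param path output file path.
#' @export
write_prediction_matrix <- function(P, path) {
  df <- as.data.frame(unclass(P))
  names(df) <- paste0("strain_", colnames(P))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
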