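#' Feature table for module classification
#'
#' One row per relative-abundance record: the record's `mean`, `std` and
#' `CV`, plus the numeric mutant id, labelled by the network module of
#' the reference species (numerator or denominator).  Records whose
#' reference species lacks a module annotation (annotation `"--"`, e.g.
#' the size variable) are dropped.
#'
#' @param records a [relative_abundance_table()].
#' @param annotation named character vector mapping species to module
#'   (typically `model$modules`).
#' @param reference which side of the ratio carries the class label.
#' @return data.frame of class `pde_feature_table` with columns `mean`,
#'   `std`, `cv`, `mutant`, `label`.
#' @export
build_feature_table <- function(records, annotation,
                                reference = c("numerator", "denominator")) {
  reference <- match.arg(reference)
  ref_species <- if (reference == "numerator") records$num else records$den
  lab <- unname(annotation[ref_species])
  keep <- !is.na(lab) & lab != "--"
  if (!any(keep)) stop("no records with an annotated reference species")
  df <- data.frame(mean = records$mean[keep], std = records$sd[keep],
                   cv = records$cv[keep],
                   mutant = as.numeric(records$mutant[keep]),
                   label = lab[keep], stringsAsFactors = FALSE)
  class(df) <- c("pde_feature_table", "data.frame")
  df
}

# midrank (Mann-Whitney) AUC of scores against binary truth
auc_midrank <- function(scores, positive) {
  n_pos <- sum(positive); n_neg <- sum(!positive)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(scores)  # ties share midranks
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' One random-forest training/evaluation pass
#'
#' Grows a forest of `n_trees` classification trees (bootstrap samples of
#' size n with replacement, Gini splits over `floor(sqrt(p))` candidate
#' features per node, unlimited depth).  Every row is scored by the vote
#' fractions of the trees for which it was out-of-bag, and one-vs-rest
#' ROC AUC (midrank convention) is computed per module.  A module with
#' fewer than 2 scored OOB rows gets `NA` with a flag.
#'
#' @param rows a [build_feature_table()] (or
#'   [make_module_structured_features()]) table.
#' @param n_trees number of trees (default 100).
#' @param seed optional RNG seed; `NULL` uses the ambient RNG state.
#' @return named numeric vector of per-module AUC values (attribute
#'   `flagged` names modules with undefined AUC).
#' @export
train_eval_once <- function(rows, n_trees = 100L, seed = NULL) {
  classes <- sort(unique(rows$label))
  if (length(classes) < 2) stop("need at least 2 modules")
  X <- as.matrix(rows[, c("mean", "std", "cv", "mutant")])
  y <- match(rows$label, classes) - 1L
  mtry <- floor(sqrt(ncol(X)))
  run <- function() cpp_rf_oob_votes(X, y, length(classes), n_trees, mtry)
  fit <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  scored <- fit$oob_trees > 0
  frac <- fit$votes[scored, , drop = FALSE] / fit$oob_trees[scored]
  lab <- y[scored]
  auc <- setNames(rep(NA_real_, length(classes)), classes)
  flagged <- character(0)
  for (c in seq_along(classes)) {
    pos <- lab == (c - 1L)
    if (sum(pos) < 2 || sum(!pos) < 2) {
      flagged <- c(flagged, classes[c])
      next
    }
    auc[c] <- auc_midrank(frac[, c], pos)
  }
  attr(auc, "flagged") <- flagged
  auc
}

#' Repeated forest evaluation with optional label-permutation null
#'
#' Runs [train_eval_once()] `n_runs` times and reports the per-module
#' mean and standard deviation of the OOB AUC, plus a one-sided Z-test
#' of the mean AUC against the no-skill value 0.5 (standard error =
#' sd over runs / sqrt(n_runs)).  With `permute = TRUE` the class labels
#' are reshuffled independently before each run, giving the
#' label-permutation null whose p-values should stay above the 0.05
#' significance threshold.
#'
#' @param rows feature table.
#' @param n_runs number of independent runs (default 100).
#' @param n_trees trees per forest.
#' @param permute permute labels independently per run.
#' @param seed RNG seed for the whole evaluation.
#' @return data.frame of class `pde_auc_report` with one row per module:
#'   `module`, `mean_auc`, `sd_auc`, `z`, `p_value`, `permuted`;
#'   attribute `auc_runs` holds the runs x modules AUC matrix.
#' @export
repeated_eval <- function(rows, n_runs = 100L, n_trees = 100L,
                          permute = FALSE, seed = 1L) {
  stopifnot(n_runs >= 2)
  classes <- sort(unique(rows$label))
  aucs <- withr::with_seed(seed, {
    t(vapply(seq_len(n_runs), function(r) {
      d <- rows
      if (permute) d$label <- sample(d$label)
      train_eval_once(d, n_trees = n_trees, seed = NULL)
    }, numeric(length(classes))))
  })
  colnames(aucs) <- classes
  mean_auc <- colMeans(aucs, na.rm = TRUE)
  sd_auc <- apply(aucs, 2, sd, na.rm = TRUE)
  se <- sd_auc / sqrt(n_runs)
  z <- ifelse(se > 0, (mean_auc - 0.5) / se,
              ifelse(mean_auc > 0.5, Inf, ifelse(mean_auc < 0.5, -Inf, 0)))
  p <- pnorm(z, lower.tail = FALSE)  # one-sided: AUC > 0.5
  out <- data.frame(module = classes, mean_auc = mean_auc, sd_auc = sd_auc,
                    z = z, p_value = p, permuted = permute,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "auc_runs") <- aucs
  class(out) <- c("pde_auc_report", "data.frame")
  out
}
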