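#' Strains consistently predicted viable across ensembles
#'
#' A strain qualifies when every row of every supplied prediction matrix
#' assigns it code 1.
#'
#' @param prediction_matrices list of prediction matrices sharing the same
#'   strain panel (column order).
#' @return integer vector of qualifying strain ids.
#' @export
consistently_viable_mutants <- function(prediction_matrices) {
  stopifnot(length(prediction_matrices) > 0)
  ids <- colnames(prediction_matrices[[1]])
  for (P in prediction_matrices) {
    if (!identical(colnames(P), ids))
      stop("prediction matrices must share the strain panel")
  }
  all_viable <- Reduce(`&`, lapply(prediction_matrices, function(P)
    apply(unclass(P) == 1L, 2, all)))
  as.integer(ids[all_viable])
}

#' Relative-abundance statistics across an ensemble
#'
#' For every strain and every ordered species pair (a, b), a != b, the
#' ratio of time-averaged abundances `mean_a / mean_b` is computed per
#' ensemble vector (strains simulated with WT-seeded initial conditions
#' per vector).  Mean, sample standard deviation (n-1) and CV = sd/mean
#' are taken across the ensemble vectors; records whose CV is non-finite
#' (zero or undefined mean, blown-up denominators) are dropped.
#'
#' @param ensemble ensemble matrix.
#' @param model a [model_spec()].
#' @param strains list of [strain_spec()] to include (the consistently
#'   viable set, plus the wild type when requested).
#' @param include_wt prepend the wild-type strain (default `TRUE`).
#' @param species which species enter the ratios (default: all, including
#'   the size variable).
#' @param dt,horizon integration settings.
#' @param keep_values keep the per-vector ratio values as a list column.
#' @return data.frame of class `pde_abundance_records` with columns
#'   `mutant`, `num`, `den`, `mean`, `sd`, `cv` (one row per finite-CV
#'   record).
#' @export
relative_abundance_table <- function(ensemble, model, strains,
                                     include_wt = TRUE, species = NULL,
                                     dt = 0.05, horizon = 2000,
                                     keep_values = FALSE) {
  strains <- as_strain_list(strains)
  if (include_wt) strains <- c(list(wt_strain()), strains)
  species <- species %||% model$species
  m <- nrow(ensemble)

  # one WT simulation per vector seeds every mutant simulation
  wt_trajs <- lapply(seq_len(m), function(i)
    simulate_strain(model, ensemble[i, ], NULL, dt = dt, horizon = horizon,
                    keep_states = FALSE))

  rows <- list()
  for (s in strains) {
    av <- matrix(NA_real_, m, length(species),
                 dimnames = list(NULL, species))
    for (i in seq_len(m)) {
      pv <- ensemble[i, ]
      wt <- wt_trajs[[i]]
      traj <- if (length(s$overrides) == 0) wt
      else if (length(wt$div_time) == 0) NULL
      else simulate_strain(model, pv, s, dt = dt, horizon = horizon,
                           init = wt$post_last_div, keep_states = FALSE)
      if (!is.null(traj) && !traj$blowup)
        av[i, ] <- traj$means[species]
    }
    for (a in species) {
      for (b in species) {
        if (a == b) next
        vals <- av[, a] / av[, b]
        vals <- vals[is.finite(vals)]
        if (length(vals) < 2) next
        mu <- mean(vals); sdev <- sd(vals)
        cv <- sdev / mu
        if (!is.finite(cv)) next
        rows[[length(rows) + 1L]] <- list(
          mutant = s$id, num = a, den = b, mean = mu, sd = sdev, cv = cv,
          values = if (keep_values) list(vals) else NULL)
      }
    }
  }
  df <- data.frame(
    mutant = vapply(rows, `[[`, integer(1), "mutant"),
    num = vapply(rows, `[[`, character(1), "num"),
    den = vapply(rows, `[[`, character(1), "den"),
    mean = vapply(rows, `[[`, numeric(1), "mean"),
    sd = vapply(rows, `[[`, numeric(1), "sd"),
    cv = vapply(rows, `[[`, numeric(1), "cv"),
    stringsAsFactors = FALSE)
  if (keep_values) df$values <- I(lapply(rows, function(r) r$values[[1]]))
  class(df) <- c("pde_abundance_records", "data.frame")
  df
}

#' Per-mutant summed CV, ranked
#'
#' The prediction-variability statistic of a mutant strain: the sum of the
#' finite CVs of all its relative-abundance records, ranked in decreasing
#' order.
#'
#' @param records a [relative_abundance_table()].
#' @return data.frame with columns `mutant`, `score`, `rank`, ordered by
#'   decreasing score.
#' @export
mutant_variability <- function(records) {
  stopifnot(nrow(records) > 0)
  agg <- aggregate(cv ~ mutant, data = records, FUN = sum)
  names(agg)[2] <- "score"
  agg <- agg[order(-agg$score, agg$mutant), ]
  agg$rank <- seq_len(nrow(agg))
  rownames(agg) <- NULL
  agg
}

#' Per-protein variability scores, percentiles and categories
#'
#' The variability score of a protein is the sum of the CVs of all
#' abundance ratios with that protein in the chosen orientation
#' (numerator or denominator).  Proteins are ranked in decreasing score;
#' `percentile = 100 * (n - rank) / (n - 1)` maps rank 1 to 100 and the
#' last rank to 0; the category is `"high"` for the top half of the
#' ranking and `"low"` for the bottom half.  Ties are broken by species
#' name for determinism.
#'
#' @param records a [relative_abundance_table()].
#' @param orientation `"numerator"` or `"denominator"`.
#' @return data.frame of class `pde_variability_report` with columns
#'   `protein`, `score`, `rank`, `percentile`, `category`.
#' @export
protein_variability_scores <- function(records,
                                       orientation = c("numerator",
                                                       "denominator")) {
  stopifnot(nrow(records) > 0)
  orientation <- match.arg(orientation)
  key <- if (orientation == "numerator") records$num else records$den
  agg <- aggregate(records$cv, by = list(protein = key), FUN = sum)
  names(agg)[2] <- "score"
  agg <- agg[order(-agg$score, agg$protein), ]
  n <- nrow(agg)
  agg$rank <- seq_len(n)
  agg$percentile <- if (n > 1) 100 * (n - agg$rank) / (n - 1) else 100
  agg$category <- ifelse(agg$rank <= n / 2, "high", "low")
  rownames(agg) <- NULL
  class(agg) <- c("pde_variability_report", "data.frame")
  agg
}

#' Pearson correlation between numerator- and denominator-based rankings
#'
#' Checks that the protein ranking does not depend on which side of the
#' ratio defines the protein's score: the Pearson correlation of the two
#' rank vectors over the shared protein set.
#'
#' @param report_num,report_den reports from
#'   [protein_variability_scores()] for the two orientations.
#' @return Pearson r.
#' @export
ranking_orientation_correlation <- function(report_num, report_den) {
  stopifnot(setequal(report_num$protein, report_den$protein))
  r1 <- report_num$rank[order(report_num$protein)]
  r2 <- report_den$rank[order(report_den$protein)]
  if (sd(r1) == 0 || sd(r2) == 0) stop("zero-variance ranks")
  cor(r1, r2)
}

#' Aggregate protein variability scores by biological process
#'
#' Each process gets the mean and sample standard deviation of the
#' variability scores of its member proteins (singleton processes get sd
#' 0), ranked by decreasing mean.  Processes with no member protein in
#' the report are excluded with a warning.
#'
#' @param report a [protein_variability_scores()] report.
#' @param annotation named list mapping protein name to a character
#'   vector of process names (a multimap).
#' @return data.frame with columns `process`, `mean`, `sd`, `n`, `rank`.
#' @export
process_variability <- function(report, annotation) {
  missing <- setdiff(names(annotation), report$protein)
  if (length(missing) > 0)
    stop("annotated proteins absent from report: ",
         paste(missing, collapse = ", "))
  pairs <- data.frame(
    protein = rep(names(annotation), lengths(annotation)),
    process = unlist(annotation, use.names = FALSE),
    stringsAsFactors = FALSE)
  if (nrow(pairs) == 0)
    return(data.frame(process = character(0), mean = numeric(0),
                      sd = numeric(0), n = integer(0), rank = integer(0)))
  pairs$score <- report$score[match(pairs$protein, report$protein)]
  agg <- do.call(rbind, lapply(split(pairs, pairs$process), function(g)
    data.frame(process = g$process[1], mean = mean(g$score),
               sd = if (nrow(g) > 1) sd(g$score) else 0,
               n = nrow(g))))
  agg <- agg[order(-agg$mean, agg$process), ]
  agg$rank <- seq_len(nrow(agg))
  rownames(agg) <- NULL
  agg
}
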