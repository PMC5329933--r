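#' Scheme registry: named ensemble-generation presets
#'
#' Maps scheme ids 1-8 to the combination of sampler, initial-population
#' selection and feasibility criteria they use:
#' 1 = Latin hypercube screening; 2 = jittered reference-ensemble
#' screening; 3 = DE with FC1 and a random initial population;
#' 4 = DE + FC1 with volume-greedy initial selection over the critical
#' axes; 5 = scheme 4 plus FC2; 6 = FC1+FC2 with volume-greedy selection
#' over all kinetic axes; 7 = prediction-diverse and volume-greedy
#' initial selection with FC1+FC2+FC3; 8 = same selection with FC1+FC3.
#'
#' @return data.frame describing the registry.
#' @export
scheme_registry <- function() {
  data.frame(
    scheme = 1:8,
    sampler = c("lhs", "reference", rep("de", 6)),
    init_mode = c(NA, NA, "random", "Vmax", "Vmax", "Vmax", "SmaxVmax",
                  "SmaxVmax"),
    init_axes = c(NA, NA, NA, "critical", "critical", "all", "all", "all"),
    criteria = c(NA, NA, "FC1", "FC1", "FC1+FC2", "FC1+FC2",
                 "FC1+FC2+FC3", "FC1+FC3"),
    stringsAsFactors = FALSE)
}

#' Assemble a run configuration
#'
#' @param scheme scheme id, 1-8 (see [scheme_registry()]).
#' @param toy_cfg a [toy_config()] describing the model.
#' @param constraint training constraint (default: the toy fixture's).
#' @param panel prediction strain panel (default: singles and pairs over
#'   two START synthesis routes and two reporter rates, which keeps
#'   desk-scale runs fast while covering viable, inviable and
#'   region-dependent phenotypes).
#' @param n_lhs samples for the LHS scheme.
#' @param n_reference size of the scheme-2 / seeding reference ensemble.
#' @param jitter reference-ensemble jitter.
#' @param de a [de_config()] holding N, F, C, t_max (criteria and
#'   volume axes are overridden by the scheme).
#' @param critical_axes parameter names used by `Vmax(critical)` schemes.
#' @param out_dir output directory.
#' @param seed global seed.
#' @param dt,horizon integration settings.
#' @return list of class `pde_run_config`.
#' @export
run_config <- function(scheme, toy_cfg = toy_config(), constraint = NULL,
                       panel = make_strain_panel(
                         c("ks_a", "ks_a2", "ks_rS1", "ks_rM1"),
                         max_order = 2),
                       n_lhs = 500, n_reference = 40,
                       jitter = 0.02, de = de_config(N = 8L, t_max = 30L),
                       critical_axes = c("ks_a", "ki_ae", "kd_a"),
                       out_dir = tempfile("pde_run_"), seed = 1L,
                       dt = 0.05, horizon = 2000) {
  if (!scheme %in% 1:8)
    stop("unknown scheme id ", scheme, "; valid ids are 1..8")
  structure(list(scheme = as.integer(scheme), toy_cfg = toy_cfg,
                 constraint = constraint, panel = panel, n_lhs = n_lhs,
                 n_reference = n_reference, jitter = jitter, de = de,
                 critical_axes = critical_axes, out_dir = out_dir,
                 seed = as.integer(seed), dt = dt, horizon = horizon),
            class = "pde_run_config")
}

#' Execute one ensemble-generation scheme
#'
#' Builds the toy model, generates an ensemble with the configured
#' scheme, computes the prediction matrix, range S, sampling and
#' feasibility efficiencies and (for DE schemes) the dynamic-volume
#' trace, and writes everything to the run directory as tab-separated
#' tables together with a JSON manifest carrying the config hash and
#' seed.  Re-running with an identical config reproduces the outputs
#' byte-for-byte.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with `ensemble`, `P`, `S`, `e_S`, `e_FC1`,
#'   `volume_trace` (or `NULL`), `dir`.
#' @export
run_scheme <- function(config) {
  stopifnot(inherits(config, "pde_run_config"))
  toy <- make_toy_model(config$toy_cfg)
  model <- toy$model
  constraint <- config$constraint %||% toy_training_constraint(config$toy_cfg)
  strains <- as_strain_list(config$panel)
  dt <- config$dt; horizon <- config$horizon
  volume_trace <- NULL

  if (config$scheme == 1) {
    ref <- make_reference_ensemble(model, toy$pv, n = config$n_reference,
                                   jitter = config$jitter,
                                   seed = derive_seed(config$seed, 1),
                                   constraint = constraint, dt = dt,
                                   horizon = horizon)
    samples <- lhs_sample(ensemble_bounds(ref), config$n_lhs,
                          seed = derive_seed(config$seed, 2))
    feasible <- apply(samples, 1, function(v)
      check_fc1(v, model, constraint, dt = dt, horizon = horizon))
    ensemble <- t(apply(samples[feasible, , drop = FALSE], 1, truncate32))
    colnames(ensemble) <- colnames(samples)
    n_tot <- config$n_lhs
  } else if (config$scheme == 2) {
    ensemble <- make_reference_ensemble(model, toy$pv,
                                        n = config$n_reference,
                                        jitter = config$jitter,
                                        seed = derive_seed(config$seed, 1),
                                        constraint = constraint, dt = dt,
                                        horizon = horizon)
    n_tot <- config$n_reference
  } else {
    reg <- scheme_registry()[config$scheme, ]
    ref <- make_reference_ensemble(model, toy$pv,
                                   n = config$n_reference,
                                   jitter = config$jitter,
                                   seed = derive_seed(config$seed, 1),
                                   constraint = constraint, dt = dt,
                                   horizon = horizon)
    criteria <- strsplit(reg$criteria, "+", fixed = TRUE)[[1]]
    axes <- if (identical(reg$init_axes, "critical")) config$critical_axes
            else intersect(model$params, colnames(ref))
    de <- config$de
    cfg <- de_config(N = de$N, F = de$F, C = de$C, t_max = de$t_max,
                     criteria = criteria, volume_axes = axes,
                     seed = derive_seed(config$seed, 3))
    init <- select_initial_population(
      ref, cfg$N, mode = reg$init_mode, axes = axes, model = model,
      prediction_strains = strains, seed = derive_seed(config$seed, 4),
      dt = dt, horizon = horizon)
    res <- run_de(model, constraint, init, cfg,
                  prediction_strains = strains, dt = dt, horizon = horizon)
    ensemble <- res$recorded
    volume_trace <- res$volume_trace
    n_tot <- cfg$t_max * cfg$N
  }

  if (nrow(ensemble) == 0) stop("scheme produced no feasible vectors")
  P <- prediction_matrix(ensemble, model, strains, dt = dt,
                         horizon = horizon)
  S <- prediction_range(P)
  metrics <- data.frame(
    metric = c("S", "e_S", "e_FC1", "n_feasible", "n_tot"),
    value = c(S, sampling_efficiency(S, n_tot),
              feasibility_efficiency(nrow(ensemble), n_tot),
              nrow(ensemble), n_tot))

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- rlang::hash(config[setdiff(names(config), "out_dir")])
  wr <- function(df, name) {
    path <- file.path(config$out_dir, name)
    con <- file(path, "w")
    writeLines(paste0("# config_hash=", cfg_hash, " seed=", config$seed),
               con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  wr(as.data.frame(ensemble), "ensemble.tsv")
  wr(as.data.frame(unclass(P)), "prediction_matrix.tsv")
  wr(metrics, "metrics.tsv")
  if (!is.null(volume_trace)) wr(volume_trace, "volume_trace.tsv")
  jsonlite::write_json(
    list(scheme = config$scheme, seed = config$seed,
         config_hash = cfg_hash,
         package_version = as.character(utils::packageVersion("phenoDE"))),
    file.path(config$out_dir, "manifest.json"), auto_unbox = TRUE)

  invisible(list(ensemble = ensemble, P = P, S = S,
                 e_S = sampling_efficiency(S, n_tot),
                 e_FC1 = feasibility_efficiency(nrow(ensemble), n_tot),
                 volume_trace = volume_trace, dir = config$out_dir))
}

#' End-to-end pipeline: ensembles to module-classification report
#'
#' Chains the full analysis on the toy fixture: generate an ensemble with
#' the configured scheme, find the consistently viable mutants, compute
#' relative-abundance records, protein/mutant variability reports, and a
#' random-forest AUC report (with its label-permutation null when
#' requested).  All artifacts are written under the run directory.
#'
#' @param config a [run_config()].
#' @param n_runs,n_trees forest evaluation settings (kept small by
#'   default for desk-scale runs).
#' @param permute also produce the permuted-label null report.
#' @return invisibly, a list with `records`, `report_num`, `mutants`,
#'   `auc`, and optionally `auc_permuted`.
#' @export
run_full_pipeline <- function(config, n_runs = 10L, n_trees = 50L,
                              permute = TRUE) {
  res <- run_scheme(config)
  toy <- make_toy_model(config$toy_cfg)
  strains <- as_strain_list(config$panel)

  viable <- consistently_viable_mutants(list(res$P))
  if (length(viable) == 0) stop("no consistently viable mutants")
  keep <- strains[vapply(strains, function(s) s$id %in% viable,
                         logical(1))]
  # cap the ensemble rows used for abundance statistics at desk scale
  ens <- res$ensemble[seq_len(min(nrow(res$ensemble), 30L)), ,
                      drop = FALSE]
  records <- relative_abundance_table(ens, toy$model, keep,
                                      dt = config$dt,
                                      horizon = config$horizon)
  report_num <- protein_variability_scores(records, "numerator")
  mutants <- mutant_variability(records)
  feats <- build_feature_table(records, toy$model$modules, "numerator")
  auc <- repeated_eval(feats, n_runs = n_runs, n_trees = n_trees,
                       permute = FALSE, seed = derive_seed(config$seed, 7))
  out <- list(records = records, report_num = report_num,
              mutants = mutants, auc = auc)
  if (permute) {
    out$auc_permuted <- repeated_eval(feats, n_runs = n_runs,
                                      n_trees = n_trees, permute = TRUE,
                                      seed = derive_seed(config$seed, 8))
  }
  wr <- function(df, name)
    write.table(df, file.path(config$out_dir, name), sep = "\t",
                quote = FALSE, row.names = FALSE)
  wr(records[, c("mutant", "num", "den", "mean", "sd", "cv")],
     "abundance_records.tsv")
  wr(report_num, "protein_variability.tsv")
  wr(mutants, "mutant_variability.tsv")
  wr(as.data.frame(out$auc), "auc_report.tsv")
  if (permute) wr(as.data.frame(out$auc_permuted), "auc_permuted.tsv")
  invisible(out)
}

#' Read and write ensembles as delimited tables
#'
#' Tab-separated tables with a parameter-name header row; comment lines
#' starting with `#` (the config-hash header written by [run_scheme()])
#' are skipped on read.
#'
#' @param ensemble ensemble matrix.
#' @param path file path.
#' @return `read_ensemble` returns the ensemble matrix.
#' @export
write_ensemble <- function(ensemble, path) {
  write.table(as.data.frame(ensemble), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  as.matrix(df)
}

#' Command-line entry point
#'
#' Subcommands: `explore` (run one scheme), `pipeline` (end-to-end run),
#' `fixture` (write the toy strain panel), `predict` (prediction matrix
#' and range for a stored ensemble), `robustness` (robustness tensor and
#' aggregates for a stored ensemble), `stats` (relative-abundance
#' variability reports), `classify` (random-forest AUC report for a
#' stored feature table).  Flags: `--scheme`, `--generations`,
#' `--ensemble FILE`, `--features FILE`, `--permute`, `--seed`, `--out`.
#' The model for `predict`/`robustness`/`stats` is the built-in toy
#' fixture.
#'
#' @param args character vector of command-line arguments (defaults to
#'   the process arguments).
#' @return invisibly, the subcommand's result.
#' @export
pde_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0)
    stop("usage: <explore|pipeline|fixture|predict|robustness|stats|",
         "classify> [--scheme N] [--generations N] [--ensemble FILE] ",
         "[--features FILE] [--permute] [--seed N] [--out DIR]")
  cmd <- args[1]
  opt <- function(name, default) {
    hit <- which(args == paste0("--", name))
    if (length(hit) == 1 && hit < length(args)) args[hit + 1] else default
  }
  seed <- as.integer(opt("seed", 1))
  out <- opt("out", tempfile("pde_run_"))
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    write.table(df, file.path(out, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
    message("wrote ", file.path(out, name))
  }
  need_ensemble <- function() {
    path <- opt("ensemble", NULL)
    if (is.null(path)) stop(cmd, " needs --ensemble FILE")
    if (!file.exists(path)) stop("ensemble file not found: ", path)
    read_ensemble(path)
  }

  if (cmd == "fixture") {
    panel <- make_strain_panel(toy_eliminable_rates(), max_order = 3)
    write_strain_panel(panel, file.path(out, "panel.tsv"))
    message("wrote ", file.path(out, "panel.tsv"))
    return(invisible(panel))
  }

  if (cmd %in% c("explore", "pipeline")) {
    scheme <- as.integer(opt("scheme", 8))
    gens <- as.integer(opt("generations", 30))
    cfg <- run_config(scheme, de = de_config(N = 8L, t_max = gens),
                      out_dir = out, seed = seed)
    res <- if (cmd == "explore") run_scheme(cfg) else run_full_pipeline(cfg)
    message("run written to ", out)
    return(invisible(res))
  }

  if (cmd == "predict") {
    ens <- need_ensemble()
    toy <- make_toy_model()
    panel <- make_strain_panel(toy_eliminable_rates()[c(1, 2, 7, 9)],
                               max_order = 2)
    P <- prediction_matrix(ens, toy$model, panel)
    write_prediction_matrix(P, file.path(out, "prediction_matrix.tsv"))
    wr(data.frame(metric = c("S", "e_S"),
                  value = c(prediction_range(P),
                            sampling_efficiency(prediction_range(P),
                                                nrow(ens)))),
       "metrics.tsv")
    return(invisible(P))
  }

  if (cmd == "robustness") {
    ens <- need_ensemble()
    toy <- make_toy_model()
    params <- c("ks_a", "ki_ae", "kd_a")
    strains <- list(strain_spec(1L, "ks_a2-del", c(ks_a2 = 0)),
                    strain_spec(2L, "rS-del", c(ks_rS1 = 0)))
    R <- robustness_tensor(ens, toy$model, params, strains)
    write_robustness_tensor(R, file.path(out, "robustness.tsv"))
    wr(data.frame(vector_id = seq_len(nrow(ens)),
                  r_hat = vapply(seq_len(nrow(ens)),
                                 function(i) r_hat(R, i), numeric(1))),
       "r_hat.tsv")
    return(invisible(R))
  }

  if (cmd == "stats") {
    ens <- need_ensemble()
    toy <- make_toy_model()
    strains <- list(strain_spec(1L, "rS-del", c(ks_rS1 = 0)),
                    strain_spec(2L, "rM-del", c(ks_rM1 = 0)))
    rec <- relative_abundance_table(ens, toy$model, strains)
    wr(rec[, c("mutant", "num", "den", "mean", "sd", "cv")],
       "abundance_records.tsv")
    wr(protein_variability_scores(rec, "numerator"),
       "protein_variability.tsv")
    wr(mutant_variability(rec), "mutant_variability.tsv")
    return(invisible(rec))
  }

  if (cmd == "classify") {
    path <- opt("features", NULL)
    if (is.null(path)) stop("classify needs --features FILE")
    if (!file.exists(path)) stop("features file not found: ", path)
    rows <- utils::read.delim(path, stringsAsFactors = FALSE)
    rep <- repeated_eval(rows, n_runs = as.integer(opt("runs", 20)),
                         n_trees = as.integer(opt("trees", 100)),
                         permute = "--permute" %in% args, seed = seed)
    wr(as.data.frame(rep), "auc_report.tsv")
    return(invisible(rep))
  }

  stop("unknown subcommand '", cmd, "'; use explore, pipeline, fixture, ",
       "predict, robustness, stats or classify")
}
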