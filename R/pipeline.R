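#' Fit QTL and genomic-selection models for all three phenology parameters
#'
#' For each of LAR, S and T0: cofactor selection, CIM scan, QTL declaration
#' at the LOD threshold, and an rrBLUP genome-wide model, all fitted on the
#' same lines.
#'
#' @param params data.frame with columns `line`, `LAR`, `S`, `T0` (e.g.
#'   `fit_phenology(...)$params`), or a `pheno_fit`.
#' @param pop `dh_population` covering at least those lines.
#' @param threshold LOD declaration threshold (default 2.5).
#' @param step,window CIM scan step and cofactor exclusion window (cM).
#' @param verbose log one line per stage (default FALSE).
#' @return list with elements `qtl` and `gs`, each a named list of models
#'   for "LAR", "S", "T0"; plus `scans` (the three `cim_scan`s) and `lines`
#'   (ids used for fitting).
#' @export
run_genetic_models <- function(params, pop, threshold = 2.5, step = 2,
                               window = 10, verbose = FALSE) {
  if (inherits(params, "pheno_fit")) params <- params$params
  idx <- match(params$line, rownames(pop$genotypes))
  if (anyNA(idx)) abort_validation("some fitted lines are absent from the population")
  sub <- dh_population(pop$genotypes[idx, , drop = FALSE], pop$map, params$line)
  out <- list(qtl = list(), gs = list(), scans = list(), lines = params$line)
  for (tr in c("LAR", "S", "T0")) {
    y <- params[[tr]]
    cof <- select_cofactors(sub, y)
    scan <- cim_scan(sub, y, cof, step = step, window = window)
    qm <- declare_qtl(scan, sub, y, threshold = threshold, trait = tr)
    gm <- rrblup(sub$genotypes, y, trait = tr)
    out$qtl[[tr]] <- qm
    out$gs[[tr]] <- gm
    out$scans[[tr]] <- scan
    if (verbose) {
      message(sprintf("[models] %s: %d cofactors, %d QTL declared, lambda = %.3g",
                      tr, length(cof), nrow(qm$loci), gm$lambda))
    }
  }
  out
}

#' Predict field induction days from genome-based parameters
#'
#' Builds each line's parameter triple (LAR, S, T0) from the chosen source
#' -- declared QTL effects, genome-wide GEBVs, or the original fitted/true
#' parameters -- and runs the two-phase development simulation under the
#' daily temperature series. Lines whose predicted parameters are invalid
#' under the series (non-positive rate denominator) or whose development is
#' censored get NA.
#'
#' @param models result of [run_genetic_models()] (required for modes "qtl"
#'   and "gs").
#' @param pop `dh_population` (or genotype matrix) of the lines to predict.
#' @param temps daily temperature series.
#' @param mode one of "qtl", "gs", "original".
#' @param original_params data.frame `line`/`LAR`/`S`/`T0` for mode
#'   "original".
#' @return named numeric vector of predicted induction days.
#' @export
predict_field <- function(models, pop, temps, mode = c("qtl", "gs", "original"),
                          original_params = NULL) {
  mode <- match.arg(mode)
  if (mode == "original") {
    if (is.null(original_params)) abort_validation("mode 'original' needs original_params")
    pt <- original_params
    if (is.null(pt$line)) pt$line <- rownames(pt)
  } else {
    mods <- models[[mode]]
    G <- if (inherits(pop, "dh_population")) pop else as.matrix(pop)
    pred_one <- function(m) {
      if (mode == "qtl") predict(m, G) else gebv(m, G)
    }
    pt <- data.frame(
      line = if (inherits(pop, "dh_population")) rownames(pop$genotypes) else rownames(G),
      LAR = pred_one(mods$LAR), S = pred_one(mods$S), T0 = pred_one(mods$T0),
      stringsAsFactors = FALSE
    )
  }
  pt$LAR <- pmax(pt$LAR, 1e-4)
  predict_induction(pt, temps = as.numeric(temps))
}

#' Evaluate predictions against observations
#'
#' Accuracy statistics of predicted vs observed induction days:
#' `r_squared` is the squared Pearson correlation, `slope` the OLS slope of
#' predicted (response) on observed (regressor) -- slopes above 1 indicate
#' over-dispersed predictions -- plus mean bias (predicted minus observed,
#' days) and RMSE.
#'
#' @param predicted,observed paired numeric vectors; pairs with NA on
#'   either side are dropped.
#' @return one-row data.frame with `r_squared`, `slope`, `bias`, `rmse`,
#'   `n`.
#' @export
evaluate_predictions <- function(predicted, observed) {
  keep <- is.finite(predicted) & is.finite(observed)
  p <- predicted[keep]; o <- observed[keep]
  if (length(p) <= 2L) abort_validation("need more than 2 paired observations")
  if (stats::sd(p) == 0 || stats::sd(o) == 0) {
    abort_validation("zero variance in predictions or observations")
  }
  data.frame(
    r_squared = stats::cor(p, o)^2,
    slope = sum((o - mean(o)) * (p - mean(p))) / sum((o - mean(o))^2),
    bias = mean(p - o),
    rmse = sqrt(mean((p - o)^2)),
    n = length(p)
  )
}

#' Default experiment configuration
#'
#' Encodes the study conditions of the synthetic experiment: 180
#' parameterization lines, 72 validation lines, 160 + 34 test hybrids, the
#' seven greenhouse treatment temperatures, 120-day trial duration, LOD
#' threshold 2.5, and the field-site presets used for validation.
#'
#' @param seed master seed.
#' @return list of class `experiment_config`.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    n_param = 180L,
    n_valid = 72L,
    n_hybrids_param = 160L,
    n_hybrids_valid = 34L,
    temperatures = c(11.75, 15.51, 17.33, 19.03, 21.44, 26.49, 27.00),
    duration_days = 120L,
    field_days = 120L,
    obs_noise_sd = 2,
    lod_threshold = 2.5,
    scan_step = 2,
    cofactor_window = 10,
    dh_sites = c("Zeewolde2011", "Zeewolde2012", "Ruthe", "Rostock"),
    hybrid_sites = c("Ocsa2011", "Ocsa2012", "Zeewolde2012")
  ), class = "experiment_config")
}

#' Read an experiment configuration from a YAML file
#' @param path YAML file; keys as in [default_config()], missing keys take
#'   the defaults.
#' @return `experiment_config`.
#' @export
read_config <- function(path) {
  usr <- yaml::read_yaml(path)
  cfg <- default_config()
  bad <- setdiff(names(usr), names(cfg))
  if (length(bad)) abort_validation(sprintf("unknown config keys: %s",
                                            paste(bad, collapse = ", ")))
  cfg[names(usr)] <- usr
  structure(cfg, class = "experiment_config")
}

#' Write an experiment configuration to YAML
#' @param config an `experiment_config`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full synthetic genotype-to-phenology experiment
#'
#' End to end: simulates the DH population (parameterization + validation
#' subsets, disjoint by construction) and its true parameters, runs the
#' seven greenhouse parameterization trials, fits per-line phenology
#' parameters, fits QTL and genomic-selection models on the
#' parameterization set only, crosses both subsets to a tester, simulates
#' field trials at the configured sites, predicts all four evaluation
#' subsets with both genome-based modes (plus the original fitted/true
#' parameters), and evaluates each prediction.
#'
#' For hybrids the multi-site convention is also reported: predicted and
#' observed days averaged per line across the hybrid sites before computing
#' accuracy (`site = "mean"`).
#'
#' @param config an `experiment_config` (see [default_config()]).
#' @param outdir optional output directory; when given, writes genotype,
#'   parameter, scan, model and report files there.
#' @param verbose log one line per stage (default FALSE).
#' @return list of class `experiment_result` with `report` (data.frame:
#'   `subset`, `site`, `mode`, accuracy columns), `delta_r2` (mean GS minus
#'   QTL R^2), `pheno_fit`, `models`, `config`, `seed`.
#' @export
run_full_experiment <- function(config = default_config(), outdir = NULL,
                                verbose = FALSE) {
  cfg <- config
  log_stage <- function(fmt, ...) if (verbose) message(sprintf(paste0("[run] ", fmt), ...))
  seeds <- split_seed(cfg$seed, 40L)
  map <- default_map()
  arch <- default_architecture()
  n_all <- cfg$n_param + cfg$n_valid
  pop <- simulate_dh_genomes(map, n_all, seed = seeds[1L])
  truth <- assign_true_params(pop, arch, seed = seeds[2L])
  id_param <- rownames(pop$genotypes)[seq_len(cfg$n_param)]
  id_valid <- rownames(pop$genotypes)[cfg$n_param + seq_len(cfg$n_valid)]
  stopifnot(length(intersect(id_param, id_valid)) == 0L) # leakage guard
  pop_param <- dh_population(pop$genotypes[id_param, , drop = FALSE], map, id_param)
  pop_valid <- dh_population(pop$genotypes[id_valid, , drop = FALSE], map, id_valid)
  log_stage("population: %d lines (%d parameterization, %d validation)",
            n_all, cfg$n_param, cfg$n_valid)

  trials <- lapply(seq_along(cfg$temperatures), function(t) {
    simulate_greenhouse_trial(truth[id_param, ], cfg$temperatures[t], arch,
                              duration_days = cfg$duration_days,
                              seed = seeds[2L + t])
  })
  fit <- fit_phenology(trials)
  log_stage("parameterization: %d lines fitted, %d excluded",
            nrow(fit$params), length(fit$excluded))

  models <- run_genetic_models(fit, pop_param, threshold = cfg$lod_threshold,
                               step = cfg$scan_step,
                               window = cfg$cofactor_window, verbose = verbose)

  # tester: one further DH genome from the same cross, mid-parent hybrids
  tester_pop <- simulate_dh_genomes(map, 1L, seed = seeds[10L], line_prefix = "T")
  tester_truth <- assign_true_params(tester_pop, arch, seed = seeds[11L])
  hyb_param <- make_test_hybrids(
    dh_population(pop_param$genotypes[seq_len(cfg$n_hybrids_param), , drop = FALSE],
                  map, id_param[seq_len(cfg$n_hybrids_param)]),
    truth[id_param[seq_len(cfg$n_hybrids_param)], ],
    tester_pop$genotypes[1L, ], tester_truth[1L, ]
  )
  hyb_valid <- make_test_hybrids(
    dh_population(pop_valid$genotypes[seq_len(cfg$n_hybrids_valid), , drop = FALSE],
                  map, id_valid[seq_len(cfg$n_hybrids_valid)]),
    truth[id_valid[seq_len(cfg$n_hybrids_valid)], ],
    tester_pop$genotypes[1L, ], tester_truth[1L, ]
  )

  subsets <- list(
    validation_dh = list(pop = pop_valid, truth = truth[id_valid, ],
                         sites = cfg$dh_sites),
    parameterization_dh = list(pop = pop_param, truth = truth[id_param, ],
                               sites = utils::head(cfg$dh_sites, 2)),
    hybrids_param = list(pop = hyb_param$pop, truth = hyb_param$true_params,
                         sites = cfg$hybrid_sites),
    hybrids_valid = list(pop = hyb_valid$pop, truth = hyb_valid$true_params,
                         sites = cfg$hybrid_sites)
  )

  report <- list()
  sseed <- 12L
  for (sub_name in names(subsets)) {
    sb <- subsets[[sub_name]]
    per_site <- list()
    for (site in sb$sites) {
      ps <- site_preset(site)
      sseed <- sseed + 2L
      temps <- simulate_field_temperatures(ps$mean, ps$min, ps$max,
                                           n_days = cfg$field_days,
                                           seed = seeds[sseed])
      ft <- simulate_field_trial(sb$truth, temps,
                                 obs_noise_sd = cfg$obs_noise_sd,
                                 seed = seeds[sseed + 1L])
      obs <- stats::setNames(ft$observations$induction_day, ft$observations$line)
      for (mode in c("qtl", "gs", "original")) {
        pred <- predict_field(models, sb$pop, temps, mode = mode,
                              original_params = sb$truth)
        ev <- evaluate_predictions(pred, obs[names(pred)])
        report[[length(report) + 1L]] <- cbind(
          data.frame(subset = sub_name, site = site, mode = mode,
                     stringsAsFactors = FALSE), ev
        )
        per_site[[mode]][[site]] <- list(pred = pred, obs = obs[names(pred)])
      }
      log_stage("%s @ %s: done (%d lines)", sub_name, site, length(obs))
    }
    # multi-site means for hybrids (average across trials per line)
    if (startsWith(sub_name, "hybrids") && length(sb$sites) > 1L) {
      for (mode in c("qtl", "gs", "original")) {
        pm <- rowMeans(do.call(cbind, lapply(per_site[[mode]], `[[`, "pred")))
        om <- rowMeans(do.call(cbind, lapply(per_site[[mode]], `[[`, "obs")))
        ev <- evaluate_predictions(pm, om)
        report[[length(report) + 1L]] <- cbind(
          data.frame(subset = sub_name, site = "mean", mode = mode,
                     stringsAsFactors = FALSE), ev
        )
      }
    }
  }
  report <- do.call(rbind, report)
  rg <- report[report$site != "mean", ]
  delta_r2 <- mean(rg$r_squared[rg$mode == "gs"]) -
    mean(rg$r_squared[rg$mode == "qtl"])

  res <- structure(
    list(report = report, delta_r2 = delta_r2, pheno_fit = fit,
         models = models, truth = truth, config = cfg, seed = cfg$seed),
    class = "experiment_result"
  )
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_genotypes(pop, file.path(outdir, "genotypes.csv"))
    write_genetic_map(map, file.path(outdir, "map.tsv"))
    write_params(fit, file.path(outdir, "fitted_params.csv"))
    write_phenotypes(trials, file.path(outdir, "parameterization"))
    for (tr in c("LAR", "S", "T0")) {
      write_scan(models$scans[[tr]], file.path(outdir, sprintf("scan_%s.csv", tr)), tr)
      write_qtl_model(models$qtl[[tr]], file.path(outdir, sprintf("qtl_%s.json", tr)))
      write_gs_model(models$gs[[tr]], file.path(outdir, sprintf("gs_%s.json", tr)))
    }
    utils::write.csv(report, file.path(outdir, "evaluation_report.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(seed = cfg$seed, delta_r2 = delta_r2),
                         file.path(outdir, "summary.json"), auto_unbox = TRUE)
  }
  res
}

#' Simulate the default parameterization study and fit per-line parameters
#'
#' Convenience wrapper producing the calibrated synthetic parameterization
#' data set: the default map and QTL architecture, `n_lines` DH genomes,
#' true parameters, the seven constant-temperature greenhouse trials and
#' the per-line phenology fit.
#'
#' @param seed master seed; all stages draw child seeds from it.
#' @param n_lines number of DH lines (default 180).
#' @param temperatures treatment temperatures (degree C).
#' @param duration_days trial duration (default 120).
#' @return list with `pop`, `truth`, `trials`, `fit` (a `pheno_fit`).
#' @export
simulate_parameterization_set <- function(seed = 1L, n_lines = 180L,
                                          temperatures = c(11.75, 15.51, 17.33,
                                                           19.03, 21.44, 26.49,
                                                           27.00),
                                          duration_days = 120L) {
  seeds <- split_seed(seed, 2L + length(temperatures))
  map <- default_map()
  arch <- default_architecture()
  pop <- simulate_dh_genomes(map, n_lines, seed = seeds[1L])
  truth <- assign_true_params(pop, arch, seed = seeds[2L])
  trials <- lapply(seq_along(temperatures), function(t) {
    simulate_greenhouse_trial(truth, temperatures[t], arch,
                              duration_days = duration_days,
                              seed = seeds[2L + t])
  })
  list(pop = pop, truth = truth, trials = trials, fit = fit_phenology(trials))
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("Synthetic genotype-to-phenology experiment (seed %d)\n", x$seed))
  cat(sprintf("  mean R^2 advantage of GS over QTL predictions: %+.3f\n", x$delta_r2))
  print(x$report, digits = 3, row.names = FALSE)
  invisible(x)
}
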