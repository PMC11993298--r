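#' Run configuration
#'
#' Builds, validates, reads and writes the configuration of a full
#' pipeline run. Every stochastic stage gets an explicit seed derived from
#' `seed` unless overridden. Configurations round-trip losslessly through
#' YAML.
#'
#' @param seed Global integer seed.
#' @param n_hv,n_esrd Arm sizes.
#' @param lloq Lower limit of quantification, pg/mL.
#' @param sigma_prop,sigma_add Residual-error overrides applied to every
#'   model.
#' @param fit Refit the population models from the simulated data (slow);
#'   when `FALSE` (default) the shipped final model parameters are used.
#' @param nsim_vpc Replicates for the VPC stage (0 skips it).
#' @param seeds Optional named list of per-stage seed overrides
#'   (`cohort`, `trial`, `map`, `lasso`, `vpc`).
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, n_hv = 14L, n_esrd = 10L, lloq = 5,
                       sigma_prop = 0.2, sigma_add = 1, fit = FALSE,
                       nsim_vpc = 0L, seeds = list()) {
  stopifnot(n_hv >= 1, n_esrd >= 1, lloq >= 0, sigma_prop >= 0, sigma_add >= 0)
  base <- list(cohort = seed, trial = seed + 1000L, map = seed + 2000L,
               lasso = seed + 3000L, vpc = seed + 4000L)
  base[names(seeds)] <- seeds
  structure(list(seed = as.integer(seed), n_hv = as.integer(n_hv),
                 n_esrd = as.integer(n_esrd), lloq = lloq,
                 sigma_prop = sigma_prop, sigma_add = sigma_add,
                 fit = isTRUE(fit), nsim_vpc = as.integer(nsim_vpc),
                 seeds = lapply(base, as.integer)),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(run_config, c(x[setdiff(names(x), "seeds")], list(seeds = x$seeds)))
}

stage_log <- function(stage, ...) {
  message(format(Sys.time(), "[%Y-%m-%dT%H:%M:%S] "), stage, ": ", ...)
}

write_csv_stamped <- function(df, path, config) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# cocktailpk run: seed %d, config %s",
                     config$seed, rlang::hash(unclass(config))), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Orchestrates cohort generation, trial simulation, dataset export,
#' non-compartmental analysis, (optional) population refitting, MAP Bayes
#' individual clearances, DMET activity estimation and the
#' correlation/LASSO stage, writing one CSV artifact per stage plus a
#' summary. Fully reproducible from the configuration; every output file
#' carries the seed and a configuration hash in a header comment.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @param models Population models (default [default_models()]).
#' @return Invisibly, a named list of the stage artifacts (tibbles).
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("pkrun"),
                         models = default_models()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  models <- lapply(models, function(m) {
    m$sigma <- list(prop = config$sigma_prop, add = config$sigma_add); m
  })
  stage_log("config", "seed ", config$seed, ", hash ",
            rlang::hash(unclass(config)))
  write_run_config(config, file.path(out_dir, "config.yaml"))

  stage_log("cohort", config$n_hv, " HV + ", config$n_esrd, " ESRD subjects")
  subjects <- simulate_cohort(config$n_hv, config$n_esrd,
                              seed = config$seeds$cohort)
  write_csv_stamped(subjects, file.path(out_dir, "cohort.csv"), config)

  stage_log("simulate", "cocktail trial records")
  records <- simulate_trial(subjects, models, seed = config$seeds$trial,
                            lloq = config$lloq)
  write_pk_dataset(records, file.path(out_dir, "dataset.csv"),
                   subjects = subjects,
                   header = sprintf("cocktailpk run: seed %d, config %s",
                                    config$seed, rlang::hash(unclass(config))))

  stage_log("nca", "per-subject exposure and group ratios")
  nca_df <- nca(records)
  ratios <- exposure_ratio_table(nca_df)
  write_csv_stamped(nca_df, file.path(out_dir, "nca_subject.csv"), config)
  write_csv_stamped(ratios, file.path(out_dir, "nca_summary.csv"), config)

  fits <- NULL
  if (config$fit) {
    stage_log("fit", "population refit of all drugs (Laplace)")
    fits <- lapply(models, function(m)
      fit_population(records, subjects, m))
    models <- lapply(fits, function(f) f$model)
    partab <- dplyr::bind_rows(
      lapply(fits, function(f) dplyr::mutate(tidy(f), drug = f$model$drug)))
    write_csv_stamped(partab, file.path(out_dir, "popfit.csv"), config)
  } else {
    stage_log("fit", "skipped; using shipped final model parameters")
  }

  stage_log("map", "individual clearances (MAP Bayes)")
  cl_tab <- dplyr::bind_rows(lapply(models, function(m) {
    mb <- map_bayes(m, records, subjects, seed = config$seeds$map)
    tibble::tibble(id = mb$id, drug = m$drug, cl = mb$cl)
  }))
  write_csv_stamped(cl_tab, file.path(out_dir, "individual_cl.csv"), config)

  stage_log("activity", "DMET activity report")
  ptv <- models$PTV
  dis_eff <- 0; th_veil <- 0; norm <- 1.08
  for (e in ptv$effects) {
    if (e$covariate == "dis") dis_eff <- e$theta
    if (e$form == "exp_linear_scaled") { th_veil <- e$theta; norm <- e$scale }
  }
  dab_dis <- 0
  for (e in models$DAB$effects) if (e$covariate == "dis") dab_dis <- e$theta
  activity <- dmet_activity_report(
    veil = max(subjects$Veillonella), dis_effect = dis_eff,
    theta_veil = th_veil, normalizer = norm, effect_esrd = -dab_dis)
  write_csv_stamped(activity, file.path(out_dir, "dmet_activity.csv"), config)

  stage_log("lasso", "covariate screen + LASSO on ESRD clearances")
  esrd <- subjects[subjects$group == "ESRD", ]
  cand <- c(setdiff(covariate_stats()$covariate, "scr"), "egfr",
            genus_ranges()$genus)
  screens <- list(); lassos <- list()
  for (m in models) {
    dat <- dplyr::inner_join(esrd, cl_tab[cl_tab$drug == m$drug, c("id", "cl")],
                             by = "id")
    sc <- correlation_screen(dat, "cl", vars = cand)
    screens[[m$drug]] <- dplyr::mutate(sc, drug = m$drug)
    keep <- sc$variable[sc$selected]
    if (length(keep) >= 1) {
      lf <- lasso_lambda_min(dat, "cl", vars = unique(c(keep, cand[1:2])),
                             seed = config$seeds$lasso)
      lassos[[m$drug]] <- dplyr::mutate(tidy(lf), drug = m$drug)
    }
  }
  write_csv_stamped(dplyr::bind_rows(screens),
                    file.path(out_dir, "correlation_screen.csv"), config)
  if (length(lassos)) {
    write_csv_stamped(dplyr::bind_rows(lassos),
                      file.path(out_dir, "lasso_selected.csv"), config)
  }

  vpc <- NULL
  if (config$nsim_vpc > 0) {
    stage_log("vpc", config$nsim_vpc, " replicates per drug")
    vpc <- lapply(models, function(m)
      vpc_bands(m, records, subjects, nsim = config$nsim_vpc,
                seed = config$seeds$vpc))
  }

  stage_log("report", "writing summary")
  summary <- list(
    seed = config$seed,
    exposure_ratios = ratios[ratios$metric == "auc_last",
                             c("drug", "ratio", "p")],
    activity = activity[, c("dmet", "quantity", "value")]
  )
  yaml::write_yaml(lapply(summary, function(x)
    if (is.data.frame(x)) as.list(x) else x),
    file.path(out_dir, "summary.yaml"))
  invisible(list(subjects = subjects, records = records, nca = nca_df,
                 ratios = ratios, fits = fits, individual_cl = cl_tab,
                 activity = activity, screens = dplyr::bind_rows(screens),
                 lasso = if (length(lassos)) dplyr::bind_rows(lassos),
                 vpc = vpc, out_dir = out_dir))
}
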