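#' Pipeline configuration
#'
#' Bundles everything an end-to-end run needs: either a generator
#' specification (design + parameters) or a path to an existing trial CSV,
#' model settings, an optional output directory, and the mandatory master
#' seed. Configurations round-trip through JSON via
#' [read_pipeline_config()].
#'
#' @param design An [experiment_design()] (required with `params`).
#' @param params A [generative_params()]; exactly one of `params` /
#'   `input_path` must be supplied.
#' @param input_path Path to a trial CSV (see [read_trials()]).
#' @param seed Master seed for every stochastic step.
#' @param model List of sampler/model settings overriding the defaults of
#'   [fit_multilevel_logistic()] and friends (`chains`, `adapt`, `burn`,
#'   `iter`, `item_re`, `priors`, `n_restarts`, ...).
#' @param outdir Optional directory for summary CSVs and the manifest.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(design = NULL, params = NULL, input_path = NULL,
                            seed, model = list(), outdir = NULL) {
  if (is.null(params) == is.null(input_path))
    stop("exactly one of 'params' or 'input_path' must be set", call. = FALSE)
  if (!is.null(params) && is.null(design))
    stop("generator configs need an experiment_design", call. = FALSE)
  if (missing(seed)) stop("a master seed is mandatory", call. = FALSE)
  structure(list(design = design, params = params, input_path = input_path,
                 seed = as.integer(seed), model = model, outdir = outdir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file with fields `design`, `params` (or `input_path`),
#'   `seed`, and optionally `model` and `outdir`.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  design <- if (!is.null(raw$design))
    do.call(experiment_design, as.list(raw$design)) else NULL
  params <- if (!is.null(raw$params))
    do.call(generative_params, as.list(raw$params)) else NULL
  pipeline_config(design = design, params = params,
                  input_path = raw$input_path, seed = raw$seed,
                  model = as.list(raw$model), outdir = raw$outdir)
}

config_hash <- function(config) {
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  plain <- strip(config)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(plain, tmp, auto_unbox = TRUE, digits = NA, null = "null")
  unname(tools::md5sum(tmp))
}

pipeline_trials <- function(config) {
  if (!is.null(config$params)) {
    simulate_experiment(config$design, config$params, seed = config$seed)
  } else {
    read_trials(config$input_path)
  }
}

model_setting <- function(config, name, default) config$model[[name]] %||% default

fit_logistic_from_config <- function(trials, coding, config, seed_offset = 0) {
  fit_multilevel_logistic(
    trials, coding = coding,
    item_re = model_setting(config, "item_re", TRUE),
    priors = model_setting(config, "priors", list(beta_sd = 2.5, re_sd_scale = 1)),
    chains = model_setting(config, "chains", 4),
    adapt = model_setting(config, "adapt", 500),
    burn = model_setting(config, "burn", 500),
    iter = model_setting(config, "iter", 1000),
    seed = config$seed + seed_offset)
}

manifest_for <- function(config, warnings) {
  list(seed = config$seed,
       config_hash = config_hash(config),
       package_version = as.character(utils::packageVersion("prodmem")),
       warnings = warnings)
}

write_report_tables <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(report$tables)) {
    utils::write.csv(report$tables[[nm]],
                     file.path(outdir, paste0(nm, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(report$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' Run the remember-know analysis pipeline
#'
#' End-to-end analysis of a remember-know experiment, in the canonical
#' order: (1) old-response model (remember/know collapsed), (2) remember
#' model, (3) know model after excluding remember trials (the independence
#' familiarity analysis). Within designs use dummy foil-intercept coding
#' and report back-transformed condition proportions with contrasts;
#' between designs use centered coding and additionally report the
#' logit-scale signal-detection metrics C_L and d'_L per group.
#'
#' @param config A [pipeline_config()] with remember-know data or
#'   generator settings.
#' @return A report list: `trials_paradigm`, `models` (one
#'   [posterior_draws] per outcome), `estimates` (back-transformed /
#'   metric summaries), `tables` (flat summary `data.frame`s), and
#'   `manifest` (seed, config hash, versions, collected warnings). Tables
#'   and manifest are also written to `config$outdir` when set.
#' @export
run_rk_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  trials <- pipeline_trials(config)
  if (!is_rk(trials))
    stop("run_rk_pipeline needs remember/know/new responses", call. = FALSE)
  between <- all(trials$group %in% c("aloud", "silent"))
  coding <- if (between) "centered_itemtype" else "dummy_foil_intercept"

  collected <- character()
  models <- list()
  estimates <- list()
  tables <- list()
  outcomes <- c("old", "remember", "know_after_exclusion")
  for (i in seq_along(outcomes)) {
    oc <- outcomes[i]
    dat <- withCallingHandlers(
      rk_outcome(trials, oc),
      warning = function(w) {
        collected <<- c(collected, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    fit <- withCallingHandlers(
      fit_logistic_from_config(dat, coding, config, seed_offset = i),
      warning = function(w) {
        collected <<- c(collected, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    models[[oc]] <- fit
    if (between) {
      sdt <- derive_sdt_metrics(fit)
      estimates[[oc]] <- sdt
      tables[[paste0(oc, "_sdt")]] <- cbind(model = oc, sdt$table)
    } else {
      bt <- backtransform_proportions(fit, conditions = list(
        foil = "b_intercept",
        silent = c("b_intercept", "b_silent"),
        aloud = c("b_intercept", "b_aloud")))
      estimates[[oc]] <- bt
      tables[[paste0(oc, "_proportions")]] <- cbind(model = oc, bt$table)
    }
    tables[[paste0(oc, "_coefficients")]] <- cbind(model = oc, summarize_draws(fit))
    collected <- c(collected, fit$warnings)
  }
  report <- list(paradigm = "remember_know",
                 design = if (between) "between" else "within",
                 models = models, estimates = estimates, tables = tables,
                 manifest = manifest_for(config, unique(collected)))
  if (!is.null(config$outdir)) write_report_tables(report, config$outdir)
  report
}

#' Run the confidence-rating analysis pipeline
#'
#' End-to-end analysis of a 6-point confidence experiment: (1) multilevel
#' logistic model on binarized old/new responses, (2) per-subject DPSD fits
#' to each subject's ROC, (3) Gaussian regressions of the recollection and
#' familiarity estimates on production (paired for within designs).
#'
#' @param config A [pipeline_config()] with confidence-rating data or
#'   generator settings.
#' @return A report list as in [run_rk_pipeline()], with `dpsd_fits`
#'   (per-subject parameter table) and Gaussian-model summaries for
#'   recollection and familiarity.
#' @export
run_confidence_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  trials <- pipeline_trials(config)
  if (!is_confidence(trials))
    stop("run_confidence_pipeline needs 1-6 confidence responses", call. = FALSE)
  between <- all(trials$group %in% c("aloud", "silent"))
  coding <- if (between) "centered_itemtype" else "dummy_foil_intercept"

  collected <- character()
  grab <- function(expr) withCallingHandlers(expr, warning = function(w) {
    collected <<- c(collected, conditionMessage(w))
    invokeRestart("muffleWarning")
  })

  dat <- binarize_confidence(trials)
  old_fit <- grab(fit_logistic_from_config(dat, coding, config, seed_offset = 1))
  tables <- list(old_coefficients = cbind(model = "old", summarize_draws(old_fit)))
  estimates <- list()
  if (between) {
    sdt <- derive_sdt_metrics(old_fit)
    estimates$old <- sdt
    tables$old_sdt <- cbind(model = "old", sdt$table)
  } else {
    bt <- backtransform_proportions(old_fit, conditions = list(
      foil = "b_intercept",
      silent = c("b_intercept", "b_silent"),
      aloud = c("b_intercept", "b_aloud")))
    estimates$old <- bt
    tables$old_proportions <- cbind(model = "old", bt$table)
  }

  dpsd <- grab(fit_dpsd_subjects(
    trials,
    objective = model_setting(config, "objective", "ml"),
    n_restarts = model_setting(config, "n_restarts", 10),
    seed = config$seed + 101))
  tables$dpsd_fits <- dpsd

  gauss <- list()
  for (measure in c("R", "dprime")) {
    fit <- grab(fit_gaussian_regression(
      dpsd[[measure]], dpsd$condition,
      subject_id = dpsd$subject_id, paired = !between,
      chains = model_setting(config, "chains", 4),
      adapt = model_setting(config, "adapt", 500),
      burn = model_setting(config, "burn", 500),
      iter = model_setting(config, "iter", 1000),
      seed = config$seed + if (measure == "R") 201 else 202))
    gauss[[measure]] <- fit
    collected <- c(collected, fit$warnings)
    label <- if (measure == "R") "recollection" else "familiarity"
    tables[[paste0(label, "_regression")]] <- cbind(model = label,
                                                    summarize_draws(fit))
  }

  report <- list(paradigm = "confidence",
                 design = if (between) "between" else "within",
                 models = c(list(old = old_fit), gauss),
                 dpsd_fits = dpsd, estimates = estimates, tables = tables,
                 manifest = manifest_for(config, unique(c(collected, old_fit$warnings))))
  if (!is.null(config$outdir)) write_report_tables(report, config$outdir)
  report
}

#' Run the meta-analysis stage
#'
#' Fits the basic random-effects model and the design-moderated model to a
#' table of standardized effects, separately per measure when a `measure`
#' column distinguishes recollection and familiarity effects, and derives
#' forest-plot data and the fraction of heterogeneity explained by design.
#'
#' @param effects An effects `data.frame` (columns `study`, `design`,
#'   `g`, `var_g`, optionally `measure`) or a path to such a CSV.
#' @param seed Integer seed.
#' @param outdir Optional output directory for summary and forest CSVs.
#' @param ... Passed to [fit_random_effects()] (priors, sampler settings).
#' @return A list per measure, each with `basic`, `moderated`
#'   (`meta_result`s), `variance_explained`, and `forest`
#'   (see [forest_data()]).
#' @export
run_meta <- function(effects, seed = 1, outdir = NULL, ...) {
  if (is.character(effects)) effects <- utils::read.csv(effects, stringsAsFactors = FALSE)
  if (nrow(effects) < 3)
    stop("need at least 3 effects to run a meta-analysis; got ", nrow(effects),
         call. = FALSE)
  measures <- if ("measure" %in% names(effects) && !anyNA(effects$measure))
    unique(effects$measure) else "all"
  out <- list()
  for (ms in measures) {
    eff <- if (identical(ms, "all")) effects else effects[effects$measure == ms, ]
    basic <- fit_random_effects(eff, moderator = FALSE, seed = seed, ...)
    moderated <- fit_random_effects(eff, moderator = TRUE, seed = seed + 1, ...)
    out[[ms]] <- list(
      basic = basic, moderated = moderated,
      variance_explained = variance_explained(basic, moderated),
      forest = rbind(cbind(model = "basic", forest_data(basic)),
                     cbind(model = "moderated", forest_data(moderated))))
    if (!is.null(outdir)) {
      dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
      utils::write.csv(out[[ms]]$forest,
                       file.path(outdir, paste0("forest_", ms, ".csv")),
                       row.names = FALSE, quote = FALSE)
      utils::write.csv(rbind(cbind(model = "basic", basic$summary),
                             cbind(model = "moderated", moderated$summary)),
                       file.path(outdir, paste0("meta_summary_", ms, ".csv")),
                       row.names = FALSE, quote = FALSE)
    }
  }
  out
}
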