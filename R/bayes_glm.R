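#' Posterior draws container
#'
#' Fitted model objects in this package carry their posterior as a plain
#' draws matrix (one row per retained draw, one named column per parameter)
#' together with chain structure and convergence diagnostics (split across
#' chains: potential scale reduction factor and effective sample size per
#' monitored scalar). Draws from all chains are concatenated row-wise.
#'
#' @param x Object to convert.
#' @return `as_draws_matrix()` returns the numeric draws matrix.
#' @name posterior_draws
#' @export
as_draws_matrix <- function(x) UseMethod("as_draws_matrix")

#' @export
as_draws_matrix.matrix <- function(x) x

#' @export
as_draws_matrix.posterior_draws <- function(x) x$draws

#' @export
print.posterior_draws <- function(x, digits = 3, ...) {
  cat(sprintf("Posterior draws: %d draws x %d parameters (%d chains)\n",
              nrow(x$draws), ncol(x$draws), x$n_chains))
  tab <- do.call(rbind, lapply(colnames(x$draws), function(nm) {
    s <- posterior_summary(x$draws[, nm])
    summary_row(nm, s)
  }))
  print(tab, digits = digits, row.names = FALSE)
  if (length(x$warnings) > 0) cat("Warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Tabulate posterior summaries for every parameter
#'
#' @param draws A `posterior_draws` object or draws matrix.
#' @return A `data.frame` with columns `quantity, median, hdi50_lo, hdi50_hi,
#'   hdi95_lo, hdi95_hi, p_gt_0`.
#' @export
summarize_draws <- function(draws) {
  m <- as_draws_matrix(draws)
  do.call(rbind, lapply(colnames(m), function(nm)
    summary_row(nm, posterior_summary(m[, nm]))))
}

new_posterior_draws <- function(draws, n_chains, diagnostics, warnings = character()) {
  structure(list(draws = draws, n_chains = n_chains,
                 diagnostics = diagnostics, warnings = warnings),
            class = "posterior_draws")
}

# Shared JAGS driver: compiles, adapts, burns, samples, renames parameters,
# and computes R-hat / effective sample size. Chain RNGs are seeded
# deterministically from `seed`.
run_jags <- function(model_string, data, monitor, rename = NULL,
                     chains = 4, adapt = 500, burn = 500, iter = 1000,
                     thin = 1, seed = 1,
                     rhat_max = 1.01, ess_min = 400) {
  inits <- lapply(seq_len(chains), function(ch)
    list(.RNG.name = "base::Wichmann-Hill",
         .RNG.seed = (as.integer(seed) * 97L + ch) %% 100000L + 1L))
  model <- rjags::jags.model(textConnection(model_string), data = data,
                             inits = inits, n.chains = chains,
                             n.adapt = adapt, quiet = TRUE)
  update(model, n.iter = burn, progress.bar = "none")
  samp <- rjags::coda.samples(model, variable.names = monitor,
                              n.iter = iter, thin = thin,
                              progress.bar = "none")
  m <- do.call(rbind, lapply(samp, as.matrix))
  if (!is.null(rename)) {
    keep <- intersect(names(rename), colnames(m))
    m <- m[, keep, drop = FALSE]
    colnames(m) <- unname(rename[keep])
  }
  warnings <- character()
  diagnostics <- NULL
  if (chains >= 2) {
    sub <- lapply(samp, function(ch) ch[, intersect(names(rename), coda::varnames(samp)), drop = FALSE])
    gd <- try(coda::gelman.diag(coda::as.mcmc.list(sub), autoburnin = FALSE,
                                multivariate = FALSE), silent = TRUE)
    rhat <- if (inherits(gd, "try-error")) rep(NA_real_, ncol(m)) else gd$psrf[, 1]
    ess <- coda::effectiveSize(coda::as.mcmc.list(sub))
    diagnostics <- data.frame(parameter = colnames(m),
                              rhat = as.numeric(rhat),
                              ess = as.numeric(ess), row.names = NULL)
    bad_rhat <- diagnostics$parameter[!is.na(diagnostics$rhat) & diagnostics$rhat > rhat_max]
    bad_ess <- diagnostics$parameter[diagnostics$ess < ess_min]
    if (length(bad_rhat) > 0)
      warnings <- c(warnings, paste0("R-hat > ", rhat_max, " for: ",
                                     paste(bad_rhat, collapse = ", ")))
    if (length(bad_ess) > 0)
      warnings <- c(warnings, paste0("effective sample size < ", ess_min,
                                     " for: ", paste(bad_ess, collapse = ", ")))
  }
  new_posterior_draws(m, chains, diagnostics, warnings)
}

# Fixed-effect design matrix for one coding scheme. Centered coding needs a
# group label (aloud/silent) per trial; foils inherit their subject's group.
logistic_design_matrix <- function(trials, coding) {
  if (coding == "dummy_foil_intercept") {
    X <- cbind(intercept = 1,
               silent = as.numeric(trials$production == "silent"),
               aloud = as.numeric(trials$production == "aloud"))
  } else {
    if (!all(trials$group %in% c("aloud", "silent")))
      stop("centered_itemtype coding requires a between-subject 'group' of ",
           "'aloud' or 'silent' for every trial", call. = FALSE)
    item <- ifelse(trials$item_type == "studied", 0.5, -0.5)
    prod <- as.numeric(trials$group == "aloud")
    X <- cbind(intercept = 1, production = prod, item_type = item,
               interaction = prod * item)
  }
  X
}

jags_logistic_model <- function(item_re, beta_sd, re_sd_scale) {
  item_lik <- if (item_re) " + v[item[i]]" else ""
  item_prior <- if (item_re) "
  for (l in 1:L) { v[l] ~ dnorm(0, tau_v) }
  sigma_v ~ dnorm(0, pow(%SD%, -2)) T(1.0E-4,)
  tau_v <- pow(sigma_v, -2)" else ""
  gsub("%SD%", format(re_sd_scale), gsub("%BSD%", format(beta_sd), paste0("
model {
  for (i in 1:N) {
    y[i] ~ dbin(p[i], n[i])
    logit(p[i]) <- inprod(X[i,], beta) + u[subj[i]]", item_lik, "
  }
  for (j in 1:J) { u[j] ~ dnorm(0, tau_u) }
  sigma_u ~ dnorm(0, pow(%SD%, -2)) T(1.0E-4,)
  tau_u <- pow(sigma_u, -2)", item_prior, "
  for (k in 1:K) { beta[k] ~ dnorm(0, pow(%BSD%, -2)) }
}
")))
}

#' Fit a Bayesian multilevel logistic regression to trial-level responses
#'
#' Models each binary response (column `y`, produced by [collapse_rk_to_old()],
#' [binarize_confidence()], [rk_outcome()], or [independence_know_subset()])
#' with a logit link, fixed effects determined by the coding scheme, and a
#' random intercept per subject (and optionally per item). Sampling is by
#' Gibbs/slice updates via JAGS.
#'
#' Two coding schemes are supported, matching the two design families:
#' * `"dummy_foil_intercept"` (within designs): item type enters as 0/1
#'   dummies for the silent and aloud conditions with foil as the reference
#'   intercept; parameters `b_intercept`, `b_silent`, `b_aloud`.
#' * `"centered_itemtype"` (between designs): item type is centered at -0.5
#'   (foil) / +0.5 (studied), production is a 0/1 dummy (silent = 0,
#'   aloud = 1), plus their interaction; parameters `b_intercept`,
#'   `b_production`, `b_item_type`, `b_interaction`. This coding is the one
#'   from which the logit-scale signal-detection metrics are derived
#'   (see [derive_sdt_metrics()]).
#'
#' When `item_re = FALSE` the Bernoulli trials are aggregated to binomial
#' counts per subject and design cell, which leaves the likelihood unchanged
#' and speeds up sampling considerably.
#'
#' @param trials Trial `data.frame` with a binary `y` column.
#' @param coding `"dummy_foil_intercept"` or `"centered_itemtype"`.
#' @param item_re,subject_re Include item / subject random intercepts.
#'   Subject intercepts are always recommended; item intercepts require
#'   trial-level sampling.
#' @param priors List with elements `beta_sd` (SD of the Normal prior on
#'   fixed effects, default 2.5) and `re_sd_scale` (scale of the half-Normal
#'   prior on random-effect SDs, default 1).
#' @param chains,adapt,burn,iter,thin Sampler settings (defaults: 4 chains,
#'   500 adaptation, 500 burn-in, 1000 retained iterations per chain).
#' @param seed Integer seed; chain RNGs are derived from it.
#'
#' @return A [posterior_draws] object with fixed-effect columns (see coding
#'   above) plus `sd_subject` (and `sd_item` if requested).
#' @export
fit_multilevel_logistic <- function(trials,
                                    coding = c("dummy_foil_intercept", "centered_itemtype"),
                                    item_re = TRUE, subject_re = TRUE,
                                    priors = list(beta_sd = 2.5, re_sd_scale = 1),
                                    chains = 4, adapt = 500, burn = 500,
                                    iter = 1000, thin = 1, seed = 1) {
  coding <- match.arg(coding)
  if (!"y" %in% names(trials))
    stop("trials must carry a binary outcome column 'y' ",
         "(use collapse_rk_to_old(), binarize_confidence(), rk_outcome(), ",
         "or independence_know_subset())", call. = FALSE)
  y <- trials$y
  if (!all(y %in% c(0, 1))) stop("outcome 'y' must be binary 0/1", call. = FALSE)
  if (all(y == 0) || all(y == 1))
    stop("outcome class is empty: all responses are ", y[1], call. = FALSE)
  n_subj <- length(unique(trials$subject_id))
  extra_warnings <- character()
  if (n_subj < 2) {
    warning("single-subject input: random-effect SD is prior-dominated",
            call. = FALSE)
    extra_warnings <- c(extra_warnings, "single-subject input")
  }

  X <- logistic_design_matrix(trials, coding)
  # possible complete separation: a whole design cell with all-0 or all-1
  cell <- apply(X, 1, paste, collapse = "/")
  cell_rate <- tapply(y, cell, mean)
  if (any(cell_rate == 0 | cell_rate == 1)) {
    warning("a design cell has all-identical responses (possible complete ",
            "separation); estimates are regularized by the priors", call. = FALSE)
    extra_warnings <- c(extra_warnings, "possible complete separation")
  }

  beta_sd <- priors$beta_sd %||% 2.5
  re_sd_scale <- priors$re_sd_scale %||% 1

  if (item_re) {
    dat <- list(N = nrow(X), K = ncol(X), X = X, y = y, n = rep(1L, nrow(X)),
                subj = as.integer(factor(trials$subject_id)),
                J = n_subj,
                item = as.integer(factor(trials$item_id)),
                L = length(unique(trials$item_id)))
  } else {
    key <- paste(trials$subject_id, cell, sep = "|")
    agg_y <- tapply(y, key, sum)
    agg_n <- tapply(y, key, length)
    first <- !duplicated(key)
    ord <- match(names(agg_y), key[first])
    Xa <- X[first, , drop = FALSE][ord, , drop = FALSE]
    subj_a <- as.integer(factor(trials$subject_id))[first][ord]
    dat <- list(N = length(agg_y), K = ncol(X), X = Xa,
                y = as.integer(agg_y), n = as.integer(agg_n),
                subj = subj_a, J = n_subj)
  }

  model_string <- jags_logistic_model(item_re, beta_sd, re_sd_scale)
  rename <- c(stats::setNames(paste0("b_", colnames(X)),
                              paste0("beta[", seq_len(ncol(X)), "]")),
              sigma_u = "sd_subject")
  monitor <- c("beta", "sigma_u")
  if (item_re) {
    monitor <- c(monitor, "sigma_v")
    rename <- c(rename, sigma_v = "sd_item")
  }
  fit <- run_jags(model_string, dat, monitor, rename = rename,
                  chains = chains, adapt = adapt, burn = burn,
                  iter = iter, thin = thin, seed = seed)
  fit$warnings <- c(extra_warnings, fit$warnings)
  fit$coding <- coding
  fit
}

#' Fit a Bayesian Gaussian regression to per-subject estimates
#'
#' Regresses one estimate per subject (x condition, for paired designs) on a
#' production dummy (silent = 0, aloud = 1), so the intercept is the silent
#' mean and the slope is the aloud-minus-silent difference. Within-subject
#' (paired) designs add a subject random intercept.
#'
#' @param estimates Numeric vector of per-subject estimates (e.g. DPSD
#'   recollection or familiarity).
#' @param production Character vector, `"aloud"`/`"silent"`, same length.
#' @param subject_id Subject labels; required when `paired = TRUE`.
#' @param paired Whether each subject contributes both conditions.
#' @param priors List: `beta_sd` (Normal prior SD on intercept/slope,
#'   default 2.5), `sigma_scale` (half-Normal scale on the residual and
#'   subject SDs, default 1).
#' @param chains,adapt,burn,iter,thin,seed Sampler settings as in
#'   [fit_multilevel_logistic()].
#'
#' @return A [posterior_draws] object with columns `b_intercept`,
#'   `b_production`, `sigma` (and `sd_subject` when paired).
#' @export
fit_gaussian_regression <- function(estimates, production, subject_id = NULL,
                                    paired = FALSE,
                                    priors = list(beta_sd = 2.5, sigma_scale = 1),
                                    chains = 4, adapt = 500, burn = 500,
                                    iter = 1000, thin = 1, seed = 1) {
  stopifnot(length(estimates) == length(production))
  if (!all(production %in% c("aloud", "silent")))
    stop("production must be 'aloud' or 'silent'", call. = FALSE)
  if (anyNA(estimates)) stop("estimates contain NA", call. = FALSE)
  if (min(table(production)) < 2)
    stop("need at least 2 subjects per production condition", call. = FALSE)
  if (paired && is.null(subject_id))
    stop("paired designs require subject_id", call. = FALSE)

  beta_sd <- priors$beta_sd %||% 2.5
  sigma_scale <- priors$sigma_scale %||% 1
  aloud <- as.numeric(production == "aloud")

  if (paired) {
    model_string <- gsub("%BSD%", format(beta_sd), gsub("%SS%", format(sigma_scale), "
model {
  for (i in 1:N) {
    y[i] ~ dnorm(b0 + b1 * x[i] + u[subj[i]], tau)
  }
  for (j in 1:J) { u[j] ~ dnorm(0, tau_u) }
  b0 ~ dnorm(0, pow(%BSD%, -2))
  b1 ~ dnorm(0, pow(%BSD%, -2))
  sigma ~ dnorm(0, pow(%SS%, -2)) T(1.0E-4,)
  tau <- pow(sigma, -2)
  sigma_u ~ dnorm(0, pow(%SS%, -2)) T(1.0E-4,)
  tau_u <- pow(sigma_u, -2)
}
"))
    dat <- list(N = length(estimates), y = estimates, x = aloud,
                subj = as.integer(factor(subject_id)),
                J = length(unique(subject_id)))
    monitor <- c("b0", "b1", "sigma", "sigma_u")
    rename <- c(b0 = "b_intercept", b1 = "b_production", sigma = "sigma",
                sigma_u = "sd_subject")
  } else {
    model_string <- gsub("%BSD%", format(beta_sd), gsub("%SS%", format(sigma_scale), "
model {
  for (i in 1:N) {
    y[i] ~ dnorm(b0 + b1 * x[i], tau)
  }
  b0 ~ dnorm(0, pow(%BSD%, -2))
  b1 ~ dnorm(0, pow(%BSD%, -2))
  sigma ~ dnorm(0, pow(%SS%, -2)) T(1.0E-4,)
  tau <- pow(sigma, -2)
}
"))
    dat <- list(N = length(estimates), y = estimates, x = aloud)
    monitor <- c("b0", "b1", "sigma")
    rename <- c(b0 = "b_intercept", b1 = "b_production", sigma = "sigma")
  }
  run_jags(model_string, dat, monitor, rename = rename, chains = chains,
           adapt = adapt, burn = burn, iter = iter, thin = thin, seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
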