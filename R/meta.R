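#' Probit-scale sensitivity from hit and false-alarm counts
#'
#' Converts remember-know-derived response counts into a conventional
#' probit d' = z(H) - z(FA), for feeding into the effect-size calculations.
#' Extreme rates (0 or 1) are pulled off the boundary by the 1/(2N)
#' convention before the probit transform, so 100 hits out of 100 becomes
#' 1 - 1/200 = 199/200 and 0 hits becomes 1/200.
#'
#' @param hits,n_old Hit count and number of old trials.
#' @param fas,n_new False-alarm count and number of new trials.
#' @return Numeric d'.
#' @export
#' @examples
#' rk_to_dprime(84, 100, 16, 100)
rk_to_dprime <- function(hits, n_old, fas, n_new) {
  if (n_old <= 0 || n_new <= 0) stop("zero trials", call. = FALSE)
  if (hits < 0 || hits > n_old || fas < 0 || fas > n_new)
    stop("counts must lie within their totals", call. = FALSE)
  rate <- function(x, n) {
    if (x == 0) 1 / (2 * n) else if (x == n) 1 - 1 / (2 * n) else x / n
  }
  qnorm(rate(hits, n_old)) - qnorm(rate(fas, n_new))
}

# Hedges' small-sample correction factor.
hedges_J <- function(df) 1 - 3 / (4 * df - 1)

#' Hedges' g for a between-subject comparison
#'
#' Bias-corrected standardized mean difference (group 1 minus group 2)
#' standardized by the pooled SD, with the standard large-sample sampling
#' variance.
#'
#' @param mean1,sd1,n1 Summary statistics for group 1 (e.g. aloud).
#' @param mean2,sd2,n2 Summary statistics for group 2 (e.g. silent).
#' @param study,measure Optional labels carried into the effects table.
#' @return An object of class `effect_size`: one-row `data.frame` with
#'   columns `study`, `design`, `measure`, `g`, `var_g`, `n`.
#' @export
#' @examples
#' hedges_g_between(1.1, 0.5, 22, 0.85, 0.5, 22)
hedges_g_between <- function(mean1, sd1, n1, mean2, sd2, n2,
                             study = NA_character_, measure = NA_character_) {
  stopifnot(sd1 > 0, sd2 > 0, n1 >= 2, n2 >= 2)
  df <- n1 + n2 - 2
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df)
  d <- (mean1 - mean2) / sp
  J <- hedges_J(df)
  g <- J * d
  var_g <- (n1 + n2) / (n1 * n2) + g^2 / (2 * (n1 + n2))
  structure(data.frame(study = study, design = "between", measure = measure,
                       g = g, var_g = var_g, n = n1 + n2),
            class = c("effect_size", "data.frame"))
}

#' Hedges' g for a within-subject comparison, raw-score metric
#'
#' Standardizes the mean paired difference by the pooled raw-score SD (not
#' by the SD of the difference scores), so within-subject effects are on the
#' same scale as between-subject effects; the two metrics differ by the
#' factor sqrt(2 (1 - r)). The sampling variance uses the repeated-measures
#' formula, which requires the cross-condition correlation `r`.
#'
#' @param mean_diff Mean of the paired differences (condition 1 - 2).
#' @param sd_raw_pooled Pooled SD of the raw scores.
#' @param r Correlation between the two conditions, in (-1, 1). When it is
#'   unknown and a default is imputed upstream, outputs are flagged.
#' @param n Number of pairs (subjects).
#' @param study,measure Optional labels.
#' @param r_imputed Mark `r` as imputed rather than observed; recorded in
#'   the output and surfaced as a warning.
#' @return An `effect_size` (see [hedges_g_between()]).
#' @export
#' @examples
#' hedges_g_within(0.14, 0.35, r = 0.5, n = 25)
hedges_g_within <- function(mean_diff, sd_raw_pooled, r, n,
                            study = NA_character_, measure = NA_character_,
                            r_imputed = FALSE) {
  stopifnot(sd_raw_pooled > 0, n >= 2)
  if (r <= -1 || r >= 1) stop("r must be in (-1, 1)", call. = FALSE)
  if (r_imputed)
    warning("within-subject correlation r was imputed, not observed; ",
            "variance of g depends on it", call. = FALSE)
  df <- n - 1
  d <- mean_diff / sd_raw_pooled
  J <- hedges_J(df)
  g <- J * d
  var_g <- (1 / n + g^2 / (2 * n)) * 2 * (1 - r)
  out <- data.frame(study = study, design = "within", measure = measure,
                    g = g, var_g = var_g, n = n)
  attr(out, "r") <- r
  attr(out, "r_imputed") <- r_imputed
  structure(out, class = c("effect_size", "data.frame"))
}

#' Bayesian random-effects meta-analysis with an optional design moderator
#'
#' Synthesizes standardized effects under the hierarchical model
#' `g_i ~ Normal(theta_i, v_i)`, `theta_i ~ Normal(mu + beta * within_i,
#' tau^2)`, where `within_i` is 1 for within-subject studies and 0 for
#' between-subject studies, so `beta` is the within-minus-between
#' difference. Priors: Normal(0, 1) on `mu` and `beta`, half-Cauchy(0.5)
#' on `tau`. Without the moderator the `beta` term is dropped.
#'
#' @param effects `data.frame` with columns `study`, `design`
#'   (`"within"`/`"between"`), `g`, `var_g` (e.g. rbind of
#'   [hedges_g_between()] / [hedges_g_within()] rows).
#' @param moderator Include study design as a moderator.
#' @param priors List: `mu_sd` (default 1), `tau_scale` (half-Cauchy scale,
#'   default 0.5).
#' @param chains,adapt,burn,iter,thin,seed Sampler settings.
#' @return An object of class `meta_result`: list with `draws`
#'   (a [posterior_draws] including `mu`, `tau`, `beta` if moderated, and
#'   shrunken per-study `theta_i`), `summary` table, `effects`, and
#'   `moderator`.
#' @export
fit_random_effects <- function(effects, moderator = FALSE,
                               priors = list(mu_sd = 1, tau_scale = 0.5),
                               chains = 4, adapt = 500, burn = 500,
                               iter = 1000, thin = 1, seed = 1) {
  stopifnot(all(c("study", "design", "g", "var_g") %in% names(effects)))
  if (any(effects$var_g <= 0)) stop("effect variances must be > 0", call. = FALSE)
  k <- nrow(effects)
  if (k < 3) stop("need at least 3 effects for a random-effects model",
                  call. = FALSE)
  if (!all(effects$design %in% c("within", "between")))
    stop("design must be 'within' or 'between'", call. = FALSE)
  if (moderator && length(unique(effects$design)) < 2)
    stop("moderator model requires both design levels", call. = FALSE)
  if (moderator && min(table(effects$design)) < 2)
    stop("moderator model requires at least 2 effects per design level",
         call. = FALSE)

  mu_sd <- priors$mu_sd %||% 1
  tau_scale <- priors$tau_scale %||% 0.5
  mod_term <- if (moderator) " + beta * x[i]" else ""
  mod_prior <- if (moderator) "\n  beta ~ dnorm(0, pow(%MSD%, -2))" else ""
  model_string <- gsub("%MSD%", format(mu_sd), gsub("%TS%", format(tau_scale), paste0("
model {
  for (i in 1:k) {
    g[i] ~ dnorm(theta[i], 1 / v[i])
    theta[i] ~ dnorm(mu", mod_term, ", tau_prec)
  }
  mu ~ dnorm(0, pow(%MSD%, -2))", mod_prior, "
  tau ~ dt(0, pow(%TS%, -2), 1) T(1.0E-4,)
  tau_prec <- pow(tau, -2)
}
")))
  dat <- list(k = k, g = effects$g, v = effects$var_g)
  if (moderator) dat$x <- as.numeric(effects$design == "within")
  monitor <- c("mu", "tau", "theta", if (moderator) "beta")
  rename <- c(mu = "mu", tau = "tau",
              stats::setNames(paste0("theta_", seq_len(k)),
                              paste0("theta[", seq_len(k), "]")))
  if (moderator) rename <- c(rename, beta = "beta")
  fit <- run_jags(model_string, dat, monitor, rename = rename,
                  chains = chains, adapt = adapt, burn = burn, iter = iter,
                  thin = thin, seed = seed)
  m <- fit$draws
  core <- c("mu", if (moderator) "beta", "tau")
  summaries <- lapply(core, function(nm) posterior_summary(m[, nm]))
  tab <- do.call(rbind, Map(summary_row, core, summaries))
  structure(
    list(draws = fit, summary = tab, effects = effects, moderator = moderator),
    class = "meta_result"
  )
}

#' @export
print.meta_result <- function(x, digits = 3, ...) {
  cat(sprintf("Bayesian random-effects meta-analysis (%d studies%s)\n",
              nrow(x$effects),
              if (x$moderator) ", design moderator" else ""))
  print(x$summary, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Heterogeneity explained by the moderator
#'
#' Fraction of between-study heterogeneity accounted for by the design
#' moderator, computed from the posterior medians of tau as
#' `(tau_basic - tau_moderated) / tau_basic`. A full-posterior version
#' (the same ratio evaluated on paired draws) is also returned.
#'
#' @param basic `meta_result` from the model without the moderator.
#' @param moderated `meta_result` from the model with the moderator.
#' @return List with `from_medians` (scalar), `tau_basic`, `tau_moderated`
#'   (posterior medians), and `posterior` (a `posterior_summary` of the
#'   per-draw ratio).
#' @export
variance_explained <- function(basic, moderated) {
  stopifnot(inherits(basic, "meta_result"), inherits(moderated, "meta_result"))
  tb <- basic$draws$draws[, "tau"]
  tm <- moderated$draws$draws[, "tau"]
  tb_med <- stats::median(tb)
  tm_med <- stats::median(tm)
  if (tb_med <= 0) stop("basic-model tau median is not positive", call. = FALSE)
  n <- min(length(tb), length(tm))
  list(from_medians = (tb_med - tm_med) / tb_med,
       tau_basic = tb_med, tau_moderated = tm_med,
       posterior = posterior_summary((tb[1:n] - tm[1:n]) / tb[1:n]))
}

#' Forest-plot data for a fitted meta-analysis
#'
#' Plot-ready rows: one per study (raw g with a 95% large-sample CI and the
#' model's shrunken estimate with HDIs) and pooled rows (the overall mean,
#' plus per-design means when the model includes the moderator).
#'
#' @param result A `meta_result`.
#' @return `data.frame` with columns `row_type` (`"study"`/`"pooled"`),
#'   `study`, `design`, `g`, `ci_lo`, `ci_hi`, `shrunken`, `shrunken_lo`,
#'   `shrunken_hi`.
#' @export
forest_data <- function(result) {
  stopifnot(inherits(result, "meta_result"))
  eff <- result$effects
  m <- result$draws$draws
  k <- nrow(eff)
  study_rows <- do.call(rbind, lapply(seq_len(k), function(i) {
    th <- m[, paste0("theta_", i)]
    h <- hdi(th, 0.95)
    data.frame(row_type = "study", study = eff$study[i], design = eff$design[i],
               g = eff$g[i],
               ci_lo = eff$g[i] - 1.96 * sqrt(eff$var_g[i]),
               ci_hi = eff$g[i] + 1.96 * sqrt(eff$var_g[i]),
               shrunken = stats::median(th), shrunken_lo = h[1], shrunken_hi = h[2],
               row.names = NULL)
  }))
  pooled_quantities <- if (result$moderator) {
    list(pooled_between = m[, "mu"], pooled_within = m[, "mu"] + m[, "beta"])
  } else {
    list(pooled = m[, "mu"])
  }
  pooled_rows <- do.call(rbind, Map(function(nm, dr) {
    h <- hdi(dr, 0.95)
    data.frame(row_type = "pooled", study = nm,
               design = sub("pooled_?", "", nm),
               g = stats::median(dr), ci_lo = h[1], ci_hi = h[2],
               shrunken = stats::median(dr), shrunken_lo = h[1], shrunken_hi = h[2],
               row.names = NULL)
  }, names(pooled_quantities), pooled_quantities))
  rbind(study_rows, pooled_rows)
}
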