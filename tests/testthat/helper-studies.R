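# Simulation studies shared by the acceptance checks: each generates data
# at a stated scale, runs the package end to end, and returns the measured
# quantity. Kept here (in code, at test time) so every number is recomputed.

# Printed logistic coefficients of the three between-subject models that are
# reproducible by exact point arithmetic, with the condition-level metrics
# they imply.
published_coefficient_sets <- function() {
  list(
    exp1b_old = list(
      coef = c(b_intercept = -0.60, b_production = -0.15,
               b_item_type = 1.79, b_interaction = 0.56),
      C_L_aloud = -0.75, d_L_aloud = 2.35),
    exp1b_remember = list(
      coef = c(b_intercept = -2.36, b_production = -0.34,
               b_item_type = 2.70, b_interaction = 0.35),
      C_L_aloud = -2.70, d_L_aloud = 3.05),
    exp1b_know = list(
      coef = c(b_intercept = -1.11, b_production = -0.04,
               b_item_type = 1.25, b_interaction = 0.68),
      C_L_aloud = -1.15, d_L_aloud = NA),
    exp2b_old = list(
      coef = c(b_intercept = -0.17, b_production = -0.38,
               b_item_type = 1.85, b_interaction = 0.43),
      C_L_aloud = -0.55, d_L_aloud = 2.28),
    exp3_old = list(
      coef = c(b_intercept = -0.38, b_production = -0.03,
               b_item_type = 2.59, b_interaction = 0.40),
      C_L_aloud = -0.41, d_L_aloud = NA)
  )
}

# A meta_result-shaped object whose tau posterior is a point mass, for
# exercising the variance-explained formula on stated tau values.
const_tau_meta <- function(tau, n = 200) {
  structure(list(
    draws = structure(list(draws = cbind(mu = rep(0, n), tau = rep(tau, n)),
                           n_chains = 1, diagnostics = NULL,
                           warnings = character()),
                      class = "posterior_draws"),
    summary = NULL, effects = NULL, moderator = FALSE),
    class = "meta_result")
}

# Noise-free DPSD identifiability over the parameter grid; returns the
# worst-case absolute errors.
dpsd_grid_errors <- function(R_grid = c(0, 0.2, 0.5, 0.8),
                             d_grid = c(0, 0.5, 1, 2),
                             criteria = c(-1, -0.5, 0, 0.5, 1),
                             n = 1e6, seed = 1) {
  base <- generative_params(0, 0, 0, 0, criteria = criteria)
  p_new <- population_response_probabilities(base, "foil")
  err_R <- 0
  err_d <- 0
  for (R in R_grid) {
    for (d in d_grid) {
      pars <- generative_params(R, R, d, d, criteria = criteria)
      p_old <- population_response_probabilities(pars, "studied", "aloud")
      fit <- fit_dpsd(p_old * n, p_new * n, seed = seed)
      err_R <- max(err_R, abs(fit$R - R))
      err_d <- max(err_d, abs(fit$dprime - d))
    }
  }
  c(R = err_R, dprime = err_d)
}

# Independence familiarity estimator recovery: simulate remember-know
# trials at known parameters and measure how far the aggregated estimator
# lands from the generative know-given-not-recollected probability.
independence_recovery_error <- function(n_trials = 1e4, seed = 1) {
  R <- 0.4
  d <- 1
  cr <- 1 - qnorm(0.35)          # pnorm(d - cr) = .35
  target <- pnorm(d - cr)
  per_subj <- 100
  des <- experiment_design("within", "remember_know",
                           n_subjects = n_trials / (2 * per_subj),
                           n_aloud = per_subj, n_silent = per_subj,
                           n_foil = 1)
  pars <- generative_params(R, R, d, d, criteria = cr)
  tr <- simulate_experiment(des, pars, seed = seed)
  est <- independence_familiarity(tr[tr$item_type == "studied", ])
  max(abs(est$familiarity - target))
}

# HDI-95 calibration of the multilevel logistic fixed effects: data are
# generated directly from the fitted model family (known slopes, Normal
# subject intercepts), so coverage of the truth is well defined. Returns
# the fraction of (replicate x fixed effect) checks whose HDI-95 contains
# the generating value.
logistic_coverage_study <- function(n_rep = 200, n_subj = 15,
                                    trials_per_cond = 40, seed = 1) {
  truth <- c(b_intercept = -1.5, b_silent = 1.6, b_aloud = 2.2)
  set.seed(seed)
  rep_seeds <- sample.int(2^30, n_rep)
  covered <- 0
  total <- 0
  for (r in seq_len(n_rep)) {
    set.seed(rep_seeds[r])
    rows <- list()
    for (s in seq_len(n_subj)) {
      u <- rnorm(1, 0, 0.5)
      for (cond in c("foil", "silent", "aloud")) {
        eta <- truth["b_intercept"] +
          ifelse(cond == "foil", 0, truth[paste0("b_", cond)]) + u
        rows[[length(rows) + 1]] <- data.frame(
          subject_id = sprintf("s%02d", s), group = "within",
          item_id = NA_character_,
          item_type = if (cond == "foil") "foil" else "studied",
          production = if (cond == "foil") "none" else cond,
          y = rbinom(trials_per_cond, 1, plogis(eta)))
      }
    }
    fit <- fit_multilevel_logistic(do.call(rbind, rows),
                                   "dummy_foil_intercept", item_re = FALSE,
                                   chains = 2, adapt = 300, burn = 300,
                                   iter = 500, seed = rep_seeds[r] %% 99991L)
    for (nm in names(truth)) {
      h <- hdi(fit$draws[, nm], 0.95)
      covered <- covered + (h[1] <= truth[nm] && truth[nm] <= h[2])
      total <- total + 1
    }
  }
  covered / total
}

# End-to-end dissociation study. Between design: equal recollection, higher
# aloud familiarity; a replicate "dissociates" when the know-model (after
# exclusion) sensitivity contrast is credible while the remember-model
# contrast is not. Within design: production boosts both processes; a
# replicate succeeds when both contrasts are credible.
dissociation_study <- function(n_rep = 5, seed = 1) {
  set.seed(seed)
  rep_seeds <- sample.int(2^30, 2 * n_rep)
  fit_fast <- function(trials, coding, seed) {
    suppressWarnings(fit_multilevel_logistic(
      trials, coding = coding, item_re = FALSE, chains = 2, adapt = 300,
      burn = 300, iter = 600, seed = seed))
  }
  excludes0 <- function(draws) {
    h <- hdi(draws, 0.95)
    h[1] > 0 || h[2] < 0
  }

  between_ok <- 0
  fam_credible <- 0
  rec_credible <- 0
  des_b <- experiment_design("between", "remember_know", n_subjects = 18,
                             n_aloud = 120, n_silent = 120, n_foil = 120)
  pars_b <- generative_params(0.3, 0.3, 1.35, 0.85, criteria = 0.5,
                              subject_sd_R = 0.4, subject_sd_d = 0.25)
  for (r in seq_len(n_rep)) {
    tr <- simulate_experiment(des_b, pars_b, seed = rep_seeds[r])
    rem <- fit_fast(rk_outcome(tr, "remember"), "centered_itemtype",
                    rep_seeds[r] %% 99991L)
    know <- fit_fast(suppressWarnings(rk_outcome(tr, "know_after_exclusion")),
                     "centered_itemtype", rep_seeds[r] %% 99991L + 1L)
    fam_cred <- excludes0(know$draws[, "b_interaction"])
    # foils draw no remember responses under the generative model (pure
    # threshold recollection), so the remember model's foil cells are
    # separated and its d'_L contrast is prior-dominated; the recollection
    # contrast is therefore evaluated on the studied items' remember rates
    # (aloud - silent on the logit scale, per draw)
    rec_cred <- excludes0(rem$draws[, "b_production"] +
                            0.5 * rem$draws[, "b_interaction"])
    fam_credible <- fam_credible + fam_cred
    rec_credible <- rec_credible + rec_cred
    if (fam_cred && !rec_cred) between_ok <- between_ok + 1
  }

  within_ok <- 0
  des_w <- experiment_design("within", "remember_know", n_subjects = 25,
                             n_aloud = 60, n_silent = 60, n_foil = 120)
  pars_w <- generative_params(0.4, 0.25, 1.35, 0.85, criteria = 0.5,
                              subject_sd_R = 0.4, subject_sd_d = 0.25)
  for (r in seq_len(n_rep)) {
    tr <- simulate_experiment(des_w, pars_w, seed = rep_seeds[n_rep + r])
    rem <- fit_fast(rk_outcome(tr, "remember"), "dummy_foil_intercept",
                    rep_seeds[n_rep + r] %% 99991L)
    know <- fit_fast(suppressWarnings(rk_outcome(tr, "know_after_exclusion")),
                     "dummy_foil_intercept", rep_seeds[n_rep + r] %% 99991L + 1L)
    rec_cred <- excludes0(rem$draws[, "b_aloud"] - rem$draws[, "b_silent"])
    fam_cred <- excludes0(know$draws[, "b_aloud"] - know$draws[, "b_silent"])
    if (rec_cred && fam_cred) within_ok <- within_ok + 1
  }

  list(between_dissociation = between_ok / n_rep,
       between_familiarity_credible = fam_credible / n_rep,
       between_recollection_credible = rec_credible / n_rep,
       within_both_credible = within_ok / n_rep,
       n_rep = n_rep)
}

# Meta-analytic recovery: simulated 12-study datasets with a design
# moderator; per parameter, the fraction of replicates whose posterior
# median lies within 2 posterior SDs of the generating value.
meta_recovery_study <- function(n_rep = 20, k = 12, mu = 0.2, beta = 0.7,
                                tau = 0.2, seed = 1) {
  set.seed(seed)
  rep_seeds <- sample.int(2^30, n_rep)
  truth <- c(mu = mu, beta = beta, tau = tau)
  hits <- c(mu = 0, beta = 0, tau = 0)
  for (r in seq_len(n_rep)) {
    set.seed(rep_seeds[r])
    design <- rep(c("within", "between"), length.out = k)
    v <- runif(k, 0.03, 0.12)
    theta <- rnorm(k, mu + beta * (design == "within"), tau)
    eff <- data.frame(study = sprintf("study%02d", 1:k), design = design,
                      g = rnorm(k, theta, sqrt(v)), var_g = v, n = 40)
    fit <- fit_random_effects(eff, moderator = TRUE, chains = 2, adapt = 300,
                              burn = 300, iter = 600,
                              seed = rep_seeds[r] %% 99991L)
    for (nm in names(truth)) {
      dr <- fit$draws$draws[, nm]
      if (abs(median(dr) - truth[nm]) <= 2 * stats::sd(dr))
        hits[nm] <- hits[nm] + 1
    }
  }
  hits / n_rep
}
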