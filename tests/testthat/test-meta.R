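test_that("remember-know counts convert to probit d' with edge correction", {
  expect_equal(rk_to_dprime(50, 100, 50, 100), 0)
  expect_equal(rk_to_dprime(84, 100, 16, 100), 2 * qnorm(0.84), tolerance = 1e-10)
  expect_equal(2 * qnorm(0.84), 1.98892, tolerance = 1e-4)

  # perfect hit rate corrected to 100.5/101 = 199/200 before the probit
  expect_equal(rk_to_dprime(100, 100, 16, 100),
               qnorm(199 / 200) - qnorm(0.16))
  expect_equal(rk_to_dprime(0, 50, 0, 50), 0)

  expect_error(rk_to_dprime(5, 0, 1, 10), "zero trials")
  expect_error(rk_to_dprime(12, 10, 1, 10), "within their totals")
})

test_that("between-subject Hedges' g matches its closed form", {
  expect_equal(hedges_g_between(0.5, 0.3, 20, 0.5, 0.4, 25)$g, 0)

  # difference of one pooled SD at large n: g ~ J(1998)
  big <- hedges_g_between(1, 1, 1000, 0, 1, 1000)
  expect_equal(big$g, 1 - 3 / (4 * 1998 - 1), tolerance = 1e-12)
  expect_equal(big$g, 0.99962, tolerance = 1e-4)

  # sampling variance at g = 0 is exactly 1/n1 + 1/n2
  v0 <- hedges_g_between(0.2, 0.5, 20, 0.2, 0.5, 20)$var_g
  expect_equal(v0, 0.1, tolerance = 1e-12)
})

test_that("within-subject g uses the raw-score metric", {
  expect_equal(hedges_g_within(0, 0.4, r = 0.3, n = 20)$g, 0)
  expect_equal(hedges_g_within(0, 0.4, r = 0.8, n = 20)$g, 0)

  # raw-score vs difference-score standardization differ by sqrt(2(1 - r))
  r <- 0.5
  sd_raw <- 0.4
  mean_diff <- 0.14
  sd_diff <- sd_raw * sqrt(2 * (1 - r))
  g_raw <- hedges_g_within(mean_diff, sd_raw, r = r, n = 25)$g
  J <- 1 - 3 / (4 * 24 - 1)
  g_diff_metric <- J * mean_diff / sd_diff
  expect_equal(g_raw / g_diff_metric, sqrt(2 * (1 - r)), tolerance = 1e-12)

  # variance decreases monotonically in r
  rs <- seq(-0.5, 0.9, by = 0.2)
  vars <- vapply(rs, function(r) hedges_g_within(0.14, 0.4, r, 25)$var_g,
                 numeric(1))
  expect_true(all(diff(vars) < 0))

  expect_warning(hedges_g_within(0.14, 0.4, r = 0.5, n = 25, r_imputed = TRUE),
                 "imputed")
  expect_error(hedges_g_within(0.1, 0.4, r = 1, n = 25), "r must be")
})

test_that("within and between designs give comparable g for the same population effect", {
  # population: silent mean .68, aloud mean .93, raw SD .4, correlation .5
  set.seed(70)
  gw <- replicate(200, {
    base <- rnorm(25, 0, 0.4)
    silent <- 0.68 + base * sqrt(0.5) + rnorm(25, 0, 0.4 * sqrt(0.5))
    aloud <- 0.93 + base * sqrt(0.5) + rnorm(25, 0, 0.4 * sqrt(0.5))
    hedges_g_within(mean(aloud - silent),
                    sqrt((var(aloud) + var(silent)) / 2),
                    r = cor(aloud, silent), n = 25)$g
  })
  gb <- replicate(200, {
    silent <- rnorm(25, 0.68, 0.4)
    aloud <- rnorm(25, 0.93, 0.4)
    hedges_g_between(mean(aloud), sd(aloud), 25, mean(silent), sd(silent), 25)$g
  })
  expect_lt(abs(mean(gw) - mean(gb)), 0.05)
})

sim_meta_effects <- function(k = 12, mu = 0.2, beta = 0.7, tau = 0.2,
                             v_range = c(0.03, 0.12)) {
  design <- rep(c("within", "between"), length.out = k)
  v <- runif(k, v_range[1], v_range[2])
  theta <- rnorm(k, mu + beta * (design == "within"), tau)
  data.frame(study = sprintf("study%02d", 1:k), design = design,
             measure = "recollection", g = rnorm(k, theta, sqrt(v)),
             var_g = v, n = 40)
}

test_that("random-effects model concentrates on a common effect when effects agree", {
  eff <- data.frame(study = paste0("s", 1:6), design = "between",
                    g = rep(0.31, 6), var_g = rep(1e-4, 6), n = 40)
  fit <- fit_random_effects(eff, chains = 2, adapt = 300, burn = 300,
                            iter = 800, seed = 1)
  expect_equal(fit$summary$median[fit$summary$quantity == "mu"], 0.31,
               tolerance = 0.02)
  expect_lt(fit$summary$median[fit$summary$quantity == "tau"], 0.1)
})

test_that("moderated model recovers the design effect at the study-count scale", {
  # with 12 studies the posterior for beta is wide, so calibrate against
  # its own posterior SD per replicate and require the mean across
  # replicates to centre on the truth
  set.seed(71)
  ok <- 0
  medians <- numeric(5)
  for (r in 1:5) {
    eff <- sim_meta_effects()
    fit <- fit_random_effects(eff, moderator = TRUE, chains = 2, adapt = 300,
                              burn = 300, iter = 800, seed = 100 + r)
    b <- fit$summary$median[fit$summary$quantity == "beta"]
    b_sd <- stats::sd(fit$draws$draws[, "beta"])
    medians[r] <- b
    if (abs(b - 0.7) < 2 * b_sd) ok <- ok + 1
  }
  expect_gte(ok, 4)
  expect_lt(abs(mean(medians) - 0.7), 0.3)
})

test_that("meta-analysis matches an independent REML fit on the same effects", {
  skip_if_not_installed("metafor")
  set.seed(72)
  eff <- sim_meta_effects(k = 14, mu = 0.3, beta = 0.5, tau = 0.25)
  bayes <- fit_random_effects(eff, moderator = TRUE, chains = 2, adapt = 500,
                              burn = 500, iter = 1500, seed = 3)
  freq <- metafor::rma(yi = eff$g, vi = eff$var_g,
                       mods = ~ I(design == "within"), data = eff)
  b_mu <- bayes$summary$median[bayes$summary$quantity == "mu"]
  b_beta <- bayes$summary$median[bayes$summary$quantity == "beta"]
  expect_equal(b_mu, unname(freq$beta[1]), tolerance = 0.1)
  expect_equal(b_beta, unname(freq$beta[2]), tolerance = 0.15)
  b_tau <- bayes$summary$median[bayes$summary$quantity == "tau"]
  expect_equal(b_tau, sqrt(freq$tau2), tolerance = 0.2)
})

test_that("model contracts reject malformed inputs", {
  eff <- sim_meta_effects(k = 4)
  expect_error(fit_random_effects(eff[1:2, ]), "at least 3")
  eff_one_design <- eff
  eff_one_design$design <- "between"
  expect_error(fit_random_effects(eff_one_design, moderator = TRUE),
               "both design levels")
  eff_bad <- eff
  eff_bad$var_g[1] <- 0
  expect_error(fit_random_effects(eff_bad), "variances")
})

test_that("variance explained follows the tau-median formula", {
  set.seed(73)
  eff <- sim_meta_effects(k = 12, mu = 0.1, beta = 0.8, tau = 0.25)
  basic <- fit_random_effects(eff, chains = 2, adapt = 300, burn = 300,
                              iter = 800, seed = 5)
  moderated <- fit_random_effects(eff, moderator = TRUE, chains = 2,
                                  adapt = 300, burn = 300, iter = 800, seed = 6)
  ve <- variance_explained(basic, moderated)
  expect_equal(ve$from_medians,
               (ve$tau_basic - ve$tau_moderated) / ve$tau_basic)
  expect_equal(ve$tau_basic,
               median(basic$draws$draws[, "tau"]))
  # the moderator soaks up heterogeneity here
  expect_gt(ve$from_medians, 0)
})

test_that("forest rows shrink toward the pooled mean and round-trip CSV", {
  set.seed(74)
  eff <- sim_meta_effects(k = 8, mu = 0.2, beta = 0, tau = 0.15)
  fit <- fit_random_effects(eff, chains = 2, adapt = 300, burn = 300,
                            iter = 1000, seed = 7)
  fd <- forest_data(fit)
  expect_equal(sum(fd$row_type == "study"), 8)
  expect_equal(sum(fd$row_type == "pooled"), 1)
  pooled <- fd$g[fd$row_type == "pooled"]
  studies <- fd[fd$row_type == "study", ]
  # partial pooling: shrunken estimate lies weakly between raw g and mu
  tol <- 0.02
  between <- (studies$shrunken >= pmin(studies$g, pooled) - tol) &
    (studies$shrunken <= pmax(studies$g, pooled) + tol)
  expect_true(all(between))

  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(fd, path, row.names = FALSE)
  back <- utils::read.csv(path, stringsAsFactors = FALSE)
  expect_equal(back$shrunken, fd$shrunken, tolerance = 1e-12)
  expect_equal(back$study, fd$study)
})
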