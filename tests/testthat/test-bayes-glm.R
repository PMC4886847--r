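test_that("hdi returns the shortest interval with the stated mass", {
  expect_equal(unname(hdi(rep(3.7, 200), 0.95)), c(3.7, 3.7))

  set.seed(1)
  u <- runif(1e5)
  h <- hdi(u, 0.5)
  expect_equal(unname(h[2] - h[1]), 0.5, tolerance = 0.02)

  set.seed(2)
  z <- rnorm(1e6)
  h95 <- hdi(z, 0.95)
  expect_equal(unname(h95), c(-1.959964, 1.959964), tolerance = 0.02)

  expect_error(hdi(rnorm(50), 0.95), "at least 100")
  expect_error(hdi(rnorm(200), 1.2), "mass")
})

test_that("HDI intervals nest and contain the median for unimodal samples", {
  # nesting of contiguous shortest intervals is guaranteed for the
  # unimodal posteriors these summaries are applied to
  set.seed(3)
  samples <- list(rnorm(5000), rexp(5000), rlnorm(5000),
                  rbeta(5000, 5, 2))
  for (x in samples) {
    s <- posterior_summary(x)
    expect_lte(s$hdi95[1], s$hdi50[1])
    expect_gte(s$hdi95[2], s$hdi50[2])
    expect_gte(s$median, s$hdi95[1])
    expect_lte(s$median, s$hdi95[2])
  }
})

test_that("contrast transforms per draw, never summarize-then-transform", {
  set.seed(4)
  m <- cbind(a = rnorm(2000, 1), b = rnorm(2000, 1))

  # identity transform matches the raw parameter summary
  s1 <- contrast(m, "a")
  s2 <- posterior_summary(m[, "a"])
  expect_equal(s1$median, s2$median)
  expect_equal(s1$hdi95, s2$hdi95)

  # difference of a parameter with itself is a point mass at 0
  s3 <- contrast(m, function(d) d["a"] - d["a"])
  expect_equal(s3$median, 0)
  expect_equal(unname(s3$hdi95), c(0, 0))

  # recomputation oracle: inverse-logit difference per draw
  s4 <- contrast(m, function(d) plogis(d["a"]) - plogis(d["b"]))
  oracle <- plogis(m[, "a"]) - plogis(m[, "b"])
  expect_identical(attr(s4, "draws"), unname(oracle))
  expect_equal(s4$median, median(oracle))

  suppressWarnings(
    expect_error(contrast(m, function(d) log(d["a"] - 10)), "non-finite"))
  expect_error(contrast(m, "zzz"), "unknown parameter")
})

test_that("multilevel logistic recovers known slopes from simulated trials", {
  # dummy-coded within design with true slopes 1.6 and 2.2 on the logit scale
  set.seed(10)
  n_subj <- 25
  b <- c(intercept = -1.5, silent = 1.6, aloud = 2.2)
  rows <- list()
  for (s in seq_len(n_subj)) {
    u <- rnorm(1, 0, 0.5)
    for (cond in c("foil", "silent", "aloud")) {
      eta <- b["intercept"] + ifelse(cond == "foil", 0, b[cond]) + u
      n_tr <- if (cond == "foil") 120 else 60
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = sprintf("s%02d", s), group = "within",
        item_id = NA_character_,
        item_type = if (cond == "foil") "foil" else "studied",
        production = if (cond == "foil") "none" else cond,
        y = rbinom(n_tr, 1, plogis(eta)))
    }
  }
  trials <- do.call(rbind, rows)
  fit <- fit_logistic_fast(trials, "dummy_foil_intercept", seed = 1)
  med <- apply(fit$draws, 2, median)
  expect_lt(abs(med["b_silent"] - 1.6), 0.25)
  expect_lt(abs(med["b_aloud"] - 2.2), 0.25)
  expect_lt(abs(med["b_intercept"] + 1.5), 0.25)

  # determinism: same seed, same data, same settings => identical draws
  fit2 <- fit_logistic_fast(trials, "dummy_foil_intercept", seed = 1)
  expect_identical(fit$draws, fit2$draws)
})

test_that("degenerate logistic inputs follow their contracts", {
  des <- experiment_design("within", "remember_know", n_subjects = 1,
                           n_aloud = 20, n_silent = 20, n_foil = 40)
  tr <- collapse_rk_to_old(simulate_experiment(des, make_rk_params(), seed = 2))
  expect_warning(
    fit_multilevel_logistic(tr, "dummy_foil_intercept", item_re = FALSE,
                            chains = 2, adapt = 200, burn = 100, iter = 200,
                            seed = 1),
    "single-subject")

  tr_all1 <- tr
  tr_all1$y <- 1L
  expect_error(fit_multilevel_logistic(tr_all1, "dummy_foil_intercept"),
               "outcome class is empty")

  tr_no_y <- tr[, setdiff(names(tr), "y")]
  expect_error(fit_multilevel_logistic(tr_no_y, "dummy_foil_intercept"),
               "outcome column")

  suppressWarnings(
    expect_error(fit_multilevel_logistic(tr, "centered_itemtype"),
                 "between-subject"))
})

test_that("dummy and centered codings agree on fitted cell probabilities", {
  des <- experiment_design("between", "remember_know", n_subjects = 15,
                           n_aloud = 60, n_silent = 60, n_foil = 60)
  p <- make_rk_params(R_aloud = 0.25, R_silent = 0.25, d_aloud = 1.3,
                      d_silent = 0.8, subject_sd_R = 0.3, subject_sd_d = 0.2)
  tr <- collapse_rk_to_old(simulate_experiment(des, p, seed = 8))

  cen <- fit_logistic_fast(tr, "centered_itemtype", seed = 3)
  dum <- fit_logistic_fast(tr, "dummy_foil_intercept", seed = 3)

  m <- cen$draws
  p_cen_silent <- median(plogis(m[, "b_intercept"] + 0.5 * m[, "b_item_type"]))
  p_cen_aloud <- median(plogis(rowSums(m[, c("b_intercept", "b_production")]) +
                                 0.5 * (m[, "b_item_type"] + m[, "b_interaction"])))
  d <- dum$draws
  p_dum_silent <- median(plogis(d[, "b_intercept"] + d[, "b_silent"]))
  p_dum_aloud <- median(plogis(d[, "b_intercept"] + d[, "b_aloud"]))
  expect_equal(p_cen_silent, p_dum_silent, tolerance = 0.03)
  expect_equal(p_cen_aloud, p_dum_aloud, tolerance = 0.03)
})

test_that("Gaussian regression recovers condition means and differences", {
  # constant data pins both coefficients
  fit_const <- fit_gaussian_regression(rep(0.4, 20),
                                       rep(c("silent", "aloud"), each = 10),
                                       chains = 2, adapt = 200, burn = 200,
                                       iter = 400, seed = 1)
  med <- apply(fit_const$draws, 2, median)
  expect_equal(unname(med["b_intercept"]), 0.4, tolerance = 0.02)
  expect_equal(unname(med["b_production"]), 0, tolerance = 0.02)

  # between-subject recovery at a study-sized n
  set.seed(20)
  reps <- replicate(5, {
    y <- c(rnorm(22, 0.68, 0.4), rnorm(22, 0.93, 0.4))
    prod <- rep(c("silent", "aloud"), each = 22)
    f <- fit_gaussian_regression(y, prod, chains = 2, adapt = 200,
                                 burn = 200, iter = 500,
                                 seed = sample.int(1e6, 1))
    median(f$draws[, "b_production"])
  })
  expect_lt(max(abs(reps - 0.25)), 0.4)   # no wild misses
  expect_lt(abs(mean(reps) - 0.25), 0.15) # unbiased across seeds

  # paired design detects a small within-subject difference
  set.seed(21)
  hits <- 0
  for (r in 1:5) {
    subj <- rep(sprintf("s%02d", 1:25), times = 2)
    base <- rnorm(25, 0.5, 0.2)
    y <- c(base + rnorm(25, 0, 0.1), base + 0.14 + rnorm(25, 0, 0.1))
    prod <- rep(c("silent", "aloud"), each = 25)
    f <- fit_gaussian_regression(y, prod, subject_id = subj, paired = TRUE,
                                 chains = 2, adapt = 300, burn = 300,
                                 iter = 600, seed = 100 + r)
    h <- hdi(f$draws[, "b_production"], 0.95)
    if (h[1] > 0) hits <- hits + 1
  }
  expect_gte(hits, 3)

  expect_error(fit_gaussian_regression(c(1, 2, 3), c("aloud", "aloud", "silent")),
               "at least 2 subjects")
  expect_error(fit_gaussian_regression(1:4 / 4, rep(c("aloud", "silent"), 2),
                                       paired = TRUE), "subject_id")
})

test_that("posterior HDIs achieve near-nominal coverage for a fixed effect", {
  # moderate replicate count here; the full calibration run lives in the
  # acceptance suite
  set.seed(30)
  n_subj <- 12
  covered <- 0
  n_rep <- 30
  for (r in seq_len(n_rep)) {
    rows <- list()
    for (s in seq_len(n_subj)) {
      u <- rnorm(1, 0, 0.4)
      for (cond in c("foil", "silent", "aloud")) {
        eta <- -1 + ifelse(cond == "silent", 1.2, ifelse(cond == "aloud", 1.8, 0)) + u
        rows[[length(rows) + 1]] <- data.frame(
          subject_id = sprintf("s%02d", s), group = "within",
          item_id = NA_character_,
          item_type = if (cond == "foil") "foil" else "studied",
          production = if (cond == "foil") "none" else cond,
          y = rbinom(40, 1, plogis(eta)))
      }
    }
    fit <- fit_multilevel_logistic(do.call(rbind, rows), "dummy_foil_intercept",
                                   item_re = FALSE, chains = 2, adapt = 200,
                                   burn = 200, iter = 500, seed = 1000 + r)
    h <- hdi(fit$draws[, "b_silent"], 0.95)
    if (h[1] <= 1.2 && 1.2 <= h[2]) covered <- covered + 1
  }
  expect_gte(covered / n_rep, 0.8)
})
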