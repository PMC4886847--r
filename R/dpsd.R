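#' Empirical ROC from 6-point confidence ratings
#'
#' Builds the receiver operating characteristic for one subject and
#' condition by sweeping the confidence criterion from strict to liberal:
#' point j pairs the false-alarm rate P(rating >= 7 - j | new) with the hit
#' rate P(rating >= 7 - j | old), for j = 1..5.
#'
#' @param trials Confidence-rating trials for a single subject and
#'   condition (foils plus one class of studied items), or `NULL` when
#'   `old_counts`/`new_counts` are given directly.
#' @param old_counts,new_counts Optional integer vectors of length 6:
#'   response counts per rating category (1..6) for old and new items.
#'
#' @return An object of class `roc_data`: list with `hits` and `fas`
#'   (cumulative rates, length 5), `old_counts`, `new_counts`.
#' @export
empirical_roc <- function(trials = NULL, old_counts = NULL, new_counts = NULL) {
  if (!is.null(trials)) {
    r <- suppressWarnings(as.integer(as.character(trials$response)))
    if (anyNA(r) || any(!r %in% 1:6))
      stop("confidence responses must be integers 1-6", call. = FALSE)
    old <- r[trials$item_type == "studied"]
    new <- r[trials$item_type == "foil"]
    if (length(old) == 0 || length(new) == 0)
      stop("need at least one old and one new trial", call. = FALSE)
    old_counts <- tabulate(old, nbins = 6)
    new_counts <- tabulate(new, nbins = 6)
  }
  stopifnot(length(old_counts) == 6, length(new_counts) == 6,
            all(old_counts >= 0), all(new_counts >= 0))
  if (sum(old_counts) == 0 || sum(new_counts) == 0)
    stop("need at least one old and one new trial", call. = FALSE)
  cum_hi <- function(x) rev(cumsum(rev(x)))[6:2] / sum(x)  # P(rating >= j), j=6..2
  structure(
    list(hits = unname(cum_hi(old_counts)), fas = unname(cum_hi(new_counts)),
         old_counts = as.numeric(old_counts), new_counts = as.numeric(new_counts)),
    class = "roc_data"
  )
}

#' @export
print.roc_data <- function(x, digits = 3, ...) {
  cat("ROC (strict -> liberal):\n")
  print(data.frame(fa = x$fas, hit = x$hits), digits = digits, row.names = FALSE)
  invisible(x)
}

#' Predicted DPSD ROC
#'
#' Cumulative hit and false-alarm rates implied by the dual-process
#' signal-detection model at given parameters:
#' `hits_j = R + (1 - R) * pnorm(dprime - c_j)` and
#' `fas_j = pnorm(-c_j)`, ordered from the strictest criterion (c_5) to the
#' most liberal (c_1) to match [empirical_roc()].
#'
#' @param R Recollection probability in \[0, 1\].
#' @param dprime Familiarity sensitivity.
#' @param criteria Strictly increasing numeric vector of length 5.
#' @return List with `hits` and `fas` (length 5, strict to liberal).
#' @export
predict_roc <- function(R, dprime, criteria) {
  stopifnot(length(criteria) == 5)
  if (any(diff(criteria) <= 0))
    stop("criteria must be strictly increasing", call. = FALSE)
  if (R < 0 || R > 1) stop("R must be in [0, 1]", call. = FALSE)
  cr <- rev(criteria)  # strict -> liberal
  list(hits = R + (1 - R) * pnorm(dprime - cr), fas = pnorm(-cr))
}

# Unconstrained parameter vector <-> DPSD parameters. R on the logit scale,
# dprime mapped to (0, d_max) when constrained (d' beyond ~4 is not
# identifiable from rating data and unbounded d' opens a flat likelihood
# ridge trading R against familiarity at the response ceiling), criteria as
# c1 + cumulative exponentials (ordering enforced by construction).
dpsd_untransform <- function(theta, d_nonneg, d_max = 5) {
  list(R = plogis(theta[1]),
       dprime = if (d_nonneg) d_max * plogis(theta[2]) else theta[2],
       criteria = theta[3] + c(0, cumsum(pmax(exp(theta[4:7]), 1e-9))))
}

dpsd_transform <- function(R, dprime, criteria, d_nonneg, d_max = 5) {
  R <- min(max(R, 1e-4), 1 - 1e-4)
  d <- if (d_nonneg) qlogis(min(max(dprime / d_max, 1e-5), 1 - 1e-5)) else dprime
  c(qlogis(R), d, criteria[1], log(pmax(diff(criteria), 1e-4)))
}

# Negative objective over the unconstrained parameterization; returns a
# large finite penalty where the parameters degenerate numerically, so
# gradient-based search can back off instead of aborting.
dpsd_objective <- function(theta, old_counts, new_counts, objective, d_nonneg,
                           d_max = 5) {
  val <- tryCatch(
    dpsd_objective_raw(theta, old_counts, new_counts, objective, d_nonneg, d_max),
    error = function(e) Inf)
  if (!is.finite(val)) 1e10 + sum(theta^2) else val
}

dpsd_objective_raw <- function(theta, old_counts, new_counts, objective,
                               d_nonneg, d_max = 5) {
  p <- dpsd_untransform(theta, d_nonneg, d_max)
  if (objective == "ml") {
    po <- pmax(dpsd_category_probs(p$R, p$dprime, p$criteria), 1e-12)
    pn <- pmax(dpsd_category_probs(0, 0, p$criteria), 1e-12)
    -(sum(old_counts * log(po)) + sum(new_counts * log(pn)))
  } else {
    pred <- predict_roc(p$R, p$dprime, p$criteria)
    obs_h <- rev(cumsum(rev(old_counts)))[6:2] / sum(old_counts)
    obs_f <- rev(cumsum(rev(new_counts)))[6:2] / sum(new_counts)
    # 1/(2N) correction pulls empty extreme categories off the 0/1 boundary
    obs_h <- pmin(pmax(obs_h, 1 / (2 * sum(old_counts))),
                  1 - 1 / (2 * sum(old_counts)))
    obs_f <- pmin(pmax(obs_f, 1 / (2 * sum(new_counts))),
                  1 - 1 / (2 * sum(new_counts)))
    sum((obs_h - pred$hits)^2) + sum((obs_f - pred$fas)^2)
  }
}

#' Fit the dual-process signal-detection model to confidence-rating counts
#'
#' Estimates recollection probability `R`, familiarity `dprime`, and five
#' ordered criteria from the 6-category response counts of one subject and
#' condition. The default objective is the multinomial log-likelihood of
#' the category counts under the DPSD response model (recollected old
#' trials emit the top rating); a least-squares mode on cumulative ROC
#' rates is provided for comparability with distributed spreadsheet
#' solvers. Optimization runs `n_restarts` times from overdispersed random
#' starts plus one heuristic start derived from the observed ROC, keeping
#' the best objective.
#'
#' @param old_counts,new_counts Integer (or expected, possibly non-integer)
#'   response counts per rating category 1..6 for old and new items.
#' @param objective `"ml"` (multinomial maximum likelihood, default) or
#'   `"sse"` (least squares on cumulative rates with a 1/(2N) correction
#'   for empty extreme categories).
#' @param n_restarts Number of random restarts (default 10).
#' @param d_nonneg Constrain `dprime >= 0` (default TRUE).
#' @param d_max Upper bound on `dprime` (default 5): familiarity beyond
#'   this is not identifiable from 6-point rating data, and an unbounded
#'   d' opens a flat likelihood ridge trading recollection against
#'   familiarity when a subject gives only top-category old responses.
#' @param seed Integer seed for the restart starts.
#'
#' @return An object of class `dpsd_fit`: list with `R`, `dprime`,
#'   `criteria`, `objective` (the maximized log-likelihood, or negative SSE),
#'   `objective_type`, `converged`, `n_restarts`.
#' @export
#' @examples
#' pars <- generative_params(0.3, 0.3, 1, 1, criteria = c(-1, -0.5, 0, 0.5, 1))
#' p_old <- population_response_probabilities(pars, "studied", "aloud")
#' p_new <- population_response_probabilities(pars, "foil")
#' fit_dpsd(p_old * 1e6, p_new * 1e6)
fit_dpsd <- function(old_counts, new_counts,
                     objective = c("ml", "sse"), n_restarts = 10,
                     d_nonneg = TRUE, d_max = 5, seed = 1) {
  objective <- match.arg(objective)
  stopifnot(length(old_counts) == 6, length(new_counts) == 6,
            all(old_counts >= 0), all(new_counts >= 0))
  n_old <- sum(old_counts); n_new <- sum(new_counts)
  if (n_old == 0 || n_new == 0)
    stop("need at least one old and one new trial", call. = FALSE)
  if (n_old < 20 || n_new < 20)
    warning("fewer than 20 old or new trials; DPSD estimates will be noisy",
            call. = FALSE)
  if (sum(old_counts > 0) == 1 && sum(new_counts > 0) == 1 &&
      which(old_counts > 0) == which(new_counts > 0))
    warning("all responses in a single category for both item types; ",
            "parameters are at the boundary", call. = FALSE)

  # heuristic start from the observed ROC (strict -> liberal)
  obs_f <- (rev(cumsum(rev(new_counts)))[6:2] + 0.5) / (n_new + 1)
  obs_h <- (rev(cumsum(rev(old_counts)))[6:2] + 0.5) / (n_old + 1)
  crit0 <- rev(-qnorm(obs_f))                     # c1 < ... < c5
  crit0 <- crit0 + seq(0, 1e-3, length.out = 5)   # break exact ties
  R0 <- min(max(obs_h[1] - obs_f[1], 0.01), 0.9)
  starts <- list(dpsd_transform(R0, 1, crit0, d_nonneg, d_max))

  old_rng <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_rng)) assign(".Random.seed", old_rng, envir = globalenv()))
  set.seed(as.integer(seed))
  for (i in seq_len(n_restarts)) {
    starts[[i + 1]] <- dpsd_transform(
      R = runif(1, 0.02, 0.9),
      dprime = runif(1, 0.05, 2.5),
      criteria = sort(runif(5, -2, 2) + c(-2, -1, 0, 1, 2) * 0.3),
      d_nonneg = d_nonneg, d_max = d_max)
  }

  best <- NULL
  any_converged <- FALSE
  for (th0 in starts) {
    res <- try(stats::optim(th0, dpsd_objective, old_counts = old_counts,
                            new_counts = new_counts, objective = objective,
                            d_nonneg = d_nonneg, d_max = d_max, method = "BFGS",
                            control = list(maxit = 500)), silent = TRUE)
    if (inherits(res, "try-error")) next
    res2 <- try(stats::optim(res$par, dpsd_objective, old_counts = old_counts,
                             new_counts = new_counts, objective = objective,
                             d_nonneg = d_nonneg, d_max = d_max,
                             method = "Nelder-Mead",
                             control = list(maxit = 2000, reltol = 1e-12)),
                silent = TRUE)
    if (!inherits(res2, "try-error") && res2$value <= res$value) res <- res2
    if (res$convergence == 0) any_converged <- TRUE
    # strict-improvement rule: likelihood ties between restarts resolve
    # to the earliest start, i.e. the ROC-derived heuristic
    if (is.null(best) || res$value < best$value - 1e-8) best <- res
  }
  if (is.null(best)) stop("DPSD optimization failed from every start", call. = FALSE)
  # polish the incumbent until the objective stops moving
  for (round in 1:6) {
    prev <- best$value
    for (meth in c("BFGS", "Nelder-Mead")) {
      res <- try(stats::optim(best$par, dpsd_objective, old_counts = old_counts,
                              new_counts = new_counts, objective = objective,
                              d_nonneg = d_nonneg, d_max = d_max, method = meth,
                              control = list(maxit = 3000, reltol = 1e-14)),
                 silent = TRUE)
      if (!inherits(res, "try-error") && res$value < best$value - 1e-12) best <- res
    }
    if (prev - best$value < 1e-10) break
  }
  if (!any_converged)
    warning("DPSD optimization did not formally converge after ",
            n_restarts + 1, " starts; best parameters returned", call. = FALSE)
  p <- dpsd_untransform(best$par, d_nonneg, d_max)
  structure(
    list(R = unname(p$R), dprime = unname(p$dprime),
         criteria = unname(p$criteria),
         objective = -best$value, objective_type = objective,
         converged = any_converged, n_restarts = n_restarts),
    class = "dpsd_fit"
  )
}

#' @export
print.dpsd_fit <- function(x, digits = 3, ...) {
  cat(sprintf("DPSD fit (%s): R = %s, d' = %s\n", x$objective_type,
              format(x$R, digits = digits), format(x$dprime, digits = digits)))
  cat("criteria:", paste(format(x$criteria, digits = digits), collapse = ", "), "\n")
  cat(sprintf("objective = %s, converged = %s\n",
              format(x$objective, digits = 6), x$converged))
  invisible(x)
}

#' Per-subject DPSD fits for a confidence-rating experiment
#'
#' Fits the DPSD model separately for every subject and production
#' condition (the per-subject strategy used with confidence-rating designs):
#' within designs yield one aloud and one silent fit per subject, each
#' pairing that condition's studied items with the subject's foils; between
#' designs yield a single fit per subject.
#'
#' @param trials Confidence-rating trial `data.frame`.
#' @param ... Passed to [fit_dpsd()].
#' @return A `data.frame` with columns `subject_id`, `condition`, `R`,
#'   `dprime`, `c1`..`c5`, `objective`, `converged`.
#' @export
fit_dpsd_subjects <- function(trials, ...) {
  if (!is_confidence(trials))
    stop("confidence-rating trials required", call. = FALSE)
  rows <- list()
  for (s in unique(trials$subject_id)) {
    sub <- trials[trials$subject_id == s, ]
    foils <- sub[sub$item_type == "foil", ]
    conds <- intersect(c("aloud", "silent"), unique(sub$production))
    for (cond in conds) {
      studied <- sub[sub$production == cond, ]
      rc <- rbind(studied, foils)
      roc <- empirical_roc(rc)
      fit <- fit_dpsd(roc$old_counts, roc$new_counts, ...)
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = s, condition = cond, R = fit$R, dprime = fit$dprime,
        c1 = fit$criteria[1], c2 = fit$criteria[2], c3 = fit$criteria[3],
        c4 = fit$criteria[4], c5 = fit$criteria[5],
        objective = fit$objective, converged = fit$converged,
        row.names = NULL)
    }
  }
  do.call(rbind, rows)
}
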