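#' Generative parameters for the dual-process recognition model
#'
#' Bundles the population-level parameters of the dual-process
#' signal-detection (DPSD) generative model: an all-or-none recollection
#' probability and an equal-variance Gaussian familiarity strength for each
#' production condition, plus the decision criteria of the test procedure.
#'
#' Under the model, a studied item is recollected with probability `R`
#' (condition-specific); recollected items always attract the most confident
#' "old" response (the top rating in the confidence procedure, "remember" in
#' the remember-know procedure). Non-recollected studied items carry a
#' familiarity signal drawn from Normal(`dprime`, 1); unstudied foils draw
#' from Normal(0, 1). Responses arise by comparing familiarity to the
#' criteria.
#'
#' @param R_aloud,R_silent Recollection probabilities in \[0, 1\] for items
#'   read aloud and silently.
#' @param dprime_aloud,dprime_silent Mean familiarity of old items in
#'   standard-deviation units (foil familiarity is standard normal).
#' @param criteria Strictly increasing numeric vector of decision thresholds:
#'   5 thresholds for the 6-point confidence procedure, or 1 old/new
#'   threshold (optionally followed by a second, unused remember threshold)
#'   for the remember-know procedure.
#' @param subject_sd_R Between-subject SD of recollection on the logit scale
#'   (>= 0). Per-subject recollection is drawn as
#'   `plogis(rnorm(1, qlogis(R), subject_sd_R))`.
#' @param subject_sd_d Between-subject SD of familiarity on the identity
#'   scale (>= 0), truncated so per-subject d' stays non-negative.
#'
#' @return An object of class `generative_params`.
#' @seealso [simulate_experiment()], [population_response_probabilities()]
#' @export
#' @examples
#' generative_params(R_aloud = 0.25, R_silent = 0.12,
#'                   dprime_aloud = 1.1, dprime_silent = 0.85,
#'                   criteria = c(-1, -0.5, 0, 0.5, 1))
generative_params <- function(R_aloud, R_silent, dprime_aloud, dprime_silent,
                              criteria, subject_sd_R = 0, subject_sd_d = 0) {
  stopifnot(is.numeric(criteria), length(criteria) >= 1)
  for (R in c(R_aloud, R_silent)) {
    if (!is.numeric(R) || length(R) != 1 || is.na(R) || R < 0 || R > 1)
      stop("recollection probabilities must be in [0, 1]", call. = FALSE)
  }
  if (any(diff(criteria) <= 0))
    stop("criteria must be strictly increasing", call. = FALSE)
  if (subject_sd_R < 0 || subject_sd_d < 0)
    stop("subject heterogeneity scales must be >= 0", call. = FALSE)
  structure(
    list(R_aloud = R_aloud, R_silent = R_silent,
         dprime_aloud = dprime_aloud, dprime_silent = dprime_silent,
         criteria = as.numeric(criteria),
         subject_sd_R = subject_sd_R, subject_sd_d = subject_sd_d),
    class = "generative_params"
  )
}

#' Recognition experiment design
#'
#' Describes the structure of a simulated recognition experiment: whether
#' production (reading aloud vs silently) is manipulated within or between
#' subjects, which test procedure is used, and the per-participant item
#' counts.
#'
#' In a within design every participant studies `n_aloud` aloud and
#' `n_silent` silent items and is tested on those plus `n_foil` unstudied
#' foils (the classic 60/60/120 layout). In a between design each group of
#' `n_subjects` participants studies all items in a single production
#' condition (`n_aloud` items for the aloud group, `n_silent` for the silent
#' group) plus `n_foil` foils at test.
#'
#' @param design `"within"` or `"between"`.
#' @param paradigm `"remember_know"` or `"confidence"`.
#' @param n_subjects Number of participants (per group, for between designs).
#' @param n_aloud,n_silent,n_foil Item counts per participant (see Details).
#'
#' @return An object of class `experiment_design`.
#' @export
#' @examples
#' experiment_design("within", "remember_know", n_subjects = 25,
#'                   n_aloud = 60, n_silent = 60, n_foil = 120)
experiment_design <- function(design = c("within", "between"),
                              paradigm = c("remember_know", "confidence"),
                              n_subjects, n_aloud = 60, n_silent = 60,
                              n_foil = 120) {
  design <- match.arg(design)
  paradigm <- match.arg(paradigm)
  counts <- c(n_subjects = n_subjects, n_aloud = n_aloud,
              n_silent = n_silent, n_foil = n_foil)
  if (any(counts <= 0) || any(counts != round(counts)))
    stop("invalid design: item and subject counts must be positive integers",
         call. = FALSE)
  structure(
    list(design = design, paradigm = paradigm,
         n_subjects = as.integer(n_subjects), n_aloud = as.integer(n_aloud),
         n_silent = as.integer(n_silent), n_foil = as.integer(n_foil)),
    class = "experiment_design"
  )
}

# DPSD category probabilities over the 6 confidence ratings.
# P(rating >= j+1) = R + (1-R) * pnorm(d - c_j) for old items, pnorm(-c_j)
# for new; recollected trials always emit rating 6.
dpsd_category_probs <- function(R, dprime, criteria) {
  if (any(diff(criteria) <= 0))
    stop("criteria must be strictly increasing", call. = FALSE)
  k <- length(criteria)
  upper <- R + (1 - R) * pnorm(dprime - criteria)  # P(rating > boundary j)
  cum <- c(1, upper, R)                            # P(rating >= j), j = 1..k+2
  probs <- cum[1:(k + 1)] - cum[2:(k + 2)]
  # top category keeps the recollection mass: P(top) = R + (1-R)*Phi(d - c_k)
  probs[k + 1] <- probs[k + 1] + R
  names(probs) <- as.character(seq_len(k + 1))
  probs
}

#' Population response-category probabilities
#'
#' Closed-form probability of each response category under the DPSD
#' generative model, for one item type and production condition. This is the
#' analytic oracle against which both the simulator and the downstream
#' estimators can be checked.
#'
#' For the confidence procedure with criteria `c_1 < ... < c_5`,
#' `P(rating >= j + 1 | old) = R + (1 - R) * pnorm(d' - c_j)` and
#' `P(rating >= j + 1 | new) = pnorm(-c_j)`; recollected old trials emit the
#' top rating. For the remember-know procedure, `P(remember | old) = R`,
#' `P(know | old) = (1 - R) * pnorm(d' - c)`, and the remainder is `new`,
#' where `c` is the old/new criterion (first element of `criteria`). Foils
#' are never recollected.
#'
#' @param params A [generative_params()] object.
#' @param item_type `"studied"` or `"foil"`.
#' @param production `"aloud"` or `"silent"` (ignored for foils).
#' @param paradigm `"confidence"` or `"remember_know"`.
#'
#' @return Named numeric vector of category probabilities summing to 1:
#'   ratings `"1"`..`"6"` for confidence, `c("remember", "know", "new")` for
#'   remember-know.
#' @export
#' @examples
#' p <- generative_params(0.3, 0.3, 1, 1, criteria = c(-1, -0.5, 0, 0.5, 1))
#' population_response_probabilities(p, "studied", "aloud", "confidence")
population_response_probabilities <- function(params, item_type = c("studied", "foil"),
                                              production = c("aloud", "silent"),
                                              paradigm = c("confidence", "remember_know")) {
  stopifnot(inherits(params, "generative_params"))
  item_type <- match.arg(item_type)
  production <- match.arg(production)
  paradigm <- match.arg(paradigm)
  if (item_type == "foil") {
    R <- 0; d <- 0
  } else if (production == "aloud") {
    R <- params$R_aloud; d <- params$dprime_aloud
  } else {
    R <- params$R_silent; d <- params$dprime_silent
  }
  if (paradigm == "confidence") {
    if (length(params$criteria) != 5)
      stop("confidence paradigm requires 5 criteria", call. = FALSE)
    dpsd_category_probs(R, d, params$criteria)
  } else {
    cr <- params$criteria[1]
    p_rem <- R
    p_know <- (1 - R) * pnorm(d - cr)
    c(remember = p_rem, know = p_know, new = 1 - p_rem - p_know)
  }
}

#' Remember-know response rule
#'
#' Deterministic response rule of the generative model, mirroring the task
#' instruction that "know" is reserved for recognition without recollection:
#' a recollected trial yields "remember" regardless of familiarity; otherwise
#' the item is called "know" when its familiarity exceeds the old/new
#' criterion and "new" when it does not.
#'
#' @param recollected Logical vector; whether the recollection process
#'   succeeded on each trial.
#' @param familiarity Numeric vector of familiarity signals.
#' @param criteria Numeric; the old/new criterion is the first element.
#'
#' @return Character vector in `c("remember", "know", "new")`.
#' @export
#' @examples
#' rk_response_rule(c(TRUE, FALSE, FALSE), c(-5, 0.4, -0.4), criteria = 0)
rk_response_rule <- function(recollected, familiarity, criteria) {
  if (any(diff(criteria) <= 0))
    stop("criteria must be strictly increasing", call. = FALSE)
  cr <- criteria[1]
  ifelse(recollected, "remember", ifelse(familiarity > cr, "know", "new"))
}

# Per-subject parameter draws: recollection perturbed on the logit scale,
# familiarity on the identity scale truncated at 0. Population R of exactly
# 0 or 1 is kept fixed (logit undefined; the threshold process is degenerate).
draw_subject_params <- function(R, d, sd_R, sd_d) {
  R_s <- if (sd_R > 0 && R > 0 && R < 1) plogis(rnorm(1, qlogis(R), sd_R)) else R
  d_s <- if (sd_d > 0) max(0, rnorm(1, d, sd_d)) else d
  list(R = R_s, d = d_s)
}

#' Simulate a recognition-memory experiment
#'
#' Generates a trial-level table of test-phase responses under the DPSD
#' generative model, for either test procedure and either production design.
#' Per-subject recollection and familiarity parameters are drawn around the
#' population values according to the heterogeneity scales in `params`, and
#' each subject's trials are generated from a deterministically derived
#' sub-stream of the master seed, so the output is byte-identical across
#' runs with the same arguments.
#'
#' @param design An [experiment_design()] object.
#' @param params A [generative_params()] object.
#' @param seed Integer master seed (mandatory).
#'
#' @return A `data.frame` with one row per test trial and columns
#'   `subject_id`, `group` (`"aloud"`/`"silent"` for between designs,
#'   `"within"` otherwise), `item_id`, `item_type` (`"studied"`/`"foil"`),
#'   `production` (`"aloud"`, `"silent"`, or `"none"` for foils), and
#'   `response` (rating 1-6 or `"remember"`/`"know"`/`"new"`).
#' @export
#' @examples
#' des <- experiment_design("within", "remember_know", n_subjects = 4,
#'                          n_aloud = 10, n_silent = 10, n_foil = 20)
#' par <- generative_params(0.25, 0.12, 1.1, 0.85, criteria = 0.5)
#' head(simulate_experiment(des, par, seed = 1))
simulate_experiment <- function(design, params, seed) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(params, "generative_params"))
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1)
    stop("an integer seed is required", call. = FALSE)
  if (design$paradigm == "confidence" && length(params$criteria) != 5)
    stop("confidence paradigm requires 5 criteria", call. = FALSE)

  set.seed(as.integer(seed))
  n_total_subj <- if (design$design == "between") 2L * design$n_subjects else design$n_subjects
  subj_seeds <- sample.int(.Machine$integer.max - 1L, n_total_subj)

  groups <- if (design$design == "between") {
    rep(c("aloud", "silent"), each = design$n_subjects)
  } else {
    rep("within", n_total_subj)
  }

  out <- vector("list", n_total_subj)
  for (s in seq_len(n_total_subj)) {
    set.seed(subj_seeds[s])
    grp <- groups[s]
    if (design$design == "within") {
      prods <- c(rep("aloud", design$n_aloud), rep("silent", design$n_silent),
                 rep("none", design$n_foil))
    } else if (grp == "aloud") {
      prods <- c(rep("aloud", design$n_aloud), rep("none", design$n_foil))
    } else {
      prods <- c(rep("silent", design$n_silent), rep("none", design$n_foil))
    }
    itypes <- ifelse(prods == "none", "foil", "studied")
    n_tr <- length(prods)

    sp_a <- draw_subject_params(params$R_aloud, params$dprime_aloud,
                                params$subject_sd_R, params$subject_sd_d)
    sp_s <- draw_subject_params(params$R_silent, params$dprime_silent,
                                params$subject_sd_R, params$subject_sd_d)
    R_tr <- ifelse(prods == "aloud", sp_a$R, ifelse(prods == "silent", sp_s$R, 0))
    d_tr <- ifelse(prods == "aloud", sp_a$d, ifelse(prods == "silent", sp_s$d, 0))

    recollected <- runif(n_tr) < R_tr
    familiarity <- rnorm(n_tr, mean = d_tr, sd = 1)

    if (design$paradigm == "remember_know") {
      response <- rk_response_rule(recollected, familiarity, params$criteria)
    } else {
      rating <- 1L + vapply(familiarity,
                            function(f) sum(f > params$criteria), integer(1))
      rating[recollected] <- 6L
      response <- rating
    }
    out[[s]] <- data.frame(
      subject_id = sprintf("s%03d", s),
      group = grp,
      item_id = sprintf("s%03d_i%03d", s, seq_len(n_tr)),
      item_type = itypes,
      production = prods,
      response = response,
      stringsAsFactors = FALSE
    )
  }
  trials <- do.call(rbind, out)
  rownames(trials) <- NULL
  attr(trials, "paradigm") <- design$paradigm
  attr(trials, "design") <- design$design
  trials
}

#' Read and write trial-level CSV files
#'
#' Trial tables are exchanged as UTF-8 CSV with the fixed header
#' `subject_id,group,item_id,item_type,production,response`.
#'
#' @param trials A trial `data.frame` as produced by [simulate_experiment()].
#' @param path File path.
#' @return `read_trials()` returns the trial `data.frame` (with a `paradigm`
#'   attribute inferred from the response column); `write_trials()` returns
#'   `path` invisibly.
#' @export
write_trials <- function(trials, path) {
  cols <- c("subject_id", "group", "item_id", "item_type", "production", "response")
  stopifnot(all(cols %in% names(trials)))
  utils::write.csv(trials[, cols], path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  trials <- utils::read.csv(path, stringsAsFactors = FALSE,
                            fileEncoding = "UTF-8")
  cols <- c("subject_id", "group", "item_id", "item_type", "production", "response")
  missing_cols <- setdiff(cols, names(trials))
  if (length(missing_cols) > 0)
    stop("trial CSV is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  validate_trials(trials)
  paradigm <- if (all(trials$response %in% c("remember", "know", "new")))
    "remember_know" else "confidence"
  if (paradigm == "confidence") trials$response <- as.integer(trials$response)
  attr(trials, "paradigm") <- paradigm
  trials
}

# Schema checks shared by read_trials and the pipelines; reports offending
# row numbers so malformed input files are easy to fix.
validate_trials <- function(trials) {
  bad <- which(!trials$item_type %in% c("studied", "foil"))
  if (length(bad) > 0)
    stop("invalid item_type at row(s) ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  bad <- which(!trials$production %in% c("aloud", "silent", "none"))
  if (length(bad) > 0)
    stop("invalid production at row(s) ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  bad <- which(trials$item_type == "foil" & trials$production != "none")
  if (length(bad) > 0)
    stop("foil trials must have production 'none'; row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  rk <- trials$response %in% c("remember", "know", "new")
  conf <- suppressWarnings(!is.na(as.numeric(trials$response))) &
    trials$response %in% as.character(1:6) | (is.numeric(trials$response) &
                                                trials$response %in% 1:6)
  bad <- which(!(rk | conf))
  if (length(bad) > 0)
    stop("invalid response at row(s) ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  invisible(trials)
}
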