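is_rk <- function(trials) all(trials$response %in% c("remember", "know", "new"))

is_confidence <- function(trials) {
  r <- suppressWarnings(as.integer(as.character(trials$response)))
  !anyNA(r) && all(r %in% 1:6)
}

#' Collapse remember/know responses into old responses
#'
#' Recodes remember-know trials into the binary old/new outcome used for
#' hit and false-alarm analyses: a "remember" or "know" response counts as
#' an "old" response (1), "new" as 0.
#'
#' @param trials Remember-know trial `data.frame`.
#' @return The trials with a binary `y` column appended.
#' @export
collapse_rk_to_old <- function(trials) {
  if (!is_rk(trials)) {
    if (is_confidence(trials))
      stop("confidence-rating input: use binarize_confidence()", call. = FALSE)
    stop("responses must be remember/know/new", call. = FALSE)
  }
  trials$y <- as.integer(trials$response %in% c("remember", "know"))
  trials
}

#' Binary outcomes from remember-know trials
#'
#' Outcome definitions for the three remember-know models: `"old"` collapses
#' remember and know into old responses; `"remember"` scores remember vs
#' anything else; `"know_after_exclusion"` applies the independence
#' procedure ([independence_know_subset()]).
#'
#' @param trials Remember-know trial `data.frame`.
#' @param outcome One of `"old"`, `"remember"`, `"know_after_exclusion"`.
#' @return Trials with a binary `y` column (and, for
#'   `"know_after_exclusion"`, remember trials removed).
#' @export
rk_outcome <- function(trials, outcome = c("old", "remember", "know_after_exclusion")) {
  outcome <- match.arg(outcome)
  switch(outcome,
         old = collapse_rk_to_old(trials),
         remember = {
           if (!is_rk(trials)) stop("responses must be remember/know/new", call. = FALSE)
           trials$y <- as.integer(trials$response == "remember")
           trials
         },
         know_after_exclusion = independence_know_subset(trials))
}

#' Binarize 6-point confidence ratings into old/new responses
#'
#' Rescores each 1, 2, or 3 rating as a "new" response (0) and each 4, 5,
#' or 6 rating as an "old" response (1).
#'
#' @param trials Confidence-rating trial `data.frame`.
#' @return The trials with a binary `y` column appended.
#' @export
binarize_confidence <- function(trials) {
  r <- suppressWarnings(as.integer(as.character(trials$response)))
  if (anyNA(r) || any(!r %in% 1:6))
    stop("confidence responses must be integers 1-6", call. = FALSE)
  trials$y <- as.integer(r >= 4)
  trials
}

#' Independence remember-know subset
#'
#' Implements the trial-level independence remember-know procedure for
#' estimating familiarity: because task instructions give recollection
#' precedence (a recollected item receives "remember" even when it is also
#' familiar), raw know rates underestimate familiarity. Excluding remember
#' trials and modelling know vs new among the remainder estimates
#' P(know | not recollected), the trial-level analogue of the aggregated
#' estimator F = P(know) / (1 - P(remember)).
#'
#' Subject-by-condition cells in which every trial received a remember
#' response carry no information after exclusion and are dropped with a
#' warning.
#'
#' @param trials Remember-know trial `data.frame`.
#' @return Trials without remember responses and with `y` = 1 for know,
#'   0 for new.
#' @export
independence_know_subset <- function(trials) {
  if (!is_rk(trials)) {
    if (is_confidence(trials))
      stop("confidence-rating input: the independence procedure applies to ",
           "remember-know data", call. = FALSE)
    stop("responses must be remember/know/new", call. = FALSE)
  }
  cell <- interaction(trials$subject_id, trials$item_type, trials$production,
                      drop = TRUE)
  all_rem <- tapply(trials$response == "remember", cell, all)
  dropped <- names(all_rem)[all_rem]
  if (length(dropped) > 0)
    warning("dropping ", length(dropped),
            " all-remember subject-by-condition cell(s): ",
            paste(utils::head(dropped, 5), collapse = ", "), call. = FALSE)
  keep <- trials$response != "remember" & !(as.character(cell) %in% dropped)
  out <- trials[keep, , drop = FALSE]
  out$y <- as.integer(out$response == "know")
  rownames(out) <- NULL
  out
}

#' Aggregated independence familiarity estimator
#'
#' The proportion-level form of the independence remember-know correction:
#' F = P(know) / (1 - P(remember)) per item type and production condition,
#' estimating the probability of a familiarity-based old response given
#' that recollection failed.
#'
#' @param trials Remember-know trial `data.frame`.
#' @return A `data.frame` with columns `item_type`, `production`,
#'   `p_remember`, `p_know`, and `familiarity`.
#' @export
independence_familiarity <- function(trials) {
  if (!is_rk(trials)) stop("responses must be remember/know/new", call. = FALSE)
  key <- interaction(trials$item_type, trials$production, drop = TRUE)
  rows <- lapply(levels(key), function(k) {
    sub <- trials[key == k, ]
    p_rem <- mean(sub$response == "remember")
    p_know <- mean(sub$response == "know")
    data.frame(item_type = sub$item_type[1], production = sub$production[1],
               p_remember = p_rem, p_know = p_know,
               familiarity = if (p_rem < 1) p_know / (1 - p_rem) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Logit-scale signal-detection metrics from logistic coefficients
#'
#' Maps the coefficients of the centered-coding logistic model (item type
#' centered at -0.5/+0.5, production dummy silent = 0 / aloud = 1, plus
#' interaction) onto logit-scale analogues of signal-detection response bias
#' and sensitivity:
#'
#' * `C_L` (response bias) aggregates the coefficients *not* involving item
#'   type: `C_L(silent) = intercept`, `C_L(aloud) = intercept + production`.
#'   Positive values indicate a liberal bias (a propensity to call items
#'   "old"); note this is the opposite sign convention from conventional
#'   probit C.
#' * `d'_L` (sensitivity) aggregates the coefficients involving item type:
#'   `d'_L(silent) = item_type`, `d'_L(aloud) = item_type + interaction`.
#'
#' With posterior draws as input the metrics are computed per draw and then
#' summarized (median, HDIs), including the aloud-minus-silent contrasts;
#' with a named point-coefficient vector the mapping is exact arithmetic.
#'
#' @param coefficients A [posterior_draws] object / draws matrix with columns
#'   `b_intercept`, `b_production`, `b_item_type`, `b_interaction` (the
#'   `b_` prefix is optional), or a named numeric vector of point estimates
#'   with those names.
#'
#' @return An object of class `sdt_metrics`. For point input: a named list
#'   with `C_L` and `d_L` (each with `silent`, `aloud`, `contrast` =
#'   aloud - silent). For draws input the same structure holds
#'   `posterior_summary` objects, plus a `table` of summary rows.
#' @export
#' @examples
#' derive_sdt_metrics(c(b_intercept = -0.60, b_production = -0.15,
#'                      b_item_type = 1.79, b_interaction = 0.56))
derive_sdt_metrics <- function(coefficients) {
  needed <- c("intercept", "production", "item_type", "interaction")
  norm_names <- function(nm) sub("^b_", "", nm)
  if (is.numeric(coefficients) && is.null(dim(coefficients))) {
    names(coefficients) <- norm_names(names(coefficients))
    check_sdt_coding(names(coefficients), needed)
    b <- coefficients[needed]
    out <- list(
      C_L = list(silent = unname(b["intercept"]),
                 aloud = unname(b["intercept"] + b["production"]),
                 contrast = unname(b["production"])),
      d_L = list(silent = unname(b["item_type"]),
                 aloud = unname(b["item_type"] + b["interaction"]),
                 contrast = unname(b["interaction"])),
      type = "point")
    return(structure(out, class = "sdt_metrics"))
  }
  m <- as_draws_matrix(coefficients)
  colnames(m) <- norm_names(colnames(m))
  check_sdt_coding(colnames(m), needed)
  quantities <- list(
    C_L_silent = m[, "intercept"],
    C_L_aloud = m[, "intercept"] + m[, "production"],
    C_L_contrast = m[, "production"],
    d_L_silent = m[, "item_type"],
    d_L_aloud = m[, "item_type"] + m[, "interaction"],
    d_L_contrast = m[, "interaction"])
  summaries <- lapply(quantities, posterior_summary)
  out <- list(
    C_L = list(silent = summaries$C_L_silent, aloud = summaries$C_L_aloud,
               contrast = summaries$C_L_contrast),
    d_L = list(silent = summaries$d_L_silent, aloud = summaries$d_L_aloud,
               contrast = summaries$d_L_contrast),
    table = do.call(rbind, Map(summary_row, names(summaries), summaries)),
    type = "draws")
  structure(out, class = "sdt_metrics")
}

check_sdt_coding <- function(nm, needed) {
  if (any(c("silent", "aloud") %in% nm))
    stop("coefficients come from dummy-foil-intercept coding; the C_L/d'_L ",
         "mapping is defined only for centered item-type coding", call. = FALSE)
  missing_nm <- setdiff(needed, nm)
  if (length(missing_nm) > 0)
    stop("missing coefficient(s): ", paste(missing_nm, collapse = ", "),
         call. = FALSE)
  invisible(nm)
}

#' @export
print.sdt_metrics <- function(x, digits = 3, ...) {
  if (x$type == "point") {
    cat(sprintf("C_L: silent %.2f, aloud %.2f (contrast %.2f)\n",
                x$C_L$silent, x$C_L$aloud, x$C_L$contrast))
    cat(sprintf("d'_L: silent %.2f, aloud %.2f (contrast %.2f)\n",
                x$d_L$silent, x$d_L$aloud, x$d_L$contrast))
  } else {
    print(x$table, digits = digits, row.names = FALSE)
  }
  invisible(x)
}

#' Back-transform logit-scale condition estimates to proportions
#'
#' Applies the inverse-logit per posterior draw to each condition's linear
#' predictor and summarizes on the proportion scale, including all pairwise
#' condition contrasts (computed per draw on the proportion scale, never
#' from summarized logits).
#'
#' @param draws A [posterior_draws] object or draws matrix.
#' @param conditions Named list mapping condition labels to transform
#'   functions (or parameter-name character vectors, summed) giving each
#'   condition's logit-scale linear predictor per draw.
#'
#' @return A list with `estimates` (per-condition `posterior_summary` on the
#'   proportion scale), `contrasts` (pairwise differences), and a combined
#'   summary `table`.
#' @export
#' @examples
#' \dontrun{
#' backtransform_proportions(fit, conditions = list(
#'   foil = "b_intercept",
#'   silent = c("b_intercept", "b_silent"),
#'   aloud = c("b_intercept", "b_aloud")))
#' }
backtransform_proportions <- function(draws, conditions) {
  m <- as_draws_matrix(draws)
  lp <- lapply(conditions, function(cond) {
    if (is.character(cond)) {
      if (!all(cond %in% colnames(m)))
        stop("unknown parameter(s): ",
             paste(setdiff(cond, colnames(m)), collapse = ", "), call. = FALSE)
      rowSums(m[, cond, drop = FALSE])
    } else {
      apply(m, 1, cond)
    }
  })
  props <- lapply(lp, plogis)
  estimates <- lapply(props, posterior_summary)
  labs <- names(conditions)
  contrasts <- list()
  if (length(labs) > 1) {
    pairs <- utils::combn(labs, 2, simplify = FALSE)
    for (p in pairs) {
      contrasts[[paste(p[2], "-", p[1])]] <-
        posterior_summary(props[[p[2]]] - props[[p[1]]])
    }
  }
  tab <- do.call(rbind, c(Map(summary_row, names(estimates), estimates),
                          Map(summary_row, names(contrasts), contrasts)))
  list(estimates = estimates, contrasts = contrasts, table = tab)
}
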