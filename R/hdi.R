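#' Highest-density interval of a sample
#'
#' Computes the shortest contiguous interval containing at least a stated
#' fraction of the draws: with `n` sorted draws and `m = ceiling(mass * n)`,
#' the interval is the narrowest window spanning `m` consecutive order
#' statistics. For unimodal posteriors this estimates the highest-density
#' region, the summary used throughout the package in place of equal-tailed
#' intervals.
#'
#' @param draws Numeric vector of posterior draws (at least 100).
#' @param mass Fraction of mass to contain, in (0, 1). Default 0.95.
#'
#' @return Numeric vector `c(lower, upper)`.
#' @export
#' @examples
#' hdi(rnorm(10000), 0.95)
hdi <- function(draws, mass = 0.95) {
  draws <- as.numeric(draws)
  if (anyNA(draws)) stop("draws contain NA", call. = FALSE)
  n <- length(draws)
  if (n < 100) stop("at least 100 draws required", call. = FALSE)
  if (!is.numeric(mass) || mass <= 0 || mass >= 1)
    stop("mass must be in (0, 1)", call. = FALSE)
  m <- ceiling(mass * n)
  if (m > n) stop("fewer draws than required mass count", call. = FALSE)
  x <- sort(draws)
  widths <- x[m:n] - x[1:(n - m + 1)]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + m - 1])
}

#' Posterior summary of a sampled quantity
#'
#' Median, 50% and 95% highest-density intervals, and the posterior
#' probability of exceeding a reference value (0 by default), matching the
#' reporting convention of parameter-estimation-style Bayesian analyses.
#'
#' @param draws Numeric vector of posterior draws.
#' @param ref Reference value for the exceedance probability.
#' @return An object of class `posterior_summary`: a named list with
#'   `median`, `hdi50`, `hdi95`, `p_gt_ref`, and `n_draws`.
#' @export
posterior_summary <- function(draws, ref = 0) {
  draws <- as.numeric(draws)
  structure(
    list(median = stats::median(draws),
         hdi50 = hdi(draws, 0.50),
         hdi95 = hdi(draws, 0.95),
         p_gt_ref = mean(draws > ref),
         ref = ref,
         n_draws = length(draws)),
    class = "posterior_summary"
  )
}

#' @export
print.posterior_summary <- function(x, digits = 3, ...) {
  cat(sprintf("median %s  HDI50 [%s, %s]  HDI95 [%s, %s]  P(> %g) = %s\n",
              format(x$median, digits = digits),
              format(x$hdi50[1], digits = digits), format(x$hdi50[2], digits = digits),
              format(x$hdi95[1], digits = digits), format(x$hdi95[2], digits = digits),
              x$ref, format(x$p_gt_ref, digits = digits)))
  invisible(x)
}

# Flatten a posterior_summary into the standard output-table row.
summary_row <- function(quantity, s) {
  data.frame(quantity = quantity, median = s$median,
             hdi50_lo = s$hdi50[1], hdi50_hi = s$hdi50[2],
             hdi95_lo = s$hdi95[1], hdi95_hi = s$hdi95[2],
             p_gt_0 = s$p_gt_ref, row.names = NULL)
}

#' Summarize a transformed function of posterior draws
#'
#' Applies a deterministic transform to each joint posterior draw and
#' summarizes the result (median, HDIs, exceedance probability). The
#' transform is always applied per draw and summarized afterwards —
#' summaries of nonlinear functions are never computed from summarized
#' parameters.
#'
#' @param draws A [posterior_draws] object or a numeric matrix with one
#'   column per parameter and one row per draw.
#' @param transform Function taking a named numeric vector (one joint draw)
#'   and returning a scalar; or a character parameter name for the identity
#'   transform on that parameter.
#' @param ref Reference value for the exceedance probability.
#'
#' @return A `posterior_summary`, with the transformed draws attached as
#'   attribute `"draws"`.
#' @export
contrast <- function(draws, transform, ref = 0) {
  m <- as_draws_matrix(draws)
  if (is.character(transform)) {
    nm <- transform
    if (!nm %in% colnames(m)) stop("unknown parameter: ", nm, call. = FALSE)
    vals <- m[, nm]
  } else {
    vals <- apply(m, 1, transform)
  }
  if (!is.numeric(vals) || anyNA(vals) || any(!is.finite(vals)))
    stop("transform produced non-finite values for some draws", call. = FALSE)
  s <- posterior_summary(vals, ref = ref)
  attr(s, "draws") <- as.numeric(vals)
  s
}
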