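#' Companion logistic odds ratio for burden counts
#'
#' Descriptive per-unit-count odds ratio accompanying a Mann-Whitney burden
#' test: a two-parameter logistic model (intercept plus slope on the count)
#' is fitted by maximum likelihood, and `exp(slope)` is reported with a Wald
#' interval from the observed information. This estimate is purely
#' descriptive; significance decisions always come from the Mann-Whitney
#' p-value. Complete separation of the two outcome groups by the count is
#' flagged and returns an infinite (or zero) odds ratio with no interval.
#'
#' @param counts Per-patient burden counts.
#' @param outcome Binary (0/1) outcome vector, same length; both classes must
#'   be present.
#' @param level Confidence level for the Wald interval.
#' @return List with `or`, `ci_low`, `ci_high`, `slope`, `se`, `separated`.
#' @export
burden_or_logistic <- function(counts, outcome, level = 0.95) {
  counts <- as.numeric(counts)
  outcome <- as.numeric(outcome)
  stopifnot(length(counts) == length(outcome))
  if (!all(outcome %in% c(0, 1)))
    stop("`outcome` must be binary 0/1", call. = FALSE)
  if (length(unique(outcome)) < 2L)
    stop("degenerate grouping: outcome has a single class", call. = FALSE)
  if (stats::var(counts) == 0)
    return(list(or = 1, ci_low = NA_real_, ci_high = NA_real_,
                slope = 0, se = NA_real_, separated = FALSE))
  c0 <- counts[outcome == 0]; c1 <- counts[outcome == 1]
  # a single covariate separates the classes iff the group ranges are disjoint
  if (max(c0) < min(c1) || max(c1) < min(c0)) {
    return(list(or = if (max(c0) < min(c1)) Inf else 0,
                ci_low = NA_real_, ci_high = NA_real_,
                slope = if (max(c0) < min(c1)) Inf else -Inf,
                se = NA_real_, separated = TRUE))
  }
  fit <- suppressWarnings(
    stats::glm(outcome ~ counts, family = stats::binomial())
  )
  slope <- unname(stats::coef(fit)[2])
  se <- sqrt(stats::vcov(fit)[2, 2])
  if (!is.finite(slope) || !is.finite(se) || se > 1e3) {
    return(list(or = if (isTRUE(slope > 0)) Inf else 0,
                ci_low = NA_real_, ci_high = NA_real_,
                slope = slope, se = se, separated = TRUE))
  }
  z <- stats::qnorm((1 + level) / 2)
  list(or = exp(slope),
       ci_low = exp(slope - z * se),
       ci_high = exp(slope + z * se),
       slope = slope, se = se, separated = FALSE)
}
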