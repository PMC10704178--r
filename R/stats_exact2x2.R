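#' Construct a 2x2 contingency table
#'
#' Orientation contract: rows index the outcome (present / absent), columns
#' the exposure (carrier / non-carrier), so `a` counts exposed patients with
#' the outcome, `b` unexposed with the outcome, `c` exposed without it and
#' `d` unexposed without it.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return A list of class `two_by_two` with the cells and margins.
#' @export
two_by_two <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(!is.finite(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop("cells must be non-negative integers", call. = FALSE)
  cells <- as.integer(round(cells))
  if (sum(cells) == 0L)
    stop("at least one margin must be positive", call. = FALSE)
  structure(list(a = cells[1L], b = cells[2L], c = cells[3L], d = cells[4L],
                 row1 = cells[1L] + cells[2L],
                 row2 = cells[3L] + cells[4L],
                 col1 = cells[1L] + cells[3L],
                 col2 = cells[2L] + cells[4L],
                 n = sum(cells)),
            class = "two_by_two")
}

as_two_by_two <- function(t) {
  if (inherits(t, "two_by_two")) return(t)
  if (is.matrix(t) && all(dim(t) == c(2L, 2L)))
    return(two_by_two(t[1, 1], t[1, 2], t[2, 1], t[2, 2]))
  if (is.numeric(t) && length(t) == 4L)
    return(two_by_two(t[1], t[2], t[3], t[4]))
  stop("cannot interpret input as a 2x2 table", call. = FALSE)
}

# Support and central log-weights of the A (= cell a) count given all margins.
# With row totals r1, r2 and first column total c1, the noncentral
# hypergeometric puts mass proportional to choose(r1,k) choose(r2,c1-k) psi^k
# on k in [max(0, c1-r2), min(r1, c1)].
nchg_support <- function(t) {
  lo <- max(0L, t$col1 - t$row2)
  hi <- min(t$row1, t$col1)
  k <- lo:hi
  list(k = k, lo = lo, hi = hi,
       lw0 = lchoose(t$row1, k) + lchoose(t$row2, t$col1 - k))
}

#' Noncentral hypergeometric distribution of a 2x2 table cell
#'
#' Returns the support and probability weights of the exposed-with-outcome
#' cell given all margins of `t`, at odds ratio `psi` (Fisher's noncentral
#' hypergeometric distribution). `psi = 1` gives the central distribution
#' underlying the Fisher exact test. Intended both for computation and as a
#' debugging aid: it exposes the full support and normalized weights for any
#' table.
#'
#' @param t A [two_by_two()] table (or 2x2 matrix / length-4 vector).
#' @param psi Odds ratio, in `[0, Inf]`.
#' @return A data.frame with columns `k` (support) and `prob`.
#' @export
nchg_distribution <- function(t, psi = 1) {
  t <- as_two_by_two(t)
  s <- nchg_support(t)
  if (psi == 0) {
    prob <- as.numeric(s$k == s$lo)
  } else if (!is.finite(psi)) {
    prob <- as.numeric(s$k == s$hi)
  } else {
    lw <- s$lw0 + s$k * log(psi)
    lw <- lw - max(lw)
    prob <- exp(lw) / sum(exp(lw))
  }
  data.frame(k = s$k, prob = prob)
}

nchg_mean <- function(s, log_psi) {
  lw <- s$lw0 + s$k * log_psi
  lw <- lw - max(lw)
  w <- exp(lw)
  sum(s$k * w) / sum(w)
}

# P(A >= a | psi) and P(A <= a | psi) on log-psi scale
nchg_tail <- function(s, log_psi, a, upper = TRUE) {
  lw <- s$lw0 + s$k * log_psi
  lw <- lw - max(lw)
  w <- exp(lw)
  if (upper) sum(w[s$k >= a]) / sum(w) else sum(w[s$k <= a]) / sum(w)
}

# Bracket-expansion + bisection root finder on the log-psi axis.
# f must be monotone increasing; returns the root of f = 0 to an absolute
# tolerance of `tol` on log psi (hence ~`tol` relative tolerance on psi).
bisect_log_psi <- function(f, tol = 1e-10, max_expand = 60L) {
  lo <- -1; hi <- 1
  i <- 0L
  while (f(lo) > 0 && i < max_expand) { lo <- lo * 2; i <- i + 1L }
  i <- 0L
  while (f(hi) < 0 && i < max_expand) { hi <- hi * 2; i <- i + 1L }
  if (f(lo) > 0 || f(hi) < 0)
    stop("root bracketing failed", call. = FALSE)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Two-sided Fisher exact p-value
#'
#' Sums central hypergeometric probabilities of all tables sharing the
#' margins of `t` whose probability does not exceed that of the observed
#' table (the minimum-likelihood two-sided rule, the convention of standard
#' statistical software). A table with a zero row or column margin carries no
#' information and returns `p = 1` with a message.
#'
#' @param t A [two_by_two()] table (or 2x2 matrix / length-4 vector).
#' @return Two-sided p-value in `(0, 1]`.
#' @examples
#' fisher_two_sided_p(two_by_two(3, 1, 1, 3)) # 34/70
#' @export
fisher_two_sided_p <- function(t) {
  t <- as_two_by_two(t)
  if (t$row1 == 0L || t$row2 == 0L || t$col1 == 0L || t$col2 == 0L) {
    message("2x2 table has a zero margin; returning p = 1")
    return(1)
  }
  s <- nchg_support(t)
  lp <- s$lw0 - lchoose(t$n, t$col1)
  p_obs <- lp[s$k == t$a]
  # relative tolerance guards against ties broken by floating-point noise
  sum(exp(lp[lp <= p_obs + 1e-7]))
}

#' Conditional maximum-likelihood odds ratio of a 2x2 table
#'
#' The odds ratio maximizing the noncentral hypergeometric likelihood of the
#' observed table given all margins, i.e. the solution of
#' `E[A | margins, psi] = a`. This is the odds-ratio convention that
#' accompanies Fisher exact test reporting. Solved by bracket expansion and
#' bisection on `log(psi)` to a relative tolerance of `1e-10`; when the
#' observed cell sits at the lower (upper) bound of its support the estimate
#' is `0` (`Inf`).
#'
#' @param t A [two_by_two()] table (or 2x2 matrix / length-4 vector).
#' @return The estimate, in `[0, Inf]`.
#' @examples
#' conditional_mle_or(two_by_two(7, 7, 12, 57)) # ~4.64
#' @export
conditional_mle_or <- function(t) {
  t <- as_two_by_two(t)
  s <- nchg_support(t)
  if (s$lo == s$hi) return(NaN) # degenerate support: psi not identifiable
  if (t$a == s$lo) return(0)
  if (t$a == s$hi) return(Inf)
  exp(bisect_log_psi(function(lp) nchg_mean(s, lp) - t$a))
}

#' Exact confidence interval for the 2x2 odds ratio
#'
#' Central exact (conditional) interval by tail inversion: the lower endpoint
#' solves `P(A >= a | psi) = (1 - level)/2` and the upper endpoint solves
#' `P(A <= a | psi) = (1 - level)/2`, with tails taken under the noncentral
#' hypergeometric distribution given the margins. Endpoints at the support
#' boundary are `0` / `Inf`.
#'
#' @param t A [two_by_two()] table (or 2x2 matrix / length-4 vector).
#' @param level Confidence level, default 0.95.
#' @return Numeric vector `c(lo, hi)`.
#' @examples
#' exact_or_ci(two_by_two(7, 7, 12, 57)) # ~ (1.16, 18.97)
#' @export
exact_or_ci <- function(t, level = 0.95) {
  stopifnot(level > 0, level < 1)
  t <- as_two_by_two(t)
  s <- nchg_support(t)
  alpha <- (1 - level) / 2
  if (s$lo == s$hi) return(c(NaN, NaN))
  lo <- if (t$a == s$lo) 0 else
    exp(bisect_log_psi(function(lp) nchg_tail(s, lp, t$a, upper = TRUE) - alpha))
  hi <- if (t$a == s$hi) Inf else
    exp(bisect_log_psi(function(lp) alpha - nchg_tail(s, lp, t$a, upper = FALSE)))
  c(lo, hi)
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha Family-wise significance level.
#' @param m Number of tests in the family (`>= 1`).
#' @return `alpha / m`.
#' @examples
#' bonferroni(0.05, 26) # 1.92e-3
#' @export
bonferroni <- function(alpha, m) {
  if (!is.numeric(m) || length(m) != 1L || m < 1)
    stop("family size `m` must be >= 1", call. = FALSE)
  alpha / m
}
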