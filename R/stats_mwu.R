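#' Mann-Whitney U test for burden counts
#'
#' Compares per-patient qualifying-variant counts between the
#' phenotype-present group `x` and the phenotype-absent group `y`.
#' `U` is the Mann-Whitney statistic of `x` computed from pooled midranks.
#'
#' Exact mode works on the permutation distribution of `U` given the pooled
#' multiset: without ties this distribution is obtained by a subset-sum
#' counting recursion over the ranks; with ties, by enumerating all
#' `choose(n1 + n2, n1)` group labelings. The exact two-sided p-value is the
#' doubled smaller tail (including the observed value), capped at 1.
#' Approximate mode uses the normal approximation with tie-corrected
#' variance and a continuity correction. `auto` picks exact when there are
#' no ties and the pooled size is at most 25, otherwise approximate.
#'
#' @param x,y Numeric vectors of counts; both must be non-empty.
#' @param mode `"auto"`, `"exact"` or `"approximate"`.
#' @return List with `statistic` (U), `p_value`, and `method`.
#' @examples
#' mann_whitney_u(c(4, 5), c(1, 2, 3), mode = "exact") # U = 6, p = 0.2
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "approximate")) {
  mode <- match.arg(mode)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L)
    stop("degenerate grouping: both groups must be non-empty", call. = FALSE)
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (length(unique(pooled)) == 1L)
    return(list(statistic = u, p_value = 1, method = "degenerate"))
  ties <- anyDuplicated(pooled) > 0L
  if (mode == "auto") mode <- if (!ties && n <= 25L) "exact" else "approximate"

  if (mode == "exact") {
    if (!ties) {
      dist <- mwu_exact_dist_noties(n1, n2)
      u_vals <- dist$u; prob <- dist$prob
    } else {
      n_comb <- choose(n, n1)
      if (n_comb > 5e5)
        stop("exact mode with ties infeasible for choose(", n, ",", n1, ") = ",
             n_comb, " labelings; use mode = \"approximate\"", call. = FALSE)
      cmb <- utils::combn(n, n1)
      us <- colSums(matrix(r[cmb], nrow = n1)) - n1 * (n1 + 1) / 2
      tab <- table(us)
      u_vals <- as.numeric(names(tab)); prob <- as.numeric(tab) / n_comb
    }
    eps <- 1e-9
    p_lo <- sum(prob[u_vals <= u + eps])
    p_hi <- sum(prob[u_vals >= u - eps])
    p <- min(1, 2 * min(p_lo, p_hi))
    return(list(statistic = u, p_value = p, method = "exact"))
  }

  mu <- n1 * n2 / 2
  tie_counts <- table(pooled)
  sigma2 <- n1 * n2 / 12 *
    ((n + 1) - sum(tie_counts^3 - tie_counts) / (n * (n - 1)))
  z <- u - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2) # continuity correction toward mean
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(statistic = u, p_value = p, method = "approximate")
}

# Exact null distribution of U for untied samples of sizes n1, n2: the number
# of size-n1 subsets of ranks 1..n with each rank sum, via subset-sum DP.
mwu_exact_dist_noties <- function(n1, n2) {
  n <- n1 + n2
  max_sum <- n * (n + 1) / 2
  # counts[s + 1, t + 1] = subsets of size s with rank sum t
  counts <- matrix(0, nrow = n1 + 1, ncol = max_sum + 1)
  counts[1, 1] <- 1
  for (k in seq_len(n)) {
    for (s in rev(seq_len(min(k, n1)))) {
      idx <- (k + 1):(max_sum + 1)
      counts[s + 1, idx] <- counts[s + 1, idx] + counts[s, idx - k]
    }
  }
  sums <- 0:max_sum
  keep <- counts[n1 + 1, ] > 0
  u <- sums[keep] - n1 * (n1 + 1) / 2
  list(u = u, prob = counts[n1 + 1, keep] / choose(n, n1))
}
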