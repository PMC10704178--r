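# Builders for small hand-written input files and independent oracles.

vcf_header <- function(samples) {
  c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

vcf_row <- function(chrom, pos, ref, alt, gts, id = ".") {
  paste(c(chrom, pos, id, ref, alt, ".", "PASS", ".", "GT", gts),
        collapse = "\t")
}

write_test_vcf <- function(samples, rows, path = tempfile(fileext = ".vcf")) {
  writeLines(c(vcf_header(samples), rows), path)
  path
}

write_test_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Independent Fisher two-sided oracle: enumerate all tables with the observed
# margins, probabilities from the factorial form of the hypergeometric pmf.
fisher_p_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || b + d == 0) return(1)
  k <- max(0, c1 - r2):min(r1, c1)
  lp <- lfactorial(r1) + lfactorial(r2) + lfactorial(c1) + lfactorial(n - c1) -
    lfactorial(n) - lfactorial(k) - lfactorial(r1 - k) -
    lfactorial(c1 - k) - lfactorial(r2 - c1 + k)
  p <- exp(lp)
  sum(p[lp <= lp[k == a] + 1e-7])
}

# Independent Mann-Whitney oracle: full enumeration of group labelings.
mwu_p_oracle <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  us <- apply(combn(n, n1), 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9)))
}

# Two-stage dense grid search maximizing the noncentral hypergeometric
# log-likelihood over log(psi); independent of the expectation-equation solver.
cmle_grid_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  k <- max(0, c1 - r2):min(r1, c1)
  lw0 <- lchoose(r1, k) + lchoose(r2, c1 - k)
  loglik <- function(lp) {
    lw <- outer(k, lp) + lw0
    a * lp - apply(lw, 2, function(v) { m <- max(v); m + log(sum(exp(v - m))) })
  }
  grid <- seq(-12, 12, length.out = 2001)
  for (i in 1:3) {
    ll <- loglik(grid)
    best <- grid[which.max(ll)]
    h <- (grid[2] - grid[1]) * 2
    grid <- seq(best - h, best + h, length.out = 2001)
  }
  exp(grid[which.max(loglik(grid))])
}

random_interior_table <- function() {
  # rejection-sample a table whose observed cell is interior to its support
  repeat {
    t <- as.integer(sample(0:12, 4, replace = TRUE))
    lo <- max(0, (t[1] + t[3]) - (t[3] + t[4]))
    hi <- min(t[1] + t[2], t[1] + t[3])
    if (lo < t[1] && t[1] < hi) return(t)
  }
}
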