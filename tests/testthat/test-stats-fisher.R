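test_that("two-sided Fisher p: frozen examples and zero-margin convention", {
  expect_equal(fisher_two_sided_p(two_by_two(3, 1, 1, 3)), 34 / 70,
               tolerance = 1e-12)
  expect_equal(fisher_two_sided_p(two_by_two(5, 5, 5, 5)), 1, tolerance = 1e-12)
  # published GRIN3A carrier-by-behavior-ADR table
  expect_lt(abs(fisher_two_sided_p(two_by_two(7, 7, 12, 57)) - 0.0143), 1e-4)
  expect_message(p0 <- fisher_two_sided_p(two_by_two(0, 0, 3, 4)),
                 "zero margin")
  expect_equal(p0, 1)
})

test_that("two-sided Fisher p matches fisher.test on random tables", {
  set.seed(42)
  for (i in 1:60) {
    t <- sample(0:15, 4, replace = TRUE)
    if ((t[1] + t[2]) * (t[3] + t[4]) * (t[1] + t[3]) * (t[2] + t[4]) == 0) next
    m <- matrix(t, nrow = 2, byrow = TRUE)
    expect_equal(fisher_two_sided_p(m), fisher.test(m)$p.value,
                 tolerance = 1e-9)
  }
})

test_that("conditional MLE: symmetry, boundaries, published value", {
  expect_equal(conditional_mle_or(two_by_two(5, 5, 5, 5)), 1, tolerance = 1e-9)
  expect_equal(conditional_mle_or(two_by_two(3, 0, 1, 4)), Inf)
  expect_equal(conditional_mle_or(two_by_two(0, 3, 4, 1)), 0)
  expect_lt(abs(conditional_mle_or(two_by_two(7, 7, 12, 57)) - 4.64), 0.01)
})

test_that("conditional MLE matches the grid-search likelihood maximizer", {
  set.seed(7)
  for (i in 1:30) {
    t <- random_interior_table()
    psi <- conditional_mle_or(two_by_two(t[1], t[2], t[3], t[4]))
    oracle <- cmle_grid_oracle(t[1], t[2], t[3], t[4])
    expect_lt(abs(psi - oracle) / oracle, 1e-3)
  }
})

test_that("conditional mean is strictly increasing in psi (uniqueness)", {
  set.seed(9)
  for (i in 1:20) {
    t <- random_interior_table()
    tb <- two_by_two(t[1], t[2], t[3], t[4])
    s <- rvburden:::nchg_support(tb)
    means <- vapply(seq(-6, 6, length.out = 40),
                    function(lp) rvburden:::nchg_mean(s, lp), 0)
    expect_true(all(diff(means) > 0))
  }
})

test_that("exact CI: published endpoints, symmetry, nesting, tail equations", {
  ci <- exact_or_ci(two_by_two(7, 7, 12, 57))
  expect_lt(abs(ci[1] - 1.16), 0.01)
  expect_lt(abs(ci[2] - 18.97) / 18.97, 0.002)

  # symmetric table: interval contains 1; swapping exposure columns maps
  # (lo, hi) -> (1/hi, 1/lo) and psi -> 1/psi
  ci_s <- exact_or_ci(two_by_two(5, 5, 5, 5))
  expect_true(ci_s[1] < 1 && 1 < ci_s[2])
  set.seed(21)
  for (i in 1:10) {
    t <- random_interior_table()
    swapped <- two_by_two(t[2], t[1], t[4], t[3])
    ci1 <- exact_or_ci(two_by_two(t[1], t[2], t[3], t[4]))
    ci2 <- exact_or_ci(swapped)
    expect_equal(ci2, rev(1 / ci1), tolerance = 1e-6)
    expect_equal(conditional_mle_or(swapped),
                 1 / conditional_mle_or(two_by_two(t[1], t[2], t[3], t[4])),
                 tolerance = 1e-6)
    # 99% interval contains the 95% interval
    ci99 <- exact_or_ci(two_by_two(t[1], t[2], t[3], t[4]), level = 0.99)
    expect_lte(ci99[1], ci1[1]); expect_gte(ci99[2], ci1[2])
    # endpoints satisfy their defining tail equations
    tb <- two_by_two(t[1], t[2], t[3], t[4])
    s <- rvburden:::nchg_support(tb)
    expect_lt(abs(rvburden:::nchg_tail(s, log(ci1[1]), tb$a, TRUE) - 0.025),
              1e-8)
    expect_lt(abs(rvburden:::nchg_tail(s, log(ci1[2]), tb$a, FALSE) - 0.025),
              1e-8)
  }
})

test_that("noncentral hypergeometric distribution dump is a valid pmf", {
  d <- nchg_distribution(two_by_two(7, 7, 12, 57), psi = 4.6)
  expect_equal(sum(d$prob), 1, tolerance = 1e-12)
  expect_equal(d$k, 0:14)
  expect_equal(nchg_distribution(two_by_two(2, 3, 4, 5), psi = 1)$prob,
               dhyper(0:5, 5, 9, 6), tolerance = 1e-12)
})

test_that("Bonferroni threshold validates the family size", {
  expect_equal(bonferroni(0.05, 1), 0.05)
  expect_error(bonferroni(0.05, 0), "family size")
})
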