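test_that("fixture: outcome counts, carrier splits, one variant per patient", {
  dat <- paper_fixture_data()
  ph <- dat$phenotypes
  expect_equal(nrow(ph), 83L)
  expect_equal(colSums(ph[outcome_names()]),
               c(response = 14, adr = 22, behavior_adr = 14,
                 retention_1yr = 61))
  expect_true(all(ph$adr[ph$behavior_adr == 1] == 1))

  ac <- dat$genotypes$allele_counts
  expect_true(all(rowSums(ac) <= 1))  # carriers distinct across variants
  # per-variant carrier splits follow the published counts
  adr <- ph$adr; beh <- ph$behavior_adr
  split_by <- function(key, y) c(sum(ac[y == 1, key]), sum(ac[y == 0, key]))
  expect_equal(split_by("10:85601585:G:A", adr), c(5, 3))
  expect_equal(split_by("10:85601287:AT:GG", adr), c(2, 1))
  expect_equal(split_by("9:101560322:C:G", beh), c(1, 0))
  expect_equal(split_by("9:101560055:C:T", beh), c(0, 1))
  expect_equal(split_by("9:101561462:A:G", beh), c(1, 3))
  expect_equal(split_by("9:101561438:C:G", beh), c(3, 1))
  expect_equal(split_by("9:101562501:TG:CA", beh), c(2, 7))
  # GRID1 gene-level carrier split across ADR: 7 vs 4
  grid1 <- rowSums(ac[, dat$variants$gene == "GRID1"])
  expect_equal(c(sum(grid1[adr == 1]), sum(grid1[adr == 0])), c(7, 4))
  expect_true(all(dat$variants$pop_af < 0.05))
  expect_equal(dat$variants$consequence[dat$variants$ref %in% c("AT", "TG")],
               rep("nonframeshift_substitution", 2))
})

test_that("fixture files parse through the loaders without warnings", {
  d <- tempfile(); paths <- paper_fixture(d)
  expect_no_warning(
    inputs <- suppressMessages(load_inputs(paths[["vcf"]],
                                           paths[["annotation"]],
                                           paths[["phenotypes"]])))
  expect_equal(nrow(inputs$variants), 7L)
  expect_false(anyNA(inputs$genotypes$allele_counts))
  # fixture emission is deterministic across runs
  paths2 <- paper_fixture(tempfile())
  expect_identical(unname(tools::md5sum(paths)), unname(tools::md5sum(paths2)))
})

test_that("simulator is seed-deterministic and seed-sensitive", {
  cfg <- simulation_config(n_patients = 30,
                           per_gene_carrier_freq = c(GRID1 = 0.2, GRIN3A = 0.3),
                           seed = 42L)
  p1 <- simulate_cohort(cfg, tempfile())$paths
  p2 <- simulate_cohort(cfg, tempfile())$paths
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
  cfg$seed <- 43L
  p3 <- simulate_cohort(cfg, tempfile())$paths
  expect_false(identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p3))))
})

test_that("simulated outcome counts hit the configured prevalences", {
  cfg <- simulation_config(n_patients = 83,
                           per_gene_carrier_freq = c(GRIN3A = 0.2))
  counts <- vapply(1:400, function(r) {
    cfg$seed <- 1000L + r
    sum(simulate_cohort_data(cfg)$phenotypes$adr)
  }, 0)
  # mean of 400 binomial(83, 22/83) draws: SE ~ 0.2
  expect_lt(abs(mean(counts) - 22), 3 * sqrt(22 * (1 - 22 / 83) / 400))
})

test_that("behavior ADR nests in ADR and inconsistent configs are rejected", {
  cfg <- simulation_config(n_patients = 500,
                           per_gene_carrier_freq = c(GRIN3A = 0.2), seed = 3L)
  ph <- simulate_cohort_data(cfg)$phenotypes
  expect_true(all(ph$adr[ph$behavior_adr == 1] == 1))
  expect_error(
    simulation_config(outcome_prevalences = c(response = 0.2, adr = 0.1,
                                              behavior_adr = 0.3,
                                              retention_1yr = 0.7)),
    "inconsistent prevalences")
})

test_that("null effect map leaves carriers independent of outcome", {
  cfg <- simulation_config(n_patients = 4000,
                           per_gene_carrier_freq = c(GRID1 = 0.15,
                                                     GRIN3A = 0.25),
                           seed = 8L)
  dat <- simulate_cohort_data(cfg)
  carr <- build_carrier_matrix(qualify_variants(dat$variants), dat$genotypes)
  for (g in c("GRID1", "GRIN3A")) {
    p <- suppressWarnings(
      chisq.test(table(carr[, g], dat$phenotypes$adr))$p.value)
    expect_gt(p, 0.001)
  }
})

test_that("a gene-level effect enriches carriers in outcome-positive patients", {
  cfg <- simulation_config(
    n_patients = 4000,
    per_gene_carrier_freq = c(GRIN3A = 0.1),
    effect_map = data.frame(unit = "GRIN3A", outcome = "adr", or = 4),
    seed = 15L)
  dat <- simulate_cohort_data(cfg)
  carr <- build_carrier_matrix(qualify_variants(dat$variants),
                               dat$genotypes)[, "GRIN3A"]
  y <- dat$phenotypes$adr
  f1 <- mean(carr[y == 1]); f0 <- mean(carr[y == 0])
  emp_or <- (f1 / (1 - f1)) / (f0 / (1 - f0))
  expect_gt(emp_or, 2.5); expect_lt(emp_or, 6)
})

test_that("recovery summary: degenerate single replicate and median recovery", {
  cfg <- simulation_config(n_patients = 300,
                           per_gene_carrier_freq = c(GRIN3A = 0.2),
                           effect_map = data.frame(unit = "GRIN3A",
                                                   outcome = "adr", or = 3),
                           seed = 77L)
  one <- recovery_experiment(cfg, replicates = 1)
  expect_equal(nrow(one$summary), 1L)
  expect_true(is.na(one$summary$ci_coverage))

  rec <- recovery_experiment(cfg, replicates = 60)
  expect_equal(rec$summary$true_or, 3)
  expect_gt(rec$summary$median_psi, 1.8)
  expect_lt(rec$summary$median_psi, 5)
})
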