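make_variants <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(variant_key = r[[1]], gene = r[[2]], consequence = r[[3]],
               pop_af = r[[4]], stringsAsFactors = FALSE)))
}

test_that("qualification verdicts follow the MAF/consequence/catalog rules", {
  v <- make_variants(
    list("10:1:G:A", "GRID1", "missense_snv", 0.01),
    list("9:2:C:T", "GRIN3A", "synonymous_snv", 0.001),
    list("10:3:AT:GG", "GRID1", "nonframeshift_substitution", NA_real_),
    list("5:4:G:C", "GRIA1", "missense_snv", 0.06),
    list("5:5:G:C", "GRIA1", "missense_snv", 0.05),  # inclusive threshold
    list("1:6:A:T", NA_character_, "missense_snv", 0.001),
    list("2:7:A:T", "TTN", "missense_snv", 0.001))
  q <- qualify_variants(v)
  expect_equal(q$reason,
               c("pass", "fail_synonymous", "pass", "fail_maf", "pass",
                 "fail_no_gene", "fail_gene_not_in_catalog"))
  expect_equal(q$verdict == "pass", q$reason == "pass")
  # stricter threshold flips the boundary variant only
  q2 <- qualify_variants(v, analysis_config(maf_threshold = 0.01))
  expect_equal(q2$reason[c(1, 5)], c("pass", "fail_maf"))
})

test_that("carrier matrix: homozygotes count once, non-carriers all-zero", {
  v <- make_variants(list("5:100:G:A", "GRIA1", "missense_snv", 0.01))
  geno <- list(patient_ids = c("A", "B"), variant_keys = "5:100:G:A",
               allele_counts = matrix(c(2L, 0L), nrow = 2,
                                      dimnames = list(c("A", "B"),
                                                      "5:100:G:A")))
  carr <- build_carrier_matrix(qualify_variants(v), geno)
  expect_equal(unname(carr[, "GRIA1"]), c(1, 0))
  expect_true(all(carr["B", ] == 0))
})

test_that("fixture GRIN3A carriers: 19 overall, 7 vs 12 by behavior ADR", {
  dat <- paper_fixture_data()
  carr <- build_carrier_matrix(qualify_variants(dat$variants), dat$genotypes)
  g3 <- carr[, "GRIN3A"]
  expect_equal(sum(g3), 19)
  expect_equal(sum(g3[dat$phenotypes$behavior_adr == 1]), 7)
  expect_equal(sum(g3[dat$phenotypes$behavior_adr == 0]), 12)
})

test_that("burden counts: partition additivity and mode contract", {
  v <- make_variants(
    list("5:1:G:A", "GRIA1", "missense_snv", 0.01),
    list("6:2:C:T", "GRIK2", "missense_snv", 0.01))
  ac <- matrix(c(1L, 2L, 1L, 0L), nrow = 2, byrow = FALSE,
               dimnames = list(c("A", "B"), c("5:1:G:A", "6:2:C:T")))
  geno <- list(patient_ids = c("A", "B"), variant_keys = colnames(ac),
               allele_counts = ac)
  q <- qualify_variants(v)
  b <- build_burden_matrix(q, geno)
  expect_equal(unname(b["A", c("AMPA", "kainate", "all_genes")]), c(1, 1, 2))
  # hom-alt: 1 under distinct_sites, 2 under allele_dosage
  expect_equal(unname(b["B", "all_genes"]), 1)
  b2 <- build_burden_matrix(q, geno,
                            config = analysis_config(burden_mode = "allele_dosage"))
  expect_equal(unname(b2["B", "all_genes"]), 2)
  # all variants failing leaves an identically zero burden matrix
  v0 <- make_variants(list("5:1:G:A", "GRIA1", "synonymous_snv", 0.01),
                      list("6:2:C:T", "GRIK2", "missense_snv", 0.2))
  expect_true(all(build_burden_matrix(qualify_variants(v0), geno) == 0))
})

test_that("missing genotypes follow the configured policy", {
  v <- make_variants(list("5:1:G:A", "GRIA1", "missense_snv", 0.01))
  ac <- matrix(c(NA_integer_, 1L), nrow = 2,
               dimnames = list(c("A", "B"), "5:1:G:A"))
  geno <- list(patient_ids = c("A", "B"), variant_keys = "5:1:G:A",
               allele_counts = ac)
  q <- qualify_variants(v)
  expect_message(carr <- build_carrier_matrix(q, geno), "1 missing")
  expect_equal(unname(carr[, "GRIA1"]), c(0, 1))
  expect_error(
    build_carrier_matrix(q, geno,
                         config = analysis_config(missing_genotype_policy = "error")),
    "patient A.*5:1:G:A")
})

test_that("properties on simulated cohorts: additivity, monotonicity, consistency", {
  cfg <- simulation_config(
    n_patients = 40,
    per_gene_carrier_freq = setNames(rep(0.3, 6),
                                     c("GRIA1", "GRID1", "GRIK2", "GRIN3A",
                                       "GRM1", "GRM8")),
    variants_per_gene = 3L,
    maf_generator = function(n) runif(n, 0, 0.1), # some sites exceed 0.05
    seed = 11L)
  for (s in 1:5) {
    cfg$seed <- 100L + s
    dat <- simulate_cohort_data(cfg)
    q <- qualify_variants(dat$variants)
    cb_carr <- build_carrier_matrix(q, dat$genotypes)
    gb <- rvburden:::carrier_and_burden(q, dat$genotypes,
                                        glutamate_receptor_catalog(),
                                        analysis_config())
    # partition additivity: whole-set burden is the sum of the 5 subgroups
    expect_equal(gb$burden[, "all_genes"],
                 rowSums(gb$burden[, names(glutamate_receptor_catalog()$groups)]))
    # carrier/burden consistency in distinct_sites mode
    expect_equal(cb_carr >= 1, gb$gene_burden >= 1)
    # relaxing the MAF threshold never decreases any burden entry
    b_strict <- build_burden_matrix(
      qualify_variants(dat$variants, analysis_config(maf_threshold = 0.01)),
      dat$genotypes)
    b_loose <- build_burden_matrix(
      qualify_variants(dat$variants, analysis_config(maf_threshold = 0.05)),
      dat$genotypes)
    expect_true(all(b_loose >= b_strict))
    # deleting a failed variant changes nothing downstream
    fail_keys <- q$variant_key[q$verdict == "fail"]
    if (length(fail_keys) > 0) {
      keep <- !(dat$variants$variant_key %in% fail_keys)
      dat2 <- dat
      dat2$variants <- dat$variants[keep, ]
      dat2$genotypes$variant_keys <- dat$genotypes$variant_keys[keep]
      dat2$genotypes$allele_counts <-
        dat$genotypes$allele_counts[, keep, drop = FALSE]
      expect_equal(build_burden_matrix(qualify_variants(dat2$variants),
                                       dat2$genotypes),
                   b_loose)
    }
  }
})
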