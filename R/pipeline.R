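#' Load and cross-validate the three input files
#'
#' Reads the multi-sample VCF, joins the annotation sidecar onto its
#' records, and reads the phenotype table, requiring its patient set to
#' coincide with the VCF samples. Phenotype rows are aligned to the VCF
#' sample order so downstream statistics are invariant to input row order.
#'
#' @param vcf,annotation,phenotypes Paths to the three input files.
#' @param catalog A [gene_set_catalog()]; defaults to the 26
#'   glutamate-receptor genes.
#' @return List with `variants`, `genotypes`, `phenotypes`, `catalog`,
#'   `paths`.
#' @export
load_inputs <- function(vcf, annotation, phenotypes,
                        catalog = glutamate_receptor_catalog()) {
  vc <- read_vcf(vcf)
  variants <- read_annotation(annotation, vc$variants)
  ph <- read_phenotypes(phenotypes, expected_ids = vc$genotypes$patient_ids)
  # canonicalize patient order so downstream statistics (including iterative
  # model fits) are bit-identical under input row/column permutations
  ids <- sort(vc$genotypes$patient_ids, method = "radix")
  vc$genotypes$allele_counts <-
    vc$genotypes$allele_counts[ids, , drop = FALSE]
  vc$genotypes$patient_ids <- ids
  ph <- ph[match(ids, ph$patient_id), , drop = FALSE]
  rownames(ph) <- NULL
  list(variants = variants, genotypes = vc$genotypes, phenotypes = ph,
       catalog = catalog,
       paths = c(vcf = vcf, annotation = annotation, phenotypes = phenotypes))
}

result_row <- function(unit, unit_kind, outcome, test, statistic, or,
                       ci_low, ci_high, p, m, alpha) {
  thr <- bonferroni(alpha, m)
  data.frame(unit = unit, unit_kind = unit_kind, outcome = outcome,
             test = test, statistic = statistic, odds_ratio = or,
             ci_low = ci_low, ci_high = ci_high, p_value = p,
             bonferroni_threshold = thr,
             significant_nominal = if (is.na(p)) NA else p < alpha,
             significant_adjusted = if (is.na(p)) NA else p < thr,
             p_bonferroni = if (is.na(p)) NA_real_ else min(1, m * p),
             stringsAsFactors = FALSE)
}

#' Gene-group burden analysis
#'
#' For each of the four outcomes, compares per-patient qualifying-variant
#' counts between outcome-present and outcome-absent patients with the
#' Mann-Whitney U test: once for the whole 26-gene set (its own single-test
#' family, reported at the nominal threshold) and once per functional
#' subgroup (Bonferroni family of 5, threshold `alpha/5`). The descriptive
#' per-count logistic odds ratio of [burden_or_logistic()] is attached to
#' each row; significance calls come from the Mann-Whitney p-value only.
#' Outcomes with a single class are skipped with a warning, as is the whole
#' analysis when every patient has zero burden.
#'
#' @param inputs Input list from [load_inputs()] (or the same shape built in
#'   memory).
#' @param config An [analysis_config()].
#' @return data.frame of association results (one row per test), with the
#'   12 reporting columns plus `p_bonferroni`.
#' @export
run_burden_analysis <- function(inputs, config = analysis_config()) {
  qualified <- qualify_variants(inputs$variants, config, inputs$catalog)
  cb <- carrier_and_burden(qualified, inputs$genotypes, inputs$catalog, config)
  burden <- cb$burden
  out <- list()
  if (all(burden == 0)) {
    warning("every patient has zero burden; burden analysis skipped",
            call. = FALSE)
    return(empty_results())
  }
  groups <- names(inputs$catalog$groups)
  for (oc in outcome_names()) {
    y <- inputs$phenotypes[[oc]]
    if (length(unique(y)) < 2L) {
      warning("outcome `", oc, "` has a single class; skipped", call. = FALSE)
      next
    }
    units <- c("all_genes", groups)
    fam <- c(1L, rep(length(groups), length(groups)))
    for (i in seq_along(units)) {
      counts <- burden[, units[i]]
      mwu <- mann_whitney_u(counts[y == 1], counts[y == 0])
      comp <- burden_or_logistic(counts, y, level = config$ci_level)
      out[[length(out) + 1L]] <- result_row(
        units[i], "group", oc, "mann_whitney", mwu$statistic,
        comp$or, comp$ci_low, comp$ci_high, mwu$p_value,
        fam[i], config$alpha)
    }
  }
  if (length(out) == 0L) return(empty_results())
  do.call(rbind, out)
}

#' Gene collapse analysis
#'
#' For each outcome, dichotomizes every catalog gene as carrier (at least
#' one qualifying variant) versus non-carrier and tests association with
#' the outcome by the Fisher exact test, reporting the conditional
#' maximum-likelihood odds ratio and exact confidence interval. The
#' Bonferroni family size stays at the full catalog size (26) regardless of
#' how many genes are testable; genes with zero carriers are reported as
#' untestable (`NA` statistics) rather than `p = 1`. The `statistic` column
#' carries the observed carrier-with-outcome cell count.
#'
#' @inheritParams run_burden_analysis
#' @return data.frame of association results.
#' @export
run_collapse_analysis <- function(inputs, config = analysis_config()) {
  qualified <- qualify_variants(inputs$variants, config, inputs$catalog)
  carrier <- carrier_and_burden(qualified, inputs$genotypes,
                                inputs$catalog, config)$carrier
  genes <- inputs$catalog$all_genes
  m <- length(genes)
  out <- list()
  for (oc in outcome_names()) {
    y <- inputs$phenotypes[[oc]]
    if (length(unique(y)) < 2L) {
      warning("outcome `", oc, "` has a single class; skipped", call. = FALSE)
      next
    }
    for (g in genes) {
      carr <- carrier[, g]
      if (sum(carr) == 0) {
        out[[length(out) + 1L]] <- result_row(
          g, "gene", oc, "fisher_exact", NA_real_, NA_real_,
          NA_real_, NA_real_, NA_real_, m, config$alpha)
        next
      }
      t <- two_by_two(sum(carr == 1 & y == 1), sum(carr == 0 & y == 1),
                      sum(carr == 1 & y == 0), sum(carr == 0 & y == 0))
      p <- fisher_two_sided_p(t)
      ci <- exact_or_ci(t, level = config$ci_level)
      out[[length(out) + 1L]] <- result_row(
        g, "gene", oc, "fisher_exact", t$a, conditional_mle_or(t),
        ci[1], ci[2], p, m, config$alpha)
    }
  }
  if (length(out) == 0L) return(empty_results())
  do.call(rbind, out)
}

empty_results <- function() {
  data.frame(unit = character(), unit_kind = character(),
             outcome = character(), test = character(),
             statistic = numeric(), odds_ratio = numeric(),
             ci_low = numeric(), ci_high = numeric(), p_value = numeric(),
             bonferroni_threshold = numeric(),
             significant_nominal = logical(),
             significant_adjusted = logical(),
             p_bonferroni = numeric(),
             stringsAsFactors = FALSE)
}

#' Run the full association pipeline
#'
#' Loads and validates the inputs, runs both the gene-group burden analysis
#' and the gene collapse analysis, and writes `results.tsv` (the combined
#' association table), `audit.tsv` (one qualification verdict per loaded
#' variant) and `manifest.json` (input digests, configuration snapshot and
#' per-stage record counts) into `out_dir`. Identical inputs and
#' configuration produce byte-identical outputs.
#'
#' @param vcf,annotation,phenotypes Paths to the three input files.
#' @param out_dir Output directory (created if absent).
#' @param config An [analysis_config()].
#' @param catalog A [gene_set_catalog()].
#' @return Invisibly, a list with `results`, `qualified`, `manifest` and the
#'   output file paths.
#' @export
run_all <- function(vcf, annotation, phenotypes, out_dir,
                    config = analysis_config(),
                    catalog = glutamate_receptor_catalog()) {
  inputs <- load_inputs(vcf, annotation, phenotypes, catalog)
  qualified <- qualify_variants(inputs$variants, config, catalog)
  burden_res <- run_burden_analysis(inputs, config)
  collapse_res <- run_collapse_analysis(inputs, config)
  results <- rbind(burden_res, collapse_res)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  results_path <- file.path(out_dir, "results.tsv")
  audit_path <- file.path(out_dir, "audit.tsv")
  manifest_path <- file.path(out_dir, "manifest.json")
  write_results(results, results_path)
  write_audit(qualified, audit_path)

  manifest <- list(
    inputs = as.list(tools::md5sum(unname(inputs$paths))),
    config = unclass(config),
    catalog = list(n_genes = length(catalog$all_genes),
                   groups = lapply(catalog$groups, identity)),
    counts = list(
      patients = nrow(inputs$phenotypes),
      variants_loaded = nrow(inputs$variants),
      variants_qualified = sum(qualified$verdict == "pass"),
      genes_with_carrier = sum(colSums(
        carrier_and_burden(qualified, inputs$genotypes, catalog,
                           config)$carrier) > 0),
      tests_run = sum(!is.na(results$p_value)),
      untestable = sum(is.na(results$p_value))
    ),
    version = as.character(utils::packageVersion("rvburden"))
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(results = results, qualified = qualified,
                 manifest = manifest,
                 paths = c(results = results_path, audit = audit_path,
                           manifest = manifest_path)))
}
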