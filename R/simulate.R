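# Synthetic placement of candidate-gene variant sites: approximate GRCh38
# gene starts, used only to mint plausible-looking coordinates. Genomic
# realism is a non-goal; positions never leave the package's own files.
gene_coordinates <- function() {
  data.frame(
    gene = c("GRIA1", "GRIA2", "GRIA3", "GRIA4",
             "GRID1", "GRID2",
             "GRIK1", "GRIK2", "GRIK3", "GRIK4", "GRIK5",
             "GRIN1", "GRIN2A", "GRIN2B", "GRIN2C", "GRIN2D",
             "GRIN3A", "GRIN3B",
             "GRM1", "GRM2", "GRM3", "GRM4", "GRM5", "GRM6", "GRM7", "GRM8"),
    chrom = c("5", "4", "X", "11", "10", "4", "21", "6", "1", "11", "19",
              "9", "16", "12", "17", "19", "9", "19",
              "6", "3", "7", "6", "11", "5", "3", "7"),
    start = c(153490000L, 157200000L, 123180000L, 105600000L,
              85600000L, 92300000L,
              29540000L, 101390000L, 36790000L, 120380000L, 41970000L,
              137140000L, 9750000L, 13530000L, 74840000L, 48390000L,
              101560000L, 995000L,
              146020000L, 51700000L, 86800000L, 34000000L, 88500000L,
              178970000L, 6800000L, 126440000L),
    stringsAsFactors = FALSE)
}

#' Simulation configuration for synthetic cohorts
#'
#' Defaults emulate the study conditions of the reference cohort: 83
#' patients with outcome prevalences 14/83 (response), 22/83 (any ADR),
#' 14/83 (behavior ADR, generated as a sub-event of ADR) and 61/83 (1-year
#' retention), and a baseline per-gene probability of 0.10 of carrying at
#' least one qualifying variant.
#'
#' @param n_patients Cohort size (>= 2).
#' @param outcome_prevalences Named vector over [outcome_names()] of marginal
#'   prevalences in `[0, 1]`; `behavior_adr` must not exceed `adr`.
#' @param per_gene_carrier_freq Named vector mapping gene symbols to baseline
#'   carrier probabilities; only these genes receive simulated variants.
#' @param effect_map Optional data.frame with columns `unit` (gene or group
#'   name), `outcome`, `or`: for gene units, the odds ratio by which carrier
#'   odds are multiplied in outcome-positive patients; group units apply the
#'   multiplier to every member gene.
#' @param variants_per_gene Number of variant sites simulated per gene.
#' @param maf_generator Function `n -> n` frequencies in `[0, 0.1]` used for
#'   the sidecar's reference-population AFs; the default Uniform(0, 0.05)
#'   keeps every simulated site below the qualification threshold.
#' @param seed Integer seed; the whole module is deterministic given it.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_patients = 83L,
                              outcome_prevalences = c(response = 14 / 83,
                                                      adr = 22 / 83,
                                                      behavior_adr = 14 / 83,
                                                      retention_1yr = 61 / 83),
                              per_gene_carrier_freq = stats::setNames(
                                rep(0.10, 26),
                                glutamate_receptor_catalog()$all_genes),
                              effect_map = NULL,
                              variants_per_gene = 2L,
                              maf_generator = function(n) stats::runif(n, 0, 0.05),
                              seed = 1L) {
  if (!is.numeric(n_patients) || n_patients < 2)
    stop("n_patients must be >= 2", call. = FALSE)
  miss <- setdiff(outcome_names(), names(outcome_prevalences))
  if (length(miss) > 0L)
    stop("outcome_prevalences missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(outcome_prevalences < 0 | outcome_prevalences > 1))
    stop("outcome prevalences must lie in [0, 1]", call. = FALSE)
  if (outcome_prevalences[["behavior_adr"]] > outcome_prevalences[["adr"]])
    stop("inconsistent prevalences: behavior_adr exceeds adr ",
         "(behavior ADRs are a subset of ADRs)", call. = FALSE)
  if (is.null(names(per_gene_carrier_freq)))
    stop("per_gene_carrier_freq must be named by gene", call. = FALSE)
  if (any(per_gene_carrier_freq < 0 | per_gene_carrier_freq > 1))
    stop("carrier frequencies must lie in [0, 1]", call. = FALSE)
  if (!is.null(effect_map)) {
    stopifnot(is.data.frame(effect_map),
              all(c("unit", "outcome", "or") %in% names(effect_map)))
    if (any(effect_map$or <= 0))
      stop("effect odds ratios must be positive", call. = FALSE)
  }
  structure(list(n_patients = as.integer(n_patients),
                 outcome_prevalences = outcome_prevalences,
                 per_gene_carrier_freq = per_gene_carrier_freq,
                 effect_map = effect_map,
                 variants_per_gene = as.integer(variants_per_gene),
                 maf_generator = maf_generator,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a cohort in memory
#'
#' Draws the four binary outcomes at their configured marginal prevalences
#' (behavior ADR as a sub-event of ADR, with conditional probability chosen
#' to hit its marginal), then per-gene carrier status with the carrier logit
#' shifted by `log(or)` for outcome-positive patients per the effect map.
#' Each carrier is assigned one heterozygous variant at a uniformly chosen
#' site of the gene. Deterministic given `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return List with `variants` (annotated records), `genotypes`
#'   (as from [read_vcf()]) and `phenotypes`.
#' @export
simulate_cohort_data <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, {
    n <- config$n_patients
    ids <- sprintf("P%04d", seq_len(n))
    prev <- config$outcome_prevalences
    ph <- data.frame(patient_id = ids, stringsAsFactors = FALSE)
    ph$response <- stats::rbinom(n, 1L, prev[["response"]])
    ph$adr <- stats::rbinom(n, 1L, prev[["adr"]])
    p_beh <- if (prev[["adr"]] > 0) prev[["behavior_adr"]] / prev[["adr"]] else 0
    ph$behavior_adr <- ph$adr * stats::rbinom(n, 1L, p_beh)
    ph$retention_1yr <- stats::rbinom(n, 1L, prev[["retention_1yr"]])

    genes <- names(config$per_gene_carrier_freq)
    coords <- gene_coordinates()
    k <- config$variants_per_gene
    bases <- c("A", "C", "G", "T")
    var_list <- list()
    ac_cols <- list()
    for (g in genes) {
      ci <- match(g, coords$gene)
      chrom <- if (is.na(ci)) "1" else coords$chrom[ci]
      start <- if (is.na(ci)) 1e6L else coords$start[ci]
      pos <- start + 137L * seq_len(k)
      ref <- sample(bases, k, replace = TRUE)
      alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
      af <- config$maf_generator(k)
      eta <- stats::qlogis(config$per_gene_carrier_freq[[g]])
      eta <- rep(eta, n)
      if (!is.null(config$effect_map)) {
        em <- config$effect_map
        hit <- em$unit == g |
          vapply(em$unit, function(u) {
            grp <- glutamate_receptor_catalog()$groups[[u]]
            !is.null(grp) && g %in% grp
          }, logical(1))
        for (r in which(hit))
          eta <- eta + log(em$or[r]) * ph[[em$outcome[r]]]
      }
      carrier <- stats::rbinom(n, 1L, stats::plogis(eta))
      site <- sample.int(k, n, replace = TRUE)
      ac <- matrix(0L, nrow = n, ncol = k)
      ac[cbind(which(carrier == 1L), site[carrier == 1L])] <- 1L
      var_list[[g]] <- data.frame(
        chrom = chrom, pos = pos, ref = ref, alt = alt,
        variant_key = paste(chrom, pos, ref, alt, sep = ":"),
        gene = g, consequence = "missense_snv", pop_af = af,
        stringsAsFactors = FALSE)
      ac_cols[[g]] <- ac
    }
    variants <- do.call(rbind, var_list)
    rownames(variants) <- NULL
    ac <- do.call(cbind, ac_cols)
    dimnames(ac) <- list(ids, variants$variant_key)
    list(variants = variants,
         genotypes = list(patient_ids = ids,
                          variant_keys = variants$variant_key,
                          allele_counts = ac),
         phenotypes = ph)
  })
}

#' Write a cohort as VCF + sidecar + phenotype files
#'
#' @param data Cohort list from [simulate_cohort_data()] or
#'   [paper_fixture_data()].
#' @param dir Output directory (created if absent).
#' @param prefix File-name prefix.
#' @return Named character vector of the three paths.
#' @export
write_cohort <- function(data, dir, prefix = "cohort") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(vcf = file.path(dir, paste0(prefix, ".vcf")),
             annotation = file.path(dir, paste0(prefix, "_annotation.tsv")),
             phenotypes = file.path(dir, paste0(prefix, "_phenotypes.tsv")))
  v <- data$variants
  ord <- order(suppressWarnings(as.integer(v$chrom)), v$chrom, v$pos,
               v$alt, method = "radix")
  write_vcf_file(v[ord, , drop = FALSE],
                 data$genotypes$allele_counts[, ord, drop = FALSE],
                 data$genotypes$patient_ids, paths[["vcf"]])
  side <- v[ord, c("variant_key", "gene", "consequence", "pop_af")]
  utils::write.table(side, paths[["annotation"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data$phenotypes, paths[["phenotypes"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths
}

#' Simulate a cohort and write its file triple
#'
#' @param config A [simulation_config()].
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Invisibly, list with `paths` and the in-memory `data`; identical
#'   seeds yield byte-identical files.
#' @export
simulate_cohort <- function(config, dir, prefix = "cohort") {
  data <- simulate_cohort_data(config)
  paths <- write_cohort(data, dir, prefix)
  invisible(list(paths = paths, data = data))
}

#' The deterministic 83-patient fixture cohort
#'
#' Reconstructs, without randomness, a cohort with the reference study's
#' marginal structure: 83 patients with outcome counts 14 (response), 22
#' (ADR), 14 (behavior ADR, nested in ADR) and 61 (1-year retention), and
#' the seven published GRID1/GRIN3A variants assigned to distinct patients
#' with their published carrier splits — GRID1 sites split (5, 3) and (2, 1)
#' across ADR / no-ADR, GRIN3A sites split (1,0), (0,1), (1,3), (3,1), (2,7)
#' across behavior ADR / no behavior ADR. All other catalog genes are
#' variant-free. Coordinates are synthetic; the two delins records carry
#' consequence `nonframeshift_substitution`, the rest `missense_snv`, and
#' every sidecar `pop_af` is below 0.05 so all seven sites qualify.
#'
#' Patient assignment (the published tables fix only the margins): behavior
#' ADR patients are P001-P014, ADR patients P001-P022; GRID1 carriers among
#' ADR patients are placed in the non-behavior stratum P015-P022, and the
#' response / retention sets are spread across the cohort, so the fixture
#' adds no association the reference tables do not themselves imply.
#'
#' @return Cohort list as from [simulate_cohort_data()].
#' @export
paper_fixture_data <- function() {
  n <- 83L
  ids <- sprintf("P%03d", seq_len(n))
  adr <- as.integer(seq_len(n) <= 22L)
  behavior <- as.integer(seq_len(n) <= 14L)
  response_idx <- c(2L, 8L, 16L, 22L, 26L, 32L, 39L, 44L, 50L, 56L, 62L,
                    68L, 74L, 80L)
  non_retained_idx <- c(3L, 7L, 11L, 14L, 18L, 21L, 25L, 28L, 31L, 34L, 38L,
                        41L, 45L, 49L, 53L, 57L, 61L, 65L, 69L, 73L, 77L, 81L)
  ph <- data.frame(
    patient_id = ids,
    response = as.integer(seq_len(n) %in% response_idx),
    adr = adr,
    behavior_adr = behavior,
    retention_1yr = as.integer(!(seq_len(n) %in% non_retained_idx)),
    stringsAsFactors = FALSE)

  variants <- data.frame(
    chrom = c("10", "10", "9", "9", "9", "9", "9"),
    pos = c(85601585L, 85601287L, 101560322L, 101560055L, 101561462L,
            101561438L, 101562501L),
    ref = c("G", "AT", "C", "C", "A", "C", "TG"),
    alt = c("A", "GG", "G", "T", "G", "G", "CA"),
    id = c("GRID1:c.1585G>A", "GRID1:c.1287_1288delinsGG",
           "GRIN3A:c.322C>G", "GRIN3A:c.55C>T", "GRIN3A:c.1462A>G",
           "GRIN3A:c.1438C>G", "GRIN3A:c.2501_2502delinsCA"),
    gene = c("GRID1", "GRID1", rep("GRIN3A", 5L)),
    consequence = c("missense_snv", "nonframeshift_substitution",
                    "missense_snv", "missense_snv", "missense_snv",
                    "missense_snv", "nonframeshift_substitution"),
    pop_af = c(0.004, 0.001, 0.0005, 0.002, 0.01, 0.008, 0.02),
    stringsAsFactors = FALSE)
  variants$variant_key <- paste(variants$chrom, variants$pos, variants$ref,
                                variants$alt, sep = ":")
  # one heterozygous variant per carrier, carriers distinct across variants
  carriers <- list(
    c(15:19, 35:37),        # GRID1 c.1585G>A: 5 ADR / 3 no-ADR
    c(20:21, 38),           # GRID1 delinsGG: 2 ADR / 1 no-ADR
    1,                      # GRIN3A c.322C>G: 1 behavior / 0
    23,                     # GRIN3A c.55C>T: 0 behavior / 1
    c(2, 24:26),            # GRIN3A c.1462A>G: 1 / 3
    c(3:5, 27),             # GRIN3A c.1438C>G: 3 / 1
    c(6:7, 28:34))          # GRIN3A delinsCA: 2 / 7
  ac <- matrix(0L, nrow = n, ncol = nrow(variants),
               dimnames = list(ids, variants$variant_key))
  for (j in seq_along(carriers)) ac[carriers[[j]], j] <- 1L
  list(variants = variants,
       genotypes = list(patient_ids = ids,
                        variant_keys = variants$variant_key,
                        allele_counts = ac),
       phenotypes = ph)
}

#' Write the fixture cohort's file triple
#'
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Named character vector of the three paths (deterministic,
#'   byte-identical across runs).
#' @export
paper_fixture <- function(dir, prefix = "fixture") {
  write_cohort(paper_fixture_data(), dir, prefix)
}

#' Parameter-recovery and type-I-error experiment
#'
#' Simulates `replicates` cohorts under `config`, runs each through variant
#' qualification, carrier collapsing and the Fisher-exact machinery for the
#' requested genes and outcome, and summarizes the conditional-MLE odds
#' ratio, exact CI coverage of the configured truth, and rejection rates at
#' the nominal and Bonferroni (catalog-family) thresholds. Cohorts are held
#' in memory; file emission fidelity is covered by the I/O round-trip
#' contract, not re-exercised per replicate.
#'
#' @param config A [simulation_config()]; replicate `r` uses seed
#'   `config$seed + r`.
#' @param replicates Number of replicates (>= 1; coverage is only reported
#'   for >= 2).
#' @param genes Genes to test; defaults to the genes named in the effect
#'   map, else all simulated genes.
#' @param outcome Outcome to test against.
#' @param catalog A [gene_set_catalog()].
#' @param analysis An [analysis_config()].
#' @return List with `summary` (one row per gene) and `replicates` (one row
#'   per replicate x gene: `psi`, `ci_low`, `ci_high`, `p`).
#' @export
recovery_experiment <- function(config, replicates, genes = NULL,
                                outcome = "adr",
                                catalog = glutamate_receptor_catalog(),
                                analysis = analysis_config()) {
  stopifnot(inherits(config, "simulation_config"), replicates >= 1)
  outcome <- match.arg(outcome, outcome_names())
  if (is.null(genes)) {
    genes <- if (!is.null(config$effect_map))
      intersect(unique(config$effect_map$unit), catalog$all_genes)
    else intersect(names(config$per_gene_carrier_freq), catalog$all_genes)
  }
  if (length(genes) == 0L) stop("no genes to test", call. = FALSE)
  true_or <- vapply(genes, function(g) {
    em <- config$effect_map
    if (is.null(em)) return(1)
    hit <- em$unit == g & em$outcome == outcome
    if (any(hit)) em$or[which(hit)[1]] else 1
  }, numeric(1))

  rows <- vector("list", replicates * length(genes))
  ri <- 0L
  for (r in seq_len(replicates)) {
    cfg <- config
    cfg$seed <- config$seed + r
    dat <- simulate_cohort_data(cfg)
    qualified <- qualify_variants(dat$variants, analysis, catalog)
    carrier <- carrier_and_burden(qualified, dat$genotypes, catalog,
                                  analysis)$carrier
    y <- dat$phenotypes[[outcome]]
    for (g in genes) {
      ri <- ri + 1L
      carr <- carrier[, g]
      if (length(unique(y)) < 2L || sum(carr) == 0) {
        rows[[ri]] <- data.frame(replicate = r, gene = g, psi = NA_real_,
                                 ci_low = NA_real_, ci_high = NA_real_,
                                 p = NA_real_, stringsAsFactors = FALSE)
        next
      }
      t <- two_by_two(sum(carr == 1 & y == 1), sum(carr == 0 & y == 1),
                      sum(carr == 1 & y == 0), sum(carr == 0 & y == 0))
      ci <- exact_or_ci(t, level = analysis$ci_level)
      rows[[ri]] <- data.frame(replicate = r, gene = g,
                               psi = conditional_mle_or(t),
                               ci_low = ci[1], ci_high = ci[2],
                               p = suppressMessages(fisher_two_sided_p(t)),
                               stringsAsFactors = FALSE)
    }
  }
  reps <- do.call(rbind, rows)
  m_family <- length(catalog$all_genes)
  summary <- do.call(rbind, lapply(genes, function(g) {
    sub <- reps[reps$gene == g, , drop = FALSE]
    ok <- !is.na(sub$p)
    truth <- true_or[[g]]
    data.frame(
      gene = g, outcome = outcome, true_or = truth,
      n_replicates = nrow(sub), n_tested = sum(ok),
      median_psi = if (any(ok)) stats::median(sub$psi[ok]) else NA_real_,
      ci_coverage = if (replicates >= 2 && any(ok))
        mean(sub$ci_low[ok] <= truth & truth <= sub$ci_high[ok])
      else NA_real_,
      reject_nominal = if (any(ok)) mean(sub$p[ok] < analysis$alpha)
      else NA_real_,
      reject_bonferroni = if (any(ok))
        mean(sub$p[ok] < analysis$alpha / m_family) else NA_real_,
      stringsAsFactors = FALSE)
  }))
  list(summary = summary, replicates = reps)
}
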