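#' Qualify rare non-synonymous variants
#'
#' Applies the rare-variant qualification rules to annotated variant
#' records: a variant qualifies when its reference-population allele
#' frequency is missing (a variant absent from the frequency resource is
#' rarer than any threshold) or at most `maf_threshold` (inclusive), its
#' consequence is not a synonymous SNV, and its gene belongs to the
#' candidate-gene catalog. Every variant receives a verdict with a reason
#' code: `pass`, `fail_maf`, `fail_synonymous`, `fail_no_gene`, or
#' `fail_gene_not_in_catalog` (the first applicable reason in the order
#' no-gene, not-in-catalog, synonymous, MAF).
#'
#' @param variants Annotated variant data.frame (from [read_annotation()]).
#' @param config An [analysis_config()].
#' @param catalog A [gene_set_catalog()].
#' @return data.frame with columns `variant_key`, `gene`, `consequence`,
#'   `pop_af`, `verdict` (`"pass"`/`"fail"`), `reason`.
#' @export
qualify_variants <- function(variants, config = analysis_config(),
                             catalog = glutamate_receptor_catalog()) {
  stopifnot(is.data.frame(variants))
  gene <- variants$gene
  reason <- rep("pass", nrow(variants))
  no_gene <- is.na(gene) | gene == ""
  not_cat <- !no_gene & !(gene %in% catalog$all_genes)
  synon <- variants$consequence == "synonymous_snv"
  maf_fail <- !is.na(variants$pop_af) & variants$pop_af > config$maf_threshold
  reason[maf_fail] <- "fail_maf"
  reason[synon] <- "fail_synonymous"
  reason[not_cat] <- "fail_gene_not_in_catalog"
  reason[no_gene] <- "fail_no_gene"
  data.frame(variant_key = variants$variant_key,
             gene = gene,
             consequence = variants$consequence,
             pop_af = variants$pop_af,
             verdict = ifelse(reason == "pass", "pass", "fail"),
             reason = reason,
             stringsAsFactors = FALSE)
}

# Shared worker: resolves missing genotypes per policy, then computes the
# per-gene carrier indicators, per-gene burden contributions and per-set
# burden counts in one pass.
carrier_and_burden <- function(qualified, genotypes, catalog, config) {
  ac <- genotypes$allele_counts
  if (anyNA(ac)) {
    if (config$missing_genotype_policy == "error") {
      idx <- which(is.na(ac), arr.ind = TRUE)[1, ]
      stop("missing genotype for patient ",
           genotypes$patient_ids[idx[1]], " at variant ",
           genotypes$variant_keys[idx[2]],
           " (missing_genotype_policy = \"error\")", call. = FALSE)
    }
    n_missing <- sum(is.na(ac))
    message(n_missing, " missing genotype(s) treated as homozygous reference")
    ac[is.na(ac)] <- 0L
  }
  pass <- qualified[qualified$reason == "pass", , drop = FALSE]
  pass <- pass[pass$variant_key %in% colnames(ac), , drop = FALSE]
  genes <- catalog$all_genes
  npat <- nrow(ac)
  gene_burden <- matrix(0, nrow = npat, ncol = length(genes),
                        dimnames = list(genotypes$patient_ids, genes))
  carrier <- gene_burden
  for (g in genes) {
    keys <- pass$variant_key[pass$gene == g]
    if (length(keys) == 0L) next
    sub <- ac[, keys, drop = FALSE]
    carried <- rowSums(sub >= 1L)
    carrier[, g] <- as.numeric(carried >= 1L)
    gene_burden[, g] <- if (config$burden_mode == "allele_dosage")
      rowSums(sub) else carried
  }
  sets <- c(catalog$groups, list(all_genes = genes))
  burden <- vapply(sets, function(gs)
    rowSums(gene_burden[, gs, drop = FALSE]), numeric(npat))
  if (npat == 1L) burden <- matrix(burden, nrow = 1,
                                   dimnames = list(genotypes$patient_ids,
                                                   names(sets)))
  list(carrier = carrier, gene_burden = gene_burden, burden = burden)
}

#' Per-patient per-gene carrier matrix
#'
#' A patient carries a gene when they have at least one qualifying variant
#' in it with allele count >= 1 (homozygous alternates count once). Missing
#' genotypes are handled per `config$missing_genotype_policy`.
#'
#' @param qualified Qualification verdicts from [qualify_variants()].
#' @param genotypes Genotype list from [read_vcf()].
#' @param catalog A [gene_set_catalog()].
#' @param config An [analysis_config()].
#' @return Patients x genes 0/1 matrix (all catalog genes as columns).
#' @export
build_carrier_matrix <- function(qualified, genotypes,
                                 catalog = glutamate_receptor_catalog(),
                                 config = analysis_config()) {
  carrier_and_burden(qualified, genotypes, catalog, config)$carrier
}

#' Per-patient gene-set burden counts
#'
#' Under the default `burden_mode = "distinct_sites"` each qualifying site
#' carried (allele count >= 1) contributes 1 to every gene set containing
#' its gene; under `"allele_dosage"` it contributes its allele count. The
#' returned matrix has one column per functional subgroup plus `all_genes`
#' (the whole catalog), which by partition additivity equals the sum of the
#' subgroup columns.
#'
#' @inheritParams build_carrier_matrix
#' @return Patients x gene-sets numeric matrix.
#' @export
build_burden_matrix <- function(qualified, genotypes,
                                catalog = glutamate_receptor_catalog(),
                                config = analysis_config()) {
  carrier_and_burden(qualified, genotypes, catalog, config)$burden
}
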