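#' Analysis configuration
#'
#' Bundles the tunable parameters of the qualification and association
#' pipeline.
#'
#' @param maf_threshold Reference-population minor-allele-frequency cut-off;
#'   a variant qualifies when its `pop_af` is missing or `<= maf_threshold`
#'   (inclusive). Default 0.05.
#' @param alpha Family-wise significance level used for nominal and
#'   Bonferroni-adjusted calls. Default 0.05.
#' @param ci_level Confidence level for odds-ratio intervals. Default 0.95.
#' @param burden_mode How a qualifying site contributes to a patient's burden
#'   count: `"distinct_sites"` (one per carried site, the default) or
#'   `"allele_dosage"` (its allele count, so homozygous alternates count
#'   twice).
#' @param missing_genotype_policy `"as_reference"` treats missing genotypes
#'   as homozygous reference (logged with a count); `"error"` aborts on the
#'   first missing genotype.
#' @param seed Integer seed for any stochastic component downstream.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(maf_threshold = 0.05,
                            alpha = 0.05,
                            ci_level = 0.95,
                            burden_mode = c("distinct_sites", "allele_dosage"),
                            missing_genotype_policy = c("as_reference", "error"),
                            seed = 1L) {
  burden_mode <- match.arg(burden_mode)
  missing_genotype_policy <- match.arg(missing_genotype_policy)
  stopifnot(is.numeric(maf_threshold), length(maf_threshold) == 1L,
            maf_threshold >= 0, maf_threshold <= 1)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("`alpha` must lie strictly between 0 and 1", call. = FALSE)
  if (!is.numeric(ci_level) || length(ci_level) != 1L ||
      ci_level <= 0 || ci_level >= 1)
    stop("`ci_level` must lie strictly between 0 and 1", call. = FALSE)
  structure(list(maf_threshold = maf_threshold,
                 alpha = alpha,
                 ci_level = ci_level,
                 burden_mode = burden_mode,
                 missing_genotype_policy = missing_genotype_policy,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

#' Controlled vocabulary of functional consequences
#'
#' @return Character vector of the allowed `consequence` tokens.
#' @export
consequence_vocabulary <- function() {
  c("synonymous_snv", "missense_snv", "nonframeshift_substitution",
    "frameshift", "stop_gain", "splice", "other", "unannotated")
}

#' Canonical outcome names
#'
#' The four binary treatment outcomes, in the fixed reporting order:
#' seizure response, any adverse drug reaction, behavior adverse drug
#' reaction, and 1-year retention.
#'
#' @return Character vector of length four.
#' @export
outcome_names <- function() {
  c("response", "adr", "behavior_adr", "retention_1yr")
}
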