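#' Read the variant annotation sidecar
#'
#' Tab-separated file with header columns `variant_key`, `gene`,
#' `consequence`, `pop_af`. `consequence` must come from the closed
#' vocabulary of [consequence_vocabulary()]; `pop_af` is the
#' reference-population alternate-allele frequency in `[0, 1]` (empty or
#' `NA` when the variant is absent from the frequency resource). When
#' `variants` (the stub data.frame from [read_vcf()]) is supplied the
#' sidecar is left-joined onto it by `variant_key`: VCF records absent from
#' the sidecar keep `consequence = "unannotated"` and `pop_af = NA`.
#'
#' @param path Path to the TSV sidecar.
#' @param variants Optional variant stubs from [read_vcf()] to join onto.
#' @return A data.frame of annotated variant records.
#' @export
read_annotation <- function(path, variants = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  side <- utils::read.delim(path, sep = "\t", header = TRUE,
                            colClasses = "character", na.strings = c("NA", ""))
  required <- c("variant_key", "gene", "consequence", "pop_af")
  miss <- setdiff(required, names(side))
  if (length(miss) > 0L)
    stop("annotation sidecar missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(stats::na.omit(unique(side$consequence)), consequence_vocabulary())
  if (length(bad) > 0L)
    stop("unknown consequence token(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(consequence_vocabulary(), collapse = ", "),
         call. = FALSE)
  side$consequence[is.na(side$consequence)] <- "unannotated"
  af <- suppressWarnings(as.numeric(side$pop_af))
  bad_af <- which(!is.na(side$pop_af) & (is.na(af) | af < 0 | af > 1))
  if (length(bad_af) > 0L)
    stop("pop_af outside [0,1] or non-numeric in sidecar row(s): ",
         paste(bad_af, collapse = ", "), call. = FALSE)
  side$pop_af <- af
  dup <- unique(side$variant_key[duplicated(side$variant_key)])
  if (length(dup) > 0L)
    stop("duplicate variant_key in sidecar: ", paste(dup, collapse = ", "),
         call. = FALSE)

  if (is.null(variants)) {
    parts <- strsplit(side$variant_key, ":", fixed = TRUE)
    if (any(vapply(parts, length, 1L) != 4L))
      stop("variant_key must be \"chrom:pos:ref:alt\"", call. = FALSE)
    return(data.frame(
      chrom = vapply(parts, `[`, "", 1L),
      pos = as.integer(vapply(parts, `[`, "", 2L)),
      ref = vapply(parts, `[`, "", 3L),
      alt = vapply(parts, `[`, "", 4L),
      variant_key = side$variant_key,
      gene = side$gene,
      consequence = side$consequence,
      pop_af = side$pop_af,
      stringsAsFactors = FALSE))
  }

  orphan <- setdiff(side$variant_key, variants$variant_key)
  if (length(orphan) > 0L)
    warning(length(orphan), " sidecar record(s) not present in the VCF: ",
            paste(utils::head(orphan, 5L), collapse = ", "),
            if (length(orphan) > 5L) ", ..." else "", call. = FALSE)
  idx <- match(variants$variant_key, side$variant_key)
  hit <- !is.na(idx)
  variants$gene[hit] <- side$gene[idx[hit]]
  variants$consequence[hit] <- side$consequence[idx[hit]]
  variants$pop_af[hit] <- side$pop_af[idx[hit]]
  variants
}

#' Read the phenotype table
#'
#' Tab-separated file with one row per patient and header columns
#' `patient_id`, `response`, `adr`, `behavior_adr`, `retention_1yr`; the
#' four outcome columns must be coded strictly 0/1. Behavior adverse drug
#' reactions are a subset of adverse drug reactions, so `behavior_adr = 1`
#' with `adr = 0` is a consistency error. When `expected_ids` (the VCF
#' sample list) is supplied, the two ID sets must coincide.
#'
#' @param path Path to the TSV phenotype table.
#' @param expected_ids Optional character vector of sample IDs that the
#'   phenotype table must match exactly (in any order).
#' @return A data.frame of validated phenotypes with integer outcome
#'   columns; outcome prevalences are reported via [message()] and attached
#'   as the `"prevalence"` attribute.
#' @export
read_phenotypes <- function(path, expected_ids = NULL) {
  if (!file.exists(path)) stop("phenotype file not found: ", path, call. = FALSE)
  ph <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  required <- c("patient_id", outcome_names())
  miss <- setdiff(required, names(ph))
  if (length(miss) > 0L)
    stop("phenotype table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(ph) == 0L) stop("no patients in phenotype table", call. = FALSE)
  for (col in outcome_names()) {
    bad <- which(!ph[[col]] %in% c("0", "1"))
    if (length(bad) > 0L)
      stop("phenotype column `", col, "` not coded 0/1 in row(s) ",
           paste(bad, collapse = ", "), " (e.g. \"", ph[[col]][bad[1]], "\")",
           call. = FALSE)
    ph[[col]] <- as.integer(ph[[col]])
  }
  dup <- unique(ph$patient_id[duplicated(ph$patient_id)])
  if (length(dup) > 0L)
    stop("duplicate patient IDs: ", paste(dup, collapse = ", "), call. = FALSE)
  incons <- ph$patient_id[ph$behavior_adr == 1L & ph$adr == 0L]
  if (length(incons) > 0L)
    stop("behavior_adr = 1 with adr = 0 (behavior ADRs are a subset of ADRs) ",
         "for patient(s): ", paste(incons, collapse = ", "), call. = FALSE)
  if (!is.null(expected_ids)) {
    extra <- setdiff(ph$patient_id, expected_ids)
    if (length(extra) > 0L)
      stop("patient(s) in phenotype table absent from VCF: ",
           paste(extra, collapse = ", "), call. = FALSE)
    missing_ph <- setdiff(expected_ids, ph$patient_id)
    if (length(missing_ph) > 0L)
      stop("VCF sample(s) absent from phenotype table: ",
           paste(missing_ph, collapse = ", "), call. = FALSE)
  }
  prev <- vapply(outcome_names(), function(o) sum(ph[[o]]), integer(1))
  message("phenotypes: ", nrow(ph), " patients; ",
          paste(sprintf("%s %d/%d", names(prev), prev, nrow(ph)),
                collapse = ", "))
  attr(ph, "prevalence") <- prev
  ph
}

#' Write association results to a TSV file
#'
#' Emits the fixed 12-column schema `unit`, `unit_kind`, `outcome`, `test`,
#' `statistic`, `odds_ratio`, `ci_low`, `ci_high`, `p_value`,
#' `bonferroni_threshold`, `significant_nominal`, `significant_adjusted`,
#' in the deterministic order (outcome in canonical order, group rows before
#' gene rows, units alphabetical). Rerunning on identical inputs yields a
#' byte-identical file.
#'
#' @param results data.frame of association results (from
#'   [run_burden_analysis()] / [run_collapse_analysis()]).
#' @param path Output file path.
#' @return Invisibly, the ordered data.frame that was written.
#' @export
write_results <- function(results, path) {
  if (!is.data.frame(results) || nrow(results) == 0L)
    stop("`results` must be a non-empty data.frame", call. = FALSE)
  cols <- c("unit", "unit_kind", "outcome", "test", "statistic", "odds_ratio",
            "ci_low", "ci_high", "p_value", "bonferroni_threshold",
            "significant_nominal", "significant_adjusted")
  miss <- setdiff(cols, names(results))
  if (length(miss) > 0L)
    stop("results missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  ord <- order(match(results$outcome, outcome_names()),
               match(results$unit_kind, c("group", "gene")),
               results$unit, method = "radix")
  out <- results[ord, cols]
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write results to ", path,
                                           ": ", conditionMessage(e),
                                           call. = FALSE))
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Write the variant qualification audit trail
#'
#' One row per loaded variant with its qualification verdict and reason, so
#' every filtering decision is inspectable.
#'
#' @param qualified data.frame from [qualify_variants()].
#' @param path Output file path.
#' @return Invisibly, `qualified`.
#' @export
write_audit <- function(qualified, path) {
  cols <- c("variant_key", "gene", "consequence", "pop_af", "verdict", "reason")
  utils::write.table(qualified[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(qualified)
}
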