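#' Read a multi-sample VCF into variant records and a genotype matrix
#'
#' Parses a VCF 4.x file (only the GT FORMAT field is used), splits
#' multi-allelic sites into one record per alternate allele, and decodes
#' diploid genotypes into per-patient alternate-allele counts: `0/0 -> 0`,
#' `0/1 -> 1`, `1/1 -> 2`, `./. -> NA`. For a split record of alternate
#' allele `j`, a genotype contributes the number of its alleles equal to
#' `j`, so `1/2` yields count 1 for each of the two split records.
#'
#' @param path Path to a VCF file.
#' @return A list with elements
#'   \describe{
#'     \item{variants}{data.frame of variant-record stubs: `chrom`, `pos`,
#'       `ref`, `alt`, `variant_key` (`"chrom:pos:ref:alt"`), and
#'       placeholder annotation columns `gene` (`NA`), `consequence`
#'       (`"unannotated"`), `pop_af` (`NA`) to be filled by
#'       [read_annotation()].}
#'     \item{genotypes}{list with `patient_ids`, `variant_keys`, and
#'       `allele_counts` (patients x variants integer matrix, `NA` for
#'       missing genotypes).}
#'   }
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path, call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0L) stop("VCF contains no variant records: ", path, call. = FALSE)
  gt <- v@gt
  if (is.null(gt) || ncol(gt) < 2L)
    stop("VCF has no sample genotype columns: ", path, call. = FALSE)
  samples <- colnames(gt)[-1]
  dup <- unique(samples[duplicated(samples)])
  if (length(dup) > 0L)
    stop("duplicate sample IDs in VCF: ", paste(dup, collapse = ", "),
         call. = FALSE)

  records <- list()
  count_cols <- list()
  n_missing <- 0L
  for (i in seq_len(nrow(fix))) {
    chrom <- fix[i, "CHROM"]; pos <- as.integer(fix[i, "POS"])
    ref <- fix[i, "REF"]; alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    fmt <- strsplit(gt[i, 1], ":", fixed = TRUE)[[1]]
    gt_idx <- match("GT", fmt)
    if (is.na(gt_idx))
      stop("VCF record ", chrom, ":", pos, " has no GT field", call. = FALSE)
    tokens <- vapply(strsplit(gt[i, -1], ":", fixed = TRUE), function(f) {
      if (length(f) < gt_idx) "." else f[gt_idx]
    }, character(1))
    tokens[is.na(tokens)] <- "."
    alleles <- strsplit(tokens, "[/|]")
    decoded <- lapply(seq_along(alleles), function(s) {
      al <- alleles[[s]]
      if (all(al == ".")) return(rep(NA_integer_, 2L))
      if (length(al) != 2L)
        stop("non-diploid GT \"", tokens[s], "\" for sample ", samples[s],
             " at ", chrom, ":", pos, call. = FALSE)
      if (any(al == ".")) return(rep(NA_integer_, 2L))
      ai <- suppressWarnings(as.integer(al))
      if (any(is.na(ai)) || any(ai < 0L) || any(ai > length(alts)))
        stop("malformed GT \"", tokens[s], "\" for sample ", samples[s],
             " at ", chrom, ":", pos, call. = FALSE)
      ai
    })
    n_missing <- n_missing + sum(vapply(decoded, anyNA, logical(1)))
    for (j in seq_along(alts)) {
      if (alts[j] == ref)
        stop("ALT equals REF at ", chrom, ":", pos, call. = FALSE)
      key <- paste(chrom, pos, ref, alts[j], sep = ":")
      records[[length(records) + 1L]] <-
        data.frame(chrom = chrom, pos = pos, ref = ref, alt = alts[j],
                   variant_key = key, stringsAsFactors = FALSE)
      count_cols[[length(count_cols) + 1L]] <-
        vapply(decoded, function(ai) {
          if (anyNA(ai)) NA_integer_ else sum(ai == j)
        }, integer(1))
    }
  }
  variants <- do.call(rbind, records)
  dupk <- unique(variants$variant_key[duplicated(variants$variant_key)])
  if (length(dupk) > 0L)
    stop("duplicate variant keys in VCF: ", paste(dupk, collapse = ", "),
         call. = FALSE)
  ac <- do.call(cbind, count_cols)
  dimnames(ac) <- list(samples, variants$variant_key)
  if (n_missing > 0L)
    message(n_missing, " missing genotype entr",
            if (n_missing == 1L) "y" else "ies", " in ", basename(path))
  variants$gene <- NA_character_
  variants$consequence <- "unannotated"
  variants$pop_af <- NA_real_
  list(variants = variants,
       genotypes = list(patient_ids = samples,
                        variant_keys = variants$variant_key,
                        allele_counts = ac))
}

# Minimal deterministic VCF 4.2 text emitter for synthetic cohorts: biallelic
# records, GT-only FORMAT. `variants` needs chrom/pos/ref/alt (+ optional id);
# `ac` is the patients x variants allele-count matrix (NA -> ./.).
write_vcf_file <- function(variants, ac, patient_ids, path) {
  gt_code <- c("0/0", "0/1", "1/1")
  header <- c("##fileformat=VCFv4.2",
              "##source=rvburden",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", patient_ids), collapse = "\t"))
  body <- vapply(seq_len(nrow(variants)), function(i) {
    counts <- ac[, i]
    gts <- ifelse(is.na(counts), "./.", gt_code[counts + 1L])
    id <- if ("id" %in% names(variants)) variants$id[i] else "."
    paste(c(variants$chrom[i], variants$pos[i], id, variants$ref[i],
            variants$alt[i], ".", "PASS", ".", "GT", gts), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
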