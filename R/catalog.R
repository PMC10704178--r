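#' Gene-set catalog
#'
#' A gene-set catalog partitions a candidate-gene panel into named functional
#' groups. [glutamate_receptor_catalog()] returns the default panel used for
#' perampanel pharmacogenetics: the 26 HGNC glutamate-receptor genes split
#' into the five functional subunit families (AMPA, delta, kainate, NMDA,
#' metabotropic).
#'
#' @param groups Named list mapping group name to a character vector of HGNC
#'   gene symbols. Groups must be disjoint and non-empty.
#' @return An object of class `gene_set_catalog`: a list with elements
#'   `groups` (the named list) and `all_genes` (the union, in group order).
#' @examples
#' cat26 <- glutamate_receptor_catalog()
#' length(cat26$all_genes) # 26
#' names(cat26$groups)
#' @export
gene_set_catalog <- function(groups) {
  if (!is.list(groups) || is.null(names(groups)) || any(names(groups) == ""))
    stop("`groups` must be a named list of character vectors", call. = FALSE)
  groups <- lapply(groups, as.character)
  if (any(vapply(groups, length, 1L) == 0L))
    stop("every gene group must contain at least one gene", call. = FALSE)
  all_genes <- unlist(groups, use.names = FALSE)
  dup <- unique(all_genes[duplicated(all_genes)])
  if (length(dup) > 0L)
    stop("gene groups must be disjoint; duplicated: ",
         paste(dup, collapse = ", "), call. = FALSE)
  structure(list(groups = groups, all_genes = all_genes),
            class = "gene_set_catalog")
}

#' @rdname gene_set_catalog
#' @export
glutamate_receptor_catalog <- function() {
  gene_set_catalog(list(
    AMPA         = paste0("GRIA", 1:4),
    delta        = paste0("GRID", 1:2),
    kainate      = paste0("GRIK", 1:5),
    NMDA         = c("GRIN1", paste0("GRIN2", c("A", "B", "C", "D")),
                     "GRIN3A", "GRIN3B"),
    metabotropic = paste0("GRM", 1:8)
  ))
}

#' Read a gene-set catalog from a YAML file
#'
#' The file maps group names to lists of HGNC symbols, e.g.
#' `delta: [GRID1, GRID2]`.
#'
#' @param path Path to a YAML file.
#' @return A [gene_set_catalog()].
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("gene-set file not found: ", path, call. = FALSE)
  gene_set_catalog(yaml::read_yaml(path))
}

#' @export
print.gene_set_catalog <- function(x, ...) {
  cat("Gene-set catalog:", length(x$all_genes), "genes in",
      length(x$groups), "groups\n")
  for (g in names(x$groups))
    cat("  ", g, ": ", paste(x$groups[[g]], collapse = ", "), "\n", sep = "")
  invisible(x)
}
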