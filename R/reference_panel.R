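#' Construct a reference genotype panel for LD computation
#'
#' Holds per-individual allele-dosage vectors (0/1/2 copies of the coded
#' allele) for a set of variants, standing in for an external reference
#' such as a European 1000 Genomes subset. Monomorphic variants (fewer
#' than two distinct dosage values) are flagged unusable for LD.
#'
#' @param variants data.frame with columns `variant_id`, `chrom`, `pos`,
#'   `coded_allele`.
#' @param dosages Numeric matrix, variants x individuals, entries in
#'   {0, 1, 2}; rownames must match `variants$variant_id`.
#' @return Object of class `reference_panel`.
#' @export
reference_panel <- function(variants, dosages) {
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  stopifnot(all(c("variant_id", "chrom", "pos") %in% names(variants)),
            nrow(variants) == nrow(dosages))
  rownames(dosages) <- variants$variant_id
  usable <- apply(dosages, 1L, function(d) length(unique(d)) >= 2L)
  structure(list(variants = variants, dosages = dosages, usable = usable),
            class = "reference_panel")
}

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf("<reference_panel> %d variants x %d individuals (%d usable for LD)\n",
              nrow(x$dosages), ncol(x$dosages), sum(x$usable)))
  invisible(x)
}

#' Read a reference panel from TSV
#'
#' Expected layout: header row; columns `variant_id`, `chrom`, `pos`,
#' `coded_allele`, then one column per individual holding dosages.
#'
#' @param path TSV file path.
#' @return A [reference_panel()].
#' @export
read_reference_panel <- function(path) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- c("variant_id", "chrom", "pos", "coded_allele")
  missing <- setdiff(meta_cols, names(raw))
  if (length(missing))
    stop("reference panel missing columns: ", paste(missing, collapse = ", "))
  dos <- as.matrix(raw[, setdiff(names(raw), meta_cols), drop = FALSE])
  storage.mode(dos) <- "double"
  reference_panel(raw[, meta_cols], dos)
}

#' Write a reference panel to TSV
#'
#' @param panel A [reference_panel()].
#' @param path Output file path.
#' @export
write_reference_panel <- function(panel, path) {
  stopifnot(inherits(panel, "reference_panel"))
  out <- cbind(panel$variants, as.data.frame(panel$dosages))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}

#' Squared LD correlation between two panel variants
#'
#' Returns the squared Pearson correlation of the two dosage vectors,
#' the standard r-squared measure of linkage disequilibrium. Symmetric
#' in its arguments.
#'
#' @param panel A [reference_panel()].
#' @param id_a,id_b Variant ids present in the panel.
#' @return Scalar in [0, 1].
#' @export
compute_ld_r2 <- function(panel, id_a, id_b) {
  stopifnot(inherits(panel, "reference_panel"))
  for (id in c(id_a, id_b)) {
    if (!id %in% rownames(panel$dosages))
      stop("variant not in reference panel: ", id)
    if (!panel$usable[[id]])
      stop("LD undefined for monomorphic variant: ", id)
  }
  stats::cor(panel$dosages[id_a, ], panel$dosages[id_b, ])^2
}
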