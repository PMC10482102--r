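#' @keywords internal
"_PACKAGE"

# Canonical record columns for a GWAS summary-statistics dataset.
.record_cols <- c("variant_id", "chrom", "pos", "effect_allele",
                  "other_allele", "eaf", "beta", "se", "pval", "n")

#' Construct a GWAS summary-statistics dataset
#'
#' A `summary_dataset` bundles per-variant association records for one
#' trait: either a microbial-taxon abundance GWAS (exposure, effects on
#' the standard-deviation scale of abundance) or a case-control disease
#' GWAS (outcome, effects on the log-odds scale).
#'
#' @param records data.frame with columns `variant_id`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `pval`, `n` and optionally `chrom`,
#'   `pos`, `eaf` (missing optional columns are filled with `NA`).
#' @param trait_id Character scalar naming the trait, e.g.
#'   `"Genus_Sellimonas"` or `"ER+ Breast cancer"`.
#' @param trait_role `"exposure"` or `"outcome"`.
#' @param taxonomic_level Optional: one of `"phylum"`, `"class"`,
#'   `"order"`, `"family"`, `"genus"`.
#' @return An object of class `summary_dataset`: a list with elements
#'   `trait_id`, `trait_role`, `taxonomic_level` and `records`.
#' @export
summary_dataset <- function(records, trait_id, trait_role,
                            taxonomic_level = NA_character_) {
  trait_role <- match.arg(trait_role, c("exposure", "outcome"))
  if (!is.na(taxonomic_level)) {
    taxonomic_level <- match.arg(
      taxonomic_level, c("phylum", "class", "order", "family", "genus"))
  }
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  for (col in setdiff(.record_cols, names(records))) {
    records[[col]] <- if (col %in% c("variant_id", "chrom",
                                     "effect_allele", "other_allele"))
      NA_character_ else NA_real_
  }
  records <- records[, .record_cols]
  rownames(records) <- NULL
  structure(
    list(trait_id = trait_id, trait_role = trait_role,
         taxonomic_level = taxonomic_level, records = records),
    class = "summary_dataset")
}

#' @export
print.summary_dataset <- function(x, ...) {
  cat(sprintf("<summary_dataset> %s (%s%s): %d variants\n",
              x$trait_id, x$trait_role,
              if (is.na(x$taxonomic_level)) "" else
                paste0(", ", x$taxonomic_level),
              nrow(x$records)))
  invisible(x)
}

#' Default column mapping for summary-statistics TSVs
#'
#' Maps canonical field names to the column headers expected in input
#' files. Cohort-specific dialects are absorbed by overriding entries
#' via the `column_map` argument of [read_summary_stats()].
#'
#' @return Named character vector: canonical name -> file column header.
#' @export
default_column_map <- function() {
  c(variant_id = "SNP", chrom = "CHR", pos = "POS",
    effect_allele = "EA", other_allele = "OA", eaf = "EAF",
    beta = "BETA", se = "SE", pval = "P", n = "N")
}

#' Read GWAS summary statistics from a tab-separated file
#'
#' Required columns: variant id, both alleles, beta, se, p-value and
#' sample size; `chrom`, `pos` and `eaf` are optional. Alleles are
#' uppercased. Rows with unparseable or invalid `beta`/`se`, alleles
#' outside single-base A/C/G/T, or identical alleles are dropped and
#' counted in the load report (attached as attribute `"load_report"`).
#'
#' @inheritParams summary_dataset
#' @param path Path to a TSV file with a header row.
#' @param column_map Named character vector overriding
#'   [default_column_map()] entries.
#' @return A [summary_dataset()] with attribute `load_report`, a list
#'   with `n_read`, `n_kept` and `dropped` (named counts by reason).
#' @export
read_summary_stats <- function(path, trait_id, trait_role,
                               column_map = NULL,
                               taxonomic_level = NA_character_) {
  cmap <- default_column_map()
  if (!is.null(column_map)) cmap[names(column_map)] <- column_map
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "",
                           check.names = FALSE, colClasses = "character")
  if (nrow(raw) == 0 && ncol(raw) == 0)
    stop("empty summary-statistics file: ", path)
  required <- c("variant_id", "effect_allele", "other_allele",
                "beta", "se", "pval", "n")
  for (field in required) {
    if (!cmap[[field]] %in% names(raw))
      stop(sprintf("required column '%s' (field '%s') missing in %s",
                   cmap[[field]], field, path))
  }
  present <- names(cmap)[cmap %in% names(raw)]
  rec <- data.frame(row.names = seq_len(nrow(raw)))
  for (field in present) rec[[field]] <- raw[[cmap[[field]]]]

  num_or_na <- function(x) suppressWarnings(as.numeric(x))
  rec$beta <- num_or_na(rec$beta)
  rec$se   <- num_or_na(rec$se)
  rec$pval <- num_or_na(rec$pval)
  rec$n    <- num_or_na(rec$n)
  if ("eaf" %in% present) rec$eaf <- num_or_na(rec$eaf)
  if ("pos" %in% present) rec$pos <- num_or_na(rec$pos)
  rec$effect_allele <- toupper(rec$effect_allele)
  rec$other_allele  <- toupper(rec$other_allele)

  bad_numeric <- is.na(rec$beta) | is.na(rec$se) | rec$se <= 0
  single_base <- rec$effect_allele %in% c("A", "C", "G", "T") &
    rec$other_allele %in% c("A", "C", "G", "T")
  same_allele <- single_base & rec$effect_allele == rec$other_allele
  keep <- !bad_numeric & single_base & !same_allele
  dropped <- c(invalid_beta_se = sum(bad_numeric),
               non_snp_allele  = sum(!single_base & !bad_numeric),
               identical_alleles = sum(same_allele & !bad_numeric))
  ds <- summary_dataset(rec[keep, , drop = FALSE], trait_id, trait_role,
                        taxonomic_level)
  attr(ds, "load_report") <- list(n_read = nrow(raw), n_kept = sum(keep),
                                  dropped = dropped)
  ds
}

#' Write a summary dataset to a tab-separated file
#'
#' Floats are serialized at 17 significant digits so that
#' `read_summary_stats(write_summary_stats(d))` round-trips every field
#' bit-identically; absent values are written as `NA`.
#'
#' @param dataset A [summary_dataset()].
#' @param path Output file path.
#' @export
write_summary_stats <- function(dataset, path) {
  stopifnot(inherits(dataset, "summary_dataset"))
  rec <- dataset$records
  out <- data.frame(
    SNP = rec$variant_id, CHR = rec$chrom, POS = .fmt_num(rec$pos),
    EA = rec$effect_allele, OA = rec$other_allele,
    EAF = .fmt_num(rec$eaf), BETA = .fmt_num(rec$beta),
    SE = .fmt_num(rec$se), P = .fmt_num(rec$pval), N = .fmt_num(rec$n),
    stringsAsFactors = FALSE, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(NULL)
}

# full-precision numeric serialization ("NA" for absent)
.fmt_num <- function(x) {
  out <- vapply(x, function(v)
    if (is.na(v)) NA_character_ else format(v, digits = 17), character(1))
  out
}

#' Validate a summary dataset
#'
#' Report-only: lists duplicate variant ids, per-record invariant
#' violations (non-positive `se`, p-value outside (0, 1], identical
#' alleles, position < 1), and optionally the number of variants with
#' p-value below a threshold. The dataset is not modified.
#'
#' @param dataset A [summary_dataset()].
#' @param p_threshold Optional p-value threshold to count against.
#' @return A list with `duplicate_ids`, `violations` (data.frame
#'   variant_id/problem) and `n_below_threshold` (NA when no threshold
#'   supplied).
#' @export
validate_dataset <- function(dataset, p_threshold = NULL) {
  stopifnot(inherits(dataset, "summary_dataset"))
  rec <- dataset$records
  dup <- unique(rec$variant_id[duplicated(rec$variant_id)])
  viol <- list()
  flag <- function(idx, problem) {
    if (any(idx, na.rm = TRUE))
      data.frame(variant_id = rec$variant_id[which(idx)],
                 problem = problem, stringsAsFactors = FALSE)
  }
  viol <- rbind(
    flag(rec$se <= 0, "se <= 0"),
    flag(rec$pval <= 0 | rec$pval > 1, "pval outside (0,1]"),
    flag(rec$effect_allele == rec$other_allele, "identical alleles"),
    flag(!is.na(rec$pos) & rec$pos < 1, "pos < 1"))
  if (is.null(viol))
    viol <- data.frame(variant_id = character(0), problem = character(0),
                       stringsAsFactors = FALSE)
  list(duplicate_ids = dup, violations = viol,
       n_below_threshold = if (is.null(p_threshold)) NA_integer_ else
         sum(rec$pval < p_threshold, na.rm = TRUE))
}
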