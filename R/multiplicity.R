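#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Step-up adjustment: with the p-values sorted ascending,
#' adj_(k) = min over j >= k of p_(j) * m / j, capped at 1, returned in
#' input order. `m` may exceed the number of supplied p-values when the
#' family is larger than the list at hand (the remaining tests assumed
#' non-limiting), as when adjusting the reported subset of a 119-genus
#' family. Delegates to [stats::p.adjust()].
#'
#' @param pvals Numeric vector of p-values in (0, 1].
#' @param m Family size, at least `length(pvals)` (default: the
#'   length).
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(pvals, m = length(pvals)) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(is.na(pvals)) || any(pvals <= 0 | pvals > 1))
    stop("p-values must lie in (0, 1]")
  if (m < length(pvals)) stop("family size m must be >= length(pvals)")
  stats::p.adjust(pvals, method = "BH", n = m)
}

#' Annotate MR results with grouped BH-FDR
#'
#' Applies [bh_adjust()] within groups of result rows. The default
#' grouping, one family per taxonomic level per outcome, reflects
#' reporting that adjusts the 119 genus-level tests separately from the
#' other taxonomic levels for each outcome.
#'
#' @param results data.frame with at least `pval` plus the grouping
#'   fields (`outcome_id` and, for the per-level grouping,
#'   `taxonomic_level`).
#' @param grouping `"per_level_per_outcome"` (default), `"per_outcome"`
#'   or `"global"`.
#' @param group_m Optional named vector of family sizes per group key
#'   (e.g. `c(genus = 119)`) overriding the group's row count; useful
#'   when only a subset of a family's rows is supplied.
#' @return `results` with an `fdr` column appended; attribute
#'   `grouping` records the key used.
#' @export
annotate_fdr <- function(results,
                         grouping = c("per_level_per_outcome",
                                      "per_outcome", "global"),
                         group_m = NULL) {
  grouping <- match.arg(grouping)
  results <- as.data.frame(results, stringsAsFactors = FALSE)
  stopifnot("pval" %in% names(results))
  key <- switch(grouping,
    per_level_per_outcome = {
      need <- c("taxonomic_level", "outcome_id")
      if (!all(need %in% names(results)))
        stop("grouping fields missing: ",
             paste(setdiff(need, names(results)), collapse = ", "))
      paste(results$taxonomic_level, results$outcome_id, sep = "|")
    },
    per_outcome = {
      if (!"outcome_id" %in% names(results))
        stop("grouping fields missing: outcome_id")
      results$outcome_id
    },
    global = rep("all", nrow(results)))
  results$fdr <- NA_real_
  for (g in unique(key)) {
    idx <- which(key == g)
    m <- length(idx)
    if (!is.null(group_m)) {
      hit <- names(group_m)[vapply(names(group_m), function(nm)
        grepl(nm, g, fixed = TRUE), logical(1))]
      if (length(hit)) m <- max(m, group_m[[hit[1]]])
    }
    results$fdr[idx] <- bh_adjust(results$pval[idx], m = m)
  }
  attr(results, "grouping") <- grouping
  results
}
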