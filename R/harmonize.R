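.complement <- c(A = "T", C = "G", G = "C", T = "A")

#' Classify an allele pair as standard or palindromic
#'
#' A palindromic (ambiguous-strand) SNP has alleles that are each
#' other's complement: A/T or C/G. Such variants cannot be strand
#' resolved from alleles alone and are excluded during harmonization.
#'
#' @param ea,oa Single-base effect and other alleles (A/C/G/T),
#'   vectorized; `ea[i] != oa[i]`.
#' @return Character vector of `"standard"` / `"palindromic"`.
#' @export
classify_allele_pair <- function(ea, oa) {
  ea <- toupper(ea); oa <- toupper(oa)
  if (!all(ea %in% names(.complement)) || !all(oa %in% names(.complement)))
    stop("invalid allele: alleles must be single bases A/C/G/T")
  if (any(ea == oa)) stop("invalid allele pair: ea == oa")
  ifelse(unname(.complement[ea]) == oa, "palindromic", "standard")
}

#' Align exposure instruments and outcome records to a common effect allele
#'
#' For each instrument, the matching outcome record (by variant id) is
#' aligned so that both effect sizes refer to the same effect allele:
#'
#' * absent from the outcome -> `dropped_missing`;
#' * palindromic A/T or C/G -> `dropped_palindromic` (unconditionally,
#'   no allele-frequency rescue);
#' * same alleles -> `kept_as_is`;
#' * swapped alleles -> outcome beta negated, eaf complemented,
#'   `flipped`;
#' * strand-complement (or swapped complement) alleles -> treated as the
#'   two cases above after complementing (disable with
#'   `strand_complement = FALSE`);
#' * anything else -> `dropped_incompatible`.
#'
#' @param instruments An [select_instruments()] `instrument_set`.
#' @param outcome Outcome [summary_dataset()].
#' @param strand_complement Attempt strand-complement matching
#'   (default TRUE).
#' @return Object of class `harmonized_set`: list with `exposure_id`,
#'   `outcome_id`, `variants` (data.frame variant_id/beta_x/se_x/
#'   beta_y/se_y/eaf/action for kept variants) and `exclusion_log`
#'   (data.frame variant_id/reason covering every instrument not kept).
#' @export
harmonize_datasets <- function(instruments, outcome,
                               strand_complement = TRUE) {
  stopifnot(inherits(instruments, "instrument_set"),
            inherits(outcome, "summary_dataset"),
            outcome$trait_role == "outcome")
  ex <- instruments$variants
  out_rec <- outcome$records
  kept <- list(); excl <- list()
  for (i in seq_len(nrow(ex))) {
    v <- ex[i, ]
    j <- match(v$variant_id, out_rec$variant_id)
    if (is.na(j)) {
      excl[[length(excl) + 1L]] <- c(v$variant_id, "dropped_missing")
      next
    }
    if (classify_allele_pair(v$effect_allele, v$other_allele) ==
        "palindromic") {
      excl[[length(excl) + 1L]] <- c(v$variant_id, "dropped_palindromic")
      next
    }
    o <- out_rec[j, ]
    oea <- o$effect_allele; ooa <- o$other_allele
    action <- NA_character_
    if (oea == v$effect_allele && ooa == v$other_allele) {
      action <- "kept_as_is"
    } else if (oea == v$other_allele && ooa == v$effect_allele) {
      action <- "flipped"
    } else if (strand_complement) {
      cea <- unname(.complement[oea]); coa <- unname(.complement[ooa])
      if (cea == v$effect_allele && coa == v$other_allele) {
        action <- "kept_as_is"
      } else if (cea == v$other_allele && coa == v$effect_allele) {
        action <- "flipped"
      }
    }
    if (is.na(action)) {
      excl[[length(excl) + 1L]] <- c(v$variant_id, "dropped_incompatible")
      next
    }
    beta_y <- if (action == "flipped") -o$beta else o$beta
    kept[[length(kept) + 1L]] <- data.frame(
      variant_id = v$variant_id, beta_x = v$beta, se_x = v$se,
      beta_y = beta_y, se_y = o$se, eaf = v$eaf, action = action,
      stringsAsFactors = FALSE)
  }
  variants <- if (length(kept)) do.call(rbind, kept) else
    data.frame(variant_id = character(0), beta_x = numeric(0),
               se_x = numeric(0), beta_y = numeric(0), se_y = numeric(0),
               eaf = numeric(0), action = character(0))
  exclusion_log <- if (length(excl))
    data.frame(variant_id = vapply(excl, `[`, "", 1L),
               reason = vapply(excl, `[`, "", 2L),
               stringsAsFactors = FALSE) else
    data.frame(variant_id = character(0), reason = character(0))
  harmonized_set(variants, instruments$trait_id, outcome$trait_id,
                 exclusion_log)
}

#' Construct a harmonized exposure/outcome variant set
#'
#' Low-level constructor used by [harmonize_datasets()] and by
#' simulation code that builds aligned effect pairs directly.
#'
#' @param variants data.frame with columns `variant_id`, `beta_x`,
#'   `se_x`, `beta_y`, `se_y` and optionally `eaf`, `action`.
#' @param exposure_id,outcome_id Trait identifiers.
#' @param exclusion_log Optional data.frame `variant_id`/`reason`.
#' @return Object of class `harmonized_set`.
#' @export
harmonized_set <- function(variants, exposure_id = "exposure",
                           outcome_id = "outcome",
                           exclusion_log = NULL) {
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  stopifnot(all(c("variant_id", "beta_x", "se_x", "beta_y", "se_y") %in%
                  names(variants)))
  if (nrow(variants)) stopifnot(all(variants$se_x > 0),
                                all(variants$se_y > 0))
  if (is.null(variants$eaf)) variants$eaf <- NA_real_
  if (is.null(variants$action)) variants$action <- "kept_as_is"
  if (is.null(exclusion_log))
    exclusion_log <- data.frame(variant_id = character(0),
                                reason = character(0))
  rownames(variants) <- NULL
  structure(list(exposure_id = exposure_id, outcome_id = outcome_id,
                 variants = variants, exclusion_log = exclusion_log),
            class = "harmonized_set")
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("<harmonized_set> %s -> %s: J = %d kept, %d excluded\n",
              x$exposure_id, x$outcome_id, nrow(x$variants),
              nrow(x$exclusion_log)))
  invisible(x)
}
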