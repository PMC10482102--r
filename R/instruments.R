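# numeric chromosome order where possible, lexicographic otherwise
.chrom_rank <- function(chrom) {
  num <- suppressWarnings(as.numeric(chrom))
  num[is.na(num)] <- 1e6 + as.numeric(factor(chrom[is.na(num)]))
  num
}

#' Greedy LD clumping of a summary dataset
#'
#' Repeatedly takes the remaining variant with the smallest p-value as
#' an index and removes every remaining variant on the same chromosome
#' within +/- `window_kb` kilobases whose squared dosage correlation
#' with the index is at least `r2_max`. Ties on p-value are broken by
#' chromosome, then position, then variant id, so the result is
#' invariant to input record order. Variants absent from the panel, or
#' lacking chromosome/position, pass through unclumped with a logged
#' warning.
#'
#' @param dataset A [summary_dataset()].
#' @param panel A [reference_panel()].
#' @param r2_max LD threshold; variants with r^2 >= `r2_max` to a
#'   better-ranked index within the window are removed (default 0.01).
#' @param window_kb Half-window in kb around each index variant
#'   (default 500, i.e. a 1 Mb total window).
#' @return Character vector of retained variant ids, with attribute
#'   `clump_log` (data.frame variant_id/note for pass-through variants).
#' @export
clump <- function(dataset, panel, r2_max = 0.01, window_kb = 500) {
  stopifnot(inherits(dataset, "summary_dataset"),
            inherits(panel, "reference_panel"))
  rec <- dataset$records
  if (nrow(rec) == 0)
    return(structure(character(0), clump_log = data.frame(
      variant_id = character(0), note = character(0))))

  in_panel <- rec$variant_id %in% rownames(panel$dosages)
  has_locus <- !is.na(rec$chrom) & !is.na(rec$pos)
  clumpable <- in_panel & has_locus
  log <- data.frame(
    variant_id = rec$variant_id[!clumpable],
    note = ifelse(!has_locus[!clumpable], "missing chrom/pos: not clumped",
                  "absent from LD panel: not clumped"),
    stringsAsFactors = FALSE)
  if (nrow(log)) warning(sprintf("%d variant(s) passed through unclumped",
                                 nrow(log)), call. = FALSE)

  cand <- rec[clumpable, , drop = FALSE]
  ord <- order(cand$pval, .chrom_rank(cand$chrom), cand$pos,
               cand$variant_id)
  cand <- cand[ord, , drop = FALSE]
  kept <- character(0)
  while (nrow(cand) > 0) {
    idx <- cand[1L, ]
    kept <- c(kept, idx$variant_id)
    cand <- cand[-1L, , drop = FALSE]
    if (nrow(cand) == 0) break
    near <- cand$chrom == idx$chrom &
      abs(cand$pos - idx$pos) <= window_kb * 1000
    if (any(near)) {
      r2 <- vapply(cand$variant_id[near], function(id)
        compute_ld_r2(panel, idx$variant_id, id), numeric(1))
      drop_ids <- cand$variant_id[near][r2 >= r2_max]
      cand <- cand[!cand$variant_id %in% drop_ids, , drop = FALSE]
    }
  }
  out <- rec$variant_id[rec$variant_id %in% c(kept, log$variant_id)]
  structure(out, clump_log = log)
}

#' Instrument strength: variance explained and F statistic
#'
#' Per-variant variance in the exposure explained by an instrument is
#' R2_j = 2 * MAF_j * (1 - MAF_j) * beta_j^2 with MAF the minor-allele
#' frequency min(eaf, 1 - eaf); the set-level F statistic is
#' F = R2 * (n - k - 1) / (k * (1 - R2)) with R2 the summed variance
#' explained and k the number of instruments. Per-variant (beta/se)^2
#' is returned as an additional diagnostic.
#'
#' @param variants data.frame of variant records with columns `eaf`,
#'   `beta`, `se`, `variant_id`.
#' @param n_exposure Exposure GWAS sample size; must exceed k + 1.
#' @return List with `per_variant_r2`, `total_r2`, `f_stat`, `k`,
#'   `f_per_variant` (diagnostic (beta/se)^2).
#' @export
instrument_strength <- function(variants, n_exposure) {
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  k <- nrow(variants)
  stopifnot(k >= 1, n_exposure > k + 1)
  if (anyNA(variants$eaf))
    stop("missing eaf for variant(s): ",
         paste(variants$variant_id[is.na(variants$eaf)], collapse = ", "))
  maf <- pmin(variants$eaf, 1 - variants$eaf)
  r2 <- 2 * maf * (1 - maf) * variants$beta^2
  total <- sum(r2)
  if (total >= 1)
    stop("degenerate instrument strength: total R^2 >= 1")
  list(per_variant_r2 = r2, total_r2 = total,
       f_stat = total * (n_exposure - k - 1) / (k * (1 - total)),
       k = k, f_per_variant = (variants$beta / variants$se)^2)
}

#' Select instrumental variables for one exposure
#'
#' Pipeline: p-value screen (`pval < p_threshold`), greedy LD
#' [clump()]ing, then the [instrument_strength()] filter. Sets with
#' F <= `f_min` are flagged weak (excluded from downstream MR by the
#' pipeline, with a logged reason); an empty post-screen set yields an
#' empty, flagged instrument set rather than an error.
#'
#' @param dataset Exposure [summary_dataset()].
#' @param panel A [reference_panel()].
#' @param p_threshold Genome-wide screen threshold (default 1e-5).
#' @inheritParams clump
#' @param f_min Minimum acceptable F statistic (default 10; sets at or
#'   below are flagged weak).
#' @return Object of class `instrument_set`: list with `trait_id`,
#'   `taxonomic_level`, `variants` (records of retained instruments),
#'   `per_variant_r2`, `total_r2`, `k`, `f_stat`, `n_exposure`, `weak`
#'   flag, `empty` flag, and a `selection_log` of per-stage counts.
#' @export
select_instruments <- function(dataset, panel, p_threshold = 1e-5,
                               r2_max = 0.01, window_kb = 500,
                               f_min = 10) {
  stopifnot(inherits(dataset, "summary_dataset"),
            dataset$trait_role == "exposure")
  rec <- dataset$records
  screened <- rec[!is.na(rec$pval) & rec$pval < p_threshold, , drop = FALSE]
  log <- list(n_input = nrow(rec), n_screened = nrow(screened))

  if (nrow(screened) == 0) {
    return(structure(list(
      trait_id = dataset$trait_id,
      taxonomic_level = dataset$taxonomic_level,
      variants = screened, per_variant_r2 = numeric(0), total_r2 = 0,
      k = 0L, f_stat = NA_real_, n_exposure = NA_real_,
      weak = TRUE, empty = TRUE, selection_log = c(log, n_clumped = 0L)),
      class = "instrument_set"))
  }

  kept_ids <- clump(summary_dataset(screened, dataset$trait_id, "exposure",
                                    dataset$taxonomic_level),
                    panel, r2_max = r2_max, window_kb = window_kb)
  iv <- screened[screened$variant_id %in% kept_ids, , drop = FALSE]
  log$n_clumped <- nrow(iv)
  log$clump_log <- attr(kept_ids, "clump_log")

  n_exp <- stats::median(iv$n, na.rm = TRUE)
  strength <- instrument_strength(iv, n_exposure = n_exp)
  structure(list(
    trait_id = dataset$trait_id,
    taxonomic_level = dataset$taxonomic_level,
    variants = iv, per_variant_r2 = strength$per_variant_r2,
    total_r2 = strength$total_r2, k = strength$k,
    f_stat = strength$f_stat, n_exposure = n_exp,
    weak = strength$f_stat <= f_min, empty = FALSE,
    selection_log = log), class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("<instrument_set> %s: k = %d, total R2 = %.4g, F = %.2f%s\n",
              x$trait_id, x$k, x$total_r2, x$f_stat,
              if (isTRUE(x$weak)) " [weak]" else ""))
  invisible(x)
}
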