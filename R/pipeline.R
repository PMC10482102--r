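#' Run the full MR analysis across taxa and outcomes
#'
#' For each exposure taxon: instrument selection (p-value screen, LD
#' clumping, F filter), then per outcome: harmonization, the requested
#' causal estimators (IVW primary; weighted median, MR-Egger, maximum
#' likelihood as sensitivity), and the heterogeneity/pleiotropy suite.
#' IVW p-values are BH-adjusted across taxa within each method x
#' taxonomic level x outcome family. Pairs whose Egger intercept test
#' rejects at 0.05 are flagged `pleiotropy_discarded`; weak-instrument
#' taxa (F <= `f_min`) are excluded from MR with a logged reason. The
#' whole run is deterministic given `seed`.
#'
#' @param exposures Named list of exposure [summary_dataset()]s (a
#'   single dataset is accepted).
#' @param outcomes Named list of outcome [summary_dataset()]s (a single
#'   dataset is accepted).
#' @param panel A [reference_panel()] for clumping.
#' @param p_threshold,r2_max,window_kb,f_min Instrument-selection
#'   thresholds (defaults 1e-5, 0.01, 500, 10).
#' @param methods Estimators to run, see [mr_all_methods()].
#' @param n_sim MR-PRESSO null replicates (default 1000).
#' @param n_boot Weighted-median bootstrap replicates (default 1000).
#' @param seed Master integer seed; per-pair seeds are derived from it.
#' @param fdr_grouping,group_m Passed to [annotate_fdr()]; the default
#'   family size for genus-level rows can be forced with
#'   `group_m = c(genus = 119)` when only a subset of taxa is analyzed.
#' @return Object of class `mr_pipeline_result`: list with `estimates`
#'   (data.frame, one row per taxon x outcome x method, with `fdr`),
#'   `sensitivity` (one row per analyzed pair), `decisions` (per-pair
#'   flags), `exclusions` (consolidated per-variant exclusion log),
#'   `skipped` (taxa excluded before MR and why), and `config`.
#' @export
run_pipeline <- function(exposures, outcomes, panel,
                         p_threshold = 1e-5, r2_max = 0.01,
                         window_kb = 500, f_min = 10,
                         methods = c("ivw", "egger", "weighted_median",
                                     "max_likelihood"),
                         n_sim = 1000, n_boot = 1000, seed = 1L,
                         fdr_grouping = "per_level_per_outcome",
                         group_m = NULL) {
  if (inherits(exposures, "summary_dataset"))
    exposures <- stats::setNames(list(exposures), exposures$trait_id)
  if (inherits(outcomes, "summary_dataset"))
    outcomes <- stats::setNames(list(outcomes), outcomes$trait_id)
  stopifnot(length(exposures) >= 1, length(outcomes) >= 1)

  est_rows <- list(); sens_rows <- list(); dec_rows <- list()
  excl_rows <- list(); skip_rows <- list()
  pair_idx <- 0L

  for (ename in names(exposures)) {
    iv <- select_instruments(exposures[[ename]], panel,
                             p_threshold = p_threshold, r2_max = r2_max,
                             window_kb = window_kb, f_min = f_min)
    if (iv$empty || iv$weak) {
      skip_rows[[length(skip_rows) + 1L]] <- data.frame(
        exposure_id = ename,
        reason = if (iv$empty) "no variants passed the p-value screen"
                 else sprintf("weak instruments (F = %.2f <= %g)",
                              iv$f_stat, f_min),
        stringsAsFactors = FALSE)
      next
    }
    for (oname in names(outcomes)) {
      pair_idx <- pair_idx + 1L
      pair_seed <- (seed + 7919L * pair_idx) %% .Machine$integer.max
      h <- harmonize_datasets(iv, outcomes[[oname]])
      if (nrow(h$exclusion_log))
        excl_rows[[length(excl_rows) + 1L]] <- cbind(
          exposure_id = ename, outcome_id = oname, h$exclusion_log)
      J <- nrow(h$variants)
      if (J == 0) {
        skip_rows[[length(skip_rows) + 1L]] <- data.frame(
          exposure_id = ename,
          reason = sprintf("no harmonized variants for outcome %s",
                           oname),
          stringsAsFactors = FALSE)
        next
      }
      ests <- mr_all_methods(h, methods = methods, n_boot = n_boot,
                             seed = pair_seed)
      for (m in names(ests)) {
        e <- ests[[m]]
        est_rows[[length(est_rows) + 1L]] <- data.frame(
          exposure_id = ename,
          taxonomic_level = exposures[[ename]]$taxonomic_level,
          outcome_id = oname, method = m, nsnp = e$nsnp,
          theta = e$theta, se = e$se, or_value = e$or_value,
          ci_low = e$ci_low, ci_high = e$ci_high, pval = e$pval,
          stringsAsFactors = FALSE)
      }
      sr <- sensitivity_report(h, n_sim = n_sim, seed = pair_seed)
      g <- function(x, f) if (is.null(x)) NA_real_ else f(x)
      sens_rows[[length(sens_rows) + 1L]] <- data.frame(
        exposure_id = ename, outcome_id = oname, nsnp = J,
        q_ivw = g(sr$q_ivw, function(s) s$q),
        p_q_ivw = g(sr$q_ivw, function(s) s$pval),
        q_egger = g(sr$q_egger, function(s) s$q),
        p_q_egger = g(sr$q_egger, function(s) s$pval),
        egger_intercept = g(sr$egger_intercept, function(s) s$b0),
        egger_intercept_p = g(sr$egger_intercept, function(s) s$pval),
        presso_rss = g(sr$presso, function(s) s$rss_obs),
        presso_global_p = g(sr$presso, function(s) s$global_p),
        presso_n_outliers = if (is.null(sr$presso)) NA_integer_ else
          length(sr$presso$outliers),
        stringsAsFactors = FALSE)
      pleio <- !is.null(sr$egger_intercept) &&
        sr$egger_intercept$pval < 0.05
      hetero <- !is.null(sr$q_ivw) && sr$q_ivw$pval < 0.05
      dec_rows[[length(dec_rows) + 1L]] <- data.frame(
        exposure_id = ename, outcome_id = oname,
        weak_instruments = FALSE, pleiotropy_discarded = pleio,
        heterogeneity_flag = hetero, stringsAsFactors = FALSE)
    }
  }

  bind <- function(rows, proto) if (length(rows)) do.call(rbind, rows)
    else proto
  estimates <- bind(est_rows, data.frame(
    exposure_id = character(0), taxonomic_level = character(0),
    outcome_id = character(0), method = character(0),
    nsnp = integer(0), theta = numeric(0), se = numeric(0),
    or_value = numeric(0), ci_low = numeric(0), ci_high = numeric(0),
    pval = numeric(0)))
  if (nrow(estimates) == 0) {
    warning("no taxa with usable instruments: empty results",
            call. = FALSE)
  } else {
    parts <- split(estimates, estimates$method)
    parts <- lapply(parts, annotate_fdr, grouping = fdr_grouping,
                    group_m = group_m)
    estimates <- do.call(rbind, parts)
    estimates <- estimates[order(estimates$exposure_id,
                                 estimates$outcome_id,
                                 estimates$method), ]
    rownames(estimates) <- NULL
  }
  decisions <- bind(dec_rows, data.frame(
    exposure_id = character(0), outcome_id = character(0),
    weak_instruments = logical(0), pleiotropy_discarded = logical(0),
    heterogeneity_flag = logical(0)))
  # a pair is reported significant when its IVW FDR clears 0.05 and no
  # pleiotropy or heterogeneity flag is raised
  if (nrow(decisions)) {
    ivw_rows <- estimates[estimates$method == "ivw", ]
    key <- paste(decisions$exposure_id, decisions$outcome_id)
    ivw_key <- paste(ivw_rows$exposure_id, ivw_rows$outcome_id)
    decisions$ivw_fdr <- ivw_rows$fdr[match(key, ivw_key)]
    decisions$significant <- !is.na(decisions$ivw_fdr) &
      decisions$ivw_fdr < 0.05 & !decisions$pleiotropy_discarded &
      !decisions$heterogeneity_flag
  }
  structure(list(
    estimates = estimates,
    sensitivity = bind(sens_rows, data.frame()),
    decisions = decisions,
    exclusions = bind(excl_rows, data.frame(
      exposure_id = character(0), outcome_id = character(0),
      variant_id = character(0), reason = character(0))),
    skipped = bind(skip_rows, data.frame(exposure_id = character(0),
                                         reason = character(0))),
    config = list(p_threshold = p_threshold, r2_max = r2_max,
                  window_kb = window_kb, f_min = f_min,
                  methods = methods, n_sim = n_sim, n_boot = n_boot,
                  seed = seed, fdr_grouping = fdr_grouping)),
    class = "mr_pipeline_result")
}

#' @export
print.mr_pipeline_result <- function(x, ...) {
  cat(sprintf(
    "<mr_pipeline_result> %d estimate rows (%d pairs), %d taxa skipped\n",
    nrow(x$estimates), nrow(x$decisions), nrow(x$skipped)))
  invisible(x)
}

# report-cell formatting: ORs and CIs at 2 decimals, p-values in
# scientific notation with a 2-decimal mantissa below 0.05, FDR at 2
# decimals
.fmt_or <- function(x) sprintf("%.2f", x)
.fmt_ci <- function(lo, hi) sprintf("%.2f-%.2f", lo, hi)
.fmt_p <- function(p) ifelse(is.na(p), "NA",
                             ifelse(p < 0.05, sprintf("%.2E", p),
                                    sprintf("%.2f", p)))
.fmt_q <- function(q, p) ifelse(is.na(q), "NA",
                                sprintf("%.2f (%.2f)", q, p))

.method_label <- c(ivw = "Inverse variance weighted",
                   wald = "Wald ratio",
                   weighted_median = "Weighted median",
                   egger = "MR Egger",
                   max_likelihood = "Maximum likelihood")

#' Write human-readable and machine-readable result tables
#'
#' Produces four files under `out_dir`: `estimates.tsv` and
#' `sensitivity.tsv` (full precision, machine readable), and
#' `estimates_formatted.tsv` / `sensitivity_formatted.tsv` rendered the
#' way MR studies print them (OR and CI to 2 decimals, small p-values
#' in scientific notation with 2-decimal mantissa, composite
#' "Q (p)" cells, `NA` where a method was inapplicable). The formatted
#' tables are pure re-renderings of the full-precision ones.
#'
#' @param result An [run_pipeline()] `mr_pipeline_result`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
format_report_tables <- function(result, out_dir) {
  stopifnot(inherits(result, "mr_pipeline_result"),
            nrow(result$estimates) > 0)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  est <- result$estimates
  sens <- result$sensitivity

  full_est <- file.path(out_dir, "estimates.tsv")
  utils::write.table(est, full_est, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  full_sens <- file.path(out_dir, "sensitivity.tsv")
  utils::write.table(sens, full_sens, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  pretty_est <- data.frame(
    `Gut bacteria` = est$exposure_id, Outcome = est$outcome_id,
    NSNP = est$nsnp,
    Method = unname(.method_label[est$method]),
    OR = .fmt_or(est$or_value), `95%CI` = .fmt_ci(est$ci_low,
                                                  est$ci_high),
    `Value of p` = .fmt_p(est$pval), FDR = sprintf("%.2f", est$fdr),
    check.names = FALSE, stringsAsFactors = FALSE)
  fmt_est <- file.path(out_dir, "estimates_formatted.tsv")
  utils::write.table(pretty_est, fmt_est, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  pretty_sens <- data.frame(
    `Bacterial taxa` = sens$exposure_id, Outcome = sens$outcome_id,
    `IVW Q (p-value)` = .fmt_q(sens$q_ivw, sens$p_q_ivw),
    `MR Egger Q (p-value)` = .fmt_q(sens$q_egger, sens$p_q_egger),
    `MR-PRESSO RSSobs (p-value)` = .fmt_q(sens$presso_rss,
                                          sens$presso_global_p),
    `MR Egger_intercept` = ifelse(is.na(sens$egger_intercept), "NA",
                                  sprintf("%.2f",
                                          sens$egger_intercept)),
    `Value of p` = ifelse(is.na(sens$egger_intercept_p), "NA",
                          sprintf("%.2f", sens$egger_intercept_p)),
    check.names = FALSE, stringsAsFactors = FALSE)
  fmt_sens <- file.path(out_dir, "sensitivity_formatted.tsv")
  utils::write.table(pretty_sens, fmt_sens, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  invisible(c(full_est, full_sens, fmt_est, fmt_sens))
}
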