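#' Upper-tail chi-square p-value for a heterogeneity statistic
#'
#' @param q Cochran's Q (or Rucker's Q') value.
#' @param df Degrees of freedom (J - 1 for the IVW form, J - 2 for the
#'   Egger form).
#' @return Upper-tail probability of chi-square(df) at `q`.
#' @export
q_pvalue <- function(q, df) {
  stopifnot(df >= 1)
  stats::pchisq(q, df, lower.tail = FALSE)
}

#' Cochran's Q heterogeneity statistic
#'
#' IVW form: Q = sum of w_j (theta_j - theta_IVW)^2 over the per-variant
#' Wald ratios theta_j with inverse-variance weights w_j =
#' (beta_x_j / se_y_j)^2, referenced to chi-square on J - 1 degrees of
#' freedom. Egger form: Rucker's Q', the weighted residual sum of
#' squares of the intercept model, on J - 2 degrees of freedom.
#'
#' @param h A [harmonized_set()].
#' @param model `"ivw"` (J >= 2) or `"egger"` (J >= 3).
#' @return List with `q`, `df`, `pval`.
#' @export
q_statistic <- function(h, model = c("ivw", "egger")) {
  model <- match.arg(model)
  v <- .h_variants(h)
  J <- nrow(v)
  if (model == "ivw") {
    if (J < 2) stop("Q (IVW) requires J >= 2")
    est <- mr_ivw(v, re_mode = "fixed")
    list(q = est$extra$q, df = J - 1L, pval = q_pvalue(est$extra$q, J - 1L))
  } else {
    if (J < 3) stop("Q' (Egger) requires J >= 3")
    est <- mr_egger(v)
    list(q = est$extra$q, df = J - 2L, pval = q_pvalue(est$extra$q, J - 2L))
  }
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' Tests whether the intercept of the MR-Egger regression differs from
#' zero (two-sided normal). A p-value below `alpha` flags the
#' taxon-outcome pair as pleiotropic, in which case the causal
#' inference is discarded by the pipeline.
#'
#' @param h A [harmonized_set()] with J >= 3.
#' @param alpha Flagging threshold (default 0.05).
#' @return List with `b0`, `se_b0`, `pval`, `pleiotropic`.
#' @export
egger_intercept_test <- function(h, alpha = 0.05) {
  est <- mr_egger(h)
  list(b0 = est$extra$intercept, se_b0 = est$extra$intercept_se,
       pval = est$extra$intercept_pval,
       pleiotropic = est$extra$intercept_pval < alpha)
}

# leave-one-out IVW slopes for each variant, vectorized over rows of
# (possibly simulated) effect matrices; w fixed at 1/se_y^2
.loo_theta <- function(bx, by, w) {
  sxy <- sum(w * bx * by); sxx <- sum(w * bx^2)
  (sxy - w * bx * by) / (sxx - w * bx^2)
}

#' MR-PRESSO global pleiotropy test and outlier search
#'
#' Observed statistic: RSS_obs = sum of w_j (beta_y_j - theta_(-j) *
#' beta_x_j)^2, where theta_(-j) is the IVW estimate excluding variant j
#' and w_j = 1/se_y_j^2. The null distribution comes from `n_sim`
#' seeded replicates redrawing beta_x_j* ~ N(beta_x_j, se_x_j) and
#' beta_y_j* ~ N(theta_(-j) * beta_x_j, se_y_j) and recomputing the
#' statistic. The global p-value uses the add-one estimator
#' (1 + #\{RSS* >= RSS_obs\}) / (n_sim + 1) so it can never be exactly
#' zero. Per-variant outlier p-values compare each observed residual
#' against that variant's simulated residual distribution and are
#' Bonferroni-corrected by J; the distortion test compares the
#' with/without-outliers estimate shift against removals of random
#' variant subsets of the same size (advisory only).
#'
#' @param h A [harmonized_set()] with J >= 4.
#' @param n_sim Null-simulation replicates (default 1000).
#' @param outlier_alpha Significance level for Bonferroni-corrected
#'   per-variant outlier calls (default 0.05).
#' @param seed Integer seed.
#' @return List with `rss_obs`, `global_p`, `outliers` (variant ids),
#'   `outlier_pvals` (named, Bonferroni-corrected), `distortion_p`
#'   (NA with a note when no outliers are flagged), `n_sim`, `seed`.
#' @export
mr_presso <- function(h, n_sim = 1000, outlier_alpha = 0.05, seed = 1L) {
  v <- .h_variants(h)
  J <- nrow(v)
  if (J < 4) stop("MR-PRESSO requires at least 4 variants (J = ", J, ")")
  w <- 1 / v$se_y^2
  th_loo <- .loo_theta(v$beta_x, v$beta_y, w)
  res_obs <- w * (v$beta_y - th_loo * v$beta_x)^2
  rss_obs <- sum(res_obs)

  sim <- .with_seed(seed, {
    bxs <- matrix(stats::rnorm(n_sim * J, rep(v$beta_x, each = n_sim),
                               rep(v$se_x, each = n_sim)), n_sim, J)
    bys <- matrix(stats::rnorm(n_sim * J,
                               rep(th_loo * v$beta_x, each = n_sim),
                               rep(v$se_y, each = n_sim)), n_sim, J)
    wm <- matrix(w, n_sim, J, byrow = TRUE)
    sxx <- rowSums(wm * bxs^2); sxy <- rowSums(wm * bxs * bys)
    th <- (sxy - wm * bxs * bys) / (sxx - wm * bxs^2)
    res <- wm * (bys - th * bxs)^2
    list(res = res, rss = rowSums(res))
  })

  global_p <- (1 + sum(sim$rss >= rss_obs)) / (n_sim + 1)
  p_snp <- (1 + colSums(sim$res >= rep(res_obs, each = n_sim))) /
    (n_sim + 1)
  p_bonf <- pmin(1, p_snp * J)
  names(p_bonf) <- v$variant_id
  outliers <- v$variant_id[p_bonf < outlier_alpha]

  distortion_p <- NA_real_
  note <- NULL
  if (length(outliers) > 0 && length(outliers) < J - 1) {
    keep <- !(v$variant_id %in% outliers)
    th_all <- mr_ivw(v, re_mode = "fixed")$theta
    th_no <- if (sum(keep) >= 2)
      mr_ivw(v[keep, ], re_mode = "fixed")$theta else
      v$beta_y[keep] / v$beta_x[keep]
    d_obs <- (th_all - th_no) / abs(th_no)
    d_null <- .with_seed(seed + 1L, {
      vapply(seq_len(n_sim), function(b) {
        drop <- sample.int(J, length(outliers))
        vb <- v[-drop, , drop = FALSE]
        thb <- if (nrow(vb) >= 2) mr_ivw(vb, re_mode = "fixed")$theta else
          vb$beta_y / vb$beta_x
        (th_all - thb) / abs(thb)
      }, numeric(1))
    })
    distortion_p <- (1 + sum(abs(d_null) >= abs(d_obs))) / (n_sim + 1)
  } else if (length(outliers) == 0) {
    note <- "no outliers flagged; distortion test skipped"
  } else {
    note <- "too few non-outliers for a distortion reference"
  }
  list(rss_obs = rss_obs, global_p = global_p, outliers = outliers,
       outlier_pvals = p_bonf, distortion_p = distortion_p,
       n_sim = n_sim, seed = seed, note = note)
}

#' Leave-one-out IVW analysis
#'
#' Re-estimates the IVW effect J times, each time excluding one
#' variant, to expose estimates driven by a single influential SNP.
#'
#' @param h A [harmonized_set()] with J >= 3.
#' @return data.frame with one row per left-out variant: `left_out`,
#'   `theta`, `se`, `pval`, `nsnp`.
#' @export
leave_one_out <- function(h) {
  v <- .h_variants(h)
  J <- nrow(v)
  if (J < 3) stop("leave-one-out requires at least 3 variants")
  rows <- lapply(seq_len(J), function(j) {
    est <- mr_ivw(v[-j, , drop = FALSE])
    data.frame(left_out = v$variant_id[j], theta = est$theta,
               se = est$se, pval = est$pval, nsnp = J - 1L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Funnel-plot coordinates
#'
#' Per-variant Wald ratio against its precision (1/se). Asymmetry
#' indicates directional pleiotropy; only the data table is produced,
#' no rendering.
#'
#' @param h A [harmonized_set()] with J >= 1.
#' @return data.frame with `variant_id`, `theta`, `precision`.
#' @export
funnel_data <- function(h) {
  v <- .h_variants(h)
  stopifnot(nrow(v) >= 1)
  se_ratio <- abs(v$se_y / v$beta_x)
  data.frame(variant_id = v$variant_id, theta = v$beta_y / v$beta_x,
             precision = 1 / se_ratio, stringsAsFactors = FALSE)
}

#' Full sensitivity suite for one taxon-outcome analysis
#'
#' Bundles both heterogeneity Q statistics, the Egger intercept test,
#' MR-PRESSO, the leave-one-out table and funnel coordinates. Methods
#' whose minimum J is not met are reported as NA with a note.
#'
#' @param h A [harmonized_set()].
#' @param n_sim MR-PRESSO null replicates.
#' @param seed Integer seed for MR-PRESSO.
#' @return Object of class `sensitivity_report` (a list).
#' @export
sensitivity_report <- function(h, n_sim = 1000, seed = 1L) {
  v <- .h_variants(h)
  J <- nrow(v)
  maybe <- function(min_j, expr) if (J >= min_j) expr else NULL
  rep <- list(
    nsnp = J,
    q_ivw = maybe(2, q_statistic(h, "ivw")),
    q_egger = maybe(3, q_statistic(h, "egger")),
    egger_intercept = maybe(3, egger_intercept_test(h)),
    presso = maybe(4, mr_presso(h, n_sim = n_sim, seed = seed)),
    loo_table = maybe(3, leave_one_out(h)),
    funnel = maybe(1, funnel_data(h)))
  structure(rep, class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  fmt <- function(s) if (is.null(s)) "NA" else
    sprintf("%.2f (%.2f)", s$q, s$pval)
  cat(sprintf("<sensitivity_report> J = %d | Q_ivw %s | Q_egger %s\n",
              x$nsnp, fmt(x$q_ivw), fmt(x$q_egger)))
  if (!is.null(x$egger_intercept))
    cat(sprintf("  Egger intercept %.3g (p = %.2f)\n",
                x$egger_intercept$b0, x$egger_intercept$pval))
  if (!is.null(x$presso))
    cat(sprintf("  MR-PRESSO RSSobs %.2f (p = %.2f), %d outlier(s)\n",
                x$presso$rss_obs, x$presso$global_p,
                length(x$presso$outliers)))
  invisible(x)
}
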