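# run code under a temporary seed, restoring the caller's RNG state
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv))
  }
  set.seed(seed)
  force(code)
}

#' Convert a log-odds effect to an odds ratio with CI and p-value
#'
#' @param theta Log-odds of outcome per SD change in exposure.
#' @param se Standard error of `theta` (> 0).
#' @param level Confidence level (default 0.95); the exact normal
#'   quantile is used (1.959964... at 0.95, not 1.96).
#' @return List with `or_value`, `ci_low`, `ci_high`, `pval` (two-sided
#'   normal).
#' @export
effect_to_or <- function(theta, se, level = 0.95) {
  stopifnot(se > 0, level > 0, level < 1)
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(or_value = exp(theta),
       ci_low = exp(theta - z * se), ci_high = exp(theta + z * se),
       pval = 2 * stats::pnorm(-abs(theta / se)))
}

# assemble an MREstimate record
.mr_estimate <- function(method, theta, se, nsnp, extra = list(),
                         level = 0.95) {
  conv <- effect_to_or(theta, se, level)
  structure(list(method = method, theta = theta, se = se,
                 or_value = conv$or_value, ci_low = conv$ci_low,
                 ci_high = conv$ci_high, pval = conv$pval,
                 nsnp = as.integer(nsnp), extra = extra),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("<mr_estimate> %s: OR %.3f (%.3f-%.3f), p = %.3g, J = %d\n",
              x$method, x$or_value, x$ci_low, x$ci_high, x$pval, x$nsnp))
  invisible(x)
}

.h_variants <- function(h) {
  if (inherits(h, "harmonized_set")) h$variants else
    as.data.frame(h, stringsAsFactors = FALSE)
}

#' Wald ratio estimate for a single variant
#'
#' theta = beta_y / beta_x with first-order delta-method standard error
#' |se_y / beta_x|. The building block for all ratio-based estimators.
#'
#' @param v One harmonized variant (data.frame row or list with
#'   `beta_x`, `se_y`, `beta_y`; `beta_x` must be nonzero).
#' @return An `mr_estimate` with method `"wald"`.
#' @export
wald_ratio <- function(v) {
  if (v$beta_x == 0) stop("Wald ratio undefined: beta_x = 0")
  .mr_estimate("wald", v$beta_y / v$beta_x, abs(v$se_y / v$beta_x), 1L)
}

#' Inverse-variance-weighted causal estimate
#'
#' The primary estimator: the weighted least-squares slope of outcome
#' effects on exposure effects through the origin with weights
#' 1/se_y^2, equivalently the inverse-variance meta-analysis of the
#' per-variant Wald ratios. The default `multiplicative_floor` mode
#' scales the fixed-effect standard error by max(1, sqrt(Q/(J-1))) so
#' that excess heterogeneity widens the interval but can never shrink
#' it below the fixed-effect value.
#'
#' @param h A [harmonized_set()] (or data.frame with `beta_x`, `se_x`,
#'   `beta_y`, `se_y`) with at least 2 variants.
#' @param re_mode `"multiplicative_floor"` (default) or `"fixed"`.
#' @return An `mr_estimate` with method `"ivw"`; `extra` carries
#'   Cochran's `q`, its `df`, and the `scale` applied to the SE.
#' @export
mr_ivw <- function(h, re_mode = c("multiplicative_floor", "fixed")) {
  re_mode <- match.arg(re_mode)
  v <- .h_variants(h)
  J <- nrow(v)
  if (J < 2) stop("IVW requires at least 2 variants (J = ", J,
                  "); use wald_ratio()")
  w <- 1 / v$se_y^2
  theta <- sum(v$beta_x * v$beta_y * w) / sum(v$beta_x^2 * w)
  se_fixed <- 1 / sqrt(sum(v$beta_x^2 * w))
  q <- sum(w * (v$beta_y - theta * v$beta_x)^2)
  scale <- if (re_mode == "multiplicative_floor")
    max(1, sqrt(q / (J - 1))) else 1
  .mr_estimate("ivw", theta, se_fixed * scale, J,
               extra = list(q = q, df = J - 1L, scale = scale,
                            re_mode = re_mode))
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome on exposure effects with an
#' intercept, each variant oriented so its exposure effect is
#' non-negative (both betas negated where needed; without this the
#' intercept is not consistently identified). The slope is the causal
#' estimate; the intercept estimates average directional pleiotropy.
#' Residual-scale handling mirrors [mr_ivw()]'s multiplicative floor
#' using Rucker's Q' on J - 2 degrees of freedom.
#'
#' @param h A [harmonized_set()] with at least 3 variants.
#' @return An `mr_estimate` with method `"egger"`; `extra` carries
#'   `intercept`, `intercept_se`, `intercept_pval`, `q` (Rucker's Q'),
#'   `df` and `scale`.
#' @export
mr_egger <- function(h) {
  v <- .h_variants(h)
  J <- nrow(v)
  if (J < 3) stop("MR-Egger requires at least 3 variants (J = ", J, ")")
  flip <- sign(v$beta_x); flip[flip == 0] <- 1
  bx <- flip * v$beta_x; by <- flip * v$beta_y
  w <- 1 / v$se_y^2
  fit <- stats::lm(by ~ bx, weights = w)
  cf <- stats::coef(fit)
  q <- sum(w * stats::residuals(fit)^2)
  sigma_hat <- sqrt(q / (J - 2))
  # lm SEs are proportional to sigma_hat; rescale to max(1, sigma_hat)
  unit <- sqrt(diag(stats::vcov(fit))) / sigma_hat
  scale <- max(1, sigma_hat)
  se_slope <- unit[["bx"]] * scale
  se_int <- unit[["(Intercept)"]] * scale
  .mr_estimate("egger", cf[["bx"]], se_slope, J,
               extra = list(
                 intercept = cf[["(Intercept)"]], intercept_se = se_int,
                 intercept_pval =
                   2 * stats::pnorm(-abs(cf[["(Intercept)"]] / se_int)),
                 q = q, df = J - 2L, scale = scale))
}

# weighted median of ordered values by cumulative standardized weight
.weighted_median_point <- function(theta, w) {
  o <- order(theta)
  theta <- theta[o]; w <- w[o]
  s <- (cumsum(w) - 0.5 * w) / sum(w)
  if (s[1] >= 0.5) return(theta[1])
  if (s[length(s)] <= 0.5) return(theta[length(theta)])
  below <- max(which(s < 0.5))
  theta[below] + (theta[below + 1] - theta[below]) *
    (0.5 - s[below]) / (s[below + 1] - s[below])
}

#' Weighted-median causal estimate
#'
#' The 50% weighted quantile of the ordered per-variant Wald ratios
#' with inverse-variance weights: consistent as long as at least half
#' of the total weight comes from valid instruments. The standard error
#' is the standard deviation of the estimate over `n_boot` parametric
#' bootstrap resamples (effects redrawn normal around their observed
#' values with their observed SEs), so it is stochastic but fully
#' reproducible given `seed`.
#'
#' @param h A [harmonized_set()] with at least 3 variants.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @return An `mr_estimate` with method `"weighted_median"`; `extra`
#'   carries `n_boot` and `seed`.
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed = 1L) {
  v <- .h_variants(h)
  J <- nrow(v)
  if (J < 3) stop("weighted median requires at least 3 variants (J = ",
                  J, ")")
  ratio <- v$beta_y / v$beta_x
  w <- (v$beta_x / v$se_y)^2     # 1 / se(ratio)^2, first-order
  theta <- .weighted_median_point(ratio, w)
  boots <- .with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bx <- stats::rnorm(J, v$beta_x, v$se_x)
      by <- stats::rnorm(J, v$beta_y, v$se_y)
      .weighted_median_point(by / bx, (bx / v$se_y)^2)
    }, numeric(1))
  })
  .mr_estimate("weighted_median", theta, stats::sd(boots), J,
               extra = list(n_boot = n_boot, seed = seed))
}

#' Maximum-likelihood causal estimate
#'
#' Joint normal model: observed exposure effects beta_x_j ~
#' N(gamma_j, se_x_j^2) and outcome effects beta_y_j ~
#' N(theta * gamma_j, se_y_j^2). The likelihood is maximized by
#' coordinate ascent over (theta, gamma_1..gamma_J), initialized at
#' gamma_j = beta_x_j and theta = the fixed-effect IVW estimate, until
#' successive theta changes fall below `tol`. The standard error comes
#' from the curvature (observed information) of the profile
#' log-likelihood at the optimum. Unlike IVW, the model accounts for
#' sampling error in the exposure effects; as se_x -> 0 it reduces to
#' fixed-effect IVW.
#'
#' @param h A [harmonized_set()] with at least 2 variants.
#' @param tol Convergence tolerance on theta (default 1e-10).
#' @param max_iter Iteration cap (default 10000).
#' @return An `mr_estimate` with method `"max_likelihood"`; `extra`
#'   carries `iterations` and the profile `loglik`.
#' @export
mr_max_likelihood <- function(h, tol = 1e-10, max_iter = 10000L) {
  v <- .h_variants(h)
  J <- nrow(v)
  if (J < 2) stop("maximum likelihood requires at least 2 variants (J = ",
                  J, ")")
  wx <- 1 / v$se_x^2; wy <- 1 / v$se_y^2
  profile_gamma <- function(theta)
    (v$beta_x * wx + theta * v$beta_y * wy) / (wx + theta^2 * wy)
  profile_ll <- function(theta) {
    g <- profile_gamma(theta)
    -0.5 * sum(wx * (v$beta_x - g)^2 + wy * (v$beta_y - theta * g)^2)
  }
  theta <- mr_ivw(v, re_mode = "fixed")$theta
  gamma <- v$beta_x
  iter <- 0L
  repeat {
    iter <- iter + 1L
    gamma <- profile_gamma(theta)
    theta_new <- sum(gamma * v$beta_y * wy) / sum(gamma^2 * wy)
    delta <- abs(theta_new - theta)
    theta <- theta_new
    if (delta < tol) break
    if (iter >= max_iter) {
      cond <- structure(
        class = c("taxaMR_convergence_error", "error", "condition"),
        list(message = sprintf(
          "maximum likelihood did not converge in %d iterations (last theta = %.10g)",
          max_iter, theta), call = sys.call(-1), last_theta = theta))
      stop(cond)
    }
  }
  # observed information of the profile log-likelihood, central difference
  step <- 1e-5 * max(1, abs(theta))
  info <- -(profile_ll(theta + step) - 2 * profile_ll(theta) +
              profile_ll(theta - step)) / step^2
  .mr_estimate("max_likelihood", theta, 1 / sqrt(info), J,
               extra = list(iterations = iter,
                            loglik = profile_ll(theta)))
}

#' Run a set of MR estimators on one harmonized set
#'
#' Applies the requested methods, falling back to the single-variant
#' Wald ratio (with a logged note) when J = 1 makes the multi-variant
#' methods inapplicable, and skipping methods whose minimum J is not
#' met.
#'
#' @param h A [harmonized_set()].
#' @param methods Character vector from `"ivw"`, `"egger"`,
#'   `"weighted_median"`, `"max_likelihood"`.
#' @param n_boot,seed Passed to [mr_weighted_median()].
#' @return Named list of `mr_estimate` objects; attribute `notes`
#'   records skipped/fallback methods.
#' @export
mr_all_methods <- function(h, methods = c("ivw", "egger",
                                          "weighted_median",
                                          "max_likelihood"),
                           n_boot = 1000, seed = 1L) {
  J <- nrow(.h_variants(h))
  min_j <- c(ivw = 2L, egger = 3L, weighted_median = 3L,
             max_likelihood = 2L)
  out <- list(); notes <- character(0)
  for (m in methods) {
    if (J < min_j[[m]]) {
      if (m == "ivw" && J == 1L) {
        out[["ivw"]] <- wald_ratio(.h_variants(h)[1L, ])
        notes <- c(notes, "ivw: J = 1, fell back to Wald ratio")
      } else {
        notes <- c(notes, sprintf("%s: inapplicable at J = %d", m, J))
      }
      next
    }
    out[[m]] <- switch(m,
      ivw = mr_ivw(h),
      egger = mr_egger(h),
      weighted_median = mr_weighted_median(h, n_boot = n_boot,
                                           seed = seed),
      max_likelihood = mr_max_likelihood(h))
  }
  attr(out, "notes") <- notes
  out
}
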