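#' Describe a horizontal-pleiotropy regime
#'
#' @param type `"none"`, `"balanced"` (alpha ~ N(0, sigma_alpha^2)),
#'   `"directional"` (alpha ~ N(mu_alpha, sigma_alpha^2); instrument
#'   effects are drawn half-normal so "directional" is defined relative
#'   to the exposure-increasing allele), or `"outlier"` (`count`
#'   instruments displaced by `magnitude` outcome standard errors).
#' @param sigma_alpha,mu_alpha,count,magnitude Regime parameters.
#' @return List of class `pleiotropy_regime`.
#' @export
pleiotropy_regime <- function(type = c("none", "balanced", "directional",
                                       "outlier"),
                              sigma_alpha = 0, mu_alpha = 0,
                              count = 0L, magnitude = 0) {
  if (!is.character(type) || !type[1] %in% c("none", "balanced",
                                             "directional", "outlier"))
    stop("unknown pleiotropy regime: ", type[1])
  structure(list(type = type[1], sigma_alpha = sigma_alpha,
                 mu_alpha = mu_alpha, count = as.integer(count),
                 magnitude = magnitude), class = "pleiotropy_regime")
}

#' Simulation configuration for synthetic GWAS summary statistics
#'
#' Defaults emulate the scale of the data the pipeline targets: 119
#' genus-level exposures from an abundance GWAS of 18,340 samples, and
#' a case-control outcome of 69,501 cases / 105,974 controls
#' (an ER+-disease-sized cohort).
#'
#' @param n_taxa Number of exposure taxa (default 119).
#' @param variants_per_taxon Variants per exposure dataset, instruments
#'   plus null background (default 50).
#' @param j_instruments True instruments per taxon (default 10,
#'   matching the 8-14 per-taxon instrument counts typical after
#'   clumping).
#' @param theta Causal log-OR per SD of abundance, recycled across taxa
#'   (0 for null taxa).
#' @param pleiotropy A [pleiotropy_regime()].
#' @param n_exposure Exposure GWAS sample size (default 18,340).
#' @param n_cases,n_controls Outcome case/control counts (defaults
#'   69,501 / 105,974).
#' @param maf_range Minor-allele-frequency range (default 0.05-0.5).
#' @param sigma_gamma SD of true instrument effects on the abundance-SD
#'   scale (default 0.05, giving F statistics in the tens for the
#'   default sample size).
#' @param palindrome_frac Fraction of variants assigned palindromic
#'   A/T or C/G alleles (default 0.1).
#' @param swap_frac Fraction of outcome records with effect/other
#'   alleles swapped (default 0.25).
#' @param complement_frac Fraction of outcome records reported on the
#'   opposite strand (default 0.25).
#' @param ld_blocks Optional list(block_size, r, n_individuals,
#'   n_variants) for reference-panel generation.
#' @param seed Integer seed; identical configs yield bit-identical
#'   datasets.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_taxa = 119, variants_per_taxon = 50,
                       j_instruments = 10, theta = 0,
                       pleiotropy = pleiotropy_regime("none"),
                       n_exposure = 18340, n_cases = 69501,
                       n_controls = 105974, maf_range = c(0.05, 0.5),
                       sigma_gamma = 0.05, palindrome_frac = 0.1,
                       swap_frac = 0.25, complement_frac = 0.25,
                       ld_blocks = NULL, seed = 1L) {
  stopifnot(n_taxa >= 1, variants_per_taxon >= j_instruments,
            j_instruments >= 1, n_exposure > 0, n_cases > 0,
            n_controls > 0, maf_range[1] > 0, maf_range[2] <= 0.5,
            inherits(pleiotropy, "pleiotropy_regime"))
  structure(list(n_taxa = n_taxa, variants_per_taxon = variants_per_taxon,
                 j_instruments = j_instruments,
                 theta = rep_len(theta, n_taxa), pleiotropy = pleiotropy,
                 n_exposure = n_exposure, n_cases = n_cases,
                 n_controls = n_controls, maf_range = maf_range,
                 sigma_gamma = sigma_gamma,
                 palindrome_frac = palindrome_frac,
                 swap_frac = swap_frac,
                 complement_frac = complement_frac,
                 ld_blocks = ld_blocks, seed = as.integer(seed)),
            class = "sim_config")
}

# per-variant truth and summary-statistic draws for one taxon; assumes
# the RNG state is already set by the caller
.draw_taxon <- function(cfg, theta, n_variants = cfg$variants_per_taxon,
                        j = cfg$j_instruments) {
  maf <- stats::runif(n_variants, cfg$maf_range[1], cfg$maf_range[2])
  is_iv <- seq_len(n_variants) <= j
  reg <- cfg$pleiotropy
  gamma <- ifelse(is_iv, stats::rnorm(n_variants, 0, cfg$sigma_gamma), 0)
  if (reg$type == "directional") gamma <- abs(gamma)
  alpha <- numeric(n_variants)
  if (reg$type == "balanced")
    alpha[is_iv] <- stats::rnorm(j, 0, reg$sigma_alpha)
  if (reg$type == "directional")
    alpha[is_iv] <- stats::rnorm(j, reg$mu_alpha, reg$sigma_alpha)

  se_x <- 1 / sqrt(2 * maf * (1 - maf) * cfg$n_exposure)
  beta_x <- stats::rnorm(n_variants, gamma, se_x)
  phi <- cfg$n_cases / (cfg$n_cases + cfg$n_controls)
  n_eff <- cfg$n_cases + cfg$n_controls
  se_y <- 1 / sqrt(2 * maf * (1 - maf) * n_eff * phi * (1 - phi))
  if (reg$type == "outlier" && reg$count > 0) {
    hit <- which(is_iv)[seq_len(min(reg$count, j))]
    alpha[hit] <- reg$magnitude * se_y[hit]
  }
  beta_y <- stats::rnorm(n_variants, theta * gamma + alpha, se_y)
  data.frame(maf = maf, is_instrument = is_iv, gamma = gamma,
             alpha = alpha, se_x = se_x, beta_x = beta_x, se_y = se_y,
             beta_y = beta_y, n_eff = n_eff)
}

# random allele bookkeeping for one variant table
.assign_alleles <- function(n, palindrome_frac) {
  bases <- c("A", "C", "G", "T")
  ea <- character(n); oa <- character(n)
  pal <- stats::runif(n) < palindrome_frac
  for (i in seq_len(n)) {
    if (pal[i]) {
      pair <- if (stats::runif(1) < 0.5) c("A", "T") else c("C", "G")
      if (stats::runif(1) < 0.5) pair <- rev(pair)
    } else {
      repeat {
        pair <- sample(bases, 2)
        if (.complement[[pair[1]]] != pair[2]) break
      }
    }
    ea[i] <- pair[1]; oa[i] <- pair[2]
  }
  data.frame(effect_allele = ea, other_allele = oa,
             stringsAsFactors = FALSE)
}

#' Simulate a full two-sample MR study with known truth
#'
#' Generates one exposure summary-statistics dataset per taxon and a
#' single shared outcome dataset over the union of all variants, under
#' the generating model: instrument effects gamma ~ N(0, sigma_gamma^2)
#' (zero for background variants), observed exposure effects
#' beta_x ~ N(gamma, se_x^2) with se_x = 1/sqrt(2 MAF (1-MAF) n), and
#' outcome effects beta_y ~ N(theta gamma + alpha, se_y^2) with the
#' case-control standard error se_y = 1/sqrt(2 MAF (1-MAF) n_eff
#' phi (1-phi)), phi the case fraction. Allele labels, strand flips,
#' allele swaps and palindromic variants are injected per the config so
#' harmonization is exercised end to end.
#'
#' @param config A [sim_config()].
#' @return List with `exposures` (named list of exposure
#'   [summary_dataset()]s), `outcome` (shared outcome dataset), and
#'   `truth` (list: per-taxon `theta`, per-variant `variants`
#'   data.frame, the `config`).
#' @export
simulate_mr_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed, {
    exposures <- list(); truth_rows <- list(); outcome_rows <- list()
    for (t in seq_len(config$n_taxa)) {
      taxon <- sprintf("Genus_synthetic%03d", t)
      d <- .draw_taxon(config, config$theta[t])
      nv <- nrow(d)
      d$variant_id <- sprintf("rs%03d%05d", t, seq_len(nv))
      d$chrom <- as.character(rep_len(1:22, nv))
      d$pos <- 1e6 + (seq_len(nv) %/% 22) * 1e6 + (t %% 97) * 1e4
      al <- .assign_alleles(nv, config$palindrome_frac)
      eaf <- ifelse(stats::runif(nv) < 0.5, d$maf, 1 - d$maf)

      exp_rec <- data.frame(
        variant_id = d$variant_id, chrom = d$chrom, pos = d$pos,
        effect_allele = al$effect_allele, other_allele = al$other_allele,
        eaf = eaf, beta = d$beta_x, se = d$se_x,
        pval = 2 * stats::pnorm(-abs(d$beta_x / d$se_x)),
        n = config$n_exposure, stringsAsFactors = FALSE)
      exposures[[taxon]] <- summary_dataset(exp_rec, taxon, "exposure",
                                            "genus")

      # outcome records: same variants, possibly swapped or strand-flipped
      swap <- stats::runif(nv) < config$swap_frac
      comp <- stats::runif(nv) < config$complement_frac
      o_ea <- al$effect_allele; o_oa <- al$other_allele
      o_beta <- d$beta_y; o_eaf <- eaf
      o_ea[swap] <- al$other_allele[swap]
      o_oa[swap] <- al$effect_allele[swap]
      o_beta[swap] <- -o_beta[swap]
      o_eaf[swap] <- 1 - o_eaf[swap]
      o_ea[comp] <- unname(.complement[o_ea[comp]])
      o_oa[comp] <- unname(.complement[o_oa[comp]])
      outcome_rows[[t]] <- data.frame(
        variant_id = d$variant_id, chrom = d$chrom, pos = d$pos,
        effect_allele = o_ea, other_allele = o_oa, eaf = o_eaf,
        beta = o_beta, se = d$se_y,
        pval = 2 * stats::pnorm(-abs(o_beta / d$se_y)),
        n = d$n_eff, stringsAsFactors = FALSE)

      truth_rows[[t]] <- data.frame(
        taxon = taxon, variant_id = d$variant_id, maf = d$maf,
        is_instrument = d$is_instrument, gamma = d$gamma,
        alpha = d$alpha, theta = config$theta[t],
        stringsAsFactors = FALSE)
    }
    truth_var <- do.call(rbind, truth_rows)
    theta <- config$theta
    names(theta) <- names(exposures)
    list(exposures = exposures,
         outcome = summary_dataset(do.call(rbind, outcome_rows),
                                   "Synthetic case-control outcome",
                                   "outcome"),
         truth = list(theta = theta, variants = truth_var,
                      config = config))
  })
}

#' Simulate an already-harmonized instrument set with known truth
#'
#' Draws only the true instruments of a single taxon under the same
#' generating model as [simulate_mr_dataset()] and returns them as a
#' [harmonized_set()] with aligned effect pairs, skipping allele
#' bookkeeping. This is the fast path for estimator-calibration Monte
#' Carlo studies, where instrument selection and harmonization are not
#' under test.
#'
#' @param j Number of instruments.
#' @param theta True causal log-OR per SD.
#' @param config A [sim_config()] supplying sample sizes, MAF range,
#'   `sigma_gamma` and the pleiotropy regime (its `theta`/`n_taxa` are
#'   ignored).
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A [harmonized_set()] with attribute `truth` (the per-variant
#'   generating values).
#' @export
simulate_harmonized <- function(j, theta, config = sim_config(),
                                seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(seed, {
    d <- .draw_taxon(config, theta, n_variants = j, j = j)
    d$variant_id <- sprintf("rs%05d", seq_len(j))
    h <- harmonized_set(d[, c("variant_id", "beta_x", "se_x", "beta_y",
                              "se_y")], "synthetic_taxon",
                        "synthetic_outcome")
    attr(h, "truth") <- d
    h
  })
}

#' Simulate a reference genotype panel with block LD structure
#'
#' Individuals' dosages are drawn from two latent haplotypes per
#' person; within an LD block each haplotype copies a shared
#' block-level allele with probability sqrt(r) (so the within-block
#' dosage correlation is approximately r) and draws independently
#' otherwise. Across blocks, draws are independent. Variants in the
#' same block share the block's allele frequency.
#'
#' @param config A [sim_config()] with `ld_blocks = list(block_size,
#'   r, n_individuals, n_variants)` (`n_variants` optional when
#'   `variants` is supplied).
#' @param variants Optional data.frame (`variant_id`, `chrom`, `pos`,
#'   optionally `maf`) to cover, e.g. a simulated exposure's records;
#'   consecutive rows on the same chromosome are grouped into blocks.
#'   When NULL a standalone grid is generated: blocks 10 kb wide,
#'   spaced 2 Mb apart on chromosome 1.
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A [reference_panel()].
#' @export
simulate_reference_panel <- function(config, variants = NULL,
                                     seed = config$seed) {
  stopifnot(inherits(config, "sim_config"), !is.null(config$ld_blocks))
  lb <- config$ld_blocks
  stopifnot(lb$block_size >= 1, lb$r >= 0, lb$r <= 1,
            lb$n_individuals >= 2)
  .with_seed(seed, {
    if (is.null(variants)) {
      nv <- if (!is.null(lb$n_variants)) lb$n_variants else 20L
      block <- as.character((seq_len(nv) - 1L) %/% lb$block_size)
      variants <- data.frame(
        variant_id = sprintf("rsP%05d", seq_len(nv)),
        chrom = "1",
        pos = 1e6 + as.integer(block) * 2e6 +
          ((seq_len(nv) - 1L) %% lb$block_size) * 1e4,
        stringsAsFactors = FALSE)
    } else {
      variants <- as.data.frame(variants, stringsAsFactors = FALSE)
      nv <- nrow(variants)
      within <- stats::ave(seq_len(nv), variants$chrom,
                           FUN = seq_along) - 1L
      block <- paste(variants$chrom, within %/% lb$block_size)
    }
    nv <- nrow(variants)
    maf_block <- stats::runif(length(unique(block)),
                              config$maf_range[1], config$maf_range[2])
    names(maf_block) <- unique(block)
    n_ind <- lb$n_individuals
    s <- sqrt(lb$r)
    dos <- matrix(0, nv, n_ind)
    for (b in unique(block)) {
      idx <- which(block == b)
      for (hap in 1:2) {
        shared <- stats::rbinom(n_ind, 1, maf_block[[b]])
        for (i in idx) {
          copy <- stats::runif(n_ind) < s
          own <- stats::rbinom(n_ind, 1, maf_block[[b]])
          dos[i, ] <- dos[i, ] + ifelse(copy, shared, own)
        }
      }
    }
    variants$coded_allele <- "A"
    reference_panel(variants[, c("variant_id", "chrom", "pos",
                                 "coded_allele")], dos)
  })
}
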