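test_that("LD r2 is the squared dosage correlation, symmetric", {
  dos <- rbind(c(0, 1, 2, 0, 1, 2),
               c(2, 1, 0, 2, 1, 0),
               c(0, 1, 2, 0, 1, 2),
               c(0, 0, 0, 0, 0, 0))
  panel <- make_panel(dos)
  expect_equal(compute_ld_r2(panel, "rs0001", "rs0003"), 1.0)
  # perfect negative correlation still squares to 1
  expect_equal(compute_ld_r2(panel, "rs0001", "rs0002"), 1.0)
  expect_equal(compute_ld_r2(panel, "rs0001", "rs0002"),
               compute_ld_r2(panel, "rs0002", "rs0001"))
  expect_error(compute_ld_r2(panel, "rs0001", "rs0004"), "monomorphic")
  expect_error(compute_ld_r2(panel, "rs0001", "nope"), "not in")
})

test_that("independent dosage vectors have near-zero r2", {
  set.seed(42)
  dos <- matrix(rbinom(2 * 1000, 2, 0.3), nrow = 2)
  panel <- make_panel(dos)
  expect_lt(compute_ld_r2(panel, "rs0001", "rs0002"), 0.05)
})

test_that("clump removes in-window correlated variants, keeps the rest", {
  rec <- make_records(3, pval = c(1e-8, 1e-6, 1e-6))
  rec$chrom <- c("1", "1", "2")
  rec$pos <- c(1e6, 1e6 + 1e5, 1e6)     # #2 within 100 kb of #1
  set.seed(1)
  base <- rbinom(500, 2, 0.3)
  dos <- rbind(base, base, rbinom(500, 2, 0.3))  # r2(#1,#2) = 1
  rownames(dos) <- rec$variant_id
  panel <- make_panel(dos, chrom = rec$chrom, pos = rec$pos)
  ds <- summary_dataset(rec, "t", "exposure")
  kept <- clump(ds, panel)
  expect_setequal(as.character(kept), c("rs0001", "rs0003"))
})

test_that("r2 below threshold keeps everything regardless of distance", {
  rec <- make_records(3, pval = c(1e-8, 1e-7, 1e-6))
  rec$chrom <- "1"; rec$pos <- c(1e6, 1.01e6, 1.02e6)
  set.seed(2)
  dos <- matrix(rbinom(3 * 2000, 2, 0.4), nrow = 3)
  rownames(dos) <- rec$variant_id
  panel <- make_panel(dos, chrom = rec$chrom, pos = rec$pos)
  ds <- summary_dataset(rec, "t", "exposure")
  expect_setequal(as.character(clump(ds, panel, r2_max = 0.5)),
                  rec$variant_id)
})

# independent re-simulation of the greedy rule over explicit r2 lookups
clump_oracle <- function(rec, r2_fun, r2_max, window_kb) {
  cand <- rec[order(rec$pval, as.numeric(rec$chrom), rec$pos,
                    rec$variant_id), ]
  kept <- character(0)
  while (nrow(cand)) {
    idx <- cand[1, ]
    kept <- c(kept, idx$variant_id)
    cand <- cand[-1, , drop = FALSE]
    if (!nrow(cand)) break
    rm <- cand$chrom == idx$chrom &
      abs(cand$pos - idx$pos) <= window_kb * 1000 &
      vapply(cand$variant_id, function(b)
        r2_fun(idx$variant_id, b), numeric(1)) >= r2_max
    cand <- cand[!rm, , drop = FALSE]
  }
  sort(kept)
}

test_that("clump matches a brute-force greedy oracle on random configurations", {
  for (seed in 1:5) {
    set.seed(seed)
    k <- 10
    rec <- make_records(k, pval = runif(k, 1e-9, 1e-5))
    rec$chrom <- as.character(sample(1:2, k, replace = TRUE))
    rec$pos <- sample(seq(1e6, 2.5e6, by = 1e4), k)
    # correlated pairs arise from shared base vectors
    base <- matrix(rbinom(3 * 400, 2, 0.3), nrow = 3)
    mix <- sample(1:3, k, replace = TRUE)
    noise <- matrix(rbinom(k * 400, 2, 0.3), nrow = k)
    lam <- runif(k)
    dos <- round(lam * base[mix, ] + (1 - lam) * noise)
    rownames(dos) <- rec$variant_id
    panel <- make_panel(dos, chrom = rec$chrom, pos = rec$pos)
    ds <- summary_dataset(rec, "t", "exposure")
    kept <- sort(as.character(clump(ds, panel, r2_max = 0.1)))
    oracle <- clump_oracle(rec, function(a, b) compute_ld_r2(panel, a, b),
                           r2_max = 0.1, window_kb = 500)
    expect_identical(kept, oracle)
    # invariance to input record order
    perm <- summary_dataset(rec[sample(k), ], "t", "exposure")
    expect_identical(sort(as.character(clump(perm, panel, r2_max = 0.1))),
                     oracle)
  }
})

test_that("variants absent from panel or lacking position pass through with a log", {
  rec <- make_records(3, pval = c(1e-8, 1e-7, 1e-6))
  rec$pos[3] <- NA
  dos <- matrix(rbinom(1 * 100, 2, 0.3), nrow = 1)
  rownames(dos) <- rec$variant_id[1]
  panel <- make_panel(dos, chrom = rec$chrom[1], pos = rec$pos[1])
  ds <- summary_dataset(rec, "t", "exposure")
  expect_warning(kept <- clump(ds, panel), "unclumped")
  expect_setequal(as.character(kept), rec$variant_id)
  log <- attr(kept, "clump_log")
  expect_setequal(log$variant_id, c("rs0002", "rs0003"))
})

test_that("instrument strength follows the 2 MAF (1-MAF) beta^2 formula", {
  v <- data.frame(variant_id = "rs1", eaf = 0.5, beta = 0.1, se = 0.01)
  s <- instrument_strength(v, n_exposure = 18340)
  expect_equal(s$total_r2, 0.005)
  expect_equal(s$f_stat, 0.005 * 18338 / (1 * 0.995))
  expect_equal(s$f_stat, 92.1507537688, tolerance = 1e-10)
  # MAF symmetry: eaf and 1 - eaf give identical strength
  v9 <- data.frame(variant_id = "rs1", eaf = 0.9, beta = 0.2, se = 0.01)
  v1 <- data.frame(variant_id = "rs1", eaf = 0.1, beta = 0.2, se = 0.01)
  expect_equal(instrument_strength(v9, 1000)$total_r2,
               instrument_strength(v1, 1000)$total_r2)
  # zero effects give zero strength
  z <- make_records(3, beta = 0)
  expect_equal(instrument_strength(z, 1000)$f_stat, 0)
  # degenerate strength rejected
  big <- make_records(2, beta = 2, eaf = 0.5)
  expect_error(instrument_strength(big, 1000), "degenerate")
})

test_that("F is monotone in total R2 and crosses 10 at the algebraic point", {
  n <- 18340; k <- 10
  f_of <- function(r2) r2 * (n - k - 1) / (k * (1 - r2))
  r2s <- seq(0.001, 0.05, by = 0.001)
  expect_true(all(diff(vapply(r2s, f_of, numeric(1))) > 0))
  r2_crit <- 10 * k / (n - k - 1 + 10 * k)
  expect_gt(f_of(r2_crit * 1.0001), 10)
  expect_lt(f_of(r2_crit * 0.9999), 10)
})

test_that("select_instruments composes screen, clump and strength filter", {
  cfg <- sim_config(n_taxa = 1, variants_per_taxon = 60,
                    j_instruments = 12, sigma_gamma = 0.15,
                    palindrome_frac = 0, seed = 8)
  sim <- simulate_mr_dataset(cfg)
  ds <- sim$exposures[[1]]
  dos <- matrix(rbinom(60 * 200, 2, 0.3), nrow = 60)
  rownames(dos) <- ds$records$variant_id
  panel <- make_panel(dos, chrom = ds$records$chrom, pos = ds$records$pos)
  iv <- select_instruments(ds, panel)
  expect_s3_class(iv, "instrument_set")
  expect_equal(iv$k, nrow(iv$variants))
  expect_true(all(iv$variants$pval < 1e-5))
  expect_equal(iv$total_r2, sum(iv$per_variant_r2))
  expect_false(iv$empty)
  expect_gt(iv$f_stat, 10)
  expect_equal(iv$selection_log$n_input, 60)
})

test_that("weak and empty instrument sets are flagged, not errors", {
  # all-null taxon: nothing passes the 1e-5 screen with high probability
  cfg <- sim_config(n_taxa = 1, variants_per_taxon = 20,
                    j_instruments = 1, sigma_gamma = 1e-6, seed = 4)
  sim <- simulate_mr_dataset(cfg)
  ds <- sim$exposures[[1]]
  dos <- matrix(rbinom(20 * 100, 2, 0.3), nrow = 20)
  rownames(dos) <- ds$records$variant_id
  panel <- make_panel(dos, chrom = ds$records$chrom, pos = ds$records$pos)
  iv <- select_instruments(ds, panel)
  expect_true(iv$empty)
  expect_true(iv$weak)
  expect_equal(iv$k, 0L)

  # tiny effects that pass a loose screen but give F below the bar
  rec <- make_records(4, beta = 0.01, se = 0.004, eaf = 0.3, pval = 0.009,
                      n = 2000)
  ds2 <- summary_dataset(rec, "t", "exposure")
  dos2 <- matrix(rbinom(4 * 100, 2, 0.3), nrow = 4)
  rownames(dos2) <- rec$variant_id
  panel2 <- make_panel(dos2, chrom = rec$chrom, pos = rec$pos)
  iv2 <- select_instruments(ds2, panel2, p_threshold = 0.01)
  expect_true(iv2$weak)
  expect_lte(iv2$f_stat, 10)
})
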