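# shared fixture builders; everything is generated in code

# minimal exposure records: k variants on distinct chromosomes
make_records <- function(k = 3, beta = 0.1, se = 0.01, eaf = 0.3,
                         pval = 1e-8, n = 18340) {
  data.frame(
    variant_id = sprintf("rs%04d", seq_len(k)),
    chrom = as.character(rep_len(1:22, k)),
    pos = 1e6 + seq_len(k) * 1e4,
    effect_allele = rep_len(c("A", "C", "G"), k),
    other_allele = rep_len(c("G", "T", "A"), k),
    eaf = rep_len(eaf, k), beta = rep_len(beta, k),
    se = rep_len(se, k), pval = rep_len(pval, k), n = n,
    stringsAsFactors = FALSE)
}

# write a records data.frame to a temporary TSV with default headers
write_tsv_fixture <- function(records, path = tempfile(fileext = ".tsv")) {
  out <- records
  names(out) <- c("SNP", "CHR", "POS", "EA", "OA", "EAF", "BETA",
                  "SE", "P", "N")[seq_along(out)]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  path
}

# harmonized set with exact effect pairs (no sampling noise)
make_h <- function(beta_x, beta_y, se_x = 0.01, se_y = 0.01) {
  J <- length(beta_x)
  harmonized_set(data.frame(
    variant_id = sprintf("v%03d", seq_len(J)),
    beta_x = beta_x, se_x = rep_len(se_x, J),
    beta_y = beta_y, se_y = rep_len(se_y, J),
    stringsAsFactors = FALSE))
}

# small panel with explicit dosage rows
make_panel <- function(dosages, chrom = NULL, pos = NULL) {
  nv <- nrow(dosages)
  if (is.null(chrom)) chrom <- rep("1", nv)
  if (is.null(pos)) pos <- 1e6 + seq_len(nv) * 1e4
  ids <- if (is.null(rownames(dosages)))
    sprintf("rs%04d", seq_len(nv)) else rownames(dosages)
  reference_panel(
    data.frame(variant_id = ids, chrom = chrom, pos = pos,
               coded_allele = "A", stringsAsFactors = FALSE),
    dosages)
}

# brute-force BH step-up oracle (independent of stats::p.adjust)
bh_oracle <- function(p, m = length(p)) {
  k <- length(p)
  o <- order(p)
  adj_sorted <- p[o] * m / seq_len(k)
  adj_sorted <- rev(cummin(rev(adj_sorted)))
  out <- numeric(k)
  out[o] <- pmin(1, adj_sorted)
  out
}
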