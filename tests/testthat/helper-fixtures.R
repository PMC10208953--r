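# shared fixtures built in code

# three-variant hand fixture used for scoring oracles
hand_sumstats <- function() {
  structure(data.frame(
    SNP = c("rs1", "rs2", "rs3"),
    A1 = c("A", "C", "G"), A2 = c("G", "T", "A"),
    BETA = c(0.5, -0.2, 0.1), SE = c(0.05, 0.05, 0.05),
    P = c(1e-9, 0.01, 0.5), FRQ = c(0.3, 0.4, 0.2),
    stringsAsFactors = FALSE
  ), class = c("summary_stats", "data.frame"))
}

write_sumstats_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# small cohort for regression tests; perfect scores by default
quick_cohort <- function(n = 2000, snps = 150, c = 0.15, m = 0.05, f = 0,
                         seed = 1, ...) {
  simulate_trio_cohort(sim_config(n_trios = n, n_snps = snps,
                                  c = c, m = m, f = f, seed = seed, ...))
}

# synthetic trio score set with exact trio correlation structure, no genotypes
synthetic_scores <- function(n, seed = 1) {
  set.seed(seed)
  gm <- rnorm(n); gf <- rnorm(n)
  gc <- (gm + gf) / 2 + rnorm(n, 0, sqrt(0.5))
  list(child = gc, mother = gm, father = gf)
}

# brute-force BH step-up: largest k with p_(k) <= k q / m, reject the k smallest
bh_oracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ok <- which(p[o] <= seq_len(m) * q / m)
  flags <- logical(m)
  if (length(ok)) flags[o[seq_len(max(ok))]] <- TRUE
  flags
}

# an 18-item response row
item_row <- function(values) {
  as.data.frame(setNames(as.list(values), sprintf("item%02d", 1:18)))
}
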