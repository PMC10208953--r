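test_that("summary statistics are parsed and validated", {
  path <- write_sumstats_tsv(hand_sumstats())
  ss <- read_sumstats(path)
  expect_equal(nrow(ss), 3)
  expect_equal(ss$SNP, c("rs1", "rs2", "rs3"))  # order preserved
  expect_equal(ss$BETA, c(0.5, -0.2, 0.1))

  bad <- hand_sumstats(); bad$P[2] <- 1.2
  expect_error(read_sumstats(write_sumstats_tsv(bad)), "rs2.*1.2",
               class = "data_error")

  dup <- rbind(hand_sumstats(), hand_sumstats()[1, ])
  expect_error(read_sumstats(write_sumstats_tsv(dup)), "duplicate",
               class = "data_error")

  # strand-ambiguous flagging and dropping
  amb <- hand_sumstats(); amb$A2[1] <- "T"   # A/T pair
  p2 <- write_sumstats_tsv(amb)
  expect_equal(read_sumstats(p2)$ambiguous, c(TRUE, FALSE, FALSE))
  expect_message(ss_d <- read_sumstats(p2, drop_ambiguous = TRUE), "ambiguous")
  expect_equal(nrow(ss_d), 2)

  # rows with missing beta are dropped with a message
  na_ss <- hand_sumstats(); na_ss$BETA[3] <- NA
  expect_message(ss_na <- read_sumstats(write_sumstats_tsv(na_ss)), "dropped")
  expect_equal(nrow(ss_na), 2)
})

test_that("threshold scores equal hand-computed weighted allele sums", {
  ss <- hand_sumstats()
  # one variant, beta 0.5, dosages 0/1/2
  g1 <- matrix(c(0, 1, 2), 3, 1, dimnames = list(NULL, "rs1_A"))
  s1 <- compute_threshold_scores(g1, ss, thresholds = 1)
  expect_equal(unname(s1$raw_scores[, 1]), c(0, 0.5, 1.0))

  # three variants, p = (1e-9, 0.01, 0.5): threshold 0.05 uses the first two
  G <- matrix(c(2, 1, 0, 1, 2, 0), 2, 3,
              dimnames = list(NULL, c("rs1_A", "rs2_C", "rs3_G")))
  s <- compute_threshold_scores(G, ss, thresholds = c(0.05, 1))
  expect_equal(unname(s$raw_scores[, 1]),
               c(0.5 * 2 - 0.2 * 0, 0.5 * 1 - 0.2 * 1))
  # threshold 1 is the full dot product
  expect_equal(unname(s$raw_scores[, 2]), as.numeric(G %*% c(0.5, -0.2, 0.1)))
  expect_equal(s$n_variants, c(2L, 3L))
})

test_that("allele alignment flips other-allele counted dosages", {
  ss <- hand_sumstats()
  # genotype file counts the OTHER allele for rs1 (G instead of A):
  # effect-allele dosage is 2 - g, so scores are beta * (2 - g)
  g_flip <- matrix(c(0, 1, 2), 3, 1, dimnames = list(NULL, "rs1_G"))
  s <- compute_threshold_scores(g_flip, ss, thresholds = 1)
  expect_equal(unname(s$raw_scores[, 1]), 0.5 * (2 - c(0, 1, 2)))

  # involution: flipping the counted allele and the stored dosages together
  # reproduces the original scores exactly
  g <- matrix(c(0, 2, 1, 1, 0, 2), 3, 2,
              dimnames = list(NULL, c("rs1_A", "rs2_C")))
  base <- compute_threshold_scores(g, ss, thresholds = 1)$raw_scores
  g2 <- 2 - g
  colnames(g2) <- c("rs1_G", "rs2_T")
  flipped <- compute_threshold_scores(g2, ss, thresholds = 1)$raw_scores
  expect_equal(unname(base), unname(flipped))

  # a variant matching neither allele is dropped with a message
  g3 <- matrix(c(1, 1, 0, 2), 2, 2, dimnames = list(NULL, c("rs1_C", "rs2_C")))
  expect_message(s3 <- compute_threshold_scores(g3, ss, thresholds = 1),
                 "neither")
  expect_equal(s3$n_variants, 1L)
  expect_error(compute_threshold_scores(
    matrix(1, 2, 1, dimnames = list(NULL, "rs99_A")), ss, thresholds = 1),
    class = "data_error")
})

test_that("scoring is linear in the weight vector", {
  set.seed(31)
  ss1 <- hand_sumstats()
  ss2 <- hand_sumstats(); ss2$BETA <- c(0.1, 0.3, -0.4)
  ss_sum <- hand_sumstats(); ss_sum$BETA <- ss1$BETA + ss2$BETA
  G <- matrix(sample(0:2, 30, TRUE), 10, 3,
              dimnames = list(NULL, c("rs1_A", "rs2_C", "rs3_G")))
  sc <- function(ss) compute_threshold_scores(G, ss, thresholds = 1)$raw_scores
  expect_equal(sc(ss_sum), sc(ss1) + sc(ss2))
})

test_that("PRS-PC matches the closed-form two-column eigendecomposition", {
  set.seed(32)
  n <- 200
  x <- rnorm(n); y <- 0.6 * x + 0.8 * rnorm(n)
  M <- cbind(t1 = x, t2 = y)
  r <- cor(x, y)
  out <- prs_pc(M)
  # equal-diagonal 2x2 correlation matrix has eigenvector (1,1)/sqrt(2)
  expect_equal(abs(unname(out$loadings)), rep(1 / sqrt(2), 2), tolerance = 1e-10)
  # first-PC variance is 1 + r
  Z <- scale(M)
  pc1_var <- var(Z %*% (sign(out$loadings) / sqrt(2)))[1]
  expect_equal(pc1_var, 1 + r, tolerance = 1e-10)
  expect_equal(out$var_explained, (1 + r) / 2, tolerance = 1e-10)
  expect_equal(mean(out$prspc), 0, tolerance = 1e-12)
  expect_equal(sd(out$prspc), 1, tolerance = 1e-12)
})

test_that("PRS-PC handles rank-1, sign and affine-rescaling cases", {
  set.seed(33)
  x <- rnorm(100)
  M <- cbind(a = x, b = x, c = x)
  out <- prs_pc(M)
  expect_equal(cor(out$prspc, x), 1, tolerance = 1e-10)

  # invariance to affine rescaling of any raw column
  M2 <- cbind(a = 3 * x + 7, b = x, c = x)
  expect_equal(prs_pc(M2)$prspc, out$prspc, tolerance = 1e-10)

  # negating every weight flips the composite up to the sign convention
  Mn <- cbind(a = -x, b = -x, c = -x)
  expect_equal(abs(cor(prs_pc(Mn)$prspc, out$prspc)), 1, tolerance = 1e-10)

  expect_error(prs_pc(matrix(1, 10, 3)), class = "degenerate_input")
  expect_message(prs_pc(cbind(x, rnorm(100), rep(2, 100))), "constant")
})

test_that("ancestry PCs match a dense SVD oracle and separate demes", {
  set.seed(34)
  toy <- matrix(sample(0:2, 50, TRUE), 5, 10)
  toy[, 1] <- 1L  # zero-variance column must be excluded
  pcs <- compute_ancestry_pcs(toy, k = 2)
  Z <- scale(toy[, apply(toy, 2, sd) > 0])
  sv <- svd(Z)
  for (j in 1:2)
    expect_equal(abs(cor(pcs[, j], sv$u[, j])), 1, tolerance = 1e-8)
  expect_equal(crossprod(pcs), diag(2), tolerance = 1e-10, ignore_attr = TRUE)

  expect_error(compute_ancestry_pcs(toy, k = 5), "k must be")

  # strong two-deme divergence: PC1 separates the demes
  p <- make_variant_panel(300, seed = 35)
  cfg <- sim_config(n_trios = 600, n_snps = 300, n_demes = 2,
                    deme_fst_like = 0.3, seed = 35)
  par <- simulate_parents(p, cfg)
  pc1 <- compute_ancestry_pcs(par$mother, k = 2)[, 1]
  expect_gt(abs(cor(pc1, par$deme)), 0.9)
})

test_that("residualization removes covariates, standardizes, and is idempotent", {
  set.seed(36)
  n <- 300
  score <- rnorm(n)
  # covariate orthogonal to the score: output is just the z-scored input
  v <- rnorm(n)
  v_orth <- residuals(lm(v ~ score))
  out <- residualize_standardize(score, data.frame(v = v_orth))
  expect_equal(out, (score - mean(score)) / sd(score), tolerance = 1e-10)

  # general case: residuals uncorrelated with every covariate column
  cov <- data.frame(pc1 = rnorm(n), pc2 = rnorm(n),
                    batch = sample(c("b1", "b2", "b3"), n, TRUE))
  r <- residualize_standardize(score + 0.5 * cov$pc1, cov)
  expect_equal(mean(r), 0, tolerance = 1e-12)
  expect_equal(sd(r), 1, tolerance = 1e-12)
  expect_lt(abs(cor(r, cov$pc1)), 1e-10)
  expect_lt(abs(cor(r, cov$pc2)), 1e-10)

  # idempotence
  r2 <- residualize_standardize(r, cov)
  expect_equal(r2, r, tolerance = 1e-12)

  # perfectly explained score degenerates
  expect_error(residualize_standardize(cov$pc1, cov), class = "degenerate_input")

  # singleton batch level merged with warning
  cov$batch[1] <- "lonely"
  expect_warning(residualize_standardize(score, cov), "singleton")
})
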