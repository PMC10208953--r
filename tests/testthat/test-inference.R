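test_that("noiseless linear outcome is recovered to machine precision", {
  sc <- synthetic_scores(500, seed = 61)
  sc <- lapply(sc, function(x) (x - mean(x)) / sd(x))
  y <- 0.3 * sc$mother
  fr <- trio_frame(y, list(f1 = sc), sex = rbinom(500, 1, 0.5),
                   birth_year = sample(2000:2007, 500, TRUE),
                   standardize_outcome = FALSE)
  # noiseless fits trip lm's perfect-fit warning; the exactness is the point
  fit <- suppressWarnings(fit_unadjusted(fr, "f1", "mother"))
  expect_equal(fit$beta, 0.3, tolerance = 1e-12)

  # Fig.2-style scale contract: rescaling the outcome rescales every beta
  fr2 <- trio_frame(2 * y + 0.17, list(f1 = sc), fr$sex, fr$birth_year,
                    standardize_outcome = FALSE)
  expect_equal(suppressWarnings(fit_unadjusted(fr2, "f1", "mother"))$beta,
               0.6, tolerance = 1e-12)
  t1 <- suppressWarnings(fit_trio(fr, "f1"))
  t2 <- suppressWarnings(fit_trio(fr2, "f1"))
  expect_equal(t2$beta, 2 * t1$beta, tolerance = 1e-10)
})

test_that("trio model recovers the generative paths with perfect scores", {
  co <- quick_cohort(n = 20000, snps = 150, c = 0.15, m = 0.05, f = 0, seed = 62)
  fr <- trio_frame_from_cohort(co)
  ft <- fit_trio(fr, "factor1")
  truth <- c(child = 0.15, mother = 0.05, father = 0)
  for (k in 1:3) expect_lt(abs(ft$beta[k] - truth[k]), 3 * ft$se[k])
  # unadjusted maternal slope is m + c/2
  un <- fit_unadjusted(fr, "factor1", "mother")
  expect_lt(abs(un$beta - 0.125), 3 * un$se)
  # CI and p internally consistent
  expect_equal(ft$ci_low, ft$beta - 1.96 * ft$se)
  expect_equal(ft$p, 2 * pnorm(-abs(ft$beta / ft$se)))
})

test_that("nurture stays null with imperfect scores under random mating", {
  co <- quick_cohort(n = 8000, snps = 200, c = 0.3, m = 0, f = 0,
                     gwas_n = 400, seed = 63)
  ss <- make_noisy_sumstats(co$panel, 400, seed = 64)
  sc <- lapply(co$dosage, function(d)
    as.numeric(compute_threshold_scores(d, ss, thresholds = 1)$raw_scores[, 1]))
  fr <- trio_frame(co$phenotype,
                   list(f1 = list(child = sc$child, mother = sc$mother,
                                  father = sc$father)),
                   co$sex, co$birth_year)
  ft <- fit_trio(fr, "f1")
  expect_lt(abs(ft$beta[ft$role == "mother"]), 3 * ft$se[ft$role == "mother"])
  expect_lt(abs(ft$beta[ft$role == "father"]), 3 * ft$se[ft$role == "father"])
  # measurement error attenuates the child path below c
  expect_lt(ft$beta[ft$role == "child"], 0.3)
})

test_that("across-factor fits partial correlated factors correctly", {
  set.seed(65)
  n <- 6000
  A <- synthetic_scores(n, seed = 66)
  # factor B scores correlated ~0.5 with A at every role, B not causal
  B <- lapply(A, function(x) 0.5 * x + sqrt(0.75) * rnorm(n))
  y <- 0.2 * A$child + 0.05 * A$mother + rnorm(n, 0, 0.95)
  fr <- trio_frame(y, list(fa = A, fb = B), rbinom(n, 1, 0.5),
                   sample(2000:2007, n, TRUE))
  out <- fit_across_factors(fr, c("fa", "fb"))
  expect_equal(nrow(out), 6)
  for (r in c("child", "mother", "father")) {
    row_b <- out[out$factor == "fb" & out$role == r, ]
    expect_lt(abs(row_b$beta), 3 * row_b$se)
  }
  # orthogonal factors: joint estimates match single-factor trio estimates
  C <- synthetic_scores(n, seed = 67)
  frC <- trio_frame(y, list(fa = A, fc = C), fr$sex, fr$birth_year)
  joint <- fit_across_factors(frC, c("fa", "fc"))
  single <- fit_trio(frC, "fa")
  for (r in c("child", "mother", "father")) {
    jb <- joint[joint$factor == "fa" & joint$role == r, ]
    sb <- single[single$role == r, ]
    expect_lt(abs(jb$beta - sb$beta), 3 * sb$se)
  }
  # duplicated factor is rank-deficient
  frD <- fr
  for (r in c("child", "mother", "father"))
    frD[[paste0("fb_", r)]] <- frD[[paste0("fa_", r)]]
  # identical factors also trip the high-correlation warning before erroring
  suppressWarnings(
    expect_error(fit_across_factors(frD, c("fa", "fb")), class = "degenerate_input"))
})

test_that("constant or short inputs are rejected by the fitters", {
  sc <- synthetic_scores(50, seed = 68)
  fr <- trio_frame(rnorm(50), list(f1 = sc), rbinom(50, 1, 0.5),
                   sample(2000:2007, 50, TRUE))
  fr$f1_child <- 0
  expect_error(fit_trio(fr, "f1"), class = "degenerate_input")
  expect_error(fit_unadjusted(fr[1:4, ], "f1", "mother"), class = "invalid_input")
})

test_that("delta-beta is c/2 under random mating and bootstrap matches analytic", {
  co <- quick_cohort(n = 10000, snps = 150, c = 0.3, m = 0, f = 0, seed = 69)
  fr <- trio_frame_from_cohort(co)
  db <- delta_beta(fr, "factor1", "mother", B = 400, seed = 70)
  expect_equal(db$delta, db$beta_unadjusted - db$beta_adjusted)
  expect_lt(abs(db$delta - 0.15), 3 * db$se_delta)
  expect_lt(db$p_delta, 0.001)
  expect_true(db$ci_low < db$delta & db$delta < db$ci_high)

  da <- delta_beta(fr, "factor1", "mother", method = "analytic")
  # cross-method concordance: -log10 p within a factor of 2
  lp_b <- -log10(db$p_delta); lp_a <- -log10(da$p_delta)
  expect_lt(max(lp_b / lp_a, lp_a / lp_b), 2)
  expect_equal(da$delta, db$delta)

  expect_error(delta_beta(fr, "factor1", "mother", B = 50), "B must be")
})

test_that("delta-beta is null-calibrated when there is nothing to attenuate", {
  co <- quick_cohort(n = 4000, snps = 100, c = 0, m = 0.1, f = 0, seed = 71)
  fr <- trio_frame_from_cohort(co)
  db <- delta_beta(fr, "factor1", "mother", B = 400, seed = 72)
  expect_lt(abs(db$delta), 3 * db$se_delta)
  expect_gt(db$p_delta, 0.001)
})

test_that("BH flags match the brute-force step-up oracle", {
  expect_equal(bh_fdr(rep(1, 10)), rep(FALSE, 10))
  p <- c(0.001, 0.01, 0.02, 0.9)
  expect_equal(bh_fdr(p, 0.05), bh_oracle(p, 0.05))

  set.seed(73)
  for (i in 1:100) {
    m <- sample(c(1, 2, 5, 36, 100), 1)
    p <- runif(m)^sample(1:3, 1)          # skewed families too
    q <- runif(1, 0.01, 0.2)
    flags <- bh_fdr(p, q)
    expect_equal(flags, bh_oracle(p, q))
    # monotone in p
    if (any(flags)) expect_true(all(p[flags] <= max(p[flags])))
    if (any(flags) && any(!flags)) expect_lt(max(p[flags]), min(p[!flags]) + 1e-12)
  }
  expect_error(bh_fdr(numeric(0)), class = "invalid_input")
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
})

test_that("mechanism labels follow the evidence pattern", {
  mk <- function(role = "mother") data.frame(factor = "f1", role = role)
  d_sig <- data.frame(factor = "f1", role = "mother", p_delta = 1e-6)
  d_ns <- data.frame(factor = "f1", role = "mother", p_delta = 0.4)
  expect_equal(classify_mechanism(mk(), mk(), d_sig, TRUE, FALSE),
               "genetic transmission")
  expect_equal(classify_mechanism(mk(), mk(), d_ns, TRUE, TRUE),
               "genetic nurture")
  expect_equal(classify_mechanism(mk(), mk(), d_sig, TRUE, TRUE), "both")
  expect_equal(classify_mechanism(mk(), mk(), d_ns, TRUE, FALSE),
               "inconclusive - possible power limitation")
  expect_equal(classify_mechanism(mk(), mk(), d_ns, FALSE, FALSE),
               "no association")
  expect_error(classify_mechanism(mk("father"), mk("mother"), d_sig, TRUE, TRUE),
               class = "invalid_input")
})

test_that("classification recovers the generative mechanism in powered designs", {
  run_design <- function(c, m, seed) {
    co <- quick_cohort(n = 6000, snps = 120, c = c, m = m, f = 0, seed = seed)
    fr <- trio_frame_from_cohort(co)
    un <- fit_unadjusted(fr, "factor1", "mother")
    tr <- fit_trio(fr, "factor1")
    trm <- tr[tr$role == "mother", ]
    db <- delta_beta(fr, "factor1", "mother", method = "analytic")
    fam_un <- bh_fdr(c(un$p, 0.5, 0.5), 0.05)[1]
    fam_tr <- bh_fdr(c(trm$p, 0.5, 0.5), 0.05)[1]
    classify_mechanism(un, trm, db, fam_un, fam_tr)
  }
  expect_equal(run_design(c = 0.25, m = 0, seed = 74), "genetic transmission")
  expect_equal(run_design(c = 0, m = 0.15, seed = 75), "genetic nurture")
})

test_that("exchanging maternal and paternal generative roles swaps the estimates", {
  co_m <- quick_cohort(n = 10000, snps = 120, c = 0.1, m = 0.12, f = 0, seed = 76)
  co_f <- quick_cohort(n = 10000, snps = 120, c = 0.1, m = 0, f = 0.12, seed = 76)
  ft_m <- fit_trio(trio_frame_from_cohort(co_m), "factor1")
  ft_f <- fit_trio(trio_frame_from_cohort(co_f), "factor1")
  expect_lt(abs(ft_m$beta[ft_m$role == "mother"] - ft_f$beta[ft_f$role == "father"]),
            3 * ft_m$se[ft_m$role == "mother"])
  expect_lt(abs(ft_m$beta[ft_m$role == "father"] - ft_f$beta[ft_f$role == "mother"]),
            3 * ft_m$se[ft_m$role == "father"])
})
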