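#' Generative configuration for a synthetic trio cohort
#'
#' Holds the parameters of the trio generative model: the direct genetic
#' path `c` (child score -> child trait), the maternal and paternal nurture
#' paths `m` and `f` (parental score -> child trait conditional on the child
#' score), the intended spousal score correlation `a_target`, optional
#' two-deme population stratification, the effective GWAS sample size that
#' controls weight noise, covariate effects, and outcome missingness.
#'
#' `noise_sd = "auto"` picks the residual SD so the population variance of
#' the phenotype is 1 given the configured paths; post-hoc standardization
#' is then a population no-op and path coefficients are read directly in
#' outcome-SD units.
#'
#' @param n_trios number of mother-father-child trios.
#' @param n_snps number of unlinked biallelic variants.
#' @param maf_range effect-allele frequency interval, within (0, 0.5].
#' @param n_causal number of causal variants (defaults to all).
#' @param c,m,f direct, maternal-nurture and paternal-nurture path
#'   coefficients, per SD of the respective true score.
#' @param a_target intended spousal correlation of true scores, in [0, 0.9].
#' @param mate_on pairing basis: "random", "score" (rank pairing on jittered
#'   true scores) or "phenotype" (rank pairing on a noisy parental trait
#'   proxy with 50% score variance).
#' @param n_demes 1 or 2 population demes.
#' @param deme_fst_like Balding-Nichols-style allele-frequency divergence
#'   scalar for the two-deme case.
#' @param deme_pheno_shift additive phenotype mean offset of deme 2.
#' @param gwas_n effective GWAS sample size for noisy summary statistics.
#' @param noise_sd residual SD of the phenotype, or "auto" (see above).
#' @param sex_effect,birthyear_effect covariate coefficients (sex coded 0/1,
#'   birth year as integer offset from the cohort mean).
#' @param missing_rate marginal phenotype missingness fraction in [0, 0.95].
#' @param n_aux number of auxiliary variables correlated with the phenotype.
#' @param aux_cor correlation of each auxiliary with the phenotype, in (-1, 1).
#' @param mar_strength logistic slope of missingness on the auxiliary mean;
#'   0 gives MCAR.
#' @param seed global seed; fixes the entire cohort bit-for-bit.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_trios = 2000, n_snps = 500,
                       maf_range = c(0.05, 0.5), n_causal = n_snps,
                       c = 0.15, m = 0.05, f = 0,
                       a_target = 0, mate_on = c("random", "score", "phenotype"),
                       n_demes = 1, deme_fst_like = 0, deme_pheno_shift = 0,
                       gwas_n = Inf, noise_sd = "auto",
                       sex_effect = 0, birthyear_effect = 0,
                       missing_rate = 0, n_aux = 5, aux_cor = 0.5,
                       mar_strength = 1, seed = 1) {
  mate_on <- match.arg(mate_on)
  assert_that(n_trios >= 1, "n_trios must be >= 1")
  assert_that(all(is.finite(c(c, m, f))), "paths c, m, f must be finite")
  assert_that(a_target >= 0 && a_target <= 0.9, "a_target must be in [0, 0.9]")
  assert_that(missing_rate >= 0 && missing_rate < 0.95,
              "missing_rate must be in [0, 0.95)")
  assert_that(n_demes %in% c(1L, 2L), "n_demes must be 1 or 2")
  assert_that(gwas_n >= 1, "gwas_n must be >= 1")
  assert_that(identical(noise_sd, "auto") || (is.numeric(noise_sd) && noise_sd >= 0),
              "noise_sd must be non-negative (or \"auto\")")
  assert_that(aux_cor > -1 && aux_cor < 1, "aux_cor must be in (-1, 1)")
  if (mate_on == "random" && a_target > 0)
    tn_stop("a_target > 0 requires mate_on = \"score\" or \"phenotype\"",
            "invalid_argument")
  if (mate_on == "phenotype" && 2 * a_target > 0.95)
    tn_stop("a_target too large for phenotype-based mating (score-phenotype correlation caps it)",
            "invalid_argument")
  structure(list(
    n_trios = as.integer(n_trios), n_snps = as.integer(n_snps),
    maf_range = maf_range, n_causal = as.integer(n_causal),
    c = c, m = m, f = f, a_target = a_target, mate_on = mate_on,
    n_demes = as.integer(n_demes), deme_fst_like = deme_fst_like,
    deme_pheno_shift = deme_pheno_shift, gwas_n = gwas_n,
    noise_sd = noise_sd, sex_effect = sex_effect,
    birthyear_effect = birthyear_effect, missing_rate = missing_rate,
    n_aux = as.integer(n_aux), aux_cor = aux_cor,
    mar_strength = mar_strength, seed = as.integer(seed)
  ), class = "sim_config")
}

# rank-pair two standard-ish score vectors with Gaussian jitter so the
# realized correlation approaches `target`: pairing the order statistics of
# independently jittered copies gives corr = 1/(1 + lambda^2/var(s)),
# hence lambda = sd(s) * sqrt(1/target - 1).
pair_by_rank <- function(score_m, score_f, target) {
  if (target <= 0) return(sample.int(length(score_f)))
  lambda <- stats::sd(score_m) * sqrt(1 / target - 1)
  om <- order(score_m + rnorm(length(score_m), 0, lambda))
  of <- order(score_f + rnorm(length(score_f), 0, lambda))
  # father index to sit opposite mother i
  idx <- integer(length(score_m))
  idx[om] <- of
  idx
}

draw_dosages <- function(n, freqs) {
  m <- length(freqs)
  mat <- matrix(rbinom(n * m, 2L, rep(freqs, each = n)), nrow = n, ncol = m)
  storage.mode(mat) <- "integer"
  mat
}

#' Simulate paired parental genotypes
#'
#' Draws maternal and paternal genotype matrices in Hardy-Weinberg
#' proportions from (per-deme) allele frequencies, then pairs spouses either
#' at random or by jittered-rank assortment on true scores or on a noisy
#' phenotype proxy. With two demes, per-deme frequencies are drawn from a
#' Balding-Nichols-style beta around the panel frequency with divergence
#' `deme_fst_like`; spouses are paired within deme.
#'
#' @param panel a `variant_panel`.
#' @param config a `sim_config` with matching `n_snps`.
#' @return list with integer dosage matrices `mother`, `father`
#'   (`n_trios` x `n_snps`), standardized `true_score_mother` /
#'   `true_score_father`, the per-trio `deme` label, the per-deme allele
#'   frequencies (`deme_freqs`), and the pooled parental score location and
#'   scale (`score_center`, `score_scale`) used to place children on the
#'   same scale.
#' @export
simulate_parents <- function(panel, config) {
  assert_that(inherits(panel, "variant_panel"), "panel must be a variant_panel")
  assert_that(nrow(panel) == config$n_snps,
              "panel and config disagree on n_snps")
  set.seed(derive_seed(config$seed, 21L))
  n <- config$n_trios

  # per-deme allele frequencies
  p0 <- panel$maf
  if (config$n_demes == 2L && config$deme_fst_like > 0) {
    F <- config$deme_fst_like
    a <- p0 * (1 - F) / F
    b <- (1 - p0) * (1 - F) / F
    deme_freqs <- list(pmin(pmax(rbeta(length(p0), a, b), 0.005), 0.995),
                       pmin(pmax(rbeta(length(p0), a, b), 0.005), 0.995))
    # orient labels so deme 2 carries the higher mean latent score: a
    # positive deme_pheno_shift is then an aligned (score-increasing deme,
    # trait-increasing environment) stratification confounder with a
    # reproducible sign, the configuration under which stratification
    # inflates nurture estimates
    mu_d <- vapply(deme_freqs, function(p) sum(panel$true_beta * 2 * p), numeric(1))
    if (mu_d[1] > mu_d[2]) deme_freqs <- rev(deme_freqs)
  } else {
    deme_freqs <- rep(list(p0), config$n_demes)
  }
  deme <- rep(seq_len(config$n_demes), length.out = n)
  deme <- sort(deme)

  gm <- matrix(0L, n, nrow(panel)); gf <- matrix(0L, n, nrow(panel))
  for (d in seq_len(config$n_demes)) {
    rows <- which(deme == d)
    gm[rows, ] <- draw_dosages(length(rows), deme_freqs[[d]])
    gf[rows, ] <- draw_dosages(length(rows), deme_freqs[[d]])
  }
  colnames(gm) <- colnames(gf) <- panel$variant_id

  raw_m <- as.numeric(gm %*% panel$true_beta)
  raw_f <- as.numeric(gf %*% panel$true_beta)

  if (config$mate_on != "random" && config$a_target > 0) {
    for (d in seq_len(config$n_demes)) {
      rows <- which(deme == d)
      if (length(rows) < 2L) next
      if (config$mate_on == "score") {
        bm <- raw_m[rows]; bf <- raw_f[rows]; target <- config$a_target
      } else {
        # phenotype proxy: score + equal-variance noise, so
        # corr(score, proxy)^2 = 1/2 and the proxy correlation must be 2a
        s <- stats::sd(raw_m[rows])
        bm <- raw_m[rows] + rnorm(length(rows), 0, s)
        bf <- raw_f[rows] + rnorm(length(rows), 0, s)
        target <- 2 * config$a_target
      }
      idx <- pair_by_rank(bm, bf, target)
      gf[rows, ] <- gf[rows[idx], , drop = FALSE]
      raw_f[rows] <- raw_f[rows[idx]]
    }
  } else if (config$mate_on != "random") {
    idx <- sample.int(n)
    gf <- gf[idx, , drop = FALSE]; raw_f <- raw_f[idx]
  }

  center <- mean(c(raw_m, raw_f))
  scale_ <- stats::sd(c(raw_m, raw_f))
  if (!is.finite(scale_) || scale_ == 0) scale_ <- 1
  list(mother = gm, father = gf,
       true_score_mother = (raw_m - center) / scale_,
       true_score_father = (raw_f - center) / scale_,
       deme = deme, deme_freqs = deme_freqs,
       score_center = center, score_scale = scale_)
}

#' Transmit one allele per parent per locus
#'
#' Mendelian segregation for unlinked biallelic loci: a homozygote parent
#' contributes its allele deterministically (dosage 0 -> 0 copies,
#' 2 -> 1 copy); a heterozygote contributes the effect allele with
#' probability 1/2, independently across trios and loci. The child dosage is
#' the sum of the two contributions.
#'
#' @param mother,father integer dosage matrices of equal shape, entries in
#'   \{0, 1, 2\}.
#' @param seed integer seed for the segregation draws.
#' @return integer child dosage matrix of the same shape.
#' @export
mendelian_transmission <- function(mother, father, seed = 1) {
  assert_that(all(dim(mother) == dim(father)),
              "mother and father dosage matrices must have equal shape")
  if (!all(mother %in% 0:2) || !all(father %in% 0:2))
    tn_stop("dosages must be integers in {0, 1, 2}", "data_error")
  set.seed(derive_seed(seed, 31L))
  contrib <- function(g) {
    out <- (g == 2L) + (g == 1L) * (runif(length(g)) < 0.5)
    matrix(as.integer(out), nrow(g), ncol(g))
  }
  child <- contrib(mother) + contrib(father)
  storage.mode(child) <- "integer"
  colnames(child) <- colnames(mother)
  child
}

# population variance of the generative phenotype, used by noise_sd = "auto"
phenotype_signal_variance <- function(config, birth_year = NULL) {
  a <- config$a_target
  vgc <- 1 + a / 2; cov_cp <- (1 + a) / 2
  v <- config$c^2 * vgc + config$m^2 + config$f^2 +
    2 * config$c * config$m * cov_cp + 2 * config$c * config$f * cov_cp +
    2 * config$m * config$f * a +
    config$sex_effect^2 * 0.25
  if (!is.null(birth_year))
    v <- v + config$birthyear_effect^2 * stats::var(birth_year - mean(birth_year))
  if (config$n_demes == 2L) v <- v + config$deme_pheno_shift^2 * 0.25
  v
}

#' Build the child phenotype from the generative paths
#'
#' phenotype = c * score_child + m * score_mother + f * score_father
#' + sex and birth-year covariate effects + deme shift + Gaussian noise,
#' then standardized to sample mean 0, SD 1.
#'
#' @param cohort a `trio_cohort` with true scores, sex and birth year filled.
#' @param config the `sim_config`.
#' @return the standardized phenotype vector; the pre-standardization mean
#'   and SD are attached as attribute `"scale"`.
#' @export
simulate_phenotype <- function(cohort, config) {
  assert_that(!is.null(cohort$true_score$child), "true scores must be populated")
  if (!identical(config$noise_sd, "auto"))
    assert_that(config$noise_sd >= 0, "noise_sd must be >= 0")
  set.seed(derive_seed(config$seed, 41L))
  by_c <- cohort$birth_year - mean(cohort$birth_year)
  noise_sd <- if (identical(config$noise_sd, "auto")) {
    sqrt(max(1 - phenotype_signal_variance(config, cohort$birth_year), 1e-4))
  } else config$noise_sd
  y <- config$c * cohort$true_score$child +
    config$m * cohort$true_score$mother +
    config$f * cohort$true_score$father +
    config$sex_effect * cohort$sex +
    config$birthyear_effect * by_c +
    config$deme_pheno_shift * (cohort$deme - 1) +
    rnorm(config$n_trios, 0, noise_sd)
  mu <- mean(y); s <- stats::sd(y)
  if (!is.finite(s) || s == 0) s <- 1
  out <- (y - mu) / s
  attr(out, "scale") <- c(mean = mu, sd = s)
  out
}

#' Observe GWAS weights with sampling error
#'
#' Emulates summary statistics from a finite-size GWAS of the latent trait:
#' the estimated per-allele effect is the true effect plus Normal error with
#' standard error \eqn{1 / \sqrt{N \cdot 2p(1-p)}}, and the p-value is the
#' two-sided normal tail of beta/SE. As `gwas_n` grows the estimates recover
#' the true effects.
#'
#' @param panel a `variant_panel`.
#' @param gwas_n effective GWAS sample size (>= 1; `Inf` gives noise-free
#'   weights with p-values 0 for causal and 1 for null variants).
#' @param seed integer seed.
#' @return a `summary_stats` data.frame with columns SNP, A1, A2, BETA, SE,
#'   P, FRQ.
#' @export
make_noisy_sumstats <- function(panel, gwas_n, seed = 1) {
  assert_that(gwas_n >= 1, "gwas_n must be >= 1")
  set.seed(derive_seed(seed, 51L))
  se <- 1 / sqrt(gwas_n * 2 * panel$maf * (1 - panel$maf))
  if (is.infinite(gwas_n)) {
    beta <- panel$true_beta
    p <- ifelse(beta == 0, 1, 0)
    se <- rep(0, nrow(panel))
  } else {
    beta <- panel$true_beta + rnorm(nrow(panel), 0, se)
    z <- beta / se
    p <- 2 * pnorm(-abs(z))
  }
  p <- pmax(p, .Machine$double.xmin)  # keep p in (0, 1]
  out <- data.frame(SNP = panel$variant_id, A1 = panel$effect_allele,
                    A2 = panel$other_allele, BETA = beta, SE = se, P = p,
                    FRQ = panel$maf, stringsAsFactors = FALSE)
  class(out) <- c("summary_stats", "data.frame")
  out
}

#' Impose (possibly informative) phenotype missingness
#'
#' Draws `n_aux` auxiliary variables with correlation `aux_cor` to the
#' phenotype, then deletes phenotypes with probability given by a logistic
#' function of the auxiliary mean (slope `mar_strength`; 0 gives MCAR). The
#' logistic intercept is solved so the marginal missingness matches
#' `missing_rate`. Missingness is MAR given the auxiliaries.
#'
#' @param cohort a `trio_cohort` with phenotype populated.
#' @param config the `sim_config`.
#' @return the cohort with `auxiliaries` (matrix) and `observed_mask`
#'   (logical) filled in.
#' @export
apply_missingness <- function(cohort, config) {
  assert_that(!is.null(cohort$phenotype), "phenotype must be populated")
  assert_that(config$aux_cor > -1 && config$aux_cor < 1,
              "aux_cor must be in (-1, 1)")
  set.seed(derive_seed(config$seed, 61L))
  n <- config$n_trios
  rho <- config$aux_cor
  aux <- matrix(rnorm(n * config$n_aux), n, config$n_aux)
  aux <- rho * as.numeric(cohort$phenotype) + sqrt(1 - rho^2) * aux
  colnames(aux) <- paste0("aux", seq_len(config$n_aux))
  cohort$auxiliaries <- aux

  if (config$missing_rate == 0) {
    cohort$observed_mask <- rep(TRUE, n)
    return(cohort)
  }
  eta <- config$mar_strength * rowMeans(aux)
  b0 <- uniroot(function(b) mean(plogis(b + eta)) - config$missing_rate,
                c(-30, 30))$root
  cohort$observed_mask <- runif(n) >= plogis(b0 + eta)
  cohort
}

#' Simulate a complete trio cohort
#'
#' End-to-end generator: variant panel, paired parents (with optional
#' stratification and assortative mating), Mendelian transmission to the
#' child, covariates, phenotype, and (when `missing_rate > 0`) auxiliaries
#' plus an observed/missing mask. Identical configs yield byte-identical
#' cohorts.
#'
#' @param config a `sim_config`.
#' @param panel optional pre-built `variant_panel` (defaults to one drawn
#'   from the config).
#' @return a `trio_cohort` list: `dosage` (mother/father/child integer
#'   matrices), `true_score` (mother/father/child, on the pooled parental
#'   scale), `deme`, `sex`, `birth_year`, `phenotype`, `auxiliaries`,
#'   `observed_mask`, `panel`, `config`.
#' @export
simulate_trio_cohort <- function(config, panel = NULL) {
  assert_that(inherits(config, "sim_config"), "config must be a sim_config")
  if (is.null(panel))
    panel <- make_variant_panel(config$n_snps, config$maf_range,
                                config$n_causal, seed = derive_seed(config$seed, 1L))
  par <- simulate_parents(panel, config)
  child <- mendelian_transmission(par$mother, par$father,
                                  seed = derive_seed(config$seed, 2L))
  raw_child <- as.numeric(child %*% panel$true_beta)

  cohort <- list(
    dosage = list(mother = par$mother, father = par$father, child = child),
    true_score = list(
      mother = par$true_score_mother,
      father = par$true_score_father,
      child = (raw_child - par$score_center) / par$score_scale
    ),
    deme = par$deme,
    trio_id = sprintf("trio%05d", seq_len(config$n_trios)),
    panel = panel, config = config
  )
  set.seed(derive_seed(config$seed, 71L))
  cohort$sex <- rbinom(config$n_trios, 1L, 0.5)
  cohort$birth_year <- sample(2000:2007, config$n_trios, replace = TRUE)
  cohort$phenotype <- simulate_phenotype(cohort, config)
  cohort <- apply_missingness(cohort, config)
  class(cohort) <- "trio_cohort"
  cohort
}

#' @export
print.trio_cohort <- function(x, ...) {
  cat(sprintf("trio_cohort: %d trios, %d SNPs, %d deme(s), %.0f%% phenotypes observed\n",
              x$config$n_trios, x$config$n_snps, x$config$n_demes,
              100 * mean(x$observed_mask)))
  invisible(x)
}
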