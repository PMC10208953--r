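#' Assemble the analysis frame for trio regressions
#'
#' One row per trio; the standardized outcome and, per parental factor, the
#' standardized child/mother/father scores, plus the child sex and
#' birth-year covariates. Scores and outcome are (re)standardized here so
#' every regression coefficient is in SD units.
#'
#' @param outcome numeric child outcome.
#' @param scores named list: one element per factor, each a list with
#'   numeric `child`, `mother`, `father` score vectors.
#' @param sex child sex (0/1).
#' @param birth_year child birth year.
#' @param trio_id optional ids (must be unique).
#' @param standardize_outcome standardize the outcome (default TRUE, the
#'   reporting convention: coefficients in outcome-SD units). Set FALSE to
#'   keep the outcome scale, e.g. when it is already standardized elsewhere
#'   or when raw-scale coefficients are wanted.
#' @return a `trio_frame` data.frame with columns `trio_id`, `outcome`,
#'   `sex`, `birth_year` and `<factor>_child/_mother/_father`; factor names
#'   in attribute `"factors"`.
#' @export
trio_frame <- function(outcome, scores, sex, birth_year, trio_id = NULL,
                       standardize_outcome = TRUE) {
  assert_that(is.list(scores) && length(scores) >= 1 && !is.null(names(scores)),
              "scores must be a named list of factors")
  n <- length(outcome)
  trio_id <- trio_id %||% sprintf("trio%05d", seq_len(n))
  assert_that(!anyDuplicated(trio_id), "trio ids must be unique")

  y <- if (standardize_outcome) standardize(outcome, "outcome") else as.numeric(outcome)
  df <- data.frame(trio_id = trio_id, outcome = y,
                   sex = sex, birth_year = birth_year,
                   stringsAsFactors = FALSE)
  for (fac in names(scores)) {
    for (role in c("child", "mother", "father")) {
      v <- scores[[fac]][[role]]
      assert_that(length(v) == n, sprintf("score %s/%s has wrong length", fac, role))
      df[[paste0(fac, "_", role)]] <- standardize(v, paste0(fac, "_", role))
    }
  }
  structure(df, factors = names(scores), class = c("trio_frame", "data.frame"))
}

#' Build a trio_frame directly from a simulated cohort
#'
#' @param cohort a `trio_cohort`.
#' @param scores either `"true"` (the generative latent scores: the
#'   perfect-score benchmark) or a named list as in [trio_frame()].
#' @param factor_name factor label when `scores = "true"`.
#' @param complete_only keep only trios with observed phenotype.
#' @return a `trio_frame`.
#' @export
trio_frame_from_cohort <- function(cohort, scores = "true",
                                   factor_name = "factor1",
                                   complete_only = TRUE) {
  if (identical(scores, "true"))
    scores <- setNames(list(cohort$true_score), factor_name)
  keep <- if (complete_only) cohort$observed_mask else rep(TRUE, cohort$config$n_trios)
  sub <- function(v) v[keep]
  trio_frame(sub(cohort$phenotype),
             lapply(scores, function(s) lapply(s, sub)),
             sub(cohort$sex), sub(cohort$birth_year), sub(cohort$trio_id))
}

score_cols <- function(factor, roles) paste0(factor, "_", roles)

# OLS + (robust) SEs for the requested coefficients, as a FitResult frame
ols_fit_result <- function(frame, terms, wanted, model_tag, factor, roles,
                           se_type = c("HC1", "classical")) {
  se_type <- match.arg(se_type)
  dat <- frame[, c("outcome", terms, "sex", "birth_year")]
  assert_that(all(stats::complete.cases(dat)), "rows must be complete")
  n <- nrow(dat)
  if (n <= length(terms) + 3) tn_stop("too few rows for the model", "invalid_input")
  for (tm in terms)
    if (stats::sd(dat[[tm]]) < 1e-12)
      tn_stop(sprintf("score '%s' is constant", tm), "degenerate_input")

  fml <- stats::reformulate(c(terms, "sex", "birth_year"), response = "outcome")
  fit <- stats::lm(fml, data = dat)
  if (fit$rank < length(coef(fit))) {
    alias <- names(coef(fit))[is.na(coef(fit))]
    tn_stop(sprintf("rank-deficient model: collinear term(s) %s",
                    paste(alias, collapse = ", ")), "degenerate_input")
  }
  V <- if (se_type == "HC1") sandwich::vcovHC(fit, type = "HC1") else stats::vcov(fit)
  b <- coef(fit)[wanted]
  se <- sqrt(diag(V))[wanted]
  z <- b / se
  data.frame(model = model_tag, factor = factor, role = roles,
             beta = unname(b), se = unname(se),
             ci_low = unname(b - 1.96 * se), ci_high = unname(b + 1.96 * se),
             p = unname(2 * pnorm(-abs(z))), n = n,
             covariates = "sex,birth_year", se_type = se_type,
             stringsAsFactors = FALSE)
}

#' Unadjusted model: outcome on one family member's score
#'
#' OLS of the standardized child outcome on a single polygenic score plus
#' the sex and birth-year covariates. Under random mating the population
#' slope for a parental score is the nurture path plus half the direct path
#' (m + c/2 for mothers): transmission and nurture are confounded here,
#' which is what the trio model untangles.
#'
#' @param frame a `trio_frame`.
#' @param factor factor name.
#' @param role one of "child", "mother", "father".
#' @param se_type "HC1" (heteroskedasticity-robust, default) or "classical".
#' @return one-row FitResult data.frame (model, factor, role, beta, se,
#'   ci_low, ci_high, p, n, covariates).
#' @export
fit_unadjusted <- function(frame, factor, role = c("mother", "father", "child"),
                           se_type = "HC1") {
  role <- match.arg(role)
  term <- score_cols(factor, role)
  ols_fit_result(frame, term, term, "unadjusted", factor, role, se_type)
}

#' Trio model: outcome on child, mother and father scores jointly
#'
#' The child coefficient estimates the direct genetic path c; the maternal
#' and paternal coefficients estimate the nurture paths m and f, because
#' conditioning on the child score removes the transmitted-allele pathway.
#'
#' @inheritParams fit_unadjusted
#' @return three-row FitResult data.frame (roles child, mother, father).
#' @export
fit_trio <- function(frame, factor, se_type = "HC1") {
  roles <- c("child", "mother", "father")
  terms <- score_cols(factor, roles)
  ols_fit_result(frame, terms, terms, "trio", factor, roles, se_type)
}

#' Across-factor model: all trios' scores for several factors jointly
#'
#' One OLS with 3 x length(factors) score predictors plus covariates, to
#' check whether correlation between factors' scores moves the trio
#' estimates. Warns when any cross-factor score correlation exceeds 0.8.
#'
#' @param frame a `trio_frame` containing every factor's scores.
#' @param factors character vector of >= 2 factor names.
#' @inheritParams fit_unadjusted
#' @return FitResult data.frame with 3 rows per factor.
#' @export
fit_across_factors <- function(frame, factors, se_type = "HC1") {
  assert_that(length(factors) >= 2, "need >= 2 factors")
  roles <- c("child", "mother", "father")
  terms <- as.vector(vapply(factors, score_cols, character(3), roles = roles))
  cc <- stats::cor(as.matrix(frame[, terms]))
  pairs_fac <- outer(rep(factors, each = 3), rep(factors, each = 3), "!=")
  if (any(abs(cc)[pairs_fac & upper.tri(cc)] > 0.8))
    warning("cross-factor score correlation exceeds 0.8; joint estimates may be unstable")
  ols_fit_result(frame, terms, terms, "across_factor",
                 rep(factors, each = 3), rep(roles, length(factors)), se_type)
}

#' Test attenuation between the unadjusted and trio models
#'
#' Estimates delta = beta_unadjusted - beta_trio for one parental score on
#' the identical row set and tests delta = 0. Default method is a paired
#' nonparametric bootstrap: trios are resampled, both models refit per
#' resample, and the p-value is the normal approximation from the bootstrap
#' SE (a percentile CI and a centered empirical p with the
#' (1 + #exceedances)/(B + 1) convention are also returned). The analytic
#' alternative stacks the two estimating equations and uses the
#' influence-function covariance of the coefficient pair.
#'
#' @param frame a `trio_frame` (complete rows).
#' @param factor factor name.
#' @param role "mother" or "father".
#' @param method "bootstrap" (default) or "analytic".
#' @param B bootstrap resamples (>= 100).
#' @param seed seed for the bootstrap.
#' @return a `delta_beta_result` one-row data.frame: factor, role,
#'   beta_unadjusted, beta_adjusted, delta, se_delta, p_delta, ci_low,
#'   ci_high, method, B.
#' @export
delta_beta <- function(frame, factor, role = c("mother", "father", "child"),
                       method = c("bootstrap", "analytic"), B = 1000, seed = 1) {
  role <- match.arg(role); method <- match.arg(method)
  roles <- c("child", "mother", "father")
  terms3 <- score_cols(factor, roles)
  term1 <- score_cols(factor, role)
  dat <- frame[, c("outcome", terms3, "sex", "birth_year")]
  if (!all(stats::complete.cases(dat)))
    tn_stop("both models must be fit on the identical complete row set",
            "invalid_input")
  n <- nrow(dat)
  y <- dat$outcome
  X1 <- cbind(1, as.matrix(dat[, c(term1, "sex", "birth_year")]))
  X3 <- cbind(1, as.matrix(dat[, c(terms3, "sex", "birth_year")]))
  j1 <- 2L                                   # coefficient of the single score
  j3 <- 1L + match(term1, terms3)            # same score inside the trio model

  b1 <- qr.coef(qr(X1), y); b3 <- qr.coef(qr(X3), y)
  delta_hat <- b1[j1] - b3[j3]

  if (method == "bootstrap") {
    assert_that(B >= 100, "B must be >= 100 for the bootstrap")
    set.seed(derive_seed(seed, 91L))
    deltas <- numeric(B)
    for (bb in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      yb <- y[idx]
      c1 <- .lm.fit(X1[idx, , drop = FALSE], yb)$coefficients
      c3 <- .lm.fit(X3[idx, , drop = FALSE], yb)$coefficients
      deltas[bb] <- c1[j1] - c3[j3]
    }
    se_d <- stats::sd(deltas)
    p <- 2 * pnorm(-abs(delta_hat) / se_d)
    p_emp <- (1 + sum(abs(deltas - mean(deltas)) >= abs(delta_hat))) / (B + 1)
    ci <- unname(stats::quantile(deltas, c(0.025, 0.975)))
  } else {
    # stacked influence functions: b_j is asymptotically
    # mean_i [(X'X)^{-1} x_i e_i]_j, so Var(delta) = sum_i (h1_i - h2_i)^2
    e1 <- y - X1 %*% b1; e3 <- y - X3 %*% b3
    h1 <- (chol2inv(qr.R(qr(X1))) %*% t(X1 * as.numeric(e1)))[j1, ]
    h3 <- (chol2inv(qr.R(qr(X3))) %*% t(X3 * as.numeric(e3)))[j3, ]
    se_d <- sqrt(sum((h1 - h3)^2) * n / (n - ncol(X3)))
    p <- 2 * pnorm(-abs(delta_hat) / se_d)
    p_emp <- NA_real_
    ci <- delta_hat + c(-1.96, 1.96) * se_d
  }
  out <- data.frame(factor = factor, role = role,
                    beta_unadjusted = unname(b1[j1]),
                    beta_adjusted = unname(b3[j3]),
                    delta = unname(delta_hat), se_delta = se_d,
                    p_delta = max(p, .Machine$double.xmin),
                    p_empirical = p_emp,
                    ci_low = ci[1], ci_high = ci[2],
                    method = method, B = if (method == "bootstrap") B else NA_integer_,
                    n = n, stringsAsFactors = FALSE)
  class(out) <- c("delta_beta_result", "data.frame")
  out
}

#' Benjamini-Hochberg discovery flags
#'
#' Step-up FDR control over the supplied family of tests (the study design
#' uses families of 36: 12 parental factors times three family members).
#'
#' @param pvalues numeric vector in (0, 1].
#' @param q target FDR level in (0, 1).
#' @return logical discovery flags, monotone in the p-values.
#' @export
bh_fdr <- function(pvalues, q = 0.05) {
  assert_that(length(pvalues) >= 1, "empty p-value vector", "invalid_input")
  assert_that(all(pvalues > 0 & pvalues <= 1), "p-values must lie in (0, 1]")
  assert_that(q > 0 && q < 1, "q must be in (0, 1)")
  p.adjust(pvalues, method = "BH") <= q
}

#' Classify the transmission mechanism for one parental score
#'
#' Combines the unadjusted fit, the trio (adjusted) fit, the attenuation
#' test and the FDR flags into a label: "genetic nurture" when the adjusted
#' parental estimate survives FDR ("both" when the attenuation test is also
#' significant); "genetic transmission" when the unadjusted association
#' survives FDR, attenuation is significant, and the adjusted estimate does
#' not survive; "inconclusive - possible power limitation" when the
#' unadjusted association survives but neither of those holds; otherwise
#' "no association".
#'
#' @param unadjusted one-row FitResult from [fit_unadjusted()].
#' @param trio the matching parental row of [fit_trio()].
#' @param delta the matching [delta_beta()] row.
#' @param fdr_unadjusted,fdr_trio logical FDR flags for the two estimates
#'   (computed over their model-family of tests).
#' @param alpha_delta attenuation significance level (default 0.05).
#' @return character label.
#' @export
classify_mechanism <- function(unadjusted, trio, delta,
                               fdr_unadjusted, fdr_trio, alpha_delta = 0.05) {
  same <- unadjusted$factor == trio$factor && trio$factor == delta$factor &&
    unadjusted$role == trio$role && trio$role == delta$role
  if (!isTRUE(same))
    tn_stop("unadjusted, trio and delta results refer to different factor/role",
            "invalid_input")
  attenuated <- delta$p_delta < alpha_delta
  if (isTRUE(fdr_trio)) {
    if (attenuated) "both" else "genetic nurture"
  } else if (isTRUE(fdr_unadjusted) && attenuated) {
    "genetic transmission"
  } else if (isTRUE(fdr_unadjusted)) {
    "inconclusive - possible power limitation"
  } else {
    "no association"
  }
}
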