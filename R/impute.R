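#' Multiply impute a partially observed outcome
#'
#' Imputes missing outcome values from complete predictors (polygenic
#' scores plus auxiliary variables) by predictive mean matching under a
#' Bayesian linear model: per imputation, the residual variance and
#' coefficients are drawn from their posterior given the observed cases,
#' predictions are formed for the missing cases, and each missing case
#' receives the observed outcome of one of the `donors` nearest observed
#' cases by predicted value. Only the outcome is incomplete here, so the
#' chained-equations system reduces to this single equation. Observed
#' values are never altered.
#'
#' @param outcome numeric vector with NAs to impute.
#' @param predictors complete data.frame or matrix of predictors;
#'   zero-variance columns are dropped with a warning.
#' @param M number of imputations (>= 2).
#' @param seed integer seed; imputations are deterministic given it.
#' @param donors donor-pool size for predictive mean matching.
#' @return an `imputation_result` list: `M`, `imputations` (list of M
#'   completed outcome vectors), `missing_index`, `seed`.
#' @export
impute_outcomes <- function(outcome, predictors, M = 20, seed = 1, donors = 5) {
  assert_that(M >= 2, "M must be >= 2")
  predictors <- as.data.frame(predictors)
  assert_that(nrow(predictors) == length(outcome),
              "predictors must have one row per outcome")
  assert_that(!anyNA(predictors), "predictors must be complete")
  if (all(is.na(outcome)))
    tn_stop("all outcomes missing: nothing to fit the imputation model on",
            "invalid_input")

  sds <- vapply(predictors, stats::sd, numeric(1))
  if (any(sds < 1e-12)) {
    warning(sprintf("%d zero-variance predictor(s) dropped from imputation model",
                    sum(sds < 1e-12)))
    predictors <- predictors[, sds >= 1e-12, drop = FALSE]
  }

  mis <- which(is.na(outcome))
  obs <- which(!is.na(outcome))
  if (length(mis) == 0)
    return(structure(list(M = as.integer(M),
                          imputations = rep(list(outcome), M),
                          missing_index = integer(0), seed = as.integer(seed)),
                     class = "imputation_result"))

  X <- cbind(`(Intercept)` = 1, as.matrix(predictors))
  Xo <- X[obs, , drop = FALSE]; yo <- outcome[obs]
  qr_o <- qr(Xo)
  assert_that(qr_o$rank == ncol(Xo) && length(obs) > ncol(Xo) + 1,
              "too few observed cases for the imputation model")
  bhat <- qr.coef(qr_o, yo)
  res <- yo - as.numeric(Xo %*% bhat)
  df <- length(obs) - ncol(Xo)
  s2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qr_o))
  Rchol <- chol(XtXinv)
  yhat_obs <- as.numeric(Xo %*% bhat)

  set.seed(derive_seed(seed, 81L))
  imputations <- vector("list", M)
  for (im in seq_len(M)) {
    sigma2_star <- s2 * df / rchisq(1, df)
    beta_star <- bhat + sqrt(sigma2_star) * as.numeric(t(Rchol) %*% rnorm(ncol(Xo)))
    yhat_mis <- as.numeric(X[mis, , drop = FALSE] %*% beta_star)
    filled <- outcome
    for (i in seq_along(mis)) {
      d <- abs(yhat_obs - yhat_mis[i])
      pool <- order(d)[seq_len(min(donors, length(obs)))]
      filled[mis[i]] <- yo[sample(pool, 1L)]
    }
    imputations[[im]] <- filled
  }
  structure(list(M = as.integer(M), imputations = imputations,
                 missing_index = mis, seed = as.integer(seed)),
            class = "imputation_result")
}

#' Pool estimates across imputations by Rubin's rules
#'
#' Pooled point estimate is the mean of the per-imputation estimates; the
#' pooled variance is the mean within-imputation variance plus
#' (1 + 1/M) times the between-imputation variance. Degrees of freedom use
#' the Barnard-Rubin small-sample adjustment when the complete-data degrees
#' of freedom are supplied, and p-values come from the t reference.
#'
#' @param fits list of >= 2 fits, each a list (or data.frame row set) with
#'   named numeric `estimate` and `se` of the same coefficients, optionally
#'   `df_residual` (complete-data residual df).
#' @return data.frame with one row per coefficient: `term`, `estimate`,
#'   `se`, `within`, `between`, `df`, `statistic`, `p`, `ci_low`, `ci_high`.
#' @export
pool_rubin <- function(fits) {
  assert_that(is.list(fits) && length(fits) >= 2, "need >= 2 fits to pool")
  est <- lapply(fits, function(f) f$estimate)
  ses <- lapply(fits, function(f) f$se)
  terms <- names(est[[1]])
  assert_that(!is.null(terms), "estimates must be named")
  ok <- vapply(seq_along(fits), function(i)
    identical(names(est[[i]]), terms) && identical(names(ses[[i]]), terms),
    logical(1))
  if (!all(ok)) tn_stop("mismatched coefficient sets across fits", "invalid_input")

  M <- length(fits)
  Q <- do.call(rbind, est)       # M x k
  U <- do.call(rbind, ses)^2
  qbar <- colMeans(Q)
  ubar <- colMeans(U)
  b <- apply(Q, 2, stats::var)
  t_var <- ubar + (1 + 1 / M) * b
  se <- sqrt(t_var)

  lambda <- pmin(pmax((1 + 1 / M) * b / t_var, 1e-12), 1 - 1e-12)
  df_old <- (M - 1) / lambda^2
  dfcom <- fits[[1]]$df_residual
  if (!is.null(dfcom) && is.finite(dfcom)) {
    df_obs <- (dfcom + 1) / (dfcom + 3) * dfcom * (1 - lambda)
    df <- df_old * df_obs / (df_old + df_obs)
  } else df <- df_old

  stat <- qbar / se
  p <- 2 * pt(-abs(stat), df)
  crit <- qt(0.975, df)
  data.frame(term = terms, estimate = qbar, se = se,
             within = ubar, between = b, df = df, statistic = stat, p = p,
             ci_low = qbar - crit * se, ci_high = qbar + crit * se,
             row.names = NULL, stringsAsFactors = FALSE)
}
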