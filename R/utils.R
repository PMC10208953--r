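#' trionurture: trio polygenic-score analysis of transmission vs nurture
#'
#' Simulation and inference for the within-family trio polygenic-score
#' design that separates genetic transmission from genetic nurture.
#'
#' @keywords internal
"_PACKAGE"

#' @importFrom stats lm coef var sd cor rnorm runif rbinom rbeta
#'   pnorm pt qt qnorm plogis uniroot prcomp model.matrix complete.cases
#'   p.adjust quantile rchisq setNames .lm.fit
#' @importFrom utils head modifyList packageVersion
NULL

# error with a condition class so callers/tests can be specific
tn_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "trionurture_error")))
}

assert_that <- function(ok, msg, class = "invalid_argument") {
  if (!isTRUE(ok)) tn_stop(msg, class)
  invisible(TRUE)
}

#' Derive a stage-specific seed from a global seed
#'
#' All randomness in the package flows from one global seed; each stage
#' (panel, parents, transmission, phenotype, GWAS noise, missingness,
#' imputation, bootstrap) draws from its own derived stream so that changing
#' one stage's parameters never perturbs another stage's draws.
#'
#' @param seed integer global seed.
#' @param stage integer stage offset (each caller uses a fixed small integer).
#' @return an integer seed in [1, 2^31 - 2].
#' @export
derive_seed <- function(seed, stage) {
  assert_that(is.numeric(seed) && length(seed) == 1L && is.finite(seed),
              "seed must be a single finite number")
  as.integer((abs(as.double(seed)) * 48271 + as.double(stage) * 7919 + 1) %% 2147483629)
}

# standardize to sample mean 0, SD 1; errors on (near-)constant input
standardize <- function(x, what = "vector", tol = 1e-10) {
  s <- stats::sd(x)
  if (!is.finite(s) || s < tol)
    tn_stop(sprintf("cannot standardize %s: standard deviation is ~0", what),
            "degenerate_input")
  (x - mean(x)) / s
}

`%||%` <- function(a, b) if (is.null(a)) b else a
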