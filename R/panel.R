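#' Create a synthetic variant panel
#'
#' Draws a panel of unlinked biallelic SNPs with effect-allele frequencies
#' uniform on `maf_range` and per-allele effects on the latent trait for
#' `n_causal` of them. Causal effects are drawn Normal and rescaled so the
#' population variance of the raw causal score,
#' \eqn{\sum_v \beta_v^2 \, 2 p_v (1 - p_v)}, is exactly 1: the latent
#' genetic value is in SD units by construction.
#'
#' @param n_snps number of variants.
#' @param maf_range length-2 numeric interval within (0, 0.5] for the
#'   effect-allele frequency.
#' @param n_causal number of variants with nonzero effect (1..n_snps).
#' @param seed integer seed; the panel is deterministic given it.
#' @return a `variant_panel` data.frame with columns `variant_id`,
#'   `effect_allele`, `other_allele`, `maf`, `true_beta`.
#' @examples
#' p <- make_variant_panel(100, c(0.05, 0.5), n_causal = 50, seed = 1)
#' sum(p$true_beta^2 * 2 * p$maf * (1 - p$maf))  # 1
#' @export
make_variant_panel <- function(n_snps, maf_range = c(0.05, 0.5),
                               n_causal = n_snps, seed = 1) {
  assert_that(n_snps >= 1, "n_snps must be >= 1")
  assert_that(length(maf_range) == 2 && maf_range[1] <= maf_range[2],
              "maf_range must be a non-empty interval")
  assert_that(maf_range[1] > 0 && maf_range[2] <= 0.5,
              "maf_range must lie within (0, 0.5]")
  assert_that(n_causal >= 1 && n_causal <= n_snps,
              "n_causal must be between 1 and n_snps")

  set.seed(derive_seed(seed, 11L))
  maf <- runif(n_snps, maf_range[1], maf_range[2])
  # alleles: effect vs other, distinct bases per variant
  bases <- c("A", "C", "G", "T")
  ea <- sample(bases, n_snps, replace = TRUE)
  oa <- vapply(ea, function(b) sample(setdiff(bases, b), 1L), character(1))

  beta <- numeric(n_snps)
  causal <- sort(sample.int(n_snps, n_causal))
  raw <- rnorm(n_causal)
  # avoid a pathological all-zero draw at tiny n_causal
  if (all(raw == 0)) raw <- rep(1, n_causal)
  v <- sum(raw^2 * 2 * maf[causal] * (1 - maf[causal]))
  beta[causal] <- raw / sqrt(v)

  out <- data.frame(
    variant_id = sprintf("rs%06d", seq_len(n_snps)),
    effect_allele = unname(ea),
    other_allele = unname(oa),
    maf = maf,
    true_beta = beta,
    stringsAsFactors = FALSE
  )
  class(out) <- c("variant_panel", "data.frame")
  out
}
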