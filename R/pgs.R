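#' Read GWAS summary statistics
#'
#' Reads a tab-separated summary-statistics file and validates it: unique
#' variant ids, p-values in (0, 1], effect and other allele distinct. Rows
#' with missing beta, p-value or alleles are dropped with a message.
#' Strand-ambiguous (A/T, C/G) variants are flagged in column `ambiguous`
#' and optionally dropped.
#'
#' @param path file path.
#' @param column_map named character vector mapping the canonical fields
#'   `variant_id`, `effect_allele`, `other_allele`, `beta`, `pvalue` (and
#'   optionally `se`, `eaf`) to the file's column names.
#' @param drop_ambiguous drop A/T and C/G variants instead of just flagging
#'   them (default FALSE: the simulator controls allele coding, so ambiguity
#'   is harmless there).
#' @return a `summary_stats` data.frame with canonical columns SNP, A1, A2,
#'   BETA, SE, P, FRQ (SE/FRQ NA when absent) plus `ambiguous`.
#' @export
read_sumstats <- function(path,
                          column_map = c(variant_id = "SNP", effect_allele = "A1",
                                         other_allele = "A2", beta = "BETA",
                                         pvalue = "P", se = "SE", eaf = "FRQ"),
                          drop_ambiguous = FALSE) {
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  raw <- data.table::fread(path, sep = "\t", data.table = FALSE,
                           showProgress = FALSE)
  required <- c("variant_id", "effect_allele", "other_allele", "beta", "pvalue")
  missing_cols <- setdiff(column_map[required], names(raw))
  assert_that(length(missing_cols) == 0,
              sprintf("missing columns: %s", paste(missing_cols, collapse = ", ")))

  get <- function(field) {
    col <- column_map[[field]]
    if (!is.null(col) && col %in% names(raw)) raw[[col]] else rep(NA, nrow(raw))
  }
  out <- data.frame(SNP = as.character(get("variant_id")),
                    A1 = toupper(as.character(get("effect_allele"))),
                    A2 = toupper(as.character(get("other_allele"))),
                    BETA = as.numeric(get("beta")),
                    SE = suppressWarnings(as.numeric(get("se"))),
                    P = as.numeric(get("pvalue")),
                    FRQ = suppressWarnings(as.numeric(get("eaf"))),
                    stringsAsFactors = FALSE)

  keep <- !is.na(out$BETA) & !is.na(out$P) & nzchar(out$A1) & nzchar(out$A2) &
    !is.na(out$A1) & !is.na(out$A2)
  if (any(!keep))
    message(sum(!keep), " row(s) dropped for missing beta/p/alleles")
  out <- out[keep, , drop = FALSE]

  if (anyDuplicated(out$SNP))
    tn_stop(sprintf("duplicate variant ids: %s",
                    paste(head(unique(out$SNP[duplicated(out$SNP)]), 3), collapse = ", ")),
            "data_error")
  bad_p <- which(out$P <= 0 | out$P > 1)
  if (length(bad_p))
    tn_stop(sprintf("p-value outside (0, 1] at row(s) %s (e.g. %s, p = %g)",
                    paste(head(bad_p, 3), collapse = ", "),
                    out$SNP[bad_p[1]], out$P[bad_p[1]]),
            "data_error")
  same <- out$A1 == out$A2
  if (any(same))
    tn_stop(sprintf("effect and other allele identical for %s", out$SNP[which(same)[1]]),
            "data_error")

  flip <- c(A = "T", T = "A", C = "G", G = "C")
  out$ambiguous <- unname(flip[out$A1]) == out$A2
  out$ambiguous[is.na(out$ambiguous)] <- FALSE
  if (drop_ambiguous && any(out$ambiguous)) {
    message(sum(out$ambiguous), " strand-ambiguous variant(s) dropped")
    out <- out[!out$ambiguous, , drop = FALSE]
  }
  rownames(out) <- NULL
  class(out) <- c("summary_stats", "data.frame")
  out
}

# align the genotype file's counted allele to the sumstats effect allele.
# Returns per-variant weight and additive offset so that the contribution is
# offset + weight * dosage: counted == effect -> (0, beta);
# counted == other -> effect-allele dosage is 2 - g, i.e. (2*beta, -beta).
align_alleles <- function(counted, sumstats) {
  i <- match(names(counted), sumstats$SNP)
  eff <- sumstats$A1[i]; oth <- sumstats$A2[i]; beta <- sumstats$BETA[i]
  status <- ifelse(is.na(i), "absent",
                   ifelse(counted == eff, "match",
                          ifelse(counted == oth, "flip", "mismatch")))
  list(index = i, status = status, beta = beta)
}

#' Compute polygenic scores at p-value thresholds
#'
#' For each threshold t, score(i, t) = sum over variants with p <= t of
#' beta * effect-allele dosage. Dosage columns counting the other allele are
#' aligned by the substitution g -> 2 - g; variants whose counted allele
#' matches neither sumstats allele are dropped with a message.
#'
#' @param dosages numeric matrix, individuals x variants. Column names are
#'   either plain variant ids (then `counted_alleles` must be given or the
#'   effect allele is assumed counted) or PLINK `.raw`-style
#'   `<ID>_<counted allele>`.
#' @param sumstats a `summary_stats` data.frame.
#' @param thresholds ascending p-value cutoffs.
#' @param counted_alleles optional named character vector (variant id ->
#'   counted allele) overriding the column-name encoding.
#' @return a `pgs_matrix` list: `ids`, `thresholds`, `raw_scores`
#'   (individuals x thresholds), `n_variants` used per threshold, and the
#'   alignment log.
#' @export
compute_threshold_scores <- function(dosages, sumstats,
                                     thresholds = default_thresholds(),
                                     counted_alleles = NULL) {
  assert_that(is.matrix(dosages) && !is.null(colnames(dosages)),
              "dosages must be a matrix with variant column names")
  assert_that(!is.unsorted(thresholds), "thresholds must be sorted ascending")

  cn <- colnames(dosages)
  if (is.null(counted_alleles)) {
    plink_style <- grepl("_[ACGT]$", cn)
    if (all(plink_style)) {
      counted_alleles <- sub("^.*_([ACGT])$", "\\1", cn)
      ids <- sub("_[ACGT]$", "", cn)
    } else {
      ids <- cn
      counted_alleles <- sumstats$A1[match(ids, sumstats$SNP)]
    }
  } else {
    ids <- cn
    counted_alleles <- unname(counted_alleles[ids])
  }
  names(counted_alleles) <- ids

  al <- align_alleles(counted_alleles, sumstats)
  usable <- al$status %in% c("match", "flip")
  if (any(al$status == "mismatch"))
    message(sum(al$status == "mismatch"),
            " variant(s) dropped: counted allele matches neither sumstats allele")
  if (!any(usable))
    tn_stop("no variants shared between dosages and summary statistics",
            "data_error")

  p <- sumstats$P[al$index][usable]
  beta <- al$beta[usable]
  flip <- al$status[usable] == "flip"
  G <- dosages[, usable, drop = FALSE]
  # effect-allele dosage after alignment
  if (any(flip)) G[, flip] <- 2 - G[, flip]

  raw <- matrix(0, nrow(dosages), length(thresholds),
                dimnames = list(rownames(dosages),
                                paste0("p", format(thresholds, trim = TRUE))))
  nv <- integer(length(thresholds))
  for (t in seq_along(thresholds)) {
    sel <- p <= thresholds[t]
    nv[t] <- sum(sel)
    if (nv[t] > 0) raw[, t] <- G[, sel, drop = FALSE] %*% beta[sel]
  }
  structure(list(ids = rownames(dosages) %||% seq_len(nrow(dosages)),
                 thresholds = thresholds, raw_scores = raw, n_variants = nv,
                 alignment = table(factor(al$status,
                                          levels = c("match", "flip", "mismatch", "absent")))),
            class = "pgs_matrix")
}

#' Default p-value threshold ladder
#' @return the standard multi-threshold grid used for PRS-PC.
#' @export
default_thresholds <- function() {
  c(5e-8, 1e-6, 1e-4, 1e-3, 0.01, 0.05, 0.1, 0.5, 1)
}

#' PRS-PC: first principal component across threshold scores
#'
#' Standardizes each threshold column (dropping constant columns with a
#' message), extracts the first principal component, aligns its sign to
#' correlate non-negatively with the mean standardized score, and
#' re-standardizes to mean 0, SD 1. Combining thresholds this way improves
#' predictive accuracy without picking a single threshold by validation.
#'
#' @param raw_scores matrix of scores, individuals x thresholds (or a
#'   `pgs_matrix`, whose `raw_scores` are used).
#' @return list: `prspc` (standardized composite), `loadings` (threshold
#'   weights of PC1 on retained columns), `var_explained`.
#' @export
prs_pc <- function(raw_scores) {
  if (inherits(raw_scores, "pgs_matrix")) raw_scores <- raw_scores$raw_scores
  assert_that(is.matrix(raw_scores), "raw_scores must be a matrix")
  assert_that(nrow(raw_scores) >= 3, "need at least 3 individuals")
  sds <- apply(raw_scores, 2, stats::sd)
  keep <- is.finite(sds) & sds > 1e-12
  if (!any(keep)) tn_stop("all threshold columns are constant", "degenerate_input")
  if (any(!keep))
    message(sum(!keep), " constant threshold column(s) dropped before PRS-PC")
  X <- raw_scores[, keep, drop = FALSE]
  assert_that(ncol(X) >= 2, "need at least 2 non-constant threshold columns")

  Z <- scale(X)
  pc <- prcomp(Z, center = FALSE, scale. = FALSE)
  score <- pc$x[, 1]
  load1 <- pc$rotation[, 1]
  if (stats::cor(score, rowMeans(Z)) < 0) {
    score <- -score; load1 <- -load1
  }
  list(prspc = standardize(score, "PRS-PC composite"),
       loadings = load1,
       var_explained = pc$sdev[1]^2 / sum(pc$sdev^2))
}

#' Ancestry principal components of a dosage matrix
#'
#' Column-standardizes the dosage matrix (zero-variance variants excluded)
#' and returns the first k left singular vectors: orthonormal sample PCs
#' ordered by singular value, for use as stratification covariates.
#'
#' @param dosages numeric matrix, individuals x variants.
#' @param k number of components, k < min(n, number of variable variants).
#' @return n x k matrix with columns PC1..PCk; singular values attached as
#'   attribute `"d"`.
#' @export
compute_ancestry_pcs <- function(dosages, k = 10) {
  sds <- apply(dosages, 2, stats::sd)
  keep <- is.finite(sds) & sds > 0
  assert_that(k >= 1 && k < min(nrow(dosages), sum(keep)),
              "k must be < min(n_individuals, n_variable_variants)")
  Z <- scale(dosages[, keep, drop = FALSE])
  s <- svd(Z, nu = k, nv = 0)
  pcs <- s$u
  colnames(pcs) <- paste0("PC", seq_len(k))
  attr(pcs, "d") <- s$d[seq_len(k)]
  pcs
}

#' Residualize a score on technical/ancestry covariates, then standardize
#'
#' Regresses the score on the selected covariates (categorical batch
#' variables expand to indicators; batch levels with a single member are
#' merged into "other" with a warning) and returns the standardized
#' residuals, which are exactly uncorrelated with every included covariate.
#'
#' @param score numeric vector.
#' @param covariates data.frame of covariates (numeric PCs, factor/character
#'   batch labels, sex, birth year ...).
#' @param which columns of `covariates` to adjust for (default all).
#' @return standardized residual score (mean 0, SD 1).
#' @export
residualize_standardize <- function(score, covariates, which = names(covariates)) {
  assert_that(is.data.frame(covariates), "covariates must be a data.frame")
  assert_that(all(which %in% names(covariates)),
              "unknown covariate column requested")
  cov <- covariates[, which, drop = FALSE]
  assert_that(nrow(cov) == length(score),
              "covariates must cover all scored individuals")
  assert_that(!anyNA(cov) && !anyNA(score), "covariates and score must be complete")

  for (j in names(cov)) {
    if (is.character(cov[[j]]) || is.factor(cov[[j]])) {
      f <- as.character(cov[[j]])
      singles <- names(which(table(f) == 1L))
      if (length(singles)) {
        warning(sprintf("batch column '%s': %d singleton level(s) merged into 'other'",
                        j, length(singles)))
        f[f %in% singles] <- "other"
      }
      cov[[j]] <- factor(f)
    }
  }
  mm <- model.matrix(~ ., data = cov)
  r <- stats::lm.fit(mm, score)$residuals
  standardize(r, "residualized score")
}
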