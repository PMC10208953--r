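#' Default pipeline configuration
#'
#' Returns the full run configuration as a nested list: the `sim` block
#' holds every [sim_config()] field; `thresholds` the p-value ladder;
#' `pca_k` the number of ancestry PCs; `fdr_q` the FDR level; `dbeta` the
#' attenuation-test method and resample count; `imputation` the number of
#' imputations (`M = 0` disables imputation and analyses are complete-case).
#' All fields can be overridden from YAML ([read_run_config()]) or by
#' argument.
#'
#' @param ... named overrides of top-level fields (`sim` is merged, not
#'   replaced).
#' @return a `run_config` list.
#' @export
default_run_config <- function(...) {
  cfg <- list(
    out = "trionurture_run",
    seed = 1L,
    factor_name = "factor1",
    sim = list(n_trios = 2000, n_snps = 500, c = 0.15, m = 0.05, f = 0,
               gwas_n = 1e5, missing_rate = 0),
    thresholds = default_thresholds(),
    pca_k = 10L,
    residualize_pcs = TRUE,
    fdr_q = 0.05,
    dbeta = list(method = "bootstrap", B = 1000L),
    imputation = list(M = 0L)
  )
  dots <- list(...)
  if (!is.null(dots$sim)) {
    cfg$sim <- modifyList(cfg$sim, dots$sim)
    dots$sim <- NULL
  }
  cfg <- modifyList(cfg, dots)
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected with the offending path so typos fail fast;
#' missing keys fall back to [default_run_config()].
#'
#' @param path YAML file.
#' @param overrides named list of overriding fields (e.g. from CLI flags).
#' @return a `run_config` list.
#' @export
read_run_config <- function(path, overrides = list()) {
  assert_that(file.exists(path), sprintf("config not found: %s", path))
  user <- yaml::read_yaml(path)
  base <- default_run_config()
  check_keys <- function(u, b, prefix = "") {
    bad <- setdiff(names(u), names(b))
    if (length(bad))
      tn_stop(sprintf("unknown config key: %s%s", prefix, bad[1]), "config_error")
  }
  check_keys(user, base)
  if (!is.null(user$sim)) check_keys(user$sim, formals(sim_config), "sim.")
  cfg <- base
  if (!is.null(user$sim)) { cfg$sim <- modifyList(cfg$sim, user$sim); user$sim <- NULL }
  cfg <- modifyList(cfg, user)
  if (length(overrides)) cfg <- modifyList(cfg, overrides)
  class(cfg) <- "run_config"
  cfg
}

#' Run the full simulate-score-impute-fit-report pipeline
#'
#' Executes the stages in dependency order, with every intermediate written
#' to `config$out` so single stages can be re-run: `simulate` writes the
#' cohort's dosage/pedigree/phenotype/sumstats files; `score` reads them
#' back, builds threshold scores and the PRS-PC composite per family role
#' (PC loadings estimated once on mothers, fathers and children pooled so
#' the composite is on one scale), computes ancestry PCs and residualizes;
#' `impute` scores the 18 items and multiply-imputes missing outcomes from
#' scores plus auxiliaries; `fit` runs the unadjusted and trio models, the
#' attenuation test, FDR and the mechanism classification (Rubin-pooled
#' across imputations when imputation is on). Re-running with the same
#' config reproduces byte-identical result tables.
#'
#' @param config a `run_config` (see [default_run_config()]).
#' @return invisibly, a list with the results table, the mechanism table and
#'   the manifest path.
#' @export
run_pipeline <- function(config = default_run_config()) {
  assert_that(inherits(config, "run_config") || is.list(config),
              "config must be a run_config")
  out <- config$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  fac <- config$factor_name
  counts <- list()

  # -- simulate ------------------------------------------------------------
  scfg <- do.call(sim_config, modifyList(config$sim, list(seed = config$seed)))
  cohort <- simulate_trio_cohort(scfg)
  paths <- write_cohort(cohort, out)
  counts$n_trios <- scfg$n_trios
  counts$n_observed <- sum(cohort$observed_mask)
  message(sprintf("simulate: %d trios (%d with observed phenotype), %d SNPs",
                  counts$n_trios, counts$n_observed, scfg$n_snps))

  # -- score ---------------------------------------------------------------
  ss <- read_sumstats(paths[["sumstats"]])
  dos <- lapply(c(mother = "dosage_mother", father = "dosage_father",
                  child = "dosage_child"),
                function(k) read_dosage_raw(paths[[k]]))
  thr <- config$thresholds
  raw_all <- lapply(dos, compute_threshold_scores, sumstats = ss, thresholds = thr)
  pooled <- do.call(rbind, lapply(raw_all, function(x) x$raw_scores))
  comp <- prs_pc(pooled)
  n <- scfg$n_trios
  role_slice <- list(mother = 1:n, father = n + 1:n, child = 2 * n + 1:n)
  scores <- lapply(role_slice, function(i) comp$prspc[i])

  if (isTRUE(config$residualize_pcs)) {
    pcs <- compute_ancestry_pcs(do.call(rbind, dos), k = config$pca_k)
    scores <- lapply(names(scores), function(role) {
      i <- role_slice[[role]]
      residualize_standardize(scores[[role]],
                              as.data.frame(pcs[i, , drop = FALSE]))
    })
    names(scores) <- names(role_slice)
  }
  score_tab <- data.frame(trio_id = cohort$trio_id,
                          mother = scores$mother, father = scores$father,
                          child = scores$child)
  data.table::fwrite(score_tab, file.path(out, "scores.tsv"), sep = "\t")

  # -- phenotype / imputation ----------------------------------------------
  pheno <- read_phenotype(paths[["phenotype"]])
  outc <- score_items(pheno)
  counts$n_scored <- sum(!is.na(outc$total_z))
  M <- config$imputation$M %||% 0L
  aux_cols <- grep("^aux", names(pheno), value = TRUE)
  predictors <- cbind(score_tab[, c("mother", "father", "child")],
                      pheno[, aux_cols, drop = FALSE])

  frames <- if (M >= 2 && anyNA(outc$total_z)) {
    imp <- impute_outcomes(outc$total_z, predictors, M = M,
                           seed = derive_seed(config$seed, 7L))
    lapply(imp$imputations, function(y)
      trio_frame(y, setNames(list(list(child = scores$child,
                                       mother = scores$mother,
                                       father = scores$father)), fac),
                 pheno$sex, pheno$birth_year, cohort$trio_id))
  } else {
    keep <- !is.na(outc$total_z)
    if (!all(keep))
      message(sprintf("fit: complete-case analysis drops %d of %d trios",
                      sum(!keep), length(keep)))
    list(trio_frame(outc$total_z[keep],
                    setNames(list(lapply(scores, function(s) s[keep])), fac),
                    pheno$sex[keep], pheno$birth_year[keep],
                    cohort$trio_id[keep]))
  }
  counts$n_analyzed <- nrow(frames[[1]])
  counts$n_imputations <- length(frames)

  # -- fit -----------------------------------------------------------------
  roles <- c("child", "mother", "father")
  fit_one_frame <- function(fr) {
    un <- do.call(rbind, lapply(roles, function(r) fit_unadjusted(fr, fac, r)))
    tr <- fit_trio(fr, fac)
    list(un = un, tr = tr)
  }
  fits <- lapply(frames, fit_one_frame)
  pick <- function(which_model, role, field) vapply(fits, function(f)
    f[[which_model]][f[[which_model]]$role == role, field], numeric(1))

  pooled_row <- function(which_model, role) {
    if (length(fits) == 1) {
      f <- fits[[1]][[which_model]]
      f[f$role == role, c("beta", "se", "p")]
    } else {
      pr <- pool_rubin(lapply(fits, function(f) {
        row <- f[[which_model]][f[[which_model]]$role == role, ]
        list(estimate = setNames(row$beta, role), se = setNames(row$se, role),
             df_residual = row$n - 6)
      }))
      data.frame(beta = pr$estimate, se = pr$se, p = pr$p)
    }
  }
  res <- do.call(rbind, lapply(c("un", "tr"), function(mdl)
    do.call(rbind, lapply(roles, function(r) {
      pr <- pooled_row(mdl, r)
      data.frame(factor = fac, role = r,
                 model = if (mdl == "un") "unadjusted" else "trio",
                 beta = pr$beta, se = pr$se,
                 ci_low = pr$beta - 1.96 * pr$se,
                 ci_high = pr$beta + 1.96 * pr$se, p = pr$p,
                 n = counts$n_analyzed, stringsAsFactors = FALSE)
    }))))

  # attenuation test per parent; analytic per imputation pooled by Rubin,
  # seeded bootstrap when there is a single analysis frame
  dmethod <- if (length(frames) > 1) "analytic" else config$dbeta$method
  deltas <- do.call(rbind, lapply(c("mother", "father"), function(r) {
    per <- lapply(seq_along(frames), function(i)
      delta_beta(frames[[i]], fac, r, method = dmethod,
                 B = config$dbeta$B, seed = derive_seed(config$seed, 900L + i)))
    if (length(per) == 1) return(per[[1]])
    pr <- pool_rubin(lapply(per, function(d)
      list(estimate = setNames(d$delta, "delta"), se = setNames(d$se_delta, "delta"),
           df_residual = d$n - 6)))
    out1 <- per[[1]]
    out1$delta <- pr$estimate; out1$se_delta <- pr$se; out1$p_delta <- pr$p
    out1$ci_low <- pr$ci_low; out1$ci_high <- pr$ci_high
    out1$method <- paste0(dmethod, "+rubin")
    out1
  }))

  q <- config$fdr_q
  fdr_un <- bh_fdr(res$p[res$model == "unadjusted"], q)
  fdr_tr <- bh_fdr(res$p[res$model == "trio"], q)
  res$fdr_flag <- c(fdr_un, fdr_tr)

  mech <- do.call(rbind, lapply(c("mother", "father"), function(r) {
    un_row <- res[res$model == "unadjusted" & res$role == r, ]
    tr_row <- res[res$model == "trio" & res$role == r, ]
    d <- deltas[deltas$role == r, ]
    lab <- classify_mechanism(
      data.frame(factor = fac, role = r, p = un_row$p),
      data.frame(factor = fac, role = r, p = tr_row$p),
      d, fdr_unadjusted = un_row$fdr_flag, fdr_trio = tr_row$fdr_flag)
    data.frame(factor = fac, role = r, mechanism = lab,
               beta_unadjusted = d$beta_unadjusted,
               beta_adjusted = d$beta_adjusted, delta = d$delta,
               p_delta = d$p_delta, stringsAsFactors = FALSE)
  }))

  fmt <- function(df) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) signif(x, 10))
    df
  }
  data.table::fwrite(fmt(res), file.path(out, "results.tsv"), sep = "\t")
  data.table::fwrite(fmt(deltas), file.path(out, "delta_beta.tsv"), sep = "\t")
  data.table::fwrite(fmt(mech), file.path(out, "mechanisms.tsv"), sep = "\t")

  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  manifest <- list(
    package_version = as.character(packageVersion("trionurture")),
    config = unclass(config),
    config_md5 = unname(tools::md5sum(tmp)),
    seed = config$seed,
    counts = counts
  )
  unlink(tmp)
  manifest_path <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  message(sprintf("fit: analyzed %d trios; mechanisms: %s",
                  counts$n_analyzed,
                  paste(mech$role, "=", mech$mechanism, collapse = "; ")))
  invisible(list(results = res, delta_beta = deltas, mechanisms = mech,
                 manifest = manifest_path, scores = score_tab))
}
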