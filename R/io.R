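#' Write a simulated cohort to standard flat files
#'
#' Emits, under `dir`: one PLINK `.raw`-style dosage TSV per family role
#' (`dosage_mother.tsv`, `dosage_father.tsv`, `dosage_child.tsv`; columns
#' FID, IID, then `<variant>_<effect allele>`), a FAM-like pedigree TSV
#' (`pedigree.tsv`: family_id, child_id, father_id, mother_id, sex), a
#' phenotype CSV (`phenotype.csv`: trio_id, item01..item18, sex, birth_year,
#' auxiliaries) in which the continuous simulated phenotype has been mapped
#' onto 18 four-point items (see Details), and the noisy summary statistics
#' (`sumstats.tsv`: SNP, A1, A2, BETA, SE, P, FRQ).
#'
#' @details The generative model produces a continuous standardized trait;
#' item responses are derived by thresholding noisy item-level copies of it
#' into the 1-4 range so that item scoring (sums, prorating, exclusion)
#' can be exercised end-to-end. Trios whose phenotype is masked missing get
#' empty item cells.
#'
#' @param cohort a `trio_cohort`.
#' @param dir output directory (created if needed).
#' @param gwas_seed seed for the noisy sumstats written alongside.
#' @return invisibly, the named vector of written paths.
#' @export
write_cohort <- function(cohort, dir, gwas_seed = cohort$config$seed) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  panel <- cohort$panel
  paths <- c()

  raw_cols <- paste0(panel$variant_id, "_", panel$effect_allele)
  for (role in c("mother", "father", "child")) {
    d <- as.data.frame(cohort$dosage[[role]])
    names(d) <- raw_cols
    d <- cbind(FID = cohort$trio_id,
               IID = paste0(cohort$trio_id, "_", role), d)
    p <- file.path(dir, sprintf("dosage_%s.tsv", role))
    data.table::fwrite(d, p, sep = "\t")
    paths[paste0("dosage_", role)] <- p
  }

  ped <- data.frame(family_id = cohort$trio_id,
                    child_id = paste0(cohort$trio_id, "_child"),
                    father_id = paste0(cohort$trio_id, "_father"),
                    mother_id = paste0(cohort$trio_id, "_mother"),
                    sex = cohort$sex)
  paths["pedigree"] <- file.path(dir, "pedigree.tsv")
  data.table::fwrite(ped, paths["pedigree"], sep = "\t")

  items <- phenotype_to_items(cohort)
  pheno <- cbind(data.frame(trio_id = cohort$trio_id), items,
                 data.frame(sex = cohort$sex, birth_year = cohort$birth_year),
                 as.data.frame(cohort$auxiliaries))
  paths["phenotype"] <- file.path(dir, "phenotype.csv")
  data.table::fwrite(pheno, paths["phenotype"], sep = ",")

  ss <- make_noisy_sumstats(panel, cohort$config$gwas_n, seed = gwas_seed)
  paths["sumstats"] <- file.path(dir, "sumstats.tsv")
  data.table::fwrite(as.data.frame(ss)[, c("SNP", "A1", "A2", "BETA", "SE", "P", "FRQ")],
                     paths["sumstats"], sep = "\t")
  invisible(paths)
}

# map the continuous standardized phenotype onto 18 four-point items:
# item_j = cut(phenotype + item noise) into quartile-ish bins. Masked trios
# get all-NA items.
phenotype_to_items <- function(cohort) {
  set.seed(derive_seed(cohort$config$seed, 101L))
  n <- cohort$config$n_trios
  y <- as.numeric(cohort$phenotype)
  items <- matrix(NA_integer_, n, 18L,
                  dimnames = list(NULL, sprintf("item%02d", 1:18)))
  cuts <- c(-Inf, qnorm(c(0.55, 0.8, 0.93), sd = sqrt(2)), Inf)
  for (j in 1:18) {
    latent <- y + rnorm(n)
    items[, j] <- as.integer(cut(latent, cuts, labels = FALSE))
  }
  items[!cohort$observed_mask, ] <- NA_integer_
  as.data.frame(items)
}

#' Read a PLINK .raw-style dosage table
#'
#' @param path TSV with FID, IID then `<variant>_<counted allele>` columns.
#' @return numeric matrix (rownames = IID) with the `.raw` column names
#'   preserved, ready for [compute_threshold_scores()].
#' @export
read_dosage_raw <- function(path) {
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  d <- data.table::fread(path, sep = "\t", data.table = FALSE,
                         showProgress = FALSE)
  meta <- intersect(c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"), names(d))
  m <- as.matrix(d[, setdiff(names(d), meta), drop = FALSE])
  rownames(m) <- if ("IID" %in% names(d)) d$IID else NULL
  m
}

#' Read a pedigree TSV (family_id, child_id, father_id, mother_id, sex)
#' @param path file path.
#' @return data.frame with those columns.
#' @export
read_pedigree <- function(path) {
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  d <- data.table::fread(path, sep = "\t", data.table = FALSE,
                         showProgress = FALSE)
  need <- c("family_id", "child_id", "father_id", "mother_id")
  assert_that(all(need %in% names(d)),
              "pedigree must have family_id, child_id, father_id, mother_id")
  d
}

#' Read the phenotype CSV written by [write_cohort()]
#' @param path file path.
#' @return data.frame with trio_id, item columns, sex, birth_year, auxiliaries.
#' @export
read_phenotype <- function(path) {
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  data.table::fread(path, sep = ",", data.table = FALSE, showProgress = FALSE)
}

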