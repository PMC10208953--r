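#' Score the 18-item ADHD rating scale
#'
#' Computes the RS-DBD total (18 items, four-point scale 1-4, range 18-72)
#' and the inattention (items 1-9) and hyperactivity-impulsivity (items
#' 10-18) subscales (range 9-36 each). Respondents with fewer than half the
#' items completed (< 9 of 18) are flagged incomplete and get no total;
#' with 9-17 items the total is prorated as the person-mean of completed
#' items times 18 (disable with `prorate = FALSE` for strict complete-case
#' scoring). Subscales require at least 5 of 9 items, prorated analogously.
#'
#' @param items data.frame with columns `item01`..`item18` (values in
#'   \{1,2,3,4\} or NA); other columns are passed through untouched.
#' @param prorate prorate partially complete responses (default TRUE).
#' @return an `outcome_set` data.frame: any pass-through columns, then
#'   `n_completed`, `complete` (>= 9 items), `total`, `inattention`,
#'   `hyperactivity`, and standardized versions `total_z`,
#'   `inattention_z`, `hyperactivity_z` (computed over scored rows).
#' @export
score_items <- function(items, prorate = TRUE) {
  item_cols <- sprintf("item%02d", 1:18)
  assert_that(all(item_cols %in% names(items)),
              "items must contain columns item01..item18")
  X <- as.matrix(items[, item_cols])
  bad <- which(!is.na(X) & !(X %in% 1:4), arr.ind = TRUE)
  if (nrow(bad) > 0)
    tn_stop(sprintf("item value outside {1,2,3,4}: row %d, %s (value %s)",
                    bad[1, 1], item_cols[bad[1, 2]], X[bad[1, , drop = FALSE]]),
            "data_error")

  subscale <- function(M, n_items, min_items) {
    k <- rowSums(!is.na(M))
    out <- rep(NA_real_, nrow(M))
    full <- k == n_items
    out[full] <- rowSums(M[full, , drop = FALSE])
    if (prorate) {
      part <- k >= min_items & k < n_items
      out[part] <- rowMeans(M[part, , drop = FALSE], na.rm = TRUE) * n_items
    }
    out
  }

  out <- items[, setdiff(names(items), item_cols), drop = FALSE]
  out$n_completed <- rowSums(!is.na(X))
  out$complete <- out$n_completed >= 9L
  out$total <- subscale(X, 18L, 9L)
  out$total[!out$complete] <- NA_real_
  out$inattention <- subscale(X[, 1:9, drop = FALSE], 9L, 5L)
  out$hyperactivity <- subscale(X[, 10:18, drop = FALSE], 9L, 5L)

  zscore <- function(x) {
    obs <- !is.na(x)
    z <- rep(NA_real_, length(x))
    if (sum(obs) >= 2 && stats::sd(x[obs]) > 0)
      z[obs] <- (x[obs] - mean(x[obs])) / stats::sd(x[obs])
    z
  }
  out$total_z <- zscore(out$total)
  out$inattention_z <- zscore(out$inattention)
  out$hyperactivity_z <- zscore(out$hyperactivity)
  class(out) <- c("outcome_set", "data.frame")
  out
}
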