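#' Benjamini-Hochberg rejection set
#'
#' Standard step-up procedure at level `alpha` applied to a vector of
#' p-values (or v-values, which share the p-value property under
#' leave-one-out or block-out censoring).
#'
#' @param v Numeric vector in (0, 1].
#' @param alpha Target FDR level in (0, 1).
#' @return A logical rejection vector.
#' @examples
#' bh_reject(c(0.01, 0.02, 0.04, 0.5), 0.05)
#' @export
bh_reject <- function(v, alpha) {
  check_prob(v, "v")
  if (length(alpha) != 1 || !is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be a single value in (0, 1).")
  }
  p.adjust(v, method = "BH") <= alpha
}

#' Sidak threshold for family-wise error control
#'
#' Rejection at `v_i <= 1 - (1 - alpha)^(1/n)` controls the FWER at `alpha`
#' for independent tests; for small `alpha` the threshold approaches the
#' Bonferroni value `alpha / n`.
#'
#' @param alpha FWER level in (0, 1).
#' @param n Number of tests (a positive integer).
#' @return The per-test threshold.
#' @export
sidak_threshold <- function(alpha, n) {
  if (length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be a single value in (0, 1).")
  }
  if (length(n) != 1 || n < 1 || n != round(n)) {
    abort("`n` must be a positive integer.")
  }
  1 - (1 - alpha)^(1 / n)
}

#' Realised false- and true-discovery proportions
#'
#' Scores one rejection set against known truth. With no rejections both
#' proportions are 0 by convention; with no non-null hypotheses the TDP is
#' undefined and reported as `NA` so that benchmark averages exclude it.
#'
#' @param rejected Logical rejection vector.
#' @param is_null Logical vector: is each hypothesis null (for the
#'   principal study)?
#' @return A one-row tibble with columns `fdp`, `tdp`, `n_reject`.
#' @examples
#' fdp_tdp(c(TRUE, TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE, FALSE))
#' @export
fdp_tdp <- function(rejected, is_null) {
  if (length(rejected) != length(is_null)) {
    abort("`rejected` and `is_null` must have equal length.")
  }
  nr <- sum(rejected)
  n_nonnull <- sum(!is_null)
  fdp <- if (nr == 0) 0 else sum(rejected & is_null) / nr
  tdp <- if (n_nonnull == 0) NA_real_
         else if (nr == 0) 0
         else sum(rejected & !is_null) / n_nonnull
  tibble(fdp = fdp, tdp = tdp, n_reject = nr)
}
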