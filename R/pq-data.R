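#' Validate a table of bivariate p-values
#'
#' The input to every cFDR computation is a table with one row per hypothesis
#' and two p-value columns: `p` for the principal study (the one being
#' tested) and `q` for the conditional study (the covariate). An optional
#' `fold` column assigns each row to a block for block-out censoring, and an
#' optional `id` column carries record identifiers.
#'
#' Both p-value columns must lie in (0, 1]. Exact zeros break the open-ended
#' domain of the ECDF estimators, so they are clamped to the smallest
#' positive double with a warning rather than rejected.
#'
#' @param data A data frame with numeric columns `p` and `q`, and optionally
#'   `fold` (block labels) and `id`.
#' @return A tibble with columns `id`, `p`, `q` (and `fold` if supplied),
#'   validated and with zero p-values clamped.
#' @examples
#' as_pq_data(data.frame(p = c(0.01, 0.5), q = c(0.2, 0.9)))
#' @export
as_pq_data <- function(data) {
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame with columns `p` and `q`.")
  }
  missing_cols <- setdiff(c("p", "q"), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("`data` is missing required column(s): ",
                 paste0("`", missing_cols, "`", collapse = ", "), "."))
  }
  out <- as_tibble(data)
  if (!is.numeric(out$p) || !is.numeric(out$q)) {
    abort("Columns `p` and `q` must be numeric.")
  }
  if (anyNA(out$p) || anyNA(out$q)) {
    abort("`p` and `q` must not contain missing values; drop or impute first.")
  }
  for (col in c("p", "q")) {
    x <- out[[col]]
    if (any(x < 0) || any(x > 1)) {
      abort(paste0("Column `", col, "` must lie in (0, 1]."))
    }
    nzero <- sum(x == 0)
    if (nzero > 0) {
      warn(paste0(nzero, " zero value(s) in `", col,
                  "` clamped to the smallest positive double."))
      x[x == 0] <- .Machine$double.xmin
      out[[col]] <- x
    }
  }
  if (!is.null(out[["fold"]])) {
    fold <- out$fold
    if (anyNA(fold)) abort("`fold` must not contain missing values.")
    tab <- table(fold)
    if (any(tab == 0) || length(tab) < 1) {
      abort("Every fold must be non-empty.")
    }
  }
  if (is.null(out[["id"]])) {
    out$id <- seq_len(nrow(out))
  }
  cols <- intersect(c("id", "p", "q", "fold"), names(out))
  out[, c(cols, setdiff(names(out), cols))]
}

# internal: check a vector of query p-values/levels lies in (0, 1]
check_prob <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x <= 0) || any(x > 1)) {
    abort(paste0("`", name, "` must lie in (0, 1]."))
  }
  invisible(x)
}
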