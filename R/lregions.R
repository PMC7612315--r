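#' Build the L-curve at a given level
#'
#' The L-region at level `alpha` is the sub-level set
#' `\{(p, q): cfdr_t(p, q) <= alpha\}` of the monotonised estimator, with the
#' moving evaluation point added to the defining set (so the region is
#' defined on the whole unit square). Its right boundary, the L-curve, is a
#' step function over q-strata delimited by the distinct observed `q_i`
#' (plus 0 and 1); within each stratum the boundary is solved analytically
#' on each inter-order-statistic interval of the relevant p-values, making
#' the construction exact rather than a raster approximation.
#'
#' L-regions are nested: `alpha1 <= alpha2` implies
#' `L(alpha1)` is contained in `L(alpha2)` stratum-wise.
#'
#' @param X A data frame validated by [as_pq_data()]; must be non-empty.
#' @param alpha Level in (0, 1].
#' @param adjusted Use the adjusted estimator (multiply by
#'   [h0q_adjustment()] computed from `X`)?
#' @param include_test_point Add the moving point to the ECDF counts
#'   (default `TRUE`, the convention used for v-values)?
#' @return A tibble of class `cfdr_lcurve` with columns `q_lo`, `q_hi`,
#'   `p_bound`, and attributes `alpha` and `source_size`.
#' @examples
#' X <- data.frame(p = runif(20), q = runif(20))
#' build_lcurve(X, 0.1)
#' @export
build_lcurve <- function(X, alpha, adjusted = FALSE,
                         include_test_point = TRUE) {
  if (length(alpha) != 1 || !is.finite(alpha) || alpha <= 0 || alpha > 1) {
    abort("`alpha` must be a single value in (0, 1].")
  }
  X <- as_pq_data(X)
  if (nrow(X) == 0) abort("`X` must be non-empty.")
  qs <- sort(unique(X$q))
  pb <- cpp_lcurve(X$p, X$q, alpha, include_test_point, adjusted)
  out <- tibble(q_lo = c(0, qs), q_hi = c(qs, 1), p_bound = as.numeric(pb))
  # the final break is 1; if max(q) == 1 the last stratum is degenerate
  out <- out[out$q_hi > out$q_lo, ]
  structure(out, class = c("cfdr_lcurve", class(out)),
            alpha = alpha, source_size = nrow(X))
}

#' v-value for a single test point
#'
#' Finds the smallest level `c` whose L-region (defined by the leave-out set
#' `X_leaveout`) contains `(p, q)`, then integrates the fitted null density
#' over that region. The resulting v-value is the probability, under the
#' null model, that a random pair falls in the smallest L-region containing
#' the point -- a quantity that behaves as a p-value.
#'
#' @param X_leaveout The defining set, excluding the test point (and its
#'   block, in block-out mode). May be empty, in which case the count guards
#'   give `c = p` and `v = p`.
#' @param p,q The test point, each in (0, 1].
#' @param model A `cfdr_null_model`.
#' @param adjusted Use the adjusted estimator?
#' @return A list with elements `v` and `c`.
#' @export
vvalue_for_point <- function(X_leaveout, p, q, model, adjusted = FALSE) {
  check_prob(p, "p")
  check_prob(q, "q")
  if (nrow(X_leaveout) == 0) {
    return(list(v = p, c = p))
  }
  cc <- cfdr_t(X_leaveout, p, q, adjusted = adjusted,
               include_test_point = TRUE)
  if (cc == 0) {
    # sub-level set at level 0 of a nonnegative statistic: strata where the
    # adjustment vanishes are fully included, everything else is empty
    region <- build_lcurve(X_leaveout, .Machine$double.xmin,
                           adjusted = adjusted)
    region$p_bound[region$p_bound < 1] <- 0
    v <- integrate_f0(region, model)
  } else {
    region <- build_lcurve(X_leaveout, min(cc, 1), adjusted = adjusted)
    v <- integrate_f0(region, model)
  }
  list(v = min(max(v, .Machine$double.xmin), 1), c = cc)
}

#' Transform p-value pairs into v-values
#'
#' The main entry point: runs the full pipeline on a table of
#' principal/conditional p-value pairs. For each record the minimal level
#' `c_i` putting `(p_i, q_i)` on an L-curve is found, and the fitted null
#' density is integrated over that L-region to give a v-value. Under
#' leave-one-out (`"loo"`) or block-out (`"lob"`) censoring the region map
#' for record `i` is built without record `i` (or its whole fold), so each
#' v-value behaves as a p-value and the set can be passed to
#' [bh_reject()] or compared against [sidak_threshold()]. The `"naive"` mode
#' keeps every record in its own map; it is anti-conservative and provided
#' for comparison only.
#'
#' @param data A data frame with columns `p` and `q` (see [as_pq_data()]);
#'   for `mode = "lob"` an optional `fold` column assigns blocks, and if
#'   absent the records are split into `nfolds` random equal folds (set the
#'   RNG seed for reproducibility).
#' @param mode Censoring scheme: `"loo"` (leave-one-out, default), `"lob"`
#'   (block-out), or `"naive"`.
#' @param adjusted Use the adjusted estimator (default `TRUE`)? Falls back
#'   to unadjusted with a warning if no record has `p > 1/2`.
#' @param null_model A `cfdr_null_model`; fitted by [fit_null_em()] on
#'   `data` when `NULL`.
#' @param nfolds Number of random folds when `mode = "lob"` and no `fold`
#'   column is present.
#' @return A tibble of class `cfdr_vvalues` with the input columns plus `c`
#'   (minimal level) and `v` (v-value), and attributes `mode`, `adjusted`
#'   and `null_model`.
#' @examples
#' set.seed(1)
#' d <- data.frame(p = runif(100), q = runif(100))
#' res <- cfdr_vvalues(d, mode = "loo")
#' head(res)
#' @export
cfdr_vvalues <- function(data, mode = c("loo", "lob", "naive"),
                         adjusted = TRUE, null_model = NULL, nfolds = 3) {
  mode <- match.arg(mode)
  X <- as_pq_data(data)
  n <- nrow(X)
  if (n == 0) abort("`data` must be non-empty.")
  if (adjusted && sum(X$p > 0.5) == 0) {
    warn("No records with p > 1/2; falling back to the unadjusted estimator.")
    adjusted <- FALSE
  }
  if (is.null(null_model)) null_model <- fit_null_em(X)
  if (mode == "lob" && is.null(X[["fold"]])) {
    X$fold <- sample(rep_len(seq_len(nfolds), n))
  }

  if (mode == "loo" && n == 1) {
    out <- X
    out$c <- X$p
    out$v <- X$p
  } else if (mode %in% c("loo", "naive")) {
    rs <- mode == "loo"
    cc <- cpp_cvalues(X$p, X$q, X$p, X$q,
                      remove_self = rs, augment = TRUE, adjusted = adjusted)
    dF <- strata_deltaF(X$q, null_model)
    v <- cpp_vsweep(X$p, X$q, X$p, X$q, cc, dF,
                    remove_self = rs, adjusted = adjusted)
    out <- X
    out$c <- cc
    out$v <- pmin(pmax(v, .Machine$double.xmin), 1)
  } else {
    out <- X
    out$c <- NA_real_
    out$v <- NA_real_
    for (b in unique(X$fold)) {
      inb <- X$fold == b
      D <- X[!inb, ]
      if (nrow(D) == 0) {
        # degenerate single-fold case: empty leave-out set
        out$c[inb] <- X$p[inb]
        out$v[inb] <- X$p[inb]
        next
      }
      adj_b <- adjusted
      if (adj_b && sum(D$p > 0.5) == 0) {
        warn(paste0("Fold ", b, ": leave-out set has no p > 1/2; ",
                    "unadjusted estimator used for this fold."))
        adj_b <- FALSE
      }
      cc <- cpp_cvalues(D$p, D$q, X$p[inb], X$q[inb],
                        remove_self = FALSE, augment = TRUE,
                        adjusted = adj_b)
      dF <- strata_deltaF(D$q, null_model)
      v <- cpp_vsweep(D$p, D$q, X$p[inb], X$q[inb], cc, dF,
                      remove_self = FALSE, adjusted = adj_b)
      out$c[inb] <- cc
      out$v[inb] <- pmin(pmax(v, .Machine$double.xmin), 1)
    }
  }
  structure(out, class = c("cfdr_vvalues", class(tibble())),
            mode = mode, adjusted = adjusted, null_model = null_model)
}

#' v-values for arbitrary test points against a fixed reference map
#'
#' Evaluates the v-value map defined by a fixed set `X` at new points that
#' are not part of `X` (no censoring is needed because the points carry no
#' influence on the map). Useful for scoring new observations against an
#' established reference set and for studying the stability of the map.
#'
#' @param X The defining set (a data frame with columns `p`, `q`).
#' @param points A data frame with columns `p`, `q` of test points.
#' @param model A `cfdr_null_model`; fitted on `X` when `NULL`.
#' @param adjusted Use the adjusted estimator?
#' @return A tibble: `points` plus columns `c` and `v`.
#' @export
cfdr_vvalues_at <- function(X, points, model = NULL, adjusted = TRUE) {
  X <- as_pq_data(X)
  pts <- as_pq_data(points)
  if (nrow(X) == 0) abort("`X` must be non-empty.")
  if (is.null(model)) model <- fit_null_em(X)
  cc <- cpp_cvalues(X$p, X$q, pts$p, pts$q,
                    remove_self = FALSE, augment = TRUE, adjusted = adjusted)
  dF <- strata_deltaF(X$q, model)
  v <- cpp_vsweep(X$p, X$q, pts$p, pts$q, cc, dF,
                  remove_self = FALSE, adjusted = adjusted)
  pts$c <- cc
  pts$v <- pmin(pmax(v, .Machine$double.xmin), 1)
  pts
}

# f0 q-marginal mass of each stratum delimited by (0, distinct sorted q, 1)
strata_deltaF <- function(q, model) {
  qs <- sort(unique(q))
  Fb <- F0q_cdf(c(0, qs, 1), model)
  diff(Fb)
}

#' @export
glance.cfdr_vvalues <- function(x, ...) {
  m <- attr(x, "null_model")
  tibble(n = nrow(x), mode = attr(x, "mode"),
         adjusted = attr(x, "adjusted"),
         pi0 = m$pi0, sigma0 = m$sigma0, em_converged = m$converged)
}
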