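#' ECDF estimator of the conditional false discovery rate
#'
#' Estimates `cFDR(p, q) = Pr(H0 for the principal study | P <= p, Q <= q)`
#' from the bivariate ECDF of the observed pairs:
#' `p * max(#\{q_i <= q\}, 1) / max(#\{p_i <= p, q_i <= q\}, 1)`.
#' The estimate is always at least `p`, and with `q = 1` (all conditional
#' p-values included) it reduces to the Benjamini-Hochberg statistic
#' `p * n / #\{p_i <= p\}`.
#'
#' @param X A data frame of observed pairs, validated by [as_pq_data()]. May
#'   be empty, in which case both count guards engage and the estimate is
#'   `p`.
#' @param p,q Numeric vectors of query points in (0, 1], recycled to a
#'   common length.
#' @return A numeric vector of cFDR estimates.
#' @examples
#' X <- data.frame(p = c(0.1, 0.6, 0.05, 0.9), q = c(0.2, 0.8, 0.3, 0.9))
#' cfdr_hat(X, 0.1, 0.3)
#' @seealso [cfdr_hat_adjusted()], [cfdr_t()]
#' @export
cfdr_hat <- function(X, p, q) {
  check_prob(p, "p")
  check_prob(q, "q")
  k <- vctrs_recycle2(p, q)
  p <- k$x; q <- k$y
  if (nrow(X) == 0) return(p)
  X <- as_pq_data(X)
  nq <- vapply(q, function(qq) sum(X$q <= qq), numeric(1))
  npq <- mapply(function(pp, qq) sum(X$p <= pp & X$q <= qq), p, q)
  p * pmax(nq, 1) / pmax(npq, 1)
}

#' ECDF estimate of Pr(H0 | Q <= q)
#'
#' The plain cFDR estimator conservatively approximates
#' `Pr(H0 | Q <= q) = 1`. This factor sharpens the approximation using the
#' observations with `p_i > 1/2` as a proxy for the principal-null
#' population: the ECDF of Q restricted to that proxy, relative to the
#' overall ECDF of Q, capped at 1 (with `pi0` taken as 1, which uniformly
#' scales all estimates and does not change rejection orderings). Every
#' count carries a zero-count guard `max(1, .)` so the factor is always
#' positive and finite.
#'
#' @inheritParams cfdr_hat
#' @param q Numeric vector of thresholds in (0, 1].
#' @return A numeric vector of probabilities; exactly 1 at `q = 1`.
#' @examples
#' X <- data.frame(p = c(0.6, 0.7, 0.3, 0.8), q = c(0.2, 0.9, 0.1, 0.5))
#' h0q_adjustment(X, 0.5)  # (2/3) / (3/4) = 8/9
#' @export
h0q_adjustment <- function(X, q) {
  check_prob(q, "q")
  X <- as_pq_data(X)
  if (nrow(X) == 0) abort("`X` must be non-empty.")
  b <- sum(X$p > 0.5)
  if (b == 0) {
    abort(paste0("No observations with p > 1/2: the null-proxy adjustment ",
                 "is undefined. Use the unadjusted estimator."))
  }
  n <- nrow(X)
  a <- vapply(q, function(qq) sum(X$q <= qq & X$p > 0.5), numeric(1))
  nq <- vapply(q, function(qq) sum(X$q <= qq), numeric(1))
  pmin(1, (pmax(a, 1) / pmax(b, 1)) / (pmax(nq, 1) / n))
}

#' Adjusted ECDF estimator of the cFDR
#'
#' The product of [cfdr_hat()] and [h0q_adjustment()]; never larger than the
#' unadjusted estimate, and equal to it at `q = 1`.
#'
#' @inheritParams cfdr_hat
#' @return A numeric vector of adjusted cFDR estimates.
#' @export
cfdr_hat_adjusted <- function(X, p, q) {
  cfdr_hat(X, p, q) * h0q_adjustment(X, q)
}

#' Monotonised cFDR estimator
#'
#' The raw estimator need not increase with `p` at fixed `q`, which would
#' let a rejection region exclude points dominated by rejected ones.
#' `cfdr_t` takes the minimum of the estimator over thresholds `p' >= p`,
#' yielding a statistic non-decreasing in `p`; its sub-level sets are the
#' L-regions used throughout the package. With `include_test_point = TRUE`
#' the moving evaluation point `(p', q)` is added to `X` before counting,
#' which extends the definition to the whole unit square (the map used for
#' v-values); the adjustment factor, when requested, is always computed from
#' `X` alone.
#'
#' Between consecutive order statistics of the relevant p-values the
#' estimator is linear in `p'`, so the minimum is attained either at `p`
#' itself or at a data point; only those candidates are searched.
#'
#' @inheritParams cfdr_hat
#' @param adjusted Multiply by the [h0q_adjustment()] factor?
#' @param include_test_point Add the moving point `(p', q)` to the counts?
#' @return A numeric vector of monotonised cFDR values.
#' @examples
#' X <- data.frame(p = c(0.01, 0.02, 0.9), q = c(1, 1, 1))
#' cfdr_t(X, 0.015, 1)  # 0.03: minimum attained at p' = 0.02
#' @export
cfdr_t <- function(X, p, q, adjusted = FALSE, include_test_point = FALSE) {
  check_prob(p, "p")
  check_prob(q, "q")
  k <- vctrs_recycle2(p, q)
  p <- k$x; q <- k$y
  X <- as_pq_data(X)
  n <- nrow(X)
  ag <- as.integer(include_test_point)
  b <- sum(X$p > 0.5)
  out <- numeric(length(p))
  for (i in seq_along(p)) {
    pp <- p[i]; qq <- q[i]
    inq <- X$q <= qq
    adj <- 1
    if (adjusted) {
      # same zero-count guards as h0q_adjustment (but without its hard
      # error when no observation has p > 1/2)
      a <- sum(inq & X$p > 0.5)
      adj <- min(1, (max(a, 1) / max(b, 1)) / (max(sum(inq), 1) / n))
    }
    N <- max(sum(inq) + ag, 1)
    cand <- c(pp, X$p[inq & X$p >= pp])
    D <- vapply(cand, function(pc) sum(X$p[inq] <= pc), numeric(1)) + ag
    out[i] <- min(cand * N / pmax(D, 1) * adj)
  }
  out
}

# recycle two vectors to a common length
vctrs_recycle2 <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx == ny) return(list(x = x, y = y))
  if (nx == 1) return(list(x = rep(x, ny), y = y))
  if (ny == 1) return(list(x = x, y = rep(y, nx)))
  abort("`p` and `q` must have equal length (or length 1).")
}
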