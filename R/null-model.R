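#' Fit the mixture-Gaussian null for the covariate by EM
#'
#' Under the principal null, the covariate z-score `z = -qnorm(q/2)` is
#' modelled as a two-component folded-Gaussian mixture: `|N(0,1)|` with
#' probability `pi0` (covariate also null) and `|N(0, sigma0^2)|` with
#' probability `1 - pi0` (covariate associated). The fit uses only records
#' with `p_i > 1/2`, a proxy for the principal-null population, and
#' maximises the observed-data likelihood by expectation-maximisation.
#'
#' `sigma0` is floored at 1 so the non-null component is at least as
#' dispersed as the null; `q = 1` maps to `z = 0` and is retained.
#'
#' @param X A data frame validated by [as_pq_data()].
#' @param m_min Minimum number of usable records (`p_i > 1/2`); default 30.
#' @param init Starting values, a list with elements `pi0` and `sigma0`.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations. Non-convergence is reported via
#'   the `converged` flag; the last iterate is still returned.
#' @return An object of class `cfdr_null_model` with fields `pi0`, `sigma0`,
#'   `n_fit`, `converged`, `loglik`, `iterations`.
#' @examples
#' set.seed(1)
#' X <- data.frame(p = runif(500), q = runif(500))
#' fit_null_em(X)
#' @export
fit_null_em <- function(X, m_min = 30, init = list(pi0 = 0.75, sigma0 = 2),
                        tol = 1e-6, max_iter = 1000) {
  X <- as_pq_data(X)
  z <- -qnorm(X$q[X$p > 0.5] / 2)
  if (length(z) < m_min) {
    abort(paste0("Only ", length(z), " records with p > 1/2; at least ",
                 m_min, " are required to fit the null model."))
  }
  pi0 <- init$pi0
  sigma0 <- max(init$sigma0, 1)
  # folded densities on z >= 0: 2 * dnorm(z, sd = sigma)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0
  repeat {
    iter <- iter + 1
    d1 <- 2 * dnorm(z)
    d2 <- 2 * dnorm(z, sd = sigma0)
    num <- pi0 * d1
    den <- num + (1 - pi0) * d2
    den[den == 0] <- .Machine$double.xmin
    r1 <- num / den
    ll <- sum(log(den))
    pi0 <- mean(r1)
    w2 <- sum(1 - r1)
    sigma0 <- if (w2 > 0) max(1, sqrt(sum((1 - r1) * z^2) / w2)) else 1
    if (is.finite(ll_old) &&
        abs(ll - ll_old) <= tol * (abs(ll_old) + tol)) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    ll_old <- ll
  }
  structure(
    list(pi0 = pi0, sigma0 = sigma0, n_fit = length(z),
         converged = converged, loglik = ll, iterations = iter),
    class = "cfdr_null_model"
  )
}

#' Construct a uniform null model
#'
#' The null model with `pi0 = 1` (or equivalently `sigma0 = 1`), under which
#' the covariate is uniform given the principal null and v-values reduce to
#' Lebesgue areas of L-regions. Useful as a fallback when the EM fit is not
#' possible and in analytic tests.
#'
#' @return A `cfdr_null_model` object.
#' @export
null_model_uniform <- function() {
  structure(
    list(pi0 = 1, sigma0 = 1, n_fit = 0L, converged = TRUE,
         loglik = NA_real_, iterations = 0L),
    class = "cfdr_null_model"
  )
}

#' @export
print.cfdr_null_model <- function(x, ...) {
  cat("Mixture-Gaussian covariate null (fit on records with p > 1/2)\n")
  cat(sprintf("  pi0 = %.4f, sigma0 = %.4f  (n_fit = %d, %s, %d iterations)\n",
              x$pi0, x$sigma0, x$n_fit,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  invisible(x)
}

#' @export
tidy.cfdr_null_model <- function(x, ...) {
  tibble(term = c("pi0", "sigma0"), estimate = c(x$pi0, x$sigma0))
}

#' @export
glance.cfdr_null_model <- function(x, ...) {
  tibble(pi0 = x$pi0, sigma0 = x$sigma0, n_fit = x$n_fit,
         converged = x$converged, loglik = x$loglik,
         iterations = x$iterations)
}

#' Density of the covariate under the principal null
#'
#' `f0q(q) = pi0 + (1 - pi0) * dnorm(qnorm(q/2), sd = sigma0) /
#' dnorm(qnorm(q/2))`, the q-marginal density of the fitted null (the
#' derivative of [F0q_cdf()]); the p-coordinate density is 1 (uniform) by
#' assumption.
#'
#' @param q Numeric vector in (0, 1) (open: the density is evaluated
#'   pointwise and the endpoints are excluded).
#' @param model A `cfdr_null_model`.
#' @return Density values.
#' @export
f0q_density <- function(q, model) {
  if (any(q <= 0) || any(q >= 1)) abort("`q` must lie strictly in (0, 1).")
  z <- qnorm(q / 2)
  model$pi0 + (1 - model$pi0) * dnorm(z, sd = model$sigma0) / dnorm(z)
}

#' Marginal CDF of the covariate under the principal null
#'
#' `F0q(q) = pi0 * q + (1 - pi0) * 2 * pnorm(qnorm(q/2) / sigma0)`. Equals
#' `q` when `sigma0 = 1` or `pi0 = 1`, and satisfies `F0q(0) = 0`,
#' `F0q(1) = 1`.
#'
#' @param q Numeric vector in \[0, 1\].
#' @param model A `cfdr_null_model`.
#' @return CDF values in \[0, 1\].
#' @export
F0q_cdf <- function(q, model) {
  if (any(q < 0) || any(q > 1)) abort("`q` must lie in [0, 1].")
  out <- model$pi0 * q + (1 - model$pi0) * 2 * pnorm(qnorm(q / 2) / model$sigma0)
  out[q == 0] <- 0
  out[q == 1] <- 1
  out
}

#' Integrate the fitted null density over a step region
#'
#' A step region is a union of rectangles `[0, p_bound_j] x [q_j, q_{j+1})`
#' over a partition of the q-axis. Because the p-marginal of the null is
#' uniform, the integral is exactly
#' `sum_j p_bound_j * (F0q(q_{j+1}) - F0q(q_j))`.
#'
#' @param region A data frame with columns `q_lo`, `q_hi`, `p_bound`
#'   describing consecutive strata: `q_lo` must start at 0, `q_hi` end at 1,
#'   strata must be contiguous and `p_bound` must lie in \[0, 1\]. The
#'   `cfdr_lcurve` objects returned by [build_lcurve()] have this form.
#' @param model A `cfdr_null_model`.
#' @return The integral, a probability in \[0, 1\].
#' @examples
#' reg <- data.frame(q_lo = c(0, 0.5), q_hi = c(0.5, 1),
#'                   p_bound = c(0.2, 0.1))
#' integrate_f0(reg, null_model_uniform())  # 0.15
#' @export
integrate_f0 <- function(region, model) {
  region <- as.data.frame(region)
  need <- c("q_lo", "q_hi", "p_bound")
  if (!all(need %in% names(region))) {
    abort("`region` must have columns `q_lo`, `q_hi`, `p_bound`.")
  }
  qlo <- region$q_lo; qhi <- region$q_hi; pb <- region$p_bound
  ok <- nrow(region) >= 1 && qlo[1] == 0 && qhi[length(qhi)] == 1 &&
    all(qhi > qlo) && all(pb >= 0) && all(pb <= 1) &&
    (nrow(region) == 1 || all(qlo[-1] == qhi[-length(qhi)]))
  if (!ok) abort("Malformed step region.")
  sum(pb * (F0q_cdf(qhi, model) - F0q_cdf(qlo, model)))
}
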