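#' Draw simulation parameters from the study design
#'
#' Parameters are drawn from the joint distribution used throughout the
#' simulation study: `n = round(10^U(3,4))` hypotheses split into four
#' classes of fixed size (`n1pq` associated with both studies, `n1p` with
#' the principal only, `n1q` with the covariate only, the rest with
#' neither), class sizes `~ round(U(0, 200))`, alternative scale factors
#' `sp, sq ~ U(3/2, 3)`, and an alternative family `d` drawn uniformly from
#' normal (1), t with 3 df (2) and Cauchy (3).
#'
#' @param n_draws Number of parameter vectors to draw.
#' @param null_only If `TRUE`, condition on `n1p + n1pq = 0` (no principal
#'   associations), the null-conditioned stream used to audit FDR control.
#' @param rho,corr_mode,n_blocks Correlation level, structure (`"none"`,
#'   `"block"`, `"equicorrelation"`) and number of blocks, applied to all
#'   draws.
#' @return A tibble with one row per draw.
#' @examples
#' set.seed(1)
#' sample_sim_params(3)
#' @export
sample_sim_params <- function(n_draws = 1, null_only = FALSE, rho = 0,
                              corr_mode = c("none", "block",
                                            "equicorrelation"),
                              n_blocks = 3) {
  corr_mode <- match.arg(corr_mode)
  n1pq <- round(runif(n_draws, 0, 200))
  n1p <- round(runif(n_draws, 0, 200))
  if (null_only) {
    n1pq <- rep(0, n_draws)
    n1p <- rep(0, n_draws)
  }
  tibble(
    n = round(10^runif(n_draws, 3, 4)),
    n1pq = n1pq,
    n1p = n1p,
    n1q = round(runif(n_draws, 0, 200)),
    sp = runif(n_draws, 3 / 2, 3),
    sq = runif(n_draws, 3 / 2, 3),
    d = sample(1:3, n_draws, replace = TRUE),
    rho = rho,
    corr_mode = corr_mode,
    n_blocks = n_blocks
  )
}

#' Reference parameter sets for the fixed-scenario benchmarks
#'
#' `"reference"`: n = 5000, all three association classes of size 100,
#' sp = sq = 2, t(3 df) alternatives, independent observations.
#' `"negative_information"`: the same but with disjoint association sets of
#' size 2000 for each study (`n1p = n1q = 2000`, `n1pq = 0`), so the
#' covariate carries fewer-than-random shared associations.
#'
#' @param preset One of `"reference"`, `"negative_information"`.
#' @return A one-row parameter tibble as from [sample_sim_params()].
#' @export
sim_params_preset <- function(preset = c("reference",
                                         "negative_information")) {
  preset <- match.arg(preset)
  if (preset == "reference") {
    tibble(n = 5000, n1pq = 100, n1p = 100, n1q = 100, sp = 2, sq = 2,
           d = 2, rho = 0, corr_mode = "none", n_blocks = 3)
  } else {
    tibble(n = 5000, n1pq = 0, n1p = 2000, n1q = 2000, sp = 2, sq = 2,
           d = 2, rho = 0, corr_mode = "none", n_blocks = 3)
  }
}

# z-scores for one coordinate of one class group, with optional
# within-group dependence via a one-factor construction; for t/Cauchy
# alternatives the dependence enters the multivariate-t way (correlated
# normals over a shared chi-square divisor), so rho is the off-diagonal of
# the normalised dependence matrix
sim_z <- function(m, scale, d, rho = 0, group = NULL) {
  if (m == 0) return(numeric(0))
  if (rho == 0 || is.null(group)) {
    z0 <- rnorm(m)
  } else {
    w <- rnorm(length(unique(group)))
    names(w) <- as.character(unique(group))
    z0 <- sqrt(rho) * w[as.character(group)] + sqrt(1 - rho) * rnorm(m)
    names(z0) <- NULL
  }
  if (d == 1) return(scale * z0)
  df <- if (d == 2) 3 else 1
  if (rho == 0 || is.null(group)) {
    denom <- sqrt(rchisq(m, df) / df)
  } else {
    cg <- rchisq(length(unique(group)), df) / df
    names(cg) <- as.character(unique(group))
    denom <- sqrt(cg[as.character(group)])
    names(denom) <- NULL
  }
  scale * z0 / denom
}

#' Simulate a dataset of bivariate p-values
#'
#' Generates one dataset under a parameter vector: hypotheses are split
#' into the four association classes; associated coordinates get z-scores
#' `z = s * T` with `T` standard normal, t(3 df) or Cauchy according to
#' `d`, null coordinates get standard-normal z-scores, and all p-values are
#' computed as `p = 2 * pnorm(-|z|)` (so null p-values are exactly
#' uniform). Under `corr_mode = "block"` z-scores are correlated at level
#' `rho` within block-and-class groups (blocks split the indices into
#' `n_blocks` contiguous equal parts); under `"equicorrelation"` the groups
#' are the classes themselves.
#'
#' @param params A one-row data frame as produced by [sample_sim_params()]
#'   or [sim_params_preset()], or a list with the same fields.
#' @return A tibble with columns `id`, `p`, `q`, `fold` (the block),
#'   `class` (`"c1"` both, `"c2"` principal-only, `"c3"` covariate-only,
#'   `"c4"` neither), `is_null_p`, `is_null_q`.
#' @examples
#' set.seed(1)
#' d <- simulate_dataset(sim_params_preset("reference"))
#' table(d$class)
#' @export
simulate_dataset <- function(params) {
  pr <- as.list(as.data.frame(params)[1, ])
  n <- pr$n
  sizes <- c(c1 = pr$n1pq, c2 = pr$n1p, c3 = pr$n1q)
  if (any(sizes < 0) || sum(sizes) > n) {
    abort("Class sizes must be nonnegative with n1pq + n1p + n1q <= n.")
  }
  sizes <- c(sizes, c4 = n - sum(sizes))
  cls <- rep(names(sizes), sizes)
  rho <- if (is.null(pr$rho)) 0 else pr$rho
  corr_mode <- if (is.null(pr$corr_mode)) "none" else pr$corr_mode
  n_blocks <- if (is.null(pr$n_blocks)) 3 else pr$n_blocks
  block <- rep(seq_len(n_blocks), each = ceiling(n / n_blocks),
               length.out = n)
  group <- switch(corr_mode,
    none = NULL,
    block = paste(block, cls, sep = "."),
    equicorrelation = cls
  )
  rho_eff <- if (corr_mode == "none") 0 else rho
  zp <- numeric(n)
  zq <- numeric(n)
  assoc_p <- cls %in% c("c1", "c2")
  assoc_q <- cls %in% c("c1", "c3")
  gp <- if (is.null(group)) NULL else group[assoc_p]
  gq <- if (is.null(group)) NULL else group[assoc_q]
  gnp <- if (is.null(group)) NULL else group[!assoc_p]
  gnq <- if (is.null(group)) NULL else group[!assoc_q]
  zp[assoc_p] <- sim_z(sum(assoc_p), pr$sp, pr$d, rho_eff, gp)
  zp[!assoc_p] <- sim_z(sum(!assoc_p), 1, 1, rho_eff, gnp)
  zq[assoc_q] <- sim_z(sum(assoc_q), pr$sq, pr$d, rho_eff, gq)
  zq[!assoc_q] <- sim_z(sum(!assoc_q), 1, 1, rho_eff, gnq)
  p <- 2 * pnorm(-abs(zp))
  q <- 2 * pnorm(-abs(zq))
  p[p == 0] <- .Machine$double.xmin
  q[q == 0] <- .Machine$double.xmin
  tibble(id = seq_len(n), p = p, q = q, fold = block, class = cls,
         is_null_p = !assoc_p, is_null_q = !assoc_q)
}

#' Empirical FDR of the raw cFDR rejection rule in the extreme scenario
#'
#' The scenario in which rejecting whenever the monotonised cFDR estimate
#' falls below `alpha` inflates the FDR most: null pairs uniform on the
#' unit square and all alternatives concentrated at the origin (clamped to
#' the smallest positive double to stay in the open square). The raw rule
#' (no v-value transformation, no test-point augmentation) is applied
#' directly at level `alpha` and the mean realised FDP is returned; for
#' large `n` it approaches the analytic limit given by
#' [extreme_case_limit()].
#'
#' @param n Number of hypotheses per replicate.
#' @param pi0 Proportion of nulls, in (0, 1).
#' @param alpha Level of the raw rejection rule.
#' @param n_reps Number of replicates.
#' @param adjusted Use the adjusted estimator?
#' @return Mean FDP across replicates, with the per-replicate values and
#'   their standard error as attributes `fdp` and `se`.
#' @export
simulate_extreme_case <- function(n, pi0, alpha, n_reps = 10,
                                  adjusted = FALSE) {
  if (pi0 <= 0 || pi0 >= 1) abort("`pi0` must lie in (0, 1).")
  n0 <- round(n * pi0)
  n1 <- n - n0
  eps <- .Machine$double.xmin
  fdp <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    p <- c(runif(n0), rep(eps, n1))
    q <- c(runif(n0), rep(eps, n1))
    is_null <- c(rep(TRUE, n0), rep(FALSE, n1))
    cc <- cpp_cvalues(p, q, p, q, remove_self = FALSE, augment = FALSE,
                      adjusted = adjusted)
    rej <- cc <= alpha
    fdp[r] <- fdp_tdp(rej, is_null)$fdp
  }
  se <- stats::sd(fdp) / sqrt(n_reps)
  structure(mean(fdp), fdp = fdp, se = se)
}

#' Analytic large-n FDR of the raw cFDR rule in the extreme scenario
#'
#' Closed-form limits of the realised FDR of the rule "reject when the
#' (monotonised) cFDR estimate is at most alpha" under the extreme
#' two-point alternative. For the unadjusted estimator the limit
#' `a` satisfies `a(1-alpha)/(alpha(1-a)) = log((1 - alpha*pi0)/(1 - pi0))`;
#' for the adjusted estimator the rejection boundary is
#' `p(q) = alpha(1-pi0)/(q(1-alpha*pi0))` capped at 1, giving null rejection
#' mass `A = c(1 - log c)` with `c = alpha(1-pi0)/(1-alpha*pi0)` and
#' `FDR = pi0 A / ((1-pi0) + pi0 A)`. Both can exceed `alpha` by an
#' arbitrarily large factor as `pi0` decreases.
#'
#' @inheritParams simulate_extreme_case
#' @return The limiting FDR.
#' @export
extreme_case_limit <- function(pi0, alpha, adjusted = FALSE) {
  if (pi0 <= 0 || pi0 >= 1) abort("`pi0` must lie in (0, 1).")
  if (!adjusted) {
    L <- log((1 - alpha * pi0) / (1 - pi0))
    x <- alpha * L / (1 - alpha)
    x / (1 + x)
  } else {
    cc <- alpha * (1 - pi0) / (1 - alpha * pi0)
    A <- if (cc >= 1) 1 else cc * (1 - log(cc))
    pi0 * A / ((1 - pi0) + pi0 * A)
  }
}
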