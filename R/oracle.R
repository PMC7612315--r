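#' Exact mixture model implied by simulation parameters
#'
#' Builds the exact class-mixture distribution of the generated `(P, Q)`
#' pairs: class weights `w_c = size_c / n`, with each coordinate either
#' null (uniform p-value, standard-normal z-score) or associated (z-score
#' `s * T` with `T` from the `d` family). The object supplies closed-form
#' marginal and joint CDFs and densities, from which the two oracle test
#' statistics are computed: the CDF statistic `C(p,q) = p F(q) / F(p,q)`
#' (the population quantity estimated by the ECDF cFDR) and the PDF
#' statistic `f0(p,q) / f(p,q)` (the likelihood-ratio statistic of the
#' optimal rejection region).
#'
#' @param params A one-row parameter table (see [sample_sim_params()]).
#' @return An object of class `cfdr_oracle`.
#' @export
oracle_model <- function(params) {
  pr <- as.list(as.data.frame(params)[1, ])
  w <- c(c1 = pr$n1pq, c2 = pr$n1p, c3 = pr$n1q,
         c4 = pr$n - pr$n1pq - pr$n1p - pr$n1q) / pr$n
  if (any(w < 0)) abort("Invalid class sizes.")
  structure(list(w = w, sp = pr$sp, sq = pr$sq, d = pr$d), class = "cfdr_oracle")
}

# CDF / density of the base family on the z-scale (standard form)
g_cdf <- function(x, d) switch(d, pnorm(x), pt(x, df = 3), pcauchy(x))
g_pdf <- function(x, d) switch(d, dnorm(x), dt(x, df = 3), dcauchy(x))

# p-scale CDF of an associated p-value: Pr(2*pnorm(-|s*T|) <= p)
F_alt <- function(p, scale, d) {
  z <- -qnorm(p / 2)
  2 * (1 - g_cdf(z / scale, d))
}

# z-scale density of |s * T| (folded)
f_alt_z <- function(z, scale, d) 2 * g_pdf(z / scale, d) / scale

# z-scale density of |N(0,1)|
f_null_z <- function(z) 2 * dnorm(z)

# marginal CDF of Q (p-scale), joint CDF F(p, q), and the q-marginal under
# the principal null
oracle_Fq <- function(or, q) {
  wa <- or$w[["c1"]] + or$w[["c3"]]
  wa * F_alt(q, or$sq, or$d) + (1 - wa) * q
}

oracle_Fpq <- function(or, p, q) {
  Fa_p <- F_alt(p, or$sp, or$d)
  Fa_q <- F_alt(q, or$sq, or$d)
  or$w[["c1"]] * Fa_p * Fa_q + or$w[["c2"]] * Fa_p * q +
    or$w[["c3"]] * p * Fa_q + or$w[["c4"]] * p * q
}

oracle_F0q <- function(or, q) {
  w3 <- or$w[["c3"]]; w4 <- or$w[["c4"]]
  if (w3 + w4 == 0) abort("No principal-null mass: f0 undefined.")
  (w3 * F_alt(q, or$sq, or$d) + w4 * q) / (w3 + w4)
}

#' Oracle test statistics
#'
#' Evaluates the CDF statistic `C(p,q) = p F(q)/F(p,q)` or the PDF
#' statistic `f0(p,q)/f(p,q)` at given points, using the exact mixture
#' distributions of the generating model. Density ratios are computed on
#' the z-scale (they are invariant to coordinate-wise monotone
#' transformations). Points where the joint CDF (or density) vanishes give
#' `Inf`.
#'
#' @param oracle A `cfdr_oracle`.
#' @param p,q Numeric vectors in (0, 1], recycled.
#' @param statistic `"cdf"` or `"pdf"`.
#' @return Statistic values.
#' @export
oracle_stat <- function(oracle, p, q, statistic = c("cdf", "pdf")) {
  statistic <- match.arg(statistic)
  k <- vctrs_recycle2(p, q)
  p <- k$x; q <- k$y
  if (statistic == "cdf") {
    den <- oracle_Fpq(oracle, p, q)
    out <- p * oracle_Fq(oracle, q) / den
    out[den == 0] <- Inf
    out
  } else {
    or <- oracle
    zp <- -qnorm(p / 2)
    zq <- -qnorm(q / 2)
    w3 <- or$w[["c3"]]; w4 <- or$w[["c4"]]
    if (w3 + w4 == 0) abort("No principal-null mass: f0 undefined.")
    f0 <- f_null_z(zp) * (w3 * f_alt_z(zq, or$sq, or$d) +
                          w4 * f_null_z(zq)) / (w3 + w4)
    fap <- f_alt_z(zp, or$sp, or$d)
    faq <- f_alt_z(zq, or$sq, or$d)
    fnp <- f_null_z(zp)
    fnq <- f_null_z(zq)
    f <- or$w[["c1"]] * fap * faq + or$w[["c2"]] * fap * fnq +
      or$w[["c3"]] * fnp * faq + or$w[["c4"]] * fnp * fnq
    out <- f0 / f
    out[f == 0] <- Inf
    out
  }
}

#' Oracle v-values by exact-null contour integration
#'
#' For each record, computes `v = Pr(stat(P, Q) <= t_i | principal null)`
#' with `t_i` the record's oracle statistic value -- the probability mass of
#' the exact sub-level contour region under the exact null density. Feeding
#' these to [bh_reject()] yields the oracle CDF / PDF comparator
#' procedures, the best achievable rejection rules of each form.
#'
#' The integral is evaluated by quadrature over the null distribution of
#' the covariate: `n_q_nodes` equal-mass quantile nodes in the q
#' (covariate) direction, with the conditional p-direction mass obtained by
#' inverting a fine tabulation of the statistic (monotone in the principal
#' coordinate) on a `n_p_grid`-point grid.
#'
#' @param data A data frame with columns `p`, `q` (e.g. from
#'   [simulate_dataset()]).
#' @param oracle A `cfdr_oracle` built from the generating parameters.
#' @param statistic `"cdf"` or `"pdf"`.
#' @param n_q_nodes,n_p_grid Quadrature resolution.
#' @return A tibble with the input columns plus `stat` and `v`.
#' @export
oracle_vvalues <- function(data, oracle, statistic = c("cdf", "pdf"),
                           n_q_nodes = 160, n_p_grid = 1500) {
  statistic <- match.arg(statistic)
  or <- oracle
  X <- as_pq_data(data)
  tval <- oracle_stat(or, X$p, X$q, statistic)

  # equal-mass nodes of Q | principal null, via inversion of its CDF on a
  # fine monotone grid
  probs <- (seq_len(n_q_nodes) - 0.5) / n_q_nodes
  qgrid <- sort(unique(c(
    10^seq(-12, 0, length.out = 4000), seq(1e-4, 1, length.out = 2000)
  )))
  F0vals <- oracle_F0q(or, qgrid)
  qnodes <- approx(F0vals, qgrid, xout = probs, rule = 2, ties = "ordered")$y

  # principal-coordinate grid: null-mass quantiles, denser in the tail
  pm <- (seq_len(n_p_grid) - 0.5) / n_p_grid
  pgrid <- c(1e-300, 1e-100, 1e-30, 10^seq(-16, -4, length.out = 200),
             pm[pm > 1e-4], 1)
  pgrid <- sort(unique(pgrid))

  v <- numeric(nrow(X))
  for (k in seq_len(n_q_nodes)) {
    tk <- oracle_stat(or, pgrid, rep(qnodes[k], length(pgrid)), statistic)
    # the statistic is nondecreasing in p at fixed q for both forms;
    # enforce monotonicity against floating-point wiggle before inversion
    tk <- cummax(tk)
    # mass in p of the sub-level region at each query level: the largest p
    # at which the statistic is below the level (the p-marginal of the null
    # is uniform). Flat stretches keep their last grid point so that
    # sub-level sets are closed.
    keep <- !duplicated(tk, fromLast = TRUE)
    tku <- tk[keep]
    pgu <- pgrid[keep]
    if (length(tku) < 2) {
      pstar <- ifelse(tval >= tku[1], 1, 0)
    } else {
      pstar <- approx(tku, pgu, xout = tval, ties = "ordered", rule = 1)$y
      pstar[tval < tku[1]] <- 0
      pstar[tval >= tku[length(tku)]] <- 1
    }
    v <- v + pstar
  }
  X$stat <- tval
  X$v <- pmin(pmax(v / n_q_nodes, .Machine$double.xmin), 1)
  X
}
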