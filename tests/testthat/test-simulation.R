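test_that("parameter draws respect the design ranges", {
  set.seed(61)
  pr <- sample_sim_params(200)
  expect_true(all(pr$n >= 1000 & pr$n <= 10000))
  expect_true(all(pr$n1pq >= 0 & pr$n1pq <= 200))
  expect_true(all(pr$n1p <= 200 & pr$n1q <= 200))
  expect_true(all(pr$sp >= 1.5 & pr$sp <= 3))
  expect_true(all(pr$d %in% 1:3))
  pr0 <- sample_sim_params(50, null_only = TRUE)
  expect_true(all(pr0$n1p + pr0$n1pq == 0))
})

test_that("simulated datasets have exact class structure and uniform nulls", {
  set.seed(62)
  d <- simulate_dataset(sim_params_preset("reference"))
  expect_equal(nrow(d), 5000)
  expect_equal(as.vector(table(d$class)[c("c1", "c2", "c3", "c4")]),
               c(100, 100, 100, 4700))
  expect_equal(d$is_null_p, d$class %in% c("c3", "c4"))
  expect_equal(d$is_null_q, d$class %in% c("c2", "c4"))
  # null principal p-values are uniform
  pn <- d$p[d$is_null_p]
  expect_gt(stats::ks.test(pn, "punif")$p.value, 1e-4)
})

test_that("associated z-scores follow the scaled alternative family", {
  set.seed(63)
  pr <- sim_params_preset("reference")
  pr$d <- 1; pr$sp <- 2; pr$n1pq <- 0; pr$n1q <- 0; pr$n1p <- 2000
  d <- simulate_dataset(pr)
  z <- -qnorm(d$p[d$class == "c2"] / 2)
  # |z| should match |2 N(0,1)|: KS against the folded scaled normal
  ks <- stats::ks.test(z, function(x) 2 * pnorm(x / 2) - 1)
  expect_gt(ks$p.value, 1e-4)
})

test_that("equicorrelation induces the requested z-score correlation", {
  # within one dataset the whole class shares one factor draw, so the
  # correlation must be measured across independent replicates; the
  # p-value folds away the sign, so use squared standardised scores:
  # for bivariate normal z-scores with correlation rho,
  # cor(z1^2, z2^2) = rho^2
  set.seed(64)
  pr <- tibble::tibble(n = 2, n1pq = 0, n1p = 2, n1q = 0,
                       sp = 2, sq = 2, d = 1, rho = 0.5,
                       corr_mode = "equicorrelation", n_blocks = 1)
  z2 <- t(replicate(400, {
    d <- simulate_dataset(pr)
    (-qnorm(d$p / 2) / 2)^2
  }))
  co <- stats::cor(z2[, 1], z2[, 2])
  expect_gt(co, 0.5^2 - 0.12)
  expect_lt(co, 0.5^2 + 0.12)
})

test_that("extreme-case FDR inflation matches the analytic limits", {
  set.seed(65)
  # unadjusted estimator, Eq-13-style limit
  lim_u <- extreme_case_limit(0.9, 0.1, adjusted = FALSE)
  got_u <- simulate_extreme_case(20000, 0.9, 0.1, n_reps = 8,
                                 adjusted = FALSE)
  expect_lt(abs(as.numeric(got_u) - lim_u), 3 * attr(got_u, "se") + 0.01)
  # the inflation is real: both far exceed the nominal level
  expect_gt(as.numeric(got_u), 0.15)

  # adjusted estimator limit
  lim_a <- extreme_case_limit(0.9, 0.1, adjusted = TRUE)
  got_a <- simulate_extreme_case(20000, 0.9, 0.1, n_reps = 8,
                                 adjusted = TRUE)
  expect_lt(abs(as.numeric(got_a) - lim_a), 3 * attr(got_a, "se") + 0.015)
  expect_gt(as.numeric(got_a), 0.15)
})

test_that("oracle statistics reduce to closed forms in degenerate cases", {
  null_pr <- tibble::tibble(n = 1000, n1pq = 0, n1p = 0, n1q = 0,
                            sp = 2, sq = 2, d = 2)
  or <- oracle_model(null_pr)
  p <- c(0.01, 0.2, 0.7); q <- c(0.5, 0.05, 0.9)
  # with everything null the population cFDR is 1 everywhere, and the
  # density ratio is 1
  expect_equal(oracle_stat(or, p, q, "cdf"), rep(1, 3), tolerance = 1e-12)
  expect_equal(oracle_stat(or, p, q, "pdf"), rep(1, 3), tolerance = 1e-12)

  # P and Q independent (no shared class): C depends on p only
  ind_pr <- tibble::tibble(n = 1000, n1pq = 0, n1p = 200, n1q = 0,
                           sp = 2, sq = 2, d = 1)
  or2 <- oracle_model(ind_pr)
  w <- 0.2
  Fp <- function(p) w * 2 * (1 - pnorm(-qnorm(p / 2) / 2)) + (1 - w) * p
  expect_equal(oracle_stat(or2, p, q, "cdf"), p / Fp(p), tolerance = 1e-12)
})

test_that("oracle v-values agree with brute-force Monte-Carlo under f0", {
  set.seed(66)
  pr <- sim_params_preset("reference")
  or <- oracle_model(pr)
  d <- simulate_dataset(pr)[1:400, ]
  for (statistic in c("cdf", "pdf")) {
    ov <- oracle_vvalues(d, or, statistic)
    # MC draw from f0: p uniform, q from the principal-null q-marginal
    nmc <- 400000
    w3 <- 100 / 4800; # c3 weight among principal-null classes
    isalt <- runif(nmc) < w3
    zq <- ifelse(isalt, 2 * abs(rt(nmc, df = 3)), abs(rnorm(nmc)))
    qmc <- pmax(2 * pnorm(-zq), 1e-300)
    pmc <- runif(nmc)
    smc <- oracle_stat(or, pmc, qmc, statistic)
    idx <- sample(nrow(d), 25)
    for (i in idx) {
      mc <- mean(smc <= ov$stat[i])
      se <- sqrt(max(mc * (1 - mc), 1e-9) / nmc)
      expect_lt(abs(ov$v[i] - mc), 3 * se + 2e-3)
    }
  }
})

test_that("benchmark output has the documented shape and determinism", {
  pr <- tibble::tibble(n = 300, n1pq = 20, n1p = 20, n1q = 20,
                       sp = 2.5, sq = 2.5, d = 1, rho = 0,
                       corr_mode = "none", n_blocks = 3)
  b1 <- run_benchmark(pr, methods = c("pval_bh", "loo"),
                      alpha = c(0.1, 0.01), n_reps = 2, seed = 7)
  b2 <- run_benchmark(pr, methods = c("pval_bh", "loo"),
                      alpha = c(0.1, 0.01), n_reps = 2, seed = 7)
  expect_identical(b1, b2)
  expect_setequal(names(b1), c("param_id", "rep", "seed", "method",
                               "alpha", "fdp", "tdp", "n_reject"))
  expect_equal(nrow(b1), 2 * 2 * 2)
  expect_error(run_benchmark(pr, methods = "nope"), "Unknown method")
  sm <- benchmark_summary(b1)
  expect_true(all(c("fdr", "tdr", "fdr_se") %in% names(sm)))
})

test_that("FDR is controlled across a stream of design draws", {
  set.seed(67)
  ndraw <- 12
  fdp_loo <- fdp_lob <- tdp_adj <- tdp_unadj <- numeric(ndraw)
  for (s in seq_len(ndraw)) {
    pr <- sample_sim_params(1)
    pr$n <- min(pr$n, 3000)  # keep the unit-test run light
    d <- simulate_dataset(pr)
    nm <- fit_null_em(d)
    vl <- cfdr_vvalues(d, "loo", null_model = nm)$v
    vb <- cfdr_vvalues(d, "lob", null_model = nm)$v
    vu <- cfdr_vvalues(d, "loo", adjusted = FALSE, null_model = nm)$v
    fdp_loo[s] <- fdp_tdp(bh_reject(vl, 0.1), d$is_null_p)$fdp
    fdp_lob[s] <- fdp_tdp(bh_reject(vb, 0.1), d$is_null_p)$fdp
    tdp_adj[s] <- fdp_tdp(bh_reject(vl, 0.1), d$is_null_p)$tdp
    tdp_unadj[s] <- fdp_tdp(bh_reject(vu, 0.1), d$is_null_p)$tdp
  }
  se <- function(x) stats::sd(x) / sqrt(length(x))
  expect_lt(mean(fdp_loo), 0.1 + 3 * se(fdp_loo))
  expect_lt(mean(fdp_lob), 0.1 + 3 * se(fdp_lob))
  # power ordering: the adjusted estimator is at least as powerful
  expect_gte(mean(tdp_adj - tdp_unadj, na.rm = TRUE), -0.005)
})

test_that("FDR control holds under block and equicorrelation structures", {
  set.seed(68)
  for (cm in c("block", "equicorrelation")) {
    fdp <- numeric(8)
    for (s in 1:8) {
      pr <- tibble::tibble(n = 1500, n1pq = 50, n1p = 50, n1q = 50,
                           sp = 2, sq = 2, d = 2, rho = 0.1,
                           corr_mode = cm, n_blocks = 3)
      d <- simulate_dataset(pr)
      nm <- fit_null_em(d)
      vb <- cfdr_vvalues(d, "lob", null_model = nm)$v
      fdp[s] <- fdp_tdp(bh_reject(vb, 0.1), d$is_null_p)$fdp
    }
    expect_lt(mean(fdp), 0.1 + 3 * stats::sd(fdp) / sqrt(8))
  }
})
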