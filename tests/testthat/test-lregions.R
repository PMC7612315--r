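test_that("L-curve covers the square at level 1 and vanishes at level ~0", {
  set.seed(31)
  X <- rand_pq(25)
  lc1 <- build_lcurve(X, 1)
  expect_true(all(lc1$p_bound == 1))
  lc0 <- build_lcurve(X, 1e-12)
  expect_true(all(lc0$p_bound <= 1e-8))
  expect_error(build_lcurve(X, 0), "alpha")
  expect_error(build_lcurve(X, 1.2), "alpha")
})

test_that("L-curve boundary matches brute-force evaluation of cfdr_t", {
  set.seed(32)
  for (rep in 1:6) {
    n <- 20
    X <- rand_pq(n)
    alpha <- runif(1, 0.02, 0.3)
    adjusted <- rep %% 2 == 0
    lc <- build_lcurve(X, alpha, adjusted = adjusted)
    # brute force on a dense grid: for q in each stratum, the boundary is
    # the largest grid p with cfdr_t <= alpha
    for (j in sample(nrow(lc), 4)) {
      qmid <- (lc$q_lo[j] + lc$q_hi[j]) / 2
      pgrid <- sort(unique(c(seq(1e-4, 1, length.out = 400), X$p,
                             pmin(1, lc$p_bound[j] + c(-1e-9, 0, 1e-9)))))
      vals <- cfdr_t(X, pgrid, rep(qmid, length(pgrid)),
                     adjusted = adjusted, include_test_point = TRUE)
      inside <- pgrid[vals <= alpha]
      brute_bound <- if (length(inside)) max(inside) else 0
      expect_lt(abs(lc$p_bound[j] - brute_bound), 1e-6)
    }
  }
})

test_that("L-regions are nested across levels", {
  set.seed(33)
  for (rep in 1:5) {
    X <- rand_pq(sample(10:40, 1))
    alphas <- sort(runif(10, 0.001, 1))
    prev <- NULL
    for (a in alphas) {
      lc <- build_lcurve(X, a, adjusted = rep %% 2 == 0)
      if (!is.null(prev)) {
        expect_true(all(lc$p_bound >= prev - 1e-12))
      }
      prev <- lc$p_bound
    }
  }
})

test_that("v-value of a single point behaves at the corners", {
  set.seed(34)
  X <- rand_pq(15)
  m <- null_model_uniform()
  r <- vvalue_for_point(X, 1, 1, m)
  expect_equal(r$c, 1)
  expect_equal(r$v, 1)
  # empty leave-out set: count guards give c = p, region [0,p] x [0,1]
  r0 <- vvalue_for_point(X[0, ], 0.3, 0.5, m)
  expect_equal(r0$v, 0.3)
  expect_equal(r0$c, 0.3)
})

test_that("with a uniform null, v equals the Lebesgue area of the region", {
  set.seed(35)
  X <- rand_pq(40)
  m <- null_model_uniform()
  for (rep in 1:4) {
    pq <- runif(2)
    r <- vvalue_for_point(X, pq[1], pq[2], m)
    lc <- build_lcurve(X, r$c)
    area <- sum(lc$p_bound * (lc$q_hi - lc$q_lo))
    expect_equal(r$v, area, tolerance = 1e-12)
    # Monte-Carlo area
    nmc <- 200000
    pm <- runif(nmc); qm <- runif(nmc)
    j <- findInterval(qm, c(lc$q_lo, 1), rightmost.closed = TRUE)
    mc <- mean(pm <= lc$p_bound[j])
    expect_lt(abs(area - mc), 3 * sqrt(mc * (1 - mc) / nmc) + 1e-4)
  }
})

test_that("closed-form strip integration matches 2-D quadrature of f0", {
  set.seed(36)
  X <- rand_pq(30)
  m <- structure(list(pi0 = 0.5, sigma0 = 2.2), class = "cfdr_null_model")
  r <- vvalue_for_point(X, 0.2, 0.3, m, adjusted = TRUE)
  lc <- build_lcurve(X, r$c, adjusted = TRUE)
  # quadrature on the z-scale (q = 2*pnorm(-z)) to tame the q -> 0
  # singularity of the density
  gz <- function(z) {
    qv <- pmin(pmax(2 * pnorm(-z), 1e-320), 1 - 1e-16)
    f0q_density(qv, m) * 2 * dnorm(z)
  }
  z_of <- function(q) -qnorm(q / 2)
  quad <- sum(vapply(seq_len(nrow(lc)), function(j) {
    lc$p_bound[j] * stats::integrate(gz, z_of(lc$q_hi[j]),
                                     if (lc$q_lo[j] == 0) Inf
                                     else z_of(lc$q_lo[j]),
                                     rel.tol = 1e-9)$value
  }, numeric(1)))
  expect_equal(r$v, quad, tolerance = 1e-6)
})

test_that("pipeline v-values equal the naive per-point recomputation", {
  set.seed(37)
  m <- structure(list(pi0 = 0.7, sigma0 = 2.5), class = "cfdr_null_model")
  for (rep in 1:10) {
    X <- rand_pq(sample(4:45, 1), n_sig = sample(0:3, 1))
    adjusted <- rep %% 2 == 0
    for (mode in c("loo", "naive", "lob")) {
      got <- suppressWarnings(
        cfdr_vvalues(X, mode, adjusted = adjusted, null_model = m))
      want <- suppressWarnings(ref_vvalues(X, mode, adjusted, m))
      expect_equal(got$c, want$c, tolerance = 0)
      if (mode == "naive") {
        # identical stratum partition: results are bit-identical
        expect_identical(got$v, want$v)
      } else {
        expect_equal(got$v, want$v, tolerance = 1e-12)
      }
    }
  }
})

test_that("single-record leave-one-out degenerates to v = p", {
  m <- null_model_uniform()
  res <- cfdr_vvalues(data.frame(p = 0.07, q = 0.4), "loo",
                      adjusted = FALSE, null_model = m)
  expect_equal(res$v, 0.07)
  expect_equal(res$c, 0.07)
})

test_that("v is non-decreasing in c within one leave-out set", {
  set.seed(38)
  X <- rand_pq(60)
  m <- structure(list(pi0 = 0.8, sigma0 = 2), class = "cfdr_null_model")
  pts <- as_pq_data(data.frame(p = runif(30), q = runif(30)))
  got <- cfdr_vvalues_at(X, pts, model = m, adjusted = TRUE)
  o <- order(got$c)
  expect_true(all(diff(got$v[o]) >= -1e-12))
})

test_that("loo and lob v-values are valid p-values under the pure null", {
  set.seed(39)
  m <- null_model_uniform()  # f0 known exactly: the uniform square
  nrep <- 12
  n <- 400
  vs_loo <- vs_lob <- matrix(NA_real_, n, nrep)
  for (r in seq_len(nrep)) {
    X <- rand_pq(n)
    vs_loo[, r] <- cfdr_vvalues(X, "loo", adjusted = TRUE,
                                null_model = m)$v
    vs_lob[, r] <- cfdr_vvalues(X, "lob", adjusted = TRUE,
                                null_model = m)$v
  }
  for (alpha in c(0.01, 0.05, 0.1, 0.5)) {
    for (vs in list(vs_loo, vs_lob)) {
      prop <- mean(vs <= alpha)
      se <- sqrt(alpha * (1 - alpha) / length(vs))
      expect_lt(prop, alpha + 3 * se)
    }
  }
})

test_that("naive v-values break the p-value property that loo retains", {
  # each point's own presence in the map inflates its local denominator
  # count, so naive v-values are stochastically too small under the null
  set.seed(40)
  m <- null_model_uniform()
  nrep <- 12; n <- 500
  vn <- vl <- NULL
  for (r in seq_len(nrep)) {
    X <- rand_pq(n)
    vn <- c(vn, cfdr_vvalues(X, "naive", null_model = m)$v)
    vl <- c(vl, cfdr_vvalues(X, "loo", null_model = m)$v)
  }
  for (a in c(0.05, 0.1)) {
    se <- sqrt(a * (1 - a) / length(vn))
    expect_gt(mean(vn <= a), a + 2 * se)   # naive: anti-conservative
    expect_lt(mean(vl <= a), a + 3 * se)   # loo: valid
  }
})
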