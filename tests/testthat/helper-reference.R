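# Independent reference implementations used as oracles in the tests.
# These deliberately avoid the package's optimised code paths.

# Hand-written Benjamini-Hochberg step-up
bh_stepup_ref <- function(p, alpha) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= alpha * seq_len(n) / n)
  rej <- logical(n)
  if (length(k) > 0) rej[o[seq_len(max(k))]] <- TRUE
  rej
}

# Exhaustive minimisation of the estimator over a dense p' grid plus all
# data p-values (brute-force cfdr_t)
brute_cfdr_t <- function(X, p, q, adjusted = FALSE,
                         include_test_point = FALSE, grid_n = 2000) {
  ag <- as.integer(include_test_point)
  n <- nrow(X)
  cand <- sort(unique(c(seq(p, 1, length.out = grid_n), X$p[X$p >= p], p)))
  inq <- X$q <= q
  adj <- 1
  if (adjusted) {
    a <- sum(inq & X$p > 0.5)
    b <- sum(X$p > 0.5)
    adj <- min(1, (max(a, 1) / max(b, 1)) / (max(sum(inq), 1) / n))
  }
  N <- max(sum(inq) + ag, 1)
  e <- vapply(cand, function(pc) {
    D <- sum(X$p[inq] <= pc) + ag
    pc * N / max(D, 1) * adj
  }, numeric(1))
  min(e)
}

# Leave-out v-values recomputed one point at a time through the plain
# lcurve/integration path, mirroring the per-fold unadjusted fallback of
# the production pipeline
ref_vvalues <- function(X, mode, adjusted, model) {
  n <- nrow(X)
  v <- numeric(n); cc <- numeric(n)
  for (i in seq_len(n)) {
    Xlo <- switch(mode,
      loo = X[-i, , drop = FALSE],
      naive = X,
      lob = X[X$fold != X$fold[i], , drop = FALSE])
    adj_i <- adjusted && sum(Xlo$p > 0.5) > 0
    r <- vvalue_for_point(Xlo, X$p[i], X$q[i], model, adjusted = adj_i)
    v[i] <- r$v; cc[i] <- r$c
  }
  list(v = v, c = cc)
}

# Draw from the q-marginal of a fitted null model
rq_null_model <- function(n, model) {
  comp2 <- runif(n) > model$pi0
  z <- abs(rnorm(n, sd = ifelse(comp2, model$sigma0, 1)))
  q <- 2 * pnorm(-z)
  pmax(q, .Machine$double.xmin)
}

# A quick random PQ table with optional signal
rand_pq <- function(n, n_sig = 0, sd_sig = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- runif(n)
  q <- runif(n)
  if (n_sig > 0) {
    idx <- seq_len(n_sig)
    p[idx] <- 2 * pnorm(-abs(rnorm(n_sig, sd = sd_sig)))
    q[idx] <- 2 * pnorm(-abs(rnorm(n_sig, sd = sd_sig)))
  }
  data.frame(p = pmax(p, 1e-300), q = pmax(q, 1e-300),
             fold = sample(rep_len(1:3, n)))
}
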