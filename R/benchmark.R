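#' Run the FDR/power benchmark
#'
#' Simulates replicate datasets under each parameter vector, applies the
#' requested rejection procedures at each level in `alpha`, and scores each
#' against the generating truth. The methods are: `pval_bh` (B-H on the
#' principal p-values alone), `naive` / `loo` / `lob` (B-H on v-values
#' with the adjusted estimator under the respective censoring scheme),
#' `loo_unadjusted` (leave-one-out with the unadjusted estimator), and
#' `cdf_oracle` / `pdf_oracle` (B-H on exact-contour oracle v-values).
#'
#' @param params A parameter tibble (one row per parameter set), e.g. from
#'   [sample_sim_params()] or [sim_params_preset()].
#' @param methods Character vector of methods (see Details).
#' @param alpha Numeric vector of FDR control levels.
#' @param n_reps Replicates per parameter row.
#' @param seed Optional integer seed; replicate `r` of parameter row `s`
#'   runs under its own derived seed so results are reproducible and
#'   individual replicates can be re-run in isolation.
#' @return A tibble with columns `param_id`, `rep`, `seed`, `method`,
#'   `alpha`, `fdp`, `tdp`, `n_reject`.
#' @examples
#' run_benchmark(sim_params_preset("reference"),
#'               methods = "pval_bh", n_reps = 2, seed = 1)
#' @export
run_benchmark <- function(params,
                          methods = c("pval_bh", "loo"),
                          alpha = 0.1, n_reps = 1, seed = NULL) {
  known <- c("pval_bh", "naive", "loo", "lob", "loo_unadjusted",
             "cdf_oracle", "pdf_oracle")
  bad <- setdiff(methods, known)
  if (length(bad) > 0) {
    abort(paste0("Unknown method(s): ", paste(bad, collapse = ", ")))
  }
  params <- as_tibble(as.data.frame(params))
  rows <- list()
  for (srow in seq_len(nrow(params))) {
    pr <- params[srow, ]
    for (r in seq_len(n_reps)) {
      rep_seed <- if (is.null(seed)) NA_integer_ else
        (seed + 7919L * (srow - 1L) + r) %% .Machine$integer.max
      if (!is.na(rep_seed)) set.seed(rep_seed)
      dat <- simulate_dataset(pr)
      vsets <- list()
      need_fit <- any(methods %in% c("naive", "loo", "lob",
                                     "loo_unadjusted"))
      nm <- if (need_fit) fit_null_em(dat) else NULL
      for (m in methods) {
        v <- switch(m,
          pval_bh = dat$p,
          naive = cfdr_vvalues(dat, "naive", adjusted = TRUE,
                               null_model = nm)$v,
          loo = cfdr_vvalues(dat, "loo", adjusted = TRUE,
                             null_model = nm)$v,
          lob = cfdr_vvalues(dat, "lob", adjusted = TRUE,
                             null_model = nm)$v,
          loo_unadjusted = cfdr_vvalues(dat, "loo", adjusted = FALSE,
                                        null_model = nm)$v,
          cdf_oracle = oracle_vvalues(dat, oracle_model(pr), "cdf")$v,
          pdf_oracle = oracle_vvalues(dat, oracle_model(pr), "pdf")$v
        )
        vsets[[m]] <- v
      }
      for (m in methods) {
        for (a in alpha) {
          sc <- fdp_tdp(bh_reject(vsets[[m]], a), dat$is_null_p)
          rows[[length(rows) + 1L]] <- tibble(
            param_id = srow, rep = r, seed = rep_seed, method = m,
            alpha = a, fdp = sc$fdp, tdp = sc$tdp, n_reject = sc$n_reject
          )
        }
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Summarise a benchmark run
#'
#' Mean FDP (estimating FDR) and mean TDP (estimating TDR, excluding
#' replicates with no non-null hypotheses) per method and level, with
#' Monte-Carlo standard errors.
#'
#' @param results A tibble from [run_benchmark()].
#' @return A tibble with one row per (method, alpha).
#' @export
benchmark_summary <- function(results) {
  results |>
    dplyr::group_by(.data$method, .data$alpha) |>
    dplyr::summarise(
      n_reps = dplyr::n(),
      fdr = mean(.data$fdp),
      fdr_se = stats::sd(.data$fdp) / sqrt(dplyr::n()),
      tdr = mean(.data$tdp, na.rm = TRUE),
      tdr_se = stats::sd(.data$tdp, na.rm = TRUE) /
        sqrt(sum(!is.na(.data$tdp))),
      .groups = "drop"
    )
}
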