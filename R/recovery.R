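#' Simulation-based calibration of the sampler: parameter-recovery study
#'
#' Repeatedly simulates trait tables from known parameters (latent level:
#' species effects plus residuals, the exact process the model assumes) on
#' freshly simulated trees, fits the model, and records whether each 95%
#' HPD interval covers its true value. With a correctly implemented sampler
#' the coverage of every parameter should be near the nominal 95%.
#'
#' @param n_reps Number of replicate simulations.
#' @param params A [sim_params()]; the truths being recovered.
#' @param n_iter,burn_in,thin MCMC controls per fit.
#' @param seed Master seed; every replicate derives its own seeds from it.
#' @return A tibble with one row per monitored parameter: `statistic`,
#'   `label`, `truth`, `coverage`, `mean_estimate`, `n_reps`.
#' @export
recovery_study <- function(n_reps = 20, params = sim_params(),
                           n_iter = 20000, burn_in = 4000, thin = 10,
                           seed) {
  if (missing(seed)) abort("a `seed` is required")
  truth_vp <- diag(params$true_vp)
  labs <- trait_labels()
  lab9 <- paste(labs$trait_class, labs$diet, sep = ".")
  # within-class diet-pair correlations implied by true_vp
  pairs <- dplyr::filter(
    tidyr::expand_grid(i = 1:9, j = 1:9), .data$i < .data$j,
    labs$trait_class[.data$i] == labs$trait_class[.data$j]
  )
  truth_corr <- mapply(function(i, j) {
    params$true_vp[i, j] / sqrt(params$true_vp[i, i] * params$true_vp[j, j])
  }, pairs$i, pairs$j)
  lab_corr <- paste0(labs$trait_class[pairs$i], ".", labs$diet[pairs$i],
                     "~", labs$diet[pairs$j])

  hits <- NULL
  ests <- NULL
  for (r in seq_len(n_reps)) {
    d <- simulate_trait_table(params, seed = seed + 101L * r)
    fit <- pmm_fit(d$table, d$A,
                   pmm_control(n_iter, burn_in, thin, seed = seed + 977L * r))
    s <- summarize_pmm(fit)
    vp <- s[s$statistic == "vp", ]
    int <- s[s$statistic == "intercept", ]
    ws <- s[s$statistic == "wing_slope", ]
    co <- s[s$statistic == "correlation" & !is.na(s$trait_class2) &
              s$trait_class == s$trait_class2, ]
    row_hit <- c(
      vp$hpd_lower <= truth_vp & truth_vp <= vp$hpd_upper,
      co$hpd_lower <= truth_corr & truth_corr <= co$hpd_upper,
      int$hpd_lower <= params$true_means & params$true_means <= int$hpd_upper,
      ws$hpd_lower <= params$wing_effect & params$wing_effect <= ws$hpd_upper
    )
    hits <- rbind(hits, row_hit)
    ests <- rbind(ests, c(vp$mean, co$mean, int$mean, ws$mean))
  }
  tibble::tibble(
    statistic = rep(c("vp", "correlation", "intercept", "wing_slope"),
                    times = c(9, length(truth_corr), 9, 9)),
    label = c(lab9, lab_corr, lab9, lab9),
    truth = c(truth_vp, truth_corr, params$true_means,
              rep(params$wing_effect, 9)),
    coverage = colMeans(hits),
    mean_estimate = colMeans(ests),
    n_reps = n_reps
  )
}

#' In-silico check of the no-interaction signature
#'
#' Simulates under "no species-by-diet interaction": within each trait
#' class the three diet traits share one mean, one variance, and a
#' between-species correlation of exactly 1 (a rank-one class block). A
#' correct analysis should then estimate within-class between-species
#' correlations close to 1 with HPD intervals far from 0 — the signature by
#' which equality of species responses across diets is judged.
#'
#' @param n_reps Number of replicate simulations (fits are the expensive
#'   part; 2-3 suffice for the qualitative check).
#' @param n_iter,burn_in,thin MCMC controls per fit.
#' @param seed Master seed.
#' @param v_load,v_surv,mean_load,mean_surv Shared within-class variances
#'   and means.
#' @return A tibble of within-class correlation summaries across replicates.
#' @export
headline_study <- function(n_reps = 2, n_iter = 10000, burn_in = 2000,
                           thin = 5, seed, v_load = 77, v_surv = 0.18,
                           mean_load = 11, mean_surv = 0.8) {
  if (missing(seed)) abort("a `seed` is required")
  params <- sim_params(
    true_vp = default_true_vp(v_load = v_load, v_surv = v_surv, rho = 1),
    true_means = c(rep(mean_load, 3), rep(mean_surv, 6))
  )
  out <- NULL
  for (r in seq_len(n_reps)) {
    d <- simulate_trait_table(params, seed = seed + 31L * r)
    fit <- pmm_fit(d$table, d$A,
                   pmm_control(n_iter, burn_in, thin, seed = seed + 53L * r))
    s <- summarize_pmm(fit)
    co <- s[s$statistic == "correlation" & !is.na(s$trait_class2) &
              s$trait_class == s$trait_class2, ]
    co$rep <- r
    out <- dplyr::bind_rows(out, co)
  }
  out
}
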