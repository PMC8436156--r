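#' Priors for the phylogenetic mixed model
#'
#' Weakly informative defaults in the style common for Bayesian animal
#' models: inverse-Wishart priors on the trait covariance matrices,
#' per-trait inverse-gamma priors on the residual variances (shape 0.5,
#' rate 0.5 times the observed data variance of the trait), and a
#' flat-by-construction Normal(0, 1e8) prior on fixed effects.
#'
#' The default inverse-Wishart scale is matched to the data scale:
#' `0.5 * diag(observed per-trait variance)` with `df = k + 1`, which makes
#' the implied marginal prior on every between-species correlation uniform
#' on \[-1, 1\]. A scale matrix far below the trait variances is not
#' harmless: the inverse-Wishart density then behaves like
#' `det(V)^-(df+k+1)/2` over the whole plausible region, which concentrates
#' correlations at +/-1 and can dominate the likelihood. Fixed scales
#' (e.g. `vp_scale = 0.02`) remain available, and [pmm_sensitivity()]
#' re-runs a fit under a list of alternatives.
#'
#' @param vp_scale,vp_df Inverse-Wishart scale matrix (a matrix; a scalar,
#'   meaning `scalar * I`; or `NULL` for 0.5 times the diagonal observed
#'   trait variances, filled in at fit time) and degrees of freedom for the
#'   phylogenetic covariance. Degrees of freedom must exceed `k - 1`;
#'   `NULL` means `k + 1`.
#' @param vs_scale,vs_df Same for the optional non-phylogenetic species
#'   covariance.
#' @param ve_shape Inverse-gamma shape for each residual variance.
#' @param ve_rate Inverse-gamma rate; `NULL` means 0.5 times each trait's
#'   observed variance, filled in at fit time.
#' @param beta_var Prior variance of the fixed effects.
#' @return A list of class `pmm_priors`.
#' @export
pmm_priors <- function(vp_scale = NULL, vp_df = NULL,
                       vs_scale = NULL, vs_df = NULL,
                       ve_shape = 0.5, ve_rate = NULL,
                       beta_var = 1e8) {
  structure(
    list(vp_scale = vp_scale, vp_df = vp_df, vs_scale = vs_scale,
         vs_df = vs_df, ve_shape = ve_shape, ve_rate = ve_rate,
         beta_var = beta_var),
    class = "pmm_priors"
  )
}

#' MCMC controls for [pmm_fit()]
#'
#' @param n_iter Total iterations, burn-in included (default 50000).
#' @param burn_in Iterations discarded before recording (default 10000).
#' @param thin Record every `thin`-th post-burn-in iteration (default 20).
#' @param seed Integer RNG seed; mandatory so every fit is reproducible.
#' @return A list of class `pmm_control`.
#' @export
pmm_control <- function(n_iter = 50000, burn_in = 10000, thin = 20, seed) {
  if (missing(seed) || is.null(seed)) abort("a `seed` is required")
  if (burn_in >= n_iter) abort("`burn_in` must be smaller than `n_iter`")
  if (thin < 1) abort("`thin` must be >= 1")
  structure(
    list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
         thin = as.integer(thin), seed = as.integer(seed)),
    class = "pmm_control"
  )
}

#' Design matrices and index vectors for the mixed model
#'
#' Maps each observation to its per-trait intercept and per-trait wing
#' slope (two nonzero fixed-effect entries per row) and to its
#' (species, trait) random-effect cell. The stacked species effects use
#' trait-major order — element `(t - 1) * n_species + s` is species `s`,
#' trait `t` — so their prior covariance is `Vp %x% A` (Kronecker product,
#' trait covariance crossed with relatedness).
#'
#' @param table A trait table from [build_trait_table()].
#' @param A A relatedness matrix whose taxa cover the table's species.
#' @return A list with `y`, `X`, 0-based `trait` and `species` indices,
#'   `species_levels`, `traits` (label tibble), `A` reordered to
#'   `species_levels`, and `k`, `m`, `n`.
#' @export
build_design <- function(table, A) {
  stopifnot(is.data.frame(table), is.matrix(A))
  table <- dplyr::mutate(table, species = trimws(.data$species))
  taxa <- trimws(rownames(A))
  sp <- sort(unique(table$species))
  not_in_tree <- setdiff(sp, taxa)
  if (length(not_in_tree)) {
    abort(paste0("species absent from the relatedness matrix: ",
                 paste(not_in_tree, collapse = ", ")))
  }
  not_in_table <- setdiff(taxa, sp)
  if (length(not_in_table)) {
    abort(paste0("taxa in the relatedness matrix but not in the data: ",
                 paste(not_in_table, collapse = ", ")))
  }
  k <- max(table$trait_index)
  if (any(table$trait_index < 1L) || k > 9L) {
    abort("trait_index must lie in 1..9")
  }
  present <- sort(unique(table$trait_index))
  if (!identical(present, seq_len(k))) {
    abort("trait indices must be contiguous 1..k; remap subsets first")
  }
  rownames(A) <- colnames(A) <- taxa
  A <- A[sp, sp, drop = FALSE]
  n <- nrow(table)
  trait0 <- table$trait_index - 1L
  species0 <- match(table$species, sp) - 1L
  X <- matrix(0, n, 2L * k)
  colnames(X) <- c(paste0("intercept_", seq_len(k)), paste0("wing_", seq_len(k)))
  X[cbind(seq_len(n), table$trait_index)] <- 1
  X[cbind(seq_len(n), k + table$trait_index)] <- table$wing
  labs <- table |>
    dplyr::distinct(.data$trait_index, .data$trait_class, .data$diet) |>
    dplyr::arrange(.data$trait_index)
  list(y = table$value, X = X, trait = trait0, species = species0,
       species_levels = sp, traits = labs, A = A,
       k = as.integer(k), m = length(sp), n = n)
}

# internal: expand scalar prior scale to a k x k matrix, default df;
# NULL scale -> 0.5 * diag(observed per-trait variance)
resolve_priors <- function(priors, k, y, trait0) {
  dv <- vapply(seq_len(k) - 1L, function(t) var(y[trait0 == t]), numeric(1))
  scale_mat <- function(s) {
    if (is.null(s)) {
      diag(0.5 * dv, k)
    } else if (is.matrix(s)) {
      stopifnot(nrow(s) == k, ncol(s) == k)
      s
    } else {
      diag(s, k)
    }
  }
  vp_df <- priors$vp_df %||% (k + 1)
  vs_df <- priors$vs_df %||% (k + 1)
  if (vp_df <= k - 1 || vs_df <= k - 1) {
    abort("inverse-Wishart degrees of freedom must exceed k - 1")
  }
  ve_rate <- priors$ve_rate
  if (is.null(ve_rate)) ve_rate <- 0.5 * dv
  ve_rate <- rep_len(ve_rate, k)
  ve_shape <- rep_len(priors$ve_shape, k)
  list(vp_scale = scale_mat(priors$vp_scale), vp_df = vp_df,
       vs_scale = scale_mat(priors$vs_scale), vs_df = vs_df,
       ve_shape = ve_shape, ve_rate = ve_rate,
       beta_prec = 1 / priors$beta_var)
}

#' Fit the multivariate phylogenetic mixed model by Gibbs sampling
#'
#' Fits, to a long-format trait table, the model
#' \deqn{y_{hit} = \beta_{1t} + \mathrm{wing}_h\,\beta_{2t} + u_{ht} + e_{hit}}
#' in which the stacked species effects are multivariate normal with
#' covariance `Vp %x% A` (between-species trait covariance crossed with the
#' Brownian-motion relatedness matrix of the phylogeny) and the residuals
#' have a diagonal trait covariance `Ve` — off-diagonal residual covariances
#' are not estimable with one measurement per vial and are fixed at zero.
#' Optionally a second, non-phylogenetic species effect with covariance
#' `Vs %x% I` is added (`include_species_term`), which is what permits
#' estimating phylogenetic heritability; the main model omits it.
#'
#' The sampler is a blocked Gibbs sampler: all location effects (fixed
#' effects and species effects jointly) are drawn from their multivariate
#' normal full conditional, `Vp` (and `Vs`) from inverse-Wishart full
#' conditionals, and each residual variance from its inverse-gamma full
#' conditional. The joint location update avoids the slow mixing of
#' one-at-a-time updates when effects are correlated through `A`.
#'
#' @param table Trait table from [build_trait_table()] (or
#'   [simulate_trait_table()]).
#' @param A Relatedness matrix (see [relatedness_matrix()]); positive
#'   semi-definite. A tiny diagonal jitter is applied if its Cholesky fails.
#' @param control A [pmm_control()] (the seed lives here).
#' @param priors A [pmm_priors()].
#' @param include_species_term Add the non-phylogenetic species effect.
#' @param trait_classes Optional subset of
#'   `c("viral_load", "survival_infected", "survival_control")`; the model
#'   is refitted on the reduced trait set with correspondingly smaller
#'   covariance matrices.
#' @param store_u Keep the per-draw species effects (memory-heavier).
#' @param include_phylo Drop the phylogenetic term entirely (for oracle
#'   checks and null fits).
#' @param fix_vp,fix_ve Fix `Vp` (matrix) or `Ve` (vector) at known values
#'   instead of sampling them; used for conjugate closed-form checks.
#' @return An object of class `pmm_fit`: list with `draws` (matrices
#'   `beta`, `vp`, `ve`, `vs`, `u`), `traits`, `species_levels`, `control`,
#'   `priors`, and the model flags.
#' @export
pmm_fit <- function(table, A, control, priors = pmm_priors(),
                    include_species_term = FALSE, trait_classes = NULL,
                    store_u = FALSE, include_phylo = TRUE,
                    fix_vp = NULL, fix_ve = NULL) {
  stopifnot(inherits(control, "pmm_control"), inherits(priors, "pmm_priors"))
  if (!is.null(trait_classes)) {
    if (!length(trait_classes)) abort("`trait_classes` must be non-empty")
    bad <- setdiff(trait_classes, trait_classes())
    if (length(bad)) abort(paste0("unknown trait classes: ", paste(bad, collapse = ", ")))
    table <- dplyr::filter(table, .data$trait_class %in% trait_classes)
    # remap to contiguous 1..k preserving (class, diet) order
    old <- sort(unique(table$trait_index))
    table$trait_index <- match(table$trait_index, old)
  }
  des <- build_design(table, A)
  k <- des$k
  counts <- tabulate(des$trait + 1L, nbins = k)
  if (any(counts < 2L)) abort("need at least 2 observations per trait")
  pr <- resolve_priors(priors, k, des$y, des$trait)

  # A^-1 via Cholesky, with a small logged jitter if A is only semi-definite
  Ainv <- tryCatch(
    chol2inv(chol(des$A)),
    error = function(e) {
      inform("relatedness matrix is singular; adding 1e-8 diagonal jitter")
      chol2inv(chol(des$A + diag(1e-8, nrow(des$A))))
    }
  )

  dv <- vapply(seq_len(k) - 1L, function(t) var(des$y[des$trait == t]), numeric(1))
  vp_init <- diag(pmax(dv / 2, 1e-6), k)
  ve_init <- pmax(dv / 2, 1e-6)

  set.seed(control$seed)
  raw <- gibbs_pmm_cpp(
    y = des$y, trait = des$trait, species = des$species, X = des$X,
    Ainv = Ainv, k = k, m = des$m,
    vp_scale = pr$vp_scale, vp_df = pr$vp_df,
    vs_scale = pr$vs_scale, vs_df = pr$vs_df,
    ve_shape = pr$ve_shape, ve_rate = pr$ve_rate,
    beta_prec = pr$beta_prec,
    include_phylo = include_phylo,
    include_species_term = include_species_term,
    vp_fixed = !is.null(fix_vp),
    fix_vp = if (is.null(fix_vp)) diag(1, k) else fix_vp,
    ve_fixed = !is.null(fix_ve),
    fix_ve = if (is.null(fix_ve)) rep(1, k) else rep_len(fix_ve, k),
    vp_init = vp_init, ve_init = ve_init,
    n_iter = control$n_iter, burn_in = control$burn_in, thin = control$thin,
    store_u = store_u
  )
  colnames(raw$beta) <- colnames(des$X)
  structure(
    list(
      draws = list(
        beta = raw$beta,
        vp = if (include_phylo) raw$vp else NULL,
        ve = raw$ve,
        vs = if (include_species_term) raw$vs else NULL,
        u = if (store_u && include_phylo) raw$u else NULL
      ),
      traits = des$traits, species_levels = des$species_levels,
      k = k, m = des$m, n = des$n,
      include_species_term = include_species_term,
      include_phylo = include_phylo,
      control = control, priors = priors
    ),
    class = "pmm_fit"
  )
}

#' Refit the model on a subset of trait classes
#'
#' Convenience wrapper around [pmm_fit()] with `trait_classes` set; the
#' covariance matrices shrink to the retained traits (3 per class).
#'
#' @inheritParams pmm_fit
#' @param trait_classes Non-empty subset of [trait_classes()].
#' @export
fit_subset <- function(table, A, control, trait_classes,
                       priors = pmm_priors(), ...) {
  pmm_fit(table, A, control, priors = priors,
          trait_classes = trait_classes, ...)
}

#' Re-run a fit under alternative priors
#'
#' @param table,A,control Passed to [pmm_fit()].
#' @param prior_list Named list of [pmm_priors()] objects.
#' @param ... Passed to [pmm_fit()].
#' @return Named list of `pmm_fit` objects.
#' @export
pmm_sensitivity <- function(table, A, control, prior_list, ...) {
  stopifnot(length(prior_list) > 0)
  purrr::map(prior_list, function(pr) pmm_fit(table, A, control, priors = pr, ...))
}

#' @export
print.pmm_fit <- function(x, ...) {
  cat("Multivariate phylogenetic mixed model fit\n")
  cat("  traits:", x$k, " species:", x$m, " observations:", x$n, "\n")
  cat("  retained draws:", nrow(x$draws$beta),
      sprintf("(n_iter %d, burn-in %d, thin %d, seed %d)\n",
              x$control$n_iter, x$control$burn_in, x$control$thin,
              x$control$seed))
  cat("  phylogenetic term:", x$include_phylo,
      " species term:", x$include_species_term, "\n")
  invisible(x)
}

#' Tidy a fitted phylogenetic mixed model
#'
#' Broom-style one-row-per-parameter summary: posterior means and 95% HPD
#' intervals for the fixed effects, the diagonal variance components and
#' the between-species correlations.
#'
#' @param x A `pmm_fit`.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `conf.low`, `conf.high`.
#' @export
tidy.pmm_fit <- function(x, ...) {
  s <- summarize_pmm(x)
  lab <- ifelse(
    is.na(s$trait_class), s$statistic,
    ifelse(is.na(s$trait_class2),
           paste0(s$statistic, "[", s$trait_class, ".", s$diet, "]"),
           paste0(s$statistic, "[", s$trait_class, ".", s$diet, ",",
                  s$trait_class2, ".", s$diet2, "]"))
  )
  tibble::tibble(term = lab, estimate = s$mean,
                 conf.low = s$hpd_lower, conf.high = s$hpd_upper)
}

#' One-row model-level summary of a fit
#'
#' @param x A `pmm_fit`.
#' @param ... Unused.
#' @return A tibble with draw counts and the minimum effective sample size
#'   across fixed effects and variance diagonals.
#' @export
glance.pmm_fit <- function(x, ...) {
  mons <- cbind(
    x$draws$beta,
    if (!is.null(x$draws$vp)) x$draws$vp[, (seq_len(x$k) - 1) * x$k + seq_len(x$k), drop = FALSE],
    x$draws$ve
  )
  ess <- tryCatch(
    as.numeric(coda::effectiveSize(coda::mcmc(mons))),
    error = function(e) rep(NA_real_, ncol(mons))
  )
  tibble::tibble(
    n_obs = x$n, n_species = x$m, n_traits = x$k,
    n_draws = nrow(x$draws$beta),
    min_ess = min(ess, na.rm = TRUE), median_ess = stats::median(ess, na.rm = TRUE)
  )
}
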