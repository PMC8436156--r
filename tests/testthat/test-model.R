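test_that("design matrices map rows to trait cells with trait-major stacking", {
  A <- identity_relatedness(2)
  tt <- toy_trait_table(A, vp = diag(c(1, 1)), ve = c(1, 1),
                        means = c(0, 0), blocks = 1, seed = 2)
  des <- build_design(tt$table, A)
  expect_equal(des$k, 2)
  expect_equal(des$m, 2)
  # one observation per cell: the (species, trait) cell indices are a
  # permutation of all 4 cells
  cells <- des$trait * des$m + des$species
  expect_setequal(cells, 0:3)
  # every fixed-effect row has exactly its intercept (wing = 0 here)
  expect_equal(rowSums(des$X != 0), rep(1, des$n))
  wtab <- tt$table
  wtab$wing <- 0.7
  desw <- build_design(wtab, A)
  expect_equal(rowSums(desw$X != 0), rep(2, desw$n))
  expect_equal(unname(colSums(desw$X[, 3:4])), c(0.7 * 2, 0.7 * 2))
})

test_that("stacking convention matches the Kronecker prior: cov = vp[t,s] * A[i,j]", {
  set.seed(9)
  tr <- simulate_tree(4, seed = 3)
  A <- relatedness_matrix(tr)
  Z <- matrix(rnorm(9), 3, 3)
  vp <- crossprod(Z) + diag(0.5, 3)
  nrep <- 4000
  m <- 4; k <- 3
  acc <- matrix(0, m * k, m * k)
  for (r in seq_len(nrep)) {
    u <- as.vector(simulate_species_effects(A, vp, seed = 40000 + r))
    acc <- acc + tcrossprod(u)
  }
  emp <- acc / nrep
  for (t1 in 1:k) for (t2 in 1:k) for (i in 1:m) for (j in 1:m) {
    want <- vp[t1, t2] * A[i, j]
    got <- emp[(t1 - 1) * m + i, (t2 - 1) * m + j]
    vfac <- vp[t1, t1] * A[i, i] * vp[t2, t2] * A[j, j] + want^2
    expect_lt(abs(got - want), 3.5 * sqrt(vfac / nrep) + 1e-12)
  }
})

test_that("design validation errors name the offending taxa and indices", {
  A <- identity_relatedness(2)
  tt <- toy_trait_table(A, diag(2), c(1, 1), c(0, 0), seed = 1)
  extra <- tt$table
  extra$species[1] <- "ghost"
  expect_error(build_design(extra, A), "ghost")
  bigA <- identity_relatedness(3)
  expect_error(build_design(tt$table, bigA), "sp03")
  bad <- tt$table
  bad$trait_index[1] <- 12
  expect_error(build_design(bad, A), "1..9|contiguous")
})

test_that("gibbs draws are reproducible given a seed", {
  A <- identity_relatedness(5)
  tt <- toy_trait_table(A, diag(c(2, 1)), c(0.5, 0.5), c(1, -1),
                        blocks = 2, seed = 4)
  f1 <- pmm_fit(tt$table, A, pmm_control(800, 200, 2, seed = 42))
  f2 <- pmm_fit(tt$table, A, pmm_control(800, 200, 2, seed = 42))
  expect_identical(f1$draws$beta, f2$draws$beta)
  expect_identical(f1$draws$vp, f2$draws$vp)
  f3 <- pmm_fit(tt$table, A, pmm_control(800, 200, 2, seed = 43))
  expect_false(identical(f1$draws$beta, f3$draws$beta))
})

test_that("every retained covariance draw is symmetric PD and residual variances positive", {
  p <- sim_params(n_species = 10)
  d <- simulate_trait_table(p, seed = 50)
  fit <- pmm_fit(d$table, d$A, pmm_control(1500, 300, 2, seed = 51),
                 include_species_term = TRUE)
  for (r in seq_len(nrow(fit$draws$vp))) {
    vp <- matrix(fit$draws$vp[r, ], 9, 9)
    expect_true(isSymmetric(vp, tol = 1e-10))
    expect_gt(min(eigen(vp, symmetric = TRUE, only.values = TRUE)$values), 0)
    vs <- matrix(fit$draws$vs[r, ], 9, 9)
    expect_gt(min(eigen(vs, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
  expect_true(all(fit$draws$ve > 0))
})

test_that("with no phylogenetic term and known ve, beta matches the GLS posterior", {
  # conjugate oracle: flat beta prior, fixed residual variance -> the
  # Gibbs draws are iid from N((X'X)^-1 X'y, ve (X'X)^-1)
  set.seed(71)
  n <- 30
  A <- identity_relatedness(3)
  labs <- trait_labels()[1, ]
  tab <- tibble::tibble(
    observation_id = as.character(1:n),
    species = rep(rownames(A), length.out = n),
    trait_class = labs$trait_class, diet = labs$diet, trait_index = 1L,
    wing = rnorm(n), value = NA_real_
  )
  beta_true <- c(2, -1.5)
  ve <- 0.7
  tab$value <- beta_true[1] + beta_true[2] * tab$wing + rnorm(n, 0, sqrt(ve))
  fit <- pmm_fit(tab, A, pmm_control(4000, 500, 1, seed = 72),
                 include_phylo = FALSE, fix_ve = ve,
                 priors = pmm_priors(beta_var = 1e12))
  X <- cbind(1, tab$wing)
  XtXinv <- solve(crossprod(X))
  post_mean <- XtXinv %*% crossprod(X, tab$value)
  post_cov <- ve * XtXinv
  draws <- fit$draws$beta
  n_eff <- nrow(draws)  # draws are iid in this conjugate setting
  for (j in 1:2) {
    mc_se <- sqrt(post_cov[j, j] / n_eff)
    expect_lt(abs(mean(draws[, j]) - post_mean[j]), 3.5 * mc_se)
    sd_se <- sqrt(post_cov[j, j]) / sqrt(2 * (n_eff - 1))
    expect_lt(abs(sd(draws[, j]) - sqrt(post_cov[j, j])), 4 * sd_se)
  }
})

test_that("with identity A and fixed covariances, species-effect shrinkage matches closed form", {
  # 3 species, 2 traits: (beta, u) | y is Gaussian with precision
  # W' R^-1 W + blockdiag(B, (Vp kron I)^-1); compare moments of the draws
  set.seed(81)
  A <- identity_relatedness(3)
  Vp <- matrix(c(2, 1.2, 1.2, 2), 2, 2)
  ve <- c(0.5, 0.8)
  tt <- toy_trait_table(A, Vp, ve, c(1, 1), blocks = 2, seed = 82)
  fit <- pmm_fit(tt$table, A, pmm_control(30000, 1000, 5, seed = 83),
                 fix_vp = Vp, fix_ve = ve, store_u = TRUE,
                 priors = pmm_priors(beta_var = 1e10))
  des <- build_design(tt$table, A)
  n <- des$n; m <- 3; k <- 2
  Z <- matrix(0, n, m * k)
  Z[cbind(seq_len(n), des$trait * m + des$species + 1)] <- 1
  W <- cbind(des$X, Z)
  Rinv <- diag(1 / ve[des$trait + 1])
  P <- matrix(0, ncol(W), ncol(W))
  diag(P)[seq_len(ncol(des$X))] <- 1e-10
  P[-seq_len(ncol(des$X)), -seq_len(ncol(des$X))] <- solve(Vp %x% diag(m))
  C <- t(W) %*% Rinv %*% W + P
  mu <- solve(C, t(W) %*% Rinv %*% des$y)
  Sig <- solve(C)
  draws <- cbind(fit$draws$beta, fit$draws$u)
  keep <- c(1, 2, 5:10)  # intercepts + the 6 species effects (wing cols unidentified)
  n_eff <- nrow(draws)
  for (j in keep) {
    mc_se <- sqrt(Sig[j, j] / n_eff)
    expect_lt(abs(mean(draws[, j]) - mu[j]), 4 * mc_se)
    expect_lt(abs(sd(draws[, j]) - sqrt(Sig[j, j])),
              4 * sqrt(Sig[j, j]) / sqrt(n_eff))
  }
})

test_that("with data carrying no information, vp draws follow the prior", {
  A <- identity_relatedness(8)
  tt <- toy_trait_table(A, diag(2), c(1, 1), c(0, 0), blocks = 2, seed = 6)
  fit <- pmm_fit(tt$table, A, pmm_control(20000, 2000, 4, seed = 7),
                 priors = pmm_priors(vp_scale = 0.5, vp_df = 6,
                                     beta_var = 1e-8),
                 fix_ve = 1e12)
  vp <- fit$draws$vp
  prior_mean <- 0.5 / (6 - 2 - 1)
  n_eff <- min(as.numeric(coda::effectiveSize(coda::mcmc(vp[, c(1, 4)]))))
  for (jj in c(1, 4)) {
    mc_se <- sd(vp[, jj]) / sqrt(n_eff)
    expect_lt(abs(mean(vp[, jj]) - prior_mean), 4 * mc_se)
  }
  expect_lt(abs(mean(vp[, 2])), 4 * sd(vp[, 2]) / sqrt(n_eff))
})

test_that("trait-class subsets shrink the covariance and all-class subset matches the full fit", {
  p <- sim_params(n_species = 8)
  d <- simulate_trait_table(p, seed = 90)
  ctrl <- pmm_control(600, 200, 2, seed = 91)
  sub <- fit_subset(d$table, d$A, ctrl, trait_classes = "viral_load")
  expect_equal(sub$k, 3)
  expect_equal(ncol(sub$draws$vp), 9)
  expect_equal(sub$traits$trait_class, rep("viral_load", 3))
  full <- pmm_fit(d$table, d$A, ctrl)
  all3 <- fit_subset(d$table, d$A, ctrl, trait_classes = trait_classes())
  expect_identical(all3$draws$beta, full$draws$beta)
  expect_identical(all3$draws$vp, full$draws$vp)
  expect_error(fit_subset(d$table, d$A, ctrl, trait_classes = character(0)),
               "non-empty")
})

test_that("posterior summaries are invariant to relabelling species order", {
  p <- sim_params(n_species = 8)
  d <- simulate_trait_table(p, seed = 95)
  ctrl <- pmm_control(8000, 2000, 3, seed = 96)
  f1 <- pmm_fit(d$table, d$A, ctrl)
  perm <- sample(8)
  A2 <- d$A[perm, perm]
  tab2 <- d$table[sample(nrow(d$table)), ]
  f2 <- pmm_fit(tab2, A2, ctrl)
  s1 <- summarize_pmm(f1)
  s2 <- summarize_pmm(f2)
  keep <- s1$statistic %in% c("vp", "ve", "repeatability")
  expect_equal(s2$mean[keep], s1$mean[keep], tolerance = 0.25)
  # correlations compared on a coarser scale (posterior sd ~ 0.1)
  kc <- s1$statistic == "correlation"
  expect_equal(s2$mean[kc], s1$mean[kc], tolerance = 0.2)
})

test_that("sensitivity helper refits under each prior in the list", {
  p <- sim_params(n_species = 6)
  d <- simulate_trait_table(p, seed = 97)
  ctrl <- pmm_control(400, 100, 2, seed = 98)
  fits <- pmm_sensitivity(
    d$table, d$A, ctrl,
    list(default = pmm_priors(), wide = pmm_priors(vp_df = 12))
  )
  expect_named(fits, c("default", "wide"))
  expect_s3_class(fits$default, "pmm_fit")
})

test_that("tidy and glance return broom-shaped tibbles", {
  p <- sim_params(n_species = 6)
  d <- simulate_trait_table(p, seed = 99)
  fit <- pmm_fit(d$table, d$A, pmm_control(1200, 200, 2, seed = 100))
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "conf.low", "conf.high") %in% names(td)))
  expect_true(any(grepl("repeatability", td$term)))
  g <- glance(fit)
  expect_equal(g$n_species, 6)
  expect_gt(g$min_ess, 0)
})

test_that("mcmc controls validate their invariants", {
  expect_error(pmm_control(100, 200, 1, seed = 1), "burn_in")
  expect_error(pmm_control(100, 10, 0, seed = 1), "thin")
  expect_error(pmm_control(100, 10, 1), "seed")
})
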