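# internal: lower square root of a symmetric PSD matrix (Cholesky when PD,
# eigen square root otherwise, so rank-deficient covariances — e.g. trait
# correlations of exactly 1 — are simulable)
psd_sqrt <- function(S) {
  L <- tryCatch(t(chol(S)), error = function(e) NULL)
  if (!is.null(L)) return(L)
  e <- eigen(S, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  e$vectors %*% diag(sqrt(vals), length(vals))
}

#' Default between-species covariance used by the simulator
#'
#' A 9x9 block-diagonal matrix over the three trait classes. Within each
#' class, the three diet traits share one variance with a common inter-diet
#' correlation; across classes covariances are zero. Defaults mirror the
#' parameter regime the cross-species infection literature reports for DCV:
#' viral-load between-species variance near 77 (log2 units squared),
#' survival-trait variances near 0.18, inter-diet correlations of 0.9.
#'
#' @param v_load,v_surv Within-class variances for viral load and for both
#'   survival classes.
#' @param rho Common inter-diet correlation within each class.
#' @return A 9x9 symmetric PSD matrix.
#' @export
default_true_vp <- function(v_load = 77, v_surv = 0.18, rho = 0.9) {
  blk <- function(v) v * (diag(1 - rho, 3) + rho)
  as.matrix(Matrix_bdiag(list(blk(v_load), blk(v_surv), blk(v_surv))))
}

# tiny block-diagonal helper (avoids importing Matrix for one call)
Matrix_bdiag <- function(blocks) {
  sizes <- vapply(blocks, nrow, integer(1))
  n <- sum(sizes)
  out <- matrix(0, n, n)
  at <- 0L
  for (b in blocks) {
    idx <- at + seq_len(nrow(b))
    out[idx, idx] <- b
    at <- at + nrow(b)
  }
  out
}

#' Parameters of the synthetic experiment
#'
#' Describes the full crossed design the generator emulates: `n_species`
#' host species on 3 diets in 3 experimental blocks, each species-diet-block
#' cell contributing one day-0/day-2 viral-load pair (measured by duplicate
#' qRT-PCR reactions on shared plates with four standards each) plus one
#' virus-challenged and one sham-inoculated vial followed daily for 21 days.
#'
#' @param n_species Number of host species (default 27).
#' @param blocks Experimental blocks (default 3).
#' @param true_vp 9x9 between-species trait covariance
#'   (default [default_true_vp()]).
#' @param true_ve Residual variances per trait (default 6.5 for the load
#'   traits, 0.02 for the survival traits).
#' @param true_means Trait means (default load 11.4, 10.6, 10.6 across
#'   diets; infected survival 0.7; control survival 0.92).
#' @param wing_effect Common slope of the centred species wing length on
#'   every trait (default -0.05).
#' @param wing_mean,wing_sd Species wing-length distribution (mm).
#' @param plate_offsets Vector of per-plate Ct offsets, recycled over
#'   plates; a scalar 0 disables plate effects.
#' @param tech_rep_sd SD of technical-replicate Ct noise (cycles).
#' @param flies_per_vial Flies per vial at day 0.
#' @param days Days of survival follow-up (default 21).
#' @param dct_day0 Baseline day-0 delta-Ct, constant per species (absolute
#'   Ct levels are arbitrary; only differences propagate).
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_species = 27, blocks = 3,
                       true_vp = default_true_vp(),
                       true_ve = c(rep(6.5, 3), rep(0.02, 6)),
                       true_means = c(11.4, 10.6, 10.6, rep(0.7, 3), rep(0.92, 3)),
                       wing_effect = -0.05,
                       wing_mean = 2, wing_sd = 0.15,
                       plate_offsets = c(-0.6, 0.3, 0, 0.8, -0.2, 0.4),
                       tech_rep_sd = 0.2,
                       flies_per_vial = 15, days = 21,
                       dct_day0 = 12) {
  stopifnot(n_species >= 2, blocks >= 1, flies_per_vial >= 1, days >= 1)
  true_vp <- as.matrix(true_vp)
  stopifnot(nrow(true_vp) == 9, isSymmetric(true_vp),
            min(eigen(true_vp, symmetric = TRUE, only.values = TRUE)$values) > -1e-8,
            length(true_ve) == 9, all(true_ve >= 0), length(true_means) == 9)
  structure(
    list(n_species = n_species, blocks = blocks, true_vp = true_vp,
         true_ve = true_ve, true_means = true_means,
         wing_effect = wing_effect, wing_mean = wing_mean, wing_sd = wing_sd,
         plate_offsets = plate_offsets, tech_rep_sd = tech_rep_sd,
         flies_per_vial = flies_per_vial, days = days, dct_day0 = dct_day0),
    class = "sim_params"
  )
}

#' Simulate a pure-birth host phylogeny, scaled to unit height
#'
#' @param n_species Number of leaves (>= 2).
#' @param seed RNG seed (mandatory).
#' @return A unit-height ultrametric `phylo` with tips `sp01`, `sp02`, ...
#' @export
simulate_tree <- function(n_species, seed) {
  if (n_species < 2) abort("need at least 2 species")
  if (missing(seed)) abort("a `seed` is required")
  set.seed(seed)
  tr <- ape::rphylo(n_species, birth = 1, death = 0)
  tr$tip.label <- sprintf("sp%02d", seq_len(n_species))
  make_ultrametric(tr, extend_tips = TRUE)
}

#' Draw species-level trait effects under Brownian motion on the tree
#'
#' Samples one realisation of a zero-mean multivariate normal with
#' covariance `true_vp %x% A` in trait-major stacking — the same convention
#' the model's design uses — returned as a species-by-trait matrix.
#'
#' @param A Relatedness matrix (PSD).
#' @param true_vp Trait covariance matrix (PSD; rank deficiency allowed).
#' @param seed RNG seed (mandatory).
#' @return `n_species x k` matrix with A's taxa as rownames.
#' @export
simulate_species_effects <- function(A, true_vp, seed) {
  if (missing(seed)) abort("a `seed` is required")
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  true_vp <- as.matrix(true_vp)
  set.seed(seed)
  m <- nrow(A)
  k <- nrow(true_vp)
  Z <- matrix(rnorm(m * k), m, k)
  U <- psd_sqrt(A) %*% Z %*% t(psd_sqrt(true_vp))
  rownames(U) <- rownames(A)
  U
}

#' Simulate a latent trait table directly from the model
#'
#' Generates exactly the data-generating process the mixed model assumes —
#' species effects from `Vp %x% A`, independent residuals per observation —
#' with `blocks` replicates per species-trait cell. This is the simulation
#' oracle for parameter-recovery checks; [simulate_experiment()] layers the
#' measurement process (Ct encoding, death counts) on top.
#'
#' @param params A [sim_params()].
#' @param seed RNG seed (mandatory).
#' @param tree Optional `phylo`; simulated from `seed` when absent.
#' @return List with `table` (a trait table), `tree`, `A`, `effects`
#'   (species-by-trait matrix), `wing` (centred species wing tibble).
#' @export
simulate_trait_table <- function(params, seed, tree = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (missing(seed)) abort("a `seed` is required")
  if (is.null(tree)) tree <- simulate_tree(params$n_species, seed = seed + 1L)
  A <- relatedness_matrix(tree)
  set.seed(seed)
  m <- nrow(A)
  wing_raw <- rnorm(m, params$wing_mean, params$wing_sd)
  wing <- tibble::tibble(species = rownames(A),
                         wing = wing_raw - mean(wing_raw))
  U <- simulate_species_effects(A, params$true_vp, seed = seed + 2L)
  labs <- trait_labels()
  grid <- tidyr::expand_grid(
    species = rownames(A), trait_index = 1:9, block = seq_len(params$blocks)
  )
  si <- match(grid$species, rownames(A))
  mu <- params$true_means[grid$trait_index] +
    wing$wing[si] * params$wing_effect +
    U[cbind(si, grid$trait_index)]
  value <- mu + rnorm(nrow(grid), 0, sqrt(params$true_ve[grid$trait_index]))
  table <- grid |>
    dplyr::left_join(labs, by = "trait_index") |>
    dplyr::left_join(wing, by = "species") |>
    dplyr::mutate(observation_id = sprintf("obs%04d", dplyr::row_number()),
                  value = value) |>
    dplyr::select("observation_id", "species", "trait_class", "diet",
                  "trait_index", "value", "wing", "block")
  list(table = table, tree = tree, A = A, effects = U, wing = wing)
}

#' Daily hazard matching a target mean proportion alive
#'
#' Inverts the survival trait for a constant-hazard vial: finds `h` such
#' that the mean over days 1..`days` of `(1 - h)^day` equals `target`, by
#' bisection to an interval width of 1e-10.
#'
#' @param target Target mean proportion alive, in (0, 1].
#' @param days Length of the observation window.
#' @return The daily death hazard, in \[0, 1).
#' @export
hazard_from_mean_survival <- function(target, days = 21) {
  if (!is.finite(target) || target <= 0 || target > 1) {
    abort("`target` must lie in (0, 1]")
  }
  if (target == 1) return(0)
  f <- function(h) mean((1 - h)^(seq_len(days))) - target
  lo <- 0; hi <- 1 - 1e-12
  if (f(hi) > 0) return(hi)  # target below the attainable minimum
  while (hi - lo > 1e-10) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Simulate the full measured experiment
#'
#' Takes the latent traits from [simulate_trait_table()] and pushes them
#' through the measurement process the analysis has to undo:
#' \itemize{
#'   \item each species-diet-block cell yields a day-0 and a day-2 qPCR
#'     sample; the reference-gene Ct sits at 18, the viral Ct at
#'     `18 + delta-Ct`, with the day-0 delta-Ct fixed per species and the
#'     day-2 delta-Ct lower by the latent log2 load change;
#'   \item samples are laid out on one plate per diet-block-day with four
#'     shared standards per plate; each plate adds its Ct offset and every
#'     reaction is duplicated with technical noise;
#'   \item each cell gets one virus and one sham vial whose daily deaths
#'     are binomial draws at the constant hazard matching the vial's latent
#'     mean survival (clamped to (0, 1]).
#' }
#' With `tech_rep_sd = 0` the qPCR path is exactly invertible (plate
#' offsets are removed by the standards), so trait construction returns the
#' latent loads to machine precision; death counts are integer-valued, so
#' survival traits match their latent values in expectation only.
#'
#' @param params A [sim_params()].
#' @param seed RNG seed (mandatory).
#' @return List with `ct` (Ct records), `survival` (wide survival records),
#'   `wing` (species wing means, uncentred on output), `tree`, and
#'   `latent` (the [simulate_trait_table()] result).
#' @export
simulate_experiment <- function(params, seed) {
  stopifnot(inherits(params, "sim_params"))
  if (missing(seed)) abort("a `seed` is required")
  latent <- simulate_trait_table(params, seed = seed)
  tab <- latent$table
  set.seed(seed + 3L)

  diets <- diet_levels()
  plate_grid <- tidyr::expand_grid(diet = diets,
                                   block = seq_len(params$blocks),
                                   day = c(0L, 2L))
  plate_grid$plate_id <- sprintf("plate_%s_b%d_d%d", plate_grid$diet,
                                 plate_grid$block, plate_grid$day)
  offs <- rep_len(params$plate_offsets, nrow(plate_grid))
  plate_grid$offset <- offs

  loads <- dplyr::filter(tab, .data$trait_class == "viral_load")
  ct_sample <- function(species, diet, block, day, dct) {
    tibble::tibble(
      sample_id = sprintf("%s_%s_b%d_day%d", species, diet, block, day),
      species = species, diet = diet, block = block, day = day,
      target = c("DCV", "RpL32"),
      true_ct = c(18 + dct, 18),
      is_standard = FALSE
    )
  }
  ct0 <- purrr::pmap(
    list(loads$species, loads$diet, loads$block),
    function(sp, dt, bl) ct_sample(sp, dt, bl, 0L, params$dct_day0)
  )
  ct2 <- purrr::pmap(
    list(loads$species, loads$diet, loads$block, loads$value),
    function(sp, dt, bl, v) ct_sample(sp, dt, bl, 2L, params$dct_day0 - v)
  )
  samples <- dplyr::bind_rows(ct0, ct2) |>
    dplyr::left_join(plate_grid[c("diet", "block", "day", "plate_id", "offset")],
                     by = c("diet", "block", "day"))

  std_true <- tidyr::expand_grid(
    std = 1:4, target = c("DCV", "RpL32")
  ) |>
    dplyr::mutate(
      sample_id = sprintf("std%d", .data$std),
      true_ct = dplyr::if_else(.data$target == "DCV", 19 + 2 * .data$std,
                               16 + 2 * .data$std)
    )
  standards <- tidyr::expand_grid(plate_id = plate_grid$plate_id,
                                  std = 1:4) |>
    dplyr::left_join(std_true, by = "std", relationship = "many-to-many") |>
    dplyr::left_join(plate_grid[c("plate_id", "offset")], by = "plate_id") |>
    dplyr::mutate(species = NA_character_, diet = NA_character_,
                  block = NA_integer_, day = NA_integer_,
                  is_standard = TRUE) |>
    dplyr::select(dplyr::all_of(names(samples)))

  ct <- dplyr::bind_rows(samples, standards) |>
    dplyr::mutate(
      ct_rep1 = .data$true_ct + .data$offset +
        rnorm(dplyr::n(), 0, params$tech_rep_sd),
      ct_rep2 = .data$true_ct + .data$offset +
        rnorm(dplyr::n(), 0, params$tech_rep_sd)
    ) |>
    dplyr::select("sample_id", "species", "diet", "block", "day",
                  "plate_id", "target", "ct_rep1", "ct_rep2", "is_standard")

  survs <- dplyr::filter(tab, .data$trait_class != "viral_load") |>
    dplyr::mutate(
      treatment = dplyr::if_else(.data$trait_class == "survival_infected",
                                 "virus", "sham"),
      target_surv = pmin(pmax(.data$value, 1e-6), 1)
    )
  day_mat <- matrix(0L, nrow(survs), params$days)
  for (i in seq_len(nrow(survs))) {
    h <- hazard_from_mean_survival(survs$target_surv[i], params$days)
    alive <- params$flies_per_vial
    for (d in seq_len(params$days)) {
      dth <- rbinom(1, alive, h)
      day_mat[i, d] <- dth
      alive <- alive - dth
    }
  }
  colnames(day_mat) <- paste0("day_", seq_len(params$days))
  survival <- survs |>
    dplyr::transmute(
      vial_id = sprintf("vial_%s_%s_b%d_%s", .data$species, .data$diet,
                        .data$block, .data$treatment),
      species = .data$species, diet = .data$diet, block = .data$block,
      treatment = .data$treatment, n_start = params$flies_per_vial
    ) |>
    dplyr::bind_cols(tibble::as_tibble(day_mat))

  wing <- dplyr::mutate(latent$wing, wing = .data$wing + params$wing_mean)
  list(ct = ct, survival = survival, wing = wing,
       tree = latent$tree, latent = latent)
}

#' Rebuild the trait table from simulated (or real) raw records
#'
#' Runs the whole trait-construction pipeline: plate correction,
#' technical-replicate QC, delta-Ct, day-0/day-2 pairing, log2 load change,
#' survival traits, assembly with centred wing means.
#'
#' @param ct Ct records tibble.
#' @param survival Wide survival records tibble.
#' @param wing Species wing means tibble (`species`, `wing`).
#' @param qc_threshold Technical-replicate QC threshold (cycles).
#' @param last_day Survival observation window.
#' @return A trait table (see [build_trait_table()]).
#' @export
construct_traits <- function(ct, survival, wing, qc_threshold = 2,
                             last_day = 20) {
  pairs <- ct |>
    plate_correct() |>
    qc_technical_replicates(qc_threshold) |>
    delta_ct() |>
    pair_day0_day2()
  loads <- dplyr::mutate(pairs,
                         value = log2_load_change(.data$dct_day0, .data$dct_day2))
  survs <- survival_traits(survival, last_day = last_day)
  build_trait_table(loads, survs, wing)
}
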