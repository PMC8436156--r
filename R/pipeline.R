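#' Write a synthetic dataset to disk
#'
#' Materialises one simulated experiment as the CSV/newick files the fitting
#' pipeline reads, together with a YAML manifest of the parameters and seed
#' so the run is reproducible.
#'
#' @param out_dir Output directory.
#' @param params A [sim_params()].
#' @param seed RNG seed (mandatory; seeds are never defaulted).
#' @param force Overwrite an existing non-empty directory.
#' @return Invisibly, a named vector of the written file paths.
#' @export
run_simulate <- function(out_dir, params = sim_params(), seed, force = FALSE) {
  if (missing(seed)) abort("a `seed` is required")
  if (dir.exists(out_dir) && length(dir(out_dir)) && !force) {
    abort(paste0("output directory ", out_dir,
                 " exists and is non-empty; use force = TRUE"))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_experiment(params, seed = seed)
  paths <- c(
    ct = file.path(out_dir, "ct_records.csv"),
    survival = file.path(out_dir, "survival_records.csv"),
    wing = file.path(out_dir, "wing_means.csv"),
    tree = file.path(out_dir, "tree.nwk"),
    manifest = file.path(out_dir, "manifest.yaml")
  )
  readr::write_csv(sim$ct, paths[["ct"]])
  readr::write_csv(sim$survival, paths[["survival"]])
  readr::write_csv(sim$wing, paths[["wing"]])
  ape::write.tree(sim$tree, file = paths[["tree"]])
  manifest <- list(
    seed = as.integer(seed),
    params = lapply(unclass(params), function(x) {
      if (is.matrix(x)) as.vector(x) else x
    }),
    files = as.list(setNames(basename(paths), names(paths))),
    package_version = as.character(utils::packageVersion("phyvir"))
  )
  yaml::write_yaml(manifest, paths[["manifest"]])
  invisible(paths)
}

#' Fit the model to files on disk
#'
#' Glue from raw files to results: reads the tree and the raw record CSVs,
#' constructs the nine traits, fits the phylogenetic mixed model and writes
#' the posterior draws, the summary table and a manifest into `out_dir`.
#' Exclusion counts (QC repeats, unpaired blocks) surface as messages and
#' are recorded in the manifest.
#'
#' @param tree_file Newick file.
#' @param ct_file,survival_file,wing_file Record CSVs (schemas as written by
#'   [run_simulate()]).
#' @param out_dir Output directory for draws/summary/manifest (optional).
#' @param control A [pmm_control()].
#' @param priors A [pmm_priors()].
#' @param trait_classes Optional trait-class subset.
#' @param extend_tips Passed to [make_ultrametric()] for non-ultrametric
#'   input trees (e.g. substitutions-per-site trees).
#' @param ... Further arguments to [pmm_fit()].
#' @return List with `fit`, `summary`, `table`, `A` (invisibly if
#'   `out_dir` given).
#' @export
run_fit <- function(tree_file, ct_file, survival_file, wing_file,
                    control, priors = pmm_priors(), trait_classes = NULL,
                    out_dir = NULL, extend_tips = FALSE, ...) {
  tree <- parse_newick(file = tree_file) |>
    make_ultrametric(extend_tips = extend_tips)
  ct <- readr::read_csv(ct_file, show_col_types = FALSE)
  survival <- readr::read_csv(survival_file, show_col_types = FALSE)
  wing <- readr::read_csv(wing_file, show_col_types = FALSE)
  inform(paste0("read ", nrow(ct), " Ct records, ", nrow(survival),
                " vials, ", nrow(wing), " wing means"))
  table <- construct_traits(ct, survival, wing)
  inform(paste0("trait table: ", nrow(table), " observations, ",
                length(unique(table$species)), " species"))
  A <- relatedness_matrix(tree)
  fit <- pmm_fit(table, A, control, priors = priors,
                 trait_classes = trait_classes, ...)
  summ <- summarize_pmm(fit)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(summ, file.path(out_dir, "summary.csv"))
    readr::write_csv(tibble::as_tibble(fit$draws$beta),
                     file.path(out_dir, "draws_beta.csv"))
    if (!is.null(fit$draws$vp)) {
      readr::write_csv(tibble::as_tibble(fit$draws$vp, .name_repair = "unique_quiet"),
                       file.path(out_dir, "draws_vp.csv"))
    }
    readr::write_csv(tibble::as_tibble(fit$draws$ve, .name_repair = "unique_quiet"),
                     file.path(out_dir, "draws_ve.csv"))
    g <- glance(fit)
    yaml::write_yaml(
      list(seed = fit$control$seed, n_iter = fit$control$n_iter,
           burn_in = fit$control$burn_in, thin = fit$control$thin,
           n_obs = g$n_obs, n_draws = g$n_draws, min_ess = g$min_ess,
           package_version = as.character(utils::packageVersion("phyvir"))),
      file.path(out_dir, "fit_manifest.yaml")
    )
    return(invisible(list(fit = fit, summary = summ, table = table, A = A)))
  }
  list(fit = fit, summary = summ, table = table, A = A)
}

#' Run a full pipeline from a YAML config
#'
#' The config mirrors the function interface: either a `simulate:` block
#' (`seed`, optional parameter overrides) or an `inputs:` block
#' (`tree`, `ct`, `survival`, `wing`), plus `mcmc:` (`n_iter`, `burn_in`,
#' `thin`, `seed`), optional `trait_classes`, and `out_dir`.
#'
#' @param config Path to a YAML file, or an equivalent named list.
#' @return The [run_fit()] result list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  has_sim <- !is.null(config$simulate)
  has_inp <- !is.null(config$inputs)
  if (has_sim == has_inp) {
    abort("config must contain exactly one of `simulate:` or `inputs:`")
  }
  if (has_sim) {
    sb <- config$simulate
    if (is.null(sb$seed)) abort("simulate block requires a seed")
    par_args <- sb[setdiff(names(sb), "seed")]
    params <- do.call(sim_params, par_args)
    out_dir <- config$out_dir %||% tempfile("phyvir_sim_")
    paths <- run_simulate(file.path(out_dir, "data"), params,
                          seed = sb$seed, force = TRUE)
    inputs <- list(tree = paths[["tree"]], ct = paths[["ct"]],
                   survival = paths[["survival"]], wing = paths[["wing"]])
  } else {
    inputs <- config$inputs
    out_dir <- config$out_dir
  }
  mc <- config$mcmc
  if (is.null(mc$seed)) abort("mcmc block requires a seed")
  control <- pmm_control(n_iter = mc$n_iter %||% 50000,
                         burn_in = mc$burn_in %||% 10000,
                         thin = mc$thin %||% 20, seed = mc$seed)
  run_fit(inputs$tree, inputs$ct, inputs$survival, inputs$wing,
          control = control,
          trait_classes = config$trait_classes,
          out_dir = if (is.null(out_dir)) NULL else file.path(out_dir, "fit"),
          extend_tips = isTRUE(config$extend_tips))
}

#' @rdname report_summary
#' @export
run_report <- function(summary, digits = 2) report_summary(summary, digits)
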