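#' Highest posterior density interval
#'
#' The shortest contiguous interval containing `ceiling(mass * n)` of the
#' sorted draws — the standard HPD estimate for a unimodal posterior.
#'
#' @param draws Numeric vector of at least 100 posterior draws.
#' @param mass Posterior mass to cover (default 0.95).
#' @return Named numeric vector `c(lower, upper)`.
#' @export
hpd_interval <- function(draws, mass = 0.95) {
  draws <- draws[!is.na(draws)]
  n <- length(draws)
  if (n < 100L) abort("hpd_interval needs at least 100 draws")
  if (!(mass > 0 && mass < 1)) abort("`mass` must be in (0, 1)")
  x <- sort(draws)
  h <- ceiling(mass * n)
  if (h >= n) return(c(lower = x[1], upper = x[n]))
  widths <- x[h:n] - x[1:(n - h + 1)]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + h - 1])
}

#' Repeatability: fraction of trait variance between species
#'
#' `vp / (vp + ve)` — the proportion of the total variance in a trait that
#' lies between species rather than within them. Vectorised so it can be
#' applied draw-by-draw; ratio statistics should always be computed per
#' posterior draw and then summarised.
#'
#' @param vp Between-species (phylogenetic) variance, >= 0.
#' @param ve Residual variance, > 0 (or both may not be zero).
#' @return Values in \[0, 1\].
#' @examples
#' repeatability(77.13, 6.45) # low-diet viral load, ~0.92
#' @export
repeatability <- function(vp, ve) {
  if (any(vp < 0, na.rm = TRUE) || any(ve < 0, na.rm = TRUE)) {
    abort("variance components must be non-negative")
  }
  if (any(vp + ve == 0, na.rm = TRUE)) {
    abort("repeatability undefined when both components are zero")
  }
  vp / (vp + ve)
}

#' Phylogenetic heritability (Pagel's lambda analogue)
#'
#' `vp / (vp + vs)`: the share of the between-species variance that tracks
#' the phylogeny, as opposed to the species-specific component independent
#' of it. Requires a model fitted with the species term included.
#'
#' @param vp Phylogenetic variance.
#' @param vs Non-phylogenetic species variance.
#' @return Values in \[0, 1\].
#' @export
phylo_heritability <- function(vp, vs) {
  if (any(vp < 0, na.rm = TRUE) || any(vs < 0, na.rm = TRUE)) {
    abort("variance components must be non-negative")
  }
  if (any(vp + vs == 0, na.rm = TRUE)) {
    abort("phylogenetic heritability undefined when both components are zero")
  }
  vp / (vp + vs)
}

#' Between-species correlation of two traits
#'
#' Correlation implied by the between-species covariance matrix:
#' `Vp[i, j] / sqrt(Vp[i, i] * Vp[j, j])`.
#'
#' @param vp A trait covariance matrix (one posterior draw).
#' @param i,j Trait indices.
#' @return A value in \[-1, 1\] for any positive-definite draw.
#' @export
interspecific_correlation <- function(vp, i, j) {
  if (vp[i, i] <= 0 || vp[j, j] <= 0) {
    abort("zero between-species variance: correlation undefined")
  }
  vp[i, j] / sqrt(vp[i, i] * vp[j, j])
}

# internal: mean + HPD of a per-draw series as a one-row tibble
summarise_draws <- function(x, mass = 0.95) {
  ci <- hpd_interval(x, mass)
  tibble::tibble(mean = mean(x), hpd_lower = ci[["lower"]], hpd_upper = ci[["upper"]])
}

#' Posterior summary table for a fitted phylogenetic mixed model
#'
#' One row per reported statistic, each summarised as the posterior mean
#' with a 95% HPD interval computed from the same per-draw series (ratios
#' are taken draw by draw, never as ratios of summaries): per-trait
#' repeatability, between-species and residual variances, trait intercepts;
#' all pairwise between-species correlations with grouping labels
#' (within-class diet pairs, load-vs-survival within diet, control-vs-
#' infected survival within diet); the per-trait wing slopes and their
#' across-trait mean; and, when the fit includes the species term,
#' per-trait phylogenetic heritability.
#'
#' @param fit A [pmm_fit()] object.
#' @param mass HPD mass (default 0.95).
#' @return A tibble of class `pmm_summary` with columns `statistic`,
#'   `trait_class`, `diet`, `trait_class2`, `diet2`, `group`, `mean`,
#'   `hpd_lower`, `hpd_upper`.
#' @export
summarize_pmm <- function(fit, mass = 0.95) {
  stopifnot(inherits(fit, "pmm_fit"))
  labs <- fit$traits
  k <- nrow(labs)
  vp <- fit$draws$vp   # n_draws x k^2, column-major vec of Vp
  ve <- fit$draws$ve
  beta <- fit$draws$beta
  rows <- list()
  add <- function(statistic, series, trait_class = NA, diet = NA,
                  trait_class2 = NA, diet2 = NA, group = NA) {
    s <- summarise_draws(series, mass)
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      statistic = statistic, trait_class = trait_class, diet = diet,
      trait_class2 = trait_class2, diet2 = diet2, group = group,
      mean = s$mean, hpd_lower = s$hpd_lower, hpd_upper = s$hpd_upper
    )
  }
  has_vp <- !is.null(vp) && ncol(vp) > 0
  for (t in seq_len(k)) {
    cl <- labs$trait_class[t]; dt <- labs$diet[t]
    if (has_vp) {
      vpt <- vp[, (t - 1) * k + t]
      add("vp", vpt, cl, dt)
      add("repeatability", repeatability(vpt, ve[, t]), cl, dt)
    }
    add("ve", ve[, t], cl, dt)
    add("intercept", beta[, t], cl, dt)
    add("wing_slope", beta[, k + t], cl, dt)
    if (!is.null(fit$draws$vs) && ncol(fit$draws$vs) > 0) {
      vst <- fit$draws$vs[, (t - 1) * k + t]
      add("phylo_heritability", phylo_heritability(vp[, (t - 1) * k + t], vst),
          cl, dt)
      add("vs", vst, cl, dt)
    }
  }
  add("wing_slope_mean", rowMeans(beta[, k + seq_len(k), drop = FALSE]))
  if (has_vp) {
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        r <- vp[, (j - 1) * k + i] /
          sqrt(vp[, (i - 1) * k + i] * vp[, (j - 1) * k + j])
        ci <- labs$trait_class[i]; cj <- labs$trait_class[j]
        di <- labs$diet[i]; dj <- labs$diet[j]
        group <- if (ci == cj) {
          paste0(ci, " across diets")
        } else if (di == dj) {
          paste0(ci, " vs ", cj, " within diet")
        } else {
          "other"
        }
        add("correlation", r, ci, di, cj, dj, group)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("pmm_summary", class(out))
  out
}

#' Render a posterior summary as a readable text report
#'
#' Groups the summary the way cross-species infection studies report it:
#' repeatabilities, variance components and means per trait, then the
#' between-species correlations grouped by trait class and diet.
#'
#' @param summary A `pmm_summary` tibble (or path to a CSV written from one).
#' @param digits Significant digits.
#' @return The report, invisibly, as a character vector of lines (also
#'   printed).
#' @export
report_summary <- function(summary, digits = 2) {
  if (is.character(summary)) {
    summary <- readr::read_csv(summary, show_col_types = FALSE)
  }
  fmt <- function(d) {
    sprintf("%s (95%% HPD: %s, %s)",
            signif(d$mean, digits + 1), signif(d$hpd_lower, digits + 1),
            signif(d$hpd_upper, digits + 1))
  }
  lines <- character()
  emit <- function(...) lines <<- c(lines, paste0(...))
  section <- function(stat, title) {
    d <- summary[summary$statistic == stat, ]
    if (!nrow(d)) return(invisible())
    emit("## ", title)
    for (i in seq_len(nrow(d))) {
      lab <- if (!is.na(d$trait_class[i])) {
        paste0(d$trait_class[i], " / ", d$diet[i])
      } else ""
      emit("  ", lab, ": ", fmt(d[i, ]))
    }
    emit("")
  }
  section("repeatability", "Repeatability (vp / (vp + ve))")
  section("phylo_heritability", "Phylogenetic heritability (vp / (vp + vs))")
  section("vp", "Between-species variance (vp)")
  section("ve", "Residual variance (ve)")
  section("intercept", "Trait means (intercepts)")
  corr <- summary[summary$statistic == "correlation", ]
  if (nrow(corr)) {
    emit("## Between-species correlations")
    for (g in unique(corr$group)) {
      d <- corr[corr$group == g, ]
      emit("  [", g, "]")
      for (i in seq_len(nrow(d))) {
        emit("    ", d$trait_class[i], " ", d$diet[i], " vs ",
             d$trait_class2[i], " ", d$diet2[i], ": ", fmt(d[i, ]))
      }
    }
    emit("")
  }
  wm <- summary[summary$statistic == "wing_slope_mean", ]
  if (nrow(wm)) emit("Wing-length slope (mean across traits): ", fmt(wm))
  cat(lines, sep = "\n")
  invisible(lines)
}
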