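#' Correct Ct values for between-plate differences using shared standards
#'
#' qRT-PCR plates drift relative to one another; a set of standard samples
#' run on every plate identifies the shift. The correction is an additive
#' per-plate, per-target offset estimated from the standards: for each plate
#' and target, the offset is (mean standard Ct on that plate) minus (grand
#' mean standard Ct across plates), and it is subtracted from every Ct on
#' the plate — standards included. This is the least-squares plate effect of
#' the linear model `Ct ~ plate` fitted to the standards, so corrected
#' standard means are equal across plates and within-plate Ct differences
#' are untouched.
#'
#' @param ct A tibble of Ct records with columns `sample_id`, `plate_id`,
#'   `target`, `ct_rep1`, `ct_rep2`, `is_standard` (plus any others, which
#'   pass through).
#' @return The input tibble with `ct_rep1`/`ct_rep2` corrected and a new
#'   `plate_offset` column recording the subtracted offset.
#' @export
plate_correct <- function(ct) {
  stopifnot(is.data.frame(ct))
  req <- c("sample_id", "plate_id", "target", "ct_rep1", "ct_rep2", "is_standard")
  missing_cols <- setdiff(req, names(ct))
  if (length(missing_cols)) {
    abort(paste0("ct table lacks columns: ", paste(missing_cols, collapse = ", ")))
  }
  std <- dplyr::filter(ct, .data$is_standard)
  plates <- unique(ct$plate_id)
  no_std <- setdiff(plates, unique(std$plate_id))
  if (length(no_std)) {
    abort(paste0("plates without standards: ", paste(no_std, collapse = ", ")))
  }
  # standards seen on a single plate carry no between-plate information
  usage <- std |>
    dplyr::distinct(.data$sample_id, .data$plate_id) |>
    dplyr::count(.data$sample_id)
  lonely <- usage$sample_id[usage$n < 2]
  if (length(lonely) && length(plates) > 1L) {
    warn(paste0(
      "standards present on only one plate excluded from plate correction: ",
      paste(lonely, collapse = ", ")
    ))
    std <- dplyr::filter(std, !.data$sample_id %in% lonely)
    if (!all(plates %in% unique(std$plate_id))) {
      abort("after excluding single-plate standards, some plates have no usable standards")
    }
  }
  offsets <- std |>
    tidyr::pivot_longer(c("ct_rep1", "ct_rep2"), values_to = "ct") |>
    dplyr::filter(!is.na(.data$ct)) |>
    dplyr::group_by(.data$target) |>
    dplyr::mutate(grand_mean = mean(.data$ct)) |>
    dplyr::group_by(.data$target, .data$plate_id) |>
    dplyr::summarise(
      plate_offset = mean(.data$ct) - .data$grand_mean[1],
      .groups = "drop"
    )
  out <- ct |>
    dplyr::left_join(offsets, by = c("target", "plate_id")) |>
    dplyr::mutate(
      ct_rep1 = .data$ct_rep1 - .data$plate_offset,
      ct_rep2 = .data$ct_rep2 - .data$plate_offset
    )
  if (anyNA(out$plate_offset)) {
    abort("some plate/target combinations have no standards to estimate an offset from")
  }
  out
}

#' Flag samples whose technical replicates disagree
#'
#' Duplicate qRT-PCR reactions of the same sample should agree closely; a
#' pair more than `threshold` cycles apart (strictly) after plate correction
#' indicates a failed reaction and the sample must be repeated. A missing
#' replicate is likewise flagged.
#'
#' @param ct A Ct record tibble (see [plate_correct()]).
#' @param threshold Maximum tolerated absolute difference in cycles
#'   (default 2; the boundary itself passes).
#' @return The tibble with a `qc` column, `"pass"` or `"repeat"`.
#' @export
qc_technical_replicates <- function(ct, threshold = 2) {
  stopifnot(is.data.frame(ct), threshold > 0)
  dplyr::mutate(
    ct,
    qc = dplyr::if_else(
      is.na(.data$ct_rep1) | is.na(.data$ct_rep2) |
        abs(.data$ct_rep1 - .data$ct_rep2) > threshold,
      "repeat", "pass"
    )
  )
}

#' Per-sample delta-Ct relative to the endogenous control
#'
#' For each sample, averages the two technical replicates per target and
#' returns `mean Ct(viral target) - mean Ct(endogenous control)`. Lower
#' viral Ct means more virus, so smaller (more negative) delta-Ct means a
#' higher viral load. Samples flagged `"repeat"` by
#' [qc_technical_replicates()] are dropped with a message; samples missing
#' either target are an error.
#'
#' @param ct A QC'd Ct record tibble.
#' @param target_virus,target_ref Target labels for the virus and the
#'   endogenous control.
#' @return Tibble with one row per retained sample: the pass-through design
#'   columns plus `delta_ct`.
#' @export
delta_ct <- function(ct, target_virus = "DCV", target_ref = "RpL32") {
  stopifnot(is.data.frame(ct))
  if (!"qc" %in% names(ct)) ct <- qc_technical_replicates(ct)
  samples <- dplyr::filter(ct, !.data$is_standard)
  n_repeat <- samples |>
    dplyr::filter(.data$qc == "repeat") |>
    dplyr::distinct(.data$sample_id) |>
    nrow()
  if (n_repeat > 0) {
    inform(paste0(n_repeat, " sample(s) dropped by technical-replicate QC"))
  }
  failed <- unique(samples$sample_id[samples$qc == "repeat"])
  samples <- dplyr::filter(samples, !.data$sample_id %in% failed)
  keys <- intersect(
    c("sample_id", "species", "diet", "block", "day"),
    names(samples)
  )
  wide <- samples |>
    dplyr::mutate(ct_mean = (.data$ct_rep1 + .data$ct_rep2) / 2) |>
    dplyr::select(dplyr::all_of(keys), "target", "ct_mean") |>
    tidyr::pivot_wider(names_from = "target", values_from = "ct_mean")
  if (nrow(wide) == 0L) {
    out <- wide[intersect(keys, names(wide))]
    out$delta_ct <- numeric(0)
    return(out)
  }
  if (!all(c(target_virus, target_ref) %in% names(wide)) ||
      anyNA(wide[[target_virus]]) || anyNA(wide[[target_ref]])) {
    bad <- wide$sample_id[
      is.na(wide[[target_virus]] %||% NA) | is.na(wide[[target_ref]] %||% NA)
    ]
    abort(paste0(
      "samples missing a target measurement: ",
      paste(utils::head(bad, 10), collapse = ", ")
    ))
  }
  wide |>
    dplyr::mutate(delta_ct = .data[[target_virus]] - .data[[target_ref]]) |>
    dplyr::select(dplyr::all_of(keys), "delta_ct")
}

#' Pair day-0 with day-2 delta-Ct values within species, diet and block
#'
#' The viral-load trait is a change between an uninfected-baseline (day 0)
#' biological replicate and a day-2 replicate from the same experimental
#' block. Pairs are matched within (species, diet, block); a block missing
#' either member contributes no pair and is reported. If a block holds more
#' than one candidate on a day, pairing is ambiguous and an explicit
#' `vial_match` column is required.
#'
#' @param dct Output of [delta_ct()] with columns `species`, `diet`,
#'   `block`, `day`, `delta_ct` (day coded 0 and 2), optionally `vial_match`.
#' @return Tibble with one row per pair: `species`, `diet`, `block`,
#'   `dct_day0`, `dct_day2`.
#' @export
pair_day0_day2 <- function(dct) {
  stopifnot(is.data.frame(dct))
  keys <- c("species", "diet", "block")
  if ("vial_match" %in% names(dct)) keys <- c(keys, "vial_match")
  counts <- dct |>
    dplyr::count(dplyr::across(dplyr::all_of(c(keys, "day"))))
  if (any(counts$n > 1)) {
    abort(paste0(
      "multiple delta-Ct candidates within a block for the same day; ",
      "provide a `vial_match` column to disambiguate"
    ))
  }
  wide <- dct |>
    dplyr::select(dplyr::all_of(keys), "day", "delta_ct") |>
    tidyr::pivot_wider(
      names_from = "day", values_from = "delta_ct", names_prefix = "day"
    )
  if (!"day0" %in% names(wide)) wide$day0 <- NA_real_
  if (!"day2" %in% names(wide)) wide$day2 <- NA_real_
  incomplete <- is.na(wide$day0) | is.na(wide$day2)
  if (any(incomplete)) {
    warn(paste0(
      sum(incomplete), " block(s) missing a day-0 or day-2 member were dropped"
    ))
  }
  wide |>
    dplyr::filter(!is.na(.data$day0), !is.na(.data$day2)) |>
    dplyr::rename(dct_day0 = "day0", dct_day2 = "day2") |>
    dplyr::select(dplyr::all_of(keys), "dct_day0", "dct_day2") |>
    dplyr::arrange(dplyr::across(dplyr::all_of(keys)))
}

#' Log2 change in viral load between day 0 and day 2
#'
#' The delta-delta-Ct statistic: `delta_ct(day 0) - delta_ct(day 2)`. One
#' qPCR cycle is one doubling, and more virus lowers the viral Ct, so this
#' difference is the log2 fold change in relative viral load over the two
#' days — positive values mean viral growth.
#'
#' @param dct_day0,dct_day2 Numeric vectors of paired delta-Ct values.
#' @return Numeric vector of log2 fold changes.
#' @export
log2_load_change <- function(dct_day0, dct_day2) {
  stopifnot(is.numeric(dct_day0), is.numeric(dct_day2),
            length(dct_day0) == length(dct_day2))
  dct_day0 - dct_day2
}

#' Mean proportion of flies alive over the observation window
#'
#' Summarises a vial's daily death counts as the mean, over days 1 to
#' `last_day`, of the fraction of flies still alive at the end of each day.
#' A vial with no deaths scores 1; a vial that dies out on day 1 scores 0.
#'
#' @param deaths Integer vector of deaths per day (day 1 first), at least
#'   `last_day` long.
#' @param n_start Number of flies at day 0 (> 0).
#' @param last_day Last day included in the average. 21 days were counted
#'   but the analysis window defaults to 20; configurable.
#' @return A value in \[0, 1\].
#' @examples
#' survival_trait(c(rep(0, 9), 5, rep(0, 11)), n_start = 10) # 0.725
#' @export
survival_trait <- function(deaths, n_start, last_day = 20) {
  if (length(n_start) != 1L || is.na(n_start) || n_start <= 0) {
    abort("`n_start` must be a single positive count")
  }
  if (length(deaths) < last_day) {
    abort(paste0("`deaths` must cover at least ", last_day, " days"))
  }
  if (any(deaths < 0, na.rm = TRUE)) abort("negative death counts")
  cum <- cumsum(deaths[seq_len(last_day)])
  if (any(cum > n_start)) abort("cumulative deaths exceed `n_start`")
  mean((n_start - cum) / n_start)
}

#' Survival traits for a table of vials
#'
#' Applies [survival_trait()] to each row of a wide survival table.
#'
#' @param surv Tibble with columns `vial_id`, `species`, `diet`, `block`,
#'   `treatment` (`"virus"` or `"sham"`), `n_start` and `day_1` ... `day_21`
#'   death counts.
#' @param last_day Passed to [survival_trait()].
#' @return Tibble with the design columns and a `value` column.
#' @export
survival_traits <- function(surv, last_day = 20) {
  stopifnot(is.data.frame(surv))
  day_cols <- paste0("day_", seq_len(last_day))
  missing_cols <- setdiff(c(day_cols, "n_start", "treatment"), names(surv))
  if (length(missing_cols)) {
    abort(paste0("survival table lacks columns: ",
                 paste(utils::head(missing_cols, 5), collapse = ", ")))
  }
  deaths <- as.matrix(surv[day_cols])
  surv |>
    dplyr::select(dplyr::any_of(c("vial_id", "species", "diet", "block",
                                  "treatment", "n_start"))) |>
    dplyr::mutate(
      value = purrr::map_dbl(
        seq_len(nrow(surv)),
        function(i) survival_trait(deaths[i, ], surv$n_start[i], last_day)
      )
    )
}

# canonical trait bookkeeping ------------------------------------------------

#' @rdname build_trait_table
#' @export
trait_classes <- function() c("viral_load", "survival_infected", "survival_control")

#' @rdname build_trait_table
#' @export
diet_levels <- function() c("low", "medium", "high")

#' @rdname build_trait_table
#' @export
trait_index <- function(trait_class, diet) {
  cl <- match(trait_class, trait_classes())
  dt <- match(diet, diet_levels())
  if (anyNA(cl)) abort("unknown trait class")
  if (anyNA(dt)) abort("unknown diet level")
  3L * (cl - 1L) + dt
}

#' @rdname build_trait_table
#' @export
trait_labels <- function(k = 9L) {
  grid <- tidyr::expand_grid(trait_class = trait_classes(), diet = diet_levels())
  grid$trait_index <- trait_index(grid$trait_class, grid$diet)
  dplyr::arrange(grid[grid$trait_index <= k, ], .data$trait_index)
}

#' Assemble the nine-trait analysis table
#'
#' Combines per-pair viral-load changes and per-vial survival traits into
#' the long-format table the mixed model consumes: one trait value per row,
#' indexed 1–9 by the (trait class, diet) combination — viral load on the
#' low, medium and high diets are traits 1–3, infected survival 4–6 and
#' control survival 7–9. The species mean wing length (a body-size proxy) is
#' attached to every row and centred to mean 0 across species so the trait
#' intercepts stay interpretable.
#'
#' @param loads Tibble with `species`, `diet`, `block`, `value` (log2 load
#'   change per day-0/day-2 pair).
#' @param survival Tibble from [survival_traits()] (columns `species`,
#'   `diet`, `block`, `treatment`, `value`).
#' @param wing_means Tibble with `species` and `wing` (mm); every species in
#'   the data must appear.
#' @return A tibble with columns `observation_id`, `species`, `trait_class`,
#'   `diet`, `trait_index`, `value`, `wing`.
#' @export
build_trait_table <- function(loads, survival, wing_means) {
  stopifnot(is.data.frame(loads), is.data.frame(survival),
            is.data.frame(wing_means))
  load_rows <- loads |>
    dplyr::transmute(
      species = trimws(.data$species), diet = .data$diet,
      trait_class = "viral_load", value = .data$value
    )
  surv_rows <- survival |>
    dplyr::transmute(
      species = trimws(.data$species), diet = .data$diet,
      trait_class = dplyr::if_else(
        .data$treatment == "virus", "survival_infected", "survival_control"
      ),
      value = .data$value
    )
  tab <- dplyr::bind_rows(load_rows, surv_rows)
  if (any(tab$trait_class != "viral_load" &
            (tab$value < 0 | tab$value > 1))) {
    abort("survival trait values must lie in [0, 1]")
  }
  wing_means <- dplyr::mutate(wing_means, species = trimws(.data$species))
  missing_sp <- setdiff(unique(tab$species), wing_means$species)
  if (length(missing_sp)) {
    abort(paste0("species without wing means: ",
                 paste(missing_sp, collapse = ", ")))
  }
  used <- dplyr::filter(wing_means, .data$species %in% unique(tab$species))
  used$wing <- used$wing - mean(used$wing)
  tab |>
    dplyr::mutate(trait_index = trait_index(.data$trait_class, .data$diet)) |>
    dplyr::left_join(used[c("species", "wing")], by = "species") |>
    dplyr::mutate(observation_id = sprintf("obs%04d", dplyr::row_number())) |>
    dplyr::select("observation_id", "species", "trait_class", "diet",
                  "trait_index", "value", "wing")
}
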