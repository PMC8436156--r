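make_ct <- function(plate, sample, target, ct, standard = FALSE,
                    species = "sp1", diet = "low", block = 1L, day = 0L) {
  tibble::tibble(
    sample_id = sample, species = ifelse(standard, NA, species),
    diet = ifelse(standard, NA, diet), block = ifelse(standard, NA, block),
    day = ifelse(standard, NA, day), plate_id = plate, target = target,
    ct_rep1 = ct, ct_rep2 = ct, is_standard = standard
  )
}

test_that("plate correction centres plates on the grand standard mean", {
  ct <- dplyr::bind_rows(
    make_ct("p1", "std1", "DCV", 20, standard = TRUE),
    make_ct("p2", "std1", "DCV", 21, standard = TRUE),
    make_ct("p1", "s1", "DCV", 25),
    make_ct("p2", "s2", "DCV", 25)
  )
  out <- plate_correct(ct)
  # grand mean 20.5: plate 1 shifted by +0.5, plate 2 by -0.5
  expect_equal(out$ct_rep1[out$sample_id == "s1"], 25.5)
  expect_equal(out$ct_rep1[out$sample_id == "s2"], 24.5)
  # standards corrected identically: both now at 20.5
  expect_equal(unique(out$ct_rep1[out$is_standard]), 20.5)
})

test_that("identical standards leave records unchanged", {
  ct <- dplyr::bind_rows(
    make_ct("p1", "std1", "DCV", 22, standard = TRUE),
    make_ct("p2", "std1", "DCV", 22, standard = TRUE),
    make_ct("p1", "s1", "DCV", 30),
    make_ct("p2", "s2", "DCV", 18)
  )
  out <- plate_correct(ct)
  expect_equal(out$ct_rep1, ct$ct_rep1)
})

test_that("plate correction equals least-squares plate effects from the standards", {
  set.seed(21)
  plates <- paste0("p", 1:3)
  offsets <- c(0.8, -0.4, 0.2)
  std <- tidyr::expand_grid(plate = plates, std = paste0("std", 1:4))
  std$true <- rep(c(20, 22, 24, 26), times = 3)
  std$ct <- std$true + offsets[match(std$plate, plates)]
  ct <- dplyr::bind_rows(
    make_ct(std$plate, std$std, "DCV", std$ct, standard = TRUE),
    make_ct(plates, paste0("s", 1:3), "DCV", c(25, 25, 25))
  )
  out <- plate_correct(ct)
  # corrected standard means equal across plates
  std_means <- out |>
    dplyr::filter(.data$is_standard) |>
    dplyr::group_by(.data$plate_id) |>
    dplyr::summarise(m = mean(ct_rep1))
  expect_equal(diff(range(std_means$m)), 0, tolerance = 1e-12)
  # equals lm(Ct ~ plate) effects on the standards (sum-to-zero coding)
  fit <- stats::lm(ct ~ plate, data = std,
                   contrasts = list(plate = "contr.sum"))
  eff <- c(stats::coef(fit)[-1], -sum(stats::coef(fit)[-1]))
  got <- out$plate_offset[match(plates, out$plate_id)]
  expect_equal(unname(got), unname(eff), tolerance = 1e-10)
})

test_that("plates without standards error; single-plate standards are excluded with a warning", {
  ct <- dplyr::bind_rows(
    make_ct("p1", "std1", "DCV", 20, standard = TRUE),
    make_ct("p2", "s1", "DCV", 25)
  )
  expect_error(plate_correct(ct), "without standards")

  ct2 <- dplyr::bind_rows(
    make_ct("p1", "std1", "DCV", 20, standard = TRUE),
    make_ct("p2", "std1", "DCV", 21, standard = TRUE),
    make_ct("p1", "std9", "DCV", 33, standard = TRUE),  # only on plate 1
    make_ct("p1", "s1", "DCV", 25)
  )
  expect_warning(out <- plate_correct(ct2), "std9")
  expect_equal(out$ct_rep1[out$sample_id == "s1"], 25.5)
})

test_that("technical-replicate QC is strict at the two-cycle boundary", {
  ct <- tibble::tibble(
    sample_id = c("a", "b", "c", "d"),
    ct_rep1 = c(20, 20, 20, 20), ct_rep2 = c(21.9, 22.1, 22.0, NA)
  )
  out <- qc_technical_replicates(ct)
  expect_equal(out$qc, c("pass", "repeat", "pass", "repeat"))
})

test_that("delta-Ct is the difference of technical-replicate means", {
  ct <- dplyr::bind_rows(
    tibble::tibble(sample_id = "s1", species = "x", diet = "low", block = 1,
                   day = 0, plate_id = "p", target = "DCV",
                   ct_rep1 = 18.4, ct_rep2 = 19.0, is_standard = FALSE),
    tibble::tibble(sample_id = "s1", species = "x", diet = "low", block = 1,
                   day = 0, plate_id = "p", target = "RpL32",
                   ct_rep1 = 21.0, ct_rep2 = 21.2, is_standard = FALSE),
    tibble::tibble(sample_id = "s2", species = "x", diet = "low", block = 2,
                   day = 0, plate_id = "p", target = "DCV",
                   ct_rep1 = 25, ct_rep2 = 26, is_standard = FALSE),
    tibble::tibble(sample_id = "s2", species = "x", diet = "low", block = 2,
                   day = 0, plate_id = "p", target = "RpL32",
                   ct_rep1 = 25, ct_rep2 = 26, is_standard = FALSE)
  )
  out <- delta_ct(ct)
  expect_equal(out$delta_ct[out$sample_id == "s1"], 18.7 - 21.1)
  expect_equal(out$delta_ct[out$sample_id == "s2"], 0)
})

test_that("QC-failed samples are dropped from delta-Ct with a message", {
  ct <- dplyr::bind_rows(
    tibble::tibble(sample_id = "bad", species = "x", diet = "low", block = 1,
                   day = 0, plate_id = "p", target = "DCV",
                   ct_rep1 = 20, ct_rep2 = 23, is_standard = FALSE),
    tibble::tibble(sample_id = "bad", species = "x", diet = "low", block = 1,
                   day = 0, plate_id = "p", target = "RpL32",
                   ct_rep1 = 20, ct_rep2 = 20, is_standard = FALSE)
  )
  expect_message(out <- delta_ct(ct), "QC")
  expect_equal(nrow(out), 0)
})

test_that("day pairing matches within block, drops incomplete blocks, ignores order", {
  dct <- tibble::tibble(
    species = "x", diet = "low", block = c(1, 1, 2, 3, 3),
    day = c(0, 2, 0, 0, 2),
    delta_ct = c(10, 3, 5, 8, 1)
  )
  expect_warning(pairs <- pair_day0_day2(dct), "missing")
  expect_equal(nrow(pairs), 2)
  expect_equal(pairs$dct_day0, c(10, 8))
  expect_equal(pairs$dct_day2, c(3, 1))

  shuffled <- dct[c(5, 2, 3, 1, 4), ]
  expect_warning(pairs2 <- pair_day0_day2(shuffled), "missing")
  expect_equal(pairs2, pairs)

  dup <- dplyr::bind_rows(dct, tibble::tibble(species = "x", diet = "low",
                                              block = 1, day = 0, delta_ct = 9))
  expect_error(pair_day0_day2(dup), "vial_match")
})

test_that("log2 load change is the day0 - day2 difference and antisymmetric", {
  expect_equal(log2_load_change(10, 3), 7)
  expect_equal(log2_load_change(5, 5), 0)
  set.seed(3)
  a <- rnorm(100); b <- rnorm(100)
  expect_equal(log2_load_change(a, b) + log2_load_change(b, a), rep(0, 100))
})

test_that("survival trait is the mean daily proportion alive", {
  expect_equal(survival_trait(rep(0, 21), 10), 1)
  expect_equal(survival_trait(c(10, rep(0, 20)), 10), 0)
  # 5 of 10 die on day 10: 9 days at 1.0, 11 days at 0.5 over a 20-day window
  expect_equal(survival_trait(c(rep(0, 9), 5, rep(0, 11)), 10), 0.725)
  expect_equal(survival_trait(c(rep(0, 9), 5, rep(0, 11)), 10, last_day = 21),
               (9 + 12 * 0.5) / 21)
  expect_error(survival_trait(rep(0, 21), 0), "positive")
  expect_error(survival_trait(c(6, 6, rep(0, 19)), 10), "exceed")
})

test_that("survival trait is non-increasing in every daily death count", {
  set.seed(8)
  for (r in 1:20) {
    deaths <- rbinom(21, 2, 0.2)
    base <- survival_trait(deaths, 50)
    d <- sample(20, 1)
    bumped <- deaths
    bumped[d] <- bumped[d] + 1
    expect_lte(survival_trait(bumped, 50), base)
  }
})

test_that("trait table assembly counts, indexes and centres correctly", {
  loads <- tidyr::expand_grid(species = c("a", "b"), diet = "low", block = 1)
  loads$value <- c(2, 3)
  surv <- tidyr::expand_grid(species = c("a", "b"), diet = "low", block = 1,
                             treatment = c("virus", "sham"))
  surv$value <- 0.9
  wing <- tibble::tibble(species = c("a", "b"), wing = c(1.9, 2.3))
  tab <- build_trait_table(loads, surv, wing)
  expect_equal(nrow(tab), 6)
  expect_setequal(unique(tab$trait_index), c(1, 4, 7))
  expect_equal(sum(unique(tab[c("species", "wing")])$wing), 0)
  expect_error(build_trait_table(loads, surv, wing[1, ]), "wing")

  # full crossed design: 27 species x 3 diets x 3 blocks per class
  full_loads <- tidyr::expand_grid(species = sprintf("sp%02d", 1:27),
                                   diet = diet_levels(), block = 1:3)
  full_loads$value <- 1
  full_surv <- tidyr::expand_grid(species = sprintf("sp%02d", 1:27),
                                  diet = diet_levels(), block = 1:3,
                                  treatment = c("virus", "sham"))
  full_surv$value <- 0.5
  full_wing <- tibble::tibble(species = sprintf("sp%02d", 1:27), wing = 2)
  full <- build_trait_table(full_loads, full_surv, full_wing)
  expect_equal(sum(full$trait_class == "viral_load"), 243)
  expect_equal(sum(full$trait_class == "survival_infected"), 243)
  expect_equal(sum(full$trait_class == "survival_control"), 243)
  expect_equal(sort(unique(full$trait_index)), 1:9)
})

test_that("trait index is a bijection of class and diet", {
  grid <- tidyr::expand_grid(cl = trait_classes(), dt = diet_levels())
  idx <- trait_index(grid$cl, grid$dt)
  expect_setequal(idx, 1:9)
  expect_equal(trait_index("viral_load", "low"), 1)
  expect_equal(trait_index("survival_control", "high"), 9)
})
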