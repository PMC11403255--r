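test_that("sampled geometry always re-classifies to its intended class", {
  set.seed(21)
  for (k in SPINE_CLASSES) {
    g <- sample_spine(k, 500)
    got <- classify_spine(g$total_length_um, g$head_diameter_um,
                          g$neck_diameter_um)
    expect_true(all(got == k))
  }
  filo <- sample_spine("filopodium", 200)
  expect_true(all(filo$total_length_um >= 3))
})

test_that("impossible geometry parameterizations fail naming the class", {
  # a 10 um median length cannot produce thin spines (length must be < 3)
  bad <- default_geometry_params()
  bad$thin$length <- c(meanlog = log(10), sdlog = 0.01)
  expect_error(sample_spine("thin", 5, geometry_params = bad,
                            max_rejections = 50), "thin")
})

test_that("exact mature prevalence matches brute-force simulation", {
  # independent oracle: direct Poisson/binomial Monte Carlo
  set.seed(31)
  p <- 0.45; lambda <- 30; reps <- 40000
  n <- rpois(reps, lambda); n <- n[n > 0]
  sim <- mean(rbinom(length(n), n, p) / n > 0.5)
  exact <- mature_prevalence(p, lambda)
  expect_lt(abs(sim - exact), 3 * sqrt(exact * (1 - exact) / length(n)))
})

test_that("built-in profiles are calibrated to the strain prevalences", {
  for (lab in c("B6-like", "BTBR-like")) {
    pr <- condition_profile(lab)
    lam <- pr$density_mean * pr$dendrite_length_um
    expect_equal(mature_prevalence(pr$class_mixture[["mushroom"]], lam),
                 pr$mature_neuron_target, tolerance = 1e-7)
    expect_equal(sum(pr$class_mixture), 1, tolerance = 1e-12)
    expect_true(all(pr$class_mixture >= 0))
  }
  expect_lt(condition_profile("BTBR-like")$class_mixture[["mushroom"]],
            condition_profile("B6-like")$class_mixture[["mushroom"]])
})

test_that("Hill shift has the right limits and mixture bookkeeping", {
  eff <- compound_effect("X", efficacy = 30, ec50 = 0.1, hill = 1)
  shift <- spinescreen:::effect_shift
  expect_equal(shift(eff, 0), 0)
  expect_lt(abs(shift(eff, 1e4) - 0.30), 1e-4)
  expect_equal(shift(eff, 0.1), 0.15)  # half-maximal at the ec50
  # monotone in concentration
  sh <- vapply(c(0.01, 0.03, 0.1, 0.3, 1), shift, 0, effect = eff)
  expect_true(all(diff(sh) > 0))
  # mass is taken from thin, then stubby, then filopodium
  mix <- c(mushroom = 0.4, thin = 0.3, stubby = 0.2, filopodium = 0.1)
  out <- spinescreen:::shift_mixture(mix, 0.35)
  expect_equal(unname(out), c(0.75, 0, 0.15, 0.1))
  expect_equal(sum(out), 1)
  expect_error(spinescreen:::shift_mixture(mix, 0.65), "valid probability")
})

test_that("expected maturity is monotone in efficacy and concentration", {
  pr <- condition_profile("BTBR-like")
  lam <- pr$density_mean * pr$dendrite_length_um
  prev_at <- function(efficacy, conc) {
    eff <- compound_effect("X", efficacy = efficacy, ec50 = 0.05)
    mix <- spinescreen:::shift_mixture(pr$class_mixture,
                                       spinescreen:::effect_shift(eff, conc))
    mature_prevalence(mix[["mushroom"]], lam)
  }
  by_eff <- vapply(c(0, 10, 20, 30), prev_at, 0, conc = 1)
  expect_true(all(diff(by_eff) > 0))
  by_conc <- vapply(c(0.01, 0.1, 1), prev_at, 0, efficacy = 30)
  expect_true(all(diff(by_conc) > 0))
})

test_that("toxicity marks damaged cells at the expected rate", {
  set.seed(41)
  pr <- condition_profile("BTBR-like")
  eff <- compound_effect("X", efficacy = 0, toxicity_prob = 0.3)
  tb <- spinescreen:::simulate_neuron_tables(pr, 600, eff, 1)
  rate <- mean(tb$neurons$damaged)
  expect_lt(abs(rate - 0.3), 3 * sqrt(0.3 * 0.7 / 600))
  tb_low <- spinescreen:::simulate_neuron_tables(pr, 600, eff, 0.1)
  expect_lt(mean(tb_low$neurons$damaged), rate)
})

test_that("dataset generation is a pure function of the seed", {
  lib <- default_library()[1:4, ]
  a <- generate_screen_dataset(lib, seed = 9)
  b <- generate_screen_dataset(lib, seed = 9)
  expect_identical(a$spines, b$spines)
  expect_identical(a$neurons, b$neurons)
  expect_identical(a$wells, b$wells)
  # layout: one plate, 4 compound wells + 2 vehicle wells
  expect_equal(nrow(a$wells), 6)
  expect_equal(sum(a$wells$treatment == "vehicle"), 2)
  expect_equal(nrow(a$neurons), 6 * 20)
})

test_that("the default library mirrors the screened collection", {
  lib <- default_library()
  expect_equal(nrow(lib), 181)
  expect_equal(sum(lib$target_class == "5-HT receptor"), 38)
  expect_equal(length(unique(lib$target_class)), 20)
  ds <- generate_screen_dataset(lib[1:2, ], secondary_for = "C001",
                                seed = 13)
  sec <- ds$wells[ds$wells$stage == "secondary" &
                    ds$wells$treatment == "compound", ]
  expect_equal(sort(sec$concentration_um),
               sort(DILUTION_LADDERS[["3fold"]]))
  expect_true(all(sec$concentration_um <= 1))
})

test_that("behavior cohorts respect the session-time composition", {
  coh <- generate_behavior_cohort(seed = 51)
  expect_equal(nrow(coh), 22)
  expect_equal(as.vector(table(coh$group)[c("vehicle", "treated")]),
               c(10L, 12L))
  sums <- coh$time_novel_mouse_s + coh$time_center_s +
    coh$time_novel_object_s
  expect_equal(sums, rep(600, 22), tolerance = 1e-9)
  expect_true(all(coh$grooming_s_per_10min >= 0 &
                    coh$grooming_s_per_10min <= 600))
})

test_that("a no-preference profile centres the sociability index at 0.5", {
  set.seed(61)
  coh <- generate_behavior_cohort(
    c(g = 400), profiles = list(g = behavior_profile(preference_mean = 0.5)))
  idx <- sociability_index(coh$time_novel_mouse_s,
                           coh$time_novel_object_s)
  # index ~ Beta(17.5, 17.5): sd = 0.5/sqrt(36)
  se <- 0.5 / sqrt(36) / sqrt(400)
  expect_lt(abs(mean(idx) - 0.5), 3 * se)
})

test_that("a strong social preference is detectable by rank test", {
  set.seed(71)
  hits <- replicate(100, {
    coh <- generate_behavior_cohort(
      c(null = 10, pref = 12),
      profiles = list(null = behavior_profile(preference_mean = 0.5),
                      pref = behavior_profile(preference_mean = 0.65)))
    s <- split(coh, coh$group)
    idx <- lapply(s, function(d)
      sociability_index(d$time_novel_mouse_s, d$time_novel_object_s))
    mann_whitney_u(idx[[1]], idx[[2]])$p_value < 0.05
  })
  expect_gt(mean(hits), 0.5)
})

test_that("mEPSC samples scale their amplitude median with the group factor", {
  set.seed(81)
  a <- generate_mepsc_samples(20000)
  b <- generate_mepsc_samples(20000, amplitude_scale = 0.8)
  expect_lt(abs(median(b$amplitude_pA) / median(a$amplitude_pA) - 0.8),
            0.02)
  expect_true(all(a$amplitude_pA > 0))
  expect_true(all(a$inter_event_interval_s > 0))
  one <- generate_mepsc_samples(1, seed = 82)
  cdf <- normalized_cdf(one$amplitude_pA)
  expect_equal(cdf$cumulative_fraction, 1)
  expect_equal(cdf$fun(one$amplitude_pA - 1e-9), 0)
})
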