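test_that("neuron maturity is strict at the 50% mushroom cut", {
  expect_equal(call_neuron_maturity(
    make_neuron(c(mushroom = 11, thin = 9))), "mature")
  expect_equal(call_neuron_maturity(
    make_neuron(c(mushroom = 10, thin = 10))), "immature")
  expect_equal(call_neuron_maturity(
    make_neuron(c(mushroom = 0, thin = 5))), "immature")
  expect_error(call_neuron_maturity(
    make_neuron(c(mushroom = 11), damaged = TRUE)), "damage")
  expect_error(call_neuron_maturity(make_neuron(c(mushroom = 0))),
               "no spines")
})

test_that("well mature fraction excludes damaged cells from both sides", {
  mature <- function(id) make_neuron(c(mushroom = 12, thin = 8),
                                     neuron_id = id)
  immature <- function(id) make_neuron(c(mushroom = 5, thin = 15),
                                       neuron_id = id)
  dam <- function(id) make_neuron(c(mushroom = 12, thin = 8),
                                  damaged = TRUE, neuron_id = id)
  w1 <- c(lapply(1:7, mature), lapply(8:20, immature))
  expect_equal(well_mature_fraction(w1), 35)
  w2 <- c(lapply(1:8, mature), lapply(9:16, immature), lapply(17:20, dam))
  expect_equal(well_mature_fraction(w2), 50)  # 8 of 16 evaluable
  # brute-force recount agrees
  ev <- Filter(function(n) !n$damaged, w2)
  expect_equal(well_mature_fraction(w2),
               100 * sum(vapply(ev, call_neuron_maturity, "") ==
                           "mature") / length(ev))
  expect_equal(well_mature_fraction(lapply(1:20, immature)), 0)
})

test_that("wells below the evaluable-neuron floor are flagged invalid", {
  few <- lapply(1:9, function(i)
    make_neuron(c(mushroom = 12, thin = 8), neuron_id = i))
  expect_warning(out <- well_mature_fraction(few), "invalid")
  expect_true(is.na(out))
  expect_equal(well_mature_fraction(few, min_evaluable = 5), 100)
})

test_that("DMSO reference is the mean of exactly two valid wells", {
  expect_equal(dmso_reference(c(20, 30)), 25)
  expect_equal(dmso_reference(c(25, 25)), 25)
  expect_error(dmso_reference(30), "two")
  expect_error(dmso_reference(c(10, 20, 30)), "two")
  expect_error(dmso_reference(c(NA, 20)), "two")
})

test_that("hit criterion is strict at 10 percentage points", {
  expect_true(call_hit(36, 25))
  expect_false(call_hit(35, 25))
  expect_false(call_hit(20, 25))
  expect_error(call_hit(120, 25), "\\[0, 100\\]")
  expect_error(call_hit(50, -5), "\\[0, 100\\]")
})

test_that("hit calls are monotone in the compound percentage", {
  for (ref in c(0, 17.5, 25, 60)) {
    calls <- vapply(seq(0, 100, by = 2.5), call_hit, logical(1),
                    dmso_ref = ref)
    expect_true(all(diff(calls) >= 0))
  }
})

test_that("secondary confirmation needs >= min_passing passing doses", {
  out <- confirm_secondary(c(1, 0.3, 0.1), c(38, 34, 28), 25)
  expect_true(out$confirmed)
  expect_equal(out$passing_concentrations, 1)
  flat <- confirm_secondary(c(1, 0.3, 0.1), c(25, 25, 25), 25)
  expect_false(flat$confirmed)
  expect_length(flat$passing_concentrations, 0)
  # empty passing set if and only if unconfirmed at min_passing = 1
  strict <- confirm_secondary(c(1, 0.3), c(38, 34), 25, min_passing = 2)
  expect_false(strict$confirmed)
  expect_warning(confirm_secondary(0.77, 50, 25), "ladder")
  expect_error(confirm_secondary(numeric(0), numeric(0), 25), "empty")
})

test_that("a planted strong active is confirmed end to end", {
  lib <- default_library()[1:12, ]
  effects <- list(C003 = compound_effect("C003", efficacy = 30,
                                         ec50 = 0.05))
  scr <- simulate_screen(lib, effects, seed = 101)
  r <- scr$results
  expect_equal(nrow(r), 12)
  expect_true(r$candidate[r$compound_id == "C003"])
  expect_true(r$confirmed[r$compound_id == "C003"])
  # confirmed implies candidate everywhere
  expect_true(all(!r$confirmed | r$candidate))
  # well percentages with 20 evaluable neurons are multiples of 5
  ev20 <- scr$wells[scr$wells$evaluable == 20 & scr$wells$valid, ]
  expect_true(all(ev20$pct_mature %% 5 == 0))
})

test_that("screens are deterministic given the seed and order-invariant", {
  lib <- default_library()[1:6, ]
  effects <- list(C002 = compound_effect("C002", efficacy = 30,
                                         ec50 = 0.05))
  a <- simulate_screen(lib, effects, seed = 202)
  b <- simulate_screen(lib, effects, seed = 202)
  expect_identical(a$results, b$results)
  # shuffling neuron rows leaves every well percentage unchanged
  ds <- a$dataset
  set.seed(1)
  ds$neurons <- ds$neurons[sample(nrow(ds$neurons)), ]
  ds$spines <- ds$spines[sample(nrow(ds$spines)), ]
  c <- run_screen(ds)
  expect_equal(a$results, c$results)
})

test_that("plates without two valid DMSO wells are excluded and logged", {
  lib <- default_library()[1:4, ]
  ds <- generate_screen_dataset(lib, seed = 77)
  # damage one whole vehicle well
  veh <- ds$wells[ds$wells$treatment == "vehicle", ][1, ]
  sel <- ds$neurons$plate_id == veh$plate_id &
    ds$neurons$well_id == veh$well_id
  ds$neurons$damaged[sel] <- 1L
  expect_message(scr <- run_screen(ds), "excluded")
  expect_equal(scr$excluded_plates, veh$plate_id)
  expect_false(any(scr$results$candidate))
})

test_that("empty library yields an empty result table", {
  ds <- structure(list(wells = data.frame(), neurons = data.frame(),
                       spines = data.frame(),
                       library = default_library()[0, ]),
                  class = "screen_dataset")
  scr <- run_screen(ds)
  expect_s3_class(scr, "spine_screen")
  expect_equal(nrow(scr$results), 0)
})

test_that("per-target tabulation conserves counts and rounds half-up", {
  res <- data.frame(
    target_class = rep(c("A", "B"), c(16, 8)),
    candidate = rep(c(TRUE, FALSE, TRUE, FALSE), c(4, 12, 3, 5)),
    confirmed = rep(c(TRUE, FALSE, TRUE, FALSE), c(1, 15, 2, 6)))
  tab <- tabulate_by_target(res)
  expect_equal(tab$n_compounds[tab$target_class == "Total"], 24)
  expect_equal(sum(tab$n_compounds[tab$target_class != "Total"]), 24)
  # 1/16 = 6.25% rounds half-up to 6.3 (not banker's 6.2)
  expect_equal(tab$hit_rate[tab$target_class == "A"], 6.3)
  expect_equal(tab$hit_rate[tab$target_class == "B"], 25.0)
  expect_equal(tab$n_hits[tab$target_class == "Total"],
               sum(tab$n_hits[tab$target_class != "Total"]))
})

test_that("classified spine tables round-trip through CSV files", {
  lib <- default_library()[1:3, ]
  ds <- generate_screen_dataset(lib, seed = 5)
  dir <- withr::local_tempdir()
  write_screen_dataset(ds, dir)
  back <- read_screen_dataset(file.path(dir, "spines.csv"),
                              file.path(dir, "neurons.csv"),
                              file.path(dir, "wells.csv"),
                              file.path(dir, "library.csv"))
  expect_equal(nrow(back$spines), nrow(ds$spines))
  out <- classify_spine_table(back$spines, back$neurons)
  expect_true(all(out$spines$spine_class %in% SPINE_CLASSES))
  expect_true(all(out$neuron_summary$n_spines > 0))
  expect_equal(run_screen(back)$results$candidate,
               run_screen(ds)$results$candidate)
})
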