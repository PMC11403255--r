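# Vectorized class-conditional geometry sampler: draws log-normal
# length/head/neck for `n` spines of one class and rejection-samples until
# every spine re-classifies to that class.
sample_class_geometry <- function(class, n, geometry_params,
                                  max_rejections = 1000) {
  pr <- geometry_params[[class]]
  out <- data.frame(total_length_um = numeric(n),
                    head_diameter_um = numeric(n),
                    neck_diameter_um = numeric(n))
  todo <- seq_len(n)
  for (iter in seq_len(max_rejections)) {
    if (length(todo) == 0) return(out)
    m <- length(todo)
    len <- rlnorm(m, pr$length[["meanlog"]], pr$length[["sdlog"]])
    head <- rlnorm(m, pr$head[["meanlog"]], pr$head[["sdlog"]])
    neck <- rlnorm(m, pr$neck[["meanlog"]], pr$neck[["sdlog"]])
    ok <- classify_spine(len, head, neck) == class
    keep <- todo[ok]
    out$total_length_um[keep] <- len[ok]
    out$head_diameter_um[keep] <- head[ok]
    out$neck_diameter_um[keep] <- neck[ok]
    todo <- todo[!ok]
  }
  stop("could not sample geometry consistent with class '", class,
       "' within ", max_rejections, " rejection rounds; ",
       "check geometry_params", call. = FALSE)
}

#' Sample spine geometries of a given morphological class
#'
#' Draws length, head and neck diameters from the class's log-normal
#' distributions and rejection-samples until [classify_spine()] returns
#' the requested class, guaranteeing round-trip consistency between the
#' generator and the classifier.
#'
#' @param class one of `mushroom, thin, stubby, filopodium`.
#' @param n number of spines.
#' @param geometry_params per-class distribution parameters (defaults to
#'   the package's built-ins).
#' @param max_rejections rejection rounds before giving up; default 1000.
#' @param seed optional integer seed; `NULL` continues the current RNG
#'   stream.
#' @return Data frame with `total_length_um`, `head_diameter_um`,
#'   `neck_diameter_um`.
#' @export
sample_spine <- function(class, n = 1,
                         geometry_params = default_geometry_params(),
                         max_rejections = 1000, seed = NULL) {
  class <- match.arg(class, SPINE_CLASSES)
  if (!is.null(seed)) set.seed(seed)
  sample_class_geometry(class, n, geometry_params, max_rejections)
}

# Core vectorized neuron generator: spine counts, classes and geometry for
# `n_neurons` neurons under one (profile, effect, concentration) setting.
# Returns list(neurons, spines) data frames with neuron_id 1..n.
simulate_neuron_tables <- function(profile, n_neurons, effect = NULL,
                                   concentration_um = NULL) {
  stopifnot(inherits(profile, "condition_profile"))
  mixture <- profile$class_mixture
  tox <- 0
  if (!is.null(effect)) {
    stopifnot(inherits(effect, "compound_effect"))
    if (is.null(concentration_um) || concentration_um <= 0)
      stop("a positive concentration is required with a compound effect",
           call. = FALSE)
    mixture <- shift_mixture(mixture, effect_shift(effect,
                                                   concentration_um))
    tox <- effect$toxicity_prob * min(concentration_um / 1, 1)
  }
  lambda <- profile$density_mean * profile$dendrite_length_um
  counts <- rpois(n_neurons, lambda)
  while (any(counts == 0))           # condition on >= 1 spine per neuron
    counts[counts == 0] <- rpois(sum(counts == 0), lambda)
  damaged <- rbinom(n_neurons, 1, tox)
  neurons <- data.frame(neuron_id = as.character(seq_len(n_neurons)),
                        dendrite_length_um = profile$dendrite_length_um,
                        damaged = damaged, stringsAsFactors = FALSE)
  total <- sum(counts)
  cls <- sample(SPINE_CLASSES, total, replace = TRUE, prob = mixture)
  geom <- data.frame(total_length_um = numeric(total),
                     head_diameter_um = numeric(total),
                     neck_diameter_um = numeric(total))
  for (k in SPINE_CLASSES) {
    idx <- which(cls == k)
    if (length(idx))
      geom[idx, ] <- sample_class_geometry(k, length(idx),
                                           profile$geometry_params)
  }
  spines <- data.frame(neuron_id = rep(neurons$neuron_id, counts),
                       spine_id = sequence(counts),
                       geom, stringsAsFactors = FALSE)
  list(neurons = neurons, spines = spines)
}

#' Sample one neuron from a condition profile
#'
#' Spine count is Poisson(density x dendrite length) conditioned on at
#' least one spine; spine classes are drawn from the profile's mixture,
#' shifted by the compound's Hill-model effect when given; geometry comes
#' from [sample_spine()]; the damaged flag is Bernoulli with the
#' compound's concentration-scaled toxicity.
#'
#' @param profile a [condition_profile()].
#' @param effect optional [compound_effect()].
#' @param concentration_um treatment concentration, uM (required with
#'   `effect`).
#' @param seed optional integer seed.
#' @return A [neuron_record()].
#' @export
sample_neuron <- function(profile, effect = NULL, concentration_um = NULL,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tb <- simulate_neuron_tables(profile, 1, effect, concentration_um)
  neuron_record("1", tb$spines[, c("total_length_um", "head_diameter_um",
                                   "neck_diameter_um")],
                tb$neurons$dendrite_length_um[1],
                tb$neurons$damaged[1] == 1)
}

#' Simulate many neurons and report their maturity calls
#'
#' Convenience wrapper for calibration checks: generates `n` neurons from
#' a profile and returns the per-neuron mushroom fractions and maturity
#' calls.
#'
#' @inheritParams sample_neuron
#' @param n number of neurons.
#' @param maturity_cut mushroom-fraction cut; default 0.5.
#' @return Data frame with `n_spines`, `n_mushroom`, `mushroom_fraction`,
#'   `mature`.
#' @export
simulate_neuron_maturity <- function(profile, n, effect = NULL,
                                     concentration_um = NULL,
                                     maturity_cut = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tb <- simulate_neuron_tables(profile, n, effect, concentration_um)
  cls <- classify_spine(tb$spines$total_length_um,
                        tb$spines$head_diameter_um,
                        tb$spines$neck_diameter_um)
  n_spines <- as.vector(table(factor(tb$spines$neuron_id,
                                     levels = tb$neurons$neuron_id)))
  n_mush <- as.vector(tapply(cls == "mushroom",
                             factor(tb$spines$neuron_id,
                                    levels = tb$neurons$neuron_id), sum))
  data.frame(n_spines = n_spines, n_mushroom = n_mush,
             mushroom_fraction = n_mush / n_spines,
             mature = maturity_from_counts(n_mush, n_spines, maturity_cut))
}

# lay out wells onto 96-well plates: 2 DMSO wells + up to 94 treatment
# wells per plate. `treatments` is a data frame with compound_id,
# concentration_um, stage.
layout_plates <- function(treatments, plate_prefix, wells_per_plate = 96) {
  cap <- wells_per_plate - 2
  n <- nrow(treatments)
  n_plates <- max(1, ceiling(n / cap))
  rows <- LETTERS[1:8]
  well_names <- paste0(rep(rows, each = 12), rep(1:12, times = 8))
  out <- vector("list", n_plates)
  for (p in seq_len(n_plates)) {
    plate_id <- sprintf("%s%02d", plate_prefix, p)
    idx <- ((p - 1) * cap + 1):min(p * cap, n)
    tw <- treatments[idx, , drop = FALSE]
    w <- data.frame(plate_id = plate_id,
                    well_id = well_names[seq_len(nrow(tw) + 2)],
                    treatment = c("vehicle", "vehicle",
                                  rep("compound", nrow(tw))),
                    compound_id = c(NA, NA, tw$compound_id),
                    concentration_um = c(NA, NA, tw$concentration_um),
                    stage = c(tw$stage[1], tw$stage[1], tw$stage),
                    stringsAsFactors = FALSE)
    out[[p]] <- w
  }
  do.call(rbind, out)
}

#' Default 181-compound screening library annotation
#'
#' A synthetic compound library mirroring the screen's per-target
#' composition (38 serotonin-receptor ligands, 23 adrenergic, ... 181
#' compounds over 20 target classes).
#'
#' @param dilution_ladder `"2fold"` or `"3fold"`, recycled per compound.
#' @return Data frame with `compound_id`, `compound_name`, `target_class`,
#'   `primary_concentration_um`, `dilution_ladder`.
#' @export
default_library <- function(dilution_ladder = "3fold") {
  sizes <- c("5-HT receptor" = 38, "Adrenergic receptor" = 23,
             "Dopamine receptor" = 17, "mACh receptor" = 17,
             "GABA receptor" = 11, "gamma-secretase" = 8,
             "AMPA receptor" = 8, "nACh receptor" = 8, "LRRK2" = 8,
             "NMDA receptor" = 7, "Opioid receptor" = 7,
             "Monoamine oxidase" = 6, "Neurokinin receptor" = 6,
             "FAAH" = 4, "SSRI" = 4, "Amyloid-beta" = 3, "AChE" = 2,
             "CGRP receptor" = 2, "beta-secretase" = 1, "MAGL" = 1)
  n <- sum(sizes)
  data.frame(compound_id = sprintf("C%03d", seq_len(n)),
             compound_name = sprintf("compound-%03d", seq_len(n)),
             target_class = rep(names(sizes), sizes),
             primary_concentration_um = 1,
             dilution_ladder = dilution_ladder,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic screening dataset
#'
#' Lays compounds out on 96-well plates (two DMSO vehicle wells per
#' plate), images `neurons_per_well` neurons per well from the given
#' condition profile, applies each compound's effect at its well
#' concentration, and emits the spine/neuron/well tables the screening
#' pipeline consumes. Primary wells are at each compound's
#' `primary_concentration_um` (1 uM by default); compounds named in
#' `secondary_for` additionally get their full dilution ladder
#' ([DILUTION_LADDERS]) on secondary plates.
#'
#' @param library annotation data frame as from [default_library()].
#' @param effects named list of [compound_effect()] keyed by compound_id;
#'   compounds without an entry are inactive.
#' @param profile the vehicle condition; default BTBR-like.
#' @param secondary_for compound_ids to lay out dilution series for.
#' @param include_primary generate the primary 1-uM plates; set `FALSE`
#'   to emit only the secondary plates of `secondary_for`.
#' @param neurons_per_well imaged neurons per well; default 20.
#' @param wells_per_plate default 96.
#' @param seed optional integer seed.
#' @return A `screen_dataset`: list of data frames `wells`, `neurons`,
#'   `spines`, `library`.
#' @export
generate_screen_dataset <- function(library = default_library(),
                                    effects = list(),
                                    profile = condition_profile("BTBR-like"),
                                    secondary_for = character(0),
                                    include_primary = TRUE,
                                    neurons_per_well = 20,
                                    wells_per_plate = 96, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(nrow(library) >= 1, wells_per_plate >= 3)
  if (!include_primary && !length(secondary_for))
    stop("nothing to generate: no primary stage and no secondary_for",
         call. = FALSE)
  wells <- NULL
  if (include_primary) {
    primary <- data.frame(compound_id = library$compound_id,
                          concentration_um = library$primary_concentration_um,
                          stage = "primary", stringsAsFactors = FALSE)
    wells <- layout_plates(primary, "P", wells_per_plate)
  }
  if (length(secondary_for)) {
    missing <- setdiff(secondary_for, library$compound_id)
    if (length(missing))
      stop("secondary_for compounds absent from library: ",
           paste(missing, collapse = ", "), call. = FALSE)
    lad <- library$dilution_ladder[match(secondary_for,
                                         library$compound_id)]
    sec <- do.call(rbind, lapply(seq_along(secondary_for), function(i) {
      conc <- DILUTION_LADDERS[[lad[i]]]
      data.frame(compound_id = secondary_for[i], concentration_um = conc,
                 stage = "secondary", stringsAsFactors = FALSE)
    }))
    wells <- rbind(wells, layout_plates(sec, "S", wells_per_plate))
  }
  neurons <- vector("list", nrow(wells))
  spines <- vector("list", nrow(wells))
  for (i in seq_len(nrow(wells))) {
    eff <- NULL; conc <- NULL
    if (wells$treatment[i] == "compound") {
      eff <- effects[[wells$compound_id[i]]]
      conc <- wells$concentration_um[i]
      if (is.null(eff)) eff <- compound_effect(wells$compound_id[i], 0)
    }
    tb <- simulate_neuron_tables(profile, neurons_per_well, eff, conc)
    key <- data.frame(plate_id = wells$plate_id[i],
                      well_id = wells$well_id[i],
                      stringsAsFactors = FALSE)
    neurons[[i]] <- cbind(key, tb$neurons)
    spines[[i]] <- cbind(key, tb$spines)
  }
  structure(list(wells = wells, neurons = do.call(rbind, neurons),
                 spines = do.call(rbind, spines), library = library),
            class = "screen_dataset")
}

#' @export
print.screen_dataset <- function(x, ...) {
  cat("Synthetic screening dataset:",
      nrow(x$library), "compounds,",
      length(unique(x$wells$plate_id)), "plates,",
      nrow(x$wells), "wells,", nrow(x$neurons), "neurons,",
      nrow(x$spines), "spines\n")
  invisible(x)
}

#' Simulate a full two-stage screen
#'
#' Orchestrates the screen the way the assay was run: generate primary
#' plates (1 uM, duplicate DMSO per plate), call candidates, generate
#' dilution-series plates for the candidates, and score the combined
#' dataset with [run_screen()].
#'
#' @inheritParams generate_screen_dataset
#' @param hit_margin_points,maturity_cut,min_evaluable,confirm_min_passing
#'   passed to [run_screen()].
#' @param seed integer seed fixing the whole simulated screen.
#' @return A `spine_screen` object (see [run_screen()]); the generated
#'   dataset is attached as `$dataset`.
#' @export
simulate_screen <- function(library = default_library(), effects = list(),
                            profile = condition_profile("BTBR-like"),
                            neurons_per_well = 20, hit_margin_points = 10,
                            maturity_cut = 0.5, min_evaluable = 10,
                            confirm_min_passing = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ds <- generate_screen_dataset(library, effects, profile,
                                secondary_for = character(0),
                                neurons_per_well = neurons_per_well)
  first <- run_screen(ds, hit_margin_points, maturity_cut, min_evaluable,
                      confirm_min_passing)
  cand <- first$results$compound_id[first$results$candidate]
  if (length(cand)) {
    sec <- generate_screen_dataset(library, effects, profile,
                                   secondary_for = cand,
                                   include_primary = FALSE,
                                   neurons_per_well = neurons_per_well)
    ds$wells <- rbind(ds$wells, sec$wells)
    ds$neurons <- rbind(ds$neurons, sec$neurons)
    ds$spines <- rbind(ds$spines, sec$spines)
  }
  out <- run_screen(ds, hit_margin_points, maturity_cut, min_evaluable,
                    confirm_min_passing)
  out$dataset <- ds
  out
}
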