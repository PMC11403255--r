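#' Call neuron maturity from its mushroom-spine fraction
#'
#' A neuron is a "mature spine neuron" when strictly more than half of its
#' spines are mushroom-type (equality at the cut counts as immature).
#'
#' @param neuron a [neuron_record()]; must be undamaged with >= 1 spine.
#' @param maturity_cut mushroom-fraction threshold; default 0.5.
#' @return `"mature"` or `"immature"`.
#' @export
call_neuron_maturity <- function(neuron, maturity_cut = 0.5) {
  if (inherits(neuron, "neuron_record") && neuron$damaged)
    stop("neuron excluded by damage annotation", call. = FALSE)
  prop <- spine_class_proportions(neuron)
  if (prop[["mushroom"]] > maturity_cut) "mature" else "immature"
}

# maturity from pre-computed counts (vectorized pipeline core)
maturity_from_counts <- function(n_mushroom, n_total, maturity_cut = 0.5) {
  n_mushroom / n_total > maturity_cut
}

#' Percentage of mature spine neurons in a well
#'
#' Damaged neurons are excluded from both numerator and denominator. A
#' well with fewer than `min_evaluable` undamaged neurons is flagged
#' invalid (`NA` with a warning) rather than yielding an unstable
#' percentage.
#'
#' @param neurons list of [neuron_record()] objects imaged in the well.
#' @param maturity_cut passed to [call_neuron_maturity()].
#' @param min_evaluable minimum undamaged neurons for a valid percentage.
#' @return Percentage in `[0, 100]`, or `NA` for an invalid well.
#' @export
well_mature_fraction <- function(neurons, maturity_cut = 0.5,
                                 min_evaluable = 10) {
  ok <- !vapply(neurons, function(n) n$damaged, logical(1))
  evaluable <- neurons[ok]
  if (length(evaluable) < min_evaluable) {
    warning(sprintf("well invalid: %d evaluable neurons < min_evaluable %d",
                    length(evaluable), min_evaluable), call. = FALSE)
    return(NA_real_)
  }
  mature <- vapply(evaluable, function(n)
    call_neuron_maturity(n, maturity_cut) == "mature", logical(1))
  100 * mean(mature)
}

#' Duplicate-DMSO plate reference
#'
#' The per-plate vehicle reference is the arithmetic mean of the mature
#' percentages of exactly two valid DMSO wells.
#'
#' @param well_pcts numeric vector of the two vehicle well percentages.
#' @return The reference percentage.
#' @export
dmso_reference <- function(well_pcts) {
  if (length(well_pcts) != 2 || any(is.na(well_pcts)))
    stop("exactly two valid DMSO vehicle wells are required per plate",
         call. = FALSE)
  mean(well_pcts)
}

#' Hit criterion against the vehicle reference
#'
#' A treatment is a hit when its mature-neuron percentage exceeds the
#' DMSO reference by strictly more than `margin_points` percentage points.
#'
#' @param compound_pct,dmso_ref percentages in `[0, 100]`.
#' @param margin_points hit margin in percentage points; default 10.
#' @return Logical.
#' @export
call_hit <- function(compound_pct, dmso_ref, margin_points = 10) {
  vals <- c(compound_pct, dmso_ref)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 100))
    stop("percentages must lie in [0, 100]", call. = FALSE)
  compound_pct - dmso_ref > margin_points
}

#' Known dilution ladders for the confirmation stage
#'
#' Concentrations (uM) of the 2-fold and 3-fold series used in the
#' secondary screen, both topping out at 1 uM.
#' @export
DILUTION_LADDERS <- list(
  `2fold` = c(1, 0.5, 0.25, 0.13, 0.06, 0.03),
  `3fold` = c(1, 0.3, 0.1, 0.03, 0.01)
)

#' Dilution-series confirmation of a candidate hit
#'
#' A candidate is confirmed when the hit criterion is met at at least
#' `min_passing` of the tested concentrations.
#'
#' @param concentrations_um tested concentrations, uM.
#' @param pct_mature mature percentages at those concentrations.
#' @param dmso_ref vehicle reference percentage(s); recycled to the
#'   series length, so each well can carry its own plate's reference.
#' @param margin_points hit margin in percentage points.
#' @param min_passing concentrations that must pass; default 1.
#' @return List with `confirmed` (logical) and `passing_concentrations`.
#' @export
confirm_secondary <- function(concentrations_um, pct_mature, dmso_ref,
                              margin_points = 10, min_passing = 1) {
  if (length(concentrations_um) == 0)
    stop("confirmation series is empty", call. = FALSE)
  stopifnot(length(concentrations_um) == length(pct_mature))
  dmso_ref <- rep_len(dmso_ref, length(concentrations_um))
  known <- vapply(concentrations_um, function(cc)
    any(vapply(DILUTION_LADDERS, function(l)
      any(abs(l - cc) < 1e-9), logical(1))), logical(1))
  if (!all(known))
    warning("concentrations not on a declared dilution ladder: ",
            paste(concentrations_um[!known], collapse = ", "),
            call. = FALSE)
  keep <- !is.na(pct_mature)
  pass <- rep(FALSE, length(concentrations_um))
  pass[keep] <- mapply(call_hit, pct_mature[keep], dmso_ref[keep],
                       MoreArgs = list(margin_points = margin_points))
  list(confirmed = sum(pass) >= min_passing,
       passing_concentrations = concentrations_um[pass])
}

# per-neuron mushroom counts for a whole spine table; returns a data frame
# keyed by plate_id/well_id/neuron_id
neuron_class_counts <- function(spines) {
  cls <- classify_spine(spines$total_length_um, spines$head_diameter_um,
                        spines$neck_diameter_um)
  key <- interaction(spines$plate_id, spines$well_id, spines$neuron_id,
                     drop = TRUE, sep = "\r")
  n_total <- as.vector(table(key))
  n_mush <- as.vector(tapply(cls == "mushroom", key, sum))
  parts <- do.call(rbind, strsplit(levels(key), "\r", fixed = TRUE))
  data.frame(plate_id = parts[, 1], well_id = parts[, 2],
             neuron_id = parts[, 3], n_spines = n_total,
             n_mushroom = n_mush, stringsAsFactors = FALSE)
}

# well-level mature percentages for a dataset; returns wells with pct and
# validity flag
well_table <- function(dataset, maturity_cut, min_evaluable) {
  for (tb in c("wells", "neurons", "spines"))
    for (col in c("plate_id", "well_id", "neuron_id"))
      if (col %in% names(dataset[[tb]]))
        dataset[[tb]][[col]] <- as.character(dataset[[tb]][[col]])
  counts <- neuron_class_counts(dataset$spines)
  neurons <- merge(dataset$neurons, counts,
                   by = c("plate_id", "well_id", "neuron_id"),
                   all.x = TRUE)
  neurons$n_spines[is.na(neurons$n_spines)] <- 0L
  ok <- neurons$damaged == 0 & neurons$n_spines > 0
  neurons$mature <- NA
  neurons$mature[ok] <- maturity_from_counts(
    neurons$n_mushroom[ok], neurons$n_spines[ok], maturity_cut)
  agg <- aggregate(cbind(evaluable = ok, mature = ok & neurons$mature %in% TRUE)
                   ~ plate_id + well_id, data = neurons, FUN = sum)
  wells <- merge(dataset$wells, agg, by = c("plate_id", "well_id"),
                 all.x = TRUE)
  wells$evaluable[is.na(wells$evaluable)] <- 0L
  wells$valid <- wells$evaluable >= min_evaluable
  wells$pct_mature <- ifelse(wells$valid,
                             100 * wells$mature / wells$evaluable, NA_real_)
  wells
}

#' Run the two-stage phenotypic screen on a plate dataset
#'
#' Classifies every spine, calls neuron maturity, computes well-level
#' mature percentages with damaged-cell exclusion, references each plate
#' to the mean of its two DMSO wells, applies the primary hit criterion
#' at 1 uM, and confirms candidates over their secondary dilution series.
#' Plates without two valid DMSO wells are excluded and logged.
#'
#' @param dataset a `screen_dataset` (see [generate_screen_dataset()]) or
#'   a list with data frames `wells`, `neurons`, `spines`, `library`.
#' @param hit_margin_points hit margin in percentage points; default 10.
#' @param maturity_cut mushroom-fraction cut for neuron maturity.
#' @param min_evaluable minimum undamaged neurons per valid well.
#' @param confirm_min_passing concentrations that must pass to confirm.
#' @return A `spine_screen` object: a list with `results` (one row per
#'   compound), `wells` (well-level detail), `excluded_plates`, and the
#'   call parameters.
#' @export
run_screen <- function(dataset, hit_margin_points = 10, maturity_cut = 0.5,
                       min_evaluable = 10, confirm_min_passing = 1) {
  params <- list(hit_margin_points = hit_margin_points,
                 maturity_cut = maturity_cut,
                 min_evaluable = min_evaluable,
                 confirm_min_passing = confirm_min_passing)
  if (nrow(dataset$library) == 0)
    return(structure(list(results = data.frame(),
                          wells = dataset$wells,
                          excluded_plates = character(), params = params),
                     class = "spine_screen"))
  wells <- well_table(dataset, maturity_cut, min_evaluable)
  veh <- wells[wells$treatment == "vehicle", ]
  refs <- list(); excluded <- character()
  for (p in unique(wells$plate_id)) {
    pv <- veh[veh$plate_id == p & veh$valid, ]
    if (nrow(pv) != 2) {
      excluded <- c(excluded, p)
      message("plate ", p, " excluded: ", nrow(pv),
              " valid DMSO wells (need 2)")
    } else refs[[p]] <- dmso_reference(pv$pct_mature)
  }
  wells <- wells[!(wells$plate_id %in% excluded), ]
  wells$dmso_ref <- if (length(refs)) unlist(refs)[wells$plate_id]
                    else rep(NA_real_, nrow(wells))

  lib <- dataset$library
  comp <- wells[wells$treatment == "compound", ]
  primary <- comp[comp$stage == "primary", ]
  secondary <- comp[comp$stage == "secondary", ]
  empty <- data.frame(compound_id = character(), target_class = character(),
                      primary_pct_mature = numeric(),
                      dmso_reference_pct = numeric(), candidate = logical(),
                      n_secondary_concentrations = integer(),
                      passing_concentrations = character(),
                      confirmed = logical(), stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(lib)), function(i) {
    cid <- lib$compound_id[i]
    pw <- primary[primary$compound_id == cid, ]
    pct <- if (nrow(pw) == 1 && pw$valid) pw$pct_mature else NA_real_
    ref <- if (nrow(pw) == 1) pw$dmso_ref else NA_real_
    candidate <- !is.na(pct) && call_hit(pct, ref, hit_margin_points)
    sw <- secondary[secondary$compound_id == cid, ]
    confirmed <- FALSE; passing <- numeric(0)
    if (candidate && nrow(sw) > 0) {
      cs <- confirm_secondary(sw$concentration_um, sw$pct_mature,
                              sw$dmso_ref, hit_margin_points,
                              confirm_min_passing)
      confirmed <- cs$confirmed; passing <- cs$passing_concentrations
    }
    data.frame(compound_id = cid, target_class = lib$target_class[i],
               primary_pct_mature = pct, dmso_reference_pct = ref,
               candidate = candidate,
               n_secondary_concentrations = nrow(sw),
               passing_concentrations =
                 paste(sort(passing, decreasing = TRUE), collapse = ";"),
               confirmed = confirmed, stringsAsFactors = FALSE)
  })
  out <- list(results = if (length(res)) do.call(rbind, res) else empty,
              wells = wells,
              excluded_plates = excluded,
              params = list(hit_margin_points = hit_margin_points,
                            maturity_cut = maturity_cut,
                            min_evaluable = min_evaluable,
                            confirm_min_passing = confirm_min_passing))
  class(out) <- "spine_screen"
  out
}

#' @export
print.spine_screen <- function(x, ...) {
  r <- x$results
  cat("Two-stage spine-maturity screen\n")
  cat(sprintf("  %d compounds, %d candidate hits, %d confirmed hits\n",
              nrow(r), sum(r$candidate), sum(r$confirmed)))
  cat(sprintf("  hit margin: >%g points over duplicate-DMSO reference\n",
              x$params$hit_margin_points))
  if (length(x$excluded_plates))
    cat("  excluded plates:", paste(x$excluded_plates, collapse = ", "),
        "\n")
  invisible(x)
}

#' @export
summary.spine_screen <- function(object, ...) {
  tabulate_by_target(object$results)
}

# round half-up to `digits` decimals (Table-style rounding; base round()
# rounds half to even)
round_half_up <- function(x, digits = 1) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Tabulate screen results per target class
#'
#' Per-target compound, candidate and confirmed-hit counts with the hit
#' rate (100 x hits / compounds, rounded half-up to one decimal), plus a
#' Total row over all classes.
#'
#' @param results data frame with columns `target_class`, `candidate`,
#'   `confirmed` (one row per compound), e.g. `$results` of a
#'   [run_screen()] object; alternatively a pre-counted data frame with
#'   columns `target_class`, `n_compounds`, `n_candidates`, `n_hits`.
#' @return Data frame with one row per target class plus `Total`.
#' @export
tabulate_by_target <- function(results) {
  if (all(c("n_compounds", "n_hits") %in% names(results))) {
    tab <- results[, c("target_class", "n_compounds",
                       if ("n_candidates" %in% names(results))
                         "n_candidates", "n_hits")]
  } else {
    stopifnot(all(c("target_class", "candidate", "confirmed")
                  %in% names(results)))
    tab <- aggregate(cbind(n_compounds = 1L,
                           n_candidates = results$candidate,
                           n_hits = results$confirmed)
                     ~ target_class, data = results, FUN = sum)
  }
  total <- data.frame(target_class = "Total", t(colSums(tab[, -1])))
  tab <- rbind(tab, total)
  tab$hit_rate <- round_half_up(100 * tab$n_hits / tab$n_compounds, 1)
  tab$hit_rate[tab$n_compounds == 0] <- NA_real_
  rownames(tab) <- NULL
  tab
}
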