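#' Read a screening dataset from its CSV tables
#'
#' Expected schemas (UTF-8, header row, '.' decimal separator):
#' * spines: `plate_id, well_id, neuron_id, spine_id, total_length_um,
#'   head_diameter_um, neck_diameter_um`
#' * neurons: `plate_id, well_id, neuron_id, dendrite_length_um, damaged`
#'   (damaged coded 0/1)
#' * wells: `plate_id, well_id, treatment ("vehicle"|"compound"),
#'   compound_id, concentration_um, stage ("primary"|"secondary")`
#' * library: `compound_id, compound_name, target_class,
#'   primary_concentration_um, dilution_ladder ("2fold"|"3fold")`
#'
#' @param spines,neurons,wells,library file paths.
#' @return A `screen_dataset` list of the four data frames.
#' @export
read_screen_dataset <- function(spines, neurons, wells, library) {
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop(what, " table lacks columns: ", paste(miss, collapse = ", "),
           call. = FALSE)
    df
  }
  ds <- list(
    spines = need(read.csv(spines),
                  c("plate_id", "well_id", "neuron_id", "total_length_um",
                    "head_diameter_um", "neck_diameter_um"), "spines"),
    neurons = need(read.csv(neurons),
                   c("plate_id", "well_id", "neuron_id",
                     "dendrite_length_um", "damaged"), "neurons"),
    wells = need(read.csv(wells),
                 c("plate_id", "well_id", "treatment", "compound_id",
                   "concentration_um", "stage"), "wells"),
    library = need(read.csv(library),
                   c("compound_id", "target_class"), "library"))
  class(ds) <- "screen_dataset"
  ds
}

#' Write a screening dataset to CSV tables
#'
#' @param dataset a `screen_dataset`.
#' @param dir output directory (created if needed); files `spines.csv`,
#'   `neurons.csv`, `wells.csv`, `library.csv`.
#' @return The directory, invisibly.
#' @export
write_screen_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("spines", "neurons", "wells", "library"))
    write.csv(dataset[[nm]], file.path(dir, paste0(nm, ".csv")),
              row.names = FALSE)
  invisible(dir)
}

#' Classify a spine table and summarise per neuron
#'
#' The batch form of [classify_spine()] for tabular input: appends a
#' `spine_class` column and returns per-neuron class counts, proportions,
#' and density.
#'
#' @param spines spine table (see [read_screen_dataset()] schema).
#' @param neurons neuron table with `dendrite_length_um` and `damaged`.
#' @return List with `spines` (classified) and `neuron_summary`.
#' @export
classify_spine_table <- function(spines, neurons) {
  spines$spine_class <- as.character(
    classify_spine(spines$total_length_um, spines$head_diameter_um,
                   spines$neck_diameter_um))
  key <- c("plate_id", "well_id", "neuron_id")
  for (col in key) {
    spines[[col]] <- as.character(spines[[col]])
    neurons[[col]] <- as.character(neurons[[col]])
  }
  counts <- neuron_class_counts(spines)
  summary <- merge(neurons, counts, by = key, all.x = TRUE)
  summary$n_spines[is.na(summary$n_spines)] <- 0L
  summary$n_mushroom[is.na(summary$n_mushroom)] <- 0L
  summary$mushroom_fraction <-
    ifelse(summary$n_spines > 0, summary$n_mushroom / summary$n_spines,
           NA_real_)
  summary$density_per_um <- summary$n_spines / summary$dendrite_length_um
  summary$density_per_10um <- 10 * summary$density_per_um
  ok <- summary$damaged == 0 & summary$n_spines > 0
  summary$maturity <- NA_character_
  summary$maturity[ok] <-
    ifelse(maturity_from_counts(summary$n_mushroom[ok],
                                summary$n_spines[ok]),
           "mature", "immature")
  list(spines = spines, neuron_summary = summary)
}
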