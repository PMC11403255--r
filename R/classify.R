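#' Spine morphological classes
#'
#' The closed set of four class labels, ordered roughly from most mature
#' (mushroom: large head on a narrow neck) to least (filopodium: long,
#' headless protrusion).
#'
#' @export
SPINE_CLASSES <- c("mushroom", "thin", "stubby", "filopodium")

# Validate geometry vectors; errors name the offending field.
validate_geometry <- function(total_length_um, head_diameter_um,
                              neck_diameter_um) {
  check_field <- function(x, name, positive) {
    if (!is.numeric(x)) stop(name, " must be numeric", call. = FALSE)
    if (any(!is.finite(x)))
      stop(name, " contains non-finite values", call. = FALSE)
    if (positive && any(x <= 0))
      stop(name, " must be strictly positive", call. = FALSE)
    if (!positive && any(x < 0))
      stop(name, " must be non-negative", call. = FALSE)
  }
  check_field(total_length_um, "total_length_um", positive = TRUE)
  check_field(head_diameter_um, "head_diameter_um", positive = FALSE)
  check_field(neck_diameter_um, "neck_diameter_um", positive = FALSE)
  n <- length(total_length_um)
  if (length(head_diameter_um) != n || length(neck_diameter_um) != n)
    stop("geometry fields must have equal length", call. = FALSE)
  invisible(TRUE)
}

#' Classify dendritic spines by the four-class geometric decision tree
#'
#' Assigns each spine to exactly one of mushroom, thin, stubby or
#' filopodium from its total length, head diameter and neck diameter
#' (all in micrometres). The tree:
#'
#' 1. Head-to-neck ratio `r = head / neck`. If `r > 1.1` the spine enters
#'    the mushroom branch: head diameter `> 0.35` um confirms *mushroom*,
#'    otherwise the spine goes to the filopodium determination.
#' 2. If `r <= 1.1` the spine enters the stubby branch: length-to-head
#'    ratio `<= 3` confirms *stubby*, otherwise the spine goes to the
#'    filopodium determination.
#' 3. Filopodium determination: total length `>= 3` um is *filopodium*,
#'    shorter spines are *thin*.
#'
#' Degenerate diameters follow head-dominance conventions: a zero neck
#' gives an infinite head-to-neck ratio (mushroom branch); a zero head in
#' the stubby branch gives an infinite length-to-head ratio (filopodium
#' determination). Comparisons are exact; no epsilon tolerance is applied.
#'
#' @param total_length_um spine total length, um; strictly positive.
#' @param head_diameter_um spine head diameter, um; non-negative.
#' @param neck_diameter_um spine neck diameter, um; non-negative.
#'
#' @return A factor with levels `mushroom, thin, stubby, filopodium`,
#'   one element per spine.
#'
#' @examples
#' classify_spine(1.0, 0.50, 0.30)  # mushroom
#' classify_spine(4.0, 0.20, 0.10)  # filopodium
#' classify_spine(0.8, 0.30, 0.30)  # stubby
#' classify_spine(2.0, 0.25, 0.25)  # thin
#' @export
classify_spine <- function(total_length_um, head_diameter_um,
                           neck_diameter_um) {
  validate_geometry(total_length_um, head_diameter_um, neck_diameter_um)
  head_neck <- ifelse(neck_diameter_um > 0,
                      head_diameter_um / neck_diameter_um, Inf)
  len_head <- ifelse(head_diameter_um > 0,
                     total_length_um / head_diameter_um, Inf)
  filo <- ifelse(total_length_um >= 3, "filopodium", "thin")
  out <- ifelse(head_neck > 1.1,
                ifelse(head_diameter_um > 0.35, "mushroom", filo),
                ifelse(len_head <= 3, "stubby", filo))
  factor(out, levels = SPINE_CLASSES)
}

#' Construct a neuron record
#'
#' Bundles one imaged neuron: its spines (a data frame with columns
#' `total_length_um`, `head_diameter_um`, `neck_diameter_um`), the length
#' of dendrite analyzed, and whether the cell was annotated as damaged.
#' Damaged neurons are never used in maturity or class-proportion
#' statistics.
#'
#' @param neuron_id identifier.
#' @param spines data frame of spine geometry (may have zero rows).
#' @param dendrite_length_um dendrite length analyzed, um; `> 0`.
#' @param damaged logical damage annotation.
#' @return An object of class `neuron_record`.
#' @export
neuron_record <- function(neuron_id, spines, dendrite_length_um,
                          damaged = FALSE) {
  stopifnot(is.data.frame(spines))
  needed <- c("total_length_um", "head_diameter_um", "neck_diameter_um")
  if (!all(needed %in% names(spines)))
    stop("spines must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  if (!is.numeric(dendrite_length_um) || length(dendrite_length_um) != 1 ||
      !is.finite(dendrite_length_um) || dendrite_length_um <= 0)
    stop("dendrite_length_um must be a single positive number",
         call. = FALSE)
  if (nrow(spines) > 0)
    validate_geometry(spines$total_length_um, spines$head_diameter_um,
                      spines$neck_diameter_um)
  structure(list(neuron_id = neuron_id, spines = spines,
                 dendrite_length_um = dendrite_length_um,
                 damaged = isTRUE(damaged)),
            class = "neuron_record")
}

#' @export
print.neuron_record <- function(x, ...) {
  cat("Neuron", x$neuron_id, "-", nrow(x$spines), "spines on",
      x$dendrite_length_um, "um of dendrite",
      if (x$damaged) "[damaged]" else "", "\n")
  invisible(x)
}

#' Per-neuron spine class proportions
#'
#' Fraction of a neuron's spines falling in each of the four classes.
#' Fractions sum to one.
#'
#' @param neuron a [neuron_record()]; must be undamaged and have at least
#'   one spine.
#' @return Named numeric vector over `mushroom, thin, stubby, filopodium`.
#' @export
spine_class_proportions <- function(neuron) {
  stopifnot(inherits(neuron, "neuron_record"))
  if (neuron$damaged)
    stop("neuron is annotated as damaged; excluded from class statistics",
         call. = FALSE)
  if (nrow(neuron$spines) == 0)
    stop("neuron has no spines", call. = FALSE)
  cls <- classify_spine(neuron$spines$total_length_um,
                        neuron$spines$head_diameter_um,
                        neuron$spines$neck_diameter_um)
  c(table(cls)) / length(cls)
}

#' Spine density along the analyzed dendrite
#'
#' @param neuron a [neuron_record()].
#' @param per_um scale of the result: length of dendrite per reporting
#'   unit (1 for spines/um, 10 for spines/10 um).
#' @return Spines per `per_um` micrometres of dendrite.
#' @export
spine_density <- function(neuron, per_um = 1) {
  stopifnot(inherits(neuron, "neuron_record"))
  per_um * nrow(neuron$spines) / neuron$dendrite_length_um
}
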