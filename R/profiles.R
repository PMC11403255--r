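# Default per-class geometry distributions: log-normal location/dispersion
# for length, head and neck diameters (um), truncated by the classifier via
# rejection sampling. Locations are medians on the natural scale.
default_geometry_params <- function() {
  list(
    mushroom   = list(length = c(meanlog = log(1.0),  sdlog = 0.35),
                      head   = c(meanlog = log(0.55), sdlog = 0.25),
                      neck   = c(meanlog = log(0.30), sdlog = 0.25)),
    thin       = list(length = c(meanlog = log(1.6),  sdlog = 0.30),
                      head   = c(meanlog = log(0.18), sdlog = 0.25),
                      neck   = c(meanlog = log(0.15), sdlog = 0.25)),
    stubby     = list(length = c(meanlog = log(0.6),  sdlog = 0.30),
                      head   = c(meanlog = log(0.32), sdlog = 0.22),
                      neck   = c(meanlog = log(0.32), sdlog = 0.22)),
    filopodium = list(length = c(meanlog = log(4.0),  sdlog = 0.30),
                      head   = c(meanlog = log(0.14), sdlog = 0.30),
                      neck   = c(meanlog = log(0.13), sdlog = 0.30))
  )
}

#' Expected mature-neuron prevalence for a given mushroom mixture weight
#'
#' With the spine count per neuron Poisson(`lambda`) (conditioned on at
#' least one spine) and each spine independently mushroom with probability
#' `p`, the probability that a neuron is mature (strictly more than half
#' of its spines mushroom) is
#' `sum_n P(N = n | N >= 1) * P(Binomial(n, p) > n/2)`.
#'
#' @param p per-spine mushroom probability.
#' @param lambda mean spine count per neuron.
#' @param maturity_cut mushroom-fraction cut; default 0.5.
#' @return Probability a neuron is called mature.
#' @export
mature_prevalence <- function(p, lambda, maturity_cut = 0.5) {
  n <- seq_len(max(30, ceiling(lambda + 10 * sqrt(lambda))))
  w <- dpois(n, lambda) / (1 - dpois(0, lambda))
  # mature iff mushroom count > n * cut, i.e. >= floor(n * cut) + 1
  sum(w * (1 - pbinom(floor(n * maturity_cut), n, p)))
}

# Solve the mushroom weight so the neuron-level mature prevalence hits the
# target; exact in the Poisson-binomial mixture model above.
calibrate_mushroom_weight <- function(target, lambda, maturity_cut = 0.5) {
  uniroot(function(p) mature_prevalence(p, lambda, maturity_cut) - target,
          interval = c(1e-4, 1 - 1e-4), tol = 1e-10)$root
}

#' Condition profile for the synthetic neuron generator
#'
#' A profile fixes the generative model of one experimental condition:
#' the spine-class mixture, the spine density, the dendrite length
#' analyzed per neuron, and per-class geometry distributions. The two
#' built-in labels are calibrated so that the neuron-level prevalence of
#' mature spine neurons matches the printed screening baselines: 35.5%
#' for the B6-like (control strain) condition and 24.7% for the BTBR-like
#' (autism-model strain) condition. The mushroom mixture weight is solved
#' numerically from the exact Poisson-binomial prevalence
#' ([mature_prevalence()]); the remaining mass is split among thin,
#' stubby and filopodium in fixed 60/28/12 proportions.
#'
#' @param label `"B6-like"` or `"BTBR-like"`, or any label when
#'   `mature_neuron_target` is supplied.
#' @param mature_neuron_target neuron-level mature prevalence in `[0, 1]`;
#'   defaults to 0.355 (B6-like) or 0.247 (BTBR-like).
#' @param density_mean spine density, spines/um; default 1.0.
#' @param dendrite_length_um dendrite analyzed per neuron, um; default 30
#'   (about 30 spines per neuron at the default density).
#' @param rest_split relative weights of thin, stubby, filopodium within
#'   the non-mushroom mass.
#' @param geometry_params per-class length/head/neck log-normal
#'   parameters; see `default_geometry_params`.
#' @return An object of class `condition_profile` with the solved
#'   `class_mixture`.
#' @export
condition_profile <- function(label = c("B6-like", "BTBR-like"),
                              mature_neuron_target = NULL,
                              density_mean = 1.0,
                              dendrite_length_um = 30,
                              rest_split = c(thin = 0.60, stubby = 0.28,
                                             filopodium = 0.12),
                              geometry_params = default_geometry_params()) {
  if (is.null(mature_neuron_target)) {
    label <- match.arg(label)
    mature_neuron_target <- switch(label, "B6-like" = 0.355,
                                   "BTBR-like" = 0.247)
  }
  stopifnot(mature_neuron_target > 0, mature_neuron_target < 1,
            density_mean > 0, dendrite_length_um > 0)
  lambda <- density_mean * dendrite_length_um
  p_mush <- calibrate_mushroom_weight(mature_neuron_target, lambda)
  rest <- rest_split / sum(rest_split) * (1 - p_mush)
  mixture <- c(mushroom = p_mush, rest[c("thin", "stubby", "filopodium")])
  names(mixture) <- SPINE_CLASSES
  structure(list(label = label,
                 mature_neuron_target = mature_neuron_target,
                 class_mixture = mixture, density_mean = density_mean,
                 dendrite_length_um = dendrite_length_um,
                 geometry_params = geometry_params),
            class = "condition_profile")
}

#' @export
print.condition_profile <- function(x, ...) {
  cat("Condition profile:", x$label, "\n")
  cat(sprintf("  mature-neuron target: %.1f%%\n",
              100 * x$mature_neuron_target))
  cat(sprintf("  density %.2f spines/um over %g um dendrite\n",
              x$density_mean, x$dendrite_length_um))
  cat("  class mixture:",
      paste(sprintf("%s %.3f", names(x$class_mixture), x$class_mixture),
            collapse = ", "), "\n")
  invisible(x)
}

#' Compound effect for the synthetic screen
#'
#' A three-parameter Hill model of a compound's action on spine maturity:
#' at concentration `c` the mushroom mixture weight gains
#' `efficacy/100 * c^hill / (ec50^hill + c^hill)`, the gain being taken
#' from the thin weight first, then stubby, then filopodium. An optional
#' per-neuron toxicity produces "Damaged cells": the damage probability at
#' concentration `c` is `toxicity_prob * min(c / 1 uM, 1)`.
#'
#' @param compound_id identifier.
#' @param efficacy maximum shift of the mushroom weight, percentage
#'   points (0 = inactive).
#' @param ec50 half-maximal concentration, uM; `> 0`.
#' @param hill Hill coefficient; default 1.
#' @param toxicity_prob per-neuron damage probability at 1 uM, in `[0,1]`.
#' @return An object of class `compound_effect`.
#' @export
compound_effect <- function(compound_id, efficacy = 0, ec50 = 0.1,
                            hill = 1, toxicity_prob = 0) {
  stopifnot(efficacy >= 0, efficacy <= 100, ec50 > 0, hill > 0,
            toxicity_prob >= 0, toxicity_prob <= 1)
  structure(list(compound_id = compound_id, efficacy = efficacy,
                 ec50 = ec50, hill = hill,
                 toxicity_prob = toxicity_prob),
            class = "compound_effect")
}

# Hill-model mushroom shift (mixture points, 0-1 scale) at a concentration
effect_shift <- function(effect, concentration_um) {
  if (is.null(effect) || concentration_um <= 0) return(0)
  (effect$efficacy / 100) * concentration_um^effect$hill /
    (effect$ec50^effect$hill + concentration_um^effect$hill)
}

# shift the mushroom weight by `delta`, taking mass from thin, then
# stubby, then filopodium
shift_mixture <- function(mixture, delta) {
  if (delta == 0) return(mixture)
  if (delta < 0 || mixture[["mushroom"]] + delta > 1)
    stop("adjusted class mixture is not a valid probability vector",
         call. = FALSE)
  take <- delta
  for (cls in c("thin", "stubby", "filopodium")) {
    got <- min(mixture[[cls]], take)
    mixture[[cls]] <- mixture[[cls]] - got
    take <- take - got
    if (take <= 1e-12) break
  }
  if (take > 1e-12)
    stop("adjusted class mixture is not a valid probability vector",
         call. = FALSE)
  mixture[["mushroom"]] <- 1 - sum(mixture[c("thin", "stubby",
                                             "filopodium")])
  mixture
}
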