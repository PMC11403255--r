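# Dirichlet draw via normalized gammas
rdirichlet <- function(n, alpha) {
  g <- matrix(rgamma(n * length(alpha), shape = alpha), nrow = n,
              byrow = TRUE)
  g / rowSums(g)
}

#' Behavioral group profile for the cohort generator
#'
#' Chamber times come from a compositional (Dirichlet) allocation of the
#' 600 s session over the novel-mouse, centre and novel-object chambers,
#' parameterized so the sociability index `t_mouse / (t_mouse + t_object)`
#' is Beta-distributed with mean `preference_mean` and concentration
#' `preference_phi` (sd about 0.08 at the defaults). Grooming durations
#' are Gamma with the given mean (seconds per 10 min), capped at the
#' session length.
#'
#' @param preference_mean expected sociability index (0.5 = none).
#' @param preference_phi Beta concentration of the index; default 35.
#' @param center_alpha Dirichlet weight of the centre chamber; default
#'   `preference_phi / 2` (about a third of the session in the centre).
#' @param grooming_mean_s mean grooming duration, s/10 min.
#' @param grooming_shape Gamma shape; default 8.
#' @return List of class `behavior_profile`.
#' @export
behavior_profile <- function(preference_mean = 0.5, preference_phi = 35,
                             center_alpha = preference_phi / 2,
                             grooming_mean_s = 110, grooming_shape = 8) {
  stopifnot(preference_mean > 0, preference_mean < 1, preference_phi > 0,
            center_alpha > 0, grooming_mean_s > 0, grooming_shape > 0)
  structure(list(preference_mean = preference_mean,
                 preference_phi = preference_phi,
                 center_alpha = center_alpha,
                 grooming_mean_s = grooming_mean_s,
                 grooming_shape = grooming_shape),
            class = "behavior_profile")
}

#' Generate a synthetic behavioral cohort
#'
#' Emits one record per animal: three-chamber times summing to the
#' session length and a grooming duration, for each named group. Default
#' group sizes mirror a vehicle/treated design of 10 and 12 animals.
#'
#' @param group_sizes named integer vector, e.g.
#'   `c(vehicle = 10, treated = 12)`.
#' @param profiles named list of [behavior_profile()], one per group.
#' @param session_s session length, seconds; default 600 (10 min).
#' @param seed optional integer seed.
#' @return Data frame with `animal_id`, `group`, `time_novel_mouse_s`,
#'   `time_center_s`, `time_novel_object_s`, `grooming_s_per_10min`.
#' @export
generate_behavior_cohort <- function(
    group_sizes = c(vehicle = 10, treated = 12),
    profiles = list(vehicle = behavior_profile(preference_mean = 0.45),
                    treated = behavior_profile(preference_mean = 0.65,
                                               grooming_mean_s = 100)),
    session_s = 600, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(group_sizes >= 1), session_s > 0,
            all(names(group_sizes) %in% names(profiles)))
  out <- lapply(names(group_sizes), function(grp) {
    n <- group_sizes[[grp]]
    pr <- profiles[[grp]]
    alpha <- c(pr$preference_mean * pr$preference_phi,
               pr$center_alpha,
               (1 - pr$preference_mean) * pr$preference_phi)
    times <- session_s * rdirichlet(n, alpha)
    groom <- pmin(rgamma(n, shape = pr$grooming_shape,
                         rate = pr$grooming_shape / pr$grooming_mean_s),
                  session_s)
    data.frame(animal_id = paste0(grp, "-", seq_len(n)), group = grp,
               time_novel_mouse_s = times[, 1],
               time_center_s = times[, 2],
               time_novel_object_s = times[, 3],
               grooming_s_per_10min = groom, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Score a behavioral cohort
#'
#' Computes per-animal sociability indices, per-group mean +/- SEM of
#' the index and of grooming, a Mann-Whitney U test between the two
#' groups on each measure, and a Kruskal-Wallis test with Dunn's post
#' hoc across the chamber times of each group.
#'
#' @param records cohort data frame as from [generate_behavior_cohort()].
#' @param adjust Dunn adjustment method; see [dunns_posthoc()].
#' @return List with `records` (indices added), `group_summary`,
#'   `index_test`, `grooming_test`, `chamber_tests`.
#' @export
behavior_summary <- function(records, adjust = "bonferroni") {
  records$sociability_index <- sociability_index(
    records$time_novel_mouse_s, records$time_novel_object_s)
  groups <- split(records, records$group)
  group_summary <- do.call(rbind, lapply(names(groups), function(g) {
    idx <- mean_sem(groups[[g]]$sociability_index)
    gr <- mean_sem(groups[[g]]$grooming_s_per_10min)
    data.frame(group = g, n = nrow(groups[[g]]),
               index_mean = idx[["mean"]], index_sem = idx[["sem"]],
               grooming_mean = gr[["mean"]], grooming_sem = gr[["sem"]],
               stringsAsFactors = FALSE)
  }))
  two <- length(groups) == 2
  index_test <- if (two)
    mann_whitney_u(groups[[1]]$sociability_index,
                   groups[[2]]$sociability_index)
  grooming_test <- if (two)
    mann_whitney_u(groups[[1]]$grooming_s_per_10min,
                   groups[[2]]$grooming_s_per_10min)
  chamber_tests <- lapply(groups, function(gd) {
    ch <- list(novel_mouse = gd$time_novel_mouse_s,
               center = gd$time_center_s,
               novel_object = gd$time_novel_object_s)
    list(kruskal_wallis = kruskal_wallis(ch),
         dunn = dunns_posthoc(ch, adjust = adjust))
  })
  list(records = records, group_summary = group_summary,
       index_test = index_test, grooming_test = grooming_test,
       chamber_tests = chamber_tests)
}

#' Generate mEPSC-style amplitude and inter-event-interval samples
#'
#' Amplitudes follow a right-skewed (log-normal) law whose median is the
#' group's `amplitude_median_pA` times `amplitude_scale`; a scale below 1
#' emulates the reduced postsynaptic strength of the autism-model
#' condition. Inter-event intervals are exponential with the given mean.
#'
#' @param n_events number of events; `>= 1`.
#' @param amplitude_median_pA baseline median amplitude, pA; default 15.
#' @param amplitude_scale multiplicative group effect on the median.
#' @param amplitude_sdlog log-scale dispersion; default 0.45.
#' @param iei_mean_s mean inter-event interval, seconds; default 0.5.
#' @param seed optional integer seed.
#' @return Data frame with `amplitude_pA` and `inter_event_interval_s`.
#' @export
generate_mepsc_samples <- function(n_events, amplitude_median_pA = 15,
                                   amplitude_scale = 1,
                                   amplitude_sdlog = 0.45,
                                   iei_mean_s = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_events >= 1, amplitude_median_pA > 0, amplitude_scale > 0,
            amplitude_sdlog > 0, iei_mean_s > 0)
  data.frame(
    amplitude_pA = rlnorm(n_events,
                          log(amplitude_median_pA * amplitude_scale),
                          amplitude_sdlog),
    inter_event_interval_s = rexp(n_events, rate = 1 / iei_mean_s))
}
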