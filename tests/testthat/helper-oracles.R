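# Independent restatement of the spine decision tree as four disjoint
# predicate sets over (length L, head H, neck N). Kept deliberately
# separate from the package's branching implementation.
oracle_classify <- function(L, H, N) {
  r <- if (N > 0) H / N else Inf
  lh <- if (H > 0) L / H else Inf
  is_mushroom <- r > 1.1 && H > 0.35
  is_stubby <- r <= 1.1 && lh <= 3
  is_filopodium <- ((r > 1.1 && H <= 0.35) || (r <= 1.1 && lh > 3)) &&
    L >= 3
  is_thin <- ((r > 1.1 && H <= 0.35) || (r <= 1.1 && lh > 3)) && L < 3
  picks <- c(mushroom = is_mushroom, thin = is_thin, stubby = is_stubby,
             filopodium = is_filopodium)
  stopifnot(sum(picks) == 1)
  names(picks)[picks]
}

# Exact null distribution of the Mann-Whitney U statistic for group sizes
# (n1, n2) by full enumeration of rank subsets. Returns a function
# p(u) giving the two-sided p-value 2 * min tail, capped at 1.
mwu_enumeration <- function(n1, n2) {
  n <- n1 + n2
  splits <- utils::combn(n, n1)
  u_all <- colSums(splits) - n1 * (n1 + 1) / 2
  function(u) {
    lo <- mean(u_all <= u)
    hi <- mean(u_all >= u)
    min(1, 2 * min(lo, hi))
  }
}

# Canonical geometry exemplars, one per class (verified by
# oracle_classify in the morphometry tests).
exemplar_geometry <- list(
  mushroom   = c(total_length_um = 1.0, head_diameter_um = 0.50,
                 neck_diameter_um = 0.30),
  thin       = c(total_length_um = 2.0, head_diameter_um = 0.25,
                 neck_diameter_um = 0.25),
  stubby     = c(total_length_um = 0.8, head_diameter_um = 0.30,
                 neck_diameter_um = 0.30),
  filopodium = c(total_length_um = 4.0, head_diameter_um = 0.20,
                 neck_diameter_um = 0.10))

# Build a neuron_record holding `counts[class]` exemplar spines per class.
make_neuron <- function(counts, dendrite_length_um = 30, damaged = FALSE,
                        neuron_id = "n1") {
  rows <- do.call(rbind, lapply(names(counts), function(k) {
    m <- counts[[k]]
    if (m == 0) return(NULL)
    as.data.frame(t(replicate(m, exemplar_geometry[[k]])))
  }))
  if (is.null(rows))
    rows <- data.frame(total_length_um = numeric(),
                       head_diameter_um = numeric(),
                       neck_diameter_um = numeric())
  neuron_record(neuron_id, rows, dendrite_length_um, damaged)
}

# Random spine geometries spanning all branches of the tree (mixture of
# broad uniforms plus mass near the thresholds).
random_geometry <- function(n) {
  data.frame(
    total_length_um = runif(n, 0.05, 6),
    head_diameter_um = ifelse(runif(n) < 0.1, 0, runif(n, 0, 1.2)),
    neck_diameter_um = ifelse(runif(n) < 0.1, 0, runif(n, 0, 1.2)))
}
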