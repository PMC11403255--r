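---
title: "Methods: spine classification, maturity screening, and the synthetic assay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spine classification, maturity screening, and the synthetic assay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinescreen)
```

## The problem

Dendritic spines — the micron-scale protrusions that house excitatory
postsynapses — mature from long, headless filopodia through thin spines into
mushroom-shaped spines with a large head on a narrow neck. In idiopathic
autism models such as the BTBR mouse strain, cortical neurons carry an excess
of immature spine shapes. A phenotypic drug screen on this readout treats
cultured BTBR-like neurons with a compound library and asks which compounds
shift neurons back toward a mature, mushroom-dominated spine complement.

`spinescreen` implements that analysis chain: per-spine geometric
classification, per-neuron maturity calling, plate-level hit calling against
duplicate vehicle wells, dilution-series confirmation, per-target
tabulation, and the behavioral and electrophysiological scoring that
accompanies such a study. Because no raw screening data are publicly
deposited, the package also ships a synthetic-data generator whose defaults
encode the study conditions, so the whole pipeline is exercised and tested
end to end.

## The spine classifier

Each spine is described by three measurements in micrometres: total length
$L$, head diameter $H$, and neck diameter $N$. Classification is a fixed
decision tree:

1. **Head-to-neck ratio** $r = H/N$. If $r > 1.1$ the spine is
   head-dominated (mushroom branch); otherwise it enters the stubby branch.
2. **Mushroom branch:** $H > 0.35\,\mu m$ confirms *mushroom*; smaller heads
   fall through to the filopodium determination.
3. **Stubby branch:** $L/H \le 3$ confirms *stubby*; elongated spines fall
   through to the filopodium determination.
4. **Filopodium determination:** $L \ge 3\,\mu m$ is *filopodium*, otherwise
   *thin*.

Boundary conventions had to be fixed, since the verbal thresholds only
define the strict sides: equality at $r = 1.1$ routes to the stubby branch,
$H = 0.35$ to the filopodium determination, $L/H = 3$ to stubby, and
$L = 3$ to filopodium. Degenerate diameters follow head-dominance: $N = 0$
gives $r = \infty$ (mushroom branch), and $H = 0$ in the stubby branch gives
$L/H = \infty$ (filopodium determination). Comparisons are exact — no
epsilon tolerance — so the classifier is a deterministic total partition of
geometry space, which the test suite checks against an independently stated
set of four disjoint predicates on random and boundary geometries.

Spine density is reported internally as spines/µm of analyzed dendrite;
`spine_density(, per_um = 10)` rescales to spines per 10 µm, a common figure
axis.

## Maturity calling and hit criteria

A neuron is a **mature spine neuron** when strictly more than half of its
spines are mushroom-type; equality at 50% counts as immature (the
conservative reading, yielding fewer hits). Damaged cells — a human
annotation consumed as a 0/1 flag — are excluded from both numerator and
denominator of the well-level mature percentage, and a well with fewer than
`min_evaluable = 10` evaluable neurons (of the 20 imaged) is flagged invalid
rather than contributing an unstable percentage.

Every plate carries two DMSO vehicle wells; their mean mature percentage is
the plate's reference. A compound is a **candidate hit** when its 1 µM well
exceeds the reference by strictly more than 10 percentage points (the margin
is points, not relative percent, matching the strain calibration that
motivates it: 35.5% mature in the control strain versus 24.7% in the model
strain). Candidates are re-tested over a 2-fold (1, 0.5, 0.25, 0.13, 0.06,
0.03 µM) or 3-fold (1, 0.3, 0.1, 0.03, 0.01 µM) dilution ladder and are
**confirmed** when the same criterion passes at `confirm_min_passing = 1` or
more concentrations. How the original screen chose its "optimal"
confirmation concentrations is not stated anywhere we could follow, so the
weakest rule consistent with a reproducibility re-test (at least one passing
dose) is the default and the threshold is exposed. Per-target hit rates are
rounded half-up to one decimal, the convention of the published table.

## The synthetic generator and its calibration

The generator's defaults are the study conditions, not tuning knobs.

* **Spine counts.** Spines per neuron are Poisson with mean `density_mean ×
  dendrite_length_um` (1.0 spines/µm × 30 µm by default, i.e. about 30
  spines in the 20–40 range), conditioned on at least one spine.
* **Class mixture.** Spine classes are i.i.d. draws from the profile's
  mixture. Only the neuron-level mature prevalences are published (35.5%
  B6-like, 24.7% BTBR-like); spine-level percentages appear only as figure
  bars. The mushroom weight is therefore solved numerically: under the
  Poisson-binomial model the mature prevalence is
  $\sum_n P(N=n \mid N \ge 1)\, P(\mathrm{Bin}(n, p) > n/2)$, computed
  exactly by `mature_prevalence()` and inverted with `uniroot()` so each
  profile hits its target (this yields mushroom weights of about 0.47 and
  0.45). The remaining mass is split thin/stubby/filopodium as 60/28/12 —
  a choice the data do not constrain, made once to echo the thin-dominated
  immature phenotype.
* **Geometry.** Per-class length/head/neck are log-normal
  (location/dispersion per class, defaults in `default_geometry_params()`),
  rejection-sampled until the classifier returns the intended class, so
  generated spines re-classify to their class by construction. A class whose
  parameters cannot satisfy its predicates fails loudly after
  `max_rejections` rounds.
* **Compound effects.** A three-parameter Hill shift — the simplest monotone
  pharmacological model — adds
  $\mathrm{efficacy}/100 \cdot c^{h}/(ec_{50}^{h}+c^{h})$ to the mushroom
  weight, taking mass from thin first, then stubby, then filopodium
  (maturation converts immature shapes). Toxicity is Bernoulli damage per
  neuron with probability `toxicity_prob × min(c/1 µM, 1)`.
* **Plates.** 96-well plates with two vehicle wells and up to 94 treatment
  wells, 20 imaged neurons per well; the default library has 181 compounds
  whose per-target composition mirrors the screened collection.
* **Behavior.** Three-chamber times are a Dirichlet allocation of the 600 s
  session, parameterized so the sociability index
  $t_{mouse}/(t_{mouse}+t_{object})$ is Beta with mean `preference_mean`
  and sd ≈ 0.08 at the default concentration; grooming is Gamma, capped at
  the session length. Default cohort sizes are 10 vehicle / 12 treated.
* **mEPSC samples.** Amplitudes are log-normal with a group scale factor on
  the median (below 1 for the model strain); inter-event intervals are
  exponential.

What the generator does *not* emulate: spatial within-plate effects, imaging
noise and detection failures, correlated spines within dendrites, neuron-to-
neuron mixture heterogeneity beyond binomial sampling, and any real
pharmacology. Passing tests therefore demonstrate that the *analysis
pipeline* is correct and well-calibrated under its stated model, not that
the model captures every feature of real assay data.

## Statistics

`mann_whitney_u()` computes U from midranks and reports the smaller of the
two mirrored statistics. The p-value is exact (permutation null of U) when
the pooled sample is at most 16 with no ties, otherwise a normal
approximation with tie and continuity corrections; tests are two-sided
throughout, since effects in both directions are of interest.
`kruskal_wallis()` uses the tie-corrected H against a $\chi^2_{k-1}$
reference; an all-tied dataset, where the tie correction degenerates, is
defined as $H = 0, p = 1$ (no evidence against the null). `dunns_posthoc()`
implements the classical rank-based pairwise z statistics with tie
correction over all pairs, Bonferroni-adjusted by default (the convention of
the common graphing software's implementation), with Holm or no adjustment
available. The ECDF (`normalized_cdf()`) is right-continuous and ends at
exactly 1. `mean_sem()` uses the n−1 sample standard deviation.

## Numerical and design choices

* Half-up rounding for hit rates (`13.2` from 5/38) rather than R's
  round-half-even.
* Exact threshold comparisons in the classifier; determinism over
  forgiveness.
* Calibration by exact Poisson-binomial inversion rather than simulation, so
  profile construction is deterministic and instant.
* Single-stream RNG: each generator takes a `seed`; orchestrators seed once
  and let nested generators continue the stream, so a whole simulated screen
  is a pure function of its seed.
* Secondary series are laid out only for designated candidates, mirroring
  the two-phase assay; `simulate_screen()` runs the primary stage, shortlists
  candidates, generates their ladders, and rescoring is deterministic.

## Problem sizes

The shipped checks simulate 5,000 neurons per profile for calibration
recovery (binomial SE ≈ 0.6 points, judged at 3 SE), enumerate all
Mann-Whitney rank splits up to pooled n = 12, use 2,000 null replicates for
type-I error, one full 181-compound two-stage screen for determinism, and
100 replicates of a 10-compound screen with one planted strong active
(efficacy 30 points, EC50 0.05 µM) for confirmation power. These sizes were
chosen so the whole suite runs in about a minute while keeping Monte-Carlo
error well inside the tested tolerances.

## Known limitations

* Neck diameters of stubby protrusions are accepted as given; how they are
  measured upstream is not modelled.
* The spine-level class mixtures are under-determined by the published
  neuron-level numbers; the 60/28/12 immature split is a modelling choice.
* The false-positive rate of the simulated screen depends on the 20-neuron
  binomial noise and the duplicate-well reference exactly as in the real
  assay; with no true actives it is substantial (double-digit candidate
  percentages), which is a property of the assay design, not a bug.
* Image-derived quantities (spine detection, damage annotation) are inputs,
  not outputs, of this package.
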