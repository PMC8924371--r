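---
title: "Models and methods: pH-dependent gene essentiality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: pH-dependent gene essentiality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acidscreen)
library(dplyr)
```

## The problem

Solid tumours are acidic: poor perfusion and high glycolytic flux push
extracellular pH (pHe) from ~7.4 down to 6.5–6.9. Cancer cells that tolerate
this environment must rely on specific genes, and those genes are candidate
therapeutic targets — a drug that inhibits them should kill cells *only*
where the tissue is acidic. Pooled CRISPR-Cas9 viability screens run in
parallel at physiological and acidic pHe can find such genes: a knockout
that drops out of the pool at pHe 6.6 but not at 7.4 marks an
*acid-essential* gene. `acidscreen` implements the full quantitative
workflow around such a screen: simulating it, scoring it, modelling the
growth–pHe relationship of validation clones, and handling the medium
chemistry and photometric calibrations that set and measure pHe.

## Differential essentiality scoring

The scorer follows the normZ scheme used for chemogenetic-interaction
screens, reimplemented here in full.

1. **Normalisation.** Each sample's counts are scaled to a common total,
   with a pseudocount: `norm = (count + p0) * S / (total + p0 * n_guides)`,
   defaults `p0 = 5`, `S = 1e7`. Per-sample normalised totals equal `S`
   exactly, and zero counts stay finite in log space.
2. **Guide fold changes.** For each replicate pair,
   `fc = log2(treated / control)`, where "treated" is the harvest-day sample
   at acidic pHe and "control" the same-replicate sample at pHe 7.4. Earlier
   passage samples, when present, are ignored by default — the contrast is
   defined at the harvest timepoint.
3. **Empirical-Bayes noise.** Fold-change noise depends strongly on
   abundance. Guides are sorted by descending normalised control reads and
   the fold-change s.d. is estimated in a sliding window of `2 × 500`
   guides, then forced non-decreasing toward low abundance with a running
   maximum: a poorly covered guide is never assigned less noise than a
   well-covered one. The window statistic is computed with cumulative sums
   (O(n)), with variances clamped at zero and a floor of 1e-6 on the s.d.
4. **Gene scores.** Guide Z-scores `z = fc / sd` are pooled over
   guide × replicate observations; `sumZ = Σz`, `normZ = sumZ / sqrt(n_obs)`.
   normZ is then standardised across genes by subtracting the median and
   dividing by the MAD-based scale estimate — a robust choice that resists
   the heavy tails contributed by true hits, keeping the null genes on an
   approximately standard normal scale. One-sided normal-tail p-values are
   taken in each direction (depletion / enrichment) and Benjamini–Hochberg
   adjusted separately per direction. Ranks are ordered by normZ, ties
   broken by gene id so output is deterministic.

Hits are genes with directional FDR below a threshold (default 0.1); the
reported `boundary_normZ` is the least extreme normZ among the hits — the
analogue of a screen's published Z cutoff, and like that cutoff it is
data-derived, so it shifts between simulations. Gene-set overrepresentation
is a one-sided Fisher's exact test per set against the scored-gene universe,
BH-adjusted across sets.

A note on a degenerate corner: when every guide Z is exactly zero, all
one-sided p-values are 0.5 and BH leaves them at 0.5 — no gene is callable
at any usual threshold, but the FDR is not 1.

## The synthetic screen generator

The generator is first-class, tested code; its defaults *are* the study
conditions the rest of the package is validated under:

| parameter | default | meaning |
|---|---|---|
| `guides_per_gene` | 4 | knockout-library design |
| `representation` | 675 | cells per guide at T0 |
| `moi` | 0.3 | infection multiplicity (recorded) |
| `days` | 11 | pH-treatment duration at harvest |
| `passage_day` | 5 | bottleneck day |
| `reseed_cells` | 3e6 | cells reseeded at passage |
| `n_replicates` | 2 | independent screen replicates |
| `depth` | 500 | mean reads per guide |
| `dispersion` | 0.1 | NB overdispersion of counts |
| `library_skew_sd` | 0.5 | log-scale T0 abundance spread |
| `guide_efficacy_range` | [0.6, 1] | per-guide knockout efficiency |

Conditions are pHe 7.4 / 6.9 / 6.63 — the media obtained from 22 / 5.5 /
2.75 mM bicarbonate at 5% CO2. Wild-type growth rates default to 0.69, 0.55
and 0.35 per day across those conditions (a ~24 h doubling time at
physiological pHe, slowed under acid, consistent with cumulative-growth
curves for acid-tolerant colorectal lines). Gene classes multiply those
rates: `core_essential` 0.5 everywhere, `acid_essential` 0.85 at pHe 6.9 and
0.7 at 6.63, `acid_dispensable` the mirror image (1.15 / 1.3), `neutral`
exactly 1. Per-guide efficacy `e ~ U(0.6, 1)` tempers the effect as
`multiplier^e`, reflecting that lentiviral pools are mixtures of edited and
unedited cells.

The generative chain is: log-normal T0 library skew (mean-preserving);
deterministic exponential growth per guide; a multinomial bottleneck at the
passage reseeding `reseed_cells`; more growth to day 11; negative-binomial
sequencing counts with mean proportional to abundance
(`Var = mu + dispersion * mu^2`; `dispersion = 0` gives Poisson). The NB
choice is the field's standard count-noise model; the bottleneck is
multinomial because reseeding a fixed number of cells from a large pool is
sampling without meaningful depletion. One RNG stream is seeded from the
config and consumed in a fixed draw order, so every output is
bit-reproducible; replicates share the T0 library but draw independent
bottlenecks and sequencing noise.

What the simulator deliberately does *not* emulate: PCR jackpotting, guide
cross-mapping, Cas9 cutting toxicity, batch effects between replicates, or
copy-number artefacts. Passing recovery and FDR benchmarks on these
simulations therefore demonstrates the scorer's statistical behaviour under
the assumed noise model, not robustness to every artefact of real
sequencing data.

## The biphasic Hill growth model

Growth versus pHe is bell-shaped: too alkaline and proton-dependent
processes starve, too acidic and proton inhibition dominates. The model is
the product of an activatory and an inhibitory Hill term in proton
concentration `h = 10^-pH`:

$$G(pH) = G_{max} \cdot \frac{h^{n_{act}}}{h^{n_{act}} + K^{n_{act}}}
        \cdot \frac{Q^{n_{inh}}}{h^{n_{inh}} + Q^{n_{inh}}}$$

Five free parameters: `G_max`, the binding constants `K` (activatory) and
`Q` (inhibitory) and their cooperativities. With `K < Q` (pK_act > pK_inh in
pH units) the curve has an interior optimum; for unit cooperativities the
optimum sits exactly at the pK midpoint, which the tests verify to 1e-6.
Internally the terms are evaluated in logistic form,
`1/(1 + 10^(n(pH - pK)))`, which never forms `h^n` and is stable at extreme
pH.

**pH50** is the acidic-side pH at which growth is half its value at the
optimum — higher pH50 means more acid-sensitive. It is found by bracketed
root-finding on `[floor, pH_opt]`. Because validation plates often stop at
pHe ≈ 6.5, pH50 frequently lies below the measured range and is an
extrapolation; the floor (default pH 5.0) bounds that extrapolation and
results at the floor are flagged `censored` rather than reported as point
estimates.

**Fitting.** Nonlinear least squares (Levenberg–Marquardt via
`minpack.lm`) on raw absorbance — SRB noise is approximately proportional
at the levels simulated, and fitting raw values keeps high-growth wells
appropriately weighted. Identifiability needed two specific choices:

* The optimiser works in `(pK_inh, gap)` with `pK_act = pK_inh + gap`,
  `gap ∈ [0.05, 4]`. Under noise, an unconstrained fit sometimes prefers a
  mirrored `K > Q` solution (for unequal cooperativities the product is
  still unimodal with the roles of the two terms exchanged and an inflated
  `G_max`); the gap parameterisation confines the search to the physical
  ordering.
* Bounds: pK values in [5, 9], cooperativities in [0.3, 8], `G_max`
  within a wide multiple of the observed maximum. Fits whose implied
  `pK_act` exceeds 9 are discarded.

The fit is multi-started from a deterministic 3 × 3 grid of
`(pK_inh, pK_act)` pairs spanning the physiological range, and the
converged start with the lowest RSS wins — the result is therefore
independent of well order (asserted in tests). At least 5 wells at 5
distinct pHe levels are required for the 5 parameters; 6 levels are
recommended, matching the bicarbonate series design.

**Group comparison.** `compare_ph50()` reports `ΔpH50 = alt − ref`
(positive = more acid-sensitive) with a percentile bootstrap CI. Wells are
case-resampled *within each pHe level* of each group; unstratified
resampling can drop entire pHe levels and make the five-parameter fit
unidentifiable, so the stratified scheme trades a little bootstrap
variability for guaranteed refittability. Resamples with censored pH50 in
more than 20% of refits flag the CI as unreliable. Wild-type reference
values measured across experimental batches should be summarised as the
mean of per-batch pH50 estimates, not a pooled fit.

## Media chemistry and photometry

* **Bicarbonate/CO2 design.** `hh_ph()` applies Henderson–Hasselbalch for
  the open CO2 system with 37 °C constants (pKa 6.1, CO2 solubility
  0.0307 mM/mmHg, 760 mmHg barometric, 47 mmHg water vapour), all exposed
  as arguments. 22 mM at 5% CO2 gives pH 7.40. The closed form predicts
  6.80 and 6.50 for 5.5 and 2.75 mM, slightly below measured values in
  serum-containing media (serum proteins and dye-based measurement add
  buffering and offset); `bicarb_series()` therefore reports the ideal
  prediction alongside an optional user-supplied empirical offset, and
  never guesses one. The series keeps `HCO3 + NaCl = 44 mM` for constant
  osmolarity.
* **Buffering capacity** sums the closed-system bell term
  `2.303·C·Ka·h/(Ka+h)²` per Good's buffer (HEPES pKa 7.5, MES pKa 6.1)
  plus `2.303·[HCO3−]` for the open CO2 system, verified against
  finite-difference derivatives of the titration curve.
* **Ratiometric dyes** (phenol red A430/A560, cSNARF1 F590/F640, HPTS
  F450/F416) share one three-parameter sigmoid; dyes whose ratio falls with
  pH simply store their plateaus in reverse order — no per-dye code path.
  Ratios outside the calibrated plateaus are censored, not extrapolated.
  The shipped default calibrations are synthetic: real instruments need a
  nigericin-clamped (pHi) or known-pH-standard (medium) calibration, and
  `fit_calibration()` rejects point sets that lie on a single plateau as
  unidentifiable.
* **Oxygen** follows Stern–Volmer quenching, `[O2] = (F0/F − 1)/Ksv`,
  with negative quenching rejected as non-physical.
* **The photometry simulator** integrates
  `dpH/dt = −J_H(pH)/β(pH)`, `dO2/dt = −OCR` (floored at 0) by forward
  Euler (default dt 0.01 h over 17 h; halving dt changes the endpoint by
  <1e-3 pH). `J_H` is a Hill-inhibited glycolytic acid flux — acid
  suppresses glycolysis, so wells acidify substantially only from alkaline
  starting pHe, reproducing the qualitative asymmetry seen in sealed-well
  assays.

## Numerical and reproducibility choices

* Every stochastic function takes an explicit seed; the demo pipeline's
  provenance records seed, config hash, package version and output digests
  but **no wall-clock timestamps**, so identical seeds reproduce every
  output file byte-for-byte (asserted in tests).
* Scale estimates that can collapse (window s.d., normZ MAD) are floored at
  1e-6 with a warning rather than producing infinite Z-scores.
* Rank ties and set orderings are broken lexicographically.

## Problem sizes used in validation

The test-suite and acceptance benchmarks run at the design scales the
package targets: screens of 2,000 genes × 4 guides at depth 500 with 2
replicates (50 null screens for FDR calibration; one planted screen with 5%
acid-essential genes at multiplier 0.7 for power), and 100 growth plates of
6 pHe levels × 3 replicates at 5% CV noise for pH50 recovery. At these
sizes the suite completes in about a minute on one CPU. Observed behaviour:
null hit fractions far below the nominal 0.1, planted-class recall 1.0,
pH50 bias ≈ 0.002 and RMSE ≈ 0.02 pH units, and noiseless parameter
recovery at machine precision.

## Known limitations

* One scoring route (normZ) is implemented; rank-aggregation or
  MLE-beta-score alternatives, and copy-number correction, are out of scope.
* Counts are the entry point — no read mapping from FASTQ.
* The biphasic model is the canonical five-parameter form; if a published
  dataset was fitted with a different parameterisation, absolute parameter
  values are not comparable, though pH_opt and pH50 largely are.
* Carbonate speciation ignores CO3²⁻ (fine below pH 8.5) and temperature
  dependence of pKa.
* Bootstrap CIs for ΔpH50 are percentile intervals; with only 18 wells per
  group they are approximate, and the coverage study in the tests (planted
  +0.3 shift recovered within the CI in ≥90% of trials) is the supported
  guarantee.
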