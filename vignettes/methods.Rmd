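---
title: "Models and methods behind nociomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nociomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nociomics)
```

This vignette explains the science and the numerical choices behind each
analysis stage, what the synthetic-data generators emulate (and what they
deliberately do not), and the limitations a user should keep in mind.

## 1. The experimental setting

A burn injury floods the injured dermis with diffusible mediators. Two
complementary measurements probe them: microdialysis, which samples the
interstitial fluid of a burned and a contralateral control limb in paired
30-minute fractions from 30 minutes before to 3 hours after injury, and
biopsy lipidomics, which compares burned and unburned skin from the same
subject days later. Candidate mediators (here, lysophosphatidylcholines)
are then applied to cultured dorsal root ganglion neurons, whose
intracellular calcium is read out as the Fura-2 excitation ratio
F355/F380 sampled every 2 s, with drug application windows, a terminal
depolarising KCl pulse, and linear 32→55 °C heat ramps.

## 2. Canonical variates analysis of the paired time course

### Model

Samples are laid out in a cell-means design over condition × fraction
cells (2 conditions × 8 fractions by default). Write $T$ for the
column-standardised intensity matrix projected onto its leading $r$
principal components, $F$ for its design-cell fitted values and
$E = T - F$ for the residuals. CVA solves

$$ B\,a = \lambda\, W a, \qquad B = F^\top F,\quad W = E^\top E , $$

via Cholesky whitening of $W$. Eigenvectors are normalised so that the
canonical variates $Z = T a$ have identity within-cell covariance, making
components mutually uncorrelated within groups. Back-projection through the
PCA loadings gives per-feature canonical weights; the design-cell means of
each variate are its canonical contrast, and the burn − control contrast
per fraction summarises the temporal shape of the effect. Each component's
sign is fixed so the final-fraction burn − control contrast is
non-negative.

### Choices that matter

* **PCA rank.** The within scatter $W$ is estimated with $n - q$ residual
  degrees of freedom ($q$ = number of design cells). Retaining all $n - q$
  PCA dimensions leaves $W$ at its singular boundary and the leading
  component simply chases noise: on planted-feature benchmarks the top-5%
  shortlist recovery collapses from 10/10 to 2/10. The default rank is
  therefore $\lfloor (n-q)/2 \rfloor$, keeping at least two residual
  degrees of freedom per retained dimension. The rank is fully exposed
  (`pca_rank`).
* **Column scaling.** Untargeted LC-MS intensities span decades and their
  noise is multiplicative, so unscaled canonical weights are dominated by
  abundance rather than discriminative information. The default is
  mean-centring plus unit-variance scaling (`scale = TRUE`); switching to
  centring only preserves intensity-scale weights when that
  interpretation is wanted.
* **Ranking.** Features are ordered by $|w_j|$, ties broken by feature id
  so the ranking is deterministic; the top-fraction shortlist is the first
  $\lceil f\,n \rceil$ entries.

### What the tests show — and do not

On synthetic cohorts the first canonical contrast reproduces the planted
rise-then-plateau profile and planted features dominate the shortlist; on
pure-noise cohorts the leading eigenvalue sits inside its
label-permutation null. Real microdialysate data add retention-time drift,
correlated features and missing values, none of which the generator
emulates, so passing tests validate the algebra and ranking machinery, not
robustness to instrument artefacts.

## 3. Lipidomics pipeline

The stage order is fixed: tissue-weight normalisation (QC samples use the
arithmetic mean biological weight), QC CV filter, median normalisation,
glog, autoscaling, Welch t tests with Holm adjustment.

* **QC CV filter.** A feature's CV across pooled-QC injections measures
  platform stability; features with CV > 30% (the conventional untargeted
  threshold) are discarded, and a feature whose QC mean is zero has
  undefined CV and is discarded too.
* **Median normalisation.** Each sample is rescaled so its median matches
  the grand median (median of per-sample medians over biological samples).
  A caveat worth knowing: with few features, strong regulation of even a
  single mid-abundance feature shifts the sample median by a few percent
  and leaks a small artefactual difference into every other feature. This
  is a property of median scaling itself, visible in the planted-effect
  simulations, and is why the univariate results should be read together
  with fold changes.
* **glog.** $g(x) = \log_2\!\big((x + \sqrt{x^2 + \lambda^2})/2\big)$,
  with $\lambda$ defaulting to the smallest positive weight-normalised
  intensity — the transform then behaves like $\log_2$ over the observed
  range while staying defined at zero.
* **Welch + Holm.** Per-feature unequal-variance t tests
  (Welch–Satterthwaite df) are computed in vectorised closed form (the
  test suite cross-checks them against `stats::t.test`), and Holm's
  step-down adjustment controls the family-wise error rate; fold changes
  are reported on the weight-normalised (pre-glog) scale, where a ratio of
  group means is interpretable.
* **Adducts.** Monoisotopic masses are computed from molecular formulae
  with standard atomic masses; positive mode searches M+H (+1.007276 Da)
  and M+Na (+22.989218 Da), negative mode M−H only, all within ±0.05 Da,
  with |δ| < 35 ppm flagged "promising". For 18:0 LPC
  (C₂₆H₅₄NO₇P, M = 523.3638 Da) the ions at m/z 524.3943 and 546.329
  annotate as M+H and M+Na within the Da tolerance while exceeding the ppm
  flag — annotation quality and match existence are deliberately separate
  outputs.

## 4. Calcium response calling

The baseline is the 30 s immediately preceding a window, clipped so it
never overlaps an earlier window (at least 10 samples must remain). A
response requires amplitude $A = \max R - \mu_b$ strictly greater than
$3\sigma_b$ *and* an onset — the first of at least two consecutive samples
above $\mu_b + 3\sigma_b$ — inside the window plus a 10-s perfusion lag.
The two-consecutive-samples requirement reflects that a genuine calcium
transient spans many 2-s frames whereas a single-sample excursion is
instrument noise; it reduces the false-positive rate of the 3σ rule on
pure-noise traces from ~7% to under 0.5% per window, which makes the KCl
viability gate behave as intended (dead cells excluded exactly) on
well-separated cohorts. Baseline-corrected AUC is integrated by trapezoid
over the same span and reported whether or not the call is positive;
amplitude and AUC are invariant to additive offsets of the whole trace.

Pooled counts per window label, and the cross-classification of two labels
(cells responding to both stimuli), feed the exact contingency tests. For
repeated-pulse sensitisation analyses, per-pulse amplitudes are also
normalised to each cell's first pulse.

## 5. Heat thresholds

### Per-cell Arrhenius estimate

During the ramp the ordinate is $y = \log_{10}(R - \mu_b + \varepsilon)$
against $x = 1000/T_K$, with $\mu_b$ the pre-ramp baseline mean and
$\varepsilon$ a vanishing fraction ($10^{-3}$) of the baseline SD that
only keeps the logarithm defined at noise dips. A cell qualifies as
"accelerating" when a two-segment fit beats one straight line (total SSE
< 0.7 of the single-line SSE) and the supra-threshold slope magnitude
exceeds the sub-threshold one by at least 1.5× — both factors
configurable, since acceleration is a qualitative criterion. The threshold
itself comes from an exhaustive breakpoint search: for every interior
split with at least 5 points per side, two independent least-squares lines
are fitted; the split minimising total SSE wins, and the temperature at
the analytic intersection of the two extrapolated lines is the cell's
threshold. Noiseless piecewise-linear traces are recovered exactly, and
the estimate is invariant to positive rescaling of the ratio (a rescaling
shifts both intercepts equally). Parallel fitted lines, or an intersection
outside the observed ramp, mark the estimate as not accepted.

### Population decomposition

Thresholds are binned into a 1 °C histogram over [32, 55] °C and a sum of
$K$ Gaussian curves is fitted to the counts by bounded least squares
(multi-start Levenberg–Marquardt; starts from moments, k-means on the raw
thresholds, quantiles, and a private seeded random stream so results do
not depend on the caller's RNG state). Two identifiability floors reflect
histogram resolution: component SDs may not fall below half a bin width,
and two fitted peaks may not sit within one bin of each other.

$K$ is chosen by F tests on the SSE reduction of each added component.
The selected $K$ is the **largest** candidate whose added component still
achieves a significant reduction (α = 0.05), not the first point where a
step fails: when an intermediate model misfits badly (a clearly 4-modal
histogram described by 2 components), its huge residual inflates the F
denominator and stalls a naive step-up rule at $K=1$. All candidate SSEs,
step p values and BICs are returned for inspection. An
expectation-maximisation fit on the raw thresholds (mclust) serves as an
independent cross-check in the test suite and agrees with the histogram
fit to well under a degree on well-separated mixtures.

The "cumulative" population threshold is reported two ways — the mean of
a single Gaussian fitted to the pooled histogram, and the mixture-weighted
mean of the component means — because a single-number summary of a
multimodal distribution is not uniquely defined. On strongly bimodal
distributions the pooled single-Gaussian fit can lock onto one mode; the
weighted mean is the stabler summary and the recommended one.

### Simulation conditions

The heat-ramp generator uses a 30-s baseline at 32 °C, a 0.1 °C/s linear
ramp to 55 °C sampled at 2 s, additive baseline noise of 0.005 ratio
units, 0.1 ratio units of signal at threshold, a sub-threshold Arrhenius
slope of −3 per (1000/K) and a 5× supra-threshold gain — values
representative of Fura-2 recordings from small DRG neurons. Population
means default to the four sensory-neuron threshold groups (33.9, 39.8,
44.4, 52 °C) with 1 °C component SDs. Mixture decomposition of thresholds
estimated through the full trace-level chain can occasionally prefer
$K=5$: per-cell estimation error makes one population's histogram
genuinely non-Gaussian, and the F test (correctly) notices. The
decomposition benchmarks therefore draw thresholds from the mixture
directly, while the trace-level chain is validated by per-cell recovery
(median absolute error well under 1 °C).

## 6. Contingency statistics

Fisher's exact test (2×2 and its Freeman–Halton r×2 extension) uses the
point-probability two-sided convention: p is the total probability of all
tables with the observed margins whose probability does not exceed the
observed table's, with a $1+10^{-7}$ relative slack for floating-point
ties — the convention of mainstream statistical environments, stated
explicitly because mid-p and doubling conventions differ. Exact network
evaluation is used up to a total of 3000 observations; beyond that an r×2
table falls back to Monte-Carlo with a reported standard error. The test
suite verifies both tests against full enumeration oracles on small
tables. Holm (FWER) and Benjamini–Yekutieli (FDR under dependence)
adjustments, and one-way ANOVA with Bonferroni-adjusted pairwise Welch
comparisons, cover the remaining univariate comparisons. Percentages are
reported with round-half-even at two decimals.

Repeated-measures mixed-design ANOVA for behavioural time courses and
normality/homogeneity screens are outside this package's scope; the
responder report notes where they would attach.

## 7. Synthetic-data generators as study-condition definitions

Each generator's defaults *are* the simulated study conditions, chosen
once:

* **Microdialysate time course** — paired burn/control limbs, fractions
  −30…180 min in 30-min bins, multiplicative log-normal intensity noise
  (the standard model for untargeted LC-MS peak areas), a per-subject
  multiplicative effect shared within each pair, and a planted burn effect
  rising linearly over the first three post-injury fractions to 2× and
  then maintained. Intensity distributions are conventional
  (log-normal about 10⁴), not fitted to any instrument.
* **Lipidomics cohort** — burn/control pairs with uniform 5–15 mg tissue
  weights, pooled-QC injections every 5 biological samples equal to the
  cohort mean plus 2% instrument noise, 10% biological/analytical CV.
* **Pharmacology traces** — discrete cell classes mapped to the windows
  they respond to (the default four: compound responder, capsaicin-only,
  KCl-only, dead), instantaneous rise with uniform onset lag up to 6 s,
  mono-exponential decay (τ = 20 s), additive Gaussian baseline noise.
  The class → window map is configurable because co-response structures
  (cells responding to a compound and to capsaicin, or to the compound
  only) need more patterns than the four defaults.
* **Heat-ramp cohort** — as in section 5.

Same seed and parameters give byte-identical outputs; zero-noise settings
reduce to closed-form expectations; truth objects round-trip losslessly
through the CSV + JSON interchange format. What no generator emulates:
chromatographic drift, isotope envelopes, missing values, photobleaching,
movement artefacts, or temperature-probe lag. Conclusions about those
belong to real-data validation, not to this test bed.

## 8. Known limitations

* Canonical weights are reported in the standardised space by default;
  their absolute magnitudes are not comparable across preprocessing
  choices.
* Median normalisation can leak small artefactual shifts under sparse,
  strong regulation (section 3).
* The accelerating-increase criterion (0.7 SSE ratio, 1.5 slope ratio) is
  a heuristic; cells near the criterion boundary are sensitive to noise.
* The histogram-based mixture fit inherits histogram resolution: SDs below
  half a bin and peaks closer than one bin are not identifiable, and
  strongly overlapping components (separation below ~2 SDs) are estimated
  with visible bias.
* Exact r×2 inference is limited to small dimensions (r ≤ 4 in practice)
  and totals up to a few thousand.
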