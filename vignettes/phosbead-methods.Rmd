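---
title: "Models and methods behind phosbead"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phosbead}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosbead)
```

phosbead analyses multiplexed bead assays in which each hydrogel bead
carries both a ratiometric lanthanide spectral code and a synthesized
phosphopeptide, with a strict 1:1 linkage between code and sequence. Two
assay geometries share the same front end: a *dephosphorylation* assay,
where a phosphatase removes phosphate groups over a time course and the
remaining phosphosignal is read out by a phospho-specific stain, and a
*binding* assay, where a phosphatase is titrated over a concentration
series and bound protein is read out by labelled antibody. Downstream, the
package applies the same statistical rules to quantified phosphoproteomic
site tables and ties everything together with sequence-motif analytics.
This vignette records the models, the defaults and why they are what they
are, the numerical choices, and the limits of what the synthetic-data
tests demonstrate.

## Spectral decoding and quality control

A bead is assigned to the spectral code whose reference lanthanide-ratio
vector is nearest in Euclidean distance, provided the distance is within
`max_distance` and the minimum is unique; otherwise it is left unassigned
with an explicit reason (`too-far` or `ambiguous-tie`). The default
radius is half the minimum inter-reference distance — the largest value
that can never mis-assign a bead lying closer to one reference than to
any other. Decoding is deliberately clustering-free: with codes laid out
on a grid and jitter small relative to spacing, nearest-reference
assignment is already essentially error-free, and there are no free
parameters to fit.

Per-code intensities are aggregated with either the mean (paired with a
standard-deviation dispersion) or the median (paired with a plain median
absolute deviation). Scoring defaults to the mean; the median is exposed
because robust summaries are preferable when reporting per-code intensity
distributions with occasional segmentation outliers.

Failed peptide syntheses leave beads with no phosphosignal above
background. The QC gate compares each code's starting (t = 0) intensity
to the per-bead intensity distribution of a phosphate-free negative
control: the threshold is `median + 1.5 × SD` of that distribution, and a
code passes iff its starting central intensity is at or above the
threshold. The per-bead (rather than per-code-median) form of the control
distribution was chosen because the gate is meant to ask whether a code's
signal is distinguishable from individual background beads; the
multiplier is exposed (`qc_sd_multiplier`) for other stringencies.

## Dephosphorylation scoring and kinetics

The dephosphorylation score for a time course on the default grid
(0, 15, 30, 60, 120, 240 minutes) is

$$\mathrm{score} = 1 - \frac{\overline{I}_{\mathrm{last}\,3}}{I(0)},$$

i.e. one minus the fraction of phosphosignal remaining, averaged over the
last three time points where the signal has typically plateaued. The
score is invariant under rescaling the whole course, bounded above by 1,
and deliberately *not* clipped below 0: negative scores flag staining or
drift artifacts and should stay visible. `n_final = 3` is the default
matched to the six-point grid but is a plain parameter for other designs.

Kinetic fits use the single-exponential model with a baseline,
$I(t) = C + A e^{-kt}$, bounded nonnegative in all three parameters and
solved by Levenberg–Marquardt least squares (`minpack.lm::nlsLM`),
initialised from the end points and a log-linear regression. The baseline
term is included because measured courses plateau above zero (incomplete
dephosphorylation and residual background); a two-parameter pure decay
would force `k` to absorb the plateau. The fit is advisory: scores never
depend on it, and a solver failure or a rate collapsing onto its lower
bound is reported as `fit_ok = FALSE` with the rate absent, because a
flat course contains no rate information. Replicate aggregation reports
the mean and SD of scores across replicates (a single replicate is
flagged `low_confidence`), and enzyme comparisons are per-peptide score
differences on the shared peptide universe.

## Binding isotherms and the ΔΔG ledger

Concentration series on the default nine-point grid (0–2,000 nM) are fit
to the Langmuir single-site isotherm $y = y_\mathrm{max}\,c/(c + K_d)$,
which passes through the origin and has no nonspecific-binding term; the
zero-concentration point participates in the fit. Local fits estimate
both parameters with bounds ($y_\mathrm{max}$ up to 10× the maximum
intensity, $K_d$ in [0.01, 10^6] nM).

Weak binders never approach saturation within the assay range, so their
two-parameter fits are poorly identified ($y_\mathrm{max}$ and $K_d$
trade off along a ridge). The global scheme fixes this by assuming all
peptides saturate at a common stoichiometry: peptides that do saturate
(top-concentration intensity above a threshold — an absolute
instrument-scale value of 12,000 for reproduction of fixed-scale
datasets, or a percentile of top-concentration intensities in the
portable `relative` mode used for synthetic data) define a shared
$y_\mathrm{max}$ as the mean of their local estimates, and every curve is
then refit with only $K_d$ free. The one-dimensional problem is solved by
golden-section search on $\log_{10} K_d$; tests verify it against a dense
grid-search oracle. Estimates above 5× the top assay concentration are
flagged as censored lower bounds rather than point estimates.

Replicate $K_d$ values aggregate by arithmetic mean on the nM scale by
default (median and log-space aggregation are provided; log-space is less
biased under multiplicative replicate noise, and the package's own tests
demonstrate that contrast, but the linear mean is kept as the default
convention for comparability with common practice).

Free-energy differences use
$\Delta\Delta G = RT \ln(K_{d,\mathrm{variant}}/K_{d,\mathrm{reference}})$
with $R = 1.9872\times10^{-3}$ kcal mol⁻¹ K⁻¹ and $T = 298.15$ K:
positive means weaker binding than the reference. The temperature is a
convention, not a measurement; it is a parameter
(`temperature_K`) everywhere it enters. Substitution tables lay
per-variant ΔΔG on a position × residue grid with unmeasured cells
explicitly absent, reference cells at zero, and duplicate claims on one
cell treated as a hard conflict.

## Regulated phosphosites and interactors

TMT channel normalisation divides each channel by its total intensity
relative to the mean channel total (equalising channel sums exactly) and
log2-transforms. A site is called regulated in an arm when a two-tailed
Welch (unequal-variance) t-test of inhibitor vs control replicates gives
`P < 0.05` *and* the log2 fold change exceeds 0.58 (1.5-fold, increase
upon inhibition). The test is two-tailed but the fold gate enforces
direction. No multiple-testing correction is applied by default — the
calling rule is a raw-p-plus-fold convention — and Benjamini–Hochberg is
available where rigour matters more than convention. Sites regulated in
exactly one arm are classed as specific to that phosphatase, in both arms
`ambiguous`, in neither `unregulated`; the four classes partition the
evaluated sites by construction.

Label-free interactor tables are completed by downshifted-normal
imputation (per sample: mean − 1.8 SD centre, 0.3 SD width — the
widely used defaults for intensities missing below the detection limit),
then gated at ≥2-fold enrichment and `P < 0.05`. Site-interactome joins
count regulated sites on interacting proteins per bait, with unmapped
identifiers excluded and counted rather than silently dropped.

A known property worth stating plainly: with triplicates, the Welch
approximation is mildly *conservative* — its true size at
$\alpha = 0.05$ is about 3.5% rather than 5% — so null-calibration
checks at triplicate depth sit slightly below the nominal rate. This is
inherent to small-sample Welch testing, not an implementation artifact;
the package's tests assert the directionally correct property (no
inflation above $\alpha$).

## Motif analytics

Sequence windows are centred 15-mers (flank 7) with `_` padding beyond
termini; pads are excluded from every count so termini cannot distort
frequencies. Enrichment logos compare foreground and background
frequency per (position, residue) cell: the enrichment score is the
frequency difference, the fold layer uses Laplace smoothing with
$\varepsilon = 1/(n_\mathrm{fg}+20)$, and significance comes from a
two-sided pooled two-proportion z-test (Fisher's exact test selectable).
The z-test is a transparent, assumption-light statistic for
percent-difference logos; tests verify its p-value ranking against
Fisher's exact test. No cross-cell multiple-testing correction is applied
by default, matching common logo-tool convention, with BH optional.

The docking-motif scanner implements the Rx(0–1)VxF architecture: both
the 4-mer (RVxF) and 5-mer (RxVxF) forms, all overlapping matches, with
a degenerate default alphabet `[RK]/[VI]/[FW]`, proline disallowed at
wildcard positions (configurable), a strict literal-RVF mode, and `X`
never matching. Lowercase phospho notation is preserved so phosphosites
at offsets −1..+4 of a match are annotated with it. Predicted ΔΔG for a
variant sums measured substitution-table cells for every deviation from
the reference — an explicit *additivity assumption*, flagged on every
multi-term prediction, and predictions with unmeasured cells are flagged
partial rather than silently completed.

Motif-distance stratification supports a fixed residue boundary
(default 1,000, inclusive — the natural convention for a single
N-terminal motif on a very large protein) and a radial
distance-to-motif-midpoint mode with configurable cutoff.

## The synthetic-data generators

The generators produce every input the pipeline consumes, with the
planted truth returned alongside, and all randomness flowing from a
single seed (same seed, identical output). Defaults encode the assay
design the package targets:

- **Design**: 96 spectral codes on a 4-channel ratio grid; ~55 beads per
  code (Poisson); time grid 0/15/30/60/120/240 min; concentration grid
  0, 15, 31, 62, 125, 250, 500, 1,000, 2,000 nM; triplicates.
- **Signal**: per-bead lognormal starting amplitudes (median 10,000,
  log-SD 0.25) over a shared baseline of 500; multiplicative noise with
  5% CV plus an additive floor of SD 100 (≈1% of the median start) for
  the dephosphorylation assay; additive noise of 3% of
  $y_\mathrm{max} = 15{,}000$ for titrations. Fluorescence assays show
  both a proportional and a floor component, hence the two-part model.
- **Planted kinetics**: a base pS rate of 0.012 min⁻¹ in a neutral
  context (placing the six-point grid across the informative part of the
  decay), ×3 for threonine, ×0.3 for +1 proline, ×1.8 for basic residues
  at −2/−3, ×0.5 for acidic +2 — the qualitative specificity structure
  the analysis modules are meant to resolve. 5% of phosphopeptide codes
  are planted as failed syntheses drawn from the background level.
- **Planted affinities**: a reference docking peptide (`AKNSRVTFSEDDEII`,
  RVxF core at 5–8) with $K_d = 125$ nM, single-substitution variants
  whose true ΔΔG values are drawn once per seed from U(−0.5, 2) kcal/mol
  (core prolines U(2, 3), strongly destabilising), and true variant
  $K_d$ composed exactly as $K_\mathrm{ref}\,e^{\Delta\Delta G/RT}$.
- **Planted phosphoproteome**: 5,000 sites over 250 proteins; 10%
  PP1-regulated, 20% B55-regulated, 2% both; regulated sites gain a log2
  effect of 2.0 (SD 0.3) in the matching inhibitor arm — a 4-fold
  change, typical of direct substrates under phosphatase inhibition —
  over replicate noise of SD 0.25. Class-specific window signatures:
  basic residues enriched at −2/−3 and threonine-tolerance for
  PP1-regulated sites; +1 proline enriched and acidic +2 deselected for
  B55-regulated sites. One long (3,000-residue) protein carries a single
  docking motif at residues 504–508 with phosphoserine/basic-context
  sites planted before residue 1,000 and phosphothreonine sites after,
  for the stratification analysis. The interactor simulation plants 5%
  true interactors at 4-fold enrichment with SD 0.5 noise and
  intensity-dependent (logistic-in-intensity) missingness, which is the
  regime downshifted imputation is designed for.

What passing tests on these data do and do not show: they demonstrate
that the estimators are unbiased and well-ranked *under the stated
generative model* — exponential decays, ideal Langmuir binding, Gaussian
replicate noise, independent sites. Real data add bead segmentation
outliers, spectral code bleed-through, peptide synthesis heterogeneity,
binding cooperativity and depletion at high bead loading, correlated
sites on shared peptides, and ratio compression in TMT quantification —
none of which the generators emulate. Recovery statistics on synthetic
data are therefore upper bounds on real-data performance, and the QC and
censoring machinery, not the simulations, is what defends the analysis in
practice.

## Numerical and edge-case choices

- Positions are 1-based and inclusive throughout; phosphoresidues are
  lowercase `s/t/y` in the canonical text form, with `pS`-prefix and
  `S(ph)` dialects accepted on read.
- Negative bead intensities (possible after upstream background
  subtraction) are clipped to zero with a reported count.
- Tie detection in decoding uses a relative tolerance of 1e-9 on squared
  distances, so floating-point-equal references are treated as ties.
- Degenerate regulated-site tests (zero variance in both groups) resolve
  by the mean difference: equal means give `p = 1`, unequal means with
  zero variance give `p = 0`.
- The one-parameter $K_d$ search runs on $\log_{10} K_d \in [-2, 6]$
  with `optimize` tolerance 1e-10; hitting the upper bound marks the
  estimate censored.
- Zero beads for a requested (code, condition) produce an absent summary
  and a message, never a fabricated zero.

Problem sizes in the test suite (200-curve recovery runs, 5,000-site
classification tables, 10,000-sequence scanner cross-checks) were chosen
so each property is measured with comfortable statistical margin while
the whole suite stays fast enough to run on every change.

## Known limitations

- The exponential and Langmuir models are phenomenological; no
  Michaelis–Menten or depletion corrections are attempted, and enzyme
  preparations are only comparable within, not across, enzymes.
- ΔΔG additivity across multiple substitutions is an assumption, flagged
  but not validated; epistasis between positions is not modelled.
- The absolute saturation threshold (12,000) is instrument-specific;
  portable analyses should use the relative mode.
- The raw-p-plus-fold calling convention controls neither FDR nor FWER;
  the BH option exists for analyses that need error-rate control.
- Censored (lower-bound) $K_d$ values propagate into ΔΔG as bounds, and
  substitution cells built from them inherit that censoring.
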