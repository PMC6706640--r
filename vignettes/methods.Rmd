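---
title: "Methods: ligand-detected T1rho screening with t1rhoscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ligand-detected T1rho screening with t1rhoscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t1rhoscreen)
```

## The measurement model

Ligand-detected T1rho NMR infers protein–metabolite binding from the
metabolite's signals, not the protein's. During a spin-lock period a free
small molecule relaxes slowly; the same molecule transiently bound to a large
protein relaxes fast. Under fast exchange the observed relaxation rate of a
metabolite signal is the population-weighted average

$$R_{obs} = (1 - p_b)\,R_{free} + p_b\,R_{bound},$$

with the bound fraction $p_b$ given by the two-state binding quadratic at
total protein concentration $P_t$, total ligand concentration $L_t$ and
dissociation constant $K_D$ (the smaller root for the complex concentration).
A screen records, for every sample, two short-spin-lock replicates (10 ms)
around one long-spin-lock spectrum (200 ms, or 400 ms for proteins below
40 kDa, whose smaller size produces weaker relaxation enhancement), for three
sample types: metabolite mix alone (M), protein alone (P), and protein + mix
(PM). Binding is quantified per metabolite peak window by the relaxation
factor difference

$$\Delta RF = \frac{M_{long}}{M_{short}} -
  \frac{PM_{long} - P_{long}}{PM_{short} - P_{short}},$$

each term a window-maximum intensity. For an ideal non-binder the two ratios
are equal and $\Delta RF = 0$; binding raises $R_{obs}$ and makes
$\Delta RF > 0$. On noiseless data the pipeline value reduces to the closed
form $e^{-R_{free}\Delta t} - e^{-R_{obs}\Delta t}$ with
$\Delta t = t_{long} - t_{short}$ (0.19 s or 0.39 s), which is the oracle the
test suite checks the spectral pipeline against.

## Processing pipeline and quality filters

1. **Calibration.** Every spectrum is shifted so that the maximum in the
   reference window (default −0.2 to 0.2 ppm, containing the DSS reference
   line) sits at exactly 0 ppm. Calibration failure is declared when no point
   in the window rises 3 robust standard deviations above the spectrum
   median. Accurate calibration is what keeps the difference spectra below
   free of subtraction artifacts.
2. **Replicate summing.** The two 10 ms replicates are summed point-wise
   (after interpolation onto a common grid), averaging slow intensity drifts
   and matching the scan count of the long spectrum.
3. **Protein subtraction.** The protein-bound quantities of $\Delta RF$ are
   quantified on the difference spectra $PM - P$ rather than as differences
   of separately quantified maxima. The two formulations agree to first
   order, but the difference-spectrum form cancels the DSS line and the broad
   protein background exactly, which is the behaviour the subtraction step
   exists to provide; the protein-only maxima are retained for provenance.
4. **Quality filters**, applied per peak window:
   - *stability*: $|a - b| / \mathrm{mean}(a, b)$ over the two PM short
     replicates' window maxima; above 0.05 the metabolite is considered
     unstable in that protein's presence. The symmetric mean denominator was
     chosen because the plain "5% difference" leaves the denominator open;
     the symmetric form is scale-free and order-independent.
   - *gain*: $1 - (PM - P)_{short} / M_{short}$ on the scale normalised to
     the free-metabolite short-delay maximum; below −0.05 the peak gained
     intensity in the protein's presence (an artefact, not relaxation) and
     is excluded. The normalisation scale is a package choice; −0.05 then
     means a 5% apparent gain.
   - *signal to noise*: the residual difference spectrum $PM - P - M$ at the
     long delay must exceed twice the noise level in the peak window. Noise
     is the standard deviation of a signal-free region (default
     10.5–11.0 ppm) after linear detrending. The long delay was chosen over
     the short one because that is where binding-induced signal loss is
     largest; the choice is exposed for sensitivity analysis. In exactly
     noiseless data the rule degenerates to: any residual means infinite
     S/N, none means zero (and the peak is gated out).

Flags are pure functions of the stored numbers and thresholds, so filter
order cannot change the outcome. Peaks failing any filter, or with a
non-positive denominator, never reach aggregation. Per pair, the default
aggregation is the mean over qualifying peaks (median and max are available
and recorded); all policies coincide when a single peak qualifies. Negative
$\Delta RF$ values are kept in the matrix as informative nulls — only
thresholding treats them as non-detections. $\Delta RF$ is only ever formed
between M and PM measurements recorded at the same long delay;
cross-delay comparison is refused, and the generator accordingly emits a
separate pure-mix reference per delay in use.

## Cutoff calibration

Detections at cutoff $c$ are the pairs with $\Delta RF > c$ (strict).
Against a reference set of known interactions, TPR $= TP/(TP+FN)$ and FPR
$= FP/(FP+TN)$ are computed at every candidate cutoff — by default all
observed $\Delta RF$ values plus $\{0, 0.5\}$, which gives the exact ROC; a
fixed grid over $[0, 0.5]$ is available for parity with grid-swept
calibrations. The working cutoff is the smallest candidate whose FPR does not
exceed the target (default 5%), which maximises TPR subject to the bound. AUC
is the trapezoidal area, equal to the tie-corrected Mann–Whitney statistic
when built from observed values. Cells with no qualifying peak are excluded
from both positives and negatives (their count is reported) rather than
silently counted as true negatives; a `missing = "nondetect"` mode implements
the harsher convention for comparison.

## Mix design

Metabolite libraries are partitioned into mixes by simulated annealing over
assignments. Two peaks of different metabolites in the same mix closer than
the overlap range (0.025 ppm) score a penalty of 100, scaled by the product
of their relative intensities when intensity scoring is on. Each step
relocates `mix_rate` (default 2) random metabolites into random other mixes —
swapping with a member when the target mix is at capacity — accepting any
improvement and worsenings with probability $e^{-\Delta/T}$. The full
published-style schedule (4 mixes of at most 15, linear cooling 10,000 → 25
over 500,000 steps, 10 restarts, exponential 50 → 25 refinement over 1,000
steps) is available via `anneal_schedule(published = TRUE)`; the default
desk-scale schedule (20,000 steps, 3 restarts) reaches the same zero-overlap
optima on libraries of this size in seconds, which the test suite verifies
across seeds on constructively clash-free libraries. Must-separate
constraints (e.g. metabolites that would react enzymatically) are enforced at
every step, and manual curation is supported as forced assignments. Ties
between equal-score designs across restarts break towards the
lexicographically smallest assignment in metabolite-id order, for
reproducibility. The optimisation stops early at score zero, the global
minimum.

Peak windows are then compiled per mix: each metabolite peak further than the
overlap range from every other metabolite's peaks gets a window of that
half-width; adjacent surviving windows are trimmed at the midpoint between
their source peaks so windows within a mix are pairwise disjoint (half-width
windows around peaks one to two overlap-ranges apart would otherwise
overlap). Metabolites left with no window are reported, not erred on — they
stay in the mix but cannot be quantified.

## Classification and network summaries

A detected binder whose maximum chemical similarity to the target enzyme's
substrates and products is below 0.5 is labelled an allosteric candidate
(active-site binding is unlikely for a dissimilar compound); at or above 0.5
it is a competitive candidate — the boundary value is competitive because
the allosteric definition is strictly "lower than". Similarity values are
consumed from a precomputed table (maximal-common-substructure scores from an
external tool); the package never computes chemical similarity itself. Pairs
without a similarity entry remain unclassified, and the three labels
partition the detections exactly. Pathway summaries count detections per
enzyme and average within pathway groups; with `exclude_catalytic = TRUE`,
detections whose known type is exactly catalytic are dropped first, while
pairs annotated both catalytic and regulatory are retained as regulatory —
the narrower reading of "excluding purely catalytic interactions". Group
comparisons use the unequal-variance t test (Welch–Satterthwaite degrees of
freedom, delegated to `stats::t.test`), cross-checked in the tests against a
permutation oracle; count correlations are squared Pearson coefficients.

## The synthetic-data generator

The generator renders what the acquisition scheme measures: per mix one M
measurement (per long delay in use), per protein one P measurement, per
(protein, mix) one PM measurement, each a (short, long, short) triple on a
shared descending ppm axis (default −0.7 to 11.2 ppm at 0.002 ppm, covering
the DSS line at 0 ppm and the 10.5–11.0 ppm noise region). Each catalogued
peak is a Lorentzian of fixed half-width (0.005 ppm) whose amplitude decays
as $e^{-R\,t_{SL}}$ with the spin-lock time; in PM samples the rate follows
the fast-exchange model above at the screen concentrations (15 μM protein,
200 μM metabolite). Default rates $R_{free} = 1/\mathrm{s}$ and
$R_{bound} = 60/\mathrm{s}$ were chosen once so that $K_D$ between 10 μM and
500 μM spans $\Delta RF$ from ≈ 0.17 to ≈ 0.46 — comfortably straddling
realistic detection cutoffs — and are configuration defaults, not physical
claims. Nuisances are: additive Gaussian noise per point; a per-spectrum ppm
calibration offset (N(0, 0.003 ppm) by default), which the DSS calibration
must undo; first-order metabolite degradation applied multiplicatively per
acquisition stage in the order short_a → long → short_b, so the stability
filter sees exactly the drift it was designed for; and a broad Gaussian
protein hump (amplitude 0.3, fast 20/s relaxation) in P and PM samples that
makes protein subtraction non-trivial. A DSS line at 0 ppm is always present
and exempt from degradation; it relaxes at the free-metabolite default rate,
as a small reference molecule does. The long spectrum carries twice the scan
weight of each short replicate, mirroring the 512- versus 256-scan
acquisition; the ratio structure of $\Delta RF$ makes results independent of
this scale. Rendered Lorentzian tails are truncated beyond 0.5 ppm from the
peak centre, where they are four orders of magnitude below the peak and far
below any realistic noise floor; the truncation keeps noiseless studies
exactly local, so the closed-form oracle and the degenerate-input rules hold
to machine precision.

What the generator does **not** emulate: scalar-coupling multiplets, solvent
and water artifacts, field-inhomogeneity lineshapes, phase errors, or
protein-specific degradation chemistry. Passing tests on synthetic data
therefore demonstrate the correctness of the pipeline's arithmetic,
filtering, calibration and ROC logic — not robustness to every artefact of
real spectrometer output.

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale, chosen so a full
check completes in about a minute on one core: a 20 × 20 protein ×
metabolite screen (two mixes, 10% planted binders with
$K_D \sim U[10, 500]$ μM, noise sd 0.01) for parameter recovery; tiny one- to
two-protein studies for oracle and filter checks; 12-metabolite libraries for
annealer properties; the annealing property runs at 20,000 steps × 3
restarts. Tolerances: the noiseless pipeline must match the closed-form
$\Delta RF$ within $10^{-6}$ (it achieves machine precision); null-study
cells must vanish within $10^{-9}$; ROC and AUC must equal brute-force
enumeration exactly. Degenerate inputs have defined behaviour rather than
NaNs: non-positive denominators mark a peak unevaluable, an empty reference
set errs only when a ROC is requested, a flat spectrum fails calibration, and
an all-zero noise region reports zero noise.

## Known limitations

- $K_D$ is not estimated from $\Delta RF$; the screen is a detector, not a
  titration.
- The reference-set recovery treats unknown pairs as negatives, so the FPR
  is an upper bound: a "false" positive may simply be unknown.
- Replicate screens (repeated PM measurements) are aggregated by mean; no
  variance model across replicates is fitted.
- Spin-echo protein-stability controls are accepted in the data model but
  not used in quantification.
- Chemical-similarity classification inherits whatever biases the upstream
  similarity tool has; 0.5 is a convention, not an inferred boundary.
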