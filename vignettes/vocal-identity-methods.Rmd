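---
title: "Methods: vocal identity ontogeny with vocalid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vocal identity ontogeny with vocalid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`vocalid` implements an analysis chain for studying how individual vocal
signatures emerge and diverge during development in a small group of known
individuals (the motivating setting is a brood of five hand-raised corvid
chicks recorded from roughly day 11 to day 45 post-hatching, in two nests,
across behavioural contexts). This vignette documents the statistical
model behind each stage, the tunable parameters, the synthetic-data world
used for validation, and the design decisions taken where the design was
genuinely open.

## 1. The acoustic descriptor set

Each call is summarised by eight descriptors. For a call of $N$ samples at
sampling rate $f_s$, the signal is framed (Hann window, 512 samples at
48 kHz ≈ 10.7 ms; 1 ms step) and per-frame power spectra computed with the
DC bin excluded:

| parameter | definition | units |
|---|---|---|
| duration | $N/f_s$ | s |
| mean amplitude | mean per-frame RMS of the raw frame | full-scale relative |
| peak frequency | argmax of the frame-averaged power spectrum | Hz |
| q25 / q50 / q75 | frequencies below which 25/50/75 % of cumulative spectral energy lies | Hz |
| spectral centroid | energy-weighted mean frequency | Hz |
| spectral slope | OLS slope of spectrum level (dB) on frequency (kHz) | dB/kHz |

Open choices and how they were resolved:

* **Window length.** Only the 1 ms step is prescribed by the emulated
  extraction tool; the window length is not. We use 512 samples (Hann),
  configurable via `frame_length`. All spectral descriptors are therefore
  resolved to $f_s/512$ = 93.75 Hz bins at 48 kHz.
* **Quantile convention.** Quantiles and centroid are computed per frame
  and averaged over frames with non-zero energy (default), matching the
  per-frame phrasing of the amplitude definition; a `mean_spectrum` mode
  computes them once on the frame-averaged spectrum.
* **No band-pass.** Spectral statistics run over the full 0–Nyquist band.
  The 400–6000 Hz pitch limits used by the original extraction tool
  constrain only pitch tracking, and no pitch parameter is in the
  descriptor set, so pitch tracking is out of scope.
* **Amplitude scale.** Recordings are uncalibrated, so amplitude is
  full-scale-relative and dimensionless. Scaling a waveform by $k$ scales
  `mean_amplitude` by $k$ exactly and leaves every frequency descriptor
  and the dB-domain slope unchanged (a dB offset moves the regression
  intercept, not its slope); this invariance is tested.

Call segmentation (`detect_call_boundaries`) thresholds a smoothed RMS
envelope at a fraction of its maximum (default 0.1), bridges gaps shorter
than `min_gap` (50 ms) and drops runs shorter than `min_duration` (30 ms).
Boundary accuracy is limited by the 5 ms smoothing window; the tests
require onsets within ±5 ms on constructed fixtures.

## 2. Permuted discriminant function analysis

The question "can calls be assigned to individuals?" is answered with a
DFA whose significance is obtained by permutation, with behavioural
context as a *restriction factor*: under the null, individual labels are
permuted only within context blocks, so the null preserves each context's
label composition and context-driven acoustic structure cannot masquerade
as identity information.

For one labeling, the statistic is computed from `n_selections` random
*balanced selections*: from every individual × context cell with at least
`n_train_per_cell + 1` calls, exactly `n_train_per_cell` calls (default:
smallest retained cell size − 1) are sampled into the training set and the
remainder are held out. Linear discriminant functions (pooled within-class
covariance, proportional priors, ridge fallback `1e-6 · tr(S)/p` on
numerical singularity) are fitted on the training calls; the percentage of
training calls correctly re-classified and of held-out calls correctly
*cross-classified* are averaged over selections.

**Calibration design decision.** A natural-seeming asymmetric scheme —
observed statistic averaged over 100 selections, each permutation
evaluated with a single selection — turns out to be severely conservative:
selection noise dominates the null spread, and in a 200-replicate null
simulation the rejection rate at $\alpha = 0.05$ was 0 (minimum null
p-value ≈ 0.09). `vocalid` therefore applies the *same* statistic
(mean over `n_selections` selections) to the observed and to every
permuted labeling. Observed and null values are then exchangeable under
the null, so the p-value
$p = (\#\{T_{null} \ge T_{obs}\} + 1)/(m + 1)$ is exactly calibrated for
*any* number of selections — `n_selections` buys precision of the point
estimates and power, not validity. With 1000 permutations the smallest
attainable p is $1/1001$, reported as 0.001. The acceptance suite verifies
a type-I rate within the binomial 95% interval [0.02, 0.09] over 200 null
datasets and p-value uniformity under single-selection exchangeability.

Chance levels are the means of the null distributions, and the *relative
cross-classification level* is cross-classified % divided by its chance
level (reported to 2 decimals). `run_pdfa_by_age_class` fits one model per
seven-day age class (11–17, …, 39–45 days, closed bins) plus one pooled
model — six models for the default age span.

## 3. Potential of identity coding

For one parameter, with calls grouped by individual,

$$\mathrm{PIC} = \frac{\mathrm{CV}_{\text{among}}}{\overline{\mathrm{CV}}_{\text{within}}},
\qquad \mathrm{CV} = \frac{s}{|\bar x|}\Bigl(1 + \frac{1}{4n}\Bigr),$$

where the numerator is the corrected CV of all calls pooled (the original
convention of the statistic, and that of the reference implementation —
not the CV of individual means) and the denominator averages the
within-individual corrected CVs. PIC ≈ 1 means a parameter varies no more
between than within individuals; values above 1 indicate identity-coding
potential. $|\bar x|$ is used because spectral slope is negative-valued; a
signed mean would flip the CV's sign (logged when applied). When every
within-individual CV is zero PIC is flagged infinite rather than silently
propagated.

Age trends regress PIC on the age-class midpoint day (14, 21, 28, 35, 42)
— midpoints preserve day units where only the class labels are given. The
Bonferroni threshold for the 8-parameter family is $0.05/8 = 0.00625$,
reported as 0.006 after 3-decimal rounding (comparisons use the raw
value); the 7-context dissimilarity family gives $0.05/7 \to 0.007$.

Factorability screening uses the Kaiser–Meyer–Olkin statistic
$\mathrm{KMO} = \sum r_{ij}^2 / (\sum r_{ij}^2 + \sum q_{ij}^2)$ over
off-diagonal pairs, with anti-image partial correlations
$q_{ij} = -R^{-1}_{ij}/\sqrt{R^{-1}_{ii} R^{-1}_{jj}}$. For two variables
$q = r$, so KMO is exactly 0.5 regardless of the correlation — a useful
closed-form test case; for more variables the implementation is tested
against a brute-force regression-residual partial-correlation oracle to
1e-10.

## 4. Dissimilarity ontogeny

Per individual and day (optionally per context), the median of each
parameter over that day's calls forms a *median profile*; for every
unordered dyad present on a day the Euclidean distance between profiles is
the *dissimilarity score*. Two open points were resolved as follows:

* **Score orientation.** The source description of the score is internally
  inconsistent ("maximum distance minus obtained distance" vs "a score of
  0 indicates perfect similarity"). The raw Euclidean distance (0 =
  identical) is the default; the max-minus-distance transform is available
  as `score = "max-minus-distance"` for comparability.
* **Standardization.** No z-scaling before distances by default (the
  described procedure specifies none), which means Hz-scaled parameters
  dominate the metric; `standardize = TRUE` applies global per-parameter
  z-scaling and logs that it did.

Trends are plain OLS of score on age in days (the described analysis used
a simple linear model, not a mixed model with dyad effects — a known
limitation, see §7), fitted for all contexts pooled and per context;
strata with fewer than 3 records or a single distinct age are flagged
`insufficient` rather than fitted.

## 5. The synthetic world

The generator stands in for undeposited field recordings. Its stated world
(defaults, chosen once):

* 5 individuals in 2 nests; ages 11–45 days; fledging at day 25 splits
  phases 1/2; Poisson(13) calls per individual-day (≈ 2 275 calls expected,
  near the ~2 200 of the motivating dataset).
* Feature model per call:
  `baseline + individual_offset + age_drift × (age − 11) + context_effect + N(0, within_sd)`.
  Baseline ≈ a 0.3 s broadband call with energy between 1 and 3 kHz and a
  −8 dB/kHz tilt; within-call SDs ~15–20 % of baseline; individual offsets
  drawn with SDs about half the within-call SDs, which puts PIC slightly
  above 1 — the regime reported for real broods; drifts small and
  zero-mean.
* Context mixture interpolates linearly with age (begging dominant early,
  declining toward independence); exact weights are free configuration
  since no per-day counts are published.
* Invalid draws (non-positive duration, frequencies outside (0, Nyquist),
  disordered quantiles) are **resampled, not clipped**, so truncation does
  not pile mass on the boundary and within-individual CVs stay
  interpretable.
* One global RNG stream per run, seeded from the config; the seed is
  written into the CSV header and the pipeline manifest.

`synthesize_call_waveform` exists to round-trip the feature extractor, not
to imitate corvid acoustics: the target power spectrum is piecewise
constant over four bands `[lo,q25],[q25,q50],[q50,q75],[q75,hi]` with a
quarter of the energy each, so the energy quantiles match by construction;
random spectral phases give band noise (juvenile corvid calls are chaotic
and lack a stable fundamental, so no F0 contour is modelled; an optional
harmonic stack is available). A green round-trip test therefore
establishes that the extractor measures what the synthesizer encoded — it
says nothing about performance on real, noisy, reverberant recordings.

Likewise, a green pDFA recovery test on synthetic data establishes
statistical correctness (calibration, power against injected signatures),
not that real crow calls are individually distinct.

## 6. Numerical choices

* pDFA p-values use the add-one convention; p can never be 0.
* LDA predictions are invariant to per-feature affine rescaling; features
  are standardized once per model purely for numerical stability.
* Splits that leave fewer than 2 training classes (possible after
  permutation reshuffles cell sizes) are redrawn, identically for observed
  and null labelings, preserving exchangeability.
* An exactly fitting OLS line reports `p` at the double floor with an
  `exact_fit` flag instead of 0 or NaN.
* `ols_trend` and the PIC/KMO formulas are verified against independent
  closed-form or brute-force oracles to 1e-10 in the test suite.
* The dissimilarity drift-recovery test compares the fitted slope to a
  Monte-Carlo generative expectation that includes median noise: the
  naive noise-free expectation $\lVert\Delta d\,(a-11)\rVert$ is biased at
  small separations (the norm of a noisy vector exceeds the norm of its
  mean), and using it would mis-flag a correct implementation.

## 7. Known limitations

* The generator's Gaussian, additive world has no amplitude-by-frequency
  interactions, no nonlinear phenomena, no recording-channel effects.
* Segmentation assumes a quiet background; it is a threshold detector,
  not a denoiser.
* Dissimilarity trends treat dyad-day records as independent (plain OLS,
  mirroring the emulated analysis); repeated dyads violate this, and a
  mixed model with a dyad random effect would be the stricter choice.
* The pDFA covers the nesting of calls within individual × context cells
  via balanced selection and blocked permutation; other nesting structures
  (e.g. recording session) are not modelled.
* WAV I/O is deliberately minimal: uncompressed PCM RIFF only.
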