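---
title: "Methods: isotopologue quantification and H/D-exchange kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isotopologue quantification and H/D-exchange kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petrokin)
```

## The problem

Petrosamine is a brominated pyridoacridinium alkaloid whose C-6 methylene,
activated by the adjacent ketone and the quaternized ring nitrogen,
exchanges both protons for deuterium within roughly two minutes of
dissolution in CD₃OD at room temperature — fast enough that NMR only sees
the end state. A rapid-sampling ESI-TOF experiment can follow the process:
spectra taken every 15 s resolve the +1.006 Da steps from the d0 cation
(m/z 422.0499) through the ephemeral d1 (423.0561) to d2 (424.0624).
This package turns such centroided time courses into the two exchange
rate constants, with every numerical step explicit and testable.

## Exact masses and isotope patterns

All masses and abundances come from one pinned table
(`inst/extdata/isotopes_nist2018.csv`, NIST 2018 atomic masses with
representative natural abundances), read through `isotope_table()`.
Reported cation m/z follows the electron-corrected convention
m/z = (M − z·mₑ)/|z|; the uncorrected sum for the petrosamine cation is
422.0504, and only the corrected value reproduces 422.0499 at the printed
precision. One historical note: the formula for the cation is sometimes
typeset with a spurious "⁸⁹Br" superscript; no stable bromine-89 exists,
and the printed mass corresponds to ⁷⁹Br, which is what `parse_formula()`
assumes.

`isotope_pattern()` builds the full isotopologue fine structure by exact
multinomial convolution per element followed by convolution across
elements, pruning products below 10⁻¹⁴ (tested against a brute-force
enumeration oracle to <10⁻¹⁰). Deuterium substitutions contribute a pure
²H mass; everything else carries natural abundance. Centroiding is
emulated by a greedy left-to-right merge: a peak joins the running cluster
while it lies within m/z divided by the resolving power of the cluster
centroid, and the merged position is the abundance-weighted mean. That
rule decides the physics that makes this analyte interesting at TOF
resolution (m/Δm = 20,000, width ≈ 0.021 Da at m/z 422):

- the ¹³C₁ satellite of d0 (+1.0034 Da) is unresolved from the d1
  monoisotopic peak (+1.0063 Da);
- the ⁸¹Br satellite of d0 (+1.9980 Da) is unresolved from the d2 peak
  (+2.0126 Da).

## The correction matrix

`build_correction_matrix()` bins the pattern of each d-species into the
d0..d2 measurement channels: a pattern peak belongs to a channel when it
lies within the resolution width of the channel center. Columns are
normalized patterns, so each column sums to at most one; abundance falling
outside all channels (for example the ⁸¹Br satellite of d2, which sits
above the last channel) is recorded as a per-column loss factor. For the
petrosamine cation the d1-channel leakage from pure d0 is 24.1% of the d0
monoisotopic intensity — about 22.7 points from ¹³C, the rest from ¹⁵N,
²H and ¹⁷O — and the d2-channel leakage is even larger because of ⁸¹Br.
Uncorrected ratios would therefore overstate exchange at early times.

`correct_fractions()` solves the triangular system M·x = raw. Noise can
push components of the exact solution slightly negative; the default
policy is transparent clip-and-renormalize with a quality flag raised when
clipping removes more than 2% of the recovered mass. An all-zero channel
vector returns a flagged no-signal record rather than an error, so sparse
early or late spectra do not abort a batch.

One pipeline subtlety: `extract_raw_intensities()` defaults to a 10 ppm
matching window, the usual TOF mass accuracy for isolated centroids. But a
merged centroid — say d1's peak fused with d0's ¹³C satellite — sits at an
abundance-weighted position that wanders with composition by more than
10 ppm. `correct_time_series()` therefore matches channels with the same
resolution-width window used to bin the matrix, which keeps extraction and
correction mutually consistent; with that choice the noiseless end-to-end
chain reproduces generator fractions to machine precision.

## Kinetic model and fitting

The sequential scheme d0 →(k₁) d1 →(k₂) d2 has the closed form

$$f_{d0} = e^{-k_1 t},\qquad
  f_{d1} = \frac{k_1}{k_2-k_1}\left(e^{-k_1 t}-e^{-k_2 t}\right),\qquad
  f_{d2} = 1-f_{d0}-f_{d1}.$$

The difference of exponentials is evaluated as
`-k₁/Δ · e^{-k₁t} · expm1(-Δt)` (Δ = k₂−k₁), which is stable for nearly
equal rates; the analytic k₁ = k₂ limit `k₁t·e^{-k₁t}` is used when
|Δ| < 10⁻⁹·max(k₁,k₂). The closed form is verified against a Runge-Kutta
integration to <10⁻⁸ across rates 10⁻³–1 s⁻¹ and t up to 300 s. Note the
classical symmetry: f_d2 is invariant under swapping k₁ and k₂, but f_d0
and f_d1 are not, so the joint three-trajectory fit is identifiable.

`fit_exchange()` minimizes unweighted least squares over all three
fraction trajectories with replicates pooled (Levenberg–Marquardt via
`minpack.lm`). Unweighted loss is the deliberate default: the experiment
reports no per-point error model, and invented weights would be harder to
defend than none. Initialization takes k₁ from a log-linear regression of
f_d0 against time and k₂ = k₁/2 — the statistical-factor prior for two
equivalent sites — imposed at initialization only; a fit that crosses to
k₁ < k₂ is reported with `swapped = TRUE`, not forced back. Box bounds
default to (10⁻⁶, 10) s⁻¹, and an estimate pinned at a bound (e.g. from a
series with no visible exchange) raises a warning and a `boundary` flag
rather than returning a silent near-zero rate.

### Uncertainty calibration

Confidence intervals are t-based Wald intervals from the Jacobian at the
optimum, with two refinements motivated by the compositional nature of the
data and checked by simulation:

1. **Degrees of freedom.** Corrected fractions sum to one per spectrum, so
   of each spectrum's three residuals only two are free; the variance
   denominator is 2m − p for m spectra and p = 2 parameters, not 3m − p.
2. **Robust allocation.** Fraction errors are correlated within a spectrum
   and strongly heteroscedastic across the time course (multiplicative
   intensity noise propagated through the correction and normalization).
   The naive pooled-variance covariance then overstates k₁'s uncertainty
   and understates k₂'s. The reported standard error of each rate is the
   wider of the pooled estimate and a cluster-robust (by spectrum)
   sandwich estimate, and the ratio's delta-method σ uses whichever
   covariance is wider.

In a 500-repeat simulation at the default study conditions this interval
covers the generating k₁ in ~99% and k₂ in ~96% of repeats; the
prescribed-textbook alternative (pooled variance over all 3m residuals)
covered k₂ in only ~83%. The package prefers a modestly conservative
interval to an anti-conservative one.

`ratio_test()` propagates the covariance to k₁/k₂ and flags consistency
with the statistical factor of 2 when the ±1.96σ interval contains it.
Two equivalent sites without a primary kinetic isotope effect predict
exactly 2; the experimentally reported ratio near 1.74 is consistent with
2 only under the large published uncertainty — at the precision the
simulated triplicate protocol actually delivers (σ ≈ 0.05), a true ratio
of 1.74 is distinguishable from 2, and the consistency flag is expected
to be false for data generated at those rates. The flag answers a
question about the data at hand, not about the mechanism in general.

`half_exchange_time()` (first t with f_d2 ≥ 0.5, by bisection to 10⁻⁶ s)
and `d1_peak_time()` (analytic t* = ln(k₁/k₂)/(k₁−k₂)) summarize fits.

## The synthetic experiment

`sim_config()` defaults encode the emulated study conditions: the
C21H17BrN3O2 monocation, k₁ = 0.1311 s⁻¹ and k₂ = 0.0755 s⁻¹, sampling at
0, 15, …, 90 s, three replicates, resolving power 20,000, and 3%
multiplicative log-normal noise per centroid (mean-one, so intensities are
unbiased). The noise level and total intensity (10⁶ counts) are the
package's own choices of a realistic TOF regime; no noise characterization
was published. t = 0 is included in the grid even though a real experiment
has an unknown dead time between dissolution and the first scan; a
`dead_time_s` parameter shifts the kinetic clock when that nuisance is to
be studied. All randomness flows from one seed through per-replicate
substreams, so results are reproducible and independent of evaluation
order.

What the generator emulates: the isotope structure including satellite
overlap at finite resolving power, instrument-style centroid merging,
multiplicative detector noise, replicate structure. What it does not:
ionization physics and ion suppression, drift of the external CH₃OH
reference (normalization is a constant scalar), profile-mode peak shapes,
chromatography, back-exchange. Passing recovery tests therefore
demonstrate the correctness of the quantification chain under the stated
noise model, not robustness to every instrumental pathology of real data.

Problem sizes in the shipped tests and scripts — 21 spectra per
experiment, 200-repeat Monte-Carlo recovery studies — were chosen as the
smallest designs that give stable coverage estimates.

## Acid–base and solvatochromism conventions

`pka_bound_from_flat_titration()` operationalizes "the spectrum is
unchanged" as: maximal |ΔA| between any pH pair, relative to the overall
maximum absorbance, below 5%. A flat series excludes the pKa from the
sampled window (quoted with a ±1 pH margin, the detectability width of a
two-state transition); otherwise the midpoint of the steepest adjacent
pair is returned as a crude locator, good to ~0.2 pH units on a 0.25-unit
grid. `tautomer_ratio_upper_bound()` converts an NMR integration detection
limit f into Keq ≤ f/(1−f) — e.g. an enol invisible below ~4.8% of the
ketone bounds Keq < 0.05.

Band shifts are reported as positive magnitudes with an explicit
hypsochromic/bathochromic label (the sign conventions in the literature
are mixed); shifts under 1 nm are classified as "none". The packaged
DMSO–water table ships exactly as printed, ε normalized to the literature
value 4700 M⁻¹cm⁻¹ at 100% water; `nm_to_ev()` uses hc = 1239.841984
eV·nm. Transition energies support comparisons with computed HOMO–LUMO
gaps but no quantum-chemical modeling is attempted here.

## Known limitations

- Single charge state, ≤2 exchangeable sites, no back-exchange, no
  Bayesian or multi-site generalization.
- The bootstrap CI option is deliberately absent: with three replicates,
  replicate resampling has only ten distinct outcomes and would suggest
  precision it cannot deliver; the robust Wald construction above is used
  instead.
- Whether published exchange ratios embed uncorrected satellite overlap
  cannot be decided without raw instrument data; `correct_time_series()`
  exposes `correction = FALSE` so both conventions can be compared on the
  same spectra.
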