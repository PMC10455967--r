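# petrokin

Quantitative analysis of rapid small-molecule hydrogen–deuterium (H/D)
exchange followed by electrospray time-of-flight mass spectrometry, built
around the chemistry of petrosamine — a brominated pyridoacridinium
alkaloid whose activated C-6 methylene exchanges both protons within
seconds of dissolution in a deuterated solvent.

The package is for analytical and natural-product chemists who want to
turn centroided ESI-TOF peak lists sampled over a fast exchange reaction
into rate constants with honest uncertainties. It covers the full chain:

- **Exact masses and isotope patterns** from a molecular formula, against
  a pinned NIST isotope table, with the electron-mass correction for ions.
- **Isotopologue quantification**: extraction of d0/d1/d2 channel
  intensities and deconvolution of natural-abundance satellite overlap.
  For a brominated analyte this matters a lot: at TOF resolving power the
  ¹³C satellite of d0 is unresolved from the d1 peak, and the ⁸¹Br
  satellite of d0 falls into the d2 channel.
- **Kinetic fitting** of the sequential first-order exchange model with
  confidence intervals and a statistical-factor ratio test.
- **Acid–base utilities** (Henderson–Hasselbalch, pKa exclusion from flat
  titrations, tautomer-ratio bounds from detection limits) and
  **solvatochromic band-shift summaries**.
- A **synthetic-data generator** reproducing the rapid-sampling
  experiment's statistical structure, so the whole pipeline is testable
  without instrument data.

## The model

Two equivalent exchangeable protons give the consecutive first-order
scheme d0 →(k₁) d1 →(k₂) d2 with closed form

    f_d0(t) = e^{-k₁ t}
    f_d1(t) = k₁/(k₂-k₁) · (e^{-k₁ t} - e^{-k₂ t})
    f_d2(t) = 1 - f_d0 - f_d1

(with the limit k₁ t e^{-k₁ t} for f_d1 when k₁ = k₂). For two equivalent
sites with no primary kinetic isotope effect the statistical factor
predicts k₁/k₂ = 2. Observed channel intensities are first deconvolved
through a lower-triangular correction matrix **M** whose column *j* is the
isotope pattern of the *j*-deuterated species binned into the measurement
channels: solving **M x = raw** yields molar amounts, normalized to
fractions.

## Worked example

```r
library(petrokin)

ec <- parse_formula("C21H17BrN3O2", charge = 1)
monoisotopic_mz(ec)                # 422.0499  (d0 cation)
monoisotopic_mz(ec, n_labile = 2)  # 424.0624  (d2 cation)

cfg <- sim_config(k1 = 0.1311, k2 = 0.0755, noise_cv = 0.03, seed = 17)
spectra <- simulate_time_course(cfg)
series  <- correct_time_series(spectra, cfg$ec,
                               resolving_power = cfg$resolving_power,
                               abundance_floor = cfg$abundance_floor)
fit_exchange(series)
```

```
Sequential H/D exchange fit (d0 -> d1 -> d2)
  k1 = 0.1301 s^-1  95% CI [0.1241, 0.1362]
  k2 = 0.0749 s^-1  95% CI [0.0725, 0.0772]
  k1/k2 = 1.739 (sigma 0.059),  R^2 = 0.9992
  63 observations, 7 timepoints, 3 replicate(s)
```

The fit recovers the generating constants to about 1% from triplicate
spectra sampled every 15 s over 90 s with 3% per-centroid noise; both 95%
intervals cover the truth. `model_fractions(0.1311, 0.0755, 90)$f_d2`
gives 0.997 — exchange is >90% complete within 90 s. The solvatochromic
summary from the packaged DMSO–water table:

```r
band_shift(petrosamine_uvvis(), band = 2)
# $delta_nm 78, $direction "hypsochromic"  (648 nm in DMSO -> 570 nm in water)
```

## Analysis workflow

The `analysis/` directory holds the numbered scripts that reproduce the
package's study end to end, writing tables under `results/`:

1. `01_exact_masses.R` — exact masses, isotope pattern, correction matrix
2. `02_simulate_exchange.R` — synthetic triplicate time course + corrected fractions
3. `03_fit_kinetics.R` — kinetic fit, ratio test, half-exchange time
4. `04_recovery_study.R` — 200-repeat Monte-Carlo bias/coverage study
5. `05_acid_base.R` — pKa exclusion window and tautomer bound
6. `06_solvatochromism.R` — band shifts and transition energies

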