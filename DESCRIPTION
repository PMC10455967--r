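Package: petrokin
Title: Isotopologue Quantification and H/D-Exchange Kinetics for Small-Molecule ESI-MS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing rapid hydrogen-deuterium exchange of small
    molecules followed by electrospray time-of-flight mass spectrometry.
    Computes monoisotopic masses and natural-abundance isotope patterns from
    molecular formulas, extracts isotopologue intensities from centroided
    spectra, deconvolves isotope-satellite overlap into molar fractions,
    fits the sequential first-order d0 -> d1 -> d2 exchange model with
    confidence intervals and a statistical-factor ratio test, and provides
    Henderson-Hasselbalch utilities, solvatochromic band-shift summaries,
    and a seeded generator of synthetic centroided spectra for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
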