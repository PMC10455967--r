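# Henderson-Hasselbalch utilities and bounds from null observations:
# a titration series whose spectra do not change across the sampled pH
# window excludes a pKa inside (and just beyond) that window, and an
# undetected minor tautomer bounds its equilibrium constant from above.

#' Fraction deprotonated at a given pH
#'
#' Henderson-Hasselbalch: pH = pKa + log10([A-]/[HA]), hence the mole
#' fraction of the conjugate base is 10^(pH-pKa) / (1 + 10^(pH-pKa)).
#'
#' @param pH Solution pH (vectorized).
#' @param pKa Acid dissociation constant (negative log).
#' @return Fraction of the deprotonated form, in [0, 1].
#' @export
#' @examples
#' hh_fraction_deprotonated(7.4, 7.4)  # 0.5
hh_fraction_deprotonated <- function(pH, pKa) {
  1 / (1 + 10^(pKa - pH))
}

#' Construct a titration series
#'
#' @param pH Numeric vector of distinct pH values.
#' @param spectra Matrix of absorbance summaries, one row per pH value,
#'   columns = fixed wavelengths; all values >= 0.
#' @return A `titration_series` object.
#' @export
titration_series <- function(pH, spectra) {
  spectra <- as.matrix(spectra)
  stopifnot(is.numeric(pH), nrow(spectra) == length(pH),
            !anyDuplicated(pH), all(spectra >= 0))
  ord <- order(pH)
  structure(list(pH = pH[ord], spectra = spectra[ord, , drop = FALSE]),
            class = "titration_series")
}

#' Read a titration series from long CSV
#'
#' Expects columns `pH,wavelength_nm,absorbance`.
#'
#' @param path Path to the CSV.
#' @return A [titration_series()].
#' @export
read_titration_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("pH", "wavelength_nm", "absorbance") %in% names(df)))
  wide <- stats::reshape(df, idvar = "pH", timevar = "wavelength_nm",
                         direction = "wide")
  titration_series(wide$pH, as.matrix(wide[, -1, drop = FALSE]))
}

#' Bound or locate a pKa from a UV-vis titration series
#'
#' If the maximal relative spectral change between any pair of pH points,
#' max over wavelengths of |A_i - A_j| divided by the overall maximum
#' absorbance, stays below `change_threshold`, the series is "flat" and the
#' pKa is excluded from the sampled window widened by one pH unit on each
#' side (the detectability margin of a two-state transition). Otherwise the
#' midpoint of the adjacent pH pair with the steepest spectral change per
#' pH unit is returned as a crude pKa locator.
#'
#' @param series A [titration_series()] with at least 3 pH points.
#' @param change_threshold Relative change defining "unchanged"
#'   (default 0.05).
#' @return List with `verdict` (`"exclusion"` or `"localized"`),
#'   `max_relative_change`, and either `excluded_interval` (the sampled pH
#'   window) plus `exclusion_margin`, or `pka_estimate`.
#' @export
pka_bound_from_flat_titration <- function(series, change_threshold = 0.05) {
  stopifnot(inherits(series, "titration_series"),
            change_threshold > 0, change_threshold < 1)
  n <- length(series$pH)
  if (n < 3L) stop("need at least 3 pH points", call. = FALSE)
  A <- series$spectra
  a_max <- max(A)
  pair_change <- function(i, j) max(abs(A[i, ] - A[j, ])) / a_max
  changes <- outer(seq_len(n), seq_len(n), Vectorize(pair_change))
  max_change <- max(changes)
  if (max_change < change_threshold) {
    return(list(verdict = "exclusion",
                max_relative_change = max_change,
                excluded_interval = range(series$pH),
                exclusion_margin = 1,
                message = sprintf(
                  "spectra unchanged: pKa outside [%g, %g] (margin +-1)",
                  min(series$pH), max(series$pH))))
  }
  grad <- vapply(seq_len(n - 1L), function(i) {
    pair_change(i, i + 1L) / (series$pH[i + 1L] - series$pH[i])
  }, numeric(1))
  i_max <- which.max(grad)
  list(verdict = "localized",
       max_relative_change = max_change,
       pka_estimate = (series$pH[i_max] + series$pH[i_max + 1L]) / 2)
}

#' Upper bound on a tautomer equilibrium constant from a detection limit
#'
#' If a minor species would have been detected at mole fraction f but is
#' not observed (e.g. NMR integration limits), its equilibrium constant
#' relative to the major form is bounded by Keq <= f / (1 - f).
#'
#' @param detection_limit_fraction Undetected minor-species mole fraction,
#'   in (0, 0.5).
#' @return Upper bound on Keq.
#' @export
#' @examples
#' tautomer_ratio_upper_bound(0.0476)  # ~0.05
tautomer_ratio_upper_bound <- function(detection_limit_fraction) {
  f <- detection_limit_fraction
  if (!is.numeric(f) || length(f) != 1L || f <= 0 || f >= 0.5) {
    stop("detection_limit_fraction must lie in (0, 0.5)", call. = FALSE)
  }
  f / (1 - f)
}
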