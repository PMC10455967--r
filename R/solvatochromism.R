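# Solvatochromic band-shift summaries over a solvent-composition series.

#' Construct a solvatochromic series
#'
#' @param df data.frame with columns `water_pct` (strictly increasing, in
#'   [0, 100]), `lmax1_nm`, `eps1`, `lmax2_nm`, `eps2` (all positive).
#' @return A `solvatochromic_series` data.frame.
#' @export
solvatochromic_series <- function(df) {
  need <- c("water_pct", "lmax1_nm", "eps1", "lmax2_nm", "eps2")
  stopifnot(is.data.frame(df), all(need %in% names(df)))
  df <- df[order(df$water_pct), need, drop = FALSE]
  df[] <- lapply(df, as.numeric)
  stopifnot(all(df$water_pct >= 0), all(df$water_pct <= 100),
            all(diff(df$water_pct) > 0),
            all(df$lmax1_nm > 0), all(df$lmax2_nm > 0),
            all(df$eps1 > 0), all(df$eps2 > 0))
  rownames(df) <- NULL
  structure(df, class = c("solvatochromic_series", "data.frame"))
}

#' Absorption maxima and molar absorptivities of petrosamine in DMSO-water
#'
#' The packaged UV-vis summary of the petrosamine cation across DMSO-water
#' mixtures: the dominant pi-pi* band (band 1) and the long-wavelength
#' n-pi* band (band 2) that gives the alkaloid its color. Molar
#' absorptivities are normalized to the literature value of 4700 for band 2
#' in pure water.
#'
#' @return A [solvatochromic_series()] with one row per water fraction
#'   (0-100% v/v).
#' @export
#' @examples
#' petrosamine_uvvis()
petrosamine_uvvis <- function() {
  path <- system.file("extdata", "petrosamine_uvvis_dmso_water.csv",
                      package = "petrokin", mustWork = TRUE)
  solvatochromic_series(utils::read.csv(path))
}

.band_columns <- function(band) {
  if (!(length(band) == 1L && band %in% c(1, 2))) {
    stop("band must be 1 or 2", call. = FALSE)
  }
  list(lambda = paste0("lmax", band, "_nm"), eps = paste0("eps", band))
}

#' Band shift across a solvent series
#'
#' Signed wavelength change of one absorption band from the first to the
#' last record along increasing water fraction, reported as a positive
#' magnitude plus a direction label: `"hypsochromic"` (blue shift, lambda
#' decreases with water content), `"bathochromic"` (red shift), or
#' `"none"` when the magnitude is below 1 nm.
#'
#' @param series A [solvatochromic_series()] with at least 2 records.
#' @param band Band index, 1 or 2.
#' @return List with `delta_nm` (magnitude), `direction`, `from_nm`,
#'   `to_nm`.
#' @export
#' @examples
#' band_shift(petrosamine_uvvis(), band = 2)  # 78 nm, hypsochromic
band_shift <- function(series, band) {
  stopifnot(inherits(series, "solvatochromic_series"), nrow(series) >= 2)
  cols <- .band_columns(band)
  lam <- series[[cols$lambda]]
  from <- lam[1L]
  to <- lam[length(lam)]
  delta <- from - to  # positive when lambda decreases with water fraction
  direction <- if (abs(delta) < 1) "none" else
    if (delta > 0) "hypsochromic" else "bathochromic"
  list(delta_nm = abs(delta), direction = direction,
       from_nm = from, to_nm = to)
}

#' Convert wavelength to transition energy
#'
#' E = hc / lambda with the pinned conversion constant 1239.841984 eV nm.
#'
#' @param lambda_nm Wavelength in nm, > 0 (vectorized).
#' @return Transition energy in eV.
#' @export
#' @examples
#' nm_to_ev(648)  # ~1.913 eV
nm_to_ev <- function(lambda_nm) {
  if (any(lambda_nm <= 0)) stop("wavelength must be positive", call. = FALSE)
  .HC_EV_NM / lambda_nm
}

#' Convert transition energy to wavelength
#'
#' @param energy_ev Energy in eV, > 0 (vectorized).
#' @return Wavelength in nm.
#' @export
ev_to_nm <- function(energy_ev) {
  if (any(energy_ev <= 0)) stop("energy must be positive", call. = FALSE)
  .HC_EV_NM / energy_ev
}

#' Monotonicity of molar absorptivity across a solvent series
#'
#' Sign consistency of successive differences of epsilon along increasing
#' water fraction, plus the endpoint ratio eps(first) / eps(last).
#'
#' @param series A [solvatochromic_series()] with at least 3 records.
#' @param band Band index, 1 or 2.
#' @return List with `verdict` (`"strictly decreasing"`,
#'   `"strictly increasing"`, `"flat"`, or `"non-monotonic"`) and
#'   `endpoint_ratio`.
#' @export
epsilon_trend <- function(series, band) {
  stopifnot(inherits(series, "solvatochromic_series"), nrow(series) >= 3)
  cols <- .band_columns(band)
  eps <- series[[cols$eps]]
  d <- diff(eps)
  verdict <- if (all(d == 0)) "flat" else
    if (all(d < 0)) "strictly decreasing" else
      if (all(d > 0)) "strictly increasing" else "non-monotonic"
  list(verdict = verdict, endpoint_ratio = eps[1L] / eps[length(eps)])
}
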