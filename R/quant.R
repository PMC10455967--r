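# Isotopologue quantification from centroided spectra.
#
# For a brominated analyte the d0/d1/d2 measurement channels are not clean:
# at TOF resolving power the 13C1 satellite of d0 is unresolved from the d1
# monoisotopic peak (0.003 Da apart) and the 81Br satellite of d0 falls in
# the d2 channel. Observed channel intensities are therefore a triangular
# convolution of the molar amounts, inverted here via a correction matrix.

#' Construct a centroided spectrum
#'
#' @param mz Numeric vector of peak positions (Da); sorted internally.
#' @param intensity Non-negative intensities, same length as `mz`.
#' @param time_s Acquisition time in seconds since dissolution.
#' @param replicate_id Replicate label.
#' @return A `centroid_spectrum` (data.frame with columns `mz`, `intensity`
#'   and attributes `time_s`, `replicate_id`).
#' @export
centroid_spectrum <- function(mz, intensity, time_s, replicate_id = "r1") {
  stopifnot(length(mz) == length(intensity), all(intensity >= 0),
            is.numeric(time_s), length(time_s) == 1L, time_s >= 0)
  ord <- order(mz)
  structure(data.frame(mz = mz[ord], intensity = intensity[ord]),
            class = c("centroid_spectrum", "data.frame"),
            time_s = as.numeric(time_s),
            replicate_id = as.character(replicate_id))
}

#' Extract raw isotopologue channel intensities from one spectrum
#'
#' Sums centroid intensities within a mass window around the monoisotopic
#' m/z of each d0..d_max species. Absent peaks contribute zero; an all-zero
#' result is flagged (`attr(, "no_signal")`) rather than raised as an error.
#'
#' @param spectrum A [centroid_spectrum()].
#' @param ec `element_counts` of the unlabeled species (charge included).
#' @param max_d Highest deuteration state to extract (default 2).
#' @param tol_ppm Half-width of the matching window in ppm (default 10,
#'   TOF mass accuracy). For correction-matrix consistency the pipeline in
#'   [correct_time_series()] instead uses the resolution width.
#' @return Numeric vector of length `max_d + 1` named `d0..`, with
#'   attribute `no_signal`.
#' @export
extract_raw_intensities <- function(spectrum, ec, max_d = 2L, tol_ppm = 10) {
  stopifnot(inherits(spectrum, "centroid_spectrum"), tol_ppm > 0, max_d >= 0)
  targets <- vapply(0:max_d, function(n) monoisotopic_mz(ec, n_labile = n),
                    numeric(1))
  raw <- vapply(targets, function(target) {
    window <- target * tol_ppm * 1e-6
    sum(spectrum$intensity[abs(spectrum$mz - target) < window])
  }, numeric(1))
  names(raw) <- paste0("d", 0:max_d)
  attr(raw, "no_signal") <- all(raw == 0)
  raw
}

#' Natural-abundance correction matrix for deuteration channels
#'
#' Column j holds the isotope pattern of the j-deuterated species binned
#' into the d0..d_max measurement channels: a pattern peak is assigned to a
#' channel when it lies within the resolution width (channel m/z divided by
#' `resolving_power`) of the channel center. Pattern abundance falling
#' outside every channel is recorded per column in `attr(, "loss")`. The
#' matrix is lower-triangular (heavier labels cannot contribute to lighter
#' channels) with column sums at most one.
#'
#' @inheritParams extract_raw_intensities
#' @param resolving_power m/dm of the instrument (default 20000).
#' @param abundance_floor Pattern pruning floor (default 1e-6).
#' @return `(max_d+1) x (max_d+1)` matrix with attributes `channels_mz`,
#'   `loss`, `resolving_power`.
#' @export
#' @examples
#' ec <- parse_formula("C21H17BrN3O2", charge = 1)
#' M <- build_correction_matrix(ec, max_d = 2)
#' M[2, 1] / M[1, 1]  # 13C satellite of d0 in the d1 channel, ~0.23
build_correction_matrix <- function(ec, max_d = 2L, resolving_power = 20000,
                                    abundance_floor = 1e-6) {
  stopifnot(inherits(ec, "element_counts"), resolving_power > 0, max_d >= 1)
  channels <- vapply(0:max_d, function(n) monoisotopic_mz(ec, n_labile = n),
                     numeric(1))
  widths <- channels / resolving_power
  if (all(diff(channels) < widths[-length(widths)])) {
    stop("channels indistinguishable at resolving power ", resolving_power,
         call. = FALSE)
  }
  k <- max_d + 1L
  M <- matrix(0, k, k)
  loss <- numeric(k)
  for (j in 0:max_d) {
    ecj <- element_counts(ec$counts, charge = ec$charge, n_labile = j)
    pat <- isotope_pattern(ecj, resolving_power = resolving_power,
                           abundance_floor = abundance_floor)
    for (n in 0:max_d) {
      M[n + 1L, j + 1L] <-
        sum(pat$abundance[abs(pat$mz - channels[n + 1L]) < widths[n + 1L]])
    }
    loss[j + 1L] <- 1 - sum(M[, j + 1L])
  }
  dimnames(M) <- list(paste0("ch_d", 0:max_d), paste0("sp_d", 0:max_d))
  structure(M, channels_mz = channels, loss = loss,
            resolving_power = resolving_power)
}

#' Deconvolve raw channel intensities into molar fractions
#'
#' Solves `M x = raw` for the molar amounts `x`, clips negative components
#' (noise can push the exact solution slightly negative), renormalizes to a
#' probability vector, and reports a quality flag: `"ok"`, `"clipped"` when
#' clipping removed more than 2% of the recovered mass, or `"no_signal"`.
#'
#' @param raw Channel intensity vector (length matching `ncol(M)`).
#' @param M Correction matrix from [build_correction_matrix()].
#' @return List with `fractions` (named, summing to 1, or NA on no signal),
#'   `amounts` (unclipped solution), `clipped_fraction`, `flag`.
#' @export
correct_fractions <- function(raw, M) {
  stopifnot(is.matrix(M), nrow(M) == ncol(M), length(raw) == nrow(M))
  if (any(abs(diag(M)) < .Machine$double.eps * 100)) {
    stop("correction matrix is singular (zero diagonal)", call. = FALSE)
  }
  labs <- paste0("d", seq_len(nrow(M)) - 1L)
  if (all(raw == 0)) {
    fr <- rep(NA_real_, length(raw))
    names(fr) <- labs
    return(list(fractions = fr, amounts = rep(0, length(raw)),
                clipped_fraction = 0, flag = "no_signal"))
  }
  x <- solve(M, as.numeric(raw))
  pos <- pmax(x, 0)
  clipped <- sum(pmax(-x, 0)) / sum(pos)
  fractions <- pos / sum(pos)
  names(fractions) <- labs
  list(fractions = fractions, amounts = x, clipped_fraction = clipped,
       flag = if (clipped > 0.02) "clipped" else "ok")
}

#' Run the extraction + correction chain over a time course of spectra
#'
#' Builds the correction matrix once, then for every spectrum extracts the
#' channel intensities and converts them to corrected molar fractions. The
#' channel matching window defaults to the resolution width (m/z divided by
#' `resolving_power`), the same criterion used to bin the correction
#' matrix, so that satellite centroids merged into a neighboring channel by
#' the instrument are assigned consistently with the matrix.
#'
#' @param spectra List of [centroid_spectrum()] objects.
#' @inheritParams build_correction_matrix
#' @param tol_ppm Optional ppm half-window override; default
#'   `1e6 / resolving_power`.
#' @param correction If `FALSE`, raw channel intensities are normalized
#'   directly without satellite deconvolution (for comparing conventions).
#' @return An `isotopologue_series` data.frame with columns `replicate_id`,
#'   `time_s`, `f_d0..f_dmax`, `raw_d0..`, `quality_flag`, ordered by
#'   replicate then time.
#' @export
correct_time_series <- function(spectra, ec, max_d = 2L,
                                resolving_power = 20000,
                                tol_ppm = NULL, correction = TRUE,
                                abundance_floor = 1e-6) {
  stopifnot(is.list(spectra), length(spectra) > 0)
  if (is.null(tol_ppm)) tol_ppm <- 1e6 / resolving_power
  M <- build_correction_matrix(ec, max_d = max_d,
                               resolving_power = resolving_power,
                               abundance_floor = abundance_floor)
  rows <- lapply(spectra, function(sp) {
    raw <- extract_raw_intensities(sp, ec, max_d = max_d, tol_ppm = tol_ppm)
    if (correction) {
      cr <- correct_fractions(raw, M)
    } else {
      tot <- sum(raw)
      fr <- if (tot > 0) raw / tot else rep(NA_real_, length(raw))
      cr <- list(fractions = fr,
                 flag = if (tot > 0) "ok" else "no_signal")
    }
    out <- data.frame(replicate_id = attr(sp, "replicate_id"),
                      time_s = attr(sp, "time_s"))
    for (n in 0:max_d) out[[paste0("f_d", n)]] <- unname(cr$fractions[n + 1L])
    for (n in 0:max_d) out[[paste0("raw_d", n)]] <- unname(raw[n + 1L])
    out$quality_flag <- cr$flag
    out
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$replicate_id, res$time_s), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("isotopologue_series", "data.frame"),
            correction = correction, resolving_power = resolving_power)
}

#' Scale raw intensities by an external reference
#'
#' Divides the raw channel intensities by the molecular-ion intensity of an
#' unlabeled reference solution at equal concentration (the experimental
#' control for ionization drift). Fractions are scale-invariant and remain
#' untouched; the scaling is diagnostic only.
#'
#' @param series An `isotopologue_series`.
#' @param reference_intensity Positive scalar reference intensity.
#' @return The series with `raw_*` columns divided by the reference and a
#'   `reference_intensity` attribute recorded.
#' @export
normalize_to_reference <- function(series, reference_intensity) {
  stopifnot(inherits(series, "isotopologue_series"))
  if (!is.numeric(reference_intensity) || length(reference_intensity) != 1L ||
      reference_intensity <= 0) {
    stop("reference_intensity must be a positive scalar", call. = FALSE)
  }
  raw_cols <- grep("^raw_d", names(series), value = TRUE)
  for (cl in raw_cols) series[[cl]] <- series[[cl]] / reference_intensity
  attr(series, "reference_intensity") <- reference_intensity
  series
}

#' Read a centroided peak list CSV
#'
#' Expects columns `replicate_id,time_s,mz,intensity` (one row per peak,
#' UTF-8, "." decimal separator). Validates non-negative intensities and
#' returns one [centroid_spectrum()] per (replicate, time) pair.
#'
#' @param path Path to the CSV file.
#' @return List of `centroid_spectrum` objects ordered by replicate, time.
#' @export
read_peaks_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("replicate_id", "time_s", "mz", "intensity")
  if (!all(need %in% names(df))) {
    stop("peak CSV must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  }
  if (any(df$intensity < 0)) stop("negative intensities in peak list", call. = FALSE)
  key <- interaction(df$replicate_id, df$time_s, drop = TRUE)
  groups <- split(df, key)
  ord <- order(vapply(groups, function(g) g$replicate_id[1], character(1)),
               vapply(groups, function(g) g$time_s[1], numeric(1)))
  lapply(groups[ord], function(g) {
    centroid_spectrum(g$mz, g$intensity, time_s = g$time_s[1],
                      replicate_id = g$replicate_id[1])
  })
}

#' Write a list of centroided spectra to the peak-list CSV dialect
#'
#' @param spectra List of [centroid_spectrum()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks_csv <- function(spectra, path) {
  rows <- lapply(spectra, function(sp) {
    data.frame(replicate_id = attr(sp, "replicate_id"),
               time_s = attr(sp, "time_s"),
               mz = sp$mz, intensity = sp$intensity)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write corrected fractions as tidy CSV
#'
#' @param series An `isotopologue_series` from [correct_time_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fractions_csv <- function(series, path) {
  keep <- c("replicate_id", "time_s",
            grep("^f_d", names(series), value = TRUE), "quality_flag")
  utils::write.csv(as.data.frame(series)[, keep], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a fractions CSV written by [write_fractions_csv()]
#'
#' @param path Path to the CSV.
#' @return An `isotopologue_series` data.frame.
#' @export
read_fractions_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("replicate_id", "time_s", "f_d0") %in% names(df))) {
    stop("not a fractions CSV", call. = FALSE)
  }
  structure(df, class = c("isotopologue_series", "data.frame"))
}
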