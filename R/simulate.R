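# Synthetic centroided ESI-TOF time courses for the H/D exchange
# experiment: per timepoint the true isotopologue fractions follow the
# sequential model, each d-species carries its natural isotope pattern at
# the configured resolving power, overlapping centroids are summed the way
# the instrument would merge them, and each surviving centroid receives
# independent log-normal multiplicative noise.

# Deterministic substream seed from a base seed and an index, kept within
# 32-bit integer range so replicate streams are order-independent.
.substream_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 69069 + as.numeric(index) * 7919) %%
               2147483647)
}

# Evaluate fn() under a temporary RNG state seeded with `seed`.
.with_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Configuration of a synthetic H/D-exchange ESI-TOF experiment
#'
#' Defaults reproduce the study conditions of the rapid-sampling
#' experiment the generator emulates: the petrosamine monocation
#' (C21H17BrN3O2, +1), exchange at k1 = 0.1311 and k2 = 0.0755 s^-1,
#' spectra every 15 s from 0 to 90 s, triplicate runs, a 20000
#' resolving-power TOF, and 3% multiplicative intensity noise per centroid.
#'
#' @param k1,k2 Exchange rate constants (s^-1).
#' @param formula Molecular formula of the unlabeled analyte.
#' @param charge Ion charge (default +1).
#' @param n_sites Number of exchangeable hydrogens; the sequential model is
#'   two-site, so this must be 2.
#' @param t_grid Sampling times in seconds (default `seq(0, 90, 15)`).
#' @param n_replicates Number of replicate runs (default 3).
#' @param resolving_power Instrument m/dm (default 20000).
#' @param noise_cv Multiplicative coefficient of variation per centroid
#'   (default 0.03; 0 for noiseless spectra).
#' @param baseline_floor Centroids below this intensity are dropped
#'   (default 0).
#' @param total_intensity Total ion intensity per spectrum before noise
#'   (arbitrary units, default 1e6).
#' @param abundance_floor Isotope-pattern pruning floor (default 1e-6);
#'   use the same value in [correct_time_series()] for exact round trips.
#' @param dead_time_s Unobserved delay between dissolution and the first
#'   scan; shifts the kinetic clock of every sample (default 0).
#' @param seed Base seed; each replicate draws from a derived substream.
#' @return A `sim_config` list with precomputed per-species isotope
#'   patterns.
#' @export
sim_config <- function(k1 = 0.1311, k2 = 0.0755,
                       formula = "C21H17BrN3O2", charge = 1L, n_sites = 2L,
                       t_grid = seq(0, 90, by = 15), n_replicates = 3L,
                       resolving_power = 20000, noise_cv = 0.03,
                       baseline_floor = 0, total_intensity = 1e6,
                       abundance_floor = 1e-6, dead_time_s = 0,
                       seed = 17L) {
  stopifnot(k1 > 0, k2 > 0, n_sites == 2L, n_replicates >= 1,
            length(t_grid) >= 1, all(t_grid >= 0), all(diff(t_grid) > 0),
            noise_cv >= 0, baseline_floor >= 0, total_intensity > 0,
            dead_time_s >= 0)
  ec <- parse_formula(formula, charge = charge)
  patterns <- lapply(0:n_sites, function(n) {
    ecn <- element_counts(ec$counts, charge = ec$charge, n_labile = n)
    isotope_pattern(ecn, resolving_power = resolving_power,
                    abundance_floor = abundance_floor)
  })
  structure(list(k1 = k1, k2 = k2, formula = formula, ec = ec,
                 n_sites = as.integer(n_sites), t_grid = t_grid,
                 n_replicates = as.integer(n_replicates),
                 resolving_power = resolving_power, noise_cv = noise_cv,
                 baseline_floor = baseline_floor,
                 total_intensity = total_intensity,
                 abundance_floor = abundance_floor,
                 dead_time_s = dead_time_s, seed = as.integer(seed),
                 patterns = patterns),
            class = "sim_config")
}

#' Simulate a centroided spectra time course
#'
#' For every replicate and timepoint: evaluates the true d0/d1/d2 fractions
#' with [model_fractions()], scales each species' isotope pattern by its
#' fraction of the total ion intensity, merges centroids closer than the
#' resolution width (intensity-weighted positions, summed intensities),
#' applies seeded log-normal multiplicative noise with the configured CV
#' (mean-one, so expected intensities are unbiased), and drops centroids
#' below the baseline floor. Replicates use independent, order-independent
#' RNG substreams derived from the base seed, so the same configuration
#' always yields identical output.
#'
#' @param cfg A [sim_config()].
#' @return List of [centroid_spectrum()] objects, ordered by replicate then
#'   time, with attribute `true_fractions` (the noiseless model fractions
#'   per timepoint).
#' @export
#' @examples
#' spectra <- simulate_time_course(sim_config(noise_cv = 0, n_replicates = 1))
#' spectra[[1]]  # pure d0 pattern at t = 0
simulate_time_course <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  truth <- model_fractions(cfg$k1, cfg$k2, cfg$t_grid + cfg$dead_time_s)
  sdlog <- sqrt(log(1 + cfg$noise_cv^2))
  spectra <- list()
  for (r in seq_len(cfg$n_replicates)) {
    rep_id <- paste0("rep", r)
    rep_spectra <- .with_seed(.substream_seed(cfg$seed, r), function() {
      lapply(seq_along(cfg$t_grid), function(i) {
        fr <- as.numeric(truth[i, c("f_d0", "f_d1", "f_d2")])
        mz <- numeric(0)
        intensity <- numeric(0)
        for (n in 0:cfg$n_sites) {
          pat <- cfg$patterns[[n + 1L]]
          mz <- c(mz, pat$mz)
          intensity <- c(intensity, pat$abundance * fr[n + 1L] *
                           cfg$total_intensity)
        }
        keep <- intensity > 0
        merged <- .merge_peaks(mz[keep], intensity[keep],
                               cfg$resolving_power)
        inten <- merged$abundance
        if (cfg$noise_cv > 0) {
          inten <- inten * stats::rlnorm(length(inten),
                                         meanlog = -sdlog^2 / 2,
                                         sdlog = sdlog)
        }
        keep2 <- inten >= cfg$baseline_floor & inten > 0
        centroid_spectrum(merged$mz[keep2], inten[keep2],
                          time_s = cfg$t_grid[i], replicate_id = rep_id)
      })
    })
    spectra <- c(spectra, rep_spectra)
  }
  attr(spectra, "true_fractions") <- truth
  spectra
}

#' Simulate a two-state UV-vis titration series
#'
#' Linear mixture of two endpoint spectra weighted by the
#' Henderson-Hasselbalch deprotonated fraction at each pH.
#'
#' @param pKa True acid dissociation constant.
#' @param pH_grid pH values to sample (distinct).
#' @param endpoint_spectra List with elements `protonated` and
#'   `deprotonated`: absorbance vectors of equal length.
#' @return A [titration_series()].
#' @export
simulate_titration <- function(pKa, pH_grid, endpoint_spectra) {
  stopifnot(is.list(endpoint_spectra),
            all(c("protonated", "deprotonated") %in% names(endpoint_spectra)))
  prot <- endpoint_spectra$protonated
  deprot <- endpoint_spectra$deprotonated
  if (length(prot) != length(deprot)) {
    stop("endpoint spectra must have equal length", call. = FALSE)
  }
  A <- t(vapply(pH_grid, function(ph) {
    f <- hh_fraction_deprotonated(ph, pKa)
    (1 - f) * prot + f * deprot
  }, numeric(length(prot))))
  titration_series(pH_grid, A)
}

#' Monte-Carlo recovery study for the full quantification pipeline
#'
#' Repeatedly simulates spectra under one configuration (fresh substream
#' seed per repeat), runs extraction + natural-abundance correction +
#' kinetic fitting, and records estimates, confidence intervals and
#' coverage of the generating rate constants.
#'
#' @param cfg A [sim_config()]; its `k1`/`k2` are the recovery truth.
#' @param n_repeats Number of Monte-Carlo repeats (default 200).
#' @param seed Base seed for the repeat substreams (default `cfg$seed`).
#' @return data.frame with one row per repeat: `k1_hat`, `k2_hat`, CI
#'   bounds, `covered_k1`, `covered_k2`, `ratio`, `ratio_sigma`,
#'   `r_squared`.
#' @export
recovery_study <- function(cfg, n_repeats = 200, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"), n_repeats >= 1)
  rows <- lapply(seq_len(n_repeats), function(i) {
    cfg_i <- cfg
    cfg_i$seed <- .substream_seed(seed, i)
    spectra <- simulate_time_course(cfg_i)
    series <- correct_time_series(spectra, cfg$ec, max_d = cfg$n_sites,
                                  resolving_power = cfg$resolving_power,
                                  abundance_floor = cfg$abundance_floor)
    fit <- fit_exchange(series)
    data.frame(repeat_id = i, k1_hat = fit$k1, k2_hat = fit$k2,
               k1_lo = fit$ci_k1[1], k1_hi = fit$ci_k1[2],
               k2_lo = fit$ci_k2[1], k2_hi = fit$ci_k2[2],
               covered_k1 = fit$ci_k1[1] <= cfg$k1 & cfg$k1 <= fit$ci_k1[2],
               covered_k2 = fit$ci_k2[1] <= cfg$k2 & cfg$k2 <= fit$ci_k2[2],
               ratio = fit$ratio, ratio_sigma = fit$ratio_sigma,
               r_squared = fit$r_squared)
  })
  do.call(rbind, rows)
}
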