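# Natural-abundance isotope patterns by multinomial convolution.
#
# Per element, the distribution over n atoms is the exact multinomial over
# the pinned isotope abundances; element distributions are then convolved
# across the formula. Fine-structure peaks are merged the way a centroiding
# TOF instrument would: greedy left-to-right aggregation of peaks closer
# than the FWHM-derived separation m/z / resolving_power.

# All compositions of n over m parts (rows), small m only.
.compositions <- function(n, m) {
  if (m == 1L) return(matrix(n, 1L, 1L))
  out <- vector("list", n + 1L)
  for (k in 0:n) {
    sub <- .compositions(n - k, m - 1L)
    out[[k + 1L]] <- cbind(rep.int(k, nrow(sub)), sub)
  }
  do.call(rbind, out)
}

# Multinomial isotopologue distribution for n atoms of one element.
.element_distribution <- function(symbol, n, prune = 1e-15) {
  iso <- .element_isotopes(symbol)
  m <- nrow(iso)
  if (m == 1L || n == 0L) {
    return(data.frame(mass = n * iso$mass_da[1L], abundance = 1))
  }
  comp <- .compositions(n, m)
  logp <- lgamma(n + 1) - rowSums(lgamma(comp + 1)) +
    as.vector(comp %*% log(iso$abundance))
  d <- data.frame(mass = as.vector(comp %*% iso$mass_da), abundance = exp(logp))
  d[d$abundance >= prune, , drop = FALSE]
}

# Convolution of two mass/abundance distributions with pruning.
.convolve_dists <- function(a, b, prune = 1e-14) {
  mass <- outer(a$mass, b$mass, "+")
  ab <- outer(a$abundance, b$abundance)
  keep <- ab >= prune
  data.frame(mass = as.vector(mass[keep]), abundance = as.vector(ab[keep]))
}

# Greedy left-to-right centroid merge. Peaks are merged into the running
# cluster while their distance to the cluster centroid is below the
# resolution width; the merged position is the abundance-weighted mean.
.merge_peaks <- function(mz, abundance, resolving_power) {
  ord <- order(mz)
  mz <- mz[ord]
  abundance <- abundance[ord]
  n <- length(mz)
  out_mz <- numeric(n)
  out_ab <- numeric(n)
  k <- 1L
  cm <- mz[1L]
  ca <- abundance[1L]
  if (n > 1L) {
    for (i in 2:n) {
      width <- if (is.finite(resolving_power)) cm / resolving_power else 1e-9
      if (mz[i] - cm < width) {
        tot <- ca + abundance[i]
        cm <- (cm * ca + mz[i] * abundance[i]) / tot
        ca <- tot
      } else {
        out_mz[k] <- cm
        out_ab[k] <- ca
        k <- k + 1L
        cm <- mz[i]
        ca <- abundance[i]
      }
    }
  }
  out_mz[k] <- cm
  out_ab[k] <- ca
  data.frame(mz = out_mz[seq_len(k)], abundance = out_ab[seq_len(k)])
}

#' Natural-abundance isotope pattern of a species
#'
#' Computes the full isotopologue fine structure of a formula by exact
#' multinomial convolution over the pinned isotope table, merges peaks that
#' a centroiding instrument of the given resolving power cannot separate,
#' prunes peaks below an abundance floor, and renormalizes abundances to
#' sum to one. Hydrogens marked as replaced by deuterium contribute a pure
#' D mass; all remaining atoms carry natural abundance. For charged species
#' masses are reported as m/z under the electron-corrected convention.
#'
#' @param ec An `element_counts` object.
#' @param resolving_power m/dm (FWHM); peaks closer than m/z divided by this
#'   are merged into one centroid (abundance-weighted mean position).
#'   `Inf` keeps the full fine structure. Default 20000 (ESI-TOF class).
#' @param abundance_floor Peaks below this relative abundance are dropped
#'   before renormalization. Must lie in [0, 1).
#' @return An `isotope_pattern`: a data.frame with columns `mz` (strictly
#'   increasing) and `abundance` (summing to 1).
#' @export
#' @examples
#' isotope_pattern(parse_formula("Br1"), resolving_power = Inf)
#' isotope_pattern(parse_formula("C21H17BrN3O2", charge = 1), 20000, 1e-4)
isotope_pattern <- function(ec, resolving_power = 20000, abundance_floor = 0) {
  stopifnot(inherits(ec, "element_counts"),
            resolving_power > 0,
            abundance_floor >= 0, abundance_floor < 1)
  counts <- .effective_counts(ec)
  if (length(counts) == 0L) stop("empty formula", call. = FALSE)
  dist <- NULL
  for (sym in names(counts)) {
    d <- .element_distribution(sym, counts[[sym]])
    dist <- if (is.null(dist)) d else .convolve_dists(dist, d)
  }
  mz <- .neutral_to_mz(dist$mass, ec$charge)
  pat <- .merge_peaks(mz, dist$abundance, resolving_power)
  pat <- pat[pat$abundance >= abundance_floor, , drop = FALSE]
  if (nrow(pat) == 0L) stop("abundance_floor removed every peak", call. = FALSE)
  pat$abundance <- pat$abundance / sum(pat$abundance)
  rownames(pat) <- NULL
  structure(pat,
            class = c("isotope_pattern", "data.frame"),
            resolving_power = resolving_power,
            charge = ec$charge)
}
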