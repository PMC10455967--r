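#' Parse a molecular formula in Hill notation
#'
#' Parses formulas such as `"C21H17BrN3O2"` into per-element atom counts and
#' attaches the ionization state (elementary charge) and the number of
#' exchangeable hydrogens explicitly replaced by deuterium. Only plain
#' element symbols with optional positive integer counts are accepted; all
#' symbols must be present in the pinned [isotope_table()].
#'
#' @param formula Character scalar, e.g. `"C21H17BrN3O2"` or `"H2O"`.
#' @param charge Integer net charge in elementary charges (default 0).
#' @param n_labile Integer number of H atoms replaced by D (default 0);
#'   must not exceed the H count.
#' @return An object of class `element_counts`: a list with `counts`
#'   (named integer vector), `charge` and `n_labile`.
#' @export
#' @examples
#' parse_formula("C21H17BrN3O2", charge = 1)
#' parse_formula("H2O")
parse_formula <- function(formula, charge = 0L, n_labile = 0L) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula, perl = TRUE)[[1]]
  tokens <- regmatches(formula, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(formula)) {
    stop("cannot parse formula '", formula,
         "': unexpected characters outside element tokens", call. = FALSE)
  }
  counts <- integer(0)
  for (tok in tokens) {
    sym <- sub("[0-9]*$", "", tok)
    cnt_str <- sub("^[A-Za-z]+", "", tok)
    cnt <- if (nzchar(cnt_str)) as.integer(cnt_str) else 1L
    if (cnt == 0L) {
      stop("zero atom count for element '", sym, "' in '", formula, "'",
           call. = FALSE)
    }
    .element_isotopes(sym)  # errors on unknown symbols
    counts[sym] <- (if (is.na(counts[sym])) 0L else counts[sym]) + cnt
  }
  element_counts(counts, charge = charge, n_labile = n_labile)
}

#' Construct an element-counts object
#'
#' Low-level constructor behind [parse_formula()]; validates the invariants
#' (non-negative counts, at least one atom, labile substitutions bounded by
#' the hydrogen count).
#'
#' @param counts Named integer vector of atom counts per element symbol.
#' @param charge Integer net charge (elementary charges).
#' @param n_labile Number of hydrogens replaced by deuterium.
#' @return An `element_counts` object.
#' @export
element_counts <- function(counts, charge = 0L, n_labile = 0L) {
  stopifnot(is.numeric(counts), !is.null(names(counts)), all(nzchar(names(counts))))
  counts <- vapply(counts, as.integer, integer(1))
  if (any(counts < 0)) stop("negative atom counts are not allowed", call. = FALSE)
  if (sum(counts) == 0L) stop("formula contains no atoms", call. = FALSE)
  charge <- as.integer(charge)
  n_labile <- as.integer(n_labile)
  n_h <- if ("H" %in% names(counts)) counts[["H"]] else 0L
  if (n_labile < 0L || n_labile > n_h) {
    stop("n_labile must lie in [0, H count = ", n_h, "]", call. = FALSE)
  }
  structure(list(counts = counts, charge = charge, n_labile = n_labile),
            class = "element_counts")
}

#' @export
print.element_counts <- function(x, ...) {
  f <- paste0(names(x$counts), ifelse(x$counts > 1, x$counts, ""), collapse = "")
  cat("<element_counts> ", f,
      "  charge ", sprintf("%+d", x$charge),
      "  D-substituted H: ", x$n_labile, "\n", sep = "")
  invisible(x)
}

# Effective composition after D substitution: replaces n_labile H by the
# pseudo-element D. Returns a named integer vector.
.effective_counts <- function(ec) {
  counts <- ec$counts
  if (ec$n_labile > 0L) {
    counts[["H"]] <- counts[["H"]] - ec$n_labile
    if (counts[["H"]] == 0L) counts <- counts[names(counts) != "H"]
    counts[["D"]] <- ec$n_labile
  }
  counts[counts > 0L]
}

# Neutral mass -> reported m/z under the charge convention: subtract
# charge * electron mass, divide by |charge| (|charge| <= 1 in practice).
.neutral_to_mz <- function(mass, charge) {
  if (charge == 0L) return(mass)
  (mass - charge * .ELECTRON_MASS_DA) / abs(charge)
}

#' Monoisotopic m/z of a (possibly deuterated, possibly charged) species
#'
#' Sums lightest-isotope atomic masses over the formula, swapping the mass
#' of deuterium for each labile H marked as replaced, and applies the
#' electron-mass correction for ions: m/z = (M - z * m_e) / |z|. For a
#' neutral species (charge 0) the neutral monoisotopic mass is returned.
#'
#' @param ec An `element_counts` object (see [parse_formula()]).
#' @param n_labile Optional override of the number of D substitutions.
#' @return Monoisotopic m/z in Da (neutral mass if charge is 0).
#' @export
#' @examples
#' ec <- parse_formula("C21H17BrN3O2", charge = 1)
#' monoisotopic_mz(ec)                 # 422.0499, the d0 cation
#' monoisotopic_mz(ec, n_labile = 2)   # 424.0624, the d2 cation
monoisotopic_mz <- function(ec, n_labile = NULL) {
  stopifnot(inherits(ec, "element_counts"))
  if (!is.null(n_labile)) {
    ec <- element_counts(ec$counts, charge = ec$charge, n_labile = n_labile)
  }
  counts <- .effective_counts(ec)
  mass <- sum(vapply(names(counts), .monoisotopic_mass_of, numeric(1)) * counts)
  .neutral_to_mz(mass, ec$charge)
}
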