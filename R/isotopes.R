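#' @keywords internal
"_PACKAGE"

# Pinned physical constants (CODATA 2018).
.ELECTRON_MASS_DA <- 5.48579909065e-4
.HC_EV_NM <- 1239.841984

.pkg_cache <- new.env(parent = emptyenv())

#' Pinned isotope mass and abundance table
#'
#' Returns the package's isotope table (NIST 2018 atomic masses and
#' representative natural abundances), shipped as a versioned CSV in
#' `inst/extdata/isotopes_nist2018.csv`. All mass and isotope-pattern
#' computations in the package draw on this single table so that printed
#' m/z values are reproducible to the table's precision.
#'
#' @return A data.frame with columns `element`, `isotope` (mass number),
#'   `mass_da` (atomic mass, Da) and `abundance` (mole fraction). Within
#'   each element, rows are ordered by increasing mass.
#' @export
#' @examples
#' head(isotope_table())
isotope_table <- function() {
  if (is.null(.pkg_cache$isotopes)) {
    path <- system.file("extdata", "isotopes_nist2018.csv",
                        package = "petrokin", mustWork = TRUE)
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    tab <- tab[order(tab$element, tab$mass_da), , drop = FALSE]
    rownames(tab) <- NULL
    .pkg_cache$isotopes <- tab
  }
  .pkg_cache$isotopes
}

#' Mass of the electron in daltons
#'
#' @return Electron rest mass in Da (CODATA 2018).
#' @export
electron_mass <- function() .ELECTRON_MASS_DA

# Isotope rows for one element, abundance-normalized. Deuterium is addressed
# by the pseudo-symbol "D" (pure 2H, used for explicit label substitution).
.element_isotopes <- function(symbol) {
  if (symbol == "D") {
    tab <- isotope_table()
    d <- tab[tab$element == "H" & tab$isotope == 2, , drop = FALSE]
    return(data.frame(mass_da = d$mass_da, abundance = 1))
  }
  tab <- isotope_table()
  rows <- tab[tab$element == symbol, , drop = FALSE]
  if (nrow(rows) == 0L) {
    stop("unknown element symbol: '", symbol, "'", call. = FALSE)
  }
  data.frame(mass_da = rows$mass_da,
             abundance = rows$abundance / sum(rows$abundance))
}

# Lightest (here also principal) isotope mass for an element symbol.
.monoisotopic_mass_of <- function(symbol) {
  .element_isotopes(symbol)$mass_da[1L]
}
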