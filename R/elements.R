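#' @keywords internal
"_PACKAGE"

# Element/isotope reference data is shipped as a plain-text TSV
# (inst/extdata/isotopes.tsv) and parsed once per session.
.eims_env <- new.env(parent = emptyenv())

#' Element and isotope reference table
#'
#' Returns the packaged isotope table as a data frame with one row per
#' isotope: `symbol`, `atomic_number`, `covalent_radius` (Angstrom),
#' `mass_number`, `exact_mass` (u) and `abundance` (mole fraction).
#' Coverage spans the 24 elements needed for typical organic,
#' organometallic and main-group EI-MS work (H through Bi).
#'
#' @return A data.frame, isotopes sorted by mass number within element.
#' @export
#' @examples
#' head(isotope_table())
isotope_table <- function() {
  if (is.null(.eims_env$isotopes)) {
    path <- system.file("extdata", "isotopes.tsv", package = "eimsim")
    tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
    tab <- tab[order(tab$symbol, tab$mass_number), ]
    # guard the shipped data: abundances must be proper per-element fractions
    sums <- tapply(tab$abundance, tab$symbol, sum)
    stopifnot(all(abs(sums - 1) < 1e-6), all(tab$covalent_radius > 0))
    .eims_env$isotopes <- tab
  }
  .eims_env$isotopes
}

#' Look up one element's reference data
#'
#' @param symbol Element symbol, e.g. `"Fe"`.
#' @return A list with `symbol`, `atomic_number`, `covalent_radius`,
#'   `average_mass` (abundance-weighted, used as the dynamical nuclear
#'   mass), and `isotopes` (data.frame of `mass_number`, `exact_mass`,
#'   `abundance` sorted by mass number).
#' @export
element_info <- function(symbol) {
  tab <- isotope_table()
  rows <- tab[tab$symbol == symbol, ]
  if (nrow(rows) == 0L)
    stop("unknown element symbol: '", symbol, "'", call. = FALSE)
  list(
    symbol = symbol,
    atomic_number = rows$atomic_number[1],
    covalent_radius = rows$covalent_radius[1],
    average_mass = sum(rows$exact_mass * rows$abundance),
    isotopes = rows[, c("mass_number", "exact_mass", "abundance")]
  )
}

# per-element scalar lookups cached as named vectors (hot path: these run
# every MD step)
.element_vectors <- function() {
  if (is.null(.eims_env$vectors)) {
    tab <- isotope_table()
    syms <- unique(tab$symbol)
    .eims_env$vectors <- list(
      radius = vapply(syms, function(s)
        tab$covalent_radius[tab$symbol == s][1], numeric(1)),
      mass = vapply(syms, function(s) {
        r <- tab[tab$symbol == s, ]
        sum(r$exact_mass * r$abundance)
      }, numeric(1)),
      principal = vapply(syms, function(s) {
        r <- tab[tab$symbol == s, ]
        r$mass_number[which.max(r$abundance)]
      }, numeric(1)))
  }
  .eims_env$vectors
}

.element_lookup <- function(vec, symbols) {
  out <- vec[symbols]
  if (anyNA(out))
    stop("unknown element symbol: '",
         paste(unique(symbols[is.na(out)]), collapse = "', '"), "'",
         call. = FALSE)
  unname(out)
}

#' @rdname element_info
#' @details `covalent_radii()` and `atomic_masses()` are vectorized
#'   conveniences over [element_info()].
#' @param symbols Character vector of element symbols.
#' @export
covalent_radii <- function(symbols) {
  .element_lookup(.element_vectors()$radius, symbols)
}

#' @rdname element_info
#' @export
atomic_masses <- function(symbols) {
  .element_lookup(.element_vectors()$mass, symbols)
}

# most abundant isotope's mass number, vectorized; basis of nominal m/z
.principal_mass_number <- function(symbols) {
  .element_lookup(.element_vectors()$principal, symbols)
}
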