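#' Molecular formulas
#'
#' A `formula` is a named integer vector of element counts plus an integer
#' `charge` attribute.  Formulas are kept in Hill order (C first, then H,
#' then other elements alphabetically) so that equal compositions always
#' print and hash identically.
#'
#' @param counts Named integer vector (or named list) of element counts,
#'   all >= 1, or a formula string such as `"C6H5"`, `"CH3"`, `"Fe"`.
#' @param charge Integer total charge (default 0).
#' @return An object of class `formula_ms`.
#' @export
#' @examples
#' ms_formula("C6H5", charge = 1)
#' ms_formula(c(C = 6, H = 6))
ms_formula <- function(counts = integer(0), charge = 0L) {
  if (is.character(counts)) counts <- .parse_formula_string(counts)
  counts <- unlist(counts)
  if (length(counts)) {
    if (is.null(names(counts)) || any(!nzchar(names(counts))))
      stop("counts must be named by element symbol", call. = FALSE)
    storage.mode(counts) <- "integer"
    if (any(counts < 1L)) stop("all element counts must be >= 1", call. = FALSE)
    counts <- counts[.hill_order(names(counts))]
  } else {
    counts <- integer(0)
  }
  structure(counts, charge = as.integer(charge), class = "formula_ms")
}

.hill_order <- function(symbols) {
  rank <- match(symbols, c("C", "H"))
  rank[is.na(rank)] <- 3L
  order(rank, symbols)
}

.parse_formula_string <- function(s) {
  stopifnot(length(s) == 1L)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s, perl = TRUE)[[1]]
  toks <- regmatches(s, list(m))[[1]]
  if (!length(toks) || sum(attr(m, "match.length")) != nchar(s))
    stop("cannot parse formula string: '", s, "'", call. = FALSE)
  counts <- integer(0)
  for (tok in toks) {
    sym <- gsub("[0-9]", "", tok)
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(n)) as.integer(n) else 1L
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + n
  }
  counts
}

#' @export
format.formula_ms <- function(x, ...) {
  if (!length(x)) return("(empty)")
  body <- paste0(names(x), ifelse(unclass(x) > 1L, unclass(x), ""),
                 collapse = "")
  q <- attr(x, "charge")
  if (is.null(q) || q == 0L) body
  else paste0(body, ifelse(q > 0, strrep("+", q), strrep("-", -q)))
}

#' @export
print.formula_ms <- function(x, ...) {
  cat("<formula> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Canonical formula string (Hill order, charge-less)
#'
#' Used as the grouping key when accumulating fragment statistical charges
#' and as the lookup key of table-driven ionization-potential providers.
#'
#' @param f A [ms_formula()] object or a formula string.
#' @return A single string, e.g. `"C6H5"`.
#' @export
formula_key <- function(f) {
  if (is.character(f)) f <- ms_formula(f)
  if (!length(f)) return("(empty)")
  paste0(names(f), ifelse(unclass(f) > 1L, unclass(f), ""), collapse = "")
}

#' Formula of a molecule
#'
#' @param mol A [molecule()].
#' @return [ms_formula()] with the multiset of the molecule's element
#'   symbols and the molecule's total charge.
#' @export
formula_of <- function(mol) {
  stopifnot(inherits(mol, "molecule"))
  tab <- table(mol$symbols)
  ms_formula(stats::setNames(as.integer(tab), names(tab)), charge = mol$charge)
}

#' Nominal m/z of a singly charged formula
#'
#' Sum over elements of count times the mass number of that element's most
#' abundant isotope — the integer labeling convention of low-resolution
#' EI-MS peak lists (phenyl C6H5+ is m/z 77, C5H5Fe+ is m/z 121).
#' Independent of the formula's charge sign; singly charged species
#' assumed.
#'
#' @param f [ms_formula()] or formula string.
#' @return Integer nominal mass-to-charge.
#' @export
#' @examples
#' nominal_mz("C4H9")   # 57
#' nominal_mz("C5H5Fe") # 121
nominal_mz <- function(f) {
  if (is.character(f)) f <- ms_formula(f)
  if (!length(f)) return(0L)
  as.integer(sum(unclass(f) * .principal_mass_number(names(f))))
}

#' Unit-mass isotope pattern of a formula
#'
#' Distributes a formula over its isotopologues by iterative convolution
#' of per-atom isotope distributions on the integer (unit) mass grid,
#' pruning isotopologue mass bins that fall below `prune_threshold`
#' relative to the current most abundant bin.  Natural isotope ratios come
#' from the packaged table; this is the post-simulation isotope treatment
#' applied to accumulated fragment intensities.
#'
#' @param f [ms_formula()] or formula string.
#' @param prune_threshold Fraction in `[0, 1)`; bins below this relative
#'   abundance are dropped after each convolution step.  `0` keeps
#'   everything and conserves total abundance to machine precision.
#' @return data.frame with integer `mz` (ascending) and `abundance`
#'   (fractions summing to 1 up to pruning loss).
#' @export
#' @examples
#' isotope_pattern("Cl")    # 35 and 37 at 0.7576 / 0.2424
#' isotope_pattern("C6H5")
isotope_pattern <- function(f, prune_threshold = 0) {
  if (is.character(f)) f <- ms_formula(f)
  stopifnot(prune_threshold >= 0, prune_threshold < 1)
  # distribution represented as abundance vector over mz = offset + 0:(len-1)
  dist <- list(offset = 0L, ab = 1.0)
  conv <- function(d1, d2) {
    ab <- .convolve_full(d1$ab, d2$ab)
    out <- list(offset = d1$offset + d2$offset, ab = ab)
    if (prune_threshold > 0) {
      keep <- out$ab >= prune_threshold * max(out$ab)
      first <- which(keep)[1]; last <- max(which(keep))
      out$ab <- out$ab[first:last]
      out$ab[!keep[first:last]] <- 0
      out$offset <- out$offset + first - 1L
    }
    out
  }
  for (sym in names(f)) {
    iso <- element_info(sym)$isotopes
    base <- list(offset = iso$mass_number[1],
                 ab = .spread(iso$mass_number, iso$abundance))
    # binary exponentiation over the atom count
    n <- unclass(f)[[sym]]
    pow <- base
    while (TRUE) {
      if (n %% 2L == 1L) dist <- conv(dist, pow)
      n <- n %/% 2L
      if (n == 0L) break
      pow <- conv(pow, pow)
    }
  }
  mz <- dist$offset + seq_along(dist$ab) - 1L
  keep <- dist$ab > 0
  data.frame(mz = as.integer(mz[keep]), abundance = dist$ab[keep])
}

# dense abundance vector over consecutive mass numbers
.spread <- function(mass_numbers, abundances) {
  ab <- numeric(max(mass_numbers) - min(mass_numbers) + 1L)
  ab[mass_numbers - min(mass_numbers) + 1L] <- abundances
  ab
}

.convolve_full <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    if (a[i] == 0) next
    idx <- i:(i + length(b) - 1L)
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

# elementwise sum of two formulas (fragment merging / additivity checks)
#' Combine two formulas by elementwise count addition
#' @param f1,f2 [ms_formula()] objects.
#' @return [ms_formula()] with summed counts and summed charge.
#' @export
formula_union <- function(f1, f2) {
  all_syms <- union(names(f1), names(f2))
  counts <- vapply(all_syms, function(s) {
    n1 <- if (s %in% names(f1)) unclass(f1)[[s]] else 0L
    n2 <- if (s %in% names(f2)) unclass(f2)[[s]] else 0L
    n1 + n2
  }, integer(1))
  ms_formula(counts, charge = attr(f1, "charge") + attr(f2, "charge"))
}
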