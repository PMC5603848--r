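#' Electronic-structure provider contract
#'
#' Every backend — the built-in surrogate or an external engine — is
#' represented as a `provider` object exposing three services:
#'
#' * `energy_gradient(mol, electronic_temperature)` returning
#'   `list(energy = <eV>, gradient = <n x 3 matrix, eV/Angstrom>)`,
#' * `mo_spectrum(mol)` returning an [mo_spectrum()],
#' * `vertical_ip(mol)` returning the vertical ionization potential in eV,
#'
#' plus an optional `subset(idx)` that restricts the provider to a subset
#' of the original atoms (used when a cascade fragment re-enters
#' propagation).  The electronic temperature is a contract parameter that
#' real backends use for Fermi smearing of fractional occupations; the
#' surrogate accepts and ignores it.
#'
#' @param energy_gradient,mo_spectrum,vertical_ip,subset Functions per the
#'   contract; `mo_spectrum`, `vertical_ip` and `subset` may be `NULL`.
#' @param name Backend label used in logs.
#' @return Object of class `provider`.
#' @export
provider <- function(energy_gradient, mo_spectrum = NULL, vertical_ip = NULL,
                     subset = NULL, name = "custom") {
  stopifnot(is.function(energy_gradient))
  structure(list(energy_gradient = energy_gradient, mo_spectrum = mo_spectrum,
                 vertical_ip = vertical_ip, subset = subset, name = name),
            class = "provider")
}

#' @export
print.provider <- function(x, ...) {
  cat("<provider> ", x$name, "\n", sep = "")
  invisible(x)
}

#' Surrogate reactive pair potential
#'
#' A desk-scale stand-in potential-energy surface built from Morse bond
#' terms over a frozen bonded topology plus a short-range exponential
#' repulsion between non-bonded pairs.  The topology is detected once from
#' the reference geometry ([detect_bonds()]), so distant atoms can never
#' spuriously re-bond and fixture fragmentation stays analytically
#' predictable.  On a charged (cation) surface every well depth is scaled
#' by `1 - charge_softening`, so ionization weakens all bonds uniformly —
#' the mechanism by which ionization-heating drives fixtures apart.
#'
#' @param de Named numeric vector of well depths D_e (eV) keyed by element
#'   pair (`"C-H"`; order-insensitive), plus an optional `default`.
#' @param a Morse width parameter(s), 1/Angstrom; named like `de` or a
#'   single value.
#' @param re Optional equilibrium lengths (Angstrom) named like `de`;
#'   defaults to the sum of covalent radii.
#' @param charge_softening Fraction in `[0, 1)` removed from every D_e on
#'   a charged surface (default 0.2).
#' @param repulsion_a,repulsion_rho Non-bonded repulsion
#'   `A * exp(-r / rho)` parameters (eV, Angstrom).
#' @return Object of class `surrogate_params`.
#' @export
surrogate_params <- function(de = c(default = 4), a = c(default = 2),
                             re = NULL, charge_softening = 0.2,
                             repulsion_a = 100, repulsion_rho = 0.08) {
  stopifnot(all(de > 0), all(a > 0), charge_softening >= 0,
            charge_softening < 1)
  if (!is.null(re)) stopifnot(all(re > 0))
  structure(list(de = de, a = a, re = re,
                 charge_softening = charge_softening,
                 repulsion_a = repulsion_a, repulsion_rho = repulsion_rho),
            class = "surrogate_params")
}

.pair_key <- function(s1, s2) {
  paste(pmin(s1, s2), pmax(s1, s2), sep = "-")
}

.pair_param <- function(tab, key, what) {
  if (length(tab) == 1L && is.null(names(tab))) return(tab[[1]])
  if (key %in% names(tab)) return(tab[[key]])
  if ("default" %in% names(tab)) return(tab[["default"]])
  stop("no surrogate ", what, " parameter for pair ", key, call. = FALSE)
}

# precompute per-bond and nonbonded-pair parameter tables for a topology
.surrogate_tables <- function(mol, params, graph) {
  n <- n_atoms(mol)
  edges <- graph$edges
  sym <- mol$symbols
  radii <- covalent_radii(sym)
  bond <- NULL
  if (nrow(edges)) {
    keys <- .pair_key(sym[edges[, 1]], sym[edges[, 2]])
    bond <- list(
      i = as.integer(edges[, 1]), j = as.integer(edges[, 2]),
      de = vapply(keys, .pair_param, numeric(1), tab = params$de, what = "D_e"),
      a = vapply(keys, .pair_param, numeric(1), tab = params$a, what = "a"),
      re = vapply(seq_along(keys), function(k) {
        if (!is.null(params$re) && keys[k] %in% names(params$re))
          params$re[[keys[k]]]
        else radii[edges[k, 1]] + radii[edges[k, 2]]
      }, numeric(1))
    )
  }
  nb <- NULL
  if (n > 1L) {
    all_pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
    bonded <- graph$adjacency[all_pairs]
    nb <- all_pairs[!bonded, , drop = FALSE]
  }
  list(bond = bond, nonbonded = nb)
}

#' Surrogate energy and analytic gradient
#'
#' @param mol A [molecule()]; a nonzero total charge activates the
#'   softened cation surface.
#' @param params A [surrogate_params()].
#' @param graph Frozen `bond_graph`; detected from `mol` if omitted.
#' @param tables Precomputed internal tables (performance path used by the
#'   provider closure); derived from `graph` if omitted.
#' @return `list(energy = <eV>, gradient = <n x 3 eV/Angstrom>)`.
#' @export
surrogate_energy_gradient <- function(mol, params, graph = NULL,
                                      tables = NULL) {
  if (is.null(tables)) {
    if (is.null(graph)) graph <- detect_bonds(mol)
    tables <- .surrogate_tables(mol, params, graph)
  }
  x <- mol$coords
  n <- nrow(x)
  soften <- if (mol$charge != 0L) 1 - params$charge_softening else 1
  energy <- 0
  grad <- matrix(0, n, 3)
  pair_accum <- function(i, j) {
    dx <- x[i, , drop = FALSE] - x[j, , drop = FALSE]
    r <- sqrt(rowSums(dx^2))
    if (any(r < 1e-6)) stop("overlapping atoms (r < 1e-6 Angstrom)",
                            call. = FALSE)
    list(r = r, dir = dx / r)
  }
  b <- tables$bond
  if (!is.null(b) && length(b$i)) {
    pr <- pair_accum(b$i, b$j)
    de <- b$de * soften
    ex <- exp(-b$a * (pr$r - b$re))
    energy <- energy + sum(de * (1 - ex)^2 - de)
    dEdr <- 2 * de * b$a * (1 - ex) * ex
    f <- pr$dir * dEdr
    for (k in seq_along(b$i)) {
      grad[b$i[k], ] <- grad[b$i[k], ] + f[k, ]
      grad[b$j[k], ] <- grad[b$j[k], ] - f[k, ]
    }
  }
  nb <- tables$nonbonded
  if (!is.null(nb) && nrow(nb)) {
    pr <- pair_accum(nb[, 1], nb[, 2])
    er <- params$repulsion_a * exp(-pr$r / params$repulsion_rho)
    energy <- energy + sum(er)
    dEdr <- -er / params$repulsion_rho
    f <- pr$dir * dEdr
    for (k in seq_len(nrow(nb))) {
      grad[nb[k, 1], ] <- grad[nb[k, 1], ] + f[k, ]
      grad[nb[k, 2], ] <- grad[nb[k, 2], ] - f[k, ]
    }
  }
  list(energy = energy, gradient = grad)
}

#' Build a surrogate-PES provider
#'
#' Freezes the bonded topology from the reference geometry and returns a
#' [provider()] whose `energy_gradient` evaluates
#' [surrogate_energy_gradient()] on that topology.  `mo_spectrum` and
#' `vertical_ip` services are attached from the supplied mock providers
#' (they may be `NULL` for pure-PES work).  `subset(idx)` restricts the
#' topology to a fragment's atoms, preserving bond parameters.
#'
#' @param ref_mol Reference [molecule()] whose geometry defines the bonded
#'   topology.
#' @param params [surrogate_params()].
#' @param mo_provider Optional function `mol -> mo_spectrum`.
#' @param ip_provider Optional function `mol -> eV`.
#' @param bond_scale Detection scale `k` for the frozen topology.
#' @return A [provider()].
#' @export
surrogate_provider <- function(ref_mol, params, mo_provider = NULL,
                               ip_provider = NULL, bond_scale = 1.2) {
  build <- function(mol0, graph) {
    tables <- .surrogate_tables(mol0, params, graph)
    provider(
      energy_gradient = function(mol, electronic_temperature = 300) {
        # electronic temperature is accepted per the contract and ignored:
        # the surrogate has no electronic structure to smear
        surrogate_energy_gradient(mol, params, tables = tables)
      },
      mo_spectrum = mo_provider,
      vertical_ip = ip_provider,
      subset = function(idx) {
        sub_adj <- graph$adjacency[idx, idx, drop = FALSE]
        sub_graph <- structure(
          list(adjacency = sub_adj,
               edges = {
                 e <- which(sub_adj & upper.tri(sub_adj), arr.ind = TRUE)
                 colnames(e) <- c("i", "j"); e
               },
               k = graph$k),
          class = "bond_graph")
        build(.subset_molecule(mol0, idx), sub_graph)
      },
      name = "surrogate-morse"
    )
  }
  build(ref_mol, detect_bonds(ref_mol, k = bond_scale))
}

#' Molecular-orbital spectrum container
#'
#' Orbital energies (ascending), the HOMO ordinal and per-orbital per-atom
#' Mulliken populations — the inputs to internal-excess-energy sampling,
#' ionized-orbital selection, internal-conversion times and velocity
#' scaling.
#'
#' @param orbital_energies Numeric vector, eV, ascending.
#' @param populations Matrix (orbitals x atoms) of Mulliken populations;
#'   each occupied orbital's row must sum to `normalization` within 1e-6.
#' @param homo_ordinal Ordinal of the highest occupied orbital; defaults
#'   to the number of orbitals (all occupied).
#' @param normalization Per-orbital population total: 2 for the
#'   doubly-occupied convention (default) or 1.
#' @return Object of class `mo_spectrum`.
#' @export
mo_spectrum <- function(orbital_energies, populations,
                        homo_ordinal = length(orbital_energies),
                        normalization = 2) {
  populations <- as.matrix(populations)
  if (is.unsorted(orbital_energies))
    stop("orbital energies must be ascending", call. = FALSE)
  if (nrow(populations) != length(orbital_energies))
    stop("populations must have one row per orbital", call. = FALSE)
  if (homo_ordinal < 1L || homo_ordinal > length(orbital_energies))
    stop("homo_ordinal out of range", call. = FALSE)
  sums <- rowSums(populations)
  if (any(abs(sums - normalization) > 1e-6))
    stop("orbital population normalization violated (row sums ",
         paste(signif(sums, 6), collapse = ", "), " vs ", normalization, ")",
         call. = FALSE)
  structure(list(orbital_energies = as.numeric(orbital_energies),
                 homo_ordinal = as.integer(homo_ordinal),
                 populations = populations,
                 normalization = normalization),
            class = "mo_spectrum")
}

#' @export
print.mo_spectrum <- function(x, ...) {
  cat(sprintf("<mo_spectrum> %d orbitals, HOMO #%d at %.3f eV\n",
              length(x$orbital_energies), x$homo_ordinal,
              x$orbital_energies[x$homo_ordinal]))
  invisible(x)
}

#' HOMO energy of an MO spectrum
#' @param spec An [mo_spectrum()].
#' @return eV.
#' @export
homo_energy <- function(spec) spec$orbital_energies[spec$homo_ordinal]

#' Mock MO provider from a fixed spectrum
#'
#' Wraps a configured [mo_spectrum()] as the `mo_spectrum` service of a
#' provider: any query molecule receives the same spectrum.  This is the
#' desk-scale stand-in for a backend's single-point MO calculation.
#'
#' @param spec An [mo_spectrum()].
#' @return Function `mol -> mo_spectrum`.
#' @export
mock_mo_provider <- function(spec) {
  stopifnot(inherits(spec, "mo_spectrum"))
  function(mol) spec
}

#' Table-driven vertical ionization potentials
#'
#' Exact lookup by canonical formula key with a constant fallback — the
#' desk-scale stand-in for a backend's delta-SCF vertical IP evaluation.
#' Lookup is independent of element ordering in the query formula.
#'
#' @param table Named numeric vector, eV, keyed by formula strings
#'   (canonicalized internally, so `"H3C"` and `"CH3"` collide correctly).
#' @param fallback IP in eV returned for formulas absent from the table.
#' @return Function `mol_or_formula -> eV` usable as a provider's
#'   `vertical_ip` service.
#' @export
heuristic_ip_provider <- function(table = numeric(0), fallback = 10) {
  if (length(table))
    names(table) <- vapply(names(table), formula_key, character(1))
  function(x) {
    f <- if (inherits(x, "molecule")) formula_of(x)
         else if (is.character(x)) ms_formula(x) else x
    key <- formula_key(f)
    if (key %in% names(table)) unname(table[[key]]) else fallback
  }
}
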