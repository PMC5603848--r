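#' Fixture molecules with analytically predictable fragmentation
#'
#' Desk-scale toy molecules paired with surrogate-PES parameters, a mock
#' MO spectrum and an IP table, designed so each protocol stage has a
#' known outcome: which bond breaks, which fragments form and which
#' moiety keeps the charge are all decided by construction.
#'
#' @name fixtures
NULL

.fixture_spec <- function(name, xyz, params, mo_spec, ip_table, ip_fallback,
                          expected_fragments, design_iee) {
  structure(list(name = name, xyz = xyz, params = params, mo_spec = mo_spec,
                 ip_table = ip_table, ip_fallback = ip_fallback,
                 expected_fragments = expected_fragments,
                 design_iee = design_iee),
            class = "fixture_spec")
}

#' @export
print.fixture_spec <- function(x, ...) {
  cat("<fixture> ", x$name, ": expected fragments ",
      paste(x$expected_fragments, collapse = " + "), "\n", sep = "")
  invisible(x)
}

#' Build the provider for a fixture
#'
#' @param fx A `fixture_spec`.
#' @return List with `mol` (the parsed fixture molecule) and `provider`
#'   (surrogate PES + mock MO + table IPs, topology frozen from the
#'   fixture geometry).
#' @export
fixture_provider <- function(fx) {
  mol <- parse_xyz(fx$xyz)
  prov <- surrogate_provider(
    mol, fx$params,
    mo_provider = mock_mo_provider(fx$mo_spec),
    ip_provider = heuristic_ip_provider(fx$ip_table, fx$ip_fallback))
  list(mol = mol, provider = prov)
}

#' Two-moiety molecule joined by one weak bond
#'
#' A 6-atom CH2–NH2 dimer: strong C–H and N–H bonds, one weak central
#' C–N bond.  Ionization-heating above `de_weak` cleaves the central bond
#' and nothing else, yielding the CH2 and NH2 moieties; the IP table
#' gives NH2 the low IP (7 eV) and CH2 the high one (11 eV) so virtually
#' all charge lands on NH2 at any fragment temperature below a few
#' thousand kelvin.
#'
#' @param de_strong Well depth of the moiety-internal bonds, eV
#'   (default 4.5).
#' @param de_weak Well depth of the central bond, eV (default 1).
#' @return A `fixture_spec`.
#' @export
make_weak_bond_dimer <- function(de_strong = 4.5, de_weak = 1) {
  stopifnot(de_weak < de_strong)
  xyz <- paste(
    "6",
    "weak-bond dimer fixture",
    "C   0.000000  0.000000  0.000000",
    "H  -0.600000  0.800000  0.000000",
    "H  -0.600000 -0.800000  0.000000",
    "N   1.450000  0.000000  0.000000",
    "H   2.050000  0.800000  0.000000",
    "H   2.050000 -0.800000  0.000000",
    sep = "\n")
  params <- surrogate_params(
    de = c("C-H" = de_strong, "H-N" = de_strong - 0.2, "C-N" = de_weak),
    a = c(default = 2),
    re = c("C-H" = 1.0, "H-N" = 1.0, "C-N" = 1.45),
    charge_softening = 0.2)
  # five occupied orbitals; a 4.6 eV HOMO/HOMO-1 gap keeps IC times short
  mo <- mo_spectrum(
    orbital_energies = c(-24.0, -19.4, -16.2, -14.6, -10.0),
    populations = matrix(2 / 6, nrow = 5, ncol = 6),
    homo_ordinal = 5)
  .fixture_spec(
    name = "weak_bond_dimer", xyz = xyz, params = params, mo_spec = mo,
    ip_table = c(CH2 = 11, NH2 = 7, CH4N = 9),
    ip_fallback = 12,
    expected_fragments = c("CH2", "NH2"),
    design_iee = 6)
}

#' Linear chain with graded bond strengths for cascade testing
#'
#' `n_links` bonds of monotonically increasing well depth along a chain
#' of distinct elements, so bonds break weakest-first and fragmentation
#' proceeds through at least two cascade levels.  The IP table assigns
#' lower IPs to larger sub-chains, so the surviving multi-atom fragment
#' always keeps the charge and continues the cascade.
#'
#' @param n_links Number of bonds (>= 2, <= 5).
#' @return A `fixture_spec`.
#' @export
make_cascade_chain <- function(n_links = 3L) {
  stopifnot(n_links >= 2L, n_links <= 5L)
  elems <- c("C", "N", "O", "F", "S", "Cl")[seq_len(n_links + 1L)]
  radii <- covalent_radii(elems)
  spacing <- radii[-length(radii)] + radii[-1]
  xs <- cumsum(c(0, spacing))
  xyz <- paste(c(
    as.character(n_links + 1L),
    "cascade chain fixture",
    sprintf("%-3s %.6f 0.000000 0.000000", elems, xs)), collapse = "\n")
  de <- 0.5 + 0.85 * (seq_len(n_links) - 1L)  # 0.5, 1.35, 2.2, ...
  keys <- .pair_key(elems[-length(elems)], elems[-1])
  mo <- mo_spectrum(
    orbital_energies = c(-24.0, -19.4, -16.2, -14.6, -10.0),
    populations = matrix(2 / (n_links + 1L), nrow = 5, ncol = n_links + 1L),
    homo_ordinal = 5)
  # every contiguous sub-chain gets an IP decreasing with its size
  ip_table <- numeric(0)
  for (len in seq_len(n_links + 1L)) {
    for (start in seq_len(n_links + 2L - len)) {
      sub <- elems[start:(start + len - 1L)]
      key <- formula_key(ms_formula(stats::setNames(
        as.integer(table(sub)), names(table(sub)))))
      ip_table[key] <- 12 - 1.5 * len
    }
  }
  .fixture_spec(
    name = paste0("cascade_chain_", n_links), xyz = xyz,
    params = surrogate_params(de = stats::setNames(de, keys),
                              a = c(default = 2),
                              re = stats::setNames(spacing, keys),
                              charge_softening = 0.2),
    mo_spec = mo,
    ip_table = ip_table, ip_fallback = 12,
    expected_fragments = elems,
    design_iee = 3.5)
}

#' List available fixtures
#' @return Character vector of fixture constructor names.
#' @export
list_fixtures <- function() c("weak_bond_dimer", "cascade_chain")

#' Construct a fixture by name
#' @param name One of [list_fixtures()].
#' @param ... Passed to the fixture constructor.
#' @return A `fixture_spec`.
#' @export
get_fixture <- function(name, ...) {
  switch(name,
         weak_bond_dimer = make_weak_bond_dimer(...),
         cascade_chain = make_cascade_chain(...),
         stop("unknown fixture '", name, "'", call. = FALSE))
}
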