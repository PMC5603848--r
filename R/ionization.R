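#' Internal-excess-energy model
#'
#' After a 70 eV electron impact the molecular ion is left with a
#' stochastic internal excess energy (IEE) that drives its unimolecular
#' decomposition.  The IEE is drawn from a Poisson-like unimodal density
#' whose mode sits at `mode_per_atom` eV per atom and whose support is
#' bounded above by `e_impact - epsilon_HOMO` (the electron cannot deposit
#' more than it brings, minus the energy spent removing the electron).
#' The density implemented here is a mode-anchored gamma with the width
#' knob `a` scaling per atom, truncated at the support bound by rejection;
#' the functional form is pluggable via [sample_iee()]'s `sampler`
#' argument so alternative parametrizations can be dropped in.
#'
#' @param a Width knob, eV per atom (default 0.2): the density's standard
#'   deviation before truncation is `a * n_atoms`.
#' @param b Dimensionless shape knob (default 1.0), multiplying the width.
#' @param mode_per_atom Mode of the density in eV per atom (default 0.6).
#' @param e_impact Impacting electron kinetic energy in eV (default 70,
#'   the standard EI condition).
#' @param epsilon_homo HOMO orbital energy in eV (negative); sets the
#'   support bound `e_impact - epsilon_homo`.
#' @return Object of class `iee_model`.
#' @export
iee_model <- function(a = 0.2, b = 1.0, mode_per_atom = 0.6, e_impact = 70,
                      epsilon_homo = -10) {
  support_max <- e_impact - epsilon_homo
  stopifnot(a > 0, b > 0, mode_per_atom > 0, support_max > 0)
  structure(list(a = a, b = b, mode_per_atom = mode_per_atom,
                 e_impact = e_impact, epsilon_homo = epsilon_homo,
                 support_max = support_max),
            class = "iee_model")
}

#' Draw internal excess energies
#'
#' @param model An [iee_model()].
#' @param n_atoms Number of atoms in the molecular ion.
#' @param n Number of draws.
#' @param sampler Optional replacement density sampler
#'   `function(n, mode, width, support_max)`; the default is the
#'   truncated-gamma described in [iee_model()].
#' @return Numeric vector of IEE values, eV, all in `(0, support_max]`.
#' @export
#' @examples
#' set.seed(1)
#' e <- sample_iee(iee_model(), n_atoms = 20, n = 1000)
#' range(e)
sample_iee <- function(model, n_atoms, n = 1L, sampler = NULL) {
  stopifnot(n_atoms >= 1)
  mode <- model$mode_per_atom * n_atoms
  if (mode >= model$support_max) {
    warning("IEE mode ", mode, " eV at or above support bound ",
            model$support_max, " eV; clipping mode to 0.9 * bound")
    mode <- 0.9 * model$support_max
  }
  width <- model$a * model$b * n_atoms
  if (!is.null(sampler)) return(sampler(n, mode, width, model$support_max))
  # gamma with mode (k-1)*theta and sd sqrt(k)*theta:
  # solve sqrt(k)/(k-1) = width/mode for k, then theta = mode/(k-1)
  rho <- width / mode
  sqrt_k <- (1 + sqrt(1 + 4 * rho^2)) / (2 * rho)
  k <- sqrt_k^2
  theta <- mode / (k - 1)
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rgamma(n - length(out), shape = k, scale = theta)
    out <- c(out, draw[draw > 0 & draw <= model$support_max])
  }
  out
}

#' Select the ionized molecular orbital
#'
#' The impacting electron can eject an electron from any occupied orbital
#' it can energetically reach: orbital `j` is accessible when its binding
#' offset from the HOMO, `eps_M - eps_j`, does not exceed the sampled IEE.
#' Selection is uniform over accessible orbitals (the HOMO is always
#' accessible); the rule is pluggable via `weights_fn`.
#'
#' @param spec An [mo_spectrum()].
#' @param iee Internal excess energy, eV.
#' @param weights_fn Optional `function(offsets)` returning unnormalized
#'   selection weights over the accessible orbitals.
#' @return Integer orbital ordinal `j <= homo_ordinal`.
#' @export
select_ionized_mo <- function(spec, iee, weights_fn = NULL) {
  stopifnot(iee >= 0)
  M <- spec$homo_ordinal
  eps <- spec$orbital_energies
  offsets <- eps[M] - eps[seq_len(M)]
  eligible <- which(offsets <= iee)
  if (!length(eligible)) eligible <- M
  if (length(eligible) == 1L) return(eligible[[1]])
  w <- if (is.null(weights_fn)) rep(1, length(eligible))
       else weights_fn(offsets[eligible])
  sample(eligible, 1L, prob = w)
}

#' Internal-conversion time from the energy-gap law
#'
#' The excited ion relaxes to a hot electronic ground state over a time
#' that shrinks exponentially with the electronic energy gap — here the
#' binding offset of the ionized orbital from the HOMO:
#' `t = k_h * exp(-alpha * (eps_M - eps_j))`.  With the defaults
#' (`alpha` 0.5 1/eV, `k_h` 2 ps) typical valence gaps give conversion
#' windows of 0.2–3 ps.  Clamped to `[dt, 10 ps]`.
#'
#' @param spec An [mo_spectrum()].
#' @param j Ionized orbital ordinal (`1 <= j <= homo_ordinal`).
#' @param alpha Gap-law exponent, 1/eV (default 0.5).
#' @param k_h Zero-gap conversion time, ps (default 2).
#' @param dt Integration time step, fs (lower clamp; default 0.5).
#' @return IC time in fs.
#' @export
ic_time <- function(spec, j, alpha = 0.5, k_h = 2, dt = 0.5) {
  M <- spec$homo_ordinal
  stopifnot(j >= 1, j <= M)
  gap <- spec$orbital_energies[M] - spec$orbital_energies[j]
  t_fs <- k_h * 1000 * exp(-alpha * gap)
  min(max(t_fs, dt), 10000)
}

#' Per-atom velocity scaling factors from the ionized orbital
#'
#' Ionizing a localized orbital should kick the nuclei near it: each
#' atom's heating weight is proportional to its Mulliken population in
#' the ionized orbital.  For molecules of 35 atoms or more the factors
#' are set to unity (localized initial states are a poor description of
#' larger systems).  Factors are normalized to mean 1 so uniform
#' populations heat every atom equally; exact per-step energy deposition
#' is enforced by the heating plan, not the factors.
#'
#' @param spec An [mo_spectrum()].
#' @param j Ionized orbital ordinal.
#' @param n_atoms Atom count of the molecule being heated.
#' @return Numeric vector of `n_atoms` nonnegative factors.
#' @export
velocity_scale_factors <- function(spec, j, n_atoms) {
  if (n_atoms >= 35L) return(rep(1, n_atoms))
  pops <- spec$populations[j, ]
  if (length(pops) != n_atoms)
    stop("population vector length ", length(pops),
         " does not match atom count ", n_atoms, call. = FALSE)
  pops <- pmax(pops, 0)
  if (sum(pops) <= 0) return(rep(1, n_atoms))
  pops / mean(pops)
}

#' Build the ionization heating plan
#'
#' The IEE is converted into nuclear kinetic energy over the internal
#' conversion window: `ceil(t_ic / dt)` equal per-step energy increments
#' that sum exactly to the IEE, each realized by scaling velocities
#' (weighted by the per-atom factors) so the kinetic-energy gain matches.
#'
#' @param iee Internal excess energy, eV (>= 0).
#' @param t_ic Internal conversion time, fs (>= dt).
#' @param dt Time step, fs.
#' @param factors Per-atom scale factors from [velocity_scale_factors()].
#' @return Object of class `heating_plan` with fields `n_steps`,
#'   `increment` (eV per step), `iee`, `factors`.
#' @export
build_heating_plan <- function(iee, t_ic, dt, factors) {
  if (iee < 0) stop("iee must be >= 0", call. = FALSE)
  stopifnot(t_ic >= dt)
  n_steps <- as.integer(ceiling(t_ic / dt - 1e-9))
  structure(list(n_steps = if (iee > 0) n_steps else 0L,
                 increment = if (iee > 0) iee / n_steps else 0,
                 iee = iee, factors = factors),
            class = "heating_plan")
}

# Scale velocities so total kinetic energy increases by `inc` eV, with the
# velocity change of atom A proportional to factors[A].  Solves the
# quadratic in the scaling amplitude lambda:
#   sum 1/2 m |v (1 + lambda f)|^2 = KE0 + inc.
# Falls back to uniform factors when the weighted atoms carry no kinetic
# energy, and to a deterministic unit-kick pattern when the molecule is
# completely frozen.
.apply_heating_increment <- function(mol, inc, factors) {
  if (inc <= 0) return(mol)
  m <- atomic_masses(mol$symbols)
  v <- mol$velocities
  f <- factors
  B <- sum(m * rowSums(v^2) * f) * .EV_KIN          # linear coefficient
  A <- 0.5 * sum(m * rowSums(v^2) * f^2) * .EV_KIN  # quadratic coefficient
  if (A < 1e-14) {
    f <- rep(1, nrow(v))
    B <- sum(m * rowSums(v^2)) * .EV_KIN
    A <- 0.5 * B
  }
  if (A < 1e-14) {
    # frozen molecule: seed an alternating-axis unit pattern with zero net
    # momentum, then rescale it to carry exactly `inc`
    n <- nrow(v)
    seedv <- matrix(0, n, 3)
    for (i in seq_len(n)) seedv[i, (i - 1L) %% 3L + 1L] <- (-1)^i
    seedv <- sweep(seedv, 2, colSums(seedv * m) / sum(m))
    ke <- 0.5 * sum(m * rowSums(seedv^2)) * .EV_KIN
    mol$velocities <- seedv * sqrt(inc / ke)
    return(mol)
  }
  lambda <- (-B + sqrt(B^2 + 4 * A * inc)) / (2 * A)
  mol$velocities <- v * (1 + lambda * f)
  mol
}
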