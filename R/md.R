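#' MD state container
#'
#' @param mol A [molecule()].
#' @param time Simulation time, fs.
#' @param provider Optional [provider()] used to fill in the potential
#'   energy; kinetic energy is computed from the velocities.
#' @param electronic_temperature Forwarded to the provider, K.
#' @return Object of class `md_state` with `mol`, `time`,
#'   `kinetic_energy`, `potential_energy` (eV) and the cached
#'   acceleration.
#' @export
md_state <- function(mol, time = 0, provider = NULL,
                     electronic_temperature = 300) {
  ke <- kinetic_energy(mol)
  pe <- NA_real_
  acc <- NULL
  if (!is.null(provider)) {
    eg <- provider$energy_gradient(mol, electronic_temperature)
    pe <- eg$energy
    acc <- .acceleration(mol, eg$gradient)
  }
  structure(list(mol = mol, time = time, kinetic_energy = ke,
                 potential_energy = pe, acceleration = acc),
            class = "md_state")
}

#' Kinetic energy of a molecule, eV
#' @param mol A [molecule()].
#' @export
kinetic_energy <- function(mol) {
  m <- atomic_masses(mol$symbols)
  0.5 * sum(m * rowSums(mol$velocities^2)) * .EV_KIN
}

#' Instantaneous kinetic temperature, K
#'
#' Uses the thermostat convention of `3N` degrees of freedom (the same
#' convention the velocity-rescaling thermostat targets); fragment
#' internal temperatures use [fragment_temperature()] instead.
#'
#' @param mol A [molecule()].
#' @export
instantaneous_temperature <- function(mol) {
  2 * kinetic_energy(mol) / (3 * n_atoms(mol) * .KB)
}

# gradient (eV/Angstrom) -> acceleration (Angstrom/fs^2)
.acceleration <- function(mol, gradient) {
  m <- atomic_masses(mol$symbols)
  -gradient / (m * .EV_KIN)
}

#' One leap-frog integration step
#'
#' Leap-frog in its synchronized kick-drift-kick form (algebraically the
#' same trajectory as the classic half-step-offset formulation, with
#' velocities and energies well defined at integer steps): half kick,
#' full drift, force refresh, half kick.
#'
#' @param state An [md_state()] carrying a cached acceleration.
#' @param provider A [provider()].
#' @param dt Time step, fs (> 0).
#' @param electronic_temperature K, forwarded to the provider.
#' @return The advanced [md_state()].
#' @export
leapfrog_step <- function(state, provider, dt,
                          electronic_temperature = 300) {
  stopifnot(dt > 0)
  mol <- state$mol
  acc <- state$acceleration
  if (is.null(acc)) {
    eg <- .provider_eval(provider, mol, electronic_temperature, state$time)
    acc <- .acceleration(mol, eg$gradient)
  }
  v_half <- mol$velocities + 0.5 * dt * acc
  mol$coords <- mol$coords + dt * v_half
  eg <- .provider_eval(provider, mol, electronic_temperature, state$time)
  acc_new <- .acceleration(mol, eg$gradient)
  mol$velocities <- v_half + 0.5 * dt * acc_new
  structure(list(mol = mol, time = state$time + dt,
                 kinetic_energy = kinetic_energy(mol),
                 potential_energy = eg$energy, acceleration = acc_new),
            class = "md_state")
}

# provider call with step context attached to any failure
.provider_eval <- function(provider, mol, electronic_temperature, time) {
  tryCatch(
    provider$energy_gradient(mol, electronic_temperature),
    error = function(e) {
      stop(structure(
        class = c("provider_failure", "error", "condition"),
        list(message = paste0("provider failure at t=", time, " fs: ",
                              conditionMessage(e)),
             call = NULL)))
    })
}

#' Maxwell–Boltzmann velocity initialization
#'
#' Per-component normal draws at temperature `T` with the center-of-mass
#' momentum removed.
#'
#' @param mol A [molecule()].
#' @param T Temperature, K.
#' @return The molecule with initialized velocities.
#' @export
init_velocities <- function(mol, T) {
  m <- atomic_masses(mol$symbols)
  sigma <- sqrt(.KB * T / (m * .EV_KIN))
  v <- matrix(stats::rnorm(3 * n_atoms(mol)), ncol = 3) * sigma
  v <- sweep(v, 2, colSums(v * m) / sum(m))
  mol$velocities <- v
  mol
}

#' NVT equilibration with a Berendsen thermostat
#'
#' Velocities are initialized Maxwell–Boltzmann from the seed, then the
#' system is propagated with per-step Berendsen velocity rescaling
#' (coupling constant `tau`, default 100 fs) toward the set-point
#' temperature.
#'
#' @param mol A [molecule()] (velocities are re-initialized).
#' @param provider A [provider()].
#' @param T Set-point temperature, K.
#' @param duration Equilibration length, fs (>= dt, or 0 for
#'   initialization only).
#' @param dt Time step, fs.
#' @param seed Integer RNG seed.
#' @param tau Berendsen coupling constant, fs.
#' @param electronic_temperature K, forwarded to the provider.
#' @return Final [md_state()], with attribute `temperature_trace` (the
#'   per-step instantaneous temperatures).
#' @export
equilibrate_nvt <- function(mol, provider, T, duration, dt = 0.5,
                            seed = 1L, tau = 100,
                            electronic_temperature = 300) {
  set.seed(seed)
  mol <- init_velocities(mol, T)
  state <- md_state(mol, 0, provider, electronic_temperature)
  n_steps <- floor(duration / dt + 1e-9)
  trace <- numeric(n_steps)
  for (s in seq_len(n_steps)) {
    state <- leapfrog_step(state, provider, dt, electronic_temperature)
    t_inst <- instantaneous_temperature(state$mol)
    trace[s] <- t_inst
    if (t_inst > 1e-12) {
      lambda <- sqrt(1 + dt / tau * (T / t_inst - 1))
      state$mol$velocities <- state$mol$velocities * lambda
      state$kinetic_energy <- kinetic_energy(state$mol)
    }
  }
  attr(state, "temperature_trace") <- trace
  state
}

#' Sample snapshots along an NVE trajectory
#'
#' Propagates `duration` fs in the microcanonical ensemble and returns
#' `n` states (geometry and velocities) at step indices drawn uniformly
#' at random without replacement, in increasing time order.
#'
#' @param traj_spec List with `duration` (fs) and `n` (snapshot count).
#' @param state0 Starting [md_state()] (e.g. from [equilibrate_nvt()]).
#' @param provider A [provider()].
#' @param dt Time step, fs.
#' @param seed Integer RNG seed for the index draw.
#' @param electronic_temperature K, forwarded to the provider.
#' @return List of `n` [md_state()]s with strictly increasing times.
#' @export
sample_snapshots <- function(traj_spec, state0, provider, dt = 0.5,
                             seed = 1L, electronic_temperature = 300) {
  n <- traj_spec$n
  stopifnot(n >= 1, traj_spec$duration >= n * dt)
  n_steps <- floor(traj_spec$duration / dt + 1e-9)
  if (n > n_steps)
    stop("requested ", n, " snapshots from ", n_steps, " steps", call. = FALSE)
  set.seed(seed)
  picks <- sort(sample.int(n_steps, n))
  out <- vector("list", n)
  state <- state0
  nxt <- 1L
  for (s in seq_len(n_steps)) {
    state <- leapfrog_step(state, provider, dt, electronic_temperature)
    if (nxt <= n && s == picks[nxt]) {
      out[[nxt]] <- state
      nxt <- nxt + 1L
    }
    if (nxt > n) break
  }
  out
}
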