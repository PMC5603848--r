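#' Default run configuration
#'
#' Returns the full protocol configuration as a nested list with the
#' standard EI simulation defaults: 0.5 fs time step; 12.5 ps NVT
#' equilibration at 500 K; 25 ps NVE sampling of 1000 snapshots; 70 eV
#' impact energy; 1000 production runs capped at 10 ps each; electronic
#' temperatures 300 K (ground-state stages) and 5000 K (production).
#' Every entry can be overridden via `...` (nested lists are merged) or
#' by a YAML configuration file ([read_run_config()]).
#'
#' @param ... Named overrides merged into the defaults, e.g.
#'   `md = list(dt = 0.25)`.
#' @return Nested configuration list.
#' @export
default_run_config <- function(...) {
  cfg <- list(
    e_impact = 70,            # eV, standard EI condition
    n_runs = 1000L,
    workers = 1L,
    master_seed = 1L,
    md = list(
      dt = 0.5,               # fs
      equilibration = list(T = 500, duration = 12500),   # K, fs
      sampling = list(duration = 25000, n_snapshots = 1000L),
      production = list(max_time = 10000),               # fs
      thermostat_tau = 100,   # fs, Berendsen coupling
      check_interval = 20L,   # steps between fragmentation checks
      persistence = 3L,       # consecutive checks before a split counts
      depth_cap = 6L,
      bond_scale = 1.2
    ),
    ionization = list(
      a = 0.2, b = 1.0,       # IEE width/shape knobs (eV/atom, -)
      mode_per_atom = 0.6,    # eV per atom
      ic_alpha = 0.5,         # 1/eV
      ic_k_h = 2,             # ps
      fixed_iee = NULL        # set a number to bypass IEE sampling
    ),
    electronic_temperature = list(ground = 300, production = 5000),
    spectrum = list(prune = 1e-4, write_prune_percent = 0.1)
  )
  utils::modifyList(cfg, list(...))
}

#' Read a YAML run configuration
#'
#' The file carries the same nested sections as
#' [default_run_config()] (`md`, `ionization`,
#' `electronic_temperature`, `spectrum`); unspecified entries keep
#' their defaults.
#'
#' @param path YAML file path.
#' @return Nested configuration list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  utils::modifyList(default_run_config(), user)
}

#' Run the full EI-MS simulation protocol
#'
#' Stages: (i) NVT equilibration of the neutral molecule and NVE
#' conformer sampling; (ii) MO spectrum from the provider; (iii)
#' `n_runs` production runs, each drawing an IEE, an ionized orbital and
#' a starting conformer from its own deterministically derived seed,
#' followed by charge accumulation and isotope convolution.  Runs are
#' embarrassingly parallel; because every run owns its seed and the
#' charge reduction is an order-independent sum, the spectrum is
#' identical for any worker count.  Failed runs (provider errors) are
#' counted, never silently dropped; more than 50% failures aborts.
#'
#' @param mol A [molecule()], or a `fixture_spec` (whose provider is then
#'   built automatically).
#' @param provider A [provider()]; ignored when `mol` is a fixture.
#' @param config Configuration list from [default_run_config()] /
#'   [read_run_config()].
#' @return List with `spectrum` (a `mass_spectrum`), `report` (class
#'   `run_report`: `n_runs`, `n_success`, `n_failed`,
#'   `failure_fraction`, `seeds`), `accumulated` (raw charge map) and
#'   `results` (per-run `production_result`s).
#' @export
run_protocol <- function(mol, provider = NULL, config = default_run_config()) {
  if (inherits(mol, "fixture_spec")) {
    fp <- fixture_provider(mol)
    mol <- fp$mol; provider <- fp$provider
  }
  if (is.null(provider)) stop("no provider available", call. = FALSE)
  cfg <- config
  dt <- cfg$md$dt
  et_ground <- cfg$electronic_temperature$ground
  et_prod <- cfg$electronic_temperature$production

  # stage i: equilibration + conformer sampling
  eq <- equilibrate_nvt(mol, provider, T = cfg$md$equilibration$T,
                        duration = cfg$md$equilibration$duration, dt = dt,
                        seed = derive_seed(cfg$master_seed, 0L),
                        tau = cfg$md$thermostat_tau,
                        electronic_temperature = et_ground)
  snaps <- sample_snapshots(
    list(duration = cfg$md$sampling$duration,
         n = cfg$md$sampling$n_snapshots),
    eq, provider, dt = dt, seed = derive_seed(cfg$master_seed, 1L),
    electronic_temperature = et_ground)

  # stage ii: MO spectrum of the neutral at its sampled geometry
  spec <- provider$mo_spectrum(mol)
  model <- iee_model(a = cfg$ionization$a, b = cfg$ionization$b,
                     mode_per_atom = cfg$ionization$mode_per_atom,
                     e_impact = cfg$e_impact,
                     epsilon_homo = homo_energy(spec))

  # stage iii: production runs (embarrassingly parallel)
  prod_cfg <- list(check_interval = cfg$md$check_interval,
                   persistence = cfg$md$persistence,
                   depth_cap = cfg$md$depth_cap,
                   bond_scale = cfg$md$bond_scale,
                   electronic_temperature = et_prod,
                   ic_alpha = cfg$ionization$ic_alpha,
                   ic_k_h = cfg$ionization$ic_k_h)
  seeds <- vapply(seq_len(cfg$n_runs), function(i)
    derive_seed(cfg$master_seed, i + 1L), integer(1))
  one_run <- function(i) {
    set.seed(seeds[i])
    snap <- snaps[[sample.int(length(snaps), 1L)]]
    iee <- cfg$ionization$fixed_iee %||%
      sample_iee(model, n_atoms(snap$mol), 1L)
    j <- select_ionized_mo(spec, iee)
    run_production(snap, provider, iee = iee, ionized_mo = j,
                   max_time = cfg$md$production$max_time, dt = dt,
                   seed = seeds[i], config = prod_cfg)
  }
  results <- if (cfg$workers > 1L) {
    parallel::mclapply(seq_len(cfg$n_runs), one_run,
                       mc.cores = cfg$workers, mc.set.seed = FALSE)
  } else {
    lapply(seq_len(cfg$n_runs), one_run)
  }
  failed <- vapply(results, function(r)
    inherits(r, "try-error") || !inherits(r, "production_result") ||
      r$terminated_by == "provider_failure", logical(1))
  n_failed <- sum(failed)
  if (n_failed > cfg$n_runs / 2)
    stop("more than 50% of production runs failed (",
         n_failed, "/", cfg$n_runs, "); aborting", call. = FALSE)

  accum <- accumulate_charges(results[!failed])
  spectrum <- convolve_and_bin(accum, prune = cfg$spectrum$prune)
  report <- structure(list(n_runs = cfg$n_runs,
                           n_success = cfg$n_runs - n_failed,
                           n_failed = n_failed,
                           failure_fraction = n_failed / cfg$n_runs,
                           seeds = seeds),
                      class = "run_report")
  list(spectrum = spectrum, report = report, accumulated = accum,
       results = results)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d runs: %d ok, %d failed (%.1f%% unsuccessful)\n",
              x$n_runs, x$n_success, x$n_failed, 100 * x$failure_fraction))
  invisible(x)
}

#' Derive a per-run seed from the master seed
#'
#' Deterministic 31-bit mixing of `(master_seed, index)`, so results are
#' reproducible and independent of how runs are scheduled across
#' workers.
#'
#' @param master_seed Integer master seed.
#' @param index Nonnegative run index.
#' @return Integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master_seed, index) {
  m <- 2147483647  # 2^31 - 1, Mersenne prime used by Lehmer generators
  s <- (as.numeric(master_seed) %% m) * 48271 + as.numeric(index) * 16807 + 1
  as.integer(s %% m + 1)
}
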