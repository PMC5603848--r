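#' One production run: heated ion dynamics with fragmentation cascades
#'
#' The sampled neutral conformer is instantaneously ionized (charge +1),
#' heated over the internal-conversion window by per-step velocity
#' scaling that deposits the sampled internal excess energy, and
#' propagated for up to `max_time` fs.  Fragmentation is tested every
#' `check_interval` steps by geometric bond detection; a split must
#' persist (identical atom partition) for `persistence` consecutive
#' checks before it is accepted, so transient bond stretches do not
#' count.  On an accepted split, fragment temperatures and vertical IPs
#' are evaluated, statistical charges assigned
#' ([statistical_weights()]), non-selected fragments stored, and the
#' highest-charge fragment re-enters propagation as a cascade with a
#' fresh `max_time` budget, its weight multiplying all deeper weights.
#' If nothing fragments before `max_time`, the intact ion is stored with
#' the full weight it carried in.
#'
#' @param snapshot An [md_state()] from conformer sampling (the molecule
#'   is re-charged to +1 here).
#' @param provider A [provider()] with `mo_spectrum` and `vertical_ip`
#'   services (the surrogate provider's `subset` service is used to
#'   restrict the topology to cascade fragments).
#' @param iee Internal excess energy to deposit, eV.
#' @param ionized_mo Ordinal of the ionized orbital (from
#'   [select_ionized_mo()]).
#' @param max_time Per-cascade-level time budget, fs (default 10000).
#' @param dt Time step, fs (default 0.5).
#' @param seed Integer seed (the run itself is deterministic; the seed
#'   pins any pluggable stochastic hooks).
#' @param config Optional list overriding `check_interval` (steps, 20),
#'   `persistence` (checks, 3), `depth_cap` (6), `bond_scale` (1.2),
#'   `electronic_temperature` (K, 5000), `ic_alpha`, `ic_k_h`.
#' @return Object of class `production_result`: `fragment_records`,
#'   `n_steps`, `terminated_by` (one of `"no_fragmentation_timeout"`,
#'   `"cascade_complete"`, `"provider_failure"`), and `events` (one row
#'   per fragmentation event).
#' @export
run_production <- function(snapshot, provider, iee, ionized_mo,
                           max_time = 10000, dt = 0.5, seed = 1L,
                           config = list()) {
  stopifnot(iee >= 0)
  cfg <- utils::modifyList(list(check_interval = 20L, persistence = 3L,
                                depth_cap = 6L, bond_scale = 1.2,
                                electronic_temperature = 5000,
                                ic_alpha = 0.5, ic_k_h = 2), config)
  set.seed(seed)
  mol <- snapshot$mol
  mol$charge <- 1L
  spec <- provider$mo_spectrum(mol)
  t_ic <- ic_time(spec, ionized_mo, alpha = cfg$ic_alpha, k_h = cfg$ic_k_h,
                  dt = dt)
  factors <- velocity_scale_factors(spec, ionized_mo, n_atoms(mol))
  plan <- build_heating_plan(iee, t_ic, dt, factors)

  records <- list()
  events <- list()
  total_steps <- 0L

  propagate_level <- function(mol, prov, weight, depth, plan) {
    # returns list(records, next_level or NULL, steps, failed)
    state <- tryCatch(
      md_state(mol, 0, prov, cfg$electronic_temperature),
      error = function(e) e)
    if (inherits(state, "error")) return(list(failed = conditionMessage(state)))
    n_steps_max <- as.integer(floor(max_time / dt + 1e-9))
    heat_left <- if (is.null(plan)) 0L else plan$n_steps
    pending_partition <- NULL
    pending_count <- 0L
    steps <- 0L
    while (steps < n_steps_max) {
      state <- tryCatch(
        leapfrog_step(state, prov, dt, cfg$electronic_temperature),
        error = function(e) e)
      if (inherits(state, "error"))
        return(list(failed = conditionMessage(state), steps = steps))
      steps <- steps + 1L
      if (heat_left > 0L) {
        state$mol <- .apply_heating_increment(state$mol, plan$increment,
                                              plan$factors)
        state$kinetic_energy <- kinetic_energy(state$mol)
        heat_left <- heat_left - 1L
      }
      if (steps %% cfg$check_interval == 0L) {
        g <- detect_bonds(state$mol, k = cfg$bond_scale)
        labels <- .components(g$adjacency)
        if (max(labels) > 1L) {
          if (!is.null(pending_partition) &&
              identical(labels, pending_partition)) {
            pending_count <- pending_count + 1L
          } else {
            pending_partition <- labels
            pending_count <- 1L
          }
          if (pending_count >= cfg$persistence) {
            frags <- split_fragments(state$mol, g)
            recs <- lapply(frags, function(fr) {
              fragment_record(
                fr,
                vertical_ip = provider$vertical_ip(fr),
                temperature = fragment_temperature(fr),
                cascade_depth = depth)
            })
            asg <- assign_and_select(recs, weight, depth_cap = cfg$depth_cap)
            nxt <- NULL
            if (!is.null(asg$next_record)) {
              idx <- attr(asg$next_record$mol, "atom_indices")
              sub_prov <- if (!is.null(prov$subset)) prov$subset(idx) else prov
              nxt <- list(mol = asg$next_record$mol, prov = sub_prov,
                          weight = asg$next_record$statistical_charge,
                          depth = depth + 1L)
            }
            return(list(records = asg$records, next_level = nxt,
                        steps = steps, failed = NULL))
          }
        } else {
          pending_partition <- NULL
          pending_count <- 0L
        }
      }
    }
    # intact for the whole budget: the ion survives with its full weight
    survivor <- fragment_record(
      state$mol,
      vertical_ip = tryCatch(provider$vertical_ip(state$mol),
                             error = function(e) NA_real_),
      temperature = fragment_temperature(state$mol),
      statistical_charge = weight,
      cascade_depth = depth)
    list(records = list(survivor), next_level = NULL, steps = steps,
         failed = NULL, timeout = TRUE)
  }

  level <- list(mol = mol, prov = provider, weight = 1.0, depth = 0L)
  lvl_plan <- plan
  timeout_seen <- FALSE
  while (!is.null(level)) {
    res <- propagate_level(level$mol, level$prov, level$weight, level$depth,
                           lvl_plan)
    lvl_plan <- NULL  # only the parent ion is heated
    total_steps <- total_steps + (res$steps %||% 0L)
    if (!is.null(res$failed)) {
      return(structure(list(fragment_records = list(), n_steps = total_steps,
                            terminated_by = "provider_failure",
                            error = res$failed, events = events),
                       class = "production_result"))
    }
    records <- c(records, res$records)
    if (isTRUE(res$timeout) && level$depth == 0L) timeout_seen <- TRUE
    if (!is.null(res$next_level)) {
      events[[length(events) + 1L]] <- list(
        depth = level$depth, time_fs = res$steps * dt,
        formulas = vapply(c(res$records, list(structure(
          list(formula = formula_of(res$next_level$mol)), class = "fragment_record"))),
          function(r) formula_key(r$formula), character(1)))
    }
    level <- res$next_level
  }
  structure(list(fragment_records = records, n_steps = total_steps,
                 terminated_by = if (timeout_seen) "no_fragmentation_timeout"
                                 else "cascade_complete",
                 events = events),
            class = "production_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.production_result <- function(x, ...) {
  cat("<production_result> ", length(x$fragment_records), " records, ",
      x$n_steps, " steps, ", x$terminated_by, "\n", sep = "")
  for (r in x$fragment_records)
    cat(sprintf("  %-12s q=%.4f depth=%d\n", formula_key(r$formula),
                r$statistical_charge, r$cascade_depth))
  invisible(x)
}
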