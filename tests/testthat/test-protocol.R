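# Production runs and full-protocol orchestration on the designed fixtures.
# Short MD budgets are used throughout: the fixtures are built to fragment
# within a few hundred femtoseconds of the heating window.

fast_cfg <- function(...) {
  default_run_config(
    n_runs = 6L, master_seed = 42L,
    md = list(equilibration = list(T = 400, duration = 200),
              sampling = list(duration = 300, n_snapshots = 6L),
              production = list(max_time = 1200)),
    ...)
}

test_that("a cold ion survives the production run intact", {
  fx <- make_weak_bond_dimer()
  fp <- fixture_provider(fx)
  snap <- md_state(fp$mol, 0, fp$provider)
  res <- run_production(snap, fp$provider, iee = 0, ionized_mo = 5,
                        max_time = 400, dt = 0.5, seed = 1)
  expect_s3_class(res, "production_result")
  expect_equal(res$terminated_by, "no_fragmentation_timeout")
  expect_length(res$fragment_records, 1L)
  rec <- res$fragment_records[[1]]
  expect_equal(formula_key(rec$formula), "CH4N")
  expect_equal(rec$statistical_charge, 1.0)
})

test_that("heating far above the weak well forces the designed dissociation", {
  fx <- make_weak_bond_dimer()
  fp <- fixture_provider(fx)
  snap <- md_state(fp$mol, 0, fp$provider)
  res <- run_production(snap, fp$provider, iee = fx$design_iee,
                        ionized_mo = 4, max_time = 1500, dt = 0.5, seed = 7)
  expect_gte(length(res$fragment_records), 2L)
  keys <- sort(vapply(res$fragment_records,
                      function(r) formula_key(r$formula), character(1)))
  nh2 <- formula_key("NH2")  # canonical (Hill) key: H before N sans carbon
  expect_equal(keys, sort(c("CH2", nh2)))
  # charge conservation across the whole run
  q <- vapply(res$fragment_records, function(r) r$statistical_charge,
              numeric(1))
  expect_equal(sum(q), 1.0, tolerance = 1e-9)
  # the low-IP moiety (NH2 at 7 eV vs CH2 at 11 eV) dominates
  expect_gt(q[keys == nh2], 0.95)
})

test_that("production runs conserve the parent's atoms", {
  fx <- make_weak_bond_dimer()
  fp <- fixture_provider(fx)
  snap <- md_state(fp$mol, 0, fp$provider)
  for (iee in c(0, 3, 6)) {
    res <- run_production(snap, fp$provider, iee = iee, ionized_mo = 4,
                          max_time = 1000, dt = 0.5, seed = 11)
    syms <- sort(unlist(lapply(res$fragment_records,
                               function(r) r$mol$symbols)))
    expect_equal(syms, sort(fp$mol$symbols))
  }
})

test_that("identical seeds and config reproduce a production run exactly", {
  fx <- make_weak_bond_dimer()
  fp <- fixture_provider(fx)
  st <- equilibrate_nvt(fp$mol, fp$provider, T = 400, duration = 100,
                        dt = 0.5, seed = 3)
  r1 <- run_production(st, fp$provider, iee = 5.5, ionized_mo = 4,
                       max_time = 800, dt = 0.5, seed = 19)
  r2 <- run_production(st, fp$provider, iee = 5.5, ionized_mo = 4,
                       max_time = 800, dt = 0.5, seed = 19)
  expect_identical(
    lapply(r1$fragment_records, function(r) r$mol$coords),
    lapply(r2$fragment_records, function(r) r$mol$coords))
  expect_identical(
    vapply(r1$fragment_records, function(r) r$statistical_charge, numeric(1)),
    vapply(r2$fragment_records, function(r) r$statistical_charge, numeric(1)))
})

test_that("provider failures terminate the run as unsuccessful", {
  fx <- make_weak_bond_dimer()
  fp <- fixture_provider(fx)
  calls <- 0L
  flaky <- provider(
    energy_gradient = function(mol, electronic_temperature = 300) {
      calls <<- calls + 1L
      if (calls > 30L) stop("SCC did not converge")
      fp$provider$energy_gradient(mol, electronic_temperature)
    },
    mo_spectrum = fp$provider$mo_spectrum,
    vertical_ip = fp$provider$vertical_ip,
    name = "flaky")
  snap <- md_state(fp$mol, 0, fp$provider)
  res <- run_production(snap, flaky, iee = 2, ionized_mo = 5,
                        max_time = 500, dt = 0.5, seed = 1)
  expect_equal(res$terminated_by, "provider_failure")
  expect_length(res$fragment_records, 0L)
  expect_match(res$error, "SCC did not converge")
})

test_that("the graded-bond chain cascades through at least two levels", {
  fx <- make_cascade_chain(3)
  fp <- fixture_provider(fx)
  snap <- md_state(fp$mol, 0, fp$provider)
  res <- run_production(snap, fp$provider, iee = fx$design_iee,
                        ionized_mo = 4, max_time = 1500, dt = 0.5, seed = 1)
  depths <- vapply(res$fragment_records, function(r) r$cascade_depth,
                   integer(1))
  expect_gte(max(depths), 2L)
  q <- vapply(res$fragment_records, function(r) r$statistical_charge,
              numeric(1))
  expect_equal(sum(q), 1.0, tolerance = 1e-9)
  # the deepest survivor's charge is the product of its stage weights,
  # hence strictly below any single-stage weight yet still the largest
  expect_equal(formula_key(res$fragment_records[[which.max(depths)]]$formula),
               "FO")
})

test_that("the full protocol is deterministic and worker-count independent", {
  fx <- make_weak_bond_dimer()
  cfg <- fast_cfg()
  res1 <- run_protocol(fx, config = cfg)
  cfg$workers <- 2L
  res2 <- run_protocol(fx, config = cfg)
  expect_identical(res1$spectrum$sticks, res2$spectrum$sticks)
  expect_identical(res1$accumulated, res2$accumulated)

  # and a different master seed gives a different (but valid) outcome
  cfg3 <- fast_cfg(); cfg3$master_seed <- 43L
  res3 <- run_protocol(fx, config = cfg3)
  expect_equal(sum(res3$accumulated), res3$report$n_success,
               tolerance = 1e-6)
})

test_that("forcing IEE to zero yields a parent-ion-only spectrum", {
  fx <- make_weak_bond_dimer()
  cfg <- fast_cfg()
  cfg$n_runs <- 1L
  cfg$md$production$max_time <- 300
  cfg$ionization$fixed_iee <- 0
  res <- run_protocol(fx, config = cfg)
  expect_equal(names(res$accumulated), "CH4N")
  base <- res$spectrum$sticks[which.max(res$spectrum$sticks$intensity), ]
  expect_equal(base$mz, nominal_mz("CH4N"))
})

test_that("run reports count successes and failures exactly", {
  fx <- make_weak_bond_dimer()
  cfg <- fast_cfg()
  res <- run_protocol(fx, config = cfg)
  rep <- res$report
  expect_equal(rep$n_success + rep$n_failed, rep$n_runs)
  expect_equal(rep$failure_fraction, rep$n_failed / rep$n_runs)
  # per-run charge normalization propagates to the ensemble total
  expect_equal(sum(res$accumulated), rep$n_success, tolerance = 1e-6)
})

test_that("per-run seeds derive deterministically and stay within 31 bits", {
  s1 <- vapply(0:50, function(i) derive_seed(42L, i), integer(1))
  s2 <- vapply(0:50, function(i) derive_seed(42L, i), integer(1))
  expect_identical(s1, s2)
  expect_true(all(s1 >= 1 & s1 < 2^31))
  expect_gt(length(unique(s1)), 50)  # no collisions over a run batch
})

test_that("YAML run configurations merge over the defaults", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("n_runs: 25",
               "md:",
               "  dt: 0.25",
               "ionization:",
               "  mode_per_atom: 0.8"), path)
  cfg <- read_run_config(path)
  expect_equal(cfg$n_runs, 25)
  expect_equal(cfg$md$dt, 0.25)
  expect_equal(cfg$ionization$mode_per_atom, 0.8)
  # untouched defaults survive the merge
  expect_equal(cfg$e_impact, 70)
  expect_equal(cfg$md$equilibration$T, 500)
  expect_equal(cfg$electronic_temperature$production, 5000)
})

test_that("fixtures round-trip through XYZ and carry their designed topology", {
  fx <- make_weak_bond_dimer()
  mol <- parse_xyz(fx$xyz)
  mol2 <- parse_xyz(write_xyz(mol))
  expect_lt(max(abs(mol2$coords - mol$coords)), 1e-6)
  g <- detect_bonds(mol)
  expect_equal(nrow(g$edges), 5L)  # 2 C-H + 1 C-N + 2 N-H

  chain <- make_cascade_chain(3)
  cm <- parse_xyz(chain$xyz)
  gc <- detect_bonds(cm)
  expect_equal(nrow(gc$edges), 3L)  # a pure chain: adjacent pairs only
})
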