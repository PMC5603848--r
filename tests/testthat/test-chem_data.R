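test_that("XYZ parsing handles the standard dialect and rejects malformed input", {
  m <- parse_xyz("1\nlone helium is not tabulated, use H\nH 0 0 0")
  expect_s3_class(m, "molecule")
  expect_equal(n_atoms(m), 1L)
  expect_equal(m$charge, 0L)
  expect_equal(m$multiplicity, 1L)
  expect_true(all(m$velocities == 0))

  # declared count mismatching the listed atoms
  expect_error(parse_xyz("3\ncomment\nH 0 0 0\nH 1 0 0"), "declared 3")
  # unknown element symbol
  expect_error(parse_xyz("1\nc\nXx 0 0 0"), "unknown element")
  # malformed count
  expect_error(parse_xyz("abc\nc\nH 0 0 0"), "malformed atom count")

  # comment-line charge/multiplicity tokens
  ion <- parse_xyz("1\ncharge=1 mult=2\nH 0 0 0")
  expect_equal(ion$charge, 1L)
  expect_equal(ion$multiplicity, 2L)
})

test_that("XYZ write/parse round-trips random molecules to 1e-6 Angstrom", {
  set.seed(11)
  for (rep in 1:10) {
    m <- random_molecule(n = sample(2:8, 1))
    m2 <- parse_xyz(write_xyz(m))
    expect_equal(m2$symbols, m$symbols)
    expect_lt(max(abs(m2$coords - m$coords)), 1e-6)
    expect_equal(m2$charge, m$charge)
  }
})

test_that("formula_of reports the atom multiset and conserves atoms across splits", {
  benzene_syms <- rep(c("C", "H"), each = 6)
  m <- molecule(benzene_syms, matrix(seq_len(36), ncol = 3))
  f <- formula_of(m)
  expect_equal(unclass(f)[["C"]], 6L)
  expect_equal(unclass(f)[["H"]], 6L)

  fe <- molecule("Fe", matrix(0, 1, 3), charge = 1L)
  ffe <- formula_of(fe)
  expect_equal(formula_key(ffe), "Fe")
  expect_equal(attr(ffe, "charge"), 1L)

  # conservation: parent formula equals elementwise sum over any split
  set.seed(3)
  for (rep in 1:5) {
    m <- random_molecule(n = 7)
    g <- detect_bonds(m)
    frags <- split_fragments(m, g)
    merged <- Reduce(formula_union, lapply(frags, formula_of))
    expect_equal(sort(unclass(merged)), sort(unclass(formula_of(m))),
                 ignore_attr = TRUE)
  }
})

test_that("nominal m/z reproduces standard EI fragment labels and is additive", {
  expect_identical(nominal_mz("C4H9"), 57L)
  expect_identical(nominal_mz("C5H5Fe"), 121L)
  expect_identical(nominal_mz("H"), 1L)
  expect_error(nominal_mz(ms_formula(c(Qq = 1))), "unknown element")

  # additivity over disjoint-union of formulas
  set.seed(5)
  syms <- c("C", "H", "N", "O", "Cl", "Fe", "S")
  for (rep in 1:10) {
    f1 <- ms_formula(setNames(sample(1:4, 3, TRUE), sample(syms, 3)))
    f2 <- ms_formula(setNames(sample(1:4, 2, TRUE), sample(syms, 2)))
    expect_identical(nominal_mz(formula_union(f1, f2)),
                     nominal_mz(f1) + nominal_mz(f2))
  }
})

test_that("isotope patterns match direct table lookups and the exhaustive oracle", {
  # empty formula: all weight at zero
  p0 <- isotope_pattern(ms_formula())
  expect_equal(p0$mz, 0L)
  expect_equal(p0$abundance, 1.0)

  # single chlorine: the two-isotope table entries verbatim
  pcl <- isotope_pattern("Cl")
  expect_equal(pcl$mz, c(35L, 37L))
  iso <- element_info("Cl")$isotopes
  expect_equal(pcl$abundance, iso$abundance, tolerance = 1e-12)

  # exhaustive enumeration oracle on multi-element formulas (<= 12 atoms)
  for (f in c("C6H5", "CH3Cl", "C2H2S2", "FeH4")) {
    pat <- isotope_pattern(f)
    oracle <- enumerate_isotope_pattern(f)
    expect_equal(pat$mz, oracle$mz)
    expect_equal(pat$abundance, oracle$abundance, tolerance = 1e-9)
  }
})

test_that("unpruned isotope patterns conserve abundance and peak at the nominal mass", {
  for (f in c("C6H5", "C3H9Si", "C4H4O2Cu", "SCl2", "FeC5H5")) {
    pat <- isotope_pattern(f, prune_threshold = 0)
    expect_equal(sum(pat$abundance), 1, tolerance = 1e-9)
    expect_false(is.unsorted(pat$mz, strictly = TRUE))
    # elements whose principal isotope dominates: top isotopologue at
    # the nominal m/z
    expect_identical(pat$mz[which.max(pat$abundance)], nominal_mz(f))
  }
})

test_that("pruning drops only minor isotopologues", {
  full <- isotope_pattern("C10H10Fe", prune_threshold = 0)
  pruned <- isotope_pattern("C10H10Fe", prune_threshold = 1e-3)
  expect_true(all(pruned$mz %in% full$mz))
  expect_gt(sum(pruned$abundance), 0.99)
})

test_that("element reference data is internally consistent", {
  tab <- isotope_table()
  # per-element abundance closure and sortedness are enforced on load
  expect_true(all(tapply(tab$abundance, tab$symbol, function(a)
    abs(sum(a) - 1) < 1e-6)))
  expect_true(all(tab$covalent_radius > 0))
  expect_true(all(tapply(tab$mass_number, tab$symbol,
                         function(x) !is.unsorted(x, strictly = TRUE))))
  # coverage: the element span used across organic, organometallic and
  # main-group EI work
  needed <- c("H", "B", "C", "N", "O", "F", "Al", "Si", "P", "S", "Cl",
              "Cr", "Fe", "Ni", "Cu", "Ge", "As", "Se", "Sn", "Sb", "Te",
              "I", "Pb", "Bi")
  expect_true(all(needed %in% tab$symbol))
})
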