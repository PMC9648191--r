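test_that("lambda states validate their components and stage schedules", {
  expect_error(lambda_state("restrain", 1.2, 0, 0), "\\[0,1\\]")
  expect_error(lambda_state("warmup", 0, 0, 0))
  sch <- default_lambda_schedules()
  expect_equal(lengths(sch), c(restrain = 6L, fep = 15L, release = 6L))
  # within a stage only that stage's component varies
  expect_true(all(vapply(sch$restrain, function(s) s$lambda_vdw == 0, TRUE)))
  expect_true(all(vapply(sch$fep, function(s) s$lambda_restraint == 1, TRUE)))
  expect_true(all(vapply(sch$release, function(s) s$lambda_coul == 1, TRUE)))
  # endpoints exactly 0/1
  expect_equal(sch$restrain[[1]]$lambda_restraint, 0)
  expect_equal(sch$restrain[[6]]$lambda_restraint, 1)
  expect_equal(sch$release[[1]]$lambda_restraint, 1)
  expect_equal(sch$release[[6]]$lambda_restraint, 0)
})

test_that("stage conventions: restrain ramps the initial copy, release the final copy", {
  m <- restraint_multipliers(lambda_state("restrain", 0.3, 0, 0))
  expect_equal(m[["rv"]], 0.3); expect_equal(m[["vr"]], 1)
  m <- restraint_multipliers(lambda_state("fep", 1, 0.5, 0.5))
  expect_equal(unname(m[c("rv", "vr")]), c(1, 1))
  m <- restraint_multipliers(lambda_state("release", 0.3, 1, 1))
  expect_equal(m[["rv"]], 1); expect_equal(m[["vr"]], 0.3)
})

test_that("soft-core pair energy: endpoint identities, finiteness, decoupling", {
  sc <- softcore_params()        # alpha 0.5, power 1, sigma 0.3 nm
  real <- list(eps = 0.5, sigma = 0.33, qq = -0.04)
  ghost <- list(eps = 0, sigma = 0.33, qq = 0)
  f <- rfepr_constants$COULOMB_KJ

  # lambda = 0: exactly the unsoftened end-state A energy
  for (r in c(0.25, 0.3, 0.5, 1.0)) {
    plain <- 4 * real$eps * ((real$sigma / r)^12 - (real$sigma / r)^6) +
      f * real$qq / r
    expect_equal(softcore_pair_energy(r, 0, 0, real, ghost, sc), plain,
                 tolerance = 1e-12)
    # full decoupling onto a ghost end state -> exactly zero
    expect_equal(softcore_pair_energy(r, 1, 1, real, ghost, sc), 0)
  }

  # finite at r = 0 for intermediate lambda, and equal to the direct formula
  v0 <- softcore_pair_energy(0, 0.5, 0.5, real, ghost, sc)
  r6 <- sc$alpha * sc$sigma^6 * 0.5
  s6 <- real$sigma^6 / r6
  direct <- 0.5 * (4 * real$eps * (s6^2 - s6)) + 0.5 * f * real$qq / r6^(1 / 6)
  expect_true(is.finite(v0))
  expect_equal(v0, direct, tolerance = 1e-12)

  # monotone decoupling: |V| non-increasing in lambda at fixed r >= sigma
  for (r in c(0.3, 0.35, 0.5)) {
    v <- vapply(seq(0, 1, by = 0.05), function(l)
      abs(softcore_pair_energy(r, l, l, real, ghost, sc)), 0.0)
    expect_true(all(diff(v) <= 1e-12))
  }
})

test_that("restraint energy: harmonic wrap, switching off, degenerate geometry", {
  # four points whose torsion is exactly 180 degrees
  coords <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0))
  rs <- restraint_set(torsions = data.frame(
    a1 = 1, a2 = 2, a3 = 3, a4 = 4, eq_deg = -105, k = 1000, copy = "single"))
  # wrap(180 - (-105)) = -75 degrees
  expect_equal(restraint_energy(coords, rs, 1),
               0.5 * 1000 * (75 * pi / 180)^2, tolerance = 1e-10)
  expect_equal(restraint_energy(coords, rs, 1), 856.7, tolerance = 1e-3)
  expect_equal(restraint_energy(coords, rs, 0), 0)
  expect_equal(restraint_energy(coords, rs, 0.25),
               0.25 * restraint_energy(coords, rs, 1))

  # equilibrium geometry -> zero at any lambda
  rs_eq <- restraint_set(torsions = data.frame(
    a1 = 1, a2 = 2, a3 = 3, a4 = 4, eq_deg = 180, k = 1000, copy = "single"))
  expect_equal(restraint_energy(coords, rs_eq, 0.7), 0)

  # equivalent equilibrium modulo 360 gives the identical energy
  rs_wrap <- restraint_set(torsions = data.frame(
    a1 = 1, a2 = 2, a3 = 3, a4 = 4, eq_deg = -105 + 360, k = 1000, copy = "single"))
  expect_equal(restraint_energy(coords, rs_wrap, 1), restraint_energy(coords, rs, 1))

  # collinear torsion definition is an error, not a silent zero
  bad <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0))
  expect_error(restraint_energy(bad, rs, 1), "collinear")
})

test_that("restraint set of all four kinds evaluates every term", {
  toy <- standard_toy(seed = 13)
  rs <- toy$restraints
  expect_equal(nrow(rs$torsions), 2)
  expect_equal(nrow(rs$distances), 2)
  expect_equal(nrow(rs$angles), 2)
  expect_length(rs$pseudodihedrals, 2)
  # at the reference geometry the dual-RV restraints are near their minima
  e_rv <- restraint_energy(toy$hybrid$coords, rs, 1, copy = "rv")
  expect_lt(e_rv, 5)  # kJ/mol; jitter keeps it small but nonzero
  e_all <- restraint_energy(toy$hybrid$coords, rs, 1)
  e_vr <- restraint_energy(toy$hybrid$coords, rs, 1, copy = "vr")
  expect_equal(e_all, e_rv + e_vr, tolerance = 1e-12)
})

test_that("reduced potential matches the compiled kernel term for term", {
  toy <- standard_toy(seed = 17)
  th <- thermo_state(300)
  states <- c(default_lambda_schedules()$restrain[c(1, 4)],
              default_lambda_schedules()$fep[c(2, 8, 14)],
              default_lambda_schedules()$release[c(3, 6)])
  set.seed(99)
  for (s in states) {
    x <- jitter_coords(toy$hybrid)
    uR <- as.numeric(reduced_potential(x, toy$hybrid, toy$restraints, s, th))
    uC <- cpp_reduced_potential(x, toy$hybrid, toy$restraints, s, th)
    expect_equal(uR, uC, tolerance = 1e-10)
  }
})

test_that("states differing only in restraint lambda agree at the restraint minimum", {
  toy <- standard_toy(seed = 17)
  th <- thermo_state(300)
  x <- toy$hybrid$coords
  # restraints whose equilibria coincide with the current geometry
  m <- toy$hybrid$meta
  chi_rv <- torsion_angle(x[m$rv$chi_atoms[1], ], x[m$rv$chi_atoms[2], ],
                          x[m$rv$chi_atoms[3], ], x[m$rv$chi_atoms[4], ])
  rs <- restraint_set(torsions = data.frame(
    a1 = m$rv$chi_atoms[1], a2 = m$rv$chi_atoms[2], a3 = m$rv$chi_atoms[3],
    a4 = m$rv$chi_atoms[4], eq_deg = chi_rv, k = 1000, copy = "rv"))
  u1 <- reduced_potential(x, toy$hybrid, rs, lambda_state("restrain", 0.2, 0, 0), th)
  u2 <- reduced_potential(x, toy$hybrid, rs, lambda_state("restrain", 0.9, 0, 0), th)
  expect_equal(as.numeric(u1), as.numeric(u2), tolerance = 1e-12)
})

test_that("nonbonded pair list respects set structure and exclusions", {
  toy <- standard_toy(seed = 13)
  pr <- nonbonded_pairs(toy$hybrid)
  p <- toy$hybrid$particles
  # only conformer-shared pairs, never conformer-conformer
  s1 <- p$set[pr$a1]; s2 <- p$set[pr$a2]
  expect_true(all(s2 == "shared"))
  expect_true(all(s1 %in% c("dual-RV", "dual-VR")))
  # bonded neighbours excluded: the anchor bond partner never appears
  anchor <- toy$hybrid$meta$rv$anchors[1]
  sa <- toy$hybrid$meta$scaffold_anchor
  expect_false(any(pr$a1 == anchor & pr$a2 == sa))
})
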