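test_that("toy builder produces the requested structure deterministically", {
  pr <- default_toy_profile()
  toy <- build_torsion_toy(pr, n_shared = 8, n_dual = 6, seed = 3)
  expect_s3_class(toy, "toy_topology")
  expect_equal(nrow(toy$particles), 14)
  expect_equal(sum(toy$particles$set == "shared"), 8)
  # chi quadruple lies entirely within the dual set
  expect_true(all(toy$particles$set[toy$meta$chi_atoms] == "dual"))
  # starting coordinates sit in the requested basin
  chi <- torsion_angle(toy$coords[toy$meta$chi_atoms[1], ],
                       toy$coords[toy$meta$chi_atoms[2], ],
                       toy$coords[toy$meta$chi_atoms[3], ],
                       toy$coords[toy$meta$chi_atoms[4], ])
  expect_lt(abs(wrap_angle(chi - (-105))), 15)
  toy2 <- build_torsion_toy(pr, n_shared = 8, n_dual = 6, seed = 3)
  expect_identical(toy, toy2)
  toy3 <- build_torsion_toy(pr, n_shared = 8, n_dual = 6, seed = 4)
  expect_false(identical(toy$coords, toy3$coords))
})

test_that("toy builder enforces its preconditions", {
  single_well <- torsion_profile(-105, depths = 45, curvatures = 28)
  expect_error(build_torsion_toy(single_well), "two minima|two-state")
  expect_error(build_torsion_toy(default_toy_profile(), n_dual = 3),
               "n_dual >= 4")
  expect_error(torsion_profile(c(-105, 200), c(1, 1), c(1, 1)), "180")
  expect_error(torsion_profile(c(-105, 64), c(-1, 1), c(1, 1)), "depth")
})

test_that("hybrid topology merges shared once, excludes cross pairs, keeps dihedrals on", {
  pr <- default_toy_profile()
  ta <- build_torsion_toy(pr, seed = 5, start = 1)
  ts <- build_torsion_toy(pr, seed = 5, start = 2)
  hy <- build_hybrid_topology(ta, ts)
  expect_equal(nrow(hy$particles), 8 + 6 + 6)
  expect_equal(sum(hy$particles$set == "dual-RV"), 6)
  expect_equal(sum(hy$particles$set == "dual-VR"), 6)
  expect_equal(nrow(hy$exclusions), 36)
  expect_true(all(!hy$dihedrals$switchable))
  # proper dihedrals of both copies present
  rv_idx <- which(hy$particles$set == "dual-RV")
  vr_idx <- which(hy$particles$set == "dual-VR")
  datoms <- as.matrix(hy$dihedrals[, c("a1", "a2", "a3", "a4")])
  expect_true(any(apply(datoms, 1, function(r) any(r %in% rv_idx))))
  expect_true(any(apply(datoms, 1, function(r) any(r %in% vr_idx))))
  # both switched profile terms tagged by copy
  expect_setequal(vapply(hy$profiles, `[[`, "", "copy"), c("rv", "vr"))

  tb <- build_torsion_toy(pr, seed = 6, start = 2) # different jitter
  expect_error(build_hybrid_topology(ta, tb), "inconsistent")
})

test_that("swapping the hybrid inputs permutes labels but preserves end-state energies", {
  pr <- default_toy_profile()
  ta <- build_torsion_toy(pr, seed = 5, start = 1)
  ts <- build_torsion_toy(pr, seed = 5, start = 2)
  h1 <- build_hybrid_topology(ta, ts)
  h2 <- build_hybrid_topology(ts, ta)
  expect_equal(nrow(h1$particles), nrow(h2$particles))
  # state lambda=0 of h1 (RV real) must equal state lambda=1 of h2 (VR real)
  th <- thermo_state(300)
  s0 <- lambda_state("restrain", 0, 0, 0)
  s1 <- lambda_state("release", 0, 1, 1)
  u1 <- reduced_potential(h1$coords, h1, NULL, s0, th)
  # h2's coordinates order differs (its RV block is the syn fragment); build
  # matching coordinates by swapping the two dual blocks of h1
  ns <- h1$meta$n_shared
  swap <- c(seq_len(ns), ns + 6 + seq_len(6), ns + seq_len(6))
  u2 <- reduced_potential(h1$coords[swap, ], h2, NULL, s1, th)
  expect_equal(as.numeric(u1), as.numeric(u2), tolerance = 1e-10)
})

test_that("fully decoupled hybrid equals the single topology plus ghost internal terms", {
  pr <- default_toy_profile()
  ta <- build_torsion_toy(pr, seed = 7, start = 1)
  ts <- build_torsion_toy(pr, seed = 7, start = 2)
  hy <- build_hybrid_topology(ta, ts)
  th <- thermo_state(300)
  s0 <- lambda_state("restrain", 0, 0, 0)  # dual-VR fully decoupled
  ns <- hy$meta$n_shared
  set.seed(31)
  base <- jitter_coords(hy)
  # the decoupled ghost contributes nothing to the switched terms
  comp_h <- energy_components(base, hy, NULL, s0)
  comp_a <- energy_components(base[seq_len(ns + 6), ], ta, NULL, s0)
  expect_equal(comp_h[["profile"]], comp_a[["profile"]], tolerance = 1e-9)
  expect_equal(comp_h[["nonbonded"]], comp_a[["nonbonded"]], tolerance = 1e-9)
  # moving the live (dual-RV) fragment changes the hybrid energy exactly as
  # it changes the single-topology energy: the ghost term is a separate
  # additive contribution, configuration by configuration
  u_base_h <- reduced_potential(base, hy, NULL, s0, th)
  u_base_a <- reduced_potential(base[seq_len(ns + 6), ], ta, NULL, s0, th)
  for (rep in 1:5) {
    x <- base
    live <- ns + seq_len(6)  # dual-RV fragment
    x[live, ] <- x[live, ] + matrix(rnorm(3 * length(live), sd = 0.01), ncol = 3)
    du_h <- reduced_potential(x, hy, NULL, s0, th) - u_base_h
    du_a <- reduced_potential(x[seq_len(ns + 6), ], ta, NULL, s0, th) - u_base_a
    expect_equal(as.numeric(du_h), as.numeric(du_a), tolerance = 1e-9)
  }
  # while moving the ghost fragment leaves the live part's energy untouched
  x <- base
  ghost <- ns + 6 + seq_len(6)
  x[ghost, ] <- x[ghost, ] + matrix(rnorm(18, sd = 0.01), ncol = 3)
  comp_g <- energy_components(x, hy, NULL, s0)
  expect_equal(comp_g[["profile"]], comp_h[["profile"]], tolerance = 1e-9)
  expect_equal(comp_g[["nonbonded"]], comp_h[["nonbonded"]], tolerance = 1e-9)
})

test_that("quadrature reference: symmetry, Gaussian limit and Richardson stability", {
  th <- thermo_state(300)
  sym <- torsion_profile(c(-90, 90), depths = c(20, 20), curvatures = c(40, 40))
  expect_equal(as.numeric(exact_free_energy_1d(sym, thermo = th)), 0,
               tolerance = 1e-9)

  # narrow equal-curvature wells offset by exactly 1 kcal/mol: deep wells
  # make the inter-well plateau contribution negligible, so the quadrature
  # approaches the closed-form Gaussian integral limit
  eps <- rfepr_constants$KJ_PER_KCAL
  narrow <- torsion_profile(c(-105, 64), depths = c(60, 60 - eps),
                            curvatures = c(2e4, 2e4))
  expect_equal(as.numeric(exact_free_energy_1d(narrow, thermo = th)), 1.0,
               tolerance = 1e-5)

  # default profile against the closed-form Gaussian-well approximation
  pr <- default_toy_profile()
  dg <- exact_free_energy_1d(pr, thermo = th)
  gauss <- ((60 - 48) + th$RT_kj / 2 * log(114 / 56)) / eps
  expect_equal(as.numeric(dg), gauss, tolerance = 2e-3)

  # grid refinement: tightening the tolerance moves the value by < 1e-6
  dg_tight <- exact_free_energy_1d(pr, thermo = th, tol = 1e-11)
  expect_lt(abs(as.numeric(dg) - as.numeric(dg_tight)), 1e-6)
  expect_lt(attr(dg_tight, "quadrature_error"), 1e-11)
})

test_that("unrestrained sampling reproduces the quadrature populations", {
  pr <- crossable_profile()
  toy <- build_torsion_toy(pr, seed = 9, start = 1)
  th <- thermo_state(300)
  st <- lambda_state("restrain", 0, 0, 0)
  tr <- metropolis_sample(toy, NULL, st, n_sweeps = 30000, seed = 21,
                          thermo = th, stride = 10, step_tor = 0.8)
  chi <- traj_torsion(tr, toy$meta$chi_atoms)
  est <- basin_free_energy(chi, thermo = th)
  exact <- as.numeric(exact_free_energy_1d(pr, thermo = th))
  g <- statistical_inefficiency(as.numeric(assign_basins(chi) == "syn"))
  se_eff <- est$se * sqrt(g)   # inflate the binomial error by the correlation
  expect_lt(abs(est$dG - exact), 3 * se_eff)
})

test_that("topology validation catches broken structures", {
  toy <- build_torsion_toy(default_toy_profile(), seed = 2)
  bad <- toy; bad$particles$mass[1] <- -1
  expect_error(validate_topology(bad), "mass")
  bad2 <- toy; bad2$bonds$a1[1] <- 99
  expect_error(validate_topology(bad2), "out of range")
  bad3 <- toy; bad3$profiles[[1]]$atoms <- c(1, 1, 2, 3)
  expect_error(validate_topology(bad3), "4 distinct")
})
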