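test_that("sampling a stiff bond satisfies equipartition", {
  # two particles, one harmonic bond: var(r) ~ RT/k for k r0^2 >> RT
  k <- 2e4; r0 <- 0.15
  topo <- rfepr:::new_toy_topology(
    particles = data.frame(id = 1:2, mass = 12, charge = 0, eps = 0,
                           sigma = 0.3, set = "shared"),
    bonds = data.frame(a1 = 1, a2 = 2, k = k, r0 = r0),
    angles = data.frame(a1 = integer(0), a2 = integer(0), a3 = integer(0),
                        k = numeric(0), theta0 = numeric(0)),
    dihedrals = data.frame(a1 = integer(0), a2 = integer(0), a3 = integer(0),
                           a4 = integer(0), mult = integer(0), k = numeric(0),
                           phase = numeric(0), switchable = logical(0)),
    profiles = list(),
    exclusions = matrix(integer(0), 0, 2),
    coords = rbind(c(0, 0, 0), c(r0, 0, 0)),
    meta = list())
  th <- thermo_state(300)
  st <- lambda_state("restrain", 0, 0, 0)
  tr <- metropolis_sample(topo, NULL, st, n_sweeps = 20000, seed = 5,
                          thermo = th, stride = 5)
  r <- vapply(seq_len(nrow(tr$frames)), function(i) {
    x <- traj_frame(tr, i); sqrt(sum((x[1, ] - x[2, ])^2))
  }, 0.0)
  g <- statistical_inefficiency(r)
  n_eff <- length(r) / g
  target <- th$RT_kj / k
  se <- target * sqrt(2 / n_eff)   # sd of a variance estimate
  expect_lt(abs(var(r) - target), 3 * se + 0.02 * target)
})

test_that("trajectories are bit-reproducible given the seed", {
  toy <- standard_toy(seed = 2)
  st <- default_lambda_schedules()$fep[[8]]
  t1 <- metropolis_sample(toy$hybrid, toy$restraints, st, 500, seed = 77)
  t2 <- metropolis_sample(toy$hybrid, toy$restraints, st, 500, seed = 77)
  expect_identical(t1$frames, t2$frames)
  t3 <- metropolis_sample(toy$hybrid, toy$restraints, st, 500, seed = 78)
  expect_false(identical(t1$frames, t3$frames))
})

test_that("acceptance fractions are strictly inside (0, 1) after burn-in", {
  toy <- standard_toy(seed = 2)
  st <- default_lambda_schedules()$restrain[[1]]
  tr <- metropolis_sample(toy$hybrid, toy$restraints, st, 2000, seed = 8)
  for (a in tr$acceptance) { expect_gt(a, 0); expect_lt(a, 1) }
  # tuning lands in a sensible window
  expect_gt(tr$acceptance[["displacement"]], 0.15)
  expect_lt(tr$acceptance[["displacement"]], 0.7)
})

test_that("logged proposals obey the Metropolis ratio exactly", {
  toy <- standard_toy(seed = 2)
  st <- default_lambda_schedules()$fep[[5]]
  tr <- metropolis_sample(toy$hybrid, toy$restraints, st, 1000, seed = 12,
                          n_log = 800)
  log <- tr$proposal_log
  expect_equal(nrow(log), 800)
  should_accept <- log[, 2] < exp(-log[, 1])
  expect_equal(as.logical(log[, 3]), should_accept)
  expect_gt(sum(log[, 3]), 0)
  expect_lt(sum(log[, 3]), 800)
})

test_that("sampled torsion histogram matches the Boltzmann weight of the profile", {
  pr <- crossable_profile()
  toy <- build_torsion_toy(pr, seed = 9, start = 1)
  th <- thermo_state(300)
  st <- lambda_state("restrain", 0, 0, 0)
  tr <- metropolis_sample(toy, NULL, st, n_sweeps = 30000, seed = 33,
                          thermo = th, stride = 10, step_tor = 0.8)
  chi <- traj_torsion(tr, toy$meta$chi_atoms)
  g <- statistical_inefficiency(chi + 0 * chi) # inefficiency of the series
  chi_ind <- chi[seq(1, length(chi), by = max(1, ceiling(g)))]
  breaks <- seq(-180, 180, by = 30)
  obs <- table(cut(wrap_angle(chi_ind), breaks))
  # expected bin probabilities by quadrature of exp(-U/RT)
  probs <- vapply(seq_len(length(breaks) - 1), function(i) {
    xs <- seq(breaks[i], breaks[i + 1], length.out = 400)
    mean(exp(-torsion_potential(pr, xs) / th$RT_kj))
  }, 0.0)
  probs <- probs / sum(probs)
  keep <- probs > 1e-4
  test <- suppressWarnings(
    stats::chisq.test(as.vector(obs)[keep], p = probs[keep], rescale.p = TRUE))
  expect_gt(test$p.value, 0.01)
})

test_that("statistical inefficiency matches closed forms", {
  set.seed(6)
  expect_lt(statistical_inefficiency(rnorm(5000)), 1.6)
  # AR(1) with coefficient 0.9: g = (1 + phi) / (1 - phi) = 19
  phi <- 0.9
  n <- 2e5
  x <- as.numeric(stats::arima.sim(list(ar = phi), n))
  expect_lt(abs(statistical_inefficiency(x) - 19), 3.5)
  # alternating series: negative correlation clamps to 1
  expect_equal(statistical_inefficiency(rep(c(1, -1), 50)), 1)
  expect_warning(g <- statistical_inefficiency(rep(2, 40)), "constant")
  expect_equal(g, 40)
  expect_error(statistical_inefficiency(1:5), "short")
})

test_that("u_kn assembly cross-evaluates all states and guards provenance", {
  toy <- standard_toy(seed = 4)
  th <- thermo_state(300)
  sch <- lambda_schedule("restrain", c(0, 0.5, 1))
  trajs <- lapply(seq_along(sch), function(i)
    metropolis_sample(toy$hybrid, toy$restraints, sch[[i]], 600, seed = 40 + i,
                      thermo = th, stride = 10))
  ukn <- collect_u_kn(trajs, sch, toy$hybrid, toy$restraints, th)
  expect_equal(dim(ukn$u), c(3L, sum(ukn$N_k)))
  expect_equal(ukn$N_k, rep(nrow(trajs[[1]]$frames), 3L))
  # identical duplicate states produce identical rows
  sch2 <- lambda_schedule("restrain", c(0.5, 0.5))
  ukn2 <- collect_u_kn(trajs[c(2, 2)], sch2, toy$hybrid, toy$restraints, th)
  expect_equal(ukn2$u[1, ], ukn2$u[2, ])
  # column entries differ between states only through lambda-coupled terms
  x <- traj_frame(trajs[[1]], 1)
  comp0 <- energy_components(x, toy$hybrid, toy$restraints, sch[[1]])
  comp1 <- energy_components(x, toy$hybrid, toy$restraints, sch[[3]])
  expect_equal(comp0[c("bonds", "angles", "dihedrals", "profile", "nonbonded")],
               comp1[c("bonds", "angles", "dihedrals", "profile", "nonbonded")])
  expect_equal((ukn$u[3, 1] - ukn$u[1, 1]) * th$RT_kj,
               unname(comp1["restraints"] - comp0["restraints"]),
               tolerance = 1e-9)
  # provenance mismatch is an error
  expect_error(collect_u_kn(trajs, rev(sch), toy$hybrid, toy$restraints, th),
               "provenance")
})

test_that("subsampling thins by the stage-wide or per-state inefficiency", {
  set.seed(3)
  u <- rbind(c(cumsum(rnorm(200)) / 10, rnorm(100)),
             c(cumsum(rnorm(200)) / 10, rnorm(100)) + 1)
  ukn <- new_u_kn(u, c(200, 100))
  thin <- subsample_u_kn(ukn)          # uniform: conservative max-g thinning
  g <- attr(thin, "g")
  expect_length(g, 2)
  expect_equal(attr(thin, "g_used"), rep(max(g), 2))
  expect_equal(thin$N_k[1], length(seq(1, 200, by = ceiling(max(g)))))
  thin2 <- subsample_u_kn(ukn, uniform = FALSE)  # per-state thinning
  expect_equal(thin2$N_k[1], length(seq(1, 200, by = ceiling(g[1]))))
  expect_equal(thin2$N_k[2], length(seq(1, 100, by = ceiling(g[2]))))
})
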