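# Closed-form reference used throughout: two 1D harmonic states with
# k2 = 4 k1 have delta f = ln(sqrt(k2/k1)) = ln 2 (dimensionless).
harmonic_pair <- function(n = 1e4, seed = 1) {
  set.seed(seed)
  x1 <- rnorm(n, sd = 1)        # beta U1 = x^2 / 2
  x2 <- rnorm(n, sd = 0.5)      # beta U2 = 2 x^2
  u <- rbind(c(x1^2 / 2, x2^2 / 2), c(2 * x1^2, 2 * x2^2))
  list(ukn = new_u_kn(u, c(n, n)),
       w_f = 2 * x1^2 - x1^2 / 2, w_r = x2^2 / 2 - 2 * x2^2)
}

test_that("MBAR on identical states gives zero difference", {
  set.seed(2)
  x <- rnorm(500)
  u <- rbind(x^2, x^2)
  fit <- mbar_solve(new_u_kn(u, c(250, 250)))
  d <- delta_f(fit)
  expect_equal(d$df, 0, tolerance = 1e-8)
  expect_lt(d$ddf, 1e-4)
})

test_that("MBAR recovers the harmonic ln 2 within 3 sigma at n = 1e4", {
  hp <- harmonic_pair(1e4, seed = 101)
  fit <- mbar_solve(hp$ukn)
  d <- delta_f(fit)
  expect_lt(abs(d$df - log(2)), 3 * d$ddf)
  expect_gt(d$ddf, 1e-4)  # honest, nonzero uncertainty
  expect_lt(d$ddf, 0.05)
})

test_that("MBAR is invariant under sample permutation and per-sample anchoring", {
  hp <- harmonic_pair(2000, seed = 7)
  fit <- mbar_solve(hp$ukn)
  perm <- sample(ncol(hp$ukn$u))
  fit_p <- mbar_solve(new_u_kn(hp$ukn$u[, perm], hp$ukn$N_k))
  expect_equal(fit_p$f, fit$f, tolerance = 1e-6)
  # adding an arbitrary constant to every column leaves delta f unchanged
  shift <- matrix(rnorm(ncol(hp$ukn$u), sd = 5), 2, ncol(hp$ukn$u), byrow = TRUE)
  fit_s <- mbar_solve(new_u_kn(hp$ukn$u + shift, hp$ukn$N_k))
  expect_equal(delta_f(fit_s)$df, delta_f(fit)$df, tolerance = 1e-6)
})

test_that("MBAR reports non-convergence instead of silently stopping", {
  hp <- harmonic_pair(500, seed = 3)
  expect_error(mbar_solve(hp$ukn, max_iter = 2L), "did not converge")
  expect_error(mbar_solve(hp$ukn$u, N_k = NULL), "N_k")
})

test_that("BAR solves the Bennett equation and agrees with MBAR on K = 2", {
  expect_equal(bar(rep(0, 50), rep(0, 50))$df, 0, tolerance = 1e-9)
  hp <- harmonic_pair(1e4, seed = 202)
  b <- bar(hp$w_f, hp$w_r)
  expect_lt(abs(b$df - log(2)), 3 * b$ddf)
  m <- delta_f(mbar_solve(hp$ukn))
  expect_lt(abs(b$df - m$df), 0.01)
  expect_error(bar(numeric(0), hp$w_r), "nonempty")
})

test_that("exponential averaging brackets BAR and the estimators agree", {
  hp <- harmonic_pair(1e4, seed = 303)
  b <- bar(hp$w_f, hp$w_r)
  ef <- exp_averaging(hp$w_f)          # forward estimate of delta f
  er <- exp_averaging(hp$w_r)          # estimates -delta f
  expect_gte(ef$df + 1e-9, b$df - 3 * (ef$ddf + b$ddf))
  expect_gte(b$df, -er$df - 3 * (er$ddf + b$ddf))
  # the one-sided estimates bracket the two-sided one on this realization
  expect_true(-er$df <= b$df && b$df <= ef$df)
  m <- delta_f(mbar_solve(hp$ukn))
  for (est in list(b, list(df = ef$df, ddf = ef$ddf),
                   list(df = -er$df, ddf = er$ddf)))
    expect_lt(abs(est$df - m$df), 3 * (est$ddf + m$ddf) + 1e-6)
})

test_that("overlap matrix: symmetry limit, disjoint limit, row normalization", {
  set.seed(5)
  # K identical states with equal N -> all entries 1/K
  x <- rnorm(900)
  u <- rbind(x^2, x^2, x^2)
  O <- overlap_matrix(new_u_kn(u, c(300, 300, 300)))
  expect_equal(as.vector(unclass(O)), rep(1 / 3, 9), tolerance = 1e-6)

  # disjoint states: off-diagonal -> 0
  ud <- rbind(c(rnorm(200), rep(400, 200)), c(rep(400, 200), rnorm(200)))
  Od <- overlap_matrix(new_u_kn(ud, c(200, 200)))
  expect_lt(max(Od[1, 2], Od[2, 1]), 1e-10)

  # random valid inputs: rows sum to one within 1e-10
  for (rep in 1:5) {
    K <- sample(2:5, 1)
    centers <- cumsum(runif(K, 0, 2))
    xs <- unlist(lapply(centers, function(m) rnorm(150, mean = m)))
    ur <- t(vapply(centers, function(m) (xs - m)^2 / 2, numeric(length(xs))))
    Or <- overlap_matrix(new_u_kn(ur, rep(150, K)))
    expect_equal(rowSums(unclass(Or)), rep(1, K), tolerance = 1e-10)
    expect_true(all(Or >= 0 & Or <= 1 + 1e-12))
  }
})

test_that("overlap matrix requires an anchored MBAR fit", {
  hp <- harmonic_pair(200, seed = 4)
  expect_error(overlap_matrix(hp$ukn, fit = list(f = c(0, 1))), "mbar_result")
})

test_that("forward/reverse series: counting, agreement on stationary data", {
  hp <- harmonic_pair(2000, seed = 11)
  fr <- forward_reverse(hp$ukn, fractions = seq(0.1, 1, by = 0.1))
  expect_equal(nrow(fr), 10)
  expect_equal(fr$fraction, seq(0.1, 1, by = 0.1))
  # final fraction uses the full data: forward and reverse coincide
  expect_equal(fr$forward[10], fr$reverse[10], tolerance = 1e-9)
  # stationary data: agreement within 2 sigma everywhere
  expect_true(all(abs(fr$forward - fr$reverse) <=
                  2 * sqrt(fr$forward_err^2 + fr$reverse_err^2) + 1e-9))
  expect_true(attr(fr, "converged"))
})

test_that("forward/reverse flags a constructed drifting series", {
  set.seed(13)
  n <- 2000
  # state-1 work series shifts mid-way: early samples see a different mean
  x1 <- c(rnorm(n / 2, 0, 1), rnorm(n / 2, 3, 1))
  x2 <- rnorm(n, 1.5, 1)
  u <- rbind(c(rep(0, n), x2), c(x1, rep(0, n)))
  ukn <- new_u_kn(u, c(n, n))
  fr <- forward_reverse(ukn, fractions = c(0.25, 0.5, 1))
  gap1 <- abs(fr$forward[1] - fr$reverse[1])
  comb1 <- sqrt(fr$forward_err[1]^2 + fr$reverse_err[1]^2)
  expect_gt(gap1, 3 * comb1)
  expect_equal(fr$forward[3], fr$reverse[3], tolerance = 1e-9)
})

test_that("fractions outside (0, 1] or non-increasing are rejected", {
  hp <- harmonic_pair(200, seed = 5)
  expect_error(forward_reverse(hp$ukn, fractions = c(0.5, 0.2)), "increase")
  expect_error(forward_reverse(hp$ukn, fractions = c(0, 1)), "increase|\\(0")
})

test_that("stage free energy converts to kcal/mol consistently", {
  hp <- harmonic_pair(5000, seed = 17)
  th <- thermo_state(300)
  est <- stage_free_energy(hp$ukn, th, subsample = FALSE)
  expect_equal(est$dG, est$df * th$RT_kcal)
  expect_equal(est$err, est$ddf * th$RT_kcal)
  expect_lt(abs(est$df - log(2)), 3 * est$ddf)
})
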