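# Shared fixtures, built in code.

# a low-barrier profile that unrestrained Monte Carlo can cross, for
# sampling-vs-quadrature comparisons
crossable_profile <- function() {
  torsion_profile(c(anti = -105, syn = 64), depths = c(6, 4),
                  curvatures = c(30, 30))
}

# random rigid rotation matrix (Haar via QR)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# jittered copies of a topology's coordinates
jitter_coords <- function(topo, sd = 0.01) {
  topo$coords + matrix(rnorm(length(topo$coords), sd = sd), ncol = 3)
}

# reduced potential via the compiled kernel, for R-vs-C++ cross checks
cpp_reduced_potential <- function(coords, topo, restraints, state, thermo) {
  tabs <- topology_tables(topo, restraints)
  rfepr:::cpp_total_energy(as.numeric(t(coords)), tabs,
                           rfepr:::state_vector(state)) / thermo$RT_kj
}
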