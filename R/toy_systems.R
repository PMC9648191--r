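# Toy molecular systems with a two-basin torsion coordinate.
#
# The generator emulates the statistical structure of a purine base
# interconverting between anti and syn about its glycosyl bond inside a
# larger scaffold: a short bonded "backbone" chain (shared set), plus a
# conformer fragment of two anchor particles and a rotor whose orientation
# about the anchor-rotor axis is the glycosyl-like torsion chi. The anti/syn
# preference is carried by an effective torsion profile term (a periodic
# double well) that represents the conformer-environment interactions and is
# therefore switched with the conformer's nonbonded coupling during FEP.
# Explicit pair nonbonded interactions (LJ + Coulomb) act between the anchor
# particles and the shared set; rotor particles are nonbonded-silent so the
# torsion coordinate decouples exactly from all other degrees of freedom and
# the system's conformational free energy equals the one-dimensional
# quadrature of the profile, which is what makes the toy an oracle.

#' Two-basin torsion profile
#'
#' A periodic potential on a torsion angle built as a sum of truncated
#' periodic harmonic wells: well m contributes
#' \eqn{\frac{1}{2} c_m \Delta^2 - D_m} for \eqn{|\Delta| \le \sqrt{2 D_m / c_m}}
#' (and 0 beyond), where \eqn{\Delta} is the wrapped distance to the well
#' center. Depth and curvature are independently tunable, the barrier between
#' non-overlapping wells equals the full well depth, and the Boltzmann
#' integral is available by quadrature.
#'
#' @param minima Well centers in degrees, each in `(-180, 180]`.
#' @param depths Well depths in kJ/mol (> 0).
#' @param curvatures Curvatures at the minima in kJ/mol/rad^2 (> 0). Thermal
#'   fluctuation width at temperature T is about `sqrt(RT/curvature)` rad.
#' @return Object of class `torsion_profile`.
#' @examples
#' # anti basin at -105 deg (sd ~12 deg at 300 K), syn at +64 deg (sd ~8.5 deg)
#' pr <- torsion_profile(c(anti = -105, syn = 64), depths = c(60, 48),
#'                       curvatures = c(56, 114))
#' @export
torsion_profile <- function(minima, depths, curvatures) {
  stopifnot(length(minima) >= 1L,
            length(depths) == length(minima),
            length(curvatures) == length(minima))
  if (any(!is.finite(minima)) || any(minima <= -180) || any(minima > 180))
    stop("profile minima must lie in (-180, 180] degrees")
  if (any(depths <= 0)) stop("well depths must be > 0 kJ/mol")
  if (any(curvatures <= 0)) stop("well curvatures must be > 0 kJ/mol/rad^2")
  labs <- names(minima)
  if (is.null(labs)) labs <- paste0("basin", seq_along(minima))
  structure(
    list(wells = data.frame(label = labs, center_deg = as.numeric(minima),
                            depth = as.numeric(depths),
                            curvature = as.numeric(curvatures))),
    class = "torsion_profile"
  )
}

#' @export
print.torsion_profile <- function(x, ...) {
  cat("<torsion_profile> wells:\n")
  print(x$wells, row.names = FALSE)
  invisible(x)
}

#' Default two-basin profile of the standard toy
#'
#' Anti well at -105 degrees with curvature 56 kJ/mol/rad^2 (thermal width
#' about 12 degrees at 300 K) and syn well at +64 degrees with curvature
#' 114 kJ/mol/rad^2 (width about 8.5 degrees); depths 60 and 48 kJ/mol.
#' Depths and curvatures are chosen jointly so that (a) both basins are
#' strictly metastable over the default sampling length (barriers of at
#' least 19 kT from either side), (b) the truncated wells do not overlap,
#' leaving a flat inter-well plateau, and (c) the anti -> syn gap is near
#' +3 kcal/mol at 300 K, comparable to the purine systems the toy emulates.
#'
#' @return A [torsion_profile()].
#' @export
default_toy_profile <- function() {
  torsion_profile(c(anti = -105, syn = 64),
                  depths = c(60, 48), curvatures = c(56, 114))
}

#' Evaluate a torsion profile
#'
#' @param profile A [torsion_profile()].
#' @param chi Torsion angle(s) in degrees (or radians with `degrees=FALSE`).
#' @param degrees Interpret `chi` in degrees (default).
#' @return Potential energy in kJ/mol, vectorized over `chi`.
#' @export
torsion_potential <- function(profile, chi, degrees = TRUE) {
  stopifnot(inherits(profile, "torsion_profile"))
  x <- if (degrees) chi * pi / 180 else chi
  u <- numeric(length(x))
  for (m in seq_len(nrow(profile$wells))) {
    ctr <- profile$wells$center_deg[m] * pi / 180
    D <- profile$wells$depth[m]
    cc <- profile$wells$curvature[m]
    reach <- sqrt(2 * D / cc)
    d <- wrap_angle(x - ctr, degrees = FALSE)
    inside <- abs(d) <= reach
    u[inside] <- u[inside] + 0.5 * cc * d[inside]^2 - D
  }
  u
}

#' Exact two-basin free-energy difference by quadrature
#'
#' Reference (oracle) value for the conformational free energy of a
#' [torsion_profile()]: \eqn{\Delta G = -RT \ln(Z_2/Z_1)} with
#' \eqn{Z_b = \int_{basin_b} e^{-U(\chi)/RT} d\chi}, integrated by composite
#' trapezoid with grid doubling until the relative change is below `tol`.
#' Basin 1 and 2 are the profile's first and second wells (anti and syn for
#' the default profile); boundaries default to the circular midpoints
#' between the two centers.
#'
#' @param profile A [torsion_profile()] with at least two wells; only the
#'   first two define the basins.
#' @param basin_boundary Optional numeric length-2 vector of boundary angles
#'   in degrees separating the two basins on the circle.
#' @param thermo A [thermo_state()] or temperature in K.
#' @param tol Relative convergence tolerance of the grid-doubling quadrature.
#' @return `dG` in kcal/mol (basin1 -> basin2; positive when basin 2 lies
#'   higher), with attributes `Z` (the two basin integrals), `boundaries`
#'   (degrees), `n_grid`, and `quadrature_error` (last relative change).
#' @export
exact_free_energy_1d <- function(profile, basin_boundary = NULL,
                                 thermo = thermo_state(300), tol = 1e-8) {
  stopifnot(inherits(profile, "torsion_profile"))
  if (nrow(profile$wells) < 2L)
    stop("two-state reference requires a profile with at least two minima")
  th <- as_thermo(thermo)
  c1 <- profile$wells$center_deg[1L]
  c2 <- profile$wells$center_deg[2L]
  if (is.null(basin_boundary)) {
    # circular midpoints between the two centers, one on each arc
    half <- wrap_angle(c2 - c1) / 2
    basin_boundary <- wrap_angle(c(c1 + half, c1 + half + 180))
  }
  stopifnot(length(basin_boundary) == 2L)

  beta <- 1 / th$RT_kj
  arc_integral <- function(lo, hi, n) {
    # integrate exp(-beta U) over the arc lo -> hi (going up, degrees may
    # exceed 180 before wrapping)
    x <- seq(lo, hi, length.out = n)
    f <- exp(-beta * torsion_potential(profile, wrap_angle(x)))
    if (any(!is.finite(f))) stop("oracle failure: non-finite Boltzmann factor")
    h <- (hi - lo) / (n - 1) * pi / 180
    h * (sum(f) - 0.5 * (f[1L] + f[n]))
  }
  # order boundaries so that arc b1 -> b2 (increasing) contains center 1
  b <- sort(basin_boundary)
  in_first <- wrap_angle(c1) > b[1L] && wrap_angle(c1) <= b[2L]
  arcs <- if (in_first) {
    list(z1 = c(b[1L], b[2L]), z2 = c(b[2L], b[1L] + 360))
  } else {
    list(z1 = c(b[2L], b[1L] + 360), z2 = c(b[1L], b[2L]))
  }

  n <- 4097L
  z <- vapply(arcs, function(a) arc_integral(a[1L], a[2L], n), 0.0)
  repeat {
    n2 <- 2L * (n - 1L) + 1L
    z2 <- vapply(arcs, function(a) arc_integral(a[1L], a[2L], n2), 0.0)
    rel <- max(abs(z2 - z) / pmax(abs(z2), .Machine$double.xmin))
    z <- z2; n <- n2
    if (rel < tol || n > 2^21) break
  }
  if (any(z <= 0)) stop("oracle failure: vanishing basin integral")
  dG <- -th$RT_kcal * log(z[["z2"]] / z[["z1"]])
  structure(dG, Z = z, boundaries = b, n_grid = n, quadrature_error = rel)
}

## ---------------------------------------------------------------------------
## Topology container

new_toy_topology <- function(particles, bonds, angles, dihedrals, profiles,
                             exclusions, coords, meta) {
  structure(
    list(particles = particles, bonds = bonds, angles = angles,
         dihedrals = dihedrals, profiles = profiles,
         exclusions = exclusions, coords = coords, meta = meta),
    class = "toy_topology"
  )
}

#' Validate a toy topology
#'
#' Checks the structural invariants: positive masses and LJ sigma, exactly
#' one set label per particle, four distinct atoms per dihedral, and index
#' ranges.
#'
#' @param topo A `toy_topology`.
#' @return `topo`, invisibly; errors on violation.
#' @export
validate_topology <- function(topo) {
  stopifnot(inherits(topo, "toy_topology"))
  p <- topo$particles
  n <- nrow(p)
  if (any(p$mass <= 0)) stop("invalid topology: masses must be > 0")
  if (any(p$sigma <= 0)) stop("invalid topology: LJ sigma must be > 0")
  ok_sets <- c("shared", "dual", "dual-RV", "dual-VR")
  if (!all(p$set %in% ok_sets)) stop("invalid topology: unknown set label")
  check_atoms <- function(tab, k) {
    if (nrow(tab) == 0L) return(invisible())
    a <- as.matrix(tab[, paste0("a", seq_len(k)), drop = FALSE])
    if (any(a < 1L | a > n)) stop("invalid topology: atom index out of range")
    if (k == 4L && any(apply(a, 1L, function(r) anyDuplicated(r) > 0L)))
      stop("invalid topology: dihedral quadruple with repeated atom")
  }
  check_atoms(topo$bonds, 2L)
  check_atoms(topo$angles, 3L)
  check_atoms(topo$dihedrals, 4L)
  for (pf in topo$profiles) {
    if (length(pf$atoms) != 4L || anyDuplicated(pf$atoms))
      stop("invalid topology: profile torsion needs 4 distinct atoms")
    if (any(pf$atoms < 1L | pf$atoms > n))
      stop("invalid topology: profile atom index out of range")
  }
  if (!is.null(topo$coords) && nrow(topo$coords) != n)
    stop("invalid topology: coordinate/particle count mismatch")
  invisible(topo)
}

#' @export
print.toy_topology <- function(x, ...) {
  sets <- table(x$particles$set)
  cat(sprintf("<toy_topology> %d particles (%s); %d bonds, %d angles, %d proper dihedrals, %d profile terms\n",
              nrow(x$particles),
              paste(sprintf("%s: %d", names(sets), sets), collapse = ", "),
              nrow(x$bonds), nrow(x$angles), nrow(x$dihedrals),
              length(x$profiles)))
  if (!is.null(x$meta$chi_atoms))
    cat("  chi torsion atoms:", paste(x$meta$chi_atoms, collapse = "-"), "\n")
  if (nrow(x$exclusions) > 0L)
    cat(sprintf("  %d excluded nonbonded pairs\n", nrow(x$exclusions)))
  invisible(x)
}

# NeRF-style placement: position a fourth point at distance r from c, with
# angle theta at c (to b) and torsion phi about b -> c relative to a.
place_atom <- function(a, b, c, r, theta, phi) {
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- cross3(ab, bc)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-12) stop("degenerate reference frame in placement")
  n <- n / nn
  m <- cross3(n, bc)
  d2 <- c(-r * cos(theta), r * sin(theta) * cos(phi), r * sin(theta) * sin(phi))
  c + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}

#' Build a single-conformer toy topology
#'
#' Constructs a bonded scaffold chain of `n_shared` particles plus a
#' conformer fragment of `n_dual` particles (two anchors bonded to the
#' scaffold and a rotor) whose torsion about the anchor-rotor axis is the
#' glycosyl-like coordinate chi, governed by `profile`. The rotor starts in
#' the basin selected by `start`.
#'
#' The chi quadruple lies entirely within the dual set (anchor1, anchor2,
#' rotor hub, first rotor arm). Proper dihedral terms (junction and
#' rotor-internal) are present and always on; the profile term is tagged as
#' conformer-environment coupling and is switched with the conformer's
#' nonbonded interactions in a hybrid topology.
#'
#' @param profile A [torsion_profile()] with at least two wells.
#' @param n_shared Number of scaffold particles (>= 6).
#' @param n_dual Number of conformer particles (>= 4).
#' @param seed Integer seed for the small coordinate jitter; identical seeds
#'   give bit-identical topologies and coordinates.
#' @param start Basin to start in: a well label or index of `profile`.
#' @return A `toy_topology` with element `coords` (n x 3 matrix, nm).
#' @export
build_torsion_toy <- function(profile, n_shared = 8L, n_dual = 6L, seed = 1L,
                              start = 1L) {
  stopifnot(inherits(profile, "torsion_profile"))
  if (nrow(profile$wells) < 2L)
    stop("two-state toy requires a profile with at least two minima")
  n_shared <- as.integer(n_shared); n_dual <- as.integer(n_dual)
  if (n_shared < 6L) stop("need n_shared >= 6 for the scaffold")
  if (n_dual < 4L) stop("need n_dual >= 4 so a glycosyl-like torsion exists within the dual set")
  if (is.character(start)) start <- match(start, profile$wells$label)
  if (is.na(start) || start < 1L || start > nrow(profile$wells))
    stop("unknown start basin")
  chi0 <- profile$wells$center_deg[start] * pi / 180

  r0 <- 0.15; th0 <- 1.9   # nm, rad: generic heavy-atom geometry
  n <- n_shared + n_dual
  xyz <- matrix(0, n, 3L)
  xyz[1L, ] <- c(0, 0, 0)
  xyz[2L, ] <- c(r0, 0, 0)
  xyz[3L, ] <- xyz[2L, ] + r0 * c(-cos(pi - th0), sin(pi - th0), 0)
  for (i in 4L:n_shared) {
    phi <- 2.9 * if (i %% 2L == 0L) 1 else -1   # near-trans zig-zag
    xyz[i, ] <- place_atom(xyz[i - 3L, ], xyz[i - 2L, ], xyz[i - 1L, ],
                           r0, th0, phi)
  }
  na <- n_shared %/% 2L                  # scaffold anchor atom
  iA1 <- n_shared + 1L; iA2 <- n_shared + 2L
  iR1 <- n_shared + 3L; rotor <- (n_shared + 4L):n
  xyz[iA1, ] <- place_atom(xyz[na - 2L, ], xyz[na - 1L, ], xyz[na, ], r0, th0, 1.2)
  xyz[iA2, ] <- place_atom(xyz[na - 1L, ], xyz[na, ], xyz[iA1, ], r0, th0, -2.6)
  xyz[iR1, ] <- place_atom(xyz[na, ], xyz[iA1, ], xyz[iA2, ], r0, th0, 2.8)
  arm_phi <- chi0 + 2 * pi * (seq_along(rotor) - 1L) / max(3L, length(rotor))
  for (j in seq_along(rotor))
    xyz[rotor[j], ] <- place_atom(xyz[iA1, ], xyz[iA2, ], xyz[iR1, ],
                                  r0, th0, arm_phi[j])

  masses <- rep(12, n)
  if (n_dual >= 5L) masses[n] <- 1.0    # one hydrogen-like rotor particle
  charge <- numeric(n)
  charge[seq_len(n_shared)] <- 0.1 * (-1)^(seq_len(n_shared))
  charge[iA1] <- 0.2; charge[iA2] <- -0.2
  eps <- numeric(n); sig <- rep(0.3, n)
  eps[seq_len(n_shared)] <- 0.25; sig[seq_len(n_shared)] <- 0.31
  eps[c(iA1, iA2)] <- 0.3
  set <- c(rep("shared", n_shared), rep("dual", n_dual))

  particles <- data.frame(id = seq_len(n), mass = masses, charge = charge,
                          eps = eps, sigma = sig, set = set,
                          stringsAsFactors = FALSE)

  kb <- 2e4; ka <- 300  # stiff bonds, moderate angles (kJ/mol/nm^2, kJ/mol/rad^2)
  bonds <- rbind(
    data.frame(a1 = seq_len(n_shared - 1L), a2 = 2L:n_shared, k = kb, r0 = r0),
    data.frame(a1 = c(na, iA1, iA2, rep(iR1, length(rotor))),
               a2 = c(iA1, iA2, iR1, rotor), k = kb, r0 = r0)
  )
  angles <- rbind(
    data.frame(a1 = seq_len(n_shared - 2L), a2 = 2L:(n_shared - 1L),
               a3 = 3L:n_shared, k = ka, theta0 = th0),
    data.frame(a1 = c(na - 1L, na, iA1, rep(iA2, length(rotor))),
               a2 = c(na, iA1, iA2, rep(iR1, length(rotor))),
               a3 = c(iA1, iA2, iR1, rotor), k = ka, theta0 = th0)
  )
  # proper dihedrals, always on. The three junction terms pin the anchor
  # orientations (single-minimum cosine with the minimum at the reference
  # geometry) so the conformer sits rigidly on the scaffold; together with
  # the rotor-internal term they are all invariant under rotation about the
  # chi axis and therefore do not bias the torsion statistics.
  pin <- function(q1, q2, q3, q4, k) {
    phi <- torsion_angle(xyz[q1, ], xyz[q2, ], xyz[q3, ], xyz[q4, ],
                         degrees = FALSE)
    data.frame(a1 = q1, a2 = q2, a3 = q3, a4 = q4, mult = 1L, k = k,
               phase = wrap_angle(phi - pi, degrees = FALSE),
               switchable = FALSE)
  }
  dihedrals <- rbind(
    # scaffold backbone pins: keep the chain semi-rigid so its collective
    # bending modes stay fast under local Monte Carlo moves
    do.call(rbind, lapply(4L:n_shared, function(i)
      pin(i - 3L, i - 2L, i - 1L, i, 100))),
    pin(na - 2L, na - 1L, na, iA1, 150),  # anchor1 azimuth about the scaffold
    pin(na - 1L, na, iA1, iA2, 150),      # anchor2 azimuth (junction)
    pin(na, iA1, iA2, iR1, 150)           # rotor-hub azimuth (chi-invariant)
  )
  if (length(rotor) >= 2L)
    dihedrals <- rbind(dihedrals,
                       data.frame(a1 = iA2, a2 = iR1, a3 = rotor[1L],
                                  a4 = rotor[2L], mult = 2L, k = 2, phase = 0,
                                  switchable = FALSE))
  chi_atoms <- c(iA1, iA2, iR1, rotor[1L])
  profiles <- list(list(atoms = chi_atoms, copy = "single", profile = profile))

  set.seed(as.integer(seed))
  xyz <- xyz + matrix(rnorm(3L * n, sd = 2e-3), n, 3L)

  topo <- new_toy_topology(
    particles = particles, bonds = bonds, angles = angles,
    dihedrals = dihedrals, profiles = profiles,
    exclusions = matrix(integer(0), 0L, 2L, dimnames = list(NULL, c("i", "j"))),
    coords = xyz,
    meta = list(n_shared = n_shared, n_dual = n_dual, seed = as.integer(seed),
                start = profile$wells$label[start], scaffold_anchor = na,
                anchors = c(iA1, iA2), rotor_hub = iR1, rotor = rotor,
                axis = c(iA2, iR1), chi_atoms = chi_atoms)
  )
  validate_topology(topo)
  topo
}

#' Combine two single-conformer topologies into a dual topology
#'
#' Builds the hybrid system containing the shared scaffold once plus both
#' conformer fragments: the `topo_a` fragment becomes the dual-RV set (real
#' at the cycle's initial state, switched off during FEP) and the `topo_b`
#' fragment the dual-VR set (switched on). The two fragments are mutually
#' non-interacting (all cross pairs excluded); proper dihedral terms of both
#' fragments are retained and flagged always-on.
#'
#' @param topo_a,topo_b `toy_topology` objects from [build_torsion_toy()]
#'   that share identical shared-set particles and differ only in the
#'   conformer coordinates.
#' @return A hybrid `toy_topology` with set labels `dual-RV`/`dual-VR`.
#' @export
build_hybrid_topology <- function(topo_a, topo_b) {
  stopifnot(inherits(topo_a, "toy_topology"), inherits(topo_b, "toy_topology"))
  sh_a <- topo_a$particles$set == "shared"
  sh_b <- topo_b$particles$set == "shared"
  if (sum(sh_a) != sum(sh_b) ||
      !isTRUE(all.equal(topo_a$particles[sh_a, ], topo_b$particles[sh_b, ],
                        tolerance = 1e-12)) ||
      !isTRUE(all.equal(topo_a$coords[sh_a, ], topo_b$coords[sh_b, ],
                        tolerance = 1e-12)))
    stop("inconsistent topology: shared sets differ between the two inputs")
  du_a <- which(topo_a$particles$set != "shared")
  du_b <- which(topo_b$particles$set != "shared")
  if (length(du_a) == 0L || length(du_b) == 0L)
    stop("inconsistent topology: empty dual set")
  if (!isTRUE(all.equal(topo_a$particles[du_a, setdiff(names(topo_a$particles), "id")],
                        topo_b$particles[du_b, setdiff(names(topo_b$particles), "id")],
                        check.attributes = FALSE, tolerance = 1e-12)))
    stop("inconsistent topology: dual-set parameters differ")

  ns <- sum(sh_a); nda <- length(du_a); ndb <- length(du_b)
  # index maps: shared keeps its indices; a-dual follows; b-dual last
  map_a <- integer(nrow(topo_a$particles)); map_a[which(sh_a)] <- seq_len(ns)
  map_a[du_a] <- ns + seq_len(nda)
  map_b <- integer(nrow(topo_b$particles)); map_b[which(sh_b)] <- seq_len(ns)
  map_b[du_b] <- ns + nda + seq_len(ndb)

  particles <- rbind(topo_a$particles[sh_a, ],
                     topo_a$particles[du_a, ],
                     topo_b$particles[du_b, ])
  particles$id <- seq_len(nrow(particles))
  particles$set <- c(rep("shared", ns), rep("dual-RV", nda), rep("dual-VR", ndb))
  rownames(particles) <- NULL

  remap_tab <- function(tab, map, k) {
    if (nrow(tab) == 0L) return(tab)
    for (cn in paste0("a", seq_len(k))) tab[[cn]] <- map[tab[[cn]]]
    tab
  }
  involves_dual <- function(tab, k, dual_idx) {
    if (nrow(tab) == 0L) return(logical(0))
    a <- as.matrix(tab[, paste0("a", seq_len(k)), drop = FALSE])
    apply(a, 1L, function(r) any(r %in% dual_idx))
  }
  bonds <- rbind(remap_tab(topo_a$bonds, map_a, 2L),
                 remap_tab(topo_b$bonds[involves_dual(topo_b$bonds, 2L, du_b), ],
                           map_b, 2L))
  angles <- rbind(remap_tab(topo_a$angles, map_a, 3L),
                  remap_tab(topo_b$angles[involves_dual(topo_b$angles, 3L, du_b), ],
                            map_b, 3L))
  dihedrals <- rbind(remap_tab(topo_a$dihedrals, map_a, 4L),
                     remap_tab(topo_b$dihedrals[involves_dual(topo_b$dihedrals, 4L, du_b), ],
                               map_b, 4L))
  dihedrals$switchable <- FALSE
  rownames(bonds) <- rownames(angles) <- rownames(dihedrals) <- NULL

  profiles <- c(
    lapply(topo_a$profiles, function(pf) {
      pf$atoms <- map_a[pf$atoms]; pf$copy <- "rv"; pf
    }),
    lapply(topo_b$profiles, function(pf) {
      pf$atoms <- map_b[pf$atoms]; pf$copy <- "vr"; pf
    })
  )

  rv_idx <- ns + seq_len(nda)
  vr_idx <- ns + nda + seq_len(ndb)
  exclusions <- as.matrix(expand.grid(i = rv_idx, j = vr_idx))

  coords <- rbind(topo_a$coords[sh_a, , drop = FALSE],
                  topo_a$coords[du_a, , drop = FALSE],
                  topo_b$coords[du_b, , drop = FALSE])

  meta <- list(
    n_shared = ns,
    scaffold_anchor = topo_a$meta$scaffold_anchor,
    rv = list(anchors = map_a[topo_a$meta$anchors],
              rotor_hub = map_a[topo_a$meta$rotor_hub],
              rotor = map_a[topo_a$meta$rotor],
              axis = map_a[topo_a$meta$axis],
              chi_atoms = map_a[topo_a$meta$chi_atoms],
              start = topo_a$meta$start),
    vr = list(anchors = map_b[topo_b$meta$anchors],
              rotor_hub = map_b[topo_b$meta$rotor_hub],
              rotor = map_b[topo_b$meta$rotor],
              axis = map_b[topo_b$meta$axis],
              chi_atoms = map_b[topo_b$meta$chi_atoms],
              start = topo_b$meta$start),
    seeds = c(topo_a$meta$seed, topo_b$meta$seed)
  )

  topo <- new_toy_topology(particles, bonds, angles, dihedrals, profiles,
                           exclusions, coords, meta)
  validate_topology(topo)
  topo
}

#' The standard two-basin toy system
#'
#' Convenience constructor for the study system used throughout the tests
#' and the worked examples: the [default_toy_profile()] with `n_shared = 8`
#' and `n_dual = 6`, built in both basins and combined into a hybrid
#' topology, together with its default restraint set.
#'
#' @param seed Integer seed passed to the coordinate jitter.
#' @param profile Optional [torsion_profile()] overriding the default.
#' @param initial Which basin is the cycle's initial (dual-RV, real) state:
#'   index or well label; default the first well (anti).
#' @param restraint_k_scale Multiplier applied to all restraint force
#'   constants (default 1).
#' @param n_shared,n_dual Particle counts forwarded to [build_torsion_toy()].
#' @return List with `hybrid` (dual `toy_topology`), `restraints`
#'   ([restraint_set()]), `profile`, `topo_initial`, `topo_final`, and
#'   `initial`/`final` well labels.
#' @export
standard_toy <- function(seed = 1L, profile = default_toy_profile(),
                         initial = 1L, restraint_k_scale = 1,
                         n_shared = 8L, n_dual = 6L) {
  if (is.character(initial)) initial <- match(initial, profile$wells$label)
  if (is.na(initial) || !initial %in% c(1L, 2L))
    stop("'initial' must identify the first or second well")
  final <- if (initial == 1L) 2L else 1L
  topo_i <- build_torsion_toy(profile, n_shared, n_dual, seed = seed, start = initial)
  topo_f <- build_torsion_toy(profile, n_shared, n_dual, seed = seed, start = final)
  hybrid <- build_hybrid_topology(topo_i, topo_f)
  restraints <- default_restraints(hybrid, profile,
                                   initial = initial, final = final,
                                   k_scale = restraint_k_scale)
  list(hybrid = hybrid, restraints = restraints, profile = profile,
       topo_initial = topo_i, topo_final = topo_f,
       initial = profile$wells$label[initial],
       final = profile$wells$label[final])
}
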