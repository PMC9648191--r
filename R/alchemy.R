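# Lambda-coupled Hamiltonian of the dual topology: Beutler-style soft-core
# switching of the conformer-environment interactions (LJ, Coulomb and the
# effective torsion profile) and linearly lambda-scaled harmonic restraints.
#
# Stage conventions follow the three-stage cycle: at the initial state the
# dual-RV conformer is real and unrestrained while the dual-VR conformer is a
# restrained ghost. The restrain stage ramps the dual-RV restraints 0 -> 1;
# the FEP stage (both conformers restrained) swaps the nonbonded coupling;
# the release stage ramps the dual-VR restraints 1 -> 0.

#' Soft-core parameters
#'
#' Radial-shift parameters of the Beutler soft-core form,
#' \eqn{r_{eff}^6 = \alpha \sigma^6 \lambda^p + r^6}, applied to the
#' vanishing side of each switched pair interaction. Defaults are
#' sc-alpha = 0.5, sc-power = 1, sc-sigma = 0.3 nm.
#'
#' @param alpha Dimensionless soft-core strength, >= 0.
#' @param power Positive integer soft-core lambda power.
#' @param sigma Soft-core radius in nm, > 0.
#' @return Object of class `softcore_params`.
#' @export
softcore_params <- function(alpha = 0.5, power = 1L, sigma = 0.3) {
  stopifnot(alpha >= 0, power >= 1, sigma > 0)
  structure(list(alpha = alpha, power = as.integer(power), sigma = sigma),
            class = "softcore_params")
}

#' One state of a coupling schedule
#'
#' @param stage One of `"restrain"`, `"fep"`, `"release"`.
#' @param lambda_restraint Restraint coupling of the stage's varying copy,
#'   in `[0,1]` (the other copy's restraints are fully on).
#' @param lambda_coul,lambda_vdw Nonbonded couplings in `[0,1]`: 0 means the
#'   dual-RV copy fully interacting and the dual-VR copy ghost, 1 the
#'   reverse.
#' @param index Position within the schedule (1-based), for bookkeeping.
#' @return Object of class `lambda_state`.
#' @export
lambda_state <- function(stage, lambda_restraint, lambda_coul, lambda_vdw,
                         index = NA_integer_) {
  stage <- match.arg(stage, c("restrain", "fep", "release"))
  for (v in c(lambda_restraint, lambda_coul, lambda_vdw))
    if (!is.finite(v) || v < 0 || v > 1) stop("lambda components must lie in [0,1]")
  structure(list(stage = stage, lambda_restraint = lambda_restraint,
                 lambda_coul = lambda_coul, lambda_vdw = lambda_vdw,
                 index = as.integer(index)),
            class = "lambda_state")
}

#' @export
print.lambda_state <- function(x, ...) {
  cat(sprintf("<lambda_state> stage=%s  lambda_R=%g  lambda_coul=%g  lambda_vdw=%g\n",
              x$stage, x$lambda_restraint, x$lambda_coul, x$lambda_vdw))
  invisible(x)
}

#' Build a lambda schedule for one stage
#'
#' @param stage `"restrain"`, `"fep"` or `"release"`.
#' @param values Numeric vector of the varying component's lambda values, in
#'   sampling order (restrain and FEP run 0 -> 1, release 1 -> 0).
#' @return List of [lambda_state()] objects.
#' @export
lambda_schedule <- function(stage, values) {
  stage <- match.arg(stage, c("restrain", "fep", "release"))
  lapply(seq_along(values), function(i) {
    v <- values[i]
    switch(stage,
      restrain = lambda_state("restrain", v, 0, 0, index = i),
      fep      = lambda_state("fep", 1, v, v, index = i),
      release  = lambda_state("release", v, 1, 1, index = i))
  })
}

#' Default lambda schedules of the three stages
#'
#' Restrain: 0, 0.05, 0.25, 0.5, 0.75, 1 (6 states). FEP: 0, 0.01, 0.025,
#' 0.05, 0.1, 0.2, 0.35, 0.5, 0.65, 0.8, 0.9, 0.95, 0.975, 0.99, 1
#' (15 states). Release: 1, 0.75, 0.5, 0.25, 0.05, 0 (6 states).
#'
#' @return Named list of three stage schedules.
#' @export
default_lambda_schedules <- function() {
  list(
    restrain = lambda_schedule("restrain", c(0, 0.05, 0.25, 0.5, 0.75, 1)),
    fep = lambda_schedule("fep", c(0, 0.01, 0.025, 0.05, 0.1, 0.2, 0.35, 0.5,
                                   0.65, 0.8, 0.9, 0.95, 0.975, 0.99, 1)),
    release = lambda_schedule("release", c(1, 0.75, 0.5, 0.25, 0.05, 0))
  )
}

#' Per-copy restraint multipliers of a lambda state
#'
#' Restrain stage: dual-RV restraints scale with `lambda_restraint`, dual-VR
#' fully on. FEP: both fully on. Release: dual-VR scales with
#' `lambda_restraint`, dual-RV fully on. Single-topology (`"single"`)
#' restraints always scale with `lambda_restraint`.
#'
#' @param state A [lambda_state()].
#' @return Named numeric vector with elements `rv`, `vr`, `single`.
#' @export
restraint_multipliers <- function(state) {
  stopifnot(inherits(state, "lambda_state"))
  lr <- state$lambda_restraint
  switch(state$stage,
    restrain = c(rv = lr, vr = 1, single = lr),
    fep      = c(rv = 1, vr = 1, single = 1),
    release  = c(rv = 1, vr = lr, single = lr))
}

## ---------------------------------------------------------------------------
## Restraints

#' Harmonic restraint set
#'
#' Container for the four restraint kinds used to hold a conformer in its
#' basin: torsion, distance, angle, and center-of-mass pseudodihedral
#' restraints. Angular equilibria are wrapped to `(-180, 180]` degrees;
#' energies are harmonic in the minimal-image deviation.
#'
#' @param torsions `data.frame(a1, a2, a3, a4, eq_deg, k, copy)` with `k` in
#'   kJ/mol/rad^2 and `copy` one of `"rv"`, `"vr"`, `"single"`.
#' @param distances `data.frame(a1, a2, r0, k, copy)` with `r0` nm and `k`
#'   kJ/mol/nm^2.
#' @param angles `data.frame(a1, a2, a3, eq_deg, k, copy)`.
#' @param pseudodihedrals List of entries `list(groups, weights, eq_deg, k,
#'   copy)` where `groups` is a list of four index vectors and `weights` the
#'   matching mass weights.
#' @return Object of class `restraint_set`.
#' @export
restraint_set <- function(torsions = NULL, distances = NULL, angles = NULL,
                          pseudodihedrals = list()) {
  empty <- function(cols) as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
  if (is.null(torsions)) torsions <- empty(c("a1","a2","a3","a4","eq_deg","k","copy"))
  if (is.null(distances)) distances <- empty(c("a1","a2","r0","k","copy"))
  if (is.null(angles)) angles <- empty(c("a1","a2","a3","eq_deg","k","copy"))
  for (tab in list(torsions, distances, angles))
    if (nrow(tab) > 0L && any(tab$k < 0)) stop("restraint force constants must be >= 0")
  torsions$eq_deg <- wrap_angle(torsions$eq_deg)
  angles$eq_deg <- wrap_angle(angles$eq_deg)
  pseudodihedrals <- lapply(pseudodihedrals, function(p) {
    stopifnot(length(p$groups) == 4L, length(p$weights) == 4L)
    if (p$k < 0) stop("restraint force constants must be >= 0")
    if (any(unlist(p$weights) <= 0)) stop("pseudodihedral weights must be positive")
    p$eq_deg <- wrap_angle(p$eq_deg)
    p
  })
  structure(list(torsions = torsions, distances = distances, angles = angles,
                 pseudodihedrals = pseudodihedrals),
            class = "restraint_set")
}

#' @export
print.restraint_set <- function(x, ...) {
  cat(sprintf("<restraint_set> %d torsion, %d distance, %d angle, %d pseudodihedral restraints\n",
              nrow(x$torsions), nrow(x$distances), nrow(x$angles),
              length(x$pseudodihedrals)))
  invisible(x)
}

#' Default restraint set of a hybrid toy topology
#'
#' Builds, for each conformer copy, a glycosyl-like torsion restraint at its
#' basin center plus hydrogen-bond-like distance and angle restraints and a
#' base-flipping pseudodihedral restraint anchored through the conformer
#' anchors (chi-independent coordinates). Equilibria other than the torsion
#' centers are measured from the reference geometry and are identical for
#' the two copies, so the restrained ghost copies contribute equally to the
#' two cycle end states. Default force constant 1000 kJ/mol/rad^2 (angles,
#' torsions) and 1000 kJ/mol/nm^2 (distances).
#'
#' @param hybrid A hybrid `toy_topology` from [build_hybrid_topology()].
#' @param profile The [torsion_profile()] of the system.
#' @param initial,final Well indices of the dual-RV and dual-VR basins.
#' @param k_scale Multiplier on all force constants.
#' @param k_base Base force constant (1000 in the package units).
#' @return A [restraint_set()].
#' @export
default_restraints <- function(hybrid, profile, initial = 1L, final = 2L,
                               k_scale = 1, k_base = 1000) {
  stopifnot(inherits(hybrid, "toy_topology"))
  m <- hybrid$meta
  if (is.null(m$rv)) stop("default_restraints needs a hybrid topology")
  k <- k_base * k_scale
  xyz <- hybrid$coords
  masses <- hybrid$particles$mass
  ns <- m$n_shared
  anchor_target <- min(ns, m$scaffold_anchor + 2L)  # a scaffold atom past the anchor

  eq_dist <- sqrt(sum((xyz[m$rv$anchors[2L], ] - xyz[anchor_target, ])^2))
  eq_ang <- angle_between(xyz[m$scaffold_anchor, ], xyz[m$rv$anchors[1L], ],
                          xyz[m$rv$anchors[2L], ]) * 180 / pi
  pd_groups_rv <- list(1:3, m$scaffold_anchor, m$rv$anchors[1L], m$rv$anchors[2L])
  pd_groups_vr <- list(1:3, m$scaffold_anchor, m$vr$anchors[1L], m$vr$anchors[2L])
  pd_spec <- pseudodihedral_spec(pd_groups_rv)
  eq_pd <- pseudodihedral(pd_spec, xyz, masses)

  restraint_set(
    torsions = data.frame(
      a1 = c(m$rv$chi_atoms[1L], m$vr$chi_atoms[1L]),
      a2 = c(m$rv$chi_atoms[2L], m$vr$chi_atoms[2L]),
      a3 = c(m$rv$chi_atoms[3L], m$vr$chi_atoms[3L]),
      a4 = c(m$rv$chi_atoms[4L], m$vr$chi_atoms[4L]),
      eq_deg = c(profile$wells$center_deg[initial], profile$wells$center_deg[final]),
      k = k, copy = c("rv", "vr"), stringsAsFactors = FALSE),
    distances = data.frame(
      a1 = c(m$rv$anchors[2L], m$vr$anchors[2L]),
      a2 = anchor_target, r0 = eq_dist, k = k,
      copy = c("rv", "vr"), stringsAsFactors = FALSE),
    angles = data.frame(
      a1 = m$scaffold_anchor,
      a2 = c(m$rv$anchors[1L], m$vr$anchors[1L]),
      a3 = c(m$rv$anchors[2L], m$vr$anchors[2L]),
      eq_deg = eq_ang, k = k, copy = c("rv", "vr"), stringsAsFactors = FALSE),
    pseudodihedrals = list(
      list(groups = pd_groups_rv, weights = lapply(pd_groups_rv, function(g) masses[g]),
           eq_deg = eq_pd, k = k, copy = "rv"),
      list(groups = pd_groups_vr, weights = lapply(pd_groups_vr, function(g) masses[g]),
           eq_deg = eq_pd, k = k, copy = "vr")
    )
  )
}

angle_between <- function(p1, p2, p3) {
  v1 <- p1 - p2; v2 <- p3 - p2
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(min(1, max(-1, cosang)))
}

#' Harmonic restraint energy
#'
#' \eqn{\lambda \sum \frac{1}{2} k \Delta^2} over all restraints (optionally
#' of one conformer copy), with angular deviations wrapped to
#' `(-180, 180]` degrees (minimal image on the circle).
#'
#' @param coords n x 3 coordinate matrix (nm).
#' @param restraints A [restraint_set()].
#' @param lambda_restraint Coupling in `[0,1]`.
#' @param copy Optional: restrict to restraints of one copy
#'   (`"rv"`, `"vr"`, `"single"`).
#' @return Energy in kJ/mol. Degenerate torsion geometry raises an
#'   undefined-angle error rather than returning 0.
#' @export
restraint_energy <- function(coords, restraints, lambda_restraint = 1,
                             copy = NULL) {
  stopifnot(inherits(restraints, "restraint_set"))
  coords <- as.matrix(coords)
  keep <- function(copies) if (is.null(copy)) rep(TRUE, length(copies)) else copies == copy
  e <- 0
  tt <- restraints$torsions[keep(restraints$torsions$copy), , drop = FALSE]
  for (i in seq_len(nrow(tt))) {
    phi <- torsion_angle(coords[tt$a1[i], ], coords[tt$a2[i], ],
                         coords[tt$a3[i], ], coords[tt$a4[i], ])
    d <- wrap_angle(phi - tt$eq_deg[i]) * pi / 180
    e <- e + 0.5 * tt$k[i] * d^2
  }
  dd <- restraints$distances[keep(restraints$distances$copy), , drop = FALSE]
  for (i in seq_len(nrow(dd))) {
    r <- sqrt(sum((coords[dd$a1[i], ] - coords[dd$a2[i], ])^2))
    e <- e + 0.5 * dd$k[i] * (r - dd$r0[i])^2
  }
  aa <- restraints$angles[keep(restraints$angles$copy), , drop = FALSE]
  for (i in seq_len(nrow(aa))) {
    th <- angle_between(coords[aa$a1[i], ], coords[aa$a2[i], ], coords[aa$a3[i], ])
    d <- wrap_angle(th * 180 / pi - aa$eq_deg[i]) * pi / 180
    e <- e + 0.5 * aa$k[i] * d^2
  }
  for (p in restraints$pseudodihedrals) {
    if (!is.null(copy) && p$copy != copy) next
    centers <- lapply(seq_len(4L), function(g) {
      w <- p$weights[[g]]
      colSums(coords[p$groups[[g]], , drop = FALSE] * w) / sum(w)
    })
    phi <- torsion_angle(centers[[1L]], centers[[2L]], centers[[3L]], centers[[4L]])
    d <- wrap_angle(phi - p$eq_deg) * pi / 180
    e <- e + 0.5 * p$k * d^2
  }
  lambda_restraint * e
}

## ---------------------------------------------------------------------------
## Soft-core pair energy

#' Soft-core switched pair interaction
#'
#' Lambda-interpolated Lennard-Jones plus Coulomb energy of one pair with
#' Beutler radial shifting applied to the vanishing side:
#' \deqn{V = (1-\lambda) V_A(r_A) + \lambda V_B(r_B)} with
#' \eqn{r_A^6 = \alpha \sigma_{sc}^6 \lambda^p + r^6} and
#' \eqn{r_B^6 = \alpha \sigma_{sc}^6 (1-\lambda)^p + r^6}. The same
#' effective radius (driven by `lambda_vdw`) is used for the LJ and Coulomb
#' parts of each side; the interpolation weight of the Coulomb part is
#' `lambda_coul`. Finite at `r = 0` for lambda strictly between 0 and 1,
#' and exactly the unsoftened end-state potential at lambda 0 or 1.
#'
#' @param r Pair distance in nm, >= 0 (vectorized).
#' @param lambda_coul,lambda_vdw Couplings in `[0,1]`.
#' @param pairA,pairB End-state pair parameters: lists with `eps` (kJ/mol),
#'   `sigma` (nm), `qq` (charge product, e^2). A ghost end state has
#'   `eps = 0, qq = 0`.
#' @param sc [softcore_params()].
#' @return Energy in kJ/mol.
#' @export
softcore_pair_energy <- function(r, lambda_coul, lambda_vdw, pairA, pairB,
                                 sc = softcore_params()) {
  stopifnot(all(r >= 0))
  f <- rfepr_constants$COULOMB_KJ
  side <- function(par, lam_off, wv, wc) {
    # lam_off: decoupling progress of this side (shift magnitude)
    r6 <- sc$alpha * sc$sigma^6 * lam_off^sc$power + r^6
    out <- numeric(length(r))
    if (par$eps != 0) {
      s6 <- par$sigma^6 / r6
      out <- out + wv * 4 * par$eps * (s6^2 - s6)
    }
    if (par$qq != 0) out <- out + wc * f * par$qq / r6^(1 / 6)
    out
  }
  side(pairA, lambda_vdw, 1 - lambda_vdw, 1 - lambda_coul) +
    side(pairB, 1 - lambda_vdw, lambda_vdw, lambda_coul)
}

## ---------------------------------------------------------------------------
## Pair list and full potential

bonded_excluded_pairs <- function(topo) {
  # 1-2 (bond) and 1-3 (angle end) neighbours, plus explicit exclusions
  ex <- rbind(
    cbind(topo$bonds$a1, topo$bonds$a2),
    if (nrow(topo$angles) > 0L) cbind(topo$angles$a1, topo$angles$a3),
    topo$exclusions
  )
  unique(t(apply(ex, 1L, sort)))
}

#' Nonbonded pair list of a toy topology
#'
#' Pairs between the conformer set(s) and the shared set, excluding 1-2 and
#' 1-3 bonded neighbours and the explicit dual-RV/dual-VR exclusions, with
#' Lorentz-Berthelot combination. Pairs whose combined parameters vanish are
#' dropped.
#'
#' @param topo A `toy_topology`.
#' @return `data.frame(a1, a2, qq, eps, sigma, group)` with `group` in
#'   `"single"`, `"rv"`, `"vr"`.
#' @export
nonbonded_pairs <- function(topo) {
  p <- topo$particles
  sh <- which(p$set == "shared")
  groups <- list(single = which(p$set == "dual"),
                 rv = which(p$set == "dual-RV"),
                 vr = which(p$set == "dual-VR"))
  ex <- bonded_excluded_pairs(topo)
  ex_key <- paste(ex[, 1L], ex[, 2L])
  out <- list()
  for (g in names(groups)) {
    du <- groups[[g]]
    if (length(du) == 0L) next
    grid <- expand.grid(a1 = du, a2 = sh)
    key <- paste(pmin(grid$a1, grid$a2), pmax(grid$a1, grid$a2))
    grid <- grid[!key %in% ex_key, , drop = FALSE]
    qq <- p$charge[grid$a1] * p$charge[grid$a2]
    eps <- sqrt(p$eps[grid$a1] * p$eps[grid$a2])
    sigma <- (p$sigma[grid$a1] + p$sigma[grid$a2]) / 2
    live <- qq != 0 | eps != 0
    if (!any(live)) next
    out[[g]] <- data.frame(a1 = grid$a1[live], a2 = grid$a2[live],
                           qq = qq[live], eps = eps[live], sigma = sigma[live],
                           group = g, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(a1 = integer(0), a2 = integer(0), qq = numeric(0),
                      eps = numeric(0), sigma = numeric(0), group = character(0))
  rownames(res) <- NULL
  res
}

group_coupling <- function(group, lambda_coul, lambda_vdw) {
  # weights (wv, wc) and decoupling progress (soft-core shift) per group
  switch(group,
    single = list(wv = 1, wc = 1, off = 0),
    rv = list(wv = 1 - lambda_vdw, wc = 1 - lambda_coul, off = lambda_vdw),
    vr = list(wv = lambda_vdw, wc = lambda_coul, off = 1 - lambda_vdw))
}

#' Potential-energy components of a configuration
#'
#' Term-by-term reference evaluation of the toy Hamiltonian at one lambda
#' state: bonded scaffold terms, always-on proper dihedrals, the switched
#' torsion profiles, soft-core switched nonbonded pairs, and lambda-scaled
#' restraints. This is the plain (naive) evaluator that the fast compiled
#' path is validated against.
#'
#' @param coords n x 3 coordinate matrix (nm).
#' @param topo A `toy_topology`.
#' @param restraints A [restraint_set()] (or `NULL` for none).
#' @param state A [lambda_state()].
#' @param sc [softcore_params()].
#' @return Named numeric vector of energy components in kJ/mol: `bonds`,
#'   `angles`, `dihedrals`, `profile`, `nonbonded`, `restraints`.
#' @export
energy_components <- function(coords, topo, restraints = NULL,
                              state = lambda_state("restrain", 0, 0, 0),
                              sc = softcore_params()) {
  coords <- as.matrix(coords)
  e_bond <- 0
  for (i in seq_len(nrow(topo$bonds))) {
    b <- topo$bonds[i, ]
    r <- sqrt(sum((coords[b$a1, ] - coords[b$a2, ])^2))
    e_bond <- e_bond + 0.5 * b$k * (r - b$r0)^2
  }
  e_ang <- 0
  for (i in seq_len(nrow(topo$angles))) {
    a <- topo$angles[i, ]
    th <- angle_between(coords[a$a1, ], coords[a$a2, ], coords[a$a3, ])
    e_ang <- e_ang + 0.5 * a$k * (th - a$theta0)^2
  }
  e_dih <- 0
  for (i in seq_len(nrow(topo$dihedrals))) {
    d <- topo$dihedrals[i, ]
    phi <- torsion_angle(coords[d$a1, ], coords[d$a2, ], coords[d$a3, ],
                         coords[d$a4, ], degrees = FALSE)
    e_dih <- e_dih + d$k * (1 + cos(d$mult * phi - d$phase))
  }
  e_prof <- 0
  for (pf in topo$profiles) {
    cpl <- group_coupling(if (pf$copy == "single") "single" else pf$copy,
                          state$lambda_coul, state$lambda_vdw)$wv
    if (cpl == 0) next
    chi <- torsion_angle(coords[pf$atoms[1L], ], coords[pf$atoms[2L], ],
                         coords[pf$atoms[3L], ], coords[pf$atoms[4L], ])
    e_prof <- e_prof + cpl * torsion_potential(pf$profile, chi)
  }
  pairs <- nonbonded_pairs(topo)
  e_nb <- 0
  for (i in seq_len(nrow(pairs))) {
    pr <- pairs[i, ]
    cpl <- group_coupling(pr$group, state$lambda_coul, state$lambda_vdw)
    if (cpl$wv == 0 && cpl$wc == 0) next
    r <- sqrt(sum((coords[pr$a1, ] - coords[pr$a2, ])^2))
    r6 <- sc$alpha * sc$sigma^6 * cpl$off^sc$power + r^6
    s6 <- pr$sigma^6 / r6
    e_nb <- e_nb + cpl$wv * 4 * pr$eps * (s6^2 - s6) +
      cpl$wc * rfepr_constants$COULOMB_KJ * pr$qq / r6^(1 / 6)
  }
  e_res <- 0
  if (!is.null(restraints)) {
    mult <- restraint_multipliers(state)
    for (cp in names(mult)) {
      if (mult[[cp]] == 0) next
      e_res <- e_res + mult[[cp]] *
        restraint_energy(coords, restraints, lambda_restraint = 1, copy = cp)
    }
  }
  c(bonds = e_bond, angles = e_ang, dihedrals = e_dih, profile = e_prof,
    nonbonded = e_nb, restraints = e_res)
}

#' Reduced potential of a configuration in a lambda state
#'
#' \eqn{u = U_{total} / RT} with the stage coupling conventions: dual-RV
#' switched terms scale with \eqn{1-\lambda}, dual-VR with \eqn{\lambda},
#' proper dihedrals of both copies always included, restraints per
#' [restraint_multipliers()].
#'
#' @inheritParams energy_components
#' @param thermo A [thermo_state()] or temperature in K.
#' @return Dimensionless reduced potential with attribute `components`
#'   (kJ/mol). Non-finite energies raise an error naming the offending term.
#' @export
reduced_potential <- function(coords, topo, restraints, state,
                              thermo = thermo_state(300),
                              sc = softcore_params()) {
  th <- as_thermo(thermo)
  comp <- energy_components(coords, topo, restraints, state, sc)
  if (any(!is.finite(comp)))
    stop("non-finite energy in term(s): ",
         paste(names(comp)[!is.finite(comp)], collapse = ", "))
  structure(sum(comp) / th$RT_kj, components = comp)
}
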