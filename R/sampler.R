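# Metropolis Monte Carlo sampling of the lambda states and assembly of the
# cross-evaluated reduced-potential matrix. The move set mixes
# single-particle Cartesian displacements with collective rotations of each
# conformer rotor about its torsion axis; step sizes are tuned to 30-50%
# acceptance during burn-in and then frozen so the post-burn-in chain
# satisfies detailed balance exactly.

#' Flatten a topology and restraint set for the compiled kernel
#'
#' Internal-format tables consumed by the C++ sampler and batch evaluator.
#' Exposed because the tables are reusable across states and stages.
#'
#' @param topo A `toy_topology`.
#' @param restraints A [restraint_set()] or `NULL`.
#' @param sc [softcore_params()].
#' @return A list of numeric matrices/vectors (opaque, documented in the
#'   source).
#' @keywords internal
#' @export
topology_tables <- function(topo, restraints = NULL, sc = softcore_params()) {
  stopifnot(inherits(topo, "toy_topology"))
  deg2rad <- pi / 180
  m0 <- function(ncol) matrix(numeric(0), 0L, ncol)
  copy_code <- function(copy) match(copy, c("single", "rv", "vr")) - 1L

  bonds <- if (nrow(topo$bonds)) as.matrix(topo$bonds[, c("a1","a2","k","r0")]) else m0(4L)
  angles <- if (nrow(topo$angles)) as.matrix(topo$angles[, c("a1","a2","a3","k","theta0")]) else m0(5L)
  dihedrals <- if (nrow(topo$dihedrals))
    as.matrix(topo$dihedrals[, c("a1","a2","a3","a4","mult","k","phase")]) else m0(7L)

  np <- length(topo$profiles)
  prof_terms <- m0(5L); prof_wells <- m0(4L)
  if (np > 0L) {
    prof_terms <- t(vapply(topo$profiles, function(pf) {
      g <- switch(pf$copy, single = 0, rv = 1, vr = 2)
      c(pf$atoms, g)
    }, numeric(5L)))
    prof_wells <- do.call(rbind, lapply(seq_len(np), function(i) {
      w <- topo$profiles[[i]]$profile$wells
      cbind(i, w$center_deg * deg2rad, w$depth, w$curvature)
    }))
  }

  pr <- nonbonded_pairs(topo)
  pairs <- if (nrow(pr))
    cbind(pr$a1, pr$a2, pr$qq, pr$eps, pr$sigma,
          vapply(pr$group, function(g) switch(g, single = 0, rv = 1, vr = 2), 0))
  else m0(6L)

  rt <- m0(7L); rd <- m0(5L); ra <- m0(6L)
  rp_idx <- integer(0); rp_w <- numeric(0); rp_off <- m0(5L); rp_par <- m0(3L)
  if (!is.null(restraints)) {
    if (nrow(restraints$torsions))
      rt <- cbind(restraints$torsions$a1, restraints$torsions$a2,
                  restraints$torsions$a3, restraints$torsions$a4,
                  restraints$torsions$eq_deg * deg2rad, restraints$torsions$k,
                  copy_code(restraints$torsions$copy))
    if (nrow(restraints$distances))
      rd <- cbind(restraints$distances$a1, restraints$distances$a2,
                  restraints$distances$r0, restraints$distances$k,
                  copy_code(restraints$distances$copy))
    if (nrow(restraints$angles))
      ra <- cbind(restraints$angles$a1, restraints$angles$a2,
                  restraints$angles$a3, restraints$angles$eq_deg * deg2rad,
                  restraints$angles$k, copy_code(restraints$angles$copy))
    if (length(restraints$pseudodihedrals)) {
      offs <- list(); pars <- list()
      for (p in restraints$pseudodihedrals) {
        o <- length(rp_idx)
        starts <- numeric(5L); starts[1L] <- o
        for (g in seq_len(4L)) {
          rp_idx <- c(rp_idx, p$groups[[g]])
          rp_w <- c(rp_w, p$weights[[g]])
          starts[g + 1L] <- length(rp_idx)
        }
        offs[[length(offs) + 1L]] <- starts
        pars[[length(pars) + 1L]] <- c(p$eq_deg * deg2rad, p$k, copy_code(p$copy))
      }
      rp_off <- do.call(rbind, offs)
      rp_par <- do.call(rbind, pars)
    }
  }

  # rotor move specification: one collective torsion move per conformer copy
  rot_idx <- integer(0); rot_off <- 0L; rot_axis <- matrix(integer(0), 0L, 2L)
  add_copy <- function(meta_copy) {
    rot_idx <<- c(rot_idx, as.integer(meta_copy$rotor))
    rot_off <<- c(rot_off, length(rot_idx))
    rot_axis <<- rbind(rot_axis, as.integer(meta_copy$axis))
  }
  if (!is.null(topo$meta$rv)) { add_copy(topo$meta$rv); add_copy(topo$meta$vr) }
  else if (!is.null(topo$meta$rotor)) add_copy(topo$meta)

  list(n = nrow(topo$particles), bonds = bonds, angles = angles,
       dihedrals = dihedrals, prof_terms = prof_terms, prof_wells = prof_wells,
       pairs = pairs, rt = rt, rd = rd, ra = ra,
       rp_idx = as.integer(rp_idx), rp_w = rp_w, rp_off = rp_off, rp_par = rp_par,
       sc = c(sc$alpha, sc$power, sc$sigma),
       fcoul = rfepr_constants$COULOMB_KJ,
       rot_idx = as.integer(rot_idx), rot_off = as.integer(rot_off),
       rot_axis = rot_axis)
}

state_vector <- function(state) {
  mult <- restraint_multipliers(state)
  c(state$lambda_coul, state$lambda_vdw, mult[["rv"]], mult[["vr"]],
    mult[["single"]])
}

#' Sample one lambda state by Metropolis Monte Carlo
#'
#' Runs a detailed-balance Markov chain at the reduced potential of `state`.
#' The first `burn_frac` of the sweeps are discarded as equilibration
#' (during which step sizes adapt); afterwards configurations are recorded
#' every `stride` sweeps.
#'
#' @param topo A `toy_topology`.
#' @param restraints A [restraint_set()] or `NULL`.
#' @param state A [lambda_state()].
#' @param n_sweeps Total MC sweeps (> 0). One sweep is one trial move per
#'   particle plus one collective rotor rotation per conformer copy.
#' @param seed Integer RNG seed; identical seeds give bit-identical
#'   trajectories.
#' @param thermo A [thermo_state()] or temperature in K.
#' @param stride Sweeps between recorded frames.
#' @param burn_frac Fraction of sweeps discarded as burn-in.
#' @param step_disp,step_tor Initial displacement (nm) and rotor rotation
#'   (rad) step sizes.
#' @param adapt Tune step sizes during burn-in (default `TRUE`).
#' @param start Optional n x 3 starting coordinates (defaults to
#'   `topo$coords`).
#' @param n_log Number of post-burn-in proposals to log (columns: reduced
#'   energy change, uniform draw, accepted), for detailed-balance audits.
#' @param sc [softcore_params()].
#' @return Object of class `rfepr_trajectory`: list with `frames`
#'   (n_frames x 3n matrix), `sweep` (recorded sweep indices), `state`,
#'   `acceptance`, `steps`, `seed`, `proposal_log`, `final_coords`.
#' @export
metropolis_sample <- function(topo, restraints, state, n_sweeps, seed,
                              thermo = thermo_state(300), stride = 10L,
                              burn_frac = 0.1, step_disp = 0.02,
                              step_tor = 0.3, adapt = TRUE, start = NULL,
                              n_log = 0L, sc = softcore_params()) {
  stopifnot(inherits(state, "lambda_state"))
  n_sweeps <- as.integer(n_sweeps)
  if (n_sweeps <= 0L) stop("n_sweeps must be > 0")
  th <- as_thermo(thermo)
  tables <- if (is.list(topo) && !inherits(topo, "toy_topology")) topo
            else topology_tables(topo, restraints, sc)
  coords <- if (is.null(start)) {
    if (inherits(topo, "toy_topology")) topo$coords else stop("need start coordinates")
  } else as.matrix(start)
  burn <- as.integer(floor(burn_frac * n_sweeps))
  set.seed(as.integer(seed))
  res <- cpp_metropolis(as.numeric(t(coords)), tables, state_vector(state),
                        1 / th$RT_kj, n_sweeps, burn, as.integer(stride),
                        step_disp, step_tor, isTRUE(adapt), as.integer(n_log))
  if (isTRUE(res$adapt_fail))
    warning("step-size adaptation failure: zero acceptance over a calibration block")
  n_frames <- nrow(res$frames)
  structure(
    list(frames = res$frames,
         sweep = if (n_frames > 0L) burn + seq_len(n_frames) * as.integer(stride) else integer(0),
         state = state, acceptance = res$acceptance, steps = res$steps,
         seed = as.integer(seed), n_sweeps = n_sweeps, burn_sweeps = burn,
         stride = as.integer(stride),
         proposal_log = res$proposal_log, final_coords = res$final_coords,
         temperature = th$temperature),
    class = "rfepr_trajectory")
}

#' @export
print.rfepr_trajectory <- function(x, ...) {
  cat(sprintf("<rfepr_trajectory> %d frames (stride %d, burn-in %d of %d sweeps), stage %s\n",
              nrow(x$frames), x$stride, x$burn_sweeps, x$n_sweeps, x$state$stage))
  cat(sprintf("  acceptance: displacement %.2f, torsion %.2f; seed %d\n",
              x$acceptance[["displacement"]], x$acceptance[["torsion"]], x$seed))
  invisible(x)
}

#' Extract one frame of a trajectory as an n x 3 matrix
#' @param traj An `rfepr_trajectory`.
#' @param i Frame index.
#' @return n x 3 coordinate matrix.
#' @export
traj_frame <- function(traj, i) {
  matrix(traj$frames[i, ], ncol = 3L, byrow = TRUE)
}

#' Torsion time series of a trajectory
#' @param traj An `rfepr_trajectory`.
#' @param atoms Integer quadruple of particle indices.
#' @return Numeric vector of torsion angles in degrees, one per frame.
#' @export
traj_torsion <- function(traj, atoms) {
  vapply(seq_len(nrow(traj$frames)), function(i) {
    x <- traj_frame(traj, i)
    torsion_angle(x[atoms[1L], ], x[atoms[2L], ], x[atoms[3L], ], x[atoms[4L], ])
  }, 0.0)
}

#' Cross-evaluated reduced-potential matrix
#'
#' Evaluates every stored configuration of every state's trajectory under
#' every lambda state of the stage, producing the K x N matrix `u_kn` and
#' per-state sample counts `N_k` consumed by [mbar_solve()]. Columns are
#' ordered state by state, chronologically within each state.
#'
#' @param trajectories List of `rfepr_trajectory`, one per state, in the
#'   same order as `states`.
#' @param states List of [lambda_state()] defining the stage's schedule.
#' @param topo,restraints,sc The Hamiltonian definition the trajectories
#'   were sampled from.
#' @param thermo A [thermo_state()] or temperature in K.
#' @return Object of class `u_kn`: list with `u` (K x N), `N_k`,
#'   `states`, `origin` (sampling-state index per column).
#' @export
collect_u_kn <- function(trajectories, states, topo, restraints,
                         thermo = thermo_state(300), sc = softcore_params()) {
  K <- length(states)
  if (length(trajectories) != K)
    stop("state list inconsistent with trajectory provenance: lengths differ")
  for (k in seq_len(K)) {
    st <- trajectories[[k]]$state
    if (!isTRUE(all.equal(unclass(st)[c("stage", "lambda_restraint", "lambda_coul", "lambda_vdw")],
                          unclass(states[[k]])[c("stage", "lambda_restraint", "lambda_coul", "lambda_vdw")])))
      stop("state list inconsistent with trajectory provenance: state ", k,
           " does not match its trajectory")
    if (nrow(trajectories[[k]]$frames) < 1L)
      stop("every state must contribute at least one sample")
  }
  th <- as_thermo(thermo)
  tables <- topology_tables(topo, restraints, sc)
  frames <- do.call(rbind, lapply(trajectories, `[[`, "frames"))
  smat <- do.call(rbind, lapply(states, state_vector))
  u <- cpp_eval_states(frames, tables, smat, 1 / th$RT_kj)
  if (any(!is.finite(u))) stop("non-finite reduced potential in cross-evaluation")
  N_k <- vapply(trajectories, function(tr) nrow(tr$frames), 0L)
  new_u_kn(u, N_k, states)
}

#' Construct a reduced-potential matrix object
#'
#' @param u K x N matrix of reduced potentials (state k, sample n).
#' @param N_k Integer vector of per-state sample counts summing to N;
#'   columns must be grouped by sampling state, chronologically ordered
#'   within each state.
#' @param states Optional list of [lambda_state()] labels.
#' @return Object of class `u_kn`.
#' @export
new_u_kn <- function(u, N_k, states = NULL) {
  u <- as.matrix(u)
  dimnames(u) <- NULL
  N_k <- as.integer(N_k)
  if (sum(N_k) != ncol(u)) stop("sum(N_k) must equal ncol(u)")
  if (length(N_k) != nrow(u)) stop("length(N_k) must equal nrow(u)")
  if (any(!is.finite(u))) stop("u_kn entries must be finite")
  structure(list(u = u, N_k = N_k, states = states,
                 origin = rep(seq_along(N_k), N_k)),
            class = "u_kn")
}

#' @export
print.u_kn <- function(x, ...) {
  cat(sprintf("<u_kn> %d states x %d samples (N_k: %s)\n", nrow(x$u), ncol(x$u),
              paste(x$N_k, collapse = ", ")))
  invisible(x)
}

#' Statistical inefficiency of a time series
#'
#' \eqn{g = 1 + 2 \sum_t C(t)} with the normalized autocorrelation sum
#' truncated at its first nonpositive value, clamped to `g >= 1`. Used to
#' subsample correlated samples to an effectively independent set.
#'
#' @param series Numeric vector, length >= 10.
#' @return `g >= 1`. A constant series returns `length(series)` (fully
#'   correlated) with a warning.
#' @examples
#' statistical_inefficiency(rnorm(1000)) # near 1
#' @export
statistical_inefficiency <- function(series) {
  n <- length(series)
  if (n < 10L) stop("series too short (need length >= 10)")
  if (var(series) == 0) {
    warning("constant series: statistical inefficiency set to series length")
    return(n)
  }
  rho <- as.numeric(stats::acf(series, lag.max = n - 1L, plot = FALSE,
                               demean = TRUE)$acf)[-1L]
  stop_at <- which(rho <= 0)
  if (length(stop_at)) rho <- rho[seq_len(stop_at[1L] - 1L)]
  max(1, 1 + 2 * sum(rho))
}

#' Subsample a reduced-potential matrix to independent frames
#'
#' Computes the statistical inefficiency of each state's own-state reduced
#' potential series and keeps every ceiling(g)-th frame. By default the
#' whole stage is thinned by the largest per-state inefficiency: that is
#' conservative for every state (never under-thins) and keeps the
#' per-state sample counts balanced, so the overlap diagnostic reflects
#' ensemble overlap rather than count imbalance.
#'
#' @param ukn A `u_kn` object with chronologically ordered columns.
#' @param g Optional numeric vector of per-state inefficiencies overriding
#'   the estimate.
#' @param uniform Thin every state by `max(g)` (default) instead of its own
#'   inefficiency.
#' @return A thinned `u_kn`, with attribute `g` (per-state inefficiencies,
#'   before any uniformization) and `g_used` (the thinning factors applied).
#' @export
subsample_u_kn <- function(ukn, g = NULL, uniform = TRUE) {
  stopifnot(inherits(ukn, "u_kn"))
  K <- length(ukn$N_k)
  offs <- c(0L, cumsum(ukn$N_k))
  if (is.null(g)) {
    g <- vapply(seq_len(K), function(k) {
      cols <- (offs[k] + 1L):offs[k + 1L]
      series <- ukn$u[k, cols]
      if (length(series) < 10L || var(series) == 0) 1 else statistical_inefficiency(series)
    }, 0.0)
  }
  g_used <- if (isTRUE(uniform)) rep(max(g), K) else g
  keep <- lapply(seq_len(K), function(k) {
    cols <- (offs[k] + 1L):offs[k + 1L]
    cols[seq(1L, length(cols), by = max(1L, ceiling(g_used[k])))]
  })
  res <- new_u_kn(ukn$u[, unlist(keep), drop = FALSE], lengths(keep), ukn$states)
  attr(res, "g") <- g
  attr(res, "g_used") <- g_used
  res
}
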