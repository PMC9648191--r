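# Geometric observables: torsions, center-of-mass pseudodihedrals,
# hydrogen-bond geometry, basin assignment and Boltzmann population
# conversion. Angle sign convention is IUPAC: looking down the p2 -> p3
# axis, a clockwise rotation of the far bond is positive; cis = 0 and
# trans = 180 degrees (fixed by the unit tests).

#' Wrap an angle to a symmetric interval
#'
#' Minimal-image convention on the circle: the result lies in `(-180, 180]`
#' degrees or `(-pi, pi]` radians.
#'
#' @param x Angle(s).
#' @param degrees If `TRUE` (default) `x` is in degrees, else radians.
#' @return Wrapped angle(s), same units as input.
#' @examples
#' wrap_angle(285)   # -75
#' wrap_angle(-180)  # 180
#' @export
wrap_angle <- function(x, degrees = TRUE) {
  period <- if (degrees) 360 else 2 * pi
  y <- x - period * round(x / period)
  # round() maps half-integers to even, so force the boundary to +period/2
  y[y == -period / 2] <- period / 2
  y
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Signed dihedral angle of four points
#'
#' Computes the torsion angle defined by four positions, e.g. a glycosyl-like
#' torsion chi over atoms (O4'-C1'-N9-C4 in a purine nucleotide).
#'
#' @param p1,p2,p3,p4 Numeric length-3 coordinate vectors (nm, or any
#'   consistent length unit).
#' @param degrees Return degrees (default) or radians.
#' @return Signed angle in `(-180, 180]` degrees (or `(-pi, pi]` rad).
#'   Errors if consecutive points coincide or the central bond is collinear
#'   with a flanking bond (the plane normals vanish and the angle is
#'   undefined).
#' @examples
#' torsion_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)) # cis: 0
#' torsion_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0)) # trans: 180
#' @export
torsion_angle <- function(p1, p2, p3, p4, degrees = TRUE) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  if (sum(b1^2) == 0 || sum(b2^2) == 0 || sum(b3^2) == 0)
    stop("undefined dihedral: consecutive points coincide")
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  n1n <- sqrt(sum(n1^2)); n2n <- sqrt(sum(n2^2))
  bref <- sqrt(sum(b1^2) * sum(b2^2))
  if (n1n < 1e-10 * bref || n2n < 1e-10 * sqrt(sum(b2^2) * sum(b3^2)))
    stop("undefined dihedral: collinear bond vectors")
  b2n <- b2 / sqrt(sum(b2^2))
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * b2n)
  ang <- atan2(y, x)
  if (degrees) wrap_angle(ang * 180 / pi) else wrap_angle(ang, degrees = FALSE)
}

#' Specification of a center-of-mass pseudodihedral
#'
#' Four particle groups (P1..P4) whose mass-weighted centers define a
#' base-flipping-style torsion angle. Hydrogens (mass below `h_mass_max`)
#' can be excluded from the centers, mirroring force-field group
#' definitions built "excluding hydrogen".
#'
#' @param groups List of four integer vectors of particle indices.
#' @param exclude_hydrogen Logical, drop light particles from the centers.
#' @param h_mass_max Mass threshold (amu) below which a particle counts as
#'   hydrogen. Default 2.
#' @return An object of class `pseudodihedral_spec`.
#' @export
pseudodihedral_spec <- function(groups, exclude_hydrogen = FALSE, h_mass_max = 2) {
  if (!is.list(groups) || length(groups) != 4L)
    stop("'groups' must be a list of four index vectors")
  groups <- lapply(groups, function(g) as.integer(g))
  for (g in groups) {
    if (length(g) == 0L) stop("pseudodihedral groups must be nonempty")
    if (anyDuplicated(g)) stop("duplicate particle index within a group")
  }
  structure(list(groups = groups,
                 exclude_hydrogen = isTRUE(exclude_hydrogen),
                 h_mass_max = h_mass_max),
            class = "pseudodihedral_spec")
}

group_com <- function(idx, coords, masses) {
  w <- masses[idx]
  colSums(coords[idx, , drop = FALSE] * w) / sum(w)
}

#' Center-of-mass pseudodihedral angle
#'
#' Torsion of the four mass-weighted group centers of a
#' [pseudodihedral_spec()], the coordinate used to restrain base-flipping
#' motion.
#'
#' @param spec A `pseudodihedral_spec`.
#' @param coords Numeric n x 3 coordinate matrix.
#' @param masses Numeric vector of particle masses (amu), length n.
#' @param degrees Return degrees (default) or radians.
#' @return Signed angle; errors if hydrogen exclusion empties a group.
#' @export
pseudodihedral <- function(spec, coords, masses, degrees = TRUE) {
  stopifnot(inherits(spec, "pseudodihedral_spec"))
  coords <- as.matrix(coords)
  groups <- spec$groups
  if (spec$exclude_hydrogen) {
    groups <- lapply(groups, function(g) g[masses[g] >= spec$h_mass_max])
    if (any(lengths(groups) == 0L))
      stop("hydrogen exclusion left an empty pseudodihedral group")
  }
  centers <- lapply(groups, group_com, coords = coords, masses = masses)
  torsion_angle(centers[[1L]], centers[[2L]], centers[[3L]], centers[[4L]],
                degrees = degrees)
}

#' Hydrogen-bond geometry
#'
#' Donor-acceptor distance and donor-hydrogen-acceptor angle, the two
#' coordinates restrained for each base-pair hydrogen bond.
#'
#' @param donor,hydrogen,acceptor Length-3 coordinate vectors (nm).
#' @return A list with `distance` (nm, donor-acceptor) and `angle`
#'   (degrees at the hydrogen).
#' @examples
#' hbond_geometry(c(0, 0, 0), c(0.1, 0, 0), c(0.3, 0, 0)) # 0.3 nm, 180 deg
#' @export
hbond_geometry <- function(donor, hydrogen, acceptor) {
  if (all(donor == hydrogen) || all(hydrogen == acceptor) || all(donor == acceptor))
    stop("hydrogen-bond geometry undefined for coincident points")
  d <- sqrt(sum((acceptor - donor)^2))
  v1 <- donor - hydrogen
  v2 <- acceptor - hydrogen
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  cosang <- min(1, max(-1, cosang))
  list(distance = d, angle = acos(cosang) * 180 / pi)
}

#' Boltzmann population ratio from a free-energy difference
#'
#' Converts a conformational free-energy difference into the equilibrium
#' population ratio of the favored over the disfavored state,
#' \eqn{P_f/P_d = \exp(\Delta G / RT)} with \eqn{\Delta G \ge 0} the
#' stability gap. This is the inverse of \eqn{\Delta G = -RT \ln(P_d/P_f)}.
#'
#' @param dG Free-energy difference in kcal/mol (favored minus disfavored,
#'   reported as a positive stability gap).
#' @param thermo A [thermo_state()] or temperature in K.
#' @return Dimensionless population ratio.
#' @examples
#' population_ratio(2.25, thermo_state(310)) # ~ 40 to the nearest ten
#' @export
population_ratio <- function(dG, thermo = thermo_state(300)) {
  th <- as_thermo(thermo)
  exp(dG / th$RT_kcal)
}

#' Free-energy difference from a population ratio
#'
#' Inverse of [population_ratio()]: \eqn{\Delta G = RT \ln r}.
#'
#' @param ratio Population ratio (favored / disfavored), > 0.
#' @param thermo A [thermo_state()] or temperature in K.
#' @return Free-energy difference in kcal/mol.
#' @export
dg_from_population <- function(ratio, thermo = thermo_state(300)) {
  if (any(ratio <= 0)) stop("population ratio must be > 0")
  th <- as_thermo(thermo)
  th$RT_kcal * log(ratio)
}

#' Assign torsion samples to conformational basins
#'
#' Labels each frame of a torsion series by its basin. Basin boundaries are
#' the circular midpoints between adjacent minima, the convention used by the
#' quadrature reference in [exact_free_energy_1d()].
#'
#' @param chi Torsion series in degrees.
#' @param minima Numeric vector of basin centers in degrees (typically
#'   `c(anti = -105, syn = 64)`).
#' @return A factor of basin labels (names of `minima`, or `basin1..k`),
#'   with attribute `boundaries` (degrees).
#' @export
assign_basins <- function(chi, minima = c(anti = -105, syn = 64)) {
  if (length(minima) < 2L) stop("need at least two basin centers")
  labs <- names(minima)
  if (is.null(labs)) labs <- paste0("basin", seq_along(minima))
  ord <- order(wrap_angle(minima))
  ctr <- wrap_angle(minima)[ord]
  labs <- labs[ord]
  k <- length(ctr)
  # circular midpoints between consecutive centers (last wraps to first)
  nxt <- c(ctr[-1L], ctr[1L] + 360)
  bounds <- unname(wrap_angle((ctr + nxt) / 2))
  # frame belongs to center i if it lies between bounds[i-1] and bounds[i]
  chi_w <- wrap_angle(chi)
  lab_out <- character(length(chi_w))
  for (i in seq_len(k)) {
    lo <- bounds[if (i == 1L) k else i - 1L]
    hi <- bounds[i]
    inside <- if (lo < hi) chi_w > lo & chi_w <= hi else chi_w > lo | chi_w <= hi
    lab_out[inside] <- labs[i]
  }
  structure(factor(lab_out, levels = labs), boundaries = bounds)
}

#' Basin populations and their free-energy difference
#'
#' Counts basin occupancies of a torsion series and converts them to
#' \eqn{\Delta G = -RT \ln(P_2/P_1)} with a binomial standard error.
#'
#' @param chi Torsion series in degrees.
#' @param minima Basin centers in degrees, length 2, names used as labels.
#' @param thermo A [thermo_state()] or temperature in K.
#' @return List with `counts`, `dG` (kcal/mol, basin1 -> basin2) and `se`
#'   (kcal/mol, delta-method standard error; `Inf` if a basin is empty).
#' @export
basin_free_energy <- function(chi, minima = c(anti = -105, syn = 64),
                              thermo = thermo_state(300)) {
  stopifnot(length(minima) == 2L)
  th <- as_thermo(thermo)
  lab <- assign_basins(chi, minima)
  counts <- table(lab)
  n1 <- as.numeric(counts[[1L]]); n2 <- as.numeric(counts[[2L]])
  if (n1 == 0 || n2 == 0) {
    return(list(counts = counts, dG = if (n2 == 0) Inf else -Inf, se = Inf))
  }
  dG <- -th$RT_kcal * log(n2 / n1)
  se <- th$RT_kcal * sqrt(1 / n1 + 1 / n2) # delta method on independent counts
  list(counts = counts, dG = dG, se = se)
}
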