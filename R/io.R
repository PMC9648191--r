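# Plain-text interchange: GROMACS-dialect XVG tables (the format free-energy
# codes emit per lambda state), a documented CSV layout for reduced-potential
# matrices, and a JSON schema for toy topologies.

#' Write a per-state cross-evaluation table as XVG
#'
#' One file per sampling state, GROMACS dhdl dialect: `#` comment lines,
#' `@` metadata (title, axis labels, one `s<i> legend` per column), then
#' whitespace-separated numeric rows of time (sweep index) followed by the
#' reduced potential of each lambda state.
#'
#' @param ukn A `u_kn` object.
#' @param state_index Which sampling state's rows to write.
#' @param path Output file path.
#' @param time Optional time column (defaults to the sample index).
#' @return `path`, invisibly.
#' @export
write_dhdl_xvg <- function(ukn, state_index, path, time = NULL) {
  stopifnot(inherits(ukn, "u_kn"))
  K <- length(ukn$N_k)
  offs <- c(0L, cumsum(ukn$N_k))
  cols <- (offs[state_index] + 1L):offs[state_index + 1L]
  block <- t(ukn$u[, cols, drop = FALSE])     # rows = samples, columns = states
  if (is.null(time)) time <- seq_len(nrow(block))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# reduced potentials cross-evaluated in all lambda states of the stage",
    sprintf("# sampling state %d of %d", state_index, K),
    "@    title \"Cross-evaluated reduced potentials\"",
    "@    xaxis  label \"Time (sweep)\"",
    "@    yaxis  label \"u (kT)\"",
    sprintf("@ s%d legend \"u at state %d\"", seq_len(K) - 1L, seq_len(K))
  ), con)
  write.table(cbind(time, block), con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an XVG table
#'
#' Parses `#` comments and `@` metadata (legends collected separately) and
#' the numeric payload of a GROMACS-dialect XVG file.
#'
#' @param path File path.
#' @return List with `data` (numeric matrix), `legends` (character),
#'   `metadata` (all `@` lines), `comments` (all `#` lines). Errors on a
#'   malformed numeric row (with its line number), on files without data,
#'   and when the column count contradicts the legend declarations.
#' @export
read_dhdl_xvg <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  is_comment <- startsWith(lines, "#")
  is_meta <- startsWith(lines, "@")
  is_blank <- grepl("^\\s*$", lines)
  data_idx <- which(!is_comment & !is_meta & !is_blank)
  if (length(data_idx) == 0L) stop("XVG file contains no data rows: ", path)
  rows <- lapply(data_idx, function(i) {
    fields <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    vals <- suppressWarnings(as.numeric(fields))
    if (any(is.na(vals)))
      stop(sprintf("malformed numeric row at line %d of %s", i, path))
    vals
  })
  ncols <- lengths(rows)
  if (length(unique(ncols)) != 1L)
    stop(sprintf("inconsistent column count at line %d of %s",
                 data_idx[which(ncols != ncols[1L])[1L]], path))
  data <- do.call(rbind, rows)
  meta <- lines[is_meta]
  leg <- regmatches(meta, regexpr('legend\\s+"[^"]*"', meta))
  legends <- gsub('legend\\s+"([^"]*)"', "\\1", leg)
  if (length(legends) > 0L && ncol(data) != length(legends) + 1L)
    stop(sprintf("schema error in %s: %d data columns but %d legends (+ time)",
                 path, ncol(data), length(legends)))
  list(data = data, legends = legends, metadata = meta,
       comments = lines[is_comment])
}

#' Assemble a reduced-potential matrix from per-state XVG files
#'
#' @param paths Character vector of K file paths, one per sampling state in
#'   schedule order, each as written by [write_dhdl_xvg()].
#' @return A `u_kn` object.
#' @export
ukn_from_xvg <- function(paths) {
  blocks <- lapply(paths, read_dhdl_xvg)
  K <- length(paths)
  for (b in blocks)
    if (ncol(b$data) != K + 1L)
      stop("each file must carry one time column plus K = ", K, " state columns")
  u <- do.call(cbind, lapply(blocks, function(b) t(b$data[, -1L, drop = FALSE])))
  new_u_kn(u, vapply(blocks, function(b) nrow(b$data), 0L))
}

#' Write a reduced-potential matrix as CSV
#'
#' Layout: comment header (`#` lines) recording `N_k`, then one row per
#' sample with columns `origin` (sampling state), `time` (index within its
#' state), and `u_1 .. u_K`.
#'
#' @param ukn A `u_kn` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ukn_csv <- function(ukn, path) {
  stopifnot(inherits(ukn, "u_kn"))
  K <- length(ukn$N_k)
  tab <- data.frame(origin = ukn$origin,
                    time = unlist(lapply(ukn$N_k, seq_len)),
                    t(ukn$u))
  names(tab)[-(1:2)] <- paste0("u_", seq_len(K))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# rfepr reduced-potential matrix (dimensionless, kT)",
               paste0("# N_k: ", paste(ukn$N_k, collapse = " "))), con)
  write.table(tab, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a reduced-potential matrix from CSV
#'
#' @param path File written by [write_ukn_csv()].
#' @return A `u_kn` object.
#' @export
read_ukn_csv <- function(path) {
  tab <- read.table(path, sep = ",", header = TRUE, comment.char = "#")
  ucols <- grep("^u_", names(tab))
  if (length(ucols) == 0L) stop("no u_k columns found in ", path)
  origin <- tab$origin
  if (is.unsorted(origin)) stop("rows must be grouped by sampling state")
  new_u_kn(t(as.matrix(tab[, ucols])), as.integer(table(origin)))
}

#' Write a trajectory as CSV
#'
#' Layout: comment header (`#` lines) recording the lambda state, seed and
#' stride, then one row per frame with columns `sweep` and
#' `x1,y1,z1,x2,y2,z2,...` (nm).
#'
#' @param traj An `rfepr_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "rfepr_trajectory"))
  n <- ncol(traj$frames) / 3L
  tab <- data.frame(sweep = traj$sweep, traj$frames)
  names(tab)[-1L] <- paste0(rep(c("x", "y", "z"), n), rep(seq_len(n), each = 3L))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# rfepr trajectory (coordinates in nm)",
    sprintf("# stage %s lambda_R %g lambda_coul %g lambda_vdw %g",
            traj$state$stage, traj$state$lambda_restraint,
            traj$state$lambda_coul, traj$state$lambda_vdw),
    sprintf("# seed %d, stride %d, burn-in %d of %d sweeps",
            traj$seed, traj$stride, traj$burn_sweeps, traj$n_sweeps)), con)
  write.table(tab, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trajectory CSV as a frame matrix
#'
#' @param path File written by [write_trajectory_csv()] (or any CSV whose
#'   non-comment columns after `sweep` are x/y/z triplets).
#' @return List with `frames` (n_frames x 3n matrix) and `sweep`.
#' @export
read_trajectory_csv <- function(path) {
  tab <- read.table(path, sep = ",", header = TRUE, comment.char = "#")
  frames <- as.matrix(tab[, -1L, drop = FALSE])
  dimnames(frames) <- NULL
  if (ncol(frames) %% 3L != 0L) stop("coordinate columns must come in x/y/z triplets")
  list(frames = frames, sweep = tab[[1L]])
}

#' Serialize a toy topology to JSON
#'
#' Documented plain-text schema: particle table, bonded terms, profile terms
#' (atoms, copy tag, well table), exclusions, coordinates, and metadata.
#'
#' @param topo A `toy_topology`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_topology <- function(topo, path) {
  stopifnot(inherits(topo, "toy_topology"))
  obj <- list(
    format = "rfepr-toy-topology-1",
    particles = topo$particles,
    bonds = topo$bonds, angles = topo$angles, dihedrals = topo$dihedrals,
    profiles = setNames(
      lapply(topo$profiles, function(pf)
        list(atoms = pf$atoms, copy = pf$copy, wells = pf$profile$wells)),
      paste0("term", seq_along(topo$profiles))),
    exclusions = as.data.frame(topo$exclusions),
    coords = topo$coords,
    meta = topo$meta
  )
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' Read a toy topology from JSON
#'
#' @param path File written by [write_topology()].
#' @return A `toy_topology`.
#' @export
read_topology <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "rfepr-toy-topology-1"))
    stop("not an rfepr toy-topology file: ", path)
  profiles <- lapply(unname(obj$profiles), function(pf) {
    wells <- pf$wells
    list(atoms = as.integer(pf$atoms), copy = pf$copy,
         profile = torsion_profile(setNames(wells$center_deg, wells$label),
                                   wells$depth, wells$curvature))
  })
  ex <- as.matrix(obj$exclusions)
  if (length(ex) == 0L) ex <- matrix(integer(0), 0L, 2L, dimnames = list(NULL, c("i", "j")))
  meta <- obj$meta
  for (cp in c("rv", "vr"))
    if (!is.null(meta[[cp]]))
      meta[[cp]][c("anchors","rotor_hub","rotor","axis","chi_atoms")] <-
        lapply(meta[[cp]][c("anchors","rotor_hub","rotor","axis","chi_atoms")], as.integer)
  for (fld in c("scaffold_anchor","anchors","rotor_hub","rotor","axis","chi_atoms"))
    if (!is.null(meta[[fld]])) meta[[fld]] <- as.integer(meta[[fld]])
  topo <- new_toy_topology(obj$particles, obj$bonds, obj$angles, obj$dihedrals,
                           profiles, ex, as.matrix(obj$coords), meta)
  validate_topology(topo)
  topo
}
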