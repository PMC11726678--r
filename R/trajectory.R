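#' Single trajectory frame
#'
#' A snapshot of the surface-hopping record: solute Cartesian coordinates,
#' adiabatic state energies, the active surface, and total energy, with
#' optional explicit-water solvent coordinates.
#'
#' @param time Time in femtoseconds (>= 0).
#' @param coords `natom x 3` coordinate matrix in Angstrom.
#' @param elements Character vector of element symbols (length `natom`).
#' @param state_energies Ordered adiabatic energies `E_S0..E_Sn` in eV.
#' @param active_state Active adiabatic state index (0 = ground state).
#' @param total_energy Total (kinetic + potential) energy in eV.
#' @param solvent_coords Optional `nwat*3 x 3` matrix of water coordinates
#'   (rows in O, H, H order per molecule).
#' @param solvent_elements Optional element symbols for the solvent rows.
#' @return Object of class `sh_frame`.
#' @export
sh_frame <- function(time, coords, elements, state_energies, active_state,
                     total_energy, solvent_coords = NULL,
                     solvent_elements = NULL) {
  if (!is.finite(time) || time < 0) stop("sh_frame: time must be >= 0")
  if (!is.matrix(coords) || ncol(coords) != 3)
    stop("sh_frame: coords must be an natom x 3 matrix")
  if (length(elements) != nrow(coords))
    stop("sh_frame: elements length must match atom count")
  if (active_state < 0 || active_state >= length(state_energies))
    stop("sh_frame: active_state out of range for the given state energies")
  if (!is.null(solvent_coords)) {
    if (!is.matrix(solvent_coords) || ncol(solvent_coords) != 3)
      stop("sh_frame: solvent_coords must be an n x 3 matrix")
    if (is.null(solvent_elements) ||
        length(solvent_elements) != nrow(solvent_coords))
      stop("sh_frame: solvent_elements must match solvent_coords rows")
  }
  structure(list(time = time, coords = coords, elements = elements,
                 state_energies = state_energies,
                 active_state = as.integer(active_state),
                 total_energy = total_energy,
                 solvent_coords = solvent_coords,
                 solvent_elements = solvent_elements),
            class = "sh_frame")
}

#' Surface-hopping trajectory
#'
#' Column-oriented container for a time-ordered sequence of frames with a
#' uniform time step: coordinates as a `[natom, 3, nframe]` array, per-state
#' energies as an `nframe x nstate` matrix, plus the active-state label and
#' total energy per frame.
#'
#' @param times Frame times in fs, strictly increasing with constant spacing.
#' @param coords `[natom, 3, nframe]` array (Angstrom).
#' @param elements Element symbols, length `natom`.
#' @param energies `nframe x nstate` matrix of adiabatic energies (eV),
#'   columns `E_S0..E_Sn`.
#' @param active_state Integer vector (0-based state index) per frame.
#' @param total_energy Numeric vector of total energies (eV) per frame.
#' @param meta List with `environment` ("gas" or "water"), `initial_state`,
#'   and optional `window` (excitation window, eV) and `dt`.
#' @param termination One of `"completed"`, `"early_ground_state"`,
#'   `"excluded_energy"`.
#' @param solvent Optional `[nwatatoms, 3, nframe]` array of solvent
#'   coordinates.
#' @param solvent_elements Optional solvent element symbols.
#' @return Object of class `sh_trajectory`.
#' @export
sh_trajectory <- function(times, coords, elements, energies, active_state,
                          total_energy, meta = list(),
                          termination = "completed",
                          solvent = NULL, solvent_elements = NULL) {
  nf <- length(times)
  if (nf < 1) stop("sh_trajectory: empty trajectory")
  if (length(dim(coords)) != 3 || dim(coords)[2] != 3 || dim(coords)[3] != nf)
    stop("sh_trajectory: coords must be a [natom, 3, nframe] array")
  if (!is.matrix(energies) || nrow(energies) != nf)
    stop("sh_trajectory: energies must be an nframe x nstate matrix")
  if (length(active_state) != nf || length(total_energy) != nf)
    stop("sh_trajectory: per-frame vectors must match the frame count")
  termination <- match.arg(termination,
                           c("completed", "early_ground_state",
                             "excluded_energy"))
  if (nf > 1) {
    dts <- diff(times)
    if (any(dts <= 0)) stop("sh_trajectory: times must be strictly increasing")
    if (diff(range(dts)) > 1e-6 * max(dts))
      stop("sh_trajectory: non-uniform time step")
    meta$dt <- dts[1]
  }
  if (any(active_state < 0 | active_state >= ncol(energies)))
    stop("sh_trajectory: active_state out of range")
  if (is.null(meta$environment)) meta$environment <- "gas"
  if (is.null(meta$initial_state)) meta$initial_state <- active_state[1]
  structure(list(times = times, coords = coords, elements = elements,
                 energies = energies, active_state = as.integer(active_state),
                 total_energy = total_energy, meta = meta,
                 termination = termination, solvent = solvent,
                 solvent_elements = solvent_elements),
            class = "sh_trajectory")
}

#' @export
print.sh_trajectory <- function(x, ...) {
  cat(sprintf(
    "sh_trajectory: %d frames, dt=%.4g fs, %d atoms, %d states, start S%d, %s (%s)\n",
    n_frames(x), x$meta$dt %||% NA, dim(x$coords)[1], ncol(x$energies),
    x$meta$initial_state, x$termination, x$meta$environment))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Number of frames in a trajectory
#' @param traj An `sh_trajectory`.
#' @export
n_frames <- function(traj) length(traj$times)

#' Extract a single frame from a trajectory
#'
#' @param traj An `sh_trajectory`.
#' @param i Frame index.
#' @return An [sh_frame()].
#' @export
get_frame <- function(traj, i) {
  if (i < 1 || i > n_frames(traj)) stop("get_frame: index out of range")
  sh_frame(time = traj$times[i],
           coords = traj$coords[, , i, drop = TRUE],
           elements = traj$elements,
           state_energies = traj$energies[i, ],
           active_state = traj$active_state[i],
           total_energy = traj$total_energy[i],
           solvent_coords = if (!is.null(traj$solvent))
             traj$solvent[, , i, drop = TRUE] else NULL,
           solvent_elements = traj$solvent_elements)
}

#' Trajectory ensemble
#'
#' @param trajectories List of [sh_trajectory()] objects.
#' @param n_total Number of trajectories actually run (defaults to the list
#'   length; may exceed it when some runs are not retained).
#' @return Object of class `sh_ensemble` with `n_traj` recomputed as the
#'   number of trajectories not flagged `excluded_energy`.
#' @export
sh_ensemble <- function(trajectories, n_total = length(trajectories)) {
  if (!length(trajectories)) stop("sh_ensemble: empty ensemble")
  if (!all(vapply(trajectories, inherits, logical(1), "sh_trajectory")))
    stop("sh_ensemble: all members must be sh_trajectory objects")
  n_traj <- sum(vapply(trajectories, function(t)
    t$termination != "excluded_energy", logical(1)))
  if (n_traj > n_total) stop("sh_ensemble: n_traj cannot exceed n_total")
  structure(list(trajectories = trajectories, n_total = as.integer(n_total),
                 n_traj = as.integer(n_traj)),
            class = "sh_ensemble")
}

#' @export
print.sh_ensemble <- function(x, ...) {
  cat(sprintf("sh_ensemble: %d trajectories run, %d retained for analysis\n",
              x$n_total, x$n_traj))
  invisible(x)
}

## trajectories surviving energy-conservation QC
.active_trajectories <- function(ens) {
  Filter(function(t) t$termination != "excluded_energy", ens$trajectories)
}

#' Write a trajectory to extended-XYZ + energy-table files
#'
#' The XYZ comment line carries `time_fs=<t> n_solute=<n>`; solvent atoms, if
#' present, are appended after the solute atoms of each frame. The energy
#' table is a TSV with header `time_fs  E_S0 ... E_Sn  E_total  active_state`.
#' Numeric values are written with 6 decimals, giving a bit-identical
#' round trip at that precision.
#'
#' @param traj An [sh_trajectory()].
#' @param xyz_path,energy_table_path Output file paths.
#' @return Invisibly, `traj`.
#' @export
write_trajectory <- function(traj, xyz_path, energy_table_path) {
  if (!inherits(traj, "sh_trajectory")) stop("write_trajectory: not a trajectory")
  nf <- n_frames(traj)
  nat <- dim(traj$coords)[1]
  nwat <- if (!is.null(traj$solvent)) dim(traj$solvent)[1] else 0L
  con <- file(xyz_path, "w", encoding = "UTF-8")
  on.exit(close(con), add = TRUE)
  for (i in seq_len(nf)) {
    writeLines(as.character(nat + nwat), con)
    writeLines(sprintf("time_fs=%.6f n_solute=%d", traj$times[i], nat), con)
    xyz <- traj$coords[, , i, drop = FALSE]
    lines <- sprintf("%-2s %14.6f %14.6f %14.6f", traj$elements,
                     xyz[, 1, 1], xyz[, 2, 1], xyz[, 3, 1])
    writeLines(lines, con)
    if (nwat > 0) {
      sxyz <- traj$solvent[, , i, drop = FALSE]
      writeLines(sprintf("%-2s %14.6f %14.6f %14.6f", traj$solvent_elements,
                         sxyz[, 1, 1], sxyz[, 2, 1], sxyz[, 3, 1]), con)
    }
  }
  ns <- ncol(traj$energies)
  tab <- data.frame(time_fs = sprintf("%.6f", traj$times))
  for (k in seq_len(ns))
    tab[[paste0("E_S", k - 1)]] <- sprintf("%.6f", traj$energies[, k])
  tab$E_total <- sprintf("%.6f", traj$total_energy)
  tab$active_state <- traj$active_state
  utils::write.table(tab, energy_table_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(traj)
}

#' Read a trajectory from extended-XYZ + energy-table files
#'
#' Counterpart of [write_trajectory()]. Frames in the XYZ file and rows of
#' the energy table must align one-to-one on time.
#'
#' @param xyz_path Extended-XYZ file (comment line `time_fs=<t>`, optionally
#'   `n_solute=<n>` when solvent atoms are appended).
#' @param energy_table_path TSV energy table with header
#'   `time_fs  E_S0 ... E_Sn  E_total  active_state`.
#' @param meta Optional metadata list (see [sh_trajectory()]).
#' @return An [sh_trajectory()]; units are Angstrom / eV / fs.
#' @export
read_trajectory <- function(xyz_path, energy_table_path, meta = list()) {
  lines <- readLines(xyz_path, encoding = "UTF-8")
  tab <- utils::read.table(energy_table_path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  ecols <- grep("^E_S[0-9]+$", names(tab), value = TRUE)
  if (!all(c("time_fs", "E_total", "active_state") %in% names(tab)) ||
      !length(ecols))
    stop("read_trajectory: energy table is missing required columns")
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat)) stop("read_trajectory: malformed XYZ atom-count line ", i)
    comment <- lines[i + 1L]
    tm <- regmatches(comment, regexec("time_fs=([-0-9.eE+]+)", comment))[[1]]
    if (length(tm) < 2) stop("read_trajectory: XYZ comment lacks time_fs")
    nsol <- regmatches(comment, regexec("n_solute=([0-9]+)", comment))[[1]]
    nsol <- if (length(nsol) >= 2) as.integer(nsol[2]) else nat
    block <- lines[(i + 2L):(i + 1L + nat)]
    parts <- strsplit(trimws(block), "[[:space:]]+")
    el <- vapply(parts, `[`, character(1), 1)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    frames[[length(frames) + 1L]] <-
      list(time = as.numeric(tm[2]), n_solute = nsol, elements = el,
           coords = xyz)
    i <- i + 2L + nat
  }
  nf <- length(frames)
  if (nf != nrow(tab))
    stop(sprintf(
      "read_trajectory: %d XYZ frames but %d energy-table rows", nf, nrow(tab)))
  times_x <- vapply(frames, `[[`, numeric(1), "time")
  if (max(abs(times_x - tab$time_fs)) > 1e-5)
    stop("read_trajectory: XYZ frame times do not match the energy table")
  nsol <- frames[[1]]$n_solute
  nat <- nrow(frames[[1]]$coords)
  if (any(vapply(frames, function(f) nrow(f$coords), integer(1)) != nat))
    stop("read_trajectory: atom count varies between frames")
  energies <- as.matrix(tab[, ecols, drop = FALSE])
  colnames(energies) <- ecols
  if (any(tab$active_state < 0 | tab$active_state >= length(ecols)))
    stop("read_trajectory: active_state index exceeds the number of state columns")
  coords <- array(NA_real_, dim = c(nsol, 3, nf))
  solvent <- if (nat > nsol) array(NA_real_, dim = c(nat - nsol, 3, nf)) else NULL
  for (k in seq_len(nf)) {
    coords[, , k] <- frames[[k]]$coords[seq_len(nsol), , drop = FALSE]
    if (!is.null(solvent))
      solvent[, , k] <- frames[[k]]$coords[(nsol + 1):nat, , drop = FALSE]
  }
  sh_trajectory(times = tab$time_fs, coords = coords,
                elements = frames[[1]]$elements[seq_len(nsol)],
                energies = energies, active_state = tab$active_state,
                total_energy = tab$E_total, meta = meta,
                solvent = solvent,
                solvent_elements = if (!is.null(solvent))
                  frames[[1]]$elements[(nsol + 1):nat] else NULL)
}

#' Validate a trajectory and report violations
#'
#' Report-based validation: returns a character vector of violation
#' messages; an empty vector means the trajectory is well formed. Checks
#' time monotonicity/uniformity, atom-count constancy, state-index bounds,
#' non-finite energies and coordinates, and metadata consistency.
#'
#' @param traj An object structured like an [sh_trajectory()] (a raw list is
#'   accepted so that malformed inputs can be reported rather than rejected).
#' @return Character vector of violations (empty iff valid).
#' @export
validate_trajectory <- function(traj) {
  v <- character()
  nf <- length(traj$times)
  if (nf == 0) return("trajectory has no frames")
  if (any(traj$times < 0)) v <- c(v, "negative frame times")
  if (nf > 1) {
    dts <- diff(traj$times)
    if (any(dts <= 0)) v <- c(v, "frame times not strictly increasing")
    else if (diff(range(dts)) > 1e-6 * max(dts))
      v <- c(v, "non-uniform time step")
  }
  if (length(dim(traj$coords)) != 3 || dim(traj$coords)[3] != nf)
    v <- c(v, "coordinate array does not match the frame count")
  else if (anyNA(traj$coords) || any(!is.finite(traj$coords)))
    v <- c(v, "non-finite coordinates")
  if (!is.matrix(traj$energies) || nrow(traj$energies) != nf) {
    v <- c(v, "energy matrix does not match the frame count")
  } else {
    if (any(!is.finite(traj$energies))) v <- c(v, "non-finite state energies")
    if (any(traj$active_state < 0 |
            traj$active_state >= ncol(traj$energies)))
      v <- c(v, "active_state index out of range")
  }
  if (any(!is.finite(traj$total_energy))) v <- c(v, "non-finite total energy")
  if (!is.null(traj$meta$initial_state) &&
      traj$meta$initial_state != traj$active_state[1])
    v <- c(v, "meta initial_state does not match the first frame")
  v
}
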