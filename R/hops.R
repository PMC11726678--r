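#' Extract S1 -> S0 hopping records from a trajectory
#'
#' One record per frame pair where the active state changes from
#' `from_state` to `to_state`. Geometry and energies are taken from the
#' first frame on the new surface (the accepted hopping geometry); the
#' pre-hop values are retained alongside for sensitivity checks.
#'
#' @param traj An [sh_trajectory()].
#' @param from_state,to_state State indices of the transition (defaults 1
#'   and 0).
#' @param sel An [atom_selection()].
#' @return data.frame with columns `time`, `theta`, `omega`, `delta_e`
#'   (`E_S1 - E_S0` at the hop frame, eV), `mechanism`, and the pre-hop
#'   `theta_prev`/`omega_prev`. Empty (0-row) if no such transition occurs.
#' @export
extract_hops <- function(traj, from_state = 1, to_state = 0,
                         sel = default_atom_selection()) {
  st <- traj$active_state
  idx <- which(st[-1] == to_state & st[-length(st)] == from_state) + 1L
  if (!length(idx))
    return(data.frame(time = numeric(), theta = numeric(), omega = numeric(),
                      delta_e = numeric(), mechanism = character(),
                      theta_prev = numeric(), omega_prev = numeric()))
  rec <- lapply(idx, function(i) {
    ic <- internal_coords(traj$coords[, , i, drop = TRUE], sel)
    icp <- internal_coords(traj$coords[, , i - 1L, drop = TRUE], sel)
    data.frame(time = traj$times[i], theta = ic$theta, omega = ic$omega,
               delta_e = traj$energies[i, "E_S1"] - traj$energies[i, "E_S0"],
               mechanism = as.character(classify_mechanism(ic$omega)),
               theta_prev = icp$theta, omega_prev = icp$omega)
  })
  out <- do.call(rbind, rec)
  rownames(out) <- NULL
  out
}

#' Classify the isomerization mechanism from the CCCC dihedral at the hop
#'
#' Rotational pathway for `55 <= omega <= 125` degrees, inversion for
#' `145 <= omega <= 180`; values in the gap (or below 55) are `unassigned`.
#'
#' @param omega CCCC dihedral magnitude(s) in degrees, within `[0, 180]`.
#' @return Factor with levels `rotational`, `inversion`, `unassigned`
#'   (vectorized).
#' @export
classify_mechanism <- function(omega) {
  if (any(omega < 0 | omega > 180, na.rm = TRUE))
    stop("classify_mechanism: omega must lie in [0, 180]")
  out <- ifelse(omega >= 55 & omega <= 125, "rotational",
         ifelse(omega >= 145 & omega <= 180, "inversion", "unassigned"))
  factor(out, levels = c("rotational", "inversion", "unassigned"))
}

#' Hop records for all retained trajectories of an ensemble
#'
#' @param ens An [sh_ensemble()].
#' @param sel An [atom_selection()].
#' @param from_state,to_state Transition, as in [extract_hops()].
#' @return data.frame of hop records with a leading `trajectory` id column.
#' @export
extract_hops_ensemble <- function(ens, sel = default_atom_selection(),
                                  from_state = 1, to_state = 0) {
  trajs <- .active_trajectories(ens)
  recs <- lapply(seq_along(trajs), function(i) {
    h <- extract_hops(trajs[[i]], from_state, to_state, sel)
    if (nrow(h)) cbind(trajectory = i, h) else NULL
  })
  recs <- Filter(Negate(is.null), recs)
  if (!length(recs))
    return(data.frame(trajectory = integer(), time = numeric(),
                      theta = numeric(), omega = numeric(),
                      delta_e = numeric(), mechanism = character(),
                      theta_prev = numeric(), omega_prev = numeric()))
  do.call(rbind, recs)
}

#' Rotational vs inversion mechanism fractions of the reactive trajectories
#'
#' Reactive (cis-final) trajectories are identified via [quantum_yield()];
#' each is classified by the CCCC dihedral of its last S1 -> S0 hop.
#' Fractions are taken over the classified reactive trajectories (records in
#' the 125-145 degree gap are reported as unassigned and excluded from the
#' denominator).
#'
#' @param ens An [sh_ensemble()] with QC applied.
#' @param sel An [atom_selection()].
#' @return List with `rotational`, `inversion` (fractions summing to 1),
#'   `n_rotational`, `n_inversion`, `n_unassigned`, `n_reactive`.
#' @export
mechanism_ratios <- function(ens, sel = default_atom_selection()) {
  trajs <- .active_trajectories(ens)
  mech <- character()
  for (t in trajs) {
    nf <- n_frames(t)
    if (t$active_state[nf] != 0) next
    ic <- internal_coords(t$coords[, , nf, drop = TRUE], sel)
    if (classify_final_geometry(ic$theta, ic$alpha) %in%
        c("cis_I", "cis_II", "cis_unassigned")) {
      h <- extract_hops(t, sel = sel)
      if (!nrow(h)) next
      mech <- c(mech, h$mechanism[nrow(h)])   # last S1 -> S0 hop
    }
  }
  if (!length(mech)) stop("mechanism_ratios: no reactive trajectories")
  n_rot <- sum(mech == "rotational")
  n_inv <- sum(mech == "inversion")
  n_un <- sum(mech == "unassigned")
  if (n_rot + n_inv == 0)
    stop("mechanism_ratios: no classifiable reactive hop geometry")
  list(rotational = n_rot / (n_rot + n_inv),
       inversion = n_inv / (n_rot + n_inv),
       n_rotational = n_rot, n_inversion = n_inv, n_unassigned = n_un,
       n_reactive = length(mech))
}
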