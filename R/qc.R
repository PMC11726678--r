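#' Energy-conservation quality-control filter
#'
#' Excludes trajectories whose total energy deviates from its initial value
#' by more than `threshold` eV at any frame (strictly greater; a deviation
#' of exactly the threshold is kept). The deviation reference is the initial
#' total energy, i.e. `max_t |E_total(t) - E_total(0)|`. Excluded
#' trajectories are flagged `excluded_energy` and retained in the returned
#' ensemble for bookkeeping; `n_traj` is recomputed.
#'
#' @param ens An [sh_ensemble()].
#' @param threshold Exclusion threshold in eV (default 0.5).
#' @return List with `ensemble` (flagged, `n_traj` recomputed) and `report`
#'   (data.frame: `id`, `max_deviation`, `excluded`, `termination`,
#'   `early_termination_time`), plus counts in the report attributes.
#' @export
energy_conservation_filter <- function(ens, threshold = 0.5) {
  if (!inherits(ens, "sh_ensemble")) stop("energy_conservation_filter: not an ensemble")
  devs <- vapply(ens$trajectories, function(t) {
    if (is.null(t$total_energy) || !length(t$total_energy))
      stop("energy_conservation_filter: trajectory lacks total energy")
    max(abs(t$total_energy - t$total_energy[1]))
  }, numeric(1))
  excluded <- devs > threshold
  ens$trajectories <- lapply(seq_along(ens$trajectories), function(i) {
    t <- ens$trajectories[[i]]
    if (excluded[i]) t$termination <- "excluded_energy"
    t
  })
  out <- sh_ensemble(ens$trajectories, n_total = ens$n_total)
  report <- data.frame(
    id = seq_along(devs),
    max_deviation = devs,
    excluded = excluded,
    termination = vapply(out$trajectories, `[[`, character(1), "termination"),
    early_termination_time = vapply(out$trajectories, function(t)
      if (t$termination == "early_ground_state") max(t$times) else NA_real_,
      numeric(1)))
  attr(report, "n_total") <- out$n_total
  attr(report, "n_traj") <- out$n_traj
  attr(report, "threshold") <- threshold
  list(ensemble = out, report = report)
}

#' Early termination of ground-state-resident trajectories
#'
#' Trajectories that reach the ground state and remain there uninterrupted
#' for at least `dwell` fs are truncated at (first arrival of that residence
#' + dwell) and flagged `early_ground_state`. Any return to an excited state
#' resets the dwell counter. Applying the rule twice equals applying it
#' once.
#'
#' @param traj An [sh_trajectory()].
#' @param dwell Required uninterrupted ground-state residence in fs
#'   (default 500).
#' @return The (possibly truncated) trajectory.
#' @export
apply_early_termination <- function(traj, dwell = 500) {
  st <- traj$active_state
  r <- rle(st == 0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    t_arrive <- traj$times[starts[k]]
    t_stay <- traj$times[ends[k]] - t_arrive
    if (t_stay >= dwell) {
      keep <- traj$times <= t_arrive + dwell
      keep[seq_len(starts[k])] <- TRUE  # never cut before the arrival
      idx <- seq_len(max(which(keep)))
      return(sh_trajectory(times = traj$times[idx],
                           coords = traj$coords[, , idx, drop = FALSE],
                           elements = traj$elements,
                           energies = traj$energies[idx, , drop = FALSE],
                           active_state = traj$active_state[idx],
                           total_energy = traj$total_energy[idx],
                           meta = traj$meta,
                           termination = "early_ground_state",
                           solvent = if (!is.null(traj$solvent))
                             traj$solvent[, , idx, drop = FALSE] else NULL,
                           solvent_elements = traj$solvent_elements))
    }
  }
  traj
}

#' Apply early termination to every retained trajectory of an ensemble
#'
#' @param ens An [sh_ensemble()].
#' @param dwell Dwell time in fs.
#' @return The ensemble with truncated trajectories.
#' @export
apply_early_termination_ensemble <- function(ens, dwell = 500) {
  ens$trajectories <- lapply(ens$trajectories, function(t)
    if (t$termination == "excluded_energy") t
    else apply_early_termination(t, dwell))
  ens
}

#' Bookkeeping table for labelled ensembles
#'
#' @param ensembles Named list of [sh_ensemble()] objects (environment x
#'   excitation-window labels).
#' @return data.frame with one row per label: `label`, `n_total`, `n_traj`.
#' @export
ensemble_counts <- function(ensembles) {
  if (!length(ensembles))
    return(data.frame(label = character(), n_total = integer(),
                      n_traj = integer()))
  data.frame(
    label = names(ensembles),
    n_total = vapply(ensembles, `[[`, integer(1), "n_total"),
    n_traj = vapply(ensembles, `[[`, integer(1), "n_traj"),
    row.names = NULL)
}
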