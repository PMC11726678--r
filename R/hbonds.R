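#' Geometric hydrogen-bond criteria
#'
#' A water hydrogen H donates a bond to a solute heteroatom X when the
#' X...H distance is at most `d_max` and the donor angle O_w-H...X (vertex
#' at the hydrogen) exceeds `angle_min`. With `one_bond_per_hydrogen` each
#' hydrogen is assigned to at most one acceptor (the nearest qualifying
#' one), which prevents double counting between the two closely spaced azo
#' nitrogens.
#'
#' @param d_max Maximum acceptor-hydrogen distance in Angstrom (default 3.0,
#'   inclusive).
#' @param angle_min Minimum donor angle in degrees (default 120, strict).
#' @param one_bond_per_hydrogen Logical (default TRUE).
#' @return Object of class `hbond_criteria`.
#' @export
hbond_criteria <- function(d_max = 3.0, angle_min = 120,
                           one_bond_per_hydrogen = TRUE) {
  if (d_max <= 0) stop("hbond_criteria: d_max must be > 0")
  if (angle_min <= 0 || angle_min >= 180)
    stop("hbond_criteria: angle_min must lie in (0, 180)")
  structure(list(d_max = d_max, angle_min = angle_min,
                 one_bond_per_hydrogen = one_bond_per_hydrogen),
            class = "hbond_criteria")
}

#' Detect solute-water hydrogen bonds in a frame
#'
#' @param frame An [sh_frame()] carrying `solvent_coords` in O, H, H order
#'   per water molecule.
#' @param acceptors Named integer vector of solute acceptor indices.
#' @param criteria An [hbond_criteria()].
#' @return data.frame with one row per detected bond: `acceptor`, `water`
#'   (molecule id), `hydrogen` (solvent row index), `distance` (Angstrom),
#'   `angle` (degrees).
#' @export
detect_hbonds <- function(frame, acceptors, criteria = hbond_criteria()) {
  sw <- frame$solvent_coords
  if (is.null(sw)) stop("detect_hbonds: frame has no solvent coordinates")
  el <- frame$solvent_elements
  if (is.null(el) || length(el) != nrow(sw))
    stop("detect_hbonds: missing solvent topology (element labels)")
  if (!nrow(sw) || !length(acceptors))
    return(.empty_bonds())
  water_id <- cumsum(el == "O")
  hyd <- which(el == "H" & rowSums(is.na(sw)) == 0)
  if (!length(hyd)) return(.empty_bonds())
  ## the O of each hydrogen's own molecule
  o_rows <- vapply(hyd, function(i) which(el == "O" & water_id == water_id[i])[1],
                   integer(1))
  if (anyNA(o_rows)) stop("detect_hbonds: hydrogen without a parent oxygen")
  cand <- list()
  for (a in seq_along(acceptors)) {
    X <- frame$coords[acceptors[[a]], ]
    dx <- sweep(sw[hyd, , drop = FALSE], 2, X)
    d <- sqrt(rowSums(dx^2))
    ok <- d <= criteria$d_max
    if (!any(ok)) next
    for (j in which(ok)) {
      ang <- bond_angle(sw[o_rows[j], ], sw[hyd[j], ], X)
      if (ang > criteria$angle_min)
        cand[[length(cand) + 1L]] <- data.frame(
          acceptor = names(acceptors)[a], water = water_id[hyd[j]],
          hydrogen = hyd[j], distance = d[j], angle = ang)
    }
  }
  if (!length(cand)) return(.empty_bonds())
  bonds <- do.call(rbind, cand)
  if (criteria$one_bond_per_hydrogen) {
    ## nearest qualifying acceptor per hydrogen; ties by distance then water id
    bonds <- bonds[order(bonds$hydrogen, bonds$distance, bonds$water), ]
    bonds <- bonds[!duplicated(bonds$hydrogen), ]
  }
  rownames(bonds) <- NULL
  bonds
}

.empty_bonds <- function() {
  data.frame(acceptor = character(), water = integer(), hydrogen = integer(),
             distance = numeric(), angle = numeric())
}

#' Ensemble-averaged hydrogen-bond time series
#'
#' Mean number of detected hydrogen bonds per acceptor (and in total,
#' omitting `exclude`d labels) over the retained trajectories at each grid
#' time of their solvated frames.
#'
#' @param ens An [sh_ensemble()] whose trajectories carry solvent
#'   coordinates (see [solvate_ensemble()]).
#' @param acceptors Named acceptor indices.
#' @param criteria An [hbond_criteria()].
#' @param exclude Acceptor labels omitted from the total (default `"F"`,
#'   whose occupancy oscillates too strongly to average meaningfully).
#' @return data.frame with columns `time`, `total`, and one mean-count
#'   column per acceptor label.
#' @export
hbond_series <- function(ens, acceptors = default_atom_selection()$acceptors,
                         criteria = hbond_criteria(), exclude = "F") {
  trajs <- Filter(function(t) !is.null(t$solvent), .active_trajectories(ens))
  if (!length(trajs)) stop("hbond_series: no solvated frames in the ensemble")
  grid <- trajs[[which.max(vapply(trajs, function(t) max(t$times), numeric(1)))]]$times
  labs <- names(acceptors)
  sums <- matrix(0, length(grid), length(labs), dimnames = list(NULL, labs))
  ncontrib <- numeric(length(grid))
  for (t in trajs) {
    for (i in seq_len(n_frames(t))) {
      g <- which(abs(grid - t$times[i]) < 1e-6)
      if (!length(g)) next
      b <- detect_hbonds(get_frame(t, i), acceptors, criteria)
      ncontrib[g] <- ncontrib[g] + 1
      if (nrow(b)) {
        tb <- table(factor(b$acceptor, levels = labs))
        sums[g, ] <- sums[g, ] + as.numeric(tb)
      }
    }
  }
  if (any(ncontrib == 0)) {
    keep <- ncontrib > 0
    grid <- grid[keep]; sums <- sums[keep, , drop = FALSE]
    ncontrib <- ncontrib[keep]
  }
  means <- sums / ncontrib
  out <- data.frame(time = grid,
                    total = rowSums(means[, setdiff(labs, exclude),
                                          drop = FALSE]))
  for (lab in labs) out[[lab]] <- means[, lab]
  out
}
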