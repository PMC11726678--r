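#' Classify a final geometry from its CNNC and CCNC dihedrals
#'
#' A geometry is trans if `theta > 150` degrees and cis if `theta < 30`;
#' cis geometries are sub-classified by the CCNC dihedral `alpha` into
#' conformer I (`alpha < 45`), conformer II (`alpha > 135`) or
#' `cis_unassigned`. Everything in between (`30 <= theta <= 150`) is
#' `intermediate`.
#'
#' @param theta CNNC dihedral magnitude(s), degrees in `[0, 180]`.
#' @param alpha CCNC dihedral magnitude(s), degrees in `[0, 180]`.
#' @return Factor with levels `trans`, `cis_I`, `cis_II`, `cis_unassigned`,
#'   `intermediate` (vectorized).
#' @export
classify_final_geometry <- function(theta, alpha) {
  if (any(theta < 0 | theta > 180 | alpha < 0 | alpha > 180, na.rm = TRUE))
    stop("classify_final_geometry: angles must lie in [0, 180]")
  out <- ifelse(theta > 150, "trans",
         ifelse(theta < 30,
                ifelse(alpha < 45, "cis_I",
                ifelse(alpha > 135, "cis_II", "cis_unassigned")),
                "intermediate"))
  factor(out, levels = c("trans", "cis_I", "cis_II", "cis_unassigned",
                         "intermediate"))
}

#' Binomial standard deviation of a fraction
#'
#' `sqrt(phi * (1 - phi) / n)`, the binomial standard deviation attached to
#' trajectory-count fractions such as the photoisomerization quantum yield.
#'
#' @param phi Fraction in `[0, 1]`.
#' @param n Count (>= 1).
#' @return Standard deviation (dimensionless).
#' @examples
#' round(binomial_sd(0.25, 112), 2)  # 0.04
#' @export
binomial_sd <- function(phi, n) {
  if (any(n < 1)) stop("binomial_sd: n must be >= 1")
  if (any(phi < 0 | phi > 1)) stop("binomial_sd: phi must lie in [0, 1]")
  sqrt(phi * (1 - phi) / n)
}

#' Photoisomerization quantum yield of an ensemble
#'
#' Eligible trajectories are those whose final active state is the ground
#' state, whether at the end of the run or after early termination;
#' still-excited and energy-excluded trajectories are left out. The quantum
#' yield is `Phi = n_cis / (n_cis + n_trans)`; ground-state finals with
#' intermediate CNNC (30-150 degrees) are counted and reported but excluded
#' from both numerator and denominator, so the alternative all-ground-state
#' convention remains recomputable from the counts.
#'
#' @param ens An [sh_ensemble()] with QC applied.
#' @param sel An [atom_selection()].
#' @return Object of class `yield_result`: `phi`, `sigma_phi` (binomial sd
#'   on `n_cis + n_trans`), `phi_I`, `phi_II` (fractions over all cis
#'   trajectories), the underlying counts, and the per-trajectory final
#'   classification (`classes`).
#' @export
quantum_yield <- function(ens, sel = default_atom_selection()) {
  trajs <- .active_trajectories(ens)
  if (!length(trajs)) stop("quantum_yield: empty ensemble")
  finals <- lapply(trajs, function(t) {
    nf <- n_frames(t)
    if (t$active_state[nf] != 0) return(NULL)
    ic <- internal_coords(t$coords[, , nf, drop = TRUE], sel)
    data.frame(theta = ic$theta, alpha = ic$alpha)
  })
  eligible <- !vapply(finals, is.null, logical(1))
  if (!any(eligible)) stop("quantum_yield: no trajectory reached the ground state")
  geom <- do.call(rbind, finals[eligible])
  cls <- classify_final_geometry(geom$theta, geom$alpha)
  n_cis_I <- sum(cls == "cis_I")
  n_cis_II <- sum(cls == "cis_II")
  n_cis_un <- sum(cls == "cis_unassigned")
  n_cis <- n_cis_I + n_cis_II + n_cis_un
  n_trans <- sum(cls == "trans")
  n_int <- sum(cls == "intermediate")
  if (n_cis + n_trans == 0)
    stop("quantum_yield: no classifiable (cis or trans) ground-state final")
  phi <- n_cis / (n_cis + n_trans)
  structure(list(
    phi = phi,
    sigma_phi = binomial_sd(phi, n_cis + n_trans),
    phi_I = if (n_cis > 0) n_cis_I / n_cis else NA_real_,
    phi_II = if (n_cis > 0) n_cis_II / n_cis else NA_real_,
    n_cis = n_cis, n_trans = n_trans, n_intermediate = n_int,
    n_cis_I = n_cis_I, n_cis_II = n_cis_II, n_cis_unassigned = n_cis_un,
    n_eligible = sum(eligible),
    n_still_excited = sum(!eligible),
    classes = cls), class = "yield_result")
}

#' @export
print.yield_result <- function(x, ...) {
  cat(sprintf(
    "quantum yield: Phi = %.3f +/- %.3f (%d cis / %d trans / %d intermediate; %d still excited)\n",
    x$phi, x$sigma_phi, x$n_cis, x$n_trans, x$n_intermediate,
    x$n_still_excited))
  if (x$n_cis > 0)
    cat(sprintf("conformer fractions: phi_I = %.3f, phi_II = %.3f\n",
                x$phi_I, x$phi_II))
  invisible(x)
}

#' Cis-conformer fractions
#'
#' Fractions of the cis trajectories that formed conformer I and II. The
#' denominator is the full cis count, so the two fractions sum to 1 exactly
#' when no cis geometry is left unassigned.
#'
#' @param x Either a `yield_result` or a factor/character vector of final
#'   classifications (levels as in [classify_final_geometry()]).
#' @return Named numeric vector `c(phi_I, phi_II)`.
#' @export
conformer_fractions <- function(x) {
  if (inherits(x, "yield_result")) {
    if (x$n_cis < 1) stop("conformer_fractions: no cis trajectories")
    return(c(phi_I = x$phi_I, phi_II = x$phi_II))
  }
  cls <- as.character(x)
  n_cis <- sum(cls %in% c("cis_I", "cis_II", "cis_unassigned"))
  if (n_cis < 1) stop("conformer_fractions: no cis trajectories")
  c(phi_I = sum(cls == "cis_I") / n_cis,
    phi_II = sum(cls == "cis_II") / n_cis)
}
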