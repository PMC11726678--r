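#' Bond angle between three points
#'
#' Angle at `p2` formed by the points `p1-p2-p3`, in degrees.
#'
#' @param p1,p2,p3 Numeric length-3 Cartesian coordinates (Angstrom).
#' @return Angle in degrees, in `[0, 180]`.
#' @examples
#' bond_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0))  # 90
#' @export
bond_angle <- function(p1, p2, p3) {
  v1 <- p1 - p2
  v2 <- p3 - p2
  n1 <- sqrt(sum(v1^2))
  n2 <- sqrt(sum(v2^2))
  if (n1 < 1e-12 || n2 < 1e-12)
    stop("bond_angle: coincident points")
  ct <- sum(v1 * v2) / (n1 * n2)
  ct <- min(1, max(-1, ct))
  acos(ct) * 180 / pi
}

#' Signed dihedral angle between four points
#'
#' Torsion about the `p2-p3` axis using the standard atan2 formulation
#' (IUPAC convention: positive clockwise looking from `p2` to `p3`).
#'
#' @param p1,p2,p3,p4 Numeric length-3 Cartesian coordinates (Angstrom).
#' @return Signed dihedral in degrees in `(-180, 180]`. Use [fold_angle()]
#'   for the folded magnitude in `[0, 180]` used by classification.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n2 <- sqrt(sum(b2^2))
  if (n2 < 1e-12) stop("dihedral: degenerate p2-p3 axis")
  c1 <- .cross3(b1, b2)
  c2 <- .cross3(b2, b3)
  if (sum(c1^2) < 1e-18 || sum(c2^2) < 1e-18)
    stop("dihedral: three consecutive points are collinear")
  m1 <- .cross3(c1, b2 / n2)
  ang <- atan2(sum(m1 * c2), sum(c1 * c2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Fold an angle to its magnitude in [0, 180]
#'
#' @param x Angle(s) in degrees.
#' @return `abs(x)` mapped into `[0, 180]`.
#' @export
fold_angle <- function(x) {
  x <- abs(x %% 360)
  ifelse(x > 180, 360 - x, x)
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## Row-wise vector helpers (n x 3 matrices) used by the frame-vectorized paths.
.vcross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}
.vdot <- function(a, b) rowSums(a * b)
.vnorm <- function(a) sqrt(rowSums(a^2))
.vunit <- function(a) a / .vnorm(a)

## Vectorized signed dihedral for stacks of quadruples (each an n x 3 matrix).
.vdihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  c1 <- .vcross(b1, b2)
  c2 <- .vcross(b2, b3)
  m1 <- .vcross(c1, .vunit(b2))
  ang <- atan2(.vdot(m1, c2), .vdot(c1, c2)) * 180 / pi
  ifelse(ang <= -180, ang + 360, ang)
}

.vangle <- function(p1, p2, p3) {
  v1 <- p1 - p2
  v2 <- p3 - p2
  ct <- .vdot(v1, v2) / (.vnorm(v1) * .vnorm(v2))
  acos(pmin(1, pmax(-1, ct))) * 180 / pi
}

#' Atom selection for the named internal coordinates
#'
#' Bundles the 1-based atom indices that define the five internal coordinates
#' of the azo core (CNNC dihedral theta, CCNC dihedral alpha, CCCC dihedral
#' omega, CNN angle gamma, NNC angle gamma_prime) together with the labelled
#' heteroatom acceptors used by the hydrogen-bond analysis.
#'
#' @param theta_atoms 4 indices (C,N,N,C).
#' @param alpha_atoms 4 indices (C,C,N,C).
#' @param omega_atoms 4 indices (C,C,C,C).
#' @param gamma_atoms 3 indices (C,N,N).
#' @param gamma_prime_atoms 3 indices (N,N,C).
#' @param acceptor_atoms Named integer vector of heteroatom acceptor indices.
#' @return Object of class `atom_selection`.
#' @seealso [default_atom_selection()] for the bundled azo-fragment indices.
#' @export
atom_selection <- function(theta_atoms, alpha_atoms, omega_atoms,
                           gamma_atoms, gamma_prime_atoms,
                           acceptor_atoms = integer()) {
  stopifnot(length(theta_atoms) == 4, length(alpha_atoms) == 4,
            length(omega_atoms) == 4, length(gamma_atoms) == 3,
            length(gamma_prime_atoms) == 3)
  for (tup in list(theta_atoms, alpha_atoms, omega_atoms,
                   gamma_atoms, gamma_prime_atoms)) {
    if (anyDuplicated(tup)) stop("atom_selection: duplicate index in a tuple")
    if (any(tup < 1)) stop("atom_selection: indices must be >= 1")
  }
  structure(list(theta = as.integer(theta_atoms),
                 alpha = as.integer(alpha_atoms),
                 omega = as.integer(omega_atoms),
                 gamma = as.integer(gamma_atoms),
                 gamma_prime = as.integer(gamma_prime_atoms),
                 acceptors = acceptor_atoms),
            class = "atom_selection")
}

#' Default atom selection for the bundled 12-atom azo fragment
#'
#' @return An [atom_selection()] matching [azo_fragment_template()].
#' @export
default_atom_selection <- function() {
  atom_selection(theta_atoms = c(2, 3, 4, 5),
                 alpha_atoms = c(7, 8, 9, 10),
                 omega_atoms = c(5, 6, 7, 8),
                 gamma_atoms = c(2, 3, 4),
                 gamma_prime_atoms = c(3, 4, 5),
                 acceptor_atoms = c(N_azo1 = 3L, N_azo2 = 4L, N_amine = 9L,
                                    O_ether = 11L, F = 12L))
}

#' Topology template for the reduced azo fragment
#'
#' A 12-atom Z-matrix-style template of the photoswitch core: two ring-anchor
#' carbons, the C-N=N-C azo unit, substituent-marker atoms carrying the CCCC
#' (omega) and CCNC (alpha) dihedrals, and ether-oxygen/fluorine markers used
#' as hydrogen-bond acceptors. Bond lengths are typical azobenzene values
#' (C-N 1.42, N=N 1.25, C-C 1.40 Angstrom); only geometric self-consistency
#' matters, not energetics.
#'
#' Placement parameters named `"theta"`, `"alpha"`, `"omega"`, `"gamma"`,
#' `"gamma_prime"` are substituted from the requested internal coordinates by
#' [build_fragment()]; numeric entries are fixed.
#'
#' @return A data.frame with columns `element`, `j`, `k`, `l` (reference
#'   atoms), `bond` (Angstrom), `angle`, `dihedral` (degrees or parameter
#'   name).
#' @export
azo_fragment_template <- function() {
  data.frame(
    element  = c("C", "C", "N", "N", "C", "C", "C", "C", "N", "C", "O", "F"),
    j        = c(NA,  1,   2,   3,   4,   5,   6,   7,   8,   9,   6,   2),
    k        = c(NA, NA,   1,   2,   3,   4,   5,   6,   7,   8,   5,   3),
    l        = c(NA, NA,  NA,   1,   2,   3,   4,   5,   6,   7,   4,   4),
    bond     = c(NA, 1.40, 1.42, 1.25, 1.42, 1.40, 1.40, 1.40, 1.45, 1.45,
                 1.36, 1.35),
    angle    = c(NA, NA, "120", "gamma", "gamma_prime", "120", "120", "115",
                 "112", "112", "120", "120"),
    dihedral = c(NA, NA, NA, "180", "theta", "-35", "70", "omega", "-60",
                 "alpha", "160", "180"),
    stringsAsFactors = FALSE
  )
}

#' Internal coordinate set
#'
#' @param theta,alpha,omega,gamma,gamma_prime Values in degrees, each within
#'   `[0, 180]` (folded magnitudes).
#' @return Object of class `internal_coords`.
#' @export
internal_coord_set <- function(theta, alpha, omega, gamma, gamma_prime) {
  v <- c(theta = theta, alpha = alpha, omega = omega, gamma = gamma,
         gamma_prime = gamma_prime)
  if (any(!is.finite(v)) || any(v < 0) || any(v > 180))
    stop("internal_coord_set: all values must lie in [0, 180]")
  structure(as.list(v), class = "internal_coords")
}

#' @export
print.internal_coords <- function(x, ...) {
  cat(sprintf(
    "internal coords [deg]: theta=%.3f alpha=%.3f omega=%.3f gamma=%.3f gamma'=%.3f\n",
    x$theta, x$alpha, x$omega, x$gamma, x$gamma_prime))
  invisible(x)
}

## Substitute template parameters with per-frame vectors; returns n x 12
## matrices of angles/dihedrals in degrees (NA where undefined).
.template_params <- function(template, ics) {
  lookup <- function(spec, n) {
    if (is.na(spec)) return(rep(NA_real_, n))
    num <- suppressWarnings(as.numeric(spec))
    if (!is.na(num)) return(rep(num, n))
    val <- ics[[spec]]
    if (is.null(val)) stop("build_fragment: template references unknown parameter ", spec)
    rep_len(as.numeric(val), n)
  }
  n <- max(vapply(c("theta", "alpha", "omega", "gamma", "gamma_prime"),
                  function(p) length(ics[[p]]), integer(1)))
  ang <- sapply(template$angle, lookup, n = n)
  dih <- sapply(template$dihedral, lookup, n = n)
  list(n = n, angle = matrix(ang, nrow = n), dihedral = matrix(dih, nrow = n))
}

## Z-matrix (NeRF) placement, vectorized over frames. theta/alpha/... may be
## vectors of equal length; returns an array [natom, 3, nframe].
.build_fragment_frames <- function(theta, alpha, omega, gamma, gamma_prime,
                                   template = azo_fragment_template()) {
  ics <- list(theta = theta, alpha = alpha, omega = omega, gamma = gamma,
              gamma_prime = gamma_prime)
  ## bond angles of exactly 0/180 make the dependent dihedral undefined;
  ## perturb by 1e-4 degrees (documented behaviour).
  for (p in c("gamma", "gamma_prime")) {
    v <- ics[[p]]
    v[v >= 180] <- 180 - 1e-4
    v[v <= 0] <- 1e-4
    ics[[p]] <- v
  }
  par <- .template_params(template, ics)
  n <- par$n
  natom <- nrow(template)
  pos <- vector("list", natom)
  zero <- matrix(0, n, 3)
  ## first three atoms define the initial frame
  pos[[1]] <- zero
  pos[[2]] <- cbind(rep(template$bond[2], n), 0, 0)
  a3 <- par$angle[, 3] * pi / 180
  r3 <- template$bond[3]
  pos[[3]] <- pos[[2]] + cbind(-r3 * cos(a3), r3 * sin(a3), 0)
  deg2rad <- pi / 180
  for (i in 4:natom) {
    A <- pos[[template$l[i]]]
    B <- pos[[template$k[i]]]
    C <- pos[[template$j[i]]]
    r <- template$bond[i]
    ang <- par$angle[, i] * deg2rad
    dih <- par$dihedral[, i] * deg2rad
    bc <- .vunit(C - B)
    nvec <- .vcross(B - A, bc)
    nn <- .vnorm(nvec)
    if (any(nn < 1e-10))
      stop("build_fragment: collinear reference atoms (degenerate dihedral)")
    nhat <- nvec / nn
    mhat <- .vcross(nhat, bc)
    d <- cbind(-r * cos(ang), r * sin(ang) * cos(dih), r * sin(ang) * sin(dih))
    pos[[i]] <- C + d[, 1] * bc + d[, 2] * mhat + d[, 3] * nhat
  }
  out <- array(NA_real_, dim = c(natom, 3, n))
  for (i in seq_len(natom)) out[i, , ] <- t(pos[[i]])
  out
}

#' Build Cartesian coordinates of the azo fragment from internal coordinates
#'
#' Z-matrix-style (NeRF) placement of the 12-atom fragment so that the five
#' named internal coordinates measured on the result reproduce the request
#' within 1e-6 degrees. Bond angles requested at exactly 0 or 180 degrees
#' (where the dependent dihedral is undefined) are perturbed by 1e-4 degrees.
#'
#' @param ics An [internal_coord_set()] (or list with elements `theta`,
#'   `alpha`, `omega`, `gamma`, `gamma_prime`, degrees).
#' @param template Topology template, see [azo_fragment_template()].
#' @return Numeric `natom x 3` coordinate matrix (Angstrom) with an
#'   `elements` attribute.
#' @examples
#' xyz <- build_fragment(internal_coord_set(95, 30, 90, 120, 120))
#' internal_coords(xyz, default_atom_selection())
#' @export
build_fragment <- function(ics, template = azo_fragment_template()) {
  for (p in c("theta", "alpha", "omega", "gamma", "gamma_prime")) {
    v <- ics[[p]]
    if (is.null(v) || !is.finite(v) || v < 0 || v > 180)
      stop("build_fragment: ", p, " must be a finite value in [0, 180]")
  }
  arr <- .build_fragment_frames(ics$theta, ics$alpha, ics$omega,
                                ics$gamma, ics$gamma_prime, template)
  out <- arr[, , 1]
  attr(out, "elements") <- template$element
  out
}

#' Measure the five named internal coordinates of a frame
#'
#' @param x Either a coordinate matrix (`natom x 3`), an `sh_frame`, or an
#'   `sh_trajectory` (in which case a per-frame data.frame is returned).
#' @param sel An [atom_selection()].
#' @return For a single frame, an `internal_coords` object with the folded
#'   magnitudes in `[0, 180]`; signed dihedrals are retained in the
#'   `"signed"` attribute. For a trajectory, a data.frame with one row per
#'   frame (columns `time`, `theta`, `alpha`, `omega`, `gamma`,
#'   `gamma_prime`).
#' @export
internal_coords <- function(x, sel = default_atom_selection()) {
  if (inherits(x, "sh_trajectory")) {
    df <- .internal_coords_traj(x, sel)
    return(df)
  }
  coords <- if (inherits(x, "sh_frame")) x$coords else x
  if (!is.matrix(coords) || ncol(coords) != 3)
    stop("internal_coords: coordinates must be an natom x 3 matrix")
  idx <- c(sel$theta, sel$alpha, sel$omega, sel$gamma, sel$gamma_prime)
  if (any(idx > nrow(coords)))
    stop("internal_coords: selection index out of range")
  th <- dihedral(coords[sel$theta[1], ], coords[sel$theta[2], ],
                 coords[sel$theta[3], ], coords[sel$theta[4], ])
  al <- dihedral(coords[sel$alpha[1], ], coords[sel$alpha[2], ],
                 coords[sel$alpha[3], ], coords[sel$alpha[4], ])
  om <- dihedral(coords[sel$omega[1], ], coords[sel$omega[2], ],
                 coords[sel$omega[3], ], coords[sel$omega[4], ])
  ga <- bond_angle(coords[sel$gamma[1], ], coords[sel$gamma[2], ],
                   coords[sel$gamma[3], ])
  gp <- bond_angle(coords[sel$gamma_prime[1], ], coords[sel$gamma_prime[2], ],
                   coords[sel$gamma_prime[3], ])
  out <- internal_coord_set(fold_angle(th), fold_angle(al), fold_angle(om),
                            ga, gp)
  attr(out, "signed") <- c(theta = th, alpha = al, omega = om)
  out
}

## Vectorized measurement over all frames of a trajectory.
.internal_coords_traj <- function(traj, sel = default_atom_selection()) {
  co <- traj$coords  # [natom, 3, nframe]
  pick <- function(i) t(co[i, , , drop = TRUE])
  quad <- function(idx) .vdihedral(pick(idx[1]), pick(idx[2]),
                                   pick(idx[3]), pick(idx[4]))
  trip <- function(idx) .vangle(pick(idx[1]), pick(idx[2]), pick(idx[3]))
  data.frame(time = traj$times,
             theta = fold_angle(quad(sel$theta)),
             alpha = fold_angle(quad(sel$alpha)),
             omega = fold_angle(quad(sel$omega)),
             gamma = trip(sel$gamma),
             gamma_prime = trip(sel$gamma_prime))
}
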