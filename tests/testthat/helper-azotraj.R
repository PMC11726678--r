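## Shared fixtures and independent oracles for the test suite.

## fast generator settings: 100-frame trajectories whose kinetics resolve
## well inside the horizon
quick_kin <- function(...) {
  args <- list(mode = "S1_start", t0 = 100, tau1 = 400, p_reactive = 0.25,
               p_conformer_I_given_rot = 0.7, p_conformer_I_given_inv = 0.3,
               p_rotational = 0.6)
  args[names(list(...))] <- list(...)
  do.call(kinetic_spec, args)
}

quick_mot <- function(dt = 25, horizon = 2500, ...)
  motion_spec(dt = dt, horizon = horizon, ...)

quick_ensemble <- function(n, seed = 1, kin = quick_kin(), mot = quick_mot(),
                           qc = TRUE) {
  ens <- generate_ensemble(n, kin, mot, seed = seed)
  if (qc)
    ens <- apply_early_termination_ensemble(
      energy_conservation_filter(ens)$ensemble)
  ens
}

## uniformly random rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

## Independent dihedral oracle: rotate the configuration so the p2->p3 axis
## lies along +z, then read the torsion as the difference of the azimuthal
## atan2 angles of p1 and p4 around that axis.
oracle_dihedral <- function(p1, p2, p3, p4) {
  z <- (p3 - p2)
  z <- z / sqrt(sum(z^2))
  ref <- if (abs(z[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  x <- ref - sum(ref * z) * z
  x <- x / sqrt(sum(x^2))
  y <- c(z[2] * x[3] - z[3] * x[2],
         z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  R <- rbind(x, y, z)
  a <- R %*% (p1 - p2)
  b <- R %*% (p4 - p3)
  phi1 <- atan2(a[2], a[1])
  phi4 <- atan2(b[2], b[1])
  ## project the azimuth sweep from p1 to p4 looking along p2 -> p3
  ## (clockwise positive, matching the package convention)
  ang <- (phi1 - phi4) * 180 / pi
  ang <- ((ang + 180) %% 360) - 180
  if (ang <= -180) ang + 360 else ang
}

## Brute-force yield oracle: classify every eligible final frame directly.
oracle_phi <- function(ens, sel = default_atom_selection()) {
  n_cis <- 0; n_trans <- 0
  for (t in ens$trajectories) {
    if (t$termination == "excluded_energy") next
    nf <- length(t$times)
    if (t$active_state[nf] != 0) next
    co <- t$coords[, , nf]
    th <- abs(dihedral(co[sel$theta[1], ], co[sel$theta[2], ],
                       co[sel$theta[3], ], co[sel$theta[4], ]))
    if (th < 30) n_cis <- n_cis + 1
    if (th > 150) n_trans <- n_trans + 1
  }
  n_cis / (n_cis + n_trans)
}

## Brute-force hop-count oracle: scan the state sequence directly.
oracle_hop_count <- function(traj, from = 1, to = 0) {
  st <- traj$active_state
  sum(st[-length(st)] == from & st[-1] == to)
}

## Minimal hand-built trajectory with prescribed state sequence and dt.
toy_trajectory <- function(states, dt = 100, theta = NULL, alpha = 90,
                           omega = 90, total_energy = NULL) {
  nf <- length(states)
  if (is.null(theta)) theta <- rep(170, nf)
  coords <- azotraj:::.build_fragment_frames(
    rep_len(theta, nf), rep_len(alpha, nf), rep_len(omega, nf),
    rep(120, nf), rep(120, nf))
  en <- cbind(E_S0 = rep(0, nf), E_S1 = rep(2, nf), E_S2 = rep(3, nf))
  sh_trajectory(times = seq(0, by = dt, length.out = nf), coords = coords,
                elements = azo_fragment_template()$element, energies = en,
                active_state = states,
                total_energy = total_energy %||% rep(5, nf),
                meta = list(initial_state = states[1]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
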