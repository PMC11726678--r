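#' Kinetic specification for the synthetic ensemble generator
#'
#' Encodes the generative excited-state kinetics: trajectories started in S1
#' hop to the ground state at `t0 + Exp(tau1)` (delayed exponential), while
#' trajectories started in S2 first relax to S1 after `Exp(tau2)` and then
#' hop after an additional `Exp(tau1)` dwell (sequential two-step kinetics).
#' Outcome probabilities control the cis/trans branching, the rotation vs
#' inversion pathway, and the conformer preference conditional on the
#' pathway.
#'
#' @param mode `"S1_start"` or `"S2_start"`.
#' @param t0 Delay time in fs (S1 start).
#' @param tau1 S1 lifetime constant in fs.
#' @param tau2 S2 lifetime constant in fs (S2 start only).
#' @param p_reactive Probability that a ground-state arrival is cis.
#' @param p_conformer_I_given_rot,p_conformer_I_given_inv Conditional
#'   probabilities of forming cis conformer I given the pathway.
#' @param p_rotational Probability that a reactive hop follows the rotational
#'   pathway.
#' @param hop_theta_band CNNC window (degrees) in which hops occur,
#'   default `c(90, 120)`.
#' @return Object of class `kinetic_spec`.
#' @export
kinetic_spec <- function(mode = c("S1_start", "S2_start"), t0 = 0,
                         tau1, tau2 = NULL, p_reactive = 0.25,
                         p_conformer_I_given_rot = 0.67,
                         p_conformer_I_given_inv = 0.33,
                         p_rotational = 1,
                         hop_theta_band = c(90, 120)) {
  mode <- match.arg(mode)
  probs <- c(p_reactive, p_conformer_I_given_rot, p_conformer_I_given_inv,
             p_rotational)
  if (any(probs < 0 | probs > 1))
    stop("kinetic_spec: probabilities must lie in [0, 1]")
  if (!is.numeric(tau1) || tau1 <= 0) stop("kinetic_spec: tau1 must be > 0")
  if (t0 < 0) stop("kinetic_spec: t0 must be >= 0")
  if (mode == "S2_start") {
    if (is.null(tau2) || tau2 <= 0)
      stop("kinetic_spec: tau2 must be > 0 for S2_start")
  }
  if (length(hop_theta_band) != 2 || any(hop_theta_band < 0) ||
      any(hop_theta_band > 180) || diff(hop_theta_band) <= 0)
    stop("kinetic_spec: hop_theta_band must be an increasing range in [0, 180]")
  structure(list(mode = mode, t0 = t0, tau1 = tau1, tau2 = tau2,
                 p_reactive = p_reactive,
                 p_conformer_I_given_rot = p_conformer_I_given_rot,
                 p_conformer_I_given_inv = p_conformer_I_given_inv,
                 p_rotational = p_rotational,
                 hop_theta_band = hop_theta_band),
            class = "kinetic_spec")
}

#' Nuclear-motion specification for the synthetic generator
#'
#' @param dt Frame spacing in fs.
#' @param horizon Propagation length in fs (at least `100 * dt`).
#' @param langevin_friction Ornstein-Uhlenbeck relaxation rate for the
#'   thermal torsional noise, fs^-1 (preset 0.02, mirroring a Langevin
#'   thermostat friction).
#' @param temperature Nominal bath temperature in K (bookkeeping only).
#' @param theta_noise_amplitude Stationary standard deviation of the CNNC
#'   thermal fluctuation, degrees.
#' @param relaxation_time_to_product Post-hop torsional relaxation constant
#'   in fs.
#' @return Object of class `motion_spec`.
#' @export
motion_spec <- function(dt, horizon, langevin_friction = 0.02,
                        temperature = 300, theta_noise_amplitude = 4,
                        relaxation_time_to_product = 150) {
  if (dt <= 0) stop("motion_spec: dt must be > 0")
  if (horizon < 100 * dt) stop("motion_spec: horizon must be >= 100 * dt")
  structure(list(dt = dt, horizon = horizon,
                 langevin_friction = langevin_friction,
                 temperature = temperature,
                 theta_noise_amplitude = theta_noise_amplitude,
                 relaxation_time_to_product = relaxation_time_to_product),
            class = "motion_spec")
}

#' Vertical-excitation band specification
#'
#' @param states data.frame with columns `state` (adiabatic label, 1-based
#'   for excited states), `center` and `width` (eV), `f_mean` and `f_sd`
#'   (oscillator strength mean and spread).
#' @param n_geometries Number of sampled geometries.
#' @return Object of class `spectrum_spec`.
#' @export
spectrum_spec <- function(states, n_geometries) {
  need <- c("state", "center", "width", "f_mean", "f_sd")
  if (!all(need %in% names(states)))
    stop("spectrum_spec: states needs columns ", paste(need, collapse = ", "))
  if (any(states$width <= 0)) stop("spectrum_spec: widths must be > 0")
  if (any(states$f_mean < 0)) stop("spectrum_spec: f_mean must be >= 0")
  if (n_geometries < 1) stop("spectrum_spec: n_geometries must be >= 1")
  structure(list(states = states, n_geometries = as.integer(n_geometries)),
            class = "spectrum_spec")
}

#' Solvent-shell specification
#'
#' Schedules the expected hydrogen-bond occupancy per acceptor over time and
#' fixes the geometry used to place bonded waters. Default placement leaves
#' a 0.2 Angstrom / 10 degree margin inside the detection criteria so tests
#' never sit on the thresholds; set `water_distance`/`water_angle` outside
#' the criteria to generate deliberate violations.
#'
#' @param schedule data.frame with a `time` column (fs) and one column per
#'   acceptor label giving the expected occupancy (linearly interpolated,
#'   held constant beyond the range).
#' @param water_distance Acceptor-to-hydrogen placement distance, Angstrom.
#' @param water_angle Placed O_w-H...X angle, degrees.
#' @param n_waters Total waters per frame (bonded + spectators).
#' @return Object of class `solvation_spec`.
#' @export
solvation_spec <- function(schedule, water_distance = 2.0, water_angle = 165,
                           n_waters = 8) {
  if (!"time" %in% names(schedule))
    stop("solvation_spec: schedule needs a time column")
  if (any(as.matrix(schedule[setdiff(names(schedule), "time")]) < 0))
    stop("solvation_spec: scheduled occupancies must be >= 0")
  structure(list(schedule = schedule, water_distance = water_distance,
                 water_angle = water_angle, n_waters = as.integer(n_waters)),
            class = "solvation_spec")
}

#' Derive reproducible child seeds from a master seed
#'
#' Splitmix-style mixing of `(master, index)` into 31-bit child seeds: two
#' multiplicative-congruential rounds with an xor-shift in between (all
#' arithmetic exact in doubles). Unlike walking a single LCG orbit, hashing
#' the pair keeps the streams of nested derivations (ensemble -> trajectory
#' -> frame) disjoint, so replicate ensembles never share member
#' trajectories.
#'
#' @param master Master seed (integer).
#' @param n Number of child seeds.
#' @return Integer vector of length `n`.
#' @export
derive_seeds <- function(master, n) {
  m <- as.numeric(master) %% 2^31
  i <- seq_len(n)
  h <- (m * 69069 + i * 40503 + 12345) %% 2^31
  h <- (h * 69069 + 1) %% 2^31
  h <- as.numeric(bitwXor(as.integer(h), as.integer(h %/% 65536))) %% 2^31
  h <- (h * 40503 + 2531011) %% 2^31
  as.integer(h)
}

#' Sample surface-hopping times from the generative kinetics
#'
#' @param spec A [kinetic_spec()].
#' @param n Number of trajectories.
#' @param seed Integer RNG seed.
#' @return data.frame with columns `t_s2_s1` (NA for S1 starts) and
#'   `t_s1_s0` (fs, ground-state arrival time).
#' @export
sample_hop_times <- function(spec, n, seed) {
  if (!inherits(spec, "kinetic_spec")) stop("sample_hop_times: invalid spec")
  if (n < 1) stop("sample_hop_times: n must be >= 1")
  set.seed(seed)
  if (spec$mode == "S1_start") {
    t10 <- spec$t0 + stats::rexp(n, rate = 1 / spec$tau1)
    data.frame(t_s2_s1 = NA_real_, t_s1_s0 = t10)
  } else {
    t21 <- stats::rexp(n, rate = 1 / spec$tau2)
    t10 <- t21 + stats::rexp(n, rate = 1 / spec$tau1)
    data.frame(t_s2_s1 = t21, t_s1_s0 = t10)
  }
}

## Analytic two-state torsional model (plus an S2 shelf). theta in degrees.
## E_S0 is the ground-state torsional profile; the S1-S0 gap is parameterized
## directly so that it stays below 0.3 eV across the 90-120 degree hop band.
.torsional_energies <- function(theta_deg) {
  tr <- theta_deg * pi / 180
  e0 <- 1.6 * sin(tr)^2
  gap <- 0.10 + 1.3 * ((theta_deg - 105) / 105)^2
  e1 <- e0 + gap
  e2 <- e1 + 0.8 + 0.4 * cos(tr)^2
  cbind(E_S0 = e0, E_S1 = e1, E_S2 = e2)
}

## Exact Ornstein-Uhlenbeck (AR(1)) path around mu; x0 start, sd amplitude.
.ou_path <- function(n, mu, sd, friction, dt, x0 = mu) {
  phi <- exp(-friction * dt)
  s <- sd * sqrt(1 - phi^2)
  eps <- stats::rnorm(n, sd = s)
  x <- numeric(n)
  x[1] <- x0
  for (k in seq_len(n - 1)) x[k + 1] <- mu + phi * (x[k] - mu) + eps[k]
  x
}

#' Generate one synthetic surface-hopping trajectory
#'
#' Emulates the statistical structure of a nonadiabatic photoisomerization
#' trajectory: the CNNC dihedral fluctuates near trans (160-180 degrees)
#' with Ornstein-Uhlenbeck noise until the drawn hop time, descends so that
#' the hop geometry lies inside `hop_theta_band`, and then relaxes to a cis
#' (< 30 degrees) or trans (> 150 degrees) product. The CCCC dihedral at the
#' hop is drawn in `[55, 125]` (rotational) or `[145, 180]` (inversion)
#' degrees, the CCNC dihedral relaxes toward the conformer implied by the
#' conditional conformer probabilities, per-state energies come from the
#' bundled analytic torsional model, and Cartesian frames are emitted via
#' [build_fragment()]. Total energy is constant to within 1e-3 eV unless
#' drift is injected afterwards with [inject_energy_drift()].
#'
#' If the drawn ground-state arrival lies beyond the horizon the trajectory
#' simply ends still excited (termination `"completed"`, never reaching S0).
#'
#' @param kin A [kinetic_spec()].
#' @param mot A [motion_spec()].
#' @param sel An [atom_selection()] (defines nothing for generation but is
#'   carried so that measured coordinates use matching indices).
#' @param seed Integer RNG seed.
#' @param environment `"gas"` or `"water"` metadata tag.
#' @param window Optional excitation window (eV) recorded in the metadata.
#' @return An [sh_trajectory()]; the generating outcome (reactive flag,
#'   mechanism, conformer, hop geometry) is attached as attribute `"truth"`.
#' @export
generate_trajectory <- function(kin, mot, sel = default_atom_selection(),
                                seed = 1, environment = "gas",
                                window = NULL) {
  if (!inherits(kin, "kinetic_spec") || !inherits(mot, "motion_spec"))
    stop("generate_trajectory: invalid specs")
  set.seed(seed)
  times <- seq(0, mot$horizon, by = mot$dt)
  nf <- length(times)
  ## outcome draws
  if (kin$mode == "S1_start") {
    t21 <- NA_real_
    t10 <- kin$t0 + stats::rexp(1, 1 / kin$tau1)
  } else {
    t21 <- stats::rexp(1, 1 / kin$tau2)
    t10 <- t21 + stats::rexp(1, 1 / kin$tau1)
  }
  reactive <- stats::runif(1) < kin$p_reactive
  rotational <- stats::runif(1) < kin$p_rotational
  p_I <- if (rotational) kin$p_conformer_I_given_rot else kin$p_conformer_I_given_inv
  conformer_I <- stats::runif(1) < p_I
  theta_hop <- stats::runif(1, kin$hop_theta_band[1], kin$hop_theta_band[2])
  omega_hop <- if (rotational) stats::runif(1, 55, 125) else stats::runif(1, 145, 180)
  delta_e_hop <- abs(stats::rnorm(1, 0, 0.1))

  ## state switches land on the first grid frame at/after the drawn time;
  ## the initial frame keeps the initial state and the two switches of an
  ## S2 start occupy distinct frames
  i21 <- if (!is.na(t21) && t21 <= mot$horizon)
    max(2L, which(times >= t21)[1]) else NA_integer_
  ih <- if (t10 <= mot$horizon) max(2L, which(times >= t10)[1]) else NA_integer_
  if (!is.na(ih) && !is.na(i21) && ih <= i21) {
    ih <- i21 + 1L
    if (ih > nf) ih <- NA_integer_
  }

  fr <- mot$langevin_friction
  amp <- mot$theta_noise_amplitude
  theta <- .ou_path(nf, mu = 170, sd = amp, friction = fr, dt = mot$dt,
                    x0 = 170 + stats::rnorm(1, 0, amp))
  omega <- .ou_path(nf, mu = 25, sd = amp, friction = fr, dt = mot$dt,
                    x0 = 25 + stats::rnorm(1, 0, amp))
  alpha <- .ou_path(nf, mu = 90, sd = amp, friction = fr, dt = mot$dt,
                    x0 = 90 + stats::rnorm(1, 0, amp))
  gamma <- .ou_path(nf, mu = 115, sd = 3, friction = fr, dt = mot$dt)
  gammap <- .ou_path(nf, mu = 115, sd = 3, friction = fr, dt = mot$dt)

  if (!is.na(ih)) {
    ## descent window: interpolate from the thermal path into the hop geometry
    t_desc <- max(times[ih] - min(200, t10), 0)
    id <- which(times >= t_desc)[1]
    if (id < ih) {
      w <- (seq(id, ih) - id) / (ih - id)
      theta[id:ih] <- theta[id] * (1 - w) + theta_hop * w
      omega[id:ih] <- omega[id] * (1 - w) + omega_hop * w
    } else {
      theta[ih] <- theta_hop
      omega[ih] <- omega_hop
    }
    ## post-hop relaxation toward the product geometry
    if (ih < nf) {
      post <- (ih + 1):nf
      tau_r <- mot$relaxation_time_to_product
      decay <- exp(-(times[post] - times[ih]) / tau_r)
      th_tgt <- if (reactive) 10 else 170
      al_tgt <- if (!reactive) 90 else if (conformer_I) 25 else 155
      om_tgt <- if (rotational) 80 else 160
      nz <- stats::rnorm(length(post), 0, amp / 3)
      theta[post] <- th_tgt + (theta_hop - th_tgt) * decay + nz * (1 - decay)
      alpha[post] <- al_tgt + (alpha[ih] - al_tgt) * decay
      omega[post] <- om_tgt + (omega_hop - om_tgt) * decay
    }
    ## inversion pathway: in-plane NNC opening near the hop
    if (!rotational) {
      near <- abs(times - times[ih]) <= 150
      bump <- 45 * exp(-((times[near] - times[ih]) / 80)^2)
      gammap[near] <- gammap[near] + bump
    }
  }
  clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))
  theta <- clamp(theta, 0.5, 179.5)
  alpha <- clamp(alpha, 0.5, 179.5)
  omega <- clamp(omega, 0.5, 179.5)
  gamma <- clamp(gamma, 95, 178)
  gammap <- clamp(gammap, 95, 178)
  if (!is.na(ih)) { theta[ih] <- theta_hop; omega[ih] <- omega_hop }

  energies <- .torsional_energies(theta)
  if (!is.na(ih)) energies[ih, "E_S1"] <- energies[ih, "E_S0"] + delta_e_hop

  active <- rep(0L, nf)
  if (kin$mode == "S1_start") {
    active[] <- ifelse(is.na(ih), 1L, NA)
    if (is.na(ih)) active <- rep(1L, nf) else active <- ifelse(seq_len(nf) < ih, 1L, 0L)
  } else {
    active <- rep(2L, nf)
    if (!is.na(i21)) active[seq_len(nf) >= i21] <- 1L
    if (!is.na(ih)) active[seq_len(nf) >= ih] <- 0L
  }

  e_total <- energies[1, active[1] + 1] + 0.30 + stats::rnorm(nf, 0, 1e-4)
  coords <- .build_fragment_frames(theta, alpha, omega, gamma, gammap)

  traj <- sh_trajectory(
    times = times, coords = coords,
    elements = azo_fragment_template()$element,
    energies = energies, active_state = active, total_energy = e_total,
    meta = list(environment = environment,
                initial_state = if (kin$mode == "S1_start") 1L else 2L,
                window = window, seed = seed))
  attr(traj, "truth") <- list(reactive = reactive, rotational = rotational,
                              conformer_I = conformer_I,
                              theta_hop = theta_hop, omega_hop = omega_hop,
                              delta_e_hop = delta_e_hop, t_s1_s0 = t10,
                              t_s2_s1 = t21)
  traj
}

#' Generate a synthetic trajectory ensemble
#'
#' @param n Ensemble size (>= 1).
#' @param kin,mot,sel,environment,window Passed to [generate_trajectory()].
#' @param seed Master seed; per-trajectory seeds are derived from it by a
#'   documented linear-congruential sequence, so ensembles are reproducible
#'   and individual members regenerable.
#' @return An [sh_ensemble()] with `n_total = n`.
#' @export
generate_ensemble <- function(n, kin, mot, sel = default_atom_selection(),
                              seed = 1, environment = "gas", window = NULL) {
  if (n < 1) stop("generate_ensemble: n must be >= 1")
  seeds <- derive_seeds(seed, n)
  trajs <- lapply(seq_len(n), function(i)
    generate_trajectory(kin, mot, sel, seed = seeds[i],
                        environment = environment, window = window))
  sh_ensemble(trajs, n_total = n)
}

#' Inject a linear total-energy drift into a trajectory
#'
#' Creates quality-control test cases: the total energy ramps linearly by
#' `magnitude` eV between `onset` and the end of the trajectory; everything
#' else is unchanged.
#'
#' @param traj An [sh_trajectory()].
#' @param magnitude Drift magnitude in eV (>= 0); 0 is the identity.
#' @param onset Drift onset time in fs (must lie within the trajectory).
#' @return The modified trajectory.
#' @export
inject_energy_drift <- function(traj, magnitude, onset = 0) {
  if (magnitude < 0) stop("inject_energy_drift: magnitude must be >= 0")
  tmax <- max(traj$times)
  if (onset >= tmax) stop("inject_energy_drift: onset beyond the horizon")
  if (magnitude == 0) return(traj)
  ramp <- pmax(0, traj$times - onset) / (tmax - onset)
  traj$total_energy <- traj$total_energy + magnitude * ramp
  traj
}

#' Generate per-geometry vertical excitation records
#'
#' Draws excitation energies `E_k ~ Normal(center_k, width_k)` and
#' non-negative oscillator strengths per excited state for each of
#' `n_geometries` sampled geometries.
#'
#' @param spec A [spectrum_spec()].
#' @param seed Integer RNG seed.
#' @return data.frame with columns `geometry`, `state`, `energy` (eV),
#'   `f` (oscillator strength); attribute `n_geometries`.
#' @export
generate_vertical_excitations <- function(spec, seed = 1) {
  if (!inherits(spec, "spectrum_spec"))
    stop("generate_vertical_excitations: invalid spec")
  set.seed(seed)
  ng <- spec$n_geometries
  recs <- do.call(rbind, lapply(seq_len(nrow(spec$states)), function(i) {
    st <- spec$states[i, ]
    data.frame(geometry = seq_len(ng), state = st$state,
               energy = stats::rnorm(ng, st$center, st$width),
               f = pmax(0, stats::rnorm(ng, st$f_mean, st$f_sd)))
  }))
  attr(recs, "n_geometries") <- ng
  recs
}

## Evaluate the occupancy schedule at a time (linear interpolation, constant
## extrapolation); returns a named numeric vector per acceptor.
.schedule_at <- function(spec, time) {
  sch <- spec$schedule
  labs <- setdiff(names(sch), "time")
  vapply(labs, function(lab) {
    if (nrow(sch) < 2) return(sch[[lab]][1])
    stats::approx(sch$time, sch[[lab]], xout = time, rule = 2)$y
  }, numeric(1))
}

## Place one water so its nearer hydrogen sits `distance` from `acceptor`
## along `u` (unit, outward) with an O_w-H...X angle of `angle` degrees.
.place_water <- function(acceptor, u, distance, angle, azimuth = 0) {
  ## local orthonormal frame around u
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  p1 <- .cross3(u, ref); p1 <- p1 / sqrt(sum(p1^2))
  p2 <- .cross3(u, p1)
  perp <- cos(azimuth) * p1 + sin(azimuth) * p2
  H1 <- acceptor + distance * u
  phi <- angle * pi / 180
  ## direction H -> X is -u; O placed so angle(O, H1, X) = angle
  dir_o <- cos(phi) * (-u) + sin(phi) * perp
  O <- H1 + 0.96 * dir_o
  H2 <- O + 0.96 * .unitv(u + 0.5 * perp)
  rbind(O, H1, H2)
}

.unitv <- function(v) v / sqrt(sum(v^2))

#' Generate a solvated frame with a scheduled number of hydrogen bonds
#'
#' Places exactly the scheduled number of waters (per acceptor, evaluated
#' from the occupancy schedule at `time`; fractional expectations are
#' realized by a Bernoulli draw on the fractional part) in geometries that
#' satisfy the detection criteria with margin, and the remaining waters far
#' from every acceptor so they violate the distance criterion.
#'
#' @param spec A [solvation_spec()].
#' @param base_frame An [sh_frame()] providing the solute geometry.
#' @param time Frame time in fs at which the schedule is evaluated.
#' @param seed Integer RNG seed.
#' @param acceptors Named acceptor indices (default from
#'   [default_atom_selection()]).
#' @return The frame with `solvent_coords`/`solvent_elements` set.
#' @export
generate_solvated_frame <- function(spec, base_frame, time, seed = 1,
                                    acceptors = default_atom_selection()$acceptors) {
  if (!inherits(spec, "solvation_spec"))
    stop("generate_solvated_frame: invalid spec")
  set.seed(seed)
  lam <- .schedule_at(spec, time)
  counts <- floor(lam) + (stats::runif(length(lam)) < (lam - floor(lam)))
  if (sum(counts) > spec$n_waters)
    stop("generate_solvated_frame: scheduled count exceeds n_waters")
  sol <- base_frame$coords
  centroid <- colMeans(sol)
  waters <- list()
  for (lab in names(counts)) {
    if (counts[[lab]] < 1) next
    if (!lab %in% names(acceptors))
      stop("generate_solvated_frame: schedule label ", lab,
           " has no acceptor index")
    X <- sol[acceptors[[lab]], ]
    u <- .unitv(X - centroid)
    for (k in seq_len(counts[[lab]])) {
      waters[[length(waters) + 1L]] <-
        .place_water(X, u, spec$water_distance, spec$water_angle,
                     azimuth = stats::runif(1, 0, 2 * pi))
    }
  }
  n_far <- spec$n_waters - length(waters)
  acc_xyz <- sol[acceptors, , drop = FALSE]
  for (k in seq_len(n_far)) {
    repeat {
      u <- .unitv(stats::rnorm(3))
      O <- centroid + 9 * u
      w <- rbind(O, O + 0.96 * .unitv(u + c(0.3, 0, 0)),
                 O + 0.96 * .unitv(u + c(0, 0.3, 0)))
      dmin <- min(sqrt(outer(rowSums(w^2), rowSums(acc_xyz^2), "+") -
                         2 * w %*% t(acc_xyz)))
      if (dmin > 3.5) break
    }
    waters[[length(waters) + 1L]] <- w
  }
  if (length(waters)) {
    swc <- do.call(rbind, waters)
    rownames(swc) <- NULL
    base_frame$solvent_coords <- swc
    base_frame$solvent_elements <- rep(c("O", "H", "H"), length(waters))
  } else {
    base_frame$solvent_coords <- matrix(numeric(0), 0, 3)
    base_frame$solvent_elements <- character(0)
  }
  base_frame$time <- time
  base_frame
}

#' Add scheduled solvent shells to every trajectory of an ensemble
#'
#' Convenience wrapper over [generate_solvated_frame()]: draws independent
#' scheduled shells for each (trajectory, strided frame) and stores them on
#' the trajectories, truncating each trajectory to the strided grid.
#'
#' @param ens An [sh_ensemble()].
#' @param spec A [solvation_spec()].
#' @param seed Master seed.
#' @param stride Keep every `stride`-th frame (solvation is the expensive
#'   per-frame operation; the hydrogen-bond series is computed on this grid).
#' @return The ensemble with solvated, strided trajectories.
#' @export
solvate_ensemble <- function(ens, spec, seed = 1, stride = 10) {
  seeds <- derive_seeds(seed, length(ens$trajectories))
  ens$trajectories <- lapply(seq_along(ens$trajectories), function(i) {
    traj <- ens$trajectories[[i]]
    keep <- seq(1, n_frames(traj), by = stride)
    fseeds <- derive_seeds(seeds[i], length(keep))
    nat <- dim(traj$coords)[1]
    sols <- vector("list", length(keep))
    for (j in seq_along(keep)) {
      fr <- generate_solvated_frame(spec, get_frame(traj, keep[j]),
                                    time = traj$times[keep[j]],
                                    seed = fseeds[j])
      sols[[j]] <- fr$solvent_coords
    }
    nw <- max(vapply(sols, nrow, integer(1)))
    solvent <- array(NA_real_, dim = c(nw, 3, length(keep)))
    for (j in seq_along(keep))
      solvent[seq_len(nrow(sols[[j]])), , j] <- sols[[j]]
    sh_trajectory(times = traj$times[keep],
                  coords = traj$coords[, , keep, drop = FALSE],
                  elements = traj$elements,
                  energies = traj$energies[keep, , drop = FALSE],
                  active_state = traj$active_state[keep],
                  total_energy = traj$total_energy[keep],
                  meta = traj$meta, termination = traj$termination,
                  solvent = solvent,
                  solvent_elements = rep(c("O", "H", "H"), nw / 3))
  })
  ens
}
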