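test_that("sampled hop times follow the configured kinetics", {
  ## delayed exponential: mean arrival = t0 + tau1
  spec <- kinetic_spec("S1_start", t0 = 250, tau1 = 1939)
  h <- sample_hop_times(spec, 1e5, seed = 1)
  expect_true(all(is.na(h$t_s2_s1)))
  expect_equal(mean(h$t_s1_s0), 2189, tolerance = 20 / 2189)
  expect_true(all(h$t_s1_s0 >= 250))
  ## sequential: mean ground-state arrival = tau2 + tau1
  spec2 <- kinetic_spec("S2_start", tau1 = 1274, tau2 = 146)
  h2 <- sample_hop_times(spec2, 1e5, seed = 1)
  expect_equal(mean(h2$t_s1_s0), 1420, tolerance = 15 / 1420)
  expect_true(all(h2$t_s1_s0 > h2$t_s2_s1))
  ## determinism under a fixed seed
  expect_identical(sample_hop_times(spec, 100, seed = 9),
                   sample_hop_times(spec, 100, seed = 9))
  expect_error(sample_hop_times(spec, 0, seed = 1), "n must be")
})

test_that("empirical survival of S1 hop times matches the delayed
           exponential law", {
  spec <- kinetic_spec("S1_start", t0 = 250, tau1 = 1939)
  h <- sample_hop_times(spec, 1e5, seed = 3)
  ## Kolmogorov-Smirnov distance between the empirical residence beyond t0
  ## and Exponential(tau1)
  x <- sort(h$t_s1_s0 - 250)
  ecdf_vals <- seq_along(x) / length(x)
  D <- max(abs(ecdf_vals - stats::pexp(x, 1 / 1939)))
  expect_lt(D, 0.01)
})

test_that("generated trajectories realize the drawn outcome", {
  kin <- quick_kin(p_reactive = 1)
  for (seed in 1:20) {
    tr <- generate_trajectory(kin, quick_mot(), seed = seed)
    tru <- attr(tr, "truth")
    if (tru$t_s1_s0 > 2500 - 400) next  # still excited or still relaxing
    ic <- internal_coords(get_frame(tr, n_frames(tr)))
    expect_lt(ic$theta, 30)
  }
  ## hop geometry inside the configured CNNC band, omega in the drawn band
  kin2 <- quick_kin()
  for (seed in 101:200) {
    tr <- generate_trajectory(kin2, quick_mot(), seed = seed)
    h <- extract_hops(tr)
    if (!nrow(h)) next
    expect_gte(h$theta[1], 90)
    expect_lte(h$theta[1], 120)
    expect_true((h$omega[1] >= 55 & h$omega[1] <= 125) ||
                  (h$omega[1] >= 145))
  }
})

test_that("clean generator ensembles conserve total energy within the QC
           threshold", {
  ens <- quick_ensemble(30, seed = 8, qc = FALSE)
  devs <- vapply(ens$trajectories, function(t)
    max(abs(t$total_energy - t$total_energy[1])), numeric(1))
  expect_lt(max(devs), 0.5)
  expect_lt(max(devs), 1e-2)
  flt <- energy_conservation_filter(ens)
  expect_identical(flt$ensemble$n_traj, 30L)
  ## state energies keep adiabatic ordering with a small gap in the hop band
  tr <- ens$trajectories[[1]]
  expect_true(all(tr$energies[, "E_S1"] >= tr$energies[, "E_S0"]))
  expect_true(all(tr$energies[, "E_S2"] > tr$energies[, "E_S1"]))
  ic <- internal_coords(tr)
  inband <- ic$theta >= 90 & ic$theta <= 120
  if (any(inband)) {
    gap <- tr$energies[inband, "E_S1"] - tr$energies[inband, "E_S0"]
    expect_lt(max(gap), 0.3)
  }
})

test_that("ensembles are reproducible and reactive fractions converge", {
  kin <- quick_kin(p_reactive = 0.3)
  e1 <- generate_ensemble(25, kin, quick_mot(), seed = 12)
  e2 <- generate_ensemble(25, kin, quick_mot(), seed = 12)
  expect_equal(e1$trajectories[[7]]$coords, e2$trajectories[[7]]$coords)
  expect_error(generate_ensemble(0, kin, quick_mot()), "n must be")
  ## reactive flag frequency within 3 binomial sigma at n = 400
  seeds <- derive_seeds(99, 400)
  reactive <- vapply(seeds, function(s) {
    set.seed(s)
    tr <- generate_trajectory(kin, quick_mot(dt = 25, horizon = 2500),
                              seed = s)
    attr(tr, "truth")$reactive
  }, logical(1))
  expect_lt(abs(mean(reactive) - 0.3), 3 * sqrt(0.3 * 0.7 / 400))
})

test_that("energy drift injection creates (only) above-threshold QC
           exclusions", {
  tr <- quick_ensemble(1, seed = 2, qc = FALSE)$trajectories[[1]]
  maxdev <- function(t) max(abs(t$total_energy - t$total_energy[1]))
  expect_identical(inject_energy_drift(tr, 0), tr)
  expect_gt(maxdev(inject_energy_drift(tr, 0.6, 500)), 0.5)
  expect_lt(maxdev(inject_energy_drift(tr, 0.4, 500)), 0.5)
  expect_error(inject_energy_drift(tr, 0.5, 1e6), "onset")
  ens <- sh_ensemble(list(inject_energy_drift(tr, 0.6, 500),
                          inject_energy_drift(tr, 0.4, 500)))
  rep <- energy_conservation_filter(ens)$report
  expect_identical(rep$excluded, c(TRUE, FALSE))
})

test_that("vertical excitation ensembles have the configured statistics", {
  spec <- spectrum_spec(data.frame(state = 1, center = 2.75, width = 0.15,
                                   f_mean = 0.05, f_sd = 0.01),
                        n_geometries = 1e4)
  exc <- generate_vertical_excitations(spec, seed = 5)
  expect_equal(nrow(exc), 1e4)
  expect_equal(mean(exc$energy), 2.75, tolerance = 0.005 / 2.75)
  expect_true(all(exc$f >= 0))
  spec857 <- preset_config("gas_npistar")$spectrum
  exc857 <- generate_vertical_excitations(spec857, seed = 1)
  expect_identical(length(unique(exc857$geometry)), 857L)
  expect_identical(generate_vertical_excitations(spec857, seed = 4),
                   generate_vertical_excitations(spec857, seed = 4))
})

test_that("solvated frames realize the scheduled hydrogen-bond counts", {
  base <- get_frame(quick_ensemble(1, seed = 1, qc = FALSE)$trajectories[[1]], 1)
  sel <- default_atom_selection()
  sched5 <- data.frame(time = 0, N_azo1 = 1, N_azo2 = 1, N_amine = 1,
                       O_ether = 1, F = 1)
  fr <- generate_solvated_frame(solvation_spec(sched5, n_waters = 8),
                                base, time = 0, seed = 3)
  bonds <- detect_hbonds(fr, sel$acceptors)
  expect_identical(nrow(bonds), 5L)
  expect_setequal(bonds$acceptor, names(sel$acceptors))
  ## empty schedule -> no bonds
  fr0 <- generate_solvated_frame(
    solvation_spec(data.frame(time = 0, N_azo1 = 0), n_waters = 4),
    base, time = 0, seed = 3)
  expect_identical(nrow(detect_hbonds(fr0, sel$acceptors)), 0L)
  ## an O-H...X angle of 119.9 degrees fails the strict 120-degree criterion
  fr119 <- generate_solvated_frame(
    solvation_spec(data.frame(time = 0, N_amine = 1), water_angle = 119.9,
                   n_waters = 1),
    base, time = 0, seed = 3)
  expect_identical(nrow(detect_hbonds(fr119, sel$acceptors)), 0L)
  ## infeasible request
  expect_error(generate_solvated_frame(
    solvation_spec(sched5, n_waters = 3), base, 0, 1), "exceeds n_waters")
})
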