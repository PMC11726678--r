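## hand-built single-water frames around a known acceptor geometry
frame_with_water <- function(distance, angle, acceptor = "N_amine") {
  base <- get_frame(quick_ensemble(1, seed = 1, qc = FALSE)$trajectories[[1]], 1)
  sel <- default_atom_selection()
  X <- base$coords[sel$acceptors[[acceptor]], ]
  u <- X - colMeans(base$coords)
  u <- u / sqrt(sum(u^2))
  w <- azotraj:::.place_water(X, u, distance, angle)
  base$solvent_coords <- w
  base$solvent_elements <- c("O", "H", "H")
  base
}

test_that("the distance and angle criteria act as specified", {
  sel <- default_atom_selection()
  ## 2.0 A, 170 degrees: one bond
  b <- detect_hbonds(frame_with_water(2.0, 170), sel$acceptors)
  expect_identical(nrow(b), 1L)
  expect_identical(b$acceptor, "N_amine")
  expect_equal(b$distance, 2.0, tolerance = 1e-9)
  expect_equal(b$angle, 170, tolerance = 1e-6)
  ## 3.2 A is beyond d_max
  expect_identical(nrow(detect_hbonds(frame_with_water(3.2, 170),
                                      sel$acceptors)), 0L)
  ## inclusive distance threshold, strict angle threshold
  expect_identical(nrow(detect_hbonds(frame_with_water(3.0, 170),
                                      sel$acceptors)), 1L)
  expect_identical(nrow(detect_hbonds(frame_with_water(2.0, 119.9),
                                      sel$acceptors)), 0L)
  expect_identical(nrow(detect_hbonds(frame_with_water(2.0, 120.5),
                                      sel$acceptors)), 1L)
  ## missing solvent topology errors
  fr <- frame_with_water(2.0, 170)
  fr$solvent_elements <- NULL
  expect_error(detect_hbonds(fr, sel$acceptors), "topology")
})

test_that("a hydrogen qualifying for both azo nitrogens forms exactly one
           bond, to the nearer", {
  base <- get_frame(quick_ensemble(1, seed = 1, qc = FALSE)$trajectories[[1]], 1)
  sel <- default_atom_selection()
  N1 <- base$coords[sel$acceptors[["N_azo1"]], ]
  N2 <- base$coords[sel$acceptors[["N_azo2"]], ]
  ## hydrogen on the N1 side of the azo midpoint, oxygen behind it so both
  ## donor angles are wide open
  mid <- (N1 + N2) / 2
  u <- N1 - N2; u <- u / sqrt(sum(u^2))
  H <- mid + 1.2 * u          # 1.2 A from midpoint: ~0.6 from N1, ~1.9 from N2
  O <- H + 0.96 * u
  fr <- base
  fr$solvent_coords <- rbind(O, H, H + c(0, 0, 0.96))
  fr$solvent_elements <- c("O", "H", "H")
  bonds <- detect_hbonds(fr, sel$acceptors)
  expect_identical(nrow(bonds), 1L)
  expect_identical(bonds$acceptor, "N_azo1")
  ## without the single-bond rule both nitrogens match
  bonds2 <- detect_hbonds(fr, sel$acceptors,
                          hbond_criteria(one_bond_per_hydrogen = FALSE))
  expect_gte(nrow(bonds2), 2L)
  ## no hydrogen is ever listed twice under the default criteria
  expect_false(any(duplicated(bonds$hydrogen)))
})

test_that("bond counts are threshold-monotone", {
  fr <- frame_with_water(2.8, 130)
  sel <- default_atom_selection()
  n <- function(d_max, angle_min)
    nrow(detect_hbonds(fr, sel$acceptors, hbond_criteria(d_max, angle_min)))
  expect_gte(n(3.0, 120), n(2.5, 120))
  expect_gte(n(3.0, 120), n(3.0, 140))
  expect_identical(n(2.5, 120), 0L)
  expect_identical(n(3.0, 140), 0L)
  expect_identical(n(3.0, 120), 1L)
})

test_that("scheduled shells are recovered exactly and the series reproduces
           a scheduled step", {
  sel <- default_atom_selection()
  ## constant integer schedule -> flat series at exactly 4 (F excluded)
  sched <- data.frame(time = c(0, 1000), N_azo1 = 1, N_azo2 = 1,
                      N_amine = 1, O_ether = 1, F = 1)
  ens <- quick_ensemble(4, seed = 23, qc = FALSE)
  solv <- solvate_ensemble(ens, solvation_spec(sched, n_waters = 8),
                           seed = 5, stride = 20)
  ser <- hbond_series(solv, sel$acceptors)
  expect_equal(ser$total, rep(4, nrow(ser)))
  expect_equal(ser$F, rep(1, nrow(ser)))
  ## fluorine is excluded from the total: zeroing its schedule changes nothing
  sched0 <- sched; sched0$F <- 0
  solv0 <- solvate_ensemble(ens, solvation_spec(sched0, n_waters = 8),
                            seed = 5, stride = 20)
  expect_equal(hbond_series(solv0, sel$acceptors)$total, ser$total)
  ## a 0.12 step down in the azo occupancies is recovered within sampling
  ## error at n = 40 trajectories
  step <- data.frame(time = c(0, 800, 1500, 2500),
                     N_azo1 = c(0.95, 0.95, 0.89, 0.89),
                     N_azo2 = c(0.95, 0.95, 0.89, 0.89),
                     N_amine = 0.95, O_ether = 0.95)
  ens40 <- quick_ensemble(40, seed = 31, qc = FALSE)
  solv40 <- solvate_ensemble(ens40, solvation_spec(step, n_waters = 6),
                             seed = 9, stride = 10)
  ser40 <- hbond_series(solv40, sel$acceptors)
  early <- mean(ser40$total[ser40$time <= 700])
  late <- mean(ser40$total[ser40$time >= 1600])
  drop <- early - late
  ## 3 sigma of the difference of two block means of Bernoulli sums
  p <- 0.95; q <- 0.89
  n_early <- 40 * sum(ser40$time <= 700); n_late <- 40 * sum(ser40$time >= 1600)
  sd_drop <- sqrt(2 * p * (1 - p) / n_early + 2 * q * (1 - q) / n_late)
  expect_lt(abs(drop - 0.12), 3 * sd_drop)
  expect_error(hbond_series(ens40, sel$acceptors), "no solvated")
})
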