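test_that("a single excitation produces a band at its energy and the total
           is the per-state sum", {
  one <- data.frame(geometry = 1, state = 1, energy = 2.75, f = 1)
  attr(one, "n_geometries") <- 1
  spec <- build_spectrum(one, sigma = 0.1)
  mx <- find_band_maxima(spec)
  expect_equal(mx$peak_energy, 2.75, tolerance = 0.011 / 2.75)
  expect_false(mx$at_boundary)
  expect_equal(spec$total, rowSums(spec$states))
  expect_true(all(spec$total >= 0))
  expect_error(build_spectrum(one[0, ]), "empty")
  expect_error(build_spectrum(one, sigma = 0), "sigma")
})

test_that("the integrated per-state intensity equals the mean oscillator
           strength", {
  sp <- spectrum_spec(data.frame(state = c(1, 2), center = c(2.75, 5.65),
                                 width = c(0.15, 0.2), f_mean = c(0.05, 0.6),
                                 f_sd = c(0.01, 0.1)), n_geometries = 4000)
  exc <- generate_vertical_excitations(sp, seed = 2)
  spec <- build_spectrum(exc, sigma = 0.1)
  dE <- diff(spec$energy[1:2])
  for (k in c(1, 2)) {
    integral <- sum(spec$states[, paste0("S", k)]) * dE
    fbar <- mean(exc$f[exc$state == k])
    expect_equal(integral, fbar, tolerance = 5e-3)
  }
})

test_that("band maxima and the water-gas shift are recovered on synthetic
           two-band ensembles", {
  mk <- function(centers) {
    sp <- spectrum_spec(data.frame(state = c(1, 2), center = centers,
                                   width = c(0.15, 0.22),
                                   f_mean = c(0.03, 0.6),
                                   f_sd = c(0.01, 0.15)), n_geometries = 857)
    build_spectrum(generate_vertical_excitations(sp, seed = 4),
                   grid = seq(1.5, 7, by = 0.01))
  }
  gas <- find_band_maxima(mk(c(2.75, 5.65)))
  water <- find_band_maxima(mk(c(3.02, 5.05)))
  expect_equal(gas$peak_energy[gas$state == "S1"], 2.75, tolerance = 0.012)
  expect_equal(water$peak_energy[water$state == "S1"], 3.02, tolerance = 0.012)
  shift <- water$peak_energy[water$state == "S1"] -
    gas$peak_energy[gas$state == "S1"]
  expect_equal(shift, 0.27, tolerance = 0.021 / 0.27)
  ## monotone (single-tail) intensity flags the boundary peak
  lowgrid <- build_spectrum(
    structure(data.frame(geometry = 1, state = 1, energy = 2.75, f = 1),
              n_geometries = 1), sigma = 0.1, grid = seq(3.2, 4, by = 0.01))
  expect_true(find_band_maxima(lowgrid)$at_boundary)
  zero <- lowgrid; zero$states[] <- 0; zero$total[] <- 0
  expect_error(find_band_maxima(zero), "flat")
})

test_that("spectra are linear in the excitation records", {
  sp <- spectrum_spec(data.frame(state = 1, center = 3, width = 0.2,
                                 f_mean = 0.1, f_sd = 0.02),
                      n_geometries = 500)
  a <- generate_vertical_excitations(sp, seed = 1)
  b <- generate_vertical_excitations(sp, seed = 2)
  grid <- seq(2, 4, by = 0.01)
  ab <- rbind(a, b)
  ab$geometry <- c(a$geometry, b$geometry + 500)
  attr(ab, "n_geometries") <- 1000
  sa <- build_spectrum(a, grid = grid)$total
  sb <- build_spectrum(b, grid = grid)$total
  sab <- build_spectrum(ab, grid = grid)$total
  expect_equal(sab, (sa + sb) / 2, tolerance = 1e-12)
})

test_that("initial-condition selection is dipole-weighted within the
           window", {
  ## two states inside the window with oscillator strengths 2:1
  n <- 1e4
  exc <- rbind(data.frame(geometry = 1:n, state = 1, energy = 2.7, f = 0.4),
               data.frame(geometry = 1:n, state = 2, energy = 2.9, f = 0.2),
               data.frame(geometry = 1:n, state = 3, energy = 5.6, f = 0.9),
               data.frame(geometry = 1:n, state = 4, energy = 2.8, f = 0))
  picks <- select_initial_conditions(exc, c(2.5, 3.0), seed = 11)
  ## states outside the window and zero-strength states are never selected
  expect_false(any(picks$state %in% c(3, 4)))
  n1 <- sum(picks$state == 1); n2 <- sum(picks$state == 2)
  ratio <- n1 / n2
  ## acceptance probabilities 1 and 0.5: ratio 2:1 within 3 binomial sigma
  sd_ratio <- 2 * sqrt(1 / n2)
  expect_lt(abs(ratio - 2), 3 * sd_ratio)
  ## selection count scales linearly with f at fixed window
  fs <- seq(0.1, 0.5, by = 0.1)
  counts <- vapply(seq_along(fs), function(i) {
    e <- data.frame(geometry = 1:n, state = 1, energy = 2.7, f = fs[i])
    e2 <- rbind(e, data.frame(geometry = 1:n, state = 2, energy = 2.9,
                              f = 0.5))
    sum(select_initial_conditions(e2, c(2.5, 3.0), seed = 20 + i)$state == 1)
  }, numeric(1))
  slope <- unname(stats::coef(stats::lm(I(counts / n) ~ 0 + fs))[1])
  expect_equal(slope, 2, tolerance = 0.02)  # 1/f_max with f_max = 0.5
  ## empty window warns and returns no assignments
  expect_warning(out <- select_initial_conditions(exc, c(10, 11)), "window")
  expect_identical(nrow(out), 0L)
  expect_error(select_initial_conditions(exc, c(3, 2)), "e_min")
})
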