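test_that("the delayed exponential model has the right boundary values", {
  expect_equal(delayed_exp_model(0, 250, 1939), 1)
  expect_equal(delayed_exp_model(250, 250, 1939), 1)
  expect_equal(delayed_exp_model(250 + 1939, 250, 1939), exp(-1))
  expect_equal(delayed_exp_model(2189, 250, 1939), 0.36788, tolerance = 1e-4)
  expect_error(delayed_exp_model(0, 0, -1), "tau1")
})

test_that("populations are the per-state trajectory fractions and
           normalize", {
  ## 4-trajectory fixture with hops at known frames: hand-counted stepwise P
  trs <- list(toy_trajectory(c(1, 1, 0, 0, 0)),
              toy_trajectory(c(1, 1, 1, 0, 0)),
              toy_trajectory(c(1, 1, 1, 1, 0)),
              toy_trajectory(c(1, 1, 1, 1, 1)))
  pop <- classical_populations(sh_ensemble(trs))
  expect_equal(pop$P1, c(1, 1, 0.75, 0.5, 0.25))
  expect_equal(pop$P0, c(0, 0, 0.25, 0.5, 0.75))
  expect_equal(rowSums(pop[, c("P0", "P1", "P2")]), rep(1, 5))
  ## generator ensembles: P1(0) = 1 and exact normalization everywhere
  ens <- quick_ensemble(30, seed = 17)
  p <- classical_populations(ens)
  expect_equal(p$P1[1], 1)
  expect_equal(rowSums(p[, grep("^P", names(p))]), rep(1, nrow(p)))
  ## early-terminated trajectories count as ground state afterwards
  expect_equal(p$P0 + p$P1 + p$P2, rep(1, nrow(p)))
  bad <- energy_conservation_filter(
    sh_ensemble(list(inject_energy_drift(trs[[1]], 1, 100))))$ensemble
  expect_error(classical_populations(bad), "empty")
})

test_that("noiseless delayed-exponential curves are recovered to 0.1%", {
  t <- seq(0, 6000, by = 10)
  series <- data.frame(time = t, P1 = delayed_exp_model(t, 250, 1939))
  series$P0 <- 1 - series$P1
  class(series) <- c("population_series", "data.frame")
  fit <- fit_delayed_exponential(series)
  expect_equal(fit$t0, 250, tolerance = 1e-3)
  expect_equal(fit$tau1, 1939, tolerance = 1e-3)
  expect_equal(fit$lifetime, 2189, tolerance = 1e-3)
  ## no decay -> explicit failure
  flat <- data.frame(time = t, P1 = rep(1, length(t)))
  expect_error(fit_delayed_exponential(flat), "no decay")
})

test_that("stochastic delayed-exponential recovery at the study ensemble
           size", {
  ## n = 112 trajectories, 20 seeds: mean recovered tau within 15%
  spec <- kinetic_spec("S1_start", t0 = 250, tau1 = 1939)
  grid <- seq(0, 6000, by = 10)
  taus <- vapply(1:20, function(s) {
    h <- sample_hop_times(spec, 112, seed = 1000 + s)
    fit_delayed_exponential(population_from_hop_times(h, grid))$tau1
  }, numeric(1))
  expect_lt(abs(mean(taus) - 1939) / 1939, 0.15)
})

test_that("the sequential model conserves probability and peaks where it
           should", {
  t <- seq(0, 6000, by = 5)
  m <- sequential_model(t, tau1 = 1274, tau2 = 146)
  expect_equal(m$P_pipistar[1], 1)
  expect_equal(m$P_npistar[1], 0)
  ground <- 1 - m$P_pipistar - m$P_npistar
  expect_true(all(ground >= -1e-12))
  expect_true(all(m$P_npistar >= -1e-12))
  ## S1 maximum at t* = ln(tau1/tau2) * tau1 tau2 / (tau1 - tau2) ~ 357 fs
  tstar <- log(1274 / 146) * 1274 * 146 / (1274 - 146)
  expect_equal(t[which.max(m$P_npistar)], tstar, tolerance = 5 / tstar)
  ## degenerate equal-lifetime limiting form
  md <- sequential_model(t, 300, 300)
  expect_equal(md$P_npistar, (t / 300) * exp(-t / 300))
})

test_that("two-stage sequential fitting recovers noiseless curves to 0.1%
           and matches the joint fit to 0.5%", {
  t <- seq(0, 6000, by = 10)
  m <- sequential_model(t, tau1 = 1274, tau2 = 146)
  series <- data.frame(time = t, P0 = 1 - m$P_pipistar - m$P_npistar,
                       P1 = m$P_npistar, P2 = m$P_pipistar)
  class(series) <- c("population_series", "data.frame")
  fit <- fit_sequential(series)
  expect_equal(fit$tau2, 146, tolerance = 1e-3)
  expect_equal(fit$tau1, 1274, tolerance = 1e-3)
  joint <- fit_sequential(series, method = "joint")
  expect_equal(joint$tau1, fit$tau1, tolerance = 5e-3)
  expect_equal(joint$tau2, fit$tau2, tolerance = 5e-3)
  ## a series without any population above S1 cannot be fitted
  expect_error(fit_sequential(series[, c("time", "P0", "P1")]), "no population")
})

test_that("stochastic sequential recovery at the study ensemble size", {
  spec <- kinetic_spec("S2_start", tau1 = 1274, tau2 = 146)
  grid <- seq(0, 6000, by = 10)
  fits <- lapply(1:20, function(s) {
    h <- sample_hop_times(spec, 207, seed = 2000 + s)
    fit_sequential(population_from_hop_times(h, grid))
  })
  tau2s <- vapply(fits, `[[`, numeric(1), "tau2")
  tau1s <- vapply(fits, `[[`, numeric(1), "tau1")
  expect_lt(abs(mean(tau2s) - 146) / 146, 0.20)
  expect_lt(abs(mean(tau1s) - 1274) / 1274, 0.15)
})

test_that("fit bias shrinks as the ensemble grows", {
  spec <- kinetic_spec("S1_start", t0 = 250, tau1 = 1939)
  grid <- seq(0, 12000, by = 20)
  err <- vapply(c(100, 1000, 10000), function(n) {
    h <- sample_hop_times(spec, n, seed = 5)
    abs(fit_delayed_exponential(population_from_hop_times(h, grid))$tau1 - 1939)
  }, numeric(1))
  expect_true(err[3] < err[1])
})
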