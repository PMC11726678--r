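#' Classical adiabatic state populations of an ensemble
#'
#' The fraction of retained trajectories residing on each surface at each
#' grid time. The grid is the native frame-time grid of the longest retained
#' trajectory (all trajectories must share the frame spacing). Trajectories
#' truncated by early termination are counted as ground state at all later
#' times.
#'
#' @param ens An [sh_ensemble()] (energy-QC applied; excluded members are
#'   skipped).
#' @param states Optional integer vector of states to report (default: all
#'   states present).
#' @return A `population_series`: data.frame with columns `time` and `P0`,
#'   `P1`, ... (fractions in `[0, 1]` summing to 1 at every grid point);
#'   attribute `n_traj`.
#' @export
classical_populations <- function(ens, states = NULL) {
  trajs <- .active_trajectories(ens)
  if (!length(trajs)) stop("classical_populations: empty ensemble")
  dts <- vapply(trajs, function(t) t$meta$dt, numeric(1))
  if (diff(range(dts)) > 1e-9)
    stop("classical_populations: trajectories must share the time step")
  grid <- trajs[[which.max(vapply(trajs, function(t) max(t$times), numeric(1)))]]$times
  nstate <- max(vapply(trajs, function(t) ncol(t$energies), integer(1)))
  counts <- matrix(0, length(grid), nstate)
  for (t in trajs) {
    nf <- n_frames(t)
    idx <- findInterval(grid, t$times)        # frame at or before each grid time
    st <- integer(length(grid))
    inside <- idx >= 1 & idx <= nf & grid <= max(t$times) + 1e-9
    st[inside] <- t$active_state[idx[inside]]
    beyond <- grid > max(t$times) + 1e-9
    ## early-terminated trajectories stay in the ground state afterwards;
    ## a completed shorter trajectory keeps its last state
    st[beyond] <- if (t$termination == "early_ground_state") 0L else
      t$active_state[nf]
    counts[cbind(seq_along(grid), st + 1L)] <-
      counts[cbind(seq_along(grid), st + 1L)] + 1
  }
  P <- counts / length(trajs)
  out <- data.frame(time = grid)
  keep <- if (is.null(states)) seq_len(nstate) - 1L else states
  for (k in keep) out[[paste0("P", k)]] <- P[, k + 1L]
  class(out) <- c("population_series", "data.frame")
  attr(out, "n_traj") <- length(trajs)
  out
}

#' Pool the populations of the upper excited states
#'
#' Adds a column `Ppool` holding the summed population of all states with
#' index `>= from` (e.g. the S2 + S3 pool fitted by the sequential model).
#'
#' @param series A `population_series`.
#' @param from Lowest state index included in the pool (default 2).
#' @return The series with an added `Ppool` column.
#' @export
pool_states <- function(series, from = 2) {
  cols <- grep("^P[0-9]+$", names(series), value = TRUE)
  idx <- as.integer(sub("^P", "", cols))
  pool <- cols[idx >= from]
  if (!length(pool)) stop("pool_states: no states at or above the pool index")
  series$Ppool <- rowSums(series[, pool, drop = FALSE])
  series
}

#' Build a population series directly from sampled hop times
#'
#' Converts draws from [sample_hop_times()] into the empirical survival
#' populations on a regular grid, without generating Cartesian trajectories.
#' Useful for fast kinetic-recovery studies.
#'
#' @param hops data.frame from [sample_hop_times()].
#' @param grid Time grid in fs.
#' @return A `population_series` with columns `P0`, `P1` (and `P2` for
#'   sequential kinetics).
#' @export
population_from_hop_times <- function(hops, grid) {
  n <- nrow(hops)
  sequential <- !all(is.na(hops$t_s2_s1))
  out <- data.frame(time = grid)
  if (sequential) {
    out$P2 <- vapply(grid, function(t) sum(hops$t_s2_s1 > t), numeric(1)) / n
    out$P1 <- vapply(grid, function(t)
      sum(hops$t_s2_s1 <= t & hops$t_s1_s0 > t), numeric(1)) / n
    out$P0 <- 1 - out$P1 - out$P2
    out <- out[, c("time", "P0", "P1", "P2")]
  } else {
    out$P1 <- vapply(grid, function(t) sum(hops$t_s1_s0 > t), numeric(1)) / n
    out$P0 <- 1 - out$P1
    out <- out[, c("time", "P0", "P1")]
  }
  class(out) <- c("population_series", "data.frame")
  attr(out, "n_traj") <- n
  out
}

#' Delayed exponential population model
#'
#' `P(t) = 1` for `t <= t0` and `exp(-(t - t0)/tau1)` for `t > t0`: the
#' excited population is constant during the delay and decays exponentially
#' afterwards.
#'
#' @param t Time(s) in fs.
#' @param t0 Delay time in fs.
#' @param tau1 Decay constant in fs (> 0).
#' @return Population fraction(s).
#' @export
delayed_exp_model <- function(t, t0, tau1) {
  if (tau1 <= 0) stop("delayed_exp_model: tau1 must be > 0")
  ifelse(t <= t0, 1, exp(-(t - t0) / tau1))
}

#' Fit the delayed exponential to an S1 population decay
#'
#' Least-squares estimation of the delay `t0` and decay constant `tau1`:
#' `t0` is initialized by a grid search over `[0, 500]` fs in 10 fs steps
#' (with `tau` from a log-linear regression of the tail at each candidate)
#' and both parameters are then refined by Nelder-Mead. Deterministic.
#'
#' @param series A `population_series`.
#' @param state State whose population is fitted (default 1).
#' @return Object of class `delayed_exp_fit`: list with `t0`, `tau1`,
#'   `lifetime` (`t0 + tau1`; the decay constant is also reported
#'   separately), `residual_norm`, and `fitted`.
#' @export
fit_delayed_exponential <- function(series, state = 1) {
  col <- paste0("P", state)
  if (!col %in% names(series)) stop("fit_delayed_exponential: no column ", col)
  t <- series$time
  y <- series[[col]]
  if (max(y) - min(y) < 1e-6)
    stop("fit_delayed_exponential: no decay observed in the population")
  ss <- function(par) {
    if (par[1] < 0 || par[2] <= 0) return(Inf)
    sum((delayed_exp_model(t, par[1], par[2]) - y)^2)
  }
  tau_init <- function(t0) {
    sel <- t > t0 & y > 1e-4
    if (sum(sel) < 3) return(NA_real_)
    fit <- stats::lm.fit(cbind(1, t[sel] - t0), log(y[sel]))
    sl <- fit$coefficients[2]
    if (!is.finite(sl) || sl >= 0) NA_real_ else -1 / sl
  }
  cand <- seq(0, 500, by = 10)
  best <- NULL
  for (t0 in cand) {
    tau <- tau_init(t0)
    if (is.na(tau)) next
    val <- ss(c(t0, tau))
    if (is.null(best) || val < best$val) best <- list(par = c(t0, tau), val = val)
  }
  if (is.null(best))
    stop("fit_delayed_exponential: could not initialize the fit")
  opt <- stats::optim(unname(best$par), ss, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  structure(list(t0 = opt$par[1], tau1 = opt$par[2],
                 lifetime = opt$par[1] + opt$par[2],
                 residual_norm = sqrt(opt$value),
                 fitted = delayed_exp_model(t, opt$par[1], opt$par[2])),
            class = "delayed_exp_fit")
}

#' @export
print.delayed_exp_fit <- function(x, ...) {
  cat(sprintf(
    "delayed exponential fit: t0 = %.1f fs, tau1 = %.1f fs (t0 + tau1 = %.1f fs)\n",
    x$t0, x$tau1, x$lifetime))
  invisible(x)
}

#' Sequential two-step irreversible kinetic model
#'
#' The standard irreversible A -> B -> C solution for bright-state decay and
#' S1 transfer: `P_pipistar(t) = exp(-t/tau2)` and
#' `P_npistar(t) = tau1/(tau1 - tau2) * (exp(-t/tau1) - exp(-t/tau2))`.
#' In the degenerate limit `tau1 == tau2` the S1 population takes the
#' limiting form `(t/tau) * exp(-t/tau)`.
#'
#' @param t Time(s) in fs.
#' @param tau1 S1 lifetime in fs.
#' @param tau2 Bright-state lifetime in fs.
#' @return List with elements `P_pipistar` and `P_npistar`.
#' @export
sequential_model <- function(t, tau1, tau2) {
  if (tau1 <= 0 || tau2 <= 0) stop("sequential_model: lifetimes must be > 0")
  p2 <- exp(-t / tau2)
  p1 <- if (abs(tau1 - tau2) < 1e-9 * tau1) {
    (t / tau1) * exp(-t / tau1)
  } else {
    tau1 / (tau1 - tau2) * (exp(-t / tau1) - exp(-t / tau2))
  }
  list(P_pipistar = p2, P_npistar = p1)
}

#' Two-stage fit of the sequential kinetic model
#'
#' Exactly mirrors the two-step procedure: stage 1 fits `tau2` by least
#' squares on the pooled population of states S2 and above; stage 2 fixes
#' `tau2` and fits `tau1` on the S1 rise-and-decay. A joint 2-parameter fit
#' is available via `method = "joint"` (used for cross-checks).
#'
#' @param series A `population_series` containing `P1` and at least one
#'   state above S1 (pooled internally via [pool_states()]).
#' @param method `"two_stage"` (default) or `"joint"`.
#' @return Object of class `sequential_fit`: list with `tau2`, `tau1`,
#'   `residual_norms` (per stage), and `fitted` (list of both curves).
#' @export
fit_sequential <- function(series, method = c("two_stage", "joint")) {
  method <- match.arg(method)
  if (!"P1" %in% names(series)) stop("fit_sequential: series lacks P1")
  cols <- grep("^P[0-9]+$", names(series), value = TRUE)
  if (!any(as.integer(sub("^P", "", cols)) >= 2))
    stop("fit_sequential: series has no population above S1")
  series <- pool_states(series, from = 2)
  t <- series$time
  y2 <- series$Ppool
  y1 <- series$P1
  if (max(y2) < 0.5)
    stop("fit_sequential: initial pooled bright-state population is not ~1")
  if (max(y2) - min(y2) < 1e-6)
    stop("fit_sequential: no bright-state decay observed")
  ss2 <- function(tau2) sum((exp(-t / tau2) - y2)^2)
  ss1 <- function(tau1, tau2)
    sum((sequential_model(t, tau1, tau2)$P_npistar - y1)^2)
  tau2_init <- {
    sel <- y2 > 1e-4 & t > 0
    fit <- stats::lm.fit(cbind(1, t[sel]), log(y2[sel]))
    sl <- unname(fit$coefficients[2])
    if (is.finite(sl) && sl < 0) -1 / sl else max(t) / 10
  }
  if (method == "two_stage") {
    o2 <- stats::optimize(ss2, interval = c(tau2_init / 50, tau2_init * 50),
                          tol = 1e-8)
    tau2 <- o2$minimum
    o1 <- stats::optimize(function(x) ss1(x, tau2),
                          interval = c(tau2 * 1.0001, max(t) * 20), tol = 1e-6)
    tau1 <- o1$minimum
    res <- c(stage1 = sqrt(o2$objective), stage2 = sqrt(o1$objective))
  } else {
    obj <- function(par) {
      if (any(par <= 0)) return(Inf)
      ss2(par[2]) + ss1(par[1], par[2])
    }
    opt <- stats::optim(c(max(t) / 4, tau2_init), obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    tau1 <- opt$par[1]; tau2 <- opt$par[2]
    res <- c(joint = sqrt(opt$value))
  }
  curves <- sequential_model(t, tau1, tau2)
  structure(list(tau2 = tau2, tau1 = tau1, residual_norms = res,
                 fitted = curves),
            class = "sequential_fit")
}

#' @export
print.sequential_fit <- function(x, ...) {
  cat(sprintf("sequential two-step fit: tau2 = %.1f fs, tau1 = %.1f fs\n",
              x$tau2, x$tau1))
  invisible(x)
}
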