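#' Run configuration for the end-to-end pipeline
#'
#' Validates and assembles everything [run_pipeline()] needs. Either start
#' from a preset (see [preset_config()]) with optional overrides, or supply
#' explicit specs. A YAML file with the same field names can be loaded via
#' `run_config_from_yaml()`.
#'
#' @param preset Preset name, or NULL when all specs are given explicitly.
#' @param seed Master seed (recorded in all outputs).
#' @param n Ensemble size override (default: the preset's `n_total`).
#' @param n_excluded Number of trajectories given an injected energy drift
#'   (default: preset value, scaled when `n` is overridden).
#' @param qc_threshold Energy-conservation threshold in eV (default 0.5).
#' @param dwell Early-termination dwell in fs (default 500).
#' @param outdir Output directory (NULL: nothing written).
#' @param sections Character vector of report sections to compute, from
#'   `c("qc", "populations", "yields", "hops", "hbonds", "spectrum",
#'   "density")`; defaults to all.
#' @param hbond_stride Frame stride for the solvated hydrogen-bond series.
#' @param kinetic,motion,spectrum,solvation Explicit specs overriding the
#'   preset's.
#' @param window,environment Overrides for the excitation window (eV) and
#'   environment tag.
#' @return Object of class `run_config`.
#' @export
run_config <- function(preset = NULL, seed = 1, n = NULL, n_excluded = NULL,
                       qc_threshold = 0.5, dwell = 500, outdir = NULL,
                       sections = c("qc", "populations", "yields", "hops",
                                    "hbonds", "spectrum", "density"),
                       hbond_stride = 10, kinetic = NULL, motion = NULL,
                       spectrum = NULL, solvation = NULL, window = NULL,
                       environment = NULL) {
  base <- if (!is.null(preset)) preset_config(preset) else
    list(label = "custom", n_total = n, n_excluded = 0L,
         phi = NA, phi_I = NA, rotational = NA)
  cfg <- list(
    label = base$label, seed = as.integer(seed),
    n = as.integer(n %||% base$n_total),
    n_excluded = as.integer(n_excluded %||%
      if (!is.null(n) && !is.null(base$n_total))
        round(base$n_excluded * n / base$n_total) else base$n_excluded),
    qc_threshold = qc_threshold, dwell = dwell, outdir = outdir,
    sections = match.arg(sections, several.ok = TRUE),
    hbond_stride = as.integer(hbond_stride),
    kinetic = kinetic %||% base$kinetic,
    motion = motion %||% base$motion,
    spectrum = spectrum %||% base$spectrum,
    solvation = solvation %||% base$solvation,
    window = window %||% base$window,
    environment = environment %||% base$environment,
    configured = list(phi = base$phi, phi_I = base$phi_I,
                      rotational = base$rotational))
  if (is.null(cfg$kinetic) || is.null(cfg$motion))
    stop("run_config: kinetic and motion specs are required")
  if (!length(cfg$n) || is.na(cfg$n) || cfg$n < 1)
    stop("run_config: ensemble size must be >= 1")
  if (cfg$qc_threshold <= 0) stop("run_config: qc_threshold must be > 0")
  if (!is.null(cfg$window) &&
      (length(cfg$window) != 2 || cfg$window[1] >= cfg$window[2]))
    stop("run_config: excitation window must satisfy e_min < e_max")
  structure(cfg, class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' @param path YAML file whose top-level keys match the [run_config()]
#'   arguments (`preset`, `seed`, `n`, `qc_threshold`, ...).
#' @return A `run_config`.
#' @export
run_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  ## YAML 1.1 reads a bare `n:` key as the boolean FALSE; accept it (and the
  ## explicit alias `size:`) as the ensemble-size argument
  names(y)[names(y) %in% c("FALSE", "size")] <- "n"
  do.call(run_config, y)
}

#' Run the end-to-end trajectory-ensemble analysis pipeline
#'
#' Generates the configured synthetic ensemble (injecting energy drift into
#' the configured number of members), applies energy-conservation QC and
#' early termination, and computes: bookkeeping counts, classical
#' populations with the matching kinetic fit, quantum yield and conformer
#' fractions, hop records and mechanism ratios, the hydrogen-bond series
#' (solvated presets), the ensemble absorption spectrum with band maxima
#' and window-selected initial conditions, and the CNNC dihedral density
#' map. All results are deterministic functions of the configuration
#' including its seed. With `outdir` set, tables are written as TSV, scalar
#' summaries as JSON, and a log records seed and package version.
#'
#' @param config A [run_config()].
#' @return Object of class `pipeline_report`: list of report sections.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) stop("run_pipeline: invalid config")
  sel <- default_atom_selection()
  seeds <- derive_seeds(config$seed, 4)
  log <- c(sprintf("azotraj %s", as.character(utils::packageVersion("azotraj"))),
           sprintf("label=%s seed=%d n=%d", config$label, config$seed, config$n))
  ens <- generate_ensemble(config$n, config$kinetic, config$motion, sel,
                           seed = seeds[1], environment = config$environment,
                           window = config$window)
  if (config$n_excluded > 0) {
    set.seed(seeds[2])
    drift_ids <- sample(config$n, config$n_excluded)
    for (i in drift_ids)
      ens$trajectories[[i]] <- inject_energy_drift(
        ens$trajectories[[i]], magnitude = 0.8,
        onset = config$motion$horizon / 3)
    log <- c(log, sprintf("energy drift injected into %d members",
                          config$n_excluded))
  }
  out <- list(config = config)
  qc <- energy_conservation_filter(ens, config$qc_threshold)
  ens <- apply_early_termination_ensemble(qc$ensemble, config$dwell)
  out$qc <- qc$report
  out$counts <- ensemble_counts(stats::setNames(list(ens), config$label))
  if ("populations" %in% config$sections) {
    out$populations <- classical_populations(ens)
    out$fit <- if (config$kinetic$mode == "S1_start")
      fit_delayed_exponential(out$populations) else
      fit_sequential(out$populations)
  }
  if ("yields" %in% config$sections)
    out$yield <- quantum_yield(ens, sel)
  if ("hops" %in% config$sections) {
    out$hops <- extract_hops_ensemble(ens, sel)
    out$mechanism <- tryCatch(mechanism_ratios(ens, sel), error = function(e) NULL)
  }
  if ("hbonds" %in% config$sections && !is.null(config$solvation)) {
    solv <- solvate_ensemble(ens, config$solvation, seed = seeds[3],
                             stride = config$hbond_stride)
    out$hbonds <- hbond_series(solv, sel$acceptors)
  }
  if ("spectrum" %in% config$sections && !is.null(config$spectrum)) {
    exc <- generate_vertical_excitations(config$spectrum, seed = seeds[4])
    out$excitations <- exc
    out$spectrum <- build_spectrum(exc)
    out$band_maxima <- find_band_maxima(out$spectrum)
    if (!is.null(config$window))
      out$initial_conditions <- select_initial_conditions(exc, config$window,
                                                          seed = seeds[4])
  }
  if ("density" %in% config$sections)
    out$density <- density_map(ens, sel = sel)
  class(out) <- "pipeline_report"
  if (!is.null(config$outdir)) .write_report(out, config$outdir, log)
  out
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("pipeline report: %s (seed %d)\n", x$config$label,
              x$config$seed))
  print(x$counts)
  if (!is.null(x$yield)) print(x$yield)
  if (!is.null(x$fit)) print(x$fit)
  invisible(x)
}

.write_report <- function(report, outdir, log) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wtsv <- function(df, name)
    utils::write.table(df, file.path(outdir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  wtsv(report$counts, "counts.tsv")
  wtsv(report$qc, "qc_report.tsv")
  if (!is.null(report$populations)) wtsv(report$populations, "populations.tsv")
  if (!is.null(report$hops)) wtsv(report$hops, "hops.tsv")
  if (!is.null(report$hbonds)) wtsv(report$hbonds, "hbonds.tsv")
  if (!is.null(report$spectrum))
    wtsv(data.frame(energy = report$spectrum$energy,
                    report$spectrum$states,
                    total = report$spectrum$total), "spectrum.tsv")
  if (!is.null(report$band_maxima)) wtsv(report$band_maxima, "band_maxima.tsv")
  if (!is.null(report$density)) {
    d <- report$density
    wtsv(data.frame(time = rep(d$time, each = length(d$angle)),
                    angle = rep(d$angle, length(d$time)),
                    density = as.vector(d$density)), "density_map.tsv")
  }
  summary <- list(label = report$config$label, seed = report$config$seed,
                  n_total = report$counts$n_total,
                  n_traj = report$counts$n_traj)
  if (!is.null(report$yield))
    summary <- c(summary, report$yield[c("phi", "sigma_phi", "phi_I",
                                         "phi_II", "n_cis", "n_trans",
                                         "n_intermediate")])
  if (!is.null(report$fit))
    summary <- c(summary,
                 if (inherits(report$fit, "delayed_exp_fit"))
                   report$fit[c("t0", "tau1", "lifetime")]
                 else report$fit[c("tau1", "tau2")])
  if (!is.null(report$mechanism))
    summary <- c(summary, report$mechanism[c("rotational", "inversion")])
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(log, file.path(outdir, "run.log"))
  invisible(report)
}

#' Time-resolved dihedral/angle density map
#'
#' Kernel-smoothed density of an internal coordinate over (time, angle),
#' with every time slice normalized to unit mass — the numerical analogue of
#' a dihedral-convolution plot.
#'
#' @param ens An [sh_ensemble()].
#' @param coordinate One of `"theta"`, `"gamma"`, `"gamma_prime"`.
#' @param time_bins Number of time bins (default 60).
#' @param angle_bins Number of angle bins over `[0, 180]` (default 90).
#' @param bw_angle Gaussian smoothing bandwidth in degrees (default 5).
#' @param sel An [atom_selection()].
#' @return Object of class `density_map`: list with `time` (bin centers,
#'   fs), `angle` (bin centers, degrees), `density` (angle x time matrix;
#'   columns sum to 1).
#' @export
density_map <- function(ens, coordinate = c("theta", "gamma", "gamma_prime"),
                        time_bins = 60, angle_bins = 90, bw_angle = 5,
                        sel = default_atom_selection()) {
  coordinate <- match.arg(coordinate)
  trajs <- .active_trajectories(ens)
  if (!length(trajs)) stop("density_map: empty ensemble")
  vals <- do.call(rbind, lapply(trajs, function(t) {
    ic <- .internal_coords_traj(t, sel)
    data.frame(time = ic$time, value = ic[[coordinate]])
  }))
  tmax <- max(vals$time)
  tedges <- seq(0, tmax, length.out = time_bins + 1)
  tcent <- (tedges[-1] + tedges[-length(tedges)]) / 2
  aedges <- seq(0, 180, length.out = angle_bins + 1)
  acent <- (aedges[-1] + aedges[-length(aedges)]) / 2
  dens <- matrix(0, angle_bins, time_bins)
  ti <- pmin(time_bins, pmax(1, findInterval(vals$time, tedges,
                                             rightmost.closed = TRUE)))
  for (b in seq_len(time_bins)) {
    v <- vals$value[ti == b]
    if (!length(v)) next
    ## Gaussian kernel density on the angle axis, evaluated at bin centers
    m <- outer(acent, v, function(a, x) stats::dnorm(a - x, sd = bw_angle))
    col <- rowSums(m)
    s <- sum(col)
    if (s > 0) dens[, b] <- col / s
  }
  structure(list(time = tcent, angle = acent, density = dens,
                 coordinate = coordinate), class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("density map of %s: %d time bins x %d angle bins\n",
              x$coordinate, length(x$time), length(x$angle)))
  invisible(x)
}

#' Plot a population series with optional fit overlay
#'
#' @param x A `population_series`.
#' @param fit Optional `delayed_exp_fit` or `sequential_fit` overlay.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.population_series <- function(x, fit = NULL, ...) {
  cols <- grep("^P[0-9]+$", names(x), value = TRUE)
  graphics::matplot(x$time, as.matrix(x[, cols]), type = "l", lty = 1,
                    xlab = "time (fs)", ylab = "population", ...)
  graphics::legend("right", legend = cols, lty = 1,
                   col = seq_along(cols), bty = "n")
  if (inherits(fit, "delayed_exp_fit"))
    graphics::lines(x$time, fit$fitted, col = "grey40", lwd = 2, lty = 2)
  if (inherits(fit, "sequential_fit")) {
    graphics::lines(x$time, fit$fitted$P_pipistar, col = "grey40", lwd = 2,
                    lty = 2)
    graphics::lines(x$time, fit$fitted$P_npistar, col = "grey40", lwd = 2,
                    lty = 3)
  }
  invisible(x)
}

#' Plot an absorption spectrum with per-state contributions
#'
#' @param x A `spectrum_result`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.spectrum_result <- function(x, ...) {
  graphics::plot(x$energy, x$total, type = "l", lwd = 2,
                 xlab = "energy (eV)", ylab = "intensity (arb.)", ...)
  for (k in seq_len(ncol(x$states)))
    graphics::lines(x$energy, x$states[, k], col = k + 1)
  graphics::legend("topright", legend = c("total", colnames(x$states)),
                   col = c(1, seq_len(ncol(x$states)) + 1), lty = 1, bty = "n")
  invisible(x)
}

#' Plot a dihedral density map
#'
#' @param x A `density_map`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.density_map <- function(x, ...) {
  graphics::image(x$time, x$angle, t(x$density), xlab = "time (fs)",
                  ylab = sprintf("%s (degrees)", x$coordinate),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE), ...)
  invisible(x)
}
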