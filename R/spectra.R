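#' Ensemble absorption spectrum from vertical excitations
#'
#' Gaussian-broadened, oscillator-strength-weighted sum over per-geometry
#' vertical excitations: for each state k,
#' `I_k(E) = (1/n_geom) * sum_i f_ik * G(E - E_ik; sigma)` with a normalized
#' Gaussian kernel, and the total spectrum is the per-state sum.
#'
#' @param excitations data.frame from [generate_vertical_excitations()]
#'   (columns `geometry`, `state`, `energy`, `f`).
#' @param sigma Gaussian kernel width in eV (default 0.1).
#' @param grid Energy grid in eV; default spans the data +/- 3 sigma in
#'   0.01 eV steps.
#' @return Object of class `spectrum_result`: list with `energy` (grid),
#'   `states` (matrix of per-state intensities), `total`, `sigma`.
#' @export
build_spectrum <- function(excitations, sigma = 0.1, grid = NULL) {
  if (!nrow(excitations)) stop("build_spectrum: empty excitation set")
  if (sigma <= 0) stop("build_spectrum: sigma must be > 0")
  n_geom <- attr(excitations, "n_geometries") %||%
    length(unique(excitations$geometry))
  if (is.null(grid))
    grid <- seq(min(excitations$energy) - 3 * sigma,
                max(excitations$energy) + 3 * sigma, by = 0.01)
  states <- sort(unique(excitations$state))
  I <- sapply(states, function(k) {
    rec <- excitations[excitations$state == k, ]
    colSums(rec$f * outer(rec$energy, grid,
                          function(e, g) stats::dnorm(g - e, sd = sigma))) / n_geom
  })
  colnames(I) <- paste0("S", states)
  structure(list(energy = grid, states = I, total = rowSums(I),
                 sigma = sigma, n_geometries = n_geom),
            class = "spectrum_result")
}

#' Band maxima (and shoulders) of a spectrum
#'
#' Locates the global maximum of each per-state intensity. Local maxima
#' exceeding `shoulder_frac` of the state's global peak are reported as
#' shoulders; a global maximum sitting on the grid boundary is flagged as
#' unreliable.
#'
#' @param spec A `spectrum_result`.
#' @param shoulder_frac Relative threshold for reporting secondary local
#'   maxima (default 0.2).
#' @return data.frame with one row per state: `state`, `peak_energy` (eV),
#'   `intensity`, `at_boundary`; attribute `"shoulders"` holds a data.frame
#'   of secondary maxima.
#' @export
find_band_maxima <- function(spec, shoulder_frac = 0.2) {
  if (all(spec$total == 0)) stop("find_band_maxima: flat zero spectrum")
  E <- spec$energy
  res <- list(); sh <- list()
  for (k in colnames(spec$states)) {
    y <- spec$states[, k]
    im <- which.max(y)
    res[[k]] <- data.frame(state = k, peak_energy = E[im], intensity = y[im],
                           at_boundary = im == 1 || im == length(y))
    loc <- which(diff(sign(diff(y))) == -2) + 1L
    loc <- setdiff(loc, im)
    loc <- loc[y[loc] > shoulder_frac * y[im]]
    if (length(loc))
      sh[[k]] <- data.frame(state = k, energy = E[loc], intensity = y[loc])
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "shoulders") <- if (length(sh)) do.call(rbind, sh) else
    data.frame(state = character(), energy = numeric(), intensity = numeric())
  out
}

#' Select excited-state initial conditions within an excitation window
#'
#' Dipole-weighted rejection sampling: every (geometry, state) vertical
#' excitation whose energy falls inside the window is accepted with
#' probability `f / f_max(window)`, so selection counts are proportional to
#' the oscillator strength. A geometry may yield zero or multiple
#' assignments.
#'
#' @param excitations data.frame of vertical excitations.
#' @param window Numeric `c(e_min, e_max)` in eV (e_min < e_max).
#' @param seed Integer RNG seed.
#' @return data.frame with columns `geometry`, `state`, `energy`, `f` of
#'   the accepted assignments (possibly 0 rows, with a warning when the
#'   window contains no excitation).
#' @export
select_initial_conditions <- function(excitations, window, seed = 1) {
  if (length(window) != 2 || window[1] >= window[2])
    stop("select_initial_conditions: window must satisfy e_min < e_max")
  set.seed(seed)
  inw <- excitations[excitations$energy >= window[1] &
                       excitations$energy <= window[2], ]
  if (!nrow(inw)) {
    warning("select_initial_conditions: no excitation falls in the window")
    return(data.frame(geometry = integer(), state = integer(),
                      energy = numeric(), f = numeric()))
  }
  fmax <- max(inw$f)
  if (fmax <= 0) {
    warning("select_initial_conditions: all in-window oscillator strengths are zero")
    return(inw[0, ])
  }
  acc <- stats::runif(nrow(inw)) < inw$f / fmax
  out <- inw[acc, c("geometry", "state", "energy", "f")]
  rownames(out) <- NULL
  out
}
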