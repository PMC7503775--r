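#' Specify chromatographic peaks for the simulator
#'
#' Peaks are exponentially modified Gaussians (EMG): a Gaussian component
#' of standard deviation `width` (minutes) convolved with an exponential
#' tail of time constant `tau`; `tau = 0` gives a pure Gaussian. The
#' profile is parameterized so that its area equals
#' `amplitude * width * sqrt(2*pi)` for every `tau` - i.e. `amplitude` is
#' the height the peak would have without tailing, and scaling `amplitude`
#' scales the area proportionally.
#'
#' @param apex_rt Gaussian-component center, minutes.
#' @param width Gaussian standard deviation, minutes (> 0).
#' @param amplitude height-equivalent amplitude, AU (>= 0).
#' @param shape `"gaussian"` or `"emg"`.
#' @param tau exponential tail constant, minutes (>= 0; ignored for
#'   `shape = "gaussian"`).
#' @return `data.frame` with one row per peak.
#' @export
peak_spec <- function(apex_rt, width, amplitude,
                      shape = "gaussian", tau = 0) {
  if (length(apex_rt) == 0) {
    return(data.frame(apex_rt = numeric(0), width = numeric(0),
                      amplitude = numeric(0), shape = character(0),
                      tau = numeric(0), stringsAsFactors = FALSE))
  }
  d <- data.frame(apex_rt = apex_rt, width = width, amplitude = amplitude,
                  shape = shape, tau = tau, stringsAsFactors = FALSE)
  if (any(d$width <= 0)) stop("'width' must be positive")
  if (any(d$amplitude < 0)) stop("'amplitude' must be non-negative")
  if (any(d$tau < 0)) stop("'tau' must be non-negative")
  if (any(!d$shape %in% c("gaussian", "emg"))) {
    stop("'shape' must be 'gaussian' or 'emg'")
  }
  d
}

# EMG profile evaluated in log space for numerical stability; tau ~ 0
# degenerates to the Gaussian.
peak_profile <- function(t, apex_rt, width, amplitude,
                         shape = "gaussian", tau = 0) {
  if (shape == "gaussian" || tau <= width * 1e-8) {
    return(amplitude * exp(-0.5 * ((t - apex_rt) / width)^2))
  }
  area <- amplitude * width * sqrt(2 * pi)
  k <- width / tau
  logd <- -log(tau) + k^2 / 2 - (t - apex_rt) / tau +
    stats::pnorm((t - apex_rt) / width - k, log.p = TRUE)
  area * exp(logd)
}

#' Create a smooth random retention-time warp
#'
#' Piecewise-linear monotone warp: `n_nodes` interior nodes evenly spaced
#' across `rt_range` are displaced by independent uniform(-magnitude,
#' +magnitude) draws; the endpoints are fixed. The returned function maps
#' observed retention time to latent (true) retention time, so peaks
#' planted at latent positions appear shifted by up to `magnitude`
#' minutes. Monotonicity is guaranteed by requiring `magnitude` to be less
#' than half the node spacing.
#'
#' @param rt_range length-2 numeric, grid endpoints in minutes.
#' @param magnitude maximal node displacement, minutes (>= 0).
#' @param n_nodes number of interior nodes.
#' @param seed optional integer seed.
#' @return monotone function mapping minutes to minutes, with a
#'   `"nodes"` attribute (`data.frame` of node positions/displacements).
#' @export
make_warp <- function(rt_range, magnitude, n_nodes = 6, seed = NULL) {
  stopifnot(length(rt_range) == 2, rt_range[2] > rt_range[1], magnitude >= 0)
  nodes <- seq(rt_range[1], rt_range[2], length.out = n_nodes + 2)
  spacing <- diff(nodes[1:2])
  if (magnitude >= spacing / 2) {
    stop("'magnitude' must be below half the warp node spacing (",
         format(spacing / 2), " min) to keep the warp monotone")
  }
  if (!is.null(seed)) set.seed(seed)
  disp <- c(0, stats::runif(n_nodes, -magnitude, magnitude), 0)
  f <- stats::approxfun(nodes, nodes + disp, rule = 2)
  attr(f, "nodes") <- data.frame(position = nodes, displacement = disp)
  f
}

#' Simulate one UPLC-PDA chromatogram
#'
#' Intensity is the sum of the peak profiles evaluated at the warped
#' retention time, plus a polynomial baseline, plus iid Gaussian noise.
#'
#' @param grid strictly increasing retention-time grid, minutes.
#' @param peaks `data.frame` from [peak_spec()] (zero rows allowed).
#' @param baseline_coeffs polynomial baseline coefficients, lowest order
#'   first (default: no baseline).
#' @param warp monotone warp function (observed -> latent minutes) fixing
#'   the grid endpoints, or `NULL` for the identity.
#' @param noise_sd standard deviation of additive Gaussian noise, AU.
#' @param seed optional integer seed.
#' @param wavelength detection wavelength tag, nm.
#' @param sample_id sample identifier tag.
#' @param sample_mass extracted sample mass tag, mg.
#' @return object of class `chromatogram`: list with `rt`, `intensity`,
#'   `wavelength`, `sample_id`, `sample_mass`.
#' @export
simulate_chromatogram <- function(grid, peaks = peak_spec(numeric(0),
                                                          numeric(0),
                                                          numeric(0)),
                                  baseline_coeffs = 0, warp = NULL,
                                  noise_sd = 0, seed = NULL,
                                  wavelength = 280, sample_id = "S0001",
                                  sample_mass = 100) {
  if (any(diff(grid) <= 0)) stop("'grid' must be strictly increasing")
  t_eval <- if (is.null(warp)) grid else warp(grid)
  if (any(diff(t_eval) <= 0)) stop("warp must be strictly monotone on the grid")
  if (!is.null(seed)) set.seed(seed)

  intensity <- numeric(length(grid))
  if (nrow(peaks) > 0) {
    for (i in seq_len(nrow(peaks))) {
      intensity <- intensity + peak_profile(
        t_eval, peaks$apex_rt[i], peaks$width[i], peaks$amplitude[i],
        peaks$shape[i], peaks$tau[i])
    }
  }
  if (any(baseline_coeffs != 0)) {
    for (j in seq_along(baseline_coeffs)) {
      intensity <- intensity + baseline_coeffs[j] * grid^(j - 1)
    }
  }
  if (noise_sd > 0) {
    intensity <- intensity + stats::rnorm(length(grid), sd = noise_sd)
  }
  if (any(!is.finite(intensity))) stop("non-finite intensities produced")
  structure(list(rt = grid, intensity = intensity, wavelength = wavelength,
                 sample_id = sample_id, sample_mass = sample_mass),
            class = "chromatogram")
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf("chromatogram %s @ %g nm: %d points, rt %.2f-%.2f min, mass %.1f mg\n",
              x$sample_id, x$wavelength, length(x$rt),
              min(x$rt), max(x$rt), x$sample_mass))
  invisible(x)
}
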