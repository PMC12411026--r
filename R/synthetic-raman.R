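#' Configuration for the synthetic Raman spectrum generator
#'
#' A tissue Raman spectrum is emulated as a broad, smooth autofluorescence
#' background (natural cubic spline through control points) plus Gaussian
#' Raman bands, Gaussian detector noise, and a Poisson number of
#' single-channel cosmic-ray spikes.
#'
#' Defaults follow the fingerprint-region contrast between benign nevi (BN)
#' and malignant melanoma (MM): carotenoid bands (~1008, 1158, 1525 cm-1)
#' stronger in MM, CH2-CH3 deformation (~1450 cm-1) and amide-I (~1655 cm-1)
#' stronger in BN, and an overall brighter autofluorescence background in MM.
#' Band amplitudes are free parameters, not literature values.
#'
#' @param group `"BN"` or `"MM"`; selects default band amplitudes and
#'   background.
#' @param wavenumbers strictly increasing Raman-shift grid, 1/cm.
#' @param band_centers,band_amplitudes,band_widths Gaussian band parameters
#'   (centers and widths in 1/cm, amplitudes in counts; widths are Gaussian
#'   sigmas).
#' @param background_control_points 2-column matrix `(wavenumber, counts)`
#'   through which the autofluorescence spline passes.
#' @param noise_sd additive Gaussian noise SD, counts.
#' @param cosmic_ray_rate expected number of spikes per spectrum.
#' @param cosmic_ray_amplitude nominal spike height, counts.
#' @param seed integer RNG seed.
#' @return an object of class `raman_sim_config`.
#' @export
raman_sim_config <- function(group = c("BN", "MM"),
                             wavenumbers = seq(800, 1800, by = 1),
                             band_centers = c(1008, 1158, 1450, 1525, 1655),
                             band_amplitudes = NULL,
                             band_widths = c(6, 7, 9, 8, 11),
                             background_control_points = NULL,
                             noise_sd = 8,
                             cosmic_ray_rate = 0.3,
                             cosmic_ray_amplitude = 3000,
                             seed = 1L) {
  group <- match.arg(group)
  if (is.null(band_amplitudes))
    band_amplitudes <- if (group == "MM") c(330, 300, 210, 290, 240)
                       else                c(190, 170, 340, 150, 390)
  if (is.null(background_control_points)) {
    background_control_points <- if (group == "MM") {
      cbind(c(800, 1000, 1300, 1550, 1800), c(2400, 2000, 1500, 1150, 950))
    } else {
      cbind(c(800, 1000, 1300, 1550, 1800), c(1800, 1500, 1150, 950, 800))
    }
  }
  cfg <- structure(list(
    group = group, wavenumbers = as.numeric(wavenumbers),
    band_centers = band_centers, band_amplitudes = band_amplitudes,
    band_widths = band_widths,
    background_control_points = background_control_points,
    noise_sd = noise_sd, cosmic_ray_rate = cosmic_ray_rate,
    cosmic_ray_amplitude = cosmic_ray_amplitude, seed = as.integer(seed)
  ), class = "raman_sim_config")
  validate_raman_sim_config(cfg)
  cfg
}

validate_raman_sim_config <- function(cfg) {
  if (!inherits(cfg, "raman_sim_config")) stop_config("not a raman_sim_config")
  if (any(diff(cfg$wavenumbers) <= 0))
    stop_config("wavenumber grid must be strictly increasing")
  nb <- length(cfg$band_centers)
  if (length(cfg$band_amplitudes) != nb || length(cfg$band_widths) != nb)
    stop_config("band parameter lengths differ")
  if (nb > 0 && any(cfg$band_widths <= 0)) stop_config("band widths must be > 0")
  if (cfg$noise_sd < 0 || cfg$cosmic_ray_rate < 0)
    stop_config("noise_sd and cosmic_ray_rate must be >= 0")
  if (nrow(cfg$background_control_points) < 2L)
    stop_config("need >= 2 background control points")
  invisible(cfg)
}

#' Construct a Raman spectrum object
#'
#' @param wavenumbers strictly increasing axis, 1/cm.
#' @param intensities counts (or normalized units downstream).
#' @param processing_log character vector of applied steps.
#' @return an object of class `raman_spectrum`.
#' @export
raman_spectrum <- function(wavenumbers, intensities,
                           processing_log = character()) {
  if (length(wavenumbers) != length(intensities))
    stop_config("axis and intensity lengths differ")
  if (any(diff(wavenumbers) <= 0))
    stop_config("wavenumber axis must be strictly increasing")
  structure(list(wavenumbers = as.numeric(wavenumbers),
                 intensities = as.numeric(intensities),
                 processing_log = processing_log),
            class = "raman_spectrum")
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("<raman_spectrum> %d channels, %.0f-%.0f cm-1\n",
              length(x$wavenumbers), min(x$wavenumbers), max(x$wavenumbers)))
  if (length(x$processing_log))
    cat("  processing:", paste(x$processing_log, collapse = " -> "), "\n")
  invisible(x)
}

#' Generate one synthetic Raman spectrum with ground truth
#'
#' @param cfg a [raman_sim_config()].
#' @param group `"BN"` or `"MM"` (defaults to the config's group; changing it
#'   here only relabels — amplitudes come from `cfg`).
#' @return a `raman_spectrum` with attributes `group`, `true_background`,
#'   `true_bands` (noise-free band sum), and `spike_channels`.
#' @export
generate_raman_spectrum <- function(cfg, group = cfg$group) {
  validate_raman_sim_config(cfg)
  w <- cfg$wavenumbers
  bg_fun <- splinefun(cfg$background_control_points[, 1],
                      cfg$background_control_points[, 2], method = "natural")
  background <- bg_fun(w)
  bands <- rep(0, length(w))
  for (i in seq_along(cfg$band_centers)) {
    bands <- bands + cfg$band_amplitudes[i] *
      exp(-0.5 * ((w - cfg$band_centers[i]) / cfg$band_widths[i])^2)
  }
  set.seed(cfg$seed)
  y <- background + bands
  if (cfg$noise_sd > 0) y <- y + rnorm(length(w), 0, cfg$noise_sd)
  spike_channels <- integer(0)
  if (cfg$cosmic_ray_rate > 0) {
    n_spikes <- rpois(1, cfg$cosmic_ray_rate)
    if (n_spikes > 0) {
      spike_channels <- sort(sample(length(w), min(n_spikes, length(w))))
      y[spike_channels] <- y[spike_channels] +
        cfg$cosmic_ray_amplitude * runif(length(spike_channels), 0.5, 1.5)
    }
  }
  out <- raman_spectrum(w, y, processing_log = "simulated")
  attr(out, "group") <- match.arg(group, c("BN", "MM"))
  attr(out, "true_background") <- background
  attr(out, "true_bands") <- bands
  attr(out, "spike_channels") <- spike_channels
  out
}
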