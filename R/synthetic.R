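#' Band specification for synthetic Raman signal models
#'
#' Describes one vibrational band as a pseudo-Voigt line: a mixture of a
#' Gaussian and a Lorentzian of common centre and full width at half maximum.
#' `mix = 1` gives a pure Lorentzian, `mix = 0` a pure Gaussian.
#'
#' @param center Band centre (cm^-1).
#' @param fwhm Full width at half maximum (cm^-1), > 0.
#' @param amplitude Peak amplitude (arbitrary units, >= 0).
#' @param mix Lorentzian fraction in [0, 1]. Default 0.5.
#' @return A `"band_spec"` list.
#' @export
band_spec <- function(center, fwhm, amplitude, mix = 0.5) {
  if (fwhm <= 0) stop("fwhm must be > 0", call. = FALSE)
  if (amplitude < 0) stop("amplitude must be >= 0", call. = FALSE)
  if (mix < 0 || mix > 1) stop("mix must be in [0, 1]", call. = FALSE)
  structure(list(center = center, fwhm = fwhm, amplitude = amplitude,
                 mix = mix), class = "band_spec")
}

# unit-height pseudo-Voigt profile evaluated on an axis
pseudo_voigt <- function(axis, center, fwhm, mix = 0.5) {
  u <- (axis - center) / fwhm
  g <- exp(-4 * log(2) * u^2)
  l <- 1 / (1 + 4 * u^2)
  mix * l + (1 - mix) * g
}

#' Evaluate a list of band specifications on a wavenumber axis
#'
#' Sums the amplitude-scaled pseudo-Voigt profiles; construction is linear
#' in the band amplitudes and nonnegative by design.
#'
#' @param axis Wavenumber grid (cm^-1).
#' @param bands List of [band_spec()] objects.
#' @return Intensity vector, one value per axis point.
#' @export
eval_bands <- function(axis, bands) {
  out <- numeric(length(axis))
  for (b in bands)
    out <- out + b$amplitude * pseudo_voigt(axis, b$center, b$fwhm, b$mix)
  out
}

#' Synthetic brain-lipid component library
#'
#' Builds reference spectra for the four components whose contributions the
#' decomposition stage quantifies: cardiolipin, cytochrome C, ganglioside and
#' cholesterol. Band positions follow the C-H stretching assignments (CH2
#' symmetric ~2850, CH3/CH asymmetric ~2930, CH3 symmetric ~2880, asymmetric
#' ~2955 cm^-1) and the fingerprint markers at 1266, 1452 and 1660 cm^-1;
#' cardiolipin concentrates amplitude at 2850 relative to 2930, while
#' cytochrome C carries the strong 1660 cm^-1 band. These are synthetic
#' stand-ins for measured reference spectra, intended for simulation and for
#' exercising the NNLS decomposition; real component spectra can be loaded
#' with [read_spectra()] and passed to [component_library()].
#'
#' @param axis Wavenumber grid (cm^-1), strictly increasing and nonempty.
#' @return A `"component_library"`: list with `grid`, `matrix` (one column
#'   per component), `names`, and the generating `bands`.
#' @export
make_component_library <- function(axis) {
  axis <- as.numeric(axis)
  if (length(axis) < 2L || any(diff(axis) <= 0))
    stop("axis must be strictly increasing with >= 2 points", call. = FALSE)
  fp <- 25; hw <- 45  # typical condensed-phase FWHMs (cm^-1)
  bands <- list(
    cardiolipin = list(
      band_spec(1266, fp, 0.40), band_spec(1452, fp, 0.60),
      band_spec(2850, hw, 1.00), band_spec(2880, hw, 0.45),
      band_spec(2930, hw, 0.25)),
    cytochrome_c = list(
      band_spec(1266, fp, 0.30), band_spec(1585, fp, 0.50),
      band_spec(1660, fp, 1.00), band_spec(2930, hw, 0.60)),
    ganglioside = list(
      band_spec(1452, fp, 0.40), band_spec(2850, hw, 0.50),
      band_spec(2880, hw, 0.50), band_spec(2930, hw, 0.70),
      band_spec(2955, hw, 0.30)),
    cholesterol = list(
      band_spec(1452, fp, 0.70), band_spec(1660, fp, 0.20),
      band_spec(2850, hw, 0.60), band_spec(2880, hw, 0.80),
      band_spec(2930, hw, 0.40), band_spec(2955, hw, 0.35)))
  mat <- vapply(bands, function(b) eval_bands(axis, b), numeric(length(axis)))
  component_library(axis, mat, bands = bands)
}

#' Assemble a component library from spectra on a shared grid
#'
#' @param grid Shared wavenumber grid (cm^-1).
#' @param matrix Numeric matrix, one column per component.
#' @param bands Optional list of generating `band_spec` lists.
#' @return A `"component_library"`.
#' @export
component_library <- function(grid, matrix, bands = NULL) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != length(grid))
    stop("component matrix must have one row per grid point", call. = FALSE)
  if (is.null(colnames(matrix)))
    colnames(matrix) <- if (!is.null(names(bands))) names(bands) else
      paste0("component_", seq_len(ncol(matrix)))
  if (any(colSums(abs(matrix)) == 0))
    stop("component library contains an all-zero component", call. = FALSE)
  structure(list(grid = as.numeric(grid), matrix = matrix,
                 names = colnames(matrix), bands = bands),
            class = "component_library")
}

#' Cohort simulation configuration
#'
#' Defaults encode the porcine study conditions: 39 injured and 12 control
#' samples, 400 spectra per sample map, a 500-3500 cm^-1 axis, and group
#' 2930/2850 peak-ratio distributions with median/IQR 2.34/0.63 (TBI) and
#' 0.48/0.12 (control).
#'
#' @param n_tbi_samples,n_control_samples Samples per group.
#' @param spectra_per_sample Spectra recorded per sample map.
#' @param axis_start,axis_stop,axis_step Wavenumber grid (cm^-1).
#' @param ratio_median_tbi,ratio_iqr_tbi Median and interquartile range of
#'   the true per-sample 2930/2850 ratio in the TBI group.
#' @param ratio_median_control,ratio_iqr_control Same for controls.
#' @param baseline_amplitude Amplitude of the broad fluorescence baseline
#'   (a.u.; the 2850 reference band has height `peak_height`).
#' @param noise_sd Standard deviation of additive Gaussian channel noise.
#' @param cosmic_ray_rate Expected cosmic-ray spikes per spectrum (Poisson).
#' @param peak_height Height of the 2850 cm^-1 band (a.u.), the ratio's
#'   denominator anchor.
#' @param amp_jitter_sd Per-spectrum multiplicative (log-normal) jitter of
#'   band amplitudes and of the realized ratio.
#' @param band_fwhm_fingerprint,band_fwhm_highwave Band widths (cm^-1).
#' @param seed RNG seed (NULL: consume the session RNG).
#' @return A validated `"cohort_config"` list.
#' @export
cohort_config <- function(n_tbi_samples = 39, n_control_samples = 12,
                          spectra_per_sample = 400,
                          axis_start = 500, axis_stop = 3500, axis_step = 1,
                          ratio_median_tbi = 2.34, ratio_iqr_tbi = 0.63,
                          ratio_median_control = 0.48,
                          ratio_iqr_control = 0.12,
                          baseline_amplitude = 0.6, noise_sd = 0.02,
                          cosmic_ray_rate = 0.1, peak_height = 1,
                          amp_jitter_sd = 0.05,
                          band_fwhm_fingerprint = 25,
                          band_fwhm_highwave = 45, seed = NULL) {
  cfg <- list(n_tbi_samples = n_tbi_samples,
              n_control_samples = n_control_samples,
              spectra_per_sample = spectra_per_sample,
              axis_start = axis_start, axis_stop = axis_stop,
              axis_step = axis_step,
              ratio_median_tbi = ratio_median_tbi,
              ratio_iqr_tbi = ratio_iqr_tbi,
              ratio_median_control = ratio_median_control,
              ratio_iqr_control = ratio_iqr_control,
              baseline_amplitude = baseline_amplitude, noise_sd = noise_sd,
              cosmic_ray_rate = cosmic_ray_rate, peak_height = peak_height,
              amp_jitter_sd = amp_jitter_sd,
              band_fwhm_fingerprint = band_fwhm_fingerprint,
              band_fwhm_highwave = band_fwhm_highwave, seed = seed)
  with(cfg, {
    if (n_tbi_samples < 1 || n_control_samples < 1 || spectra_per_sample < 1)
      stop("all counts must be >= 1", call. = FALSE)
    if (axis_step <= 0 || axis_stop <= axis_start)
      stop("axis must be strictly increasing", call. = FALSE)
    if (axis_start > 1266 || axis_stop < 2955)
      stop("axis must cover the signal bands (1266-2955 cm^-1)",
           call. = FALSE)
    if (ratio_median_tbi <= 0 || ratio_median_control <= 0)
      stop("ratio medians must be > 0", call. = FALSE)
    if (ratio_iqr_tbi <= 0 || ratio_iqr_control <= 0)
      stop("ratio IQRs must be > 0", call. = FALSE)
    if (noise_sd < 0 || cosmic_ray_rate < 0 || baseline_amplitude < 0)
      stop("noise_sd, cosmic_ray_rate, baseline_amplitude must be >= 0",
           call. = FALSE)
  })
  structure(cfg, class = "cohort_config")
}

#' Log-normal parameters from a median and interquartile range
#'
#' For X ~ LogNormal(mu, sigma): median = exp(mu) and
#' IQR = 2 median sinh(sigma z) with z = qnorm(0.75), so
#' mu = log(median), sigma = asinh(IQR / (2 median)) / z — an exact
#' inversion of the two printed summary statistics.
#'
#' @param median Target median (> 0).
#' @param iqr Target interquartile range (> 0).
#' @return List with `mu` and `sigma`.
#' @export
lognormal_params <- function(median, iqr) {
  if (!is.finite(median) || !is.finite(iqr) || median <= 0 || iqr <= 0)
    stop("log-normal calibration failed: median and IQR must be finite ",
         "and > 0 (got median=", median, ", IQR=", iqr, ")", call. = FALSE)
  list(mu = log(median), sigma = asinh(iqr / (2 * median)) / qnorm(0.75))
}

# fixed "other band" table of the signal model (amplitudes relative to
# peak_height; 2850/2930 amplitudes are solved per spectrum)
signal_bands <- function(cfg) {
  data.frame(center = c(1266, 1452, 1660, 2880, 2955),
             amp = c(0.35, 0.50, 0.60, 0.30, 0.25),
             fwhm = c(rep(cfg$band_fwhm_fingerprint, 3),
                      rep(cfg$band_fwhm_highwave, 2)))
}

# broad fluorescence background: main band centred in the fingerprint region,
# declining toward high wavenumber
fluorescence_baseline <- function(axis, amplitude) {
  amplitude * (exp(-((axis - 900) / 800)^2) + 0.15)
}

# precompute everything per-spectrum simulation reuses
signal_basis <- function(cfg) {
  axis <- seq(cfg$axis_start, cfg$axis_stop, by = cfg$axis_step)
  sb <- signal_bands(cfg)
  other <- vapply(seq_len(nrow(sb)), function(i)
    pseudo_voigt(axis, sb$center[i], sb$fwhm[i]), numeric(length(axis)))
  b2850 <- pseudo_voigt(axis, 2850, cfg$band_fwhm_highwave)
  b2930 <- pseudo_voigt(axis, 2930, cfg$band_fwhm_highwave)
  i2850 <- which.min(abs(axis - 2850)); i2930 <- which.min(abs(axis - 2930))
  # 2x2 cross-talk of the two ratio bands at each other's centres
  M <- rbind(c(b2850[i2850], b2930[i2850]),
             c(b2850[i2930], b2930[i2930]))
  list(axis = axis, other = other, other_amp = sb$amp,
       b2850 = b2850, b2930 = b2930, i2850 = i2850, i2930 = i2930,
       M = M, baseline = fluorescence_baseline(axis, cfg$baseline_amplitude))
}

# simulate one spectrum on a precomputed basis; returns intensity + truth
simulate_on_basis <- function(cfg, basis, sample_ratio) {
  n <- length(basis$axis)
  jitter <- exp(rnorm(length(basis$other_amp) + 1, 0, cfg$amp_jitter_sd))
  amps <- basis$other_amp * jitter[-1] * cfg$peak_height
  r <- sample_ratio * jitter[1]
  signal <- drop(basis$other %*% amps)
  # solve the 2850/2930 amplitudes so the summed signal hits the target peak
  # heights (peak_height, peak_height * r) at the two band centres
  tgt <- c(cfg$peak_height - signal[basis$i2850],
           cfg$peak_height * r - signal[basis$i2930])
  a <- solve(basis$M, tgt)
  a <- pmax(a, 0)
  signal <- signal + a[1] * basis$b2850 + a[2] * basis$b2930
  y <- signal + basis$baseline + rnorm(n, 0, cfg$noise_sd)
  n_spikes <- rpois(1, cfg$cosmic_ray_rate)
  spike_channels <- integer(0)
  spike_id <- integer(0)
  if (n_spikes > 0) {
    for (k in seq_len(n_spikes)) {
      ch <- sample.int(n, 1)
      width <- sample.int(3, 1)
      factor <- runif(1, 5, 50)
      idx <- ch:min(ch + width - 1L, n)
      y[idx] <- y[idx] + factor * max(signal[ch], 0.1 * cfg$peak_height)
      spike_channels <- c(spike_channels, idx)
      spike_id <- c(spike_id, rep(k, length(idx)))
    }
  }
  list(intensity = y, realized_ratio = r, spike_channels = spike_channels,
       spike_id = spike_id)
}

#' Simulate one synthetic retinal Raman spectrum
#'
#' The spectrum is a band mixture whose 2930 vs 2850 cm^-1 peak amplitudes
#' realize `sample_ratio` (up to the configured per-spectrum jitter), plus a
#' broad fluorescence baseline, additive Gaussian noise and Poisson-counted
#' cosmic-ray spikes.
#'
#' @param config A [cohort_config()].
#' @param sample_ratio True 2930/2850 peak ratio (> 0).
#' @param seed Optional RNG seed; NULL consumes the session RNG.
#' @return A `"raman_spectrum"` whose `meta` carries `true_ratio` (jittered,
#'   as realized) and `spike_channels` (injected cosmic-ray channel indices).
#' @export
simulate_spectrum <- function(config, sample_ratio, seed = NULL) {
  if (!is.finite(sample_ratio) || sample_ratio <= 0)
    stop("sample_ratio must be > 0", call. = FALSE)
  basis <- signal_basis(config)
  sim <- with_seed(seed, simulate_on_basis(config, basis, sample_ratio))
  raman_spectrum(basis$axis, sim$intensity,
                 meta = list(true_ratio = sim$realized_ratio,
                             spike_channels = sim$spike_channels))
}

#' Simulate labeled TBI and control cohorts
#'
#' Per-sample true 2930/2850 ratios are drawn from group-wise log-normal
#' distributions calibrated to the configured medians and IQRs (see
#' [lognormal_params()]); each sample then contributes
#' `spectra_per_sample` spectra sharing its true ratio up to per-spectrum
#' jitter. All injected artifacts are recorded as ground truth.
#'
#' @param config A [cohort_config()].
#' @return A `"raman_cohort"`: shared `wavenumber` axis, `intensities`
#'   matrix (one column per spectrum), `meta` data frame (`sample_id`,
#'   `class`), and `truth` with per-sample true ratios and the cosmic-ray
#'   table (`spectrum`, `spike`, `channel`: one row per affected channel).
#' @export
simulate_cohorts <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    basis <- signal_basis(config)
    p_tbi <- lognormal_params(config$ratio_median_tbi, config$ratio_iqr_tbi)
    p_ctl <- lognormal_params(config$ratio_median_control,
                              config$ratio_iqr_control)
    n_t <- config$n_tbi_samples; n_c <- config$n_control_samples
    per <- config$spectra_per_sample
    ratios <- c(rlnorm(n_t, p_tbi$mu, p_tbi$sigma),
                rlnorm(n_c, p_ctl$mu, p_ctl$sigma))
    classes <- c(rep("TBI", n_t), rep("control", n_c))
    ids <- c(sprintf("TBI_%02d", seq_len(n_t)),
             sprintf("CTL_%02d", seq_len(n_c)))
    n_total <- (n_t + n_c) * per
    intens <- matrix(0, length(basis$axis), n_total)
    spikes <- vector("list", n_total)
    col <- 0L
    for (s in seq_along(ratios)) {
      for (j in seq_len(per)) {
        col <- col + 1L
        sim <- simulate_on_basis(config, basis, ratios[s])
        intens[, col] <- sim$intensity
        if (length(sim$spike_channels))
          spikes[[col]] <- data.frame(spectrum = col,
                                      spike = sim$spike_id,
                                      channel = sim$spike_channels)
      }
    }
    meta <- data.frame(sample_id = rep(ids, each = per),
                       class = rep(classes, each = per),
                       stringsAsFactors = FALSE)
    truth <- list(
      samples = data.frame(sample_id = ids, class = classes,
                           true_ratio = ratios, stringsAsFactors = FALSE),
      cosmic_rays = do.call(rbind, c(spikes[!vapply(spikes, is.null,
                                                    logical(1))],
                                     make.row.names = FALSE)))
    if (is.null(truth$cosmic_rays))
      truth$cosmic_rays <- data.frame(spectrum = integer(0),
                                      spike = integer(0),
                                      channel = integer(0))
    structure(list(wavenumber = basis$axis, intensities = intens,
                   meta = meta, truth = truth, config = config),
              class = c("raman_cohort", "spectral_map"))
  })
}

#' Extract one sample's spectra as a spectral map
#'
#' @param cohort A `"raman_cohort"` from [simulate_cohorts()].
#' @param sample_id Sample identifier.
#' @return A `"spectral_map"` of that sample's spectra.
#' @export
cohort_sample_map <- function(cohort, sample_id) {
  idx <- which(cohort$meta$sample_id == sample_id)
  if (!length(idx)) stop("unknown sample_id: ", sample_id, call. = FALSE)
  spectral_map(cohort$wavenumber, cohort$intensities[, idx, drop = FALSE],
               meta = cohort$meta[idx, , drop = FALSE])
}
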