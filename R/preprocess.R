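#' Baseline correction configuration
#'
#' @param method `"spline"` (iterative knot placement at local minima, the
#'   in-package reading of the instrument's proprietary "intelligent spline")
#'   or `"modified_poly"` (iteratively reweighted polynomial with
#'   peak-region exclusion).
#' @param n_nodes Spline knot count (>= 4). Default 11.
#' @param poly_order Polynomial order (>= 1). Default 9.
#' @param noise_tolerance Residual-sd multiplier above which points are
#'   treated as peak regions and excluded. Default 1.50.
#' @param max_iterations Iteration cap.
#' @param convergence_tol Relative baseline change declaring convergence.
#' @return A `"baseline_config"` list.
#' @export
baseline_config <- function(method = c("spline", "modified_poly"),
                            n_nodes = 11, poly_order = 9,
                            noise_tolerance = 1.50, max_iterations = 50,
                            convergence_tol = 1e-4) {
  method <- match.arg(method)
  if (n_nodes < 4) stop("n_nodes must be >= 4", call. = FALSE)
  if (poly_order < 1) stop("poly_order must be >= 1", call. = FALSE)
  if (noise_tolerance <= 0) stop("noise_tolerance must be > 0", call. = FALSE)
  structure(list(method = method, n_nodes = n_nodes,
                 poly_order = poly_order,
                 noise_tolerance = noise_tolerance,
                 max_iterations = max_iterations,
                 convergence_tol = convergence_tol),
            class = "baseline_config")
}

#' Remove cosmic-ray spikes from a spectral map
#'
#' Nearest-neighbour despiking: each spectrum is compared channel-wise with
#' the median of its `k` nearest neighbours in the map (spatially nearest
#' when `x`/`y` positions are present in `meta`, adjacent acquisition order
#' otherwise). Channels exceeding the neighbour median by more than
#' `z_threshold` robust standard deviations (MAD) are replaced by it; all
#' other channels are left bit-identical. Only positive excursions are
#' flagged — cosmic rays are additive — so a clean spectrum is never
#' corrupted by a spiked neighbour. Spikes are narrow, high-amplitude and
#' uncorrelated between map positions, which is what makes the neighbour
#' comparison safe.
#'
#' @param map A `"spectral_map"` with >= 2 spectra.
#' @param z_threshold Robust z-score flag threshold. Default 8.
#' @param k Number of neighbour spectra. Default 2.
#' @return The despiked map; attribute `"flagged"` holds a data frame of
#'   replaced (spectrum, channel) pairs.
#' @export
remove_cosmic_rays <- function(map, z_threshold = 8, k = 2) {
  stopifnot(inherits(map, "spectral_map"))
  m <- n_spectra(map)
  if (m < 2L)
    stop("map has a single spectrum: no neighbours to compare against; ",
         "use despike_spectrum() (within-spectrum median filter) instead",
         call. = FALSE)
  k <- min(k, m - 1L)
  has_pos <- all(c("x", "y") %in% names(map$meta))
  out <- map$intensities
  flagged <- list()
  for (i in seq_len(m)) {
    if (has_pos) {
      d <- (map$meta$x - map$meta$x[i])^2 + (map$meta$y - map$meta$y[i])^2
      d[i] <- Inf
      nb <- order(d)[seq_len(k)]
    } else {
      nb <- setdiff(order(abs(seq_len(m) - i)), i)[seq_len(k)]
    }
    ref <- apply(map$intensities[, nb, drop = FALSE], 1, median)
    dev <- map$intensities[, i] - ref
    rsd <- mad(dev)
    if (rsd == 0) rsd <- .Machine$double.eps * max(1, max(abs(ref)))
    hit <- which(dev > z_threshold * rsd)
    if (length(hit)) {
      out[hit, i] <- ref[hit]
      flagged[[length(flagged) + 1L]] <-
        data.frame(spectrum = i, channel = hit)
    }
  }
  res <- spectral_map(map$wavenumber, out, map$meta)
  attr(res, "flagged") <- if (length(flagged))
    do.call(rbind, c(flagged, make.row.names = FALSE)) else
    data.frame(spectrum = integer(0), channel = integer(0))
  res
}

#' Within-spectrum cosmic-ray fallback (running-median filter)
#'
#' For isolated spectra with no map neighbours: channels deviating from a
#' running median by more than `z_threshold` robust standard deviations are
#' replaced by the median value.
#'
#' @param spectrum A `"raman_spectrum"`.
#' @param z_threshold Robust z-score flag threshold.
#' @param window Odd running-median window width (channels); the default 5
#'   targets 1-2-channel spikes while passing narrow Raman bands through.
#' @return The despiked spectrum.
#' @export
despike_spectrum <- function(spectrum, z_threshold = 8, window = 5) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  med <- stats::runmed(spectrum$intensity, window)
  dev <- spectrum$intensity - med
  # floor the scale at 1% of the filtered maximum: band curvature on a
  # noiseless spectrum must not read as a spike
  rsd <- max(mad(dev), 0.01 * max(abs(med)), .Machine$double.xmin)
  hit <- dev > z_threshold * rsd
  y <- spectrum$intensity
  y[hit] <- med[hit]
  raman_spectrum(spectrum$wavenumber, y, spectrum$meta)
}

# iteratively reweighted polynomial baseline: points above
# fit + noise_tolerance * residual-sd are treated as peaks and clipped out
modpoly_baseline <- function(axis, y, cfg) {
  ax <- (axis - mean(axis)) / (diff(range(axis)) / 2)  # conditioning
  P <- cbind(1, stats::poly(ax, cfg$poly_order))
  qrP <- qr(P)
  ywork <- y
  base <- rep(mean(y), length(y))
  scale <- max(abs(y), 1e-300)
  converged <- FALSE
  for (it in seq_len(cfg$max_iterations)) {
    newbase <- qr.fitted(qrP, ywork)
    sdres <- sd(ywork - newbase)
    delta <- max(abs(newbase - base)) / scale
    base <- newbase
    if (delta < cfg$convergence_tol || sdres < 1e-12 * scale) {
      converged <- TRUE
      break
    }
    ywork <- pmin(ywork, base + cfg$noise_tolerance * sdres)
  }
  if (!converged)
    warning("baseline fit did not converge in ", cfg$max_iterations,
            " iterations; returning best iterate", call. = FALSE)
  base
}

# spline baseline: knots at local minima of a running-median-smoothed copy,
# one knot per axis segment, iterated so the spline hugs the background
spline_baseline <- function(axis, y, cfg) {
  n <- length(y)
  win <- max(3L, 2L * (n %/% 200L) + 1L)
  ywork <- y
  base <- rep(min(y), n)
  scale <- max(abs(y), 1e-300)
  edges <- seq(axis[1], axis[n], length.out = cfg$n_nodes + 1L)
  seg <- pmin(findInterval(axis, edges, rightmost.closed = TRUE),
              cfg$n_nodes)
  converged <- FALSE
  for (it in seq_len(cfg$max_iterations)) {
    sm <- stats::runmed(ywork, win)
    kx <- kv <- numeric(cfg$n_nodes)
    for (s in seq_len(cfg$n_nodes)) {
      idx <- which(seg == s)
      j <- idx[which.min(sm[idx])]
      kx[s] <- axis[j]; kv[s] <- sm[j]
    }
    newbase <- stats::spline(kx, kv, xout = axis, method = "natural")$y
    delta <- max(abs(newbase - base)) / scale
    base <- newbase
    if (delta < cfg$convergence_tol) {
      converged <- TRUE
      break
    }
    ywork <- pmin(ywork, base)
  }
  if (!converged)
    warning("baseline fit did not converge in ", cfg$max_iterations,
            " iterations; returning best iterate", call. = FALSE)
  base
}

#' Fit and subtract a fluorescence baseline
#'
#' Two variants: an iterative cubic-spline fit through knots placed at local
#' minima (default 11 nodes), and a modified-polynomial fit (default order
#' 9) that excludes peak regions above `fit + noise_tolerance * residual-sd`
#' on each iteration until the baseline stabilizes.
#'
#' @param spectrum A `"raman_spectrum"`.
#' @param config A [baseline_config()].
#' @return List with `corrected` (input minus baseline) and `baseline`
#'   (the fitted background), both `"raman_spectrum"` objects.
#' @export
subtract_baseline <- function(spectrum, config = baseline_config()) {
  stopifnot(inherits(spectrum, "raman_spectrum"),
            inherits(config, "baseline_config"))
  n <- length(spectrum$wavenumber)
  if (n <= max(config$poly_order + 2, config$n_nodes + 2))
    stop("spectrum too short (", n, " channels) for baseline fitting",
         call. = FALSE)
  base <- switch(config$method,
                 modified_poly = modpoly_baseline(spectrum$wavenumber,
                                                  spectrum$intensity, config),
                 spline = spline_baseline(spectrum$wavenumber,
                                          spectrum$intensity, config))
  list(corrected = raman_spectrum(spectrum$wavenumber,
                                  spectrum$intensity - base, spectrum$meta),
       baseline = raman_spectrum(spectrum$wavenumber, base, spectrum$meta))
}

#' Standard normal variate normalization
#'
#' Per-spectrum centring and scaling: `(x - mean(x)) / sd(x)`. Removes
#' multiplicative and additive intensity effects before classification.
#'
#' @param x A `"raman_spectrum"` or `"spectral_map"` (applied per spectrum).
#' @return Object of the same class, normalized.
#' @export
snv_normalize <- function(x) {
  if (inherits(x, "spectral_map") && !inherits(x, "raman_spectrum")) {
    mu <- colMeans(x$intensities)
    sdv <- apply(x$intensities, 2, sd)
    if (any(sdv == 0))
      stop("constant spectrum (sd = 0) at column(s) ",
           paste(which(sdv == 0), collapse = ", "), call. = FALSE)
    return(spectral_map(x$wavenumber,
                        scale(x$intensities, center = mu, scale = sdv),
                        x$meta))
  }
  stopifnot(inherits(x, "raman_spectrum"))
  sdv <- sd(x$intensity)
  if (sdv == 0)
    stop("constant spectrum (sd = 0)",
         if (!is.null(x$meta$sample_id)) paste0(": ", x$meta$sample_id),
         call. = FALSE)
  raman_spectrum(x$wavenumber, (x$intensity - mean(x$intensity)) / sdv,
                 x$meta)
}

#' Unit-area normalization
#'
#' Scales intensities so the trapezoidal integral over the wavenumber axis
#' (the spectrum's area under the curve) equals 1, putting spectra from
#' different instruments on a common scale.
#'
#' @param x A `"raman_spectrum"` or `"spectral_map"` (applied per spectrum).
#' @return Object of the same class, with unit integral per spectrum.
#' @export
area_normalize <- function(x) {
  if (inherits(x, "spectral_map") && !inherits(x, "raman_spectrum")) {
    ints <- apply(x$intensities, 2, trapz_integral,
                  wavenumber = x$wavenumber)
    if (any(ints <= 0))
      stop("nonpositive spectral area at column(s) ",
           paste(which(ints <= 0), collapse = ", "), call. = FALSE)
    return(spectral_map(x$wavenumber,
                        sweep(x$intensities, 2, ints, "/"), x$meta))
  }
  stopifnot(inherits(x, "raman_spectrum"))
  a <- trapz_integral(x$wavenumber, x$intensity)
  if (!is.finite(a) || a <= 0)
    stop("nonpositive spectral area: ", a, call. = FALSE)
  raman_spectrum(x$wavenumber, x$intensity / a, x$meta)
}

#' Resample onto the unit wavenumber grid
#'
#' Linear interpolation onto integer wavenumbers from `ceil(min)` to
#' `floor(max)` in 1 cm^-1 increments, never extrapolating beyond the input
#' support. Used to align spectra and component libraries before NNLS.
#'
#' @param x A `"raman_spectrum"` or `"spectral_map"`.
#' @return Same class on the integer grid.
#' @export
resample_unit_grid <- function(x) {
  w <- x$wavenumber
  if (diff(range(w)) < 2)
    stop("axis span < 2 cm^-1: cannot resample to unit grid", call. = FALSE)
  grid <- seq(ceiling(min(w)), floor(max(w)), by = 1)
  if (inherits(x, "spectral_map") && !inherits(x, "raman_spectrum")) {
    ints <- apply(x$intensities, 2, function(y)
      approx(w, y, xout = grid)$y)
    return(spectral_map(grid, ints, x$meta))
  }
  stopifnot(inherits(x, "raman_spectrum"))
  raman_spectrum(grid, approx(w, x$intensity, xout = grid)$y, x$meta)
}

#' Crop to a wavenumber region
#'
#' @param x A `"raman_spectrum"` or `"spectral_map"`.
#' @param lo,hi Region bounds (cm^-1), `lo < hi`; channels with
#'   `lo <= wavenumber <= hi` are kept in order.
#' @return Same class, cropped.
#' @export
crop_region <- function(x, lo, hi) {
  if (lo >= hi) stop("lo must be < hi", call. = FALSE)
  keep <- x$wavenumber >= lo & x$wavenumber <= hi
  if (sum(keep) < 2L)
    stop("crop [", lo, ", ", hi, "] leaves fewer than 2 channels",
         call. = FALSE)
  if (inherits(x, "spectral_map") && !inherits(x, "raman_spectrum"))
    return(spectral_map(x$wavenumber[keep],
                        x$intensities[keep, , drop = FALSE], x$meta))
  stopifnot(inherits(x, "raman_spectrum"))
  raman_spectrum(x$wavenumber[keep], x$intensity[keep], x$meta)
}
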